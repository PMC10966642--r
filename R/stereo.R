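# Chirality assignment at the alpha carbons, sequence checking, and
# reflection-based correction.
#
# Label convention: for the alpha carbon C2 with substituents O1, C3, C4,
# H5, the signed volume det[r_O1 - r_H5, r_C3 - r_H5, r_C4 - r_H5] is
# negative for an L monomer and positive for a D monomer.  The sign is fixed
# by the synthetic generator's canonical L monomer and is consistent with
# CIP rules for the fixed PLA substituent priority O1 > C3 > C4 > H5
# (L = S configuration), which cip_label() cross-checks.

.CHIRAL_L_SIGN <- -1
.CHIRAL_DET_TOL <- 1e-6  # nm^3; smaller magnitudes are 'undefined'

.chain_coords <- function(config, chain_index) {
  sys <- .as_system(config$topology)
  ch <- sys$chains[[chain_index]]
  list(chain = ch, coords = config$coords[
    sys$atom_offsets[chain_index] + seq_len(ch$n_atoms), , drop = FALSE])
}

.chiral_det <- function(coords, center_row) {
  h5 <- coords[center_row[["H5"]], ]
  det(cbind(coords[center_row[["O1"]], ] - h5,
            coords[center_row[["C3"]], ] - h5,
            coords[center_row[["C4"]], ] - h5))
}

#' Chirality label of one monomer
#'
#' Signed-volume test at the alpha carbon.  Near-planar arrangements
#' (|determinant| below 1e-6 nm^3) are reported as `"undefined"` rather than
#' silently assigned.
#'
#' @param config An [atomistic_config()].
#' @param monomer Global monomer index.
#' @return `"L"`, `"D"` or `"undefined"`.
#' @export
chirality_label <- function(config, monomer) {
  sys <- .as_system(config$topology)
  ci <- findInterval(monomer - 1L, sys$monomer_offsets)
  ch <- sys$chains[[ci]]
  local <- monomer - sys$monomer_offsets[ci]
  row <- ch$chiral_centers[local, ] + sys$atom_offsets[ci]
  if (anyNA(row)) stop("monomer ", monomer, " has no complete chiral center")
  d <- .chiral_det(config$coords, row)
  if (abs(d) < .CHIRAL_DET_TOL) return("undefined")
  if (sign(d) == .CHIRAL_L_SIGN) "L" else "D"
}

.all_labels <- function(config) {
  sys <- .as_system(config$topology)
  labels <- character(sys$total_monomers)
  for (ci in seq_len(sys$n_chains)) {
    ch <- sys$chains[[ci]]
    rows <- ch$chiral_centers + sys$atom_offsets[ci]
    for (m in seq_len(ch$n_monomers)) {
      d <- .chiral_det(config$coords, rows[m, ])
      labels[sys$monomer_offsets[ci] + m] <-
        if (abs(d) < .CHIRAL_DET_TOL) "undefined"
        else if (sign(d) == .CHIRAL_L_SIGN) "L" else "D"
    }
  }
  labels
}

#' Check the stereochemistry of a configuration against a requested sequence
#'
#' @param config An [atomistic_config()].
#' @param sequence Requested stereo labels over all monomers (character
#'   vector, concatenated over chains, or list of per-chain sequences).
#' @return List of class `"stereo_report"`: `labels`, `requested`,
#'   `mismatch_indices` (monomers whose label differs from the request;
#'   `"undefined"` counts as a mismatch), `n_mismatch`, `n_monomers`,
#'   `percent` (2 significant figures, over all monomers).
#' @export
check_sequence <- function(config, sequence) {
  if (is.list(sequence)) sequence <- unlist(sequence)
  sys <- .as_system(config$topology)
  if (length(sequence) != sys$total_monomers) {
    stop("requested sequence has ", length(sequence), " labels for ",
         sys$total_monomers, " monomers")
  }
  labels <- .all_labels(config)
  mism <- which(labels != sequence)
  structure(list(labels = labels, requested = as.character(sequence),
                 mismatch_indices = mism, n_mismatch = length(mism),
                 n_monomers = sys$total_monomers,
                 percent = signif(100 * length(mism) / sys$total_monomers, 2L)),
            class = "stereo_report")
}

#' @export
print.stereo_report <- function(x, ...) {
  cat("Stereochemistry report: ", x$n_mismatch, "/", format(x$percent),
      " (wrong monomers / % of ", x$n_monomers, ")\n", sep = "")
  invisible(x)
}

#' Format a stereo report in count/percent table style
#' @param report A [check_sequence()] report.
#' @return A string `"count/percent"` with the percent at 2 significant
#'   figures.
#' @export
format_stereo_report <- function(report) {
  paste0(report$n_mismatch, "/", format(report$percent))
}

#' Flip the handedness of one monomer by reflection
#'
#' Reflects the H5 atom and the methyl group (C4, H6, H7, H8) through the
#' plane spanned by the backbone atoms C2, O1 and C3 of that monomer, the
#' unique plane choice that keeps the backbone fixed while swapping the two
#' off-backbone substituents.  The reflection is an isometry (bond lengths
#' to C2 are preserved) and an involution.
#'
#' @param config An [atomistic_config()].
#' @param monomer Global monomer index.
#' @return The modified configuration.
#' @export
correct_monomer <- function(config, monomer) {
  sys <- .as_system(config$topology)
  ci <- findInterval(monomer - 1L, sys$monomer_offsets)
  ch <- sys$chains[[ci]]
  local <- monomer - sys$monomer_offsets[ci]
  off <- sys$atom_offsets[ci]
  row <- ch$chiral_centers[local, ] + off
  c2 <- config$coords[row[["C2"]], ]
  u <- config$coords[row[["O1"]], ] - c2
  v <- config$coords[row[["C3"]], ] - c2
  nrm <- c(u[2L] * v[3L] - u[3L] * v[2L],
           u[3L] * v[1L] - u[1L] * v[3L],
           u[1L] * v[2L] - u[2L] * v[1L])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9) stop("degenerate reflection plane: C2, O1, C3 are collinear in monomer ", monomer)
  nrm <- nrm / nn
  sel <- which(ch$atoms$monomer == local &
               ch$atoms$name %in% c("H5", "C4", "H6", "H7", "H8")) + off
  rel <- sweep(config$coords[sel, , drop = FALSE], 2L, c2)
  config$coords[sel, ] <- sweep(rel - 2 * (rel %*% nrm) %*% t(nrm), 2L, c2, `+`)
  config
}

#' Correct every mismatched monomer of a configuration
#'
#' Applies [correct_monomer()] to each monomer whose assigned label differs
#' from the requested one.  Monomers with an undefined (near-planar) center
#' are left untouched and reported as unresolved.  A minimum-distance audit
#' over the reflected atoms flags overlaps possibly created by reflection;
#' resolving them is left to external relaxation.
#'
#' @param config An [atomistic_config()].
#' @param sequence Requested stereo labels (vector or per-chain list).
#' @return List with `config` (corrected), `before` and `after`
#'   ([check_sequence()] reports), `unresolved` (undefined centers) and
#'   `min_distance` (nm, over all atom pairs closer than 0.5 nm after
#'   correction involving a reflected atom; `Inf` when none were reflected).
#' @export
correct_all <- function(config, sequence) {
  if (is.list(sequence)) sequence <- unlist(sequence)
  before <- check_sequence(config, sequence)
  undef <- before$mismatch_indices[
    before$labels[before$mismatch_indices] == "undefined"]
  fix <- setdiff(before$mismatch_indices, undef)
  for (m in fix) config <- correct_monomer(config, m)
  after <- check_sequence(config, sequence)
  min_d <- Inf
  if (length(fix)) {
    sys <- .as_system(config$topology)
    touched <- unlist(lapply(fix, function(m) {
      ci <- findInterval(m - 1L, sys$monomer_offsets)
      ch <- sys$chains[[ci]]
      local <- m - sys$monomer_offsets[ci]
      which(ch$atoms$monomer == local &
            ch$atoms$name %in% c("H5", "C4", "H6", "H7", "H8")) +
        sys$atom_offsets[ci]
    }))
    d <- .min_image_dist(config$coords[touched, , drop = FALSE],
                         config$coords, config$box)
    d[cbind(seq_along(touched), touched)] <- Inf
    min_d <- min(d)
  }
  list(config = config, before = before, after = after,
       unresolved = undef, min_distance = min_d)
}

#' CIP-style cross-check label for the fixed PLA substituent set
#'
#' Independent of the signed-volume convention: views the stereocenter from
#' the side opposite the lowest-priority substituent (H5) and reports the
#' rotational sense of O1 -> C3 -> C4 (the fixed priority order
#' O1 > C3 > C4 > H5).  Counterclockwise (S) corresponds to an L monomer.
#'
#' @param config An [atomistic_config()].
#' @param monomer Global monomer index.
#' @return `"R"` or `"S"` (or `"undefined"`).
#' @export
cip_label <- function(config, monomer) {
  sys <- .as_system(config$topology)
  ci <- findInterval(monomer - 1L, sys$monomer_offsets)
  ch <- sys$chains[[ci]]
  local <- monomer - sys$monomer_offsets[ci]
  row <- ch$chiral_centers[local, ] + sys$atom_offsets[ci]
  c2 <- config$coords[row[["C2"]], ]
  view <- config$coords[row[["H5"]], ] - c2   # viewer sits opposite H5
  p <- lapply(c("O1", "C3", "C4"), function(a) config$coords[row[[a]], ] - c2)
  # signed circulation of the priority triangle about the view axis
  tri <- (p[[2]] - p[[1]])
  tri2 <- (p[[3]] - p[[1]])
  nrm <- c(tri[2L] * tri2[3L] - tri[3L] * tri2[2L],
           tri[3L] * tri2[1L] - tri[1L] * tri2[3L],
           tri[1L] * tri2[2L] - tri[2L] * tri2[1L])
  s <- sum(nrm * view)
  if (abs(s) < 1e-12) return("undefined")
  # circulation counterclockwise as seen from -view (opposite H5) => S
  if (s > 0) "S" else "R"
}
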