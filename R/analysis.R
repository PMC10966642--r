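# Validation statistics: dihedral-angle distributions, intra/intermolecular
# radial distribution functions, internal distances, radius of gyration,
# mass density, and block averaging.

.AMU_PER_NM3_TO_KG_M3 <- 1.66053906660  # 1 amu / nm^3 in kg/m^3

#' Block averaging
#'
#' Splits a series into `n_blocks` contiguous equal blocks (any trailing
#' remainder is dropped), and reports the mean of the block means and their
#' standard deviation as the confidence half-width.
#'
#' @param series Numeric vector (e.g. one value per frame).
#' @param n_blocks Number of blocks (default 4).
#' @return List with `mean`, `ci` (sd of block means) and `block_means`.
#' @export
block_average <- function(series, n_blocks = 4L) {
  n <- length(series)
  if (n < n_blocks) stop("series of length ", n, " is shorter than ", n_blocks, " blocks")
  len <- n %/% n_blocks
  bm <- vapply(seq_len(n_blocks), function(b) {
    mean(series[(b - 1L) * len + seq_len(len)])
  }, numeric(1))
  list(mean = mean(bm), ci = stats::sd(bm), block_means = bm)
}

.ensemble_frames <- function(ensemble) {
  if (inherits(ensemble, "aa_config")) return(list(ensemble))
  if (inherits(ensemble[[1L]], "aa_config")) return(ensemble)
  lapply(ensemble, function(fr) fr$aa)   # pla_ensemble frames
}

#' Pooled dihedral-angle distribution
#'
#' Pools every dihedral of the requested class (see [dihedral_classes()])
#' over all chains and frames and returns a normalized histogram over
#' `(-pi, pi]`.
#'
#' @param ensemble A [pack_frames()] ensemble, one [atomistic_config()], or
#'   a list of them.
#' @param class Dihedral class name (`"phi"`, `"psi"`, `"omega"`, or an
#'   atom-name pattern such as `"C3-O1-C2-H5"`).
#' @param stereo Optional stereo filter (`"L"`/`"D"`) on the monomer owning
#'   the alpha carbon of the central bond.
#' @param pair Optional junction filter (`"LL"`, `"LD"`, `"DD"`) for
#'   inter-monomeric dihedrals.
#' @param bins Number of bins (default 100).
#' @return List of class `"pla_histogram"`: `edges` (radians), `mids`,
#'   `density` (per radian, integrates to 1), `counts`, `n`.
#' @export
dihedral_distribution <- function(ensemble, class, stereo = NULL, pair = NULL,
                                  bins = 100L) {
  frames <- .ensemble_frames(ensemble)
  sys <- .as_system(frames[[1L]]$topology)
  values <- list()
  for (ci in seq_len(sys$n_chains)) {
    ch <- sys$chains[[ci]]
    dc <- dihedral_classes(ch)
    sel <- dc$class == class
    if (!is.null(stereo)) sel <- sel & !is.na(dc$stereo) & dc$stereo == stereo
    if (!is.null(pair)) sel <- sel & !is.na(dc$pair) & dc$pair == pair
    if (!any(sel)) next
    quads <- ch$dihedrals[sel, , drop = FALSE]
    off <- sys$atom_offsets[ci]
    for (fr in frames) {
      values[[length(values) + 1L]] <-
        dihedral_angles(fr$coords[off + seq_len(ch$n_atoms), , drop = FALSE], quads)
    }
  }
  x <- unlist(values)
  if (!length(x)) stop("no dihedrals match class '", class, "' with the given filters")
  edges <- seq(-pi, pi, length.out = bins + 1L)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  width <- diff(edges)[1L]
  structure(list(edges = edges, mids = edges[-1L] - width / 2,
                 density = counts / (sum(counts) * width),
                 counts = counts, n = length(x)),
            class = "pla_histogram")
}

.resolve_selection <- function(sys, selection) {
  # selection: atom name(s) or global atom indices; returns global indices
  if (is.numeric(selection)) return(as.integer(selection))
  idx <- integer(0)
  for (ci in seq_len(sys$n_chains)) {
    ch <- sys$chains[[ci]]
    idx <- c(idx, sys$atom_offsets[ci] + which(ch$atoms$name %in% selection))
  }
  idx
}

.chain_of_atoms <- function(sys) {
  rep(seq_len(sys$n_chains),
      vapply(sys$chains, `[[`, integer(1), "n_atoms"))
}

#' Radial distribution function
#'
#' Pair distances under the minimum-image convention in an orthorhombic
#' box, normalized by the ideal-gas shell expectation at the system's
#' admissible-pair density, pooled over frames.  `mode = "intermolecular"`
#' counts only pairs on different chains, `"intramolecular"` only pairs on
#' the same chain.
#'
#' @param ensemble Ensemble, configuration, or list of configurations.
#' @param selection_a,selection_b Atom-name vectors (e.g. `"C2"`) or global
#'   atom indices.
#' @param mode `"intermolecular"` or `"intramolecular"`.
#' @param r_max Histogram range (nm); must be below half the smallest box
#'   length.
#' @param bin_width Bin width (nm), default 0.01.
#' @return List of class `"rdf_profile"`: `r` (bin centers), `g`, `mode`,
#'   `n_pairs`.
#' @export
rdf <- function(ensemble, selection_a, selection_b = selection_a,
                mode = c("intermolecular", "intramolecular"),
                r_max = NULL, bin_width = 0.01) {
  mode <- match.arg(mode)
  frames <- .ensemble_frames(ensemble)
  sys <- .as_system(frames[[1L]]$topology)
  box <- frames[[1L]]$box
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9) {
    stop("r_max = ", r_max, " nm exceeds half the smallest box length (",
         min(box) / 2, " nm)")
  }
  ia <- .resolve_selection(sys, selection_a)
  ib <- .resolve_selection(sys, selection_b)
  if (!length(ia) || !length(ib)) stop("empty atom selection")
  chain_of <- .chain_of_atoms(sys)
  same <- outer(chain_of[ia], chain_of[ib], `==`)
  admissible <- if (mode == "intermolecular") !same else same
  if (length(ia) == length(ib) && all(ia == ib)) {
    admissible <- admissible & !diag(TRUE, length(ia))
  }
  n_adm <- sum(admissible)
  if (n_adm == 0L) {
    stop("no admissible ", mode, " pairs for this selection (single chain?)")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  vol <- prod(box)
  for (fr in frames) {
    d <- .min_image_dist(fr$coords[ia, , drop = FALSE],
                         fr$coords[ib, , drop = FALSE], box)
    dv <- d[admissible]
    dv <- dv[dv < r_max]
    counts <- counts + graphics::hist(dv, breaks = edges, plot = FALSE)$counts
  }
  shell <- (4 / 3) * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  expected <- length(frames) * n_adm * shell / vol
  structure(list(r = edges[-1L] - diff(edges) / 2, g = counts / expected,
                 mode = mode, n_pairs = n_adm, edges = edges),
            class = "rdf_profile")
}

#' Internal-distance profile
#'
#' Mean-squared spatial distance between backbone atoms separated by `n`
#' backbone positions, divided by `n`, averaged over all pairs, chains and
#' frames; the confidence half-width comes from [block_average()] over
#' frames.
#'
#' @param ensemble Ensemble, configuration, or list of configurations
#'   (unwrapped coordinates).
#' @param n_blocks Blocks for the confidence estimate.
#' @return Data frame with `n`, `rn2_over_n` (nm^2), `ci`.
#' @export
internal_distances <- function(ensemble, n_blocks = 4L) {
  frames <- .ensemble_frames(ensemble)
  sys <- .as_system(frames[[1L]]$topology)
  nb <- length(sys$chains[[1L]]$backbone)
  per_frame <- matrix(0, length(frames), nb - 1L)
  for (f in seq_along(frames)) {
    acc <- numeric(nb - 1L); cnt <- numeric(nb - 1L)
    for (ci in seq_len(sys$n_chains)) {
      ch <- sys$chains[[ci]]
      bb <- frames[[f]]$coords[sys$atom_offsets[ci] + ch$backbone, , drop = FALSE]
      for (n in seq_len(nrow(bb) - 1L)) {
        d <- bb[seq_len(nrow(bb) - n) + n, , drop = FALSE] -
             bb[seq_len(nrow(bb) - n), , drop = FALSE]
        acc[n] <- acc[n] + sum(d * d)
        cnt[n] <- cnt[n] + (nrow(bb) - n)
      }
    }
    per_frame[f, ] <- acc / cnt / seq_len(nb - 1L)
  }
  ci_half <- rep(NA_real_, nb - 1L)
  mean_v <- colMeans(per_frame)
  if (length(frames) >= n_blocks) {
    for (n in seq_len(nb - 1L)) {
      ba <- block_average(per_frame[, n], n_blocks)
      mean_v[n] <- ba$mean; ci_half[n] <- ba$ci
    }
  }
  data.frame(n = seq_len(nb - 1L), rn2_over_n = mean_v, ci = ci_half)
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration per chain, averaged over chains, with a
#' block-averaged confidence over frames.
#'
#' @param ensemble Ensemble, configuration, or list of configurations.
#' @param n_blocks Blocks for the confidence estimate.
#' @return List with `mean` (nm), `ci`, `per_frame`.
#' @export
radius_of_gyration <- function(ensemble, n_blocks = 4L) {
  frames <- .ensemble_frames(ensemble)
  sys <- .as_system(frames[[1L]]$topology)
  per_frame <- vapply(frames, function(fr) {
    rg <- vapply(seq_len(sys$n_chains), function(ci) {
      ch <- sys$chains[[ci]]
      cc <- fr$coords[sys$atom_offsets[ci] + seq_len(ch$n_atoms), , drop = FALSE]
      w <- ch$atoms$mass / sum(ch$atoms$mass)
      com <- colSums(cc * w)
      sqrt(sum(w * rowSums(sweep(cc, 2L, com)^2)))
    }, numeric(1))
    mean(rg)
  }, numeric(1))
  if (length(per_frame) >= n_blocks) {
    ba <- block_average(per_frame, n_blocks)
    list(mean = ba$mean, ci = ba$ci, per_frame = per_frame)
  } else {
    list(mean = mean(per_frame), ci = NA_real_, per_frame = per_frame)
  }
}

#' Mass density of the system
#'
#' Total mass divided by the box volume, converted to kg/m^3.
#'
#' @param ensemble Ensemble, configuration, or list of configurations.
#' @param n_blocks Blocks for the confidence estimate (density varies over
#'   frames only if the box does).
#' @return List with `mean` (kg/m^3), `ci`, `per_frame`.
#' @export
mass_density <- function(ensemble, n_blocks = 4L) {
  frames <- .ensemble_frames(ensemble)
  sys <- .as_system(frames[[1L]]$topology)
  total_mass <- sum(vapply(sys$chains, function(ch) sum(ch$atoms$mass), numeric(1)))
  per_frame <- vapply(frames, function(fr) {
    total_mass / prod(fr$box) * .AMU_PER_NM3_TO_KG_M3
  }, numeric(1))
  if (length(per_frame) >= n_blocks) {
    ba <- block_average(per_frame, n_blocks)
    list(mean = ba$mean, ci = ba$ci, per_frame = per_frame)
  } else {
    list(mean = mean(per_frame), ci = NA_real_, per_frame = per_frame)
  }
}
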