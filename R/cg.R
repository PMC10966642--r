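# Coarse-graining operator (one bead per monomer at its center of mass),
# monomer-type labeling, and the bond-vector codec that turns a chain into
# the padded (S, k+3) input / (S, 3) target tensors of the network and back.
#
# Codec layout: one row per atom in traversal order.  The monomer root (O1)
# row carries the anchor vector v0 = r(root) - Q(monomer); every other row
# carries the bond vector b = r(atom) - r(parent).  All vectors are divided
# by a fixed rescale factor so targets lie strictly inside [-1, 1] (the
# tanh output range).  Decoding rebuilds each monomer from its bond vectors
# and rigidly translates it so its center of mass coincides exactly with the
# CG bead (COM anchoring); the anchor rows are auxiliary, which keeps
# reconstruction well-posed even when the anchor penalty weight is zero.

CODEC_SCHEME_VERSION <- "pla-bv-1"

#' Construct an atomistic configuration
#'
#' @param coords N x 3 coordinate matrix (nm), unwrapped (bonds must not
#'   jump across the periodic box).
#' @param box Length-3 periodic box (nm).
#' @param topology A [build_chain()] or [build_system()] topology.
#' @return List of class `"aa_config"`.
#' @export
atomistic_config <- function(coords, box, topology) {
  n <- if (inherits(topology, "pla_system")) topology$total_atoms else topology$n_atoms
  coords <- as.matrix(coords)
  if (nrow(coords) != n) {
    stop("coordinate count (", nrow(coords), ") does not match topology atoms (", n, ")")
  }
  if (any(box <= 0)) stop("box lengths must be positive")
  structure(list(coords = coords, box = as.numeric(box), topology = topology),
            class = "aa_config")
}

.as_system <- function(topology) {
  if (inherits(topology, "pla_system")) return(topology)
  structure(list(chains = list(topology), atom_offsets = 0L,
                 monomer_offsets = 0L, total_atoms = topology$n_atoms,
                 total_monomers = topology$n_monomers, n_chains = 1L),
            class = "pla_system")
}

#' Map an atomistic configuration to its CG representation
#'
#' Places one CG bead at the mass-weighted center of each monomer (cap atoms
#' belong to their monomer) and assigns monomer types via [assign_types()].
#'
#' @param config An [atomistic_config()].
#' @param composition Training-set composition for the type scheme:
#'   `"homopolymer"`, `"copolymer"` or `"combined"`.
#' @return List of class `"cg_config"` with `Q` (M x 3 bead coordinates,
#'   nm), `types` (integer per bead), `k`, `box`.
#' @export
map_to_cg <- function(config, composition = "homopolymer") {
  stopifnot(inherits(config, "aa_config"))
  sys <- .as_system(config$topology)
  mono_global <- integer(sys$total_atoms)
  mass <- numeric(sys$total_atoms)
  for (ci in seq_len(sys$n_chains)) {
    ch <- sys$chains[[ci]]
    idx <- sys$atom_offsets[ci] + seq_len(ch$n_atoms)
    mono_global[idx] <- sys$monomer_offsets[ci] + ch$atoms$monomer
    mass[idx] <- ch$atoms$mass
  }
  w <- mass / rowsum(mass, mono_global)[mono_global, 1L]
  Q <- rowsum(config$coords * w, mono_global)
  ty <- assign_types(sys, composition)
  structure(list(Q = unname(Q), types = ty$types, k = ty$k,
                 box = config$box, composition = composition),
            class = "cg_config")
}

#' Assign monomer (CG bead) types
#'
#' The first and last monomers of every chain are their own types.  For a
#' homopolymer training set the interior monomers share one type (k = 3);
#' for a copolymer set the L and D interiors are distinct (k = 4); when
#' homopolymer and copolymer systems are combined, interior labels are kept
#' distinct per context (homopolymer L/D interiors, copolymer L/D
#' interiors) with shared chain-end types, totaling k = 6.
#'
#' @param topology A [build_chain()] or [build_system()] topology.
#' @param composition `"homopolymer"`, `"copolymer"` or `"combined"`.
#' @return List with `types` (integer vector over all monomers, values in
#'   `1..k`), `k`, and `labels` (names of the type slots).
#' @export
assign_types <- function(topology, composition = "homopolymer") {
  sys <- .as_system(topology)
  if (!composition %in% c("homopolymer", "copolymer", "combined")) {
    stop("unknown training composition: ", composition)
  }
  k <- switch(composition, homopolymer = 3L, copolymer = 4L, combined = 6L)
  labels <- switch(composition,
    homopolymer = c("interior", "first", "last"),
    copolymer   = c("L-interior", "D-interior", "first", "last"),
    combined    = c("homo-L-interior", "homo-D-interior",
                    "copo-L-interior", "copo-D-interior", "first", "last"))
  types <- integer(sys$total_monomers)
  for (ci in seq_len(sys$n_chains)) {
    ch <- sys$chains[[ci]]
    n <- ch$n_monomers
    idx <- sys$monomer_offsets[ci] + seq_len(n)
    t_int <- switch(composition,
      homopolymer = rep(1L, n),
      copolymer   = ifelse(ch$sequence == "L", 1L, 2L),
      combined    = {
        homo <- length(unique(ch$sequence)) == 1L
        base <- if (homo) 0L else 2L
        base + ifelse(ch$sequence == "L", 1L, 2L)
      })
    types[idx] <- t_int
    types[idx[1L]] <- k - 1L          # first
    if (n > 1L) types[idx[n]] <- k    # last
  }
  list(types = types, k = k, labels = labels)
}

#' Codec rescaling and capacity settings
#'
#' @param s Chain capacity in monomers per network sample (default 100).
#' @param vec_scale Rescale factor (nm) dividing every bond/anchor vector; a
#'   generous bound on any such vector so scaled targets lie in `[-1, 1]`.
#' @param cg_scale Rescale factor (nm) for the CG input feature.
#' @param cg_feature `"prev"` (bead displacement from the previous bead,
#'   zero for the first monomer) or `"com"` (bead minus chain bead centroid).
#' @return List of class `"codec_scales"`; `S` is the smallest power of two
#'   holding the `9 s + 3` rows of a full chain.
#' @export
codec_scales <- function(s = 100L, vec_scale = 0.3, cg_scale = 1.5,
                         cg_feature = c("prev", "com")) {
  cg_feature <- match.arg(cg_feature)
  rows <- 9L * as.integer(s) + 3L
  S <- 2L^ceiling(log2(rows))
  structure(list(s = as.integer(s), S = S, vec_scale = vec_scale,
                 cg_scale = cg_scale, cg_feature = cg_feature,
                 scheme = CODEC_SCHEME_VERSION),
            class = "codec_scales")
}

#' Encode one chain as padded network tensors
#'
#' @param chain A [build_chain()] topology.
#' @param coords Chain coordinates (n_atoms x 3, nm, unwrapped).
#' @param Q Chain bead coordinates (n_monomers x 3, nm).
#' @param types Integer monomer types for this chain (values in `1..k`).
#' @param k Number of type slots in the one-hot block.
#' @param scales A [codec_scales()].
#' @param monomers Optional integer range of monomers (a fragment); defaults
#'   to the whole chain.
#' @return List of class `"encoded_sample"`: `input` (S x (k+3)), `target`
#'   (S x 3), `mask` (length-S logical, TRUE on informative rows), `rows`
#'   (atom rows used), plus bookkeeping (`roles`, `monomer`, `scales`).
#' @export
encode_chain <- function(chain, coords, Q, types, k, scales = codec_scales(),
                         monomers = NULL) {
  stopifnot(inherits(chain, "pla_chain"), inherits(scales, "codec_scales"))
  if (is.null(monomers)) monomers <- seq_len(chain$n_monomers)
  if (length(monomers) > scales$s) {
    stop("chain fragment of ", length(monomers), " monomers exceeds capacity s = ",
         scales$s, "; use fragment_chain()")
  }
  rows <- which(chain$atoms$monomer %in% monomers)
  n_rows <- length(rows)
  S <- scales$S
  mono_of <- chain$atoms$monomer[rows]
  parent <- chain$parent[rows]
  is_anchor <- parent == 0L

  target <- matrix(0, S, 3L)
  vec <- coords[rows, , drop = FALSE]
  vec[!is_anchor, ] <- vec[!is_anchor, , drop = FALSE] -
    coords[parent[!is_anchor], , drop = FALSE]
  vec[is_anchor, ] <- vec[is_anchor, , drop = FALSE] -
    Q[mono_of[is_anchor], , drop = FALSE]
  sv <- vec / scales$vec_scale
  if (any(abs(sv) > 1)) {
    bad <- rows[which(abs(sv) > 1, arr.ind = TRUE)[1L, 1L]]
    stop("scaled vector component out of [-1, 1] for atom ", bad, " (",
         chain$atoms$name[bad], ", monomer ", chain$atoms$monomer[bad],
         "): vector scale ", scales$vec_scale, " nm is too small")
  }
  target[seq_len(n_rows), ] <- sv

  feat <- matrix(0, length(monomers), 3L)
  if (scales$cg_feature == "prev") {
    prev <- monomers - 1L
    has_prev <- prev >= 1L
    feat[has_prev, ] <- (Q[monomers[has_prev], , drop = FALSE] -
                         Q[prev[has_prev], , drop = FALSE]) / scales$cg_scale
  } else {
    cen <- colMeans(Q[monomers, , drop = FALSE])
    feat <- sweep(Q[monomers, , drop = FALSE], 2L, cen) / scales$cg_scale
  }
  input <- matrix(0, S, k + 3L)
  local_m <- match(mono_of, monomers)
  input[seq_len(n_rows), 1:3] <- feat[local_m, , drop = FALSE]
  input[cbind(seq_len(n_rows), 3L + types[mono_of])] <- 1

  mask <- c(rep(TRUE, n_rows), rep(FALSE, S - n_rows))
  structure(list(input = input, target = target, mask = mask,
                 rows = rows, roles = ifelse(is_anchor, "anchor", "bond"),
                 monomer = mono_of, monomers = monomers, k = k,
                 scales = scales),
            class = "encoded_sample")
}

#' Decode predicted vectors into Cartesian coordinates
#'
#' Rebuilds every monomer from its (unscaled) bond vectors along the codec
#' traversal, then rigidly translates it so its mass-weighted center
#' coincides exactly with the CG bead; anchor rows do not influence
#' placement.  By construction, re-mapping the decoded structure returns the
#' input beads.
#'
#' @param predicted S x 3 matrix of scaled vectors (e.g. network output).
#' @param sample The [encode_chain()] sample that defines rows and masks.
#' @param chain The chain topology.
#' @param Q Chain bead coordinates (n_monomers x 3, nm).
#' @return Coordinate matrix for the encoded atoms (length(rows) x 3, nm).
#' @export
decode_vectors <- function(predicted, sample, chain, Q) {
  stopifnot(inherits(sample, "encoded_sample"))
  if (nrow(predicted) != length(sample$mask) || ncol(predicted) != 3L) {
    stop("predicted matrix must be ", length(sample$mask), " x 3")
  }
  rows <- sample$rows
  n_rows <- length(rows)
  vec <- predicted[seq_len(n_rows), , drop = FALSE] * sample$scales$vec_scale
  parent <- chain$parent[rows]
  local <- match(seq_len(chain$n_atoms), rows)  # global -> local row
  coords <- matrix(0, n_rows, 3L)
  for (r in seq_len(n_rows)) {     # parents precede children in traversal order
    p <- parent[r]
    if (p != 0L) coords[r, ] <- coords[local[p], ] + vec[r, ]
  }
  mass <- chain$atoms$mass[rows]
  mono <- sample$monomer
  for (m in unique(mono)) {
    sel <- mono == m
    w <- mass[sel] / sum(mass[sel])
    shift <- Q[m, ] - colSums(coords[sel, , drop = FALSE] * w)
    coords[sel, ] <- sweep(coords[sel, , drop = FALSE], 2L, shift, `+`)
  }
  coords
}

#' Split a long chain into encodable fragments
#'
#' Consecutive non-overlapping windows of at most `s` monomers; decoded
#' pieces concatenate to the original chain because decoding is local to
#' each monomer (COM anchoring).
#'
#' @param chain A [build_chain()] topology.
#' @param s Fragment capacity in monomers.
#' @return List of integer monomer ranges.
#' @export
fragment_chain <- function(chain, s) {
  stopifnot(inherits(chain, "pla_chain"), s >= 1L)
  n <- chain$n_monomers
  starts <- seq(1L, n, by = as.integer(s))
  lapply(starts, function(a) seq(a, min(a + s - 1L, n)))
}

#' Encode every chain of every frame of an ensemble
#'
#' One network sample per chain per frame.
#'
#' @param ensemble List of frames, each a list with `aa` ([atomistic_config()])
#'   and `cg` ([map_to_cg()]) entries, sharing one system topology.
#' @param composition Type-scheme composition flag.
#' @param scales A [codec_scales()].
#' @return List with `inputs` (n x S x (k+3) array), `targets` (n x S x 3),
#'   `mask` (length-S logical, shared), `k`, `scales`, `frame`/`chain` index
#'   vectors, and `samples` (the per-sample [encode_chain()] objects).
#' @export
encode_dataset <- function(ensemble, composition = "homopolymer",
                           scales = codec_scales()) {
  sys <- .as_system(ensemble[[1L]]$aa$topology)
  ty <- assign_types(sys, composition)
  n_fr <- length(ensemble)
  n_samp <- n_fr * sys$n_chains
  S <- scales$S
  inputs <- array(0, c(n_samp, S, ty$k + 3L))
  targets <- array(0, c(n_samp, S, 3L))
  samples <- vector("list", n_samp)
  frame_id <- integer(n_samp); chain_id <- integer(n_samp)
  i <- 0L
  for (f in seq_len(n_fr)) {
    fr <- ensemble[[f]]
    for (ci in seq_len(sys$n_chains)) {
      ch <- sys$chains[[ci]]
      arange <- sys$atom_offsets[ci] + seq_len(ch$n_atoms)
      mrange <- sys$monomer_offsets[ci] + seq_len(ch$n_monomers)
      enc <- encode_chain(ch, fr$aa$coords[arange, , drop = FALSE],
                          fr$cg$Q[mrange, , drop = FALSE],
                          ty$types[mrange], ty$k, scales)
      i <- i + 1L
      inputs[i, , ] <- enc$input
      targets[i, , ] <- enc$target
      samples[[i]] <- enc
      frame_id[i] <- f; chain_id[i] <- ci
    }
  }
  list(inputs = inputs, targets = targets, mask = samples[[1L]]$mask,
       k = ty$k, scales = scales, frame = frame_id, chain = chain_id,
       samples = samples, composition = composition,
       chain_topology = sys$chains[[1L]])
}
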