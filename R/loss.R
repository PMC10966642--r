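# Composite geometric loss on bond-vector predictions.
#
# Five terms, each a mean penalty over its own population:
#   bv: mean squared Euclidean deviation of bond vectors,
#   bl: mean squared deviation of bond lengths (vector magnitudes),
#   ba: mean squared deviation of bending angles,
#   da: mean of 1 - cos(delta phi) over dihedral angles (periodic-safe),
#   v0: mean squared Euclidean deviation of anchor vectors.
# All terms are computed on unscaled (nm) vectors, so the weights are
# physically comparable; the tanh rescaling is inverted inside the loss.
# Angles and dihedrals are functions of reconstructed positions, which are
# linear in the bond vectors under COM anchoring; their gradients are
# propagated through that linear map.  Padded rows contribute nothing.

#' Loss-term weights
#'
#' The reference model penalizes bond vectors and bond lengths only
#' (`bv = bl = 1`, all others 0).
#'
#' @param bv,bl,ba,da,v0 Non-negative weights.
#' @return List of class `"loss_weights"`.
#' @export
loss_weights <- function(bv = 1, bl = 1, ba = 0, da = 0, v0 = 0) {
  w <- list(bv = bv, bl = bl, ba = ba, da = da, v0 = v0)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  if (all(unlist(w) == 0)) stop("at least one loss weight must be positive")
  structure(w, class = "loss_weights")
}

#' Bond lengths from a vector matrix
#'
#' Euclidean norms of the unscaled vectors on the bond-role rows; masked
#' (padding and anchor) rows are excluded from the output.
#'
#' @param vectors Matrix (rows x 3) of vectors (nm).
#' @param bond_mask Logical vector marking bond-role rows.
#' @return Numeric vector of lengths, one per bond row.
#' @export
bond_lengths <- function(vectors, bond_mask) {
  .row_norms(vectors[bond_mask, , drop = FALSE])
}

#' Precompute the loss bookkeeping for one chain topology
#'
#' Builds row-role masks, term counts, local angle/dihedral index tables and
#' the per-monomer linear map from bond vectors to positions used for the
#' angle/dihedral gradient.
#'
#' @param chain A [build_chain()] topology.
#' @param scales A [codec_scales()].
#' @return List of class `"loss_context"`.
#' @export
loss_context <- function(chain, scales = codec_scales()) {
  stopifnot(inherits(chain, "pla_chain"))
  n_rows <- chain$n_atoms
  parent <- chain$parent
  bond_rows <- which(parent != 0L)
  anchor_rows <- which(parent == 0L)
  mono <- chain$atoms$monomer
  mass <- chain$atoms$mass
  monomers <- vector("list", chain$n_monomers)
  for (m in seq_len(chain$n_monomers)) {
    atoms <- which(mono == m)
    bonds <- atoms[parent[atoms] != 0L]
    P <- matrix(0, length(atoms), length(bonds))
    for (ai in seq_along(atoms)) {
      a <- atoms[ai]
      while (parent[a] != 0L) {           # walk up to the monomer root
        P[ai, match(a, bonds)] <- 1
        a <- parent[a]
      }
    }
    w <- mass[atoms] / sum(mass[atoms])
    G <- P - matrix(1, length(atoms), 1L) %*% (t(w) %*% P)
    monomers[[m]] <- list(atoms = atoms, bonds = bonds, G = G)
  }
  structure(list(
    n_rows = n_rows, bond_rows = bond_rows, anchor_rows = anchor_rows,
    n_bv = length(bond_rows), n_v0 = length(anchor_rows),
    angles = chain$angles, dihedrals = chain$dihedrals,
    n_ba = nrow(chain$angles), n_da = nrow(chain$dihedrals),
    monomers = monomers, vec_scale = scales$vec_scale, chain = chain
  ), class = "loss_context")
}

# reconstruct positions from unscaled vectors (COM anchored at Q)
.positions_from_vectors <- function(vec, ctx, Q) {
  chain <- ctx$chain
  coords <- matrix(0, ctx$n_rows, 3L)
  parent <- chain$parent
  for (r in seq_len(ctx$n_rows)) {
    p <- parent[r]
    if (p != 0L) coords[r, ] <- coords[p, ] + vec[r, ]
  }
  mass <- chain$atoms$mass
  for (m in seq_along(ctx$monomers)) {
    sel <- ctx$monomers[[m]]$atoms
    w <- mass[sel] / sum(mass[sel])
    shift <- Q[m, ] - colSums(coords[sel, , drop = FALSE] * w)
    coords[sel, ] <- sweep(coords[sel, , drop = FALSE], 2L, shift, `+`)
  }
  coords
}

#' Loss terms for one predicted sample
#'
#' @param predicted,target S x 3 matrices of scaled vectors (network space).
#' @param ctx A [loss_context()].
#' @param Q Chain bead coordinates; needed only when the angle or dihedral
#'   term is requested.
#' @param need_angles Compute the (more expensive) angle/dihedral terms?
#' @return Named list `bv`, `bl`, `ba`, `da`, `v0` (NA for angle terms when
#'   not requested).
#' @export
loss_terms <- function(predicted, target, ctx, Q = NULL, need_angles = TRUE) {
  sv <- ctx$vec_scale
  n <- ctx$n_rows
  vp <- predicted[seq_len(n), , drop = FALSE] * sv
  vt <- target[seq_len(n), , drop = FALSE] * sv
  br <- ctx$bond_rows; ar <- ctx$anchor_rows
  dbv <- vp[br, , drop = FALSE] - vt[br, , drop = FALSE]
  L_bv <- sum(dbv * dbv) / ctx$n_bv
  lp <- .row_norms(vp[br, , drop = FALSE]); lt <- .row_norms(vt[br, , drop = FALSE])
  L_bl <- sum((lp - lt)^2) / ctx$n_bv
  dv0 <- vp[ar, , drop = FALSE] - vt[ar, , drop = FALSE]
  L_v0 <- sum(dv0 * dv0) / ctx$n_v0
  L_ba <- NA_real_; L_da <- NA_real_
  if (need_angles) {
    if (is.null(Q)) stop("bead coordinates Q are required for angle/dihedral terms")
    pp <- .positions_from_vectors(vp, ctx, Q)
    pt <- .positions_from_vectors(vt, ctx, Q)
    th_p <- bending_angles(pp, ctx$angles); th_t <- bending_angles(pt, ctx$angles)
    L_ba <- mean((th_p - th_t)^2)
    ph_p <- dihedral_angles(pp, ctx$dihedrals); ph_t <- dihedral_angles(pt, ctx$dihedrals)
    L_da <- mean(1 - cos(ph_p - ph_t))
  }
  list(bv = L_bv, bl = L_bl, ba = L_ba, da = L_da, v0 = L_v0)
}

#' Weighted total loss
#'
#' @param terms Output of [loss_terms()].
#' @param weights A [loss_weights()].
#' @return Scalar `sum(lambda_x * L_x)` over the terms with positive weight.
#' @export
total_loss <- function(terms, weights = loss_weights()) {
  tot <- 0
  for (nm in names(weights)) {
    if (weights[[nm]] > 0) {
      if (is.na(terms[[nm]])) stop("term ", nm, " requested but not computed")
      tot <- tot + weights[[nm]] * terms[[nm]]
    }
  }
  tot
}

# d(theta)/d(positions) for angle triples; returns list of three n x 3 blocks
.angle_grad <- function(coords, triples) {
  u <- coords[triples[, 1L], , drop = FALSE] - coords[triples[, 2L], , drop = FALSE]
  v <- coords[triples[, 3L], , drop = FALSE] - coords[triples[, 2L], , drop = FALSE]
  nu <- .row_norms(u); nv <- .row_norms(v)
  uh <- u / nu; vh <- v / nv
  cth <- pmin(1, pmax(-1, rowSums(uh * vh)))
  sth <- sqrt(pmax(1e-12, 1 - cth^2))
  di <- -(vh - cth * uh) / (nu * sth)
  dk <- -(uh - cth * vh) / (nv * sth)
  dj <- -(di + dk)
  list(di = di, dj = dj, dk = dk)
}

# d(phi)/d(positions) for dihedral quadruples
.dihedral_grad <- function(coords, quads) {
  b1 <- coords[quads[, 2L], , drop = FALSE] - coords[quads[, 1L], , drop = FALSE]
  b2 <- coords[quads[, 3L], , drop = FALSE] - coords[quads[, 2L], , drop = FALSE]
  b3 <- coords[quads[, 4L], , drop = FALSE] - coords[quads[, 3L], , drop = FALSE]
  n1 <- .row_cross(b1, b2); n2 <- .row_cross(b2, b3)
  nb2 <- .row_norms(b2)
  sq1 <- pmax(1e-12, rowSums(n1 * n1)); sq2 <- pmax(1e-12, rowSums(n2 * n2))
  di <- n1 * (nb2 / sq1)
  dl <- -n2 * (nb2 / sq2)
  A <- rowSums(b1 * b2) / nb2^2
  Bc <- rowSums(b3 * b2) / nb2^2
  dj <- -(1 + A) * di + Bc * dl
  dk <- A * di - (1 + Bc) * dl
  list(di = di, dj = dj, dk = dk, dl = dl)
}

.accumulate_rows <- function(dpos, idx_list, blocks) {
  all_idx <- unlist(idx_list)
  all_blk <- do.call(rbind, blocks)
  acc <- rowsum(all_blk, all_idx)
  rows <- as.integer(rownames(acc))
  dpos[rows, ] <- dpos[rows, , drop = FALSE] + acc
  dpos
}

#' Loss terms and gradient with respect to the prediction
#'
#' Computes the weighted loss on one sample together with its exact gradient
#' in the scaled prediction space (what the network outputs).  Terms with
#' zero weight are skipped.
#'
#' @inheritParams loss_terms
#' @param weights A [loss_weights()].
#' @return List with `terms`, `total`, and `grad` (S x 3 matrix).
#' @export
loss_and_grad <- function(predicted, target, ctx, weights = loss_weights(),
                          Q = NULL) {
  sv <- ctx$vec_scale
  n <- ctx$n_rows
  vp <- predicted[seq_len(n), , drop = FALSE] * sv
  vt <- target[seq_len(n), , drop = FALSE] * sv
  br <- ctx$bond_rows; ar <- ctx$anchor_rows
  need_ang <- weights$ba > 0 || weights$da > 0
  terms <- loss_terms(predicted, target, ctx, Q = Q, need_angles = need_ang)
  dvec <- matrix(0, n, 3L)   # gradient wrt unscaled vectors
  if (weights$bv > 0) {
    dvec[br, ] <- dvec[br, , drop = FALSE] +
      weights$bv * 2 / ctx$n_bv * (vp[br, , drop = FALSE] - vt[br, , drop = FALSE])
  }
  if (weights$bl > 0) {
    lp <- .row_norms(vp[br, , drop = FALSE]); lt <- .row_norms(vt[br, , drop = FALSE])
    dir <- vp[br, , drop = FALSE] / pmax(lp, 1e-12)
    dvec[br, ] <- dvec[br, , drop = FALSE] +
      weights$bl * 2 / ctx$n_bv * (lp - lt) * dir
  }
  if (weights$v0 > 0) {
    dvec[ar, ] <- dvec[ar, , drop = FALSE] +
      weights$v0 * 2 / ctx$n_v0 * (vp[ar, , drop = FALSE] - vt[ar, , drop = FALSE])
  }
  if (need_ang) {
    if (is.null(Q)) stop("bead coordinates Q are required for angle/dihedral gradients")
    pp <- .positions_from_vectors(vp, ctx, Q)
    pt <- .positions_from_vectors(vt, ctx, Q)
    dpos <- matrix(0, n, 3L)
    if (weights$ba > 0) {
      tr <- ctx$angles
      th_p <- bending_angles(pp, tr); th_t <- bending_angles(pt, tr)
      g <- .angle_grad(pp, tr)
      coef <- weights$ba * 2 / ctx$n_ba * (th_p - th_t)
      dpos <- .accumulate_rows(dpos,
        list(tr[, 1L], tr[, 2L], tr[, 3L]),
        list(coef * g$di, coef * g$dj, coef * g$dk))
    }
    if (weights$da > 0) {
      qd <- ctx$dihedrals
      ph_p <- dihedral_angles(pp, qd); ph_t <- dihedral_angles(pt, qd)
      g <- .dihedral_grad(pp, qd)
      coef <- weights$da / ctx$n_da * sin(ph_p - ph_t)
      dpos <- .accumulate_rows(dpos,
        list(qd[, 1L], qd[, 2L], qd[, 3L], qd[, 4L]),
        list(coef * g$di, coef * g$dj, coef * g$dk, coef * g$dl))
    }
    # positions are linear in bond vectors: p(monomer) = Q + G %*% vec(bonds)
    for (m in ctx$monomers) {
      if (!length(m$bonds)) next
      dvec[m$bonds, ] <- dvec[m$bonds, , drop = FALSE] +
        crossprod(m$G, dpos[m$atoms, , drop = FALSE])
    }
  }
  grad <- matrix(0, nrow(predicted), 3L)
  grad[seq_len(n), ] <- dvec * sv
  list(terms = terms, total = total_loss(terms, weights), grad = grad)
}
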