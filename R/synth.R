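# Synthetic melt-ensemble generator with fully known geometric statistics.
#
# Chains are grown atom-by-atom by the standard internal-to-Cartesian
# construction: bonds at exact specified lengths, bending angles drawn from
# Gaussians, torsions from stereo-label-dependent wrapped-Gaussian mixtures.
# Frames are independent: each frame places freshly sampled chains at
# uniformly random positions and orientations in the periodic box (no
# inter-chain relaxation is claimed).  Every distributional property of the
# ensemble is therefore available in closed form, which is what makes the
# codec, training and analysis stages testable end to end.

.deg <- function(x) x * pi / 180

.default_bonds <- c(
  "O1-C2" = 0.144, "C2-C3" = 0.152, "C2-C4" = 0.153, "C2-H5" = 0.109,
  "C4-H"  = 0.109, "C3-O2" = 0.122, "C3-O1'" = 0.134, "C3-O3" = 0.134,
  "O3-HO3" = 0.097, "O1-HO1" = 0.097)

.default_angles <- list(            # mean (rad), sd (rad)
  "O1-C2-C3"  = c(.deg(109.5), .deg(2.5)),
  "O1-C2-H5"  = c(.deg(109.0), .deg(2.0)),
  "O1-C2-C4"  = c(.deg(109.5), .deg(2.0)),
  "C2-C4-H"   = c(.deg(110.0), .deg(2.0)),
  "C2-C3-O2"  = c(.deg(125.0), .deg(2.0)),
  "C2-C3-O1'" = c(.deg(111.0), .deg(2.0)),
  "C3-O1'-C2" = c(.deg(116.0), .deg(2.5)),
  "C2-C3-O3"  = c(.deg(112.0), .deg(2.0)),
  "C3-O3-HO3" = c(.deg(107.0), .deg(2.5)),
  "C2-O1-HO1" = c(.deg(108.0), .deg(2.5)))

.mirror_mixture <- function(mx) {
  mx$modes <- -mx$modes
  mx
}

.default_torsions <- function() {
  phi_L <- list(modes = .deg(c(-60, 60, 180)), sd = rep(0.32, 3L),
                weights = c(0.5, 0.3, 0.2))
  psi_L <- list(modes = .deg(c(150, -30)), sd = rep(0.29, 2L),
                weights = c(0.7, 0.3))
  list(
    phi    = list(L = phi_L, D = .mirror_mixture(phi_L)),
    psi    = list(L = psi_L, D = .mirror_mixture(psi_L)),
    omega  = list(L = list(modes = .deg(180), sd = 0.16, weights = 1),
                  D = list(modes = .deg(180), sd = 0.16, weights = 1)),
    methyl = list(modes = .deg(60),  sd = 0.41, weights = 1),
    o2     = list(modes = .deg(-30), sd = 0.22, weights = 1),
    o3     = list(modes = .deg(150), sd = 0.22, weights = 1),
    hcap   = list(modes = .deg(180), sd = 0.70, weights = 1),
    ho3    = list(modes = .deg(180), sd = 0.70, weights = 1))
}

#' Parameters of the synthetic PLA melt generator
#'
#' Defaults emulate the melt ensembles used to train the reference models:
#' 70 chains of 100 monomers, frames saved every 200 ps over 1 microsecond
#' (5000 frames), box sized to a melt density of 1100 kg/m^3.  Geometric
#' parameters are loosely PLA-like generator configuration (standard
#' covalent bond lengths, near-tetrahedral angles, multimodal backbone
#' torsions mirrored between L and D); they are not claimed to reproduce any
#' particular force field.
#'
#' @param n_chains Chains per frame.
#' @param n_monomers Monomers per chain.
#' @param sequences Stereo sequences (list, one per chain); default all-L.
#' @param duration,save_interval Frame schedule (ps); the frame count is
#'   `floor(duration / save_interval)`.
#' @param box Length-3 box (nm); `NULL` sizes a cubic box to `density`.
#' @param density Target melt density (kg/m^3) used to size the box.
#' @param bonds,angles,torsions Geometric parameter tables; see defaults.
#' @param seed Integer seed for all generator randomness.
#' @return List of class `"generator_params"` (includes the built
#'   [build_system()] topology).
#' @export
generator_params <- function(n_chains = 70L, n_monomers = 100L,
                             sequences = NULL,
                             duration = 1e6, save_interval = 200,
                             box = NULL, density = 1100,
                             bonds = .default_bonds,
                             angles = .default_angles,
                             torsions = .default_torsions(),
                             seed = 1L) {
  if (is.null(sequences)) sequences <- rep(list(rep("L", n_monomers)), n_chains)
  topology <- build_system(n_chains, sequences)
  total_mass <- sum(vapply(topology$chains,
                           function(ch) sum(ch$atoms$mass), numeric(1)))
  if (is.null(box)) {
    vol_nm3 <- total_mass * 1.66053906660e-27 / density * 1e27
    box <- rep(vol_nm3^(1 / 3), 3L)
  }
  w <- vapply(torsions$phi$L$weights, identity, numeric(1))
  stopifnot(abs(sum(w) - 1) < 1e-9)
  structure(list(n_chains = as.integer(n_chains),
                 n_monomers = as.integer(n_monomers),
                 sequences = sequences, topology = topology,
                 duration = duration, save_interval = save_interval,
                 n_frames = as.integer(floor(duration / save_interval)),
                 box = box, total_mass = total_mass,
                 bonds = bonds, angles = angles, torsions = torsions,
                 seed = as.integer(seed)),
            class = "generator_params")
}

.sample_mixture <- function(mx, n = 1L) {
  j <- if (length(mx$weights) == 1L) rep(1L, n)
       else sample.int(length(mx$weights), n, replace = TRUE, prob = mx$weights)
  .wrap_angle(mx$modes[j] + stats::rnorm(n, 0, mx$sd[j]))
}

.sample_angle <- function(angles, key, n = 1L) {
  a <- angles[[key]]
  stats::rnorm(n, a[1L], a[2L])
}

#' Wrapped-Gaussian mixture density
#'
#' Analytic density of the generator's torsion mixtures on `(-pi, pi]`.
#'
#' @param x Angles (radians).
#' @param mx Mixture spec: `modes`, `sd`, `weights` (summing to 1).
#' @return Density values (per radian); integrates to 1 over one period.
#' @export
mixture_density <- function(x, mx) {
  d <- numeric(length(x))
  for (j in seq_along(mx$weights)) {
    for (wrap in -3:3) {
      d <- d + mx$weights[j] * stats::dnorm(x - mx$modes[j] - 2 * pi * wrap,
                                            0, mx$sd[j])
    }
  }
  d
}

# stereo sign convention: the canonical L monomer places H5 at phi + 120 deg
# and the methyl C4 at phi - 120 deg about the O1->C2 axis
.STEREO_BRANCH_SIGN <- c(L = 1, D = -1)

#' Grow one all-atom PLA chain from internal coordinates
#'
#' Bonds are exact, bending angles Gaussian, torsions drawn from the
#' stereo label's mixture; the alpha-carbon substituents H5 and C4 are
#' placed at +/-120 degrees about the backbone reference torsion with the
#' sign set by the monomer's stereo label, so every monomer has the correct
#' chirality by construction.
#'
#' @param params A [generator_params()].
#' @param sequence Stereo sequence for this chain.
#' @return Coordinate matrix (`9 n + 3` rows, nm), atom order as in
#'   [build_chain()].
#' @export
sample_chain <- function(params, sequence) {
  chain <- build_chain(sequence)
  n <- chain$n_monomers
  B <- params$bonds; A <- params$angles; Tn <- params$torsions
  coords <- matrix(NA_real_, chain$n_atoms, 3L)
  atom_names <- c("O1", "HO1", "C2", "H5", "C4", "H6", "H7", "H8",
                  "C3", "O2", "O3", "HO3")
  amap <- matrix(NA_integer_, n, length(atom_names),
                 dimnames = list(NULL, atom_names))
  amap[cbind(chain$atoms$monomer, match(chain$atoms$name, atom_names))] <-
    seq_len(chain$n_atoms)
  idx <- function(m, name) amap[m, name]
  for (i in seq_len(n)) {
    lab <- sequence[i]
    iO1 <- idx(i, "O1"); iC2 <- idx(i, "C2"); iC3 <- idx(i, "C3")
    if (i == 1L) {
      coords[iO1, ] <- c(0, 0, 0)
      coords[iC2, ] <- c(B[["O1-C2"]], 0, 0)
      th <- .sample_angle(A, "O1-C2-C3")
      coords[iC3, ] <- coords[iC2, ] +
        B[["C2-C3"]] * c(-cos(th), sin(th), 0)
      iH <- idx(1L, "HO1")
      coords[iH, ] <- place_atom(coords[iC3, ], coords[iC2, ], coords[iO1, ],
                                 B[["O1-HO1"]], .sample_angle(A, "C2-O1-HO1"),
                                 .sample_mixture(Tn$hcap))
      a_ref <- coords[iH, ]
      t3 <- dihedral_angles(rbind(a_ref, coords[iO1, ], coords[iC2, ],
                                  coords[iC3, ]), matrix(1:4, 1L))
    } else {
      pO1 <- idx(i - 1L, "O1"); pC2 <- idx(i - 1L, "C2"); pC3 <- idx(i - 1L, "C3")
      plab <- sequence[i - 1L]
      coords[iO1, ] <- place_atom(coords[pO1, ], coords[pC2, ], coords[pC3, ],
                                  B[["C3-O1'"]], .sample_angle(A, "C2-C3-O1'"),
                                  .sample_mixture(Tn$psi[[plab]]))
      coords[iC2, ] <- place_atom(coords[pC2, ], coords[pC3, ], coords[iO1, ],
                                  B[["O1-C2"]], .sample_angle(A, "C3-O1'-C2"),
                                  .sample_mixture(Tn$omega[[plab]]))
      t3 <- .sample_mixture(Tn$phi[[lab]])
      coords[iC3, ] <- place_atom(coords[pC3, ], coords[iO1, ], coords[iC2, ],
                                  B[["C2-C3"]], .sample_angle(A, "O1-C2-C3"), t3)
      a_ref <- coords[pC3, ]
    }
    sgn <- .STEREO_BRANCH_SIGN[[lab]]
    iH5 <- idx(i, "H5"); iC4 <- idx(i, "C4")
    coords[iH5, ] <- place_atom(a_ref, coords[iO1, ], coords[iC2, ],
                                B[["C2-H5"]], .sample_angle(A, "O1-C2-H5"),
                                t3 + sgn * 2 * pi / 3)
    coords[iC4, ] <- place_atom(a_ref, coords[iO1, ], coords[iC2, ],
                                B[["C2-C4"]], .sample_angle(A, "O1-C2-C4"),
                                t3 - sgn * 2 * pi / 3)
    chi <- .sample_mixture(Tn$methyl)
    for (jj in 1:3) {
      iH <- idx(i, c("H6", "H7", "H8")[jj])
      coords[iH, ] <- place_atom(coords[iO1, ], coords[iC2, ], coords[iC4, ],
                                 B[["C4-H"]], .sample_angle(A, "C2-C4-H"),
                                 chi + (jj - 1L) * 2 * pi / 3)
    }
    iO2 <- idx(i, "O2")
    coords[iO2, ] <- place_atom(coords[iO1, ], coords[iC2, ], coords[iC3, ],
                                B[["C3-O2"]], .sample_angle(A, "C2-C3-O2"),
                                .sample_mixture(Tn$o2))
    if (i == n) {
      iO3 <- idx(i, "O3"); iHO3 <- idx(i, "HO3")
      coords[iO3, ] <- place_atom(coords[iO1, ], coords[iC2, ], coords[iC3, ],
                                  B[["C3-O3"]], .sample_angle(A, "C2-C3-O3"),
                                  .sample_mixture(Tn$o3))
      coords[iHO3, ] <- place_atom(coords[iC2, ], coords[iC3, ], coords[iO3, ],
                                   B[["O3-HO3"]], .sample_angle(A, "C3-O3-HO3"),
                                   .sample_mixture(Tn$ho3))
    }
  }
  coords
}

#' Generate an ensemble of independent frames
#'
#' Each frame contains `n_chains` freshly grown chains, randomly rotated
#' and placed uniformly in the periodic box, paired with the CG
#' configuration obtained by [map_to_cg()].
#'
#' @param params A [generator_params()].
#' @param composition Type-scheme flag passed to [map_to_cg()].
#' @param n_frames Override of the frame count (default from the schedule).
#' @param excluded_volume If `TRUE`, re-draw a chain placement while any two
#'   beads of different chains are closer than `core` (soft-core rejection).
#' @param core Hard-core tolerance (nm) for the rejection pass.
#' @return List of class `"pla_ensemble"`: frames, each with `aa` and `cg`;
#'   `params` attached as an attribute.
#' @export
pack_frames <- function(params, composition = "homopolymer",
                        n_frames = NULL, excluded_volume = FALSE,
                        core = 0.2) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(n_frames)) n_frames <- params$n_frames
  set.seed(params$seed)
  sys <- params$topology
  box <- params$box
  if (excluded_volume) {
    min_vol <- params$n_chains * (4 / 3) * pi * core^3
    if (prod(box) < min_vol) stop("box too small to pack chains at the hard-core tolerance")
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    coords <- matrix(NA_real_, sys$total_atoms, 3L)
    placed_beads <- NULL
    for (ci in seq_len(params$n_chains)) {
      ch_coords <- sample_chain(params, params$sequences[[ci]])
      for (attempt in seq_len(200L)) {
        R <- random_rotation()
        shift <- stats::runif(3L) * box
        cc <- ch_coords %*% t(R)
        cc <- sweep(cc, 2L, colMeans(cc) - shift, `-`)
        if (!excluded_volume || is.null(placed_beads)) break
        ch <- sys$chains[[ci]]
        beads <- rowsum(cc * ch$atoms$mass, ch$atoms$monomer) /
          as.vector(rowsum(ch$atoms$mass, ch$atoms$monomer))
        d <- .min_image_dist(beads, placed_beads, box)
        if (min(d) >= core) break
        if (attempt == 200L) stop("could not place chain ", ci,
                                  " without core overlap; box too small")
      }
      idx <- sys$atom_offsets[ci] + seq_len(sys$chains[[ci]]$n_atoms)
      coords[idx, ] <- cc
      if (excluded_volume) {
        ch <- sys$chains[[ci]]
        beads <- rowsum(cc * ch$atoms$mass, ch$atoms$monomer) /
          as.vector(rowsum(ch$atoms$mass, ch$atoms$monomer))
        placed_beads <- rbind(placed_beads, beads)
      }
    }
    aa <- atomistic_config(coords, box, sys)
    frames[[f]] <- list(aa = aa, cg = map_to_cg(aa, composition))
  }
  structure(frames, class = "pla_ensemble", params = params)
}

# all pairwise minimum-image distances between two point sets
.min_image_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (d in 1:3) {
    dd <- outer(a[, d], b[, d], `-`)
    dd <- dd - box[d] * round(dd / box[d])
    out <- out + dd * dd
  }
  sqrt(out)
}

#' Reference (ground-truth) distributions of the generator
#'
#' Analytic densities for every torsion class and stereo label, the exact
#' bond lengths, the bending-angle means/sd, and a semi-analytic
#' internal-distance expectation obtained by large-sample simulation with a
#' fixed oracle seed (independent of the ensemble's frame schedule).
#'
#' @param params A [generator_params()].
#' @param n_oracle_chains Chains simulated for the internal-distance
#'   reference.
#' @param oracle_seed Fixed seed for the reference simulation.
#' @return List with `torsion_density(class, label)` (a function of angle in
#'   radians), `bonds`, `angles`, and `internal_distances` (data frame
#'   `n`, `rn2_over_n`).
#' @export
generator_reference <- function(params, n_oracle_chains = 200L,
                                oracle_seed = 20240301L) {
  stopifnot(inherits(params, "generator_params"))
  td <- function(class, label = "L") {
    mx <- params$torsions[[class]]
    if (!is.null(mx$modes)) return(function(x) mixture_density(x, mx))
    mx <- mx[[label]]
    function(x) mixture_density(x, mx)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(oracle_seed)
  seq1 <- params$sequences[[1L]]
  chain <- build_chain(seq1)
  bb <- chain$backbone
  nb <- length(bb)
  acc <- numeric(nb - 1L); cnt <- numeric(nb - 1L)
  for (r in seq_len(n_oracle_chains)) {
    cc <- sample_chain(params, seq1)[bb, , drop = FALSE]
    for (n in seq_len(nb - 1L)) {
      d <- cc[seq_len(nb - n) + n, , drop = FALSE] - cc[seq_len(nb - n), , drop = FALSE]
      acc[n] <- acc[n] + sum(d * d)
      cnt[n] <- cnt[n] + (nb - n)
    }
  }
  internal <- data.frame(n = seq_len(nb - 1L),
                         rn2_over_n = acc / cnt / seq_len(nb - 1L))
  list(torsion_density = td, bonds = params$bonds, angles = params$angles,
       internal_distances = internal)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
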