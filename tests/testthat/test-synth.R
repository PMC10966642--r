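test_that("generated chains have exact bond lengths and correct chirality", {
  seqs <- c("L", "D", "D", "L", "L")
  p <- tiny_params(1L, 5L, sequences = list(seqs))
  set.seed(41)
  cc <- sample_chain(p, seqs)
  ch <- build_chain(seqs)
  bl <- sqrt(rowSums((cc[ch$bonds[, 1], ] - cc[ch$bonds[, 2], ])^2))
  # every realized bond equals one of the specified lengths exactly
  expect_true(all(vapply(bl, function(b) {
    any(abs(b - unlist(p$bonds)) < 1e-9)
  }, logical(1))))
  cfg <- atomistic_config(cc, p$box, ch)
  expect_identical(vapply(1:5, function(m) chirality_label(cfg, m),
                          character(1)), seqs)
})

test_that("frame schedule and seeding behave as configured", {
  p <- generator_params(n_chains = 1, n_monomers = 3,
                        duration = 1e6, save_interval = 200, seed = 1)
  expect_equal(p$n_frames, 5000L)
  p2 <- generator_params(n_chains = 1, n_monomers = 3,
                         duration = 1000, save_interval = 200, seed = 1)
  expect_equal(p2$n_frames, 5L)
  e1 <- pack_frames(p2)
  expect_length(e1, 5L)
  e2 <- pack_frames(p2)
  expect_equal(e1[[3]]$aa$coords, e2[[3]]$aa$coords)   # same seed
  p3 <- generator_params(n_chains = 1, n_monomers = 3,
                         duration = 1000, save_interval = 200, seed = 2)
  e3 <- pack_frames(p3)
  expect_gt(max(abs(e1[[1]]$aa$coords - e3[[1]]$aa$coords)), 1e-6)
})

test_that("sampled torsions follow the analytic mixture density", {
  n_mono <- 40L
  p <- generator_params(n_chains = 1, n_monomers = n_mono,
                        duration = 200, save_interval = 200, seed = 5)
  ch <- build_chain(rep("L", n_mono))
  dc <- dihedral_classes(ch)
  quads <- ch$dihedrals[dc$class == "phi", ]
  set.seed(77)
  draws <- unlist(lapply(1:120, function(i) {
    dihedral_angles(sample_chain(p, rep("L", n_mono)), quads)
  }))
  expect_gte(length(draws), 4000L)
  bins <- seq(-pi, pi, length.out = 37)
  counts <- hist(draws, breaks = bins, plot = FALSE)$counts
  mx <- p$torsions$phi$L
  probs <- vapply(seq_len(36), function(b) {
    stats::integrate(function(x) mixture_density(x, mx),
                     bins[b], bins[b + 1])$value
  }, numeric(1))
  expected <- length(draws) * probs
  # each bin within 3.5 sigma multinomial bands (plus a small floor)
  sd_bin <- sqrt(pmax(expected, 1))
  expect_true(all(abs(counts - expected) < 3.5 * sd_bin + 3))
  # mixture density integrates to 1
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("L and D torsion statistics are mirror images", {
  n_mono <- 30L
  p <- generator_params(n_chains = 1, n_monomers = n_mono,
                        duration = 200, save_interval = 200, seed = 5)
  ch <- build_chain(rep("L", n_mono))
  quads <- ch$dihedrals[dihedral_classes(ch)$class == "phi", ]
  set.seed(12)
  phi_L <- unlist(lapply(1:40, function(i)
    dihedral_angles(sample_chain(p, rep("L", n_mono)), quads)))
  set.seed(12)
  phi_D <- unlist(lapply(1:40, function(i)
    dihedral_angles(sample_chain(p, rep("D", n_mono)), quads)))
  # antisymmetric mixture: means of sin(phi) are opposite
  expect_lt(abs(mean(sin(phi_L)) + mean(sin(phi_D))), 0.05)
  expect_lt(abs(mean(cos(phi_L)) - mean(cos(phi_D))), 0.05)
})

test_that("sampled bending angles recover the configured mean and sd", {
  n_mono <- 50L
  p <- generator_params(n_chains = 1, n_monomers = n_mono,
                        duration = 200, save_interval = 200, seed = 5)
  ch <- build_chain(rep("L", n_mono))
  nm <- ch$atoms$name
  tri <- ch$angles[nm[ch$angles[, 1]] == "O1" & nm[ch$angles[, 2]] == "C2" &
                   nm[ch$angles[, 3]] == "C3", , drop = FALSE]
  set.seed(13)
  th <- unlist(lapply(1:40, function(i)
    bending_angles(sample_chain(p, rep("L", n_mono)), tri)))
  spec <- p$angles[["O1-C2-C3"]]
  expect_lt(abs(mean(th) - spec[1]), 0.01)
  expect_lt(abs(sd(th) - spec[2]), 0.05 * spec[2] + 0.002)
})

test_that("generated ensembles survive the codec roundtrip at scale", {
  ens <- tiny_ensemble(n_frames = 2, n_chains = 2, n_monomers = 5)
  data <- encode_dataset(ens, "homopolymer", codec_scales(s = 5))
  sys <- attr(ens, "params")$topology
  for (i in seq_len(dim(data$inputs)[1])) {
    f <- data$frame[i]; ci <- data$chain[i]
    ch <- sys$chains[[ci]]
    arange <- sys$atom_offsets[ci] + seq_len(ch$n_atoms)
    mrange <- sys$monomer_offsets[ci] + seq_len(ch$n_monomers)
    dec <- decode_vectors(data$targets[i, , ], data$samples[[i]], ch,
                          ens[[f]]$cg$Q[mrange, , drop = FALSE])
    expect_equal(dec, ens[[f]]$aa$coords[arange, ], tolerance = 1e-9)
  }
})

test_that("the generator reference is reproducible and normalized", {
  p <- tiny_params(1L, 8L)
  ref1 <- generator_reference(p, n_oracle_chains = 10)
  ref2 <- generator_reference(p, n_oracle_chains = 10)
  expect_equal(ref1$internal_distances, ref2$internal_distances)
  dens <- ref1$torsion_density("phi", "L")
  expect_equal(stats::integrate(dens, -pi, pi)$value, 1, tolerance = 1e-6)
  expect_equal(nrow(ref1$internal_distances), 3 * 8 - 1)
})
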