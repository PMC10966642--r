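test_that("CG mapping places beads at monomer centers of mass", {
  # two equal-mass atoms: bead at the midpoint
  ch <- build_chain("L")
  m <- ch$atoms$mass
  coords <- matrix(0, ch$n_atoms, 3)
  coords[, 1] <- seq_len(ch$n_atoms)
  cfg <- atomistic_config(coords, c(20, 20, 20), ch)
  cg <- map_to_cg(cfg)
  expect_equal(cg$Q[1, 1], sum(m * coords[, 1]) / sum(m))
  # linearity: translating all atoms translates the bead
  cfg2 <- cfg; cfg2$coords <- sweep(cfg$coords, 2, c(1, -2, 3), `+`)
  expect_equal(map_to_cg(cfg2)$Q, cg$Q + rep(c(1, -2, 3), each = nrow(cg$Q)))
})

test_that("bead counts and type schemes match the bookkeeping", {
  sys <- build_system(3, rep("L", 10))
  coords <- matrix(rnorm(sys$total_atoms * 3), ncol = 3)
  cg <- map_to_cg(atomistic_config(coords, c(50, 50, 50), sys))
  expect_equal(nrow(cg$Q), 30L)
  expect_equal(assign_types(sys, "homopolymer")$k, 3L)
  expect_equal(assign_types(sys, "copolymer")$k, 4L)
  expect_equal(assign_types(sys, "combined")$k, 6L)
  expect_error(assign_types(sys, "blend"), "unknown")
  ty <- assign_types(sys, "homopolymer")
  # chain ends get their own types
  expect_equal(as.integer(table(ty$types)[c("1", "2", "3")]), c(24L, 3L, 3L))
  # copolymer: L/D interiors distinct, shared ends
  seqs <- random_copolymer_sequence(10, 0.5, 2, rng_seed = 3)
  sys2 <- build_system(2, seqs)
  ty2 <- assign_types(sys2, "copolymer")
  expect_setequal(unique(ty2$types), 1:4)
})

test_that("encoding yields the padded tensor layout", {
  fx <- tiny_encoded(rep("L", 4))
  enc <- fx$enc
  expect_equal(dim(enc$input), c(fx$scales$S, 3 + 3))
  expect_equal(dim(enc$target), c(fx$scales$S, 3))
  n_rows <- fx$chain$n_atoms
  expect_equal(sum(enc$mask), n_rows)
  # padded rows are exactly zero
  expect_true(all(enc$input[!enc$mask, ] == 0))
  expect_true(all(enc$target[!enc$mask, ] == 0))
  # scaled targets lie in [-1, 1]
  expect_true(all(abs(enc$target) <= 1))
  # 100-mer layout: 1024 rows, 903 informative
  sc100 <- codec_scales(s = 100)
  expect_equal(sc100$S, 1024L)
  expect_equal(9 * 100 + 3, 903)
  # 30-mer in the 100-mer layout: 273 informative rows, 751 zero rows
  expect_equal(1024 - 273, 751)
})

test_that("codec roundtrip is lossless and CG-consistent", {
  for (seqs in list(rep("L", 5), c("D", "D", "L", "D"))) {
    fx <- tiny_encoded(seqs)
    dec <- decode_vectors(fx$enc$target, fx$enc, fx$chain, fx$cg$Q)
    expect_equal(dec, fx$coords, tolerance = 1e-9)
    # mapping the decoded structure returns the beads exactly, even for
    # arbitrary (non-target) vectors
    set.seed(9)
    fake <- matrix(runif(length(fx$enc$target), -0.5, 0.5),
                   nrow(fx$enc$target))
    dec2 <- decode_vectors(fake, fx$enc, fx$chain, fx$cg$Q)
    cg2 <- map_to_cg(atomistic_config(dec2, fx$params$box, fx$chain))
    expect_lt(max(abs(cg2$Q - fx$cg$Q)), 1e-6)
    # zero vectors collapse each monomer onto its bead
    dec0 <- decode_vectors(matrix(0, nrow(fx$enc$target), 3), fx$enc,
                           fx$chain, fx$cg$Q)
    for (m in seq_along(seqs)) {
      sel <- fx$chain$atoms$monomer == m
      expect_lt(max(abs(sweep(dec0[sel, , drop = FALSE], 2, fx$cg$Q[m, ]))),
                1e-12)
    }
  }
})

test_that("encoding is invariant under rigid translation", {
  fx <- tiny_encoded(rep("L", 4))
  shift <- c(2.5, -1.0, 0.75)
  coords2 <- sweep(fx$coords, 2, shift, `+`)
  cfg2 <- atomistic_config(coords2, fx$params$box, fx$chain)
  cg2 <- map_to_cg(cfg2)
  enc2 <- encode_chain(fx$chain, coords2, cg2$Q, fx$types$types, 3, fx$scales)
  expect_equal(enc2$target, fx$enc$target, tolerance = 1e-12)
  expect_equal(enc2$input, fx$enc$input, tolerance = 1e-12)
})

test_that("out-of-range vectors are rejected with the offending atom", {
  fx <- tiny_encoded(rep("L", 4))
  bad <- fx$coords
  bad[5, ] <- bad[5, ] + 5   # tear one atom away from its parent
  expect_error(
    encode_chain(fx$chain, bad, fx$cg$Q, fx$types$types, 3, fx$scales),
    "out of \\[-1, 1\\].*atom")
})

test_that("fragmenting splits into consecutive windows that decode to the whole", {
  fx <- tiny_encoded(rep("L", 9), seed = 13)
  frags <- fragment_chain(fx$chain, 4)
  expect_equal(lapply(frags, range), list(c(1, 4), c(5, 8), c(9, 9)))
  expect_equal(fragment_chain(fx$chain, 9), list(1:9))
  sc <- codec_scales(s = 4)
  rebuilt <- matrix(NA_real_, fx$chain$n_atoms, 3)
  for (fr in frags) {
    enc <- encode_chain(fx$chain, fx$coords, fx$cg$Q, fx$types$types, 3, sc,
                        monomers = fr)
    rebuilt[enc$rows, ] <- decode_vectors(enc$target, enc, fx$chain, fx$cg$Q)
  }
  expect_equal(rebuilt, fx$coords, tolerance = 1e-9)
  expect_error(encode_chain(fx$chain, fx$coords, fx$cg$Q, fx$types$types, 3, sc),
               "exceeds capacity")
})

test_that("scale inverse holds and scheme constants are recorded", {
  sc <- codec_scales(s = 20, vec_scale = 0.3, cg_scale = 1.5)
  x <- c(-0.2, 0, 0.11)
  expect_equal((x / sc$vec_scale) * sc$vec_scale, x)
  expect_equal(sc$S, 256L)
  expect_true(is.character(sc$scheme) && nzchar(sc$scheme))
})
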