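test_that("monomer templates have the lactic-acid constitution", {
  tl <- build_monomer_template("L", "interior")
  td <- build_monomer_template("D", "interior")
  expect_equal(nrow(tl$atoms), 9L)
  expect_equal(nrow(tl$bonds), 8L)
  # constitution is stereo-independent
  expect_identical(tl$atoms, td$atoms)
  expect_identical(tl$bonds, td$bonds)
  expect_identical(tl$chiral_center$substituents, c("O1", "C3", "C4", "H5"))
  # caps add 3 atoms in total per chain
  n_first <- nrow(build_monomer_template("L", "first")$atoms)
  n_last <- nrow(build_monomer_template("L", "last")$atoms)
  expect_equal((n_first - 9L) + (n_last - 9L), 3L)
  expect_error(build_monomer_template("X"), "stereo_label")
  expect_error(build_monomer_template("L", "middle"), "position_flag")
})

test_that("chain atom and bond counts follow 9n + 3 and acyclicity", {
  for (n in c(1L, 2L, 5L, 30L, 100L)) {
    ch <- build_chain(rep("L", n))
    expect_equal(ch$n_atoms, 9L * n + 3L)
    expect_equal(nrow(ch$bonds), ch$n_atoms - 1L)
  }
  expect_equal(build_chain(rep("L", 100))$n_atoms, 903L)
  expect_equal(build_chain(rep("L", 30))$n_atoms, 273L)
  expect_error(build_chain(character(0)), "at least one")
  expect_error(build_chain(c("L", "Q")), "only")
})

test_that("the bond graph is connected", {
  ch <- build_chain(c("L", "D", "L"))
  nb <- lapply(seq_len(ch$n_atoms), function(i) integer(0))
  for (r in seq_len(nrow(ch$bonds))) {
    a <- ch$bonds[r, 1]; b <- ch$bonds[r, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  seen <- logical(ch$n_atoms)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  expect_true(all(seen))
})

test_that("every dihedral is a bonded 4-path and every angle a 3-path", {
  ch <- build_chain(c("L", "L", "D"))
  key <- paste(pmin(ch$bonds[, 1], ch$bonds[, 2]),
               pmax(ch$bonds[, 1], ch$bonds[, 2]))
  is_bond <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% key
  expect_true(all(is_bond(ch$angles[, 1], ch$angles[, 2])))
  expect_true(all(is_bond(ch$angles[, 2], ch$angles[, 3])))
  expect_true(all(is_bond(ch$dihedrals[, 1], ch$dihedrals[, 2])))
  expect_true(all(is_bond(ch$dihedrals[, 2], ch$dihedrals[, 3])))
  expect_true(all(is_bond(ch$dihedrals[, 3], ch$dihedrals[, 4])))
  # four distinct atoms per dihedral
  expect_true(all(apply(ch$dihedrals, 1, function(q) length(unique(q)) == 4L)))
})

test_that("dihedral enumeration is invariant under direction reversal", {
  ch <- build_chain(c("L", "D", "L", "L"))
  canon <- function(m) {
    m <- unname(m)
    rev <- m[, 4] < m[, 1]
    m[rev, ] <- m[rev, c(4, 3, 2, 1), drop = FALSE]
    dimnames(m) <- NULL
    m[order(m[, 1], m[, 2], m[, 3], m[, 4]), ]
  }
  # reversing every quadruple and re-canonicalizing gives the same set
  flipped <- ch$dihedrals[, 4:1]
  expect_equal(canon(ch$dihedrals), canon(flipped))
})

test_that("chiral centers reference each monomer's own alpha-carbon frame", {
  ch <- build_chain(rep("L", 4))
  for (m in 1:4) {
    row <- ch$chiral_centers[m, ]
    expect_true(all(ch$atoms$monomer[row] == m))
    expect_identical(ch$atoms$name[row], c("C2", "O1", "C3", "C4", "H5"))
  }
})

test_that("system totals match the tabulated bookkeeping", {
  expect_equal(build_system(70, rep("L", 100))$total_atoms, 63210L)
  expect_equal(build_system(70, rep("L", 30))$total_atoms, 19110L)
  expect_equal(build_system(1, rep("L", 1))$total_atoms, 12L)
  expect_equal(build_system(70, rep("L", 100))$total_monomers, 7000L)
  expect_error(build_system(0, rep("L", 5)), ">= 1")
  expect_error(build_system(3, list(rep("L", 5), rep("L", 5))), "per chain")
})

test_that("random copolymer sequences hit the exact D content", {
  s <- random_copolymer_sequence(100, 0.55, n_chains = 4, rng_seed = 1)
  expect_true(all(vapply(s, function(x) sum(x == "D"), integer(1)) == 55L))
  expect_true(all(vapply(s, identical, logical(1), s[[1]])))
  s2 <- random_copolymer_sequence(30, 0.16, n_chains = 6,
                                  per_chain_identical = FALSE, rng_seed = 2)
  expect_true(all(vapply(s2, function(x) sum(x == "D"), integer(1)) == 5L))
  expect_false(all(vapply(s2, identical, logical(1), s2[[1]])))
  expect_true(all(unlist(random_copolymer_sequence(20, 0, n_chains = 2)) == "L"))
  expect_error(random_copolymer_sequence(10, 1.5), "\\[0, 1\\]")
})

test_that("dihedral classes tag the backbone torsions with stereo context", {
  ch <- build_chain(c("L", "D", "L"))
  dc <- dihedral_classes(ch)
  expect_true(all(c("phi", "psi", "omega") %in% dc$class))
  # one phi / psi torsion per junction-bearing monomer
  expect_equal(sum(dc$class == "phi"), 2L)   # monomers 2..n
  expect_equal(sum(dc$class == "psi"), 2L)   # monomers 1..n-1
  phi_stereo <- dc$stereo[dc$class == "phi"]
  expect_identical(sort(phi_stereo), c("D", "L"))
  expect_true(all(is.na(dc$stereo[dc$class == "omega"])))
})

test_that("dihedral enumeration is invariant under atom relabeling", {
  ch <- build_chain(c("L", "D", "L"))
  set.seed(9)
  perm <- sample.int(ch$n_atoms)            # new label for each atom
  bonds_p <- matrix(perm[ch$bonds], ncol = 2)
  nb <- plabackmap:::.neighbour_list(
    t(apply(bonds_p, 1, sort)), ch$n_atoms)
  dih_p <- plabackmap:::.enumerate_dihedrals(
    t(apply(bonds_p, 1, sort)), nb)
  # map the permuted enumeration back and compare as sets
  inv <- integer(ch$n_atoms); inv[perm] <- seq_len(ch$n_atoms)
  back <- matrix(inv[dih_p], ncol = 4)
  canon <- function(m) {
    m <- unname(m)
    rev <- m[, 4] < m[, 1] | (m[, 4] == m[, 1] & m[, 3] < m[, 2])
    m[rev, ] <- m[rev, c(4, 3, 2, 1), drop = FALSE]
    dimnames(m) <- NULL
    m[order(m[, 1], m[, 2], m[, 3], m[, 4]), ]
  }
  expect_equal(canon(back), canon(ch$dihedrals))
})
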