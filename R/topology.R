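# Chemical model of poly(lactic acid) chains: monomer templates with a
# chiral alpha carbon, full bonded topology (bonds, bending angles,
# dihedrals), backbone trace and chiral-center bookkeeping.
#
# The interior repeat unit -O-CH(CH3)-C(=O)- has 9 atoms:
#   O1 (ester oxygen), C2 (alpha carbon), H5, C4 (methyl carbon),
#   H6 H7 H8 (methyl hydrogens), C3 (carbonyl carbon), O2 (carbonyl oxygen).
# Monomers are linked C3(i) -> O1(i+1).  The first monomer carries a
# hydroxyl hydrogen HO1 on O1 and the last monomer a terminal hydroxyl
# (O3, HO3) on C3, so a chain of n monomers has 9 n + 3 atoms.

.ATOM_MASS <- c(C = 12.011, O = 15.999, H = 1.008)

.INTERIOR_ATOMS <- data.frame(
  name    = c("O1", "C2", "H5", "C4", "H6", "H7", "H8", "C3", "O2"),
  element = c("O", "C", "H", "C", "H", "H", "H", "C", "O"),
  # traversal parent within the monomer (NA = monomer root)
  parent  = c(NA, "O1", "C2", "C2", "C4", "C4", "C4", "C2", "C3"),
  stringsAsFactors = FALSE
)

#' Build a PLA monomer template
#'
#' Returns the constitution of one lactic-acid repeat unit: its atoms (with
#' standard atomic masses), intra-monomer bonds, the chiral alpha carbon with
#' its four substituents, and the linking atoms towards the neighbouring
#' monomers.  The L and D templates are constitutionally identical; only the
#' handedness of the stereocenter differs, which is a property of coordinates,
#' not of the template.
#'
#' @param stereo_label `"L"` or `"D"`.
#' @param position_flag `"first"`, `"interior"` or `"last"`.  The first
#'   monomer carries a hydroxyl hydrogen `HO1` on the ester oxygen; the last
#'   monomer carries a terminal hydroxyl `O3`/`HO3` on the carbonyl carbon.
#' @return A list of class `"pla_monomer_template"` with elements `atoms`
#'   (data frame: `name`, `element`, `mass`, `parent`), `bonds` (character
#'   matrix of atom-name pairs), `chiral_center` (list with `center` and the
#'   four `substituents` in the fixed order O1, C3, C4, H5), `link_in`,
#'   `link_out`, `root`, `stereo_label` and `position_flag`.
#' @export
build_monomer_template <- function(stereo_label, position_flag = "interior") {
  if (!is.character(stereo_label) || length(stereo_label) != 1L ||
      !(stereo_label %in% c("L", "D"))) {
    stop("`stereo_label` must be \"L\" or \"D\", got: ",
         paste(utils::head(stereo_label), collapse = ", "))
  }
  if (!(position_flag %in% c("first", "interior", "last"))) {
    stop("`position_flag` must be one of \"first\", \"interior\", \"last\"")
  }
  atoms <- .INTERIOR_ATOMS
  if (position_flag == "first") {
    # hydroxyl hydrogen on the ester oxygen, placed right after the root
    atoms <- rbind(atoms[1L, ],
                   data.frame(name = "HO1", element = "H", parent = "O1"),
                   atoms[-1L, ])
  } else if (position_flag == "last") {
    atoms <- rbind(atoms,
                   data.frame(name = "O3",  element = "O", parent = "C3"),
                   data.frame(name = "HO3", element = "H", parent = "O3"))
  }
  rownames(atoms) <- NULL
  atoms$mass <- unname(.ATOM_MASS[atoms$element])
  bonded <- atoms$name[!is.na(atoms$parent)]
  bonds <- cbind(atoms$parent[!is.na(atoms$parent)], bonded)
  colnames(bonds) <- c("from", "to")
  structure(list(
    stereo_label  = stereo_label,
    position_flag = position_flag,
    atoms         = atoms[, c("name", "element", "mass", "parent")],
    bonds         = bonds,
    chiral_center = list(center = "C2",
                         substituents = c("O1", "C3", "C4", "H5")),
    link_in  = "O1",
    link_out = "C3",
    root     = "O1"
  ), class = "pla_monomer_template")
}

#' Build the bonded topology of one PLA chain
#'
#' Assembles monomer templates along a stereo-sequence, links consecutive
#' monomers via C3(i)-O1(i+1), and enumerates every bending angle (bonded
#' 3-path) and dihedral angle (bonded 4-path) of the resulting acyclic bond
#' graph.  Atom order follows the per-monomer codec traversal
#' O1 (root) -> C2 -> H5 -> C4 -> H6,H7,H8 -> C3 -> O2, with cap atoms
#' inserted at their parents.
#'
#' @param sequence Character vector of stereo labels (`"L"`/`"D"`), one per
#'   monomer.
#' @return A list of class `"pla_chain"` with: `sequence`, `n_monomers`,
#'   `n_atoms`, `atoms` (data frame: `name`, `element`, `mass`, `monomer`),
#'   `bonds`/`angles`/`dihedrals` (integer index matrices), `backbone`
#'   (ordered O1-C2-C3 indices), `chiral_centers` (matrix, one row per
#'   monomer: C2, O1, C3, C4, H5), `parent` (traversal parent per atom, 0 for
#'   monomer roots), `root_atoms` and `link_atoms` (per-monomer O1 and C3).
#' @export
build_chain <- function(sequence) {
  if (length(sequence) < 1L) stop("`sequence` must contain at least one monomer")
  sequence <- as.character(sequence)
  if (!all(sequence %in% c("L", "D"))) {
    stop("stereo sequence may only contain \"L\" and \"D\"")
  }
  n <- length(sequence)

  atom_list <- vector("list", n)
  parent <- integer(0)
  offset <- 0L
  roots <- integer(n)
  links <- integer(n)
  chiral <- matrix(NA_integer_, n, 5L,
                   dimnames = list(NULL, c("C2", "O1", "C3", "C4", "H5")))
  extra_bonds <- NULL
  for (i in seq_len(n)) {
    flag <- if (n == 1L) "last" else if (i == 1L) "first"
            else if (i == n) "last" else "interior"
    # a single-monomer chain still needs both caps
    tmpl <- build_monomer_template(sequence[i], flag)
    atoms <- tmpl$atoms
    if (n == 1L) {  # add the HO1 cap manually to the 'last' template
      atoms <- rbind(atoms[1L, ],
                     data.frame(name = "HO1", element = "H", mass = .ATOM_MASS[["H"]],
                                parent = "O1"),
                     atoms[-1L, ])
      rownames(atoms) <- NULL
    }
    local_idx <- stats::setNames(seq_len(nrow(atoms)) + offset, atoms$name)
    p <- ifelse(is.na(atoms$parent), 0L, local_idx[atoms$parent])
    parent <- c(parent, as.integer(p))
    roots[i] <- local_idx[["O1"]]
    links[i] <- local_idx[["C3"]]
    chiral[i, ] <- local_idx[c("C2", "O1", "C3", "C4", "H5")]
    if (i > 1L) extra_bonds <- rbind(extra_bonds, c(links[i - 1L], roots[i]))
    atom_list[[i]] <- data.frame(name = atoms$name, element = atoms$element,
                                 mass = atoms$mass, monomer = i)
    offset <- offset + nrow(atoms)
  }
  atoms <- do.call(rbind, atom_list)
  rownames(atoms) <- NULL
  n_atoms <- nrow(atoms)

  tree_bonds <- cbind(parent[parent > 0L], which(parent > 0L))
  bonds <- rbind(tree_bonds, extra_bonds)
  bonds <- t(apply(bonds, 1L, sort))
  bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
  storage.mode(bonds) <- "integer"

  nb <- .neighbour_list(bonds, n_atoms)
  angles <- .enumerate_angles(nb)
  dihedrals <- .enumerate_dihedrals(bonds, nb)

  bb <- as.vector(t(chiral[, c("O1", "C2", "C3")]))

  structure(list(
    sequence = sequence, n_monomers = n, n_atoms = n_atoms,
    atoms = atoms, bonds = bonds, angles = angles, dihedrals = dihedrals,
    backbone = bb, chiral_centers = chiral,
    parent = parent, root_atoms = roots, link_atoms = links
  ), class = "pla_chain")
}

.neighbour_list <- function(bonds, n_atoms) {
  nb <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

.enumerate_angles <- function(nb) {
  out <- vector("list", length(nb))
  for (b in seq_along(nb)) {
    ns <- sort(nb[[b]])
    if (length(ns) < 2L) next
    pairs <- utils::combn(ns, 2L)
    out[[b]] <- cbind(pairs[1L, ], b, pairs[2L, ])
  }
  ang <- do.call(rbind, out)
  storage.mode(ang) <- "integer"
  colnames(ang) <- c("i", "j", "k")
  ang[order(ang[, 2L], ang[, 1L], ang[, 3L]), , drop = FALSE]
}

.enumerate_dihedrals <- function(bonds, nb) {
  out <- list()
  for (r in seq_len(nrow(bonds))) {
    b <- bonds[r, 1L]; c <- bonds[r, 2L]
    as <- setdiff(nb[[b]], c); ds <- setdiff(nb[[c]], b)
    if (!length(as) || !length(ds)) next
    g <- expand.grid(a = as, d = ds)
    g <- g[g$a != g$d, , drop = FALSE]
    if (!nrow(g)) next
    quad <- cbind(g$a, b, c, g$d)
    # canonical direction: smaller terminal atom first
    rev <- quad[, 4L] < quad[, 1L]
    quad[rev, ] <- quad[rev, c(4L, 3L, 2L, 1L), drop = FALSE]
    out[[length(out) + 1L]] <- quad
  }
  dih <- do.call(rbind, out)
  dih <- dih[order(dih[, 2L], dih[, 3L], dih[, 1L], dih[, 4L]), , drop = FALSE]
  storage.mode(dih) <- "integer"
  colnames(dih) <- c("i", "j", "k", "l")
  dih
}

#' Build a multi-chain system topology
#'
#' @param n_chains Number of chains (positive integer).
#' @param sequences Either a single stereo sequence (recycled for every
#'   chain) or a list of per-chain sequences of equal length in monomers.
#' @return A list of class `"pla_system"` with `chains` (list of
#'   [build_chain()] topologies), `atom_offsets`/`monomer_offsets` (global
#'   index offsets per chain), `total_atoms`, `total_monomers`, `n_chains`.
#' @export
build_system <- function(n_chains, sequences) {
  if (length(n_chains) != 1L || n_chains < 1L) stop("`n_chains` must be >= 1")
  n_chains <- as.integer(n_chains)
  if (!is.list(sequences)) sequences <- rep(list(sequences), n_chains)
  if (length(sequences) != n_chains) {
    stop("need one stereo sequence per chain (got ", length(sequences),
         " for ", n_chains, " chains)")
  }
  # identical stereo-sequences share one built topology
  keys <- vapply(sequences, paste, character(1), collapse = "")
  uniq <- !duplicated(keys)
  built <- lapply(sequences[uniq], build_chain)
  chains <- built[match(keys, keys[uniq])]
  n_at <- vapply(chains, `[[`, integer(1), "n_atoms")
  n_mo <- vapply(chains, `[[`, integer(1), "n_monomers")
  structure(list(
    chains = chains,
    atom_offsets = c(0L, cumsum(n_at))[seq_len(n_chains)],
    monomer_offsets = c(0L, cumsum(n_mo))[seq_len(n_chains)],
    total_atoms = sum(n_at), total_monomers = sum(n_mo),
    n_chains = n_chains
  ), class = "pla_system")
}

#' Random copolymer stereo-sequences with fixed D content
#'
#' Generates per-chain stereo sequences containing exactly
#' `round(d_fraction * n_monomers)` D monomers each.  With
#' `per_chain_identical = TRUE` one random arrangement is drawn and shared by
#' all chains (the 100-mer protocol); otherwise every chain gets an
#' independent arrangement at the same D content (the 30-mer protocol).
#'
#' @param n_monomers Monomers per chain.
#' @param d_fraction Fraction of D monomers in `[0, 1]`.
#' @param n_chains Number of chains.
#' @param per_chain_identical Share one arrangement across chains?
#' @param rng_seed Optional integer seed.
#' @return List of character vectors, one per chain.
#' @export
random_copolymer_sequence <- function(n_monomers, d_fraction, n_chains = 1L,
                                      per_chain_identical = TRUE,
                                      rng_seed = NULL) {
  if (d_fraction < 0 || d_fraction > 1) stop("`d_fraction` must lie in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_d <- round(d_fraction * n_monomers)
  draw <- function() {
    s <- rep("L", n_monomers)
    if (n_d > 0L) s[sample.int(n_monomers, n_d)] <- "D"
    s
  }
  if (per_chain_identical) {
    rep(list(draw()), n_chains)
  } else {
    replicate(n_chains, draw(), simplify = FALSE)
  }
}

#' Tag every dihedral of a chain with a named class
#'
#' Classes are derived from the atom-name pattern along the 4-path and are
#' used to pool dihedrals for distribution analysis: `"phi"`
#' (C3-O1-C2-C3, backbone rotation about O1-C2 at the stereocenter),
#' `"psi"` (O1-C2-C3-O1, about C2-C3), `"omega"` (C2-C3-O1-C2, the ester
#' linkage) plus side-group classes named by their atom pattern.
#'
#' @param chain A [build_chain()] topology.
#' @return Data frame with one row per dihedral: `class`, `stereo` (label of
#'   the monomer owning the alpha carbon on the central bond, `NA` when none)
#'   and `pair` (two-letter junction label, e.g. `"LD"`, for inter-monomeric
#'   dihedrals).
#' @export
dihedral_classes <- function(chain) {
  stopifnot(inherits(chain, "pla_chain"))
  dih <- chain$dihedrals
  nm <- chain$atoms$name
  mono <- chain$atoms$monomer
  key <- matrix(nm[dih], ncol = 4L)
  fwd <- apply(key, 1L, paste, collapse = "-")
  bwd <- apply(key[, 4:1, drop = FALSE], 1L, paste, collapse = "-")
  canon <- ifelse(fwd <= bwd, fwd, bwd)
  cls <- rep(NA_character_, nrow(dih))
  cls[canon == "C3-C2-O1-C3" | canon == "C3-O1-C2-C3"] <- "phi"
  cls[canon == "O1-C2-C3-O1"] <- "psi"
  cls[canon == "C2-C3-O1-C2" | canon == "C2-O1-C3-C2"] <- "omega"
  cls[is.na(cls)] <- canon[is.na(cls)]
  # stereo context: the monomer of the alpha carbon C2 on the central bond
  ctx <- rep(NA_character_, nrow(dih))
  for (col in c(2L, 3L)) {
    is_c2 <- nm[dih[, col]] == "C2" & is.na(ctx)
    ctx[is_c2] <- chain$sequence[mono[dih[is_c2, col]]]
  }
  m1 <- mono[dih[, 1L]]; m4 <- mono[dih[, 4L]]
  pair <- ifelse(m1 == m4, NA_character_,
                 paste0(chain$sequence[pmin(m1, m4)], chain$sequence[pmax(m1, m4)]))
  data.frame(class = cls, stereo = ctx, pair = pair, stringsAsFactors = FALSE)
}

#' @export
print.pla_chain <- function(x, ...) {
  cat("PLA chain: ", x$n_monomers, " monomers (",
      sum(x$sequence == "L"), " L / ", sum(x$sequence == "D"), " D), ",
      x$n_atoms, " atoms, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals\n", sep = "")
  invisible(x)
}

#' @export
print.pla_system <- function(x, ...) {
  cat("PLA system: ", x$n_chains, " chains, ", x$total_monomers,
      " monomers, ", x$total_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Serialize a chain topology as JSON
#'
#' Documented schema: `schema` (version tag), `sequence`, `atoms` (name,
#' element, mass, monomer), `bonds`/`angles`/`dihedrals` (1-based index
#' tuples), `backbone`, `chiral_centers`.
#'
#' @param chain A [build_chain()] topology.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
topology_to_json <- function(chain, path = NULL) {
  stopifnot(inherits(chain, "pla_chain"))
  obj <- list(
    schema = "pla-topology-1",
    sequence = chain$sequence,
    atoms = chain$atoms,
    bonds = unname(chain$bonds),
    angles = unname(chain$angles),
    dihedrals = unname(chain$dihedrals),
    backbone = chain$backbone,
    chiral_centers = unname(chain$chiral_centers))
  txt <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a chain topology from its JSON serialization
#'
#' Validates the schema tag and rebuilds the topology from the stored
#' stereo sequence (the bonded terms are regenerated, then checked against
#' the stored ones).
#'
#' @param path File path or JSON string.
#' @return A [build_chain()] topology.
#' @export
topology_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, "pla-topology-1")) {
    stop("unrecognized topology schema: ", obj$schema)
  }
  chain <- build_chain(obj$sequence)
  if (!identical(unname(chain$bonds), matrix(as.integer(obj$bonds),
                                             ncol = 2L))) {
    stop("stored bond list does not match the rebuilt topology")
  }
  chain
}

#' Export a minimal force-field-free topology listing
#'
#' Writes the atoms and bonds sections of a chain in a GROMACS-itp-like
#' plain-text layout.  No force-field parameters are emitted.
#'
#' @param chain A [build_chain()] topology.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_listing <- function(chain, path) {
  stopifnot(inherits(chain, "pla_chain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("; plabackmap chain topology (constitution only, no force field)", con)
  writeLines("[ atoms ]", con)
  writeLines(sprintf("%6d %-4s %6d %-4s %10.4f",
                     seq_len(chain$n_atoms), chain$atoms$element,
                     chain$atoms$monomer, chain$atoms$name, chain$atoms$mass), con)
  writeLines("[ bonds ]", con)
  writeLines(sprintf("%6d %6d", chain$bonds[, 1L], chain$bonds[, 2L]), con)
  invisible(path)
}
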