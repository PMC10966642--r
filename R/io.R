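# Coordinate and sequence file I/O.  GRO is the primary coordinate dialect
# (fixed-column, nm, 3 decimals); multi-frame files are concatenated GRO
# blocks.  Stereo-sequence files carry one line of L/D letters per chain.

#' Read a (possibly multi-frame) GRO coordinate file
#'
#' @param path File path.
#' @return List of frames; each frame is a list with `title`, `atom_names`,
#'   `res_ids`, `res_names`, `coords` (N x 3, nm) and `box` (length 3).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i, ": missing atom count")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed atom count at line ", i + 1L, ": '", lines[i + 1L], "'")
    if (i + 1L + nat + 1L > length(lines)) {
      stop("truncated GRO file: header at line ", i, " declares ", nat,
           " atoms but the file ends early")
    }
    at <- lines[i + 1L + seq_len(nat)]
    res_ids <- as.integer(substr(at, 1L, 5L))
    res_names <- trimws(substr(at, 6L, 10L))
    atom_names <- trimws(substr(at, 11L, 15L))
    x <- as.numeric(substr(at, 21L, 28L))
    y <- as.numeric(substr(at, 29L, 36L))
    z <- as.numeric(substr(at, 37L, 44L))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
      stop("malformed coordinate record at line ", i + 1L + bad)
    }
    box <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1L]])[1:3]
    if (anyNA(box)) stop("malformed box line at line ", i + 2L + nat)
    frames[[length(frames) + 1L]] <-
      list(title = title, atom_names = atom_names, res_ids = res_ids,
           res_names = res_names, coords = cbind(x, y, z), box = box)
    i <- i + nat + 3L
  }
  frames
}

#' Write one or more frames to a GRO file
#'
#' Positions are written in nm at the format's 3-decimal precision; monomers
#' map to residues (1-based), stereo labels to residue names `LLA`/`DLA`.
#'
#' @param configs An [atomistic_config()] or list of them.
#' @param path Output file path.
#' @param title Title line (a provenance header is appended).
#' @return `path`, invisibly.
#' @export
write_gro <- function(configs, path, title = "plabackmap configuration") {
  if (inherits(configs, "aa_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    sys <- .as_system(cfg$topology)
    nm <- character(sys$total_atoms); rid <- integer(sys$total_atoms)
    rnm <- character(sys$total_atoms)
    for (ci in seq_len(sys$n_chains)) {
      ch <- sys$chains[[ci]]
      idx <- sys$atom_offsets[ci] + seq_len(ch$n_atoms)
      nm[idx] <- ch$atoms$name
      rid[idx] <- sys$monomer_offsets[ci] + ch$atoms$monomer
      rnm[idx] <- ifelse(ch$sequence[ch$atoms$monomer] == "L", "LLA", "DLA")
    }
    writeLines(title, con)
    writeLines(sprintf("%5d", sys$total_atoms), con)
    atom_id <- seq_len(sys$total_atoms) %% 100000L
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       rid %% 100000L, rnm, nm, atom_id,
                       cfg$coords[, 1L], cfg$coords[, 2L], cfg$coords[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", cfg$box[1L], cfg$box[2L], cfg$box[3L]), con)
  }
  invisible(path)
}

#' Read a stereo-sequence file
#'
#' One line of `L`/`D` letters per chain; blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @param topology Optional [build_system()] topology to validate against.
#' @return List of character vectors, one per chain.
#' @export
read_sequence_file <- function(path, topology = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  seqs <- lapply(lines, function(l) {
    s <- strsplit(gsub("\\s+", "", l), "")[[1L]]
    if (!all(s %in% c("L", "D"))) {
      stop("illegal character in stereo sequence '", l,
           "': only L and D are allowed")
    }
    s
  })
  if (!is.null(topology)) {
    sys <- .as_system(topology)
    if (length(seqs) != sys$n_chains) {
      stop("sequence file has ", length(seqs), " chains; topology has ", sys$n_chains)
    }
    for (ci in seq_along(seqs)) {
      if (length(seqs[[ci]]) != sys$chains[[ci]]$n_monomers) {
        stop("chain ", ci, ": sequence has ", length(seqs[[ci]]),
             " letters but the topology has ", sys$chains[[ci]]$n_monomers,
             " monomers")
      }
    }
  }
  seqs
}

#' Write a stereo-sequence file
#' @param sequences List of per-chain label vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_file <- function(sequences, path) {
  writeLines(vapply(sequences, paste, character(1), collapse = ""), path)
  invisible(path)
}
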