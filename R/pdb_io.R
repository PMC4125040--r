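#' PDB topology / multi-model trajectory I/O
#'
#' Minimal fixed-column PDB reader and writer sufficient for topologies
#' and multi-model trajectories of protein complexes.  Coordinates are
#' converted between the file's Angstrom convention and the package's
#' internal nanometre unit on the way in and out.  Solvent and common
#' counter-ion residues (HOH/SOL/WAT/NA/CL/K/MG) are dropped on read.
#'
#' @name pdb_io
NULL

SOLVENT_RESNAMES <- c("HOH", "SOL", "WAT", "TIP3", "SPC", "NA", "CL",
                      "NA+", "CL-", "K", "MG", "ION")

pdb_field <- function(lines, from, to) trimws(substr(lines, from, to))

element_from_name <- function(name) {
  # strip leading digits (e.g. "1HB2"), take the first alphabetic character;
  # good enough for standard protein atoms
  core <- sub("^[0-9]*", "", name)
  el <- toupper(substr(core, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Read a (multi-model) PDB file
#'
#' @param path PDB file.
#' @param drop_solvent drop water/ion residues (default TRUE).
#' @return list with `atoms` (data.frame) and `coords` (T x N x 3 array, nm).
#' @export
read_pdb <- function(path, drop_solvent = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign model index to every atom line
  model_break <- cumsum(trimws(rec) == "MODEL")
  model_of_atom <- model_break[is_atom]
  if (all(model_of_atom == 0)) model_of_atom <- rep(1L, sum(is_atom))

  al <- lines[is_atom]
  name <- pdb_field(al, 13, 16)
  resname <- pdb_field(al, 18, 20)
  chain <- pdb_field(al, 22, 22)
  resseq <- as.integer(pdb_field(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resseq)) {
    stop("malformed ATOM records in ", path)
  }
  elem <- pdb_field(al, 77, 78)
  elem <- ifelse(elem == "", element_from_name(name), toupper(elem))

  keep <- rep(TRUE, length(al))
  if (drop_solvent) keep <- !(resname %in% SOLVENT_RESNAMES)
  first_model <- model_of_atom == model_of_atom[1]
  atoms <- data.frame(
    name = name[first_model & keep],
    element = elem[first_model & keep],
    residue_index = resseq[first_model & keep],
    residue_name = resname[first_model & keep],
    chain_id = chain[first_model & keep],
    stringsAsFactors = FALSE
  )
  n <- nrow(atoms)

  models <- unique(model_of_atom)
  tt <- length(models)
  coords <- array(NA_real_, dim = c(tt, n, 3))
  for (m in seq_along(models)) {
    idx <- which(model_of_atom == models[m] & keep)
    if (length(idx) != n) {
      stop("model ", m, " in ", path, " has ", length(idx),
           " atoms, expected ", n)
    }
    coords[m, , 1] <- x[idx]
    coords[m, , 2] <- y[idx]
    coords[m, , 3] <- z[idx]
  }
  list(atoms = atoms, coords = coords * 0.1)  # Angstrom -> nm
}

#' Load a simulation into an `ensemble`
#'
#' Reads a topology PDB and zero or more coordinate (multi-model PDB)
#' files sharing its atom count and order, concatenating frames in source
#' order.  Frame times are synthesised as an arithmetic sequence
#' `t0_ns + (0:(T-1)) * dt_ns` because the PDB format carries no time
#' information; the defaults label frame i with i nanoseconds.
#'
#' @param topology_source path to the topology PDB.
#' @param coordinate_sources character vector of trajectory PDB paths
#'   (optional; the topology's own models are used when empty).
#' @param sim_id simulation identifier.
#' @param dt_ns time step between frames, ns.
#' @param t0_ns time of the first frame, ns (default `dt_ns`).
#' @param drop_solvent drop water/ion residues (default TRUE).
#' @return an [ensemble].
#' @export
load_ensemble <- function(topology_source, coordinate_sources = character(),
                          sim_id, dt_ns = 1, t0_ns = dt_ns,
                          drop_solvent = TRUE) {
  top <- read_pdb(topology_source, drop_solvent = drop_solvent)
  frames <- list()
  if (length(coordinate_sources) == 0) {
    frames[[1]] <- top$coords
  } else {
    for (src in coordinate_sources) {
      tr <- read_pdb(src, drop_solvent = drop_solvent)
      if (dim(tr$coords)[2] != nrow(top$atoms)) {
        stop("atom-count mismatch: trajectory '", src, "' has ",
             dim(tr$coords)[2], " atoms, topology has ", nrow(top$atoms))
      }
      frames[[length(frames) + 1]] <- tr$coords
    }
  }
  tt <- sum(vapply(frames, function(f) dim(f)[1], integer(1)))
  coords <- array(NA_real_, dim = c(tt, nrow(top$atoms), 3))
  at <- 0
  for (f in frames) {
    nf <- dim(f)[1]
    coords[at + seq_len(nf), , ] <- f
    at <- at + nf
  }
  times <- t0_ns + (seq_len(tt) - 1) * dt_ns
  ensemble(top$atoms, coords, times, sim_id)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param x an `ensemble`.
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  a <- x$atoms
  # left-justify short names at column 14, PDB convention
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  for (m in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    fr <- frame_coords(x, m) * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), nm, a$residue_name, a$chain_id, a$residue_index,
      fr[, 1], fr[, 2], fr[, 3], a$element
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
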