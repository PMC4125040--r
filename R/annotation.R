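#' Complex annotation: mapping atoms and residues to structural roles
#'
#' A `complex_annotation` records which chain plays which role in a
#' TCR/peptide/MHC complex and where the analysis regions live: the six
#' CDR loops, the two MHC groove helices with their central kink residues,
#' and the conserved C-alpha cores of the two TCR variable domains used
#' for the inter-domain orientation measurement.
#'
#' All residue intervals are inclusive `(chain, first, last)` triples in
#' the per-chain numbering of the input files.
#'
#' @param role_of_chain named character vector mapping chain id to one of
#'   `peptide`, `MHC`, `TCR_alpha`, `TCR_beta`, `beta2m`.
#' @param cdr_ranges named list `cdr1a..cdr3a, cdr1b..cdr3b`, each a list
#'   with `chain`, `first`, `last`.
#' @param helix_ranges named list `helix1`, `helix2` on the MHC chain,
#'   same interval format.
#' @param kink_residues named list `helix1`, `helix2`, each a list with
#'   `chain` and `residue` (the central kink residue of that helix).
#' @param core_alpha,core_beta lists with `chain` and integer `residues`:
#'   the ordered conserved C-alpha sets of the V-alpha / V-beta domains
#'   (at least 4 residues each so the principal axes have rank >= 2).
#' @param peptide_length number of peptide residues.
#' @return object of class `complex_annotation`.
#' @export
complex_annotation <- function(role_of_chain, cdr_ranges, helix_ranges,
                               kink_residues, core_alpha, core_beta,
                               peptide_length) {
  roles <- c("peptide", "MHC", "TCR_alpha", "TCR_beta", "beta2m")
  if (is.null(names(role_of_chain)) || !all(role_of_chain %in% roles)) {
    stop("`role_of_chain` must be a named vector with roles in: ",
         paste(roles, collapse = ", "))
  }
  cdr_names <- c("cdr1a", "cdr2a", "cdr3a", "cdr1b", "cdr2b", "cdr3b")
  if (!all(cdr_names %in% names(cdr_ranges))) {
    stop("`cdr_ranges` must name all six CDRs: ",
         paste(cdr_names, collapse = ", "))
  }
  if (!all(c("helix1", "helix2") %in% names(helix_ranges))) {
    stop("`helix_ranges` must name helix1 and helix2")
  }
  for (h in c("helix1", "helix2")) {
    k <- kink_residues[[h]]
    r <- helix_ranges[[h]]
    if (is.null(k)) stop("missing kink residue for ", h)
    if (k$chain != r$chain || k$residue < r$first || k$residue > r$last) {
      stop("kink residue of ", h, " must lie inside its helix range")
    }
  }
  for (core in list(core_alpha, core_beta)) {
    if (length(core$residues) < 4) {
      stop("conserved cores need at least 4 residues")
    }
  }
  structure(
    list(role_of_chain = role_of_chain,
         cdr_ranges = cdr_ranges,
         helix_ranges = helix_ranges,
         kink_residues = kink_residues,
         core_alpha = core_alpha,
         core_beta = core_beta,
         peptide_length = as.integer(peptide_length)),
    class = "complex_annotation"
  )
}

#' Read / write an annotation as a JSON config file
#' @param path file path.
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rng <- function(r) list(chain = r$chain, first = r$first, last = r$last)
  complex_annotation(
    role_of_chain = unlist(j$role_of_chain),
    cdr_ranges = lapply(j$cdr_ranges, rng),
    helix_ranges = lapply(j$helix_ranges, rng),
    kink_residues = lapply(j$kink_residues, function(k)
      list(chain = k$chain, residue = k$residue)),
    core_alpha = list(chain = j$core_alpha$chain,
                      residues = as.integer(j$core_alpha$residues)),
    core_beta = list(chain = j$core_beta$chain,
                     residues = as.integer(j$core_beta$residues)),
    peptide_length = j$peptide_length
  )
}

#' @rdname read_annotation
#' @param x a `complex_annotation`.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "complex_annotation"))
  jsonlite::write_json(list(
    role_of_chain = as.list(x$role_of_chain),
    cdr_ranges = x$cdr_ranges,
    helix_ranges = x$helix_ranges,
    kink_residues = x$kink_residues,
    core_alpha = x$core_alpha,
    core_beta = x$core_beta,
    peptide_length = x$peptide_length
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

region_names <- function() {
  c("peptide", "MHC", "TCR_alpha", "TCR_beta",
    "cdr1a", "cdr2a", "cdr3a", "cdr1b", "cdr2b", "cdr3b",
    "helix1", "helix2", "core_alpha", "core_beta")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Select atom indices for an annotated region
#'
#' @param atoms atom table of an [ensemble] (or the ensemble itself).
#' @param annotation a [complex_annotation].
#' @param region one of `peptide`, `MHC`, `TCR_alpha`, `TCR_beta`,
#'   `cdr1a..cdr3b`, `helix1`, `helix2`, `core_alpha`, `core_beta`.
#' @param atom_subset `"all"`, `"heavy"` (non-hydrogen), `"backbone"`
#'   (N, CA, C, O) or `"calpha"`.
#' @return integer vector of atom indices (row numbers of the atom table).
#' @export
select_atoms <- function(atoms, annotation, region,
                         atom_subset = c("all", "heavy", "backbone",
                                         "calpha")) {
  if (inherits(atoms, "ensemble")) atoms <- atoms$atoms
  atom_subset <- match.arg(atom_subset)
  stopifnot(inherits(annotation, "complex_annotation"))
  a <- annotation
  mask <- switch(
    region,
    peptide = ,
    MHC = ,
    TCR_alpha = ,
    TCR_beta = {
      chains <- names(a$role_of_chain)[a$role_of_chain == region]
      atoms$chain_id %in% chains
    },
    helix1 = ,
    helix2 = in_range(atoms, a$helix_ranges[[region]]),
    core_alpha = ,
    core_beta = {
      core <- a[[region]]
      atoms$chain_id == core$chain & atoms$residue_index %in% core$residues
    },
    {
      if (!region %in% names(a$cdr_ranges)) {
        stop("unknown region '", region, "'")
      }
      in_range(atoms, a$cdr_ranges[[region]])
    }
  )
  idx <- which(mask)
  if (length(idx) == 0) stop("region '", region, "' selects no atoms")
  nm <- atoms$name[idx]
  el <- atoms$element[idx]
  idx <- switch(atom_subset,
                all = idx,
                heavy = idx[el != "H"],
                backbone = idx[nm %in% BACKBONE_ATOMS],
                calpha = idx[nm == "CA"])
  if (length(idx) == 0) {
    stop("region '", region, "' has no '", atom_subset, "' atoms")
  }
  idx
}

in_range <- function(atoms, r) {
  atoms$chain_id == r$chain &
    atoms$residue_index >= r$first & atoms$residue_index <= r$last
}

# atom indices of one residue
residue_atoms <- function(atoms, chain, residue) {
  idx <- which(atoms$chain_id == chain & atoms$residue_index == residue)
  if (length(idx) == 0) {
    stop("residue ", chain, ":", residue, " not found")
  }
  idx
}
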