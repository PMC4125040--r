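#' Interface distances of the TCR/peptide/MHC complex
#'
#' Sixteen named distances characterise the binding interface: the kink
#' residue of each MHC groove helix to the three CDRs of the opposing TCR
#' chain, the groove width at its beginning / middle / end, and the
#' peptide's first / middle / last residue (plus its overall mean) to the
#' CDR3 loops.  Single residues are represented by their C-alpha; regions
#' (CDRs, the whole peptide) by the unweighted centroid of their
#' non-hydrogen atoms.
#'
#' @name interface_geometry
NULL

#' Resolve a reference point for a residue or region in one frame
#'
#' @param coords N x 3 frame coordinates (nm).
#' @param atoms atom table.
#' @param annotation a [complex_annotation].
#' @param endpoint a list: either `list(residue = list(chain, residue))`
#'   (C-alpha of that residue), `list(region = "...")` (heavy-atom
#'   centroid of the region), or `list(regions = c(...))` (joint centroid
#'   of several regions).
#' @return length-3 numeric point (nm).
#' @export
region_point <- function(coords, atoms, annotation, endpoint) {
  if (!is.null(endpoint$residue)) {
    r <- endpoint$residue
    idx <- residue_atoms(atoms, r$chain, r$residue)
    ca <- idx[atoms$name[idx] == "CA"]
    if (length(ca) == 0) {
      stop("residue ", r$chain, ":", r$residue, " has no C-alpha atom")
    }
    return(coords[ca[1], ])
  }
  regions <- endpoint$regions %||% endpoint$region
  if (is.null(regions)) stop("endpoint must name a residue or region")
  idx <- unique(unlist(lapply(regions, function(rg)
    select_atoms(atoms, annotation, rg, atom_subset = "heavy"))))
  colMeans(coords[idx, , drop = FALSE])
}

#' The sixteen default interface distance specifications
#'
#' @param annotation a [complex_annotation]; kink residues, helix ranges,
#'   CDR ranges and the peptide length are taken from it.  The peptide's
#'   middle residue of a length-L peptide is residue `floor((L + 1) / 2)`
#'   (residue 5 of a 9-mer).
#' @return named list of specs, each `list(label, a, b)` with endpoint
#'   format as in [region_point], ordered as conventionally plotted (A-P).
#' @export
default_distance_specs <- function(annotation) {
  a <- annotation
  pep_chain <- names(a$role_of_chain)[a$role_of_chain == "peptide"][1]
  L <- a$peptide_length
  pep_first <- list(residue = list(chain = pep_chain, residue = 1L))
  pep_mid <- list(residue = list(chain = pep_chain,
                                 residue = as.integer((L + 1) %/% 2)))
  pep_last <- list(residue = list(chain = pep_chain, residue = L))
  k1 <- list(residue = list(chain = a$kink_residues$helix1$chain,
                            residue = a$kink_residues$helix1$residue))
  k2 <- list(residue = list(chain = a$kink_residues$helix2$chain,
                            residue = a$kink_residues$helix2$residue))
  h1 <- a$helix_ranges$helix1; h2 <- a$helix_ranges$helix2
  hres <- function(h, r) list(residue = list(chain = h$chain, residue = r))
  rg <- function(x) list(region = x)
  specs <- list(
    list(label = "h1kink_cdr1b", a = k1, b = rg("cdr1b")),
    list(label = "h1kink_cdr2b", a = k1, b = rg("cdr2b")),
    list(label = "h1kink_cdr3b", a = k1, b = rg("cdr3b")),
    list(label = "h2kink_cdr1a", a = k2, b = rg("cdr1a")),
    list(label = "h2kink_cdr2a", a = k2, b = rg("cdr2a")),
    list(label = "h2kink_cdr3a", a = k2, b = rg("cdr3a")),
    list(label = "groove_begin", a = hres(h1, h1$first), b = hres(h2, h2$first)),
    list(label = "groove_middle", a = k1, b = k2),
    list(label = "groove_end", a = hres(h1, h1$last), b = hres(h2, h2$last)),
    list(label = "pepmid_cdr3a", a = pep_mid, b = rg("cdr3a")),
    list(label = "pepmid_cdr3b", a = pep_mid, b = rg("cdr3b")),
    list(label = "pepfirst_cdr3a", a = pep_first, b = rg("cdr3a")),
    list(label = "pepfirst_cdr3b", a = pep_first, b = rg("cdr3b")),
    list(label = "peplast_cdr3a", a = pep_last, b = rg("cdr3a")),
    list(label = "peplast_cdr3b", a = pep_last, b = rg("cdr3b")),
    list(label = "pepmean_cdr3mean", a = rg("peptide"),
         b = list(regions = c("cdr3a", "cdr3b")))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Evaluate the interface distances on one frame
#'
#' @param coords N x 3 frame coordinates (nm).
#' @param atoms atom table.
#' @param annotation a [complex_annotation].
#' @param specs distance specs (default [default_distance_specs]).
#' @return named numeric vector of Euclidean distances (nm), one per spec,
#'   in spec order.
#' @export
interface_distances <- function(coords, atoms, annotation,
                                specs = default_distance_specs(annotation)) {
  vapply(specs, function(s) {
    pa <- region_point(coords, atoms, annotation, s$a)
    pb <- region_point(coords, atoms, annotation, s$b)
    vnorm(pa - pb)
  }, numeric(1))
}

#' Interface-distance time series over one or more simulations
#'
#' @param ensembles an [ensemble] or list of ensembles.
#' @param annotation a [complex_annotation].
#' @param specs distance specs (default [default_distance_specs]).
#' @param stride frame stride (default 1).
#' @return named list of [sample_distribution] objects, one per distance
#'   label, pooling all frames of all simulations.
#' @export
distance_series <- function(ensembles, annotation,
                            specs = default_distance_specs(annotation),
                            stride = 1) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  labels <- names(specs)
  vals <- stats::setNames(vector("list", length(labels)), labels)
  ids <- character(0)
  for (ens in ensembles) {
    frames <- seq(1, n_frames(ens), by = stride)
    m <- vapply(frames, function(i)
      interface_distances(frame_coords(ens, i), ens$atoms, annotation,
                          specs),
      numeric(length(labels)))
    m <- matrix(m, nrow = length(labels))
    for (k in seq_along(labels)) {
      vals[[k]] <- c(vals[[k]], m[k, ])
    }
    ids <- c(ids, rep(ens$sim_id, length(frames)))
  }
  lapply(vals, function(v) sample_distribution(v, ids))
}
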