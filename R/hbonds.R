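#' Geometric hydrogen-bond detection
#'
#' A hydrogen bond is recorded between a donor heavy atom D (N or O
#' carrying a covalently attached hydrogen H) and an acceptor heavy atom A
#' (N or O) when the donor-acceptor distance is at most `dist_cutoff_nm`
#' and the hydrogen-donor-acceptor angle is at most `angle_cutoff_deg` --
#' the standard geometric criterion of MD trajectory tools
#' (defaults 0.35 nm / 30 degrees).  Hydrogens are associated with their
#' donor by proximity (H within `covalent_cutoff_nm` of an N/O) because the
#' PDB dialect carries no bond topology.
#'
#' @param coords N x 3 coordinate matrix (nm) for one frame.
#' @param atoms atom table (see [ensemble]).
#' @param donor_selection,acceptor_selection integer atom indices; must be
#'   disjoint at the atom level.
#' @param dist_cutoff_nm donor-acceptor distance cutoff, nm.
#' @param angle_cutoff_deg hydrogen-donor-acceptor angle cutoff, degrees.
#' @param angle_convention `"hda"` (angle at the donor between D->H and
#'   D->A, default) or `"dha"` (angle at the hydrogen between H->D and
#'   H->A, where the cutoff is interpreted as deviation from linearity,
#'   i.e. 180 - angle <= cutoff).
#' @param covalent_cutoff_nm H considered attached to a donor within this
#'   distance (default 0.12 nm).
#' @return data.frame with one row per (donor, hydrogen, acceptor) triple:
#'   atom indices, donor-acceptor distance (nm) and the angle (deg).
#' @export
detect_hbonds <- function(coords, atoms, donor_selection, acceptor_selection,
                          dist_cutoff_nm = 0.35, angle_cutoff_deg = 30,
                          angle_convention = c("hda", "dha"),
                          covalent_cutoff_nm = 0.12) {
  angle_convention <- match.arg(angle_convention)
  if (dist_cutoff_nm <= 0 || angle_cutoff_deg <= 0) {
    stop("cutoffs must be positive")
  }
  if (length(intersect(donor_selection, acceptor_selection)) > 0) {
    stop("donor and acceptor selections must be disjoint")
  }
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())

  don <- donor_selection[atoms$element[donor_selection] %in% c("N", "O")]
  acc <- acceptor_selection[atoms$element[acceptor_selection] %in% c("N", "O")]
  hyd <- which(atoms$element == "H")
  if (length(don) == 0 || length(acc) == 0 || length(hyd) == 0) return(empty)

  # attach hydrogens to donors by proximity
  dh <- cross_dist(coords[don, , drop = FALSE], coords[hyd, , drop = FALSE])
  att <- which(dh <= covalent_cutoff_nm, arr.ind = TRUE)
  if (nrow(att) == 0) return(empty)

  da <- cross_dist(coords[don, , drop = FALSE], coords[acc, , drop = FALSE])
  out <- vector("list", nrow(att))
  for (k in seq_len(nrow(att))) {
    di <- att[k, 1]; hi <- att[k, 2]
    ok <- which(da[di, ] <= dist_cutoff_nm)
    if (length(ok) == 0) next
    D <- coords[don[di], ]; H <- coords[hyd[hi], ]
    angs <- vapply(ok, function(ai) {
      A <- coords[acc[ai], ]
      if (angle_convention == "hda") vec_angle(H - D, A - D)
      else 180 - vec_angle(D - H, A - H)
    }, numeric(1))
    keep <- ok[angs <= angle_cutoff_deg]
    if (length(keep) == 0) next
    out[[k]] <- data.frame(donor = don[di], hydrogen = hyd[hi],
                           acceptor = acc[keep],
                           distance = da[di, keep],
                           angle = angs[angs <= angle_cutoff_deg])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[res$donor != res$acceptor, , drop = FALSE]
  rownames(res) <- NULL
  res
}

cross_dist <- function(a, b) {
  # pairwise Euclidean distances, rows of a x rows of b
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Per-residue hydrogen-bond footprint (normalized frequency score)
#'
#' Counts every hydrogen bond bridging two annotated regions across all
#' frames of all supplied ensembles and normalizes by the total frame
#' count.  The resulting score for a residue is 0 if it mediates no bond
#' in any frame, 1 if exactly one bond persists through every frame, and
#' exceeds 1 when a residue mediates several simultaneous bonds (as the
#' peptide anchor residues typically do).  Both the donor-side and the
#' acceptor-side residue of a bond are credited.
#'
#' @param ensembles a single [ensemble] or list of ensembles (one per
#'   simulation; scores pool all of them).
#' @param annotation a [complex_annotation].
#' @param region_a,region_b two distinct region labels (see
#'   [select_atoms]); donors of either region are paired with acceptors of
#'   the other.
#' @param dist_cutoff_nm,angle_cutoff_deg,angle_convention see
#'   [detect_hbonds].
#' @param stride analyse every `stride`-th frame (default 1; the
#'   normalization always uses the number of frames actually analysed).
#' @return data.frame `chain`, `residue_index`, `residue_name`, `region`,
#'   `score`, covering every residue of both regions.
#' @export
hbond_footprint <- function(ensembles, annotation, region_a, region_b,
                            dist_cutoff_nm = 0.35, angle_cutoff_deg = 30,
                            angle_convention = "hda", stride = 1) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0) stop("no ensembles supplied")
  if (identical(region_a, region_b)) {
    stop("footprint regions must differ")
  }
  at <- ensembles[[1]]$atoms
  sel_a <- select_atoms(at, annotation, region_a)
  sel_b <- select_atoms(at, annotation, region_b)
  if (length(intersect(sel_a, sel_b)) > 0) {
    stop("regions '", region_a, "' and '", region_b, "' overlap")
  }

  reskey <- paste(at$chain_id, at$residue_index)
  counts <- numeric(0)
  total_frames <- 0
  for (ens in ensembles) {
    frames <- seq(1, n_frames(ens), by = stride)
    total_frames <- total_frames + length(frames)
    for (i in frames) {
      fr <- frame_coords(ens, i)
      hb <- rbind(
        detect_hbonds(fr, at, sel_a, sel_b, dist_cutoff_nm,
                      angle_cutoff_deg, angle_convention),
        detect_hbonds(fr, at, sel_b, sel_a, dist_cutoff_nm,
                      angle_cutoff_deg, angle_convention)
      )
      if (nrow(hb) == 0) next
      touched <- c(reskey[hb$donor], reskey[hb$acceptor])
      tb <- table(touched)
      for (nm in names(tb)) {
        cur <- counts[nm]
        counts[nm] <- (if (is.na(cur)) 0 else cur) + tb[[nm]]
      }
    }
  }

  both <- sort(union(sel_a, sel_b))
  res_rows <- !duplicated(reskey[both])
  idx <- both[res_rows]
  key <- reskey[idx]
  sc <- ifelse(is.na(counts[key]), 0, counts[key]) / total_frames
  data.frame(
    chain = at$chain_id[idx],
    residue_index = at$residue_index[idx],
    residue_name = at$residue_name[idx],
    region = ifelse(idx %in% sel_a, region_a, region_b),
    score = as.numeric(sc),
    row.names = NULL
  )
}
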