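#' Root mean square fluctuation per residue
#'
#' For every atom of the target selection the RMSF is the square root of
#' the time-averaged squared displacement from the atom's time-average
#' position.  Per-residue values are the unweighted mean over the
#' residue's backbone atoms (N, CA, C, O).  When a fit selection is given
#' the ensemble is first rigid-body superposed (two-pass mean-structure
#' reference, see [superpose]) so that global translation/rotation does
#' not inflate the fluctuations; pass `fit_selection = NULL` for
#' pre-aligned ensembles.
#'
#' @param x an [ensemble] with at least two frames.
#' @param target_selection atom indices to report on (default: all atoms).
#' @param fit_selection atom indices used for superposition, or NULL to
#'   skip fitting.
#' @return data.frame `chain`, `residue_index`, `residue_name`, `rmsf`
#'   (nm, backbone mean); per-atom values in attribute `atom_rmsf`
#'   (named by atom index).
#' @export
rmsf <- function(x, target_selection = seq_len(n_atoms(x)),
                 fit_selection = NULL) {
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) < 2) {
    stop("RMSF undefined for a single-frame ensemble")
  }
  if (!is.null(fit_selection)) x <- superpose(x, fit_selection)
  sel <- as.integer(target_selection)
  cc <- x$coords[, sel, , drop = FALSE]
  mean_pos <- apply(cc, c(2, 3), mean)
  # squared displacement from the mean position, averaged over frames
  dev2 <- sweep(cc, c(2, 3), mean_pos)^2
  msd <- apply(dev2, 2, mean) * 3  # mean over frames & dims -> sum of dims
  atom_rmsf <- sqrt(msd)

  at <- x$atoms
  bb <- at$name[sel] %in% BACKBONE_ATOMS
  key <- paste(at$chain_id[sel], at$residue_index[sel])
  ukey <- key[!duplicated(key)]
  res_val <- vapply(ukey, function(k) {
    i <- which(key == k & bb)
    if (length(i) == 0) i <- which(key == k)  # no backbone atoms: use all
    mean(atom_rmsf[i])
  }, numeric(1))
  first <- match(ukey, key)
  out <- data.frame(
    chain = at$chain_id[sel][first],
    residue_index = at$residue_index[sel][first],
    residue_name = at$residue_name[sel][first],
    rmsf = as.numeric(res_val),
    row.names = NULL
  )
  attr(out, "atom_rmsf") <- stats::setNames(atom_rmsf, sel)
  out
}
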