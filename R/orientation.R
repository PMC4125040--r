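#' Relative orientation of the TCR variable domains
#'
#' The mutual orientation of V-alpha and V-beta is described by five
#' angles and one distance, following the principal-axis construction
#' used for antibody VH/VL domains.  For each domain the first and second
#' principal components (A1/A2 for V-alpha, B1/B2 for V-beta) of its
#' conserved C-alpha core are computed, with signs registered against a
#' reference orientation so the axes never flip between frames.  The
#' inter-domain vector C runs from the V-alpha anchor (core centroid) to
#' the V-beta anchor.  Then
#' \itemize{
#'   \item DC: anchor separation (nm);
#'   \item BA: signed torsion angle between A1 and B1 about C
#'     (right-hand rule, degrees in (-180, 180]);
#'   \item AC1 = angle(A1, C), BC1 = angle(B1, -C): tilt angles;
#'   \item AC2 = angle(A2, C), BC2 = angle(B2, -C): twist angles.
#' }
#'
#' @name tcr_orientation
NULL

#' Principal-axis frame of one variable domain
#'
#' @param core_coords n x 3 C-alpha coordinates of the conserved core
#'   (n >= 4, not collinear).
#' @param reference_axes optional 2 x 3 matrix (rows: reference first and
#'   second axes); computed axes are sign-flipped to have positive dot
#'   product with the reference.
#' @return list with unit vectors `a1`, `a2`, the `anchor` (core
#'   centroid) and the singular values `sv`.
#' @export
domain_frame <- function(core_coords, reference_axes = NULL) {
  p <- as.matrix(core_coords)
  if (nrow(p) < 4) stop("domain core needs at least 4 residues")
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  s <- svd(pc)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop("degenerate domain core: points are (near) collinear")
  }
  a1 <- s$v[, 1]; a2 <- s$v[, 2]
  if (!is.null(reference_axes)) {
    if (sum(a1 * reference_axes[1, ]) < 0) a1 <- -a1
    if (sum(a2 * reference_axes[2, ]) < 0) a2 <- -a2
  }
  list(a1 = a1, a2 = a2, anchor = ctr, sv = s$d)
}

#' Build a shared sign-fixing reference from one frame
#'
#' The reference stores, per domain, the core C-alpha coordinates and the
#' principal axes computed on them.  When a later frame is analysed the
#' reference core is rigidly fitted onto the frame's core and the
#' reference axes are transported by that rotation before the sign fix,
#' so axis signs stay stable even when a domain swings far from the
#' reference orientation (a static dot-product fix would flip beyond 90
#' degrees of rotation).
#'
#' @param coords N x 3 coordinates of the reference frame (nm).
#' @param atoms atom table.
#' @param annotation a [complex_annotation].
#' @return list with per-domain entries `alpha` and `beta`, each holding
#'   `axes` (2 x 3) and `core` (n x 3).
#' @export
orientation_reference <- function(coords, atoms, annotation) {
  ca <- select_atoms(atoms, annotation, "core_alpha", "calpha")
  cb <- select_atoms(atoms, annotation, "core_beta", "calpha")
  pa <- coords[ca, , drop = FALSE]
  pb <- coords[cb, , drop = FALSE]
  fa <- domain_frame(pa)
  fb <- domain_frame(pb)
  list(alpha = list(axes = rbind(fa$a1, fa$a2), core = pa),
       beta = list(axes = rbind(fb$a1, fb$a2), core = pb))
}

# transport a domain reference onto the current core coordinates:
# rigid-fit the stored core onto the frame's core and rotate the stored
# axes along, yielding co-moving comparison axes for the sign fix
transported_axes <- function(domain_ref, core_now) {
  if (is.null(domain_ref)) return(NULL)
  if (is.matrix(domain_ref)) return(domain_ref)  # bare 2 x 3 axes
  k <- kabsch(domain_ref$core, core_now)
  domain_ref$axes %*% t(k$R)
}

#' Orientation angles and distance for one frame
#'
#' @param coords N x 3 frame coordinates (nm).
#' @param atoms atom table.
#' @param annotation a [complex_annotation].
#' @param reference sign-fixing reference from [orientation_reference]
#'   (optional for a single frame; mandatory consistency across frames is
#'   handled by [orientation_series]).
#' @return named numeric vector `BA`, `BC1`, `BC2`, `AC1`, `AC2`
#'   (degrees) and `DC` (nm).
#' @export
orientation_angles <- function(coords, atoms, annotation,
                               reference = NULL) {
  ca <- select_atoms(atoms, annotation, "core_alpha", "calpha")
  cb <- select_atoms(atoms, annotation, "core_beta", "calpha")
  pa <- coords[ca, , drop = FALSE]
  pb <- coords[cb, , drop = FALSE]
  fa <- domain_frame(pa, transported_axes(reference$alpha, pa))
  fb <- domain_frame(pb, transported_axes(reference$beta, pb))
  C <- fb$anchor - fa$anchor
  dc <- vnorm(C)
  if (dc < 1e-9) stop("degenerate geometry: coincident domain anchors")
  ch <- C / dc
  c(
    BA = axial_torsion(fa$a1, fb$a1, ch),
    BC1 = vec_angle(fb$a1, -ch),
    BC2 = vec_angle(fb$a2, -ch),
    AC1 = vec_angle(fa$a1, ch),
    AC2 = vec_angle(fa$a2, ch),
    DC = dc
  )
}

#' Orientation time series over one or more simulations
#'
#' For cross-simulation comparability all ensembles share one sign-fixing
#' reference; by default it is derived from the first frame of the first
#' ensemble.
#'
#' @param ensembles an [ensemble] or list of ensembles.
#' @param annotation a [complex_annotation].
#' @param reference optional shared reference ([orientation_reference]).
#' @param stride frame stride (default 1).
#' @return named list of six [sample_distribution] objects: `BA`, `BC1`,
#'   `BC2`, `AC1`, `AC2` (degrees), `DC` (nm).
#' @export
orientation_series <- function(ensembles, annotation, reference = NULL,
                               stride = 1) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  if (is.null(reference)) {
    e1 <- ensembles[[1]]
    reference <- orientation_reference(frame_coords(e1, 1), e1$atoms,
                                       annotation)
  }
  labels <- c("BA", "BC1", "BC2", "AC1", "AC2", "DC")
  vals <- matrix(numeric(0), nrow = 6)
  ids <- character(0)
  for (ens in ensembles) {
    frames <- seq(1, n_frames(ens), by = stride)
    m <- vapply(frames, function(i)
      orientation_angles(frame_coords(ens, i), ens$atoms, annotation,
                         reference),
      numeric(6))
    vals <- cbind(vals, matrix(m, nrow = 6))
    ids <- c(ids, rep(ens$sim_id, length(frames)))
  }
  out <- lapply(seq_len(6), function(k) sample_distribution(vals[k, ], ids))
  stats::setNames(out, labels)
}
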