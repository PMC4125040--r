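#' Coordinate ensembles
#'
#' An `ensemble` holds one simulation: an atom table, a `T x N x 3`
#' coordinate array in nanometres, per-frame times in nanoseconds and an
#' opaque simulation identifier used as the resampling unit by the
#' group-comparison machinery.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_index`,
#'   `residue_name`, `chain_id` (one row per atom, file order).
#' @param coords numeric array of dimension `c(T, N, 3)`, coordinates in nm.
#' @param times numeric vector of length `T`, strictly increasing, in ns.
#' @param sim_id single character string identifying the simulation.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, coords, times, sim_id) {
  req <- c("name", "element", "residue_index", "residue_name", "chain_id")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("`atoms` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("`coords` must be a T x N x 3 array")
  }
  if (dim(coords)[2] != nrow(atoms)) {
    stop("frame atom count (", dim(coords)[2],
         ") does not match atom table (", nrow(atoms), ")")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  if (length(times) != dim(coords)[1]) {
    stop("`times` length must equal the number of frames")
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  structure(
    list(atoms = atoms, coords = coords, times = as.numeric(times),
         sim_id = as.character(sim_id)),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble '%s': %d frames x %d atoms, t = %.3g..%.3g ns>\n",
              x$sim_id, n_frames(x), n_atoms(x),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname ensemble
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Extract one frame as an N x 3 matrix (nm).
#' @param x an `ensemble`.
#' @param i frame index.
#' @export
frame_coords <- function(x, i) {
  if (i < 1 || i > n_frames(x)) stop("frame index out of range")
  matrix(x$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Discard the equilibration phase of a trajectory
#'
#' Drops every frame whose time is less than or equal to `cutoff_ns`,
#' keeping only the production part of the run.  The conventional cutoff
#' treats the first 10 ns as system relaxation, so a 100 ns run analysed
#' at 1 frame/ns retains 90 frames.
#'
#' @param x an `ensemble`.
#' @param cutoff_ns non-negative equilibration time in ns (default 10).
#' @return The truncated `ensemble`; `sim_id` is preserved.
#' @export
discard_equilibration <- function(x, cutoff_ns = 10) {
  stopifnot(inherits(x, "ensemble"))
  if (!is.numeric(cutoff_ns) || cutoff_ns < 0) {
    stop("`cutoff_ns` must be >= 0")
  }
  keep <- which(x$times > cutoff_ns)
  if (length(keep) == 0) {
    stop("equilibration cutoff of ", cutoff_ns,
         " ns removes every frame of simulation '", x$sim_id, "'")
  }
  ensemble(x$atoms,
           x$coords[keep, , , drop = FALSE],
           x$times[keep], x$sim_id)
}

#' Least-squares rigid-body superposition of trajectory frames
#'
#' Removes global translation and rotation by fitting a selection of atoms
#' of every frame onto a common reference with the optimal (SVD-based)
#' rigid transform.  The transform computed on the fit selection is applied
#' to all atoms, so internal geometry is untouched.  When no reference is
#' supplied a two-pass procedure is used: frames are first aligned to frame
#' 1, the arithmetic mean structure of the aligned frames then serves as
#' the reference for the final pass.
#'
#' @param x an `ensemble`.
#' @param fit_selection integer atom indices used to compute the fit.
#' @param reference_coords optional N x 3 reference (same atom count as
#'   `x`); default is the two-pass mean structure.
#' @return The superposed `ensemble`.
#' @export
superpose <- function(x, fit_selection, reference_coords = NULL) {
  stopifnot(inherits(x, "ensemble"))
  sel <- as.integer(fit_selection)
  if (length(sel) == 0) stop("`fit_selection` must be nonempty")
  check_fit_geometry(frame_coords(x, 1)[sel, , drop = FALSE])
  if (is.null(reference_coords)) {
    pass1 <- apply_fit(x, sel, frame_coords(x, 1))
    reference_coords <- colMeans_frames(pass1)
  } else {
    reference_coords <- as.matrix(reference_coords)
    if (nrow(reference_coords) != n_atoms(x)) {
      stop("reference atom count does not match ensemble")
    }
  }
  apply_fit(x, sel, reference_coords)
}

# mean structure over frames -> N x 3
colMeans_frames <- function(x) {
  matrix(apply(x$coords, c(2, 3), mean), ncol = 3)
}

check_fit_geometry <- function(p) {
  if (nrow(p) < 3) stop("degenerate fit: need at least 3 fit atoms")
  pc <- sweep(p, 2, colMeans(p))
  sv <- svd(pc)$d
  if (sv[2] < 1e-8) stop("degenerate fit: fit atoms are (near) collinear")
  invisible(TRUE)
}

# Kabsch: rotation R and translation mapping moving points onto ref points.
kabsch <- function(moving, ref) {
  cm <- colMeans(moving); cr <- colMeans(ref)
  H <- t(sweep(moving, 2, cm)) %*% sweep(ref, 2, cr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, center_moving = cm, center_ref = cr)
}

apply_fit <- function(x, sel, reference_coords) {
  refsel <- reference_coords[sel, , drop = FALSE]
  out <- x$coords
  for (i in seq_len(n_frames(x))) {
    fr <- frame_coords(x, i)
    k <- kabsch(fr[sel, , drop = FALSE], refsel)
    moved <- sweep(fr, 2, k$center_moving) %*% t(k$R)
    out[i, , ] <- sweep(moved, 2, k$center_ref, `+`)
  }
  ensemble(x$atoms, out, x$times, x$sim_id)
}
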