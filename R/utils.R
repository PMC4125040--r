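# Small geometry / RNG helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' @noRd
deg <- function(rad) rad * 180 / pi

#' Angle between two vectors in degrees, in [0, 180].
#' @noRd
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  deg(acos(max(-1, min(1, ca))))
}

#' Signed torsion of vector a relative to vector b about unit axis c,
#' right-hand rule, degrees in (-180, 180].
#' @noRd
axial_torsion <- function(a, b, axis) {
  ax <- unit(axis)
  ap <- a - sum(a * ax) * ax
  bp <- b - sum(b * ax) * ax
  if (vnorm(ap) < 1e-10 || vnorm(bp) < 1e-10) {
    stop("torsion undefined: vector parallel to the axis")
  }
  cr <- c(
    ap[2] * bp[3] - ap[3] * bp[2],
    ap[3] * bp[1] - ap[1] * bp[3],
    ap[1] * bp[2] - ap[2] * bp[1]
  )
  ang <- deg(atan2(sum(cr * ax), sum(ap * bp)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rotation matrix for angle (degrees) about an arbitrary unit axis
#' (Rodrigues). Points are rows, so apply as x %*% t(R).
#' @noRd
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate row-point matrix `x` about the line through `point` along `axis`.
#' @noRd
rotate_about_line <- function(x, point, axis, angle_deg) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(x, 2, point) %*% t(R), 2, point, `+`)
}

#' Evaluate `expr` with the global RNG seeded to `seed`, restoring the
#' caller's RNG state afterwards.  All stochastic entry points in the
#' package funnel through this so a user-visible seed argument never
#' perturbs unrelated randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
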