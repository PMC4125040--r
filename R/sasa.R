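#' Solvent-accessible surface area (rolling-probe, point-sphere method)
#'
#' Deterministic Shrake-Rupley style SASA: each atom is inflated by the
#' probe radius, its surface is sampled with a fixed quasi-uniform point
#' set (golden-section spiral), and the accessible fraction is the share
#' of points not buried inside any neighbouring inflated sphere.  By
#' default hydrogens are ignored, matching the united-atom convention of
#' common MD analysis tools.
#'
#' @name sasa
NULL

# van der Waals radii (nm) by element; configurable via `radii`
DEFAULT_VDW_RADII <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                       P = 0.180, H = 0.120)

#' Deterministic quasi-uniform unit-sphere point set (golden spiral).
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue and total SASA of one frame
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param atoms atom table (see [ensemble]).
#' @param selection atom indices forming the body whose surface is
#'   computed; the same atoms act as occluders.
#' @param probe_radius_nm probe sphere radius (default 0.14 nm, water).
#' @param n_sphere_points surface sample points per atom (default 960).
#' @param radii named vector of per-element radii in nm (merged over the
#'   built-in table).
#' @param include_hydrogens include H atoms as surface/occluding spheres
#'   (default FALSE).
#' @return list with `atom_area` (named by atom index, nm^2), `residue`
#'   (data.frame chain, residue_index, residue_name, area) and `total`.
#'   Residue areas sum exactly to the total.
#' @export
sasa_frame <- function(coords, atoms, selection,
                       probe_radius_nm = 0.14, n_sphere_points = 960,
                       radii = NULL, include_hydrogens = FALSE) {
  rt <- DEFAULT_VDW_RADII
  if (!is.null(radii)) rt[names(radii)] <- radii
  sel <- as.integer(selection)
  if (!include_hydrogens) sel <- sel[atoms$element[sel] != "H"]
  if (length(sel) == 0) stop("SASA selection empty")
  el <- atoms$element[sel]
  unknown <- setdiff(unique(el), names(rt))
  if (length(unknown) > 0) {
    stop("no radius configured for element(s): ",
         paste(unknown, collapse = ", "))
  }
  r <- rt[el] + probe_radius_nm
  xyz <- coords[sel, , drop = FALSE]
  pts <- sphere_points(n_sphere_points)

  nsel <- length(sel)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(nsel)
  for (i in seq_len(nsel)) {
    neigh <- which(d2[i, ] < (r[i] + r)^2 & seq_len(nsel) != i)
    if (length(neigh) == 0) {
      acc <- n_sphere_points
    } else {
      surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
      buried <- rep(FALSE, n_sphere_points)
      for (j in neigh) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < r[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * r[i]^2 * acc / n_sphere_points
  }

  key <- paste(atoms$chain_id[sel], atoms$residue_index[sel])
  first <- !duplicated(key)
  res_area <- as.numeric(tapply(area, factor(key, levels = key[first]), sum))
  list(
    atom_area = stats::setNames(area, sel),
    residue = data.frame(
      chain = atoms$chain_id[sel][first],
      residue_index = atoms$residue_index[sel][first],
      residue_name = atoms$residue_name[sel][first],
      area = res_area,
      row.names = NULL
    ),
    total = sum(area)
  )
}

#' Per-frame SASA series of a region
#'
#' Applies [sasa_frame] to every `stride`-th frame of an ensemble and
#' returns the total-area time series tagged with the simulation id, ready
#' for pooling into a [sample_distribution].
#'
#' @param x an [ensemble].
#' @param selection atom indices (see [select_atoms]).
#' @param stride frame stride (default 1).
#' @inheritParams sasa_frame
#' @return data.frame `sim_id`, `time_ns`, `area` (nm^2).
#' @export
sasa_series <- function(x, selection, stride = 1, probe_radius_nm = 0.14,
                        n_sphere_points = 960, radii = NULL,
                        include_hydrogens = FALSE) {
  stopifnot(inherits(x, "ensemble"))
  frames <- seq(1, n_frames(x), by = stride)
  vals <- vapply(frames, function(i) {
    sasa_frame(frame_coords(x, i), x$atoms, selection,
               probe_radius_nm, n_sphere_points, radii,
               include_hydrogens)$total
  }, numeric(1))
  data.frame(sim_id = x$sim_id, time_ns = x$times[frames], area = vals)
}
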