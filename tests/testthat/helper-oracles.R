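# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately written from first principles (plain
# loops, closed forms) and never calls the implementation paths it checks.

# ---- shared toy fixtures ----------------------------------------------

TOY <- build_toy_complex()

noiseless_spec <- function(...) {
  toy_complex_spec(
    sigma = c(peptide = 0, MHC = 0, TCR_alpha = 0, TCR_beta = 0),
    sim_dc_sd_nm = 0, sim_ba_sd_deg = 0, ...
  )
}

# ---- random rigid transforms ------------------------------------------

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, `+`)
}

# ---- brute-force hydrogen-bond oracle ---------------------------------
# plain loops over every donor/hydrogen/acceptor triple applying the two
# inequalities directly
oracle_hbonds <- function(coords, atoms, donors, acceptors,
                          dist_cut = 0.35, ang_cut = 30, cov_cut = 0.12) {
  hyd <- which(atoms$element == "H")
  out <- NULL
  for (d in donors) {
    if (!atoms$element[d] %in% c("N", "O")) next
    for (h in hyd) {
      if (sqrt(sum((coords[d, ] - coords[h, ])^2)) > cov_cut) next
      for (a in acceptors) {
        if (!atoms$element[a] %in% c("N", "O")) next
        if (a == d) next
        dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
        if (dda > dist_cut) next
        v1 <- coords[h, ] - coords[d, ]
        v2 <- coords[a, ] - coords[d, ]
        cosang <- sum(v1 * v2) /
          (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        ang <- acos(max(-1, min(1, cosang))) * 180 / pi
        if (ang <= ang_cut) {
          out <- rbind(out, c(d, h, a))
        }
      }
    }
  }
  out
}

hbond_key <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character(0))
  sort(apply(m, 1, paste, collapse = "-"))
}

# ---- closed-form rigid-fit oracle (Horn quaternion method) ------------
# minimal RMSD between two point sets over all rigid transforms, via the
# largest eigenvalue of Horn's 4x4 matrix -- no SVD, independent of the
# Kabsch path used by the package.
oracle_min_rmsd <- function(moving, ref) {
  X <- sweep(moving, 2, colMeans(moving))
  Y <- sweep(ref, 2, colMeans(ref))
  S <- t(X) %*% Y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(0, msd))
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# ---- type-7 quantile oracle -------------------------------------------
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ---- dense-grid SASA oracle -------------------------------------------
# random-direction surface sampling, independent of the deterministic
# golden-spiral point set used by the implementation
oracle_sasa <- function(centers, radii_ext, n_dirs = 1e5, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dirs <- matrix(rnorm(3 * n_dirs), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  total <- 0
  for (i in seq_len(nrow(centers))) {
    pts <- sweep(dirs * radii_ext[i], 2, centers[i, ], `+`)
    acc <- rep(TRUE, n_dirs)
    for (j in seq_len(nrow(centers))) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, centers[j, ])^2)
      acc <- acc & d2 >= radii_ext[j]^2
    }
    total <- total + 4 * pi * radii_ext[i]^2 * mean(acc)
  }
  total
}

# minimal two-chain annotation for custom hydrogen-bond fixtures; the
# CDR/helix/core fields are config-complete but reference chains that the
# fixture atoms never populate
minimal_annotation <- function(peptide_length = 1) {
  complex_annotation(
    role_of_chain = c(P = "peptide", M = "MHC",
                      A = "TCR_alpha", B = "TCR_beta"),
    cdr_ranges = list(
      cdr1a = list(chain = "A", first = 1, last = 1),
      cdr2a = list(chain = "A", first = 2, last = 2),
      cdr3a = list(chain = "A", first = 3, last = 3),
      cdr1b = list(chain = "B", first = 1, last = 1),
      cdr2b = list(chain = "B", first = 2, last = 2),
      cdr3b = list(chain = "B", first = 3, last = 3)
    ),
    helix_ranges = list(helix1 = list(chain = "M", first = 1, last = 2),
                        helix2 = list(chain = "M", first = 3, last = 4)),
    kink_residues = list(helix1 = list(chain = "M", residue = 1),
                         helix2 = list(chain = "M", residue = 3)),
    core_alpha = list(chain = "A", residues = 1:4),
    core_beta = list(chain = "B", residues = 1:4),
    peptide_length = peptide_length
  )
}

make_atoms <- function(name, element, residue_index, chain_id,
                       residue_name = "GLY") {
  data.frame(name = name, element = element,
             residue_index = residue_index,
             residue_name = residue_name,
             chain_id = chain_id, stringsAsFactors = FALSE)
}
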