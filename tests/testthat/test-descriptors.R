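# descriptors: hydrogen bonds, footprints, SASA, RMSF

test_that("detect_hbonds applies the geometric criterion", {
  # linear N-H...O with N-O = 0.29 nm, H on the axis
  at <- make_atoms(c("N", "H", "O"), c("N", "H", "O"),
                   c(1, 1, 2), c("P", "P", "M"))
  xyz <- rbind(c(0, 0, 0), c(0.10, 0, 0), c(0.29, 0, 0))
  hb <- detect_hbonds(xyz, at, donor_selection = 1:2,
                      acceptor_selection = 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1)
  expect_equal(hb$acceptor, 3)
  expect_equal(hb$distance, 0.29, tolerance = 1e-12)
  expect_equal(hb$angle, 0, tolerance = 1e-9)

  # beyond the distance cutoff: no bond
  xyz2 <- rbind(c(0, 0, 0), c(0.10, 0, 0), c(0.40, 0, 0))
  expect_equal(nrow(detect_hbonds(xyz2, at, 1:2, 3)), 0)
  # beyond the angle cutoff: no bond
  xyz3 <- rbind(c(0, 0, 0), c(0, 0.10, 0), c(0.29, 0, 0))
  expect_equal(nrow(detect_hbonds(xyz3, at, 1:2, 3)), 0)
  # overlapping selections rejected
  expect_error(detect_hbonds(xyz, at, 1:2, 2:3), "disjoint")
})

test_that("detect_hbonds matches the brute-force oracle on random configs", {
  set.seed(31)
  for (trial in 1:100) {
    nd <- sample(2:4, 1); na <- sample(2:5, 1)
    # donors: N with an attached H at distance 0.1; acceptors: O
    don_pos <- matrix(runif(3 * nd, 0, 0.8), ncol = 3)
    hdir <- matrix(rnorm(3 * nd), ncol = 3)
    hdir <- hdir / sqrt(rowSums(hdir^2))
    h_pos <- don_pos + 0.1 * hdir
    acc_pos <- matrix(runif(3 * na, 0, 0.8), ncol = 3)
    at <- make_atoms(
      c(rep(c("N", "H"), nd), rep("O", na)),
      c(rep(c("N", "H"), nd), rep("O", na)),
      c(rep(seq_len(nd), each = 2), nd + seq_len(na)),
      c(rep("P", 2 * nd), rep("M", na))
    )
    xyz <- rbind(
      do.call(rbind, lapply(seq_len(nd), function(i)
        rbind(don_pos[i, ], h_pos[i, ]))),
      acc_pos
    )
    donors <- seq_len(2 * nd)
    acceptors <- 2 * nd + seq_len(na)
    got <- detect_hbonds(xyz, at, donors, acceptors)
    want <- oracle_hbonds(xyz, at, donors, acceptors)
    expect_equal(hbond_key(as.matrix(got[, 1:3])), hbond_key(want))
  }
})

test_that("footprint scores are bond counts over total frames", {
  # persistent single bond in every frame -> score 1 for both residues
  e <- generate_ensemble(TOY, "fp", seed = 5,
                         spec = noiseless_spec(n_frames = 4))
  fp <- hbond_footprint(e, TOY$annotation, "peptide", "MHC")
  expect_equal(fp$score[fp$chain == "P" & fp$residue_index == 2], 1.0)
  expect_equal(fp$score[fp$chain == "M" & fp$residue_index == 4], 1.0)
  expect_true(all(fp$score[!(fp$residue_index %in% c(2, 4))] == 0))
  # every peptide and MHC residue is reported
  expect_equal(nrow(fp), 9 + 24)

  # doubling the ensembles leaves every score unchanged (linearity)
  fp2 <- hbond_footprint(list(e, e), TOY$annotation, "peptide", "MHC")
  expect_equal(fp2$score, fp$score)
})

test_that("a residue mediating two simultaneous bonds scores 2", {
  # one donor residue with two N-H groups, each bonded to its own acceptor
  at <- make_atoms(c("N", "H", "N", "H", "O", "O"),
                   c("N", "H", "N", "H", "O", "O"),
                   c(1, 1, 1, 1, 1, 2), c("P", "P", "P", "P", "M", "M"))
  xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0),      # donor 1
               c(0, 1, 0), c(0.1, 1, 0),      # donor 2 (same residue)
               c(0.29, 0, 0), c(0.29, 1, 0))  # acceptors (different res)
  coords <- array(rep(xyz, each = 3), dim = c(3, 6, 3))
  ens <- ensemble(at, coords, 1:3, "two")
  fp <- hbond_footprint(ens, minimal_annotation(), "peptide", "MHC")
  expect_equal(fp$score[fp$chain == "P"], 2.0)
  expect_equal(fp$score[fp$chain == "M"], c(1.0, 1.0))
})

test_that("intermittent bonds score count/frames", {
  # bond present in 45 of 90 frames -> 0.5 exactly
  e <- generate_ensemble(TOY, "occ", seed = 17,
                         spec = noiseless_spec(n_frames = 90,
                                               hbond_occupancy = 0.5))
  fp <- hbond_footprint(e, TOY$annotation, "peptide", "MHC")
  s <- fp$score[fp$chain == "P" & fp$residue_index == 2]
  expect_equal(s * 90, round(s * 90), tolerance = 1e-9)  # integer count
  expect_gt(s, 0.3)  # binomial(90, .5) bounds
  expect_lt(s, 0.7)
})

test_that("SASA reproduces closed forms and the grid oracle", {
  at1 <- make_atoms("O", "O", 1, "Z", "X")
  s1 <- sasa_frame(matrix(0, 1, 3), at1, 1)
  expect_equal(s1$total, 4 * pi * (0.152 + 0.14)^2, tolerance = 1e-9)
  # configurable radius: r = 0.15, probe 0.14 -> 4 pi 0.29^2
  s1b <- sasa_frame(matrix(0, 1, 3), at1, 1, radii = c(O = 0.15))
  expect_equal(s1b$total, 4 * pi * 0.29^2, tolerance = 1e-9)

  at2 <- make_atoms(c("O", "O"), c("O", "O"), 1:2, "Z", "X")
  # far apart: no occlusion, areas add
  far <- rbind(c(0, 0, 0), c(10, 0, 0))
  s2 <- sasa_frame(far, at2, 1:2)
  expect_equal(s2$total, 2 * s1$total, tolerance = 1e-9)
  expect_equal(sum(s2$residue$area), s2$total, tolerance = 1e-9)

  # overlapping pair vs dense random-direction oracle
  near <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  s3 <- sasa_frame(near, at2, 1:2)
  want <- oracle_sasa(near, rep(0.152 + 0.14, 2))
  expect_lt(abs(s3$total - want) / want, 0.01)
  # occlusion never increases the partner's area
  expect_lt(s3$atom_area[[1]], s1$total)
})

test_that("SASA obeys the k^2 scale law and monotone occlusion", {
  set.seed(41)
  at <- make_atoms(rep("C", 5), rep("C", 5), 1:5, "Z", "X")
  xyz <- matrix(runif(15, 0, 0.5), ncol = 3)
  base <- sasa_frame(xyz, at, 1:5)
  k <- 2.5
  scaled <- sasa_frame(xyz * k, at, 1:5, probe_radius_nm = 0.14 * k,
                       radii = c(C = 0.170 * k))
  expect_equal(scaled$total, k^2 * base$total, tolerance = 1e-9)

  # adding an occluder never increases any other atom's area
  at6 <- make_atoms(rep("C", 6), rep("C", 6), 1:6, "Z", "X")
  xyz6 <- rbind(xyz, colMeans(xyz))
  with6 <- sasa_frame(xyz6, at6, 1:6)
  expect_true(all(with6$atom_area[1:5] <= base$atom_area + 1e-12))
})

test_that("sasa_series is consistent with sasa_frame", {
  e <- generate_ensemble(TOY, "sasa", seed = 7,
                         spec = noiseless_spec(n_frames = 4))
  sel <- select_atoms(e$atoms, TOY$annotation, "peptide", "heavy")
  ser <- sasa_series(e, sel, stride = 2, n_sphere_points = 240)
  expect_equal(nrow(ser), 2)  # strided frames
  f1 <- sasa_frame(frame_coords(e, 1), e$atoms, sel,
                   n_sphere_points = 240)
  expect_equal(ser$area[1], f1$total, tolerance = 1e-12)
  # static ensemble -> constant series
  expect_equal(ser$area[2], ser$area[1], tolerance = 1e-12)
  expect_equal(ser$sim_id, rep("sasa", 2))
})

test_that("RMSF matches the Gaussian closed form and rigid invariance", {
  # identical frames -> zero fluctuation
  e0 <- generate_ensemble(TOY, "static", seed = 2,
                          spec = noiseless_spec(n_frames = 3))
  r0 <- rmsf(e0, fit_selection = NULL)
  expect_true(all(r0$rmsf < 1e-12))

  # iid Gaussian jitter, sigma = 0.05 nm/coordinate -> RMSF = sigma*sqrt(3)
  set.seed(53)
  natom <- 12
  ref <- matrix(runif(3 * natom), ncol = 3)
  nT <- 2000
  coords <- array(rep(ref, each = nT), dim = c(nT, natom, 3)) +
    array(rnorm(nT * natom * 3, 0, 0.05), dim = c(nT, natom, 3))
  at <- make_atoms(rep(c("N", "CA", "C", "O"), 3), rep("X", natom),
                   rep(1:3, each = 4), "P")
  at$element <- c("N", "C", "C", "O")[match(at$name, c("N", "CA", "C", "O"))]
  ens <- ensemble(at, coords, 1:nT, "gauss")
  rr <- rmsf(ens, fit_selection = NULL)
  expect_equal(mean(rr$rmsf), 0.05 * sqrt(3), tolerance = 0.03)

  # rigid rotations of one structure vanish under fitting
  coordsR <- array(NA_real_, dim = c(5, natom, 3))
  for (i in 1:5) {
    coordsR[i, , ] <- apply_rigid(ref, random_rotation_matrix(), rnorm(3))
  }
  ensR <- ensemble(at, coordsR, 1:5, "rigid")
  rR <- rmsf(ensR, fit_selection = seq_len(natom))
  expect_true(all(rR$rmsf < 1e-6))
  # global rigid transform of all frames leaves fitted RMSF unchanged
  R <- random_rotation_matrix(); tr <- rnorm(3)
  coordsG <- coords[1:50, , , drop = FALSE]
  for (i in 1:50) coordsG[i, , ] <- apply_rigid(coordsG[i, , ], R, tr)
  a <- rmsf(ensemble(at, coords[1:50, , , drop = FALSE], 1:50, "a"),
            fit_selection = seq_len(natom))
  b <- rmsf(ensemble(at, coordsG, 1:50, "b"),
            fit_selection = seq_len(natom))
  expect_equal(a$rmsf, b$rmsf, tolerance = 1e-9)

  expect_error(rmsf(ensemble(at, coords[1, , , drop = FALSE], 1, "one")),
               "single-frame")
})
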