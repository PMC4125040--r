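# trajectory_io: PDB reading/writing, equilibration cut, superposition

pdb_line <- function(serial, name, resn, chain, resi, x, y, z, el) {
  sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resn, chain, resi, x, y, z, el)
}

test_that("load_ensemble converts Angstrom to nm and synthesises times", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "GLY", "P", 1, 10, 20, 30, "N"),
    pdb_line(2, "CA", "GLY", "P", 1, 11, 21, 31, "C"),
    pdb_line(3, "C", "GLY", "P", 1, 12, 22, 32, "C"),
    "END"
  ), f)
  ens <- load_ensemble(f, sim_id = "s")
  expect_equal(n_frames(ens), 1)
  expect_equal(n_atoms(ens), 3)
  expect_equal(frame_coords(ens, 1),
               matrix(c(1, 1.1, 1.2, 2, 2.1, 2.2, 3, 3.1, 3.2), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
               tolerance = 1e-12)
  expect_equal(ens$atoms$element, c("N", "C", "C"))
})

test_that("trajectory files are concatenated and validated", {
  toy_spec <- noiseless_spec(n_frames = 5)
  e5 <- generate_ensemble(TOY, "s", seed = 1, spec = toy_spec)
  top <- withr::local_tempfile(fileext = ".pdb")
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ensemble(e5$atoms, e5$coords[1, , , drop = FALSE], 1, "s"), top)
  write_pdb(e5, t1)
  write_pdb(e5, t2)
  ens <- load_ensemble(top, c(t1, t2), sim_id = "s")
  expect_equal(n_frames(ens), 10)
  expect_equal(ens$times, 1:10)

  # atom-count mismatch -> format error
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "N", "GLY", "P", 1, 0, 0, 0, "N"),
               pdb_line(2, "CA", "GLY", "P", 1, 1, 0, 0, "C"),
               "END"), bad)
  expect_error(load_ensemble(bad, t1, sim_id = "s"), "mismatch")
  expect_error(load_ensemble(withr::local_tempfile(), sim_id = "s"),
               "cannot read")
})

test_that("PDB round-trip reproduces coordinates to format precision", {
  ens <- generate_ensemble(TOY, "rt", seed = 3,
                           spec = toy_complex_spec(n_frames = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, f)
  back <- load_ensemble(f, sim_id = "rt")
  expect_equal(back$atoms$name, ens$atoms$name)
  expect_equal(back$atoms$chain_id, ens$atoms$chain_id)
  expect_lt(max(abs(back$coords - ens$coords)), 1.0001e-4)  # 0.001 A
})

test_that("solvent residues are dropped on load", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "GLY", "P", 1, 0, 0, 0, "N"),
    pdb_line(2, "OW", "SOL", "W", 1, 5, 5, 5, "O"),
    pdb_line(3, "NA", "NA", "I", 1, 6, 6, 6, "N"),
    "END"), f)
  ens <- load_ensemble(f, sim_id = "s")
  expect_equal(n_atoms(ens), 1)
})

test_that("discard_equilibration keeps frames strictly after the cutoff", {
  at <- make_atoms("CA", "C", 1, "P")
  coords <- array(rnorm(100 * 1 * 3), dim = c(100, 1, 3))
  ens <- ensemble(at, coords, times = 1:100, sim_id = "x")

  cut <- discard_equilibration(ens, 10)
  expect_equal(n_frames(cut), 90)            # last 90 ns of a 100 ns run
  expect_equal(cut$times, 11:100)
  expect_equal(cut$sim_id, "x")
  # idempotent at fixed cutoff
  expect_equal(discard_equilibration(cut, 10), cut)
  # cutoff 0 is the identity
  expect_equal(discard_equilibration(ens, 0), ens)
  expect_error(discard_equilibration(ens, 200), "every frame")
  expect_error(discard_equilibration(ens, -1), ">= 0")
})

test_that("superpose recovers rigidly transformed frames exactly", {
  ref <- TOY$coords
  at <- TOY$atoms
  sel <- select_atoms(at, TOY$annotation, "MHC", "backbone")
  set.seed(11)
  nT <- 6
  coords <- array(NA_real_, dim = c(nT, nrow(ref), 3))
  for (i in seq_len(nT)) {
    coords[i, , ] <- apply_rigid(ref, random_rotation_matrix(), rnorm(3))
  }
  ens <- ensemble(at, coords, 1:nT, "rigid")
  fit <- superpose(ens, sel, reference_coords = ref)
  for (i in seq_len(nT)) {
    expect_lt(rmsd_of(frame_coords(fit, i)[sel, ], ref[sel, ]), 1e-6)
  }
  # intra-frame pairwise distances preserved
  d0 <- dist(frame_coords(ens, 1))
  d1 <- dist(frame_coords(fit, 1))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # already-aligned input is returned unchanged (within tolerance)
  again <- superpose(fit, sel, reference_coords = ref)
  expect_lt(max(abs(again$coords - fit$coords)), 1e-9)
})

test_that("post-fit RMSD matches the closed-form rigid-fit oracle", {
  set.seed(21)
  ref <- TOY$coords
  sel <- select_atoms(TOY$atoms, TOY$annotation, "TCR_alpha", "backbone")
  nT <- 5
  coords <- array(NA_real_, dim = c(nT, nrow(ref), 3))
  for (i in seq_len(nT)) {
    jit <- ref + matrix(rnorm(length(ref), 0, 0.04), ncol = 3)
    coords[i, , ] <- apply_rigid(jit, random_rotation_matrix(), rnorm(3))
  }
  ens <- ensemble(TOY$atoms, coords, 1:nT, "jit")
  fit <- superpose(ens, sel, reference_coords = ref)
  for (i in seq_len(nT)) {
    got <- rmsd_of(frame_coords(fit, i)[sel, ], ref[sel, ])
    want <- oracle_min_rmsd(frame_coords(ens, i)[sel, ], ref[sel, ])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("degenerate fit selections are rejected", {
  at <- make_atoms(rep("CA", 3), rep("C", 3), 1:3, "P")
  line <- cbind(0:2, 0, 0)
  ens <- ensemble(at, array(rep(line, each = 2), dim = c(2, 3, 3)),
                  1:2, "l")
  expect_error(superpose(ens, 1:3), "collinear")
  expect_error(superpose(ens, integer(0)), "nonempty")
})

test_that("annotation survives a JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(TOY$annotation, f)
  back <- read_annotation(f)
  expect_equal(back$role_of_chain, TOY$annotation$role_of_chain)
  expect_equal(back$cdr_ranges$cdr3b, TOY$annotation$cdr_ranges$cdr3b)
  expect_equal(back$core_beta$residues, TOY$annotation$core_beta$residues)
  expect_equal(back$peptide_length, TOY$annotation$peptide_length)
})
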