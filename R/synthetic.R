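#' Synthetic test data: APL sets, toy complexes and planted-effect ensembles
#'
#' The synthetic module generates everything the pipeline consumes:
#' the single-substitution altered-peptide-ligand (APL) set of a wild-type
#' epitope, immunogenicity tables for the group split, and toy
#' TCR/peptide/MHC-like coordinate ensembles.  The toy complex is
#' deliberately not a physical protein model -- it is the minimal
#' five-region geometry (peptide strand between two helix rods, two
#' variable-domain cores above) carrying backbone atoms (N, H, CA, C, O)
#' so hydrogen-bond, SASA, RMSF, interface-distance and orientation
#' operations all run, with controllable per-region fluctuation,
#' plantable inter-domain effects and a switchable peptide-MHC hydrogen
#' bond.
#'
#' @name synthetic_data
NULL

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Enumerate all single-substitution altered peptide ligands
#'
#' Returns the wild-type sequence first, followed by every single-position
#' substitution to each of the 19 other standard residues in
#' position-major order.  A 9-mer such as FLRGRAYGL therefore yields
#' 9 x 19 + 1 = 172 unique sequences.
#'
#' @param wildtype_sequence peptide over the 20-letter amino-acid
#'   alphabet.
#' @return character vector of unique sequences, wild-type first.
#' @export
enumerate_apls <- function(wildtype_sequence) {
  wt <- toupper(wildtype_sequence)
  aa <- strsplit(wt, "")[[1]]
  if (length(aa) == 0 || !all(aa %in% AMINO_ACIDS)) {
    stop("wild-type sequence must use the 20 standard amino-acid letters")
  }
  out <- wt
  for (pos in seq_along(aa)) {
    for (sub in setdiff(AMINO_ACIDS, aa[pos])) {
      mut <- aa
      mut[pos] <- sub
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Specification of the toy complex and its simulated dynamics
#'
#' Defaults describe the stated world of the analyses: a 9-mer peptide,
#' 12-residue groove helices, 100 frames at 1 ns spacing (so the 10 ns
#' equilibration cut retains 90 frames), 0.05 nm per-coordinate thermal
#' jitter in every region, a 1.6 nm separation between the variable
#' domain anchors, and small simulation-level random offsets of the
#' inter-domain geometry (0.03 nm in DC, 1.5 degrees about the domain
#' axis) that give each trajectory its own mean -- the random effect the
#' trajectory-level permutation test must respect.
#'
#' @param peptide_length peptide residues (default 9).
#' @param helix_length residues per MHC groove helix (default 12).
#' @param n_frames frames per generated ensemble (default 100).
#' @param dt_ns frame spacing, ns (default 1).
#' @param sigma named per-region fluctuation sigma in nm (per coordinate),
#'   names `peptide`, `MHC`, `TCR_alpha`, `TCR_beta`.
#' @param domain_separation_nm V-alpha to V-beta anchor distance (nm).
#' @param base_ba_deg baseline inter-domain torsion imprinted on the
#'   reference geometry (degrees).
#' @param sim_dc_sd_nm,sim_ba_sd_deg standard deviation of the
#'   simulation-level random offsets of DC and of the V-beta rotation.
#' @param dc_shift_nm,ba_offset_deg planted group effects: a rigid
#'   translation of V-beta along the inter-domain axis and a rigid
#'   rotation of V-beta about it.
#' @param hbond_occupancy fraction of frames in which the switchable
#'   peptide-to-helix1 hydrogen bond (donor: peptide residue 2 backbone
#'   N-H) is formed (default 1).
#' @return object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(peptide_length = 9, helix_length = 12,
                             n_frames = 100, dt_ns = 1,
                             sigma = c(peptide = 0.05, MHC = 0.05,
                                       TCR_alpha = 0.05, TCR_beta = 0.05),
                             domain_separation_nm = 1.6,
                             base_ba_deg = -40,
                             sim_dc_sd_nm = 0.03, sim_ba_sd_deg = 1.5,
                             dc_shift_nm = 0, ba_offset_deg = 0,
                             hbond_occupancy = 1) {
  if (peptide_length < 3) stop("peptide_length must be >= 3")
  if (helix_length < 4) stop("helix_length must be >= 4")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(sigma < 0)) stop("fluctuation sigma must be >= 0")
  if (hbond_occupancy < 0 || hbond_occupancy > 1) {
    stop("hbond_occupancy must be in [0, 1]")
  }
  structure(as.list(environment()), class = "toy_complex_spec")
}

# residue backbone template: 5 atoms in the (ex, ey) plane around the CA.
# ey is the direction the amide H points (the N-H bond axis).
place_residue <- function(origin, ex, ey) {
  offs <- rbind(
    N = -0.12 * ex + 0.09 * ey,
    H = -0.12 * ex + 0.19 * ey,
    CA = c(0, 0, 0),
    C = 0.12 * ex + 0.09 * ey,
    O = 0.12 * ex + 0.19 * ey
  )
  sweep(offs, 2, origin, `+`)
}

#' Build the reference toy complex
#'
#' Chains: `P` peptide (residues 1..L along x), `M` MHC (helix1 residues
#' 1..H at y = +0.7 nm, helix2 residues H+1..2H at y = -0.7 nm), `A` and
#' `B` TCR alpha/beta (residues 1..8 an anisotropic box-corner core used
#' for the principal axes, residues 9..17 three 3-residue CDR stand-ins).
#' Helix1 residue 4 is displaced toward the peptide so its carbonyl
#' oxygen accepts the switchable hydrogen bond from peptide residue 2's
#' backbone N-H at a donor-acceptor distance of 0.29 nm.
#'
#' @param spec a [toy_complex_spec].
#' @return list (class `toy_complex`) with `atoms`, `coords` (reference
#'   N x 3, nm), `annotation` ([complex_annotation]) and bookkeeping used
#'   by [generate_ensemble].
#' @export
build_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  L <- spec$peptide_length
  H <- spec$helix_length
  ex <- c(1, 0, 0); ey_up <- c(0, 1, 0); ey_dn <- c(0, -1, 0)

  rows <- list()
  add <- function(chain, resi, resn, origin, ex, ey) {
    p <- place_residue(origin, ex, ey)
    rows[[length(rows) + 1]] <<- list(
      atoms = data.frame(name = rownames(p),
                         element = c("N", "H", "C", "C", "O"),
                         residue_index = resi, residue_name = resn,
                         chain_id = chain, stringsAsFactors = FALSE),
      coords = p)
  }

  # peptide: amide hydrogens point up toward helix1
  for (i in seq_len(L)) {
    add("P", i, "GLY", c(0.38 * (i - 1), 0, 0), ex, ey_up)
  }
  # helix rods; carbonyls face the peptide
  x0 <- 0.38 * (L - 1) / 2 - 0.38 * (H - 1) / 2  # centred on the peptide
  for (i in seq_len(H)) {
    add("M", i, "ALA", c(x0 + 0.38 * (i - 1), 0.70, 0), ex, ey_dn)
  }
  for (i in seq_len(H)) {
    add("M", H + i, "ALA", c(x0 + 0.38 * (i - 1), -0.70, 0), ex, ey_up)
  }
  # displace helix1 residue 4: its O accepts the switchable bond from the
  # peptide residue-2 donor (N at (0.26, 0.09, 0), bond axis +y)
  acceptor_target <- c(0.38 * 1 - 0.12, 0.09 + 0.29, 0)  # = N + 0.29*y
  rows[[L + 4]]$coords <- place_residue(
    acceptor_target - c(0.12, 0.19, 0), ex, ey_up)

  # TCR variable-domain cores: box corners with distinct side lengths so
  # the principal axes are unambiguous (1st axis z, 2nd axis y)
  box <- as.matrix(expand.grid(x = c(-0.15, 0.15), y = c(-0.30, 0.30),
                               z = c(-0.45, 0.45)))
  xm <- 0.38 * (L - 1) / 2
  sep <- spec$domain_separation_nm
  anchor_a <- c(xm - sep / 2, 0, 1.5)
  anchor_b <- c(xm + sep / 2, 0, 1.5)
  Rb <- rotation_matrix(c(1, 0, 0), spec$base_ba_deg)
  for (i in 1:8) {
    add("A", i, "GLY", anchor_a + box[i, ], ex, ey_up)
    add("B", i, "GLY", anchor_b + as.numeric(Rb %*% box[i, ]), ex, ey_up)
  }
  # CDR stand-ins: 3 residues each, below the cores toward the peptide
  cdr_origin <- list(
    A = list(c(-0.5, -0.35, 0.8), c(-0.5, 0.35, 0.8), c(0.25, 0.0, 0.7)),
    B = list(c(0.5, -0.35, 0.8), c(0.5, 0.35, 0.8), c(-0.25, 0.0, 0.7))
  )
  for (ch in c("A", "B")) {
    base <- if (ch == "A") anchor_a else anchor_b
    base <- c(base[1], 0, 0)
    for (k in 1:3) {
      o <- cdr_origin[[ch]][[k]]
      for (j in 1:3) {
        add(ch, 8 + (k - 1) * 3 + j, "GLY",
            base + o + c(0.2 * (j - 2), 0, 0), ex, ey_up)
      }
    }
  }

  atoms <- do.call(rbind, lapply(rows, `[[`, "atoms"))
  coords <- do.call(rbind, lapply(rows, `[[`, "coords"))
  rownames(atoms) <- rownames(coords) <- NULL

  ann <- complex_annotation(
    role_of_chain = c(P = "peptide", M = "MHC",
                      A = "TCR_alpha", B = "TCR_beta"),
    cdr_ranges = list(
      cdr1a = list(chain = "A", first = 9, last = 11),
      cdr2a = list(chain = "A", first = 12, last = 14),
      cdr3a = list(chain = "A", first = 15, last = 17),
      cdr1b = list(chain = "B", first = 9, last = 11),
      cdr2b = list(chain = "B", first = 12, last = 14),
      cdr3b = list(chain = "B", first = 15, last = 17)
    ),
    helix_ranges = list(
      helix1 = list(chain = "M", first = 1, last = H),
      helix2 = list(chain = "M", first = H + 1, last = 2 * H)
    ),
    kink_residues = list(
      helix1 = list(chain = "M", residue = as.integer((H + 1) %/% 2)),
      helix2 = list(chain = "M", residue = as.integer(H + (H + 1) %/% 2))
    ),
    core_alpha = list(chain = "A", residues = 1:8),
    core_beta = list(chain = "B", residues = 1:8),
    peptide_length = L
  )

  donor_res <- residue_atoms(atoms, "P", 2)
  structure(
    list(atoms = atoms, coords = coords, annotation = ann, spec = spec,
         anchor_a = anchor_a, anchor_b = anchor_b,
         hbond_donor_atoms = donor_res[atoms$name[donor_res] %in%
                                         c("N", "H")]),
    class = "toy_complex"
  )
}

#' Generate a synthetic trajectory for one simulation
#'
#' Frames are the (optionally effect-modified) reference coordinates plus
#' iid Gaussian jitter with the per-region sigma of the spec.  Planted
#' group effects: V-beta is rigidly rotated about the inter-domain axis
#' by `ba_offset_deg` (changing the BA torsion by exactly that amount on
#' noiseless frames) and translated along it by `dc_shift_nm` (shifting
#' DC).  On top of the planted effect every simulation draws its own
#' constant offsets (`sim_dc_sd_nm`, `sim_ba_sd_deg`), so frames within a
#' trajectory are correlated.  The switchable peptide-helix1 hydrogen
#' bond is formed in a Bernoulli(`hbond_occupancy`) subset of frames; in
#' "off" frames the donor N-H pair is displaced 0.15 nm away from the
#' acceptor, putting it outside the 0.35 nm criterion.
#'
#' @param toy a [build_toy_complex] result.
#' @param sim_id simulation identifier.
#' @param seed mandatory RNG seed for this simulation.
#' @param spec optional [toy_complex_spec] overriding the one the toy was
#'   built with (geometry fields must match).
#' @return an [ensemble].
#' @export
generate_ensemble <- function(toy, sim_id, seed, spec = toy$spec) {
  stopifnot(inherits(toy, "toy_complex"))
  if (missing(seed)) stop("`seed` is mandatory")
  at <- toy$atoms
  n <- nrow(at)
  role <- toy$annotation$role_of_chain
  sig <- spec$sigma[role[at$chain_id]]
  tt <- spec$n_frames

  with_seed(seed, {
    dc_eff <- spec$dc_shift_nm + stats::rnorm(1, 0, spec$sim_dc_sd_nm)
    ba_eff <- spec$ba_offset_deg + stats::rnorm(1, 0, spec$sim_ba_sd_deg)
    ref <- toy$coords
    bsel <- which(at$chain_id == "B")
    axis <- unit(toy$anchor_b - toy$anchor_a)
    if (ba_eff != 0) {
      ref[bsel, ] <- rotate_about_line(ref[bsel, , drop = FALSE],
                                       toy$anchor_b, axis, ba_eff)
    }
    if (dc_eff != 0) {
      ref[bsel, ] <- sweep(ref[bsel, , drop = FALSE], 2, dc_eff * axis, `+`)
    }
    bond_on <- stats::runif(tt) <= spec$hbond_occupancy
    coords <- array(NA_real_, dim = c(tt, n, 3))
    for (f in seq_len(tt)) {
      fr <- ref + matrix(stats::rnorm(3 * n, 0, rep(sig, 3)), ncol = 3)
      if (!bond_on[f]) {
        fr[toy$hbond_donor_atoms, 2] <- fr[toy$hbond_donor_atoms, 2] - 0.15
      }
      coords[f, , ] <- fr
    }
    ensemble(at, coords, spec$dt_ns * seq_len(tt), sim_id)
  })
}

#' Generate a synthetic immunogenicity table
#'
#' Peptides are drawn as unique random 9-mers; a `never` fraction gets no
#' 50\%-lysis concentration, a `strong` fraction gets a negative log10
#' molar value in [6.94, 9] (at or beyond the group-M threshold) and the
#' remaining `mid` fraction a value in [4, 6.8] (excluded by the default
#' threshold policy).
#'
#' @param n_peptides number of peptides.
#' @param fractions named numeric `c(never=, strong=, mid=)` summing to 1.
#' @param seed mandatory RNG seed.
#' @return data.frame `peptide_sequence`, `lysis50_neg_log10_molar`
#'   (character: number or "never") and the planted `class` column.
#' @export
generate_immunogenicity_table <- function(n_peptides,
                                          fractions = c(never = 0.3,
                                                        strong = 0.3,
                                                        mid = 0.4),
                                          seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (!all(c("never", "strong", "mid") %in% names(fractions)) ||
      any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must name never/strong/mid and sum to 1")
  }
  with_seed(seed, {
    peps <- character(0)
    while (length(peps) < n_peptides) {
      cand <- vapply(seq_len(n_peptides - length(peps)), function(i)
        paste(sample(AMINO_ACIDS, 9, replace = TRUE), collapse = ""),
        character(1))
      peps <- unique(c(peps, cand))
    }
    n_never <- round(fractions[["never"]] * n_peptides)
    n_strong <- round(fractions[["strong"]] * n_peptides)
    n_mid <- n_peptides - n_never - n_strong
    cls <- sample(rep(c("never", "strong", "mid"),
                      c(n_never, n_strong, n_mid)))
    val <- character(n_peptides)
    val[cls == "never"] <- "never"
    val[cls == "strong"] <- format(stats::runif(sum(cls == "strong"),
                                                6.94, 9), digits = 6)
    val[cls == "mid"] <- format(stats::runif(sum(cls == "mid"),
                                             4, 6.8), digits = 6)
    data.frame(peptide_sequence = peps,
               lysis50_neg_log10_molar = val,
               class = cls, stringsAsFactors = FALSE)
  })
}

#' Simulation manifest bookkeeping
#'
#' @param sim_ids simulation identifiers.
#' @param length_ns simulated length per run, ns (recycled).
#' @return data.frame `sim_id`, `length_ns` of class `sim_manifest`.
#' @export
simulation_manifest <- function(sim_ids, length_ns = 100) {
  structure(
    data.frame(sim_id = as.character(sim_ids),
               length_ns = rep_len(as.numeric(length_ns),
                                   length(sim_ids)),
               stringsAsFactors = FALSE),
    class = c("sim_manifest", "data.frame")
  )
}

#' Total simulated time of a manifest
#'
#' @param manifest a [simulation_manifest] (or data.frame with
#'   `length_ns`).
#' @return list `n_simulations`, `total_ns`, `total_us` (172 runs of
#'   100 ns give 17200 ns = 17.2 microseconds).
#' @export
manifest_summary <- function(manifest) {
  total_ns <- sum(manifest$length_ns)
  list(n_simulations = nrow(manifest),
       total_ns = total_ns,
       total_us = total_ns / 1000)
}
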