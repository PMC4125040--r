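# tcrpmhc

Comparative analysis of molecular-dynamics ensembles of T-cell receptor /
peptide / MHC (TCRpMHC) complexes.

## The problem

When a TCR surveys a peptide presented by an MHC molecule, which structural
and dynamical features of the interface — if any — track the peptide's
immunogenicity?  Answering that requires comparing *groups* of simulations
(complexes carrying more immunogenic peptides vs. less immunogenic ones)
rather than cherry-picking a pair of trajectories, and it requires a
statistical framework that respects the fact that frames within one
trajectory are correlated.

This package implements that comparison machinery for anyone analysing
TCRpMHC (or similar multi-chain interface) MD data:

* **Per-residue hydrogen-bond footprints.**  For regions A and B, the score
  of residue *r* is the number of A–B hydrogen bonds involving *r*, summed
  over all frames of all simulations, divided by the total frame count:
  0 = never bonded, 1 = one persistent bond, >1 = several simultaneous
  bonds (typical for peptide anchor residues).  Bond criterion:
  donor–acceptor distance ≤ 0.35 nm and H–donor–acceptor angle ≤ 30°.
* **SASA** (deterministic Shrake–Rupley, 960 points, 0.14 nm probe) and
  **RMSF** (two-pass mean-structure superposition, backbone atoms) series.
* **Sixteen named interface distances**: each MHC groove-helix kink to the
  three CDRs of the opposing TCR chain, groove width at begin/middle/end,
  and peptide first/middle/last/mean to the CDR3 loops.
* **TCR inter-domain orientation**: five angles and a distance from the
  principal axes (A1/A2, B1/B2) of conserved Cα cores of Vα and Vβ —
  the torsion BA about the inter-domain vector C, tilts AC1 = ∠(A1,C),
  BC1 = ∠(B1,−C), twists AC2 = ∠(A2,C), BC2 = ∠(B2,−C), and DC = |C|.
* **Two-group statistics**: total variation distance
  tvd = ½ Σᵢ |pᵢ − qᵢ| between binned pooled distributions, the
  normalized mean distance d/r = |mean₁ − mean₂| / (2.5 %-trimmed pooled
  range), and a permutation test that reassigns whole simulations
  (n = 2000 by default) with verbal categories at the 90/95/99 %
  percentiles ("slight" / "difference" / "strong").
* **Group split from experimental immunogenicity**: "never reaches 50 %
  lysis" → groupL; 50 % lysis at ≤ 10⁻⁶·⁹⁴ M → groupM.
* **Synthetic data**: the 172-member single-substitution APL scan of a
  9-mer epitope (e.g. FLRGRAYGL), immunogenicity tables, and toy
  five-region coordinate ensembles with controllable fluctuations and
  plantable effects — everything needed to validate the pipeline without
  production trajectories.

## Worked example

Generate a synthetic two-group dataset (5 + 5 simulations of a toy
TCRpMHC complex; group M carries a planted 0.12 nm shift of the
inter-domain distance DC) and run the full pipeline:

```r
library(tcrpmhc)
td  <- tempfile()
cfg <- write_synthetic_dataset(td, n_per_group = 5, seed = 7,
                               n_frames = 20, dc_shift_nm = 0.12,
                               n_perm = 500)
res <- run_analysis(cfg)
res$report[res$report$descriptor %in%
             c("orient_DC", "orient_BA", "dist_groove_middle"),
           c("descriptor", "observed_tvd", "observed_dr",
             "pct_tvd", "pct_dr", "category")]
```

```
         descriptor observed_tvd observed_dr pct_tvd pct_dr   category
 dist_groove_middle         0.20     0.08018   0.252  0.714       none
          orient_BA         0.18     0.00688   0.264  0.056       none
          orient_DC         0.90     0.49424   0.988  0.988 difference
```

Reading: the groove width and the BA torsion — where nothing was planted —
show high overlap and unremarkable permutation percentiles ("none"), while
the planted DC shift produces near-disjoint distributions (tvd = 0.90), a
mean separation of 49 % of the trimmed pooled range, and beats 98.8 % of
500 trajectory-level permutations ("difference"; with more simulations per
group the same effect reaches "strong").  All tables, pooled
distributions, per-group H-bond footprints and a structured log are
written under `file.path(td, "results")`.

The same pipeline runs from the shell:

```sh
Rscript -e 'tcrpmhc::tcrpmhc_cli()' simulate-data --out data --seed 7 --n-per-group 5
Rscript -e 'tcrpmhc::tcrpmhc_cli()' run --config data/config.json
```

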