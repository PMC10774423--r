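# bir2dyn

Non-synonymous pathogenic variants in the BIR2 domain of XIAP (residues
163–234) abolish its interaction with RIP2 kinase and, with it, normal NOD2
inflammatory signalling. `bir2dyn` packages the computational machinery for
studying that failure mode at desk scale, for structural bioinformaticians
and biophysicists who want a seeded, testable stand-in for the full
experimental/simulation stack:

* **FCCS quantification of binding.** Two-channel intensity traces are
  summarized by the fluctuation correlation estimator
  `G_x(τ) = 1 + ⟨δI_i(t)·δI_j(t+τ)⟩ / (⟨I_i⟩⟨I_j⟩)`, fitted with the
  one-to-three-component 3D diffusion model
  `G(τ) = 1 + (1/N) Σ_i F_i (1+τ/τ_i)^{-1} (1+τ/(s²τ_i))^{-1/2}`
  (optional triplet factor), and condensed into the relative
  cross-correlation amplitude `RCA = [G_c(0)−1]/[G_r(0)−1]`, the proxy for
  the bound fraction N_c/N_g.
* **A ground-truth FCCS simulator**: green-only, red-only and dual-labeled
  Brownian emitters diffusing through 3D Gaussian confocal volumes in a
  periodic box.
* **A coarse-grained BIR2-like Gō model** (one bead per residue, synthetic
  reference fold) with per-variant perturbations encoding four
  destabilization mechanisms — hydrophobic-core collapse (W173G, L189P,
  V198M, L207P), loss of the 166–185 helix–helix hydrogen bond (R166I,
  R166K), spatial rearrangement around G188 (G188E), and Zn-finger loss
  (H220Y) — run under temperature replica-exchange BAOAB Langevin dynamics
  (eight rungs, 300.00–325.00 K).
* **Trajectory statistics** reproducing the analysis suite: Kabsch
  superposition, subset RMSD, RMSF, hydrogen-bond occupancy,
  secondary-structure fractions from virtual Cα geometry, β-segment
  distances, and an end-to-end variant report.

See `vignettes/bir2-variant-dynamics.Rmd` for the models, assumptions,
parameter choices and limitations.

## Worked example

A mixture in which half of the labeled molecules are dual-labeled
(bound) recovers its ground truth through the full
simulate → correlate → fit → RCA chain:

```r
library(bir2dyn)
sim <- simulate_fccs_traces(
  dplyr::bind_rows(fccs_species("green_only", 20, 25),
                   fccs_species("red_only", 20, 25),
                   fccs_species("dual", 20, 25)),
  detection_volume(w0 = 0.25, s = 5), box_size = 3,
  duration = 1, dt = 2e-5, seed = 1)
fccs_analyze(sim$traces, n_components = 1, s_fixed = 5)
#>   amp_gg amp_rr amp_rg   rca
#> 1  1.533  1.476  0.734 0.497
sim$ground_truth$n_c / sim$ground_truth$n_g
#> [1] 0.5
```

The fitted auto-correlation amplitudes (≈1.5) are `1/N` for the ~0.65
particles of each color in the effective volume; the cross-amplitude is
half the red auto-amplitude, so RCA ≈ 0.50, matching the planted bound
fraction.

On the structural side, a core-collapse variant loosens the 11-residue
hydrophobic core relative to the wild-type reference:

```r
model <- build_cg_model(bir2_reference())
#> <cg_model> 72 beads, 311 native contacts, 6 restraints
vc <- variant_catalog()
mut <- apply_variant(model, vc[vc$name == "W173G", ])
r <- run_remd(mut, n_steps = 10000, stride = 100, seed = 2)
core <- subset_rmsd(analysis_ensemble(r), bir2_reference()$coords,
                    fit_selection = load_selections(name = "domain"),
                    measure_selection = load_selections(name = "hydrophobic_core"))
median(core$rmsd)
#> [1] 1.6   # Angstrom; the wild type sits near 1.0 under the same protocol
```

The full study — WT plus eight variants, three seeds each, REMD plus the
FCCS arm, aggregated by median — is one call:

```r
report <- run_pipeline(pipeline_config(), seed = 1)
autoplot(report)
```

The report carries, per variant: hydrophobic-core RMSD (median and 90th
percentile), RMSF over the 174–182 / 192–198 / 205–215 regions, 166–185
hydrogen-bond surrogate occupancy, β-segment 198–200↔206–208 distance, and
RCA, with seeds and a config hash for exact re-runs.

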