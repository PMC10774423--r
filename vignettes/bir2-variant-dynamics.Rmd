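---
title: "Methods: FCCS quantification and coarse-grained variant dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FCCS quantification and coarse-grained variant dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`bir2dyn` studies how pathogenic substitutions in the BIR2 domain of XIAP
(residues 163–234) destabilize the fold that binds RIP2 kinase, and how the
loss of that interaction shows up in live-cell fluorescence
cross-correlation spectroscopy (FCCS). It has two arms:

* an **FCCS arm**: a Brownian-emitter simulator with known ground truth, a
  fluctuation correlation estimator, multi-component diffusion-model
  fitting, and the relative cross-correlation amplitude (RCA) statistic;
* a **structural arm**: a bead-per-residue Gō-type model of a BIR2-like
  fold, temperature replica-exchange Langevin dynamics, and trajectory
  statistics (subset RMSD, RMSF, hydrogen-bond occupancy,
  secondary-structure fractions, segment distances).

Everything is desk-scale and seeded; nothing here attempts to reproduce
microsecond all-atom ensembles. The structural arm is a *generator of
planted truths*: each variant's mechanism class is built into the model
perturbation, and the analysis pipeline is validated by whether it recovers
those planted contrasts.

## The FCCS model

Fluorescence fluctuations in channel pair $(i, j)$ are summarized by

$$G_x(\tau) = 1 + \frac{\langle \delta I_i(t)\, \delta I_j(t+\tau) \rangle}
  {\langle I_i \rangle \langle I_j \rangle},$$

estimated directly (an $O(n \cdot n_\mathrm{lags})$ sum over all valid start
times on a quasi-logarithmic lag grid). We prefer the direct estimator to a
multi-tau cascade because at these trace lengths it is exact,
brute-force-verifiable, and fast enough.

Curves are fitted with the standard 3D-diffusion model for a Gaussian
detection volume of lateral radius $w_0$ and axial half-length $z_0 = s
w_0$:

$$G(\tau) = 1 + \frac{1}{N} \sum_i F_i
  \left(1+\frac{\tau}{\tau_i}\right)^{-1}
  \left(1+\frac{\tau}{s^2\tau_i}\right)^{-1/2},$$

with one to three components. The triplet correction is the standard
multiplicative factor $1 + \frac{T}{1-T} e^{-\tau/\tau_T}$ applied to the
diffusion sum. Live-cell FCCS curves are routinely fitted with or without
a triplet term; its exact functional form is a convention, and we adopt
the standard one as an explicit assumption of this package.

The RCA is $[G_c(0)-1]/[G_r(0)-1]$ with the **fitted** amplitudes
($G(0)-1 = 1/N$), never the noisy first lag point. The red-channel
denominator is the default (the printed convention); a green-channel flag
is provided because the normalization channel is described both ways. Under
ideal co-diffusion the simple amplitude ratio already equals the bound
fraction $N_c/N_g$, and no overlap-volume correction is attempted — the
exact estimator behind "fraction of associated molecules" is not specified,
so we implement the defensible simple ratio and stop there. Reported RCA is
clipped to $[-0.1, 1.5]$ with the raw value retained alongside.

### Numerical choices in the fitter

Parameters are transformed (log $N$, log $\tau_i$, stick-breaking logits
for fractions) so the optimizer works unconstrained inside hard box bounds.
Two bounds matter in practice:

* $\tau_i$ is confined to the measured lag window. Below the smallest lag
  the model is flat over the data and the extrapolated amplitude is
  unconstrained — a ridge that otherwise produces absurd $G(0)$ values on
  near-flat (negative-control) cross-correlation curves.
* $N \in [10^{-6}, 10^{12}]$, so "no correlation" is representable as a
  vanishing amplitude rather than a failure.

Starts are moment-based (amplitude from the small-lag excess, $\tau$ from
the half-decay lag) with four deterministically jittered restarts; the best
residual norm wins. MINPACK termination codes 1–4 count as convergence
(code 4 is the gradient-orthogonality test, the usual exit on flat curves).
A curve that never exceeds 1 short-circuits to an amplitude-zero result
with a warning. Weighting is uniform by default; `"lag_bin"` weighting
(inverse local grid spacing) is available but not the default since the
measurement error model is unspecified.

## The FCCS simulator

Green-only, red-only and dual-labeled species perform independent Brownian
steps (per-axis $\mathcal{N}(0, \sqrt{2D\,dt})$) in a periodic cube;
periodic wrapping keeps concentration constant, emulating a cytosolic
measurement position far from boundaries. Channel intensities are sums of
per-particle Gaussian detection weights; channels are perfectly
co-registered by default and crosstalk-free (no detector crosstalk model
is attempted; channel offsets are exposed for robustness experiments). Shot noise is off by default so estimator
tests are deterministic given particle paths.

Default study conditions (chosen once as realistic for cytosolic
GFP/RFP-tagged proteins): $w_0 = 0.25\ \mu m$, $s = 5$, $D = 25\ \mu
m^2/s$ (so $\tau_D = w_0^2/4D = 625\ \mu s$), box edge $3\ \mu m$
($12 w_0$), $dt = 20\ \mu s$, traces of 1 s (50,000 samples, roughly 1,600
diffusion times). The negative control is 50 green-only plus 50 red-only
particles; the pipeline's variant arm maps interaction classes to
ground-truth bound fractions 0.75 (WT), 0.30 (R166I/R166K, which retain
partial binding), 0.10 (all other variants).

What passing tests show: the estimator-fitter-RCA chain is unbiased and
monotone in the true bound fraction under the model's own assumptions.
What they do not show: robustness to photophysics (blinking, bleaching),
spectral crosstalk, cellular confinement, or vesicle artifacts — none of
which are simulated.

## The coarse-grained structural arm

### Reference fold

The reference geometry is a **synthetic** bead-per-residue fold built by
distance-geometry optimization, not deposited coordinates. The target
distance set encodes the domain architecture reported for BIR2: helices
163–168 and 181–186 in contact (with the 166–185 pair as the surrogate for
their stabilizing hydrogen bond), the RIP2-binding loops 174–182 and
205–215, the antiparallel β-segments 198–200/206–208 joined by the 201–204
turn, the buried 188 position stapled to 201 and 229, a C-terminal helix
216–225, the CCHC Zn-finger quartet 200/203/220/227 drawn into a pocket,
and pairwise clustering of the 11 hydrophobic-core residues (F170, W173,
A177, L179, L184, A187, L189, V198, L207, W210, A216). The optimization
(L-BFGS-B with analytic gradients from a fixed-seed compact random walk) is
deterministic and cached per session.

### Potential and integrator

The Gō potential is: harmonic virtual bonds $k_b (r-r_0)^2$ with $k_b =
100$ kcal/mol/Å²; 12-10 Lennard-Jones native wells
$\varepsilon[5(r_0/r)^{12} - 6(r_0/r)^{10}]$ for non-adjacent pairs within
6.5 Å of the reference; $(\sigma/r)^{12}$ excluded-volume repulsion
($\sigma = 4$ Å) for everything else; harmonic pair restraints ($k = 5$
kcal/mol/Å²) among the Zn quartet. A full all-atom treatment with
explicit zinc coordination is not desk-reachable; the Gō stand-in is an
explicit design substitution and its functional forms are documented here
and in code.

Integration is BAOAB Langevin with $\gamma = 2$ ps⁻¹ (the nominal collision
frequency kept verbatim), 110 amu beads, and a 0.002 ps step — the nominal
"2 fs" carried into the reduced model, comfortably below the stiffest bond
period (~0.3 ps). The temperature ladder is kept verbatim in Kelvin
(300.00–325.00 K, 8 rungs, ≈3.7 K spacing) and exchanges are attempted
every 5000 steps, the step-count image of "every 10 ps". Exchange sweeps
alternate even/odd neighbour pairs; accepted swaps exchange rung
temperatures and rescale velocities by $\sqrt{T_{new}/T_{old}}$. Pressure
coupling is deliberately omitted (constant-volume toy). A single-rung
ladder degrades to plain Langevin dynamics by design.

### Calibration of the generator

Well depth and contact density control whether the planted mechanisms can
express at 300 K. With a dense contact list (8 Å cutoff) and
$\varepsilon = 1$ kcal/mol the fold is so over-stabilized that deleting a
residue's contacts barely moves any observable. The defaults —
**6.5 Å cutoff, $\varepsilon = 0.7$ kcal/mol ($\approx 1.2\,k_BT$ per
contact), doubled well depth on the 166–185 pair, $k_{Zn} = 5$** — were
chosen during model construction so that the wild type is stable (core RMSD
≈ 1 Å, 166–185 surrogate occupancy ≈ 90%, consistent with a stably folded
wild type) while each mechanism class measurably destabilizes its target
observable. These are generator parameters defining the study conditions,
not tuning knobs of the analysis code, and the analysis pipeline never sees
them.

### Variant perturbations

* `core_collapse` (W173G, L189P, V198M, L207P): all native contacts of the
  mutated residue are deleted (they revert to plain repulsion).
* `helix_hbond_loss` (R166I, R166K): the 166–185 contact is deleted. Both
  substitutions receive the same perturbation; the toy does not resolve
  the finer R166I/R166K distinction reported experimentally.
* `rearrangement` (G188E): contacts touching residues 187–189 (the "188
  neighbourhood") or the 201–204 turn are weakened to 25% depth; β-segment
  separation then emerges from turn release rather than being imposed
  directly.
* `zn_loss` (H220Y): all Zn-finger restraints are removed.

C203Y and G204del are listed in the catalog as previously characterized
Zn-finger variants but excluded from the default simulated set.

### Trajectory statistics

Superposition is Kabsch (SVD with determinant correction; reflections
excluded). The default is to **fit on the full domain and measure on the
named subset**; the alternative (fit = subset) is one argument away, since
either convention is defensible. RMSF uses the mean structure after one
re-superposition pass (a common convention) rather than the initial frame.
Hydrogen-bond geometry defaults to the distance measured from the
**hydrogen** to the acceptor (3.6 Å) with a 135° donor–H–acceptor angle
and carbon allowed as an acceptor; a `"heavy"` distance mode is provided
because the hydrogen-to-acceptor convention is unusual. For bead ensembles a distance-only surrogate on the
166–185 pair applies, with a 7 Å cutoff (≈1.1× the native bead distance).
Secondary structure uses a virtual Cα angle/dihedral classifier (helix:
angle 75–115°, dihedral +25–100°; sheet: angle 100–155°, |dihedral| ≥
120°; else coil); full DSSP needs backbone carbonyls that a bead model
does not have. "Loop widening" of 205–215 is reported as the loop's radius
of gyration — an interpretation, labelled as such.

## Pipeline scale and determinism

The default pipeline runs WT + 8 variants × 3 seeds, 30,000 steps per
replica (8 replicas), recording every 100 steps and analysing the final
half of the lowest rung (~150 frames), plus one FCCS simulation (0.5 s
trace) per variant and seed; this completes in a few minutes on one CPU,
comfortably inside a ten-minute budget. Seeds for every stage are derived arithmetically from the master
seed, all randomness flows through R's RNG (the compiled integrator draws
from it too), and reruns are byte-identical — the report carries the seeds
and a config hash. Aggregation across seeds is by median, which is robust
at n = 3.

Test problem sizes were likewise chosen once: property tests use 25 random
fit-recovery draws, 20 noise seeds, $10^5$ Metropolis trials, $10^5$-frame
jitter ensembles, and 3,000-cycle toy REMD runs with thinned samples for
the chi-square/KS diagnostics (both tests assume independent samples, so
occupancy and energy series are subsampled well past their correlation
time).

## Known limitations

* The Gō model cannot report on side-chain chemistry; R166I vs R166K, or
  why V198M is milder than V198 deletion would be, are outside its
  resolution. It recovers *classes* of destabilization, by construction.
* Absolute occupancies and RMSD magnitudes from the toy ensembles are not
  comparable to all-atom values; only orderings against WT are meaningful.
* The FCCS arm's RCA-to-bound-fraction identity holds only for ideal,
  co-registered, crosstalk-free volumes.
* Binding free energies are out of scope.
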