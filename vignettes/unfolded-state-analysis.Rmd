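---
title: "Quantifying residual structure in unfolded protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying residual structure in unfolded protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucoil)
library(dplyr)
```

## The problem

The unfolded state of a globular protein under native-favouring conditions is
the starting point of folding, but it is rarely populated at equilibrium and
is therefore hard to observe. One productive strategy is to destabilise the
protein by point substitutions until the unfolded ensemble dominates without
any denaturant, and then ask how far that ensemble departs from a true random
coil: is it compact, does it transiently sample helix, do hydrophobic side
chains cluster locally? `ucoil` implements the quantitative machinery for
answering those questions from solution data — NMR chemical shifts,
transverse relaxation rates, HNHA scalar couplings, sedimentation velocity,
circular dichroism and equilibrium denaturation — with the four-helix
colicin immunity protein Im7 and its triply substituted variant
(L18A–L19A–L37A) as the built-in worked system.

Every analysis stage is paired with a seeded synthetic-data generator that
produces inputs with the statistical structure the stage assumes, so the
whole pipeline is testable end to end without any external data.

## The intrinsic relaxation baseline and hydrophobic clusters

An unfolded chain without any residual structure still shows
sequence-dependent ¹⁵N transverse relaxation, because bulky side chains slow
local reorientation and that effect propagates a few residues along the
chain. The intrinsic rate of residue *i* is modelled as

$$R_{2,i} = k \sum_{j=1}^{N} R_{g,j}^{3}\, e^{-|i-j|/\lambda_j},$$

where $R_{g,j}$ is the side-chain radius of gyration of residue *j*,
$\lambda_j$ is a persistence length for segmental motion (2 residues when the
contribution derives from alanine or glycine, 7 for all other residue types),
and $k$ is a single empirical scale absorbing the Stokes-law proportionality.
Two readings of this model required a decision:

* the exponent is read as $e^{-|i-j|/\lambda_j}$ — a persistence *length*
  only makes dimensional sense dividing the sequence separation;
* $\lambda$ is assigned by the **contributing** residue *j* (as its subscript
  indicates), not by the observed residue *i*.

The side-chain $R_g$ values ship as a replaceable packaged table; the proline
entry is raised from its tabulated 1.25 Å to 2.0 Å at load time, reflecting
the restriction of conformational space by the closed pyrrolidine ring. The
cube $R_g^3$ makes the baseline quite sensitive to this override.

The scale $k$ is not predicted by the model. `fit_scale_factor()` estimates
it by a least-absolute-deviations proportional fit of the unit-scale baseline
shape to the observed rates, solved exactly as the weighted median of the
per-residue ratios. The L1 loss was chosen (over least squares) so that the
fitted baseline hugs the non-cluster floor of the profile: cluster residues
are high outliers by construction, and a quadratic loss would drag the
baseline up into them. Known cluster regions can additionally be excluded
explicitly.

Residual hydrophobic clustering appears as contiguous elevations above the
baseline. `detect_clusters()` flags maximal runs of at least `min_run = 3`
consecutive residues whose excess exceeds `z = 2` times the per-residue
uncertainty (or a robust spread — the MAD of the excess — when uncertainties
are absent). Both knobs are exposed because no universal criterion exists;
the defaults recover clusters of the size seen in unfolded-state data
(amplitudes a few times the rate noise over ≥ 4 residues) with ≥ 95%
sensitivity and no false positives in the packaged simulation tests. For a
flat-topped excess plateau the reported centre is the middle residue of the
plateau.

Per-residue rates come from 11-point monoexponential decay series
(`fit_exponential_decay()`); the delay schedule spans 1.60–191.6 ms. The
rate uncertainty is taken from the fit covariance and inflated when an
independent spectral-noise estimate, or the spread of duplicate time points,
implies a larger noise floor. Fitted rates ≤ 0 are returned flagged, never
silently.

## Chemical-shift helicity: secondary shifts and SSP

Secondary shifts are observed shifts minus a sequence-, temperature- and
pH-corrected random-coil reference. The reference base values ship as a
replaceable packaged table (Cα, Cβ, CO, Hα); neighbour corrections
(offsets −2…+2), temperature coefficients and pH terms are supported but
default to zero, and every analysis records which table version was used. A
reference-free alternative, `urea_difference_shifts()`, subtracts the shifts
measured in concentrated urea so the random-coil terms cancel entirely;
Cα differences beyond 1 ppm are flagged as atypical for a residually
structured unfolded state, since full helix formation moves Cα by only
about +2.6 ppm.

The secondary-structure-propensity (SSP) score combines the Cα and Cβ
secondary shifts in a sliding window (default 5 residues, uniform weights):
the shifts are summed with Cβ sign-inverted (helical sampling moves Cβ
upfield) and divided by the summed full-structure magnitudes — full-helix
values when the window consensus is positive, full-sheet values otherwise —
so that +1 means 100% helix propensity and −1 means 100% strand. Scores are
clamped to [−1, 1] (the raw ratio can exceed the bounds on noisy data),
shifts larger than 3 times the expected full-structure magnitude are
excluded as referencing outliers, and positions with fewer than two usable
shifts in the window are undefined rather than extrapolated. Glycine, which
has no Cβ, is scored from Cα alone. `region_helicity()` then averages the
score over each helix interval (defaults: I 12–25, II 31–45, III 51–56,
IV 65–79 in wild-type numbering) and reports percent helix.

Exact numerical agreement with any particular release of the original SSP
software is not attempted — reference sets differ between versions — but the
score is internally calibrated: simulated shifts carrying an injected helix
fraction *f* score *f* pointwise without noise, and regional recovery stays
within ±2 percentage points at realistic noise (0.03–0.05 ppm on carbon
shifts).

## HNHA couplings

The HNHA experiment encodes the ³J(HN–Hα) coupling in the cross- to
diagonal-peak intensity ratio, $I_\mathrm{cross}/I_\mathrm{diag} =
-\tan^2(2\pi J \Delta)$. `j_from_hnha()` inverts this as
$J = \arctan(\sqrt{-I_\mathrm{cross}/I_\mathrm{diag}})/(2\pi\Delta)$, with
Δ defaulting to 12.54 ms (a 25.08 ms mixing time). The arctangent bounds
recovered couplings inside $(0, 1/(4\Delta)) \approx (0, 19.9)$ Hz, so the
tangent singularity is unreachable by construction. Positive intensity
ratios indicate a phasing or assignment artefact and raise an error rather
than being clipped — silent clipping would hide a data problem. Uncertainties
propagate to first order from the two peak-height noises, assumed
independent, and no correction is applied for differential relaxation during
the delay. Couplings ≤ 6 Hz classify as helical, ≥ 8 Hz as extended.

## Hydrodynamics: from sedimentation coefficient to compaction

An observed sedimentation coefficient is first corrected to standard
conditions (water, 20 °C) using the buffer's density and viscosity at the
experimental temperature (user inputs) and packaged water correlations (the
Kell density polynomial and a CRC-style viscosity correlation, valid
0–45 °C). The Svedberg equation converts s₂₀,w to a translational friction
coefficient, $f = M(1-\bar v \rho_{20,w})/(N_A\, s_{20,w})$; the Stokes
reference sphere of equal anhydrous volume gives
$R_0 = (3M\bar v/4\pi N_A)^{1/3}$ and $f_0 = 6\pi\eta R_0$; and the
frictional ratio $f/f_0$ scales $R_0$ to the hydrodynamic radius
$R_h = (f/f_0)R_0$.

The reference sphere deliberately uses the **anhydrous** volume: the chain
of equations above closes exactly only for the equal-volume sphere, and the
package verifies the identity ($f/f_0 = 1$, $R_h = R_0$ to 1 part in 10¹⁰)
for a synthetic perfect sphere. An optional hydration parameter
(g water per g protein) is provided for users who want a hydrated reference,
but it defaults to 0. Sedimentation coefficients use 1 S = 10⁻¹³ s; a
packaged test recomputes one record fully in SI units to audit the cgs
conversions.

Empirical chain-length predictions (`wilkins_rh()`) use the power laws
4.75 N^0.29 Å for folded and 2.21 N^0.57 Å for highly denatured chains. The
chain length must include any expression-tag residues: for the His-tagged
87-residue Im7 construct the appropriate N is 94, which predicts 17.7 Å
folded and 29.4 Å denatured. `compaction_metrics()` reports the ratio of two
radii and the percent compaction.

## Stability and reporter assays

CD helical content at 222 nm is the variant-to-wild-type MRE ratio scaled by
50, the helicity of native wild-type Im7.

Equilibrium urea titrations are fitted to the standard two-state model with
linear baselines. The fitted $\Delta G^\circ_{UF}$ uses the unfolding
convention (positive for a stable fold, R = 8.314×10⁻³ kJ/mol/K); the
folding free energy $-\Delta G^\circ_{UF}$ is reported alongside because the
folding literature usually quotes that sign. Start values come from
straight-line fits to the first and last three points, m = 5 kJ/mol/M, and
the mid-signal crossing; the optimiser is Levenberg–Marquardt. Before
parameters are reported, an F-test (α = 0.01) must reject a straight line in
favour of the transition model; degenerate data that a line fits essentially
exactly are declared transition-free directly, because the six-parameter
model also fits them perfectly and the F statistic is undefined there. This
mirrors how a highly destabilised variant manifests: a titration without a
detectable cooperative transition is a *result*, and the fit refuses to
report parameters for it rather than returning noise.

Fluorescence emission maxima are refined to sub-nanometre resolution by a
parabola through the grid maximum and its neighbours (blue shifts of ~2 nm
are meaningful on a 1 nm grid); maxima at the spectrum edge are flagged, not
interpolated. The colicin-protection gamma statistic is the exact relative
luminescence increase over control.

## The synthetic-data generators

Each generator is a pure function of its parameters and seed, and emits data
in the same tabular dialects the readers consume:

* `simulate_r2_dataset()` — scaled intrinsic baseline + Gaussian-shaped
  cluster bumps (default centres 18, 42, 56, 73; amplitude 1.5 s⁻¹, width
  2.5 residues, noise 0.1 s⁻¹) with the truth returned for recovery scoring.
  Gaussian bumps are a choice, not a claim about cluster shape — any
  localised elevation exercises the detector.
* `simulate_shift_dataset()` — random-coil reference + region-wise
  fraction × full-helix offset (Cβ sign-inverted) + shift noise.
* `simulate_hnha()` — exact forward intensity ratios + intensity noise.
* `simulate_denaturation()` — two-state curves on the 0–8 M, 0.2 M-step urea
  grid (41 points) with Gaussian signal noise.
* `simulate_decay_series()` — monoexponential decays on the 11-point delay
  schedule, with optional duplicate points.

Noise is Gaussian and homoscedastic per observable. That emulates spectral
noise well, but real data also carry exchange broadening, baseline
distortions, peak overlap and referencing offsets that these generators do
not model — passing the recovery tests therefore demonstrates correctness of
the estimators under their stated assumptions, not robustness to every
experimental pathology.

## Problem sizes and numerical choices

The packaged tests run the heavier simulations at sizes chosen to give
stable statistics in seconds: 100 seeded titrations for stability-recovery
bias and interval coverage, 200 replicates per point for decay-rate and
coupling bias, 100 seeds for cluster sensitivity, and random sequences up to
N = 200 for the vectorised-versus-brute-force baseline identity (agreement
to 10⁻¹²). The AABUF smoothing window defaults to 9 residues (the scale's
common presentation; the profile is min–max normalised to 0–10, with
constant profiles mapping to 0 by convention), and the SSP window to 5.

## Known limitations

* The absolute scale of the intrinsic R₂ baseline is empirical; only its
  shape is predicted, so cross-dataset comparisons should compare fitted
  scales cautiously.
* The random-coil tables ship with base values only; users needing full
  neighbour/temperature/pH corrections should supply their preferred
  published correction set via `random_coil_reference()`.
* Two-state fitting assumes linear baselines and exactly two populated
  states; intermediates bias both ΔG° and m.
* The NMR-STAR reader handles the assigned-chemical-shift loop of v3 files,
  which is all this workflow needs; it is not a general STAR parser.
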