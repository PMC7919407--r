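---
title: "Models and methods behind ssrox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrox)
```

`ssrox` evaluates data-collection strategies for room-temperature serial
synchrotron rotation crystallography (SS-ROX). Because its statistics —
CC~1/2~, R~split~, Wilson B factors, the resolution-versus-photons scaling
law — are properties of *merged ensembles* rather than of single images, the
package pairs every analysis with a synthetic experiment generator that has
the same statistical structure as a real serial acquisition. This vignette
records the models, the defaults and why they were chosen, the numerical
details, and the limits of what the synthetic tests demonstrate.

## 1. Ground truth: Wilson intensities

A truth set (`generate_truth()`) enumerates the symmetry-unique reflections
of a unit cell to a resolution limit `d_min` and draws one true intensity per
reflection from the acentric Wilson distribution: an exponential law with
mean

$$\langle I\rangle(s) = \Sigma_0\, e^{-B\,s/2}, \qquad s = 1/d^2 .$$

Throughout the package $s$ is the square inverse of the Bragg spacing, so
this decay is equivalent to the familiar $\exp(-2B\sin^2\theta/\lambda^2)$.
All reflections are treated as acentric; centric zones (which follow a
half-normal law with larger relative variance) are deliberately omitted for
simplicity — for the tetragonal test cells they are a small minority and do
not change any ensemble statistic the package reports.

Supported Laue groups are `4/mmm` (the tetragonal holohedry of the
lysozyme-like default cell, a = b = 78.4 Å, c = 38.4 Å) and `identity`
(Friedel pairing only). The reciprocal-metric arithmetic is closed-form
triclinic; unit tests freeze d-spacings verified against an independent
crystallographic toolkit and a brute-force enumeration oracle.

Default truth parameters are `b_true = 13` Å² and `sigma0 = 100`, matching
the overall B factor of a well-ordered room-temperature lysozyme data set at
moderate dose.

## 2. The acquisition model

`simulate_stream()` emits one record per image, in scan-major acquisition
order (all images of scan 0, then scan 1, ...; indices 0-based). The default
geometry is 100 helical scans of 222 images (22 200 images per data set),
0.25°/image rotation, 9 µm translation, 20 µm scan spacing.

**Hits and indexing.** The number of crystal lattices in the beam is
Poisson(`lambda_crystals`); an image with ≥ 1 lattice is a *hit*; a hit
indexes with probability $q_1\,\gamma^{\,n-1}$, so every extra lattice
multiplies the single-lattice success rate $q_1$ by a decay factor
$\gamma$. This functional form is a modelling assumption — the simplest
mechanism that reproduces the empirical anti-correlation between hit rate
and index rate (dense loading produces multi-lattice images that defeat
single-lattice indexing). The defaults λ = 0.543, q₁ = 0.75, γ = 0.6 are
fixed to the operating point of the reference experiment the simulator
emulates: a 41.9% overall hit rate and 66.9% indexing of hits.

**What an indexed image sees.** Ewald-sphere geometry is *not* simulated.
Each indexed image observes a seeded random subset (`obs_fraction`, default
0.04) of the truth set with partiality drawn uniformly on (0, 1]. The
statistics the package exists for (CC~1/2~, R~split~, Wilson B, the scaling
law) depend on multiplicity and noise, not on which reflections co-occur on
an image, so modelling the co-occurrence structure would add cost without
changing any tested quantity. The Lorentz factor $L = 1/\sin 2\theta$ (with
$\sin\theta = \lambda\sqrt{s}/2$) is applied to recorded intensities exactly
as rotation hardware would, and divided back out during merging.

**Per-image scale.** Log-normal with median 1 and log-sd `scale_sdlog`
(default 0.2), covering crystal-volume and illumination variation.

**Radiation damage.** An intensity at resolution $s$ recorded after the
crystal absorbs dose $D$ (MGy) is damped by

$$\exp(-\beta\, f\, D\, s/2),$$

i.e. damage manifests as B-factor growth at rate β (Å²/MGy). The factor
`dose_fraction_applied` $f$ (default 0.5) encodes a mean-dose convention:
intensities integrated while the dose accumulates experience on average half
of it. Because serial collection exposes fresh crystals at every position,
$D$ is the *per-image* dose of the beam condition, not a cumulative dose.
The exponential-in-$s$ generative form is an assumption (real damage also
has specific chemistry); its fitted consequence is exact within the model:
the recovered Wilson B is $B_{\mathrm{true}} + \beta f D$, which the test
suite verifies. The default β = 15 Å²/MGy is calibrated so that B roughly
doubles (13 → ≈ 26 Å²) by 1.7 MGy, the behaviour of room-temperature
lysozyme.

**Unit-cell drift.** Each cell parameter follows a piecewise-linear
trajectory: linear from `start` to `end` over the first `knot` fraction of
the acquisition (default 0.5), constant afterwards, plus per-image Gaussian
jitter. This mimics the equilibration seen in humidity-controlled RT runs —
e.g. c growing from 38.38 to 38.79 Å (a 1% increase) and then holding
steady — without committing to a physical humidity model. Alternative
trajectory shapes were considered out of scope.

**Counting noise.** The expected *signal* counts of an observation are
`gain × photons_per_image × intensity`; underneath sits a scattering
background of `background_per_photon × photons_per_image` expected counts in
the spot integration area. Raw counts are Poisson(signal + background); the
known background expectation is subtracted (recorded intensities can
therefore be negative), Gaussian read noise (`read_noise_sd`, default 3
counts) is added, and

$$\sigma_{\mathrm{obs}} = \sqrt{\max(\mathrm{raw\ counts}, 0) +
\sigma_{\mathrm{read}}^2}$$

is mapped back to the intensity scale. The background term matters
structurally: if per-image noise were independent of the photon budget,
brighter (higher-dose) conditions would improve CC~1/2~ without bound and no
tolerable-dose plateau could exist. With background noise growing as
$\sqrt{N_{\mathrm{photon}}}$ while damage damps the signal exponentially in
dose, the simulator reproduces the observed behaviour that doses beyond
≈ 210 kGy stop paying.

**Calibration of the noise defaults.** `gain = 5e-12` and
`background_per_photon = 2e-10` were fixed, once, by requiring that the
reference beam condition (4.8×10¹² ph/s × 19.4% / 100 Hz = 9.3×10⁹
photons/image, 42 kGy/image) merged over ~3000 indexed images crosses
CC~1/2~ = 0.5 near 1.7 Å with low-resolution CC~1/2~ ≈ 0.99 and highest-shell
⟨I/σ⟩ ≈ 1–2 — the data quality of the experiment the simulator emulates.

**Reproducibility.** One master seed drives a simulation. Every stochastic
stage (truth, lattice counts, indexing, scales, per-image observation
subsets, counting noise, per-image cell jitter) draws from its own substream
whose seed is derived from (master seed, stage key) by a polynomial string
hash mod 2³¹−1. Identical seeds and configurations give bit-identical
streams, and adding a stage never perturbs the draws of existing ones.

## 3. Monte Carlo merging and half-set statistics

`estimate_image_scales()` implements iterative per-image linear scaling:
pass 0 merges the Lorentz-corrected observations unscaled into a reference
$R_h$; each of `n_iterations` (default 3) passes then sets

$$g_j = \frac{\sum_h I_{jh} R_h}{\sum_h R_h^2}$$

— the least-squares slope of image $j$'s intensities on the reference — and
re-merges with $I/g$. Scales are renormalised to geometric mean 1 (only
relative scales are identifiable) and clamped to [0.01, 100] to guard
degenerate images; a degenerate scale is reset to 1 and counted in a
returned flag rather than stopping the run.

`monte_carlo_merge()` averages the corrected observations per Laue-unique
index. The merged σ is the *sample* standard deviation over the multiplicity
divided by √m (undefined at m = 1), not a propagation of the per-observation
σ — per-observation sigmas are unreliable for partial serial observations,
and the scatter-based estimate is the Monte Carlo merging convention. Half
sets are split by image-index *parity* (even/odd acquisition index), the
deterministic analogue of the usual odd/even split; CC~1/2~ is the Pearson
correlation of the half-set means and

$$R_{\mathrm{split}} = 100\cdot 2^{-1/2}\,
\frac{\sum_h |I_e - I_o|}{\tfrac12 \sum_h (I_e + I_o)}$$

with the 1/√2 prefactor compensating for each half holding half the data.
Whether CC~1/2~ should be computed on scaled or unscaled halves is not
universally specified; `ssrox` computes it on the scaled merge.

`shell_statistics()` uses equal-count shells (default 20) over the
*theoretically possible* reflections: boundaries are chosen so each shell
holds an equal share of the enumerated unique reflections, matching the
shell populations of standard serial-crystallography reporting tools.
Degenerate spacings of the tetragonal metric put ties at some boundaries, so
per-shell possible counts can differ by a few. Completeness is
100·observed/possible per shell.

## 4. The tanh CC~1/2~ resolution estimate

The per-shell CC~1/2~ values are fitted (on shell midpoints in $s$; the fit
is defined on the $s$ axis, so midpoints in $s$ are the consistent abscissa)
with the variable-plateau sigmoid

$$CC(s) = \tfrac12\{1 - \tanh[(s - d_0)/r]\}\,d_{cc} - d_{cc} + b ,$$

which plateaus at $b$ at low resolution and $b - d_{cc}$ at high resolution.
Fixing $b = 1$ is the classical choice; `ssrox` frees it (bounded at 1.05)
because sets merged from few images sit visibly below 1 even in
low-resolution shells. The least-squares fit (Levenberg–Marquardt) is
unweighted by default, with optional shell-count weights. Initialisation:
$b$ ← max CC, $d_{cc}$ ← CC range, $d_0$ ← first $s$ below the half-drop,
$r$ ← a tenth of the $s$ range; bounds $r > 0$, $d_{cc} \in (0, 1.5]$,
$b \in [-0.5, 1.05]$. Constant input collapses $d_{cc}$ onto its bound and
is returned as a flagged non-converged result with residuals, never an
exception.

The threshold crossing is closed-form:

$$s^* = d_0 + r\,\mathrm{artanh}\!\Big(1 - \frac{2(\tau + d_{cc} - b)}{d_{cc}}\Big),
\qquad d = 1/\sqrt{s^*},$$

valid when $b - d_{cc} < \tau < b$; a threshold outside the plateaus or a
crossing at $s^* \le 0$ raises a descriptive error. The inversion is tested
against bisection on the forward model at 10⁻⁹.

## 5. The photon-budget scaling law

Across data sets of increasing merged-image count the achieved resolution
follows

$$1/d^2 = a \ln(b\, N_{\mathrm{photon}}),$$

fitted by ordinary least squares in $(\ln N, 1/d^2)$. $N_{\mathrm{photon}}$
counts photons over the *merged (indexed)* images only, each image worth
flux × transmission / frame-rate photons. The reference coefficients used as
defaults are a = 0.044 Å⁻², b = 6.5×10⁻¹¹ photons⁻¹; note that a is
sometimes quoted tenfold larger (0.44), but only 0.044 is consistent with
the observed 1/d² range of ≈ 0.25–0.39 Å⁻² over N ≈ 2×10¹²–1.3×10¹⁴
photons, so 0.044 is used wherever a single value is needed and the
discrepancy is documented rather than silently resolved.

The model supports planning: `predict_resolution()` inverts the law,
`images_needed()` returns ⌈exp((1/d²)/a)/(b·photons per image)⌉, and
`zero_crossing()` gives the measurability threshold N₀ = 1/b ≈ 1.5×10¹⁰
photons below which 1/d² ≤ 0 — no meaningful data.

**Wilson-plot interpretation.** Starting from the Wilson plot with the
squared atomic scattering factor approximated by a single exponential,
$\overline{f^2}(s) \approx \overline{f^2}(0)\, e^{-k_f s}$, the mean
recorded intensity at resolution $s$ of a data set built from
$N_{\mathrm{photon}}$ photons is proportional to
$n\,c\,N_{\mathrm{photon}}\overline{f^2}(0)\,e^{-(B/2 + k_f)s}$, with $n$
the atoms in the unit cell and $c$ the proportionality constant between
photons and recorded intensity. Setting this equal to the minimum measurable
intensity $I_{\min}$ at $s = 1/d^2$ gives the logarithmic law with

$$a = \frac{2}{B + 2k_f}, \qquad
b = \frac{\overline{f^2}(0)\, n\, c}{I_{\min}} = \frac{21.3\, n\, c}{I_{\min}},$$

where 21.3 is the zero-angle mean squared scattering factor per atom for
protein composition (H through S, hydrogen included). Inverting the slope
relation gives the mapping shipped as the default of the pluggable
`b_mapping` argument of `wilson_interpretation()`:

$$B = 2/a - 2 k_f, \qquad k_f = 5.08\ \text{Å}^2,$$

so a = 0.044 maps to B = 35.3 Å². This B is roughly twice the directly
fitted Wilson B of the corresponding merged data — the single-exponential
approximation of $\overline{f^2}$ degrades at high resolution, so the
mapping is semi-quantitative and is kept isolated behind one documented,
replaceable formula rather than hard-coded into the model core.

## 6. Dose, photon and rate bookkeeping

Exposure time is 1/frame-rate exactly, so `photons_per_image()` =
flux × transmission / frame-rate and `dose_per_image()` = dose-rate /
frame-rate (reported in kGy). The standard dose ladder
(`dose_series_conditions()`) reaches 21–210 kGy at 100 Hz by attenuation and
420–1700 kGy by reducing the frame rate at full transmission and a 23 MGy/s
dose rate; the reduced-frame-rate rows compute to 426, 852 and 1769 kGy
against their nominal 420/830/1700 labels, and both values are carried
(`dose_kgy_computed` vs `nominal_dose_kgy`) because the nominal labels
follow a presentation rounding whose exact path is not recoverable.

`rate_summary()` reports per-set and pooled hit and index rates;
percentages are carried at full precision with display columns rounded
half-up (not half-even) to one decimal, matching standard table
presentation. An index rate over zero hits is `NA` and counted in a flag
attribute, not an error.

## 7. Drift and damage analyses

`bin_cell_drift()` divides the full acquisition — *all* images, including
non-hits — into sequential bins (default 10) and reports mean ± σ of each
cell parameter over the *indexed* images per bin; empty bins are flagged.
The package deliberately ships no automatic "stable region" selector: which
bins to merge is a data-driven judgement the analyst should make from the
bin table.

`wilson_b()` regresses ln(shell-mean merged intensity) on shell-mean $s$
over equal-count shells and reports B = −2 × slope. The default fit range
starts at $s \ge 0.1$ Å⁻² (≈ 3.2 Å) to avoid the low-resolution non-Wilson
regime; shells with non-positive mean intensity are excluded. Shell
averaging of an exponential leaves a small Jensen bias (≈ 0.1% of B at the
default shell widths), which is why even the noiseless oracle test uses a
tolerance rather than exact equality.

`b_ratio_series()` forms the damage metric B₀/Bₙ against dose. Local
(per-atom) damage metrics are out of reach without structure refinement;
the package substitutes the overall Wilson-B ratio and says so here
explicitly.

## 8. Problem sizes and what the tests show

The test and acceptance suites run the full pipeline at desk scale, chosen
to keep the whole suite within a few minutes while preserving the statistics
of interest: truth sets to 1.5 Å (merged-image series, ~20k unique
reflections) and 1.3 Å (dose series, ~30k), 250–4000 merged images for the
scaling-law series, 3000 merged images per dose point, 20 shells. At these
sizes the simulated series reproduce, with fixed seeds: monotone resolution
improvement with merged-image count spanning ≈ 2.3 → 1.7 Å; linearity of
1/d² in ln N (R² ≥ 0.99); and a tolerable-dose plateau with degradation at
830–1700 kGy.

Passing these tests demonstrates that the *statistical machinery* — Wilson
sampling, Poisson hits, scaling, merging, half-set statistics, the sigmoid
fit, the law's emergence from the pipeline — is internally correct and
calibrated to a realistic operating point. It does not validate detector
physics: the generator has no Ewald-sphere geometry, no co-occurrence
structure, no centric statistics, no preferred orientation, no real
background profile or spot shape, and its damage and drift laws are idealised
forms. Conclusions about a real instrument require real streams, for which
the text stream format is a deliberately simplified stand-in.

## 9. Numerical choices, edge cases, limitations

* Scales clamped to [0.01, 100]; degenerate scales flagged, reset to 1.
* Merged σ undefined (NA) at multiplicity 1; CC~1/2~ undefined below 3
  half-set pairs or at zero variance — flagged, never thrown.
* Shell boundaries: upper edges inclusive; first shell starts at s = 0; ties
  at degenerate spacings may shift possible counts by a few per shell.
* The stream text format writes 17 significant digits so read(write(x))
  round-trips every stored numeric exactly; unknown header keys are
  preserved; malformed lines fail with the line number; a missing final
  blank-line terminator is reported as truncation.
* Percent display rounding is half-up, full precision retained.
* The helical-scan nominal rotation bookkeeping stores the per-image step
  only; a ±0.25° bookkeeping ambiguity in the total rotation of a 222-image
  scan at 0.25°/image is noted and left unresolved.
* `hit_model()` parameters are user-set, not fitted from data; estimating
  (λ, q₁, γ) from observed hit/index tables is future work.
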