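---
title: "Models and methods in hyaloSF"
author: "hyaloSF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hyaloSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyaloSF)
```

# Scope

hyaloSF implements the computational chain used to characterize hyaluronan
(HA) and its heavy-chain complexes in synovial fluid, such as in equine
osteoarthritis cohorts: molecular-weight (MW) distributions from gel
densitometry and from solid-state nanopore traces, viscosity from passive
particle-tracking microrheology, heavy chain–HA (HC-HA) quantification from
paired immunoblots, and the cohort-level statistics tying these together.
Wet-lab procedures, raw-video particle tracking, SEC-MALS instrument
processing and image scoring are out of scope; trajectories, band densities
and lane profiles are inputs. Seeded generators reproduce every input
modality with known ground truth so the whole chain is testable without
clinical samples.

# Molecular-weight distributions

A distribution is a discrete grid of masses $M_i$ (kDa) with non-negative
weights $w_i$. With mass weighting (stain intensity is proportional to the
mass in a slice),

$$M_w = \frac{\sum_i w_i M_i}{\sum_i w_i}, \qquad
  M_n = \frac{\sum_i w_i}{\sum_i w_i / M_i}, \qquad
  \mathrm{PDI} = M_w / M_n \ge 1 .$$

These are the standard definitions of the weight- and number-average
molecular weight of a polymer sample; PDI $\ge 1$ follows from the
Cauchy–Schwarz inequality with equality only for a monodisperse sample.
Number-weighted data (one count per nanopore event) are converted with
$w_i = n_i M_i$ before the mass-weighted formulas are applied, which makes
the summaries equal to the event-sample statistics $M_n = \bar M$ and
$M_w = \sum M^2 / \sum M$.

Weights are interpreted as *mass per grid slice*. When the slices are gel
pixels we deliberately apply **no Jacobian correction** for the nonlinear
pixel-to-MW map: the densitometric reading of a pixel already is the mass
that migrated there, so re-weighting by $|dM/dx|$ would double-count the
transformation. Masses are stored in kDa throughout; Da are converted once
on input.

# Gel densitometry

A lane profile is intensity versus migration distance (pixels from the
well, 0 at the well, increasing toward the front — distances on a unit
pixel grid).

**Background.** The baseline is a morphological opening of the profile
(erosion then dilation), with either the classical ball-shaped structuring
element or a flat one. An opening never exceeds the signal, so subtracted
intensities are non-negative, and it is equivariant under constant offsets.
Two practical caveats are documented rather than hidden:

* The ball element couples the pixel axis to the intensity axis, so its
  effect depends on the intensity scale (the same behavior exists in the
  classical 2-D implementation, which rescales images internally). The flat
  element is scale-free.
* The radius must exceed the half-width of features that should *survive*.
  HA smears are hundreds of pixels wide; a radius of tens of pixels treats
  the smear itself as background. For flat-offset removal under a broad
  smear, a radius of at least the profile length (equivalent to subtracting
  the global minimum) is the conservative choice. The default radius is
  50 px and is appropriate for narrow-band work, not for smears.
* An opening rides along the *lower envelope* of the noise, so after
  subtraction the residual noise floor sits several noise SDs above zero
  along the entire lane. Because every pixel maps to a mass, this residue
  leaks weight into the extreme MW bins and inflates PDI. `gelMWSummary()`
  therefore takes a `noiseFloor` (default 0); about 6 times the per-pixel
  noise SD suppresses the residue in our synthetic experiments.

The 1-D opening on profiles is assumed interchangeable with the original
2-D rolling ball on the gel image followed by profiling; for lane-shaped
regions the two differ only through cross-lane averaging, which the
extraction step performs anyway.

**Calibration.** Ladder anchors (migration px, MW kDa) must have MW
strictly decreasing with distance. The map is piecewise linear in
(distance, $\log_{10}$ MW): exact at every anchor, monotone by
construction, and free of the oscillation a global polynomial can add. No
functional form is claimed beyond interpolation; queries outside the anchor
range return `NA` and the affected intensity fraction is reported as
`excludedFraction` rather than extrapolated — MW beyond the ladder is not
measurable. Ladder band masses are configuration inputs (commercial HA
ladder compositions vary); the test suite uses a deliberately wide
synthetic ladder (20–80 000 kDa) so simulated log-normal tails stay in
range.

# Solid-state nanopore sizing

Traces are ionic current in pA sampled at 200 kHz (the standard acquisition
rate). The analysis chain:

1. **Filter**: zero-phase 4th-order Butterworth low-pass at 5 kHz
   (`filtfilt` forward–backward, unit DC gain). The trace is
   reflection-padded by 20 filter time constants so the IIR start-up
   transient never touches the data. The acquisition-side 100-kHz Bessel is
   part of the simulated instrument, not re-applied in analysis.
2. **Baseline and noise**: median and scaled MAD (1.4826) of the *filtered*
   trace. Robust estimators shift by well under 2% when events occupy a few
   percent of the samples, where mean/SD would be badly biased. Whether the
   original instrument software computed its SD before or after filtering
   is unknowable from the description; filtered is the default here and
   matters only through the threshold scale.
3. **Detection**: maximal runs with deviation $\ge k\sigma$ from baseline
   ($k = 5$ by default), blockade direction (below baseline) by default and
   configurable, since the sign of a blockade depends on the voltage
   convention. Runs with duration outside [25 µs, 2.5 ms] are discarded.
   Indices are 1-based and inclusive (the R convention);
   `duration_s = n_samples / rate`.
4. **Ringing merge**: a zero-phase filter at cutoff $f_c$ rings with lobes
   of order $1/(2 f_c)$; inside one deep event the current can rebound
   briefly above threshold, splitting the run. Runs separated by less than
   `mergeGapS` (default 200 µs $\approx 1/f_c$) are merged before gating.
   Physical inter-event gaps at the measured rates are milliseconds, three
   orders of magnitude larger, so the merge cannot join distinct molecules
   in practice; set `mergeGapS = 0` to disable.
5. **ECD**: the event charge deficit is
   $\sum |i_t - \text{baseline}|\,\Delta t$ over the event's samples
   (pA s; 1 pA s = 1000 fC) — integration over the above-threshold samples,
   matching a threshold-referenced instrument definition.
6. **Calibration**: least-squares line in (log ECD, log MW) through the
   per-standard mean ECDs of seven quasi-monodisperse HA standards
   (54–2384 kDa). Only the means enter; the standards' residual
   polydispersity (1.001–1.035) is ignored. Conversions outside the
   standard range are flagged as extrapolated. A log-log line is the
   minimal monotone model consistent with a power-law ECD–mass
   relationship; nothing stronger is assumed.

The trace simulator realizes each event as a rectangle (duration uniform in
[50 µs, 2 ms], depth = ECD/duration) because the rectangle has an exact,
analytic ECD; a filtered trace then exercises the detector under realistic
edge smearing. Durations are resampled when the implied depth would fall
below 6 noise SDs — below the detection design point, such events are not
part of the calibrated regime. Overlapping placements are rejected with a
250-µs guard interval. The default synthetic ECD calibration
(`simECDCalibration()`, ECD $= 2\times10^{-5}\,\mathrm{MW}^{1.2}$ pA s) is a
simulation convention chosen to give realistic 10–800 pA depths, not a
measured curve.

# Microrheology

Bead trajectories (2-D positions, µm, uniform frame interval; 16 Hz, three
30-s videos with ~15 beads each in the reference acquisition) are reduced
to the time- and ensemble-averaged mean-squared displacement,

$$\mathrm{MSD}(\tau) = \langle \Delta x^2 + \Delta y^2 \rangle ,$$

averaging over all start frames of all tracks with pair-count weights. A
weighted least-squares line $\mathrm{MSD} = 4 D \tau + b$ over lags 1–8
(0.0625–0.5 s at 16 Hz) gives the diffusion coefficient; the intercept $b$
absorbs static localization noise so it does not bias $D$. The lag window
balances statistics (short lags have many pairs) against the downward bias
long lags suffer from finite track length; it is configurable. Viscosity
follows from Stokes–Einstein for a sphere,

$$\eta = \frac{k_B T}{6 \pi r D},$$

reported in cP (1 cP = 1 mPa s). Defaults: $T = 295.15$ K (22 °C, the
temperature stated for the companion viscometer measurements; the
microscope stage temperature is not separately known) and bead radius
0.25 µm. The source protocol names a "0.5-nm" bead but the product used is
the 0.5-µm FluoSpheres microsphere; we treat the nm figure as a typo — a
0.5-nm tracer would diffuse six orders of magnitude faster and could not be
imaged as a particle at 16 Hz. The radius is configurable for other beads.
Only a Newtonian viscosity is reported (no $G'$/$G''$), matching the
measurement being reproduced; drift correction is off by default and
available as per-video mean-displacement subtraction. Samples with fewer
than 5 tracks or 200 displacement pairs are flagged `wide_uncertainty`, and
a non-positive fitted slope yields no viscosity rather than a meaningless
one.

# Immunoblot HC-HA

Each sample runs as a lane pair: undigested ("−", endogenous free heavy
chain) and hyaluronidase-digested ("+", endogenous plus HA-released heavy
chain). The HC band is normalized to the Pre-IαI band *of the same lane* —
the formula is per-lane, which makes the result invariant to per-lane
exposure differences — and

$$\mathrm{a.u.} = \frac{\mathrm{HC}^{+}}{\mathrm{PreI\alpha I}^{+}}
               - \frac{\mathrm{HC}^{-}}{\mathrm{PreI\alpha I}^{-}} .$$

Negative values (digestion or loading noise) are retained, not clamped;
group summaries use medians, which are robust to them. Rows with a
non-positive normalizer band are flagged and excluded instead of aborting
the batch.

# Cohort statistics

**Normality-gated comparison.** Shapiro–Wilk (α = 0.05) in both groups on
the raw data; if both pass, Welch's unpaired t-test with means ± SEM.
Otherwise a skew-directed transform — cube root for right skew, log for
left skew, direction decided by the sample skewness sign and overridable
per variable — and the t-test on the transformed scale if normality is then
achieved; otherwise the Wilcoxon rank-sum test with medians ± IQR. The rank
test is exact for combined n ≤ 40 without ties and uses the tie-corrected
normal approximation with continuity correction otherwise. The report
records the path taken. Under a null of one common skewed distribution the
gate's empirical type-I error over 1000 simulations stays near the nominal
0.05 (the adaptive choice inflates it slightly; both branch tests are
level-α, and rank tests are invariant under the monotone transforms
involved). No multiple-testing correction is applied by default, matching
the analysis being reproduced; Benjamini–Hochberg can be applied to the
reported p-values by the caller.

**Gene expression.** $\Delta C_T = C_T(\text{gene}) - C_T(\text{18S})$,
$\Delta\Delta C_T = \Delta C_T - \text{center}(\Delta C_T^{\text{healthy}})$,
fold $= 2^{-\Delta\Delta C_T}$. The source description is internally
inconsistent — the formula text centers on the healthy *average* while the
reporting convention anchors the healthy *median* at fold 1.0. Both are
implemented; the median is the default so that the healthy median fold is
exactly 1.0.

**Immunoassay calibration.** The five-parameter logistic
$y = a + b/(1 + (x/c)^d)^f$ is fitted by Levenberg–Marquardt with $c, d, f$
constrained positive (curve direction is carried by the sign of $b$), from
data-driven starts; all-equal responses are rejected as degenerate.
Inversion uses the closed form
$x = c\,((b/(y-a))^{1/f} - 1)^{1/d}$; responses at or beyond the asymptotes
$a$ and $a+b$ are censored with a below-/above-range flag, and zeros from
censored cytokines can be floored (`floorUndetectable`, default 1, to be
chosen below the assay's detection limit). With $f = 1$ the model reduces
to the 4PL, which serves as an independent cross-check in the tests.

**Viscosity–concentration law.** $y = B_0 + B_1 x + B_2 x^2$ constrained to
$B_0 = 1, B_1 = 0$ (relative viscosity 1 at zero polymer) has the closed
form $B_2 = \sum x_i^2 (y_i - 1) / \sum x_i^4$; $R^2$ is reported as-is and
may be ≤ 0. Spearman correlations use average ranks with a two-sided
p-value. Intra-assay CV is the mean over samples (and plates) of
$100\,s/\bar x$ with the $n-1$ sd; note that duplicate-based sample SDs are
biased low by $c_4(2) = \sqrt{2/\pi}$, which matters when comparing a
target CV to duplicate-derived estimates. The viscometer replicate filter
removes all segments at the lowest flow rate (the 950 s⁻¹ shear-rate pair,
excessively variable), retaining 5 of the 7 standard segments.

# Synthetic data: what it does and does not show

Generators take an explicit integer seed, are bit-reproducible, and never
touch the caller's RNG stream. Defaults encode the reference study
conditions: cohort sizes 25 healthy / 61 OA; gel targets $M_w$ 3660 kDa /
PDI 2.26 (healthy) and 3070 / 2.38 (OA); cytokine and HC-HA group medians
and IQRs from the reference tables (TNF-α 4.97/15.6, CCL11 0.86/0.53,
HC-HA 0.10/0.38); viscosity generated from HA concentration through
$y = 1 + B_2 x^2$ with $B_2 = 434$ (OA) and 256 (healthy) and log-normal
noise (sdlog 0.2, a chosen plausible scatter); 45 Brownian tracks of 480
frames (three 30-s videos at 16 Hz); nanopore events Poisson-arriving at
20–50 s⁻¹ over 5–20 s of 200-kHz trace. Where the study states no value
(noise SDs, baseline current 4000 pA, blot base ratio 0.3), one realistic
value was chosen and fixed.

The log-normal MW generator solves the moment relations in closed form
($\sigma^2 = \log \mathrm{PDI}$, $\mu = \log M_w - \sigma^2/2$ for the
mass-weighted density), so its analytic $M_w$ and PDI equal the targets
exactly and discretization is the only approximation. Cohort variables are
*independent* log-normals matched to medians and IQRs (except the
deterministic-plus-noise viscosity link), so passing tests demonstrate
correct computation and effect-direction recovery — not the covariance
structure, outliers, censoring patterns or assay drift of real synovial
fluid. Likewise the rectangular-event trace and pure Brownian tracks omit
pore clogging, multi-level events, drift and localization-error
correlation; recoveries within the stated tolerances on these inputs bound
algorithmic error, not instrument error.

Problem sizes in the tests and the acceptance script (20 gel lanes, ~1000
nanopore events over 20 s of trace, 45×480-frame track sets, 1000 null
simulations) were chosen as the smallest sizes at which the Monte-Carlo
error of each check is comfortably below its tolerance.

# Numerical conventions and degenerate inputs

* 1-based, inclusive indices everywhere (R convention); half-open
  quantities are expressed through explicit `n_samples`.
* Units: kDa, pA, pA s (ECD; ×1000 = fC), µm, µm²/s, cP, K recorded per
  column in cohort CSVs (`#units` row).
* Ties in Spearman and Wilcoxon use average ranks / tie corrections;
  constant vectors are flagged, not errored, where a summary can proceed.
* Degenerate inputs fail loudly and specifically: empty or all-zero
  distributions, non-monotone calibrations (the offending anchor pair is
  named), zero in-range lane intensity, σ ≤ 0 detection thresholds,
  non-positive Pre-IαI normalizers, all-equal 5PL responses.
* A single 2-frame trajectory runs end to end and is flagged rather than
  refused; a non-positive diffusion slope yields no viscosity.

# Interfaces

The package's exported functions and classes are the interface, organized
as S4 classes with validity checks (`MWDistribution`, `LaneProfile`,
`GelCalibration`, `CurrentTrace`, `ECDCalibration`, `TrackSet`,
`MSDCurve`, `RheologyConfig`, `FiveParamLogistic`, `CohortTable`) plus
plain-text I/O (CSV with a units row, trace/trajectory/event CSVs) and the
umbrella driver `runFullAnalysis()`, which runs configured stages on seeded
synthetic inputs and writes a JSON + markdown report. No shell executable
is shipped; `scripts/acceptance.R` shows the scripted usage pattern.

# Known limitations

* Gel background subtraction on broad smears requires a radius/floor choice
  by the analyst; there is no automatic radius selection.
* The ECD–MW calibration is a single log-log line; curvature across three
  decades of MW, if present in a real pore, becomes calibration residual.
* The event detector models single-level blockades only.
* The 5PL fit can be sensitive to poor dynamic-range coverage; convergence
  diagnostics are returned and should be inspected.
* Cohort simulation draws variables independently; correlation-structure
  claims beyond the viscosity–concentration link cannot be tested on it.
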