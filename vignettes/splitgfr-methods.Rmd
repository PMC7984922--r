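---
title: "Methods: split GFR from scintigraphy and dual-plasma clearance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split GFR from scintigraphy and dual-plasma clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgfr)
```

## The measurement problem

Per-kidney glomerular filtration rate is the quantity that decides
whether a hydronephrotic or tumour-bearing kidney is worth preserving.
The two established measurements are complementary and individually
insufficient:

* **Dual-plasma (slope-intercept) clearance** of Tc-99m-DTPA measures
  *total* GFR accurately — two blood draws at 2 h and 4 h, counted per
  mL, assuming mono-exponential late plasma disappearance — but is blind
  to the left/right division.
* **Gates camera processing** of the dynamic renogram divides function
  between kidneys, but its absolute values inherit error from every
  operator-dependent step: background-ROI placement, attenuation/depth
  assumptions, net-dose measurement, and the empirical uptake-to-GFR
  regression.

The combined estimator implemented here uses each measurement for what
it is good at. The renogram is processed with *kidney outlines only*
(blank background, gGFR′), which removes the single most
operator-sensitive step; only the ratio
`gGFR′_L / (gGFR′_L + gGFR′_R)` is retained. The dual-plasma tGFR then
sets the scale:

$$\mathrm{pGFR}_L = \frac{\mathrm{gGFR}'_L}{\mathrm{gGFR}'_L +
\mathrm{gGFR}'_R}\,\mathrm{tGFR}, \qquad
\mathrm{pGFR}_R = \mathrm{tGFR} - \mathrm{pGFR}_L.$$

Conservation $\mathrm{pGFR}_L + \mathrm{pGFR}_R = \mathrm{tGFR}$ holds
exactly in `split_pgfr()` because the right kidney is computed as the
remainder; the ratio form alone can drift by an ulp.

## The plasma module

`dual_plasma_gfr()` evaluates

$$\mathrm{GFR} = \frac{D\,\ln(P_1/P_2)}{T_2-T_1}
\exp\!\left[\frac{T_1\ln P_2 - T_2\ln P_1}{T_2-T_1}\right],$$

with times in minutes, which equals $D k / P_0$ for the
mono-exponential through the two samples.

**Numerical form.** The implementation uses the algebraically identical
$D\hat k/(P_1 e^{\hat k T_1})$ with
$\hat k = \ln(P_1/P_2)/(T_2-T_1)$: the textbook exponent
$(T_1\ln P_2 - T_2\ln P_1)/(T_2-T_1)$ subtracts two numbers of order
$T\ln P$ (thousands) to produce one of order $\ln P_0$ (units), and the
avoided cancellation is worth roughly a factor two in worst-case ulp
error. A sensitivity analysis is worth recording here because it bounds
what any implementation can promise: perturbing the plasma counts by
relative $\delta$ perturbs the result by roughly
$\delta\,[1/(k\Delta T) + T_2/\Delta T]$. Input rounding alone
($\delta \approx \varepsilon/2$) therefore exceeds 10 ulp whenever the
plasma declines by only a few percent between draws. The package's
property tests consequently sample the protocol's *operating domain* —
draws at 2 h/4 h (±10 min) and clearance constants
$k \in [0.004, 0.03]\,\mathrm{min}^{-1}$, i.e. at least ~38% decline
between samples, the regime in which a two-sample design is informative
— where the measured worst-case error is below 7 ulp.

**Corrections.** No Brøchner–Mortensen (or other single-compartment)
correction is applied by default: the uncorrected slope-intercept value
is what this method calls tGFR. A hook exists
(`splitgfr_config(brochner_mortensen = TRUE)`, adult polynomial).
Physical decay correction of plasma counts is likewise off by default —
when both samples are counted in one session the decay factor cancels
in $\ln(P_1/P_2)$ only partially, but the reference procedure counts
both with the dose calibration, and `decay_correct_rate()` (half-life
6.0058 h) is available for split counting sessions.

**Units.** Times are minutes; feeding hours silently multiplies GFR by
60, so the API documents minutes everywhere and the test suite pins the
trap.

**Scale of tGFR entering the apportioning.** The reporting unit of the
camera method is mL·min⁻¹·(1.73 m²)⁻¹, so the default
(`tgfr_scale = "bsa"`) apportions the BSA-normalized tGFR; a `"raw"`
switch exists. The split fraction is unaffected either way. BSA uses
DuBois ($0.007184\,W^{0.425}H^{0.725}$) by default, Haycock as the
alternative.

## The Gates module

Processing steps, each an exported function and each configurable
through `splitgfr_config()`:

1. **Uptake window** `[120, 180)` s post-injection (the classic 2–3 min
   window). Frames overlapping the window partially are weighted by
   their overlap fraction (`frame_window_weights()`); for the standard
   schedule of 30 × 2 s + 20 × 60 s frames the window selects exactly
   one 60 s frame.
2. **Background.** Conventional variant: predicted background under
   each kidney = mean counts per pixel of that side's background ROI ×
   kidney ROI pixel count. The blank-background variant subtracts
   nothing. Negative net counts are clamped to zero with a warning —
   a displaced background ROI over a hot structure can predict more
   counts than the kidney ROI holds, and an error would be wrong since
   the clamp is the standard defensive behaviour.
3. **Depth/attenuation.** Tønnesen depths
   $d = a\,(W/H) + b$ (left $a=13.2$, right $a=13.3$, $b=0.7$ cm;
   weight kg, height cm) and attenuation factor $e^{-\mu d}$ with
   $\mu = 0.153\,\mathrm{cm}^{-1}$ for the 140 keV photopeak. All three
   constants live in the config block, not in code.
4. **Dose.** Net injected rate = full-syringe rate − residual rate,
   optionally decay-corrected to injection time (off by default; vendor
   practice varies and the flag is explicit).
5. **Regression.** $\mathrm{GFR} = 9.8127 \times \mathrm{uptake\%} -
   6.82519$, clamped at zero; per-kidney values split the total in
   proportion to attenuation-corrected counts.

Only the posterior view is analysed by default (classic Gates);
anterior frames are accepted and stored, and a geometric-mean mode is a
config choice rather than a default because the reference procedure the
package follows is posterior-view.

Degenerate inputs: if the regression clamps the *total* to zero, the
per-kidney split falls back to 0.5/0.5 inside `gates_pipeline()` (the
GFRs are all zero anyway); `evaluate_recovery()` apportions tGFR by the
uptake ratio instead of the gGFR′ ratio in that case, since the uptake
ratio carries the same left:right information without the regression's
intercept.

## Concordance statistics

`kendalls_w()` ranks subjects within each rater (average ranks on
ties) and computes

$$W = \frac{12\,S}{m^2(n^3-n) - m\sum_j T_j},\qquad
T_j = \sum_{\text{tie groups}} (t^3 - t),$$

with $S$ the sum of squared deviations of subject rank-sums. The
chi-square approximation $\chi^2 = m(n-1)W$ on $n-1$ df provides the
p-value; for small tables a permutation p-value is available
(`p_method = "permutation"`), enumerated exhaustively when
$(n!)^{m-1} \le 2\times10^5$ and Monte-Carlo sampled otherwise — a full
exact enumeration is infeasible beyond toy sizes, which is why the
chi-square form is the default (the intended use has $n \ge 60$, well
inside its validity). A table in which every rater is constant carries
no ranking information and is reported as `NA` with a warning rather
than a spurious 0 or NaN.

**Stacking.** The method reports a single W per processing variant over
split-kidney values. The package's default stacks left and right
kidneys as separate "subjects" ($n = 2\times$ patients); per-side modes
exist (`stacking = "left"/"right"`). Per-kidney values enter the tables
raw (not BSA-normalized) in `evaluate_recovery()` so that concordance
reflects ROI handling, not biometric differences.

`pearson_r()` (product-moment r, $r^2$, t-based two-sided p) supports
correlating tGFR with biochemical indices. Note that $r^2$ is a square:
a negative "coefficient of determination" sometimes seen in clinical
reports is not reproducible by any correct computation, and the package
makes no attempt to.

## The phantom

`simulate_cohort()` generates everything the pipeline consumes, with
known truth. Its defaults *are* the study conditions the package is
validated under; they were fixed once, on the grounds below, and the
test suite treats them as frozen.

**Kinetics.** Plasma concentration
$c(t) = (D/V_p - D/V)e^{-\alpha t} + (D/V)e^{-kt}$ with
$k = \mathrm{tGFR}/V$. The fast phase has fully decayed by the 2 h
draw, so the 2 h/4 h samples lie exactly on the mono-exponential and
noiseless dual-plasma processing inverts the construction to float
precision. Each kidney accumulates tracer at
$\mathrm{split}_s \times \mathrm{tGFR} \times c(t)$, carries a small
vascular component (0.3% of dose at $t=0$, following the blood curve),
and is attenuated by $e^{-\mu d_s}$ with Tønnesen depths from the
subject's simulated biometrics — so the pipeline's depth correction
inverts the geometry exactly rather than approximately.

**Calibration.** $V = 200$ mL/kg (extracellular volume);
$V_p = 32$ mL/kg with $\alpha = 0.05\,\mathrm{min}^{-1}$. The central
volume is deliberately below the anatomic plasma volume: it is the
*effective* distribution volume during the incompletely mixed 2–3 min
window, chosen so that simulated uptake tracks the Gates regression's
own calibration (total uptake ≈ (GFR + 6.8)/9.8 percent). Kidney
activity is distributed as the planar projection of a homogeneous
ellipsoid (per-pixel weight $\sqrt{1-\rho^2}$): bright centre, dim rim.
A uniform-disk phantom would make a one-pixel ROI disagreement cost
~30% of a kidney's counts, which no real renogram does, and would
overstate rater variability accordingly.

**Cohort.** True tGFR ~ truncated normal, mean 89.62, SD 46.57 mL/min,
truncated above 5 (the moments of the hydronephrosis population this
method targets); left split fraction ~ U(0.2, 0.8); adult biometrics.
Acquisition: 30 × 2 s + 20 × 60 s frames, 64 × 64 matrix, posterior
view. Counting: full syringe 60 s before injection, residual 6 s after;
all counts Poisson unless `noise = FALSE` (which substitutes exact
expectations — frames are then non-integer, and `validate_study()`
deliberately checks non-negativity but not integrality so that
expectation-valued phantoms remain first-class inputs).

**Raters.** Five simulated physicians re-delineate the ROIs: outlining
*style* (dilate/erode up to 1 px) is drawn per rater per subject and
applied to both kidneys alike — tight-vs-generous outlining is a
physician trait and largely cancels in the left:right ratio — while
placement shifts (±1 px per kidney) and background-ring displacement
(±3 px per side) are independent. Background placement is deliberately
the dominant channel, and the image contains a bright para-aortic
blood-pool stripe between the kidneys so that a displaced ring samples
genuinely different background. This is the causal structure of the
method's central claim: blank-background processing is immune to the
one channel that most degrades conventional gGFR concordance. The
jitter magnitudes are synthetic — no inter-rater delineation
variability measurements exist to fit them to — and are labelled as
such wherever they appear.

**What the phantom does not model**, hence what passing tests do not
show about clinical data: no anatomically realistic kidneys or
neighbouring organs (liver/spleen), no scatter or septal penetration,
no patient motion, no pelvicalyceal retention (the mechanism by which
severe hydronephrosis inflates camera GFR), no anterior-view
simulation, and rater behaviour far simpler than human delineation.
The phantom validates the *computational chain* and the *direction* of
the concordance comparison, not clinical accuracy.

## Validation summary

The test suite (sizes chosen as the package's own defaults) checks,
among others:

* the plasma formula inverts 1000 random mono-exponential constructions
  from the protocol's operating domain to within 10 ulp;
* `split_pgfr()` conserves tGFR to ≤ 2 ulp over 1000 random inputs and
  splits symmetric inputs exactly 50/50;
* Kendall's W agrees exhaustively with a first-principles
  pairwise-Spearman oracle on all 36 two-rater orderings of three
  subjects (and with `vegan::kendall.global` on random tables);
* on a noiseless, background-free cohort the blank-background split
  fraction equals the generative truth to float precision, and window
  selection matches brute-force interval enumeration;
* on the default noisy cohort (30 subjects, 5 raters, fixed seed)
  W(pGFR) strictly exceeds W(conventional gGFR), the ordering holds in
  at least 18 of 20 independent seeds, and the split-fraction MAE stays
  within 0.05.

`scripts/acceptance.R` recomputes all headline quantities from scratch
for any seed.

## Known limitations

* The Gates regression constants, depth coefficients and μ are
  literature values exposed in one config block; sites calibrating
  their own camera should override them.
* The dual-plasma method itself overestimates very low clearances (no
  late third sample is modelled); the Brøchner–Mortensen hook mitigates
  but is off by default to match the reference procedure.
* The concordance comparison is qualitative by construction: simulated
  W values depend on synthetic jitter magnitudes, and only their
  ordering is a claim.
* Geometric-mean (anterior×posterior) processing is plumbed but not
  simulated; depth-complement attenuation for the anterior view would
  be needed for a meaningful end-to-end test.
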