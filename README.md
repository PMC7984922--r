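# splitgfr

Precise per-kidney (split) glomerular filtration rate from Tc-99m-DTPA
dynamic renal scintigraphy combined with two-sample plasma clearance.

## The problem

Total GFR can be measured accurately from two timed plasma samples after
a Tc-99m-DTPA injection (the slope-intercept "dual-plasma" method), but
plasma clearance cannot tell the two kidneys apart. Camera-based Gates
processing of the dynamic renogram *can* split function between kidneys,
but its absolute values are sensitive to many operator-dependent factors
— above all the hand-drawn background region of interest, which differs
between physicians and degrades between-reader reproducibility. This
matters wherever per-kidney function drives decisions: hydronephrosis
work-up, nephrectomy planning, living-donor evaluation.

`splitgfr` implements the combined method: the imaging fixes only the
**left:right ratio** (processed with a blank background, i.e. kidney
outlines only, removing the dominant operator-dependent step), and the
plasma clearance fixes the **scale**.

## The method

Total GFR from two plasma samples at `T1`, `T2` minutes (dose `D`,
plasma counts `P1 > P2` per mL, one shared counting calibration):

```
tGFR = [ D ln(P1/P2) / (T2 − T1) ] · exp[ (T1 ln P2 − T2 ln P1) / (T2 − T1) ]
```

(the slope-intercept formula; algebraically `D·k/P0` for the
mono-exponential `P(t) = P0 e^(−kt)` through the two samples).

Per-kidney Gates GFR from the renogram: counts in each kidney ROI over
the 2–3 min uptake window, background-subtracted (conventional gGFR) or
not (blank-background gGFR′), attenuation-corrected with
`exp(−μ·depth)` (Tønnesen depth from height/weight, μ = 0.153 cm⁻¹),
divided by the net injected counts to give percent uptake, mapped to
GFR by the Gates regression `GFR = 9.8127·uptake% − 6.82519` and split
in proportion to per-kidney corrected counts.

The combination:

```
pGFR_left  = gGFR′_left  / (gGFR′_left + gGFR′_right) × tGFR
pGFR_right = gGFR′_right / (gGFR′_left + gGFR′_right) × tGFR
```

Between-reader agreement is quantified with the tie-corrected Kendall
coefficient of concordance W over a subjects × raters table of
per-kidney values.

Because clinical rater studies of this design are not redistributable,
the package ships a compartmental renogram phantom
([`simulate_cohort()`]) that generates dynamic frame stacks
(30 × 2 s + 20 × 60 s on a 64 × 64 matrix), syringe records, plasma
samples consistent with the same clearance, and per-rater jittered ROI
sets — so the whole chain, including the concordance comparison, is
testable against known ground truth.

## Worked example

```r
library(splitgfr)

coh <- simulate_cohort(4, seed = 2024)       # 4 subjects, 5 raters
s   <- coh$subjects[[1]]
s$truth$tgfr_true                            # 135.35 mL/min
s$truth$split_fraction_left_true             # 0.608

st <- renogram_study(s$renogram, s$rois_true, s$biometrics,
                     s$injection, plasma = s$plasma)
run_full_study(st)
#>   tgfr_raw tgfr_bsa   bsa_m2 ggfr_left ggfr_right ggfr_prime_left
#> 1 134.2264 124.1237 1.870809  61.34593   38.93362        69.68378
#>   ggfr_prime_right pgfr_left pgfr_right split_fraction_left
#> 1         47.15831  74.02646   50.09721           0.5963928
```

Reading the output: the dual-plasma tGFR (134.2 mL/min raw,
124.1 mL·min⁻¹·(1.73 m²)⁻¹ after body-surface-area normalization)
recovers the generative 135.4 mL/min; the blank-background gGFR′ ratio
(69.7 : 47.2) estimates the left split fraction as 0.596 against a true
0.608; the per-kidney pGFR values apportion the normalized tGFR in that
ratio and sum to it exactly.

The rater-concordance comparison on the same cohort:

```r
evaluate_recovery(coh)
#> phantom recovery report
#>   W(pGFR)              = 1.0000
#>   W(gGFR conventional) = 0.8724
#>   split-fraction MAE   = 0.0293
#>   tGFR mean abs pct err= 0.77%
```

pGFR is markedly more concordant across the five simulated raters than
conventional background-subtracted gGFR, because the blank-background
ratio is immune to background-ROI placement — the phantom's dominant
rater-variability channel.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/splitgfr.R", package = "splitgfr"))')
Rscript $CLI simulate --n 30 --raters 5 --seed 42 --out cohort/
Rscript $CLI full cohort/subject_01 --out report
Rscript $CLI pgfr --left 40 --right 60 --tgfr 80
#> pGFR: left 32.00 / right 48.00 of tGFR 80.00 mL/min (split 40.0% L)
```

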