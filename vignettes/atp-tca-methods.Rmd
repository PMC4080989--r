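---
title: "ATP-TCA analysis: models, parameters and numerical choices"
author: "atpTCA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ATP-TCA analysis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpTCA)
```

# The assay and its model

An ATP-based tumour chemosensitivity assay (ATP-TCA) measures viable
cell mass after drug exposure through luciferin–luciferase
luminescence, which is proportional to cellular ATP. A 96-well plate
carries up to four drugs or drug combinations, each in triplicate at
six doubling dilutions spanning 200% down to 6.25% of a test drug
concentration (TDC) chosen to be clinically achievable, plus one
control row: medium-only (MO) wells defining the 0%-inhibition
reference and maximum-inhibitor (MI) wells defining complete kill.
An ATP standard curve run before each read maps counts to ATP amounts;
it is used for instrument QC only, because the inhibition statistic is
a ratio of raw counts against the plate's own controls:

$$\%I = \left(1 - \frac{\mathrm{Test} - \mathrm{MI}}
                       {\mathrm{MO} - \mathrm{MI}}\right)\times 100$$

This ratio makes the whole analysis invariant to the emission scale
(any rescaling of all counts on a plate cancels), which the test suite
asserts as a property.

## Replicate variability

Replicate agreement is summarized as the coefficient of variance
(sd/mean, %) of the raw replicate counts at each dilution step; the
assay's typical replicate CV is below 10%, which is the default QC
limit. CV is computed on counts rather than on derived inhibition
because the averaging happens on counts; a configuration switch
(`cvOn = "inhibition"`) provides the alternative. Control wells are
aggregated as the mean of the MO wells and the mean of the MI wells.
A control well is dropped (with a warning) when it lies more than 3
standard deviations from the *other* control wells: the leave-one-out
form matters because with six or fewer control wells a single extreme
value inflates the pooled sd enough to mask itself. MO ≤ MI is a
control failure and aborts the plate — no inhibition value is
meaningful without a positive control window.

## Sensitivity statistics

Per condition, the six mean inhibition values are kept unclipped (noise
can push counts above MO or below MI) and clipped to $[0, 100]$ before
any derived statistic, so that the sensitivity index is bounded:

$$\mathrm{IndexSUM} = \sum_{k=1}^{6}\bigl(100 - \%I_k^{\mathrm{clip}}\bigr)
  \in [0, 600]$$

with 0 = complete inhibition, 600 = no inhibition, and 300
corresponding to 50% inhibition across the tested range. An agent is
called **active** when IndexSUM < 300, strictly: an index of exactly
300 is inactive.

IC50 and IC90 are located as the *first crossing* of the target effect,
scanning from the lowest to the highest concentration, by linear
interpolation of clipped inhibition against $\log_2$(concentration) —
the natural axis for a doubling-dilution ladder, on which the six steps
are equally spaced. Crossings outside the tested range are censored
(`>top` when the effect is never reached, `<bottom` when the lowest
dose already exceeds it) and the bounding concentration is carried with
the marker. Censored values propagate as "not estimable" downstream —
they are never replaced by the bound, which would fabricate synergy or
resistance. Non-monotone profiles are taken as measured (first crossing
wins); no isotonic smoothing is applied by default. As an alternative
backend, a Hill model

$$I(c) = \frac{I_{\max}\,c^{h}}{EC_{50}^{h} + c^{h}},
  \qquad I_{\max}\in[0,100],\; h>0$$

is fitted by Levenberg–Marquardt least squares (`minpack.lm`) and
inverted analytically; profiles with no usable signal (maximum
inhibition below 5%) and optimizer failures are returned as degenerate,
unconverged fits rather than defaults. Interpolation is the default
backend because it makes the fewest assumptions about curve shape;
the Hill backend is preferable when extrapolation strictly inside the
tested range is acceptable and the response is believed sigmoid.

## Combination analysis

Combinations are tested as fixed-ratio rays: step $k$ of the mixture
adds step $k$ of each drug's own dilution series simultaneously, so the
component ratio is constant. At effect level $F$ (50% and 90%), with
$d_A, d_B$ the component doses of the mixture crossing and $D_A, D_B$
the single-agent doses at the same effect, the Chou–Talalay combination
index is

$$CI = \frac{d_A}{D_A} + \frac{d_B}{D_B}
     + \alpha\,\frac{d_A d_B}{D_A D_B}$$

with $\alpha = 0$ for mutually exclusive drugs (the default — the
choice is exposed as a flag and recorded in the run manifest) and
$\alpha = 1$ for mutually non-exclusive ones. Classification uses
CI < 0.8 synergy, 0.8–1.2 additive, > 1.2 antagonism; the boundary
values are assigned to the additive band. The mixture crossing is
located on the drug-A component axis (equivalent, up to a constant
log-shift, to the total-dose axis for a fixed ratio) and split by the
design ratio.

# The synthetic-data generator

The generator exists so that every downstream statistic can be checked
against known truth. It emulates the statistical structure the analysis
assumes, not the biology that produces it:

* **Dose–response**: each cell line × drug pair follows a Hill model
  with parameters $(I_{\max}, EC_{50}, h)$.
* **Mixtures**: the expected mixture inhibition solves the Loewe
  equation $d_A/D_A(I) + d_B/D_B(I) = \rho$ numerically on the effect
  axis (`uniroot`, tolerance $10^{-12}$). $\rho = 1$ is exact Loewe
  additivity — the null against which the analyzer must report
  CI ≈ 1 — and $\rho < 1$ shifts potency so that, for equal-shape
  pairs, the recovered CI50 equals $\rho$ exactly. For partial
  agonists with unequal ceilings the equation has no root once the
  stronger drug alone pushes the effect past the weaker drug's
  $I_{\max}$; beyond its own ceiling a drug's dose-equivalent
  contribution is taken as zero (the generalized-Loewe treatment),
  which extends the solve continuously to the stronger ceiling. A
  genuinely rootless solve marks the step invalid rather than imputing
  a value.
* **Counts**: expected counts are
  $\mathrm{MI} + (\mathrm{MO}-\mathrm{MI})(1 - I(c)/100)$, with
  replicate counts drawn from a normal law with constant CV per well,
  truncated at zero. Default CV 8% (below the assay's typical sub-10%
  replicate variability), MO ≈ 50,000 and MI ≈ 500 counts — the
  emission scale is arbitrary by necessity (no raw counts are
  published for this assay class) and the analysis is proven
  scale-invariant, so only the MO:MI window matters. Defaults use
  triplicates; the control row (row H) holds six MO and six MI wells.
* **Determinism**: every plate is seeded; identical seeds give
  bit-identical well tables.

What the generator does *not* emulate: edge effects and spatial drift
across the plate, count-dependent (heteroscedastic beyond
constant-CV) detector noise, carry-over between wells, cell-growth
kinetics, or any mechanistic pathway signalling. Passing tests
therefore validate the *computational* pipeline under the assay's
stated noise model, not the wet-lab assay itself.

## The isogenic panel preset

`scenarioIsogenicPanel()` encodes a six-line isogenic breast-epithelial
panel (parental plus PIK3CA H1047R, PIK3CA E545K, EGFR ΔE746-A750,
BRAF V600E and AKT E17K knock-ins) against gefitinib, erlotinib
(EGFR), ZSTK474 (PI3K) and sirolimus (mTOR), with dose series matching
clinically achievable ranges (gefitinib 0.06–2 µM, erlotinib
0.2–6.5 µM, ZSTK474 0.07–2.2 µM, sirolimus 0.06–2 µM). Ground truth is
parameterized by target IndexSUM values per line × drug — the
characteristic pattern being PIK3CA mutants (E545K ahead of H1047R)
most sensitive to EGFR inhibition with the parental line most
resistant to gefitinib, and BRAF V600E markedly resistant to sirolimus
— and the EC50 reproducing each target index is solved numerically
(Hill $I_{\max}=100$, $h=1$). The four preset combinations (each EGFR
inhibitor with ZSTK474 and with sirolimus) default to a synergistic
potency shift $\rho = 0.6$. Because mixture inhibition under any
$\rho \le 1$ dominates each single agent at every step, every
combination is more active (lower IndexSUM) than both of its
components — a property the test suite checks line by line.

# Numerical choices and degenerate inputs

* Doubling-dilution ratios are validated to $10^{-9}$ relative
  tolerance; combination rays must hold their component ratio to the
  same tolerance.
* Interpolated crossings hit grid points exactly (a step measuring
  exactly the target effect returns that step's concentration).
* The Hill fit constrains $I_{\max}\in[0,100]$, $h\in[10^{-3},20]$,
  and starts from the observed maximum and the concentration nearest
  half-maximum; convergence and the residual norm are reported.
* A flat profile has no IC50: it is censored, and the Hill fit flags
  it degenerate instead of returning arbitrary parameters.
* ciReport evaluates effect levels independently, so a CI90 can exist
  when the CI50 does not (and vice versa), matching how censoring
  plays out on real resistant lines.
* Human-readable tables round to 2 decimals; JSON mirrors keep full
  precision. Reruns with the same inputs and seed are byte-identical.

# Validation strategy and problem sizes

The suite validates each stage against an independent oracle rather
than against itself: interpolated ICs against a $10^5$-point
brute-force grid search over the same interpolant (1,000 random
monotone profiles, 0.1% relative agreement); Hill fits against a
grid-search oracle and analytic inverses; Loewe mixture crossings
against an isobole solve on the dose axis; CI identities against
closed-form sham constructions (a drug combined with itself at half
doses must give CI = 1 to $10^{-6}$ — interpolation bias cancels
between single and mixture crossings); additive ground truth against
the CI ∈ [0.95, 1.05] band on 200 equal-shape Loewe pairs (unequal
Hill slopes deviate from 1 under the mutually exclusive formula;
h = 1 vs 3 stays within ±0.15); and parameter recovery on 200 noisy
triplicate plates (CV 10%), where the interpolated IC50 falls within
±25% of the true EC50 in at least 90% of plates. These sizes keep the
whole suite under a minute while leaving the Monte-Carlo margins wide.

# Known limitations

* CI values carry no confidence intervals; replicate uncertainty is
  summarized at the QC stage only.
* The mutually exclusive/non-exclusive $\alpha$ is a user choice, not
  estimated from the data.
* Loewe additivity with unequal Hill slopes is not exactly CI = 1
  under the two-term formula; the package documents and bounds the
  deviation instead of hiding it.
* The plate reader, extraction chemistry and plate-image parsing are
  out of scope: input is the per-well count table.
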