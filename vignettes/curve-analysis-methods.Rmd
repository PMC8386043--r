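---
title: "Amplification and melting curve analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplification and melting curve analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmelt)
```

## The model behind the amplification analysis

A qPCR amplification curve passes through four phases: a *ground* phase in
which amplification-dependent fluorescence is below the measurement noise, an
*exponential* phase in which the amplicon amount multiplies by a constant
efficiency $E \in (1, 2]$ per cycle, a *transition* phase in which reagents
become limiting, and a *plateau*. On a log-fluorescence axis the exponential
phase is a straight line with slope $\log_{10} E$. The analysis rests on
three quantities per run: the per-assay efficiency $E_{tar}$, a common
quantification threshold $N_q$ placed in the exponential phase of every
reaction, and the per-reaction quantification cycle $C_q$. The reported
result is the efficiency-corrected target quantity

$$N_0 = N_q / E_{tar}^{C_q},$$

expressed in threshold-fluorescence units. $N_0$ values are comparable
across assays and runs; $C_q$ values, which depend on the efficiency, are
reported but not recommended for direct comparison.

### Baseline estimation

The observed fluorescence contains an amplification-independent baseline
(unbound dye, incomplete quenching). Instead of extrapolating a trend through
the noisy ground-phase cycles, the baseline is found as the subtraction
constant that *straightens the exponential phase*: starting from a
deliberately high candidate (99 % of the minimum fluorescence over the
candidate exponential region), the exponential-phase cycles are split into a
lower and an upper half (by cycle; odd counts give the middle cycle to the
lower half) and the slopes of the two log-linear half-fits are compared. The
candidate is lowered step-wise until the upper half becomes steeper than the
lower half, then raised one step, the step halved, and so on until the
slopes differ by less than `slope_diff_tol = 1e-4` (log10 fluorescence per
cycle; at $E = 1.8$ this equals an efficiency difference of
$\ln(10) \cdot 1.8 \cdot 10^{-4} \approx 4\times10^{-4}$).

Three numerical choices make this loop robust:

* The half-slope window ends two doublings below the second-derivative
  maximum (SDM). The efficiency already declines as the curve approaches
  the SDM, and including those cycles tilts the comparison.
* Both half fits use inverse-variance weights $(f/(f+B))^2$ derived from the
  multiplicative noise model (noise proportional to total signal $f + B$,
  baseline $B$): the log of near-ground cycles is noise-dominated and
  left-skewed, and unweighted fits are steered by it.
* With noisy data the slope difference is not a continuous function of the
  candidate (the set of usable cycles changes discretely), so the
  $10^{-4}$ criterion alone may be unattainable. The search is therefore
  also accepted once the bisection interval has collapsed below $10^{-9}$
  of the candidate scale, *provided a sign change was bracketed*. A curve
  with no sign change anywhere — e.g. a monotone drift with no exponential
  segment — still fails with a baseline error.

### Exponential phase and window-of-linearity

The exponential phase starts at the first cycle of the maximal strictly
increasing run that persists to the SDM (central second difference of the
3-point-smoothed curve; ties to the earlier cycle) and ends at the SDM.
Reactions that never rise above `no_amp_factor` (7) times the ground noise
are excluded as non-amplifying; rising curves whose last five cycles still
climb steeper than `plateau_slope_frac` (0.25) of the maximum slope are
flagged "no plateau" and excluded from the window search by default.

Per assay, individual efficiencies are fitted inside a shared fluorescence
band — the window-of-linearity — and the band is stepped down from an
initial high position until the coefficient of variation (CV) of the
efficiencies stops improving. Three parameters shape this search, with the
following rationale:

* `wol_band_width = log10(64)` (six doublings). A band must hold at least
  `min_window_cycles = 3` cycles up to $E = 2$; short windows also make the
  individual fits so noisy that the CV criterion starts selecting
  coincidental agreement. The noise-model weights inside the band let it be
  tall without letting ground-level cycles degrade the fit.
* `wol_top_gap = log10(16)`: the scan starts four doublings below the
  highest exponential-phase top. In the logistic growth model (and in real
  reactions) the effective efficiency at a fluorescence $f$ is reduced by
  roughly $(E-1) \, f/P$ with plateau $P$; cycles just under the SDM are
  already several percent short of the exponential-phase efficiency.
* `wol_cv_tol = 0.25`: the selected position is the *highest* band whose CV
  is within 25 % of the minimum. A strict minimum is noise-seeking: among
  many candidate positions it prefers the one where the individual
  estimates happen to coincide, which is a biased selection.

Reactions flagged as efficiency outliers (below) are excluded from
$E_{tar}$ but still receive $C_q$ and $N_0$ from the assay efficiency, and
their individual efficiency is reported for manual calculation.

### Outlier screening

Two strategies are available. `fixed_band` excludes efficiencies outside
median ± `fixed_band_halfwidth` (0.05) — simple, but it discards too much in
wide, symmetric distributions. The default `grubbs` mode computes the
adjusted Fisher–Pearson skewness and applies a one-sided Grubbs test (at
`grubbs_alpha = 0.05`, critical value from the $t$ distribution) to the
extreme value on the skewed side, iterating until no further rejection.
When the skewness is numerically zero the test is applied two-sided to the
larger deviation. Because exclusion changes the distribution, the window
search and the screening are alternated until the inclusion mask is stable
(capped at 10 rounds; an oscillating mask keeps the variant with the most
inclusions and warns).

### Threshold, Cq and N0

One threshold serves the whole run: the geometric mean of the bounds of the
intersection of all valid reactions' exponential-phase fluorescence ranges.
If the intersection is empty (very heterogeneous plates), the geometric mean
of the phase centres is used and every reaction whose phase excludes the
threshold is flagged. $C_q$ is called on an idealized curve — anchored at
the weighted centre of the reaction's exponential phase, with slope
$\log E_{tar}$ — which cancels residual per-reaction efficiency noise:

$$C_q = c_{centre} + \frac{\log(N_q / F_{centre})}{\log E_{tar}}.$$

The centre fit is restricted to cycles two doublings below the SDM and uses
the same noise-model weights; without this, the residual baseline error
(which can exceed the ground-phase signal of very low-input reactions)
bends the anchor line and shifts $C_q$ by up to a cycle.

## The melting analysis

Heating releases the DNA-binding dye as each product denatures at its
melting temperature $T_m$; $-dF/dT$ shows one peak per product. The analysis
chain is smoothing → normalization → derivatives → peak calling →
expected-$T_m$ validation → peak fluorescence fractions → optional
correction.

**Smoothing** uses a simplified supersmoother: running local-linear fits for
a span ladder (0.01, 0.05, 0.2, 0.5 of the number of points, floored at 3),
compared through locally averaged leave-one-out residuals. Per point the
*largest* span within `bass_tol = 0.3` of the best residual wins (wide spans
on featureless stretches, narrow spans across transitions), the span
sequence is smoothed, adjacent passes blended, and a final light pass runs
only when the residual noise is non-negligible — so noise-free curves pass
through essentially unchanged (the smallest span in the ladder exists
precisely to make that true) and peak positions move by less than about one
temperature step.

**Normalization** removes the temperature-dependent but
dissociation-independent fluorescence loss. Anchor windows are the lowest
and highest `anchor_frac = 0.1` of the temperature range. *Bilinear* fits
straight trends to both anchors and rescales the curve between them
(pre-melt ≈ 1, post-melt ≈ 0). *Exponential* estimates a decay rate from
the two anchor slopes, $k = \ln(s_1/s_2)/(T_2-T_1)$, divides the decay out
and rescales on the anchors; $k$ is set to zero when both anchor slopes are
negligible, which makes the flat- and linear-background limits safe.
*Combined* (default) runs bilinear after exponential.

**Peak calling**: candidates are local maxima of $-dF/dT$; apexes whose
separating valley stays above `peak_valley_frac = 0.8` of the smaller apex
are merged (a shallow dip on a peak top is not two products). Inflection
points are the extreme-curvature points within the valley-bounded support of
each peak; the delta peak height (apex minus mean derivative at the
inflection points) and the width (inflection-point separation) filter the
candidates: peaks below `min_peak_height_frac = 0.05` of the summed delta
heights or wider than `max_peak_width = 5` °C are discarded — the width rule
acts as a *maximum* so that broad drift bumps are excluded. A peak within
`tm_tolerance = 1.0` °C of the annotated product $T_m$ is the expected
product (the closest one if several qualify); no expected peak raises a
warning, more than one product a note.

**Fractions and correction**: the fluorescence of a peak is the loss of the
normalized curve between its inflection temperatures; fractions over the
retained peaks sum to one. When the run used a saturating dye and exactly
one expected-product peak was found with fraction < 1, the amplification
results are corrected as $N_0' = \text{fraction} \times N_0$ and
$C_q' = C_q - \log(\text{fraction})/\log(E_{tar})$, preserving
$N_0' = N_q / E_{tar}^{C_q'}$. With a non-saturating dye the correction is
refused, and `apply_correction = FALSE` reports melt results without
touching the amplification output.

## The synthetic plate generator

The simulator exists so every stage is testable with known truth. Noiseless
amplification follows the resource-limited recurrence
$N_{c+1} = N_c\,(1 + (E-1)(1 - N_c/P))$ — the minimal model producing all
four phases — observed as $F_c = (B + N_c)(1 + \epsilon_c)$ with
multiplicative noise. Melting curves are sums of logistic dissociation
transitions on a linear background. Defaults describe an optimized
DNA-dye assay: baseline $B = 50$ at 1 % of the plateau $P = 5000$,
efficiencies 1.8–1.95, 45 cycles, 1 % multiplicative curve noise, 0.5 %
melting noise (instruments average several acquisitions per temperature
step), unknowns log-spaced over four decades, one positive and one negative
control per target, melting grid 65–95 °C at 0.1 °C.

What the simulator does *not* emulate: cycle-correlated noise and drift,
probe chemistries, between-well optical calibration differences, primer
depletion kinetics distinct from the logistic cap, temperature-dependent
quenching beyond a linear/exponential background, and plate-edge effects.
Passing the recovery tests therefore demonstrates correctness of the
algorithms under the stated noise model, not instrument-grade validation.

Two fixture choices worth noting: recovery tests run 55 cycles because six
decades of starting quantities at $E = 1.7$ do not finish in 45 cycles, and
the verified recovery bounds are: assay efficiency within ±0.01 (noiseless)
and ±0.03 (1 % noise, 8 replicates) for $E \in \{1.7, 1.8, 1.9, 2.0\}$,
$N_0$ within 10 % (noiseless), melt $T_m$ within 0.1 °C (noiseless) and
0.3 °C (0.5 % noise), two-product fractions within ±0.03 (noiseless). The
test suite exercises plates up to 96 wells and completes in well under a
minute.

## File formats

RDML files are zip archives holding one XML document. The package writes a
single v1.2-style dialect (entry `rdml_data.xml`; fixed timestamps, so equal
content gives byte-identical archives) and reads versions 1.1–1.3 by
tolerant element lookup; the react `id` attribute serves as the well label.
Because pre-1.3 schemas have no dedicated fields for them, the expected
product melting temperature is stored as a `meltingTemperature` child and
the saturating-dye property as a `dyeSaturating` child of `target`, and the
melting correction factor as `corrF` (with `corrCq`) inside the reaction's
`data` element. Full XSD validation is out of scope; `cmd_validate()` checks
the container, version and structural invariants. Numbers are written with
17 significant digits so that read-after-write reproduces every double
exactly. CSV exports use UTF-8, comma delimiters, `.` decimals and
`;`-joined flags; unavailable values (e.g. $C_q$ of a silent well) stay
empty.

## Known limitations

* The efficiency model assumes one dominant amplicon per reaction; the
  melting correction partitions fluorescence but the amplification fit
  itself is single-species.
* Standard-curve efficiency estimation and downstream normalization
  (reference-gene models, fold-change statistics) are out of scope; export
  the $N_0$ table to dedicated tools.
* Very late reactions (no plateau within the run) are analyzable only with
  `exclude_no_plateau = FALSE`, and their efficiencies are less reliable.
* The Grubbs iteration assumes approximately unimodal efficiency
  distributions; a 50/50 mixture of two efficiency populations will not be
  split.
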