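---
title: "Respiratory impedance modelling and bronchoprovocation analysis with fotmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory impedance modelling and bronchoprovocation analysis with fotmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fotmech)
```

## The measurement problem

Low-frequency forced oscillations superimposed on a quiet airway opening
measure the mechanical input impedance of the respiratory system,
$Z_{rs}(f)$, a complex-valued function of oscillation frequency. In small
animals the standard partition of $Z_{rs}$ into airway and tissue
compartments is the constant-phase model:

$$Z_{rs}(\omega) = R_{aw} + j\omega I_{aw} + \frac{G - jH}{\omega^{\alpha}},
\qquad \alpha = \frac{2}{\pi}\arctan\!\left(\frac{H}{G}\right),$$

with $\omega = 2\pi f$ in rad/s. $R_{aw}$ (cmH$_2$O·s/l) is the
frequency-independent Newtonian resistance, dominated by the conducting
airways; $I_{aw}$ (cmH$_2$O·s$^2$/l) is the inertance of the airway gas
column; $G$ (tissue damping) and $H$ (tissue elastance, both cmH$_2$O/l)
describe a tissue compartment whose pressure-flow phase angle is constant
across frequency — hence the name. The exponent $\alpha$ is not a free
parameter: it is tied to $G$ and $H$, which keeps the dissipative and
elastic tissue processes coupled (their ratio $\eta = G/H$ is the
hysteresivity). `fotmech` stores spectra in Hz and converts to angular
frequency internally, because stimulus bands are universally quoted in Hz
(the default band is 0.5–21 Hz).

Two degenerate cases are deliberately legal: $G = H = 0$ means "no tissue
compartment" (so purely resistive test fixtures are expressible), and
$G = 0,\,H > 0$ gives $\alpha = 1$, a purely elastic tissue.

## From pressure signals to impedance: the wave tube

The measurement chain is modelled after the wave-tube (two-point) technique:
a loudspeaker drives a pseudorandom multifrequency stimulus through a tube of
known acoustics terminated by the animal's airway, and lateral pressures
$P_1$ (loudspeaker end) and $P_2$ (tracheal end) give the load impedance via

$$\frac{P_1}{P_2} = \cosh(\gamma L) + \frac{Z_0}{Z_L}\sinh(\gamma L)
\quad\Longleftrightarrow\quad
Z_L = \frac{Z_0 \sinh(\gamma L)}{P_1/P_2 - \cosh(\gamma L)}.$$

Design choices, in the absence of a canonical geometry:

* **Propagation model.** The default is a lossless tube,
  $\gamma(\omega) = j\omega/c$ with $L = 1$ m and $c = 343$ m/s; a lossy
  $\gamma(\omega)$ can be injected as a function.
* **Characteristic impedance.** $Z_0 = 300$ cmH$_2$O·s/l by default, of the
  order of the rat load impedances themselves. This is a conditioning
  choice: perturbation of the recovered load by transfer-function noise
  scales as $|Z_L|^2 / (Z_0\,|\sinh(\gamma L)|)$, which is worst at the
  lowest frequencies where $|\sinh(\gamma L)|$ is small, so a small $Z_0$
  makes low-frequency bins uselessly noisy.
* **Stimulus.** Components are prime multiples of the record's frequency
  resolution $1/T$ (default $T = 6$ s), spread across 0.5–21 Hz. Prime
  multiples guarantee no component is an integer harmonic of another, and
  record-periodicity makes whole-record Fourier coefficients leakage-free,
  so no windowing is used. Phases are random (seeded); amplitudes default
  to 1.
* **Frame averaging.** Replicate frames are combined by cross-spectral
  averaging, $\hat T = \sum_k P_1^{(k)} \overline{P_2^{(k)}} / \sum_k
  |P_2^{(k)}|^2$, which reduces per-bin impedance RMSE approximately as
  $1/\sqrt{K}$.
* **Singular bins.** $P_1/P_2 \to \cosh(\gamma L)$ is the closed-end
  condition; such bins are flagged per-bin (`NA` + attribute) rather than
  failing the record.
* **Cannula correction.** Whether the emulated system subtracted the
  tracheal cannula's own impedance before fitting is not documented; no
  subtraction is applied, and spectra can be corrected upstream if needed.

## Fitting the model

`fit_constant_phase()` minimises
$\sum_f \left[(\mathrm{Re}\,\hat Z - \mathrm{Re}\,Z)^2 +
(\mathrm{Im}\,\hat Z - \mathrm{Im}\,Z)^2\right]$ over
$(R_{aw}, I_{aw}, G, H)$, all bounded below by zero, with $\alpha$
eliminated through its defining relation so the search stays
4-dimensional. Real and imaginary parts are weighted equally and no
frequency weighting is applied — the simplest faithful reading of
"minimising the differences between measured and modelled impedance";
weighting would be a one-line change in the residual function.

The optimiser is Levenberg–Marquardt (`minpack.lm`). The starting point
matters more than the optimiser here, and is computed by a deterministic
linearisation: at a fixed exponent, $\mathrm{Re}\,Z = R_{aw} + G u$ and
$\mathrm{Im}\,Z = \omega I_{aw} - H u$ with $u = \omega^{-\alpha}$ are
linear least-squares problems; starting at $\alpha = 0.9$, the exponent is
refreshed from the fitted $G, H$ and the linear fits repeated four times.
Over random draws spanning the rat parameter range this start lands within
a factor of 3 of the truth on all four parameters in about 96% of cases.
Four additional starts (default total 5 for a single fit; the pipeline
uses 2, see below) perturb the heuristic log-uniformly within a factor of
3, seeded for reproducibility.

Protocols record several 6-s spectra per condition; `aggregate_recordings()`
fits each independently, rejects fits whose residual RMS exceeds a
threshold, and averages the accepted parameters (fit-then-average rather
than average-spectra-then-fit; with record-periodic noiseless-mean spectra
the two agree within noise bands, and fit-then-average yields a
between-recording SE for free). The default threshold of 5 cmH$_2$O·s/l
sits several times above the residual level observed when fitting spectra
carrying the generator's default measurement noise (complex Gaussian,
SD 1 cmH$_2$O·s/l per component), so it rejects only genuinely broken
recordings.

## Lung volume by Boyle's law

During an end-expiratory occlusion the animal makes 3–4 inspiratory efforts
against the closed airway inside a body plethysmograph. With no flow, the
alveolar gas obeys Boyle's law, and the end-expiratory lung volume follows
from the slope of thoracic volume change against tracheal pressure change:

$$\mathrm{EELV} = (P_B - P_{H_2O}) \cdot \frac{\Delta V}{\Delta P_{tr}}.$$

The box pressure is first corrected for the plethysmograph's own dynamics.
The box is modelled as a first-order system (static gain + time constant),
inverted exactly in the frequency domain; gain 1 and time constant 0 is the
identity. This minimal model is a stand-in chosen to make "correcting for
the box impedance" a testable inverse operation — the original correction
method is cited but not specified in the emulated protocol. The slope is a
least-squares regression of $\Delta V$ on $\Delta P_{tr}$ over each effort
(less noise-sensitive than the peak-to-peak ratio, which remains available
via `method = "peak"`), efforts with a tracheal swing below 5 cmH$_2$O are
excluded, and the manoeuvre's EELV is the mean over accepted efforts. No
barometric constant is hard-coded; $P_B - P_{H_2O}$ defaults to
970 cmH$_2$O and is configurable per manoeuvre.

## Dose–response and ED50

Methacholine is infused at 2, 4, 8, 12 and 24 µg/kg/min and the airway
resistance refitted at each steady state. The responsiveness index is the
**ED50**: the equivalent dose producing a 50% increase in $R_{aw}$ over
baseline, computed by linear interpolation with baseline treated as dose 0.
Conventions for cases the interpolation rule alone does not settle:

* If the first measured dose already exceeds the target, interpolation runs
  on $[0, d_1]$ (keeps ED50 defined for strongly hyperreactive animals).
* Non-monotone (noisy) curves use the first crossing.
* If the target is never reached within the schedule, the default policy
  extends the final dose segment's line beyond the schedule and flags the
  value as extrapolated. This mirrors how group-mean ED50s larger than the
  top infusion rate can be reported at all; a strict censoring policy
  (top dose + censored flag) is available, and censored values are excluded
  from group means by default.

`percent_change()` and `specific_raw()` (resistance × absolute lung volume,
cmH$_2$O·s) complete the per-animal quantities: normalising $R_{aw}$ to the
lung volume can expose airway narrowing that basal resistance alone hides.

## Group statistics

The battery mirrors the standard analysis of such studies: Lilliefors-type
Kolmogorov–Smirnov normality tests (parameters estimated from the sample —
the appropriate form when no normal is prespecified; `nortest`), one-way
ANOVA across groups, a mixed-design two-way repeated-measures ANOVA
(between-subject treatment, within-subject dose, subjects nested in
treatment; unadjusted univariate F, as is conventional when no sphericity
correction is reported), Student–Newman–Keuls stepwise post-hoc
comparisons, and Pearson correlation with per-group and pooled regression
lines and pairwise-complete deletion (pressure recordings are missing for
some animals by design).

The SNK procedure sorts group means, compares each pair against
$q(\alpha, p, \mathrm{df}_e)$ where $p$ is the span of the pair in the
ordered means, and enforces the containment rule: a non-significant span
blocks every pair inside it. Unequal group sizes use the harmonic-mean
(Tukey–Kramer) standard error, and studentized-range quantiles come from
`qtukey()`, i.e. numerically from the distribution function rather than
tables. The procedure runs only after a significant one-way ANOVA unless
explicitly overridden. A completely flat repeated-measures response is
reported as $F = 0$ (there is no variance to partition) rather than the
0/0 floating-point artefact.

## The synthetic-cohort generator

No raw data from the emulated study design are available, so the
generator is a first-class module providing ground truth for every
pipeline stage. It draws:

* **Cohorts** — six groups (CC n=13, CS n=10, VIP n=8, ILO n=10, SIL n=7,
  TEZ n=8). Baseline $G$ and $H$ per group use the emulated design's
  printed means with between-animal SDs reconstructed as SE·√n. Baseline
  $R_{aw}$ (28 ± 4 cmH$_2$O·s/l), $I_{aw}$ (0.10 ± 0.02), EELV
  (5.5 ± 0.8 ml) and all absolute pulmonary arterial pressures are
  calibration values chosen as plausible adult-rat levels — the emulated
  design reports these only graphically, so they must not be read as
  published values. Systolic Ppa is elevated in all shunted groups
  (38 ± 5 mmHg vs 24 ± 3 in controls) and largely normalised under
  iloprost (27 ± 4).
* **True ED50** — log-normal per group (positivity and right skew), with
  the log-mean set so the *arithmetic* group mean equals the configured
  value: CS 9.9 and ILO 43 µg/kg with sdlog 0.508 and 0.709 reconstructed
  from the printed SEs; the remaining groups are control-like
  (CC 35, VIP 32, TEZ 30, SIL 55 µg/kg, sdlog 0.5 — calibration values).
  An animal's log-ED50 is additionally shifted by
  `ppa_ed50_coupling` × (its systolic Ppa deviation from the group mean),
  −0.02 per mmHg by default, encoding the mechanical-interdependence
  hypothesis; the pooled Ppa–ED50 correlation of generated cohorts is
  negative in ≥95% of seeds, by both this coupling and the group-level
  structure.
* **Missingness** — Ppa is masked completely at random per group at the
  emulated subgroup rates (7/13, 10/10, 4/8, 5/10, 2/7, 6/8 acceptable),
  mirroring technically unacceptable catheterisations.
* **Measurements** — 4–6 baseline and 3–5 per-dose impedance recordings
  per animal (noisy forward model evaluations; or, in full-chain mode,
  simulated wave-tube pressure frames with 3·10⁻⁴ cmH$_2$O transducer
  noise), plus one occlusion manoeuvre consistent with the animal's EELV,
  distorted by a 20 ms box time constant the analysis must undo.
* **Dose–response shape** — $R_{aw}(d) = b\,(1 + 0.5\,(d/\mathrm{ED50})^s)$,
  which crosses the 50% target exactly at the true ED50 for any steepness
  $s$; $s \to \infty$ is a step at ED50. The default $s = 1$ (linear in
  dose) was chosen over a saturating sigmoid because the estimator under
  test is itself piecewise-linear: with a saturating truth the
  interpolation/extrapolation ED50 is biased for animals whose ED50 lies
  beyond the top dose, and that bias is a property of the estimator, not
  of the pipeline's recovery, which is what the generator is meant to
  probe. Tissue responses are far more moderate (G +30%, H +22% at the
  top dose, linear in dose).

The truth table (true ED50, unmasked Ppa) is kept separate from the
observable cohort and never written into the observable files.

**What the generator does not emulate:** breathing artefacts and
nonstationarity within a recording, cardiogenic oscillations, shunt
hemodynamics (Ppa is drawn, not mechanistically modelled), drug
pharmacokinetics, and any chest-wall/lung partitioning. Passing tests
therefore demonstrate correctness of the computational chain under the
stated noise model, not robustness to every artefact of real recordings.

## Numerical choices and problem sizes

* Forward evaluation uses the principal real power $\omega^\alpha$
  ($\omega > 0$ enforced).
* The resonant-frequency diagnostic brackets the unique zero of
  $\mathrm{Im}\,Z$ (strictly increasing in $\omega$) and solves by
  `uniroot`.
* LM fits run with `ftol = ptol = 1e-14`, max 200 iterations; ties across
  multistarts resolve to the lowest sum of squares.
* The pipeline default of 2 starts per fit (vs 5 for standalone fits)
  reflects that protocol-shaped spectra start within the heuristic's
  basin essentially always; a six-group study involves thousands of fits.
* Validation problem sizes: fit recovery on 100 random draws; wave-tube
  noise decay at K = 1, 4, 6 over 50 seeds; ED50 oracle equivalence on
  1000 random curves; type-I error of the one-way ANOVA over 10,000 null
  simulations; end-to-end ED50 recovery over 100 replicate two-group
  studies (n = 10 per group). The acceptance script averages 60 replicate
  studies per target group.

## Worked example

```{r example}
design <- cohort_design(groups = default_study_groups(c("CC", "CS")))
study <- simulate_study(design, seed = 1)
results <- run_study_pipeline(study)
results$group_ed50
results$stats$rm_anova_raw$treatment
results$stats$ppa_ed50$pooled[c("r", "p", "n")]
```

The untreated-shunt group's recovered mean ED50 sits far below the
control group's (bronchial hyperreactivity), the repeated-measures
treatment effect tests that separation across the dose range, and the
pooled Ppa–ED50 correlation is negative, as the coupling in the design
dictates.

## Known limitations

* The box-impedance correction is a first-order stand-in; real
  plethysmographs can need higher-order models.
* Extrapolated ED50s inherit the last dose segment's slope; with strongly
  saturating real dose-responses they would understate true ED50s well
  beyond the top dose (the censoring policy exists for exactly that
  doubt).
* The RM-ANOVA reports unadjusted univariate F; a sphericity correction
  is not implemented, only argued away by convention.
* Statistics are validated against definitional oracles and synthetic
  data, not against the emulated study's animal-data p-values, which are
  not reproducible without the animals.
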