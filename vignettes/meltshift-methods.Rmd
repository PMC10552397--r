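---
title: "Thermal proteome profiling with meltshift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal proteome profiling with meltshift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltshift)
```

## The measurement

Thermal proteome profiling (TPP) probes ligand binding proteome-wide: intact
cells are treated with a compound or vehicle, briefly heated to a series of
temperatures, and the *soluble* (non-denatured) fraction of every protein is
quantified by TMT-multiplexed mass spectrometry. A ligand that binds a
protein usually raises its melting point, so the compound arm's melting
curve shifts right. CETSA is the immunoblot, single-protein version of the
same idea.

`meltshift` analyzes two designs:

* **TR (temperature range)** — fixed compound concentration, ten heating
  temperatures from 36.5 to 67 °C. Treatment and control samples of the same
  temperature share a TMT 10plex labeling set (five temperatures per set,
  two sets per replicate, three replicates: 60 samples in 6 sets), so every
  compound/vehicle ratio is a within-run ratio.
* **CCR (compound concentration range)** — fixed heating temperature
  (50 °C, where most proteins are partially melted) over a fourfold dilution
  series from 6400 nM down to 0.098 nM plus vehicle, with a 37 °C companion
  experiment that reads out abundance rather than stability.

## The melting model

Soluble fraction versus temperature is modeled by a four-parameter sigmoid

$$I(T) = I_{min} + (I_{max} - I_{min}) \Big/
  \left\{1 + \exp\left[(T_m/T - 1)\, s\, T_m\right]\right\},$$

with plateaus $I_{min} < I_{max}$, melting point $T_m$ (the temperature of
the half-way point) and slope $s < 0$ for melters. The equivalent form with
$\exp[-(a/T - b)]$ maps through $T_m = a/b$, $s = -b^2/a$; both are
implemented and property-tested for equality. Temperatures are handled in
degrees Celsius throughout: melting points are reported on the Celsius
scale and the fit grid is a Celsius grid, so the $T_m/T$ ratio is a
Celsius-scale ratio. (Using Kelvin inside the exponent would change the
meaning of $s$ but barely the fitted $T_m$; Celsius matches how the
parameters are reported in practice.)

`fit_melting()` minimizes unweighted squared residuals via
Levenberg–Marquardt with a small multi-start grid ($T_m$ at the median
observed temperature and at the half-range crossing; $s \in \{-0.5,
-0.05\}$; plateaus from the data extremes), with box bounds
($T_m \in [\min T - 10, \max T + 10]$, $I_{min} \ge 0$) and a
three-parameter fallback ($I_{min} = 0$) when the four-parameter fit fails
to converge or pins $T_m$ to a bound. A `log_scale` option minimizes
log-intensity residuals instead, which is the correct objective whenever
errors are multiplicative.

## Three-step TR normalization

1. **Within temperature.** The six samples heated at one temperature (2
   arms × 3 replicates) differ by pipetting and cell-count errors. Each
   group's reference is the sample to which the others compare positively
   (most positive median log2 fold changes — the highest-level sample,
   ties to the lowest index); every other sample is multiplied by
   $c = 2^{\mathrm{median}\,\log_2(\mathrm{ref}/\mathrm{sample})}$, driving
   its median log2 fold change versus the reference to zero. The fold-change
   orientation matters: only with $FC = \mathrm{ref}/\mathrm{sample}$ does
   multiplying by $c$ align samples upward to the reference level. This
   step assumes most proteins are unaffected by treatment — heavy,
   one-sided effect loads would drag the medians.
2. **Between temperatures (global curve).** For each temperature, the mean
   of the 36 pairwise median log2 fold changes of its six samples against
   the six samples at the lowest temperature gives a summary intensity
   $I(T)$; the melting model is fitted to the ten $(T, I(T))$ points and
   every sample in the group at $T$ is multiplied by
   $c(T) = I_{fit}(T)/I(T)$. Because $I(T)$ is ratio-derived, its errors
   are multiplicative, and the global fit is therefore performed on the
   log scale — on the linear scale, residual misfit concentrates at the
   hot, low-intensity end of the grid and leaks a curve-like distortion
   into every protein's fitted melting point. One constant per group means
   no within-temperature ratio changes (exact up to the last ulp of the
   multiplication).
3. **Per-protein labeling-set leveling.** Each labeling set is first
   roughly leveled by its maximum intensity, then the protein's melting
   curve is fitted to the combined 60 points and, with the curve frozen, a
   single scaling factor per set is solved in closed form
   ($sf = \sum y m / \sum m^2$) and divided out; fit-and-scale runs three
   times (stopping early once every $sf$ is within $10^{-6}$ of 1).
   Within-set ratios — and hence all matched compound/vehicle fold
   changes — are untouched.

Proteins quantified in fewer than 80% of the channels of any labeling set
(configurable) are excluded with a recorded reason; this is a surrogate
for quality filtering whose exact original criteria are not public.
Step-1 renormalization is exactly idempotent when the previous references
are reused (`normalize_tr_step1(x, references = ...)`); a free rerun may
elect a different reference because medians are not transitive across
samples.

## Differential stability and abundance

For each protein the pipeline reports:

* **Per-temperature tests** — the mean over replicates of matched
  within-(temperature, replicate) log2 compound/vehicle ratios, with a
  two-sided one-sample t-test across replicates. Zero-variance cases are
  flagged: all-zero ratios give $p = 1$, a nonzero ratio with zero spread
  is reported at the smallest representable p-value rather than hidden.
* **Melting-point shift** $\Delta T_m$ — per replicate, melting points of
  both arms are fitted and differenced; the mean over replicates and a
  one-sample t-test provide the estimate and its significance. The
  per-replicate fits are deliberately conditioned: a protein's plateau
  ratio and slope are shape constants estimated once from all 60 points
  (by a pooled two-arm fit that models an arm offset and an arm shift, so
  the shape is not biased by pooling shifted curves), and the
  per-replicate fits freeze that shape, fit on the log-intensity scale
  (reporter noise is multiplicative), and — when the protein shows no
  abundance evidence — share one amplitude between the paired arms of a
  replicate. Ten points per arm with 10% noise do not support free
  four-parameter fits; conditioning roughly halves the shift variance
  while leaving the estimate unbiased. Arms are fit with separate
  amplitudes whenever the abundance readout calls a change
  ($p < 0.05$ *and* $|\log_2 FC| > 0.1$ at the lowest temperature), so
  abundance effects cannot masquerade as shifts.
* **Abundance change** — the same ratio test restricted to the lowest
  temperature (36.5 °C), where essentially nothing is denatured, reading
  out concentration rather than stability.
* **Distance score** — a collated effect size: the signed Euclidean norm
  of the log2 ratios over temperatures with uncorrected $p < 0.05$,
  signed by their mean, with the collation ratio
  $2^{\mathrm{mean}\ \log_2 \mathrm{ratio}}$ over the same temperatures.
  This is a documented surrogate for the score produced by external
  ratio-based analysis software whose formula is not public; it is the
  single place to swap in another definition.
* **Classification** — protein-level significance combines the
  per-temperature p-values by Fisher's method and adjusts across proteins
  by Benjamini–Hochberg; significant proteins are classed
  stabilized/destabilized or abundance up/down by whichever component
  (shift or abundance) is individually significant, the larger
  standardized effect deciding ties (the runner-up is kept as a
  secondary class).

The whole stage is scale invariant (a global intensity factor changes
nothing) and antisymmetric (swapping arm labels negates shifts, ratios and
scores) — both property-tested.

**CETSA.** Immunoblot series are not mutually calibrated, so each of the
six series (2 arms × 3 replicates) is normalized by the $I_{max}$ of its
own three-parameter fit ($I_{min} = 0$), then passed through the same
shift/ratio machinery with free per-arm fits (there is no 60-point
combined fit to condition on).

## Dose–response analysis (CCR)

Within each labeling set, samples are scaled so their median log2 fold
change against the vehicle (0 nM) channel is zero, and intensities are
expressed relative to the per-protein vehicle mean at the same assay
temperature. The response is modeled as a four-parameter log-logistic in
$pc = -\log_{10}(\mathrm{concentration\ in\ M})$:

$$r(c) = r_{low} + (r_{high} - r_{low}) \big/
  \left(1 + 10^{\,H (pEC_{50} - pc)}\right),$$

fitted best-of-16 from the starting grid $pEC_{50} \in \{9.5, 8.2, 6.8,
5.5\}$, $H \in \{-3, -0.33, 0.33, 3\}$ and rated by
pseudo-$R^2 = 1 - RSS/TSS$. The vehicle dose has no log coordinate and is
used only as the normalization anchor, never in the fit. Because
$(H, r_{low}, r_{high})$ and $(-H, r_{high}, r_{low})$ describe the same
curve, fits are canonicalized to $H < 0$, making $r_{low}$ always the
zero-dose plateau and $\mathrm{sign}(r_{high} - r_{low})$ the response
direction. $pEC_{50}$ is bounded to $[4, 12]$; a fit pinned to a bound is
a non-responder.

A protein is a responder when its 50 °C pseudo-$R^2$ reaches 0.8. The
37 °C control discriminates mechanisms: stability effects melt at 50 °C
but are flat at 37 °C (pseudo-$R^2$ difference ≥ 0.4, configurable, with
the 37 °C fit below threshold), abundance effects respond identically at
both temperatures, anything else among responders is mixed. The 0.4
default is a package choice — the quantity is conventionally displayed as
point size rather than thresholded.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes so
that every stage is testable with known ground truth:

* per-protein sigmoidal melting with baselines log-uniform over three
  orders of magnitude ($10^4$–$10^7$), plateau fractions U(0.02, 0.15),
  $T_m \sim$ U(42, 60) °C (informative on the 36.5–67 °C grid), and slopes
  $s \sim -$U(0.35, 0.55), i.e. melting transitions spanning roughly 8–13
  °C, the morphology real TPP curves show;
* effect classes with defaults of 85% unaffected, 5% stabilized (+2 °C,
  the scale of a genuine ligand hit), 4% destabilized (−2 °C), 3% + 3%
  two-fold abundance shifts — a small, roughly balanced minority of
  responders, which is exactly the regime the median-based normalization
  assumes;
* multiplicative log-normal measurement noise (default CV 0.1 — a typical
  reporter-ion replicate spread; the studies themselves do not state a
  replicate noise magnitude), per-sample scale errors of SD 0.2 log2
  units shared across proteins (the pipetting/cell-count errors step 1
  must remove), and 2% dropout;
* one master seed with per-protein substreams derived by stable hashing,
  so enlarging a cohort never changes earlier proteins' data.

CCR data place responders on the log-logistic curve around their thermal
baseline at 50 °C (flat at 37 °C), and abundance-affected proteins on the
identical relative trend at both temperatures.

What the generator does **not** emulate: peptide-level quantification and
protein inference, TMT isotope impurity and co-isolation interference,
intensity-dependent missingness, correlated (batch-structured) noise, and
melting curves that deviate from the sigmoid (multi-domain proteins,
aggregation artifacts). Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to every
pathology of real MS data.

## Numerical choices and degenerate inputs

* Optimizer: Levenberg–Marquardt (`minpack.lm`), parameter tolerance
  $10^{-8}$, multi-start as described; solver bounds and tolerances are
  package choices, as the originals are not stated anywhere.
* Median of an even count is the mean of the central pair (R's default).
* Raw intensity 0 is converted to missing at load: a zero reporter ion is
  a non-detection, and keeping it would poison log-ratios.
* Constant series: melting fits flag them instead of converging; constant
  dose responses get pseudo-$R^2 = 0$ and a `constant` flag.
* A melting point pinned to its box bound, or an all-zero series, is a
  failed fit: the replicate (or CETSA series) is dropped, never silently
  reported.
* The `dtm` parameter of paired fits starts at 0.1, not 0 — numeric
  derivative steps are value-scaled and would vanish at exactly zero.

## Problem sizes used by the test suite

The packaged tests run cohorts of 300–1000 proteins per simulation (about
200 effect proteins pooled across simulations for recovery rates, 1000
proteins for null calibration, 200 fits for dose-response recovery) —
sizes chosen so that binomial noise on the checked rates is small relative
to the margins being asserted, while a full run stays comfortably inside a
coffee break on one core.

## Known limitations

* The distance score and the quality filter are documented surrogates;
  numbers produced by the original external software for the same data
  will differ in detail (sign conventions and ranking behave the same).
* Between-temperature normalization can only remove per-temperature scale
  errors to the extent the proteome consensus is itself sigmoid-shaped;
  with large per-sample scale errors a small curve-like residual remains
  and is shared by both arms (it cancels in $\Delta T_m$ to first order).
* With three replicates, per-temperature t-tests have two degrees of
  freedom; power for ±2 °C shifts at protein-level FDR control is modest,
  and the package reports honest, uncorrected per-temperature p-values
  alongside the corrected protein-level calls.
* Fisher's combination across temperatures assumes independent
  per-temperature tests; replicate-level correlation (e.g. shared
  labeling-set artifacts) would make the combined p-values anti-
  conservative.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_tr_experiment(500, truth_spec(), noise_model(), seed = 1)
run <- run_tr_pipeline(sim$matrix, tpp_config("TR"), output_dir = "out")
head(run$results[order(run$results$adj_p), ])

ccr <- simulate_ccr_experiment(200, seed = 1)
dose <- run_ccr_pipeline(ccr$matrix)
subset(dose$results, mechanism == "stability")
```
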