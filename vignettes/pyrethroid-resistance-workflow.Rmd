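---
title: "Quantifying pyrethroid resistance: probit bioassays, channel modification and kdr genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pyrethroid resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrtox)
```

## The problem

Knockdown resistance (*kdr*) to pyrethroid insecticides in *Aedes aegypti*
is characterised along three complementary lines of evidence:

1. **Bioassays** establish *how resistant* a strain is: concentration–
   mortality curves for larvae and adults give LC50s, and the resistance
   ratio (RR) of resistant over susceptible LC50 quantifies the fold
   difference. Synergist co-exposure (PBO, DEM, TPP) separates metabolic
   detoxification from target-site insensitivity.
2. **Electrophysiology** establishes *why*: candidate sodium-channel
   mutations are expressed in *Xenopus* oocytes and the fraction of
   channels modified by a pyrethroid is measured from tail currents under a
   repeated depolarising pulse train; EC50 shifts between variants quantify
   the loss of channel sensitivity.
3. **Genotyping** establishes *where and how often*: strain coding
   sequences are compared, individual mosquitoes are genotyped at the kdr
   codons (410 and 1534), and field populations are screened for the mutant
   alleles.

kdrtox implements all three stages plus a synthetic-data module that
generates each kind of raw data with known truth, so that every estimator
in the chain can be validated by recovery.

## Probit concentration–mortality analysis

Mortality at concentration $c$ is modelled as
$\Phi^{-1}(p) = \alpha + \beta \log_{10} c$. The dose metameter is
$\log_{10}$ — the toxicological convention and the default of the
classical PROBIT procedures. Fitting is maximum likelihood via iteratively
reweighted least squares (deviance tolerance $10^{-10}$); replicates at the
same concentration are pooled.

* **LC quantiles.** $\mathrm{LC}_p = 10^{(\Phi^{-1}(p)-\alpha)/\beta}$,
  with 95% limits from Fieller's theorem applied to the ratio
  $(\Phi^{-1}(p)-\alpha)/\beta$. Fieller rather than delta intervals are
  used because the slope's sampling error makes the ratio distribution
  visibly asymmetric in small assays; the parametric-bootstrap comparison
  in the test suite shows the two constructions agree to within 10% on a
  typical design.
* **Goodness of fit.** Pearson $\chi^2$ on the pooled concentration groups
  with $k-2$ df. When $P < 0.05$ the parameter covariance is inflated by
  the heterogeneity factor $\chi^2/\mathrm{df}$ and the normal quantile is
  replaced by the $t$ quantile with $k-2$ df — the standard correction for
  extra-binomial variation.
* **Natural mortality.** Control mortality is handled by a separate Abbott
  pre-correction, `abbott_correct()`, rather than a natural-response
  parameter in the likelihood; control jars are the observed estimate of
  natural response and the treated mortalities are rescaled by
  $(p - p_c)/(1 - p_c)$ carried as effective counts.
* **Resistance ratios.** $\mathrm{RR} = \mathrm{LC50}_R / \mathrm{LC50}_S$
  with $\operatorname{var}(\log_{10}\mathrm{LC50})$ by the delta method
  from each fit's covariance, variances summed, and the CI back-transformed.
  The ratio is significant when the CI excludes 1 — the lethal-dose-ratio
  test familiar from toxicology practice. `resistance_ratio_from_summary()`
  applies the same construction when only published LC50s with CIs are
  available, recovering the log-scale SE from the interval width.
* **Degenerate data.** Complete separation (all groups fully dead or fully
  alive) and non-monotone data (negative slope at the optimum) are flagged,
  not fitted; flagged fits refuse to produce LC values or ratios.

```{r, eval = FALSE}
tb <- simulate_mortality(mortality_sim_spec(
  true_lc50 = 7.6e-6, true_slope = 5.3,
  concentrations = design_concentrations(7.6e-6, 5.3),
  n_per_conc = 134, seed = 42), unit = "ug a.i./cm2")
fit_probit(tb)
```

## Synergist comparison

Replicate jar/vial mortality proportions at a fixed LC50 challenge are
compared by one-way ANOVA with Scheffé post hoc contrasts, both computed
from first principles (direct sums of squares; the Scheffé bound
$\sqrt{(k-1)F_{\alpha;k-1,N-k}}\cdot\sqrt{\mathrm{MSW}(1/n_i+1/n_j)}$).
The replicate proportion — not the individual insect — is the observation
unit. Proportions are analysed untransformed by default, matching common
reporting practice for these assays; an arcsine–square-root option is
available (`transform = "asin"`) for strongly bounded data. Scheffé is used
for the per-synergist reference contrasts as well, which makes the
procedure conservative: its significant set is provably contained in the
unadjusted pairwise-t set, a property the test suite checks.

## The channel model and the M statistic

The paper-level quantity is the percentage of pyrethroid-modified
channels,

$$M = \frac{I_\mathrm{tail}/(E_h - E_\mathrm{Na})}
           {I_\mathrm{Na}/(E_t - E_\mathrm{Na})}\times 100,$$

a tail-to-peak conductance ratio: $I_\mathrm{tail}$ is the maximal tail
current after the final repolarization, $I_\mathrm{Na}$ the peak current
during depolarization, $E_h$ the repolarization potential, $E_t$ the step
potential, and $E_\mathrm{Na}$ the reversal potential interpolated from
the IV curve. The default protocol is the 100-pulse train of 5-ms steps
from −120 to 0 mV with 5-ms interpulse intervals.

The generator needs an explicit conductance model; none is dictated by the
assay, so kdrtox adopts a deliberately simple m³h scheme:

| parameter | default | meaning |
|---|---|---|
| `g_max` | 0.15 µS | maximal conductance |
| `e_na` | +50 mV | reversal potential |
| $\tau_m$(−120) | ≈0.12 ms | unmodified deactivation (fast) |
| $\tau_h$(0) | ≈25 ms | inactivation at the step potential (slow) |
| `tau_slow` | 50 ms | deactivation of modified channels |
| `sample_interval` | 0.05 ms | sampling grid |

Three choices matter and are worth justifying:

* **Piecewise-exponential evaluation.** At constant voltage the gating
  ODEs are linear, so within each protocol epoch the states relax exactly
  as single exponentials. Traces are therefore evaluated analytically —
  there is no integrator error to distinguish from model behaviour.
* **Slow inactivation at 0 mV.** Only the tail/peak ratio enters M, but
  if the first-pulse peak is strongly inactivation-limited the mapping from
  the planted modified fraction $f$ to extracted M becomes noticeably
  concave, and a Hill curve planted in $f$ is recovered with a biased EC50.
  With $\tau_h(0) \approx 25$ ms the peak is activation-dominated, M is
  nearly proportional to $f$, and the noiseless EC50 recovery bias stays
  under 5%. Because the apparent M(c) curve depends on concentration only
  through $c/\mathrm{EC50}$, EC50 *ratios* between variants are exactly
  preserved regardless of this residual nonlinearity — which is why the
  fold-shift recovery is the robust end-to-end check.
* **Modified channels.** A fraction $f$ of channels activates normally,
  does not inactivate, and deactivates with `tau_slow` ≫ the unmodified
  deactivation constant, producing a well-separated tail. The concentration
  dependence of $f$ is a Hill curve,
  $f(c) = (M_\mathrm{max}/100)\,c^h/(c^h + \mathrm{EC50}^h)$ — the assay
  literature plots such curves but rarely writes the model; Hill with free
  slope and plateau is the standard choice for channel-modification data
  and is what `fit_hill()` fits back.

Noise is additive Gaussian on the sampled current; `noise_sd_for_m()`
converts a noise level expressed as a fraction of the M plateau into
current units through the M formula. No capacitive transients or leak are
simulated, and extraction correspondingly applies only a 0.3-ms blanking
window after repolarization (configurable) plus a 0.25-ms running-mean
before taking the tail maximum — smoothing confined to the blanked window
so the fast pre-blank decay cannot leak in. On noiseless traces the
extraction pipeline reproduces the generator's closed-form expected M to
well within 1%.

`expected_m()` is the oracle: it evolves the same model analytically
(end-of-epoch state recursion, fine-grid first-pulse peak, tail taken at
the blanking edge) but shares no code with the extraction path.

Peak current "before pyrethroid exposure" strictly calls for a paired
pre-drug trace. The generator returns single traces and the default
pipeline takes the peak from the same trace; `percent_modified_trace()`
accepts an explicit `i_na` when a paired pre-drug recording exists. The
expected-M oracle is defined consistently with the same-trace convention.
Per-oocyte M values at all concentrations enter one Hill fit per variant
(no pre-averaging across oocytes): averaging first would discard the
between-oocyte variance that the fit's standard errors should reflect.

## Sequence analysis

* Translation uses the standard genetic code; full-CDS translation rejects
  ambiguity codes, because it is only meaningful for an unambiguous
  consensus.
* `compare_cds()` requires positionally comparable (equal-length,
  same-offset) sequences; alignment is deliberately out of scope since the
  use case is complete cloned CDSs of one gene. Every mismatch is reported
  with codon context and a synonymous/nonsynonymous class.
* Genotypes are called by IUPAC expansion of the codon string: one
  expansion is homozygous, two expansions with distinct amino acids are
  heterozygous, and more than two expansions cannot arise from one diploid
  site and are labelled ambiguous — never silently resolved. Residues are
  1-based and mapped through a per-sequence offset (the bundled synthetic
  template uses offset 0).
* Allele frequencies use diploid accounting (hom-mutant 2, het 1) with
  ambiguous individuals excluded and the reduced n reported. Population
  screens count *carriers* (any call containing the mutant amino acid),
  since population rows are consensus calls in which zygosity of the
  underlying individuals is not observable.

The synthetic module plants single-base synonymous changes (third-position
wobble picks, seeded) so that a planted design of 6 synonymous sites plus
V410L (GTA→TTA) and F1534C (TTC→TGC) yields exactly 8 nucleotide
differences of which 2 are nonsynonymous. Panels are Sanger-style: one
consensus sequence per individual with IUPAC codes at heterozygous bases —
no read pairs, no chromatograms.

## What the generators do and do not emulate

The mortality generator reproduces binomial sampling under an exactly
probit truth with optional natural mortality; it does not emulate
between-jar overdispersion, dose-preparation error, or time-to-death
structure. The trace generator reproduces deterministic macroscopic gating
with additive noise; it does not emulate single-channel stochasticity,
capacitive/leak artefacts, rundown, or oocyte batch effects. The sequence
generator plants exactly the configured variants on a fixed background.
Passing recovery tests therefore demonstrates correctness of the
estimators under their own assumptions — not robustness to the real-world
artefacts listed above, which is the usual caveat for simulation-validated
analysis code.

## Problem sizes and numerical choices

The validation studies use desk-scale designs chosen to mirror the
published experiments while keeping a full run in the order of seconds to
a minute: 200 replicate bioassays of the adult susceptible deltamethrin
design (five concentrations spanning 5–95% mortality, 134 insects each)
for probit recovery; two variants × 6 concentrations × 5 oocytes with
noise equivalent to 2% of the M plateau for the fold-shift pipeline;
500 simulations for the $\chi^2$ calibration check and 1000 simulated
strain pairs for RR interval coverage. Optimizer settings: glm IRLS with
deviance tolerance $10^{-10}$; Hill fits by Levenberg–Marquardt from a
5×3×2 multi-start grid over (log EC50, slope, plateau) keeping the lowest
residual sum of squares, with the plateau bounded at 100%.

## Known limitations

* The probit module fits a single link; logit or complementary log-log
  alternatives are out of scope.
* Fieller intervals become unbounded when the slope is not distinguishable
  from zero; such intervals are returned as `NA` rather than clipped.
* The Scheffé reference contrasts are conservative by construction; a
  Dunnett-style many-to-one procedure would be more powerful but is not
  what the assay convention reports.
* The channel model is a convention, not a biophysical fit; absolute M
  values depend on it, while fold shifts between variants do not.
* Population screening trusts the supplied consensus codon strings; it
  performs no base-calling or quality control.
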