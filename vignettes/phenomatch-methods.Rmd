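---
title: "Identifying undiagnosed suicidality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying undiagnosed suicidality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

`phenomatch` operationalizes a simple epidemiological idea: patients whose
comorbidity profiles look like those of diagnosed suicidality cases, but
who carry no suicidality ICD-10 code themselves, are where undocumented
cases concentrate. This vignette explains each stage's model, the
parameters that matter, the synthetic data generator used in place of
protected hospital records, and the numerical and design choices a
maintainer would want written down.

## 1. Case definition

Suicidality is operationalized purely through ICD-10 codes, in three
severity subtypes:

* **ideation** — `R45.851` only; ICD-10 has no history-of-ideation code,
  so ideation is always documented for the present encounter;
* **self-harm** — represented in the packaged default by the four
  personal-history codes `R45.88`, `Z91.5`, `Z91.51`, `Z91.52`. The full
  self-harm code family runs to roughly 1,400 codes and is maintained
  externally; the codeset file is deliberately user-extensible (add exact
  codes or `"X71*"`-style prefix patterns) and the package does not claim
  to reproduce the full family;
* **attempt** — `T14.91` plus its initial (`XA`), subsequent (`XD`) and
  sequela (`XS`) encounter forms.

Matching is exact on normalized codes (uppercase, dot-free); prefix
semantics must be requested explicitly with a trailing `*`. Silent prefix
matching would inflate large code families unpredictably, so it is opt-in
per pattern. History-of codes count toward case status at any encounter:
the source codeset places them inside the self-harm subtype without
restriction, and a personal-history code is still evidence the patient is
a case.

A patient is a **case** if any encounter matches any subtype; the **index
date** is the earliest such encounter; the patient's subtype set is the
union over encounters. Study selection keeps encounters aged 6–18
inclusive at both ends, dated in a half-open `[start, end)` window (a
window quoted "June 2016 to June 2022" has no stated boundary semantics;
a documented convention beats ambiguity), and carrying an ED note.

## 2. Comorbidity screen

For the suicidality codeset $A$ and any other observed code $B$,

$$P(A \mid B) = \frac{P(A \cap B)}{P(B)} = \frac{n_{AB}}{n_B},$$

counted **per patient over the whole study period** — co-occurrence means
"in the same patient", not "at the same visit". The screen, per stratum
(age group × sex × subtype, by default the overall population plus each
one-factor margin):

1. candidate codes are all observed codes outside the suicidality
   codeset;
2. codes with $n_B < 20$ patients are dropped (rare-event guard; the
   alternative reading, $n_{AB} < 20$, is available via
   `rare_filter = "n_AB"`);
3. the 20 codes with the highest $P(A \mid B)$ are retained, ties broken
   by larger $n_B$ then code string, for determinism;
4. each retained code's 2×2 patient table is tested with Pearson's
   chi-square (no continuity correction, df = 1);
5. p-values are Bonferroni-corrected with family size $m$ = the total
   number of (code, stratum) tests actually performed in the run — the
   family size is recorded on the result for audit — and flagged
   significant below $\alpha = 0.05$.

Selection happens **before** testing, mirroring a screen-then-test
workflow; the union of codes significant in at least one stratum, with
stratum provenance, feeds the propensity model.

Two statistical caveats are worth stating. First, with a phenotype
prevalence of a few percent, the chi-square approximation needs enough
cases among code carriers; the $n_B \ge 20$ filter alone does not
guarantee expected cell counts above the usual rule of thumb in very
small strata. Second, $P(A \mid B)$ measured on *documented* cases
understates the conditional probability of *true* suicidality whenever
documentation is incomplete — that is precisely the gap the matching
stage exploits.

DSM-5 grouping pools sparse codes into disorder categories via an
ordered, first-match-wins pattern file (`F63*` before `F6*` carves
impulse-control codes out of the personality block). DSM-5 publishes no
official ICD-10 crosswalk, so the packaged mapping covers the common
pediatric mental-health categories through F-chapter ranges and is
user-replaceable; unmapped codes are counted and reported, not silently
dropped.

## 3. Feature matrix

Units are encounters, not patients: the case cohort is every
case-defining encounter of a case patient; the comparator cohort is every
encounter of every non-case patient (options restrict cases to the index
encounter, or comparators to one encounter per patient). Features
aggregate each patient's history **cumulatively up to the unit encounter
date, inclusive** — the diagnosis motivating a visit is recorded at that
visit, so the unit encounter's own codes count; an exclusive
(strictly-before) variant is available for sensitivity analysis.

Blocks, in fixed order with alphabetical columns inside each block:
demographics (adolescent indicator, female indicator, race one-hots with
the alphabetically first level as reference and `"unknown"` kept as its
own level, since EHR missingness is informative); utilization (prior
visit count, distinct note types seen); DSM-5 category indicators; and
significant-code indicators.

Codes matching the suicidality codeset are stripped from the history
before any feature is computed, and are refused as explicit features, so
the outcome cannot leak into the covariates; a construction test asserts
that injecting extra suicidality codes changes no feature value.

## 4. Propensity estimation and matching

A logistic model of case status on the feature matrix is fit by
iteratively reweighted least squares. The default adds an L2 penalty of
$\lambda = 10^{-6}$ on the slopes (intercept unpenalized): EHR one-hot
matrices are separation-prone, and the tiny ridge keeps the optimum
finite while remaining indistinguishable from the MLE away from
separation (the unpenalized mode is retained, agrees with `glm` to
$10^{-6}$ in tests, and raises an explicit error when separation makes it
diverge). Convergence is declared at a relative penalized log-likelihood
change below $10^{-8}$; zero-variance columns get coefficient 0 and are
reported.

Matching operates on the **logit** of the score, where resolution is
highest near 0 and 1. Cases are processed in descending logit order
(hardest to match first); each takes its $k$ nearest not-yet-used
comparators by absolute logit difference, ties broken by comparator
encounter id, optionally within a caliper. The greedy, without-
replacement, $k = 1$, no-caliper defaults mirror common PSM tooling; none
of these knobs is dictated by the underlying study, so all are exposed
and recorded in the run manifest. Injectivity of the comparator
assignment is asserted on every run.

Diagnostics: standardized mean differences per feature
($(\bar x_1 - \bar x_0) / \sqrt{(s_1^2 + s_0^2)/2}$; zero pooled SD gives
0 for equal means and a flagged `Inf` otherwise) before and after
matching, and binned score distributions with threshold fractions (shares
of each group at score ≥ 0.9 and < 0.5, the conventional summary of how
far matching pulls the comparator mass toward the cases).

## 5. The synthetic generator

Real pediatric ED extracts are protected, so validation runs on a seeded
generator whose structure matches what the analysis assumes — including
the one thing no real extract can provide: ground truth.

Per patient, in order:

1. **race** from a configurable distribution;
2. **comorbidity flags**, independent Bernoulli draws with configured
   marginal prevalences;
3. **latent suicidality** from a logistic model on the flags. The
   intercept is exactly `qlogis(baseline)`; each coefficient is solved
   numerically (1-D root finding swept to joint convergence within
   $10^{-9}$, marginalizing over the other flags by exact product-
   Bernoulli enumeration — hence the cap of 12 planted codes) so that the
   *population* conditional $P(\text{latent} \mid \text{flag}_j)$ equals
   its target;
4. **sex and age group**, drawn conditional on latent status so the
   female/adolescent skew among cases is plantable without touching the
   latent model (latent status never depends on demographics, so the
   coefficient solution is unaffected);
5. **documentation**: documented = latent AND
   Bernoulli(`documentation_sensitivity`), default 0.5 — chart-review
   audits of this phenotype find roughly half of true cases carry codes;
6. **encounters**: 1 + Poisson(0.52) per patient (matching ~91k
   encounters per ~60k patients; the true per-patient distribution is
   unreported, so Poisson+1 is a stand-in and config-exposed), clustered
   within ±90 days of an anchor date so age at visit is constant per
   patient; birth year is derived from the anchor;
7. **code placement**: each comorbidity/noise flag lands on one uniformly
   chosen encounter; documented patients get subtype memberships
   (ideation 0.86, self-harm 0.39, attempt 0.067, at least one
   guaranteed) whose codes land on one encounter; unintentional-injury
   codes are emitted at a base rate of 0.01 with a ×5 relative rate among
   latent cases, emulating "accidental" harm codes that track true
   self-harm;
8. **notes**: every encounter carries an ED note; a categorical
   distribution adds a discharge summary (0.20) or psychiatric note
   (0.10).

Default planted comorbidities follow the published pediatric conditional-
probability profile: rare codes with high conditionals (personality
disorder 0.3% prevalence / 0.44 target; gender dysphoria 0.6% / 0.43),
mid-range psychiatric codes (bipolar 1% / 0.36; schizophrenia-spectrum
0.8% / 0.32; depression 9.1% / 0.34) and common-but-weak anxiety
(15.6% / 0.10, a package choice — its conditional is not published). Ten
noise codes (respiratory, GI, injury, headache…) with no suicidality
association give the screen a realistic null pool. The baseline latent
probability is 0.029; with half of cases documented, the documented
encounter-level prevalence lands near 2–3%, and latent patient-level
prevalence near 7%.

What the generator deliberately does **not** emulate: correlation between
comorbidities (flags are independent given nothing; the latent status
depends on them, not vice versa — the simplest structure consistent with
a marginal conditional-probability analysis), realistic frequencies for
the long tail of ICD-10, longitudinal disease progression, and coding
practice drift over calendar time. Passing tests therefore show the
machinery is correct and the mechanism works under the assumed structure;
they do not certify effect sizes on real EHR data, where correlated
comorbidities and unmeasured confounding will change the numbers.

Ground truth (`latent_suicidality`) is stored out-of-band in the patients
table and written to a separately named file; the encounters table never
distinguishes an undocumented case from a non-case.

## 6. Numerical and testing choices

* All generation and matching is deterministic given the seed; identical
  configurations reproduce byte-identical artifacts (manifests differ
  only in timestamp).
* The 2×2 chi-square is computed in double precision from the closed form
  $N(ad-bc)^2/(r_1 r_2 c_1 c_2)$ (the cross-product overflows 32-bit
  integers at realistic cohort sizes) and matches `chisq.test(correct =
  FALSE)` to $10^{-9}$; the two-proportion z-test matches `prop.test`
  likewise; the Woolf odds-ratio interval matches the saturated weighted
  logistic fit, whose Wald interval has the same closed form at the MLE,
  to the oracle's own convergence (~$10^{-6}$). Zero cells get the
  Haldane–Anscombe 0.5 correction, flagged.
* Degenerate inputs fail loudly: $P(A\mid B)$ with $n_B = 0$, chi-square
  with a zero margin, logit at 0 or 1, pooled proportions of 0 or 1, and
  inverted age/date ranges all raise validation errors rather than
  returning NaN.
* Parameter-recovery tests compare empirical conditionals on a draw of
  $10^6$ patients against targets within ±0.03: the rarest planted code
  has ~3 carriers per 1,000 patients, so the draw is sized to keep its
  Monte-Carlo error well inside the band (the solver itself is verified
  to $10^{-6}$ by exact enumeration, independently of simulation).
* The null-calibration suite (no planted effects, injury rate ratio 1)
  uses 200 replicates of 10,000 patients — large enough that every
  candidate code's expected case cell clears the chi-square
  approximation's working range — and checks the family-wise
  false-positive rate against $0.05 + 3\,\mathrm{SE}$. At much smaller
  replicate sizes the Pearson statistic is visibly anticonservative on
  sparse tables; that is a property of the test, shared by any
  implementation, and worth remembering when screening small strata.
* The full-scale acceptance run uses the default ~60k-patient
  configuration and completes in about 90 seconds on one CPU.

## 7. Known limitations

Greedy nearest-neighbour matching is not optimal matching; with a small
comparator reservoir near the top of the score distribution, early cases
can take the best comparators. The packaged DSM-5 crosswalk is a
pragmatic F-chapter mapping, not a clinically validated one. The screen's
conditional probabilities are descriptive associations — no temporal
ordering of comorbidity versus suicidality onset is attempted. And the
enrichment evaluation requires ground truth: on real data that means a
chart-review adjudication file, with all the sampling caveats that
implies; the synthetic latent labels stand in for it here.
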