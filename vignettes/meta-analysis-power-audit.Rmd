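---
title: "Auditing the power and equivalence of a meta-analytic literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the power and equivalence of a meta-analytic literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A meta-analysis is only as informative as the studies inside it. When those
studies are small and the plausible effects are small — the situation in
much of the intranasal oxytocin literature, where summary standardized mean
differences cluster around 0.1–0.2 — two failure modes are easy to confuse:

1. a non-significant summary because there is no worthwhile effect, and
2. a non-significant summary because no design in the corpus could have
   detected one.

`poweraudit` separates these with four instruments applied corpus-wide:
per-study power profiling, equivalence (TOST) testing of summary estimates,
subgroup contrasts from summary statistics, and the Test of Excess
Significance. A generative model of such corpora closes the loop, letting
every instrument be calibrated against data whose truth is known.

```{r, eval = FALSE}
library(poweraudit)
audit <- run_audit(generator_config(seed = 7), quiet = TRUE)
audit
```

## Power model

Every study enters as an SMD estimate with standard error. Power is
normal-theory ("Wald"): for an assumed true effect $\delta^\*$,

$$\mathrm{power}(\delta^\*, se) =
  1 - \Phi\!\left(z_{1-\alpha/2} - \tfrac{\delta^\*}{se}\right) +
  \Phi\!\left(-z_{1-\alpha/2} - \tfrac{\delta^\*}{se}\right),$$

with $\alpha = 0.05$ two-sided by default. There is no small-sample $t$
correction: the inputs are estimates with standard errors, not raw data, and
the z treatment keeps power, significance ($|d|/se > z_{1-\alpha/2}$) and the
one-sample TOST on a single consistent scale. At $\delta^\* = 0$ the formula
returns exactly $\alpha$, which doubles as a self-check in the test-suite.

Profiles are evaluated on a grid of assumed effects (default 0.1–1.0 in
steps of 0.1, configurable; values above 1 are rarely informative for this
literature because everything has near-ceiling power there) and at the
parent meta-analysis's observed summary estimate — the literature's own best
guess of the truth.

Two aggregation rules keep studies from being double-counted:

- a study reporting several outcomes contributes the **median** of its
  per-outcome powers (`dedup_power()`), and its significance status is that
  of its median-$|z|$ outcome (an "any outcome significant" rule is
  available and strictly more liberal);
- a study appearing in several meta-analyses is collapsed to one value per
  condition by the median before corpus-level summaries.

Percent summaries are rounded half-away-from-zero to one decimal, so a
median power of 0.0545 prints as 5.5%, never 5.4%.

## Equivalence testing

For a summary estimate $(d, se)$ and a smallest effect size of interest
(SESOI) $\Delta$, the two one-sided tests are

$$p_{upper} = \Phi\!\left(\tfrac{d - \Delta}{se}\right), \qquad
  p_{lower} = 1 - \Phi\!\left(\tfrac{d + \Delta}{se}\right), \qquad
  p_{TOST} = \max(p_{upper}, p_{lower}),$$

declared equivalent when $p_{TOST} \le \alpha$ — identical to the
$(1-2\alpha)$ (i.e. 90%) confidence interval lying strictly inside
$(-\Delta, +\Delta)$. That duality is enforced as a property test on $10^4$
random triples with zero tolerated disagreements. The tie at exactly
$p_{TOST} = \alpha$ is declared equivalent (closed boundary). Default bounds
$\Delta \in \{0.1, 0.2, 0.3\}$ bracket the small summary effects typical of
this literature; they are ordinary arguments, not constants.

"Non-significant meta-analysis" — the denominator of the equivalence counts
— is decided from the data ($|d|/se$ against the z criterion), not from the
source publication's own claim, so the screen is reproducible from the
tables alone.

Subgroup contrasts (clinical vs healthy populations; multiple vs single
dosing within clinical studies) compare per-study power percentages through
the Welch $t$-test computed from group summary statistics, with
Welch–Satterthwaite degrees of freedom, plus a two-sample TOST whose
Cohen's-d bound (default 0.2) is converted to the raw scale by
$\Delta_{raw} = d \cdot \sqrt{(sd_1^2 + sd_2^2)/2}$ and tested on the Welch
df. Note that two-sample contrasts are $t$-based while one-sample summary
tests are $z$-based: the former have genuine group sizes, the latter do not.

## Test of Excess Significance

For each univariate meta-analysis with $n \ge 2$ studies, the observed
number of significant studies $O$ is compared with the expected number
$E = \sum_i \mathrm{power}(\theta_{ref}, se_i)$, where $\theta_{ref}$
defaults to the meta-analysis's own summary estimate (a user-fixed effect is
available; fixed- vs random-effects provenance of the summary is whatever
the ingested table contains). Two forms:

- **chi-square** (default): $A = (O-E)^2/E + (O-E)^2/(n-E)$, with the
  $\chi^2_1$ tail halved and assigned to the excess direction;
- **exact**: the one-sided Poisson-binomial tail $P(X \ge O)$ computed by
  direct convolution of the per-study power vector — also the automatic
  fallback when $E$ is degenerate (0 or $n$), where the $A$ statistic is
  undefined.

A meta-analysis is flagged only when $p < 0.05$ **and** $O > E$: a deficit
of significant studies is not "excess". No continuity correction is applied.
Multivariate meta-analyses are excluded because their constituent estimates
are not independent significance tests of a single effect. The exact tail is
verified against full $2^n$ enumeration ($n \le 12$, $10^{-10}$ tolerance),
and the screen is calibrated on simulated corpora: with no censoring the
exact form flags at most 8% of 500 unbiased meta-analyses (the test is
conservative because $O$ is discrete and $\theta_{ref}$ is estimated), and
heavy censoring of non-significant studies must raise that rate.

## Power over time

`trend_table()` gives yearly medians of deduplicated study power at each
grid effect; `power_trend_anova()` runs a classical one-way ANOVA of
per-study power (at the observed summary, by default) on publication year,
with years as given — no binning. Degenerate inputs are explicit: all-equal
values return $F = 0$, $p = 1$ with a warning; zero within-group variance
with differing means returns an infinite $F$. The ANOVA's type-I rate is
checked by simulation ($10^4$ null replicates, 5 groups of 10) and the
$SS_{total} = SS_{between} + SS_{within}$ identity to $10^{-9}$.

## The synthetic corpus generator

`generate_corpus()` draws a corpus under a nested random-effects model:

$$\theta_k \sim N(\mu, \tau^2), \qquad
  \theta_{ki} \sim N(\theta_k, \tau_w^2), \qquad
  d_{ki} \sim N(\theta_{ki}, SE^2), \qquad
  SE = \sqrt{2/n + d^2/(4n)},$$

the last being the large-sample sampling variance of an SMD from two equal
groups of size $n$. Defaults — 35 meta-analyses of 2–5 studies each,
$\mu = 0.14$, $\tau = \tau_w = 0.1$, $n$ per group uniform on 10–40 — are
chosen so the emitted corpus has the statistical silhouette of the published
oxytocin literature: ~110 unique studies, summary SMDs with median near
0.14, and median study power in the single digits at those effects. Label
frequencies (64% clinical, 44% multiple-dose, 18/35 univariate, 8/35
sign-reversed) mirror the same corpus. Publication bias is a single knob:
each non-significant study is dropped with probability `censor_prob`
(default 0), with a meta-analysis regenerated if it loses every study.
Summaries are pooled by fixed-effect inverse variance by default — the
models actually used by audited meta-analyses are unknowable from summary
tables, and the fixed-effect choice is the transparent one — with a
DerSimonian–Laird option; both are cross-checked against `metafor::rma()`
in the tests. One RNG stream is seeded from the config with deterministic
per-meta sub-seeds, so corpora are byte-identical across runs.

What the generator deliberately does **not** emulate: correlated outcomes
within a study (outcomes are drawn independently around the study's true
effect), heterogeneous effect-size flavors (Hedges' g vs Cohen's d are
treated as one SMD scale, as the ingest schema also does), unequal group
sizes, rounding of published numbers, and any pharmacological structure
behind the population/dosing labels (they are exchangeable tags). A passing
calibration on synthetic corpora therefore shows the pipeline's statistics
behave as designed under the stated model — not that any real literature
satisfies that model.

## Numerical and design choices

- Normal quantile for 95% CI-to-SE conversion: `qnorm(0.975)` = 1.959964,
  never a rounded 1.96.
- Sign reversal negates effects and swaps CI bounds; SEs untouched; the
  operation is an involution, and fixtures are written in the publication
  direction so write→read is the identity.
- Study deduplication keys on the supplied `study_id`; fuzzy matching of
  titles is editorial work, not computation, and is out of scope. Which
  meta-analyses need `reverse_sign` is likewise an input, not inferred.
- Unknown population/dosing labels are kept but excluded from the
  corresponding contrasts only.
- Emitted report tables use fixed 6-significant-digit, locale-independent
  formatting so repeated runs are byte-identical; corpus schema files use 17
  significant digits so doubles round-trip exactly.
- Test problem sizes (e.g. $10^5$-replicate Monte-Carlo oracles, 500-meta
  calibration corpora, 100-replicate parameter recovery) were sized to give
  three-binomial-SE resolution on the rates being checked while keeping the
  suite comfortably under a couple of minutes.

## Limitations

- The audit consumes summary tables; it cannot detect extraction errors or
  recompute effect sizes from raw study data.
- Power is normal-theory; for very small constituent studies a t-based power
  would be slightly lower, so single-digit medians here are, if anything,
  optimistic.
- The Test of Excess Significance conditions on an estimated reference
  effect; with strong heterogeneity or few studies its p-values are
  approximate, which is why both forms and the calibration simulations are
  shipped.
- The trend ANOVA treats year as an unordered factor; it tests *any*
  year-to-year difference, not a monotone improvement.
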