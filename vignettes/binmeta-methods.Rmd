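---
title: "Interpreting heterogeneity in GWAS meta-analysis with m-values and the binary effects test"
author: "binmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting heterogeneity in GWAS meta-analysis with m-values and the binary effects test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmeta)
```

# The problem

A GWAS meta-analysis combines per-study effect estimates $X_i$ (log odds
ratios) with known variances $V_i = \mathrm{se}_i^2$ for $n$ independent
studies. When the estimates disagree more than sampling noise allows, the
analyst faces a question the per-study p-values cannot answer: *in which
studies does the effect actually exist?* A non-significant p-value is not
evidence of absence — it may simply reflect a small sample. binmeta
implements a cross-study answer: the **m-value**, the posterior probability
that the effect exists in each study, together with the **P-M plot** for
reading it, and the **binary effects (BE) association test** that exploits
it.

# The model

## Binary effects assumption

Two assumptions define the model. First, the effect is either present or
absent in each study — heterogeneity is modelled as a binary pattern, not a
continuum. Second, where the effect is present, its size is similar across
studies: a single true effect $\mu$ shared by the effect-carrying studies,
with a zero-centred normal prior $\mu \sim N(0, \sigma^2)$. The binary
pattern is encoded by a configuration vector $c \in \{0,1\}^n$.

## Priors

* $\sigma$ (`EffectPrior(sigma=)`, default 0.2) is the prior standard
  deviation of the true log odds ratio. 0.2 suits the small effects typical
  of complex traits; 0.4 suits large effects. It is the one tunable that
  materially moves m-values and should be set from prior knowledge of the
  trait, not from the data.
* The probability that any study carries the effect has a
  $\mathrm{Beta}(\alpha, \beta)$ prior (default $\alpha=\beta=1$, uniform).
  Integrating it out gives the configuration prior
  $P(c) = B(k+\alpha,\, n-k+\beta)/B(\alpha,\beta)$ with $k$ the number of
  ones; the $2^n$ configuration probabilities sum to one. An analyst
  expecting most studies to carry the effect can use an asymmetric prior
  (e.g. $\alpha > \beta$).

## Likelihood and m-values

Given $c$, studies with $c_i=0$ contribute $N(X_i; 0, V_i)$ and the
effect-carrying set $A$ contributes
$\int \prod_{i \in A} N(X_i; \mu, V_i)\, N(\mu; 0, \sigma^2)\, d\mu$.
Completing the square over $\mu$ with precisions $w_i = 1/V_i$,
$W = \sum_{A} w_i$, $S = \sum_{A} w_i X_i$ gives the closed form used
throughout:

$$\log P(X \mid c) = \sum_{i=1}^n \log N(X_i; 0, V_i)
  - \tfrac12 \log(1 + \sigma^2 W) + \frac{S^2}{2\,(W + 1/\sigma^2)}.$$

The scaling constants are included, so the value is a proper joint density
over $X$; a quadrature oracle in the test suite pins the algebra to 1e-8
relative error. The m-value is then Bayes' theorem summed over half the
configuration space:

$$m_i = \frac{\sum_{c:\,c_i=1} P(X|c)P(c)}{\sum_{c} P(X|c)P(c)}.$$

All posterior arithmetic is done in log space with log-sum-exp; GWAS
variances are small enough that raw densities overflow otherwise.

```{r}
panel <- MetaPanel(beta = c(0.32, 0.30, 0.01, 0.15),
                   se   = c(0.06, 0.07, 0.05, 0.20),
                   labels = c("bigA", "bigB", "bigNull", "small"))
mvalues(mvaluesExact(panel))
classifyStudies(mvaluesExact(panel))
```

## Exact enumeration, MCMC, thresholds

`mvaluesExact()` enumerates all $2^n$ configurations with vectorised closed
forms up to $n = 20$ (about a million configurations; beyond that the cost
and memory double per study, and enumeration is refused).
`mvaluesMCMC()` is the alternative: a Metropolis–Hastings random walk whose
proposals are, with equal probability, a single-bit flip or a uniform
random permutation of the current bit vector. Both proposals are symmetric,
so acceptance is the plain posterior ratio; the shuffle move exists to hop
between modes when observed effect directions conflict. Defaults (burn-in
1,000, samples 10,000) keep the 8-study experiments stable; the per-study
Monte-Carlo standard error is a binomial SE on an effective sample size
estimated from the chain's autocorrelation (with a continuity-corrected
proportion so it never collapses to zero), and the suite verifies 3-SE
agreement with exact enumeration.

Prediction thresholds default to $m \ge 0.9$ (predicted effect) and
$m \le 0.1$ (predicted no effect), the conventional values for this method;
the interesting studies usually stand out regardless of the exact cut.

# Association tests

* `feWeightedZ()` — fixed effects, $Z = \sum w_i z_i / \sqrt{\sum w_i^2}$,
  two-sided normal p-value. Weights default to $\sqrt{N_i}$ when sample
  sizes are known, else $1/\mathrm{se}_i$; `maf_adjusted` uses
  $\sqrt{2 f_i (1-f_i) N_i}$.
* `reHanEskin()` — random effects: the likelihood over
  $X_i \sim N(\mu, V_i + \tau^2)$ is maximised ($\tau^2 \ge 0$, via a
  profile over $\tau^2$: coarse grid then `optimize()`) and referred to the
  boundary mixture $\tfrac12\chi^2_1 + \tfrac12\chi^2_2$. We use the
  asymptotic mixture as-is, without the small-study tabulated null of the
  original method. With five studies this makes the test noticeably
  conservative (empirical size ~0.03 at the 0.05 level in our null
  simulations) — a known, documented deviation; rankings and the
  experiments below are unaffected, but exact RE size should not be read
  off this implementation at small $n$.
* `abfWakefield()` — the single-study asymptotic Bayes factor
  $\sqrt{V/(V+\sigma^2)}\exp\!\left(z^2\sigma^2/(2(V+\sigma^2))\right)$,
  oriented so values above 1 favour the presence of an effect.
* `beStatistic()` — the binary effects statistic
  $S = \sum m_i w_i z_i / \sqrt{\sum (m_i w_i)^2}$: a weighted-z test whose
  weights are multiplied by the m-values estimated from the same data, so
  studies predicted to lack the effect drop out. With all $m_i$ equal it
  reduces to the FE statistic.

## The BE p-value

Because the m-values are functions of the data, $S$ is not normal under the
null; `bePvalue()` estimates $P(|S_{null}| \ge |S_{obs}|)$ by sampling null
panels ($z_i \sim N(0,1)$, the observed standard errors and weights, m-values
recomputed per draw — exact enumeration for $n \le 14$ with the
configuration matrices precomputed once per panel and shared across draws,
reduced-sample MCMC beyond).

Plain Monte Carlo is hopeless at genome-wide tails, so draws come from an
importance-sampling mixture built by exponential tilting. A design point
worth recording: a single tilt along the weight vector (all studies shifted
together) covers only the homogeneous route into the tail, while the
m-value weighting means the null tail is also reached by draws where *few*
studies are very strong; with a single tilt the importance weights are
heavy-tailed and the empirical standard error under-covers badly. The
proposal therefore mixes, for each subset scale $k = 1..n$ and each sign, a
component that tilts every coordinate independently with probability $k/n$
by $\pm |S_{obs}|/\sqrt{k}$, plus 20% plain null draws. Each component
density is a product of two-point normal mixtures, so the exact mixture
density — and an unbiased importance weight, bounded by 5 — is cheap.
Stratified allocation with mixture-density weights keeps the estimator
unbiased for the plain Monte-Carlo tail probability; the reported standard
error is the stratified empirical SE. The suite checks unbiasedness against
a 4e5-draw plain Monte-Carlo oracle and the $1/\sqrt{N}$ decay of the
run-to-run spread. At 1,000 samples the spread-to-p ratio is roughly 0.12
on a genome-wide-borderline panel, and `beAdaptive()` implements the usual
screening economy: a small run for every locus, a large rerun only below a
promotion threshold (default first-stage p ≤ 0.01).

# The simulator and the experiments

`simulateStudy()` emulates a balanced case-control study under a
multiplicative per-allele risk model in the small-prevalence limit: control
MAF $f$, case MAF $f\,\mathrm{rr}/(f\,\mathrm{rr}+1-f)$, allele counts drawn
from the rounded normal approximation to the binomial, Woolf standard
errors with a Haldane–Anscombe 0.5 correction when a cell is empty. It
reproduces the study conditions of the published experiments: MAF 0.3,
equal cases and controls, genome-wide threshold $5\times 10^{-8}$
(configurable everywhere). It does *not* emulate linkage disequilibrium,
imputation error, covariates, unbalanced designs or allele-frequency
mismatch between studies — passing tests say nothing about those features
of real data, and allele-orientation harmonisation remains the caller's
job.

Four harnesses wrap it:

* `fprExperiment()` — null panels (5 studies of 1,000), empirical
  false-positive rates of FE/RE/BE with the rate-to-threshold ratio. The
  published calibration used 1e8 panels with 10,000 importance samples; we
  run 1e6 (FE/RE) and 1e5 panels with 1,000 samples (BE) as desk-scale
  defaults in the acceptance script — enough for three-binomial-SE
  comparisons at the thresholds we report.
* `mvalueHistogramExperiment()` — the four-study-type design: two studies
  each of large ($N = 2{,}000$) / small ($N = 200$) sample crossed with
  effect ($\mathrm{rr} = 1.3$) / no effect, kept only when no single study
  reaches genome-wide significance but the RE meta-analysis does
  (acceptance rate ~0.12 here). Large effect studies should concentrate
  above 0.9 and large null studies below 0.1.
* `rocExperiment()` — 10 studies, 1–9 of them (uniformly) carrying
  rr = 1.3, sizes uniform on 500–2,000 (rounded to even), same acceptance
  filter; pools the per-study m-value, Wakefield ABF and p-value over all
  accepted sets and compares them as predictors of effect presence and
  absence by ROC/AUC.
* `powerExperiment()` — five studies of 1,000; binary mode sweeps how many
  studies carry the effect (5 down to 2) with relative risks 1.3, 1.35,
  1.45, 1.6 — the published grid raises the risk as fewer studies carry it
  so the curves stay comparable, and with the exact published ladder not
  recoverable from our source these values were fixed once to keep every
  method's power in the informative mid-range; lognormal mode draws each
  study's log relative risk from
  $N(\log 1.3,\ (h \log 1.3)^2)$ sweeping $h$ from 0 to 1.

Replicate counts in the test suite (600–1,000 sets per condition) were
chosen as the smallest sizes at which the published orderings are stable
across seeds; all experiments are exactly reproducible from
`(scenario, seed)`.

# Numerical choices and degenerate inputs

* A standard error of zero is rejected, never treated as infinite
  precision.
* p-values are floored at 1e-300 (and clipped there before the
  $-\log_{10}$ transform in plots).
* The RE profile search brackets $\tau^2$ with a data-driven log grid
  before `optimize()`; the boundary $\tau^2 = 0$ is always compared.
  Batch experiments use a vectorised grid maximisation and re-solve any
  panel whose p-value lands within a factor of four of a decision
  threshold with the scalar path.
* BE with all m-values zero is an error (the statistic is undefined);
  an observed statistic of exactly zero yields p = 1.
* Per-SNP seeds in `runPipeline()` derive from (master seed, SNP id) by a
  31-bit string hash, so results are independent of row order.

# Limitations

The m-value is conditioned on the binary effects assumption; under smooth
effect-size heterogeneity it still ranks studies sensibly but its
calibration as a posterior probability degrades (the lognormal power
experiment quantifies the test-side cost). It also cannot distinguish true
biological heterogeneity from statistical heterogeneity caused by design
factors — that requires external information such as a replication study.
The RE implementation is conservative at small study counts, as noted
above. Enumeration cost doubles per study; beyond 20 studies only the MCMC
path is available.
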