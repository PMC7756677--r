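---
title: "Tolerance intervals for method comparison studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tolerance intervals for method comparison studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtol)
```

## The problem

A method comparison (or bridging) study measures the same subjects with two
measurement methods — two hematology analyzers, two assays, a new device
against a reference — and asks whether the methods are interchangeable: are
their individual differences small enough to be clinically irrelevant?

The standard analysis works on the per-subject differences
$D_i = X_i - Y_i$ and their summary statistics, the mean $\bar{D}$ and the
sample standard deviation $S$ (divisor $n-1$).  The classic tool is the
Bland–Altman *agreement interval*

$$\mathrm{AI}: \quad \bar{D} \pm z_{0.975}\,S,$$

intended to contain 95% of the differences.  It is approximate and too
narrow: it treats $\bar{D}$ and $S$ as if they were the population values,
so its effective content collapses at small $n$ (about 85% at $n = 5$,
see below).  Wrapping a confidence interval around each AI bound
($\bar{D} \pm z S \pm t_{n-1} S \sqrt{1/n + z^2/(2(n-1))}$, six numbers in
total) does not repair the interpretation.  `mdtol` computes those
intervals for completeness, and the two intervals that actually answer the
question:

* the **prediction interval / beta-expectation tolerance interval**
  ($\beta$TI),
  $$\bar{D} \pm t_{(1+\beta)/2,\,n-1}\, S \sqrt{1 + 1/n},$$
  which contains a future difference with confidence $\beta$, and on
  average over repeated studies contains exactly a proportion $\beta$ of
  the population of differences, at every sample size;

* the **beta–gamma content tolerance interval** ($\beta\gamma$TI),
  $\bar{D} \pm k S$, which contains *at least* a proportion $\beta$ of the
  differences with confidence $\gamma$ — an assurance-of-safety margin on
  top of the content claim.

Equivalence of the two methods is then judged against a pre-specified
*acceptance interval* of tolerable differences: the methods are declared
equivalent only when the tolerance interval lies entirely inside it.

## The tolerance factor

The exact two-sided factor $k$ solves

$$\sqrt{\frac{2n}{\pi}} \int_0^\infty
  \Pr\!\left(\chi^2_{n-1} > \frac{(n-1)\,\chi^2_{1,\beta}(z^2)}{k^2}\right)
  e^{-n z^2 / 2}\, dz \;=\; \gamma,$$

where $\chi^2_{1,\beta}(z^2)$ is the $\beta$-quantile of the noncentral
chi-square distribution with 1 degree of freedom and noncentrality $z^2$.
The integral is the probability, over the joint sampling distribution of
$(\bar{D}, S)$, that $\bar{D} \pm kS$ captures at least $\beta$ of the
population; the half-normal weight is the density of the standardized
sample mean.

`bg_factor_exact()` solves this equation; `bg_factor_approx()` implements
the explicit first-order approximation

$$k \approx z_{(1+\beta)/2}\,\sqrt{1 + 1/n}\,
  \sqrt{\frac{n-1}{\chi^2_{1-\gamma,\,n-1}}},$$

the Student quantile of the prediction interval replaced by a normal
quantile and $S$ inflated to the upper bound of its chi-square confidence
interval.  Across $n \in [10, 10^4]$ and $\gamma \in \{0.8, 0.9, 0.95\}$
at $\beta = 0.95$ the two factors agree within 0.4% relative, which is why
the approximation is the default in the analysis pipeline (the exact
factor is always computed alongside it).

### Numerical choices

The equation has no closed form, so the implementation makes the
following choices:

* **Quadrature.** Adaptive quadrature (`stats::integrate`, relative
  tolerance $10^{-10}$) on $[0, z_{\max}]$ with
  $z_{\max} = 10/\sqrt{n} + 8$; beyond that point the half-normal weight
  leaves tail mass below $10^{-12}$, so truncation is harmless and avoids
  feeding the noncentral quantile enormous noncentralities.
* **Root finding.** Brent bracketing (`stats::uniroot`) seeded at the
  approximate factor times $[0.8, 1.3]$; the bracket is widened
  geometrically (up to 12 times) if the residual does not change sign,
  and a failure to bracket raises an error carrying the residuals.  The
  achieved confidence at the returned root reproduces $\gamma$ to
  better than $10^{-5}$ (the test suite checks $10^{-5}$; in practice
  residuals are near machine precision).
* **Quantile conventions.** All probabilities are cumulative from the
  left; two-sided bounds use $(1+\beta)/2$.  $S$ always uses divisor
  $n-1$, which is what makes the $t$-based interval exact.
* **Degenerate input.** $S = 0$ yields the degenerate interval
  $\{\bar{D}\}$ with a warning rather than an error: tied assay readings
  occur in practice and should not crash a pipeline.

## Orderings, and where they stop holding

At equal $\beta$ and the confidence levels used in practice
($\gamma \ge 0.8$) the three intervals nest:
$\mathrm{AI} \subset \beta\mathrm{TI} \subset \beta\gamma\mathrm{TI}$,
and the $\beta\gamma$TI widens with $\gamma$.  Two boundary facts are
worth recording because they shape the tests:

* Near $\gamma = 0.5$ the content TI is *similar but not equal* to the
  beta-expectation TI — at $n = 20$, $\beta = 0.95$ the exact factor at
  50% confidence is 2.041 against the prediction factor 2.145 — so the
  nesting of $\beta$TI inside $\beta\gamma$TI does **not** hold for all
  $\gamma > 0.5$.  The package asserts nesting at
  $\gamma \in \{0.8, 0.9, 0.95\}$ and $n \ge 5$.
* The AI width converges to the $\beta$TI width like $1/n$ (relative gap
  0.17% at $n = 10^3$), while the $\beta\gamma$TI converges like
  $|z_{1-\gamma}|\sqrt{2/n}/2$, an order of magnitude slower (0.59% at
  $n = 10^4$).  "Converged for practical purposes" at those sample sizes
  means a few tenths of a percent, not zero.

## The analysis pipeline

`md_analyze()` mirrors the classical mean-difference workflow:

1. Replicates are averaged per subject per method, then per-subject means
   $M_i$ and differences $D_i$ are formed.  With repeated measures the
   tolerance interval therefore describes differences of per-subject
   means; replicate-level measurement error is deliberately not
   propagated into the interval, and reports say so.  (Averaging first is
   the simplest defensible treatment of unstacked replicate columns; a
   variance-component decomposition is a different estimand.)
2. An optional `log10` or natural-log transform is applied *before*
   differencing, for positively skewed, ratio-like measurements; the
   Shapiro–Wilk p-value is reported on the analysis scale as an advisory
   check (it never blocks the computation).
3. All intervals are computed from the difference summary.  The
   content-TI confidence level has no default: $\gamma$ must be chosen a
   priori from the study objectives, so when it is omitted only the
   $\beta$TI is computed.
4. The equivalence decision compares the requested tolerance intervals —
   the $\beta$TI and, when $\gamma$ is given, the $\beta\gamma$TI, both
   required — against the acceptance band.  The agreement interval never
   enters the decision.

Acceptance bands come in four forms: constant $\pm\Delta$; two-threshold
($\Delta_1$ strictly below a cutoff on $M$, $\Delta_2$ at or above it —
the tie goes to the high side by definition here); percentage
$\pm(\Delta/100)\,M$, where the check is pointwise over the observed $M$
range (equivalently, against the intersection of the bands at the
observed means); and ratio form for log-scale analyses.  An absolute
band cannot be meaningfully placed on a log scale, so for log analyses
the band is specified as a tolerated relative difference $f$ and applied
after back-transformation as $(1-f,\ 1/(1-f))$ — for $f = 0.2$,
$(0.8, 1.25)$, symmetric on the ratio scale.

`antilog_intervals()` maps every bound $b$ to $\mathrm{base}^b$: the
x-axis becomes geometric means, differences become ratios, and the
centre the geometric-mean ratio.  Subjects with any missing replicate
are dropped with a reported count, since the paired design needs
complete pairs.

## The Monte-Carlo engine

`run_coverage_study()` measures what the intervals actually deliver,
under the design the formulas assume: an unreplicated study under
equivalence, both devices adding independent Gaussian errors with unit
SD (defaults), so the true differences are
$N(0, \sqrt{2})$.  For each simulated study the *effective content* of
each interval is computed analytically,
$\Phi((u-\mu)/\sigma) - \Phi((l-\mu)/\sigma)$ — no inner simulation —
and two summaries are aggregated: the mean effective content, and for
content TIs the *effective confidence*, the fraction of studies whose
content reaches $\beta$, with binomial Monte-Carlo standard errors.

Default `reps` is $10^4$ (a desk run); the acceptance script uses
$10^5$, at which the nominal levels are resolved to about 0.1%.  The
estimand does not depend on `reps`, only the Monte-Carlo error does, and
the standard errors are always reported.  Reproducibility: the master
seed draws one substream seed per sample size, so a grid entry's results
are identical whether it is simulated alone or as part of a larger grid.

What the simulation emulates — and what it does not: Gaussian,
homoscedastic, bias-free errors with one measurement per subject.  Real
assay data can be heteroscedastic (spread growing with the measurand),
proportional-error (hence the log-scale pipeline), or trending in the
(M, D) plot, in which case horizontal tolerance lines are the wrong
model and a regression-based analysis is needed; `mdtol` flags none of
this automatically beyond the normality p-value.  Passing coverage tests
here demonstrates correctness of the interval mathematics under the
stated model, not robustness to violations of it.

The synthetic paired-sample generator (`generate_paired_fixture()`)
follows the same error model with a subject-level spread (default: true
values $N(5, 1)$, chosen as a generic mid-scale measurand so that
differences are small relative to the measurements), and
`calibrate_to_summary()` affinely rescales a sample's differences to hit
a published $(\bar{D}, S)$ exactly — the route by which analyses reported
only through summary statistics are reproduced here.

## Bootstrap alternative

`bootstrap_t_pi()` is the nonparametric check on the $t$-based interval.
The $t$ interval's pivot is $(D_{\text{new}} - \bar{D})/(S\sqrt{1+1/n})$;
the bootstrap version draws a resample (giving $\bar{D}^*, S^*$) plus one
further observation $d^*$ from the data and forms
$r = (d^* - \bar{D}^*)/(S^*\sqrt{1+1/n})$, then substitutes the empirical
$(1\pm\beta)/2$ quantiles of $r$ for $\pm t$.  Resamples with zero spread
are skipped and counted.  For Gaussian data at moderate $n$ it tracks the
$t$ interval closely; its coverage runs slightly below nominal at small
$n$, which is the known price of the resampling approximation.

## Problem sizes used in the test suite

The packaged checks run the coverage engine at $10^5$ replicates for the
headline configurations ($n = 20$ and $n = 50$) and $2\times10^4$ or less
elsewhere; the exact-factor/approximation comparison spans
$n \in \{10, \dots, 10^4\}$.  These sizes resolve every asserted quantity
well inside its tolerance (three Monte-Carlo standard errors for
simulated levels) while keeping a full run on one core under a minute
for the unit suite.

## Known limitations

* Gaussian differences are assumed throughout; only the advisory
  Shapiro–Wilk check guards the assumption.
* One-sided content tolerance bounds (noncentral-$t$ based) are not
  implemented, nor are Bayesian tolerance intervals or multivariate
  tolerance regions; the Šidák adjustment (`sidak_adjust()`) is the
  supported route to simultaneous univariate intervals.
* No regression-based (errors-in-variables) analysis for trending (M, D)
  plots.
* Replicate-level variance decomposition is out of scope (see above).
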