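---
title: "Methods: effort-discounting model fitting and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effort-discounting model fitting and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effdisc)
```

## The measurement model

A titration (adjusting-amount) questionnaire presents, per experimental
condition, a fixed effortful payoff of amount $A$ against 30 effortless
alternatives descending from 100% to 0% of $A$. The participant chooses row
by row until preference switches to the effortful option; the last
effortless amount chosen is the indifference point (IP), the behavioral
estimate of the effortful payoff's subjective value $SV$. The canonical
design crosses 2 effort domains (physical, cognitive) with 3 amounts
(PLN 80, 400, 3000) and 5 effort intensities (30–150 task units), i.e. 30
conditions, each payoff additionally carrying a fixed 30-minute delay so
that effort level, not delivery time, varies across conditions. Zero-effort
pages measure a delay-only "first indifference point" that is excluded from
analysis: the delay is constant by design, and at zero effort most
respondents show no discounting at all.

Two conventions close the extraction rule at its limits: choosing the
effortful option already in the top row (where both options equal $A$)
records $IP = A$ — no measurable discounting — and never switching records
$IP = 0$ — full discounting. Sequences with more than one preference switch
cannot arise under the questionnaire's stop-at-switch procedure and are
treated as data errors: excluded and reported, never imputed.

Only the PLN 80 ladder is fixed by the instrument
(80, 79, 77, 74, …, 2, 1, 0). Ladders for other amounts reuse that
percentage profile, rescaled and rounded half-up to integer PLN; this keeps
30 rows and the 100%-to-0% span. Whether the original instrument rounded or
hand-picked those lists is unknowable from the instrument description; the
scaled profile is the only reconstruction that preserves the printed design
exactly at PLN 80.

## The candidate models

Seven subjective-value functions are compared, each with a non-negative
rate parameter $l$ per reward magnitude and, for four of them, a second
parameter $s$:
hyperbolic $A/(1+lE)$, exponential $Ae^{-lE}$, parabolic $A-lE^2$,
Myerson–Green hyperboloid $A/(1+lE)^s$, Rachlin hyperboloid $A/(1+lE^s)$,
two-parameter exponential $(A-s)e^{-lE}+s$ (asymptote $s<A$, in PLN), and
the two-parameter power function $A-lE^s$. The concave models (parabolic,
power) may predict negative values at high effort; these are deliberately
not clamped, because the ability of an effort-discounting curve to reach
and cross zero — a reward not worth any effort beyond one's capability — is
a substantive property that distinguishes the concave family from the
asymptotic one. At $E=0$ every model returns $A$. Useful reductions:
Myerson–Green with $s=1$ is the hyperbolic, the power function with $s=2$
is the parabolic, and the two-parameter exponential with $s=0$ is the plain
exponential; these identities anchor the test suite.

## Joint estimation across magnitudes

Each model is fitted simultaneously to all reward magnitudes of one
analysis unit (a participant, or the table of group-median IPs) within one
effort domain: a single pooled sum of squared errors over all
$3 \times 5 = 15$ points, with magnitude-specific parameter variants — the
dummy-variable scheme, in which indicator variables switch on the variant
belonging to each point's magnitude. Because every parameter touches only
its own magnitude's residuals, the pooled objective is exactly
block-separable, and the estimator exploits that structure directly:
each magnitude's slice is minimised by bounded multi-start nonlinear least
squares and the coordinates are composed into the joint solution. An
independent per-magnitude fitting route (`fit_magnitude()`) exists purely
as a cross-check; the test suite verifies on random data that the pooled
SSe equals the sum of the three independent fits for every model.

Numerical choices, all deterministic:

* **Start grid.** $l$ starts on the log-spaced grid
  $\{10^{-6},\dots,10^{0}\}$; exponent-type $s$ on $\{0.25,0.5,1,2,4\}$.
  Starts are ranked by their raw SSE and polished with `nlminb` (PORT),
  with restarts from the incumbent until the objective stops improving.
* **Bounds.** $l \ge 0$; $s \in (0, 10]$ for the exponent models (the upper
  bound mirrors the largest estimates such instruments produce and is a
  package constant); $s < A$ for the two-parameter exponential asymptote.
* **Variable projection.** The power function is linear in $l$ given $s$,
  and the two-parameter exponential is linear in $s$ given $l$; the linear
  parameter is profiled out in closed form, leaving a one-dimensional
  search. This removes the flattest direction of those models' $l$–$s$
  ridges from the iteration and makes their fits fast and reproducible.
* **Convergence.** PORT's "relative/absolute/X-convergence" and also its
  "singular" and "false convergence" terminations are accepted as
  stationary points — the latter two are routine on hyperboloid ridges —
  while iteration/evaluation-limit terminations mark the fit
  non-converged (reported with $R^2 = 0$).

The coefficient of determination uses the pooled total sum of squares
around the grand mean of all 15 points, matching the single-goodness-of-fit
logic of the joint fit. When the grand mean outperforms the model
($R^2 < 0$, or zero variance), the fit is *clamped*: $R^2$ is reported as 0
and the parameter estimates as missing. Clamp counts per model are
themselves an outcome, compared across models with Cochran's Q and McNemar
tests.

## Model selection

Because $R^2$ ignores complexity, models of different parameter counts are
compared with SSE-based criteria: $AIC = n\ln(SSe/n) + 2p$, the
small-sample corrected $AICc = AIC + 2p(p+1)/(n-p-1)$, and
$BIC = n\ln(SSe/n) + p\ln(n)$, where $p$ counts the free regression
parameters of the joint fit (3 for one-parameter, 6 for two-parameter
models; no error-variance term — a constant offset would shift all models
equally within a complexity class and cancel in deltas). Comparisons are
reported as deltas from the best (lowest) model. Group-level inference uses
both the median-IP fit and, as a fixed-effects aggregate, criterion values
summed across participants. A perfect fit ($SSe = 0$, possible on noiseless
synthetic data) is reported as a $-\infty$ sentinel with a warning and
wins its comparison; subjects with any clamped, non-converged or perfect
fit are excluded listwise from summed comparisons (and logged), since their
criterion values are undefined or degenerate. Best-model frequency tables
credit every model tied at the minimum; tie counts are reported so the
no-credit convention is recomputable.

## The nonparametric suite

Model fits and parameters are compared with the distribution-free tests
standard for skewed discounting measures: Friedman's test (mid-ranks,
tie-corrected $\chi^2$, mean ranks reported) as the omnibus, pairwise
Wilcoxon signed-rank tests with the classical conventions — zero
differences dropped, tied absolute differences mid-ranked, tie-corrected
normal approximation without continuity correction — and Šidák-adjusted
p values $1-(1-p)^m$. The effect size is $r = |Z|/\sqrt{2N}$ with $N$ the
number of pairs including zeros: with 114 paired observations this is the
only convention under which $Z = 4.56$ yields $r = .30$, which pins the
denominator. Failure-to-fit indicators are compared with Cochran's Q and
continuity-corrected McNemar tests $(|b-c|-1)^2/(b+c)$ from the discordant
counts; parameter coherence across magnitudes and effort domains uses
Spearman's $\rho$.

## The synthetic cohort

The generator produces agents whose titration behavior has the statistical
structure the analysis assumes, so that every pipeline stage is testable
end to end.

* **True model.** Power function by default, 114 agents, with
  magnitude-specific true parameters per effort domain.
* **Medians.** Exponents $s$ = (1.35, 1.8, 3.0) for PLN (80, 400, 3000) —
  the magnitudes group-median titration fits report, rising with amount —
  and rates $l$ = (0.0848, 0.0412, 6.93·10⁻⁴), equivalent to discounting
  92%, 85% and 78% of the reward at maximum effort: deep but rarely
  complete discounting, proportionally weaker for larger amounts (the
  magnitude effect).
* **Heterogeneity.** $s$ varies log-normally (log-sd 0.12) via an
  agent-level multiplier shared across magnitudes; $l$ is drawn
  *conditionally on* $s$ so that the discount depth at maximum effort —
  not $l$ itself — is log-normal (log-sd 0.08). Depth is exponentially
  sensitive to $s$ ($l E_{\max}^{s}/A$), so independent draws would
  scatter agents between no discounting and total discounting and censor
  the ladders at their floors and ceilings; the conditional draw keeps
  every agent's curve spanning the ladder and reproduces the strong
  negative $l$–$s$ rank correlation within magnitudes that titration
  studies report. Latents are truncated at ±2 sd, which also guarantees
  each agent's $l$ decreases and $s$ increases strictly with amount.
* **Cross-domain coherence.** Physical and cognitive latents share a
  standard-normal factor with weight $\sqrt{\rho}$ ($\rho = 0.5$ by
  default), yielding positive rank correlations of parameters between
  domains.
* **Choice noise.** One Gaussian valuation draw per condition
  (sd $= 0.03A$ by default), truncated to $[0, A]$; the agent takes the
  effortless option while its amount exceeds the valuation, once more at
  the first row at or below it, then switches. A single draw per page
  guarantees the single-switch pattern the questionnaire's stop rule
  enforces behaviorally; per-row noise would generate impossible records.
  The extracted IP is therefore the largest ladder value not exceeding the
  valuation — floor quantization, the property the extraction tests check
  by brute-force ladder scan. Negative valuations cannot be recorded by
  the instrument and are truncated, not modeled.

What the generator does *not* emulate: real response processes (lapses,
inattention, anchoring on round numbers), session order effects (page order
is recorded but behaviorally inert), model uncertainty across participants
(every agent discounts by the same functional form), and any effort-delay
interaction. Passing tests therefore show that the pipeline recovers the
structure it assumes — identifiable generating model, magnitude effects,
cross-domain coherence — not that real populations obey a power law.

## Validation experiments

Three end-to-end properties are exercised at study scale (problem sizes
chosen to match the instrument: 114 agents for selection experiments, 50
for recovery):

1. **Decomposition oracle.** Joint SSe equals the sum of independent
   per-magnitude SSe for all seven models on random data (tolerance
   $10^{-8}$ relative).
2. **Noiseless recovery.** With choice noise off, the only estimation error
   is ladder quantization. Per agent and magnitude, a brute-force bound is
   computed by refitting under many random quantization-error patterns
   (each point shifted down by an amount uniform on one local ladder step)
   and taking the worst parameter deviation; the median recovery error
   stays below the median bound. The error itself is substantial for $l$
   (tens of percent) — five quantized points per magnitude genuinely
   underdetermine a two-parameter curve along its $l$–$s$ ridge — and the
   bound shows that this is a property of the instrument, not the
   estimator.
3. **Generative model selection.** On a default 114-agent cohort the power
   function attains summed $\Delta AICc = 0$ and $\Delta BIC = 0$ in both
   effort domains and the largest BIC best-model frequency, and the fitted
   $l$ (falling) and $s$ (rising) mean ranks across amounts are confirmed
   by Friedman tests at $\alpha = .01$.

## Known limitations

* The optimizer is multi-start local search; on pathological inputs
  (e.g. anti-discounting random data) it finds a reproducible near-optimum,
  not a certified global one. The decomposition oracle guards the
  structure, not global optimality.
* The $s \le 10$ bound is a pragmatic identifiability guard; curves with
  effectively larger exponents fit at the bound.
* Individual-level $l$ estimates from 5-level titration data carry large
  quantization-driven uncertainty (see recovery experiment); group-level
  and rank-based analyses are the reliable summaries.
* The IP convention records the last effortless value *accepted*, which
  floor-quantizes the underlying valuation by up to one ladder step; an
  agent with vanishing discounting is recorded one step below $A$ unless
  it values the payoff at exactly $A$.
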