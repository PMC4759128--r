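---
title: "Scoring drug-combination matrices with the zero interaction potency delta"
author: "zipscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-combination matrices with the zero interaction potency delta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(zipscore)
```

## The problem

High-throughput combination screens test two drugs over a full factorial
grid of concentrations (typically 6 x 6, serially diluted, with a zero-dose
row and column carrying the monotherapies) and measure a phenotypic
response per well, usually percent inhibition of cell growth. Calling a
combination synergistic requires a *reference model* stating what the
combination response would be if the drugs did not interact. The classical
references disagree with each other and misbehave on noisy large-scale
data:

* **HSA** expects the stronger single-agent effect, `max(y1, y2)` — so
  lenient that even a drug combined with itself scores as synergistic.
* **Bliss independence** treats the drugs as independent probabilistic
  events, `y1 + y2 - y1*y2`.
* **Loewe additivity** expects the effect of a drug combined with itself,
  defined implicitly by `x1/D1(y) + x2/D2(y) = 1`, where `D_i(y)` is the
  single-agent dose producing `y`. It is undefined whenever the
  combination outperforms the weaker drug's maximal effect — common in
  discovery screens where many single agents are barely active — and its
  curve-fitting requirements break on irregular response rows.

## The zero interaction potency model

`zipscore` centers on a reference that combines the dose-response
perspective of Loewe with the probabilistic one of Bliss. Monotherapies
are modeled with the log-logistic (4PL) curve

$$y(x) = \frac{E_{min} + E_{max}\,(x/m)^\lambda}{1 + (x/m)^\lambda},$$

with midpoint dose $m$ (relative IC50), slope $\lambda$, and
$0 \le E_{min} < E_{max} \le 1$ on the inhibition-fraction scale. The
zero-interaction assumption is *zero potency shift*: a non-interacting
partner at dose $x_2$ only lifts the baseline of the other drug's curve
to $y_2$, leaving $m$ and $\lambda$ untouched:

$$y_{1 \leftarrow 2}(x) = \frac{y_2 + (x/m_1)^{\lambda_1}}{1 + (x/m_1)^{\lambda_1}}.$$

For curves running from 0 to 1 this construction factorizes exactly into
the multiplicative-survival form $y_1 + y_2 - y_1 y_2$ — probabilistic
independence — and is invariant under the order in which the drugs are
added. (The additive rendering $y_2 + t/(1+t)$ sometimes seen for such
baseline-shift curves exceeds 1 at saturation and breaks the
factorization; the bounded form above is the one consistent with both
properties, and is what this package implements throughout.)

Interaction is then measured as a *potency shift*. For each fixed partner
dose, the combination responses along the matrix row or column are
refitted with the same functional form, the baseline pinned to the fitted
partner effect and the maximum at 1, yielding conditional parameters
$(m_{1\leftarrow2}, \lambda_{1\leftarrow2})$ and
$(m_{2\leftarrow1}, \lambda_{2\leftarrow1})$. The **delta score** of a
dose pair is the average deviation of the two fitted conditional
responses from the zero-interaction expectation:

$$\delta(x_1, x_2) = \tfrac12\left[\hat y_c^{1\leftarrow2} +
  \hat y_c^{2\leftarrow1}\right] - y_{ZIP}(x_1, x_2).$$

$\delta$ is in units of fractional inhibition ($\delta = 0.2$ means 20
percentage points of inhibition beyond expectation), symmetric around 0,
and directly comparable across dose pairs and combinations. The grid of
$\delta$ over the combination region is the **interaction landscape**;
its mean $\Delta$ summarizes the block. A cutoff of $\Delta \ge 0.05$ —
the typical noise level of a large screen — is the default synergy call
in the command-line interface.

```{r pipeline}
tr <- syntheticTruth("potency-shift", potencyShift = 0.5, noiseSd = 0.03,
                     seed = 11)
mat <- generateSyntheticMatrix(tr)
land <- deltaScore(mat)
land
plotLandscape(land)
```

## Curve fitting choices

All fits are bounded least squares on the 4PL curve, optimized on
`log10(m)` and `log10(lambda)`; the zero-dose well enters through the
analytic baseline value rather than a log transform.

* **Default monotherapy constraints.** `eMin` is fixed at 0 and `eMax`
  fitted freely in (0, 1]: weakly effective drugs stay representable
  (the scenario where Loewe breaks), while the baseline of a normalized
  screen is 0 by construction. A full four-parameter fit is available by
  passing `eMinFixed = NULL`.
* **Bounds.** `m` within [min positive dose / 100, max dose x 100] and
  `lambda` within [0.05, 10]. These stop the solver escaping to absurd
  curves on flat or noisy rows yet cover all realistic slopes.
* **Initialization.** Deterministic: `m` from linear interpolation of the
  dose reaching half the observed response range, `lambda = 1`. No random
  restarts, so identical inputs always give identical fits.
* **Convergence.** Judged by fit adequacy rather than the optimizer's
  exit code: a fit is accepted when it explains the data at least as well
  as a constant or leaves residuals within typical assay noise
  (rms of 0.1 inhibition). Inverted or erratic series fail both tests and
  fall back to piecewise-linear interpolation of the observations clamped
  to [0, 1], flagged `converged = FALSE`. Fallbacks still produce delta
  values (flagged, never dropped), so one bad row cannot abort a batch.
* **Out-of-range responses** (negative inhibition, inhibition above 1)
  are fitted as observed; only fitted curves are bounded.

The Loewe solver brackets the additivity equation on the open effect band
between the curves' baselines and maxima and bisects to 1e-10 (200
iterations maximum); an empty band or a root outside it yields an
explicit `unreachable` status rather than a number, which propagates to
`NA` Combination Index and alpha values with status flags in the score
panel.

## The comparison score panel

For compatibility with published screen analyses, `scorePanel()` computes
alongside $\Delta$: NumExcess (wells beating both monotherapies),
ExcessHSA and LS3x3 (total and best-3x3-block excess over the HSA
expectation on the percent-*viability* scale, so synergy is negative),
MedianExcess (median per-well excess on the percent-*inhibition* scale,
synergy positive — the two conventions deliberately coexist because the
screens that defined these scores reported them with opposite signs),
and the closed-form least-squares multipliers beta (against Bliss
viability) and gamma (against the stronger single-agent viability), both
left-bounded at 0 with 1 as the non-interaction point. Beta and gamma use
observed monotherapy wells, not fitted curves, per their original
definitions. ExcessCRX (a dilution-factor-adjusted HSA variant) is
reserved but not computed: its published description is not reproducible.
Medians of the per-well Combination Index and interaction-index alpha are
reported as a convention, flagged `undefined` when no well admits them.

## Statistical significance

`bootstrapDelta()` implements a parametric bootstrap: the curve
parameters touching a well are estimated together with standard errors
(validated against `nls`), `nBoot` parameter sets are drawn from
independent normals at those means and standard deviations, and the
closed-form delta is re-evaluated per draw. `pSynergy` is the proportion
of draws above zero; because that is a support proportion rather than a
classical p-value, a two-sided `2*min(pSynergy, pAntagonism)` is also
reported. For the confidence interval
$\hat\delta \pm z_{1-\alpha/2}\sqrt{\mathrm{var}(\delta)/n}$ the package
defaults to $n = 1$ — the bootstrap spread already estimates the sampling
standard deviation of $\hat\delta$, and dividing by $\sqrt{n_{boot}}$
would shrink the interval toward zero width as draws are added. The
literal $n = $ number-of-samples convention remains available in
`deltaConfidenceInterval()`.

**Known limitation.** Propagating per-fit parameter uncertainty through
independent draws understates the sampling variability of $\hat\delta$
at screen-sized designs: with six points per curve the four contributing
fits share wells and baselines, so their errors are strongly correlated,
and measured interval coverage on noisy null matrices falls well short of
nominal (roughly 30-60% instead of 95% at noise sd 0.05, whether or not
per-fit covariance is used). Treat the intervals as optimistic
lower bounds on uncertainty; the matrix-resampling route below is the
more faithful error model when an anchor drug's replicates exist.

For one-vs-many screens without replicates, `monotherapyVariance()`
estimates per-concentration noise from the anchor drug's monotherapy
wells across blocks, and `resampleMatrixDelta()` redraws every well from
`N(y_ij, sigma_i^2)` and recomputes $\Delta$ per draw (1000 draws by
default).

## The synthetic generator

`generateSyntheticMatrix()` emulates the standard screen design: five
half-log dilutions centered on each drug's midpoint dose plus the zero
dose (6 x 6 wells), monotherapy margins from the generating curves, and
i.i.d. Gaussian noise on every well (default sd 0.05 inhibition, the
noise level typical of large combination screens). Three combination
surfaces are available: `bliss-null` (the zero-interaction surface; true
delta 0), `loewe-sham` (a drug combined with itself, responding as the
single agent at $x_1 + x_2$), and `potency-shift` (conditional midpoints
multiplied by `potencyShift`, default 0.5 — a two-fold sensitization —
with the true delta surface available in closed form via
`trueDeltaSurface()`).

What the generator does *not* emulate: plate-position and edge effects,
dose-dependent (heteroscedastic) noise, correlated well errors,
normalization artifacts from positive/negative controls, and compounds
whose response is non-monotone. Passing the simulation-based tests
therefore demonstrates correctness of the scoring machinery under the
stated noise model, not robustness to every pathology of real plates —
the fallback fitting path is the designed safety net for those.

Two numerical facts about the pipeline are worth stating plainly. First,
on noiseless zero-interaction matrices the fitted delta vanishes to
better than 1e-4 everywhere. Second, on shifted (interacting) matrices
the fitted delta tracks the generating closed form only approximately:
the conditional family with baselines pinned to the *unshifted*
monotherapy fits is not closed under potency shifts (one can show the
only surface exactly fittable in both directions is the null surface),
so the pipeline's least-squares projection deviates from the closed-form
delta by up to ~0.01 inhibition at a two-fold shift. The summary
$\Delta$ is much less affected (error ~0.003), and with realistic noise
the end-to-end mean absolute error of $\Delta$ against truth stays below
0.03. A sham (self-combination) surface likewise does not yield exactly
zero delta under this construction; the zero-interaction anchor of the
implementation is the multiplicative-survival surface.

## Problem sizes used in the test suite

Property suites run on 6 x 6 matrices: 1e4 random parameter draws for the
algebraic identities, 100 random matrices for the brute-force score
oracles, 50 noisy screens for end-to-end recovery, and 500 replicates
with 200 bootstrap draws each for interval-coverage measurement. These
sizes make the full suite complete in well under a minute per file while
keeping Monte-Carlo error comfortably inside the asserted tolerances.

## Using files and the command line

`readCombinationTable()` and `writeCombinationTable()` exchange blocks in
a long per-well CSV or a matrix-with-headers dialect; the response scale
(percent viability or percent inhibition) must always be declared, never
guessed, and viability is converted via `inhibition = (100 - v)/100`
without clamping. `exportLandscape()` writes the delta grid CSV (percent
scale, the canonical artifact) plus 2-D and 3-D PNG views. The thin
command-line interface at `inst/cli/zipscore.R` wraps scoring
(`score`), landscape export (`landscape`), simulation (`simulate`) and
significance (`significance`) for batch use; per-block failures are
logged and do not abort a batch.
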