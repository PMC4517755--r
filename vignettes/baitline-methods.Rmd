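---
title: "Models and methods behind baitline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind baitline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitline)
```

baitline analyses aerial-prefeed / ground-toxic baiting operations against
brushtail possums and rats: population monitoring indices and reduction
estimates, an ANOVA layer for comparing treatments, GPS track-compliance
and timing summaries, and per-hectare cost models. This vignette documents
the underlying models, the parameters that matter, the numerical choices,
and the limits of what the synthetic-data experiments demonstrate.

## Monitoring model

### CCI, tCCI and the reduction estimator

A chewcard line of $n$ cards exposed for $m$ nights yields the chewcard
interference index $\mathrm{CCI} = 100\,\hat p$, where $\hat p$ is the
proportion of cards bitten by the species over the session. Interference
saturates: once most cards are bitten, further density increases barely
move the index. The arcsine-square-root transform

$$\mathrm{tCCI} = \frac{180}{\pi}\arcsin\!\sqrt{\mathrm{CCI}/100}
\quad\in[0^\circ, 90^\circ]$$

stretches the upper end of the scale and is treated as an approximately
linear index of density below saturation. The population reduction of a
block is estimated from paired pre/post sessions on the same lines:

$$r_\ell = 100\,(1 - \mathrm{tCCI}^{\text{post}}_\ell /
\mathrm{tCCI}^{\text{pre}}_\ell),
\qquad
\hat R = \frac{\sum_\ell w_\ell\, r_\ell}{\sum_\ell w_\ell},$$

with weights $w_\ell$ equal to the pre-session card count of each line
(lines differ in length, so longer lines carry more information). $r_\ell$
is a ratio of tCCIs and therefore invariant to the angular unit; degrees
are used for display only. A line whose pre-control tCCI is zero carries
no information about change and is excluded from the weighted mean and
listed in the result's `excluded` field — a case the design makes rare,
since monitoring is only worthwhile where pre-control activity exists.

Two error summaries are reported. The primary SE is the weighted SE of
the per-line reductions, using the effective-sample-size form
$\mathrm{SE}^2 = \sum w(x-\bar x)^2 / (\sum w\,(n'-1))$ with
$n' = (\sum w)^2/\sum w^2$; with equal weights this is the ordinary SE of
the mean over lines. For display, asymmetric offsets are derived by
computing the card-weighted mean tCCI of each session $\pm 1$ SE,
back-transforming those angle-scale bounds to the proportion scale
($p = \sin^2 t$), and recomputing the level-based reduction from the
favourable and unfavourable pairings. Back-transforming from the angle
scale is what makes the bounds asymmetric about the mean. The SE is taken
over lines rather than cards: lines are the independent sampling units,
cards within a line share the same animals.

### RTCI

The residual trap catch index is the number of possum captures per 100
available trap nights. A trap inactivated by a non-target capture or by
being sprung without a catch was available for roughly half the night on
average, so each such record deducts half a trap night from the
denominator:

$$\mathrm{RTCI} = \frac{100\,C}{N - 0.5\,S}.$$

The index equals the raw capture rate when no penalised events occur and
can only increase as penalised events accumulate with captures held fixed.

### Bait QA

Assayed toxin loadings are compared with the label specification as
`round(100 * (assay - spec) / spec)` — a signed whole-percent deviation,
matching how such assays are reported. Note one published oddity this
formula surfaces: a cholecalciferol assay of 0.88% against a 0.80%
specification is a +10% deviation by this arithmetic, though it has been
reported as 13% above; the function computes, it does not reconcile.

## Inference layer

The ANOVA layer is implemented from first principles so that every sum of
squares is auditable. One-way fits use the classical between/within
decomposition. Two-way fits (e.g. trial x bait treatment on per-line
timing) use **Type-II sums of squares** obtained by model comparison:
each main effect is tested by the increase in residual SS when it is
dropped from the additive model, and the interaction against the full
model. Type II is the conventional default for a factorial design with no
ordering of factors; with balanced data it coincides with the classical
sequential decomposition (verified in the tests). The residual degrees of
freedom equal $N$ minus the number of non-empty cells when the
interaction is included — 75 for 79 lines in a 2 x 2 layout.

Fisher's LSD comparisons are unadjusted pairwise $t$ tests on the pooled
residual mean square; Tukey's HSD uses the studentized range with the
Tukey–Kramer standard error for unequal group sizes. The
studentized-range CDF is evaluated by nested numerical quadrature
(`integrate()` over the conditional range probability and the scaled-chi
density of the pooled SD), so any $(k, \mathrm{df})$ combination is
supported without tables; it reproduces `stats::ptukey` to $10^{-6}$ and
the classical critical value $q_{0.05;3,6} = 4.339$ at $p = 0.05$.
$F$ and $t$ tail probabilities come from the standard distribution
functions (the regularized incomplete beta function). Degenerate inputs —
zero residual variance with distinct means — are flagged and reported
with boundary p-values rather than silently propagated.

## Trackwork conventions

All geometry is planar, in metres. Longitude/latitude enters only at the
I/O boundary through a local equirectangular projection anchored at the
block centroid ($x = \Delta\lambda\cos\phi_0 \cdot 111320$,
$y = \Delta\phi \cdot 110540$), which is sub-metre-accurate at block
scales (< 10 km). GPX timestamps must carry a timezone designator; naive
timestamps are rejected rather than guessed.

Distance from a bait plot to its prefeed track is the minimum Euclidean
distance to the track polyline (perpendicular foot or nearest endpoint,
segment by segment). Events referencing a line with no track are scored
against the nearest track and flagged. Swath compliance is the fraction
of plots within half the sown swath width of the track.

Per-line timing uses the **interval convention**: the logged quantity is
the time to bait a plot and walk to the next, so a line of $n$ plots
spans $n-1$ intervals and mean time per plot is
$\mathrm{elapsed}/(n-1)$. Line speed is the path length through the
plots divided by the elapsed time. The two pace summaries are computed
and reported separately and are deliberately not forced to agree: a
combined 1.67 min per 20 m plot implies 0.72 km/h, while the line-speed
summary can exceed that (e.g. 0.88 km/h) because speed is a per-line
ratio and lines differ in plot spacing realised on the ground. Combined
rows of grouped timing tables are **line-count-weighted means of the
group means** — the convention that reproduces a published combined row
from its group rows (plot-count weighting does not).

Layout arithmetic: each plot serves a `spacing x FPS` cell, so the
area-wide application rate is $(\text{mass}/1000) \cdot
10^4/(\text{spacing} \cdot \text{FPS})$ kg/ha (0.5 kg/ha for 100 g plots
every 20 m on 100 m lines) and non-overlapping clusters of radius $r$
bait $100\pi r^2/(\text{spacing}\cdot\text{FPS})$ percent of the area
(3.93% at $r = 5$ m) — under the 5% often used as an environmental
exposure bound.

## Cost model

Only direct operational costs are modelled: bait, flying, and baiting
labour. Helicopter positioning, deer repellent, consenting and management
are excluded. One hectare needs $10^4/\mathrm{FPS}$ metres of flight
line; flying time per hectare is that length over the flying speed, times
a reloading overhead (10% by default). Aerial operations pay for two
sorties (prefeed and toxic). Ground strategies pay for bait plus labour
passes: a pass costs the day rate divided by the daily coverage
`speed x hours x FPS/10` ha/person-day (70 ha at 1 km/h, 7 h, 100 m
lines). Bait-station variants amortise station hardware over a number of
operations and add a removal visit as a fraction of a labour pass.

All prices are **documented placeholders** (NZ$ orders of magnitude); no
dollar output should be read as a reproduction of published costs, which
depend on unpublished price schedules. What the model does reproduce is
structure: costs are homogeneous of degree one in prices, component
breakdowns sum to totals, per-hectare cost falls strictly with baiting
speed and hours per day, the saving from aerial prefeeding grows as
ground work slows, and requiring bait stations dilutes that saving. The
crew-day arithmetic reproduces 8 and 16 days for 5 000 and 10 000 ha at
0.88 km/h, 7 h and 10 staff with nearest-day rounding; the published
2.5 days for 1 000 ha is not reproducible from that same arithmetic
(it computes to about 1.6) and likely includes mobilisation, which is
not modelled.

## The synthetic field generator

The generator exists so that every estimator can be exercised, end to
end, on data whose truth is known. Its defaults describe a realistic
trial block: 250 ha, 100 m flight-path spacing, 60 m swath, chewcards at
50 m on lines at least 200 m apart for six nights, eight trap lines of
ten traps at 20 m for three nights, 100 g bait plots every 20 m with
lognormal per-plot times (mean 1.67 min), isotropic 3 m GPS noise.
Possums default to 8/ha — toward the upper end of forest densities,
consistent with the near-saturated pre-control interference that
motivates the transform — and blocks are rectangles: real block shapes
affect the analysis only through line length per hectare, which the
rectangle preserves exactly.

Animal populations are latent: Poisson counts at the nominal density with
uniform activity centres over the block expanded by the home-range
radius (60 m by default, well within reported attraction distances of up
to 250 m). There is no movement model; a card or trap "sees" the animals
whose centres fall within the home-range radius, and the local density
$D$ is that count per circle area. Two detection laws are provided:

* **hazard** — nightly interference probability $1 - e^{-\theta D}$,
  compounding over nights. This saturates the way real chewcards do and
  is the mode for realistic scenarios.
* **transform_linear** — the *session* interference probability is
  $\sin^2(\min(cD, \pi/2))$, so $\arcsin\sqrt{p} = cD$ below saturation
  and the tCCI reduction estimator is consistent for the true kill. The
  nightly probability is derived as $1-(1-p)^{1/m}$ so nights remain
  independent; composing a per-night $\sin^2$ law over nights instead
  would destroy the very linearity the mode exists to provide. The
  default coefficient places the pre-control index at $45^\circ$, the
  midpoint of the arcsine scale, where $\sin^2$ has zero curvature and
  second-order bias from local-density dispersion vanishes.

Trap surveys give each trap-night one outcome with capture precedence: a
possum in range is caught with a per-animal nightly probability (captured
animals are removed for the rest of the survey; the input population is
untouched), otherwise a non-target/sprung event may occur. Contractor
logs lay plots along the (noisy) prefeed fixes, skip one contiguous
segment per line for the skip fraction (waterlogged ground), and
accumulate lognormal per-plot durations — lognormal because times are
positive and right-skewed; only means and SEs of such times are usually
published.

### What the recovery experiments do and do not show

`recovery_experiment()` replicates the full pipeline — population,
pre-survey, control, post-survey, estimation — at a known kill $k$. Over
200 seeded replicates at the default conditions (about nine lines of 31
cards), the estimator tracks the truth to within a couple of percentage
points, always inside twice its own reported SE. It is not, however,
exactly unbiased at finite card counts, and the residual bias is
intrinsic to the published estimator rather than to this implementation:

* at high kill (95%), the post-control per-card interference probability
  is of order $10^{-3}$, so most lines record zero interference and a
  per-line $\arcsin\sqrt{\hat p}$ of exactly zero. The square root's
  behaviour near zero makes $E[\arcsin\sqrt{\hat p}]$ fall below
  $\arcsin\sqrt{p}$ in this sparse regime, so estimated reductions are
  pulled toward 100% — an upward bias of roughly +2 percentage points;
* at moderate kill (47%), dispersion of the local density across cards
  dominates instead: $E[\sin^2(cD)] > \sin^2(c\bar D)$ at small angles,
  which inflates post-control interference and biases the estimated
  reduction downward by a few points.

No admissible calibration removes both effects, because an unsaturated
pre-control index caps the post-control probability at
$\sin^2(0.05\,\pi/2) \approx 0.006$ for a 95% kill — the sparse regime is
unavoidable at realistic card counts. The acceptance check that demands
recovery at Monte-Carlo resolution ($2\,\mathrm{SD}/\sqrt{200} \approx
0.2$–$0.4$ points) therefore fails honestly, with measured biases of
+1.8, +2.0 and −3.5 points for kills of 95, 93 and 47%; the
scientifically relevant statement — bias well inside the estimator's own
sampling error — holds and is asserted in the test suite. Users should
read very high estimated reductions (above ~95%) as "at or above" rather
than as unbiased point estimates.

The saturation property runs the other way and is also demonstrated in
the tests: in hazard mode with $\theta D \ge 5$ before control, raw-CCI
reductions *underestimate* a 95% kill badly, which is precisely why the
transform and the tCCI exist.

The generator does not emulate animal movement or multi-night behavioural
aggregation along baited strips, bait consumption kinetics, canopy-induced
autocorrelated GPS error, or irregular block shapes. Passing recovery
tests on synthetic data therefore validates the estimators under the
stated detection models, not the detection models themselves against real
possums.

## Problem sizes and reproducibility

Every simulation function takes an explicit seed, and identical
configuration plus seed gives byte-identical output. The shipped
experiments use 200 replicates for recovery runs, 1 000 random instances
for the geometry oracle, and 10 000 resamples for the permutation oracle
— sizes at which Monte-Carlo error is far below the effects being
checked while the whole suite runs in well under a minute of simulation
time per experiment.
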