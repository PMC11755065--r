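---
title: "Methods: testing foraging-strategy complementarity within breeding pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing foraging-strategy complementarity within breeding pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairforage)
```

## The question and the inference

In colonial seabirds with obligate biparental care, both members of a
breeding pair provision the chick from the same central place. Partners
might benefit from *similar* foraging strategies (coordination) or from
*dissimilar* ones (risk partitioning: one mate takes the high-risk,
high-reward option while the other stays conservative). `pairforage`
implements the complete analysis chain for deciding between these
alternatives from biologging data: GPS fixes every few minutes, pressure
(depth) at 1 Hz, and morphometrics for both mates of each pair, over two
field seasons.

The inferential contrast is between **real** breeding pairs and
**randomized** pairs. Within each season every tracked female is crossed
with every tracked male (with $n_F = n_M$ per season, e.g. $19 \times 19 =
361$ and $21 \times 21 = 441$ combinations), each combination carries the
absolute female minus male difference $|\Delta x|$ in every behavioural and
morphometric trait, and a binary response marks the observed pairs. A
weighted binomial logistic model

$$\operatorname{logit} \Pr(\text{real}) = \beta_0 + \beta_1 |\Delta x|$$

then asks whether mates are more dissimilar ($\beta_1 > 0$, disassortative)
or more similar ($\beta_1 < 0$, assortative) than chance, with AICc model
selection across single-trait candidates and an intercept-only null. Real
pairs are rare ($n_{\text{real}} \ll n_F n_M$), so real rows are weighted
$n_{\text{rand}}/n_{\text{real}}$ within their season (randomized rows get
1), balancing total class weight; the exact weights the original field
analysis used are unreported, so this is a documented choice with a
`weight_real` override.

Each bird appears in many rows of the cross-pair table, which a fixed-effect
logistic model ignores. Rather than a crossed binomial GLMM, the package
pairs the logistic fit with a **matching-permutation test**
(`matching_permutation_test()`): the null redraws, within each season, a
uniform random perfect matching between females and males, so every
pseudo-dataset preserves "each bird has exactly one mate" — exactly the
exchangeability at stake. The statistic is the mean $|\Delta x|$ over real
(or pseudo-real) pairs minus the mean over all potential pairs; the
two-sided p-value uses the add-one rule $(1 + \#\{|T^\*| \ge |T|\})/(1 +
n_{\text{perm}})$, and tiny seasons are enumerated exhaustively. This was a
genuinely open design point: a hand-rolled Laplace GLMM would be
disproportionate to its role, while the permutation null is exact for the
dependency that matters.

## From raw tracks to traits

**Regularization.** Tracks are resampled to a 300 s grid (grid anchored at
the first fix) by exact great-circle interpolation between bracketing fixes.
Gaps longer than 30 min are still filled but flagged, and flagged steps stay
out of metric numerators. The field analysis this emulates imputed with a
continuous-time correlated random walk; at 3-min fix rates the downstream
quantities are trip-level aggregates that are insensitive to within-gap
curvature, so the package deliberately ships the simpler interpolation with
the same contract (a position at every grid time, imputations flagged). All
spherical geometry uses radius 6371 km; 1° of latitude is 111.19 km.

**Activity classification.** A four-state hidden Markov model labels each
step `colony`, `diving`, `flying` or `swimming` from three emissions: step
length (Gamma), a flight-intensity scalar standing in for wing-beat
frequency (Normal), and a Bernoulli dive indicator. Fitting is by
Baum–Welch EM over all birds jointly (log-space forward/backward with
per-step max shifts; exact M-steps, Newton iterations for the Gamma shape),
so the log-likelihood is non-decreasing; decoding is log-space Viterbi with
ties broken toward the lower state index, plus forward–backward posteriors.
The published starting values for the emission distributions live in a
supplement that is not shipped; `hmm_spec()` therefore encodes physically
obvious starting values (near-zero steps at the colony, ~4 km steps in
flight, dive probability 0.95 in the diving state, at most 0.05 elsewhere)
and treats them as replaceable configuration. Two numerical floors matter:
step lengths are floored at 1 m so stationary fixes stay inside the Gamma
support, and per-observation log-densities at $-690$ so no observation has
zero likelihood under every state. After decoding, steps within 1 km of the
colony with no dive are forced to `colony` — the splashdown filter applied
as a deterministic override rather than as a distance emission, which keeps
the four-state model stable. A state that loses essentially all posterior
responsibility keeps its parameters frozen instead of crashing the M-step,
so degenerate one-state data converge with a near-absorbing transition row.

**Dives and trips.** A dive is a maximal run of depth $\ge$ 1 m lasting
$\ge$ 3 s — thresholds not fixed by the emulated protocol, chosen above the
0.1 m sensor resolution and surface splash, and both exposed as
configuration. A foraging trip is a maximal run of steps farther than 1 km
from the colony that lasts longer than 20 min and overlaps at least one
dive; all three predicates are re-checked by tests as a post-hoc audit.
Trip distance ("total distance traveled") is colony-to-colony: the step
lengths across the trip plus the approach and return legs. Per-deployment
metrics average per-trip metrics, with these conventions: "per day" rates
divide by the exact deployment span in days (not calendar days); the SD of
a single-trip metric is 0 with a `single_trip` flag (not missing), so pair
differencing never drops a bird; azimuth summaries are arithmetic means of
bearings in $[0, 360)$ — matching how such tables are conventionally
reported — with a warning when a bird's bearings span more than 180°.
**Differential depth** removes the diurnal cycle: each dive's mean depth
minus the mean dive depth for its hour of (colony-local, UTC−5) day. Whether
that hourly mean should be per-bird or population-wide is ambiguous in the
emulated design; the default is population-wide within season,
configurable.

**Space use.** Positions are projected to a local azimuthal-equidistant
plane about the colony (the 200 m grid and metre bandwidths are metric
quantities). The kernel UD uses an isotropic Gaussian kernel; points are
binned at cell resolution, which displaces a point by at most half a cell
(100 m) against bandwidths an order of magnitude larger, and makes the
smooth two small matrix products. Grids snap to a global lattice so any two
birds' grids align cell-for-cell. The reference bandwidth is the bivariate
ad hoc rule $h = \tfrac12(\mathrm{sd}_x + \mathrm{sd}_y)\, n^{-1/6}$,
computed per bird, averaged, and applied as one common $h$ (default 2720 m,
the averaged value of the emulated configuration). Volume contours take
cells by descending mass until the target fraction is reached, ties at the
cut retained. Bhattacharyya's affinity $\sum_c \sqrt{p_1(c) p_2(c)}$
compares the 50% (core-area) masked UDs after renormalizing each mask to
sum 1 — renormalization is what makes "identical UDs give 1" hold at any
contour level; the unrenormalized variant is available via
`renormalize = FALSE` for cross-checks.

## The synthetic colony generator

Real deployments are not shipped; every stage is validated against
`sim_config()` colonies whose structure is known. Defaults encode the
emulated study design: two seasons of 19 and 21 pairs (80 birds), 72 h
deployments, a fix every 180 s, depth at 1 Hz, colony at (−82.019, 62.948)
— the published colony coordinates appear lat/lon-swapped for this site, and
the generator uses the swap-corrected reading. Sex-specific trait means and
SDs are scale-realistic for a chick-rearing murre colony (females ranging
farther, diving deeper and more often); pre/post body masses default to
981 ± 65 g and 961 ± 61 g. Tracks are biased correlated random walks in
the tangent plane — out along the bird's preferred azimuth at ~60 km h⁻¹,
a slow foraging drift, return — with V-shaped dives (1.2 m s⁻¹ legs,
10–30 s bottoms) placed in foraging phases; no physiological flight model,
because only the trip-level summaries matter downstream. Accelerometer
channels are not simulated; the per-step flight-intensity scalar plays
their role as an HMM emission. One integer seed drives everything;
per-bird streams derive deterministically from it.

**Disassortment.** For a trait with disassortment $d$, the two mates are
drawn independently from their sex-specific distributions and then spread
about their midpoint by $(1+d)$, so

$$\mathbb{E}\lvert F - M \rvert_{\text{real}} \;=\; (1+d)\,
\mathbb{E}\lvert F - M \rvert_{\text{independent}}$$

holds *exactly, for any trait distributions*. This exactness is why the
spread acts on the whole signed difference: constructions that preserve the
sex marginals exactly (e.g. a negative-correlation Gaussian copula) cannot
exceed a ratio of $\sqrt 2$ and cannot express strong disassortment. The
price is documented rather than hidden: pair midpoints keep their mean, but
each sex's marginal mean moves to $\mu + d(\mu - \mu_{\text{other}})/2$
(the sex gap widens by $(1+d)$ like every other component), and marginal
variances inflate, so randomized-pair differences are somewhat inflated
too — which *attenuates* the real-vs-random contrast and can only make
recovery conservative. Positivity is enforced by a floor, so declared
moments hold where truncation is negligible. Wing length instead uses a
correlation parameter: mates' wings are jointly Gaussian with correlation
`wing_assortment` (identical at 1).

**Default effect sizes.** The generator's defaults are the study conditions
for all replicated validation: `disassortment = c(mean_trip_distance = 1.2,
dives_per_day = 1.8)` and `wing_assortment = 0.4`. They were calibrated once,
at design time, so that the single-covariate models beat the intercept-only
null by AICc margins of the order the emulated study's selection tables
print (wing ~42, dive count ~12–15), with the trip-distance channel set
strong enough that a 100-replicate recovery study at $n = 40$ pairs has
high power; they were not revisited afterwards. Observation noise on the
phenotype-level metrics defaults to 15% of each trait's between-bird SD.

## What the validation does and does not show

Two chains are exercised. The *track chain* (simulate → regularize → HMM →
dives/trips → metrics → UD/overlap → pair models) runs end-to-end on small
colonies (3–6 pairs, 18–24 h deployments) in the tests and acceptance
script: trip counts match the generator's plan exactly, every emitted trip
passes the three filters, and phenotype-level trip distances and dive rates
are recovered with correlations above 0.99. The *replicated chain* (100
studies at the full 19 + 21-pair design) draws bird-level metrics directly
from phenotypes plus observation noise, because the pair-level inference
consumes bird-level metrics — re-running HMM fits and 1 Hz depth synthesis
per replicate would add nothing to what the replication measures. With the
default effects, coefficient signs and AICc preference are recovered in
well over 90% of replicates, and with all structure zeroed the
matching-permutation p-value is uniform (Kolmogorov–Smirnov check).

Passing these validations shows the *pipeline* is correct and the *design*
is adequately powered for effects of the built-in size. It does not show
that real murre colonies behave like the generator: real tracks have tides,
wind, prey patches, device failures and irregular sampling that the
generator deliberately omits (no oceanography, no multi-colony structure),
and real effect sizes may be weaker than the calibrated defaults — the
emulated study's own trip-distance effect was detectable but modest.

Numerical cores are additionally checked against independent oracles:
Viterbi against exhaustive path enumeration, the forward likelihood against
brute-force path summation, the IRLS logistic fit against `glm()` and a
derivative-free simplex maximizer, the Bhattacharyya overlap of offset
Gaussians against its closed form $\exp(-d^2/8\sigma^2)$, the reference
bandwidth and AICc against hand arithmetic
($\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$).

## Known limitations

- Collinearity screening (`collinearity_filter()`, $|r| > 0.8$) resolves
  groups by a lexical rule (prefer the "mean" variant); genuinely
  non-nested correlated groups fall back to column order.
- Complete separation in the logistic model is detected by coefficient
  divergence and raised as an error, not penalized (no Firth correction).
- The BA model group enters model selection but not the permutation test
  (overlap is a pair property, not a bird trait difference).
- Azimuth handling is linear by default; the circular mean is available but
  means of bearings spanning more than a half-circle should be read with
  the warning they come with.
- A bird whose deployment yields no kept trips is excluded (and reported);
  seasons can then lose the $n_F = n_M$ balance that the permutation null
  requires, in which case that test is skipped with a message while the
  logistic/AICc results stand.
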