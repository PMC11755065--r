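# pairforage

Do breeding partners in a central-place foraging seabird colony have
*complementary* foraging strategies? In species with obligate biparental
care, mates could benefit from being alike (coordination) or from being
different (risk partitioning: one mate takes a long-range, many-dive,
high-reward strategy while the other stays conservative). `pairforage` is
an R package for movement ecologists that implements the full analysis
chain for this question from raw biologging data — GPS fixes every few
minutes, 1 Hz depth, morphometrics for both mates — together with a
synthetic colony generator so that every stage of the inference can be
validated by parameter recovery without any field data.

## The inference

Within each season, every tracked female is crossed with every tracked
male: with 19 and 21 pairs in two seasons this gives 19×19 + 21×21 =
361 + 441 = 802 potential pairs, of which 40 are the real ones. Each row
carries the absolute female−male difference |Δx| in every trait (trip
distance, dive count, dive depth, differential depth, azimuth, wing
length, ...) and the core-area overlap of the two birds' utilization
distributions (Bhattacharyya affinity of the 50% volume-contour-masked,
renormalized kernel UDs). The probability that a combination is a real
pair is modelled as

    logit Pr(real) = β₀ + β₁ |Δx|

by weighted binomial logistic regression (IRLS; real pairs weighted
n_rand/n_real within season to balance the classes), with AICc model
selection across single-trait candidates:

    AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1),   wᵢ = exp(−Δᵢ/2) / Σⱼ exp(−Δⱼ/2)

β₁ > 0 means mates are more *dissimilar* than random pairs
(disassortative), β₁ < 0 more similar (assortative). Because every bird
appears in many rows, significance additionally comes from a
matching-permutation test: the null redraws random perfect matchings
between females and males within season — each bird keeps exactly one
mate — and compares the mean |Δx| over (pseudo-)real pairs against all
potential pairs.

Upstream of the pair table the package provides: great-circle track
regularization to 5-min steps; a four-state hidden Markov activity model
(colony / diving / flying / swimming; Gamma step lengths, Normal flight
intensity, Bernoulli dive indicator; Baum–Welch fitting, Viterbi
decoding); dive detection (≥ 1 m for ≥ 3 s) and foraging-trip
segmentation (> 1 km from the colony, > 20 min, ≥ 1 dive); per-trip and
per-deployment behavioural metrics including differential depth (a dive's
depth minus the hourly mean, removing the diurnal cycle); and kernel
utilization distributions on a 200 m metric grid (ad hoc bandwidth
h = ½(sd_x + sd_y) n^(−1/6), common-h workflow, default 2720 m).

## Worked example

Simulate a two-season study at the default design (19 + 21 pairs, with
built-in disassortment in trip distance and dive count and assortment in
wing length), build the cross-pair table, and compare candidate models:

```r
library(pairforage)

study <- simulate_pair_study(sim_config(seed = 42))
pt <- build_pair_table(study$metrics,
                       traits = c("mean_trip_distance", "dives_per_day",
                                  "wing_length", "head_bill", "body_mass"),
                       standardize = c("mean_trip_distance", "wing_length"))
pt
#> Pair table: 802 potential pairs ( 40 real / 762 randomized ) across year(s) 2022, 2023
#>    female_id    male_id year is_real d_mean_trip_distance d_dives_per_day ...
#> 1 2022_P01_F 2022_P01_M 2022       1            1.7580427       155.85483
#> 2 2022_P02_F 2022_P01_M 2022       0           -0.6250330       263.24846
#> ... and 796 more rows

fits <- list(
  null      = wlogit(is_real ~ 1, pt, weights = pt$weight),
  trip_dist = wlogit(is_real ~ d_mean_trip_distance, pt, weights = pt$weight),
  dives     = wlogit(is_real ~ d_dives_per_day, pt, weights = pt$weight),
  wing      = wlogit(is_real ~ d_wing_length, pt, weights = pt$weight))
print(aicc_rank(fits), digits = 4)
#>       model k loglik AICc dAICc    weight deviance
#> 1      wing 2  -1032 2068  0.00 9.997e-01     2064
#> 2 trip_dist 2  -1040 2084 16.56 2.530e-04     2080
#> 3     dives 2  -1052 2108 39.66 2.443e-09     2104
#> 4      null 1  -1056 2115 46.86 6.676e-11     2113

coef(fits$trip_dist)
#>          (Intercept) d_mean_trip_distance
#>          -0.03659008           0.26274602
coef(fits$wing)
#>   (Intercept) d_wing_length
#>   -0.06273575   -0.38918296
```

Every candidate with a trait beats the intercept-only null; the
trip-distance slope is positive (mates more dissimilar than random pairs)
and the wing slope negative (mates more similar). The
dependence-respecting significance check:

```r
perm <- matching_permutation_test(pt, "mean_trip_distance",
                                  n_perm = 999, seed = 1)
#> statistic = 0.309, p = 0.0010 (999 matchings)
```

Real pairs differ in (standardized) mean trip distance by 0.31 more than
the average potential pair, and none of 999 random matchings reached that
— the smallest p-value the add-one rule allows.

For raw-track workflows, `simulate_colony()` produces full GPS + depth
deployments, `write_fixture_set()` / `read_fixture_set()` round-trip them
as CSV, and `analyze_colony()` / `run_pipeline()` run regularization, HMM
classification, trip segmentation, metrics, space use and the pair models
end to end (writing per-stage CSV artifacts and a JSON results bundle).

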