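---
title: "Methods: PA-use metrics, social networks and matrix permutation tests in sightnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PA-use metrics, social networks and matrix permutation tests in sightnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sightnet)
```

`sightnet` analyses longitudinal sighting tables from individual-ID
mark–resight studies of social mammals: how continuously individuals use
a protected observation area, how male use relates to motivational state
(foraging vs musth) and age, and whether female social affiliation
predicts similarity in area use. This vignette explains each model and
procedure, the tunable parameters, the numerical choices, and what the
simulation-based validation does and does not establish.

## The between-sightings interval

Sighting data record *when an individual was seen*, never when it
entered or left the area, so residence time is not identifiable. The
between-sightings interval (BSI) — days elapsed between consecutive
sightings — is the observable proxy: short mean BSIs indicate an
individual that is continuously available for observation; long ones
leave room for absences. Two numerical conventions matter:

- Repeat sightings on one day collapse to a single date; BSI is defined
  in whole days, so the smallest gap is 1 and `mean_bsi >= 1`.
- The mean is taken over the span from the first to the last sighting
  only: on distinct days $d_1 < \dots < d_k$ it equals
  $(d_k - d_1)/(k - 1)$, the algebraic identity of averaging the
  consecutive gaps. With $k < 2$ the mean is `NA`, never 0 — a singleton
  carries no interval information, and downstream filters treat it that
  way (`filter_glmm_males()` removes singletons; `residency_flag()`
  returns `FALSE`).

The *overall* mean keeps cross-year gaps (an individual seen once per
year for three years has a well-defined, very long mean BSI), whereas
`yearly_mean_bsi` uses within-year gaps only and is `NA` for years with
fewer than two sighting days. This split is a deliberate design choice:
the overall mean answers "how continuously over the whole study", the
yearly vector feeds the pairwise similarity analysis where cross-year
gaps would leak between-year signal into a within-year quantity.

A *possible resident* has mean BSI strictly below 90 days **and** was
seen in at least two study years. The 90-day cutoff is an argument
(`resident_cutoff`) everywhere it is used. Study years are 365-day bins
anchored at the study window start ("observation years"), not calendar
years; a `year_basis = "calendar"` switch exists because some field
datasets are organised that way. Anchored years keep simulation and
analysis self-consistent when a study starts mid-calendar-year.

## Male strategies, male-weeks and musth bouts

A mature male's *strategy* summarises the state in which he was ever
seen: `foraging_only` if no sighting showed musth, `musth_only` if every
sighting did, `foraging_and_musth` otherwise. A musth sighting while
feeding counts as musth — the rare "foraging while in musth" observation
belongs to the mixed strategy by definition.

Because field sampling is not daily, male sighting effort is aggregated
into **male-weeks**: consecutive 7-day bins from a configurable origin
(default: study start). Each male-week scores 0 (unseen), 1 (seen,
foraging only) or 2 (seen in musth at any time that week); musth
dominates within a bin. Anchored 7-day bins rather than ISO calendar
weeks make the binning reproducible and independent of locale. The
resident subset's musth male-week proportion is compared with the whole
population's by `exact_binomial_test()`.

**Musth bouts** are maximal runs of date-consecutive musth sightings
uninterrupted by non-musth sightings; duration is days between the first
and last musth sighting of the run (0 for a single sighting). A bout is
`complete` only when bracketed by non-musth sightings on both sides —
otherwise the start or end was plausibly censored by the study window or
by the male leaving the area. Field studies stage musth by physical
appearance; the simulator, which has no morphology, stages by thirds of
the latent window (early/peak/late).

## Exact tests

`exact_binomial_test(k, n, p0)` uses the minimum-likelihood two-tailed
rule: the p-value sums the probabilities of every outcome whose
point probability under $\mathrm{Binomial}(n, p_0)$ does not exceed that
of $k$ (with a $1 + 10^{-7}$ relative tie tolerance, the usual
convention). The implementation is a direct enumeration of the pmf; the
test suite checks it against brute-force enumeration and against
`stats::binom.test` for all $n \le 20$.

`contingency_independence_test()` computes the Pearson chi-square
statistic exactly and never relies on its asymptotic distribution: 2×2
tables are enumerated hypergeometrically (fixed margins, two-sided by
minimum likelihood, which reproduces Fisher's exact test); larger tables
are evaluated by Monte-Carlo sampling of tables with fixed margins
(`stats::r2dtable`), with the observed table counted in numerator and
denominator.

## The simple ratio index and its sampling unit

For a pair $(i, j)$, over a set of sampling units,
$$\mathrm{SRI}_{ij} = \frac{x}{x + y_A + y_B + y_{AB}}$$
with $x$ units containing both together, $y_A, y_B$ units containing
exactly one, and $y_{AB}$ units in which both were seen but apart. With
**group sightings** as sampling units (the default) $y_{AB}$ is
structurally zero — one group either contains an individual or not — so
the denominator reduces to "units containing at least one of the pair".
A `sampling_unit = "day"` option treats the day as the unit, in which
case two individuals seen in different groups on one day contribute a
genuine $y_{AB}$. The choice matters in dense data; both are exposed
because field conventions differ, and the default mirrors the
group-sighting event structure of the data model. Pairs never seen in
any common unit have SRI 0, and `0 <= SRI <= 1` always; the matrix is
symmetric with an ignored diagonal.

## Community detection and dynamic tracking

Yearly networks (SRI edge weights over the females passing the
first-two-years filter) are clustered by Louvain weighted-modularity
maximisation via `igraph`. The heuristic is stochastic and sensitive to
node order, so `detect_communities()` seeds the RNG and shuffles the
node order deterministically under that seed, then renumbers community
labels contiguously by lowest member index — the same input and seed
always give the same partition. An edgeless network returns the
all-singletons partition with a warning rather than an error, because a
sparse year can legitimately have no observed associations.

Clusters in consecutive years are linked by **reciprocal majority**:
$A$ (year $t$) and $B$ (year $t+1$) are the same community iff
$|A \cap B| > |A|/2$ **and** $|A \cap B| > |B|/2$, both strict — an
exactly-half overlap does not match. Strictness makes the match
one-to-one: two disjoint strict majorities of the same cluster are
impossible. Matched clusters inherit the earlier persistent ID;
unmatched clusters get fresh IDs.

Individuals receive a two-year **consensus assignment**. When an
individual's year-1 cluster participated in a match it keeps that
persistent ID; otherwise, if its year-2 cluster matched, it follows that
one; failing both, the year-1 ID (or year-2 for individuals absent in
year 1). The rationale: membership in a community that demonstrably
persisted across years is stronger evidence than membership in a
transient fragment. In sparse years Louvain tends to shed poorly
connected individuals as singletons; preferring the matched side of the
pair reattaches them to the community where the rest of their associates
sit, which is what the two-year design is for.

## MRQAP

Dyadic observations violate the independence assumptions of ordinary
regression — every dyad shares a node with $2(n-2)$ others. The multiple
regression quadratic assignment procedure keeps the OLS point estimates
(computed on the vectorized upper-triangle dyads) but replaces the
sampling distribution with one generated by **node-label permutations**,
which preserve the row/column exchangeability structure.

The default scheme is Dekker-style **double semi-partialing** (DSP):
for each predictor $X_k$, regress $X_k$ on the remaining predictors over
the dyads, reshape the residuals into a symmetric matrix, permute its
rows and columns jointly by a random node relabeling, and recompute the
pivotal $t$ statistic of the permuted residual in the full model. DSP is
the default because it is robust to collinearity among predictors and
to autocorrelation, and it is the scheme used by the implementations
this analysis family descends from; simple dependent-matrix permutation
(`method = "y"`) is available, and is the only scheme that yields an
intercept p-value (the intercept's p is `NA` under DSP). Two-tailed
p-values count the observed statistic in both numerator and denominator,
so $p \ge 1/(n_\mathrm{perm}+1)$ and is never exactly zero.

Numerical details: the design is solved by QR; a rank-deficient design
(e.g. a constant predictor, collinear with the intercept) is an error;
fewer than 99 permutations triggers a warning. Masked dyads (see below)
are dropped listwise; when masks are present the permuted residual
matrix can move `NA`s around, and each permutation re-restricts to the
dyads valid on both sides. With complete matrices a Frisch–Waugh
shortcut (project once on the fixed predictors, then one inner product
per permutation) makes the permutation loop cheap.

The three matrices of the female analysis:

- dependent: pairwise Pearson correlation of yearly mean-BSI vectors
  over the years where both are defined. Pairs sharing fewer than
  `min_overlap` years (default 3) or with a constant shared vector are
  masked — a correlation on two points is ±1 by construction and on a
  constant is undefined, and imputing dyadic data would manufacture
  observations. The default of 3 is the smallest overlap at which a
  correlation carries any information beyond its sign.
- predictor 1: the SRI association matrix pooled over the whole study.
- predictor 2: Euclidean distances between per-individual sighting
  centroids (mean of planar coordinates), controlling for gross spatial
  overlap. Coordinates are projected planar metres throughout; the
  package never does geodetic arithmetic.

## The simulator as a validation instrument

`simulate_population()` / `simulate_sightings()` generate data with the
structure the analysis assumes, with ground truth retained:

- **Residency**: alternating in/out bouts with exponential lengths
  (defaults: mean 30 d in, 90 d out) — memoryless and controlled by two
  interpretable knobs, enough to create short-BSI "resident" and
  long-BSI "transient" phenotypes. Each community has a shared schedule;
  a member copies each day from the shared schedule with probability
  `residency_mixing_rho` and from her own independent schedule
  otherwise, so `rho = 1` moves the community as one and `rho = 0`
  decouples members.
- **Grouping**: each community-day, present members are partitioned by a
  Chinese-restaurant process whose concentration is the single
  fission–fusion knob (0 = never split).
- **Males**: age classes 21–30 / 31–40 / 41–50 / 51–60; one musth window
  per year with gamma-distributed duration (shape 6) around an
  age-class mean (defaults 25/33/45/45 d, lengthening with age, the
  oldest two classes sharing a plateau); the strategy decides whether
  presence follows the foraging schedule minus musth windows
  (`foraging_only`), the windows alone (`musth_only`), or their union.
- **Detection**: independent per individual-day (default 0.35); group
  sightings consist of the detected members, located at the mean of
  member centroids plus isotropic Gaussian noise (`centroid_sd`,
  default 2000 m).
- **Determinism**: every individual, community and community-day draws
  from its own counter-derived substream of the base seed, so enlarging
  the population never perturbs the draws of existing individuals.

Default population: 16 communities sized 2–22 (130 females) and 216
males with strategy probabilities 0.458/0.107/0.435 — the scale and
composition of the motivating study system. Dates are ISO-8601 calendar
dates with the day as the finest unit.

What the simulator does **not** emulate: spatially explicit movement
(home-range kernels, habitat), demography (births, deaths beyond an
exclusion list), observation-effort variation (routes, seasons of no
fieldwork), and any correlation between detection and state or age.
Passing the validation suite therefore shows that the estimators recover
the structure *they assume*, not that real sighting data satisfy those
assumptions.

## Validation design and problem sizes

The test suite pairs every estimator with an independent oracle:
vectorized-OLS via `lm()` for MRQAP point estimates (50 random
instances up to 30 nodes), brute-force pmf enumeration and
`binom.test` for the exact binomial test (all $n \le 20$),
set-arithmetic enumeration for reciprocal-majority matching (1,000
random partition pairs), and the $(d_k-d_1)/(k-1)$ identity for the BSI
(1,000 random date sequences). Calibration and power use problem sizes
chosen to give stable answers in minutes on one CPU:

- Type-I error of the MRQAP association test over 500 replicates of
  independent random symmetric matrices (30 nodes, 499 permutations):
  the rejection rate at $\alpha = 0.05$ must sit inside the exact
  binomial 95% band $[0.032, 0.071]$.
- Community recovery: planted 3-block SRI weights (within ≈ 0.6,
  between ≈ 0.02, 30 nodes) are recovered with adjusted Rand index
  above 0.9 (median over 10 seeds); the full pipeline at
  `rho = 0.9, detection = 0.6` recovers simulated communities likewise.
- Power: 20 replicates of the full female pipeline (3 communities of 8,
  5 years, 199 permutations) at `rho = 0.9` must reject at
  $\alpha = 0.05$ at least 80% of the time.

One honest caveat: the `rho = 0` pipeline run is *not* an exact null for
the association–BSI regression. Even with independent schedules, a pair
that by chance is co-present more often both associates more (higher
SRI) and shares more of its yearly sighting profile (higher BSI
correlation) — association is defined by spatiotemporal co-occurrence,
so the two quantities are generatively coupled. Empirically the
rejection rate at `rho = 0` sits slightly above the nominal 5%
(on the order of 10% over many replicates). The strict type-I
calibration is the independent-matrices experiment above; the `rho = 0`
run bounds the pipeline's false-positive behaviour under a *weakly*
coupled generative process.

## Degenerate inputs and tie-breaks

- Empty sighting files read as empty tables; an empty network partitions
  into singletons with a warning; an all-foraging cohort skips the
  binomial comparison (`p = NA`) rather than testing against a zero
  proportion.
- Exactly-half cluster overlaps do not match; the 90-day residency
  cutoff is strict; `mean_bsi` for singletons is `NA`, and such males
  are excluded from the model frame rather than imputed.
- Percent formatting offers nearest (default) and truncation modes
  because published tabulations of this kind mix both conventions;
  all computations keep full precision and rounding is applied only at
  the reporting edge.
- The male mixed-model frame (`build_glmm_frame()`: response = interval
  days; age class, strategy, ID, month, year) is constructed but never
  fitted — mixed-model estimation is a standard step for which users
  should reach for their preferred tool (`lme4`, `glmmTMB`), and the
  appropriate family/link for interval responses is a modelling decision
  the package does not impose.

## Known limitations

- The BSI confounds absence with non-detection; only with an estimate of
  detection probability (not attempted here) could the two be separated.
- Louvain is a greedy heuristic: on weak block structure different seeds
  can give different partitions; the package makes this reproducible,
  not exact.
- The consensus community assignment uses the first two study years
  only, as the study design intends; later-year partitions are computed
  on request (`match_communities()` chains via `persistent_t`) but feed
  nothing downstream by default.
- MRQAP p-values are approximate under strong heteroskedasticity of
  dyadic errors; DSP is the most robust of the standard schemes but not
  a cure-all.
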