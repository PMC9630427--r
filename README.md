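# sightnet

Protected-area (PA) use and social structure from longitudinal
individual-identification sighting data.

Long-term mark–resight studies of social mammals — the motivating case is
wild Asian elephants observed inside a fenced national park over many
years — produce sighting tables: one row per identified individual per
group sighting, with a date, a location, sex, age class and (for males) a
motivational state, foraging or musth. `sightnet` turns such tables into
the standard analyses of this study design:

- **Between-sightings interval (BSI).** For an individual sighted on
  distinct days $d_1 < d_2 < \dots < d_k$, the mean BSI is
  $\overline{\mathrm{BSI}} = (d_k - d_1)/(k-1)$ days — the average gap
  between consecutive sightings, a proxy for how continuously the
  individual uses the observed area. It is undefined (not zero) for
  singletons. A *possible resident* has mean BSI < 90 days and was seen
  in multiple study years.
- **Male strategies and male-weeks.** Each mature male is classified
  `foraging_only` (never seen in musth), `musth_only` (only ever seen in
  musth) or `foraging_and_musth`; sightings are aggregated into 7-day
  bins scored 0 (unseen) / 1 (seen foraging only) / 2 (seen in musth),
  and the musth male-week proportion of the resident subset is compared
  with the population by a two-tailed exact binomial test
  (minimum-likelihood method). Musth bouts and their durations (days
  between first and last musth sighting of an uninterrupted run) are
  extracted per male.
- **Female social networks.** A group-by-individual matrix feeds the
  simple ratio index, $\mathrm{SRI} = x/(x + y_A + y_B)$ — the
  proportion of sampling units containing either of a pair in which both
  were together. Yearly SRI networks are clustered with Louvain
  modularity maximisation, and clusters in consecutive years are linked
  by *reciprocal majority*: clusters sharing more than half the members
  of **both** are the same persistent community.
- **MRQAP.** The pairwise Pearson correlation of yearly mean-BSI vectors
  is regressed on the SRI association matrix, controlling for Euclidean
  distance between per-individual sighting centroids. Coefficients are
  OLS on the vectorized dyads; two-tailed p-values come from node-label
  permutations with Dekker-style double semi-partialing.
- **Simulator.** A seeded fission–fusion sighting simulator (residency
  bouts, community-shared schedules, Chinese-restaurant grouping, musth
  windows, imperfect detection) generates tables with known ground truth
  so every stage can be validated without field data.

## Worked example

```r
library(sightnet)

cfg <- sim_config(study_days = 1825, n_communities = 4,
                  community_sizes = c(9, 7, 5, 3), n_males = 40,
                  residency_mixing_rho = 0.9, detection_prob = 0.5,
                  seed = 42)
pop       <- simulate_population(cfg)
sightings <- simulate_sightings(pop$roster, pop$truth, cfg)
report    <- run_report(sightings, n_perm = 999, seed = 42)

print(report$male$strategy_years)
#> Mature males by strategy and years seen (n = 40 )
#>          foraging_only musth_only foraging_and_musth
#> seen_5yr 19 ( 95%)     1 (100%)   19 (100%)
#> seen_4yr 1 (  5%)      0 (  0%)   0 (  0%)
#> ...

report$female$community_summary$communities[, c("community", "size")]
#>   community size
#> 1         1    9
#> 2         2    7
#> 3         3    5
#> 4         4    3

print(report$female$mrqap)
#> MRQAP (dsp, 999 node permutations, 276 dyads)
#>              Estimate     t Two-tailed p
#> (Intercept) -2.96e-01 -4.63           NA
#> association  9.19e+00 14.63        0.001
#> distance     2.26e-05  4.06        0.003
#> Adjusted R-squared = 0.4623, Residual SE = 0.4579, df = 273
```

With `residency_mixing_rho = 0.9` community members share 90% of their
residency schedule, so social associates have similar temporal PA-use:
the association coefficient is positive with the smallest attainable
permutation p (0.001 at 999 permutations), the four simulated
communities are recovered exactly, and the strategy-by-years table shows
the cohort structure that the simulator planted. An undefined intercept
p is expected under double semi-partialing.

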