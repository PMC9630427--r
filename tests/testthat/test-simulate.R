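small_cfg <- function(...) {
  sim_config(study_days = 730L, n_communities = 2L,
             community_sizes = c(3L, 2L), n_males = 4L, seed = 7L, ...)
}

test_that("population construction follows the configuration", {
  pop <- simulate_population(small_cfg())
  females <- pop$roster[pop$roster$sex == "F", ]
  expect_equal(nrow(females), 5L)
  expect_equal(females$community, c(1L, 1L, 1L, 2L, 2L))
  expect_true(all(is.na(females$strategy)))
  males <- pop$roster[pop$roster$sex == "M", ]
  expect_equal(nrow(males), 4L)
  expect_true(all(males$strategy %in%
                    c("foraging_only", "musth_only", "foraging_and_musth")))
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_cfg()
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  t1 <- simulate_sightings(p1$roster, p1$truth, cfg)
  t2 <- simulate_sightings(p2$roster, p2$truth, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("adding individuals does not perturb earlier ones", {
  cfg_a <- small_cfg()
  cfg_b <- sim_config(study_days = 730L, n_communities = 2L,
                      community_sizes = c(3L, 2L), n_males = 6L, seed = 7L)
  pa <- simulate_population(cfg_a)
  pb <- simulate_population(cfg_b)
  shared <- pa$roster$individual_id
  expect_equal(pa$roster, pb$roster[match(shared, pb$roster$individual_id), ],
               ignore_attr = TRUE)
  expect_equal(pa$truth$presence, pb$truth$presence[shared, ])
})

test_that("invalid configurations are rejected by field name", {
  expect_error(sim_config(community_sizes = c(1L), n_communities = 1L),
               "community_sizes")
  expect_error(sim_config(detection_prob = 1.5), "detection_prob")
  expect_error(sim_config(study_days = 100), "study_days")
  expect_error(sim_config(n_communities = 3L, community_sizes = c(2L, 2L)),
               "length")
  expect_error(sim_config(strategy_probs = c(0.9, 0.2, 0.2)), "sum to 1")
})

test_that("perfect detection of one always-present cohesive community gives one full group per day", {
  cfg <- sim_config(study_days = 730L, n_communities = 1L,
                    community_sizes = 3L, n_males = 0L,
                    residency_mean_in = 1e8, residency_mean_out = 1e-3,
                    detection_prob = 1, grouping_concentration = 0,
                    seed = 3L)
  pop <- simulate_population(cfg)
  # the always-in limit: the first "in" bout covers the window
  expect_true(all(pop$truth$presence))
  tab <- simulate_sightings(pop$roster, pop$truth, cfg)
  per_day <- table(tab$date)
  expect_equal(length(per_day), 730L)
  expect_true(all(per_day == 3L))
  expect_equal(length(unique(tab$group_id)), 730L)
})

test_that("zero detection yields an empty sighting table", {
  cfg <- small_cfg(detection_prob = 0)
  pop <- simulate_population(cfg)
  tab <- simulate_sightings(pop$roster, pop$truth, cfg)
  expect_equal(nrow(tab), 0L)
})

test_that("sightings respect residency schedules, windows and musth truth", {
  cfg <- sim_config(study_days = 1095L, n_communities = 2L,
                    community_sizes = c(4L, 3L), n_males = 12L,
                    detection_prob = 0.5, seed = 21L)
  pop <- simulate_population(cfg)
  tab <- simulate_sightings(pop$roster, pop$truth, cfg)
  expect_true(all(tab$date >= cfg$study_start))
  expect_true(all(tab$date < cfg$study_start + cfg$study_days))
  # nobody is sighted on a day their schedule marks absent
  day_idx <- as.integer(tab$date - cfg$study_start) + 1L
  present <- pop$truth$presence[cbind(match(tab$individual_id,
                                            rownames(pop$truth$presence)),
                                      day_idx)]
  expect_true(all(present))
  # musth-only males are sighted only inside their musth windows, in musth
  m_only <- names(pop$truth$strategy)[pop$truth$strategy == "musth_only"]
  for (id in m_only) {
    rec <- tab[tab$individual_id == id, ]
    if (!nrow(rec)) next
    expect_true(all(rec$state == "musth"))
    w <- pop$truth$musth_windows[pop$truth$musth_windows$individual_id == id, ]
    d <- as.integer(rec$date - cfg$study_start) + 1L
    inside <- vapply(d, function(dd) any(dd >= w$start_day & dd <= w$end_day),
                     logical(1))
    expect_true(all(inside))
  }
  # musth stage recorded iff state is musth (table invariant, by construction)
  expect_true(all((tab$state == "musth") == (tab$musth_stage != "none")))
})

test_that("residency mixing rho controls schedule sharing within communities", {
  sched_cor <- function(rho, seed) {
    cfg <- sim_config(study_days = 730L, n_communities = 2L,
                      community_sizes = c(3L, 3L), n_males = 0L,
                      residency_mixing_rho = rho, seed = seed)
    pop <- simulate_population(cfg)
    p <- pop$truth$presence * 1
    cm <- pop$truth$community
    cc <- suppressWarnings(stats::cor(t(p)))
    pairs <- which(upper.tri(cc), arr.ind = TRUE)
    same <- cm[pairs[, 1]] == cm[pairs[, 2]]
    c(within = mean(cc[pairs][same], na.rm = TRUE),
      between = mean(cc[pairs][!same], na.rm = TRUE))
  }
  res1 <- vapply(1:10, function(s) sched_cor(1, s), numeric(2))
  res0 <- vapply(1:10, function(s) sched_cor(0, s), numeric(2))
  expect_true(all(res1["within", ] > 0.999))
  expect_lt(abs(mean(res0["within", ])), 0.15)
  expect_lt(abs(mean(res0["within", ]) - mean(res0["between", ])), 0.15)
})

test_that("ground truth serialises to a JSON sidecar", {
  pop <- simulate_population(small_cfg())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(pop$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$seed, 7L)
  expect_equal(length(back$community), 5L)
})
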