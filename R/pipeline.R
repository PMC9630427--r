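# End-to-end orchestration: male and female analyses and a combined,
# reproducible report.

#' Male protected-area-use analysis
#'
#' Runs the full male pipeline on a sighting table: per-male BSI summaries
#' and strategy labels, the strategy-by-years-seen tabulation, male-week
#' scoring with per-strategy totals, the exact binomial comparison of the
#' musth male-week proportion in the putative-resident subset against the
#' whole male population, the strategy x age cross-tabulation with an
#' independence test, and musth-bout durations by age class.
#'
#' @param table a [sighting_table()].
#' @param resident_cutoff days; BSI threshold for the residency flag
#'   (default 90).
#' @param week_origin first day of week 1 for male-week scoring (default:
#'   study window start).
#' @param n_mc Monte-Carlo draws for the independence test when the
#'   cross-tabulation exceeds 2 x 2.
#' @param seed integer seed for the independence test.
#' @return list of class `male_report`: `metrics` (per-male data.frame
#'   with strategy and residency), `strategy_years`
#'   ([tabulate_strategy_by_years()]), `male_weeks`
#'   ([male_week_scores()]), `resident_binomial` (list: counts,
#'   proportions, p-value; p `NA` when there are no musth male-weeks),
#'   `strategy_by_age` (counts + test), `musth_durations` (per complete
#'   bout, with age class; plus per-class medians).
#' @export
run_male_analysis <- function(table, resident_cutoff = 90,
                              week_origin = NULL, n_mc = 9999, seed = 1L) {
  males <- sort(unique(table$individual_id[table$sex == "M" &
                                             table$age_class != "subadult"]))
  if (!length(males)) stop("no mature males in the table", call. = FALSE)
  win <- study_window(table)

  metrics <- bsi_table(table, males)
  metrics$resident <- vapply(males, function(id) {
    residency_flag(compute_bsi(table[table$individual_id == id, ,
                                     drop = FALSE],
                               study_start = win[1]),
                   cutoff = resident_cutoff)
  }, logical(1))
  metrics$strategy <- vapply(males, function(id) {
    classify_strategy(table[table$individual_id == id, , drop = FALSE])
  }, character(1))

  labels <- stats::setNames(metrics$strategy, metrics$individual_id)
  years <- stats::setNames(metrics$n_years_seen, metrics$individual_id)
  strategy_years <- tabulate_strategy_by_years(labels, years)

  mw <- male_week_scores(table, males, week_origin = week_origin)
  total_weeks <- sum(mw$scores >= 1L)
  total_musth <- sum(mw$scores == 2L)

  residents <- metrics$individual_id[metrics$resident]
  res_scores <- mw$scores[residents, , drop = FALSE]
  res_weeks <- sum(res_scores >= 1L)
  res_musth <- sum(res_scores == 2L)
  resident_binomial <- list(
    n_residents = length(residents),
    population_weeks = total_weeks, population_musth = total_musth,
    population_musth_prop = if (total_weeks) total_musth / total_weeks
                            else NA_real_,
    resident_weeks = res_weeks, resident_musth = res_musth,
    resident_musth_prop = if (res_weeks) res_musth / res_weeks else NA_real_,
    p_value = if (total_musth > 0 && res_weeks > 0) {
      exact_binomial_test(res_musth, res_weeks, total_musth / total_weeks)
    } else NA_real_)

  age_tab <- unclass(base::table(
    factor(metrics$age_class, levels = MALE_AGE_LEVELS),
    factor(metrics$strategy, levels = STRATEGY_LEVELS)))
  nonzero <- age_tab[rowSums(age_tab) > 0, colSums(age_tab) > 0,
                     drop = FALSE]
  age_test <- if (nrow(nonzero) >= 2 && ncol(nonzero) >= 2) {
    contingency_independence_test(nonzero, n_mc = n_mc, seed = seed)
  } else NULL

  bouts <- do.call(rbind, lapply(males, function(id) {
    musth_bouts(table[table$individual_id == id, , drop = FALSE])
  }))
  complete_bouts <- bouts[bouts$complete, , drop = FALSE]
  if (nrow(complete_bouts)) {
    complete_bouts$age_class <- metrics$age_class[
      match(complete_bouts$individual_id, metrics$individual_id)]
    medians <- tapply(complete_bouts$duration, complete_bouts$age_class,
                      stats::median)
  } else {
    medians <- numeric(0)
  }

  structure(list(metrics = metrics,
                 strategy_years = strategy_years,
                 male_weeks = mw,
                 resident_binomial = resident_binomial,
                 strategy_by_age = list(counts = age_tab, test = age_test),
                 musth_durations = list(bouts = complete_bouts,
                                        median_by_age = medians)),
            class = "male_report")
}

#' Female protected-area-use and social-network analysis
#'
#' Runs the full female pipeline: restrict to adult females seen in both
#' of the first two study years (minus known deaths); build a
#' group-by-individual matrix and SRI network per study year; detect
#' Louvain communities in years 1 and 2 and link them by reciprocal
#' majority into persistent communities; compute yearly mean-BSI vectors;
#' and regress pairwise BSI correlation on pairwise SRI (association,
#' pooled over the study) controlling for centroid Euclidean distance via
#' MRQAP.
#'
#' @param table a [sighting_table()].
#' @param known_deaths individual IDs excluded as known mortalities.
#' @param n_perm MRQAP permutations.
#' @param seed integer seed (community detection and MRQAP substreams are
#'   derived from it).
#' @param min_overlap minimum shared defined years for a BSI correlation
#'   dyad.
#' @param sampling_unit sampling unit for the SRI (see [sri_matrix()]).
#' @return list of class `female_report`: `females`, `partitions` (years 1
#'   and 2), `community_map`, `community_summary`, `yearly_bsi`,
#'   `matrices` (the three dyadic matrices), `mrqap`.
#' @export
run_female_analysis <- function(table, known_deaths = character(),
                                n_perm = 999, seed = 1L, min_overlap = 3,
                                sampling_unit = c("group", "day")) {
  sampling_unit <- match.arg(sampling_unit)
  females <- filter_females_first_two_years(table, known_deaths)
  if (length(females) < 2) {
    stop("fewer than 2 qualifying females", call. = FALSE)
  }
  win <- study_window(table)
  ftab <- table[table$individual_id %in% females, , drop = FALSE]
  yrs <- study_year(ftab$date, win[1])

  year_partition <- function(y) {
    sub <- ftab[yrs == y, , drop = FALSE]
    gbi <- build_gbi(sub, females)
    assoc <- sri_matrix(gbi, sampling_unit = sampling_unit, period = y)
    detect_communities(assoc, seed = substream_seed(seed, 100L + y))
  }
  p1 <- year_partition(1L)
  p2 <- year_partition(2L)
  cmap <- match_communities(p1, p2)

  ybsi <- yearly_bsi_matrix(table, females)
  years_seen <- stats::setNames(
    vapply(females, function(id) {
      length(unique(study_year(
        ftab$date[ftab$individual_id == id], win[1])))
    }, integer(1)), females)
  csum <- community_summary(cmap$assignment, years_seen)

  gbi_all <- build_gbi(ftab, females)
  assoc_all <- sri_matrix(gbi_all, sampling_unit = sampling_unit,
                          period = "all")
  dep <- bsi_correlation_matrix(ybsi, min_overlap = min_overlap)
  dist_m <- centroid_distance_matrix(ftab, females)
  fit <- mrqap(dep,
               list(association = assoc_all$sri, distance = dist_m),
               n_perm = n_perm, seed = substream_seed(seed, 999L))

  structure(list(females = females,
                 partitions = list(year1 = p1, year2 = p2),
                 community_map = cmap,
                 community_summary = csum,
                 yearly_bsi = ybsi,
                 matrices = list(bsi_correlation = dep,
                                 association = assoc_all$sri,
                                 distance = dist_m),
                 mrqap = fit),
            class = "female_report")
}

#' Combined analysis report
#'
#' Runs both the male and the female pipelines and assembles the headline
#' numbers into one list that regenerates bit-identically from
#' `(table, arguments, seed)`; optionally serialised to JSON.
#'
#' @param table a [sighting_table()].
#' @param known_deaths passed to [run_female_analysis()].
#' @param n_perm MRQAP permutations.
#' @param seed integer seed.
#' @param path optional path: when given, the summary is written there as
#'   JSON.
#' @return list with `male`, `female` (the two section objects) and
#'   `summary` (plain numbers: strategy counts and percentages, male-week
#'   totals, binomial p, community sizes, MRQAP coefficients and
#'   p-values).
#' @export
run_report <- function(table, known_deaths = character(), n_perm = 999,
                       seed = 1L, path = NULL) {
  male <- run_male_analysis(table, seed = substream_seed(seed, 1L))
  female <- run_female_analysis(table, known_deaths = known_deaths,
                                n_perm = n_perm,
                                seed = substream_seed(seed, 2L))
  strat_n <- male$strategy_years$n
  summary <- list(
    n_males = sum(strat_n),
    strategy_counts = as.list(strat_n),
    strategy_pct = as.list(100 * strat_n / sum(strat_n)),
    male_weeks_seen = sum(male$male_weeks$scores >= 1L),
    musth_male_weeks = sum(male$male_weeks$scores == 2L),
    resident_binomial_p = male$resident_binomial$p_value,
    n_females = length(female$females),
    community_sizes = female$community_summary$communities$size,
    mrqap_coefficients = as.list(female$mrqap$coefficients),
    mrqap_p_values = as.list(female$mrqap$p_values),
    mrqap_adj_r_squared = female$mrqap$adj_r_squared,
    seed = seed)
  if (!is.null(path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  list(male = male, female = female, summary = summary)
}
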