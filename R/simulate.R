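# Synthetic fission-fusion sighting simulator.
#
# Generates individual-ID sighting tables with the statistical structure the
# downstream analysis assumes: community-structured female grouping with
# fission-fusion, seasonal residency bouts in and out of the observation
# area, male musth cycles with age-dependent duration, and imperfect per-day
# detection. Ground truth (communities, strategies, musth windows, activity
# centroids, residency schedules) is retained for parameter-recovery tests.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_population()] /
#' [simulate_sightings()]. Defaults describe a population of the kind the
#' package targets: 16 female social communities of 2-22 members (130
#' adult females), 216 mature males across four age classes, a 9-year
#' study window, exponential residency bouts, annual musth windows whose
#' mean duration lengthens with age, and imperfect daily detection.
#'
#' @param study_start first observable date (ISO-8601 string or Date).
#' @param study_days length of the study window in days (>= 730; the
#'   analysis requires at least two study years).
#' @param n_communities number of female social communities.
#' @param community_sizes integer vector (length `n_communities`, each
#'   >= 2) of community sizes.
#' @param n_males number of mature males.
#' @param male_age_class_probs probabilities over age classes
#'   `21-30, 31-40, 41-50, 51-60`.
#' @param residency_mean_in,residency_mean_out mean length (days) of the
#'   alternating exponential in-area / out-of-area residency bouts.
#' @param residency_mixing_rho fraction in `[0, 1]` of a female's
#'   residency schedule copied day-by-day from her community's shared
#'   schedule (vs drawn from her own independent schedule). 1 = the whole
#'   community moves as one; 0 = schedules independent.
#' @param detection_prob per-individual, per-day probability of being
#'   detected given present.
#' @param grouping_concentration positive concentration of the
#'   Chinese-restaurant random partition splitting a community-day into
#'   groups; -> 0 means the community is always one group.
#' @param musth_duration_means named numeric vector, mean musth duration
#'   (days) per male age class.
#' @param musth_annual logical; one musth window per year per male (TRUE)
#'   or a single window in one random year (FALSE).
#' @param strategy_probs probabilities over the male strategies
#'   `foraging_only`, `musth_only`, `foraging_and_musth`, governing whether
#'   a male's in-area presence occurs in the foraging state, the musth
#'   state, or both.
#' @param centroid_sd spatial scatter (metres) of individual activity
#'   centres around their community centre, and of sighting locations
#'   around group centroids.
#' @param seed base integer seed; all randomness flows from it through
#'   counter-based substreams per individual, so adding individuals does
#'   not perturb earlier ones.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(study_start = "2007-01-01",
                       study_days = 3287L,
                       n_communities = 16L,
                       community_sizes = c(22L, 16L, 13L, 11L, 10L, 9L, 8L,
                                           8L, 7L, 6L, 5L, 4L, 4L, 3L, 2L, 2L),
                       n_males = 216L,
                       male_age_class_probs = c(`21-30` = 0.44, `31-40` = 0.36,
                                                `41-50` = 0.19, `51-60` = 0.01),
                       residency_mean_in = 30,
                       residency_mean_out = 90,
                       residency_mixing_rho = 0.8,
                       detection_prob = 0.35,
                       grouping_concentration = 1,
                       musth_duration_means = c(`21-30` = 25, `31-40` = 33,
                                                `41-50` = 45, `51-60` = 45),
                       musth_annual = TRUE,
                       strategy_probs = c(foraging_only = 0.458,
                                          musth_only = 0.107,
                                          foraging_and_musth = 0.435),
                       centroid_sd = 2000,
                       seed = 1L) {
  cfg <- list(study_start = as.Date(study_start),
              study_days = as.integer(study_days),
              n_communities = as.integer(n_communities),
              community_sizes = as.integer(community_sizes),
              n_males = as.integer(n_males),
              male_age_class_probs = male_age_class_probs,
              residency_mean_in = residency_mean_in,
              residency_mean_out = residency_mean_out,
              residency_mixing_rho = residency_mixing_rho,
              detection_prob = detection_prob,
              grouping_concentration = grouping_concentration,
              musth_duration_means = musth_duration_means,
              musth_annual = isTRUE(musth_annual),
              strategy_probs = strategy_probs,
              centroid_sd = centroid_sd,
              seed = as.integer(seed))

  if (cfg$study_days < 730L) {
    stop("invalid configuration: 'study_days' must be >= 730 (two study years)",
         call. = FALSE)
  }
  if (length(cfg$community_sizes) != cfg$n_communities) {
    stop("invalid configuration: 'community_sizes' must have length 'n_communities'",
         call. = FALSE)
  }
  if (any(cfg$community_sizes < 2L)) {
    stop("invalid configuration: each entry of 'community_sizes' must be >= 2",
         call. = FALSE)
  }
  assert_prob(cfg$male_age_class_probs, "male_age_class_probs")
  assert_prob(cfg$strategy_probs, "strategy_probs")
  assert_prob(cfg$residency_mixing_rho, "residency_mixing_rho")
  assert_prob(cfg$detection_prob, "detection_prob")
  if (abs(sum(cfg$male_age_class_probs) - 1) > 1e-6) {
    stop("invalid configuration: 'male_age_class_probs' must sum to 1",
         call. = FALSE)
  }
  if (abs(sum(cfg$strategy_probs) - 1) > 1e-6) {
    stop("invalid configuration: 'strategy_probs' must sum to 1", call. = FALSE)
  }
  if (length(cfg$male_age_class_probs) != 4L) {
    stop("invalid configuration: 'male_age_class_probs' needs 4 entries",
         call. = FALSE)
  }
  if (!all(MALE_AGE_LEVELS %in% names(cfg$musth_duration_means))) {
    stop("invalid configuration: 'musth_duration_means' must name all male age classes",
         call. = FALSE)
  }
  if (cfg$grouping_concentration < 0) {
    stop("invalid configuration: 'grouping_concentration' must be >= 0",
         call. = FALSE)
  }
  if (cfg$residency_mean_in <= 0 || cfg$residency_mean_out <= 0) {
    stop("invalid configuration: residency bout means must be positive",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Flat key-value YAML; any key omitted falls back to the [sim_config()]
#' default.
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

# Alternating exponential in/out residency bouts; starts "in" with the
# stationary probability of the two-state renewal process.
gen_schedule <- function(days, mean_in, mean_out) {
  state <- stats::runif(1) < mean_in / (mean_in + mean_out)
  out <- logical(days)
  t <- 0L
  while (t < days) {
    len <- max(1L, as.integer(ceiling(
      stats::rexp(1, rate = 1 / (if (state) mean_in else mean_out)))))
    out[(t + 1L):min(days, t + len)] <- state
    t <- t + len
    state <- !state
  }
  out
}

# Chinese-restaurant random partition of n items; alpha -> 0 gives a single
# group. Returns integer group labels.
crp_partition <- function(n, alpha) {
  labels <- integer(n)
  labels[1L] <- 1L
  k <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      counts <- tabulate(labels[1:(i - 1L)], k)
      g <- sample.int(k + 1L, 1L, prob = c(counts, alpha))
      if (g == k + 1L) k <- k + 1L
      labels[i] <- g
    }
  }
  labels
}

# Musth window draws for one male: start uniform within each year, duration
# gamma-distributed (shape 6) around the age-class mean, >= 3 days.
gen_musth_windows <- function(age_class, config) {
  n_years <- as.integer(ceiling(config$study_days / 365))
  years <- if (config$musth_annual) seq_len(n_years) else
    sample.int(n_years, 1L)
  m <- config$musth_duration_means[[age_class]]
  starts <- integer(0); ends <- integer(0)
  for (y in years) {
    s <- (y - 1L) * 365L + sample.int(365L, 1L)
    if (s > config$study_days) next
    d <- max(3L, as.integer(round(stats::rgamma(1, shape = 6, scale = m / 6))))
    starts <- c(starts, s)
    ends <- c(ends, min(config$study_days, s + d - 1L))
  }
  data.frame(start_day = starts, end_day = ends)
}

#' Simulate a study population with ground truth
#'
#' Draws the roster (females in communities, males with age class and
#' strategy, activity centroids) and the latent structure the sighting
#' process runs on: per-individual residency schedules (community-shared
#' vs independent, mixed day-by-day by `residency_mixing_rho`), and
#' per-male musth windows. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `roster` (data.frame: `individual_id`, `sex`,
#'   `age_class`, `community`, `strategy`, `centroid_x`, `centroid_y`) and
#'   `truth` (list: `community`, `strategy`, `centroids`, `musth_windows`
#'   data.frame, `presence` logical individuals x days matrix, `config`).
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config", call. = FALSE)
  }
  days <- config$study_days
  n_f <- sum(config$community_sizes)
  female_ids <- sprintf("F%03d", seq_len(n_f))
  male_ids <- sprintf("M%03d", seq_len(config$n_males))
  community <- rep(seq_len(config$n_communities), config$community_sizes)
  names(community) <- female_ids

  # community centres and shared schedules, one substream per community
  centers <- matrix(NA_real_, config$n_communities, 2)
  shared <- matrix(FALSE, config$n_communities, days)
  for (c in seq_len(config$n_communities)) {
    with_seed(substream_seed(config$seed, 3000L + c), {
      centers[c, ] <- stats::runif(2, 0, 20000)
      shared[c, ] <- gen_schedule(days, config$residency_mean_in,
                                  config$residency_mean_out)
    })
  }

  ids <- c(female_ids, male_ids)
  n_all <- length(ids)
  presence <- matrix(FALSE, n_all, days, dimnames = list(ids, NULL))
  centroids <- matrix(NA_real_, n_all, 2, dimnames = list(ids, c("x", "y")))
  age_class <- character(n_all)
  strategy <- rep(NA_character_, n_all)
  windows <- vector("list", config$n_males)

  adult_classes <- MALE_AGE_LEVELS
  for (i in seq_len(n_f)) {
    with_seed(substream_seed(config$seed, 10000L + i), {
      age_class[i] <- sample(adult_classes, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
      centroids[i, ] <- centers[community[i], ] +
        stats::rnorm(2, 0, config$centroid_sd)
      own <- gen_schedule(days, config$residency_mean_in,
                          config$residency_mean_out)
      use_shared <- stats::runif(days) < config$residency_mixing_rho
      presence[i, ] <- ifelse(use_shared, shared[community[i], ], own)
    })
  }

  for (j in seq_len(config$n_males)) {
    i <- n_f + j
    with_seed(substream_seed(config$seed, 500000L + j), {
      age_class[i] <- sample(adult_classes, 1L,
                             prob = config$male_age_class_probs)
      strategy[i] <- sample(STRATEGY_LEVELS, 1L, prob = config$strategy_probs)
      centroids[i, ] <- stats::runif(2, 0, 20000)
      sched <- gen_schedule(days, config$residency_mean_in,
                            config$residency_mean_out)
      w <- gen_musth_windows(age_class[i], config)
      in_musth <- logical(days)
      for (r in seq_len(nrow(w))) {
        in_musth[w$start_day[r]:w$end_day[r]] <- TRUE
      }
      presence[i, ] <- switch(strategy[i],
        foraging_only      = sched & !in_musth,
        musth_only         = in_musth,
        foraging_and_musth = sched | in_musth)
      windows[[j]] <- if (nrow(w)) cbind(individual_id = male_ids[j], w)
    })
  }

  musth_windows <- do.call(rbind, windows[!vapply(windows, is.null, TRUE)])
  if (is.null(musth_windows)) {
    musth_windows <- data.frame(individual_id = character(),
                                start_day = integer(), end_day = integer())
  }
  rownames(musth_windows) <- NULL

  roster <- data.frame(
    individual_id = ids,
    sex = c(rep("F", n_f), rep("M", config$n_males)),
    age_class = age_class,
    community = c(unname(community), rep(NA_integer_, config$n_males)),
    strategy = strategy,
    centroid_x = centroids[, "x"],
    centroid_y = centroids[, "y"],
    stringsAsFactors = FALSE)
  rownames(roster) <- NULL

  truth <- list(community = community,
                strategy = stats::setNames(strategy[-seq_len(n_f)], male_ids),
                centroids = centroids,
                musth_windows = musth_windows,
                presence = presence,
                config = config)
  list(roster = roster, truth = truth)
}

musth_stage_of <- function(day, start, end) {
  len <- end - start + 1L
  pos <- day - start
  ifelse(pos < len / 3, "early", ifelse(pos < 2 * len / 3, "peak", "late"))
}

#' Simulate the daily sighting process
#'
#' Runs the observation model over the simulated population: on each day,
#' community members whose residency schedule marks them present are
#' partitioned into groups by a Chinese-restaurant process; each present
#' individual is independently detected with `detection_prob`; detected
#' members of a group form one group sighting located at the mean of their
#' activity centroids plus isotropic Gaussian noise. Males are sighted
#' solitarily; a male inside one of his musth windows carries
#' `state = "musth"` with stage early/peak/late by thirds of the window.
#'
#' @param roster,truth output of [simulate_population()].
#' @param config the same [sim_config()].
#' @return a [sighting_table()] spanning the configured study window.
#' @export
simulate_sightings <- function(roster, truth, config) {
  days <- config$study_days
  ids <- roster$individual_id
  n_all <- length(ids)
  presence <- truth$presence

  detect <- matrix(FALSE, n_all, days, dimnames = list(ids, NULL))
  for (i in seq_len(n_all)) {
    with_seed(substream_seed(config$seed, 2000000L + i), {
      detect[i, ] <- stats::runif(days) < config$detection_prob
    })
  }
  seen <- presence & detect

  acc_id <- list(); acc_grp <- list(); acc_day <- list()
  acc_x <- list(); acc_y <- list(); k <- 0L

  # females: community-day partitions
  female_ids <- ids[roster$sex == "F"]
  for (c in seq_len(config$n_communities)) {
    members <- female_ids[truth$community[female_ids] == c]
    sub <- seen[members, , drop = FALSE]
    for (day in which(colSums(sub) > 0L)) {
      present <- members[sub[, day]]
      with_seed(substream_seed(config$seed, 4000000L + c * 10000L + day), {
        labels <- crp_partition(length(present), config$grouping_concentration)
        for (g in unique(labels)) {
          grp <- present[labels == g]
          ctr <- colMeans(truth$centroids[grp, , drop = FALSE]) +
            stats::rnorm(2, 0, config$centroid_sd)
          k <- k + 1L
          acc_id[[k]] <- grp
          acc_grp[[k]] <- rep(sprintf("d%04d_c%02d_g%02d", day, c, g),
                              length(grp))
          acc_day[[k]] <- rep(day, length(grp))
          acc_x[[k]] <- rep(ctr[1], length(grp))
          acc_y[[k]] <- rep(ctr[2], length(grp))
        }
      })
    }
  }

  # males: solitary sightings
  male_rows <- which(roster$sex == "M")
  state_m <- character(0); stage_m <- character(0)
  for (j in seq_along(male_rows)) {
    i <- male_rows[j]
    id <- ids[i]
    sdays <- which(seen[i, ])
    if (!length(sdays)) next
    w <- truth$musth_windows[truth$musth_windows$individual_id == id, ,
                             drop = FALSE]
    in_musth <- rep(FALSE, length(sdays))
    stage <- rep("none", length(sdays))
    for (r in seq_len(nrow(w))) {
      hit <- sdays >= w$start_day[r] & sdays <= w$end_day[r]
      in_musth[hit] <- TRUE
      stage[hit] <- musth_stage_of(sdays[hit], w$start_day[r], w$end_day[r])
    }
    noise <- with_seed(substream_seed(config$seed, 6000000L + j),
                       matrix(stats::rnorm(2 * length(sdays), 0,
                                           config$centroid_sd), ncol = 2))
    k <- k + 1L
    acc_id[[k]] <- rep(id, length(sdays))
    acc_grp[[k]] <- sprintf("d%04d_%s", sdays, id)
    acc_day[[k]] <- sdays
    acc_x[[k]] <- truth$centroids[id, "x"] + noise[, 1]
    acc_y[[k]] <- truth$centroids[id, "y"] + noise[, 2]
    state_m <- c(state_m, ifelse(in_musth, "musth", "foraging"))
    stage_m <- c(stage_m, stage)
  }

  out_id <- unlist(acc_id) %||% character(0)
  n_female_rows <- length(out_id) - length(state_m)
  records <- data.frame(
    date = config$study_start + (unlist(acc_day) %||% integer(0)) - 1L,
    x = unlist(acc_x) %||% numeric(0),
    y = unlist(acc_y) %||% numeric(0),
    group_id = unlist(acc_grp) %||% character(0),
    individual_id = out_id,
    stringsAsFactors = FALSE)
  idx <- match(records$individual_id, ids)
  records$sex <- roster$sex[idx]
  records$age_class <- roster$age_class[idx]
  records$state <- c(rep("foraging", n_female_rows), state_m)
  records$musth_stage <- c(rep("none", n_female_rows), stage_m)

  sighting_table(records,
                 study_start = config$study_start,
                 study_end = config$study_start + days - 1L)
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth ground-truth list from [simulate_population()].
#' @param path output JSON file. The (large) day-by-day presence matrix is
#'   summarised as per-individual presence-day counts.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    seed = truth$config$seed,
    community = as.list(truth$community),
    strategy = as.list(truth$strategy),
    centroids = as.data.frame(truth$centroids),
    musth_windows = truth$musth_windows,
    presence_days = as.list(rowSums(truth$presence)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
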