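# Protected-area-use metrics: between-sightings interval (BSI), male
# strategy classification, male-week scoring, musth bouts, residency.

#' Between-sightings interval (BSI) summary for one individual
#'
#' The BSI is the number of days elapsed between consecutive sightings of
#' an individual; its mean, taken over the span from first to last
#' sighting, proxies how continuously the individual uses the observation
#' area. Multiple sightings on one day collapse to a single date (the BSI
#' is defined in days elapsed), so on distinct-day sequences the mean BSI
#' equals `(last - first) / (n_distinct_days - 1)`. With fewer than two
#' distinct sighting days the mean is undefined and reported as `NA`,
#' never zero.
#'
#' Yearly means use within-year gaps only (both endpoints of a gap in the
#' same study year) and are `NA` for years with fewer than two distinct
#' sighting days.
#'
#' @param records sighting rows for a single individual (a subset of a
#'   [sighting_table()], or any data.frame with `individual_id` and
#'   `date`).
#' @param study_start start of the study window used to index study years;
#'   defaults to the records' `study_start` attribute or first date.
#' @param year_basis `"study"` (365-day years; default) or `"calendar"`.
#' @return object of class `bsi_summary`: list with `individual_id`,
#'   `n_sightings` (records), `n_days` (distinct days), `mean_bsi` (days,
#'   `NA` if undefined), `first_date`, `last_date`, `years_seen` (integer
#'   vector) and `yearly_mean_bsi` (named numeric per year seen).
#' @examples
#' rec <- data.frame(individual_id = "A",
#'                   date = as.Date("2010-01-01") + c(0, 10, 30))
#' compute_bsi(rec)$mean_bsi  # 15
#' @export
compute_bsi <- function(records, study_start = NULL,
                        year_basis = c("study", "calendar")) {
  year_basis <- match.arg(year_basis)
  id <- unique(records$individual_id)
  if (length(id) > 1) {
    stop("records mix individual IDs: ", paste(id, collapse = ", "),
         call. = FALSE)
  }
  if (!length(id)) id <- NA_character_
  study_start <- as.Date(study_start %||% attr(records, "study_start") %||%
                           suppressWarnings(min(records$date)))
  d <- sort(unique(as.Date(records$date)))
  n_days <- length(d)
  mean_bsi <- if (n_days >= 2) {
    as.numeric(d[n_days] - d[1]) / (n_days - 1)
  } else NA_real_

  yrs <- study_year(d, study_start, year_basis)
  years_seen <- sort(unique(yrs))
  yearly <- vapply(years_seen, function(y) {
    dy <- d[yrs == y]
    if (length(dy) >= 2) mean(as.numeric(diff(dy))) else NA_real_
  }, numeric(1))
  names(yearly) <- years_seen

  structure(list(individual_id = id,
                 n_sightings = nrow(records),
                 n_days = n_days,
                 mean_bsi = mean_bsi,
                 first_date = if (n_days) d[1] else as.Date(NA),
                 last_date = if (n_days) d[n_days] else as.Date(NA),
                 years_seen = years_seen,
                 yearly_mean_bsi = yearly),
            class = "bsi_summary")
}

#' @export
print.bsi_summary <- function(x, ...) {
  cat(sprintf("BSI summary for %s: %d sightings on %d days, mean BSI %s d, years %s\n",
              x$individual_id, x$n_sightings, x$n_days,
              ifelse(is.na(x$mean_bsi), "undefined",
                     format(round(x$mean_bsi, 1))),
              paste(x$years_seen, collapse = ",")))
  invisible(x)
}

#' BSI summaries for every individual in a table
#'
#' @param table a [sighting_table()].
#' @param ids individuals to summarise (default: all in the table).
#' @inheritParams compute_bsi
#' @return data.frame with one row per individual: `individual_id`, `sex`,
#'   `age_class`, `n_sightings`, `n_days`, `mean_bsi`, `first_date`,
#'   `last_date`, `n_years_seen`, `resident` ([residency_flag()] at the
#'   default 90-day cutoff).
#' @export
bsi_table <- function(table, ids = NULL, year_basis = c("study", "calendar")) {
  year_basis <- match.arg(year_basis)
  ids <- ids %||% unique(table$individual_id)
  start <- attr(table, "study_start")
  rows <- lapply(ids, function(id) {
    rec <- table[table$individual_id == id, , drop = FALSE]
    s <- compute_bsi(rec, study_start = start, year_basis = year_basis)
    data.frame(individual_id = id,
               sex = rec$sex[1], age_class = rec$age_class[1],
               n_sightings = s$n_sightings, n_days = s$n_days,
               mean_bsi = s$mean_bsi,
               first_date = s$first_date, last_date = s$last_date,
               n_years_seen = length(s$years_seen),
               resident = residency_flag(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Yearly mean-BSI matrix
#'
#' @param table a [sighting_table()].
#' @param ids individuals (rows).
#' @inheritParams compute_bsi
#' @return numeric matrix individuals x study years; `NA` where a year has
#'   fewer than two distinct sighting days for that individual.
#' @export
yearly_bsi_matrix <- function(table, ids = NULL,
                              year_basis = c("study", "calendar")) {
  year_basis <- match.arg(year_basis)
  ids <- ids %||% unique(table$individual_id)
  win <- study_window(table)
  n_years <- max(study_year(win[2], win[1], year_basis), 1L)
  m <- matrix(NA_real_, length(ids), n_years,
              dimnames = list(ids, seq_len(n_years)))
  for (id in ids) {
    s <- compute_bsi(table[table$individual_id == id, , drop = FALSE],
                     study_start = win[1], year_basis = year_basis)
    ok <- s$years_seen >= 1 & s$years_seen <= n_years
    m[id, s$years_seen[ok]] <- s$yearly_mean_bsi[ok]
  }
  m
}

#' Classify a mature male's area-use strategy
#'
#' `foraging_only` (f) if never seen showing musth, `musth_only` (m) if
#' every sighting was in musth, `foraging_and_musth` (f+m) if seen in both
#' states at any time during the study. Invariant to record order.
#'
#' @param records sighting rows for one male (>= 1 row).
#' @return one of `"foraging_only"`, `"musth_only"`, `"foraging_and_musth"`.
#' @export
classify_strategy <- function(records) {
  if (!nrow(records)) {
    stop("cannot classify a male with zero sightings", call. = FALSE)
  }
  musth <- records$state == "musth"
  if (!any(musth)) "foraging_only"
  else if (all(musth)) "musth_only"
  else "foraging_and_musth"
}

#' Score male-weeks
#'
#' Aggregates each male's sightings into consecutive 7-day bins from
#' `week_origin` and scores each male-week 0 if unseen, 1 if seen only
#' foraging, 2 if seen in musth at any time during the week. Also returns
#' per-strategy totals of male-weeks seen (score >= 1) and musth
#' male-weeks (score = 2); the two foraging/musth counts partition the
#' total seen.
#'
#' @param table a [sighting_table()].
#' @param males IDs of the males to score (default: all males in the
#'   table).
#' @param week_origin first day of week 1 (default: study window start);
#'   must not postdate the first sighting.
#' @return object of class `male_week_matrix`: list with `scores` (integer
#'   matrix males x weeks), `totals` (data.frame per strategy:
#'   `male_weeks_seen`, `musth_weeks`, `foraging_weeks`), `week_origin`.
#' @export
male_week_scores <- function(table, males = NULL, week_origin = NULL) {
  males <- males %||% unique(table$individual_id[table$sex == "M"])
  win <- study_window(table)
  week_origin <- as.Date(week_origin %||% win[1])
  tab <- table[table$individual_id %in% males, , drop = FALSE]
  if (nrow(tab) && min(tab$date) < week_origin) {
    stop("'week_origin' must not postdate the first sighting", call. = FALSE)
  }
  n_weeks <- max(1L, as.integer(ceiling(
    (as.numeric(win[2] - week_origin) + 1) / 7)))
  scores <- matrix(0L, length(males), n_weeks,
                   dimnames = list(males, seq_len(n_weeks)))
  if (nrow(tab)) {
    wk <- as.integer(floor(as.numeric(tab$date - week_origin) / 7)) + 1L
    ridx <- match(tab$individual_id, males)
    val <- ifelse(tab$state == "musth", 2L, 1L)
    # musth dominates within a week: apply foraging first, then musth
    ord <- order(val)
    scores[cbind(ridx[ord], wk[ord])] <- val[ord]
  }
  strategy <- vapply(males, function(id) {
    rec <- tab[tab$individual_id == id, , drop = FALSE]
    if (!nrow(rec)) NA_character_ else classify_strategy(rec)
  }, character(1))
  totals <- do.call(rbind, lapply(STRATEGY_LEVELS, function(s) {
    m <- scores[which(strategy == s), , drop = FALSE]
    data.frame(strategy = s,
               male_weeks_seen = sum(m >= 1L),
               musth_weeks = sum(m == 2L),
               foraging_weeks = sum(m == 1L))
  }))
  structure(list(scores = scores, totals = totals, strategy = strategy,
                 week_origin = week_origin),
            class = "male_week_matrix")
}

#' Musth bouts of one male
#'
#' Maximal runs of date-consecutive musth sightings uninterrupted by
#' non-musth sightings. Duration is days elapsed between the first and
#' last musth sighting of the run (0 for a single-sighting bout). A bout
#' is `complete` when it is bracketed by non-musth sightings on both
#' sides, i.e. the musth period was observed from beginning to end.
#'
#' @param records sighting rows for one male, sorted by date (resorted if
#'   not).
#' @return data.frame: `individual_id`, `start`, `end`, `duration` (days),
#'   `n_sightings`, `complete`.
#' @export
musth_bouts <- function(records) {
  records <- records[order(records$date), , drop = FALSE]
  id <- unique(records$individual_id)
  if (length(id) > 1) {
    stop("records mix individual IDs", call. = FALSE)
  }
  musth <- records$state == "musth"
  if (!any(musth)) {
    return(data.frame(individual_id = character(), start = as.Date(character()),
                      end = as.Date(character()), duration = numeric(),
                      n_sightings = integer(), complete = logical()))
  }
  runs <- rle(musth)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(r) {
    i0 <- starts[r]; i1 <- ends[r]
    data.frame(individual_id = id,
               start = records$date[i0], end = records$date[i1],
               duration = as.numeric(records$date[i1] - records$date[i0]),
               n_sightings = i1 - i0 + 1L,
               complete = i0 > 1L && i1 < nrow(records),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Residency flag
#'
#' A possible resident is an individual with mean BSI below `cutoff`
#' (strictly) that was seen across multiple study years. An undefined BSI
#' (single sighting day) can never evidence residency.
#'
#' @param summary a [compute_bsi()] result.
#' @param cutoff days; default 90.
#' @return logical.
#' @export
residency_flag <- function(summary, cutoff = 90) {
  if (is.na(summary$mean_bsi)) return(FALSE)
  summary$mean_bsi < cutoff && length(summary$years_seen) >= 2
}

#' Tabulate strategy by number of years seen
#'
#' Contingency table of mature males by (number of distinct study years in
#' which the male was seen) x (strategy), with within-strategy column
#' percentages summing to 100 within each strategy.
#'
#' @param labels named character vector of strategy labels (names are
#'   individual IDs).
#' @param years_seen named integer vector of distinct-years-seen counts
#'   over the same males.
#' @param max_years largest years-seen frequency to tabulate (default: the
#'   observed maximum).
#' @return object of class `strategy_years_table`: list with `counts` and
#'   `pct` matrices (rows = years-seen frequency, descending; columns =
#'   strategies) and `n` per strategy.
#' @examples
#' labels <- setNames(rep("foraging_only", 3), c("a", "b", "c"))
#' years <- setNames(c(1, 1, 6), c("a", "b", "c"))
#' tabulate_strategy_by_years(labels, years)$pct
#' @export
tabulate_strategy_by_years <- function(labels, years_seen, max_years = NULL) {
  ids <- names(labels)
  if (!setequal(ids, names(years_seen))) {
    stop("'labels' and 'years_seen' must cover the same males", call. = FALSE)
  }
  years_seen <- years_seen[ids]
  max_years <- max_years %||% max(years_seen)
  counts <- table(factor(years_seen, levels = max_years:1),
                  factor(labels, levels = STRATEGY_LEVELS))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  n <- colSums(counts)
  pct <- sweep(counts, 2, pmax(n, 1L), "/") * 100
  structure(list(counts = counts, pct = pct, n = n),
            class = "strategy_years_table")
}

#' @export
print.strategy_years_table <- function(x, digits = 1,
                                       mode = c("nearest", "trunc"), ...) {
  cat("Mature males by strategy and years seen (n =", sum(x$n), ")\n")
  shown <- matrix(sprintf("%d (%s%%)", x$counts,
                          format(round_pct(x$pct, digits, mode))),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  dimnames(shown) <- list(paste0("seen_", rownames(x$counts), "yr"),
                          colnames(x$counts))
  print(shown, quote = FALSE)
  invisible(x)
}
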