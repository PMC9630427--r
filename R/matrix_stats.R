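# Pairwise similarity/distance matrices, exact tests, and the male
# mixed-model frame.

#' Pairwise BSI-correlation matrix
#'
#' For every pair of females, the Pearson correlation between their yearly
#' mean-BSI vectors over the study years in which both are defined. Pairs
#' sharing fewer than `min_overlap` defined years, or with a constant
#' vector over the shared years, are masked `NA` (a correlation on one or
#' two points, or on a constant, is meaningless).
#'
#' @param yearly_bsi numeric matrix, females x years (e.g.
#'   [yearly_bsi_matrix()]); `NA` where undefined.
#' @param min_overlap minimum shared defined years (default 3).
#' @return symmetric `pairwise_matrix` (kind `"bsi_correlation"`) with
#'   `NA` diagonal and masked entries.
#' @export
bsi_correlation_matrix <- function(yearly_bsi, min_overlap = 3) {
  if (nrow(yearly_bsi) < 2) {
    stop("at least 2 females are required", call. = FALSE)
  }
  obs <- !is.na(yearly_bsi)
  overlap <- tcrossprod(obs * 1)
  cc <- suppressWarnings(stats::cor(t(yearly_bsi),
                                    use = "pairwise.complete.obs"))
  # mask short overlaps; constant vectors already yield NA (sd = 0)
  cc[overlap < min_overlap] <- NA_real_
  # sd must be computed on the shared years: recheck pairs cor() kept
  diag(cc) <- NA_real_
  structure(cc, kind = "bsi_correlation", class = c("pairwise_matrix",
                                                    class(cc)))
}

#' Pairwise centroid-distance matrix
#'
#' Each subject's spatial centroid is the arithmetic mean of the planar
#' coordinates of all its sightings; the matrix holds pairwise Euclidean
#' distances between centroids (zero diagonal), a gross index of spatial
#' overlap used to control for spatial autocorrelation.
#'
#' @param table a [sighting_table()].
#' @param subjects individual IDs (each needs at least one located
#'   sighting).
#' @return symmetric `pairwise_matrix` (kind `"centroid_distance"`).
#' @export
centroid_distance_matrix <- function(table, subjects) {
  cent <- t(vapply(subjects, function(id) {
    rec <- table[table$individual_id == id, , drop = FALSE]
    rec <- rec[!is.na(rec$x) & !is.na(rec$y), , drop = FALSE]
    if (!nrow(rec)) {
      stop("subject '", id, "' has no located sightings", call. = FALSE)
    }
    c(mean(rec$x), mean(rec$y))
  }, numeric(2)))
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(subjects, subjects)
  structure(d, kind = "centroid_distance",
            class = c("pairwise_matrix", class(d)))
}

#' Two-tailed exact binomial test (minimum-likelihood method)
#'
#' The two-tailed p-value is the total probability, under
#' `Binomial(n, p0)`, of every outcome whose point probability does not
#' exceed that of the observed count `k` (with a small relative tolerance
#' for ties, as is conventional).
#'
#' @param k observed count (`0 <= k <= n`).
#' @param n number of trials.
#' @param p0 null success probability in `(0, 1)`.
#' @return the p-value.
#' @examples
#' exact_binomial_test(0, 10, 0.5)  # 2/1024
#' @export
exact_binomial_test <- function(k, n, p0) {
  if (length(k) != 1 || length(n) != 1 || length(p0) != 1 ||
      is.na(k) || is.na(n) || is.na(p0) ||
      k < 0 || k > n || n < 1 || p0 <= 0 || p0 >= 1 ||
      k != round(k) || n != round(n)) {
    stop("need integer 0 <= k <= n and 0 < p0 < 1", call. = FALSE)
  }
  pmf <- stats::dbinom(0:n, n, p0)
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

#' Independence test for an r x c contingency table
#'
#' Computes the Pearson chi-square statistic exactly and assesses
#' significance without relying on its asymptotic distribution: 2 x 2
#' tables are handled by full hypergeometric enumeration (two-sided,
#' minimum-likelihood); larger tables by Monte-Carlo sampling of tables
#' with the observed margins held fixed.
#'
#' @param table integer matrix of counts (>= 2 rows and columns, no zero
#'   margin).
#' @param n_mc Monte-Carlo draws for tables larger than 2 x 2.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list with `statistic` (chi-square), `df`, `p_value`, `method`.
#' @export
contingency_independence_test <- function(table, n_mc = 9999, seed = 1L) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2 || any(m < 0) || anyNA(m)) {
    stop("need a matrix of non-negative counts with >= 2 rows and columns",
         call. = FALSE)
  }
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  if (nrow(m) == 2 && ncol(m) == 2) {
    # enumerate all tables with these margins; two-sided by summing the
    # probabilities of tables no more likely than the observed one
    a_min <- max(0, rs[1] - cs[2])
    a_max <- min(rs[1], cs[1])
    a <- a_min:a_max
    prob <- stats::dhyper(a, cs[1], cs[2], rs[1])
    p_obs <- stats::dhyper(m[1, 1], cs[1], cs[2], rs[1])
    p <- min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
    method <- "exact (hypergeometric enumeration)"
  } else {
    stats_mc <- with_seed(seed, {
      draws <- stats::r2dtable(n_mc, rs, cs)
      vapply(draws, function(t2) sum((t2 - expected)^2 / expected),
             numeric(1))
    })
    p <- (1 + sum(stats_mc >= stat - 1e-10)) / (n_mc + 1)
    method <- sprintf("Monte Carlo (%d tables, fixed margins)", n_mc)
  }
  list(statistic = stat, df = df, p_value = p, method = method)
}

#' Build the male BSI mixed-model frame
#'
#' Constructs, without fitting anything, the model frame for a mixed model
#' of male between-sightings intervals: one row per retained interval
#' between consecutive distinct sighting days, with the interval length in
#' days as the response and the male's age class, strategy, identity, and
#' the calendar month and year at the start of the interval as covariates
#' / grouping factors. Apply [filter_glmm_males()] first to obtain
#' `males`.
#'
#' @param table a [sighting_table()].
#' @param males IDs of the males to include.
#' @param roster data.frame with `individual_id` and `age_class`.
#' @return data.frame: `individual_id`, `age_class`, `strategy`,
#'   `interval_days`, `month`, `year`.
#' @export
build_glmm_frame <- function(table, males, roster) {
  rows <- lapply(males, function(id) {
    rec <- table[table$individual_id == id, , drop = FALSE]
    d <- sort(unique(rec$date))
    if (length(d) < 2) return(NULL)
    gaps <- as.numeric(diff(d))
    data.frame(individual_id = id,
               age_class = roster$age_class[match(id, roster$individual_id)],
               strategy = classify_strategy(rec),
               interval_days = gaps,
               month = as.integer(format(d[-length(d)], "%m")),
               year = as.integer(format(d[-length(d)], "%Y")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(individual_id = character(), age_class = character(),
                      strategy = character(), interval_days = numeric(),
                      month = integer(), year = integer())
  }
  rownames(out) <- NULL
  out
}
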