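# Builders for small in-code fixtures.

# One-liner sighting-table builder; vectors recycle against `dates`.
mk_table <- function(ids, dates, state = "foraging", stage = NULL,
                     sex = "M", age = "31-40", group = NULL,
                     x = 0, y = 0, study_start = NULL, study_end = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  df <- data.frame(
    date = dates,
    x = rep_len(x, n), y = rep_len(y, n),
    group_id = if (is.null(group)) sprintf("g%03d", seq_len(n))
               else rep_len(group, n),
    individual_id = rep_len(ids, n),
    sex = rep_len(sex, n),
    age_class = rep_len(age, n),
    state = rep_len(state, n),
    stringsAsFactors = FALSE)
  df$musth_stage <- if (is.null(stage)) ifelse(df$state == "musth",
                                               "peak", "none")
                    else rep_len(stage, n)
  sighting_table(df, study_start = study_start, study_end = study_end)
}

day0 <- as.Date("2010-01-01")

# random symmetric matrix with zero diagonal
rsym <- function(n, gen = stats::rnorm) {
  m <- matrix(gen(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("i%02d", seq_len(n))
  m
}

# random partition of ids into <= k groups, as a community_partition
rpartition <- function(ids, k) {
  memb <- sample.int(k, length(ids), replace = TRUE)
  memb <- as.integer(factor(memb))  # contiguous labels
  structure(list(membership = stats::setNames(memb, ids),
                 modularity = NA_real_, period = NULL),
            class = "community_partition")
}

# planted-block SRI-like weight matrix: high within, near-zero between
planted_sri <- function(block_sizes, within = 0.6, between = 0.02) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  w <- matrix(stats::runif(n * n, 0, 2 * between), n)
  same <- outer(lab, lab, "==")
  w[same] <- stats::runif(sum(same), within - 0.2, within + 0.2)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  rownames(w) <- colnames(w) <- sprintf("i%02d", seq_len(n))
  list(w = w, labels = lab)
}
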