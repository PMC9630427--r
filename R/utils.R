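# Internal helpers shared across modules.

SEX_LEVELS      <- c("F", "M")
AGE_LEVELS      <- c("subadult", "21-30", "31-40", "41-50", "51-60")
MALE_AGE_LEVELS <- AGE_LEVELS[-1]
STATE_LEVELS    <- c("foraging", "musth")
STAGE_LEVELS    <- c("none", "early", "peak", "late")
STRATEGY_LEVELS <- c("foraging_only", "musth_only", "foraging_and_musth")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it, runs `expr`, restores the state.
#' All stochastic operations in the package route through this so that a
#' user's simulation stream is never silently disturbed.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Counter-based substream seed
#'
#' Derives a deterministic 31-bit seed for stream `id` of a base seed, so
#' that each simulated individual (or community-day) owns an independent
#' stream: adding individuals never perturbs the draws of earlier ones.
#' Arithmetic stays below 2^53 so it is exact in doubles.
#' @noRd
substream_seed <- function(seed, id) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + (id %% m) * 69621 + 1) %% m
  as.integer(s)
}

#' Study-year index of a date
#'
#' Year 1 is the first 365 days from `study_start` (observation years), or
#' the calendar year offset when `basis = "calendar"`.
#' @noRd
study_year <- function(dates, study_start, basis = c("study", "calendar")) {
  basis <- match.arg(basis)
  if (basis == "study") {
    as.integer(floor(as.numeric(dates - study_start) / 365)) + 1L
  } else {
    as.integer(format(dates, "%Y")) - as.integer(format(study_start, "%Y")) + 1L
  }
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("invalid configuration: '%s' must be a probability in [0, 1]",
                 field), call. = FALSE)
  }
  invisible(x)
}

is_symmetric_num <- function(m) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE))
}

#' Round percentages under a stated convention
#'
#' Field reports mix nearest-rounding and truncation when printing
#' percentages; both are offered so tabulated output can match either.
#' @param x numeric vector of percentages.
#' @param digits number of decimal digits to keep.
#' @param mode `"nearest"` (default) or `"trunc"`.
#' @return numeric vector.
#' @export
round_pct <- function(x, digits = 1, mode = c("nearest", "trunc")) {
  mode <- match.arg(mode)
  f <- 10^digits
  if (mode == "nearest") round(x * f) / f else trunc(x * f) / f
}
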