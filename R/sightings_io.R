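# Sighting-table data model, delimited IO, group-by-individual matrices and
# the study's inclusion/exclusion filters.

SIGHTING_COLUMNS <- c("date", "x", "y", "group_id", "individual_id",
                      "sex", "age_class", "state", "musth_stage")

#' Construct and validate a sighting table
#'
#' A sighting table holds one row per identified individual per group
#' sighting: the atomic observation of a mark-resight study. Each row
#' records the calendar date, a planar (projected, metres) location shared
#' by the group, the group-sighting identifier, the individual's identity,
#' sex, coarse age class, motivational state (`foraging` or `musth`) and,
#' for musth sightings, the musth stage (`early`/`peak`/`late`).
#'
#' Validation enforces the record invariants: `musth_stage != "none"`
#' exactly when `state == "musth"`; females are always
#' `state = "foraging"`, `musth_stage = "none"`; every date falls inside
#' the declared study window; and `(group_id, individual_id)` pairs are
#' unique.
#'
#' @param records data.frame with columns `date` (Date or ISO-8601
#'   character), `x`, `y` (numeric, planar metres), `group_id`,
#'   `individual_id` (character), `sex` (`"F"`/`"M"`), `age_class` (one of
#'   `"subadult"`, `"21-30"`, `"31-40"`, `"41-50"`, `"51-60"`), `state`,
#'   `musth_stage`.
#' @param study_start,study_end first and last observable date of the
#'   study window; default to the range of the records.
#' @return A `sighting_table`: a data.frame sorted by date with attributes
#'   `study_start` and `study_end`.
#' @examples
#' tab <- sighting_table(data.frame(
#'   date = as.Date("2010-01-05"), x = 0, y = 0, group_id = "g1",
#'   individual_id = "F001", sex = "F", age_class = "21-30",
#'   state = "foraging", musth_stage = "none"))
#' study_window(tab)
#' @export
sighting_table <- function(records, study_start = NULL, study_end = NULL) {
  missing_cols <- setdiff(SIGHTING_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[SIGHTING_COLUMNS]
  if (!inherits(records$date, "Date")) {
    parsed <- as.Date(as.character(records$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(records$date))
    if (length(bad)) {
      stop(sprintf("row %d: unparseable date '%s'", bad[1],
                   records$date[bad[1]]), call. = FALSE)
    }
    records$date <- parsed
  }
  for (col in c("group_id", "individual_id", "sex", "age_class",
                "state", "musth_stage")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$x <- as.numeric(records$x)
  records$y <- as.numeric(records$y)

  check_enum <- function(col, levels) {
    bad <- which(!(records[[col]] %in% levels))
    if (length(bad)) {
      stop(sprintf("row %d: unknown value '%s' in field '%s'",
                   bad[1], records[[col]][bad[1]], col), call. = FALSE)
    }
  }
  if (nrow(records)) {
    check_enum("sex", SEX_LEVELS)
    check_enum("age_class", AGE_LEVELS)
    check_enum("state", STATE_LEVELS)
    check_enum("musth_stage", STAGE_LEVELS)

    bad <- which((records$state == "musth") != (records$musth_stage != "none"))
    if (length(bad)) {
      stop(sprintf(
        "row %d: field 'musth_stage' ('%s') inconsistent with state '%s'",
        bad[1], records$musth_stage[bad[1]], records$state[bad[1]]),
        call. = FALSE)
    }
    bad <- which(records$sex == "F" & records$state != "foraging")
    if (length(bad)) {
      stop(sprintf("row %d: field 'state' must be 'foraging' for females",
                   bad[1]), call. = FALSE)
    }
    dup <- duplicated(records[c("group_id", "individual_id")])
    if (any(dup)) {
      stop(sprintf("row %d: duplicate (group_id, individual_id) pair",
                   which(dup)[1]), call. = FALSE)
    }
  }

  study_start <- as.Date(study_start %||% suppressWarnings(min(records$date)))
  study_end   <- as.Date(study_end   %||% suppressWarnings(max(records$date)))
  if (nrow(records)) {
    bad <- which(records$date < study_start | records$date > study_end)
    if (length(bad)) {
      stop(sprintf("row %d: date %s outside study window [%s, %s]",
                   bad[1], records$date[bad[1]], study_start, study_end),
           call. = FALSE)
    }
    records <- records[order(records$date, records$group_id,
                             records$individual_id), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(records, study_start = study_start, study_end = study_end,
            class = c("sighting_table", "data.frame"))
}

#' Study window of a sighting table
#' @param table a `sighting_table`.
#' @return Date vector of length 2 (`start`, `end`).
#' @export
study_window <- function(table) {
  c(start = attr(table, "study_start"), end = attr(table, "study_end"))
}

#' Read / write sighting tables as CSV
#'
#' The on-disk schema is comma-separated UTF-8 with ISO-8601 dates and one
#' row per (group sighting, individual); `read_sightings(write_sightings(t))`
#' reproduces `t` record for record. Validation errors name the offending
#' row and field.
#'
#' @param path file path.
#' @param study_start,study_end optional study window override (defaults to
#'   the range of dates in the file).
#' @return `read_sightings`: a [sighting_table()]. `write_sightings`:
#'   `path`, invisibly.
#' @export
read_sightings <- function(path, study_start = NULL, study_end = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(SIGHTING_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sighting_table(raw, study_start = study_start, study_end = study_end)
}

#' @param table a `sighting_table` (or coercible data.frame).
#' @rdname read_sightings
#' @export
write_sightings <- function(table, path) {
  if (!inherits(table, "sighting_table")) table <- sighting_table(table)
  out <- as.data.frame(table)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a group-by-individual (GBI) matrix
#'
#' Binary incidence matrix of group sightings (rows, the sampling units)
#' by individuals (columns), the canonical input to association indices.
#' Only group sightings containing at least one subject are kept, so the
#' matrix never has an all-zero row; column sums equal each individual's
#' number of group sightings. Row order follows the date-sorted table, but
#' every downstream statistic is invariant to row order.
#'
#' @param table a [sighting_table()].
#' @param subjects character vector of individual IDs to keep as columns.
#' @return integer 0/1 matrix with group IDs as rownames, subjects as
#'   colnames, and a `dates` attribute giving each row's sighting date
#'   (used by day-level association options).
#' @examples
#' tab <- sighting_table(data.frame(
#'   date = as.Date("2010-01-05") + c(0, 0, 1),
#'   x = 0, y = 0, group_id = c("g1", "g1", "g2"),
#'   individual_id = c("A", "B", "A"), sex = "F", age_class = "21-30",
#'   state = "foraging", musth_stage = "none"))
#' build_gbi(tab, c("A", "B"))
#' @export
build_gbi <- function(table, subjects) {
  if (!length(subjects)) stop("'subjects' must be non-empty", call. = FALSE)
  subjects <- unique(as.character(subjects))
  keep <- table$individual_id %in% subjects
  tab <- table[keep, , drop = FALSE]
  groups <- unique(tab$group_id)
  gbi <- matrix(0L, nrow = length(groups), ncol = length(subjects),
                dimnames = list(groups, subjects))
  if (nrow(tab)) {
    gbi[cbind(match(tab$group_id, groups),
              match(tab$individual_id, subjects))] <- 1L
  }
  dates <- tab$date[match(groups, tab$group_id)]
  attr(gbi, "dates") <- dates
  gbi
}

#' Export a GBI matrix
#'
#' Writes the incidence matrix either as dense CSV (rownames = group IDs)
#' or in MatrixMarket coordinate format for sparse tooling.
#'
#' @param gbi matrix from [build_gbi()].
#' @param path output file.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_gbi <- function(gbi, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(unclass(gbi)[, , drop = FALSE]), path,
                     row.names = TRUE)
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("package 'Matrix' is required for MatrixMarket export",
           call. = FALSE)
    }
    m <- Matrix::Matrix(unclass(gbi)[, , drop = FALSE], sparse = TRUE)
    attr(m, "dates") <- NULL
    Matrix::writeMM(m, path)
  }
  invisible(path)
}

#' Adult females present in both of the first two study years
#'
#' The female analysis is restricted to adult females seen in year 1 AND
#' year 2 of the study (so that each had the chance to be observed over
#' the full duration), minus individuals known to have died. Idempotent.
#'
#' @param table a [sighting_table()].
#' @param known_deaths individual IDs to exclude (known mortalities).
#' @param year_basis `"study"` (365-day observation years from the window
#'   start; default) or `"calendar"`.
#' @return sorted character vector of qualifying IDs.
#' @export
filter_females_first_two_years <- function(table, known_deaths = character(),
                                           year_basis = c("study", "calendar")) {
  year_basis <- match.arg(year_basis)
  win <- study_window(table)
  if (as.numeric(win[2] - win[1]) < 365) {
    stop("study window must span at least 2 years", call. = FALSE)
  }
  adult_f <- table$sex == "F" & table$age_class != "subadult"
  tab <- table[adult_f, , drop = FALSE]
  yrs <- study_year(tab$date, win[1], year_basis)
  ids_y1 <- unique(tab$individual_id[yrs == 1L])
  ids_y2 <- unique(tab$individual_id[yrs == 2L])
  keep <- setdiff(intersect(ids_y1, ids_y2), known_deaths)
  sort(keep)
}

#' Inclusion filter for the male BSI mixed-model frame
#'
#' From a roster of mature males, removes the oldest age class (51-60) and
#' males seen only once, for whom a between-sightings interval is
#' undefined. Idempotent.
#'
#' @param roster data.frame with columns `individual_id` and `age_class`
#'   (mature males only, classes `"21-30"` ... `"51-60"`).
#' @param sighting_counts named integer vector of per-male sighting counts
#'   (distinct days); names are individual IDs.
#' @return character vector of retained individual IDs, in roster order.
#' @export
filter_glmm_males <- function(roster, sighting_counts) {
  if (!nrow(roster)) return(character())
  counts <- sighting_counts[match(roster$individual_id,
                                  names(sighting_counts))]
  counts[is.na(counts)] <- 0L
  keep <- roster$age_class != "51-60" & counts >= 2
  roster$individual_id[keep]
}
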