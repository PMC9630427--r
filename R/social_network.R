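# SRI association matrices, community detection, and reciprocal-majority
# dynamic community matching across study years.

#' Simple-ratio-index association matrix
#'
#' The simple ratio index (SRI) for a pair is the proportion of sampling
#' units in which the two were seen together out of all sampling units in
#' which at least one of them was seen: `x / (x + yA + yB)` with `x` the
#' units containing both and `yA`, `yB` the units containing exactly one.
#' With group sightings as sampling units a pair can never be "both seen
#' but apart" within one unit; with day-level sampling units
#' (`sampling_unit = "day"`) days on which both were seen in different
#' groups enter the denominator (the classical `yAB` term).
#'
#' @param gbi group-by-individual matrix from [build_gbi()].
#' @param sampling_unit `"group"` (one group sighting per row; default) or
#'   `"day"` (rows collapsed by the `dates` attribute).
#' @param period optional label (e.g. the study year) carried on the
#'   result.
#' @return object of class `sri_matrix`: list with `sri` (symmetric
#'   matrix, values in `[0, 1]`, zero diagonal), `x` (joint counts), `n`
#'   (per-individual unit counts), `denom`, `period`, `sampling_unit`.
#' @examples
#' gbi <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
#' colnames(gbi) <- c("A", "B")
#' sri_matrix(gbi)$sri["A", "B"]  # 2 / 4
#' @export
sri_matrix <- function(gbi, sampling_unit = c("group", "day"), period = NULL) {
  sampling_unit <- match.arg(sampling_unit)
  if (!nrow(gbi) || !ncol(gbi)) {
    stop("'gbi' must be non-empty", call. = FALSE)
  }
  g <- unclass(gbi)
  storage.mode(g) <- "double"
  if (sampling_unit == "group") {
    x <- crossprod(g)                      # units with both together
    n <- diag(x)                           # units with each individual
    denom <- outer(n, n, "+") - x          # units with at least one
  } else {
    dates <- attr(gbi, "dates")
    if (is.null(dates)) {
      stop("day-level sampling requires a 'dates' attribute on the GBI",
           call. = FALSE)
    }
    day <- as.integer(factor(as.character(dates)))
    together <- rowsum(g, day) ; together[together > 0] <- 1  # seen that day
    # same-group co-occurrence per day: a pair is "together" on a day if
    # some single group that day contains both
    co <- crossprod(g[1, , drop = FALSE]) * 0
    for (d in unique(day)) {
      sub <- g[day == d, , drop = FALSE]
      joint <- crossprod(sub)
      joint[joint > 0] <- 1
      co <- co + joint
    }
    x <- co
    n <- diag(crossprod(together))
    both_seen <- crossprod(together)       # days both seen (any groups)
    denom <- outer(n, n, "+") - both_seen
  }
  sri <- ifelse(denom > 0, x / denom, 0)
  diag(sri) <- 0
  diag(x) <- 0
  structure(list(sri = sri, x = x, n = n, denom = denom,
                 period = period, sampling_unit = sampling_unit),
            class = "sri_matrix")
}

as_adjacency <- function(assoc) {
  if (inherits(assoc, "sri_matrix")) assoc$sri else as.matrix(assoc)
}

#' Detect social communities by Louvain modularity maximisation
#'
#' Runs the Louvain multi-level heuristic (via igraph) on the weighted
#' association network. The heuristic is stochastic; the node order is
#' shuffled under `seed` and igraph's own randomness is seeded the same
#' way, so results are reproducible. Community labels are contiguous
#' integers, renumbered by each community's lowest member index.
#'
#' @param assoc an [sri_matrix()] or symmetric non-negative weight matrix
#'   over at least two individuals.
#' @param seed integer seed.
#' @return object of class `community_partition`: list with `membership`
#'   (named integer vector), `modularity`, `period`.
#' @export
detect_communities <- function(assoc, seed = 1L) {
  w <- as_adjacency(assoc)
  if (nrow(w) < 2) {
    stop("association matrix needs at least 2 individuals", call. = FALSE)
  }
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- sprintf("V%d", seq_len(nrow(w)))
  }
  period <- if (inherits(assoc, "sri_matrix")) assoc$period else NULL
  if (all(w[upper.tri(w)] == 0)) {
    warning("empty network: returning the all-singletons partition")
    membership <- stats::setNames(seq_len(nrow(w)), rownames(w))
    return(structure(list(membership = membership, modularity = 0,
                          period = period),
                     class = "community_partition"))
  }
  res <- with_seed(seed, {
    perm <- sample.int(nrow(w))
    wp <- w[perm, perm]
    gr <- igraph::graph_from_adjacency_matrix(wp, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    cl <- igraph::cluster_louvain(gr)
    list(membership = igraph::membership(cl)[rownames(w)],
         modularity = max(cl$modularity))
  })
  # contiguous labels ordered by lowest member index
  memb <- res$membership
  first_idx <- tapply(seq_along(memb), memb, min)
  relabel <- stats::setNames(rank(first_idx), names(first_idx))
  membership <- stats::setNames(as.integer(relabel[as.character(memb)]),
                                names(memb))
  structure(list(membership = membership, modularity = res$modularity,
                 period = period),
            class = "community_partition")
}

partition_groups <- function(p) {
  split(names(p$membership), p$membership)
}

#' Match communities across consecutive periods (reciprocal majority)
#'
#' Cluster `A` at period t and cluster `B` at period t+1 are the same
#' social community iff their intersection exceeds half of BOTH cluster
#' sizes (strictly): `|A n B| > |A|/2` and `|A n B| > |B|/2`. At most one
#' `B` can match a given `A` (two disjoint strict majorities of `A` are
#' impossible), so the matching is one-to-one. Matched clusters inherit
#' the period-t persistent ID; unmatched period-t+1 clusters receive
#' fresh IDs.
#'
#' Individuals are also given a consensus assignment over the two periods:
#' when an individual's period-t cluster took part in a match it keeps
#' that persistent ID; otherwise, if its period-t+1 cluster matched, it
#' follows that one (membership in a community that demonstrably
#' persisted is stronger evidence than a transient fragment); failing
#' both, the period-t ID, or the period-t+1 ID for individuals absent
#' at t.
#'
#' @param p_t,p_t1 [detect_communities()] partitions over overlapping
#'   individual sets.
#' @param persistent_t optional named vector mapping period-t community
#'   labels to persistent IDs (defaults to the labels themselves), for
#'   chaining across more than two periods.
#' @return object of class `community_map`: list with `pairs` (data.frame
#'   `from`, `to`, `intersection`, `size_from`, `size_to`),
#'   `persistent_t1` (named vector: period-t+1 label -> persistent ID),
#'   `assignment` (named vector: individual -> persistent ID).
#' @export
match_communities <- function(p_t, p_t1, persistent_t = NULL) {
  ga <- partition_groups(p_t)
  gb <- partition_groups(p_t1)
  if (is.null(persistent_t)) {
    persistent_t <- stats::setNames(as.integer(names(ga)), names(ga))
  }
  pairs <- data.frame(from = integer(), to = integer(),
                      intersection = integer(), size_from = integer(),
                      size_to = integer())
  for (a in names(ga)) {
    for (b in names(gb)) {
      inter <- length(intersect(ga[[a]], gb[[b]]))
      if (inter > length(ga[[a]]) / 2 && inter > length(gb[[b]]) / 2) {
        pairs <- rbind(pairs, data.frame(
          from = as.integer(a), to = as.integer(b),
          intersection = inter, size_from = length(ga[[a]]),
          size_to = length(gb[[b]])))
      }
    }
  }
  next_id <- max(c(persistent_t, 0L)) + 1L
  persistent_t1 <- stats::setNames(rep(NA_integer_, length(gb)), names(gb))
  for (i in seq_len(nrow(pairs))) {
    persistent_t1[as.character(pairs$to[i])] <-
      persistent_t[as.character(pairs$from[i])]
  }
  for (b in names(persistent_t1)) {
    if (is.na(persistent_t1[b])) {
      persistent_t1[b] <- next_id
      next_id <- next_id + 1L
    }
  }
  ids_t <- names(p_t$membership)
  ids_t1 <- names(p_t1$membership)
  all_ids <- union(ids_t, ids_t1)
  pid1 <- stats::setNames(rep(NA_integer_, length(all_ids)), all_ids)
  pid2 <- pid1
  pid1[ids_t] <- persistent_t[as.character(p_t$membership[ids_t])]
  pid2[ids_t1] <- persistent_t1[as.character(p_t1$membership[ids_t1])]
  matched1 <- !is.na(pid1) &
    pid1 %in% persistent_t[as.character(pairs$from)]
  matched2 <- !is.na(pid2) &
    pid2 %in% persistent_t1[as.character(pairs$to)]
  assignment <- ifelse(matched1 | is.na(pid2), pid1,
                       ifelse(matched2 | is.na(pid1), pid2, pid1))
  assignment <- stats::setNames(as.integer(assignment), all_ids)
  structure(list(pairs = pairs, persistent_t1 = persistent_t1,
                 assignment = assignment),
            class = "community_map")
}

#' Summarise persistent communities
#'
#' @param assignment named vector, individual -> persistent community ID
#'   (e.g. `match_communities()$assignment`).
#' @param years_seen optional named integer vector of per-individual
#'   distinct-years-seen counts.
#' @return list with `communities` (data.frame: `community`, `size`,
#'   `members` comma-joined) and `members` (data.frame: `individual_id`,
#'   `community`, `years_seen`).
#' @export
community_summary <- function(assignment, years_seen = NULL) {
  groups <- split(names(assignment), assignment)
  communities <- data.frame(
    community = as.integer(names(groups)),
    size = lengths(groups),
    members = vapply(groups, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  communities <- communities[order(-communities$size), , drop = FALSE]
  rownames(communities) <- NULL
  members <- data.frame(
    individual_id = names(assignment),
    community = unname(assignment),
    years_seen = if (is.null(years_seen)) NA_integer_
                 else unname(years_seen[names(assignment)]),
    stringsAsFactors = FALSE)
  rownames(members) <- NULL
  list(communities = communities, members = members)
}

#' Export an association network
#'
#' Writes the weighted network either as an edge-list CSV
#' (`id_i, id_j, sri, period`; zero-weight dyads omitted) or as GraphML
#' for external viewers.
#'
#' @param assoc an [sri_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(assoc, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  w <- as_adjacency(assoc)
  if (format == "csv") {
    ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    edges <- data.frame(id_i = rownames(w)[ut[, 1]],
                        id_j = colnames(w)[ut[, 2]],
                        sri = w[ut],
                        period = if (inherits(assoc, "sri_matrix"))
                          assoc$period %||% NA else NA)
    utils::write.csv(edges, path, row.names = FALSE)
  } else {
    gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}
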