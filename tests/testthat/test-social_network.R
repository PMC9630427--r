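test_that("SRI matches direct counts on toy GBIs", {
  # together in both groups where either appears
  g <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  colnames(g) <- c("A", "B")
  expect_equal(sri_matrix(g)$sri["A", "B"], 1)
  # x = 2, yA = 1, yB = 1 over a 4-row GBI
  g2 <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
  colnames(g2) <- c("A", "B")
  expect_equal(sri_matrix(g2)$sri["A", "B"], 0.5)
  # never co-sighted
  g3 <- rbind(c(1, 0), c(0, 1))
  colnames(g3) <- c("A", "B")
  expect_equal(sri_matrix(g3)$sri["A", "B"], 0)
  expect_error(sri_matrix(g3[0, , drop = FALSE]), "non-empty")
})

test_that("SRI equals a brute-force pair count on random GBIs and is row-order invariant", {
  set.seed(5)
  for (rep in 1:20) {
    g <- matrix(rbinom(8 * 6, 1, 0.4), 8, 6,
                dimnames = list(NULL, sprintf("i%d", 1:6)))
    g <- g[rowSums(g) > 0, , drop = FALSE]
    if (nrow(g) < 2) next
    s <- sri_matrix(g)$sri
    for (i in 1:5) for (j in (i + 1):6) {
      x <- sum(g[, i] == 1 & g[, j] == 1)
      either <- sum(g[, i] == 1 | g[, j] == 1)
      expect_equal(s[i, j], if (either) x / either else 0)
    }
    expect_equal(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
    perm <- sample(nrow(g))
    expect_equal(sri_matrix(g[perm, , drop = FALSE])$sri, s)
  }
})

test_that("day-level sampling units count the both-seen-but-apart term", {
  # day 1: A and B together; day 2: A and B in different groups
  tab <- mk_table(c("A", "B", "A", "B"), day0 + c(0, 0, 1, 1),
                  group = c("g1", "g1", "g2", "g3"), sex = "F", age = "21-30")
  gbi <- build_gbi(tab, c("A", "B"))
  expect_equal(sri_matrix(gbi, "group")$sri["A", "B"], 1 / 3)
  expect_equal(sri_matrix(gbi, "day")$sri["A", "B"], 1 / 2)
})

test_that("Louvain detection recovers obvious block structure", {
  w <- matrix(0, 8, 8, dimnames = list(sprintf("i%d", 1:8),
                                       sprintf("i%d", 1:8)))
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  p <- detect_communities(w, seed = 1)
  expect_equal(length(unique(p$membership)), 2L)
  expect_equal(unname(p$membership[1:4]), rep(1L, 4))
  expect_equal(unname(p$membership[5:8]), rep(2L, 4))
  expect_gt(p$modularity, 0)
  # fully connected uniform network: a single community
  u <- matrix(0.5, 6, 6); diag(u) <- 0
  expect_equal(length(unique(detect_communities(u, 1)$membership)), 1L)
  # disconnected components are never merged
  set.seed(2)
  for (rep in 1:10) {
    b <- planted_sri(c(5, 6), within = 0.5, between = 0)
    pm <- detect_communities(b$w, seed = rep)$membership
    expect_equal(length(unique(pm[b$labels == 1])), 1L)
    expect_false(any(pm[b$labels == 1] %in% pm[b$labels == 2]))
  }
})

test_that("community detection is seeded and handles degenerate input", {
  set.seed(3)
  b <- planted_sri(c(6, 6, 6))
  p1 <- detect_communities(b$w, seed = 9)
  p2 <- detect_communities(b$w, seed = 9)
  expect_identical(p1, p2)
  expect_warning(p0 <- detect_communities(matrix(0, 3, 3), seed = 1),
                 "empty network")
  expect_equal(length(unique(p0$membership)), 3L)
  expect_error(detect_communities(matrix(0, 1, 1)), "at least 2")
})

test_that("planted three-block SRI networks are recovered", {
  skip_if_not_installed("mclust")
  set.seed(11)
  b <- planted_sri(c(10, 10, 10))
  p <- detect_communities(b$w, seed = 4)
  expect_gt(mclust::adjustedRandIndex(p$membership, b$labels), 0.9)
})

test_that("reciprocal-majority matching follows strict double majorities", {
  mk_part <- function(members, labels) {
    structure(list(membership = stats::setNames(labels, members),
                   modularity = NA_real_, period = NULL),
              class = "community_partition")
  }
  # A = {1,2,3}, B = {1,2,4}: |A n B| = 2 > 1.5 both sides -> matched
  pa <- mk_part(c("1", "2", "3"), c(1L, 1L, 1L))
  pb <- mk_part(c("1", "2", "4"), c(1L, 1L, 1L))
  m <- match_communities(pa, pb)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$persistent_t1[["1"]], 1L)
  # A = {1,2}, B = {1,3,4,5}: 1 is not > 1 and not > 2 -> unmatched
  pa2 <- mk_part(c("1", "2"), c(1L, 1L))
  pb2 <- mk_part(c("1", "3", "4", "5"), c(1L, 1L, 1L, 1L))
  m2 <- match_communities(pa2, pb2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$persistent_t1[["1"]], 2L)  # fresh ID
  # exactly-half overlap does not match
  ph1 <- mk_part(c("1", "2", "3", "4"), c(1L, 1L, 1L, 1L))
  ph2 <- mk_part(c("1", "2", "5", "6"), c(1L, 1L, 1L, 1L))
  expect_equal(nrow(match_communities(ph1, ph2)$pairs), 0L)
  # identical partitions map to themselves
  pid <- mk_part(sprintf("i%d", 1:9), rep(1:3, each = 3))
  mid <- match_communities(pid, pid)
  expect_equal(mid$pairs$from, mid$pairs$to)
  expect_equal(unname(mid$persistent_t1), 1:3)
  expect_equal(mid$assignment, pid$membership)
})

test_that("a cluster can reciprocally match at most one partner (random partitions)", {
  set.seed(6)
  ids <- sprintf("x%02d", 1:20)
  for (rep in 1:100) {
    p1 <- rpartition(sample(ids, 16), 4)
    p2 <- rpartition(sample(ids, 16), 4)
    m <- match_communities(p1, p2)
    expect_false(any(duplicated(m$pairs$from)))
    expect_false(any(duplicated(m$pairs$to)))
    # symmetric up to direction
    rev <- match_communities(p2, p1)
    expect_equal(unname(as.matrix(m$pairs[c("from", "to")])),
                 unname(as.matrix(rev$pairs[order(rev$pairs$to),
                                            c("to", "from")])))
  }
})

test_that("community summaries partition the assigned individuals", {
  assignment <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 2L)
  cs <- community_summary(assignment, c(a = 3L, b = 1L, c = 2L, d = 2L, e = 1L))
  expect_equal(sum(cs$communities$size), 5L)
  expect_equal(cs$communities$size, c(3L, 2L))  # sorted descending
  expect_equal(nrow(cs$members), 5L)
  two <- community_summary(c(p = 7L, q = 7L))
  expect_equal(two$communities$size, 2L)
})

test_that("networks export as edge lists and GraphML", {
  g2 <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  colnames(g2) <- c("A", "B", "C")
  assoc <- sri_matrix(g2, period = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_network(assoc, csv, "csv")
  edges <- utils::read.csv(csv)
  expect_equal(nrow(edges), 3L)
  expect_true(all(edges$sri > 0))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(assoc, gml, "graphml")
  expect_true(file.size(gml) > 0)
})
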