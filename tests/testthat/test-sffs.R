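# Brute-force 2-means: score all 2^n binary partitions by within-cluster SS
# and return the best; independent of the package's Lloyd implementation.
brute_2means_quality <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  best_ss <- Inf
  best_assign <- NULL
  for (code in 1:(2^n - 2)) {
    a <- as.integer(intToBits(code)[1:n])
    if (length(unique(a)) < 2) next
    ss <- 0
    for (g in 0:1) {
      rows <- X[a == g, , drop = FALSE]
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best_assign <- a }
  }
  lab01 <- as.integer(labels == unique(labels)[2])
  match <- sum(best_assign == lab01)
  max(match, n - match) / n
}

test_that("cluster quality separates, is pairing-invariant and handles degeneracy", {
  x <- matrix(c(0, 0, 0, 10, 10, 10))
  expect_equal(cluster_quality(x, c("a", "a", "a", "b", "b", "b")), 1)
  expect_equal(cluster_quality(x, c("b", "b", "b", "a", "a", "a")), 1)
  # identical rows -> majority fraction
  expect_equal(cluster_quality(matrix(1, 6, 2), c("a", "a", "a", "a", "b", "b")),
               4 / 6)
  expect_error(cluster_quality(x, rep("a", 6)), "two classes")
})

test_that("cluster quality agrees with the brute-force 2-means oracle", {
  set.seed(7)
  for (i in 1:10) {
    # well-separated pairs of blobs so Lloyd finds the global optimum
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    X <- rbind(matrix(rnorm(n1 * 2, 0, 0.4), n1, 2),
               matrix(rnorm(n2 * 2, 5, 0.4), n2, 2))
    labels <- sample(rep(c("a", "b"), c(n1, n2)))
    expect_equal(cluster_quality(X, labels), brute_2means_quality(X, labels))
  }
})

test_that("single-run deltas follow the forward/backward hand traces", {
  lab <- c("a", "a", "a", "b", "b", "b")
  # a feature that alone clusters perfectly: +1 forward, +1 backward
  expect_equal(as.integer(sffs_single_run(matrix(c(0, 0, 0, 9, 9, 9)), lab, 1)), 2L)
  # a constant feature with balanced labels: -1 forward, -1 backward
  expect_equal(as.integer(sffs_single_run(matrix(1, 6, 1), lab, 1)), -2L)
  # two features: perfect + constant, both orders
  X <- cbind(c(0, 0, 0, 9, 9, 9), rep(1, 6))
  d12 <- sffs_single_run(X, lab, c(1, 2))
  d21 <- sffs_single_run(X, lab, c(2, 1))
  expect_equal(as.integer(d12), c(2L, -2L))
  expect_equal(as.integer(d21), c(2L, -2L))
  expect_error(sffs_single_run(X, lab, c(1, 1)), "permutation")
  expect_error(sffs_single_run(matrix(0, 6, 0), lab, integer(0)), "empty")
})

test_that("per-run deltas stay in {-2, 0, 2} and scores are bounded", {
  set.seed(11)
  X <- matrix(rnorm(12 * 6), 12, 6)
  lab <- rep(c("a", "b"), 6)
  for (i in 1:5) {
    d <- sffs_single_run(X, lab, sample(6))
    expect_true(all(d %in% c(-2L, 0L, 2L)))
  }
  sc <- sffs_score(X, lab, n_runs = 40, seed = 2)
  expect_true(all(abs(sc$score) <= 2 * 40))
})

test_that("sffs_score is deterministic and composes with single runs", {
  set.seed(12)
  X <- matrix(rnorm(10 * 5), 10, 5)
  lab <- rep(c("a", "b"), 5)
  s1 <- sffs_score(X, lab, n_runs = 25, seed = 9)
  s2 <- sffs_score(X, lab, n_runs = 25, seed = 9)
  expect_identical(s1$score, s2$score)
  # n_runs = 1 equals one single run with the first sampled ordering
  ord <- dbmorph:::with_seed(9, sample.int(5))
  expect_equal(sffs_score(X, lab, n_runs = 1, seed = 9)$score,
               as.integer(sffs_single_run(X, lab, ord)))
  expect_error(sffs_score(X, lab, n_runs = 0), "n_runs")
})

test_that("a planted separating feature wins the score ranking", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 20), 20, 20)
    lab <- rep(c("a", "b"), each = 10)
    X[, 7] <- ifelse(lab == "a", 0, 6) + rnorm(20, sd = 0.3)
    sc <- sffs_score(X, lab, n_runs = 250, seed = seed + 100)
    if (which.max(sc$score) == 7L) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the planted feature's margin is large in expectation", {
  margins <- vapply(1:10, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(16 * 12), 16, 12)
    lab <- rep(c("a", "b"), 8)
    X[, 4] <- ifelse(lab == "a", -3, 3) + rnorm(16, sd = 0.3)
    sc <- sffs_score(X, lab, n_runs = 100, seed = seed)
    sc$score[4] - max(sc$score[-4])
  }, numeric(1))
  expect_gt(mean(margins), 0.5 * 100)
})

test_that("top_k sorts by score with index tie-breaks", {
  sc <- structure(list(score = c(5L, 3L, 9L), n_runs = 10L,
                       ordering_seed = 1L, descriptors = NULL),
                  class = "feature_scores")
  expect_equal(top_k(sc, 2)$column, c(3, 1))
  sc2 <- structure(list(score = rep(0L, 6), n_runs = 10L,
                        ordering_seed = 1L, descriptors = NULL),
                   class = "feature_scores")
  expect_equal(top_k(sc2, 5)$column, 1:5)
  expect_equal(top_k(sc, 3)$column, c(3, 1, 2))
  expect_error(top_k(sc, 4), "exceeds")
})

test_that("brute-force best single feature lands in the SFFS top-3", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 10; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    lab <- rep(c("a", "b"), each = 5)
    X[, 3] <- ifelse(lab == "a", -1.6, 1.6) + rnorm(n, sd = 0.6)
    best <- which.max(vapply(seq_len(p), function(j)
      cluster_quality(X[, j, drop = FALSE], lab), numeric(1)))
    sc <- sffs_score(X, lab, n_runs = 100, seed = seed + 55)
    if (best %in% top_k(sc, 3)$column) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
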