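test_that("semi-partial correlation handles degenerate two- and three-ROI cases", {
  set.seed(1)
  x <- rnorm(50)
  ts2 <- cbind(a = x, b = x)
  sc <- suppressWarnings(semipartial_matrix(ts2))
  expect_equal(sc$r["a", "b"], 1)            # identical signals, no controls
  # exactly orthogonal (and centered) triple: all semi-partials vanish
  q <- qr.Q(qr(scale(matrix(rnorm(60 * 3), 60, 3), scale = FALSE)))
  colnames(q) <- c("a", "b", "c")
  sc3 <- semipartial_matrix(q)
  expect_lt(max(abs(sc3$r)), 1e-10)
})

test_that("semi-partial matrix equals the per-pair OLS residualization oracle", {
  set.seed(7)
  for (rep in 1:10) {
    p <- sample(4:8, 1)
    A <- matrix(rnorm(p * p, sd = 0.4), p, p) + diag(p)
    X <- matrix(rnorm(60 * p), 60, p) %*% A
    colnames(X) <- paste0("r", seq_len(p))
    expect_equal(semipartial_matrix(X)$r, oracle_semipartial(X),
                 tolerance = 1e-8)
  }
})

test_that("semi-partial correlations of independent signals vanish with T", {
  set.seed(11)
  X <- matrix(rnorm(5000 * 6), 5000, 6)
  colnames(X) <- paste0("r", 1:6)
  expect_lt(max(abs(semipartial_matrix(X)$r)), 0.05)
})

test_that("semi-partial matrix rejects rank-deficient and short inputs", {
  set.seed(2)
  x <- rnorm(40)
  X <- cbind(a = x, b = x, c = rnorm(40), d = rnorm(40))
  expect_error(semipartial_matrix(X), "rank-deficient")
  Xs <- matrix(rnorm(3 * 5), 3, 5)
  expect_error(semipartial_matrix(Xs), "timepoints")
})

test_that("Fisher transform is the log form, odd, and clamps |r| >= 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log((1 + 0.5) / (1 - 0.5)) / 2)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("group edge statistics match the closed-form t-test", {
  meta <- tiny_meta(n_pairs = 2, n_mid = 0)
  make_sc <- function(z) {
    r <- tanh(z)
    dimnames(r) <- list(meta$name, meta$name)
    diag(r) <- 0
    structure(list(r = r, z = atanh(r)), class = "subject_connectivity")
  }
  set.seed(3)
  zs <- rnorm(10, mean = 0.3, sd = 0.2)
  cohort <- lapply(zs, function(z) make_sc(matrix(z, 4, 4)))
  st <- group_edge_stats(cohort, n_perm = 200, seed = 1)
  t_expect <- mean(zs) / (sd(zs) / sqrt(10))
  expect_equal(st$edges$t, rep(t_expect, nrow(st$edges)), tolerance = 1e-10)
  expect_equal(st$edges$p_edge,
               rep(2 * pt(-abs(t_expect), 9), nrow(st$edges)),
               tolerance = 1e-10)

  # all-zero cohort: t = 0, p = 1 everywhere, omnibus p = 1
  cohort0 <- lapply(1:5, function(i) make_sc(matrix(0, 4, 4)))
  st0 <- group_edge_stats(cohort0, n_perm = 100, seed = 1)
  expect_true(all(st0$edges$t == 0))
  expect_true(all(st0$edges$p_edge == 1))
  expect_true(all(st0$seeds$p_seed == 1))

  # zero-variance nonzero mean: underflow sentinel with warning
  cohort_c <- lapply(1:5, function(i) make_sc(matrix(0.5, 4, 4)))
  expect_warning(stc <- group_edge_stats(cohort_c, n_perm = 100, seed = 1),
                 "zero-variance")
  expect_true(all(stc$edges$p_edge <= .Machine$double.xmin))
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    # order invariance up to the inverse permutation
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm])[order(perm)], bh_fdr(p), tolerance = 1e-12)
  }
})

test_that("edge retention applies the two-level predicate exactly", {
  rois <- c("a", "b", "c", "d")
  pairs <- t(combn(rois, 2))
  st <- structure(list(
    edges = data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2],
                       mean_z = 0.3,
                       t = c(5, 5, 0.5, 5, 5, 5),
                       p_edge = c(0.001, 0.001, 0.5, 0.001, 0.001, 0.001)),
    seeds = data.frame(roi = rois,
                       p_seed = c(0.001, 0.5, 0.5, 0.001),
                       q_seed = c(0.004, 0.6, 0.6, 0.004)),
    n_subjects = 10, rois = rois), class = "group_edge_stats")
  kept <- threshold_edges(st, seed_alpha = 0.05, edge_alpha = 0.01)
  # survivors: p_edge < 0.01 AND a significant endpoint (a or d);
  # (a,d) fails the edge threshold, (b,c) has no significant endpoint
  expect_equal(paste(kept$roi_i, kept$roi_j),
               c("a b", "a c", "b d", "c d"))
  expect_equal(kept$weight, abs(kept$t))

  # all p_edge at 1: nothing retained
  st$edges$p_edge <- 1
  expect_equal(nrow(threshold_edges(st)), 0)

  # everything passing: complete graph
  st$edges$p_edge <- 1e-6
  st$seeds$q_seed <- 1e-4
  expect_equal(nrow(threshold_edges(st)), 6)
})

test_that("lowering edge_alpha never adds edges", {
  co <- tiny_cohort(seed = 4)
  st <- group_edge_stats(lapply(co$ts, semipartial_matrix),
                         n_perm = 200, seed = 2)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  ns <- vapply(alphas, function(a)
    nrow(threshold_edges(st, edge_alpha = a)), numeric(1))
  expect_true(all(diff(ns) <= 0))
  keys <- lapply(alphas, function(a) {
    k <- threshold_edges(st, edge_alpha = a)
    paste(k$roi_i, k$roi_j)
  })
  for (i in 2:4) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
})
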