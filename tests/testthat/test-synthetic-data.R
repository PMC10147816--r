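test_that("metadata generation honours pair/midline arithmetic and pairing rules", {
  meta <- generate_metadata(45, 7, default_module_plan(), seed = 1)
  expect_equal(nrow(meta), 97)
  expect_equal(sum(!is.na(meta$pair_id)) / 2, 45)
  expect_equal(sum(meta$hemisphere == "midline"), 7)
  expect_equal(meta$roi_id, 0:96)
  # every pair_id occurs exactly twice with one left and one right member
  tab <- table(meta$pair_id)
  expect_true(all(tab == 2))
  for (p in names(tab)) {
    h <- meta$hemisphere[!is.na(meta$pair_id) & meta$pair_id == as.integer(p)]
    expect_setequal(h, c("left", "right"))
  }
  # midline-only atlas
  m2 <- generate_metadata(0, 4, data.frame(name = "X", size = 4), seed = 1)
  expect_equal(nrow(m2), 4)
  expect_true(all(m2$hemisphere == "midline"))
  expect_true(all(is.na(m2$pair_id)))
})

test_that("lateralized twin modules receive the left and right pair members", {
  plan <- data.frame(name = c("L", "R"), size = c(2L, 2L),
                     lateralized = TRUE)
  meta <- generate_metadata(2, 0, plan, seed = 1)
  expect_setequal(meta$hemisphere[meta$group == "L"], "left")
  expect_setequal(meta$hemisphere[meta$group == "R"], "right")
  # the same physical pairs span the two twins
  expect_setequal(meta$pair_id[meta$group == "L"],
                  meta$pair_id[meta$group == "R"])
})

test_that("metadata generation rejects inconsistent plans", {
  expect_error(generate_metadata(4, 1, data.frame(name = "A", size = 5)),
               "9")
  expect_error(
    generate_metadata(2, 0, data.frame(name = c("L", "R"), size = c(3L, 1L),
                                       lateralized = TRUE)),
    "equal size")
})

test_that("pure-noise signals are uncorrelated and generation is deterministic", {
  meta <- tiny_meta(n_pairs = 3, n_mid = 0)
  spec <- generator_spec(n_subjects = 2, n_timepoints = 600, loading = 0,
                         homolog_coupling = 0, seed = 42)
  ts1 <- generate_timeseries(meta, spec)
  C <- cor(ts1[[1]])
  expect_lt(mean(abs(C[upper.tri(C)])), 3 / sqrt(600))
  ts2 <- generate_timeseries(meta, spec)
  expect_identical(ts1, ts2)
})

test_that("homolog pair correlation matches the closed form of the latent model", {
  # one bilateral module: x_L = l F + c H + s e, x_R likewise (shared F, H)
  meta <- tiny_meta(n_pairs = 2, n_mid = 0)
  l <- 0.6; cc <- 0.8; s <- 1
  spec <- generator_spec(n_subjects = 1, n_timepoints = 10000, loading = l,
                         homolog_coupling = cc, noise_sd = s, seed = 7)
  X <- generate_timeseries(meta, spec)[[1]]
  pr <- bilateral_pairs(meta)
  r_model <- (l^2 + cc^2) / (l^2 + cc^2 + s^2)
  for (i in seq_len(nrow(pr)))
    expect_lt(abs(cor(X[, pr$left[i]], X[, pr$right[i]]) - r_model), 0.05)
})

test_that("columns are standardized and stationarity is enforced", {
  co <- tiny_cohort(seed = 3, n_subjects = 2, n_timepoints = 50)
  for (X in co$ts) {
    expect_lt(max(abs(colMeans(X))), 1e-8)
    expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-8)
    expect_false(anyNA(X))
  }
  expect_error(generator_spec(ar_coefficient = 1), "stationarity")
})

test_that("planted modules are recoverable from sample correlations", {
  plan <- data.frame(name = c("A", "B", "C"), size = c(6L, 6L, 6L))
  meta <- generate_metadata(9, 0, plan, seed = 2)
  for (seed in 1:3) {
    spec <- generator_spec(n_subjects = 1, n_timepoints = 200, loading = 0.7,
                           noise_sd = 1, seed = seed)
    X <- generate_timeseries(meta, spec)[[1]]
    C <- cor(X)
    same <- outer(meta$group, meta$group, `==`) & upper.tri(C)
    diff <- (!outer(meta$group, meta$group, `==`)) & upper.tri(C)
    expect_gt(mean(C[same]), mean(C[diff]))
  }
})

test_that("overlap tables concentrate voxels on the planted network", {
  meta <- tiny_meta(n_pairs = 4, n_mid = 0)
  nets <- list(N1 = meta$name[1:4], N2 = meta$name[5:8])
  ov0 <- generate_overlap_table(meta, nets, jitter = 0, seed = 1)
  for (roi in nets$N1) expect_true(all(ov0["N2", roi] == 0))
  for (roi in nets$N2) expect_true(all(ov0["N1", roi] == 0))
  # jittered counts still recover membership by brute-force argmax
  ov <- generate_overlap_table(meta, nets, jitter = 0.4, seed = 5)
  for (roi in unlist(nets)) {
    planted <- if (roi %in% nets$N1) "N1" else "N2"
    expect_equal(rownames(ov)[which.max(ov[, roi])], planted)
  }
  # empty planted network gives an all-zero row
  ov_e <- generate_overlap_table(meta, c(nets, list(N3 = character(0))),
                                 jitter = 0.2, seed = 2)
  expect_true(all(ov_e["N3", ] == 0))
  expect_error(generate_overlap_table(meta, nets, jitter = 1), "jitter")
})

test_that("metadata and time-series round-trip through their TSV formats", {
  co <- tiny_cohort(seed = 9, n_subjects = 1, n_timepoints = 30)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_metadata(co$meta, f1)
  m2 <- read_metadata(f1)
  expect_equal(as.data.frame(m2), as.data.frame(co$meta))
  write_timeseries(co$ts[[1]], f2)
  x2 <- read_timeseries(f2)
  orig <- co$ts[[1]]
  attr(x2, "subject_id") <- attr(orig, "subject_id") <- NULL
  expect_equal(x2, unclass(orig), tolerance = 1e-12)
})
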