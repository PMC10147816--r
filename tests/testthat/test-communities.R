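two_cliques <- function(n = 5) {
  nodes <- c(paste0("a", 1:n), paste0("b", 1:n))
  el <- rbind(t(combn(paste0("a", 1:n), 2)), t(combn(paste0("b", 1:n), 2)),
              c("a1", "b1"))
  named_graph(data.frame(from = el[, 1], to = el[, 2]), nodes)
}

planted_blocks <- function(seed, sizes = rep(10, 4), p_in = 0.8, p_out = 0.05) {
  set.seed(seed)
  P <- matrix(p_out, length(sizes), length(sizes))
  diag(P) <- p_in
  g <- igraph::sample_sbm(sum(sizes), P, sizes)
  igraph::V(g)$name <- paste0("n", seq_len(sum(sizes)))
  list(g = g, truth = rep(seq_along(sizes) - 1, sizes))
}

test_that("community detection finds unambiguous clique structure", {
  g <- two_cliques()
  part <- detect_communities(g, resolution = 1, seed = 1)
  expect_equal(length(unique(part$labels)), 2)
  expect_equal(length(unique(part$labels[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(part$labels[paste0("b", 1:5)])), 1)
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("x", 1:6)
  expect_equal(length(unique(detect_communities(k6, seed = 1)$labels)), 1)
  expect_error(detect_communities(igraph::make_empty_graph(3), seed = 1),
               "at least one edge")
})

test_that("detection recovers planted blocks exactly", {
  pb <- planted_blocks(17)
  part <- detect_communities(pb$g, resolution = 1, seed = 3)
  expect_equal(adjusted_rand(unname(part$labels), pb$truth), 1)
})

test_that("modularity matches the hand-computed partition quality", {
  expect_equal(modularity_score(igraph::make_full_graph(4) |>
                                  igraph::set_vertex_attr("name", value = letters[1:4]),
                                setNames(rep(0L, 4), letters[1:4]),
                                resolution = 1), 0)
  # two triangles joined by one edge, partition = the triangles:
  # m = 7, each module: e_c = 3, d_c = 7 -> Q = 2 (3/7 - (7/14)^2)
  el <- rbind(c("a1","a2"), c("a2","a3"), c("a1","a3"),
              c("b1","b2"), c("b2","b3"), c("b1","b3"), c("a1","b1"))
  g <- named_graph(data.frame(from = el[, 1], to = el[, 2]),
                   c(paste0("a", 1:3), paste0("b", 1:3)))
  lab <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), igraph::V(g)$name)
  expect_equal(modularity_score(g, lab, 1), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)
  # label-permutation invariance
  lab2 <- setNames(c(5L, 5L, 5L, 2L, 2L, 2L), igraph::V(g)$name)
  expect_equal(modularity_score(g, lab2, 1), modularity_score(g, lab, 1))
  expect_error(modularity_score(g, lab[1:3], 1), "missing")
})

test_that("consensus over deterministic repeats equals the single run", {
  g <- two_cliques()
  single <- detect_communities(g, resolution = 1, seed = derive_seeds(5, 1))
  cons <- consensus_partition(g, resolution = 1, n_repeats = 10, seed = 5)
  expect_equal(adjusted_rand(cons$labels[names(single$labels)],
                             single$labels), 1)
  # n_repeats = 1 reduces to detect_communities at the derived seed
  one <- consensus_partition(g, resolution = 1, n_repeats = 1, seed = 9)
  direct <- detect_communities(g, resolution = 1, seed = derive_seeds(9, 1))
  expect_equal(adjusted_rand(one$labels[names(direct$labels)],
                             direct$labels), 1)
})

test_that("consensus is deterministic and at least as accurate as its repeats", {
  diffs <- numeric(0)
  for (seed in 1:20) {
    pb <- planted_blocks(seed, sizes = rep(8, 4), p_in = 0.7, p_out = 0.12)
    repeat_aris <- vapply(derive_seeds(seed, 5), function(s)
      adjusted_rand(unname(detect_communities(pb$g, resolution = 1,
                                              seed = s)$labels), pb$truth),
      numeric(1))
    cons <- consensus_partition(pb$g, resolution = 1, n_repeats = 5,
                                seed = seed)
    diffs <- c(diffs, adjusted_rand(unname(cons$labels), pb$truth) -
                 median(repeat_aris))
    if (seed == 1) {
      again <- consensus_partition(pb$g, resolution = 1, n_repeats = 5,
                                   seed = seed)
      expect_identical(again$labels, cons$labels)
    }
  }
  expect_gte(mean(diffs), 0)
})

test_that("lateralized split only refines the chosen modules", {
  co <- tiny_cohort(seed = 6)
  st <- group_edge_stats(lapply(co$ts, semipartial_matrix), n_perm = 200,
                         seed = 2)
  g <- build_graph(threshold_edges(st), co$meta)
  p1 <- consensus_partition(g, resolution = 0.6, n_repeats = 5, seed = 3)
  p2 <- split_lateralized(g, p1, co$meta, top_k = 2, seed = 4)
  expect_gte(length(unique(p2$labels)), length(unique(p1$labels)))
  # nodes outside split modules keep their co-membership structure
  outside <- names(p1$labels)[!p1$labels %in% p2$split_modules]
  for (m in setdiff(unique(p1$labels), p2$split_modules)) {
    mem <- names(p1$labels)[p1$labels == m]
    expect_equal(length(unique(p2$labels[mem])), 1)
  }
  # a graph with no lateralized module is returned unchanged
  mid_meta <- generate_metadata(0, 6, data.frame(name = "M", size = 6), seed = 1)
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- mid_meta$name
  pk <- detect_communities(k6, seed = 1)
  expect_message(ps <- split_lateralized(k6, pk, mid_meta, top_k = 2, seed = 1),
                 "0 lateralized")
  expect_equal(unname(ps$labels), unname(pk$labels))
})

test_that("strong homolog coupling makes weight symmetry exceed degree symmetry", {
  for (seed in c(11, 12)) {
    co <- simulate_cohort(seed = seed)
    sp <- co$spec
    sp$homolog_coupling <- 0.7
    ts <- generate_timeseries(co$meta, sp)
    st <- suppressWarnings(group_edge_stats(lapply(ts, semipartial_matrix),
                                            n_perm = 500, seed = seed))
    g <- build_graph(threshold_edges(st), co$meta)
    sym <- homolog_symmetry(g, co$meta)
    expect_gt(sym$rho_weight, sym$rho_degree)
    expect_gt(sym$rho_degree, 0)
  }
})

test_that("community density equals brute-force pair counting", {
  # 4-node module with 3 internal edges -> 0.5
  nodes <- paste0("n", 1:6)
  el <- data.frame(from = c("n1", "n1", "n2", "n5"),
                   to = c("n2", "n3", "n4", "n6"))
  g <- named_graph(el, nodes)
  lab <- setNames(c(0L, 0L, 0L, 0L, 1L, 1L), nodes)
  d <- community_density(g, lab)
  expect_equal(d$density[d$module == 0], 3 / 6)
  expect_equal(d$density[d$module == 1], 1)
  expect_equal(sum(d$n_nodes), 6)
  # clique module scores 1; singleton flagged with density 0
  lab2 <- setNames(c(0L, 0L, 0L, 1L, 2L, 2L), nodes)
  d2 <- community_density(g, lab2)
  expect_true(d2$singleton[d2$module == 1])
  expect_equal(d2$density[d2$module == 1], 0)
  # random case against exhaustive pair scan
  set.seed(12)
  gr <- igraph::sample_gnp(15, 0.3)
  igraph::V(gr)$name <- paste0("v", 1:15)
  labr <- setNames(sample(0:2, 15, replace = TRUE), paste0("v", 1:15))
  dr <- community_density(gr, labr)
  adj <- as.matrix(igraph::as_adjacency_matrix(gr))
  for (m in unique(labr)) {
    mem <- which(labr == m)
    if (length(mem) < 2) next
    e_c <- sum(adj[mem, mem]) / 2
    expect_equal(dr$density[dr$module == m],
                 2 * e_c / (length(mem) * (length(mem) - 1)))
  }
})

test_that("homolog symmetry is the Spearman correlation over pairs", {
  meta <- tiny_meta(n_pairs = 5, n_mid = 0)
  pr <- bilateral_pairs(meta)
  # mirrored hemispheres: identical degrees left and right
  el <- do.call(rbind, lapply(1:4, function(i)
    data.frame(from = c(pr$left[i], pr$right[i]),
               to = c(pr$left[i + 1], pr$right[i + 1]))))
  g <- named_graph(el, meta$name)
  igraph::E(g)$weight <- rep(seq(1, 4) * 1.5, each = 2)
  sym <- homolog_symmetry(g, meta)
  expect_equal(sym$rho_degree, 1)
  expect_equal(sym$rho_weight, 1)
  # asymmetric weights: check against rank-then-Pearson oracle
  igraph::E(g)$weight <- c(1, 9, 2, 5, 7, 3, 4, 8)
  sym2 <- homolog_symmetry(g, meta)
  wd <- igraph::strength(g)
  expect_equal(sym2$rho_weight,
               oracle_spearman(wd[pr$left], wd[pr$right]), tolerance = 1e-10)
  expect_error(homolog_symmetry(named_graph(el[1:2, ], meta$name),
                                tiny_meta(n_pairs = 2, n_mid = 0)),
               "at least 3")
})
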