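# Independent oracles and small fixture builders used across the suite.

# brute-force semi-partial matrix: explicit per-pair OLS residualization
# (residual of x_i on all except i and j, correlated with raw x_j),
# symmetrized by averaging -- independent of the package's precision-matrix
# implementation
oracle_semipartial <- function(X) {
  p <- ncol(X)
  s <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    ctrl <- setdiff(seq_len(p), c(i, j))
    e_i <- if (length(ctrl) == 0) X[, i]
           else stats::resid(stats::lm(X[, i] ~ X[, ctrl]))
    s[i, j] <- stats::cor(X[, j], e_i)
  }
  r <- (s + t(s)) / 2
  diag(r) <- 0
  dimnames(r) <- list(colnames(X), colnames(X))
  r
}

# step-up Benjamini-Hochberg evaluated literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}

# Spearman rho by definition: Pearson correlation of average ranks
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# exhaustive triangle enumeration over all node triples
oracle_triangles <- function(adj) {
  n <- nrow(adj)
  cnt <- 0
  for (a in seq_len(n - 2)) for (b in seq(a + 1, n - 1)) for (cc in seq(b + 1, n))
    if (adj[a, b] && adj[b, cc] && adj[a, cc]) cnt <- cnt + 1
  cnt
}

# ring lattice: n nodes, each joined to its k nearest neighbours (k even)
ring_lattice <- function(n, k) {
  el <- NULL
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    el <- rbind(el, c(i, j))
  }
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# named igraph from an edge data frame over explicitly listed nodes
named_graph <- function(edges, nodes) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

# minimal metadata table: n_pairs bilateral pairs, n_mid midline ROIs, one
# module unless a plan is given
tiny_meta <- function(n_pairs = 3, n_mid = 1, plan = NULL, seed = 1) {
  if (is.null(plan))
    plan <- data.frame(name = "M1", size = 2 * n_pairs + n_mid)
  generate_metadata(n_pairs, n_mid, plan, seed = seed)
}

# small planted cohort for pipeline-level tests: 4 modules (one lateralized
# twin pair with hidden sub-structure), 11 bilateral pairs, 22 ROIs total
tiny_plan <- function() {
  data.frame(name = c("A", "B", "LatL", "LatR"),
             size = c(6L, 8L, 4L, 4L),
             lateralized = c(FALSE, FALSE, TRUE, TRUE),
             n_sub = c(1L, 1L, 2L, 2L))
}

tiny_cohort <- function(seed = 1, n_subjects = 6, n_timepoints = 80) {
  plan <- tiny_plan()
  meta <- generate_metadata(n_pairs = 11, n_midline = 0, plan, seed = seed)
  spec <- generator_spec(n_subjects = n_subjects,
                         n_timepoints = n_timepoints, seed = seed)
  list(meta = meta, ts = generate_timeseries(meta, spec), spec = spec)
}
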