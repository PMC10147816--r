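#' Single-run community detection by weighted modularity maximization
#'
#' Greedy multi-level (Louvain) maximization of weighted modularity at the
#' given resolution; deterministic given the seed. Module ids are contiguous
#' integers from 0 in order of first appearance along the node order.
#'
#' @param g graph with at least one edge.
#' @param resolution resolution multiplier on the null term of the
#'   modularity quality function (the analysis default is 0.6).
#' @param seed integer seed.
#' @return list of class `community_partition`: `labels` (named integer
#'   vector, node -> module id), `Q` (modularity at `resolution`), `layer`,
#'   `resolution`, `n_repeats`, `seed`.
#' @export
detect_communities <- function(g, resolution = 0.6, seed = 1L) {
  if (igraph::ecount(g) < 1)
    stop("community detection needs at least one edge", call. = FALSE)
  stopifnot(resolution > 0)
  w <- edge_weights(g)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  labels <- relabel0(igraph::membership(cl))
  names(labels) <- igraph::V(g)$name
  new_partition(g, labels, resolution, layer = 1L, n_repeats = 1L, seed = seed)
}

edge_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
}

new_partition <- function(g, labels, resolution, layer, n_repeats, seed) {
  structure(list(labels = labels,
                 Q = modularity_score(g, labels, resolution),
                 layer = layer, resolution = resolution,
                 n_repeats = n_repeats, seed = seed),
            class = "community_partition")
}

#' Weighted modularity of a labeling, with resolution multiplier
#'
#' Standard Newman modularity `Q = sum_c (e_c / m - r (d_c / 2m)^2)` with
#' resolution `r` scaling the degree-based null term.
#'
#' @param g graph.
#' @param labels integer module ids, one per node (named or in node order).
#' @param resolution resolution multiplier.
#' @return Q.
#' @export
modularity_score <- function(g, labels, resolution = 1) {
  lab <- align_labels(g, labels)
  igraph::modularity(g, membership = lab + 1L, weights = edge_weights(g),
                     resolution = resolution)
}

align_labels <- function(g, labels) {
  nodes <- igraph::V(g)$name
  if (!is.null(names(labels))) {
    if (!all(nodes %in% names(labels)))
      stop("labels missing for nodes: ",
           paste(setdiff(nodes, names(labels)), collapse = ", "),
           call. = FALSE)
    labels <- labels[nodes]
  } else if (length(labels) != length(nodes)) {
    stop("labels must cover every node", call. = FALSE)
  }
  as.integer(labels)
}

#' Consensus community structure over repeated detection runs
#'
#' Runs [detect_communities()] `n_repeats` times with derived seeds, builds
#' the node-by-node co-assignment frequency matrix, keeps co-assignments with
#' frequency >= 0.5 as a weighted consensus graph, re-clusters it, and
#' iterates until the co-assignment matrix is block-constant (all frequencies
#' 0 or 1), up to 20 iterations (non-convergence returns the last partition
#' with a warning). Nodes never co-assigned with anyone become singleton
#' modules.
#'
#' @param g graph.
#' @param resolution resolution passed to every detection run.
#' @param n_repeats number of repeats per iteration.
#' @param seed master seed.
#' @return `community_partition` (Q evaluated on `g`).
#' @export
consensus_partition <- function(g, resolution = 0.6, n_repeats = 10L,
                                seed = 1L) {
  stopifnot(n_repeats >= 1)
  nodes <- igraph::V(g)$name
  g_cur <- g
  labels <- NULL
  for (iter in seq_len(20)) {
    seeds <- derive_seeds(seed + iter - 1L, n_repeats)
    parts <- lapply(seeds, function(s)
      detect_communities(g_cur, resolution = resolution, seed = s)$labels)
    D <- Reduce(`+`, lapply(parts, function(lb) {
      outer(lb[nodes], lb[nodes], `==`) * 1
    })) / n_repeats
    off <- D[upper.tri(D)]
    if (all(off %in% c(0, 1)) || n_repeats == 1) {
      A <- D >= 0.5
      diag(A) <- TRUE
      gc2 <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                                 diag = FALSE)
      labels <- relabel0(igraph::components(gc2)$membership)
      names(labels) <- nodes
      return(new_partition(g, labels, resolution, layer = 1L,
                           n_repeats = n_repeats, seed = seed))
    }
    W <- D
    W[W < 0.5] <- 0
    diag(W) <- 0
    g_cur <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                                 weighted = TRUE, diag = FALSE)
    labels <- parts[[1]]
  }
  warning("consensus did not converge in 20 iterations; returning last run")
  labels <- labels[nodes]
  new_partition(g, relabel_named(labels), resolution, layer = 1L,
                n_repeats = n_repeats, seed = seed)
}

relabel_named <- function(labels) {
  out <- relabel0(labels)
  names(out) <- names(labels)
  out
}

#' Split the most populous lateralized modules into sub-communities
#'
#' Second community layer. A module is lateralized when more than 70% of its
#' members lie in a single hemisphere (midline ROIs count toward neither).
#' The `top_k` most populous lateralized modules are each re-clustered by
#' [consensus_partition()] on their induced subgraphs; all other modules are
#' untouched. If fewer than `top_k` modules qualify, whatever qualifies is
#' split and the shortfall is messaged.
#'
#' @param g graph.
#' @param part layer-1 `community_partition`.
#' @param meta `roi_metadata`.
#' @param top_k number of lateralized modules to split.
#' @param n_repeats,seed consensus parameters for the sub-clustering.
#' @param lateral_frac hemisphere-dominance threshold (default 0.7).
#' @return layer-2 `community_partition` with contiguous final labels and an
#'   extra `split_modules` element naming the layer-1 modules that were
#'   re-clustered.
#' @export
split_lateralized <- function(g, part, meta, top_k = 2L,
                              n_repeats = part$n_repeats, seed = 1L,
                              lateral_frac = 0.7) {
  stopifnot(inherits(part, "community_partition"), part$layer == 1L)
  labels <- part$labels
  hemi <- meta$hemisphere
  names(hemi) <- meta$name
  mods <- sort(unique(labels))
  lat <- vapply(mods, function(m) {
    h <- hemi[names(labels)[labels == m]]
    n <- length(h)
    max(sum(h == "left"), sum(h == "right")) > lateral_frac * n
  }, logical(1))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  cand <- mods[lat][order(-sizes[lat], mods[lat])]
  if (length(cand) < top_k)
    message("only ", length(cand), " lateralized module(s) found (wanted ",
            top_k, ")")
  split_ids <- utils::head(cand, top_k)

  new_labels <- labels
  next_id <- max(labels) + 1L
  sub_seeds <- derive_seeds(seed, max(1, length(split_ids)))
  for (k in seq_along(split_ids)) {
    m <- split_ids[k]
    members <- names(labels)[labels == m]
    sg <- igraph::induced_subgraph(g, members)
    if (igraph::ecount(sg) == 0) next
    sub <- consensus_partition(sg, resolution = part$resolution,
                               n_repeats = n_repeats, seed = sub_seeds[k])
    for (sm in sort(unique(sub$labels))) {
      new_labels[names(sub$labels)[sub$labels == sm]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- new_partition(g, relabel_named(new_labels), part$resolution,
                       layer = 2L, n_repeats = n_repeats, seed = seed)
  out$split_modules <- split_ids
  out$layer1_labels <- labels
  out
}

#' Per-community internal edge density
#'
#' Induced-subgraph density `2 E_c / (n_c (n_c - 1))` per module; singleton
#' modules report density 0 with a flag.
#'
#' @param g graph.
#' @param part `community_partition` (or named label vector).
#' @return data.frame (`module`, `n_nodes`, `density`, `singleton`).
#' @export
community_density <- function(g, part) {
  labels <- if (inherits(part, "community_partition")) part$labels else part
  labels <- labels[igraph::V(g)$name]
  mods <- sort(unique(labels))
  out <- lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    n_c <- length(members)
    if (n_c < 2)
      return(data.frame(module = m, n_nodes = n_c, density = 0,
                        singleton = TRUE))
    sg <- igraph::induced_subgraph(g, members)
    data.frame(module = m, n_nodes = n_c,
               density = 2 * igraph::ecount(sg) / (n_c * (n_c - 1)),
               singleton = FALSE)
  })
  do.call(rbind, out)
}

#' Bilateral homolog symmetry of node degree and node weight
#'
#' Spearman rank correlation across bilateral pairs between the left and
#' right member's binary degree, and between their weighted degree (node
#' strength). Pairs with both members isolated are dropped; at least three
#' usable pairs are required. A hemisphere with constant values yields an
#' undefined rho, reported as NA with a warning.
#'
#' @param g graph.
#' @param meta `roi_metadata`.
#' @return list: `rho_degree`, `p_degree`, `rho_weight`, `p_weight`,
#'   `n_pairs`.
#' @export
homolog_symmetry <- function(g, meta) {
  pairs <- bilateral_pairs(meta)
  nodes <- igraph::V(g)$name
  pairs <- pairs[pairs$left %in% nodes & pairs$right %in% nodes, ]
  deg <- igraph::degree(g)
  wd <- igraph::strength(g, weights = edge_weights(g))
  use <- deg[pairs$left] + deg[pairs$right] > 0
  pairs <- pairs[use, ]
  if (nrow(pairs) < 3)
    stop("need at least 3 bilateral pairs with nonzero degree", call. = FALSE)
  spear <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant values on one hemisphere: rho undefined")
      return(list(estimate = NA_real_, p.value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  d <- spear(deg[pairs$left], deg[pairs$right])
  w <- spear(wd[pairs$left], wd[pairs$right])
  list(rho_degree = d$estimate, p_degree = d$p.value,
       rho_weight = w$estimate, p_weight = w$p.value,
       n_pairs = nrow(pairs))
}

#' Write a partition and a density table as TSV
#'
#' @param part layer-2 (or layer-1) `community_partition`.
#' @param dens density table from [community_density()].
#' @param partition_path,density_path file paths.
#' @export
write_partition <- function(part, dens, partition_path, density_path) {
  lab1 <- if (!is.null(part$layer1_labels)) part$layer1_labels else part$labels
  df <- data.frame(roi = names(part$labels),
                   layer1_module = unname(lab1[names(part$labels)]),
                   final_module = unname(part$labels))
  utils::write.table(df, partition_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dens, density_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(partition_path)
}
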