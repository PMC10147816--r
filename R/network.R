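#' Build the weighted undirected brain graph
#'
#' Nodes are all ROIs of the metadata table (ROIs with no surviving edge are
#' kept as isolated, degree-0 nodes); edges come from [threshold_edges()].
#' Node attributes carry hemisphere, bilateral pair id and planted module.
#'
#' @param edges data.frame with columns `roi_i`, `roi_j`, `weight`
#'   (positive); additional columns become edge attributes.
#' @param meta `roi_metadata` table.
#' @return igraph object of class `brain_graph`.
#' @export
build_graph <- function(edges, meta) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("roi_i", "roi_j", "weight") %in% names(edges)))
    unknown <- setdiff(unique(c(edges$roi_i, edges$roi_j)), meta$name)
    if (length(unknown))
      stop("edge endpoints not in metadata: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    key <- paste(pmin(edges$roi_i, edges$roi_j),
                 pmax(edges$roi_i, edges$roi_j), sep = "--")
    if (anyDuplicated(key))
      stop("duplicate edges: ", paste(unique(key[duplicated(key)]),
                                      collapse = ", "), call. = FALSE)
    if (any(edges$roi_i == edges$roi_j))
      stop("self-loop edges are not allowed", call. = FALSE)
    if (any(edges$weight <= 0))
      stop("edge weights must be positive", call. = FALSE)
  }
  vertices <- data.frame(name = meta$name, hemisphere = meta$hemisphere,
                         pair_id = meta$pair_id, module = meta$group,
                         stringsAsFactors = FALSE)
  ecols <- if (nrow(edges) > 0)
    edges[, c("roi_i", "roi_j",
              setdiff(names(edges), c("roi_i", "roi_j")))]
  else data.frame(roi_i = character(0), roi_j = character(0),
                  weight = numeric(0))
  g <- igraph::graph_from_data_frame(ecols, directed = FALSE,
                                     vertices = vertices)
  class(g) <- c("brain_graph", class(g))
  g
}

#' Connection density of a graph
#'
#' `2E / (N (N - 1))`: the fraction of possible edges present.
#'
#' @param g graph.
#' @return density in `[0, 1]`.
#' @export
connection_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("density undefined for fewer than two nodes", call. = FALSE)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Number of distinct triangles (3-cliques) in the binarized graph
#'
#' @param g graph.
#' @return integer count.
#' @export
triangle_count <- function(g) {
  sum(igraph::count_triangles(g)) / 3
}

#' Mean binary local clustering coefficient
#'
#' Mean over all nodes of triangles-through-node / neighbour pairs; nodes of
#' degree < 2 contribute 0.
#'
#' @param g graph.
#' @return C in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(cc)
}

#' Characteristic (binary) path length
#'
#' Mean shortest-path length over all node pairs within the same connected
#' component; infinite inter-component distances are excluded rather than
#' averaged. The number of components is attached as an attribute.
#'
#' @param g graph.
#' @return numeric L with attribute `n_components`.
#' @export
char_path_length <- function(g) {
  if (igraph::ecount(g) == 0)
    stop("path length undefined: no connected pair", call. = FALSE)
  L <- igraph::mean_distance(g, directed = FALSE, weights = NA,
                             unconnected = TRUE)
  structure(L, n_components = igraph::components(g)$no)
}

#' Degree-preserving rewired null graph
#'
#' Double-edge-swap randomization: attempts `swap_factor * E` swaps,
#' rejecting any swap that would create a self-loop or multi-edge, so the
#' degree sequence is preserved exactly. `swap_factor = 0` returns the graph
#' unchanged (degenerate null used in tests).
#'
#' @param g graph with at least 2 edges.
#' @param swap_factor swap attempts per edge.
#' @param seed integer seed.
#' @return rewired igraph object with the same degree multiset.
#' @export
rewire_null <- function(g, swap_factor = 10, seed = 1L) {
  if (igraph::ecount(g) < 2)
    stop("rewiring needs at least two edges", call. = FALSE)
  if (swap_factor == 0) return(g)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                           niter = swap_factor * igraph::ecount(g)))
}

#' Small-world scalars against degree-preserving nulls
#'
#' Computes the classical small-world quantities on the binarized graph:
#' clustering coefficient C and characteristic path length L, their means
#' `C_rand`, `L_rand` over `n_null` independent degree-preserving rewired
#' null graphs, the normalised ratios `gamma = C / C_rand`,
#' `lambda = L / L_rand`, and the small-world scalar
#' `sigma = gamma / lambda`. A small-world graph has `gamma > 1`,
#' `lambda ~ 1`, `sigma > 1`.
#'
#' @param g graph; a warning is issued if the largest component covers less
#'   than 90% of nodes (L is then dominated by within-component pairs).
#' @param n_null number of null graphs.
#' @param seed integer seed.
#' @param swap_factor swap attempts per edge for each null.
#' @return list of class `small_world_result`: `C`, `L`, `C_rand`, `L_rand`,
#'   `gamma`, `lambda`, `sigma`, `n_null`.
#' @export
small_world <- function(g, n_null = 100L, seed = 1L, swap_factor = 10) {
  comp <- igraph::components(g)
  if (max(comp$csize) < 0.9 * igraph::vcount(g))
    warning("largest component covers <90% of nodes; small-world scalars ",
            "describe the connected core only")
  C <- clustering_coefficient(g)
  L <- as.numeric(char_path_length(g))
  seeds <- derive_seeds(seed, n_null)
  null_CL <- vapply(seeds, function(s) {
    gn <- rewire_null(g, swap_factor = swap_factor, seed = s)
    c(clustering_coefficient(gn), as.numeric(char_path_length(gn)))
  }, numeric(2))
  C_rand <- mean(null_CL[1, ])
  L_rand <- mean(null_CL[2, ])
  if (C_rand == 0)
    stop("degenerate null: rewired graphs contain no triangles", call. = FALSE)
  gamma <- C / C_rand
  lambda <- L / L_rand
  structure(list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_null = n_null),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(paste0("Small-world summary (%d degree-preserving nulls)\n",
                     "  C = %.3f (null %.3f)   L = %.3f (null %.3f)\n",
                     "  gamma = %.2f   lambda = %.2f   sigma = %.2f\n"),
              x$n_null, x$C, x$C_rand, x$L, x$L_rand,
              x$gamma, x$lambda, x$sigma))
  invisible(x)
}

#' Small-world scalar from its normalised components
#'
#' The classical scalar is the ratio of the normalised clustering
#' coefficient to the normalised path length, `sigma = gamma / lambda`;
#' exposed separately so published gamma/lambda values can be combined.
#'
#' @param gamma normalised clustering coefficient `C / C_rand`.
#' @param lambda normalised path length `L / L_rand`.
#' @return sigma.
#' @export
small_world_sigma <- function(gamma, lambda) {
  stopifnot(gamma > 0, lambda > 0)
  gamma / lambda
}

#' Export a brain graph
#'
#' GraphML with node attributes (hemisphere, pair, module) and edge weights,
#' plus a plain edge-list CSV (`source`, `target`, `weight`) for force-layout
#' visualisation tools.
#'
#' @param g `brain_graph`.
#' @param graphml_path,csv_path output paths (either may be NULL to skip).
#' @export
export_graph <- function(g, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(graphml_path)) {
    g2 <- g
    # GraphML writers reject NA attribute values
    pid <- igraph::V(g2)$pair_id
    igraph::V(g2)$pair_id <- ifelse(is.na(pid), -1L, pid)
    class(g2) <- "igraph"
    igraph::write_graph(g2, graphml_path, format = "graphml")
  }
  if (!is.null(csv_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(source = el$from, target = el$to, weight = el$weight)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
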