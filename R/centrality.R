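#' Per-node centrality table
#'
#' Weighted degree (node strength: sum of incident edge weights), binary
#' degree, and Brandes shortest-path betweenness on the binarized graph —
#' unnormalized, with fractional credit for tied shortest paths. Isolated
#' nodes score 0 on all three.
#'
#' @param g graph.
#' @return data.frame of class `centrality_table`: `roi`, `wd`, `d`, `bc`.
#' @export
node_centralities <- function(g) {
  out <- data.frame(
    roi = igraph::V(g)$name,
    wd = unname(igraph::strength(g, weights = edge_weights(g))),
    d = unname(igraph::degree(g)),
    bc = unname(igraph::betweenness(g, directed = FALSE, weights = NA)),
    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Collapse a centrality table to bilateral pairs
#'
#' One row per bilateral pair, holding the mean of the two members for each
#' metric (averaging precedes ranking); midline ROIs pass through unchanged
#' and compete in the same rankings.
#'
#' @param tab `centrality_table` from [node_centralities()].
#' @param meta `roi_metadata`.
#' @return data.frame: `unit` (pair stem or midline ROI name), `type`
#'   (`pair`/`midline`), `wd`, `d`, `bc`.
#' @export
bilateral_average <- function(tab, meta) {
  pairs <- bilateral_pairs(meta)
  missing <- setdiff(c(pairs$left, pairs$right), tab$roi)
  if (length(missing))
    stop("pair members missing from centrality table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rownames(tab) <- tab$roi
  pair_rows <- data.frame(
    unit = pairs$unit, type = "pair",
    wd = (tab[pairs$left, "wd"] + tab[pairs$right, "wd"]) / 2,
    d = (tab[pairs$left, "d"] + tab[pairs$right, "d"]) / 2,
    bc = (tab[pairs$left, "bc"] + tab[pairs$right, "bc"]) / 2,
    stringsAsFactors = FALSE)
  mid <- meta$name[meta$hemisphere == "midline" & meta$name %in% tab$roi]
  mid_rows <- if (length(mid))
    data.frame(unit = mid, type = "midline",
               wd = tab[mid, "wd"], d = tab[mid, "d"],
               bc = tab[mid, "bc"], stringsAsFactors = FALSE)
  else NULL
  out <- rbind(pair_rows, mid_rows)
  rownames(out) <- NULL
  out
}

#' Top-k ranking by one centrality metric
#'
#' Descending by the metric; ties broken alphabetically by unit name so
#' rankings are byte-reproducible.
#'
#' @param tab (pair-collapsed) centrality table with a `unit` or `roi`
#'   column.
#' @param metric one of `"wd"`, `"d"`, `"bc"`.
#' @param k number of rows.
#' @return data.frame `rank`, `unit`, `value`.
#' @export
top_k_nodes <- function(tab, metric = c("wd", "d", "bc"), k = 20L) {
  metric <- match.arg(metric)
  unit <- if ("unit" %in% names(tab)) tab$unit else tab$roi
  stopifnot(k <= length(unit))
  val <- tab[[metric]]
  ord <- order(-val, unit)
  out <- data.frame(rank = seq_len(k), unit = unit[ord][seq_len(k)],
                    value = val[ord][seq_len(k)], stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  out
}

#' Consensus hubs: intersection of the three top-k rankings
#'
#' Nodes (pairs/midline units) ranked in the top k for weighted degree,
#' degree, and betweenness simultaneously.
#'
#' @param rankings list of ranked tables from [top_k_nodes()] (their `unit`
#'   columns are intersected; each is truncated to its first `k` rows).
#' @param k top-list depth.
#' @return character vector of unit names (sorted).
#' @export
consensus_hubs <- function(rankings, k = 20L) {
  sets <- lapply(rankings, function(r) utils::head(r$unit, k))
  sort(Reduce(intersect, sets))
}

#' Write the three rankings and the consensus-hub set as TSVs
#'
#' @param rankings named list of ranked tables (`wd`, `d`, `bc`).
#' @param hubs consensus hub units.
#' @param dir output directory.
#' @export
write_rankings <- function(rankings, hubs, dir) {
  for (m in names(rankings)) {
    utils::write.table(rankings[[m]], file.path(dir, paste0("top_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(hubs, file.path(dir, "consensus_hubs.tsv"))
  invisible(dir)
}
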