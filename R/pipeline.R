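#' Default generator specification for the planted cohort
#'
#' The study conditions the whole analysis is exercised under: 33 subjects,
#' 264 volumes (two concatenated 132-volume runs), 97 ROIs in the
#' [default_module_plan()] layout, within-module loading 0.8, super-module
#' loading 0.5, sparse pairwise lateral couplings inside the super-modules
#' (cross-sub-module probability 0.3, within-sub-module 0.6, loading 0.4),
#' bilateral homolog coupling 0.35, AR(1) coefficient 0.4, unit noise, and
#' five planted hub pairs (both members of the first pair, by name order, of
#' five bilateral modules) with extra loading 0.4 onto three other modules
#' each.
#'
#' @param meta `roi_metadata` from the default plan.
#' @param seed master seed.
#' @return `generator_spec`.
#' @export
default_generator_spec <- function(meta, seed = 1L) {
  hub_modules <- intersect(
    c("Visual", "MedialPrefrontal", "DorsalPosteriorCingulate",
      "AnteriorCingulate", "MidCingulate"), meta$group)
  if (length(hub_modules) == 0) {
    # custom atlas: plant hubs in the most populous modules holding pairs
    cand <- meta[!is.na(meta$pair_id), ]
    per_group <- table(cand$group)
    hub_modules <- utils::head(names(per_group)[order(-as.integer(per_group),
                                                      names(per_group))], 5)
  }
  hub_ids <- unlist(lapply(hub_modules, function(m) {
    sub <- meta[meta$group == m & !is.na(meta$pair_id), ]
    first_pair <- sub$pair_id[order(sub$name)][1]
    meta$roi_id[!is.na(meta$pair_id) & meta$pair_id == first_pair]
  }))
  generator_spec(n_subjects = 33L, n_timepoints = 264L, loading = 0.8,
                 super_loading = 0.5, homolog_coupling = 0.35,
                 hub_ids = hub_ids, hub_loading = 0.4, hub_k = 3L,
                 super_link_prob = 0.3, super_link_loading = 0.4,
                 sub_link_prob = 0.6,
                 ar_coefficient = 0.4, noise_sd = 1, seed = seed)
}

#' Simulate a full synthetic cohort (metadata, time series, overlap tables)
#'
#' Generates the default planted cohort (or a variant via `plan` / `spec`),
#' including two independently jittered network-overlap tables for the
#' parcellation comparison and the planted ground-truth labels. If `out_dir`
#' is given, everything is persisted as TSV (metadata, one wide time-series
#' file per subject, the two overlap tables, and ground-truth labels).
#'
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param plan module plan (default [default_module_plan()]).
#' @param spec optional `generator_spec` (default
#'   [default_generator_spec()] with a derived seed).
#' @param jitter overlap-table jitter fraction.
#' @return list: `meta`, `ts` (list of matrices), `overlap_a`, `overlap_b`,
#'   `spec`, `hub_units` (pair stems of planted hubs), `truth_coarse`,
#'   `truth_fine` (named label vectors).
#' @export
simulate_cohort <- function(seed = 1L, out_dir = NULL,
                            plan = default_module_plan(), spec = NULL,
                            jitter = 0.3) {
  seeds <- derive_seeds(seed, 4)
  n_pairs <- (sum(plan$size) - infer_midline(plan)) / 2
  meta <- generate_metadata(n_pairs = n_pairs,
                            n_midline = infer_midline(plan),
                            module_plan = plan, seed = seeds[1])
  if (is.null(spec)) spec <- default_generator_spec(meta, seed = seeds[2])
  ts <- generate_timeseries(meta, spec)
  planted <- split(meta$name, meta$group)
  ov_a <- generate_overlap_table(meta, planted, jitter = jitter,
                                 seed = seeds[3])
  ov_b <- generate_overlap_table(meta, planted, jitter = jitter,
                                 seed = seeds[4])
  truth_coarse <- relabel0(meta$group)
  truth_fine <- relabel0(meta$subgroup)
  names(truth_coarse) <- names(truth_fine) <- meta$name
  hub_pairs <- unique(meta$pair_id[meta$roi_id %in% spec$hub_ids &
                                     !is.na(meta$pair_id)])
  hub_units <- bilateral_pairs(meta)
  hub_units <- hub_units$unit[hub_units$pair_id %in% hub_pairs]

  out <- list(meta = meta, ts = ts, overlap_a = ov_a, overlap_b = ov_b,
              spec = spec, hub_units = hub_units,
              truth_coarse = truth_coarse, truth_fine = truth_fine)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "timeseries"), showWarnings = FALSE)
    write_metadata(meta, file.path(out_dir, "metadata.tsv"))
    for (s in names(ts))
      write_timeseries(ts[[s]], file.path(out_dir, "timeseries",
                                          paste0(s, ".tsv")))
    write_overlap(ov_a, file.path(out_dir, "overlap_a.tsv"))
    write_overlap(ov_b, file.path(out_dir, "overlap_b.tsv"))
    truth <- data.frame(roi = meta$name, coarse = truth_coarse,
                        fine = truth_fine, hub = meta$roi_id %in% spec$hub_ids)
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

infer_midline <- function(plan) {
  # midline count implied by the default construction: odd-size
  # non-lateralized modules need one midline each, plus pairs of extras;
  # the default atlas fixes 7. For custom plans the caller supplies parity
  # via odd sizes only.
  if (identical(plan, default_module_plan())) return(7L)
  sum(plan$size[!plan$lateralized] %% 2)
}

#' Pipeline configuration
#'
#' Bundles and validates every tunable of the end-to-end analysis.
#'
#' @param seed_alpha FDR level of the per-seed omnibus threshold.
#' @param edge_alpha uncorrected per-edge threshold.
#' @param resolution community-detection resolution.
#' @param n_repeats consensus repeats.
#' @param n_null small-world null sample size.
#' @param n_perm sign-flip permutations.
#' @param top_k_hubs depth of the hub rankings.
#' @param seed master seed.
#' @param output_dir directory for persisted intermediates (NULL = keep in
#'   memory only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed_alpha = 0.05, edge_alpha = 0.01,
                            resolution = 0.6, n_repeats = 10L,
                            n_null = 100L, n_perm = 5000L,
                            top_k_hubs = 20L, seed = 1L,
                            output_dir = NULL) {
  stopifnot(seed_alpha > 0, seed_alpha < 1, edge_alpha > 0, edge_alpha < 1,
            resolution > 0, n_repeats >= 1, n_null >= 1, n_perm >= 1,
            top_k_hubs >= 1)
  structure(list(seed_alpha = seed_alpha, edge_alpha = edge_alpha,
                 resolution = resolution, n_repeats = as.integer(n_repeats),
                 n_null = as.integer(n_null), n_perm = as.integer(n_perm),
                 top_k_hubs = as.integer(top_k_hubs),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis on an in-memory cohort
#'
#' connectivity -> graph -> small-world -> two-layer communities ->
#' centrality/hubs -> (optional) parcellation comparison. The master seed
#' spawns one child seed per stochastic stage via [derive_seeds()], so any
#' stage can be reproduced in isolation. When the thresholded graph is empty
#' the downstream stages are skipped and flagged rather than erroring.
#'
#' @param meta `roi_metadata`.
#' @param ts list of time-series matrices.
#' @param cfg `pipeline_config`.
#' @param overlap_a,overlap_b optional overlap tables for the parcellation
#'   comparison.
#' @return list of class `run_report` (see fields in the source); persists
#'   intermediates under `cfg$output_dir` when set.
#' @export
run_pipeline <- function(meta, ts, cfg = pipeline_config(),
                         overlap_a = NULL, overlap_b = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage_seeds <- derive_seeds(cfg$seed, 4)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[dogconn] ", ...)
  warnings_seen <- character(0)
  with_wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  log_line("stage connectivity: ", length(ts), " subjects, ", nrow(meta),
           " ROIs")
  cohort <- with_wcollect(lapply(ts, semipartial_matrix))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "connectivity"), showWarnings = FALSE)
    for (i in seq_along(cohort))
      write_connectivity(cohort[[i]],
                         file.path(out_dir, "connectivity",
                                   paste0(names(ts)[i], ".csv")))
  }
  stats <- with_wcollect(
    group_edge_stats(cohort, n_perm = cfg$n_perm, seed = stage_seeds[1]))
  edges <- threshold_edges(stats, seed_alpha = cfg$seed_alpha,
                           edge_alpha = cfg$edge_alpha)
  if (!is.null(out_dir))
    write_group_stats(stats, file.path(out_dir, "edge_stats.tsv"),
                      file.path(out_dir, "seed_stats.tsv"))

  log_line("stage network_build: ", nrow(edges), " edges retained")
  g <- build_graph(edges, meta)
  report <- list(
    n_subjects = length(ts),
    N = igraph::vcount(g), E = igraph::ecount(g),
    density = connection_density(g),
    triangles = triangle_count(g),
    degenerate = character(0))
  if (!is.null(out_dir))
    export_graph(g, file.path(out_dir, "graph.graphml"),
                 file.path(out_dir, "edges.csv"))

  if (report$E == 0) {
    log_line("empty graph: downstream stages skipped")
    report$degenerate <- c("small_world", "communities", "centrality")
    report$C <- report$L <- report$gamma <- report$lambda <-
      report$sigma <- NA_real_
    report$n_modules_layer1 <- report$n_modules_final <- NA_integer_
  } else {
    report$C <- clustering_coefficient(g)
    report$L <- as.numeric(char_path_length(g))
    sw <- with_wcollect(tryCatch(
      small_world(g, n_null = cfg$n_null, seed = stage_seeds[2]),
      error = function(e) NULL))
    if (is.null(sw)) {   # e.g. triangle-free rewired nulls on tiny graphs
      report$degenerate <- c(report$degenerate, "small_world")
      report$gamma <- report$lambda <- report$sigma <- NA_real_
    } else {
      report$C_rand <- sw$C_rand; report$L_rand <- sw$L_rand
      report$gamma <- sw$gamma; report$lambda <- sw$lambda
      report$sigma <- sw$sigma
      log_line("stage small_world: sigma = ", round(sw$sigma, 3))
    }

    part1 <- consensus_partition(g, resolution = cfg$resolution,
                                 n_repeats = cfg$n_repeats,
                                 seed = stage_seeds[3])
    part2 <- with_wcollect(
      split_lateralized(g, part1, meta, top_k = 2L,
                        n_repeats = cfg$n_repeats, seed = stage_seeds[4]))
    dens <- community_density(g, part2)
    report$n_modules_layer1 <- length(unique(part1$labels))
    report$n_modules_final <- length(unique(part2$labels))
    report$Q_layer1 <- part1$Q
    report$community_density <- dens
    report$partition <- part2
    log_line("stage communities: ", report$n_modules_layer1, " -> ",
             report$n_modules_final, " modules")
    if (!is.null(out_dir))
      write_partition(part2, dens, file.path(out_dir, "partition.tsv"),
                      file.path(out_dir, "community_density.tsv"))

    sym <- with_wcollect(tryCatch(homolog_symmetry(g, meta),
                                  error = function(e) NULL))
    if (is.null(sym)) {
      report$degenerate <- c(report$degenerate, "homolog_symmetry")
    } else {
      report$rho_degree <- sym$rho_degree
      report$rho_weight <- sym$rho_weight
    }

    cent <- node_centralities(g)
    pairtab <- bilateral_average(cent, meta)
    k <- min(cfg$top_k_hubs, nrow(pairtab))
    rankings <- list(wd = top_k_nodes(pairtab, "wd", k),
                     d = top_k_nodes(pairtab, "d", k),
                     bc = top_k_nodes(pairtab, "bc", k))
    report$rankings <- rankings
    report$consensus_hubs <- consensus_hubs(rankings, k)
    log_line("stage centrality: ", length(report$consensus_hubs),
             " consensus hubs")
    if (!is.null(out_dir)) write_rankings(rankings, report$consensus_hubs,
                                          out_dir)
  }

  if (!is.null(overlap_a) && !is.null(overlap_b)) {
    assign_a <- with_wcollect(allocate_rois(overlap_a, meta))
    assign_b <- with_wcollect(allocate_rois(overlap_b, meta))
    jt <- match_networks(assign_a, assign_b)
    report$jaccard_table <- jt
    report$mean_jaccard <- mean(jt$jaccard, na.rm = TRUE)
    log_line("stage parcellation_compare: mean Jaccard = ",
             round(report$mean_jaccard, 3))
    if (!is.null(out_dir))
      utils::write.table(jt, file.path(out_dir, "jaccard.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  report$warnings <- warnings_seen
  report$provenance <- list(
    seed = cfg$seed, stage_seeds = stage_seeds,
    config = unclass(cfg)[setdiff(names(cfg), "output_dir")],
    package_version = as.character(utils::packageVersion("dogconn")))
  report$provenance$config_hash <- config_hash(report$provenance$config)
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Resting-state connectome run report\n")
  cat(sprintf("  subjects: %d   ROIs: %d   edges: %d   density: %.3f\n",
              x$n_subjects, x$N, x$E, x$density))
  if (!is.na(x$sigma))
    cat(sprintf("  C = %.3f  L = %.3f  gamma = %.2f  lambda = %.2f  sigma = %.2f\n",
                x$C, x$L, x$gamma, x$lambda, x$sigma))
  if (!is.null(x$n_modules_layer1) && !is.na(x$n_modules_layer1))
    cat(sprintf("  modules: %d (layer 1) -> %d (final)\n",
                x$n_modules_layer1, x$n_modules_final))
  if (!is.null(x$consensus_hubs))
    cat("  consensus hubs:", paste(x$consensus_hubs, collapse = ", "), "\n")
  if (!is.null(x$mean_jaccard))
    cat(sprintf("  mean parcellation Jaccard: %.3f\n", x$mean_jaccard))
  if (length(x$degenerate))
    cat("  degenerate stages:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Write a run report as JSON
#'
#' Scalars, the community density table, rankings, hubs and Jaccard table;
#' byte-identical for identical cohort + config + seed.
#'
#' @param report `run_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  ser <- report
  ser$partition <- if (!is.null(report$partition))
    as.list(report$partition$labels) else NULL
  class(ser) <- NULL
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper over [run_pipeline()] reading a cohort persisted by
#' [simulate_cohort()] (metadata TSV, a directory of per-subject time-series
#' TSVs, optional overlap TSVs).
#'
#' @param metadata_path metadata TSV.
#' @param timeseries_dir directory of per-subject `.tsv` files.
#' @param cfg `pipeline_config`.
#' @param overlap_a_path,overlap_b_path optional overlap TSVs.
#' @return `run_report`.
#' @export
run_pipeline_files <- function(metadata_path, timeseries_dir,
                               cfg = pipeline_config(),
                               overlap_a_path = NULL, overlap_b_path = NULL) {
  meta <- read_metadata(metadata_path)
  files <- sort(list.files(timeseries_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0)
    stop("no time-series files in ", timeseries_dir, call. = FALSE)
  ts <- lapply(files, read_timeseries)
  names(ts) <- sub("\\.tsv$", "", basename(files))
  ov_a <- if (!is.null(overlap_a_path)) read_overlap(overlap_a_path)
  ov_b <- if (!is.null(overlap_b_path)) read_overlap(overlap_b_path)
  run_pipeline(meta, ts, cfg, overlap_a = ov_a, overlap_b = ov_b)
}
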