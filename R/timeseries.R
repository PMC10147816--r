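#' Specification of the synthetic cohort generator
#'
#' The generative model is a linear latent-factor model with AR(1) temporal
#' structure, the simplest process producing the block covariance plus
#' autocorrelation typical of denoised BOLD. Every ROI signal is
#'
#' \deqn{x = \lambda F_{sub} + \lambda_{sup} G_{group} + c H_{pair}
#'       + \sum_k h F_{target_k} + \sigma \epsilon,}
#'
#' where `F_sub` is the ROI's planted (sub)module factor, `G_group` an extra
#' shared factor for modules hiding >1 sub-module (the lateralized
#' super-modules), `H_pair` a factor shared by the two bilateral homologs,
#' the `h`-terms extra cross-loadings onto `k` other modules' factors for
#' planted hub ROIs, and `\epsilon` AR(1) noise. All latent components are
#' AR(1) processes with coefficient `ar_coefficient` scaled to unit
#' stationary variance, so pairwise correlations follow in closed form from
#' the loadings. Columns are standardized after generation.
#'
#' @param n_subjects cohort size.
#' @param n_timepoints volumes per subject.
#' @param loading within-(sub)module factor loading `\lambda`.
#' @param super_loading loading `\lambda_sup` on the shared super-module
#'   factor (only modules with >1 planted sub-module).
#' @param homolog_coupling loading `c` on the pair-shared factor, in `[0, 1]`.
#' @param hub_ids roi_id values of planted hub nodes.
#' @param hub_loading extra loading `h` of hubs onto other modules' factors.
#' @param hub_k number of other modules each hub loads onto.
#' @param super_link_prob probability that a cross-sub-module pair inside a
#'   super-module receives a pair-specific lateral coupling factor. A
#'   diffuse factor shared by all ~15 members of a super-module is removed
#'   almost entirely by the semi-partial estimator (its contribution to any
#'   one pair is explained away by the remaining members), so the
#'   within-hemisphere cohesion of a super-module is planted the way it
#'   plausibly arises anatomically: sparse pairwise couplings between
#'   neighbouring regions. The link set is drawn once per cohort.
#' @param super_link_loading loading of those lateral coupling factors.
#' @param sub_link_prob probability of an additional pair-specific lateral
#'   coupling between members of the same sub-module inside a super-module
#'   (reinforces sub-module cohesion the same pairwise way).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param noise_sd noise scale `\sigma` (stationary SD).
#' @param seed master seed for the cohort.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 33L, n_timepoints = 264L,
                           loading = 0.8, super_loading = 0.5,
                           homolog_coupling = 0.35,
                           hub_ids = integer(0), hub_loading = 0.4,
                           hub_k = 3L, super_link_prob = 0.3,
                           super_link_loading = 0.4, sub_link_prob = 0.6,
                           ar_coefficient = 0.4,
                           noise_sd = 1, seed = 1L) {
  if (ar_coefficient >= 1 || ar_coefficient < 0)
    stop("ar_coefficient must lie in [0, 1) for stationarity", call. = FALSE)
  stopifnot(n_subjects >= 1, n_timepoints >= 2,
            homolog_coupling >= 0, homolog_coupling <= 1,
            loading >= 0, super_loading >= 0, hub_loading >= 0,
            super_link_prob >= 0, super_link_prob <= 1,
            sub_link_prob >= 0, sub_link_prob <= 1,
            super_link_loading >= 0, noise_sd > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 loading = loading, super_loading = super_loading,
                 homolog_coupling = homolog_coupling,
                 hub_ids = as.integer(hub_ids), hub_loading = hub_loading,
                 hub_k = as.integer(hub_k),
                 super_link_prob = super_link_prob,
                 super_link_loading = super_link_loading,
                 sub_link_prob = sub_link_prob,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# AR(1) sample of length n with unit stationary variance (burn-in discarded)
ar1_series <- function(n, phi, burn = 100L) {
  innov_sd <- if (phi > 0) sqrt(1 - phi^2) else 1
  e <- stats::rnorm(n + burn, sd = innov_sd)
  x <- stats::filter(e, phi, method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

# deterministic hub -> target-module map: each hub loads onto the hub_k most
# populous modules other than its own (ties by name), so hub-borne bridges
# attach to large communities whose degree-based null term resists merging
hub_targets <- function(meta, spec) {
  sizes <- table(meta$group)
  groups <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  out <- list()
  for (id in spec$hub_ids) {
    own <- meta$group[meta$roi_id == id]
    others <- setdiff(groups, own)
    out[[as.character(id)]] <- utils::head(others, spec$hub_k)
  }
  out
}

#' Generate a cohort of synthetic ROI time series
#'
#' Draws subject-level realisations of the latent-factor model described in
#' [generator_spec()]. All latent factors are redrawn per subject; column
#' order follows `meta`; every column is standardized to sample mean 0 and
#' SD 1. Identical `meta`, `spec` (including seed) reproduce the output
#' bit-for-bit.
#'
#' @param meta `roi_metadata` table.
#' @param spec `generator_spec`.
#' @return named list of `n_subjects` numeric matrices
#'   (`n_timepoints` x ROIs) with ROI names as column names.
#' @export
generate_timeseries <- function(meta, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$ar_coefficient >= 1)
    stop("ar_coefficient must be < 1 for stationarity", call. = FALSE)
  if (length(spec$hub_ids) && !all(spec$hub_ids %in% meta$roi_id))
    stop("hub_ids not present in metadata", call. = FALSE)

  p <- nrow(meta)
  tp <- spec$n_timepoints
  phi <- spec$ar_coefficient
  subgroups <- unique(meta$subgroup)
  super_groups <- unique(meta$group[ave(meta$subgroup, meta$group,
                                       FUN = function(s) length(unique(s))) > 1])
  pair_ids <- sort(unique(meta$pair_id[!is.na(meta$pair_id)]))
  targets <- hub_targets(meta, spec)
  # a hub's extra loading attaches to the target module's principal factor:
  # the single subgroup factor, or the shared super factor for super-modules
  principal_of <- function(g) {
    if (g %in% super_groups) paste0("G::", g)
    else unique(meta$subgroup[meta$group == g])[1]
  }

  seeds <- derive_seeds(spec$seed, spec$n_subjects + 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # cohort-level lateral link set inside super-modules: cross-sub pairs,
  # drawn once so the planted structure is common to all subjects
  set.seed(seeds[spec$n_subjects + 1L])
  sub_lp <- if (is.null(spec$sub_link_prob)) 0 else spec$sub_link_prob
  super_links <- NULL
  for (grp in super_groups) {
    mem <- which(meta$group == grp)
    for (a in mem) for (b in mem) {
      if (a >= b) next
      lp <- if (meta$subgroup[a] != meta$subgroup[b])
        spec$super_link_prob else sub_lp
      if (stats::runif(1) < lp)
        super_links <- rbind(super_links, c(a, b))
    }
  }

  out <- vector("list", spec$n_subjects)
  names(out) <- sprintf("sub%02d", seq_len(spec$n_subjects))
  for (s in seq_len(spec$n_subjects)) {
    set.seed(seeds[s])
    f_sub <- sapply(subgroups, function(x) ar1_series(tp, phi))
    colnames(f_sub) <- subgroups
    g_sup <- if (length(super_groups))
      sapply(super_groups, function(x) ar1_series(tp, phi)) else NULL
    if (!is.null(g_sup)) colnames(g_sup) <- super_groups
    h_pair <- if (length(pair_ids))
      sapply(pair_ids, function(x) ar1_series(tp, phi)) else NULL
    if (!is.null(h_pair)) colnames(h_pair) <- as.character(pair_ids)
    link_f <- if (!is.null(super_links))
      sapply(seq_len(nrow(super_links)), function(x) ar1_series(tp, phi))
    else NULL

    X <- matrix(0, tp, p, dimnames = list(NULL, meta$name))
    for (j in seq_len(p)) {
      x <- spec$loading * f_sub[, meta$subgroup[j]]
      if (meta$group[j] %in% super_groups)
        x <- x + spec$super_loading * g_sup[, meta$group[j]]
      if (!is.na(meta$pair_id[j]))
        x <- x + spec$homolog_coupling * h_pair[, as.character(meta$pair_id[j])]
      tg <- targets[[as.character(meta$roi_id[j])]]
      for (g in tg) {
        pf <- principal_of(g)
        comp <- if (startsWith(pf, "G::"))
          g_sup[, sub("^G::", "", pf)] else f_sub[, pf]
        x <- x + spec$hub_loading * comp
      }
      X[, j] <- x + spec$noise_sd * ar1_series(tp, phi)
    }
    if (!is.null(link_f)) {
      for (l in seq_len(nrow(super_links))) {
        X[, super_links[l, 1]] <- X[, super_links[l, 1]] +
          spec$super_link_loading * link_f[, l]
        X[, super_links[l, 2]] <- X[, super_links[l, 2]] +
          spec$super_link_loading * link_f[, l]
      }
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    attr(X, "subject_id") <- names(out)[s]
    out[[s]] <- X
  }
  out
}

#' Write / read one subject's time series as TSV
#'
#' Wide layout: first column `t` (volume index from 1), remaining columns
#' named by ROI.
#'
#' @param ts numeric matrix (timepoints x ROIs) with ROI column names.
#' @param path file path.
#' @return `read_timeseries` returns the matrix with a `subject_id`
#'   attribute taken from the file name.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(t = seq_len(nrow(ts)), ts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in time series ", path, call. = FALSE)
  attr(m, "subject_id") <- sub("\\.tsv$", "", basename(path))
  m
}
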