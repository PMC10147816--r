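#' Symmetrized semi-partial correlation matrix for one subject
#'
#' The first-level connectivity estimate. For each ordered ROI pair the
#' semi-partial (part) correlation `s(i -> j)` is the Pearson correlation
#' between the raw signal of ROI `j` and the residual of ROI `i` after
#' ordinary least-squares regression on all remaining ROIs (all except `i`
#' and `j`), i.e. the unique contribution of `i` to `j` after discounting
#' every other region. The inherently directed values are symmetrized by
#' averaging, `r_ij = (s(i->j) + s(j->i)) / 2`, and Fisher z-transformed.
#'
#' Computation uses the precision-matrix identity for the conditional
#' covariance of a pair given the rest: with `K = S^{-1}` (S the sample
#' covariance),
#' `s(i->j) = -K_ij / sqrt(K_jj (K_ii K_jj - K_ij^2) S_jj)`,
#' which equals explicit per-pair residualization exactly but needs a single
#' matrix inversion. With only two ROIs the controlling set is empty and the
#' value is the plain Pearson correlation.
#'
#' @param ts numeric matrix, rows = timepoints, columns = ROIs (named).
#' @return list of class `subject_connectivity` with elements `r` (symmetric
#'   semi-partial correlation matrix, zero diagonal) and `z` (Fisher
#'   transform), plus `subject_id` if present on `ts`.
#' @export
semipartial_matrix <- function(ts) {
  X <- as.matrix(ts)
  tp <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least two ROIs", call. = FALSE)
  if (tp <= p - 1)
    stop("need more timepoints (", tp, ") than ROIs minus one (", p - 1,
         ") for full-rank regression", call. = FALSE)
  if (p == 2) {
    r12 <- stats::cor(X[, 1], X[, 2])
    r <- matrix(c(0, r12, r12, 0), 2, 2, dimnames = list(colnames(X), colnames(X)))
    return(new_subject_connectivity(r, attr(ts, "subject_id")))
  }
  S <- stats::cov(X)
  K <- tryCatch(solve(S), error = function(e) {
    qx <- qr(X)
    bad <- if (qx$rank < p)
      paste(colnames(X)[qx$pivot[seq(qx$rank + 1, p)]], collapse = ", ")
    else "<numerically ill-conditioned>"
    stop("rank-deficient regressor matrix; collinear ROI set includes: ",
         bad, call. = FALSE)
  })
  dK <- diag(K)
  det_ij <- outer(dK, dK) - K^2          # K_ii K_jj - K_ij^2
  # s[i, j] = s(i -> j)
  s <- -K / sqrt(det_ij * outer(rep(1, p), dK * diag(S)))
  r <- (s + t(s)) / 2
  diag(r) <- 0
  dimnames(r) <- list(colnames(X), colnames(X))
  new_subject_connectivity(r, attr(ts, "subject_id"))
}

new_subject_connectivity <- function(r, subject_id = NULL) {
  structure(list(r = r, z = fisher_z(r), subject_id = subject_id),
            class = "subject_connectivity")
}

#' Fisher z-transform of a correlation
#'
#' Variance-stabilizing `atanh` transform applied before group-level
#' t-statistics. Correlations at or beyond +/-1 (possible with degenerate
#' synthetic signals) are clamped to `+/-(1 - 1e-7)` with a warning.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return z-value(s), same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlations at |r| >= 1 clamped to 1 - 1e-7 before atanh")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Group-level edge statistics with per-seed sign-flip omnibus test
#'
#' Second-level inference: does the average connectivity of an edge differ
#' from zero across subjects? Per edge, a one-sample two-sided t-test of the
#' Fisher z-values against 0. Per seed ROI, an omnibus test of its whole
#' connectivity profile: the observed statistic is the mean over the seed's
#' edges of `|mean_z|`, compared against `n_perm` random subject-level sign
#' flips of the z-matrices, with the permutation-count correction
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`. Seed p-values are
#' Benjamini-Hochberg adjusted across ROIs.
#'
#' Edges whose z-values have zero variance across subjects but a nonzero
#' mean get a `p_edge` underflow sentinel (the smallest positive double)
#' with a warning; all-zero edges get `t = 0`, `p_edge = 1`.
#'
#' @param cohort list of `subject_connectivity` objects sharing ROI order.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed for the permutation draws.
#' @return list of class `group_edge_stats`: `edges` data.frame
#'   (`roi_i`, `roi_j`, `mean_z`, `t`, `p_edge`) over all unordered pairs,
#'   `seeds` data.frame (`roi`, `p_seed`, `q_seed`), `n_subjects`, `rois`.
#' @export
group_edge_stats <- function(cohort, n_perm = 5000L, seed = 1L) {
  stopifnot(length(cohort) >= 3)
  rois <- colnames(cohort[[1]]$r)
  for (sc in cohort) {
    if (!identical(colnames(sc$r), rois))
      stop("subjects have mismatched ROI sets/order", call. = FALSE)
  }
  p <- length(rois)
  pairs <- upper_pairs(p)
  n_edge <- nrow(pairs)
  n <- length(cohort)
  Z <- t(vapply(cohort, function(sc) sc$z[pairs], numeric(n_edge)))

  mean_z <- colMeans(Z)
  sd_z <- apply(Z, 2, stats::sd)
  tstat <- ifelse(sd_z > 0, mean_z / (sd_z / sqrt(n)), ifelse(mean_z == 0, 0, Inf))
  p_edge <- ifelse(is.finite(tstat),
                   2 * stats::pt(-abs(tstat), df = n - 1),
                   .Machine$double.xmin)
  if (any(!is.finite(tstat))) {
    warning(sum(!is.finite(tstat)),
            " zero-variance edge(s): p_edge set to underflow sentinel")
    tstat[!is.finite(tstat)] <- sign(mean_z[!is.finite(tstat)]) / .Machine$double.eps
  }
  p_edge[p_edge == 0] <- .Machine$double.xmin

  # seed-level omnibus: mean |mean_z| over the seed's incident edges
  inc <- matrix(0, n_edge, p)
  inc[cbind(seq_len(n_edge), pairs[, 1])] <- 1
  inc[cbind(seq_len(n_edge), pairs[, 2])] <- 1
  obs <- as.numeric(abs(mean_z) %*% inc) / (p - 1)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_mean <- (signs %*% Z) / n
  perm_stat <- (abs(perm_mean) %*% inc) / (p - 1)
  exceed <- colSums(perm_stat >= matrix(obs, n_perm, p, byrow = TRUE))
  p_seed <- (1 + exceed) / (1 + n_perm)
  q_seed <- bh_fdr(p_seed)

  structure(list(
    edges = data.frame(roi_i = rois[pairs[, 1]], roi_j = rois[pairs[, 2]],
                       mean_z = mean_z, t = tstat, p_edge = p_edge,
                       stringsAsFactors = FALSE),
    seeds = data.frame(roi = rois, p_seed = p_seed, q_seed = q_seed,
                       stringsAsFactors = FALSE),
    n_subjects = n, rois = rois),
    class = "group_edge_stats")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (q-values), capped at 1 and monotone
#' in rank; delegates to [stats::p.adjust()].
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return q-values in input order; empty input gives an empty vector.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Two-level edge thresholding
#'
#' Retains edge `(i, j)` iff its uncorrected per-edge p-value passes
#' `edge_alpha` AND at least one endpoint's FDR-adjusted omnibus q-value
#' passes `seed_alpha` — the connection-level threshold nested inside the
#' seed-level (cluster) threshold. Retained edges carry weight `|t|` by
#' default (group test-statistic magnitude) or `|mean_z|`.
#'
#' @param stats `group_edge_stats`.
#' @param seed_alpha FDR level for the per-seed omnibus test.
#' @param edge_alpha uncorrected per-edge level.
#' @param weight `"abs_t"` (default) or `"abs_mean_z"`.
#' @return data.frame (`roi_i`, `roi_j`, `weight`, `t`, `mean_z`, `p_edge`)
#'   sorted by (`roi_i`, `roi_j`).
#' @export
threshold_edges <- function(stats, seed_alpha = 0.05, edge_alpha = 0.01,
                            weight = c("abs_t", "abs_mean_z")) {
  weight <- match.arg(weight)
  stopifnot(inherits(stats, "group_edge_stats"))
  q <- stats$seeds$q_seed
  names(q) <- stats$seeds$roi
  e <- stats$edges
  keep <- e$p_edge < edge_alpha &
    (q[e$roi_i] < seed_alpha | q[e$roi_j] < seed_alpha)
  out <- e[keep, , drop = FALSE]
  out$weight <- if (weight == "abs_t") abs(out$t) else abs(out$mean_z)
  out <- out[order(out$roi_i, out$roi_j),
             c("roi_i", "roi_j", "weight", "t", "mean_z", "p_edge")]
  rownames(out) <- NULL
  out
}

#' Write one subject's connectivity matrix as CSV (square, ROI-named)
#'
#' @param sc `subject_connectivity`.
#' @param path file path.
#' @export
write_connectivity <- function(sc, path) {
  utils::write.csv(sc$r, path, quote = FALSE)
  invisible(path)
}

#' Write group edge statistics as two TSVs (per-edge and per-seed)
#'
#' @param stats `group_edge_stats`.
#' @param edge_path,seed_path file paths.
#' @export
write_group_stats <- function(stats, edge_path, seed_path) {
  utils::write.table(stats$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(stats$seeds, seed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, seed_path))
}
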