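#' Generate a synthetic network-by-ROI voxel overlap table
#'
#' Emulates counting overlap voxels between a voxelwise network decomposition
#' (e.g. ICA spatial maps registered to the atlas) and the ROI atlas. Each
#' ROI has a per-ROI voxel budget; its planted network receives a `1 - jitter`
#' share and the remaining `jitter` share is split randomly across the other
#' networks, so at any `jitter < 0.5` the planted network keeps the majority
#' of the ROI's voxels.
#'
#' @param meta `roi_metadata` table.
#' @param planted_networks named list mapping network name to a character
#'   vector of member ROI names. Every ROI must belong to at most one
#'   network; unlisted ROIs get all-zero columns.
#' @param jitter fraction in `[0, 1)` of each ROI's voxels leaked to
#'   non-planted networks.
#' @param seed integer seed.
#' @param base_voxels mean per-ROI voxel budget.
#' @return integer matrix of class `parcellation_overlap`, rows = networks,
#'   columns = ROIs (named).
#' @export
generate_overlap_table <- function(meta, planted_networks, jitter = 0,
                                   seed = 1L, base_voxels = 200L) {
  if (jitter < 0 || jitter >= 1)
    stop("jitter must lie in [0, 1)", call. = FALSE)
  members <- unlist(planted_networks, use.names = FALSE)
  if (anyDuplicated(members))
    stop("an ROI may be planted in at most one network", call. = FALSE)
  if (!all(members %in% meta$name))
    stop("planted networks reference unknown ROIs", call. = FALSE)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  nets <- names(planted_networks)
  ov <- matrix(0L, length(nets), nrow(meta),
               dimnames = list(nets, meta$name))
  allocatable <- nets[lengths(planted_networks) > 0]
  for (roi in members) {
    own <- nets[vapply(planted_networks, function(x) roi %in% x, logical(1))]
    n_vox <- stats::rpois(1, base_voxels)
    leak <- round(jitter * n_vox)
    ov[own, roi] <- n_vox - leak
    others <- setdiff(allocatable, own)
    if (leak > 0 && length(others) > 0) {
      split <- stats::rmultinom(1, leak, rep(1, length(others)))[, 1]
      ov[others, roi] <- ov[others, roi] + split
    }
  }
  storage.mode(ov) <- "integer"
  class(ov) <- c("parcellation_overlap", class(ov))
  ov
}

#' Write / read an overlap table as TSV (rows = networks, columns = ROIs)
#'
#' @param ov overlap matrix.
#' @param path file path.
#' @export
write_overlap <- function(ov, path) {
  df <- data.frame(network = rownames(ov), unclass(ov), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap
#' @export
read_overlap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$network
  storage.mode(m) <- "integer"
  class(m) <- c("parcellation_overlap", class(m))
  m
}
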