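#' Generate an ROI atlas metadata table with bilateral pairs and planted modules
#'
#' Builds the per-ROI metadata the whole pipeline keys on: ROI identity,
#' hemisphere, bilateral homolog pairing, and planted module membership.
#' Bilateral pair members are assigned to the same module, except for
#' lateralized modules, which are declared as consecutive equal-size twins in
#' `module_plan`: the left member of each consumed pair goes to the first
#' twin, the right member to the second. Modules may additionally declare
#' `n_sub` planted sub-modules; the `subgroup` column records this finer
#' ground truth (used by the second community layer), splitting members as
#' evenly as possible (by whole pairs for non-lateralized modules).
#'
#' @param n_pairs number of bilateral homolog pairs.
#' @param n_midline number of unpaired midline ROIs.
#' @param module_plan data.frame with columns `name`, `size` and optionally
#'   `lateralized` (logical, default FALSE) and `n_sub` (integer, default 1).
#'   `sum(size)` must equal `2 * n_pairs + n_midline`.
#' @param seed integer seed controlling the (deterministic) shuffling of
#'   pair-to-module assignment.
#' @return data.frame of class `roi_metadata` with columns `roi_id` (0-based,
#'   contiguous), `name`, `hemisphere` (`left`/`right`/`midline`), `pair_id`
#'   (integer or NA), `group`, `subgroup`.
#' @export
generate_metadata <- function(n_pairs, n_midline, module_plan, seed = 1L) {
  plan <- as.data.frame(module_plan)
  stopifnot(all(c("name", "size") %in% names(plan)))
  if (is.null(plan$lateralized)) plan$lateralized <- FALSE
  if (is.null(plan$n_sub)) plan$n_sub <- 1L
  total_rois <- 2L * n_pairs + n_midline
  if (sum(plan$size) != total_rois) {
    stop("module plan totals ", sum(plan$size), " ROIs but pairs/midline give ",
         total_rois, call. = FALSE)
  }

  # lateralized modules must arrive as consecutive equal-size twins (L, R)
  lat_idx <- which(plan$lateralized)
  if (length(lat_idx) %% 2 != 0)
    stop("lateralized modules must be declared as L/R twins", call. = FALSE)
  twin_first <- lat_idx[seq_along(lat_idx) %% 2 == 1]
  for (i in twin_first) {
    if (!isTRUE(plan$lateralized[i + 1]) || plan$size[i] != plan$size[i + 1])
      stop("lateralized twins must be consecutive and of equal size",
           call. = FALSE)
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_lat_pairs <- sum(plan$size[twin_first])
  if (n_lat_pairs > n_pairs)
    stop("lateralized modules require ", n_lat_pairs, " pairs but only ",
         n_pairs, " exist", call. = FALSE)

  # midline allocation: one to each odd-size non-lateralized module, the
  # (necessarily even) remainder two at a time; remaining capacity is then
  # even and filled with whole pairs
  nl <- which(!plan$lateralized)
  midline_alloc <- integer(nrow(plan))
  odd <- nl[plan$size[nl] %% 2 == 1]
  if (length(odd) > n_midline)
    stop(length(odd), " odd-size modules but only ", n_midline,
         " midline ROIs", call. = FALSE)
  midline_alloc[odd] <- 1L
  left_over <- n_midline - length(odd)
  if (left_over %% 2 != 0)
    stop("midline/parity mismatch in module plan", call. = FALSE)
  k <- 1
  while (left_over > 0) {
    cand <- nl[plan$size[nl] - midline_alloc[nl] >= 2]
    if (length(cand) == 0) stop("cannot place midline ROIs", call. = FALSE)
    cand <- cand[order(-plan$size[cand])]   # largest modules absorb extras
    tgt <- cand[((k - 1) %% length(cand)) + 1]
    midline_alloc[tgt] <- midline_alloc[tgt] + 2L
    left_over <- left_over - 2L
    k <- k + 1
  }
  pair_alloc <- integer(nrow(plan))
  pair_alloc[nl] <- (plan$size[nl] - midline_alloc[nl]) %/% 2L
  pair_alloc[twin_first] <- plan$size[twin_first]
  if (sum(pair_alloc) != n_pairs)
    stop("internal pair allocation mismatch", call. = FALSE)

  pair_order <- sample.int(n_pairs)   # which physical pair lands where
  rows <- list()
  pair_cursor <- 0L
  midline_cursor <- 0L
  for (m in seq_len(nrow(plan))) {
    if (plan$lateralized[m] && !(m %in% twin_first)) next
    mod_name <- plan$name[m]
    n_sub <- max(1L, plan$n_sub[m])
    if (plan$lateralized[m]) {
      ids <- pair_order[pair_cursor + seq_len(pair_alloc[m])]
      pair_cursor <- pair_cursor + pair_alloc[m]
      sub_of <- rep(seq_len(n_sub), length.out = length(ids))
      sub_of <- sort(sub_of)
      twin_r <- plan$name[m + 1]
      for (s in seq_along(ids)) {
        base <- sprintf("roi%03d", ids[s])
        sgL <- if (n_sub > 1) paste0(mod_name, ".", letters[sub_of[s]]) else mod_name
        sgR <- if (n_sub > 1) paste0(twin_r, ".", letters[sub_of[s]]) else twin_r
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0(base, c("_L", "_R")),
          hemisphere = c("left", "right"),
          pair_id = ids[s],
          group = c(mod_name, twin_r),
          subgroup = c(sgL, sgR))
      }
    } else {
      ids <- if (pair_alloc[m] > 0)
        pair_order[pair_cursor + seq_len(pair_alloc[m])] else integer(0)
      pair_cursor <- pair_cursor + pair_alloc[m]
      n_units <- pair_alloc[m] + midline_alloc[m]
      sub_of <- sort(rep(seq_len(n_sub), length.out = n_units))
      u <- 0L
      for (s in seq_along(ids)) {
        u <- u + 1L
        base <- sprintf("roi%03d", ids[s])
        sg <- if (n_sub > 1) paste0(mod_name, ".", letters[sub_of[u]]) else mod_name
        rows[[length(rows) + 1]] <- data.frame(
          name = paste0(base, c("_L", "_R")),
          hemisphere = c("left", "right"),
          pair_id = ids[s],
          group = mod_name, subgroup = sg)
      }
      if (midline_alloc[m] > 0) {
        for (j in seq_len(midline_alloc[m])) {
          u <- u + 1L
          midline_cursor <- midline_cursor + 1L
          sg <- if (n_sub > 1) paste0(mod_name, ".", letters[sub_of[u]]) else mod_name
          rows[[length(rows) + 1]] <- data.frame(
            name = sprintf("mid%03d_M", midline_cursor),
            hemisphere = "midline", pair_id = NA_integer_,
            group = mod_name, subgroup = sg)
        }
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta <- data.frame(roi_id = seq_len(nrow(meta)) - 1L, meta,
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  validate_metadata(meta)
  class(meta) <- c("roi_metadata", "data.frame")
  meta
}

validate_metadata <- function(meta) {
  stopifnot(!anyDuplicated(meta$name),
            identical(meta$roi_id, seq_len(nrow(meta)) - 1L))
  pid <- meta$pair_id[!is.na(meta$pair_id)]
  tab <- table(pid)
  if (any(tab != 2)) stop("pair_id must occur exactly twice", call. = FALSE)
  for (p in unique(pid)) {
    h <- sort(meta$hemisphere[!is.na(meta$pair_id) & meta$pair_id == p])
    if (!identical(h, c("left", "right")))
      stop("pair ", p, " members must be one left and one right", call. = FALSE)
  }
  invisible(meta)
}

#' Bilateral pairs of a metadata table
#'
#' @param meta `roi_metadata` table.
#' @return data.frame with one row per pair: `pair_id`, `left`, `right`
#'   (ROI names) and `unit` (pair label, the common name stem).
#' @export
bilateral_pairs <- function(meta) {
  pid <- sort(unique(meta$pair_id[!is.na(meta$pair_id)]))
  out <- lapply(pid, function(p) {
    sub <- meta[!is.na(meta$pair_id) & meta$pair_id == p, ]
    l <- sub$name[sub$hemisphere == "left"]
    r <- sub$name[sub$hemisphere == "right"]
    stem <- sub("_[LR]$", "", l)
    if (!identical(stem, sub("_[LR]$", "", r))) stem <- paste(l, r, sep = "|")
    data.frame(pair_id = p, left = l, right = r, unit = stem)
  })
  do.call(rbind, out)
}

#' Write / read ROI metadata as TSV
#'
#' @param meta `roi_metadata` table.
#' @param path file path.
#' @return `read_metadata` returns a validated `roi_metadata` table.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  meta$roi_id <- as.integer(meta$roi_id)
  meta$pair_id <- as.integer(meta$pair_id)
  validate_metadata(meta)
  class(meta) <- c("roi_metadata", "data.frame")
  meta
}

#' The default synthetic atlas plan
#'
#' 97 ROIs — 45 bilateral pairs plus 7 midline ROIs — organised into ten
#' planted modules: eight bilateral modules and one pair of lateralized
#' 15-ROI super-modules (`SylvianL`/`SylvianR`), each of which hides two
#' planted sub-modules that only the second community layer should resolve.
#'
#' @return module plan data.frame accepted by [generate_metadata()].
#' @export
default_module_plan <- function() {
  data.frame(
    name = c("Visual", "Hippocampal", "MedialPrefrontal", "DorsalPrefrontal",
             "DorsalPosteriorCingulate", "AnteriorCingulate", "MidCingulate",
             "Amygdala", "SylvianL", "SylvianR"),
    size = c(8L, 4L, 12L, 8L, 10L, 7L, 10L, 8L, 15L, 15L),
    lateralized = c(rep(FALSE, 8), TRUE, TRUE),
    n_sub = c(rep(1L, 8), 2L, 2L))
}
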