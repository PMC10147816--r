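#' Allocate ROIs to networks by overlap majority vote
#'
#' Assigns each ROI to the network with the largest overlapping voxel count.
#' For bilateral pairs the per-network counts of the two members are averaged
#' before the argmax, so homologs always share an assignment. ROIs (pairs)
#' with all-zero counts go to the unallocated set. Argmax ties are broken by
#' the lowest network row with a warning.
#'
#' @param ov overlap matrix (networks x ROIs) with ROI column names matching
#'   `meta$name`.
#' @param meta `roi_metadata`.
#' @return list of class `network_assignment`: `assignment` (named character
#'   vector ROI -> network) and `unallocated` (character vector).
#' @export
allocate_rois <- function(ov, meta) {
  if (!setequal(colnames(ov), meta$name))
    stop("overlap columns do not match metadata ROIs", call. = FALSE)
  ov <- ov[, meta$name, drop = FALSE]
  pairs <- bilateral_pairs(meta)
  units <- c(lapply(seq_len(nrow(pairs)), function(i)
               c(pairs$left[i], pairs$right[i])),
             as.list(meta$name[meta$hemisphere == "midline"]))
  assignment <- character(0)
  unallocated <- character(0)
  tied <- 0L
  for (u in units) {
    counts <- if (length(u) == 2) (ov[, u[1]] + ov[, u[2]]) / 2 else ov[, u[1]]
    if (all(counts == 0)) {
      unallocated <- c(unallocated, u)
      next
    }
    top <- which(counts == max(counts))
    if (length(top) > 1) tied <- tied + 1L
    assignment[u] <- rownames(ov)[top[1]]
  }
  if (tied > 0)
    warning(tied, " allocation tie(s) broken by lowest network row")
  structure(list(assignment = assignment, unallocated = unallocated),
            class = "network_assignment")
}

#' Jaccard similarity of two ROI sets
#'
#' `|a intersect b| / |a union b|`; undefined (error) when both sets are
#' empty.
#'
#' @param a,b character vectors (ROI names).
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0)
    stop("Jaccard similarity undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / length(u)
}

#' Match networks across two parcellations by Jaccard score
#'
#' For every network of assignment A, finds a one-to-one partner in B by
#' greedy descending-Jaccard matching over all cross pairs; unmatched
#' networks are listed with an empty partner and score NA.
#'
#' @param assign_a,assign_b `network_assignment` objects over the same ROI
#'   universe.
#' @param method `"greedy"` (default) or `"optimal"` (Hungarian-style
#'   maximum-sum matching via exhaustive search over the smaller side;
#'   intended for the handful of networks of a parcellation table).
#' @return data.frame (`network_a`, `network_b`, `jaccard`) sorted by
#'   descending score, unmatched rows last.
#' @export
match_networks <- function(assign_a, assign_b,
                           method = c("greedy", "optimal")) {
  method <- match.arg(method)
  sets_a <- split(names(assign_a$assignment), assign_a$assignment)
  sets_b <- split(names(assign_b$assignment), assign_b$assignment)
  na <- names(sets_a); nb <- names(sets_b)
  J <- outer(seq_along(na), seq_along(nb),
             Vectorize(function(i, j) jaccard(sets_a[[i]], sets_b[[j]])))
  dimnames(J) <- list(na, nb)
  pairs_df <- NULL
  if (method == "greedy") {
    Jw <- J
    repeat {
      if (all(is.na(Jw)) || max(Jw, na.rm = TRUE) < 0) break
      best <- which(Jw == max(Jw, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pairs_df <- rbind(pairs_df, data.frame(
        network_a = rownames(Jw)[best[1]], network_b = colnames(Jw)[best[2]],
        jaccard = Jw[best[1], best[2]], stringsAsFactors = FALSE))
      Jw[best[1], ] <- NA
      Jw[, best[2]] <- NA
      if (all(is.na(Jw))) break
    }
  } else {
    # exhaustive optimal assignment over the smaller side
    flip <- length(na) > length(nb)
    M <- if (flip) t(J) else J
    rows <- rownames(M); cols <- colnames(M)
    perms <- all_injections(length(rows), length(cols))
    scores <- vapply(perms, function(pm) sum(M[cbind(seq_along(pm), pm)]),
                     numeric(1))
    pm <- perms[[which.max(scores)]]
    pairs_df <- data.frame(
      network_a = if (flip) cols[pm] else rows,
      network_b = if (flip) rows else cols[pm],
      jaccard = M[cbind(seq_along(pm), pm)], stringsAsFactors = FALSE)
    pairs_df <- pairs_df[order(-pairs_df$jaccard), ]
  }
  un_a <- setdiff(na, pairs_df$network_a)
  un_b <- setdiff(nb, pairs_df$network_b)
  if (length(un_a) || length(un_b)) {
    pairs_df <- rbind(pairs_df,
      data.frame(network_a = c(un_a, rep("", length(un_b))),
                 network_b = c(rep("", length(un_a)), un_b),
                 jaccard = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(pairs_df) <- NULL
  pairs_df
}

# all injective maps 1..n -> 1..m (n <= m), as a list of index vectors
all_injections <- function(n, m) {
  stopifnot(n <= m)
  if (n == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == n) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    for (j in setdiff(seq_len(m), chosen)) rec(c(chosen, j))
  }
  rec(integer(0))
  out
}
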