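#' Derive reproducible child seeds from a master seed
#'
#' Stages of the pipeline (per-subject simulation, permutation testing,
#' community detection repeats, null-model sampling) each consume their own
#' seed so that any stage can be re-run in isolation. Child seeds are drawn
#' from a temporary RNG stream keyed by the master seed; the caller's RNG
#' state is left untouched.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same nodes,
#' corrected for chance (1 = identical partitions, ~0 = independent).
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# relabel an arbitrary label vector to contiguous integer ids from 0,
# in order of first appearance
relabel0 <- function(labels) {
  as.integer(match(labels, unique(labels))) - 1L
}

# indices (i, j) of the upper triangle in column-major order, as used for
# vectorized edge statistics; i < j
upper_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}
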