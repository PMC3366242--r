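#' Ordinal ranks of a score vector
#'
#' Ranks ascending: the smallest value gets rank 1. Ties are broken by input
#' position (the earlier individual gets the smaller rank), so each column of
#' a rank table is a permutation of `1..n` -- the zoning step needs distinct
#' positions. Rank direction is fixed package-wide; only consistency between
#' the known and unknown sets matters for the zone distances.
#'
#' @param values numeric vector, all finite.
#' @return Integer vector of ranks, same length as `values`.
#' @examples
#' rank_scores(c(0.3, 0.1, 0.2)) # 3 1 2
#' rank_scores(c(2, 2, 1))       # 2 3 1 (tie broken by position)
#' @export
rank_scores <- function(values) {
  if (length(values) < 1L)
    stop("need at least one value to rank")
  if (!all(is.finite(values)))
    stop("cannot rank non-finite values")
  as.integer(rank(values, ties.method = "first"))
}

#' Per-variable rank table of a dataset
#'
#' Applies [rank_scores()] to every biomarker column.
#'
#' @param d a `przn_dataset` with complete scores.
#' @return Integer matrix of the same shape and dimnames as `d$scores`.
#' @export
rank_table <- function(d) {
  stopifnot(inherits(d, "przn_dataset"))
  r <- apply(d$scores, 2L, rank_scores)
  dimnames(r) <- dimnames(d$scores)
  r
}

#' Extract the validation-candidate set from a known dataset
#'
#' The candidates are the known individuals with the lowest validation values
#' (lowest egg counts): with `base = ceiling(n_B * fraction)`, every
#' individual whose validation value is less than or equal to the `base`-th
#' smallest is a candidate, so ties at the boundary are all included and the
#' candidate count `cn` can exceed `base`. Candidates are ordered by
#' ascending validation value (`ej = 1..cn`), ties by input position. Their
#' ranks are their ranks within the full known set.
#'
#' @param b a `przn_dataset` carrying a validation variable, complete scores.
#' @param fraction fraction of the known set to take, in `(0, 1]`;
#'   default 0.1.
#' @return An object of class `przn_candidates`: list with `order_index`
#'   (`1..cn`), `ids`, `scores` (`cn x m`), `ranks` (`cn x m`, ranks within
#'   the full known set), `validation` (non-decreasing), `cn` and `n_b`.
#' @export
select_validation_candidates <- function(b, fraction = 0.1) {
  stopifnot(inherits(b, "przn_dataset"))
  if (is.null(b$validation))
    stop("the known dataset has no validation variable")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be a single number in (0, 1]")
  n_b <- length(b$ids)
  base <- ceiling(n_b * fraction)
  boundary <- sort(b$validation)[base]
  keep <- which(b$validation <= boundary)
  keep <- keep[order(b$validation[keep], keep)]
  ranks <- rank_table(b)
  structure(list(order_index = seq_along(keep),
                 ids = b$ids[keep],
                 scores = b$scores[keep, , drop = FALSE],
                 ranks = ranks[keep, , drop = FALSE],
                 validation = b$validation[keep],
                 cn = length(keep),
                 n_b = n_b),
            class = "przn_candidates")
}

#' @export
print.przn_candidates <- function(x, ...) {
  cat(sprintf("<przn_candidates> cn = %d of n_B = %d known individuals\n",
              x$cn, x$n_b))
  cat("  validation range:", x$validation[1L], "..",
      x$validation[x$cn], "\n")
  invisible(x)
}

#' Transfer ordinal ranks onto another cohort's rank scale
#'
#' When the two cohorts differ in size, a rank in the unknown set has no
#' direct counterpart in the known set; multiplying by the size ratio
#' `n_B / n_A` places the unknown ranks on the known set's `1..n_B` scale.
#'
#' @param ranks_a integer ranks of the unknown set (values in `1..n_a`).
#' @param n_a unknown-set size.
#' @param n_b known-set size.
#' @return Numeric vector `ranks_a * n_b / n_a`.
#' @examples
#' transfer_ranks(c(1, 76), 76, 77) # 1.013158 77
#' @export
transfer_ranks <- function(ranks_a, n_a, n_b) {
  stopifnot(n_a >= 1, n_b >= 1)
  if (any(ranks_a < 1 | ranks_a > n_a))
    stop("ranks must lie in 1..n_a")
  ranks_a * n_b / n_a
}

#' Transfer scores onto another cohort's location and scale
#'
#' Z-score matching: an unknown-set value is standardized against the unknown
#' set's moments and re-expressed with the known set's moments, so that the
#' transferred column has exactly the known set's mean and standard deviation
#' (the map is affine and strictly increasing, hence order-preserving).
#'
#' @param scores_a numeric vector of unknown-set values for one variable.
#' @param mean_a,sd_a unknown-set mean and sample SD; `sd_a` must be > 0.
#' @param mean_b,sd_b known-set mean and sample SD.
#' @param variable variable name used in the degenerate-variable error.
#' @return Numeric vector `(scores_a - mean_a) * sd_b / sd_a + mean_b`.
#' @examples
#' transfer_scores(c(0, 1, 2), 1, 1, 10, 2) # 8 10 12
#' @export
transfer_scores <- function(scores_a, mean_a, sd_a, mean_b, sd_b,
                            variable = "") {
  if (!is.finite(sd_a) || sd_a <= 0)
    stop("degenerate variable",
         if (nzchar(variable)) paste0(" '", variable, "'") else "",
         ": zero spread in the unknown set, scores cannot be transferred")
  (scores_a - mean_a) * sd_b / sd_a + mean_b
}

#' Build the transferred table of an unknown dataset
#'
#' Applies the rank transfer and the score transfer variable-by-variable,
#' mapping the whole unknown set onto the known set's rank scale and score
#' distribution. Both datasets must be complete and share the same variables
#' in the same order.
#'
#' @param a unknown `przn_dataset`.
#' @param b known `przn_dataset`.
#' @return An object of class `przn_transfer`: list with `t_ranks` and
#'   `t_scores` (`n_A x m` numeric matrices, rows named by unknown ids),
#'   `ids`, `variable_names` and `n_b`.
#' @export
transfer_table <- function(a, b) {
  stopifnot(inherits(a, "przn_dataset"), inherits(b, "przn_dataset"))
  if (!identical(a$variable_names, b$variable_names))
    stop("unknown and known datasets must share the same variables")
  n_a <- length(a$ids)
  n_b <- length(b$ids)
  ranks_a <- rank_table(a)
  t_ranks <- transfer_ranks(ranks_a, n_a, n_b)
  t_scores <- a$scores
  for (p in seq_along(a$variable_names)) {
    t_scores[, p] <- transfer_scores(
      a$scores[, p],
      mean(a$scores[, p]), stats::sd(a$scores[, p]),
      mean(b$scores[, p]), stats::sd(b$scores[, p]),
      variable = a$variable_names[p])
  }
  structure(list(t_ranks = t_ranks, t_scores = t_scores,
                 ids = a$ids, variable_names = a$variable_names,
                 n_b = n_b),
            class = "przn_transfer")
}
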