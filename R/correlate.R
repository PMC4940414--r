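#' All-pairs Spearman rank correlation over line-level profiles
#'
#' Computes, for every unordered pair of features, the Spearman rank
#' correlation of their per-line values (average ranks for ties), a two-sided
#' p-value from the t approximation with `n - 2` degrees of freedom, and the
#' Benjamini-Hochberg q-value over all pairs. Constant (zero-variance)
#' features carry no rank information and are excluded with a warning.
#'
#' @param blups Long tibble from [compute_blups()] (`line_id`, `feature_id`,
#'   `blup`), or any long tibble with those columns.
#'
#' @return A tibble of class `trait_correlation` with one row per unordered
#'   feature pair: `feature_a`, `feature_b`, `rho`, `p`, `q`, `n` (number of
#'   lines). Attributes `features` (retained features, in input order) and
#'   `n_lines` are set.
#' @export
spearman_all_pairs <- function(blups) {
  m <- blups_to_matrix(blups)
  if (nrow(m) < 5L) abort("At least 5 lines are required for correlation.")
  if (anyNA(m)) abort("`blups` must be complete (no missing line values).")
  constant <- apply(m, 2, function(x) var(x) == 0)
  if (any(constant)) {
    warn(paste0("Excluding constant feature(s): ",
                paste(colnames(m)[constant], collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
  }
  if (ncol(m) < 2L) abort("Need at least 2 non-constant features.")

  n <- nrow(m)
  ranks <- apply(m, 2, rank) # average ranks for ties
  rho <- cor(ranks)          # Pearson on ranks == Spearman
  pair <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[pair]
  p <- spearman_p(r, n)
  out <- tibble(
    feature_a = colnames(m)[pair[, 1]],
    feature_b = colnames(m)[pair[, 2]],
    rho = r,
    p = p,
    q = p.adjust(p, method = "BH"),
    n = n
  )
  new_tibble(out, class = "trait_correlation",
             features = colnames(m), n_lines = n)
}

# Two-sided p from the t approximation; rho = +/-1 gives p = 0.
spearman_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Benjamini-Hochberg p-value cutoff for a target q-value
#'
#' Applies the BH step-up rule to a collection of p-values and returns the
#' largest order statistic `p(i)` satisfying `p(i) <= (i / m) * q_target`
#' (0 if none passes). Filtering at `p <= bh_threshold(p, q)` retains exactly
#' the tests with BH-adjusted q-value at most `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`, or a
#'   `trait_correlation` tibble (its `p` column is used).
#' @param q_target Target false-discovery rate in `(0, 1)`.
#'
#' @return The p-value cutoff (a single number).
#' @export
bh_threshold <- function(p_values, q_target = 0.05) {
  if (inherits(p_values, "trait_correlation") || is.data.frame(p_values)) {
    p_values <- p_values$p
  }
  if (length(p_values) == 0L) abort("`p_values` must be non-empty.")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  assert_scalar_number(q_target, "q_target", 0, 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  ps <- sort(p_values)
  m <- length(ps)
  ok <- ps <= seq_len(m) / m * q_target
  if (!any(ok)) 0 else ps[max(which(ok))]
}
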