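# Internal helpers shared across stages.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      name,
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  invisible(as.integer(x))
}

# Long (line, replicate) x feature tibble -> numeric matrix with
# "line|replicate" rownames and feature columns, in a fixed order.
profiles_to_matrix <- function(profiles, value_col = "value") {
  wide <- profiles |>
    mutate(.sample = paste(.data$line_id, .data$replicate_id, sep = "\r")) |>
    select(".sample", "feature_id", all_of(value_col)) |>
    pivot_wider(names_from = "feature_id", values_from = all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$.sample
  m
}

matrix_to_profiles <- function(m, template) {
  keys <- do.call(rbind, strsplit(rownames(m), "\r", fixed = TRUE))
  tibble(
    line_id = rep(keys[, 1], times = ncol(m)),
    replicate_id = rep(keys[, 2], times = ncol(m)),
    feature_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

# Line x feature BLUP tibble -> matrix (lines in rows).
blups_to_matrix <- function(blups) {
  wide <- blups |>
    select("line_id", "feature_id", "blup") |>
    pivot_wider(names_from = "feature_id", values_from = "blup") |>
    arrange(.data$line_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$line_id
  m
}
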