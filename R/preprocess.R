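#' Normalize metabolite records by their internal standard
#'
#' Divides each metabolite observation by the internal-standard (control)
#' value recorded for its chromatogram, i.e. per line-by-replicate sample.
#' Enzyme records pass through untouched.
#'
#' @param profiles Long tibble with columns `line_id`, `replicate_id`,
#'   `plate_id`, `feature_id`, `value`, `control_value`.
#' @param features Annotation tibble with `feature_id` and `molecular_class`
#'   (`"metabolite"` or `"enzyme"`).
#'
#' @return The input tibble with metabolite `value`s replaced by
#'   `value / control_value` and `control_value` cleared to `NA` (consumed).
#' @export
normalize_metabolites <- function(profiles, features) {
  check_profiles(profiles)
  is_met <- profiles$feature_id %in%
    features$feature_id[features$molecular_class == "metabolite"]
  bad <- is_met & (is.na(profiles$control_value) | profiles$control_value <= 0)
  if (any(bad)) {
    offenders <- profiles[bad, c("line_id", "replicate_id", "feature_id")]
    abort(paste0(
      "Metabolite records with missing or non-positive control value: ",
      paste(head(sprintf("%s/%s/%s", offenders$line_id, offenders$replicate_id,
                         offenders$feature_id), 5L), collapse = ", "),
      if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L)
    ))
  }
  profiles |>
    mutate(
      value = ifelse(is_met, .data$value / .data$control_value, .data$value),
      control_value = ifelse(is_met, NA_real_, .data$control_value)
    )
}

#' Standardize enzyme records by plate, then center per enzyme
#'
#' Two steps: (1) each enzyme value is standardized by the mean of its plate,
#' computed across all enzyme records on that plate (`method = "divide"`
#' divides by the plate mean, `"subtract"` subtracts it); (2) per enzyme, the
#' overall mean of the standardized values is subtracted, so every enzyme
#' column of the result has mean zero. Metabolite records pass through
#' untouched.
#'
#' @inheritParams normalize_metabolites
#' @param method How the plate mean is removed in step 1: `"divide"`
#'   (default) or `"subtract"`.
#' @return The input tibble with enzyme `value`s standardized.
#' @export
standardize_enzymes <- function(profiles, features, method = c("divide", "subtract")) {
  check_profiles(profiles)
  method <- match.arg(method)
  is_enz <- profiles$feature_id %in%
    features$feature_id[features$molecular_class == "enzyme"]
  if (!any(is_enz)) return(profiles)
  if (any(is_enz & (is.na(profiles$plate_id) | profiles$plate_id == ""))) {
    abort("Every enzyme record must carry a plate id.")
  }

  enz <- profiles[is_enz, ]
  plate_means <- enz |>
    group_by(.data$plate_id) |>
    summarise(plate_mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (method == "divide" && any(abs(plate_means$plate_mean) < .Machine$double.eps)) {
    abort(paste0("Plate mean is zero for plate(s): ",
                 paste(plate_means$plate_id[abs(plate_means$plate_mean) <
                                              .Machine$double.eps],
                       collapse = ", ")))
  }
  enz <- enz |>
    left_join(plate_means, by = "plate_id") |>
    mutate(value = if (method == "divide") .data$value / .data$plate_mean
           else .data$value - .data$plate_mean) |>
    group_by(.data$feature_id) |>
    mutate(value = .data$value - mean(.data$value, na.rm = TRUE)) |>
    ungroup() |>
    select(-"plate_mean")

  out <- profiles
  out[is_enz, ] <- enz[, names(profiles)]
  out
}

#' Normalize a raw replicated profile table
#'
#' Convenience wrapper: internal-standard normalization of metabolites
#' ([normalize_metabolites()]) followed by plate standardization of enzymes
#' ([standardize_enzymes()]).
#'
#' @inheritParams standardize_enzymes
#' @return Normalized long tibble.
#' @export
normalize_profiles <- function(profiles, features, method = c("divide", "subtract")) {
  profiles |>
    normalize_metabolites(features) |>
    standardize_enzymes(features, method = method)
}

check_profiles <- function(profiles) {
  needed <- c("line_id", "replicate_id", "feature_id", "value")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    abort(paste0("`profiles` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"control_value" %in% names(profiles)) profiles$control_value <- NA_real_
  if (!"plate_id" %in% names(profiles)) profiles$plate_id <- NA_character_
  key <- paste(profiles$line_id, profiles$replicate_id, profiles$feature_id)
  if (anyDuplicated(key)) abort("Duplicate (line, replicate, feature) records.")
  invisible(profiles)
}

#' Impute missing values by iterative low-rank (EM-PCA) reconstruction
#'
#' Missing cells are initialized at their feature (column) means and refined
#' by alternating a rank-`n_components` truncated SVD reconstruction of the
#' column-centered sample-by-feature matrix with re-imputation of the missing
#' cells, until the relative change of the imputed values falls below `tol`.
#' Observed cells are never altered. The procedure is deterministic.
#'
#' @param profiles Long normalized tibble (`line_id`, `replicate_id`,
#'   `feature_id`, `value`) possibly containing `NA` values.
#' @param n_components Rank of the reconstruction; must be smaller than both
#'   the number of samples and the number of features.
#' @param tol Convergence tolerance on the relative change (Frobenius) of the
#'   imputed cells.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with a warning.
#'
#' @return The input tibble with `NA` values filled in and a logical column
#'   `imputed` flagging the filled cells.
#' @export
impute_missing <- function(profiles, n_components = 3, tol = 1e-6,
                           max_iter = 500) {
  check_profiles(profiles)
  m <- profiles_to_matrix(profiles)
  n_components <- assert_count(n_components, "n_components")
  if (n_components >= min(dim(m))) {
    abort("`n_components` must be smaller than both matrix dimensions.")
  }
  miss <- is.na(m)
  fully_missing <- colnames(m)[colSums(!miss) == 0L]
  if (length(fully_missing)) {
    abort(paste0("Feature(s) entirely missing: ",
                 paste(fully_missing, collapse = ", ")))
  }

  out_long <- profiles |>
    mutate(imputed = is.na(.data$value))
  if (!any(miss)) return(out_long)

  # Standardize columns on their observed cells so features measured on very
  # different scales contribute equally to the low-rank fit; undone at the end.
  obs_mean <- colMeans(m, na.rm = TRUE)
  obs_sd <- apply(m, 2, sd, na.rm = TRUE)
  obs_sd[!is.finite(obs_sd) | obs_sd == 0] <- 1
  z <- sweep(sweep(m, 2, obs_mean, `-`), 2, obs_sd, `/`)
  z[miss] <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(z)
    zc <- sweep(z, 2, mu, `-`)
    sv <- svd(zc, nu = n_components, nv = n_components)
    recon <- sv$u %*% (diag(sv$d[seq_len(n_components)], n_components) %*%
                         t(sv$v))
    recon <- sweep(recon, 2, mu, `+`)
    delta <- sqrt(sum((recon[miss] - z[miss])^2)) /
      max(sqrt(sum(z[miss]^2)), .Machine$double.eps)
    z[miss] <- recon[miss]
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("EM-PCA imputation did not converge in %d iterations; returning best iterate.",
                 max_iter))
  }
  x <- m
  x[miss] <- (sweep(sweep(z, 2, obs_sd, `*`), 2, obs_mean, `+`))[miss]

  filled <- matrix_to_profiles(x) |>
    rename(imputed_value = "value")
  out_long |>
    left_join(filled, by = c("line_id", "replicate_id", "feature_id")) |>
    mutate(value = ifelse(.data$imputed, .data$imputed_value, .data$value)) |>
    select(-"imputed_value")
}
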