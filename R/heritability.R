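#' Per-feature variance components and broad-sense heritability by REML
#'
#' Fits, for every feature, the one-way random-effects model
#' `value = mu + line + error` by REML (via [lme4::lmer()]) and returns the
#' genetic (between-line) variance, the residual variance, and broad-sense
#' heritability `h2 = sigma2_g / (sigma2_g + sigma2_e)` on the
#' per-observation basis. Negative component estimates are clipped at zero by
#' the REML fit itself, so `h2` always lies in `[0, 1]`.
#'
#' Features with (numerically) zero total variance cannot be decomposed and
#' are flagged `degenerate` with `h2 = NA`.
#'
#' @param profiles Long tibble with `line_id`, `replicate_id`, `feature_id`,
#'   `value`. Missing values are dropped per feature.
#' @param basis `"observation"` (default) computes
#'   `h2 = sigma2_g / (sigma2_g + sigma2_e)`; `"line_mean"` uses
#'   `sigma2_g / (sigma2_g + sigma2_e / r)` with `r` the mean replicate count.
#'
#' @return Tibble with one row per feature: `feature_id`, `sigma2_g`,
#'   `sigma2_e`, `h2`, `degenerate`.
#' @export
fit_variance_components <- function(profiles, basis = c("observation", "line_mean")) {
  check_profiles(profiles)
  basis <- match.arg(basis)
  if (length(unique(profiles$line_id)) < 2L) {
    abort("At least 2 lines are required to separate variance components.")
  }

  split(profiles, profiles$feature_id) |>
    imap(function(d, fid) {
      d <- d[!is.na(d$value), ]
      tot_var <- if (nrow(d) >= 2L) var(d$value) else 0
      scale2 <- max(mean(d$value)^2, 1)
      if (!is.finite(tot_var) || tot_var <= 1e-12 * scale2) {
        return(tibble(feature_id = fid, sigma2_g = 0, sigma2_e = 0,
                      h2 = NA_real_, degenerate = TRUE))
      }
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ 1 + (1 | line_id), data = d, REML = TRUE)
      ))
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2g <- max(vc$vcov[vc$grp == "line_id"], 0)
      s2e <- max(vc$vcov[vc$grp == "Residual"], 0)
      denom <- if (basis == "observation") {
        s2g + s2e
      } else {
        s2g + s2e / mean(table(d$line_id))
      }
      tibble(feature_id = fid, sigma2_g = s2g, sigma2_e = s2e,
             h2 = if (denom > 0) s2g / denom else NA_real_,
             degenerate = FALSE)
    }) |>
    list_rbind() |>
    arrange(match(.data$feature_id, unique(profiles$feature_id)))
}

#' Best linear unbiased prediction of line effects
#'
#' For each feature, shrinks every line's deviation from the grand mean by the
#' closed-form one-way BLUP factor
#' \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e / n_i)}, where \eqn{n_i} is the
#' line's (non-missing) replicate count. The grand mean is the GLS estimate
#' \eqn{\hat\mu = \sum_i w_i \bar y_i / \sum_i w_i} with
#' \eqn{w_i = 1 / (\sigma^2_g + \sigma^2_e / n_i)}, which matches the mixed
#'-model intercept; the predictions coincide with [lme4::ranef()] conditional
#' modes. A feature with `sigma2_g = 0` gets all-zero BLUPs.
#'
#' @param profiles Long tibble (`line_id`, `replicate_id`, `feature_id`,
#'   `value`), normally complete after [impute_missing()].
#' @param components Output of [fit_variance_components()] on the same data.
#'
#' @return Long tibble with one row per line and feature: `line_id`,
#'   `feature_id`, `blup` (predicted random line effect, mean ~0), and
#'   `grand_mean` (the feature's fixed intercept).
#' @export
compute_blups <- function(profiles, components) {
  check_profiles(profiles)
  missing_fit <- setdiff(unique(profiles$feature_id), components$feature_id)
  if (length(missing_fit)) {
    abort(paste0("`components` lacks fits for: ",
                 paste(missing_fit, collapse = ", ")))
  }
  profiles |>
    filter(!is.na(.data$value)) |>
    group_by(.data$feature_id, .data$line_id) |>
    summarise(line_mean = mean(.data$value), n_i = dplyr::n(), .groups = "drop") |>
    left_join(components, by = "feature_id") |>
    group_by(.data$feature_id) |>
    mutate(
      w = 1 / pmax(.data$sigma2_g + .data$sigma2_e / .data$n_i,
                   .Machine$double.xmin),
      grand_mean = sum(.data$w * .data$line_mean) / sum(.data$w),
      shrinkage = ifelse(.data$sigma2_g > 0,
                         .data$sigma2_g /
                           (.data$sigma2_g + .data$sigma2_e / .data$n_i),
                         0),
      blup = .data$shrinkage * (.data$line_mean - .data$grand_mean)
    ) |>
    ungroup() |>
    select("line_id", "feature_id", "blup", "grand_mean") |>
    arrange(.data$line_id, .data$feature_id)
}

#' Per-feature descriptive statistics on the BLUP scale
#'
#' Computes, per feature, the sample variance, mean, and coefficient of
#' variation of the line values `blup + grand_mean` (BLUPs shifted back to
#' the measurement scale, since raw BLUP deviations are centered at zero and
#' would make `sd/mean` ill-defined), together with the heritability bin
#' (`[0, 0.1), [0.1, 0.2), ..., [0.9, 1]`).
#'
#' @param blups Output of [compute_blups()].
#' @param components Output of [fit_variance_components()]; supplies `h2`.
#'
#' @return Tibble with one row per feature: `feature_id`, `mean`, `variance`,
#'   `cv`, `h2`, `h2_bin` (integer 1-10, `NA` for degenerate features).
#' @export
descriptive_stats <- function(blups, components) {
  if (length(unique(blups$line_id)) < 3L) {
    abort("At least 3 lines are required for descriptive statistics.")
  }
  stats <- blups |>
    mutate(rescaled = .data$blup + .data$grand_mean) |>
    group_by(.data$feature_id) |>
    summarise(
      mean = mean(.data$rescaled),
      variance = var(.data$rescaled),
      sd = sd(.data$rescaled),
      .groups = "drop"
    ) |>
    mutate(cv = ifelse(abs(.data$mean) < .Machine$double.eps, NA_real_,
                       .data$sd / .data$mean)) |>
    select(-"sd")
  if (anyNA(stats$cv)) {
    warn(paste0("CV undefined (mean zero) for: ",
                paste(stats$feature_id[is.na(stats$cv)], collapse = ", ")))
  }
  stats |>
    left_join(components |> select("feature_id", "h2"), by = "feature_id") |>
    mutate(h2_bin = h2_bin_index(.data$h2))
}

# Bin index for h2 in [0,1]: 10 bins of width 0.1, h2 = 1 falls in bin 10.
h2_bin_index <- function(h2) {
  ifelse(is.na(h2), NA_integer_, pmin(as.integer(floor(h2 * 10)) + 1L, 10L))
}

#' Heritability histogram over 0.1-wide bins
#'
#' Bins heritability estimates into the ten intervals
#' `[0, 0.1), ..., [0.8, 0.9), [0.9, 1]` and reports counts and relative
#' frequencies, optionally per molecular class.
#'
#' @param components Output of [fit_variance_components()] (or any tibble
#'   with `feature_id` and `h2`).
#' @param features Optional annotation tibble with `feature_id` and
#'   `molecular_class`; when given, frequencies are computed per class.
#'
#' @return Tibble with `bin` (1-10), `bin_lower`, `bin_upper`, `n`,
#'   `rel_freq` (and `molecular_class` when `features` is supplied).
#' @export
h2_histogram <- function(components, features = NULL) {
  d <- components |>
    filter(!is.na(.data$h2)) |>
    mutate(bin = h2_bin_index(.data$h2))
  grid <- tibble(bin = 1:10)
  if (!is.null(features)) {
    d <- d |> left_join(features |> select("feature_id", "molecular_class"),
                        by = "feature_id")
    grid <- tidyr::crossing(molecular_class = unique(d$molecular_class),
                            bin = 1:10)
    counts <- d |> count(.data$molecular_class, .data$bin)
    out <- grid |>
      left_join(counts, by = c("molecular_class", "bin")) |>
      group_by(.data$molecular_class)
  } else {
    counts <- d |> count(.data$bin)
    out <- grid |> left_join(counts, by = "bin")
  }
  out |>
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      rel_freq = .data$n / max(sum(.data$n), 1L),
      bin_lower = (.data$bin - 1) / 10,
      bin_upper = .data$bin / 10
    ) |>
    ungroup() |>
    relocate("bin", "bin_lower", "bin_upper")
}
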