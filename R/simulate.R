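#' Configure a synthetic replicated trait panel
#'
#' Describes a simulated metabolite/enzyme profiling experiment on a panel of
#' inbred lines: per-line latent genetic values with a planted correlation
#' block structure, replicate-level residual noise tuned to per-feature target
#' broad-sense heritabilities, an internal-standard (control) channel that
#' multiplicatively scales metabolite observations, additive plate offsets on
#' enzyme observations, and missing values inserted completely at random.
#'
#' The defaults emulate a maize inbred-panel leaf profiling study: 101 lines
#' with 5 replicates each, 43 metabolites and 13 enzymes, and 5.7% missing
#' cells. Target heritabilities default to a right-skewed spectrum
#' (`qbeta(ppoints(m), 2, 3)`, roughly three quarters below 0.5) and the
#' default planted blocks mirror three co-regulated feature communities (an
#' enzyme-dominated block and two metabolite blocks).
#'
#' @param n_lines Number of inbred lines.
#' @param n_replicates Replicates per line (>= 2).
#' @param n_metabolites,n_enzymes Number of features of each molecular class.
#' @param blocks Planted correlation blocks: a list of lists with elements
#'   `id`, `features` (character vector of feature ids), and `correlation`
#'   (within-block latent correlation in `[0, 1]`). Memberships must be
#'   disjoint. `NULL` plants the default three-block structure.
#' @param h2 Target broad-sense heritability per feature, in `[0, 1]`: a
#'   single number, a vector of length `n_metabolites + n_enzymes`, or `NULL`
#'   for the default skewed spectrum.
#' @param missing_rate Fraction of observation cells set missing, in `[0, 1)`.
#' @param n_plates Number of assay plates enzyme samples are spread over.
#' @param control_mean,control_cv Mean and coefficient of variation of the
#'   lognormal internal-standard channel.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#'
#' @return A list of class `simulation_config`.
#' @seealso [generate_panel()]
#' @export
simulation_config <- function(n_lines = 101,
                              n_replicates = 5,
                              n_metabolites = 43,
                              n_enzymes = 13,
                              blocks = NULL,
                              h2 = NULL,
                              missing_rate = 0.057,
                              n_plates = 6,
                              control_mean = 1e4,
                              control_cv = 0.15,
                              seed = 1L) {
  n_lines <- assert_count(n_lines, "n_lines", min = 2L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L)
  n_metabolites <- assert_count(n_metabolites, "n_metabolites", min = 0L)
  n_enzymes <- assert_count(n_enzymes, "n_enzymes", min = 0L)
  n_features <- n_metabolites + n_enzymes
  if (n_features < 1L) abort("At least one feature is required.")
  assert_scalar_number(missing_rate, "missing_rate", 0, 1, closed_upper = FALSE)
  n_plates <- assert_count(n_plates, "n_plates", min = 1L)
  assert_scalar_number(control_mean, "control_mean", 0, Inf, closed_lower = FALSE)
  assert_scalar_number(control_cv, "control_cv", 0, Inf)
  seed <- assert_count(seed, "seed", min = 0L)

  met_ids <- if (n_metabolites > 0) sprintf("met%02d", seq_len(n_metabolites)) else character()
  enz_ids <- if (n_enzymes > 0) sprintf("enz%02d", seq_len(n_enzymes)) else character()
  feature_ids <- c(met_ids, enz_ids)

  if (is.null(h2)) {
    h2 <- qbeta(ppoints(n_features), 2, 3)
  } else if (length(h2) == 1L) {
    h2 <- rep(h2, n_features)
  }
  if (length(h2) != n_features || anyNA(h2) || any(h2 < 0 | h2 > 1)) {
    abort("`h2` must supply one target in [0, 1] per feature.")
  }
  h2 <- setNames(as.double(h2), feature_ids)

  if (is.null(blocks)) blocks <- default_blocks(met_ids, enz_ids)
  validate_blocks(blocks, feature_ids)

  structure(
    list(
      n_lines = n_lines, n_replicates = n_replicates,
      n_metabolites = n_metabolites, n_enzymes = n_enzymes,
      feature_ids = feature_ids, metabolite_ids = met_ids,
      enzyme_ids = enz_ids, blocks = blocks, h2 = h2,
      missing_rate = missing_rate, n_plates = n_plates,
      control_mean = control_mean, control_cv = control_cv,
      seed = seed
    ),
    class = "simulation_config"
  )
}

# Three planted blocks: one enzyme-dominated, two metabolite blocks.
default_blocks <- function(met_ids, enz_ids) {
  blocks <- list()
  b1 <- c(head(enz_ids, 9), if (length(met_ids) >= 27) utils::tail(met_ids, 3))
  if (length(b1) >= 2) blocks <- c(blocks, list(list(id = 1L, features = b1, correlation = 0.50)))
  b2 <- met_ids[seq_len(min(16, max(0, length(met_ids) - 3 * (length(met_ids) >= 27))))]
  if (length(b2) >= 2) blocks <- c(blocks, list(list(id = 2L, features = b2, correlation = 0.55)))
  if (length(met_ids) >= 24) {
    blocks <- c(blocks, list(list(id = 3L, features = met_ids[17:24], correlation = 0.60)))
  }
  blocks
}

validate_blocks <- function(blocks, feature_ids) {
  if (length(blocks) == 0L) return(invisible(blocks))
  members <- unlist(lapply(blocks, `[[`, "features"))
  if (anyDuplicated(members)) abort("Block memberships must be disjoint.")
  if (!all(members %in% feature_ids)) {
    abort(paste0(
      "Unknown block features: ",
      paste(setdiff(members, feature_ids), collapse = ", ")
    ))
  }
  rs <- vapply(blocks, `[[`, numeric(1), "correlation")
  if (any(rs < 0 | rs > 1)) abort("Within-block correlations must lie in [0, 1].")
  invisible(blocks)
}

# Equicorrelated blocks on the unit-diagonal latent correlation matrix.
planted_correlation_matrix <- function(config) {
  m <- length(config$feature_ids)
  R <- diag(m)
  dimnames(R) <- list(config$feature_ids, config$feature_ids)
  for (b in config$blocks) {
    idx <- match(b$features, config$feature_ids)
    R[idx, idx] <- b$correlation
    diag(R)[idx] <- 1
  }
  R
}

#' Generate a synthetic replicated trait panel
#'
#' Draws a complete panel from a [simulation_config()]: line-level genetic
#' values from a multivariate normal with the planted block correlation,
#' replicate values as genetic value plus independent normal residual noise
#' scaled so that \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e)} equals each
#' feature's target heritability, a lognormal internal-standard value per
#' chromatogram that multiplies the metabolite observations, additive
#' per-plate offsets on enzyme observations, and missing cells inserted
#' completely at random.
#'
#' @param config A [simulation_config()].
#'
#' @return A list of class `trait_panel` with elements
#'   * `profiles`: long tibble with columns `line_id`, `replicate_id`,
#'     `plate_id` (enzyme records only), `feature_id`, `value`,
#'     `control_value` (metabolite records only);
#'   * `features`: annotation tibble (`feature_id`, `molecular_class`,
#'     `compound_class`);
#'   * `truth`: the planted ground truth (class `planted_truth`) holding the
#'     true variance components, latent correlation matrix, block map, drawn
#'     genetic values, and the noiseless replicate-level signal.
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config().")
  }
  R <- planted_correlation_matrix(config)
  m <- length(config$feature_ids)
  is_met <- config$feature_ids %in% config$metabolite_ids

  with_seed(config$seed, {
    # Measurement scales: lognormal baselines, class-specific phenotypic CV.
    mu <- numeric(m)
    mu[is_met] <- rlnorm(sum(is_met), meanlog = log(1000), sdlog = 1)
    mu[!is_met] <- rlnorm(sum(!is_met), meanlog = log(50), sdlog = 0.5)
    cv_p <- ifelse(is_met, 0.30, 0.25)
    sigma2_p <- (cv_p * mu)^2
    sigma2_g <- config$h2 * sigma2_p
    sigma2_e <- (1 - config$h2) * sigma2_p

    Z <- tryCatch(
      MASS::mvrnorm(config$n_lines, mu = rep(0, m), Sigma = R),
      error = function(e) {
        abort(paste0(
          "Planted block specification is not positive semi-definite: ",
          conditionMessage(e)
        ))
      }
    )
    Z <- matrix(Z, nrow = config$n_lines)
    G <- sweep(Z, 2, sqrt(sigma2_g), `*`)

    line_ids <- sprintf("L%03d", seq_len(config$n_lines))
    rep_ids <- sprintf("r%d", seq_len(config$n_replicates))
    samples <- tidyr::crossing(line_id = line_ids, replicate_id = rep_ids)
    n_samples <- nrow(samples)
    line_index <- match(samples$line_id, line_ids)

    plate_of <- sample(rep_len(seq_len(config$n_plates), n_samples))
    plate_sd <- if (any(!is_met)) 0.1 * stats::median(mu[!is_met]) else 0
    plate_offsets <- rnorm(config$n_plates, 0, plate_sd)

    sdlog <- sqrt(log(1 + config$control_cv^2))
    control <- rlnorm(n_samples, meanlog = log(config$control_mean) - sdlog^2 / 2,
                      sdlog = sdlog)

    E <- sweep(matrix(rnorm(n_samples * m), n_samples, m), 2, sqrt(sigma2_e), `*`)
    signal <- matrix(mu, n_samples, m, byrow = TRUE) + G[line_index, , drop = FALSE] + E

    observed <- signal
    observed[, is_met] <- signal[, is_met, drop = FALSE] * control
    if (any(!is_met)) {
      observed[, !is_met] <- signal[, !is_met, drop = FALSE] +
        plate_offsets[plate_of]
    }
    miss <- matrix(runif(n_samples * m) < config$missing_rate, n_samples, m)
    observed[miss] <- NA_real_
  })

  profiles <- tibble(
    line_id = rep(samples$line_id, times = m),
    replicate_id = rep(samples$replicate_id, times = m),
    feature_id = rep(config$feature_ids, each = n_samples),
    value = as.vector(observed),
    control_value = ifelse(rep(is_met, each = n_samples),
                           rep(control, times = m), NA_real_),
    plate_id = ifelse(rep(is_met, each = n_samples), NA_character_,
                      rep(sprintf("P%d", plate_of), times = m))
  ) |>
    select("line_id", "replicate_id", "plate_id", "feature_id",
           "value", "control_value") |>
    arrange(.data$line_id, .data$replicate_id, .data$feature_id)

  compound_classes <- c("amino acid", "sugar", "organic acid",
                        "phosphorylated intermediate", "polyamine",
                        "specialized")
  features <- tibble(
    feature_id = config$feature_ids,
    molecular_class = ifelse(is_met, "metabolite", "enzyme"),
    compound_class = ifelse(
      is_met,
      rep_len(compound_classes, length(config$feature_ids)),
      "enzyme activity"
    )
  )

  block_map <- if (length(config$blocks)) {
    purrr::map(config$blocks, function(b) {
      tibble(feature_id = b$features, block_id = b$id, correlation = b$correlation)
    }) |> purrr::list_rbind()
  } else {
    tibble(feature_id = character(), block_id = integer(), correlation = double())
  }

  G_named <- G
  dimnames(G_named) <- list(line_ids, config$feature_ids)
  truth <- structure(
    list(
      sigma2_g = setNames(sigma2_g, config$feature_ids),
      sigma2_e = setNames(sigma2_e, config$feature_ids),
      h2 = config$h2,
      mu = setNames(mu, config$feature_ids),
      latent_correlation = R,
      blocks = block_map,
      genetic_values = G_named,
      # noiseless replicate-level signal mu + g (no residual, control or
      # plate term): the reference for imputation-accuracy checks
      signal = tibble(
        line_id = rep(samples$line_id, times = m),
        replicate_id = rep(samples$replicate_id, times = m),
        feature_id = rep(config$feature_ids, each = n_samples),
        value = as.vector(matrix(mu, n_samples, m, byrow = TRUE) +
                            G[line_index, , drop = FALSE])
      )
    ),
    class = "planted_truth"
  )

  structure(list(profiles = profiles, features = features, truth = truth),
            class = "trait_panel")
}

#' Summarize planted ground truth as a serializable record
#'
#' Flattens a `planted_truth` object into plain vectors and data frames so it
#' can be written as JSON (e.g. with [jsonlite::write_json()]) and asserted
#' against in tests; `truth_report()` round-trips through JSON unchanged up to
#' double precision.
#'
#' @param truth The `truth` element of a [generate_panel()] result.
#' @return A named list: per-feature variance components and true
#'   heritability, the block map, and the planted latent correlation matrix.
#' @export
truth_report <- function(truth) {
  if (!inherits(truth, "planted_truth")) abort("`truth` must be a planted_truth.")
  list(
    n_blocks = length(unique(truth$blocks$block_id)),
    features = tibble(
      feature_id = names(truth$h2),
      sigma2_g = unname(truth$sigma2_g),
      sigma2_e = unname(truth$sigma2_e),
      h2 = unname(truth$h2)
    ),
    blocks = truth$blocks,
    latent_correlation = truth$latent_correlation
  )
}

#' @export
print.trait_panel <- function(x, ...) {
  n_missing <- sum(is.na(x$profiles$value))
  cat(sprintf(
    "<trait_panel> %d lines x %s replicates, %d features (%d metabolites, %d enzymes)\n",
    length(unique(x$profiles$line_id)),
    length(unique(x$profiles$replicate_id)),
    nrow(x$features),
    sum(x$features$molecular_class == "metabolite"),
    sum(x$features$molecular_class == "enzyme")
  ))
  cat(sprintf("  %d records, %.1f%% missing; %d planted blocks\n",
              nrow(x$profiles), 100 * n_missing / nrow(x$profiles),
              length(unique(x$truth$blocks$block_id))))
  invisible(x)
}
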