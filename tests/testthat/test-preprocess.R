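met_annotation <- function() {
  tibble::tibble(feature_id = "m1", molecular_class = "metabolite",
                 compound_class = "sugar")
}

test_that("internal-standard normalization divides per chromatogram", {
  prof <- tibble::tibble(
    line_id = c("L1", "L2", "L3"), replicate_id = "r1",
    plate_id = NA_character_, feature_id = "m1",
    value = c(300, 600, 900), control_value = c(100, 200, 300)
  )
  out <- normalize_metabolites(prof, met_annotation())
  expect_equal(out$value, c(3, 3, 3))

  one <- prof[1, ]
  one$value <- 1000
  one$control_value <- 500
  expect_equal(normalize_metabolites(one, met_annotation())$value, 2)

  bad <- prof
  bad$control_value[2] <- 0
  expect_error(normalize_metabolites(bad, met_annotation()), "L2/r1/m1")
})

test_that("plate standardization follows the two stated steps", {
  ann <- tibble::tibble(feature_id = "e1", molecular_class = "enzyme",
                        compound_class = "enzyme activity")
  prof <- tibble::tibble(
    line_id = c("L1", "L2"), replicate_id = "r1", plate_id = "P1",
    feature_id = "e1", value = c(2, 4), control_value = NA_real_
  )
  out <- standardize_enzymes(prof, ann)
  # plate mean 3 -> (2/3, 4/3); overall mean 1 -> (-1/3, +1/3)
  expect_equal(out$value, c(-1 / 3, 1 / 3))

  flat <- prof
  flat$value <- c(7, 7)
  expect_equal(standardize_enzymes(flat, ann)$value, c(0, 0))

  noplate <- prof
  noplate$plate_id <- NA_character_
  expect_error(standardize_enzymes(noplate, ann), "plate id")
})

test_that("enzyme columns always end centered, under both plate methods", {
  set.seed(21)
  prof <- profiles_from_values(
    e1 = matrix(rlnorm(24, 2), 6), e2 = matrix(rlnorm(24, 3), 6),
    plate_id = NA_character_
  )
  prof$plate_id <- rep_len(c("P1", "P2", "P3"), nrow(prof))
  ann <- feature_annotation(prof, "enzyme")
  for (m in c("divide", "subtract")) {
    out <- standardize_enzymes(prof, ann, method = m)
    means <- tapply(out$value, out$feature_id, mean)
    expect_equal(as.numeric(means), c(0, 0), tolerance = 1e-12)
  }
})

test_that("imputation is an identity on complete data and never touches observed cells", {
  set.seed(31)
  prof <- profiles_from_values(
    f1 = matrix(rnorm(40), 10), f2 = matrix(rnorm(40), 10),
    f3 = matrix(rnorm(40), 10)
  )
  out <- impute_missing(prof, n_components = 2)
  expect_identical(out$value, prof$value)
  expect_false(any(out$imputed))

  holey <- prof
  drop_idx <- c(3, 17, 44, 80)
  holey$value[drop_idx] <- NA
  out2 <- impute_missing(holey, n_components = 2)
  expect_identical(out2$value[-drop_idx], prof$value[-drop_idx])
  expect_false(anyNA(out2$value))
  expect_identical(which(out2$imputed), as.integer(drop_idx))
  # deterministic
  expect_identical(impute_missing(holey, n_components = 2)$value, out2$value)
})

test_that("a removed cell of a rank-1 matrix is recovered exactly", {
  u <- c(1, 2, 3, 4, 5, 6)
  v <- c(2, 5, 1, 7)
  m <- outer(u, v)
  dimnames(m) <- list(NULL, paste0("f", seq_along(v)))
  prof <- do.call(profiles_from_values,
                  setNames(lapply(seq_along(v), function(j) m[, j, drop = FALSE]),
                           colnames(m)))
  target <- prof$value[prof$feature_id == "f2" & prof$line_id == "L003"]
  prof$value[prof$feature_id == "f2" & prof$line_id == "L003"] <- NA
  out <- impute_missing(prof, n_components = 1, tol = 1e-10)
  got <- out$value[out$feature_id == "f2" & out$line_id == "L003"]
  expect_lt(abs(got - target) / abs(target), 1e-6)
})

test_that("imputation refuses a fully missing feature", {
  prof <- profiles_from_values(f1 = matrix(rnorm(20), 5),
                               f2 = matrix(rnorm(20), 5))
  prof$value[prof$feature_id == "f2"] <- NA
  expect_error(impute_missing(prof, n_components = 1), "f2")
})

test_that("imputed cells on a synthetic panel beat the residual noise floor", {
  cfg <- simulation_config(n_lines = 60, n_replicates = 5, n_metabolites = 12,
                           n_enzymes = 0,
                           blocks = list(list(id = 1L,
                                              features = sprintf("met%02d", 1:12),
                                              correlation = 0.7)),
                           h2 = 0.6, missing_rate = 0.057, seed = 5)
  panel <- generate_panel(cfg)
  norm <- normalize_metabolites(panel$profiles, panel$features)
  # one planted equicorrelated block -> the line-level structure is rank 1
  imp <- impute_missing(norm, n_components = 1)
  truth <- panel$truth$signal |>
    dplyr::rename(true_value = "value")
  cells <- imp |>
    dplyr::filter(.data$imputed) |>
    dplyr::left_join(truth, by = c("line_id", "replicate_id", "feature_id")) |>
    dplyr::left_join(
      tibble::tibble(feature_id = names(panel$truth$sigma2_e),
                     sd_e = sqrt(panel$truth$sigma2_e)),
      by = "feature_id"
    )
  scaled_err <- (cells$value - cells$true_value) / cells$sd_e
  expect_lt(sqrt(mean(scaled_err^2)), 1)
})

test_that("variance components hit the boundary cases", {
  # zero residual: replicates identical within line, lines differ
  prof <- profiles_from_values(f1 = matrix(rep(c(1, 5, 9, 13), 3), 4))
  vc <- fit_variance_components(prof)
  expect_equal(vc$h2, 1, tolerance = 1e-6)

  # zero genetic: all line means equal, replicates noisy
  set.seed(41)
  noise <- matrix(rnorm(120), 30)
  noise <- noise - rowMeans(noise)
  vc2 <- fit_variance_components(profiles_from_values(f1 = noise + 10))
  expect_lt(vc2$h2, 0.05)

  # constant feature: degenerate, h2 reported missing
  vc3 <- fit_variance_components(profiles_from_values(f1 = matrix(4, 5, 3)))
  expect_true(vc3$degenerate)
  expect_true(is.na(vc3$h2))
})

test_that("REML estimates match the balanced one-way ANOVA closed form", {
  set.seed(43)
  r <- 4
  vals <- matrix(rnorm(25, sd = 2), 25, r) + matrix(rnorm(100), 25, r)
  prof <- profiles_from_values(f1 = vals)
  vc <- fit_variance_components(prof)
  line_means <- rowMeans(vals)
  msb <- r * var(line_means)
  mse <- sum((vals - line_means)^2) / (25 * r - 25)
  expect_equal(vc$sigma2_e, mse, tolerance = 1e-6)
  expect_equal(vc$sigma2_g, max((msb - mse) / r, 0), tolerance = 1e-6)
})

test_that("heritability is invariant to affine rescaling", {
  set.seed(44)
  vals <- matrix(rnorm(20, sd = 1.5), 20, 5) + matrix(rnorm(100), 20, 5)
  h_raw <- fit_variance_components(profiles_from_values(f1 = vals))$h2
  h_scaled <- fit_variance_components(
    profiles_from_values(f1 = 3.7 * vals + 11)
  )$h2
  expect_equal(h_raw, h_scaled, tolerance = 1e-8)
})

test_that("planted heritability is recovered on a synthetic panel", {
  errs <- c()
  for (s in 1:2) {
    cfg <- simulation_config(n_lines = 100, n_replicates = 5,
                             n_metabolites = 8, n_enzymes = 0,
                             blocks = list(), h2 = 0.5, missing_rate = 0,
                             seed = s)
    panel <- generate_panel(cfg)
    norm <- normalize_metabolites(panel$profiles, panel$features)
    vc <- fit_variance_components(norm)
    errs <- c(errs, abs(vc$h2 - 0.5))
  }
  expect_lt(mean(errs), 0.05)
})

test_that("BLUP shrinkage follows the closed form on a balanced toy", {
  prof <- profiles_from_values(f1 = rbind(c(9, 11), c(13, 15)))
  comp <- tibble::tibble(feature_id = "f1", sigma2_g = 1, sigma2_e = 2,
                         h2 = 1 / 3, degenerate = FALSE)
  b <- compute_blups(prof, comp)
  # line means 10 and 14, grand mean 12, shrinkage 1/(1 + 2/2) = 0.5
  expect_equal(b$grand_mean, c(12, 12))
  expect_equal(b$blup, c(-1, 1))

  # sigma2_g = 0: every BLUP exactly zero
  comp0 <- dplyr::mutate(comp, sigma2_g = 0)
  expect_identical(compute_blups(prof, comp0)$blup, c(0, 0))

  # vanishing residual: BLUP equals line mean minus grand mean
  comp1 <- dplyr::mutate(comp, sigma2_e = 0)
  expect_equal(compute_blups(prof, comp1)$blup, c(-2, 2))
})

test_that("BLUPs match lme4 conditional modes on unbalanced data", {
  set.seed(47)
  prof <- profiles_from_values(f1 = matrix(rnorm(60, sd = 1), 12, 5) +
                                 rnorm(12, sd = 2))
  prof <- prof[-c(2, 15, 31, 44), ] # unbalance the replicate counts
  vc <- fit_variance_components(prof)
  b <- compute_blups(prof, vc)
  fit <- lme4::lmer(value ~ 1 + (1 | line_id), data = prof, REML = TRUE)
  expect_equal(b$blup, unname(lme4::ranef(fit)$line_id[["(Intercept)"]]),
               tolerance = 1e-6)
  expect_equal(b$grand_mean[1], unname(lme4::fixef(fit))[1], tolerance = 1e-6)
  # shrinkage bound: |BLUP| never exceeds |line mean - grand mean|
  lm_dev <- tapply(prof$value, prof$line_id, mean) - b$grand_mean[1]
  expect_true(all(abs(b$blup) <= abs(lm_dev) + 1e-12))
})

test_that("descriptive statistics and heritability bins are correct", {
  blups <- tibble::tibble(
    line_id = c("L1", "L2", "L3"), feature_id = "f1",
    blup = c(-2, 0, 2), grand_mean = 4
  )
  comp <- tibble::tibble(feature_id = "f1", sigma2_g = 1, sigma2_e = 1,
                         h2 = 0.5, degenerate = FALSE)
  st <- descriptive_stats(blups, comp)
  expect_equal(st$mean, 4)
  expect_equal(st$variance, 4)
  expect_equal(st$cv, 0.5) # sd 2 over mean 4

  # constant feature: variance 0, cv 0
  stc <- descriptive_stats(
    dplyr::mutate(blups, blup = 0), comp
  )
  expect_equal(stc$variance, 0)
  expect_equal(stc$cv, 0)

  # zero mean: cv reported missing, with a warning
  expect_warning(
    st0 <- descriptive_stats(dplyr::mutate(blups, grand_mean = 0), comp),
    "CV undefined"
  )
  expect_true(is.na(st0$cv))

  comp3 <- tibble::tibble(feature_id = c("a", "b", "c"),
                          sigma2_g = 1, sigma2_e = 1,
                          h2 = c(0.05, 0.15, 0.95), degenerate = FALSE)
  bins <- h2_histogram(comp3)
  expect_equal(bins$n[bins$bin %in% c(1, 2, 10)], c(1L, 1L, 1L))
  expect_equal(sum(bins$n), 3L)
  expect_equal(bins$rel_freq[bins$bin == 1], 1 / 3)
  # h2 = 1 belongs to the top bin [0.9, 1]
  expect_equal(traitnet:::h2_bin_index(1), 10L)
})
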