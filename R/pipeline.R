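#' Network analysis of a line-level BLUP table
#'
#' Runs the network stages on a BLUP (line x feature) table: all-pairs
#' Spearman correlation, Benjamini-Hochberg p-value cutoff at `q_target`,
#' correlation-threshold calibration by network-property stability (skipped
#' when `r_cutoff` is fixed by the caller), network construction, walktrap
#' community detection with community-significance testing and merging, node
#' degree/betweenness statistics with optional permutation p-values, and
#' Pearson shared-variance edge validation.
#'
#' @param blups Long tibble (`line_id`, `feature_id`, `blup`); a `grand_mean`
#'   column is allowed and ignored here.
#' @param features Optional feature annotation (`feature_id`,
#'   `molecular_class`, `compound_class`).
#' @param q_target Target q-value for the BH p-cutoff (default 0.05).
#' @param r_cutoff Fixed correlation threshold; `NULL` (default) calibrates it
#'   with [select_r_cutoff()].
#' @param candidates,p_grid,stability_tolerance Passed to [select_r_cutoff()].
#' @param walktrap_steps Random-walk length for [walktrap_communities()].
#' @param alpha Significance level for community tests and merging.
#' @param n_perm Permutation iterations for [permutation_test()]; 0 skips the
#'   permutation stage.
#' @param seed Seed for the permutation stage.
#'
#' @return A list of class `trait_network_analysis`: `correlation`,
#'   `calibration` (or `NULL`), `p_cutoff`, `r_cutoff`, `network`,
#'   `properties`, `partition` (pre-merge, with significance), `merged`
#'   (post-merge partition), `node_stats`, `permutation` (or `NULL`),
#'   `edge_validation`.
#' @export
analyze_blups <- function(blups, features = NULL, q_target = 0.05,
                          r_cutoff = NULL,
                          candidates = seq(0.10, 0.60, by = 0.05),
                          p_grid = seq(0.01, 0.05, by = 0.01),
                          stability_tolerance = 0.01,
                          walktrap_steps = 4, alpha = 0.05,
                          n_perm = 0, seed = 1L) {
  corr <- spearman_all_pairs(blups)
  p_cutoff <- bh_threshold(corr$p, q_target = q_target)
  if (p_cutoff == 0) {
    abort("No correlation passes the BH cutoff; the network would be empty.")
  }
  calibration <- NULL
  if (is.null(r_cutoff)) {
    calibration <- select_r_cutoff(corr, candidates = candidates,
                                   p_grid = p_grid,
                                   tolerance = stability_tolerance)
    r_cutoff <- calibration$r_cutoff
  }
  net <- build_network(corr, r_cutoff = r_cutoff, p_cutoff = p_cutoff,
                       features = features)
  partition <- walktrap_communities(net, steps = walktrap_steps) |>
    (\(p) test_communities(net, p))()
  merged <- merge_communities(net, partition, alpha = alpha)
  stats <- node_stats(net)
  permutation <- NULL
  if (n_perm > 0) {
    permutation <- permutation_test(blups, r_cutoff = r_cutoff,
                                    p_cutoff = p_cutoff, n_iter = n_perm,
                                    seed = seed)
  }
  structure(
    list(
      correlation = corr,
      calibration = calibration,
      p_cutoff = p_cutoff,
      r_cutoff = r_cutoff,
      network = net,
      properties = network_properties(net),
      partition = partition,
      merged = merged,
      node_stats = stats,
      permutation = permutation,
      edge_validation = edge_validation(blups, net)
    ),
    class = "trait_network_analysis"
  )
}

#' Run the full profiling-to-network pipeline
#'
#' End-to-end orchestration: simulate (when given a [simulation_config()]) or
#' ingest a replicated profile table, normalize metabolites by their internal
#' standard and standardize enzymes by plate, impute missing values by EM-PCA
#' (skipped and logged when the data are complete), estimate per-feature
#' variance components and heritability by REML, compute line BLUPs and
#' descriptive statistics, then run the network stage ([analyze_blups()]).
#' Identical seed and configuration give identical results.
#'
#' @param x A [simulation_config()], a [generate_panel()] result, or a long
#'   profile tibble (then `features` must be given).
#' @param features Feature annotation tibble; ignored when `x` carries one.
#' @param impute_components Rank of the EM-PCA imputation.
#' @param plate_method Plate standardization method, see
#'   [standardize_enzymes()].
#' @param h2_basis Heritability basis, see [fit_variance_components()].
#' @param ... Passed to [analyze_blups()] (`q_target`, `r_cutoff`, `n_perm`,
#'   `seed`, ...).
#'
#' @return A list of class `trait_pipeline`: the `panel` inputs, `normalized`
#'   profiles, `imputed` flag table, `components`, `blups`, `stats`,
#'   `h2_bins`, the network `analysis`, and a flat `report` list of headline
#'   numbers ([glance()] returns it as a one-row tibble).
#' @export
run_pipeline <- function(x, features = NULL, impute_components = 3,
                         plate_method = c("divide", "subtract"),
                         h2_basis = c("observation", "line_mean"), ...) {
  plate_method <- match.arg(plate_method)
  h2_basis <- match.arg(h2_basis)
  truth <- NULL
  if (inherits(x, "simulation_config")) {
    panel <- generate_panel(x)
    profiles <- panel$profiles
    features <- panel$features
    truth <- panel$truth
  } else if (inherits(x, "trait_panel")) {
    profiles <- x$profiles
    features <- x$features
    truth <- x$truth
  } else {
    profiles <- as_tibble(x)
    if (is.null(features)) abort("`features` annotation is required.")
  }

  normalized <- normalize_profiles(profiles, features, method = plate_method)
  imputation_skipped <- !anyNA(normalized$value)
  if (imputation_skipped) {
    inform("No missing values; imputation stage skipped.")
    imputed <- normalized |> mutate(imputed = FALSE)
  } else {
    imputed <- impute_missing(normalized, n_components = impute_components)
  }
  components <- fit_variance_components(imputed, basis = h2_basis)
  blups <- compute_blups(imputed, components)
  stats <- descriptive_stats(blups, components)
  analysis <- analyze_blups(blups, features = features, ...)

  structure(
    list(
      profiles = profiles,
      features = features,
      truth = truth,
      normalized = normalized,
      imputed = imputed,
      imputation_skipped = imputation_skipped,
      components = components,
      blups = blups,
      stats = stats,
      h2_bins = h2_histogram(components, features),
      analysis = analysis,
      report = pipeline_report(components, analysis)
    ),
    class = "trait_pipeline"
  )
}

# Headline numbers of a run, all recomputable from the persisted stages.
pipeline_report <- function(components, analysis) {
  props <- analysis$properties
  ns <- analysis$node_stats
  sig <- analysis$merged$significance
  ev <- analysis$edge_validation
  list(
    p_cutoff = analysis$p_cutoff,
    r_cutoff = analysis$r_cutoff,
    n_nodes = props$n_nodes,
    n_edges = props$n_edges,
    avg_degree = props$avg_degree,
    max_degree = if (nrow(ns)) max(ns$degree) else NA_real_,
    avg_betweenness = if (nrow(ns)) mean(ns$betweenness) else NA_real_,
    max_betweenness = if (nrow(ns)) max(ns$betweenness) else NA_real_,
    clustering = props$clustering,
    density = props$density,
    diameter = props$diameter,
    n_communities = nrow(analysis$partition$sizes),
    n_communities_merged = nrow(analysis$merged$sizes),
    community_p = setNames(sig$p_value, paste0("community_", sig$community_id)),
    pearson_bins = table(factor(ev$r_bin,
                                levels = c("<=0.4", "(0.4,0.6]", ">0.6"))),
    shared_variance_bins = table(factor(ev$r2_bin,
                                        levels = c("<=20%", "(20%,40%]", ">40%"))),
    mean_h2 = mean(components$h2, na.rm = TRUE),
    frac_h2_below_0.5 = mean(components$h2 < 0.5, na.rm = TRUE)
  )
}

#' @export
print.trait_pipeline <- function(x, ...) {
  r <- x$report
  cat("<trait_pipeline>\n")
  cat(sprintf("  thresholds: |rho| >= %.2f, p <= %.4g (BH)\n",
              r$r_cutoff, r$p_cutoff))
  cat(sprintf("  network: %d nodes, %d edges, avg degree %.2f, avg betweenness %.2f\n",
              r$n_nodes, r$n_edges, r$avg_degree, r$avg_betweenness))
  cat(sprintf("  communities: %d detected, %d after merging\n",
              r$n_communities, r$n_communities_merged))
  invisible(x)
}

#' @export
print.trait_network_analysis <- function(x, ...) {
  cat(sprintf(
    "<trait_network_analysis> %d nodes, %d edges; %d -> %d communities\n",
    x$properties$n_nodes, x$properties$n_edges,
    nrow(x$partition$sizes), nrow(x$merged$sizes)
  ))
  invisible(x)
}

#' Export a trait network with node statistics and communities
#'
#' Writes the network as GraphML (node attributes: molecular and compound
#' class, community and merged community id, degree, betweenness; edge
#' attributes: rho, sign, p, q) and/or as a Cytoscape-compatible edge table
#' (`source`, `interaction`, `target`, `rho`, `p`, `q`).
#'
#' @param net A `trait_network`.
#' @param path Output file path (extension not enforced).
#' @param partition Optional `community_partition` to embed.
#' @param stats Optional [node_stats()] tibble to embed.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, partition = NULL, stats = NULL,
                           format = c("graphml", "edgelist")) {
  if (length(format) == 1L && !format %in% c("graphml", "edgelist")) {
    abort(sprintf("Unsupported format '%s'; supported: graphml, edgelist.",
                  format))
  }
  format <- match.arg(format)
  g <- net
  if (!is.null(partition)) {
    idx <- match(igraph::V(g)$name, partition$membership$feature_id)
    igraph::V(g)$community <- partition$membership$community_id[idx]
    merged_of <- setNames(partition$merges$merged_community,
                          partition$merges$original_community)
    igraph::V(g)$merged_community <-
      as.integer(merged_of[as.character(igraph::V(g)$community)])
  }
  if (!is.null(stats)) {
    idx <- match(igraph::V(g)$name, stats$feature_id)
    igraph::V(g)$degree <- stats$degree[idx]
    igraph::V(g)$betweenness <- stats$betweenness[idx]
  }
  if (format == "graphml") {
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    readr::write_tsv(
      tibble(
        source = el[, 1],
        interaction = ifelse(igraph::E(g)$sign >= 0, "positive", "negative"),
        target = el[, 2],
        rho = igraph::E(g)$rho,
        p = igraph::E(g)$p,
        q = igraph::E(g)$q
      ),
      path
    )
  }
  invisible(path)
}

#' Persist every pipeline stage to a directory
#'
#' Writes the intermediate artifacts of a [run_pipeline()] result as
#' plain-text files: normalized/imputed profiles, variance components, BLUPs,
#' descriptive statistics, heritability bins, the correlation pair list, the
#' threshold-stability scan, node statistics, permutation results (if run),
#' edge validation, community memberships, the GraphML network, the edge
#' table, and the report as JSON.
#'
#' @param result A `trait_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, name) readr::write_tsv(d, file.path(dir, name))
  w(result$normalized, "normalized_profiles.tsv")
  w(result$imputed, "imputed_profiles.tsv")
  w(result$components, "variance_components.tsv")
  w(result$blups, "blups.tsv")
  w(result$stats, "descriptive_stats.tsv")
  w(result$h2_bins, "h2_bins.tsv")
  w(as_tibble(result$analysis$correlation), "correlations.tsv")
  if (!is.null(result$analysis$calibration)) {
    w(result$analysis$calibration$scan, "threshold_scan.tsv")
  }
  w(result$analysis$node_stats, "node_stats.tsv")
  if (!is.null(result$analysis$permutation)) {
    w(result$analysis$permutation, "permutation_tests.tsv")
  }
  w(result$analysis$edge_validation, "edge_validation.tsv")
  membership <- result$analysis$merged$membership |>
    rename(merged_community_id = "community_id") |>
    left_join(result$analysis$partition$membership, by = "feature_id") |>
    left_join(result$analysis$merged$significance |>
                select(merged_community_id = "community_id",
                       community_p_value = "p_value"),
              by = "merged_community_id") |>
    select("feature_id", "community_id", "merged_community_id",
           "community_p_value")
  w(membership, "communities.tsv")
  export_network(result$analysis$network, file.path(dir, "network.graphml"),
                 partition = result$analysis$merged,
                 stats = result$analysis$node_stats, format = "graphml")
  export_network(result$analysis$network, file.path(dir, "edges.tsv"),
                 format = "edgelist")
  report <- result$report
  report$pearson_bins <- as.list(report$pearson_bins)
  report$shared_variance_bins <- as.list(report$shared_variance_bins)
  report$community_p <- as.list(report$community_p)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
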