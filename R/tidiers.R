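#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trait network into an edge tibble
#'
#' @param x A `trait_network`.
#' @param ... Unused.
#' @return Tibble with one row per edge: `feature_a`, `feature_b`, `rho`,
#'   `p`, `q`, `sign`.
#' @method tidy trait_network
#' @export
tidy.trait_network <- function(x, ...) {
  el <- igraph::as_edgelist(x)
  if (nrow(el) == 0L) {
    return(tibble(feature_a = character(), feature_b = character(),
                  rho = double(), p = double(), q = double(),
                  sign = integer()))
  }
  tibble(
    feature_a = el[, 1],
    feature_b = el[, 2],
    rho = igraph::E(x)$rho,
    p = igraph::E(x)$p,
    q = igraph::E(x)$q,
    sign = igraph::E(x)$sign
  )
}

#' Global property summary of a trait network
#'
#' @param x A `trait_network`.
#' @param ... Unused.
#' @return One-row tibble, see [network_properties()].
#' @method glance trait_network
#' @export
glance.trait_network <- function(x, ...) network_properties(x)

#' Tidy a community partition into a node tibble
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `community_id`, and (when significance
#'   has been computed) the community `size`, `p_value`, `tested`.
#' @method tidy community_partition
#' @export
tidy.community_partition <- function(x, ...) {
  out <- x$membership
  if (!is.null(x$significance)) {
    out <- out |>
      left_join(x$significance |>
                  select("community_id", "size", "p_value", "tested"),
                by = "community_id")
  }
  out
}

#' One-row summary of a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return Tibble with community counts, size range, and the number of
#'   significant communities at the recorded tests.
#' @method glance community_partition
#' @export
glance.community_partition <- function(x, ...) {
  sig <- x$significance
  tibble(
    n_communities = nrow(x$sizes),
    n_nodes = nrow(x$membership),
    min_size = min(x$sizes$size),
    max_size = max(x$sizes$size),
    n_tested = if (is.null(sig)) NA_integer_ else sum(sig$tested),
    n_standalone = length(x$standalone)
  )
}

#' Tidy a threshold calibration into the full stability scan
#'
#' @param x A `threshold_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per (candidate, p) pair and the four network
#'   properties, plus the per-candidate stability verdict.
#' @method tidy threshold_calibration
#' @export
tidy.threshold_calibration <- function(x, ...) {
  x$scan |>
    left_join(x$stable, by = "candidate")
}

#' One-row summary of a threshold calibration
#'
#' @param x A `threshold_calibration`.
#' @param ... Unused.
#' @return Tibble with the chosen cutoff, tolerance, and counts of stable
#'   candidates.
#' @method glance threshold_calibration
#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble(
    r_cutoff = x$r_cutoff,
    tolerance = x$tolerance,
    n_candidates = length(x$candidates),
    n_stable = sum(x$stable$stable)
  )
}

#' One-row headline summary of a pipeline run
#'
#' @param x A `trait_pipeline`.
#' @param ... Unused.
#' @return One-row tibble with the chosen thresholds, network size and
#'   property summary, community counts, and heritability summary.
#' @method glance trait_pipeline
#' @export
glance.trait_pipeline <- function(x, ...) {
  r <- x$report
  tibble(
    p_cutoff = r$p_cutoff, r_cutoff = r$r_cutoff,
    n_nodes = r$n_nodes, n_edges = r$n_edges,
    avg_degree = r$avg_degree, max_degree = r$max_degree,
    avg_betweenness = r$avg_betweenness, max_betweenness = r$max_betweenness,
    clustering = r$clustering, density = r$density, diameter = r$diameter,
    n_communities = r$n_communities,
    n_communities_merged = r$n_communities_merged,
    mean_h2 = r$mean_h2, frac_h2_below_0.5 = r$frac_h2_below_0.5
  )
}
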