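#' Build the trait network from a correlation table
#'
#' Keeps an edge between two features iff `|rho| >= r_cutoff` and
#' `p <= p_cutoff`; the sign of the correlation is stored on the edge.
#' Features with no retained edge are dropped from the node set, so the
#' result is a simple undirected graph whose nodes all have degree >= 1.
#'
#' @param corr A `trait_correlation` tibble from [spearman_all_pairs()] (or
#'   any tibble with `feature_a`, `feature_b`, `rho`, `p`, and optionally `q`).
#' @param r_cutoff Absolute correlation threshold in `(0, 1)`.
#' @param p_cutoff P-value threshold in `(0, 1)`, typically from
#'   [bh_threshold()].
#' @param features Optional annotation tibble (`feature_id`,
#'   `molecular_class`, `compound_class`) copied onto the nodes.
#'
#' @return An [igraph][igraph::igraph-package] graph of class
#'   `trait_network`; edge attributes `rho`, `p`, `q`, `sign`; graph
#'   attributes `r_cutoff`, `p_cutoff`.
#' @export
build_network <- function(corr, r_cutoff, p_cutoff, features = NULL) {
  assert_scalar_number(r_cutoff, "r_cutoff", 0, 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  assert_scalar_number(p_cutoff, "p_cutoff", 0, 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  edges <- corr |>
    as_tibble() |>
    filter(abs(.data$rho) >= r_cutoff, .data$p <= p_cutoff)
  g <- igraph::graph_from_data_frame(
    edges |>
      transmute(
        from = .data$feature_a, to = .data$feature_b,
        rho = .data$rho, p = .data$p,
        q = if ("q" %in% names(edges)) .data$q else NA_real_,
        sign = ifelse(.data$rho >= 0, 1L, -1L)
      ),
    directed = FALSE,
    vertices = tibble(name = sort(unique(c(edges$feature_a, edges$feature_b))))
  )
  if (!is.null(features)) {
    idx <- match(igraph::V(g)$name, features$feature_id)
    if ("molecular_class" %in% names(features)) {
      igraph::V(g)$molecular_class <- features$molecular_class[idx]
    }
    if ("compound_class" %in% names(features)) {
      igraph::V(g)$compound_class <- features$compound_class[idx]
    }
  }
  g$r_cutoff <- r_cutoff
  g$p_cutoff <- p_cutoff
  class(g) <- c("trait_network", class(g))
  g
}

#' Global network properties
#'
#' Average node degree (`2E/N`), average local (Watts-Strogatz) clustering
#' coefficient with nodes of degree < 2 contributing 0, density
#' (`2E/(N(N-1))`), the diameter of the largest connected component
#' (unweighted longest shortest path), and the number of connected
#' components.
#'
#' @param net A `trait_network` (or any undirected igraph graph).
#' @return A one-row tibble: `n_nodes`, `n_edges`, `avg_degree`,
#'   `clustering`, `density`, `diameter`, `n_components`. All-`NA` metrics
#'   for an empty graph.
#' @export
network_properties <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) {
    return(tibble(n_nodes = 0L, n_edges = 0L, avg_degree = NA_real_,
                  clustering = NA_real_, density = NA_real_,
                  diameter = NA_real_, n_components = 0L))
  }
  e <- igraph::ecount(net)
  local_cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  comps <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comps$membership == which.max(comps$csize))
  )
  diam <- if (igraph::vcount(giant) >= 2L) {
    as.numeric(igraph::diameter(giant, weights = NA))
  } else {
    0
  }
  tibble(
    n_nodes = n,
    n_edges = e,
    avg_degree = 2 * e / n,
    clustering = mean(local_cc),
    density = if (n > 1L) 2 * e / (n * (n - 1)) else NA_real_,
    diameter = diam,
    n_components = comps$no
  )
}

#' Calibrate the correlation threshold by network-property stability
#'
#' For each candidate correlation cutoff, builds the network at every p-value
#' in `p_grid` and computes the four global properties (average degree,
#' clustering coefficient, density, diameter). A candidate is *stable* when,
#' across the grid, the relative range `(max - min) / mean` of average
#' degree, clustering, and density is at most `tolerance` and the (integer)
#' diameter does not change at all. The chosen cutoff is the smallest stable
#' candidate.
#'
#' @inheritParams build_network
#' @param candidates Ascending candidate correlation cutoffs.
#' @param p_grid P-values to scan (at least 3).
#' @param tolerance Maximum relative range counted as stable.
#'
#' @return A list of class `threshold_calibration`: `r_cutoff` (the chosen
#'   cutoff), `stable` (logical per candidate), `scan` (tibble of properties
#'   per candidate and grid p-value), `candidates`, `p_grid`, `tolerance`.
#' @export
select_r_cutoff <- function(corr,
                            candidates = seq(0.10, 0.60, by = 0.05),
                            p_grid = seq(0.01, 0.05, by = 0.01),
                            tolerance = 0.01) {
  if (length(p_grid) < 3L || any(p_grid <= 0 | p_grid >= 1)) {
    abort("`p_grid` must contain at least 3 values in (0, 1).")
  }
  if (is.unsorted(candidates)) abort("`candidates` must be sorted ascending.")
  assert_scalar_number(tolerance, "tolerance", 0, Inf)

  scan <- tidyr::crossing(candidate = candidates, p = p_grid) |>
    mutate(props = purrr::map2(.data$candidate, .data$p, function(r, p) {
      network_properties(build_network(corr, r_cutoff = r, p_cutoff = p))
    })) |>
    tidyr::unnest("props")

  rel_range <- function(x) {
    if (anyNA(x)) return(Inf)
    if (max(x) == min(x)) return(0)
    mu <- mean(x)
    if (mu == 0) return(Inf)
    (max(x) - min(x)) / mu
  }
  verdict <- scan |>
    group_by(.data$candidate) |>
    summarise(
      stable = rel_range(.data$avg_degree) <= tolerance &&
        rel_range(.data$clustering) <= tolerance &&
        rel_range(.data$density) <= tolerance &&
        !anyNA(.data$diameter) &&
        (max(.data$diameter) - min(.data$diameter)) == 0,
      .groups = "drop"
    )
  if (!any(verdict$stable)) {
    abort(paste0(
      "No candidate correlation cutoff is stable across the p-value grid; ",
      "widen `candidates` or relax `tolerance`."
    ))
  }
  structure(
    list(
      r_cutoff = min(verdict$candidate[verdict$stable]),
      stable = verdict,
      scan = scan,
      candidates = candidates,
      p_grid = p_grid,
      tolerance = tolerance
    ),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration> r_cutoff = %.2f (%d of %d candidates stable; tolerance %.3g)\n",
    x$r_cutoff, sum(x$stable$stable), nrow(x$stable), x$tolerance
  ))
  invisible(x)
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf(
    "<trait_network> %d nodes, %d edges (|rho| >= %s, p <= %s)\n",
    igraph::vcount(x), igraph::ecount(x),
    format(x$r_cutoff %||% NA), format(signif(x$p_cutoff %||% NA, 3))
  ))
  invisible(x)
}
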