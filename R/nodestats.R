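#' Node degree and Freeman betweenness
#'
#' Degree and unnormalized Freeman betweenness for every node: for node `v`,
#' the sum over unordered node pairs `(s, t)` (both distinct from `v`) of the
#' fraction of shortest `s`-`t` paths passing through `v`. Paths are
#' unweighted; the fractional counting over equally shortest paths yields
#' non-integer values.
#'
#' @param net A `trait_network` (or undirected igraph graph).
#' @return Tibble with `feature_id`, `degree`, `betweenness`, sorted by
#'   decreasing degree then name.
#' @export
node_stats <- function(net) {
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA,
                             normalized = FALSE)
  tibble(
    feature_id = igraph::V(net)$name,
    degree = as.numeric(deg),
    betweenness = as.numeric(btw)
  ) |>
    arrange(desc(.data$degree), .data$feature_id)
}

#' Permutation test for node degree and betweenness
#'
#' Tests whether each node of the observed network is more connected / more
#' central than expected under the null of no inter-feature association. In
#' the default `mode = "profile"`, every iteration independently permutes
#' each feature's line-level values across lines (preserving all marginals,
#' destroying all associations), rebuilds the network with the *same* fixed
#' cutoffs, and records every original node's degree and betweenness (0 when
#' the node drops out). `mode = "rewire"` instead draws degree-preserving
#' rewirings of the observed graph, targeting the null of random wiring given
#' the degree sequence. P-values use the add-one estimator
#' `(1 + #{permuted >= observed}) / (1 + n_iter)`, so the smallest attainable
#' p-value is `1 / (1 + n_iter)` and an observed statistic of 0 yields 1.
#'
#' @param blups Long BLUP tibble ([compute_blups()]).
#' @param r_cutoff,p_cutoff The fixed network thresholds under test.
#' @param n_iter Number of permutations (>= 100; unstable below).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param statistic Which statistics to test: `"both"` (default), `"degree"`,
#'   or `"betweenness"` (degree-only runs skip shortest-path work).
#' @param mode Null model: `"profile"` (per-feature row permutation, default)
#'   or `"rewire"` (degree-preserving graph rewiring).
#'
#' @return Tibble with one row per observed-network node: `feature_id`,
#'   `degree`, `degree_p`, `betweenness`, `betweenness_p` (the latter two
#'   `NA` when `statistic = "degree"`), plus attribute `n_iter`.
#' @export
permutation_test <- function(blups, r_cutoff, p_cutoff, n_iter = 1000,
                             seed = 1L, statistic = c("both", "degree", "betweenness"),
                             mode = c("profile", "rewire")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  n_iter <- assert_count(n_iter, "n_iter", min = 100L)
  m <- blups_to_matrix(blups)
  n <- nrow(m)
  keep <- apply(m, 2, function(x) var(x) > 0)
  m <- m[, keep, drop = FALSE]
  ranks <- apply(m, 2, rank)
  # combined |rho| threshold: p <= p_cutoff is monotone in |rho| at fixed n
  rho_at_p <- stats::uniroot(
    function(r) spearman_p(r, n) - p_cutoff, c(1e-12, 1 - 1e-12)
  )$root
  thr <- max(r_cutoff, rho_at_p)

  scaled <- scale(ranks) / sqrt(n - 1) # crossprod gives the correlation
  adj_obs <- abs(crossprod(scaled)) >= thr
  diag(adj_obs) <- FALSE
  g_obs <- igraph::graph_from_adjacency_matrix(adj_obs, mode = "undirected")
  observed <- igraph::V(g_obs)$name[igraph::degree(g_obs) > 0]
  if (length(observed) == 0L) {
    abort("Observed network has no edges at the given cutoffs.")
  }
  obs_deg <- igraph::degree(g_obs)[observed]
  want_btw <- statistic %in% c("both", "betweenness")
  obs_btw <- if (want_btw) {
    igraph::betweenness(g_obs, directed = FALSE, weights = NA)[observed]
  } else {
    rep(NA_real_, length(observed))
  }

  ge_deg <- numeric(length(observed))
  ge_btw <- numeric(length(observed))
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      if (mode == "profile") {
        perm <- apply(scaled, 2, function(col) col[sample.int(n)])
        adj <- abs(crossprod(perm)) >= thr
        diag(adj) <- FALSE
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      } else {
        g <- igraph::rewire(
          g_obs, igraph::keeping_degseq(niter = 10 * igraph::ecount(g_obs))
        )
      }
      deg_i <- igraph::degree(g)[observed]
      ge_deg <- ge_deg + (deg_i >= obs_deg)
      if (want_btw) {
        btw_i <- igraph::betweenness(g, directed = FALSE, weights = NA)[observed]
        ge_btw <- ge_btw + (btw_i >= obs_btw)
      }
    }
  })

  out <- tibble(
    feature_id = observed,
    degree = as.numeric(obs_deg),
    degree_p = if (statistic %in% c("both", "degree")) {
      unname((1 + ge_deg) / (1 + n_iter))
    } else {
      NA_real_
    },
    betweenness = as.numeric(obs_btw),
    betweenness_p = if (want_btw) {
      unname((1 + ge_btw) / (1 + n_iter))
    } else {
      NA_real_
    }
  )
  attr(out, "n_iter") <- n_iter
  out
}

#' Pearson linear-dependency validation of network edges
#'
#' For every edge of the network, the Pearson product-moment correlation of
#' the two features' line-level BLUP profiles, the shared variance `r^2`, and
#' the bin labels used to summarize them: absolute linear dependency
#' `<= 0.4`, `(0.4, 0.6]`, `> 0.6`; shared variance `<= 20%`, `(20%, 40%]`,
#' `> 40%`. Bin counts always partition the edge set.
#'
#' @param blups Long BLUP tibble ([compute_blups()]).
#' @param net The `trait_network` whose edges are validated.
#'
#' @return Tibble with one row per edge: `feature_a`, `feature_b`,
#'   `pearson_r`, `shared_variance` (in percent), `r_bin`, `r2_bin`,
#'   `degenerate` (endpoint constant, correlation undefined).
#' @export
edge_validation <- function(blups, net) {
  m <- blups_to_matrix(blups)
  el <- igraph::as_edgelist(net)
  if (!all(c(el) %in% colnames(m))) {
    abort("Every edge endpoint must be present in `blups`.")
  }
  if (nrow(el) == 0L) {
    return(tibble(feature_a = character(), feature_b = character(),
                  pearson_r = double(), shared_variance = double(),
                  r_bin = character(), r2_bin = character(),
                  degenerate = logical()))
  }
  r <- vapply(seq_len(nrow(el)), function(i) {
    a <- m[, el[i, 1]]
    b <- m[, el[i, 2]]
    if (var(a) == 0 || var(b) == 0) NA_real_ else cor(a, b)
  }, numeric(1))
  tibble(
    feature_a = el[, 1],
    feature_b = el[, 2],
    pearson_r = r,
    shared_variance = 100 * r^2,
    r_bin = dplyr::case_when(
      is.na(r) ~ NA_character_,
      abs(r) <= 0.4 ~ "<=0.4",
      abs(r) <= 0.6 ~ "(0.4,0.6]",
      TRUE ~ ">0.6"
    ),
    r2_bin = dplyr::case_when(
      is.na(r) ~ NA_character_,
      100 * r^2 <= 20 ~ "<=20%",
      100 * r^2 <= 40 ~ "(20%,40%]",
      TRUE ~ ">40%"
    ),
    degenerate = is.na(r)
  )
}
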