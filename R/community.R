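#' Walktrap community detection on the unweighted trait network
#'
#' Partitions the network with the walktrap algorithm (agglomerative
#' clustering of short random-walk distances, dendrogram cut at maximum
#' modularity), run on the unweighted graph: correlation coefficients carried
#' on the edges are deliberately ignored. A graph with no edges yields one
#' singleton community per node.
#'
#' @param net A `trait_network` (or any undirected igraph graph).
#' @param steps Random-walk length (default 4, the algorithm's standard).
#'
#' @return A list of class `community_partition` with `membership` (tibble
#'   `feature_id`, `community_id`), `sizes` (tibble `community_id`, `size`),
#'   and empty significance/merge slots to be filled by
#'   [test_communities()] and [merge_communities()].
#' @export
walktrap_communities <- function(net, steps = 4) {
  steps <- assert_count(steps, "steps")
  if (igraph::vcount(net) == 0L) abort("`net` must contain at least one node.")
  if (igraph::ecount(net) == 0L) {
    membership <- tibble(
      feature_id = igraph::V(net)$name,
      community_id = seq_len(igraph::vcount(net))
    )
  } else {
    g <- net
    if ("weight" %in% igraph::edge_attr_names(g)) {
      g <- igraph::delete_edge_attr(g, "weight")
    }
    cl <- igraph::cluster_walktrap(g, steps = steps, weights = NULL)
    membership <- tibble(
      feature_id = igraph::V(net)$name,
      community_id = as.integer(igraph::membership(cl))
    )
  }
  new_partition(membership)
}

#' Construct a community partition from a membership table
#'
#' Wraps a node-to-community assignment (e.g. an externally defined or
#' hand-crafted partition) in the `community_partition` structure used by
#' [test_communities()] and [merge_communities()].
#'
#' @param membership Tibble with columns `feature_id` and `community_id`.
#' @return A `community_partition`.
#' @export
as_community_partition <- function(membership) {
  if (!all(c("feature_id", "community_id") %in% names(membership))) {
    abort("`membership` needs columns feature_id and community_id.")
  }
  if (anyDuplicated(membership$feature_id)) {
    abort("Each node must belong to exactly one community.")
  }
  new_partition(as_tibble(membership))
}

new_partition <- function(membership, significance = NULL, merges = NULL,
                          standalone = character()) {
  sizes <- membership |>
    count(.data$community_id, name = "size") |>
    arrange(.data$community_id)
  structure(
    list(
      membership = membership,
      sizes = sizes,
      significance = significance,
      merges = merges %||% tibble(
        original_community = sizes$community_id,
        merged_community = sizes$community_id
      ),
      standalone = standalone
    ),
    class = "community_partition"
  )
}

#' Internal vs. residual degree of community members
#'
#' For every node of a community: the *internal* degree is its degree in the
#' community's induced subgraph (the community in isolation); the *residual*
#' degree is its degree in the full network after deleting all
#' community-internal edges. For each member,
#' `internal + residual = full-network degree`.
#'
#' @param net A `trait_network` (or undirected igraph graph).
#' @param community Character vector of member node names.
#'
#' @return Tibble with `feature_id`, `internal_degree`, `residual_degree`.
#' @export
degree_pairs <- function(net, community) {
  if (length(community) == 0L) abort("`community` must be non-empty.")
  if (!all(community %in% igraph::V(net)$name)) {
    abort("`community` contains nodes absent from the network.")
  }
  sub <- igraph::induced_subgraph(net, community)
  internal <- igraph::degree(sub)[community]
  el <- igraph::as_edgelist(net)
  intra <- el[, 1] %in% community & el[, 2] %in% community
  stripped <- igraph::delete_edges(net, which(intra))
  residual <- igraph::degree(stripped)[community]
  tibble(
    feature_id = community,
    internal_degree = as.numeric(internal),
    residual_degree = as.numeric(residual)
  )
}

#' Structural significance of one community
#'
#' One-sided Wilcoxon signed-rank test on the paired internal and residual
#' degrees of the community members (alternative: internal > residual), i.e.
#' the test of whether the community is denser inside than its members'
#' remaining connectivity to the rest of the network. Zero differences are
#' dropped (Wilcoxon convention); the exact conditional distribution (a
#' subset-sum recursion over the tie-averaged ranks) is used for up to 25
#' informative pairs, a normal approximation with continuity and tie
#' correction above. Communities of 4 or fewer nodes are not tested.
#'
#' @param pairs Output of [degree_pairs()] for one community.
#'
#' @return One-row tibble: `size`, `n_informative`, `statistic` (the signed
#'   -rank sum W+), `p_value`, `tested`. Untested communities carry
#'   `tested = FALSE` and `p_value = NA`.
#' @export
community_significance <- function(pairs) {
  size <- nrow(pairs)
  if (size <= 4L) {
    return(tibble(size = size, n_informative = NA_integer_,
                  statistic = NA_real_, p_value = NA_real_, tested = FALSE))
  }
  res <- signed_rank_greater(pairs$internal_degree, pairs$residual_degree)
  tibble(size = size, n_informative = res$n, statistic = res$statistic,
         p_value = res$p_value, tested = TRUE)
}

# One-sided (x > y) Wilcoxon signed-rank test. Exact for n <= `exact_max`
# informative pairs via the subset-sum distribution over doubled average
# ranks (valid under ties, conditional on the observed |d|); otherwise the
# normal approximation with continuity correction and tie correction.
signed_rank_greater <- function(x, y, exact_max = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    s <- as.integer(round(2 * r)) # doubled ranks are integers
    counts <- numeric(sum(s) + 1L) # counts[k+1] = #subsets with doubled sum k
    counts[1L] <- 1
    for (si in s) {
      shifted <- c(numeric(si), counts[seq_len(length(counts) - si)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    p <- sum(counts[(w2 + 1L):length(counts)]) / 2^n
  } else {
    e_w <- n * (n + 1) / 4
    ties <- table(r)
    v_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (v_w <= 0) {
      p <- if (w > e_w) 0 else 1
    } else {
      p <- pnorm((w - e_w - 0.5) / sqrt(v_w), lower.tail = FALSE)
    }
  }
  list(statistic = w, p_value = min(max(p, 0), 1), n = n)
}

#' Test the structural significance of every community
#'
#' Runs [community_significance()] on each community of a partition
#' (communities of more than four nodes; smaller ones are marked untested).
#'
#' @param net The `trait_network` the partition lives on.
#' @param partition A `community_partition`.
#'
#' @return The partition with its `significance` slot filled: a tibble with
#'   `community_id`, `size`, `n_informative`, `statistic`, `p_value`,
#'   `tested`.
#' @export
test_communities <- function(net, partition) {
  sig <- partition_significance(net, partition$membership)
  partition$significance <- sig
  partition
}

partition_significance <- function(net, membership) {
  split(membership$feature_id, membership$community_id) |>
    imap(function(members, cid) {
      community_significance(degree_pairs(net, members)) |>
        mutate(community_id = as.integer(cid), .before = 1L)
    }) |>
    list_rbind() |>
    arrange(.data$community_id)
}

#' Merge non-significant communities into adjacent significant ones
#'
#' Iteratively merges every community that is either untestable (size <= 4)
#' or non-significant (`p > alpha`) into the *significant* community to which
#' it has the largest number of inter-community edges (ties broken toward the
#' larger community, then the lowest community id). After each single merge,
#' significance is re-tested on the merged partition and the procedure
#' repeats until all remaining communities are significant or unmergeable. A
#' non-significant community with no edge to any significant community is
#' left standalone and flagged; a partition with no significant community at
#' all is returned unchanged with a warning.
#'
#' @param net The `trait_network` the partition lives on.
#' @param partition A `community_partition` (significance is computed if
#'   absent).
#' @param alpha Significance level for the community test (default 0.05).
#'
#' @return The merged `community_partition`; `merges` maps every original
#'   community id to its final (merged) id, and `standalone` lists flagged
#'   unmergeable communities.
#' @export
merge_communities <- function(net, partition, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  membership <- partition$membership
  provenance <- setNames(unique(membership$community_id),
                         unique(membership$community_id))
  el <- igraph::as_edgelist(net)
  standalone <- integer()

  repeat {
    sig <- partition_significance(net, membership)
    significant <- sig$community_id[sig$tested & sig$p_value <= alpha]
    pending <- setdiff(sig$community_id, c(significant, standalone))
    if (length(pending) == 0L) break
    if (length(significant) == 0L) {
      warn("No significant community to merge into; partition left unchanged.")
      break
    }

    merged_one <- FALSE
    for (cid in sort(pending)) {
      members <- membership$feature_id[membership$community_id == cid]
      comm_of <- setNames(membership$community_id, membership$feature_id)
      a <- comm_of[el[, 1]]
      b <- comm_of[el[, 2]]
      cross <- (a == cid & b %in% significant) | (b == cid & a %in% significant)
      if (!any(cross)) next
      other <- ifelse(a[cross] == cid, b[cross], a[cross])
      counts <- table(other)
      best <- as.integer(names(counts)[counts == max(counts)])
      if (length(best) > 1L) {
        sizes <- sig$size[match(best, sig$community_id)]
        best <- best[sizes == max(sizes)]
        best <- min(best)
      }
      membership$community_id[membership$community_id == cid] <- best
      provenance[provenance == cid] <- best
      merged_one <- TRUE
      break
    }
    if (!merged_one) {
      # every pending community lacks edges to a significant one
      standalone <- sort(unique(c(standalone, pending)))
      if (length(standalone)) {
        warn(paste0(
          "Community(ies) without edges to any significant community left standalone: ",
          paste(standalone, collapse = ", ")
        ))
      }
      break
    }
  }

  out <- new_partition(
    membership,
    significance = partition_significance(net, membership),
    merges = tibble(
      original_community = as.integer(names(provenance)),
      merged_community = as.integer(unname(provenance))
    ),
    standalone = as.character(standalone)
  )
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes\n",
              nrow(x$sizes), nrow(x$membership)))
  if (!is.null(x$significance)) {
    tested <- x$significance[x$significance$tested, ]
    if (nrow(tested)) {
      cat(sprintf("  tested (size > 4): %s\n",
                  paste(sprintf("#%d p=%.3g", tested$community_id,
                                tested$p_value), collapse = ", ")))
    }
  }
  invisible(x)
}
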