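# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths (and igraph's
# algorithms beyond graph storage), so they can certify them.

bfs_dist <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

adjacency_list <- function(g) {
  lapply(seq_len(igraph::vcount(g)),
         function(v) as.integer(igraph::neighbors(g, v)))
}

# Explicit enumeration of every shortest path between every node pair.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- adjacency_list(g)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    if (s == n) next
    dist_s <- bfs_dist(adj, s)
    for (t in seq((s + 1), n)) {
      if (is.infinite(dist_s[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1L]] <<- c(s, acc)
          return(invisible())
        }
        for (w in adj[[v]]) {
          if (dist_s[w] == dist_s[v] - 1) walk(w, c(v, acc))
        }
      }
      walk(t, integer())
      sigma <- length(paths)
      for (p in paths) {
        inner <- p[-c(1L, length(p))]
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  stats::setNames(btw, nm)
}

# Triangle-count clustering, all-pairs-BFS diameter, component count.
brute_properties <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  e <- sum(A) / 2
  local <- vapply(seq_len(n), function(v) {
    k <- deg[v]
    if (k < 2) return(0)
    nb <- which(A[v, ] == 1)
    (sum(A[nb, nb]) / 2) / (k * (k - 1) / 2)
  }, numeric(1))
  adj <- lapply(seq_len(n), function(v) which(A[v, ] == 1))
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  giant <- which(comp == which.max(tabulate(comp)))
  diam <- 0
  if (length(giant) >= 2) {
    for (s in giant) diam <- max(diam, max(bfs_dist(adj, s)[giant]))
  }
  list(avg_degree = mean(deg), density = if (n > 1) 2 * e / (n * (n - 1)) else NA,
       clustering = mean(local), diameter = diam, n_components = cid)
}

# Graph from the bits of an upper-triangle index (exhaustive enumeration).
graph_from_bits <- function(n, code) {
  A <- matrix(0L, n, n)
  idx <- which(upper.tri(A))
  bits <- as.integer(intToBits(code))[seq_along(idx)]
  A[idx[bits == 1L]] <- 1L
  A <- A + t(A)
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Long BLUP tibble from a lines x features matrix.
blups_from_matrix <- function(m, grand_mean = 0) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%03d", seq_len(nrow(m)))
  tibble::as_tibble(m, rownames = "line_id") |>
    tidyr::pivot_longer(-"line_id", names_to = "feature_id",
                        values_to = "blup") |>
    dplyr::mutate(grand_mean = grand_mean)
}

# Long profile tibble from per-feature (line x replicate) value matrices.
profiles_from_values <- function(..., plate_id = NA_character_,
                                 control_value = NA_real_) {
  feats <- list(...)
  purrr::imap(feats, function(m, fid) {
    tibble::tibble(
      line_id = rep(sprintf("L%03d", seq_len(nrow(m))), times = ncol(m)),
      replicate_id = rep(sprintf("r%d", seq_len(ncol(m))), each = nrow(m)),
      plate_id = plate_id,
      feature_id = fid,
      value = as.vector(m),
      control_value = control_value
    )
  }) |> purrr::list_rbind()
}

feature_annotation <- function(profiles,
                               molecular_class = "metabolite") {
  ids <- unique(profiles$feature_id)
  tibble::tibble(
    feature_id = ids,
    molecular_class = rep_len(molecular_class, length(ids)),
    compound_class = "unspecified"
  )
}

# Minimal correlation table accepted by build_network()/select_r_cutoff().
corr_table <- function(feature_a, feature_b, rho, p, n = 101) {
  tibble::tibble(
    feature_a = feature_a, feature_b = feature_b, rho = rho, p = p,
    q = stats::p.adjust(p, "BH"), n = n
  )
}

# Adjusted Rand index between two labelled partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
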