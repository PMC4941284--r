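# Independent brute-force oracles used to validate the implementation.
# Everything here is written from first principles (plain R, no igraph),
# so that agreement with the package is a genuine cross-check.

# adjacency list from a 2-column edge matrix over `nodes`
oracle_adjacency <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(x) character(0)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, unique)
}

# single-source BFS: distances and shortest-path counts
oracle_bfs <- function(adj, source) {
  nodes <- names(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  sigma <- setNames(rep(0, length(nodes)), nodes)
  dist[source] <- 0
  sigma[source] <- 1
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# all four centralities by exhaustive all-pairs BFS and direct definitions
oracle_centralities <- function(edges, nodes) {
  adj <- oracle_adjacency(edges, nodes)
  n <- length(nodes)
  bfs <- lapply(nodes, function(s) oracle_bfs(adj, s))
  names(bfs) <- nodes

  degree <- vapply(adj, length, 1L)

  harmonic <- vapply(nodes, function(v) {
    d <- bfs[[v]]$dist
    sum(1 / d[names(d) != v & is.finite(d)])
  }, 1.0)

  betweenness <- setNames(rep(0, n), nodes)
  if (n >= 3) {
    pairs <- utils::combn(nodes, 2)
    for (j in seq_len(ncol(pairs))) {
      s <- pairs[1, j]; t <- pairs[2, j]
      dst <- bfs[[s]]$dist[t]
      if (!is.finite(dst)) next
      sig_st <- bfs[[s]]$sigma[t]
      # v lies on a shortest s-t path iff d(s,v) + d(v,t) = d(s,t)
      on_path <- bfs[[s]]$dist + bfs[[t]]$dist == dst
      on_path[c(s, t)] <- FALSE
      on_path[!is.finite(bfs[[s]]$dist) | !is.finite(bfs[[t]]$dist)] <- FALSE
      betweenness[on_path] <- betweenness[on_path] +
        bfs[[s]]$sigma[on_path] * bfs[[t]]$sigma[on_path] / sig_st
    }
  }

  # k-core by literal peeling at each k
  kcore <- setNames(rep(0L, n), nodes)
  for (k in seq_len(max(degree) + 1L)) {
    alive <- nodes
    repeat {
      deg_alive <- vapply(alive, function(v) {
        length(intersect(adj[[v]], alive))
      }, 1L)
      drop <- alive[deg_alive < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
    }
    kcore[alive] <- k
  }

  data.frame(node = nodes, degree = as.numeric(degree),
             betweenness = as.numeric(betweenness),
             closeness = as.numeric(harmonic), k_core = as.integer(kcore),
             stringsAsFactors = FALSE)
}

# textbook Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# hypergeometric upper tail by direct factorial summation
oracle_hyper_tail <- function(k, K, n, N) {
  lf <- lgamma(seq(0, N) + 1)
  lch <- function(a, b) lf[a + 1] - lf[b + 1] - lf[a - b + 1]
  js <- seq(max(k, 0, K + n - N), min(K, n))
  if (!length(js) || k > min(K, n)) return(0)
  sum(exp(lch(K, js) + lch(N - K, n - js) - lch(N, n)))
}

# random simple undirected graph as an edge matrix (plus node names)
random_edge_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  list(nodes = nodes,
       edges = t(pairs[, keep, drop = FALSE]))
}

as_test_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = g$nodes)
  )
}
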