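# Independent brute-force oracles used to pin down expected values.
# Everything here is deliberately naive (enumeration, grid search) and
# shares no code path with the package implementation.

# upper-tail hypergeometric by exhaustive enumeration of all C(N, M) draws
bf_hyper_upper <- function(x, N, K, M) {
  if (M == 0 || N == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, M)
  k_set <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% k_set))
  mean(overlaps >= x)
}

# Benjamini-Hochberg step-up by hand: min over j >= i of p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# undirected graph as a 0/1 adjacency matrix from an edge list
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(unlist(edges), ncol = 2, byrow = TRUE)
    a[cbind(e[, 1], e[, 2])] <- 1L
    a[cbind(e[, 2], e[, 1])] <- 1L
  }
  a
}

# all-pairs geodesic distances by naive BFS on the adjacency matrix
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- integer()
      for (u in frontier) nxt <- c(nxt, which(a[u, ] == 1 & !is.finite(d[s, ])))
      nxt <- setdiff(unique(nxt), which(is.finite(d[s, ])))
      d[s, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

# explicit enumeration of every shortest path between two nodes
bf_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (u in which(a[, t] == 1)) {
    if (d[s, u] == d[s, t] - 1) {
      for (p in bf_paths(a, d, s, u)) out[[length(out) + 1]] <- c(p, t)
    }
  }
  out
}

# degree, closeness and both betweenness variants from enumerated paths
bf_centralities <- function(a) {
  n <- nrow(a)
  d <- bf_distances(a)
  deg <- rowSums(a)
  cc <- vapply(seq_len(n), function(v) {
    ds <- d[v, -v]
    ds <- ds[is.finite(ds)]
    if (!length(ds) || sum(ds) == 0) 0 else 1 / sum(ds)
  }, 0)
  bc_frac <- numeric(n)
  bc_raw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- bf_paths(a, d, s, t)
      sigma <- length(paths)
      if (sigma == 0) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (!length(interior)) next
      cnt <- table(interior)
      idx <- as.integer(names(cnt))
      bc_raw[idx] <- bc_raw[idx] + as.numeric(cnt)
      bc_frac[idx] <- bc_frac[idx] + as.numeric(cnt) / sigma
    }
  }
  list(degree = deg, closeness = cc, bc_frac = bc_frac, bc_raw = bc_raw)
}

# brute-force clique percolation: enumerate every k-clique, build the
# explicit overlap graph, take its components by DFS
bf_cpm <- function(a, k) {
  n <- nrow(a)
  if (n < k) return(list())
  cliques <- list()
  for (cand in utils::combn(n, k, simplify = FALSE)) {
    sub <- a[cand, cand]
    if (all(sub[upper.tri(sub)] == 1)) cliques[[length(cliques) + 1]] <- cand
  }
  if (!length(cliques)) return(list())
  nc <- length(cliques)
  overlap <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i != j) overlap[i, j] <- length(intersect(cliques[[i]], cliques[[j]])) >= k - 1
    }
  }
  seen <- rep(FALSE, nc)
  comms <- list()
  for (i in seq_len(nc)) {
    if (seen[i]) next
    stack <- i
    grp <- integer()
    while (length(stack)) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      grp <- c(grp, cur)
      stack <- c(stack, which(overlap[cur, ] & !seen))
    }
    comms[[length(comms) + 1]] <- sort(unique(unlist(cliques[grp])))
  }
  comms
}

# all maximal cliques by subset enumeration (tiny graphs only)
bf_maximal_cliques <- function(a) {
  n <- nrow(a)
  all_cl <- list()
  for (size in seq_len(n)) {
    for (cand in utils::combn(n, size, simplify = FALSE)) {
      sub <- a[cand, cand, drop = FALSE]
      if (size == 1 || all(sub[upper.tri(sub)] == 1)) {
        all_cl[[length(all_cl) + 1]] <- cand
      }
    }
  }
  keep <- vapply(all_cl, function(cl) {
    !any(vapply(all_cl, function(other) {
      length(other) > length(cl) && all(cl %in% other)
    }, TRUE))
  }, TRUE)
  all_cl[keep]
}

# igraph object with letter names from an integer edge list
toy_graph <- function(n, edges) {
  a <- adj_from_edges(n, edges)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Cox partial likelihood for one covariate, maximised by grid search
bf_cox_grid <- function(time, event, x, grid = seq(-4, 4, by = 1e-4)) {
  loglik <- vapply(grid, function(b) {
    lp <- b * x
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + lp[i] - log(sum(exp(lp[risk])))
    }
    ll
  }, 0)
  grid[which.max(loglik)]
}

# small fast study configuration for unit tests; dots override defaults
small_cfg <- function(seed = 11, ...) {
  args <- list(
    n_samples = 80, n_mrna = 150, n_lncrna = 20, n_mirna = 40,
    n_seed_genes = 8, n_planted_modules = 2, module_size = 6,
    mirnas_per_module = 4, background_targets_per_rna = 2,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
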