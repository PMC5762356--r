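#' Node centralities of a ceRNA network
#'
#' Degree, closeness and betweenness for every node of an unweighted,
#' undirected network, computed per connected component:
#'
#' * closeness `CC(v) = 1 / sum_j d(v, j)` over the nodes `j` reachable from
#'   `v`; isolated nodes get `CC = 0` by convention;
#' * betweenness in the standard fraction form
#'   `BC(v) = sum_{s != t != v} sigma_st(v) / sigma_st` over unordered
#'   reachable pairs (`bc = "fraction"`, what igraph and Cytoscape report),
#'   or as raw shortest-path counts `sum sigma_st(v)` (`bc = "raw"`).
#'
#' The raw variant is computed from explicit all-pairs shortest-path counts
#' and is intended for small to moderate graphs.
#'
#' @param net an igraph network.
#' @param bc betweenness variant.
#' @return A tibble with `node`, `group` (the vertex `group` attribute, if
#'   any), `degree`, `closeness`, `betweenness`.
#' @export
network_centralities <- function(net, bc = c("fraction", "raw")) {
  bc <- match.arg(bc)
  if (igraph::vcount(net) == 0) stop("empty network")
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  d <- igraph::distances(net)
  diag(d) <- Inf
  dsum <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  cc <- ifelse(dsum > 0, 1 / dsum, 0)
  btw <- if (bc == "fraction") {
    igraph::betweenness(net, directed = FALSE)
  } else {
    betweenness_raw(net)
  }
  grp <- igraph::V(net)$group
  tibble::tibble(
    node = nodes,
    group = if (is.null(grp)) NA_character_ else grp,
    degree = as.integer(unname(deg)),
    closeness = unname(cc),
    betweenness = unname(btw)
  )
}

# all-pairs geodesic distances and shortest-path counts by level-wise BFS
all_pairs_shortest_counts <- function(net) {
  n <- igraph::vcount(net)
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  d <- igraph::distances(net)
  s <- matrix(0, n, n)
  for (src in seq_len(n)) {
    dv <- d[src, ]
    sig <- numeric(n)
    sig[src] <- 1
    lmax <- suppressWarnings(max(dv[is.finite(dv)]))
    l <- 1
    while (l <= lmax) {
      prev <- which(dv == l - 1)
      cur <- which(dv == l)
      if (!length(cur)) break
      sig[cur] <- as.numeric(a[cur, prev, drop = FALSE] %*% sig[prev])
      l <- l + 1
    }
    s[src, ] <- sig
  }
  list(d = d, sigma = s)
}

# betweenness as raw counts of shortest paths through v (no sigma_st
# denominator), unordered pairs, endpoints excluded
betweenness_raw <- function(net) {
  ap <- all_pairs_shortest_counts(net)
  d <- ap$d
  s <- ap$sigma
  n <- nrow(d)
  finite <- is.finite(d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- (outer(d[, v], d[v, ], "+") == d) & finite
    contrib <- (s[, v] %o% s[v, ]) * on_path
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    out[v] <- sum(contrib) / 2
  }
  out
}

#' Compare a centrality metric between node groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a centrality metric
#' between the two node groups (typically seed genes vs their ceRNAs);
#' centrality distributions are heavily skewed, so a rank test is used.
#'
#' @param profiles centrality tibble from [network_centralities()]; `group`
#'   must contain exactly two levels.
#' @param metric which column to compare.
#' @return A one-row tibble: `metric`, `p_value`, `direction` (the group
#'   with the larger median), group sizes.
#' @export
compare_centrality <- function(profiles, metric = c("degree", "closeness", "betweenness")) {
  metric <- match.arg(metric)
  groups <- unique(profiles$group)
  if (length(groups) != 2) stop("`profiles` must contain exactly two groups")
  x <- profiles[[metric]][profiles$group == groups[1]]
  y <- profiles[[metric]][profiles$group == groups[2]]
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 nodes")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  med <- c(stats::median(x), stats::median(y))
  direction <- if (med[1] == med[2]) "tied" else groups[which.max(med)]
  tibble::tibble(
    metric = metric,
    p_value = wt$p.value,
    direction = direction,
    n_group1 = length(x), n_group2 = length(y),
    group1 = groups[1], group2 = groups[2]
  )
}

#' Degree distribution with a log-log power-law fit
#'
#' Tabulates node degrees and fits a least-squares line to
#' `log10(frequency)` vs `log10(degree)` over the nonzero-degree bins — the
#' usual visual check that a network's degree distribution follows a power
#' law. The fit needs at least 5 distinct positive degree values; otherwise
#' only the histogram is returned and the fit is flagged unavailable.
#'
#' @param net an igraph network.
#' @param nodes optional subset of node names to tabulate.
#' @return A `cerna_degree_dist` list: `histogram` (tibble `degree`, `n`),
#'   `exponent` (slope), `r_squared`, `fit_available`.
#' @export
degree_distribution_fit <- function(net, nodes = NULL) {
  deg <- igraph::degree(net)
  if (!is.null(nodes)) deg <- deg[intersect(nodes, names(deg))]
  if (!length(deg)) stop("no nodes to tabulate")
  hist <- dplyr::count(tibble::tibble(degree = as.integer(unname(deg))),
                       .data$degree, name = "n")
  fit <- fit_power_law_loglog(hist)
  structure(list(histogram = hist, exponent = fit$exponent,
                 r_squared = fit$r_squared, fit_available = fit$available),
            class = "cerna_degree_dist")
}

#' @rdname degree_distribution_fit
#' @param histogram a tibble with `degree` and `n` (frequency) columns.
#' @export
fit_power_law_loglog <- function(histogram) {
  h <- histogram[histogram$degree > 0 & histogram$n > 0, , drop = FALSE]
  if (length(unique(h$degree)) < 5) {
    return(list(exponent = NA_real_, r_squared = NA_real_, available = FALSE))
  }
  fit <- stats::lm(log10(n) ~ log10(degree), data = h)
  # exact power-law histograms fit perfectly; the lm summary warning about
  # that is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(
    exponent = unname(stats::coef(fit)[2]),
    r_squared = r2,
    available = TRUE
  )
}

#' Extract the hub subnetwork
#'
#' The hub set is the `floor(top_frac * |V|)` highest-degree nodes (so a
#' 1322-node network at the default decile yields 132 hubs); ties at the
#' boundary are broken by lexicographic node id, which makes the selection
#' deterministic. The result is the induced subgraph on the hub set;
#' isolated hubs are retained as nodes.
#'
#' @param net an igraph network with at least 10 nodes.
#' @param top_frac fraction of nodes to keep.
#' @return An igraph object (the hub network).
#' @export
extract_hub_network <- function(net, top_frac = 0.10) {
  n <- igraph::vcount(net)
  if (n < 10) stop("hub extraction needs a network with at least 10 nodes")
  stopifnot(top_frac > 0, top_frac <= 1)
  n_hub <- max(1L, as.integer(floor(top_frac * n)))
  deg <- igraph::degree(net)
  nm <- igraph::V(net)$name
  hubs <- nm[lex_order(-deg, nm)][seq_len(n_hub)]
  igraph::induced_subgraph(net, hubs)
}
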