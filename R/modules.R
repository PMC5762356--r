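#' Maximal cliques of a network
#'
#' Enumerates all maximal cliques (via Bron-Kerbosch with pivoting, as
#' implemented in igraph) and returns them in a deterministic order: size
#' descending, ties by lexicographic member order. A clique-count budget
#' guards against pathologically dense graphs.
#'
#' @param net a simple undirected igraph network.
#' @param min_size smallest clique size to report.
#' @param budget maximum number of maximal cliques tolerated.
#' @return A list of character vectors (each a sorted clique).
#' @export
find_maximal_cliques <- function(net, min_size = 1, budget = 5e6) {
  n_cl <- igraph::count_max_cliques(net, min = min_size)
  if (n_cl > budget) {
    stop("more than ", format(budget, scientific = FALSE),
         " maximal cliques; use a sparser graph or raise `budget`")
  }
  cl <- igraph::max_cliques(net, min = min_size)
  nm <- igraph::V(net)$name
  cl <- lapply(cl, function(v) lex_sort(nm[v]))
  keys <- vapply(cl, paste, "", collapse = "\r")
  cl[lex_order(-lengths(cl), keys)]
}

#' k-clique percolation communities
#'
#' Classic clique-percolation (CFinder-style) community detection: maximal
#' cliques of size >= k are adjacent when they share at least k - 1 nodes,
#' and each community is the node union over a connected component of that
#' clique-adjacency structure. Working on maximal cliques rather than all
#' k-cliques is the standard optimisation and yields identical communities.
#'
#' Modules are indexed per k by size descending (ties by lexicographically
#' smallest member set) and named `K{k}M{index}`.
#'
#' @param net a simple undirected igraph network.
#' @param k clique size parameter, at least 3.
#' @param budget passed to [find_maximal_cliques()].
#' @return A tibble with `name`, `k`, `index`, `size` and a `members` list
#'   column; zero rows when the graph has no clique of size k.
#' @export
k_clique_communities <- function(net, k, budget = 5e6) {
  stopifnot(k >= 3)
  cl <- find_maximal_cliques(net, min_size = k, budget = budget)
  if (!length(cl)) return(empty_modules())
  nodes <- lex_sort(unique(unlist(cl)))
  memb <- Matrix::sparseMatrix(
    i = rep(seq_along(cl), lengths(cl)),
    j = match(unlist(cl), nodes),
    x = 1, dims = c(length(cl), length(nodes))
  )
  overlap <- Matrix::tcrossprod(memb)
  adj <- overlap >= (k - 1)
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  cmp <- igraph::components(cg)$membership
  communities <- unname(lapply(split(seq_along(cl), cmp), function(ix) {
    lex_sort(unique(unlist(cl[ix])))
  }))
  keys <- vapply(communities, paste, "", collapse = "\r")
  communities <- communities[lex_order(-lengths(communities), keys)]
  tibble::tibble(
    name = sprintf("K%dM%d", k, seq_along(communities)),
    k = as.integer(k),
    index = seq_along(communities),
    size = lengths(communities),
    members = communities
  )
}

empty_modules <- function() {
  tibble::tibble(name = character(), k = integer(), index = integer(),
                 size = integer(), members = list())
}

#' Discover k-clique modules across a range of k
#'
#' Runs [k_clique_communities()] for every k from `k_min` up to the largest
#' maximal-clique size of the network and concatenates the results. The same
#' nodes typically re-appear at several k (communities nest as k grows);
#' this is expected and preserved.
#'
#' @param net a simple undirected igraph network.
#' @param k_min smallest clique parameter (default 11, i.e. "k > 10").
#' @param budget passed to [find_maximal_cliques()].
#' @return Module tibble as in [k_clique_communities()], all k values
#'   stacked.
#' @export
discover_modules <- function(net, k_min = 11, budget = 5e6) {
  stopifnot(k_min >= 3)
  if (igraph::vcount(net) == 0) return(empty_modules())
  k_max <- igraph::clique_num(net)
  if (k_max < k_min) return(empty_modules())
  purrr::map_dfr(seq(k_min, k_max), ~ k_clique_communities(net, .x, budget = budget))
}

#' Internal ceRNA edges of a module
#'
#' @param members character vector of module member ids.
#' @param pairs a `cerna_pairs` tibble.
#' @return The rows of `pairs` with both endpoints in the module.
#' @export
module_internal_edges <- function(members, pairs) {
  pairs[pairs$rna_a %in% members & pairs$rna_b %in% members, , drop = FALSE]
}
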