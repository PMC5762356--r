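#' Build a ceRNA network from scored pairs
#'
#' Turns retained ceRNA pairs into a simple undirected igraph graph. Edges
#' carry the pair statistics (`x`, `q_hyper`, `rho`, `q_corr`); vertices
#' carry the RNA class and a seed-gene flag. Duplicate pair records (after
#' canonical ordering) are collapsed with a warning; self-pairs are dropped.
#'
#' @param pairs a `cerna_pairs` tibble from [score_candidate_pairs()], or any
#'   data frame with `rna_a`/`rna_b` columns.
#' @param classes optional RNA class labels: a named character vector or a
#'   data frame with `rna_id`/`rna_class`. Unknown RNAs get class `"mRNA"`.
#' @param seeds optional character vector of seed ("ageing") gene ids.
#' @return An igraph object with a `provenance` graph attribute recording the
#'   filter thresholds used.
#' @export
build_cerna_network <- function(pairs, classes = NULL, seeds = character()) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("rna_a", "rna_b") %in% names(pairs))) {
    stop("`pairs` needs rna_a/rna_b columns")
  }
  self <- pairs$rna_a == pairs$rna_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    pairs <- pairs[!self, , drop = FALSE]
  }
  a <- pmin(pairs$rna_a, pairs$rna_b)
  b <- pmax(pairs$rna_a, pairs$rna_b)
  pairs$rna_a <- a
  pairs$rna_b <- b
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate pair record(s) collapsed")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  nodes <- lex_sort(unique(c(pairs$rna_a, pairs$rna_b)))
  cls <- normalise_classes(classes, nodes)
  vertices <- data.frame(
    name = nodes,
    class = unname(cls[nodes]),
    is_seed = nodes %in% seeds,
    stringsAsFactors = FALSE
  )
  edge_df <- as.data.frame(pairs[, intersect(
    c("rna_a", "rna_b", "x", "K", "M", "p_hyper", "q_hyper", "rho", "p_corr", "q_corr"),
    names(pairs)
  )])
  if (!is.null(pairs[["shared_mirnas"]])) {
    edge_df$shared_mirnas <- vapply(pairs$shared_mirnas, paste, "", collapse = ",")
  }
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = vertices)
  thr <- attr(pairs, "thresholds")
  igraph::graph_attr(g, "provenance") <- if (is.null(thr)) list() else thr
  g
}

normalise_classes <- function(classes, nodes) {
  if (is.null(classes)) {
    cls <- stats::setNames(rep("mRNA", length(nodes)), nodes)
  } else if (is.data.frame(classes)) {
    cls <- stats::setNames(classes$rna_class, classes$rna_id)
  } else {
    cls <- classes
  }
  missing <- setdiff(nodes, names(cls))
  if (length(missing)) cls[missing] <- "mRNA"
  cls
}

#' Count edges per RNA-class category
#'
#' @param net a ceRNA network from [build_cerna_network()].
#' @return A tibble with `category` (e.g. `"lncRNA-mRNA"`) and `n`.
#' @export
edge_category_counts <- function(net) {
  if (igraph::ecount(net) == 0) return(tibble::tibble(category = character(), n = integer()))
  el <- igraph::as_edgelist(net)
  cls <- stats::setNames(igraph::V(net)$class, igraph::V(net)$name)
  c1 <- cls[el[, 1]]
  c2 <- cls[el[, 2]]
  cat <- paste(pmin(c1, c2), pmax(c1, c2), sep = "-")
  dplyr::count(tibble::tibble(category = cat), .data$category, name = "n")
}

#' Extract the seed-gene subnetwork (maximal connected component)
#'
#' Induces the subgraph on the seed genes plus their direct network
#' neighbours ("ceRNAs of seeds"), then returns its largest connected
#' component. Ties on component size are broken by the lexicographically
#' smallest member set. Vertices are labelled `group = "seed"` or `"ceRNA"`.
#'
#' @param net a ceRNA network.
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   network are ignored with a warning.
#' @return An igraph object (the seed-anchored component).
#' @export
extract_seed_subnetwork <- function(net, seeds) {
  if (!length(seeds)) stop("`seeds` must be non-empty")
  present <- intersect(seeds, igraph::V(net)$name)
  if (!length(present)) stop("no seed gene is present in the network")
  n_missing <- length(setdiff(seeds, present))
  if (n_missing) message(n_missing, " seed(s) absent from the network were ignored")
  nb <- unique(c(present, unlist(lapply(
    igraph::adjacent_vertices(net, present),
    function(v) igraph::V(net)$name[v]
  ))))
  sub <- igraph::induced_subgraph(net, nb)
  comp <- igraph::components(sub)
  best <- largest_component_id(comp, igraph::V(sub)$name)
  keep <- igraph::V(sub)$name[comp$membership == best]
  out <- igraph::induced_subgraph(sub, keep)
  igraph::V(out)$is_seed <- igraph::V(out)$name %in% seeds
  igraph::V(out)$group <- ifelse(igraph::V(out)$is_seed, "seed", "ceRNA")
  out
}

# component id of the largest component; size ties broken by the
# lexicographically smallest sorted member vector
largest_component_id <- function(comp, names) {
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) == 1) return(cand)
  keys <- vapply(cand, function(id) {
    paste(lex_sort(names[comp$membership == id]), collapse = "\r")
  }, "")
  cand[lex_order(keys)[1]]
}

#' Validate seed-ceRNA correlations in an independent dataset
#'
#' Recomputes the Pearson correlation of every seed-to-ceRNA edge whose two
#' endpoints are measured in an independent expression dataset, and reports
#' the fraction that replicate: same correlation sign as at discovery and
#' p-value below `alpha`.
#'
#' @param net a seed subnetwork (vertices must carry `group` or `is_seed`,
#'   edges must carry the discovery `rho`).
#' @param indep_expr an independent log2-transformed [expr_table()].
#' @param alpha replication significance level.
#' @return A one-row tibble: `fraction`, `n_verified`, `n_evaluated`.
#' @export
validate_correlations <- function(net, indep_expr, alpha = 0.05) {
  stopifnot(inherits(indep_expr, "cerna_expr"))
  if (expr_transform(indep_expr) != "log2") {
    stop("independent expression must be log2-transformed")
  }
  is_seed <- igraph::V(net)$is_seed
  if (is.null(is_seed)) stop("network vertices lack a seed flag")
  seed_names <- igraph::V(net)$name[is_seed]
  el <- igraph::as_edgelist(net)
  rho0 <- igraph::E(net)$rho
  if (is.null(rho0)) stop("network edges lack discovery correlations")
  seed_edge <- el[, 1] %in% seed_names | el[, 2] %in% seed_names
  m <- expr_matrix(indep_expr)
  have <- el[, 1] %in% rownames(m) & el[, 2] %in% rownames(m)
  use <- which(seed_edge & have)
  if (!length(use)) stop("no seed-ceRNA edge has both endpoints in the independent dataset")
  pp <- pair_pearson(m, match(el[use, 1], rownames(m)), match(el[use, 2], rownames(m)))
  ok <- !pp$undefined & sign(pp$rho) == sign(rho0[use]) & pp$p < alpha
  tibble::tibble(
    fraction = mean(ok),
    n_verified = sum(ok),
    n_evaluated = length(use)
  )
}
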