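#' Rank the miRNAs shared by a module's ceRNA pairs
#'
#' For every internal ceRNA edge of the module, collects the miRNAs shared
#' by the pair, counts per miRNA over how many pairs it is shared, and
#' ranks by count (descending, ties alphabetical). miRNAs tied with the
#' k-th ranked count are all included in the top list, so the returned top
#' list can overflow `top_k`. When a target map is supplied, the bipartite
#' miRNA-RNA regulation network restricted to (top miRNAs) x (module
#' members) is returned as well.
#'
#' @param members character vector of module member ids (or a one-row slice
#'   of a module tibble).
#' @param pairs a `cerna_pairs` tibble carrying `shared_mirnas`.
#' @param tmap optional target map (`mirna`, `rna`) for the bipartite
#'   network.
#' @param top_k size of the top list before tie expansion.
#' @return A `cerna_mirna_report` list: `counts` (all miRNAs), `top`
#'   (tie-expanded top list), `n_overflow`, `bipartite_edges` (tibble
#'   `mirna`, `rna`, `rna_class` when `tmap` carries classes, else `NA`).
#' @export
module_mirna_regulators <- function(members, pairs, tmap = NULL, top_k = 10) {
  if (is.data.frame(members)) members <- unlist(members$members)
  internal <- module_internal_edges(members, pairs)
  if (nrow(internal) == 0) stop("module has no internal ceRNA pair")
  if (is.null(internal[["shared_mirnas"]])) stop("`pairs` lacks the shared_mirnas column")
  counts <- tibble::tibble(mirna = unlist(internal$shared_mirnas))
  counts <- dplyr::count(counts, .data$mirna, name = "pair_count")
  counts <- counts[lex_order(-counts$pair_count, counts$mirna), , drop = FALSE]
  k_eff <- min(top_k, nrow(counts))
  cutoff <- counts$pair_count[k_eff]
  top <- counts[counts$pair_count >= cutoff, , drop = FALSE]
  bipartite <- NULL
  if (!is.null(tmap)) {
    tm <- tibble::as_tibble(tmap)
    bipartite <- tm[tm$mirna %in% top$mirna & tm$rna %in% members,
                    c("mirna", "rna"), drop = FALSE]
    bipartite <- bipartite[lex_order(bipartite$mirna, bipartite$rna), , drop = FALSE]
  }
  structure(
    list(counts = counts, top = top, n_overflow = nrow(top) - k_eff,
         bipartite_edges = bipartite, n_internal_edges = nrow(internal)),
    class = "cerna_mirna_report"
  )
}

#' @export
print.cerna_mirna_report <- function(x, ...) {
  cat("miRNA regulators over", x$n_internal_edges, "module ceRNA pairs\n")
  print(x$top)
  invisible(x)
}
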