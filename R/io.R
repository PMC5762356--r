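#' Read and write the study file formats
#'
#' The pipeline exchanges plain text files: an expression TSV (first column
#' `rna_id`, second `rna_class`, remaining columns one per sample), target
#' TSVs (`mirna<TAB>rna`, one interaction per line, duplicates dropped on
#' read), a seed-gene list (one id per line, `#` comments and blank lines
#' ignored) and a clinical TSV (`sample`, `os_time`, `os_event`, `age`,
#' `gender`).
#'
#' @param path file path.
#' @param transform preprocessing state of the stored expression values.
#' @return `read_expression()` returns a [expr_table()]; the other readers
#'   return tibbles / character vectors.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_expression <- function(path, transform = "raw") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("rna_id", "rna_class") %in% names(df))) {
    stop("expression TSV needs rna_id and rna_class columns")
  }
  m <- as.matrix(df[, setdiff(names(df), c("rna_id", "rna_class")), drop = FALSE])
  rownames(m) <- df$rna_id
  expr_table(m, stats::setNames(df$rna_class, df$rna_id), transform = transform)
}

#' @rdname study_io
#' @param expr a [expr_table()].
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(tibble::as_tibble(expr), path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @param paths one or more target TSV paths (merged and de-duplicated).
#' @export
read_target_map <- function(paths) {
  tm <- purrr::map_dfr(paths, function(p) {
    readr::read_tsv(p, col_names = c("mirna", "rna"), col_types = "cc",
                    comment = "#", progress = FALSE)
  })
  dplyr::distinct(tm)
}

#' @rdname study_io
#' @param tmap a target map tibble.
#' @export
write_target_map <- function(tmap, path) {
  readr::write_tsv(tibble::as_tibble(tmap)[, c("mirna", "rna")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_seed_genes <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' @rdname study_io
#' @param seeds character vector of seed ids.
#' @export
write_seed_genes <- function(seeds, path) {
  readr::write_lines(seeds, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "os_time", "os_event", "age", "gender")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical TSV lacks column(s): ", paste(miss, collapse = ", "))
  df$os_event <- as.integer(df$os_event)
  df
}

#' @rdname study_io
#' @param clin a clinical tibble.
#' @export
write_clinical <- function(clin, path) {
  readr::write_tsv(tibble::as_tibble(clin), path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Emits the exact input formats the pipeline reads (expression TSV, target
#' TSV, seed list, clinical TSV) plus a `ground_truth.json` ledger of the
#' planted structure.
#'
#' @param study a [simulate_cerna_study()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "cerna_sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_target_map(study$tmap, file.path(dir, "targets.tsv"))
  write_seed_genes(study$seed_genes, file.path(dir, "seed_genes.txt"))
  write_clinical(study$clinical, file.path(dir, "clinical.tsv"))
  gt <- study$ground_truth
  jsonlite::write_json(
    list(
      planted_pairs = gt$planted_pairs,
      planted_modules = gt$planted_modules,
      module_mirnas = gt$module_mirnas,
      prognostic_module_index = gt$prognostic_module_index,
      true_beta = gt$true_beta,
      seed_genes = gt$seed_genes
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write a network as edge list and GraphML
#'
#' @param net an igraph network.
#' @param stem output path stem; writes `<stem>.edges.tsv` and
#'   `<stem>.graphml`.
#' @return The stem, invisibly.
#' @export
write_network <- function(net, stem) {
  el <- igraph::as_data_frame(net, what = "edges")
  readr::write_tsv(tibble::as_tibble(el), paste0(stem, ".edges.tsv"), progress = FALSE)
  g <- net
  for (at in igraph::graph_attr_names(g)) {
    v <- igraph::graph_attr(g, at)
    if (!(is.character(v) || is.numeric(v) || is.logical(v)) || length(v) != 1) {
      g <- igraph::delete_graph_attr(g, at)
    }
  }
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  invisible(stem)
}
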