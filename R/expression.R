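#' Expression tables
#'
#' An expression table is a wide tibble with one row per RNA: an `rna_id`
#' column, an `rna_class` column (`"mRNA"` or `"lncRNA"`) and one numeric
#' column per sample. A `transform` attribute tracks the preprocessing state
#' (`"raw"` RPKM-like values, `"filtered"` after the zero-fraction filter,
#' `"log2"` after log transformation) so each step can only be applied once
#' and in order.
#'
#' @param values numeric matrix, RNAs in rows (rownames = RNA ids), samples
#'   in columns (colnames = sample ids).
#' @param classes character vector of `"mRNA"`/`"lncRNA"` labels, either
#'   named by RNA id or in row order of `values`.
#' @param transform preprocessing state of `values`.
#' @return A `cerna_expr` tibble.
#' @export
expr_table <- function(values, classes, transform = c("raw", "filtered", "log2")) {
  transform <- match.arg(transform)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have RNA ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate RNA ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!is.null(names(classes))) classes <- classes[rownames(values)]
  if (length(classes) != nrow(values) || anyNA(classes)) {
    stop("`classes` must provide one mRNA/lncRNA label per RNA")
  }
  out <- tibble::tibble(
    rna_id = rownames(values),
    rna_class = unname(as.character(classes))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values, .name_repair = "minimal"))
  new_cerna_expr(out, transform)
}

new_cerna_expr <- function(df, transform) {
  structure(df,
    class = unique(c("cerna_expr", class(tibble::tibble()))),
    transform = transform
  )
}

#' @rdname expr_table
#' @param expr a `cerna_expr` table.
#' @export
expr_matrix <- function(expr) {
  stopifnot(inherits(expr, "cerna_expr"))
  m <- as.matrix(expr[, expr_samples(expr), drop = FALSE])
  rownames(m) <- expr$rna_id
  m
}

#' @rdname expr_table
#' @export
expr_samples <- function(expr) {
  setdiff(names(expr), c("rna_id", "rna_class"))
}

#' @rdname expr_table
#' @export
expr_transform <- function(expr) {
  attr(expr, "transform") %||% "raw"
}

#' @rdname expr_table
#' @export
expr_classes <- function(expr) {
  stats::setNames(expr$rna_class, expr$rna_id)
}

#' Remove RNAs that are zero in most samples
#'
#' Drops every RNA whose expression is exactly zero in strictly more than
#' `max_zero_frac` of the samples (an RNA at exactly the boundary is kept).
#' This is the usual guard against genes that are not expressed across most
#' of an RPKM-like RNA-seq cohort.
#'
#' @param expr a raw `cerna_expr` table.
#' @param max_zero_frac maximum tolerated fraction of zero entries per RNA.
#' @return The filtered table, `transform` state `"filtered"`; row order is
#'   otherwise preserved.
#' @export
filter_expression <- function(expr, max_zero_frac = 0.5) {
  stopifnot(inherits(expr, "cerna_expr"))
  if (expr_transform(expr) != "raw") {
    stop("filter_expression() expects a raw expression table")
  }
  stopifnot(max_zero_frac >= 0, max_zero_frac <= 1)
  m <- expr_matrix(expr)
  zero_frac <- rowMeans(m == 0)
  keep <- zero_frac <= max_zero_frac
  if (!any(keep)) stop("no RNA passes the zero-fraction filter; input looks degenerate")
  new_cerna_expr(expr[keep, , drop = FALSE], "filtered")
}

#' Log2-transform expression values
#'
#' Applies `log2(value + pseudocount)` entry-wise. The default pseudocount of
#' 1 keeps zero entries (which survive the zero-fraction filter in up to half
#' of the samples) defined, mapping 0 to 0.
#'
#' @param expr a filtered `cerna_expr` table.
#' @param pseudocount value added before taking logs.
#' @return The transformed table, `transform` state `"log2"`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "cerna_expr"))
  if (expr_transform(expr) != "filtered") {
    stop("log2_transform() expects a filtered expression table (run filter_expression() first)")
  }
  stopifnot(pseudocount >= 0)
  m <- expr_matrix(expr)
  if (any(m < 0)) stop("raw expression values must be non-negative")
  out <- expr
  out[, colnames(m)] <- tibble::as_tibble(log2(m + pseudocount), .name_repair = "minimal")
  new_cerna_expr(out, "log2")
}
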