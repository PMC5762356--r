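#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# deterministic lexicographic ordering independent of the session locale
lex_order <- function(...) {
  args <- list(...)
  do.call(order, c(args, list(method = "radix")))
}

lex_sort <- function(x) x[lex_order(x)]
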