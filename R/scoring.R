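#' Upper-tail hypergeometric probability of sharing miRNAs
#'
#' For two RNAs regulated by `K` and `M` miRNAs out of a universe of `N`,
#' the probability of sharing at least `x` regulators by chance is the
#' upper tail of a hypergeometric distribution:
#' \deqn{P(X \ge x) = 1 - \sum_{t=0}^{x-1} \binom{K}{t}\binom{N-K}{M-t} / \binom{N}{M}.}
#' Evaluated through the survival function of [stats::phyper()], which works
#' in log space internally and is stable for large universes.
#'
#' All arguments are vectorised and recycled.
#'
#' @param x observed number of shared miRNAs (may be `min(K, M) + 1`, giving 0).
#' @param N number of distinct miRNAs in the study.
#' @param K,M number of miRNAs targeting each RNA of the pair.
#' @return `P(X >= x)`, in `[0, 1]`.
#' @export
hyper_shared_pval <- function(x, N, K, M) {
  n <- max(length(x), length(N), length(K), length(M))
  x <- rep_len(x, n); N <- rep_len(N, n); K <- rep_len(K, n); M <- rep_len(M, n)
  if (any(N < 0) || any(K < 0) || any(M < 0) || any(K > N) || any(M > N)) {
    stop("need 0 <= K, M <= N")
  }
  if (any(x < 0) || any(x > pmin(K, M) + 1)) {
    stop("need 0 <= x <= min(K, M) + 1")
  }
  stats::phyper(x - 1, K, N - K, M, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, `min` over ranks `j >= i` of `p_(j) * m / j`,
#' capped at 1 (the standard "FDR-adjusted p-value").
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with a two-sided t-test
#'
#' @param a,b numeric vectors of equal length (at least 3), neither constant.
#' @return A tibble with `rho` and `p_value` (t distribution, n - 2 df).
#' @export
pearson_test <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

# vectorised Pearson rho + two-sided t p for many row pairs of a matrix
pair_pearson <- function(m, ia, ib) {
  z <- m - rowMeans(m)
  ss <- sqrt(rowSums(z^2))
  denom <- ss[ia] * ss[ib]
  rho <- rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE]) / denom
  rho <- pmin(pmax(rho, -1), 1)
  n <- ncol(m)
  tt <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  list(rho = rho, p = p, undefined = denom == 0)
}

#' Score candidate ceRNA pairs
#'
#' Two-stage filter over all unordered RNA pairs that share at least one
#' miRNA regulator (pairs sharing none can never reach the shared-miRNA
#' threshold and are skipped via an inverted-index join):
#'
#' 1. *Shared-miRNA stage* — upper-tail hypergeometric p-value for the
#'    shared count `x` given per-RNA regulator counts `K`, `M` and universe
#'    `N`; BH-adjust across all enumerated pairs; keep pairs with
#'    `x >= min_shared` **and** adjusted p `< q_hyper_max`.
#' 2. *Co-expression stage* — Pearson correlation of the log2 expression of
#'    the surviving pairs; BH-adjust (over survivors by default, see
#'    `fdr_scope`); keep `|rho| > rho_min_abs` **and** adjusted p
#'    `< q_corr_max`. With `positive_only = TRUE` the sign constraint of the
#'    ceRNA model is enforced (`rho > rho_min_abs`).
#'
#' @param expr a log2-transformed [expr_table()].
#' @param tmap target map: a data frame with `mirna` and `rna` columns
#'   (merged miRNA-mRNA and miRNA-lncRNA interactions; duplicates dropped).
#' @param min_shared minimum shared-miRNA count `x`.
#' @param q_hyper_max FDR threshold for the hypergeometric stage.
#' @param rho_min_abs minimum absolute Pearson correlation.
#' @param q_corr_max FDR threshold for the correlation stage.
#' @param positive_only require positive correlation instead of `|rho|`.
#' @param fdr_scope `"sequential"` adjusts correlation p-values across the
#'   stage-1 survivors only; `"global"` adjusts across every enumerated pair.
#' @return A `cerna_pairs` tibble, one row per retained pair, with
#'   canonically ordered ids (`rna_a < rna_b`), `x`, `K`, `M`, `p_hyper`,
#'   `q_hyper`, `rho`, `p_corr`, `q_corr` and a `shared_mirnas` list column.
#'   The miRNA universe size and thresholds are stored as attributes.
#' @export
score_candidate_pairs <- function(expr, tmap,
                                  min_shared = 3, q_hyper_max = 0.01,
                                  rho_min_abs = 0.5, q_corr_max = 0.01,
                                  positive_only = FALSE,
                                  fdr_scope = c("sequential", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(expr, "cerna_expr"))
  if (expr_transform(expr) != "log2") {
    stop("score_candidate_pairs() expects log2-transformed expression")
  }
  tmap <- as.data.frame(tmap)
  if (!all(c("mirna", "rna") %in% names(tmap))) {
    stop("`tmap` needs `mirna` and `rna` columns")
  }
  tmap <- dplyr::distinct(tmap[, c("mirna", "rna")])
  if (nrow(tmap) == 0) stop("empty target map")
  n_universe <- dplyr::n_distinct(tmap$mirna)

  rnas <- lex_sort(intersect(expr$rna_id, unique(tmap$rna)))
  if (length(rnas) < 2) stop("fewer than two RNAs appear in both expression and target map")
  tm <- tmap[tmap$rna %in% rnas, , drop = FALSE]
  mirnas <- lex_sort(unique(tm$mirna))

  adj <- Matrix::sparseMatrix(
    i = match(tm$rna, rnas), j = match(tm$mirna, mirnas),
    x = 1, dims = c(length(rnas), length(mirnas))
  )
  shared <- Matrix::tcrossprod(adj)
  sm <- Matrix::summary(Matrix::triu(shared, 1))
  if (nrow(sm) == 0) {
    return(empty_pairs(n_universe, min_shared, q_hyper_max, rho_min_abs,
                       q_corr_max, positive_only, fdr_scope))
  }
  deg <- Matrix::rowSums(adj)

  ord <- lex_order(rnas[sm$i], rnas[sm$j])
  pairs <- tibble::tibble(
    rna_a = rnas[sm$i], rna_b = rnas[sm$j],
    x = as.integer(sm$x),
    K = as.integer(deg[sm$i]), M = as.integer(deg[sm$j])
  )[ord, ]
  pairs$p_hyper <- hyper_shared_pval(pairs$x, n_universe, pairs$K, pairs$M)
  pairs$q_hyper <- fdr_adjust(pairs$p_hyper)

  stage1 <- pairs$x >= min_shared & pairs$q_hyper < q_hyper_max
  corr_on <- if (fdr_scope == "global") rep(TRUE, nrow(pairs)) else stage1
  pairs$rho <- pairs$p_corr <- pairs$q_corr <- NA_real_
  if (any(corr_on)) {
    m <- expr_matrix(expr)
    ia <- match(pairs$rna_a[corr_on], rownames(m))
    ib <- match(pairs$rna_b[corr_on], rownames(m))
    pp <- pair_pearson(m, ia, ib)
    if (any(pp$undefined)) {
      warning(sum(pp$undefined), " pair(s) dropped: constant expression vector")
      pp$rho[pp$undefined] <- NA_real_
      pp$p[pp$undefined] <- NA_real_
    }
    pairs$rho[corr_on] <- pp$rho
    pairs$p_corr[corr_on] <- pp$p
    ok <- corr_on & !is.na(pairs$p_corr)
    pairs$q_corr[ok] <- fdr_adjust(pairs$p_corr[ok])
  }

  corr_pass <- if (positive_only) pairs$rho > rho_min_abs else abs(pairs$rho) > rho_min_abs
  keep <- stage1 & !is.na(pairs$rho) & corr_pass & pairs$q_corr < q_corr_max
  keep[is.na(keep)] <- FALSE
  out <- pairs[keep, , drop = FALSE]

  # shared miRNA sets only for the retained pairs
  tsets <- split(tm$mirna, tm$rna)
  out$shared_mirnas <- purrr::map2(out$rna_a, out$rna_b,
                                   ~ lex_sort(intersect(tsets[[.x]], tsets[[.y]])))
  structure(out,
    class = unique(c("cerna_pairs", class(out))),
    n_mirna_universe = n_universe,
    thresholds = list(min_shared = min_shared, q_hyper_max = q_hyper_max,
                      rho_min_abs = rho_min_abs, q_corr_max = q_corr_max,
                      positive_only = positive_only, fdr_scope = fdr_scope)
  )
}

empty_pairs <- function(n_universe, min_shared, q_hyper_max, rho_min_abs,
                        q_corr_max, positive_only, fdr_scope) {
  out <- tibble::tibble(
    rna_a = character(), rna_b = character(), x = integer(),
    K = integer(), M = integer(), p_hyper = double(), q_hyper = double(),
    rho = double(), p_corr = double(), q_corr = double(),
    shared_mirnas = list()
  )
  structure(out,
    class = unique(c("cerna_pairs", class(out))),
    n_mirna_universe = n_universe,
    thresholds = list(min_shared = min_shared, q_hyper_max = q_hyper_max,
                      rho_min_abs = rho_min_abs, q_corr_max = q_corr_max,
                      positive_only = positive_only, fdr_scope = fdr_scope)
  )
}
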