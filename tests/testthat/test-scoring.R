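test_that("hypergeometric tail matches direct evaluation of the sum formula", {
  # boundary conventions
  expect_equal(hyper_shared_pval(0, 20, 5, 6), 1)
  expect_equal(hyper_shared_pval(min(5, 6) + 1, 20, 5, 6), 0)
  # x = 3, N = 20, K = 5, M = 6 against the explicit sum over the upper tail
  direct <- sum(vapply(3:5, function(t) {
    choose(5, t) * choose(15, 6 - t) / choose(20, 6)
  }, 0))
  expect_equal(hyper_shared_pval(3, 20, 5, 6), direct, tolerance = 1e-14)
  # exhaustive-enumeration oracle on a small grid
  for (N in c(5, 7, 8)) {
    for (K in 0:N) {
      for (M in c(0, 2, N)) {
        if (M > N) next
        for (x in 0:(min(K, M) + 1)) {
          expect_equal(hyper_shared_pval(x, N, K, M), bf_hyper_upper(x, N, K, M),
                       tolerance = 1e-12,
                       label = sprintf("x=%d N=%d K=%d M=%d", x, N, K, M))
        }
      }
    }
  }
  # domain violations rejected
  expect_error(hyper_shared_pval(1, 5, 7, 2))
  expect_error(hyper_shared_pval(4, 10, 3, 2))
})

test_that("FDR adjustment is BH step-up, monotone and order-invariant", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.3, 5)), rep(0.3, 5))
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bf_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(seq_along(p))
    expect_equal(fdr_adjust(p[perm]), adj[perm])
  }
  expect_error(fdr_adjust(c(0.1, 1.2)))
})

test_that("pearson_test matches the covariance formula and flags constants", {
  res <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  a <- rnorm(10)
  expect_equal(pearson_test(a, a)$rho, 1)
  expect_equal(pearson_test(a, -a)$rho, -1)
  expect_error(pearson_test(a, rep(1, 10)), "constant")
  expect_error(pearson_test(1:3, 1:4), "equal length")
})

scoring_fixture <- function() {
  # 6 RNAs over a 12-miRNA universe; a/b/c form a strongly co-regulated
  # trio, d shares too few miRNAs, e is anti-correlated, f uncorrelated
  tmap <- tibble::tibble(
    mirna = c(rep(paste0("m", 1:5), times = 3),     # a, b, c share m1..m5
              "m1", "m2",                            # d: only 2 shared with a
              paste0("m", 1:5),                      # e shares m1..m5 with trio
              paste0("m", 6:20)),                    # f pads the universe to N = 20
    rna = c(rep(c("a", "b", "c"), each = 5), "d", "d", rep("e", 5), rep("f", 15))
  )
  set.seed(99)
  n <- 60
  z <- rnorm(n)
  m <- rbind(
    a = 5 + z + rnorm(n, sd = 0.1),
    b = 5 + z + rnorm(n, sd = 0.1),
    c = 5 + z + rnorm(n, sd = 0.1),
    d = 5 + z + rnorm(n, sd = 0.1),
    e = 5 - z + rnorm(n, sd = 0.1),
    f = 5 + rnorm(n)
  )
  colnames(m) <- sprintf("s%02d", seq_len(n))
  expr <- expr_table(2^m - 1 + 1e-9, stats::setNames(rep("mRNA", 6), rownames(m)),
                     transform = "raw")
  expr <- log2_transform(filter_expression(expr))
  list(expr = expr, tmap = tmap)
}

test_that("pair scoring applies both filter stages conjunctively", {
  fx <- scoring_fixture()
  pairs <- score_candidate_pairs(fx$expr, fx$tmap)
  keys <- pair_key(pairs$rna_a, pairs$rna_b)
  # the co-regulated, co-expressed trio survives
  expect_true(all(c("a b", "a c", "b c") %in% keys))
  # d is strongly correlated but shares only 2 miRNAs: x threshold rejects
  expect_false(any(grepl("d", keys)))
  # e shares 5 miRNAs and is strongly negatively correlated: |rho| keeps it
  expect_true("a e" %in% keys)
  # positive-only mode drops the negative-correlation pairs
  pos <- score_candidate_pairs(fx$expr, fx$tmap, positive_only = TRUE)
  expect_false(any(grepl("e", pair_key(pos$rna_a, pos$rna_b))))
  # f never shares 3 miRNAs with anyone
  expect_false(any(grepl("f", keys)))
  # record integrity
  expect_true(all(pairs$rna_a < pairs$rna_b))
  expect_true(all(pairs$x <= pmin(pairs$K, pairs$M)))
  expect_true(all(pairs$q_hyper < 0.01 & pairs$x >= 3))
  expect_true(all(abs(pairs$rho) > 0.5 & pairs$q_corr < 0.01))
  expect_identical(lengths(pairs$shared_mirnas), as.integer(pairs$x))
})

test_that("pair scoring is invariant to row and sample order and monotone in thresholds", {
  fx <- scoring_fixture()
  base <- score_candidate_pairs(fx$expr, fx$tmap)
  # permute RNAs and samples
  perm_expr <- fx$expr[sample(nrow(fx$expr)), ]
  perm_expr <- perm_expr[, c("rna_id", "rna_class", sample(expr_samples(fx$expr)))]
  attr(perm_expr, "transform") <- "log2"
  class(perm_expr) <- class(fx$expr)
  perm <- score_candidate_pairs(perm_expr, fx$tmap[sample(nrow(fx$tmap)), ])
  expect_equal(
    perm[, setdiff(names(perm), "shared_mirnas")],
    base[, setdiff(names(base), "shared_mirnas")],
    ignore_attr = TRUE
  )
  # stricter thresholds never add pairs
  for (args in list(list(min_shared = 5), list(rho_min_abs = 0.9))) {
    strict <- do.call(score_candidate_pairs, c(list(fx$expr, fx$tmap), args))
    expect_true(all(pair_key(strict$rna_a, strict$rna_b) %in%
                      pair_key(base$rna_a, base$rna_b)))
  }
  expect_error(score_candidate_pairs(fx$expr, fx$tmap[0, ]), "empty")
})
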