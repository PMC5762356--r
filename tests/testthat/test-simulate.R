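test_that("configuration validation rejects impossible designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mirnas_per_module = 50, n_mirna = 40), "exceed")
  expect_error(sim_config(n_planted_modules = 10, mirnas_per_module = 20,
                          n_mirna = 100), "disjoint")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_samples = 0))
})

test_that("target map plants co-sharing modules and is deterministic", {
  cfg <- small_cfg(seed = 5)
  tm <- simulate_target_map(cfg)
  mods <- attr(tm, "modules")
  expect_length(mods, 2)
  # every within-module pair shares the full miRNA block
  tsets <- split(tm$mirna, tm$rna)
  for (mod in mods) {
    for (pair in utils::combn(mod, 2, simplify = FALSE)) {
      expect_gte(length(intersect(tsets[[pair[1]]], tsets[[pair[2]]])),
                 cfg$mirnas_per_module)
    }
  }
  # background RNAs carry the configured number of targets
  bg <- setdiff(unique(tm$rna), unlist(mods))
  expect_true(all(lengths(tsets[bg]) <= cfg$background_targets_per_rna))
  # identical seed, identical map; different seed differs
  expect_identical(tibble::as_tibble(tm), tibble::as_tibble(simulate_target_map(cfg)))
  expect_false(identical(tibble::as_tibble(tm),
                         tibble::as_tibble(simulate_target_map(small_cfg(seed = 6)))))
  # no planted modules: plain background map
  tm0 <- simulate_target_map(small_cfg(seed = 5, n_planted_modules = 0))
  expect_length(attr(tm0, "modules"), 0)
})

test_that("expression follows the shared-activity correlation model", {
  # closed form: two RNAs sharing all 5 regulators, weight 1, noise 0.1
  # have latent correlation 5 / (5 + 0.01) > 0.99; demand > 0.9 at n = 5000
  cfg <- sim_config(n_samples = 5000, n_mrna = 60, n_lncrna = 5, n_mirna = 30,
                    n_seed_genes = 4, n_planted_modules = 1, module_size = 4,
                    mirnas_per_module = 5, background_targets_per_rna = 2,
                    noise_sd = 0.1, zero_inflation = 0, seed = 77)
  st <- simulate_cerna_study(cfg)
  mod <- st$ground_truth$planted_modules[[1]]
  m <- log2(expr_matrix(st$expr) + 1)
  rho <- cor(m[mod[1], ], m[mod[2], ])
  expect_gte(rho, 0.9)
  # no repression effect: correlations vanish
  cfg0 <- sim_config(n_samples = 2000, n_mrna = 40, n_lncrna = 0, n_mirna = 20,
                     n_seed_genes = 4, n_planted_modules = 1, module_size = 4,
                     mirnas_per_module = 5, background_targets_per_rna = 2,
                     effect_w = 0, zero_inflation = 0, seed = 78)
  st0 <- simulate_cerna_study(cfg0)
  mod0 <- st0$ground_truth$planted_modules[[1]]
  m0 <- log2(expr_matrix(st0$expr) + 1)
  expect_lt(abs(cor(m0[mod0[1], ], m0[mod0[2], ])), 0.1)
  # zero-inflation fraction is honoured within +/- 0.05 per gene
  cfgz <- small_cfg(seed = 9, n_samples = 400, zero_inflation = 0.1)
  stz <- simulate_cerna_study(cfgz)
  zf <- rowMeans(expr_matrix(stz$expr) == 0)
  expect_true(all(abs(zf - 0.1) < 0.05))
  # values are non-negative
  expect_true(all(expr_matrix(stz$expr) >= 0))
})

test_that("planted-structure calibration holds on the strong preset", {
  st <- simulate_cerna_study(sim_config(seed = 123))
  gt <- st$ground_truth
  tsets <- split(st$tmap$mirna, st$tmap$rna)
  m <- log2(expr_matrix(st$expr) + 1)
  ok <- vapply(seq_len(nrow(gt$planted_pairs)), function(i) {
    a <- gt$planted_pairs$rna_a[i]
    b <- gt$planted_pairs$rna_b[i]
    x <- length(intersect(tsets[[a]], tsets[[b]]))
    x >= 3 && abs(cor(m[a, ], m[b, ])) > 0.5
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("clinical outcomes honour censoring and the planted hazard", {
  cfg <- small_cfg(seed = 41)
  st <- simulate_cerna_study(cfg)
  expect_true(all(st$clinical$os_time > 0))
  expect_equal(mean(st$clinical$os_event == 0), cfg$censor_rate, tolerance = 0.12)
  # censor_rate = 0: every event observed
  st0 <- simulate_cerna_study(small_cfg(seed = 42, censor_rate = 0))
  expect_true(all(st0$clinical$os_event == 1))
  # beta_surv = 0: survival independent of expression -> log-rank null
  stn <- simulate_cerna_study(small_cfg(seed = 43, beta_surv = 0, n_samples = 120))
  expect_equal(nrow(stn$ground_truth$true_beta), 0)
  mod <- stn$ground_truth$planted_modules[[1]]
  m <- log2(expr_matrix(stn$expr) + 1)
  grp <- ifelse(colMeans(m[mod, ]) > median(colMeans(m[mod, ])), "hi", "lo")
  p <- logrank_test(stn$clinical, grp)$p_value
  expect_gt(p, 0.001)  # not systematically significant under the null
  # full-study determinism
  st2 <- simulate_cerna_study(small_cfg(seed = 41))
  expect_identical(st$clinical, st2$clinical)
  expect_identical(expr_matrix(st$expr), expr_matrix(st2$expr))
  expect_identical(st$seed_genes, st2$seed_genes)
})

test_that("Cox refit on the true module recovers the planted coefficient signs", {
  agree <- vapply(1:6, function(i) {
    cfg <- sim_config(n_samples = 400, module_size = 10, beta_surv = 1,
                      seed = 500 + i)
    st <- simulate_cerna_study(cfg)
    expr <- log2_transform(filter_expression(st$expr))
    tb <- st$ground_truth$true_beta
    m <- expr_matrix(expr)[tb$rna, , drop = FALSE]
    df <- cbind(st$clinical[, c("os_time", "os_event")],
                as.data.frame(t(m), check.names = FALSE))
    ft <- tidy(fit_cox(df, covariates = tb$rna))
    mean(sign(ft$estimate[match(tb$rna, ft$term)]) == sign(tb$beta))
  }, 0)
  expect_gte(mean(agree), 0.9)
})

test_that("a study round-trips through the on-disk formats", {
  st <- simulate_cerna_study(small_cfg(seed = 61))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("expression.tsv", "targets.tsv", "seed_genes.txt",
           "clinical.tsv", "ground_truth.json")
  ))))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr_matrix(expr), expr_matrix(st$expr), tolerance = 1e-9)
  tm <- read_target_map(file.path(dir, "targets.tsv"))
  expect_equal(nrow(tm), nrow(st$tmap))
  expect_identical(read_seed_genes(file.path(dir, "seed_genes.txt")), st$seed_genes)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$os_time, st$clinical$os_time, tolerance = 1e-9)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(gt$prognostic_module_index, 1)
})
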