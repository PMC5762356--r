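sim_surv <- function(n, beta = 0, x = rnorm(n), censor = 0.2, rate0 = 1 / 500) {
  tt <- rexp(n, rate0 * exp(beta * x))
  if (censor > 0) {
    # exponential censoring gives P(censored) = censor exactly when beta = 0
    cens <- rexp(n, rate0 * censor / (1 - censor))
    time <- pmin(tt, cens)
    event <- as.integer(tt <= cens)
  } else {
    time <- tt
    event <- rep(1L, n)
  }
  tibble::tibble(sample = sprintf("s%04d", seq_len(n)), os_time = time,
                 os_event = event, x = x,
                 age = rnorm(n, 65, 10),
                 gender = sample(c("male", "female"), n, replace = TRUE))
}

test_that("cohort split follows the floor convention and the seed", {
  ids <- sprintf("p%03d", 1:251)
  sp <- split_cohort(ids, seed = 3)
  expect_length(sp$train, 125)
  expect_length(sp$test, 126)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_cohort(ids, seed = 3))
  expect_false(identical(sp$train, split_cohort(ids, seed = 4)$train))
  even <- split_cohort(sprintf("p%03d", 1:10), seed = 1)
  expect_length(even$train, 5)
  expect_length(even$test, 5)
  expect_error(split_cohort(ids[1:3]), "at least 4")
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  # tiny dataset, single binary covariate, no ties
  df <- tibble::tibble(
    os_time = c(2, 5, 7, 11, 13, 17),
    os_event = c(1, 1, 0, 1, 1, 0),
    x = c(1, 0, 1, 0, 1, 0)
  )
  fit <- fit_cox(df, covariates = "x")
  oracle <- bf_cox_grid(df$os_time, df$os_event, df$x)
  expect_equal(tidy(fit)$estimate, oracle, tolerance = 1e-3)
  expect_equal(tidy(fit)$hr, exp(oracle), tolerance = 1e-2)
  g <- glance(fit)
  expect_equal(g$n, 6)
  expect_equal(g$n_events, 4)
})

test_that("Cox estimates are scale-equivariant and nulls are near zero", {
  set.seed(8)
  df <- sim_surv(400, beta = 0.7)
  f1 <- tidy(fit_cox(df, covariates = "x"))
  df$x2 <- 2 * df$x
  f2 <- tidy(fit_cox(df, covariates = "x2"))
  expect_equal(f2$estimate, f1$estimate / 2, tolerance = 1e-6)
  # independent covariate: small coefficient, CI covers zero-ish effect
  df0 <- sim_surv(500, beta = 0)
  f0 <- tidy(fit_cox(df0, covariates = "x"))
  expect_lt(abs(f0$estimate), 0.15)
  expect_error(fit_cox(df0[df0$os_event == 0, ], covariates = "x"), "2 events")
  # collinear covariates are reported, not silently dropped
  dfc <- sim_surv(100, beta = 0.5)
  dfc$xdup <- dfc$x
  expect_error(fit_cox(dfc, covariates = c("x", "xdup")), "collinear")
})

test_that("risk scores follow the linear formula with a training-mean threshold", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expr <- expr_table(m, c(g1 = "mRNA", g2 = "mRNA"), transform = "log2")
  rs <- risk_scores(expr, c(g1 = 1, g2 = 0.5))
  expect_equal(rs$risk_score, c(2, 5, 8))  # 1*x1 + 0.5*x2
  # zero coefficients: everything low risk under the strict > rule
  rs0 <- risk_scores(expr, c(g1 = 0, g2 = 0))
  expect_true(all(rs0$risk_group == "low"))
  # adding a zero-coefficient gene never changes RS; gene order irrelevant
  rs2 <- risk_scores(expr, c(g2 = 0.5, g1 = 1))
  expect_equal(rs2$risk_score, rs$risk_score)
  # training threshold classifies the test set too
  rs3 <- risk_scores(expr, c(g1 = 1, g2 = 0.5), train = c("s1", "s2"))
  expect_equal(attr(rs3, "threshold"), mean(c(2, 5)))
  expect_equal(rs3$risk_group, c("low", "high", "high"))
  expect_error(risk_scores(expr, c(gX = 1)), "absent")
})

test_that("Kaplan-Meier matches the hand-computed product-limit table", {
  # 5 subjects: events at 1, 3, 5; censorings at 2, 4
  clin <- tibble::tibble(os_time = 1:5, os_event = c(1, 0, 1, 0, 1))
  km <- kaplan_meier(clin)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$estimate, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  # curve is non-increasing and starts at 1
  expect_true(all(diff(km$estimate) <= 1e-12))
  expect_true(all(km$estimate <= 1))
  # no censoring: empirical survival
  clin2 <- tibble::tibble(os_time = c(2, 4, 6, 8), os_event = 1)
  km2 <- kaplan_meier(clin2)
  expect_equal(km2$estimate, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  clin3 <- tibble::tibble(os_time = 1:4, os_event = 0)
  expect_true(all(kaplan_meier(clin3)$estimate == 1))
})

test_that("log-rank is symmetric, null on identical patterns, powered on real effects", {
  clin <- tibble::tibble(os_time = rep(c(1, 2, 3, 4), 2),
                         os_event = rep(c(1, 1, 0, 1), 2))
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(clin, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)
  # symmetry in group labels
  set.seed(12)
  df <- sim_surv(120, beta = 0.8, x = rep(0:1, each = 60))
  p1 <- logrank_test(df, df$x)$p_value
  p2 <- logrank_test(df, 1 - df$x)$p_value
  expect_equal(p1, p2)
  # strong effect detected
  df2 <- sim_surv(200, beta = log(3), x = rep(0:1, each = 100), censor = 0)
  expect_lt(logrank_test(df2, df2$x)$p_value, 0.001)
  expect_error(logrank_test(clin, rep("a", 8)), "two non-empty")
})

test_that("time-dependent AUC behaves at its analytic anchors", {
  # perfect ranking without censoring
  set.seed(10)
  n <- 80
  tt <- sort(rexp(n, 1 / 100))
  auc <- time_dependent_auc(-tt, tt, rep(1, n))
  expect_equal(auc$auc, 1)
  # marker equal to time reverses to AUC 0
  expect_equal(time_dependent_auc(tt, tt, rep(1, n))$auc, 0)
  # no-censoring AUC equals the Mann-Whitney statistic of cases vs controls
  mk <- rnorm(n)
  res <- time_dependent_auc(mk, tt, rep(1, n), horizon = median(tt))
  case <- tt <= median(tt)
  w <- wilcox.test(mk[case], mk[!case], exact = FALSE)$statistic
  expect_equal(res$auc, unname(w) / (sum(case) * sum(!case)))
  # ROC endpoints
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(max(res$roc$tpr), 1)
  expect_error(time_dependent_auc(mk, tt, rep(1, n), horizon = max(tt) * 2),
               "follow-up")
})

test_that("prognostic screen passes the planted module and reports Table-1 analyses", {
  cfg <- small_cfg(seed = 31, n_samples = 160, beta_surv = 1.2)
  st <- simulate_cerna_study(cfg)
  expr <- log2_transform(filter_expression(st$expr))
  gt <- st$ground_truth
  modules <- tibble::tibble(
    name = c("planted", "null"),
    k = 4L, index = 1:2,
    size = lengths(gt$planted_modules),
    members = gt$planted_modules
  )
  scr <- prognostic_screen(modules, expr, st$clinical, seed = 5)
  expect_s3_class(scr, "cerna_screen")
  planted <- scr[scr$module == "planted", ]
  expect_true(planted$passes)
  # multivariate HR of the risk score exceeds 1 for the planted module
  ct <- planted$cox_table[[1]]
  hr_rs <- ct$hr[ct$term == "risk_score" & ct$analysis == "multivariate"]
  expect_true(all(hr_rs > 1))
  # high-risk test samples die faster than low-risk ones
  rs <- planted$risk[[1]]
  test_rs <- rs[rs$set == "test", ]
  clin_t <- st$clinical[match(test_rs$sample, st$clinical$sample), ]
  rate_high <- mean(clin_t$os_event[test_rs$risk_group == "high"])
  rate_low <- mean(clin_t$os_event[test_rs$risk_group == "low"])
  expect_gte(rate_high, 1.2 * rate_low)
  # a module with a gene missing from expression is reported, not fatal
  modules2 <- dplyr::bind_rows(modules, tibble::tibble(
    name = "broken", k = 4L, index = 3L, size = 2L,
    members = list(c("NOT_A_GENE", gt$planted_modules[[1]][1]))
  ))
  scr2 <- prognostic_screen(modules2, expr, st$clinical, seed = 5)
  expect_true(is.na(scr2$logrank_p_train[scr2$module == "broken"]))
  expect_match(scr2$error[scr2$module == "broken"], "absent")
})
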