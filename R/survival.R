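#' Split a cohort into training and test sets
#'
#' Seeded uniform random partition. With an odd number of samples the extra
#' sample goes to the test set (e.g. 251 samples split as 125 training /
#' 126 test at the default 50/50 fraction).
#'
#' @param samples character vector of sample ids, or a clinical tibble with
#'   a `sample` column.
#' @param train_frac fraction assigned to the training set.
#' @param seed RNG seed (the split is deterministic given the seed).
#' @return A list with `train` and `test` id vectors.
#' @export
split_cohort <- function(samples, train_frac = 0.5, seed = 1L) {
  if (is.data.frame(samples)) samples <- samples$sample
  n <- length(samples)
  if (n < 4) stop("need at least 4 samples to split")
  stopifnot(train_frac > 0, train_frac < 1)
  n_train <- as.integer(floor(train_frac * n))
  train <- withr::with_seed(as.integer(seed), sample(samples, n_train))
  list(train = lex_sort(train), test = lex_sort(setdiff(samples, train)))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximisation via [survival::coxph()] with Efron tie
#' handling (tolerance 1e-9, up to 100 iterations). An optional ridge
#' penalty stabilises fits with many correlated covariates relative to the
#' number of events. Character covariates (e.g. gender) are coded as
#' factors; `"female"`/`"male"` uses female as the reference level.
#'
#' @param df data frame with `os_time`, `os_event` and covariate columns.
#' @param covariates covariate column names (default: everything except
#'   `sample`, `os_time`, `os_event`).
#' @param ridge ridge penalty (0 = none).
#' @param ties tie-handling method.
#' @return A `cerna_cox` object; [tidy()] returns the coefficient table
#'   (`term`, `estimate`, `hr`, `conf_low`, `conf_high`, `p_value`),
#'   [glance()] the fit summary.
#' @export
fit_cox <- function(df, covariates = NULL, ridge = 0, ties = "efron") {
  df <- as.data.frame(df, check.names = FALSE)
  covariates <- covariates %||% setdiff(names(df), c("sample", "os_time", "os_event"))
  if (!length(covariates)) stop("no covariates to fit")
  n_events <- sum(df$os_event)
  if (n_events < 2) stop("Cox fit needs at least 2 events")
  for (cv in covariates) {
    if (is.character(df[[cv]])) {
      lev <- lex_sort(unique(df[[cv]]))
      if (setequal(lev, c("female", "male"))) lev <- c("female", "male")
      df[[cv]] <- factor(df[[cv]], levels = lev)
    }
  }
  bt <- function(x) paste0("`", x, "`")
  rhs <- if (ridge > 0) {
    paste0("survival::ridge(", paste(bt(covariates), collapse = ", "),
           ", theta = ", ridge, ", scale = FALSE)")
  } else {
    paste(bt(covariates), collapse = " + ")
  }
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (!converged) {
    stop("Cox fit did not converge for covariates [",
         paste(covariates, collapse = ", "),
         "]; consider a ridge penalty (`ridge > 0`)")
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear covariates dropped by the Cox fit: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  term <- if (ridge > 0 && length(cf) == length(covariates)) {
    covariates
  } else {
    gsub("`", "", names(cf))
  }
  z <- cf / se
  table <- tibble::tibble(
    term = term,
    estimate = unname(cf),
    se = unname(se),
    hr = exp(unname(cf)),
    conf_low = exp(unname(cf - 1.96 * se)),
    conf_high = exp(unname(cf + 1.96 * se)),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE)
  )
  structure(
    list(model = fit, table = table, n = nrow(df), n_events = n_events,
         ridge = ridge, ties = ties),
    class = "cerna_cox"
  )
}

#' @method tidy cerna_cox
#' @export
tidy.cerna_cox <- function(x, ...) x$table

#' @method glance cerna_cox
#' @export
glance.cerna_cox <- function(x, ...) {
  conc <- tryCatch(unname(summary(x$model)$concordance[1]), error = function(e) NA_real_)
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    loglik = as.numeric(utils::tail(x$model$loglik, 1)),
    concordance = conc, ridge = x$ridge
  )
}

#' @export
print.cerna_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Module risk scores
#'
#' The risk score of a sample is the linear combination
#' `RS = sum_i R(i) * Exp(i)` of module gene expression weighted by the Cox
#' regression coefficients `R(i)`. Samples with RS strictly greater than
#' the mean RS of the *training* samples are classified high risk; the same
#' threshold classifies training and test samples alike.
#'
#' @param expr a log2-transformed [expr_table()].
#' @param coefficients named numeric vector of per-gene Cox coefficients.
#' @param train training sample ids used for the threshold (default: all
#'   samples).
#' @return A `cerna_risk` tibble: `sample`, `risk_score`, `set`
#'   (train/test), `risk_group` (high/low); the threshold and coefficients
#'   are stored as attributes.
#' @export
risk_scores <- function(expr, coefficients, train = NULL) {
  stopifnot(inherits(expr, "cerna_expr"), length(coefficients) > 0)
  genes <- names(coefficients)
  missing <- setdiff(genes, expr$rna_id)
  if (length(missing)) {
    stop("module gene(s) absent from expression: ", paste(missing, collapse = ", "))
  }
  m <- expr_matrix(expr)[genes, , drop = FALSE]
  rs <- as.numeric(crossprod(m, unname(coefficients)))
  samples <- colnames(m)
  train <- train %||% samples
  if (!all(train %in% samples)) stop("training ids absent from expression")
  threshold <- mean(rs[samples %in% train])
  out <- tibble::tibble(
    sample = samples,
    risk_score = rs,
    set = ifelse(samples %in% train, "train", "test"),
    risk_group = ifelse(rs > threshold, "high", "low")
  )
  structure(out,
    class = unique(c("cerna_risk", class(out))),
    threshold = threshold, coefficients = coefficients
  )
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survival function under right censoring,
#' optionally per group.
#'
#' @param clin clinical tibble with `os_time` and `os_event`.
#' @param group optional grouping vector aligned with `clin` rows.
#' @return A `cerna_km` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate` (the curve starts implicitly at S(0) = 1).
#' @export
kaplan_meier <- function(clin, group = NULL) {
  stopifnot(nrow(clin) > 0)
  df <- data.frame(os_time = clin$os_time, os_event = clin$os_event)
  df$group <- if (is.null(group)) "all" else as.character(group)
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = df)
  strata <- if (is.null(sf$strata)) {
    rep(unique(df$group), length(sf$time))
  } else {
    rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  out <- tibble::tibble(
    group = strata, time = sf$time,
    n_risk = sf$n.risk, n_event = sf$n.event, n_censor = sf$n.censor,
    estimate = sf$surv
  )
  structure(out, class = unique(c("cerna_km", class(out))))
}

#' Two-sided log-rank test
#'
#' Chi-squared statistic from observed-minus-expected event counts across
#' event times, comparing survival between groups.
#'
#' @param clin clinical tibble with `os_time` and `os_event`.
#' @param group grouping vector aligned with `clin` rows (two or more
#'   non-empty groups, at least one event overall).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(clin, group) {
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2 || any(tab == 0)) stop("log-rank needs two non-empty groups")
  if (sum(clin$os_event) < 1) stop("log-rank needs at least one event")
  df <- data.frame(os_time = clin$os_time, os_event = clin$os_event, group = group)
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = df, rho = 0)
  k <- length(sd$n) - 1
  tibble::tibble(
    statistic = sd$chisq,
    df = k,
    p_value = stats::pchisq(sd$chisq, k, lower.tail = FALSE)
  )
}

#' Time-dependent ROC curve and AUC
#'
#' Cumulative-case / dynamic-control discrimination of a risk marker at a
#' horizon t: cases are subjects with an observed event by t, controls are
#' subjects still under observation beyond t. Censoring before t is handled
#' by inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution evaluated at the left limit of
#' each case's event time. Tied marker values contribute 1/2.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param time,event follow-up time and event indicator.
#' @param horizon evaluation time (default: median follow-up).
#' @return A `cerna_auc` list: `auc`, `horizon`, `n_cases`, `n_controls`
#'   and the weighted `roc` curve (tibble `threshold`, `fpr`, `tpr`).
#' @export
time_dependent_auc <- function(marker, time, event, horizon = NULL) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  horizon <- horizon %||% stats::median(time)
  if (horizon <= 0 || horizon > max(time)) {
    stop("`horizon` must lie within the observed follow-up")
  }
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case)) stop("no case (observed event) by the horizon")
  if (!any(ctrl)) stop("no control under observation beyond the horizon")
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  g_minus <- stats::stepfun(cfit$time, c(1, cfit$surv), right = TRUE)
  w <- 1 / g_minus(time[case])
  if (any(!is.finite(w))) stop("degenerate censoring weights at the horizon")
  mi <- marker[case]
  mj <- marker[ctrl]
  comp <- outer(mi, mj, ">") + 0.5 * outer(mi, mj, "==")
  auc <- sum(w * rowSums(comp)) / (sum(w) * length(mj))
  thr <- sort(unique(marker), decreasing = TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(cc) sum(w * (mi >= cc)) / sum(w), 0)),
    fpr = c(0, vapply(thr, function(cc) mean(mj >= cc), 0))
  )
  structure(
    list(auc = auc, horizon = horizon, n_cases = sum(case),
         n_controls = sum(ctrl), roc = roc),
    class = "cerna_auc"
  )
}

#' @export
print.cerna_auc <- function(x, ...) {
  cat(sprintf("time-dependent AUC at t = %.4g: %.4f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Table-1 style Cox analysis of risk score, age and gender
#'
#' Univariate Cox regressions for each of risk score, gender and age, plus
#' one multivariate model with all three, on a single cohort subset.
#'
#' @param clin clinical tibble (with `age`, `gender`) restricted to one set.
#' @param risk_score numeric risk score aligned with `clin` rows.
#' @return A tibble: `term`, `analysis` (univariate/multivariate), `hr`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
covariate_cox_table <- function(clin, risk_score) {
  df <- data.frame(
    os_time = clin$os_time, os_event = clin$os_event,
    risk_score = risk_score, age = clin$age, gender = clin$gender,
    check.names = FALSE
  )
  covs <- c("risk_score", "gender", "age")
  if (length(unique(df$gender)) < 2) covs <- setdiff(covs, "gender")
  uni <- purrr::map_dfr(covs, function(cv) {
    ft <- tidy(fit_cox(df, covariates = cv))
    ft$analysis <- "univariate"
    ft
  })
  multi <- tidy(fit_cox(df, covariates = covs))
  multi$analysis <- "multivariate"
  out <- dplyr::bind_rows(uni, multi)
  out[, c("term", "analysis", "hr", "conf_low", "conf_high", "p_value")]
}

#' Screen modules for prognostic ability
#'
#' For every module: fit a multivariate Cox model on the module genes
#' (training samples only by default; `paper_mode = TRUE` fits on the full
#' cohort), compute per-sample risk scores, dichotomise at the training-set
#' mean risk score, and test high vs low risk survival with the two-sided
#' log-rank test separately in the training and the test set. A module
#' passes when the log-rank p-value is below `alpha` in **both** sets.
#' Time-dependent AUCs and a Table-1 style univariate/multivariate Cox
#' analysis (risk score, age, gender) are attached for each module.
#'
#' @param modules module tibble from [discover_modules()] (columns `name`,
#'   `k`, `size`, `members`).
#' @param expr log2-transformed [expr_table()].
#' @param clin clinical tibble (`sample`, `os_time`, `os_event`, `age`,
#'   `gender`).
#' @param alpha significance level of the log-rank screen.
#' @param seed seed for the cohort split.
#' @param train_frac training fraction of the split.
#' @param paper_mode fit Cox coefficients on all samples instead of the
#'   training set only.
#' @param ridge ridge penalty passed to [fit_cox()].
#' @param horizon AUC evaluation horizon (default: median follow-up).
#' @return A `cerna_screen` tibble, one row per module, ranked with passing
#'   modules first: log-rank p-values and AUCs per set, high/low group
#'   sizes, `passes`, plus list columns `risk` (the [risk_scores()] table),
#'   `cox_table` (Table-1 style analysis per set) and `error` for modules
#'   that could not be evaluated.
#' @export
prognostic_screen <- function(modules, expr, clin, alpha = 0.05, seed = 1L,
                              train_frac = 0.5, paper_mode = FALSE,
                              ridge = 0, horizon = NULL) {
  stopifnot(nrow(modules) >= 1, inherits(expr, "cerna_expr"))
  if (expr_transform(expr) != "log2") {
    stop("prognostic_screen() expects log2-transformed expression")
  }
  samples <- intersect(expr_samples(expr), clin$sample)
  if (length(samples) < 4) stop("too few samples shared by expression and clinical data")
  clin <- clin[match(samples, clin$sample), , drop = FALSE]
  split <- split_cohort(samples, train_frac = train_frac, seed = seed)
  horizon <- horizon %||% stats::median(clin$os_time)
  m <- expr_matrix(expr)

  rows <- purrr::map(seq_len(nrow(modules)), function(i) {
    members <- modules$members[[i]]
    res <- tryCatch(
      screen_one_module(members, m, clin, split, paper_mode, ridge, horizon, alpha),
      error = function(e) list(error = conditionMessage(e))
    )
    base <- tibble::tibble(
      module = modules$name[i], k = modules$k[i], size = modules$size[i]
    )
    if (!is.null(res$error)) {
      return(dplyr::bind_cols(base, tibble::tibble(
        logrank_p_train = NA_real_, logrank_p_test = NA_real_,
        auc_train = NA_real_, auc_test = NA_real_,
        n_high_train = NA_integer_, n_low_train = NA_integer_,
        n_high_test = NA_integer_, n_low_test = NA_integer_,
        passes = FALSE, risk = list(NULL), cox_table = list(NULL),
        error = res$error
      )))
    }
    dplyr::bind_cols(base, res$row)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$passes, pmax(out$logrank_p_train, out$logrank_p_test),
                   method = "radix"), , drop = FALSE]
  structure(out,
    class = unique(c("cerna_screen", class(out))),
    alpha = alpha, split = split, horizon = horizon, paper_mode = paper_mode
  )
}

screen_one_module <- function(members, m, clin, split, paper_mode, ridge,
                              horizon, alpha) {
  missing <- setdiff(members, rownames(m))
  if (length(missing)) {
    stop("module gene(s) absent from expression: ", paste(missing, collapse = ", "))
  }
  fit_ids <- if (paper_mode) clin$sample else split$train
  fit_clin <- clin[clin$sample %in% fit_ids, , drop = FALSE]
  covar <- as.data.frame(t(m[members, fit_clin$sample, drop = FALSE]), check.names = FALSE)
  fit_df <- cbind(fit_clin[, c("os_time", "os_event")], covar)
  fit <- fit_cox(fit_df, covariates = members, ridge = ridge)
  coefs <- stats::setNames(fit$table$estimate, fit$table$term)[members]

  expr_like <- expr_table(m, stats::setNames(rep("mRNA", nrow(m)), rownames(m)),
                          transform = "log2")
  rs <- risk_scores(expr_like, coefs, train = split$train)
  rs <- rs[match(clin$sample, rs$sample), , drop = FALSE]

  per_set <- lapply(c(train = "train", test = "test"), function(st) {
    idx <- rs$set == st
    cl <- clin[idx, , drop = FALSE]
    grp <- rs$risk_group[idx]
    p <- tryCatch(logrank_test(cl, grp)$p_value, error = function(e) NA_real_)
    auc <- tryCatch(
      time_dependent_auc(rs$risk_score[idx], cl$os_time, cl$os_event, horizon)$auc,
      error = function(e) NA_real_
    )
    cox <- tryCatch({
      ct <- covariate_cox_table(cl, rs$risk_score[idx])
      ct$set <- st
      ct
    }, error = function(e) NULL)
    list(p = p, auc = auc, n_high = sum(grp == "high"), n_low = sum(grp == "low"),
         cox = cox)
  })
  passes <- isTRUE(per_set$train$p < alpha) && isTRUE(per_set$test$p < alpha)
  list(row = tibble::tibble(
    logrank_p_train = per_set$train$p, logrank_p_test = per_set$test$p,
    auc_train = per_set$train$auc, auc_test = per_set$test$auc,
    n_high_train = per_set$train$n_high, n_low_train = per_set$train$n_low,
    n_high_test = per_set$test$n_high, n_low_test = per_set$test$n_low,
    passes = passes,
    risk = list(rs),
    cox_table = list(dplyr::bind_rows(per_set$train$cox, per_set$test$cox)),
    error = NA_character_
  ))
}

#' @method tidy cerna_screen
#' @export
tidy.cerna_screen <- function(x, ...) {
  tibble::as_tibble(x)[, c("module", "k", "size", "logrank_p_train",
                           "logrank_p_test", "auc_train", "auc_test",
                           "passes")]
}

#' @method glance cerna_screen
#' @export
glance.cerna_screen <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x), n_passing = sum(x$passes),
    alpha = attr(x, "alpha"), horizon = attr(x, "horizon"),
    paper_mode = attr(x, "paper_mode")
  )
}
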