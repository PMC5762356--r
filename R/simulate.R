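#' Configuration for a synthetic ceRNA study
#'
#' Defines the conditions of a simulated cohort: a miRNA-target map with
#' planted co-regulated modules, an RPKM-like expression matrix whose
#' co-expression structure is driven by shared miRNA activities, a seed
#' ("ageing") gene list anchoring each planted module, and right-censored
#' survival outcomes driven by the first planted module.
#'
#' The defaults are the "strong" study preset: 300 samples, 2000 RNAs
#' (1800 mRNA + 200 lncRNA), 150 miRNAs, four planted 12-gene modules each
#' co-regulated by a disjoint block of 5 miRNAs, and a prognostic hazard
#' signal of magnitude 1 (log-hazard per log2-expression unit, alternating
#' sign across the module genes) attached to module 1 only.
#'
#' @param n_samples number of samples.
#' @param n_mrna,n_lncrna number of mRNAs / lncRNAs.
#' @param n_mirna number of miRNAs in the study universe.
#' @param n_seed_genes size of the seed ("ageing") gene list; one member of
#'   each planted module is always a seed.
#' @param n_planted_modules number of planted co-regulated modules (0 for a
#'   pure background simulation).
#' @param module_size genes per planted module.
#' @param mirnas_per_module miRNAs co-targeting every gene of a module.
#' @param background_targets_per_rna miRNA targets drawn uniformly for each
#'   non-module RNA.
#' @param effect_w repression weight: log2-expression units per unit of
#'   miRNA activity.
#' @param noise_sd per-gene expression noise SD (log2 scale).
#' @param zero_inflation fraction of entries set to zero, emulating dropout
#'   in RPKM data that has already passed a zero-fraction filter.
#' @param mu_range range of baseline log2 expression (uniform per gene).
#' @param beta_surv magnitude of the per-gene log-hazard coefficients of the
#'   prognostic module (signs alternate across its genes; 0 disables the
#'   survival signal).
#' @param censor_rate target fraction of censored samples in `[0, 1)`.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @param age_mean,age_sd age distribution (years); age has no true hazard
#'   effect, giving covariate comparisons a known null.
#' @param p_male probability of male gender (no true hazard effect either).
#' @param seed RNG seed; identical configurations give identical studies.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 300, n_mrna = 1800, n_lncrna = 200,
                       n_mirna = 150, n_seed_genes = 30,
                       n_planted_modules = 4, module_size = 12,
                       mirnas_per_module = 5, background_targets_per_rna = 3,
                       effect_w = 1, noise_sd = 0.5, zero_inflation = 0.02,
                       mu_range = c(4, 9),
                       beta_surv = 1, censor_rate = 0.3,
                       baseline_hazard = log(2) / 1500,
                       age_mean = 68, age_sd = 10, p_male = 0.75,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_mrna = as.integer(n_mrna),
    n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
    n_seed_genes = as.integer(n_seed_genes),
    n_planted_modules = as.integer(n_planted_modules),
    module_size = as.integer(module_size),
    mirnas_per_module = as.integer(mirnas_per_module),
    background_targets_per_rna = as.integer(background_targets_per_rna),
    effect_w = effect_w, noise_sd = noise_sd,
    zero_inflation = zero_inflation, mu_range = mu_range,
    beta_surv = beta_surv, censor_rate = censor_rate,
    baseline_hazard = baseline_hazard,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_samples > 0, n_mrna > 0, n_lncrna >= 0, n_mirna > 0,
      n_seed_genes > 0, n_planted_modules >= 0, module_size >= 2,
      mirnas_per_module > 0, background_targets_per_rna >= 0,
      noise_sd >= 0, zero_inflation >= 0, zero_inflation < 1,
      censor_rate >= 0, censor_rate < 1, baseline_hazard > 0,
      seed >= 0, seed < 2^31 - 100
    )
    if (mirnas_per_module > n_mirna) {
      stop("mirnas_per_module cannot exceed n_mirna")
    }
    if (n_planted_modules * mirnas_per_module > n_mirna) {
      stop("planted modules need disjoint miRNA blocks: n_planted_modules * mirnas_per_module <= n_mirna")
    }
    if (n_planted_modules * module_size > n_mrna) {
      stop("not enough mRNAs for the planted modules")
    }
    if (background_targets_per_rna > n_mirna) {
      stop("background_targets_per_rna cannot exceed n_mirna")
    }
  })
  structure(cfg, class = "sim_config")
}

sim_ids <- function(cfg) {
  list(
    mrna = sprintf("G%05d", seq_len(cfg$n_mrna)),
    lncrna = if (cfg$n_lncrna > 0) sprintf("L%05d", seq_len(cfg$n_lncrna)) else character(),
    mirna = sprintf("miR-%04d", seq_len(cfg$n_mirna)),
    sample = sprintf("S%04d", seq_len(cfg$n_samples))
  )
}

#' Generate a synthetic miRNA-target map
#'
#' Each planted module receives a disjoint block of `mirnas_per_module`
#' miRNAs that target every module gene, so any within-module pair shares
#' the whole block (shared count x = block size by construction). Every
#' remaining RNA receives `background_targets_per_rna` targets drawn
#' uniformly from all miRNAs. When `n_planted_modules > 0` the first module
#' contains one lncRNA member (mirroring mixed mRNA/lncRNA modules seen in
#' real ceRNA networks); all other members are mRNAs.
#'
#' @param cfg a [sim_config()].
#' @return A `cerna_sim_tmap`: tibble with `mirna` and `rna` columns;
#'   attributes `modules` (list of member id vectors), `module_mirnas`
#'   (list of miRNA block vectors) and `ids`.
#' @export
simulate_target_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_ids(cfg)
  withr::with_seed(cfg$seed + 101L, {
    modules <- list()
    module_mirnas <- list()
    module_members <- character()
    if (cfg$n_planted_modules > 0) {
      pool <- sample(ids$mrna, cfg$n_planted_modules * cfg$module_size)
      for (i in seq_len(cfg$n_planted_modules)) {
        mem <- pool[((i - 1) * cfg$module_size + 1):(i * cfg$module_size)]
        if (i == 1 && cfg$n_lncrna > 0) {
          mem[cfg$module_size] <- sample(ids$lncrna, 1)
        }
        modules[[i]] <- lex_sort(mem)
        module_mirnas[[i]] <- ids$mirna[((i - 1) * cfg$mirnas_per_module + 1):(i * cfg$mirnas_per_module)]
      }
      module_members <- unlist(modules)
    }
    background <- setdiff(c(ids$mrna, ids$lncrna), module_members)
    edges <- list()
    if (length(modules)) {
      edges <- purrr::map2(modules, module_mirnas, function(mem, mir) {
        tibble::tibble(mirna = rep(mir, each = length(mem)), rna = rep(mem, length(mir)))
      })
    }
    if (cfg$background_targets_per_rna > 0 && length(background)) {
      bg <- tibble::tibble(
        rna = rep(background, each = cfg$background_targets_per_rna),
        mirna = unlist(lapply(background, function(.)
          sample(ids$mirna, cfg$background_targets_per_rna)))
      )
      edges <- c(edges, list(bg[, c("mirna", "rna")]))
    }
    tm <- dplyr::distinct(dplyr::bind_rows(edges))
    tm <- tm[lex_order(tm$mirna, tm$rna), ]
    structure(tm,
      class = unique(c("cerna_sim_tmap", class(tm))),
      modules = modules, module_mirnas = module_mirnas, ids = ids
    )
  })
}

#' Generate a synthetic expression matrix with planted co-expression
#'
#' Latent-activity model: each miRNA m carries an independent per-sample
#' activity `a_ms ~ N(0, 1)`; the log2-scale latent expression of RNA g is
#' `L_gs = mu_g - effect_w * sum_{m in targets(g)} a_ms + eps`,
#' `eps ~ N(0, noise_sd^2)`; the RPKM-like value is `max(2^L - 1, 0)`, after
#' which a `zero_inflation` fraction of entries is zeroed at random. RNAs
#' co-targeted by many shared miRNAs are thereby positively correlated
#' (latent correlation `shared / sqrt(deg_A deg_B)` up to noise), and the
#' pipeline's `log2(x + 1)` transform recovers the latent scale.
#'
#' @param cfg a [sim_config()].
#' @param tmap the matching [simulate_target_map()] output.
#' @return A list: `expr` (raw [expr_table()]) and `ground_truth` (see
#'   [simulate_cerna_study()]).
#' @export
simulate_expression <- function(cfg, tmap) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tmap, "cerna_sim_tmap"))
  ids <- attr(tmap, "ids")
  rnas <- c(ids$mrna, ids$lncrna)
  classes <- stats::setNames(
    c(rep("mRNA", length(ids$mrna)), rep("lncRNA", length(ids$lncrna))), rnas
  )
  withr::with_seed(cfg$seed + 202L, {
    act <- matrix(stats::rnorm(cfg$n_mirna * cfg$n_samples),
                  nrow = cfg$n_mirna, dimnames = list(ids$mirna, ids$sample))
    tgt <- Matrix::sparseMatrix(
      i = match(tmap$rna, rnas), j = match(tmap$mirna, ids$mirna),
      x = 1, dims = c(length(rnas), cfg$n_mirna)
    )
    mu <- stats::runif(length(rnas), cfg$mu_range[1], cfg$mu_range[2])
    latent <- mu - cfg$effect_w * as.matrix(tgt %*% act) +
      matrix(stats::rnorm(length(rnas) * cfg$n_samples, sd = cfg$noise_sd),
             nrow = length(rnas))
    raw <- pmax(2^latent - 1, 0)
    if (cfg$zero_inflation > 0) {
      mask <- matrix(stats::runif(length(raw)) < cfg$zero_inflation, nrow = nrow(raw))
      raw[mask] <- 0
    }
    dimnames(raw) <- list(rnas, ids$sample)
    expr <- expr_table(raw, classes, transform = "raw")
    list(expr = expr, ground_truth = make_ground_truth(cfg, tmap))
  })
}

#' Generate an independent replicate cohort
#'
#' Draws a second expression matrix from the same latent-activity model and
#' the same target map (so the planted co-regulation structure is shared)
#' but with fresh miRNA activities and noise — an independent validation
#' cohort in the sense of a replication dataset.
#'
#' @param cfg the original [sim_config()].
#' @param tmap the original [simulate_target_map()] output.
#' @param replicate_seed seed for the replicate draw (must differ from
#'   `cfg$seed` to be independent).
#' @return A raw [expr_table()].
#' @export
simulate_replicate_expression <- function(cfg, tmap, replicate_seed) {
  cfg2 <- cfg
  cfg2$seed <- as.integer(replicate_seed)
  stopifnot(cfg2$seed >= 0, cfg2$seed < 2^31 - 100)
  simulate_expression(cfg2, tmap)$expr
}

make_ground_truth <- function(cfg, tmap) {
  modules <- attr(tmap, "modules")
  planted_pairs <- if (length(modules)) {
    purrr::imap_dfr(modules, function(mem, i) {
      cmb <- utils::combn(lex_sort(mem), 2)
      tibble::tibble(rna_a = cmb[1, ], rna_b = cmb[2, ], module = i)
    })
  } else {
    tibble::tibble(rna_a = character(), rna_b = character(), module = integer())
  }
  true_beta <- if (length(modules) && cfg$beta_surv != 0) {
    mem <- modules[[1]]
    tibble::tibble(
      rna = mem,
      beta = cfg$beta_surv * rep_len(c(1, -1), length(mem))
    )
  } else {
    tibble::tibble(rna = character(), beta = double())
  }
  list(
    planted_pairs = planted_pairs,
    planted_modules = modules,
    module_mirnas = attr(tmap, "module_mirnas"),
    prognostic_module_index = if (length(modules)) 1L else NA_integer_,
    true_beta = true_beta
  )
}

#' Generate synthetic clinical outcomes
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(sum_i beta_i * (Exp_i - mean_i))` using the
#' centred log2 expression of the prognostic module's genes (no module or
#' `beta_surv = 0` gives outcome-independent survival). Censoring times are
#' independent `Uniform(0, c)` with `c` tuned by root finding so the
#' expected censored fraction equals `censor_rate`. Age and gender are
#' generated with zero true hazard effect.
#'
#' @param cfg a [sim_config()].
#' @param expr expression table from [simulate_expression()].
#' @param ground_truth matching ground truth list.
#' @return A clinical tibble: `sample`, `os_time` (days, > 0), `os_event`
#'   (1 death, 0 censored), `age`, `gender`.
#' @export
simulate_clinical <- function(cfg, expr, ground_truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(expr, "cerna_expr"))
  samples <- expr_samples(expr)
  n <- length(samples)
  withr::with_seed(cfg$seed + 303L, {
    lp <- numeric(n)
    if (nrow(ground_truth$true_beta) > 0) {
      m <- log2(expr_matrix(expr) + 1)[ground_truth$true_beta$rna, , drop = FALSE]
      m <- m - rowMeans(m)
      lp <- as.numeric(crossprod(m, ground_truth$true_beta$beta))
    }
    rate <- cfg$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate)
    if (cfg$censor_rate > 0) {
      cens_frac <- function(cc) mean(pmin(t_event / cc, 1)) - cfg$censor_rate
      upper <- max(t_event) * 1e3
      cc <- stats::uniroot(cens_frac, lower = min(t_event) * 1e-6, upper = upper,
                           tol = 1e-8)$root
      t_cens <- stats::runif(n, 0, cc)
      os_time <- pmin(t_event, t_cens)
      os_event <- as.integer(t_event <= t_cens)
    } else {
      os_time <- t_event
      os_event <- rep(1L, n)
    }
    os_time <- pmax(os_time, 1e-6) # strictly positive follow-up by construction
    tibble::tibble(
      sample = samples,
      os_time = os_time,
      os_event = os_event,
      age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
      gender = ifelse(stats::runif(n) < cfg$p_male, "male", "female")
    )
  })
}

#' Generate a complete synthetic ceRNA study
#'
#' Bundles [simulate_target_map()], [simulate_expression()],
#' [simulate_clinical()] and the seed-gene list. The seed list contains one
#' designated member of every planted module (so each module lies inside a
#' seed gene's direct neighbourhood) topped up with random background mRNAs.
#'
#' @param cfg a [sim_config()].
#' @return A `cerna_sim_study` list: `config`, `tmap`, `expr` (raw),
#'   `clinical`, `seed_genes` and `ground_truth` (planted pair table,
#'   planted module list, miRNA blocks, prognostic module index, true
#'   hazard coefficients, seed genes).
#' @export
simulate_cerna_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  tmap <- simulate_target_map(cfg)
  ex <- simulate_expression(cfg, tmap)
  clinical <- simulate_clinical(cfg, ex$expr, ex$ground_truth)
  modules <- attr(tmap, "modules")
  seeds <- withr::with_seed(cfg$seed + 404L, {
    anchor <- vapply(modules, function(m) m[[1]], character(1))
    pool <- setdiff(sim_ids(cfg)$mrna, unlist(modules))
    extra <- max(0L, cfg$n_seed_genes - length(anchor))
    lex_sort(c(anchor, sample(pool, min(extra, length(pool)))))
  })
  gt <- ex$ground_truth
  gt$seed_genes <- seeds
  structure(
    list(config = cfg, tmap = tmap, expr = ex$expr, clinical = clinical,
         seed_genes = seeds, ground_truth = gt),
    class = "cerna_sim_study"
  )
}
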