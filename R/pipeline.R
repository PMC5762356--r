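#' Pipeline configuration
#'
#' Collects the input paths, output directory, stage thresholds, mode flags
#' and the seed for every stochastic step of [run_cerna_pipeline()].
#' Defaults mirror the canonical analysis: zero-fraction filter at 0.5,
#' log2 pseudocount 1, shared-miRNA threshold x >= 3 with FDR < 0.01,
#' |rho| > 0.5 with FDR < 0.01, top-decile hubs, clique parameter k >= 11,
#' 50/50 cohort split, log-rank screen at alpha = 0.05.
#'
#' @param expression path to the expression TSV.
#' @param targets path(s) to target TSVs (miRNA-mRNA and miRNA-lncRNA maps
#'   are merged).
#' @param seeds path to the seed-gene list.
#' @param clinical path to the clinical TSV (set `NULL` to skip the
#'   survival stage).
#' @param out_dir output directory.
#' @param max_zero_frac,pseudocount expression preprocessing parameters.
#' @param min_shared,q_hyper_max,rho_min_abs,q_corr_max pair-scoring
#'   thresholds.
#' @param positive_only,fdr_scope pair-scoring mode flags.
#' @param top_frac hub fraction.
#' @param bc betweenness variant (`"fraction"` or `"raw"`).
#' @param k_min clique-percolation parameter.
#' @param alpha,train_frac,paper_mode,ridge,horizon survival-stage
#'   parameters.
#' @param seed RNG seed for the cohort split.
#' @return A `cerna_pipeline_config` list.
#' @export
pipeline_config <- function(expression, targets, seeds, clinical = NULL,
                            out_dir = "cerna_run",
                            max_zero_frac = 0.5, pseudocount = 1,
                            min_shared = 3, q_hyper_max = 0.01,
                            rho_min_abs = 0.5, q_corr_max = 0.01,
                            positive_only = FALSE, fdr_scope = "sequential",
                            top_frac = 0.10, bc = "fraction",
                            k_min = 11, alpha = 0.05, train_frac = 0.5,
                            paper_mode = FALSE, ridge = 0, horizon = NULL,
                            seed = 1L) {
  cfg <- list(
    expression = expression, targets = targets, seeds = seeds,
    clinical = clinical, out_dir = out_dir,
    max_zero_frac = max_zero_frac, pseudocount = pseudocount,
    min_shared = min_shared, q_hyper_max = q_hyper_max,
    rho_min_abs = rho_min_abs, q_corr_max = q_corr_max,
    positive_only = positive_only, fdr_scope = fdr_scope,
    top_frac = top_frac, bc = bc, k_min = k_min, alpha = alpha,
    train_frac = train_frac, paper_mode = paper_mode, ridge = ridge,
    horizon = horizon, seed = as.integer(seed)
  )
  stopifnot(
    cfg$max_zero_frac >= 0, cfg$max_zero_frac <= 1, cfg$pseudocount >= 0,
    cfg$min_shared >= 0, cfg$q_hyper_max > 0, cfg$q_hyper_max <= 1,
    cfg$rho_min_abs >= 0, cfg$rho_min_abs <= 1,
    cfg$q_corr_max > 0, cfg$q_corr_max <= 1,
    cfg$top_frac > 0, cfg$top_frac <= 1, cfg$k_min >= 3,
    cfg$alpha > 0, cfg$alpha < 1, cfg$train_frac > 0, cfg$train_frac < 1,
    cfg$ridge >= 0, cfg$seed >= 0, cfg$seed < 2^31 - 100
  )
  structure(cfg, class = "cerna_pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields are [pipeline_config()] arguments.
#' @return A `cerna_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, args)
}

stage_error <- function(stage, message) {
  rlang::abort(paste0("[stage ", stage, "] ", message),
               class = "cerna_stage_error", stage = stage)
}

#' Validate the pipeline input files
#'
#' Checks format conformance and mutual consistency of the inputs: readable
#' files, required columns, duplicate ids, non-positive follow-up times,
#' id overlap between expression / clinical / targets / seeds. Warns via
#' the issue table, never mutates any input.
#'
#' @param expression,targets,seeds,clinical input file paths
#'   (`clinical = NULL` skips clinical checks).
#' @return A tibble of issues (`severity`, `check`, `message`); zero rows
#'   means a clean bundle.
#' @export
validate_study_inputs <- function(expression, targets, seeds, clinical = NULL) {
  issues <- list()
  note <- function(severity, check, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message
    )
  }
  for (p in c(expression, targets, seeds, clinical)) {
    if (!file.exists(p)) {
      rlang::abort(paste0("input file not readable: ", p), class = "cerna_input_error")
    }
  }
  expr <- read_expression(expression)
  if (anyDuplicated(expr$rna_id)) note("error", "expression", "duplicate RNA ids")
  tmap <- read_target_map(targets)
  sg <- read_seed_genes(seeds)
  n_missing_seed <- length(setdiff(sg, expr$rna_id))
  if (n_missing_seed > 0) {
    note("warning", "seeds",
         paste0(n_missing_seed, " seed gene(s) absent from the expression matrix"))
  }
  if (length(intersect(unique(tmap$rna), expr$rna_id)) < 2) {
    note("error", "targets", "fewer than 2 target-map RNAs appear in the expression matrix")
  }
  if (!is.null(clinical)) {
    clin <- read_clinical(clinical)
    if (anyDuplicated(clin$sample)) note("error", "clinical", "duplicate sample ids")
    n_bad <- sum(clin$os_time <= 0)
    if (n_bad > 0) {
      note("error", "clinical",
           paste0(n_bad, " sample(s) with non-positive overall survival time"))
    }
    overlap <- intersect(clin$sample, expr_samples(expr))
    if (length(overlap) < 4) {
      note("error", "clinical",
           "fewer than 4 samples shared by expression and clinical tables")
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(severity = character(), check = character(), message = character())
}

#' Run the ceRNA analysis pipeline end to end
#'
#' Executes filter, log2 transform, pair scoring, network construction,
#' seed-subnetwork extraction, topology analysis, k-clique module
#' discovery, the prognostic survival screen and per-module miRNA ranking,
#' writing every artifact (TSV tables, edge-list + GraphML networks, JSON
#' reports) plus a run manifest into `out_dir`. Re-running with an
#' identical configuration reproduces identical tables and manifest.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_cerna_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cerna_pipeline_config"))
  say <- function(...) if (!quiet) message("[cernasurv] ", ...)

  issues <- validate_study_inputs(config$expression, config$targets,
                                  config$seeds, config$clinical)
  if (any(issues$severity == "error")) {
    stage_error("validate", paste(issues$message[issues$severity == "error"],
                                  collapse = "; "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  say("reading inputs")
  expr <- read_expression(config$expression)
  tmap <- read_target_map(config$targets)
  seeds <- read_seed_genes(config$seeds)
  clin <- if (!is.null(config$clinical)) read_clinical(config$clinical) else NULL

  say("preprocessing expression")
  expr <- tryCatch({
    log2_transform(filter_expression(expr, config$max_zero_frac),
                   pseudocount = config$pseudocount)
  }, error = function(e) stage_error("preprocess", conditionMessage(e)))
  write_expression(expr, out("expression_log2.tsv"))

  say("scoring candidate ceRNA pairs")
  pairs <- tryCatch(
    score_candidate_pairs(expr, tmap,
                          min_shared = config$min_shared,
                          q_hyper_max = config$q_hyper_max,
                          rho_min_abs = config$rho_min_abs,
                          q_corr_max = config$q_corr_max,
                          positive_only = config$positive_only,
                          fdr_scope = config$fdr_scope),
    error = function(e) stage_error("score_pairs", conditionMessage(e))
  )
  pair_tbl <- tibble::as_tibble(pairs)
  pair_tbl$shared_mirnas <- vapply(pair_tbl$shared_mirnas, paste, "", collapse = ",")
  readr::write_tsv(pair_tbl, out("cerna_pairs.tsv"), progress = FALSE)

  say("building ceRNA network (", nrow(pairs), " pairs)")
  net <- build_cerna_network(pairs, classes = expr_classes(expr), seeds = seeds)
  write_network(net, out("cerna_network"))
  readr::write_tsv(edge_category_counts(net), out("edge_categories.tsv"), progress = FALSE)

  say("extracting seed subnetwork")
  agenet <- tryCatch(extract_seed_subnetwork(net, seeds),
                     error = function(e) stage_error("seed_subnetwork", conditionMessage(e)))
  write_network(agenet, out("seed_subnetwork"))

  say("topology analysis")
  cent <- network_centralities(agenet, bc = config$bc)
  readr::write_tsv(cent, out("centralities.tsv"), progress = FALSE)
  comparisons <- NULL
  if (length(unique(cent$group)) == 2 && all(table(cent$group) >= 2)) {
    comparisons <- purrr::map_dfr(c("degree", "closeness", "betweenness"),
                                  ~ compare_centrality(cent, .x))
    readr::write_tsv(comparisons, out("group_comparisons.tsv"), progress = FALSE)
  }
  dd <- degree_distribution_fit(agenet)
  readr::write_tsv(dd$histogram, out("degree_histogram.tsv"), progress = FALSE)
  hub <- if (igraph::vcount(agenet) >= 10) {
    h <- extract_hub_network(agenet, top_frac = config$top_frac)
    write_network(h, out("hub_network"))
    h
  } else NULL

  say("module discovery (k >= ", config$k_min, ")")
  modules <- discover_modules(agenet, k_min = config$k_min)
  mod_tbl <- modules
  mod_tbl$members <- vapply(mod_tbl$members, paste, "", collapse = ",")
  readr::write_tsv(mod_tbl, out("modules.tsv"), progress = FALSE)
  jsonlite::write_json(
    purrr::pmap(modules, function(name, k, index, size, members) {
      edges <- module_internal_edges(members, pairs)
      list(name = name, k = k, size = size, members = members,
           internal_edges = edges[, c("rna_a", "rna_b")])
    }),
    out("modules.json"), auto_unbox = TRUE, digits = NA
  )

  screen <- NULL
  mirna_reports <- list()
  if (!is.null(clin) && nrow(modules) > 0) {
    say("prognostic screen over ", nrow(modules), " module(s)")
    screen <- tryCatch(
      prognostic_screen(modules, expr, clin, alpha = config$alpha,
                        seed = config$seed, train_frac = config$train_frac,
                        paper_mode = config$paper_mode, ridge = config$ridge,
                        horizon = config$horizon),
      error = function(e) stage_error("survival", conditionMessage(e))
    )
    readr::write_tsv(tidy(screen), out("prognostic_screen.tsv"), progress = FALSE)
    for (i in which(screen$passes)) {
      name <- screen$module[i]
      rep <- tryCatch(
        module_mirna_regulators(
          modules$members[[match(name, modules$name)]], pairs, tmap = tmap),
        error = function(e) NULL
      )
      if (!is.null(rep)) {
        mirna_reports[[name]] <- rep
        readr::write_tsv(rep$counts, out(paste0("mirna_ranking_", name, ".tsv")),
                         progress = FALSE)
      }
    }
  } else if (is.null(clin)) {
    say("no clinical table: survival stage skipped")
  } else {
    say("no module at k >= ", config$k_min, ": survival stage skipped")
  }

  manifest <- list(
    package = "cernasurv",
    version = as.character(utils::packageVersion("cernasurv")),
    config = config[setdiff(names(config), "out_dir")],
    # hash the canonical JSON form so integer/double typing does not matter
    config_hash = rlang::hash(as.character(jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")], auto_unbox = TRUE, digits = NA
    ))),
    n_rna_after_filter = nrow(expr),
    n_pairs = nrow(pairs),
    n_seed_subnetwork_nodes = igraph::vcount(agenet),
    n_modules = nrow(modules),
    n_passing_modules = if (is.null(screen)) 0L else sum(screen$passes)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    expr = expr, pairs = pairs, network = net, seed_subnetwork = agenet,
    centralities = cent, comparisons = comparisons, degree_dist = dd,
    hub_network = hub, modules = modules, screen = screen,
    mirna_reports = mirna_reports, manifest = manifest, out_dir = config$out_dir
  ))
}
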