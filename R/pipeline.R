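#' Assemble a full experiment configuration
#'
#' Bundles the inputs of one ABC experiment: the scenario configuration,
#' the observed data (FASTA + population map, or an alignment tibble), and
#' the ABC settings.
#'
#' @param experiment An `abc_experiment` or the path to a YAML scenario
#'   config (see [read_scenario_config()]).
#' @param fasta,map Paths to the observed aligned FASTA and population map
#'   TSV; alternatively supply `alignment`.
#' @param alignment Observed alignment tibble (`id`, `population`,
#'   `sequence`).
#' @param sample_sizes Simulated sample sizes per population; default = the
#'   observed per-population sample sizes.
#' @param n_rows Reference-table rows (full-scale default 1e6).
#' @param tolerance Rejection tolerance fraction (default 0.01).
#' @param method Posterior method, `"logistic"` (default) or `"direct"`.
#' @param n_pods Datasets for posterior-based confidence (default 500; 0
#'   skips the confidence step).
#' @param length Alignment length for the simulations; default = observed
#'   length.
#' @param seed Master seed (recorded in every output).
#' @param out_dir Output directory; NULL runs without writing files.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment, fasta = NULL, map = NULL,
                              alignment = NULL, sample_sizes = NULL,
                              n_rows = 1e6, tolerance = 0.01,
                              method = c("logistic", "direct"),
                              n_pods = 500, length = NULL, seed = 1,
                              out_dir = NULL) {
  method <- match.arg(method)
  if (is.character(experiment)) {
    if (!file.exists(experiment)) {
      abort(sprintf("scenario config not found: %s", experiment))
    }
    experiment <- read_scenario_config(experiment)
  }
  if (!inherits(experiment, "abc_experiment")) {
    abort("`experiment` must be an abc_experiment or a YAML path")
  }
  if (is.null(alignment)) {
    if (is.null(fasta) || is.null(map)) {
      abort("supply either `alignment` or both `fasta` and `map`")
    }
    alignment <- read_alignment(fasta, map)
  } else {
    validate_alignment(alignment)
  }
  structure(list(experiment = experiment, alignment = alignment,
                 sample_sizes = sample_sizes, n_rows = n_rows,
                 tolerance = tolerance, method = method, n_pods = n_pods,
                 length = length, seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

empirical_base_freq <- function(alignment) {
  chars <- unlist(strsplit(toupper(alignment$sequence), "", fixed = TRUE))
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  pmax(f, 1e-3) / sum(pmax(f, 1e-3))
}

#' Run one complete ABC experiment
#'
#' haplotypes, observed statistics, reference table, rejection, posterior
#' probabilities, PCA pre-evaluation and (optionally) posterior-based
#' confidence; writes a result-table-shaped CSV (`Prob.`, 95% CI bounds,
#' experiment-level `Conf.`), a JSON report and a log with the seed and
#' package versions. On error, partial outputs are removed.
#'
#' @param config An [experiment_config()].
#' @return A list with `posterior` (`scenario_posterior`), `prior_check`,
#'   `confidence`, `observed` (statistic vector), `paths` (written files)
#'   and `config`, invisibly classed `abc_report`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must come from experiment_config()")
  }
  exp <- config$experiment
  issues <- validate_experiment(exp, n_draw_checks = 2, seed = config$seed)
  if (nrow(issues) > 0) {
    abort(sprintf("invalid scenario '%s': %s", issues$scenario[1],
                  issues$message[1]))
  }

  paths <- character(0)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(name) {
    stages[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  res <- tryCatch({
    aln <- config$alignment
    sampled <- intersect(exp$populations$name, unique(aln$population))
    if (length(sampled) < 1) {
      abort("observed alignment shares no population with the experiment")
    }
    cfg <- stat_config(sampled)
    observed <- compute_summary_vector(aln, cfg)
    if (is.null(exp$mutation$base_freq)) {
      exp$mutation$base_freq <- empirical_base_freq(aln)
    }
    n_obs <- table(aln$population)[sampled]
    sample_sizes <- config$sample_sizes %||%
      setNames(as.integer(n_obs), sampled)
    L <- config$length %||% alignment_length(aln)
    tick("observed_stats")

    ref <- build_reference_table(exp, sample_sizes, n_rows = config$n_rows,
                                 seed = config$seed, length = L,
                                 config = cfg)
    tick("reference_table")

    rej <- rejection_select(ref, observed, tolerance = config$tolerance)
    post <- estimate_posteriors(rej, method = config$method)
    tick("posterior")

    check <- prior_scenario_check(ref, observed)
    tick("prior_check")

    conf <- NA_real_
    if (config$n_pods > 0) {
      conf <- as.numeric(scenario_confidence(post, n_pods = config$n_pods,
                                             seed = derive_seed(config$seed, 999999)))
    }
    attr(post, "confidence") <- conf
    tick("confidence")

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      csv <- file.path(config$out_dir, "posterior.csv")
      json <- file.path(config$out_dir, "report.json")
      log <- file.path(config$out_dir, "log.txt")
      paths <<- c(csv, json, log)

      td <- tidy(post)
      out_tab <- data.frame(Scenario = td$scenario, `Prob.` = td$prob,
                            `CI.low` = td$ci_low, `CI.high` = td$ci_high,
                            `Conf.` = conf, check.names = FALSE)
      readr::write_csv(out_tab, csv)
      jsonlite::write_json(list(
        experiment = exp$name, seed = config$seed,
        n_rows = config$n_rows, tolerance = config$tolerance,
        method = attr(post, "method"),
        posterior = td, selected = attr(post, "selected"),
        confidence = conf,
        prior_check = list(inside = check$inside,
                           starred = check$stats$stat[check$stats$stars != ""]),
        diagnostics = attr(post, "diagnostics")),
        json, auto_unbox = TRUE, digits = NA)
      writeLines(c(
        sprintf("experiment: %s", exp$name),
        sprintf("seed: %d", config$seed),
        sprintf("abcroutes version: %s",
                as.character(utils::packageVersion("abcroutes"))),
        sprintf("R version: %s", R.version.string),
        sprintf("stage seconds: %s",
                paste(names(stages), round(unlist(stages), 2), sep = "=",
                      collapse = ", "))), log)
    }

    invisible(structure(list(posterior = post, prior_check = check,
                             confidence = conf, observed = observed,
                             reference = ref, paths = paths,
                             config = config),
                        class = "abc_report"))
  }, error = function(e) {
    unlink(paths)
    abort(sprintf("experiment '%s' failed: %s", exp$name,
                  conditionMessage(e)))
  })
  res
}

#' Re-run an experiment after eliminating improbable scenarios
#'
#' Drops every scenario whose posterior probability fell below `threshold`
#' in a previous report and re-runs the analysis on the survivors (the
#' two-round procedure used when many candidate scenarios are compared).
#'
#' @param config The [experiment_config()] of the first round.
#' @param previous_report The `abc_report` returned by [run_experiment()].
#' @param threshold Elimination threshold (default 0.10).
#' @return An `abc_report` for the second round.
#' @export
run_elimination_round <- function(config, previous_report, threshold = 0.10) {
  post <- previous_report$posterior
  keep <- post$scenario[post$prob >= threshold]
  if (length(keep) < 2) {
    abort("fewer than two scenarios survive the threshold: nothing to compare")
  }
  exp <- config$experiment
  ids <- vapply(exp$scenarios, function(s) as.character(s$id), character(1))
  exp$scenarios <- exp$scenarios[ids %in% keep]
  config$experiment <- exp
  if (!is.null(config$out_dir)) {
    config$out_dir <- file.path(config$out_dir, "round2")
  }
  run_experiment(config)
}

#' List or load the packaged worldwide-analysis scenario configs
#'
#' The exact scenario configurations of the eleven worldwide experiments
#' (native source of the pre-2008 US, Canada, northwestern US, Europe and
#' Greece populations; admixture variants; the seven California scenarios;
#' the US-to-Europe and US-to-Italy bridgehead tests; the Greece/Hungary
#' history) ship with the package.
#'
#' @param name Optional experiment name; with no argument, the available
#'   names are returned.
#' @return A character vector of names, or an `abc_experiment`.
#' @export
table2_experiments <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "abcroutes",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.yaml$")
  names <- sub("\\.yaml$", "", files)
  if (is.null(name)) return(names)
  if (!name %in% names) {
    abort(sprintf("unknown experiment '%s'; available: %s", name,
                  paste(names, collapse = ", ")))
  }
  read_scenario_config(file.path(dir, paste0(name, ".yaml")))
}

#' Run one packaged worldwide experiment on user-supplied data
#'
#' One-command replication entry point: give it the experiment name, an
#' aligned CO1 FASTA and a population map whose labels match the
#' experiment's populations, and it runs the full pipeline.
#'
#' @param name One of [table2_experiments()].
#' @param fasta,map Observed data paths.
#' @param ... Passed to [experiment_config()] (e.g. `n_rows`, `seed`,
#'   `out_dir`).
#' @return An `abc_report`.
#' @export
run_table2_experiment <- function(name, fasta, map, ...) {
  run_experiment(experiment_config(table2_experiments(name),
                                   fasta = fasta, map = map, ...))
}
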