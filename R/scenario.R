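#' Construct an invasion scenario
#'
#' A scenario is a rooted backward-time demographic program: sampled and
#' unsampled populations, merge/admixture/size-change events at symbolic
#' times, and inequality conditions on the parameters (e.g. the introduced
#' effective size smaller than every native size). Event fields may be
#' parameter names (drawn from priors) or fixed numbers.
#'
#' @param id Scenario identifier (integer or string).
#' @param events A data frame with columns `time`, `kind`
#'   (`merge`/`admixture`/`size_change`), `child`, `parent` (merge target, or
#'   recipient-A for admixture), and optionally `parent_b` and `rate` for
#'   admixture, `size` for size changes. Backward in time, a merge moves all
#'   `child` lineages into `parent`; an admixture sends each `child` lineage
#'   to `parent` with probability `rate`, else to `parent_b`.
#' @param conditions Character vector of R inequality expressions over
#'   parameter names, all of which must hold for a draw to be accepted.
#' @param description Free-text label.
#' @return An `abc_scenario` object.
#' @export
abc_scenario <- function(id, events, conditions = character(0),
                         description = "") {
  events <- as_tibble(events)
  for (col in c("parent_b", "rate", "size")) {
    if (!col %in% names(events)) events[[col]] <- NA
  }
  stopifnot(all(c("time", "kind", "child", "parent") %in% names(events)))
  bad <- setdiff(events$kind, c("merge", "admixture", "size_change"))
  if (length(bad) > 0) abort(sprintf("unknown event kind '%s'", bad[1]))
  structure(list(id = id, events = events,
                 conditions = as.character(conditions),
                 description = description),
            class = "abc_scenario")
}

#' Construct an ABC experiment: populations, priors, mutation model, scenarios
#'
#' @param name Experiment label.
#' @param populations A data frame with columns `name`, `role`
#'   (`native`/`introduced`) and optionally `size` (size parameter name,
#'   default `N_<name>`).
#' @param priors Named list of prior specs, each
#'   `list(dist = "uniform"|"loguniform", min =, max =)`.
#' @param scenarios List of [abc_scenario()] objects.
#' @param mutation Mutation-model prior block; see [default_mutation_priors()].
#' @param conditions Conditions applied to every scenario.
#' @param sample_sizes Optional named default sample sizes per population.
#' @return An `abc_experiment` object.
#' @export
abc_experiment <- function(name, populations, priors, scenarios,
                           mutation = default_mutation_priors(),
                           conditions = character(0), sample_sizes = NULL) {
  populations <- as_tibble(populations)
  stopifnot(all(c("name", "role") %in% names(populations)))
  if (anyDuplicated(populations$name) > 0) {
    abort("population names must be unique")
  }
  if (!"size" %in% names(populations)) {
    populations$size <- paste0("N_", populations$name)
  }
  ids <- vapply(scenarios, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids) > 0) abort("scenario ids must be unique")
  structure(list(name = name, populations = populations, priors = priors,
                 mutation = mutation, scenarios = scenarios,
                 conditions = as.character(conditions),
                 sample_sizes = sample_sizes),
            class = "abc_experiment")
}

#' Default mutation-model priors for the CO1 barcode analyses
#'
#' HKY substitution model with 10% invariant sites and gamma (shape 2) rate
#' heterogeneity across the remaining sites. The mean mutation rate is
#' uniform on `[1e-7, 1e-5]` per site per generation and the realised locus
#' rate is gamma (shape 2) around the drawn mean; the transition coefficient
#' kappa (C/T) has mean uniform on `[1.5, 20]` with a gamma (shape 2) locus
#' value around the drawn mean.
#'
#' @return A list understood by [sample_parameters()] and
#'   [simulate_dataset()].
#' @export
default_mutation_priors <- function() {
  list(model = "HKY", p_invariant = 0.10, gamma_shape = 2,
       mean_rate = list(dist = "uniform", min = 1e-7, max = 1e-5),
       rate_shape = 2,
       mean_kappa = list(dist = "uniform", min = 1.5, max = 20),
       kappa_shape = 2,
       base_freq = NULL) # NULL = empirical frequencies of the observed data
}

#' @export
print.abc_scenario <- function(x, ...) {
  cat(sprintf("<abc_scenario %s> %s\n", x$id, x$description))
  print(as.data.frame(x$events))
  invisible(x)
}

#' @export
print.abc_experiment <- function(x, ...) {
  cat(sprintf("<abc_experiment '%s': %d populations, %d scenarios>\n",
              x$name, nrow(x$populations), length(x$scenarios)))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [abc_experiment()]: `experiment`, `populations`,
#' `priors`, optional `mutation`, `conditions`, `sample_sizes`, and a
#' `scenarios` list each with `id`, `description`, `events`, `conditions`.
#'
#' @param path YAML file path.
#' @return An `abc_experiment`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("experiment", "populations", "priors", "scenarios")
  missing <- setdiff(need, names(y))
  if (length(missing) > 0) {
    abort(sprintf("config is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  pops <- dplyr::bind_rows(lapply(y$populations, as_tibble))
  scen <- lapply(y$scenarios, function(s) {
    ev <- dplyr::bind_rows(lapply(s$events, function(e) {
      as_tibble(e[!vapply(e, is.null, logical(1))])
    }))
    abc_scenario(id = s$id, events = ev,
                 conditions = s$conditions %||% character(0),
                 description = s$description %||% "")
  })
  mut <- default_mutation_priors()
  if (!is.null(y$mutation)) mut[names(y$mutation)] <- y$mutation
  sample_sizes <- if (!is.null(y$sample_sizes)) unlist(y$sample_sizes)
  abc_experiment(name = y$experiment, populations = pops, priors = y$priors,
                 scenarios = scen, mutation = mut,
                 conditions = y$conditions %||% character(0),
                 sample_sizes = sample_sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_params <- function(scenario, experiment) {
  ev <- scenario$events
  syms <- c(ev$time, ev$rate, ev$size, experiment$populations$size)
  syms <- syms[!is.na(syms)]
  unique(syms[suppressWarnings(is.na(as.numeric(syms)))])
}

#' Structural validation of a scenario
#'
#' Checks that every event references a known population, every symbolic
#' parameter has a prior, at least one merge path can root all populations,
#' no population is merged away twice, and (by test draws) that the event
#' ordering implied by drawn times leaves no lineage stranded.
#'
#' @param scenario An `abc_scenario`.
#' @param experiment The `abc_experiment` providing populations and priors.
#' @param n_draw_checks Number of parameter draws used to probe time-ordering
#'   consistency.
#' @param seed Seed for the draw checks.
#' @return A tibble of diagnostics with columns `check` and `message`;
#'   zero rows means the scenario is valid.
#' @export
validate_scenario <- function(scenario, experiment, n_draw_checks = 5,
                              seed = 1) {
  issues <- list()
  note <- function(check, message) {
    issues[[length(issues) + 1]] <<- tibble(check = check, message = message)
  }
  pops <- experiment$populations$name
  ev <- scenario$events

  refs <- unique(c(ev$child, ev$parent, ev$parent_b))
  refs <- refs[!is.na(refs)]
  unknown <- setdiff(refs, pops)
  if (length(unknown) > 0) {
    note("unknown_population",
         sprintf("event references unknown population '%s'", unknown[1]))
  }

  params <- scenario_params(scenario, experiment)
  no_prior <- setdiff(params, names(experiment$priors))
  if (length(no_prior) > 0) {
    note("missing_prior",
         sprintf("parameter(s) without prior: %s",
                 paste(no_prior, collapse = ", ")))
  }

  closing <- ev$kind %in% c("merge", "admixture")
  closed_children <- ev$child[closing]
  if (anyDuplicated(closed_children) > 0) {
    note("double_merge", sprintf("population '%s' is merged away twice",
                                 closed_children[anyDuplicated(closed_children)]))
  }
  open_at_end <- setdiff(pops, closed_children)
  if (length(open_at_end) != 1) {
    note("no_common_root",
         sprintf("%d populations never merge into a common root (%s)",
                 length(open_at_end), paste(open_at_end, collapse = ", ")))
  }

  if (length(issues) == 0 && n_draw_checks > 0) {
    ok <- with_seed(seed, tryCatch({
      for (i in seq_len(n_draw_checks)) {
        draw <- sample_parameters(scenario, experiment)
        check_event_timeline(scenario, experiment, draw)
      }
      TRUE
    }, error = function(e) conditionMessage(e)))
    if (!isTRUE(ok)) note("timeline", as.character(ok))
  }

  if (length(issues) == 0) {
    tibble(check = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

# With concrete drawn times, replay events in time order and confirm no
# event uses a population already merged away and all populations reach the
# root.
check_event_timeline <- function(scenario, experiment, draw) {
  ev <- resolve_events(scenario, draw)
  ev <- ev[order(ev$time), , drop = FALSE]
  closed <- character(0)
  for (r in seq_len(nrow(ev))) {
    if (ev$kind[r] == "size_change") next
    if (ev$child[r] %in% closed) {
      abort(sprintf("population '%s' used after being merged away",
                    ev$child[r]))
    }
    parents <- c(ev$parent[r], ev$parent_b[r])
    parents <- parents[!is.na(parents)]
    if (any(parents %in% closed)) {
      abort(sprintf("merge target '%s' already merged away at time %g",
                    intersect(parents, closed)[1], ev$time[r]))
    }
    closed <- c(closed, ev$child[r])
  }
  invisible(TRUE)
}

#' Validate every scenario of an experiment
#'
#' @inheritParams validate_scenario
#' @return A tibble of diagnostics with a `scenario` column (zero rows =
#'   all valid).
#' @export
validate_experiment <- function(experiment, n_draw_checks = 5, seed = 1) {
  out <- lapply(experiment$scenarios, function(s) {
    d <- validate_scenario(s, experiment, n_draw_checks, seed)
    if (nrow(d) > 0) d$scenario <- as.character(s$id)
    d
  })
  dplyr::bind_rows(out)
}

draw_prior <- function(spec) {
  if (is.numeric(spec)) return(spec)
  switch(spec$dist,
    uniform = runif(1, spec$min, spec$max),
    loguniform = exp(runif(1, log(spec$min), log(spec$max))),
    abort(sprintf("unknown prior distribution '%s'", spec$dist)))
}

#' Draw one parameter set for a scenario
#'
#' Rejection-samples the demographic parameters until every inequality
#' condition of the scenario (and of the experiment) holds, then draws the
#' mutation parameters: the locus rate is gamma (shape `rate_shape`) around
#' a uniformly drawn mean, and likewise for kappa.
#'
#' @param scenario An `abc_scenario`.
#' @param experiment The `abc_experiment`.
#' @param max_rejections Abort after this many rejected draws.
#' @return A named list (the parameter draw) including `mean_rate`, `rate`,
#'   `mean_kappa`, `kappa`.
#' @export
sample_parameters <- function(scenario, experiment, max_rejections = 10000) {
  params <- scenario_params(scenario, experiment)
  conds <- c(experiment$conditions, scenario$conditions)
  conds <- lapply(conds, function(s) str2lang(s))
  tries <- 0
  repeat {
    tries <- tries + 1
    if (tries > max_rejections) {
      abort(sprintf(
        "no accepted draw after %d rejections; conditions may be unsatisfiable",
        max_rejections))
    }
    draw <- lapply(experiment$priors[params], draw_prior)
    ok <- all(vapply(conds, function(e) isTRUE(eval(e, draw)), logical(1)))
    if (ok) break
  }

  mut <- experiment$mutation
  draw$mean_rate <- draw_prior(mut$mean_rate)
  draw$rate <- rgamma(1, shape = mut$rate_shape,
                      scale = draw$mean_rate / mut$rate_shape)
  draw$mean_kappa <- draw_prior(mut$mean_kappa)
  draw$kappa <- rgamma(1, shape = mut$kappa_shape,
                       scale = draw$mean_kappa / mut$kappa_shape)
  draw
}

# events with all symbolic fields replaced by drawn values
resolve_events <- function(scenario, draw) {
  ev <- scenario$events
  num <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    sym <- is.na(out) & !is.na(x)
    if (any(sym)) {
      vals <- unlist(draw[x[sym]])
      if (length(vals) != sum(sym) || anyNA(vals)) {
        abort(sprintf("no drawn value for parameter '%s'",
                      x[sym][which(is.na(match(x[sym], names(draw))))[1]]))
      }
      out[sym] <- vals
    }
    out
  }
  tibble(time = num(ev$time), kind = ev$kind, child = ev$child,
         parent = ev$parent, parent_b = ev$parent_b, rate = num(ev$rate),
         size = num(ev$size))
}
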