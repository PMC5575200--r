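#' HKY mutation model with invariant sites and gamma rate heterogeneity
#'
#' @param rate Locus mutation rate per site per generation (mean substitution
#'   rate at stationarity for a non-invariant site of relative rate 1).
#' @param kappa Transition (A/G, C/T) rate coefficient.
#' @param base_freq Stationary base frequencies (A, C, G, T); must be
#'   positive and sum to 1.
#' @param p_invariant Fraction of sites with rate 0.
#' @param gamma_shape Shape of the gamma distribution of relative rates
#'   (mean 1) across non-invariant sites.
#' @return A `mutation_model` object.
#' @export
mutation_model <- function(rate, kappa = 2, base_freq = rep(0.25, 4),
                           p_invariant = 0.10, gamma_shape = 2) {
  stopifnot(rate >= 0, kappa > 0, length(base_freq) == 4,
            all(base_freq > 0), abs(sum(base_freq) - 1) < 1e-8,
            p_invariant >= 0, p_invariant < 1, gamma_shape > 0)
  structure(list(rate = rate, kappa = kappa, base_freq = base_freq,
                 p_invariant = p_invariant, gamma_shape = gamma_shape),
            class = "mutation_model")
}

# Pre-compile a scenario into a numeric event-matrix template plus the
# index bookkeeping needed to fill in a parameter draw; called once, the
# returned closure is the per-row hot path.
compile_scenario <- function(scenario, experiment) {
  pops <- experiment$populations$name
  size_sym <- experiment$populations$size
  size_fix <- suppressWarnings(as.numeric(size_sym))
  size_na <- which(is.na(size_fix))

  ev <- scenario$events
  kind_code <- c(merge = 0, admixture = 1, size_change = 2)
  val_sym <- ifelse(ev$kind == "size_change", as.character(ev$size),
                    as.character(ev$rate))
  bad_pop <- setdiff(stats::na.omit(c(ev$child, ev$parent, ev$parent_b)), pops)
  if (length(bad_pop) > 0) {
    abort(sprintf("event references unknown population '%s'", bad_pop[1]))
  }
  em0 <- cbind(suppressWarnings(as.numeric(ev$time)),
               kind_code[ev$kind],
               match(ev$child, pops) - 1L,
               match(ev$parent, pops) - 1L,
               ifelse(is.na(ev$parent_b), -1L, match(ev$parent_b, pops) - 1L),
               suppressWarnings(as.numeric(val_sym)))
  time_na <- which(is.na(em0[, 1]))
  time_sym <- as.character(ev$time)[time_na]
  val_na <- which(is.na(em0[, 6]) & !is.na(val_sym))
  val_na_sym <- val_sym[val_na]
  em0[is.na(em0)] <- -1

  function(draw) {
    sizes <- size_fix
    if (length(size_na) > 0) {
      sizes[size_na] <- unlist(draw[size_sym[size_na]], use.names = FALSE)
    }
    if (anyNA(sizes)) abort("population size parameter missing from draw")
    em <- em0
    if (length(time_na) > 0) {
      em[time_na, 1] <- unlist(draw[time_sym], use.names = FALSE)
    }
    if (length(val_na) > 0) {
      em[val_na, 6] <- unlist(draw[val_na_sym], use.names = FALSE)
    }
    list(sizes = sizes, events = em)
  }
}

# experiment + draw + sample sizes -> flat arguments for the C++ simulator
genealogy_args <- function(scenario, experiment, draw, sample_sizes) {
  pops <- experiment$populations$name
  n <- setNames(rep(0L, length(pops)), pops)
  known <- intersect(names(sample_sizes), pops)
  if (length(known) < length(sample_sizes)) {
    abort(sprintf("sample size given for unknown population '%s'",
                  setdiff(names(sample_sizes), pops)[1]))
  }
  n[known] <- as.integer(sample_sizes[known])
  filled <- compile_scenario(scenario, experiment)(draw)
  list(n_pops = length(pops), sizes = filled$sizes, events = filled$events,
       samples = n)
}

#' Simulate a coalescent genealogy under a scenario
#'
#' Backward-time structured coalescent: within each population pairs of
#' lineages coalesce at rate k(k-1)/2 scaled by the population's haploid
#' effective size; at a merge event lineages move child to parent; at an
#' admixture event each lineage of the child goes independently to one of
#' the two parents; simulation runs until a single root lineage remains.
#'
#' @param scenario An `abc_scenario`.
#' @param experiment The `abc_experiment` (populations, priors).
#' @param draw A parameter draw from [sample_parameters()].
#' @param sample_sizes Named integer vector of sampled lineages per
#'   population (populations absent or 0 are unsampled).
#' @param seed Integer seed.
#' @return A tibble with one row per genealogy node: `node`, `parent` (NA at
#'   the root), `time` (generations before present), `population` (leaves
#'   only), `label` (leaves only); leaves come first.
#' @export
simulate_genealogy <- function(scenario, experiment, draw, sample_sizes,
                               seed) {
  a <- genealogy_args(scenario, experiment, draw, sample_sizes)
  if (sum(a$samples) < 1) abort("at least one sampled lineage is required")
  g <- cpp_simulate_genealogy(a$n_pops, a$sizes, a$events, a$samples,
                              as.numeric(seed))
  n <- g$n_leaves
  pops <- experiment$populations$name
  leaf_pop <- pops[g$leaf_pop + 1L]
  labels <- paste0(leaf_pop, "_", stats::ave(seq_len(n), leaf_pop,
                                             FUN = seq_along))
  tibble(node = seq_along(g$parent),
         parent = ifelse(g$parent < 0, NA_integer_, g$parent + 1L),
         time = g$time,
         population = c(leaf_pop, rep(NA_character_, length(g$parent) - n)),
         label = c(labels, rep(NA_character_, length(g$parent) - n)))
}

# per-site relative rates: p_invariant of sites at 0, the rest gamma with
# mean 1
draw_site_rates <- function(model, length, seed) {
  with_seed(seed, {
    inv <- runif(length) < model$p_invariant
    r <- numeric(length)
    r[!inv] <- rgamma(sum(!inv), shape = model$gamma_shape,
                      scale = 1 / model$gamma_shape)
    r
  })
}

#' Drop HKY mutations on a genealogy, producing an alignment
#'
#' Per-site relative rates are drawn first (invariant fraction at 0, the
#' rest gamma with mean 1); the ancestral sequence is drawn from the
#' stationary base frequencies; substitutions follow the HKY process along
#' each branch (exact continuous-time simulation; multiple hits allowed).
#'
#' @param genealogy A genealogy tibble from [simulate_genealogy()].
#' @param model A [mutation_model()].
#' @param length Number of sites.
#' @param seed Integer seed.
#' @return An alignment tibble (`id`, `population`, `sequence`).
#' @export
mutate_alignment <- function(genealogy, model, length, seed) {
  stopifnot(length >= 1)
  m <- mutate_codes(genealogy, model, length, seed)
  leaves <- !is.na(genealogy$population)
  tibble(id = genealogy$label[leaves],
         population = genealogy$population[leaves],
         sequence = decode_sequences(m))
}

mutate_codes <- function(genealogy, model, length, seed) {
  rates <- draw_site_rates(model, length, derive_seed(seed, 101))
  n_leaves <- sum(!is.na(genealogy$population))
  parent0 <- ifelse(is.na(genealogy$parent), -1L, genealogy$parent - 1L)
  cpp_mutate(parent0, genealogy$time, n_leaves, rates, model$rate,
             model$kappa, model$base_freq,
             as.numeric(derive_seed(seed, 102)))
}

draw_mutation_model <- function(experiment, draw) {
  mut <- experiment$mutation
  mutation_model(rate = draw$rate, kappa = draw$kappa,
                 base_freq = mut$base_freq %||% rep(0.25, 4),
                 p_invariant = mut$p_invariant,
                 gamma_shape = mut$gamma_shape)
}

#' Simulate one pseudo-observed dataset under a scenario
#'
#' One prior draw, one genealogy, one alignment: the raw material of a
#' reference-table row.
#'
#' @inheritParams simulate_genealogy
#' @param length Alignment length in sites (the barcode default is 685).
#' @param draw Optional fixed parameter draw; by default parameters are
#'   drawn from the priors.
#' @return A list with `draw` (the parameter draw) and `alignment` (tibble).
#' @export
simulate_dataset <- function(scenario, experiment, sample_sizes, seed,
                             length = 685, draw = NULL) {
  if (is.null(draw)) {
    draw <- with_seed(derive_seed(seed, 1),
                      sample_parameters(scenario, experiment))
  }
  g <- simulate_genealogy(scenario, experiment, draw, sample_sizes,
                          derive_seed(seed, 2))
  aln <- mutate_alignment(g, draw_mutation_model(experiment, draw), length,
                          derive_seed(seed, 3))
  list(draw = draw, alignment = aln)
}

# One-time context for bulk simulation: compiled scenarios, flattened
# sample sizes, statistic-panel index maps. Rows simulated through the
# context use the same derived seeds as simulate_dataset(), so a
# reference-table row is bit-identical to the composable path.
make_sim_context <- function(experiment, sample_sizes, config, length) {
  pops <- experiment$populations$name
  samples <- setNames(rep(0L, length(pops)), pops)
  known <- intersect(names(sample_sizes), pops)
  if (length(known) < length(sample_sizes)) {
    abort(sprintf("sample size given for unknown population '%s'",
                  setdiff(names(sample_sizes), pops)[1]))
  }
  samples[known] <- as.integer(sample_sizes[known])
  ids <- vapply(experiment$scenarios, function(s) as.character(s$id),
                character(1))
  compiled <- setNames(lapply(experiment$scenarios, compile_scenario,
                              experiment = experiment), ids)
  # map experiment population index -> stat-config population index
  cfg_map <- match(pops, config$populations)
  pairs0 <- if (length(config$pairs) > 0) {
    do.call(rbind, lapply(config$pairs, function(pr)
      match(pr, config$populations) - 1L))
  } else matrix(integer(0), 0, 2)
  mut <- experiment$mutation
  list(experiment = experiment, pops = pops, samples = samples,
       compiled = compiled, cfg_map = cfg_map, pairs0 = pairs0,
       n_cfg_pops = length(config$populations),
       names = stat_names(config),
       base_freq = mut$base_freq %||% rep(0.25, 4),
       p_invariant = mut$p_invariant, gamma_shape = mut$gamma_shape,
       length = length)
}

sim_stats_ctx <- function(ctx, scenario_id, seed, draw = NULL) {
  scen <- ctx$compiled[[as.character(scenario_id)]]
  if (is.null(scen)) abort(sprintf("unknown scenario id '%s'", scenario_id))
  if (is.null(draw)) {
    draw <- with_seed(derive_seed(seed, 1),
                      sample_parameters(
                        ctx$experiment$scenarios[[
                          match(as.character(scenario_id),
                                names(ctx$compiled))]],
                        ctx$experiment))
  }
  filled <- scen(draw)
  g <- cpp_simulate_genealogy(length(ctx$pops), filled$sizes, filled$events,
                              ctx$samples, as.numeric(derive_seed(seed, 2)))
  mseed <- derive_seed(seed, 3)
  rates <- with_seed(derive_seed(mseed, 101), {
    inv <- runif(ctx$length) < ctx$p_invariant
    r <- numeric(ctx$length)
    r[!inv] <- rgamma(sum(!inv), shape = ctx$gamma_shape,
                      scale = 1 / ctx$gamma_shape)
    r
  })
  m <- cpp_mutate(g$parent, g$time, g$n_leaves, rates, draw$rate,
                  draw$kappa, ctx$base_freq,
                  as.numeric(derive_seed(mseed, 102)))
  pop0 <- ctx$cfg_map[g$leaf_pop + 1L]
  keep <- !is.na(pop0)
  v <- cpp_summary_stats(m[keep, , drop = FALSE], pop0[keep] - 1L,
                         ctx$n_cfg_pops, ctx$pairs0)
  list(draw = draw, stats = setNames(as.numeric(v), ctx$names))
}

# fast path: same draws and seeds as simulate_dataset but keeps the coded
# matrix and goes straight to the C++ statistic panel
sim_stats_row <- function(scenario, experiment, sample_sizes, seed, length,
                          config, draw = NULL) {
  if (is.null(draw)) {
    draw <- with_seed(derive_seed(seed, 1),
                      sample_parameters(scenario, experiment))
  }
  g <- simulate_genealogy(scenario, experiment, draw, sample_sizes,
                          derive_seed(seed, 2))
  m <- mutate_codes(g, draw_mutation_model(experiment, draw), length,
                    derive_seed(seed, 3))
  leaf_pops <- g$population[!is.na(g$population)]
  stats <- stats_from_codes(m, leaf_pops, config)
  list(draw = draw, stats = stats)
}
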