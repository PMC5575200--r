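#' Default synthetic study design: three native sources, two introductions
#'
#' A study-shaped toy mirroring the structure of the worldwide barcode
#' analysis: three native populations joined by ancient divergences, and two
#' introduced populations founded from the first native population by
#' recent, strongly bottlenecked divergence (small effective size since
#' founding). Two scenarios differ in the source of the second introduced
#' population: from the native source directly, or as a secondary spread
#' (bridgehead) from the first introduced population.
#'
#' @param n_native,n_introduced Effective-size prior bounds are fixed by
#'   role: natives uniform on `[1000, 10000]`, introduced uniform on
#'   `[10, 500]` (the founder bottleneck).
#' @return An `abc_experiment` with scenarios `source` and `bridgehead`.
#' @export
synthetic_experiment <- function(n_native = 3, n_introduced = 2) {
  stopifnot(n_native == 3, n_introduced == 2) # fixed design
  pops <- tibble(
    name = c("NativeA", "NativeB", "NativeC", "Intro1", "Intro2"),
    role = c("native", "native", "native", "introduced", "introduced"))
  priors <- list(
    N_NativeA = list(dist = "uniform", min = 1000, max = 10000),
    N_NativeB = list(dist = "uniform", min = 1000, max = 10000),
    N_NativeC = list(dist = "uniform", min = 1000, max = 10000),
    N_Intro1 = list(dist = "uniform", min = 10, max = 500),
    N_Intro2 = list(dist = "uniform", min = 10, max = 500),
    t_intro1 = list(dist = "uniform", min = 10, max = 200),
    t_intro2 = list(dist = "uniform", min = 10, max = 200),
    t_nat1 = list(dist = "uniform", min = 5000, max = 20000),
    t_nat2 = list(dist = "uniform", min = 5000, max = 20000))
  base_events <- tibble(
    time = c("t_intro1", "t_nat1", "t_nat2"),
    kind = "merge",
    child = c("Intro1", "NativeB", "NativeC"),
    parent = c("NativeA", "NativeA", "NativeA"))
  conds <- c("t_intro1 < t_nat1", "t_intro2 < t_nat1", "t_nat1 < t_nat2",
             "N_Intro1 < min(N_NativeA, N_NativeB, N_NativeC)",
             "N_Intro2 < min(N_NativeA, N_NativeB, N_NativeC)")
  s1 <- abc_scenario(
    "source",
    dplyr::bind_rows(base_events,
                     tibble(time = "t_intro2", kind = "merge",
                            child = "Intro2", parent = "NativeA")),
    description = "both introductions directly from NativeA")
  s2 <- abc_scenario(
    "bridgehead",
    dplyr::bind_rows(base_events,
                     tibble(time = "t_intro2", kind = "merge",
                            child = "Intro2", parent = "Intro1")),
    conditions = "t_intro2 < t_intro1",
    description = "second introduction spreads from the first (bridgehead)")
  abc_experiment("synthetic_invasion", pops, priors, list(s1, s2),
                 conditions = conds,
                 sample_sizes = c(NativeA = 30, NativeB = 20, NativeC = 20,
                                  Intro1 = 25, Intro2 = 25))
}

#' Generate a synthetic study with known ground truth
#'
#' Simulates one dataset under a chosen scenario, writes per-population
#' FASTA files, a population map TSV and a JSON truth record (scenario id,
#' full parameter draw, seed, sample sizes) sufficient to regenerate the
#' dataset bit-exactly.
#'
#' @param scenario An `abc_scenario` (e.g. one of
#'   [synthetic_experiment()]'s).
#' @param experiment The owning `abc_experiment`.
#' @param sample_sizes Named integer vector; default the experiment's.
#' @param seed Integer seed.
#' @param length Alignment length (default 685).
#' @param dir Output directory (created if missing).
#' @param draw Optional fixed parameter draw (otherwise drawn from priors).
#' @return Invisibly, a list with `fasta` (named vector of paths), `map`
#'   (path), `truth` (path), `alignment` (tibble) and `truth_record`.
#' @export
generate_study <- function(scenario, experiment,
                           sample_sizes = experiment$sample_sizes,
                           seed = 1, length = 685,
                           dir = tempfile("synthstudy"), draw = NULL) {
  if (is.null(sample_sizes)) abort("sample_sizes are required")
  sim <- simulate_dataset(scenario, experiment, sample_sizes, seed,
                          length = length, draw = draw)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  pops <- unique(sim$alignment$population)
  fasta <- setNames(file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", pops),
                                          ".fasta")), pops)
  for (p in pops) {
    write_alignment_fasta(sim$alignment[sim$alignment$population == p, ],
                          fasta[[p]])
  }
  map <- file.path(dir, "population_map.tsv")
  write_population_map(sim$alignment, map)

  truth_record <- list(scenario = as.character(scenario$id),
                       draw = sim$draw, seed = seed,
                       sample_sizes = as.list(sample_sizes),
                       length = length)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_record, truth, auto_unbox = TRUE, digits = NA)

  invisible(list(fasta = fasta, map = map, truth = truth,
                 alignment = sim$alignment, truth_record = truth_record))
}

#' Randomised haplotype count table with the study's signature structure
#'
#' Emulates the shape of the worldwide table: native populations carry a
#' long tail of rare haplotypes, introduced populations are dominated by a
#' single founder haplotype with at most a few minor variants.
#'
#' @param seed Integer seed.
#' @param totals Named sample totals per population; names starting with
#'   `"Intro"` are treated as introduced. Defaults mirror the
#'   native-158/introduced-108 design of the real table.
#' @return A `haplotype_table`.
#' @export
table1_like_counts <- function(seed = 1,
                               totals = c(NativeA = 158, NativeB = 44,
                                          NativeC = 12, Intro1 = 108,
                                          Intro2 = 139)) {
  with_seed(seed, {
    pops <- names(totals)
    introduced <- grepl("^Intro", pops)
    rows <- list()
    n_haps <- 0L
    for (i in seq_along(pops)) {
      n <- totals[[i]]
      if (introduced[i]) {
        # one dominant founder haplotype, occasionally 1-2 rare variants
        k <- 1L + stats::rbinom(1, 2, 0.4)
        w <- c(1, rep(0.02, k - 1L))
      } else {
        # long tail: geometric-ish decay of haplotype frequencies
        k <- max(2L, stats::rpois(1, min(20, n / 6)))
        w <- 0.5^(seq_len(k) - 1) + 0.01
      }
      cnt <- drop(stats::rmultinom(1, n, w))
      keep <- cnt > 0
      labels <- paste0("H", n_haps + seq_len(sum(keep)))
      n_haps <- n_haps + sum(keep)
      rows[[i]] <- tibble(population = pops[i], haplotype = labels,
                          count = as.integer(cnt[keep]))
    }
    counts <- dplyr::bind_rows(rows)
    labels <- unique(counts$haplotype)
    new_haplotype_table(
      counts,
      tibble(haplotype = labels,
             sequence = synthetic_haplotype_sequences(labels, length = 685L)))
  })
}
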