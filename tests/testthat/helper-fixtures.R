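# Shared fixture builders: everything is generated in code at test time.

toy_alignment <- function(seqs, populations = "P", ids = NULL) {
  n <- length(seqs)
  if (length(populations) == 1) populations <- rep(populations, n)
  tibble::tibble(id = ids %||% paste0("s", seq_len(n)),
                 population = populations, sequence = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_fasta <- function(seqs, ids = paste0("s", seq_along(seqs)),
                            path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_toy_map <- function(ids, populations,
                          path = tempfile(fileext = ".tsv")) {
  writeLines(c("id\tpopulation", paste(ids, populations, sep = "\t")), path)
  path
}

# random clean alignment (A/C/G/T only) for property tests
random_alignment <- function(n, L, n_pops = 1, seed = 1) {
  withr::with_seed(seed, {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
    toy_alignment(seqs, populations = paste0("P",
                                             sample(n_pops, n, replace = TRUE)))
  })
}

# One-population experiment with a fixed haploid size and no events; used
# for analytic coalescent checks.
one_pop_experiment <- function(N = 500) {
  abcroutes::abc_experiment(
    "one_pop",
    tibble::tibble(name = "P", role = "native", size = as.character(N)),
    priors = list(),
    scenarios = list(
      abcroutes::abc_scenario(
        "only", tibble::tibble(time = character(0), kind = character(0),
                               child = character(0), parent = character(0)))))
}

# Two-population experiment with a merge at a fixed split time.
split_experiment <- function(N = 500, t_split = 200) {
  abcroutes::abc_experiment(
    "split",
    tibble::tibble(name = c("A", "B"), role = c("native", "introduced"),
                   size = as.character(c(N, N))),
    priors = list(),
    scenarios = list(
      abcroutes::abc_scenario(
        "split",
        tibble::tibble(time = as.character(t_split), kind = "merge",
                       child = "B", parent = "A")),
      abcroutes::abc_scenario(
        "split2",
        tibble::tibble(time = as.character(2 * t_split), kind = "merge",
                       child = "B", parent = "A"))))
}

# Well-separated two-scenario toy: the scenarios differ only in the
# introduced population's effective size (tiny founder population vs large),
# which strongly shifts the introduced population's diversity.
separable_experiment <- function() {
  pops <- tibble::tibble(name = c("Native", "Intro"),
                         role = c("native", "introduced"))
  priors <- list(
    N_Native = list(dist = "uniform", min = 4000, max = 8000),
    N_Intro = list(dist = "uniform", min = 10, max = 10000),
    t_intro = list(dist = "uniform", min = 50, max = 200))
  ev <- tibble::tibble(time = "t_intro", kind = "merge", child = "Intro",
                       parent = "Native")
  abcroutes::abc_experiment(
    "separable", pops, priors,
    scenarios = list(
      abcroutes::abc_scenario("bottleneck", ev,
                              conditions = "N_Intro < 100"),
      abcroutes::abc_scenario("large", ev,
                              conditions = "N_Intro > 4000")))
}

# Two literally identical scenarios (posterior symmetry checks).
twin_experiment <- function() {
  pops <- tibble::tibble(name = c("Native", "Intro"),
                         role = c("native", "introduced"))
  priors <- list(
    N_Native = list(dist = "uniform", min = 1000, max = 5000),
    N_Intro = list(dist = "uniform", min = 50, max = 500),
    t_intro = list(dist = "uniform", min = 50, max = 200))
  ev <- tibble::tibble(time = "t_intro", kind = "merge", child = "Intro",
                       parent = "Native")
  abcroutes::abc_experiment(
    "twins", pops, priors,
    scenarios = list(abcroutes::abc_scenario("twin1", ev),
                     abcroutes::abc_scenario("twin2", ev)))
}

# hand genealogy: k leaves all joined to a root at time t_root (star tree);
# with k = 2 the branch pair has total length 2 t_root
star_genealogy <- function(k, t_root, pop = "P") {
  lab <- c(paste0(pop, "_", seq_len(k)), NA_character_)
  tibble::tibble(
    node = seq_len(k + 1),
    parent = c(rep(k + 1L, k), NA_integer_),
    time = c(rep(0, k), t_root),
    population = c(rep(pop, k), NA_character_),
    label = lab)
}
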