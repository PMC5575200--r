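test_that("structural validation flags rootless and underspecified scenarios", {
  one <- one_pop_experiment()
  expect_equal(nrow(validate_scenario(one$scenarios[[1]], one)), 0)

  # two populations, no merge event -> no common root
  two <- abc_experiment(
    "two", tibble::tibble(name = c("A", "B"), role = c("native", "native"),
                          size = c("100", "100")),
    priors = list(),
    scenarios = list(abc_scenario(
      "none", tibble::tibble(time = character(0), kind = character(0),
                             child = character(0), parent = character(0)))))
  d <- validate_scenario(two$scenarios[[1]], two)
  expect_true("no_common_root" %in% d$check)

  # parameter without a prior
  ex <- separable_experiment()
  broken <- ex
  broken$priors$t_intro <- NULL
  d2 <- validate_scenario(broken$scenarios[[1]], broken)
  expect_true("missing_prior" %in% d2$check)

  # event naming an unknown population
  bad <- abc_scenario("bad", tibble::tibble(
    time = "t_intro", kind = "merge", child = "Intro", parent = "Mars"))
  d3 <- validate_scenario(bad, ex)
  expect_true("unknown_population" %in% d3$check)
})

test_that("every packaged worldwide experiment is structurally valid", {
  names <- table2_experiments()
  expect_length(names, 11)
  scenario_counts <- c(
    california = 7, canada_admixture = 4, canada_source = 3,
    emilia_romagna = 3, europe_bridgehead = 3, europe_source = 3,
    greece_hungary = 3, greece_source = 3, nw_us_admixture = 3,
    nw_us_source = 3, pre2008_us_source = 3)
  for (nm in names) {
    ex <- table2_experiments(nm)
    expect_length(ex$scenarios, unname(scenario_counts[nm]))
    expect_equal(nrow(validate_experiment(ex, n_draw_checks = 2)), 0,
                 label = nm)
  }
})

test_that("parameter draws respect prior bounds and all conditions", {
  ex <- synthetic_experiment()
  s <- ex$scenarios[[1]]
  draws <- withr::with_seed(5, lapply(1:300, function(i)
    sample_parameters(s, ex)))
  mr <- vapply(draws, `[[`, numeric(1), "mean_rate")
  expect_true(all(mr >= 1e-7 & mr <= 1e-5))
  mk <- vapply(draws, `[[`, numeric(1), "mean_kappa")
  expect_true(all(mk >= 1.5 & mk <= 20))
  for (d in draws) {
    expect_lt(d$N_Intro1, min(d$N_NativeA, d$N_NativeB, d$N_NativeC))
    expect_lt(d$t_intro1, d$t_nat1)
    expect_lt(d$t_nat1, d$t_nat2)
  }
})

test_that("per-locus rates are gamma around the drawn mean", {
  ex <- separable_experiment()
  n <- 4000
  draws <- withr::with_seed(11, lapply(seq_len(n), function(i)
    sample_parameters(ex$scenarios[[2]], ex)))
  rate <- vapply(draws, `[[`, numeric(1), "rate")
  mean_rate <- vapply(draws, `[[`, numeric(1), "mean_rate")
  # E[rate | mean] = mean, so the overall means agree (Monte-Carlo, 3 SE)
  se <- sd(rate - mean_rate) / sqrt(n)
  expect_lt(abs(mean(rate) - mean(mean_rate)), 3 * se)
  # conditional CV of a gamma(shape 2) is 1/sqrt(2)
  cv <- sd(rate / mean_rate) / mean(rate / mean_rate)
  expect_lt(abs(cv - 1 / sqrt(2)), 0.05)
})

test_that("unconditioned marginals match their priors (KS at alpha = 0.001)", {
  ex <- separable_experiment()
  # t_intro and N_Native are unconstrained by the scenario's size condition
  draws <- withr::with_seed(23, lapply(1:10000, function(i)
    sample_parameters(ex$scenarios[[2]], ex)))
  t_intro <- vapply(draws, `[[`, numeric(1), "t_intro")
  ks1 <- stats::ks.test(t_intro, "punif", 50, 200)
  expect_gt(ks1$p.value, 0.001)
  n_native <- vapply(draws, `[[`, numeric(1), "N_Native")
  ks2 <- stats::ks.test(n_native, "punif", 4000, 8000)
  expect_gt(ks2$p.value, 0.001)
  mr <- vapply(draws, `[[`, numeric(1), "mean_rate")
  ks3 <- stats::ks.test(mr, "punif", 1e-7, 1e-5)
  expect_gt(ks3$p.value, 0.001)
})

test_that("draws are reproducible under a fixed seed and reject impossible conditions", {
  ex <- separable_experiment()
  d1 <- withr::with_seed(7, sample_parameters(ex$scenarios[[1]], ex))
  d2 <- withr::with_seed(7, sample_parameters(ex$scenarios[[1]], ex))
  expect_identical(d1, d2)

  impossible <- abc_scenario(
    "imp", tibble::tibble(time = "t_intro", kind = "merge",
                          child = "Intro", parent = "Native"),
    conditions = "N_Intro > 20000") # outside the prior support
  expect_error(withr::with_seed(1, sample_parameters(impossible, ex,
                                                     max_rejections = 200)),
               "rejections")
})

test_that("YAML configs round-trip through the constructor", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "experiment: toy",
    "populations:",
    "  - {name: A, role: native}",
    "  - {name: B, role: introduced}",
    "priors:",
    "  N_A: {dist: uniform, min: 10, max: 100}",
    "  N_B: {dist: uniform, min: 10, max: 100}",
    "  t0: {dist: uniform, min: 5, max: 50}",
    "conditions: [\"N_B < N_A\"]",
    "sample_sizes: {A: 4, B: 4}",
    "scenarios:",
    "  - id: 1",
    "    description: simple",
    "    events:",
    "      - {time: t0, kind: merge, child: B, parent: A}",
    "  - id: 2",
    "    description: admixed-free twin",
    "    events:",
    "      - {time: t0, kind: merge, child: B, parent: A}"), path)
  ex <- read_scenario_config(path)
  expect_s3_class(ex, "abc_experiment")
  expect_equal(ex$populations$size, c("N_A", "N_B"))
  expect_equal(nrow(validate_experiment(ex)), 0)
  expect_error(read_scenario_config(tempfile()), "not found")
})
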