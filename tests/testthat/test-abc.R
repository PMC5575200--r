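test_that("scenarios are drawn with equal weight and tables are reproducible", {
  ex <- three_scenario_experiment()
  sizes <- c(Native = 4, Intro = 4)
  ref <- build_reference_table(ex, sizes, n_rows = 1000, seed = 2,
                               length = 60)
  counts <- table(ref$scenario)
  expect_length(counts, 3)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)

  ref2 <- build_reference_table(ex, sizes, n_rows = 40, seed = 2, length = 60)
  expect_identical(ref$stats[1:40, ], ref2$stats)
  expect_identical(ref$params[1:40, ], ref2$params)
  expect_identical(ref$scenario[1:40], ref2$scenario)

  # the full-scale default is one million rows
  expect_equal(eval(formals(build_reference_table)$n_rows), 1e6)
})

test_that("rejection retains the closest rows, matching a full-sort oracle", {
  ex <- twin_experiment()
  sizes <- c(Native = 5, Intro = 5)
  ref <- build_reference_table(ex, sizes, n_rows = 300, seed = 9, length = 80)
  observed <- ref$stats[17, ] # a known row: must come back at distance 0

  rej <- rejection_select(ref, observed, tolerance = 0.05)
  expect_equal(nrow(rej$retained), ceiling(0.05 * 300))
  expect_true(17 %in% rej$retained$row)
  expect_equal(min(rej$retained$distance), 0)

  # brute-force oracle: impute, standardise, sort all distances
  stats <- ref$stats
  mu <- colMeans(stats, na.rm = TRUE)
  for (j in seq_len(ncol(stats))) stats[is.na(stats[, j]), j] <- mu[j]
  obs <- observed; obs[is.na(obs)] <- mu[is.na(obs)]
  sdv <- apply(stats, 2, sd)
  keep <- sdv > 0
  z <- sweep(sweep(stats[, keep], 2, mu[keep]), 2, sdv[keep], "/")
  zo <- (obs[keep] - mu[keep]) / sdv[keep]
  d <- sqrt(rowSums(sweep(z, 2, zo)^2))
  oracle_idx <- order(d, seq_along(d))[seq_len(ceiling(0.05 * 300))]
  expect_setequal(rej$retained$row, oracle_idx)

  # tolerance 1 retains everything
  expect_equal(nrow(rejection_select(ref, observed, 1)$retained), 300)
})

test_that("zero-variance statistics are dropped from the distance with a warning", {
  fake <- list(stats = cbind(a = rep(1, 50), b = rnorm(50)),
               scenario = rep(c("x", "y"), 25))
  expect_warning(rejection_select(fake, c(a = 1, b = 0), tolerance = 0.1),
                 "zero-variance")
})

test_that("direct posteriors are retained-set proportions with binomial CIs", {
  y <- factor(rep(c("A", "B"), c(30, 10)), levels = c("A", "B"))
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("s1", "s2")))
  rej <- fake_rejection(y, X)
  post <- estimate_posteriors(rej, method = "direct")
  expect_equal(post$prob, c(0.75, 0.25))
  expect_equal(sum(post$prob), 1)
  ciA <- stats::binom.test(30, 40)$conf.int
  expect_equal(post$ci_low[1], ciA[1])
  expect_equal(post$ci_high[1], ciA[2])
  expect_true(all(post$ci_low <= post$prob & post$prob <= post$ci_high))

  # single represented scenario -> probability 1 for it
  y1 <- factor(rep("A", 20), levels = c("A", "B"))
  p1 <- estimate_posteriors(fake_rejection(y1, X[1:20, , drop = FALSE],
                                           ids = c("A", "B")),
                            method = "direct")
  expect_equal(p1$prob, c(1, 0))
})

test_that("logistic posteriors match an independent likelihood maximisation", {
  set.seed(31)
  n <- 90
  y <- factor(rep(c("A", "B", "C"), each = n / 3))
  mu <- rbind(c(0, 0), c(1.2, 0.4), c(-0.6, 1.0))
  X <- t(vapply(seq_len(n), function(i)
    rnorm(2, mu[as.integer(y[i]), ], 1), numeric(2)))
  colnames(X) <- c("u", "v")

  post <- estimate_posteriors(fake_rejection(y, X), method = "logistic")
  oracle <- oracle_multinom_probs(y, X)
  expect_equal(post$prob, unname(oracle[post$scenario]), tolerance = 1e-4)
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  expect_true(all(post$ci_low <= post$prob + 1e-12 &
                  post$prob <= post$ci_high + 1e-12))
  expect_true(all(post$ci_low >= 0 & post$ci_high <= 1))
})

test_that("identical twin scenarios split the posterior evenly", {
  ex <- twin_experiment()
  sizes <- c(Native = 10, Intro = 10)
  ref <- build_reference_table(ex, sizes, n_rows = 1500, seed = 4,
                               length = 150)
  obs <- simulate_dataset(ex$scenarios[[1]], ex, sizes, seed = 1234,
                          length = 150)
  ov <- compute_summary_vector(obs$alignment, ref$config)
  rej <- rejection_select(ref, ov, tolerance = 0.4)
  for (m in c("direct", "logistic")) {
    post <- estimate_posteriors(rej, method = m)
    expect_lt(abs(post$prob[1] - 0.5), if (m == "direct") 0.15 else 0.2)
    expect_true(post$ci_low[1] <= 0.5 + 0.1 && post$ci_high[1] >= 0.5 - 0.1)
  }
})

test_that("the PCA pre-evaluation flags only genuinely extreme observations", {
  ex <- twin_experiment()
  ref <- build_reference_table(ex, c(Native = 10, Intro = 10), n_rows = 400,
                               seed = 6, length = 150)
  center <- colMeans(ref$stats, na.rm = TRUE)
  chk <- prior_scenario_check(ref, center)
  expect_true(chk$inside)
  expect_true(all(chk$stats$q >= 0 & chk$stats$q <= 1))
  expect_false(any(chk$stats$stars == "***"))

  extreme <- center
  extreme["pi_Native"] <- max(ref$stats[, "pi_Native"], na.rm = TRUE) * 10
  chk2 <- prior_scenario_check(ref, extreme)
  expect_equal(chk2$stats$stars[chk2$stats$stat == "pi_Native"], "***")
})

test_that("posterior-based confidence is a reclassification rate in [0, 1]", {
  ex <- twin_experiment()
  sizes <- c(Native = 8, Intro = 8)
  ref <- build_reference_table(ex, sizes, n_rows = 400, seed = 12,
                               length = 100)
  obs <- simulate_dataset(ex$scenarios[[1]], ex, sizes, seed = 555,
                          length = 100)
  ov <- compute_summary_vector(obs$alignment, ref$config)
  rej <- rejection_select(ref, ov, tolerance = 0.1)
  post <- estimate_posteriors(rej, method = "direct")
  conf <- scenario_confidence(post, n_pods = 40, seed = 3)
  expect_gte(as.numeric(conf), 0)
  expect_lte(as.numeric(conf), 1)
  # twins are indistinguishable: confidence should hover near one half
  expect_lt(abs(as.numeric(conf) - 0.5), 0.3)
  expect_length(attr(conf, "assignments"), 40)
})

test_that("tidy, glance and autoplot work on posterior objects", {
  y <- factor(rep(c("A", "B"), c(12, 8)))
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("s1", "s2")))
  post <- estimate_posteriors(fake_rejection(y, X), method = "direct")
  td <- tidy(post)
  expect_named(td, c("scenario", "prob", "ci_low", "ci_high"))
  gl <- glance(post)
  expect_equal(gl$selected, "A")
  expect_equal(gl$n_retained, 20)
  p <- autoplot(post)
  expect_s3_class(p, "ggplot")
})
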