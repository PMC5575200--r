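#' Build a reference table of pseudo-observed datasets
#'
#' Each row: a scenario drawn with equal weight, one parameter draw from the
#' priors (respecting the scenario's conditions), one simulated dataset, one
#' summary-statistic vector. Per-row seeds are split deterministically from
#' the master seed, so the table is reproducible and independent of
#' evaluation order or worker count.
#'
#' @param experiment An `abc_experiment`.
#' @param sample_sizes Named integer vector of sampled lineages per
#'   population (typically the observed sample sizes).
#' @param n_rows Number of rows; the full-scale default is 1e6, tests use
#'   far fewer.
#' @param seed Integer master seed.
#' @param length Alignment length (default 685).
#' @param config Optional [stat_config()]; default: all sampled populations
#'   in experiment order, all pairs.
#' @return A `reference_table` object.
#' @export
build_reference_table <- function(experiment, sample_sizes, n_rows = 1e6,
                                  seed = 1, length = 685, config = NULL) {
  stopifnot(n_rows >= 1)
  if (length(experiment$scenarios) < 2) {
    abort("at least two scenarios are required")
  }
  if (is.null(config)) {
    sampled <- intersect(experiment$populations$name,
                         names(sample_sizes)[sample_sizes > 0])
    config <- stat_config(sampled)
  }
  ids <- vapply(experiment$scenarios, function(s) as.character(s$id),
                character(1))
  scen_of_row <- with_seed(derive_seed(seed, 0),
                           sample(ids, n_rows, replace = TRUE))

  all_params <- unique(c(
    unlist(lapply(experiment$scenarios, scenario_params,
                  experiment = experiment)),
    c("mean_rate", "rate", "mean_kappa", "kappa")))
  params <- matrix(NA_real_, n_rows, length(all_params),
                   dimnames = list(NULL, all_params))
  stats <- matrix(NA_real_, n_rows, length(stat_names(config)),
                  dimnames = list(NULL, stat_names(config)))

  ctx <- make_sim_context(experiment, sample_sizes, config, length)
  for (i in seq_len(n_rows)) {
    row <- tryCatch(
      sim_stats_ctx(ctx, scen_of_row[i], derive_seed(seed, i)),
      error = function(e) {
        abort(sprintf("simulation failed at reference-table row %d (scenario %s): %s",
                      i, scen_of_row[i], conditionMessage(e)))
      })
    params[i, names(row$draw)] <- unlist(row$draw)
    stats[i, ] <- row$stats
  }

  structure(list(scenario = scen_of_row, params = params, stats = stats,
                 config = config, experiment = experiment,
                 sample_sizes = sample_sizes, length = length, seed = seed),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("<reference_table: %d rows, %d scenarios, %d statistics>\n",
              length(x$scenario), length(unique(x$scenario)),
              ncol(x$stats)))
  invisible(x)
}

#' @export
tidy.reference_table <- function(x, ...) {
  dplyr::bind_cols(tibble(row = seq_along(x$scenario), scenario = x$scenario),
                   as_tibble(x$params), as_tibble(x$stats))
}

#' Write a reference table to CSV
#'
#' @param table A `reference_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(table, path) {
  readr::write_csv(tidy(table), path)
  invisible(path)
}

# column-mean imputation + standardisation against reference moments;
# returns list(ref_std, obs_std, dropped)
standardize_against <- function(ref_stats, observed) {
  mu <- colMeans(ref_stats, na.rm = TRUE)
  for (j in seq_len(ncol(ref_stats))) {
    nas <- is.na(ref_stats[, j])
    if (any(nas)) ref_stats[nas, j] <- mu[j]
  }
  obs <- observed[colnames(ref_stats)]
  obs[is.na(obs)] <- mu[is.na(obs)]
  sdv <- apply(ref_stats, 2, sd)
  keep <- is.finite(sdv) & sdv > 0
  if (!all(keep)) {
    warn(sprintf("dropping zero-variance statistic(s) from the distance: %s",
                 paste(colnames(ref_stats)[!keep], collapse = ", ")))
  }
  ref_std <- sweep(sweep(ref_stats[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sdv[keep], "/")
  obs_std <- (obs[keep] - mu[keep]) / sdv[keep]
  list(ref_std = ref_std, obs_std = obs_std, dropped = colnames(ref_stats)[!keep])
}

#' Rejection step: retain the simulations closest to the observed data
#'
#' Statistics are imputed (column mean) and standardised by the
#' reference-table mean and standard deviation; the Euclidean distance to
#' the standardised observed vector is computed and the closest
#' `ceiling(tolerance * n)` rows are retained, ties broken by row index.
#'
#' @param table A `reference_table`.
#' @param observed Named summary-statistic vector of the observed data
#'   (from [compute_summary_vector()] with the same [stat_config()]).
#' @param tolerance Retained fraction in (0, 1]; the default 0.01 keeps the
#'   closest 1%.
#' @return An `abc_rejection` object: tibble of retained rows (`row`,
#'   `scenario`, `distance`) plus standardised coordinates.
#' @export
rejection_select <- function(table, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  std <- standardize_against(table$stats, observed)
  dist2 <- rowSums(sweep(std$ref_std, 2, std$obs_std)^2)
  n_keep <- ceiling(tolerance * length(dist2))
  ord <- order(dist2, seq_along(dist2))
  idx <- ord[seq_len(n_keep)]
  structure(list(
    retained = tibble(row = idx, scenario = table$scenario[idx],
                      distance = sqrt(dist2[idx])),
    retained_std = std$ref_std[idx, , drop = FALSE],
    observed_std = std$obs_std,
    dropped = std$dropped,
    tolerance = tolerance,
    table = table),
    class = "abc_rejection")
}

#' @export
print.abc_rejection <- function(x, ...) {
  cat(sprintf("<abc_rejection: %d of %d rows retained (tolerance %g)>\n",
              nrow(x$retained), length(x$table$scenario), x$tolerance))
  print(table(x$retained$scenario))
  invisible(x)
}

#' Estimate scenario posterior probabilities from the retained set
#'
#' `method = "direct"`: retained-set scenario proportions with exact
#' binomial (Clopper-Pearson) 95% intervals. `method = "logistic"`
#' (default, the estimate reported in the result tables): multinomial
#' logistic regression of the scenario id on the standardised statistics
#' centred at the observed point, evaluated at the observed point, with
#' intervals by the delta method on the fitted coefficients. Complete
#' separation triggers a ridge-regularised refit, flagged in the
#' diagnostics.
#'
#' @param rejection An `abc_rejection`.
#' @param method `"logistic"` or `"direct"`.
#' @param level Credible level for the intervals (default 0.95).
#' @return A `scenario_posterior`: tibble (`scenario`, `prob`, `ci_low`,
#'   `ci_high`) with attributes `selected`, `method`, `diagnostics`.
#' @export
estimate_posteriors <- function(rejection, method = c("logistic", "direct"),
                                level = 0.95) {
  method <- match.arg(method)
  ids <- vapply(rejection$table$experiment$scenarios,
                function(s) as.character(s$id), character(1))
  scen <- factor(rejection$retained$scenario, levels = ids)
  diagnostics <- list()

  if (method == "direct" || length(unique(rejection$retained$scenario)) < 2) {
    if (method == "logistic") {
      diagnostics$fallback <- "single scenario retained; direct estimate used"
      method <- "direct"
    }
    n <- length(scen)
    counts <- table(scen)
    res <- lapply(ids, function(k) {
      x <- as.integer(counts[[k]])
      ci <- stats::binom.test(x, n, conf.level = level)$conf.int
      tibble(scenario = k, prob = x / n, ci_low = ci[1], ci_high = ci[2])
    })
    out <- dplyr::bind_rows(res)
  } else {
    X <- sweep(rejection$retained_std, 2, rejection$observed_std)
    colnames(X) <- paste0("s", seq_len(ncol(X))) # syntactic names for the fit
    present <- levels(droplevels(scen))
    y <- droplevels(scen)
    fit <- fit_multinom(y, X, diagnostics)
    diagnostics <- fit$diagnostics
    est <- multinom_point_ci(fit$fit, level = level)
    out <- tibble(scenario = ids,
                  prob = 0, ci_low = 0, ci_high = 0)
    m <- match(present, ids)
    out$prob[m] <- est$prob
    out$ci_low[m] <- est$lo
    out$ci_high[m] <- est$hi
    if (length(present) < length(ids)) {
      diagnostics$absent <- setdiff(ids, present)
    }
    out$prob <- out$prob / sum(out$prob)
  }

  structure(out, class = c("scenario_posterior", class(out)),
            selected = out$scenario[which.max(out$prob)],
            method = method, level = level,
            diagnostics = diagnostics, rejection = rejection)
}

fit_multinom <- function(y, X, diagnostics) {
  dat <- data.frame(y = y, X)
  form <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = 1000, reltol = 1e-13)
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || max(abs(co)) > 20) {
    # near-separation: ridge-regularised refit
    fit <- nnet::multinom(form, data = dat, Hess = TRUE, trace = FALSE,
                          maxit = 1000, reltol = 1e-13, decay = 0.01)
    diagnostics$regularized <- TRUE
  }
  list(fit = fit, diagnostics = diagnostics)
}

# point estimate and delta-method CI of the class probabilities at x = 0
multinom_point_ci <- function(fit, level = 0.95) {
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(NULL, names(cf)))
  K <- nrow(cf) + 1
  eta <- c(0, cf[, "(Intercept)"])
  p <- exp(eta - max(eta))
  p <- p / sum(p)

  se <- rep(NA_real_, K)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(V)) {
    # intercept entries, in class order 2..K
    int_idx <- grep("\\(Intercept\\)$", rownames(V))
    Vi <- V[int_idx, int_idx, drop = FALSE]
    for (k in seq_len(K)) {
      # dp_k / d eta_j for j = 2..K
      g <- vapply(2:K, function(j) p[k] * ((k == j) - p[j]), numeric(1))
      se[k] <- sqrt(max(0, t(g) %*% Vi %*% g))
    }
  }
  z <- qnorm(1 - (1 - level) / 2)
  list(prob = p,
       lo = pmax(0, p - z * se),
       hi = pmin(1, p + z * se))
}

#' @export
print.scenario_posterior <- function(x, ...) {
  cat(sprintf("<scenario_posterior (%s)> selected: %s\n",
              attr(x, "method"), attr(x, "selected")))
  NextMethod()
}

#' @export
tidy.scenario_posterior <- function(x, ...) {
  as_tibble(unclass(x)[c("scenario", "prob", "ci_low", "ci_high")])
}

#' @export
glance.scenario_posterior <- function(x, ...) {
  tibble(selected = attr(x, "selected"),
         prob = max(x$prob),
         method = attr(x, "method"),
         confidence = attr(x, "confidence") %||% NA_real_,
         n_retained = nrow(attr(x, "rejection")$retained))
}

#' @export
autoplot.scenario_posterior <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = "scenario", y = "posterior probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Prior/scenario pre-evaluation against the observed data
#'
#' Fits a PCA to the standardised reference-table statistics, projects the
#' observed vector, and reports (a) whether the observed point lies within
#' the central empirical `[0.5%, 99.5%]` box of each leading component and
#' (b) for every statistic the tail probability `q` = fraction of simulated
#' values below the observed value, starred at two-sided 5% (`*`), 1%
#' (`**`) and 0.1% (`***`). Many three-star statistics indicate
#' scenario/prior combinations unable to reproduce the data.
#'
#' @param table A `reference_table`.
#' @param observed Named observed summary-statistic vector.
#' @param n_pca Number of leading components to check.
#' @return An `abc_prior_check`: list with `components` and `stats` tibbles
#'   and overall flag `inside`.
#' @export
prior_scenario_check <- function(table, observed, n_pca = 2) {
  std <- standardize_against(table$stats, observed)
  pca <- prcomp(std$ref_std, center = FALSE, scale. = FALSE)
  n_pca <- min(n_pca, ncol(pca$x))
  proj <- drop(matrix(std$obs_std, 1) %*% pca$rotation[, seq_len(n_pca),
                                                       drop = FALSE])
  comp <- lapply(seq_len(n_pca), function(k) {
    qs <- quantile(pca$x[, k], c(0.005, 0.995), names = FALSE)
    tibble(component = paste0("PC", k), coord = proj[k],
           lo = qs[1], hi = qs[2],
           inside = proj[k] >= qs[1] & proj[k] <= qs[2])
  })

  mu <- colMeans(table$stats, na.rm = TRUE)
  stats <- lapply(colnames(table$stats), function(s) {
    x <- table$stats[, s]
    x[is.na(x)] <- mu[s]
    o <- observed[[s]]
    if (is.na(o)) o <- mu[s]
    q <- mean(x < o) + 0.5 * mean(x == o) # mid-p for ties
    stars <- if (q < 0.0005 || q > 0.9995) "***"
             else if (q < 0.005 || q > 0.995) "**"
             else if (q < 0.025 || q > 0.975) "*"
             else ""
    tibble(stat = s, observed = o, q = q, stars = stars)
  })

  structure(list(components = dplyr::bind_rows(comp),
                 stats = dplyr::bind_rows(stats),
                 inside = all(vapply(comp, function(d) d$inside, logical(1)))),
            class = "abc_prior_check")
}

#' @export
print.abc_prior_check <- function(x, ...) {
  cat(sprintf("<abc_prior_check: observed %s the central PCA cloud; %d starred statistic(s)>\n",
              if (x$inside) "inside" else "OUTSIDE",
              sum(x$stats$stars != "")))
  print(x$components)
  print(x$stats[x$stats$stars != "", ])
  invisible(x)
}

#' Posterior-based confidence in scenario choice
#'
#' Simulates `n_pods` datasets from the selected scenario with parameters
#' resampled from its retained (posterior) draws, re-runs the full
#' rejection + posterior classification on each against the same reference
#' table, and reports the fraction assigned back to the selected scenario
#' (a posterior-predictive reclassification rate).
#'
#' @param posterior A `scenario_posterior`.
#' @param n_pods Number of posterior pseudo-observed datasets (default 500).
#' @param seed Integer seed.
#' @param method Classification method for the re-runs; defaults to the
#'   posterior's own method.
#' @return The confidence value in `[0, 1]`, with the per-POD assignments
#'   as attribute `assignments`.
#' @export
scenario_confidence <- function(posterior, n_pods = 500, seed = 1,
                                method = NULL) {
  stopifnot(n_pods >= 1)
  rej <- attr(posterior, "rejection")
  ref <- rej$table
  sel <- attr(posterior, "selected")
  method <- method %||% attr(posterior, "method")

  rows <- rej$retained$row[rej$retained$scenario == sel]
  if (length(rows) == 0) {
    abort("no retained draws for the selected scenario")
  }
  ctx <- make_sim_context(ref$experiment, ref$sample_sizes, ref$config,
                          ref$length)

  pick <- with_seed(derive_seed(seed, 0),
                    sample(rows, n_pods, replace = TRUE))
  assigned <- character(n_pods)
  for (i in seq_len(n_pods)) {
    pr <- ref$params[pick[i], ]
    draw <- as.list(pr[!is.na(pr)])
    row <- sim_stats_ctx(ctx, sel, derive_seed(seed, i), draw = draw)
    r <- suppressWarnings(rejection_select(ref, row$stats, rej$tolerance))
    p <- estimate_posteriors(r, method = method)
    assigned[i] <- attr(p, "selected")
  }
  structure(mean(assigned == sel), assignments = assigned)
}
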