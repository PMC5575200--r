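# Independent test oracles shared across test files: brute-force
# enumerations, closed forms and separately coded likelihood fits that
# never call the package paths they check.

# occupancy probability P(exactly j sites hit | K uniform hits on m sites)
# from the Stirling-number formula, in log space (independent arithmetic
# from the package's forward Markov-chain DP)
occupancy_stirling <- function(K, j, m) {
  if (j > K || j > m) return(0)
  # log S2(n, k) triangle
  logS <- matrix(-Inf, K + 1, j + 1)
  logS[1, 1] <- 0 # S2(0,0) = 1
  for (n in 1:K) {
    for (k in 1:min(n, j)) {
      a <- log(k) + logS[n, k + 1]
      b <- logS[n, k]
      logS[n + 1, k + 1] <- max(a, b) + log1p(exp(-abs(a - b)))
      if (!is.finite(a) && !is.finite(b)) logS[n + 1, k + 1] <- -Inf
    }
  }
  exp(lchoose(m, j) + lfactorial(j) + logS[K + 1, j + 1] - K * log(m))
}

oracle_parsimony_probability <- function(j, m, k_window = 200L) {
  terms <- vapply(j:(j + k_window), occupancy_stirling, numeric(1),
                  j = j, m = m)
  terms[1] / sum(terms)
}

oracle_parsimony_limit <- function(m, confidence = 0.95) {
  j <- 0L
  while (j < m && oracle_parsimony_probability(j + 1L, m) >= confidence) {
    j <- j + 1L
  }
  j
}

# brute-force per-site comparison for the step matrix
oracle_steps <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  d <- 0L
  for (s in seq_along(a)) {
    if (a[s] %in% c("N", "-") || b[s] %in% c("N", "-")) next
    if (a[s] != b[s]) d <- d + 1L
  }
  d
}

# union of all minimum spanning trees by exhaustive Pruefer enumeration
oracle_msn_edges <- function(steps) {
  h <- nrow(steps)
  labs <- rownames(steps)
  if (h == 2) return(data.frame(a = min(labs), b = max(labs)))
  pruefer <- expand.grid(rep(list(seq_len(h)), h - 2))
  decode <- function(code) {
    degree <- rep(1L, h)
    for (x in code) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, h - 1, 2)
    code <- as.integer(code)
    for (i in seq_along(code)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, code[i])
      degree[leaf] <- 0L
      degree[code[i]] <- degree[code[i]] - 1L
    }
    edges[h - 1, ] <- which(degree == 1L)
    edges
  }
  trees <- lapply(seq_len(nrow(pruefer)), function(r)
    decode(unlist(pruefer[r, ], use.names = FALSE)))
  wt <- vapply(trees, function(e) sum(steps[e]), numeric(1))
  best <- trees[abs(wt - min(wt)) < 1e-9]
  all_edges <- unique(do.call(rbind, lapply(best, function(e) {
    t(apply(e, 1, sort))
  })))
  data.frame(a = labs[all_edges[, 1]], b = labs[all_edges[, 2]])
}

# observed-to-observed connections implied by a built network (direct
# edges plus paths through labelled intermediates)
network_connections <- function(net) {
  ed <- net$edges
  inter <- grepl("^i\\.", ed$from) | grepl("^i\\.", ed$to)
  direct <- ed[!inter, c("from", "to")]
  mids <- unique(c(ed$from, ed$to))
  mids <- mids[grepl("^i\\.", mids)]
  via <- unique(do.call(rbind, lapply(mids, function(mid) {
    parts <- strsplit(mid, ".", fixed = TRUE)[[1]]
    data.frame(from = parts[2], to = parts[3])
  })))
  out <- rbind(direct, via)
  out <- as.data.frame(t(apply(out, 1, sort)))
  names(out) <- c("a", "b")
  unique(out[order(out$a, out$b), , drop = FALSE])
}

canon <- function(df) {
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}


# literal double-loop oracles, independent of the package implementation
oracle_pair_diff <- function(sa, sb) {
  a <- strsplit(toupper(sa), "")[[1]]
  b <- strsplit(toupper(sb), "")[[1]]
  ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
  sum(a[ok] != b[ok])
}

oracle_within <- function(seqs) {
  n <- length(seqs)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, oracle_pair_diff(seqs[i], seqs[j]))
  }
  d
}


# independent multinomial-logistic maximum-likelihood oracle (BFGS on the
# explicit log-likelihood with analytic gradient)
oracle_multinom_probs <- function(y, X) {
  classes <- levels(y)
  K <- length(classes)
  p <- ncol(X)
  Xd <- cbind(1, X)
  Y <- vapply(classes, function(k) as.numeric(y == k),
              numeric(length(y)))
  nll <- function(theta) {
    B <- matrix(theta, ncol = K - 1)
    eta <- cbind(0, Xd %*% B)
    -sum(Y * (eta - log(rowSums(exp(eta)))))
  }
  grad <- function(theta) {
    B <- matrix(theta, ncol = K - 1)
    eta <- cbind(0, Xd %*% B)
    P <- exp(eta) / rowSums(exp(eta))
    -as.vector(t(Xd) %*% (Y - P)[, -1, drop = FALSE])
  }
  fit <- stats::optim(rep(0, (p + 1) * (K - 1)), nll, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  eta0 <- c(0, matrix(fit$par, ncol = K - 1)[1, ])
  pr <- exp(eta0 - max(eta0))
  setNames(pr / sum(pr), classes)
}

fake_rejection <- function(y, X, ids = levels(y)) {
  structure(list(
    retained = tibble::tibble(row = seq_along(y), scenario = as.character(y),
                              distance = 0),
    retained_std = X,
    observed_std = rep(0, ncol(X)),
    dropped = character(0),
    tolerance = 1,
    table = list(experiment = list(scenarios = lapply(ids, function(k)
      list(id = k))))),
    class = "abc_rejection")
}

three_scenario_experiment <- function() {
  ex <- twin_experiment()
  ex$scenarios <- c(ex$scenarios, list(
    abc_scenario("twin3", ex$scenarios[[1]]$events)))
  ex
}

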