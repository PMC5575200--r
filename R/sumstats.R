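#' Choose which populations and pairs enter the summary-statistic vector
#'
#' The panel is the single-locus DNA set used for rejection: per population
#' the number of distinct haplotypes (`H`), segregating sites (`S`), mean
#' (`pi`) and variance (`pivar`) of pairwise differences and private
#' segregating sites (`privS`); per pair the mean between-population
#' differences (`dxy`), the pooled haplotype count (`Hpool`) and Hudson-style
#' FST (`fst`).
#'
#' @param populations Character vector of population labels (fixed order:
#'   this defines the coordinates of the rejection space).
#' @param pairs List of length-2 character vectors; default all unordered
#'   pairs in order.
#' @return A `stat_config` list.
#' @export
stat_config <- function(populations, pairs = NULL) {
  stopifnot(length(populations) >= 1, !anyDuplicated(populations))
  if (is.null(pairs)) {
    pairs <- if (length(populations) > 1) {
      utils::combn(populations, 2, simplify = FALSE)
    } else list()
  }
  for (p in pairs) {
    if (length(p) != 2 || !all(p %in% populations)) {
      abort("each pair must name two configured populations")
    }
  }
  structure(list(populations = populations, pairs = pairs),
            class = "stat_config")
}

stat_names <- function(config) {
  per_pop <- unlist(lapply(config$populations, function(p)
    paste0(c("H_", "S_", "pi_", "pivar_", "privS_"), p)))
  per_pair <- unlist(lapply(config$pairs, function(pr)
    paste0(c("dxy_", "Hpool_", "fst_"), pr[1], ".", pr[2])))
  c(per_pop, per_pair)
}

# masked pairwise difference between two code rows (NA sites skipped)
row_diff <- function(a, b) sum(a != b, na.rm = TRUE)

#' Within-population summary statistics
#'
#' @param alignment An alignment tibble (`id`, `population`, `sequence`).
#' @param population Population label.
#' @return A named list: `H`, `S`, `pi`, `pivar`, `privS`. With a single
#'   sequence the pairwise statistics are `NA` and `S = 0`. Sites with `N`
#'   or `-` are excluded pairwise.
#' @export
per_population_stats <- function(alignment, population) {
  validate_alignment(alignment)
  if (!population %in% alignment$population) {
    abort(sprintf("population '%s' absent from alignment", population))
  }
  codes <- encode_sequences(alignment$sequence)
  in_pop <- alignment$population == population
  sub <- codes[in_pop, , drop = FALSE]
  n <- nrow(sub)

  H <- length(unique(toupper(alignment$sequence[in_pop])))
  distinct_bases <- function(m) {
    apply(m, 2, function(col) length(unique(col[!is.na(col)])))
  }
  S <- if (n >= 2) sum(distinct_bases(sub) > 1) else 0L
  privS <- 0L
  if (S > 0) {
    poly <- distinct_bases(sub) > 1
    others <- codes[!in_pop, , drop = FALSE]
    if (nrow(others) == 0) {
      privS <- sum(poly)
    } else {
      mono_elsewhere <- distinct_bases(others) <= 1
      privS <- sum(poly & mono_elsewhere)
    }
  }

  pi_mean <- pi_var <- NA_real_
  if (n >= 2) {
    d <- utils::combn(n, 2, function(ix) row_diff(sub[ix[1], ], sub[ix[2], ]))
    pi_mean <- mean(d)
    pi_var <- mean((d - pi_mean)^2)
  }
  list(H = H, S = as.integer(S), pi = pi_mean, pivar = pi_var,
       privS = as.integer(privS))
}

#' Between-population summary statistics
#'
#' `dxy` is the mean difference over all cross-population pairs; `Hpool` the
#' haplotype count of the pooled sample; `fst` the Hudson-style estimator
#' `1 - pi_w / dxy`, where `pi_w` averages the two within-population
#' with-replacement mean differences (so identically composed samples give
#' exactly 0). `fst` is `NA` when `dxy` is 0.
#'
#' @param alignment An alignment tibble.
#' @param pop_a,pop_b Population labels.
#' @return A named list: `dxy`, `Hpool`, `fst`.
#' @export
pairwise_population_stats <- function(alignment, pop_a, pop_b) {
  validate_alignment(alignment)
  for (p in c(pop_a, pop_b)) {
    if (!p %in% alignment$population) {
      abort(sprintf("population '%s' absent from alignment", p))
    }
  }
  codes <- encode_sequences(alignment$sequence)
  ia <- which(alignment$population == pop_a)
  ib <- which(alignment$population == pop_b)

  cross <- 0
  for (i in ia) for (j in ib) cross <- cross + row_diff(codes[i, ], codes[j, ])
  dxy <- cross / (length(ia) * length(ib))

  Hpool <- length(unique(toupper(alignment$sequence[c(ia, ib)])))

  pi_wr <- function(idx) {
    n <- length(idx)
    if (n < 2) return(NA_real_)
    tot <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      tot <- tot + row_diff(codes[idx[a], ], codes[idx[b], ])
    }
    2 * tot / (n * n)
  }
  wa <- pi_wr(ia); wb <- pi_wr(ib)
  within <- if (!is.na(wa) && !is.na(wb)) (wa + wb) / 2 else
    if (!is.na(wa)) wa else if (!is.na(wb)) wb else NA_real_
  fst <- if (is.finite(dxy) && dxy > 0 && !is.na(within)) 1 - within / dxy
         else NA_real_
  list(dxy = dxy, Hpool = Hpool, fst = fst)
}

#' Compute the full summary-statistic vector of an alignment
#'
#' @param alignment An alignment tibble.
#' @param config A [stat_config()]; every configured population must be
#'   present in the alignment.
#' @return A named numeric vector in the fixed, documented order (per
#'   population `H`, `S`, `pi`, `pivar`, `privS`; per pair `dxy`, `Hpool`,
#'   `fst`). Undefined entries are `NA` (imputation happens against the
#'   reference table, see [rejection_select()]).
#' @export
compute_summary_vector <- function(alignment, config) {
  validate_alignment(alignment)
  absent <- setdiff(config$populations, alignment$population)
  if (length(absent) > 0) {
    abort(sprintf("population '%s' absent from alignment", absent[1]))
  }
  sub <- alignment[alignment$population %in% config$populations, ,
                   drop = FALSE]
  clean <- !grepl("[N-]", toupper(sub$sequence))
  out <- numeric(0)
  if (all(clean)) {
    # clean data take the C++ fast path (identical panel, tested equal)
    m <- encode_sequences(sub$sequence)
    out <- stats_from_codes(m, sub$population, config)
  } else {
    for (p in config$populations) {
      s <- per_population_stats(sub, p)
      out <- c(out, s$H, s$S, s$pi, s$pivar, s$privS)
    }
    for (pr in config$pairs) {
      s <- pairwise_population_stats(sub, pr[1], pr[2])
      out <- c(out, s$dxy, s$Hpool, s$fst)
    }
    names(out) <- stat_names(config)
  }
  out
}

# coded matrix (0..3, no NA) + population labels -> named statistic vector
stats_from_codes <- function(m, leaf_pops, config) {
  pop_idx <- match(leaf_pops, config$populations)
  keep <- !is.na(pop_idx)
  pairs <- if (length(config$pairs) > 0) {
    do.call(rbind, lapply(config$pairs, function(pr)
      match(pr, config$populations) - 1L))
  } else matrix(integer(0), 0, 2)
  v <- cpp_summary_stats(m[keep, , drop = FALSE], pop_idx[keep] - 1L,
                         length(config$populations), pairs)
  setNames(as.numeric(v), stat_names(config))
}

#' Write summary vectors to CSV
#'
#' @param vectors A named numeric vector or a matrix/data frame of rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(vectors, path) {
  if (is.null(dim(vectors))) vectors <- t(as.matrix(vectors))
  readr::write_csv(as.data.frame(vectors), path)
  invisible(path)
}
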