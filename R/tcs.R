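#' Pairwise mutational-step matrix between haplotypes
#'
#' Hamming distance over unambiguous sites: for each pair, sites where either
#' sequence has `N` or `-` are skipped.
#'
#' @param table A `haplotype_table`.
#' @return A symmetric integer matrix of site differences with haplotype
#'   labels as dimnames.
#' @export
step_matrix <- function(table) {
  haps <- table$haplotypes
  if (nrow(haps) < 1) abort("at least one haplotype is required")
  lens <- nchar(haps$sequence)
  if (length(unique(lens)) != 1) abort("haplotype sequences differ in length")
  codes <- encode_sequences(haps$sequence) # NA at N/-
  h <- nrow(haps)
  m <- matrix(0L, h, h, dimnames = list(haps$haplotype, haps$haplotype))
  if (h > 1) {
    for (a in 1:(h - 1)) {
      for (b in (a + 1):h) {
        d <- sum(codes[a, ] != codes[b, ], na.rm = TRUE)
        m[a, b] <- m[b, a] <- as.integer(d)
      }
    }
  }
  m
}

# P(exactly j occupied sites | K mutations thrown uniformly on m sites),
# forward Markov-chain DP on the occupied count. Fast path for
# parsimony_limit(); the test oracle recomputes it from the Stirling-number
# formula.
occupancy_dp <- function(K, j, m) {
  p <- c(1, numeric(K)) # p[o+1] = P(o occupied)
  for (step in seq_len(K)) {
    o <- 0:(step - 1)
    p_new <- numeric(K + 1)
    stay <- p[o + 1] * o / m
    up <- p[o + 1] * (1 - o / m)
    p_new[o + 1] <- p_new[o + 1] + stay
    p_new[o + 2] <- p_new[o + 2] + up
    p <- p_new
  }
  if (j > K) 0 else p[j + 1]
}

#' Statistical-parsimony connection limit
#'
#' Largest number of observed differences `j` such that the estimated
#' probability that `j` differences between two sequences of length
#' `seq_length` arose without homoplasy (every observed difference caused by
#' exactly one mutation) is at least `confidence`. Following the
#' statistical-parsimony rationale of Templeton, Crandall and Sing, the
#' probability is evaluated under an explicit finite-sites model: mutations
#' strike sites independently and uniformly; given `j` differing sites the
#' posterior probability that the true number of mutations K equals `j`
#' (i.e. no site was hit twice) is computed with a uniform prior on K over
#' `j, ..., j + k_window`.
#'
#' @param seq_length Alignment length in sites (the barcode uses 685).
#' @param confidence Connection confidence, default 0.95.
#' @param k_window Size of the truncated uniform prior window on the number
#'   of mutations beyond the observed differences.
#' @return Integer: the maximum number of connectable steps (0 if even a
#'   single difference fails the criterion).
#' @export
parsimony_limit <- function(seq_length, confidence = 0.95, k_window = 200L) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  j <- 0L
  repeat {
    jn <- j + 1L
    p <- parsimony_probability(jn, seq_length, k_window)
    if (p < confidence) break
    j <- jn
    if (j >= seq_length) break
  }
  j
}

#' @rdname parsimony_limit
#' @param j Number of observed differences.
#' @export
parsimony_probability <- function(j, seq_length, k_window = 200L) {
  m <- seq_length
  if (j > m) return(0)
  terms <- vapply(j:(j + k_window), function(K) occupancy_dp(K, j, m),
                  numeric(1))
  terms[1] / sum(terms)
}

#' Assemble a statistical-parsimony haplotype network
#'
#' Agglomerative minimum-spanning-network assembly: candidate connections are
#' processed in increasing mutational-step order up to the parsimony limit;
#' within one step class, every pair joining components that were distinct
#' before the class is connected (so alternative equal-step connections are
#' retained as loops), with ties broken deterministically by lexicographic
#' label order. Multi-step connections insert `steps - 1` zero-frequency
#' intermediate nodes. Haplotype pairs farther apart than the limit stay in
#' disconnected components.
#'
#' @param steps A step matrix from [step_matrix()].
#' @param table The `haplotype_table` the matrix came from (frequencies and
#'   population composition).
#' @param limit Maximum connectable steps, e.g. from [parsimony_limit()].
#' @return A `haplotype_network`: list with `nodes` (tibble `label`,
#'   `frequency`, `is_intermediate`, and one `pop_*` count column per
#'   population), `edges` (tibble `from`, `to`, `step = 1`), and `limit`.
#' @export
build_network <- function(steps, table, limit) {
  stopifnot(limit >= 1)
  labels <- rownames(steps)
  h <- length(labels)

  freq <- table$counts %>%
    dplyr::group_by(.data$haplotype) %>%
    dplyr::summarise(frequency = sum(.data$count), .groups = "drop")
  pops <- sort(unique(table$counts$population))
  comp <- tidyr::pivot_wider(table$counts, names_from = "population",
                             values_from = "count", values_fill = 0L,
                             names_prefix = "pop_")

  # candidate pairs in (step, label, label) order
  cand <- NULL
  if (h > 1) {
    idx <- which(upper.tri(steps), arr.ind = TRUE)
    cand <- tibble(a = labels[idx[, 1]], b = labels[idx[, 2]],
                   d = steps[idx])
    swap <- cand$a > cand$b
    tmp <- cand$a[swap]; cand$a[swap] <- cand$b[swap]; cand$b[swap] <- tmp
    cand <- cand %>%
      dplyr::filter(.data$d >= 1, .data$d <= limit) %>%
      dplyr::arrange(.data$d, .data$a, .data$b)
  }

  parent <- seq_len(h)
  names(parent) <- labels
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }

  edges <- list()
  inter_nodes <- character(0)
  if (!is.null(cand) && nrow(cand) > 0) {
    for (d in sort(unique(cand$d))) {
      class_pairs <- cand[cand$d == d, , drop = FALSE]
      snapshot <- vapply(seq_len(h), function(i) find(i), numeric(1))
      added <- list()
      for (r in seq_len(nrow(class_pairs))) {
        ia <- match(class_pairs$a[r], labels)
        ib <- match(class_pairs$b[r], labels)
        if (snapshot[ia] != snapshot[ib]) {
          a <- class_pairs$a[r]; b <- class_pairs$b[r]
          if (d == 1) {
            edges[[length(edges) + 1]] <- tibble(from = a, to = b)
          } else {
            mids <- paste0("i.", a, ".", b, ".", seq_len(d - 1))
            inter_nodes <- c(inter_nodes, mids)
            path <- c(a, mids, b)
            for (s in seq_len(d)) {
              edges[[length(edges) + 1]] <- tibble(from = path[s],
                                                   to = path[s + 1])
            }
          }
          added[[length(added) + 1]] <- c(ia, ib)
        }
      }
      for (pr in added) parent[find(pr[1])] <- find(pr[2])
    }
  }

  nodes <- tibble(label = c(labels, inter_nodes),
                  is_intermediate = c(rep(FALSE, h),
                                      rep(TRUE, length(inter_nodes)))) %>%
    dplyr::left_join(freq, by = c(label = "haplotype")) %>%
    dplyr::left_join(comp, by = c(label = "haplotype")) %>%
    dplyr::mutate(dplyr::across(dplyr::starts_with("pop_") | dplyr::matches("^frequency$"),
                                ~ tidyr::replace_na(.x, 0L)))

  structure(list(nodes = nodes,
                 edges = if (length(edges) > 0) {
                   dplyr::mutate(dplyr::bind_rows(edges), step = 1L)
                 } else {
                   tibble(from = character(0), to = character(0),
                          step = integer(0))
                 },
                 limit = as.integer(limit)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network: %d observed + %d intermediate nodes, %d edges, limit %d>\n",
              sum(!x$nodes$is_intermediate), sum(x$nodes$is_intermediate),
              nrow(x$edges), x$limit))
  invisible(x)
}

#' @export
tidy.haplotype_network <- function(x, ...) x$nodes

#' Convert a haplotype network to an igraph object
#'
#' @param network A `haplotype_network`.
#' @return An undirected igraph graph with node attributes `frequency`,
#'   `is_intermediate` and per-population counts, and edge attribute `step`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = as.data.frame(network$nodes))
}

#' Write a haplotype network to GraphML (or a CSV edge list)
#'
#' @param network A `haplotype_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"csv"` (edge list).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    readr::write_csv(network$edges, path)
  }
  invisible(path)
}

#' @export
autoplot.haplotype_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes[match(igraph::V(g)$name, object$nodes$label), ]
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$label)]
  ed$y <- nodes$y[match(ed$from, nodes$label)]
  ed$xend <- nodes$x[match(ed$to, nodes$label)]
  ed$yend <- nodes$y[match(ed$to, nodes$label)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$frequency,
                                     shape = .data$is_intermediate)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::geom_text(data = nodes[!nodes$is_intermediate, ],
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "sequences", shape = "inferred node")
}
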