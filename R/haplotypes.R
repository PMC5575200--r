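#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences (after uppercasing; `N` and `-` match only themselves,
#' no wildcard expansion) share one haplotype. Labels are assigned `H1`,
#' `H2`, ... in order of first appearance, unless a user label map is
#' supplied, which lets a table reuse established haplotype numbering.
#'
#' @param alignment A tibble with columns `id`, `population`, `sequence`.
#' @param label_map Optional named character vector mapping sequence strings
#'   to haplotype labels; sequences not covered get fresh `H<k>` labels.
#' @return A `haplotype_table`: list with `counts` (tibble `population`,
#'   `haplotype`, `count`) and `haplotypes` (tibble `haplotype`, `sequence`).
#' @examples
#' aln <- tibble::tibble(
#'   id = c("a", "b", "c"), population = "P",
#'   sequence = c("AAA", "AAA", "AAT"))
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(alignment, label_map = NULL) {
  validate_alignment(alignment)
  seqs <- toupper(alignment$sequence)
  uniq <- unique(seqs)

  labels <- character(length(uniq))
  if (!is.null(label_map)) {
    names(label_map) <- toupper(names(label_map))
    hit <- match(uniq, names(label_map))
    labels[!is.na(hit)] <- unname(label_map[hit[!is.na(hit)]])
    if (anyDuplicated(labels[labels != ""]) > 0) {
      abort("label_map assigns the same label to distinct sequences")
    }
  }
  k <- 0L
  used <- labels[labels != ""]
  for (i in seq_along(labels)) {
    if (labels[i] == "") {
      repeat {
        k <- k + 1L
        cand <- paste0("H", k)
        if (!cand %in% used) break
      }
      labels[i] <- cand
      used <- c(used, cand)
    }
  }

  hap_of <- labels[match(seqs, uniq)]
  counts <- tibble(population = alignment$population, haplotype = hap_of) %>%
    dplyr::count(.data$population, .data$haplotype, name = "count")

  new_haplotype_table(
    counts = counts,
    haplotypes = tibble(haplotype = labels, sequence = uniq)
  )
}

new_haplotype_table <- function(counts, haplotypes, groups = NULL) {
  stopifnot(all(c("population", "haplotype", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("haplotype counts must be non-negative")
  if (anyDuplicated(haplotypes$sequence) > 0) {
    abort("haplotype sequences must be pairwise distinct")
  }
  structure(
    list(counts = as_tibble(counts), haplotypes = as_tibble(haplotypes),
         groups = groups),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  n_pop <- dplyr::n_distinct(x$counts$population)
  cat(sprintf("<haplotype_table: %d sequences, %d haplotypes, %d populations>\n",
              sum(x$counts$count), nrow(x$haplotypes), n_pop))
  print(hap_matrix(x))
  invisible(x)
}

#' @export
tidy.haplotype_table <- function(x, ...) x$counts

#' Population-by-haplotype count matrix
#'
#' @param table A `haplotype_table`.
#' @return An integer matrix, rows = populations, columns = haplotype labels.
#' @export
hap_matrix <- function(table) {
  wide <- tidyr::pivot_wider(table$counts, names_from = "haplotype",
                             values_from = "count", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- wide$population
  # order haplotype columns numerically where labelled H<k>
  num <- suppressWarnings(as.integer(sub("^H", "", colnames(m))))
  m[, order(is.na(num), num, colnames(m)), drop = FALSE]
}

resolve_populations <- function(table, populations) {
  pops <- unique(table$counts$population)
  if (is.null(populations)) return(pops)
  out <- character(0)
  for (p in populations) {
    if (p %in% pops) {
      out <- c(out, p)
    } else if (!is.null(table$groups) && p %in% names(table$groups)) {
      out <- c(out, intersect(table$groups[[p]], pops))
    } else {
      abort(sprintf("unknown population label '%s'", p))
    }
  }
  unique(out)
}

#' Sample-size and haplotype-richness census of a haplotype table
#'
#' Totals per population plus an aggregate row `(all)` whose `n_haplotypes`
#' is the number of distinct haplotypes with nonzero count anywhere in the
#' selected subset.
#'
#' @param table A `haplotype_table`.
#' @param populations Optional character vector restricting the census to a
#'   subset; entries may be population labels or, if the table carries named
#'   groups (e.g. countries grouping localities), group labels.
#' @return A tibble with columns `population`, `n_sequences`, `n_haplotypes`.
#' @export
census <- function(table, populations = NULL) {
  sel <- resolve_populations(table, populations)
  counts <- dplyr::filter(table$counts, .data$population %in% sel)
  per_pop <- counts %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(
      n_sequences = sum(.data$count),
      n_haplotypes = dplyr::n_distinct(.data$haplotype[.data$count > 0]),
      .groups = "drop")
  total <- tibble(
    population = "(all)",
    n_sequences = sum(counts$count),
    n_haplotypes = dplyr::n_distinct(counts$haplotype[counts$count > 0]))
  dplyr::bind_rows(per_pop, total)
}

#' Write a haplotype table as CSV plus representative-sequence FASTA
#'
#' @param table A `haplotype_table`.
#' @param csv_path Output CSV (rows = populations, columns = haplotypes).
#' @param fasta_path Optional FASTA of one representative sequence per
#'   haplotype.
#' @return `csv_path`, invisibly.
#' @export
write_haplotype_table <- function(table, csv_path, fasta_path = NULL) {
  m <- hap_matrix(table)
  df <- data.frame(population = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, csv_path)
  if (!is.null(fasta_path)) {
    x <- Biostrings::BStringSet(setNames(table$haplotypes$sequence,
                                         table$haplotypes$haplotype))
    Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  }
  invisible(csv_path)
}

#' Bar chart of haplotype frequencies by population
#'
#' @param table A `haplotype_table`.
#' @return A ggplot object.
#' @export
plot_haplotype_frequencies <- function(table) {
  ggplot2::ggplot(table$counts,
                  ggplot2::aes(x = .data$population, y = .data$count,
                               fill = .data$haplotype)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sequences", fill = "haplotype") +
    ggplot2::theme_minimal()
}
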