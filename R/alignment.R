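#' Read an aligned FASTA with a sample-to-population map
#'
#' Reads aligned barcode sequences (e.g. the 685 bp CO1 fragment) and attaches
#' a population label to every record. The population map is a tab-separated
#' file with header columns `id` and `population`; every FASTA identifier must
#' appear in it.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param population_map_path Path to a two-column TSV (`id`, `population`).
#' @return A tibble with columns `id`, `population`, `sequence` (uppercased),
#'   one row per record; all sequences have equal length.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tpopulation", "s1\tA", "s2\tA"), tsv)
#' read_alignment(fa, tsv)
#' @export
read_alignment <- function(fasta_path, population_map_path) {
  if (!file.exists(fasta_path)) {
    abort(sprintf("FASTA file not found: %s", fasta_path))
  }
  if (!file.exists(population_map_path)) {
    abort(sprintf("population map not found: %s", population_map_path))
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) abort("no sequences in FASTA")
  ids <- sub("\\s.*$", "", names(seqs))

  pop_map <- readr::read_tsv(population_map_path, col_types = readr::cols(
    id = readr::col_character(), population = readr::col_character()))
  if (!all(c("id", "population") %in% names(pop_map))) {
    abort("population map must have header columns 'id' and 'population'")
  }
  missing <- setdiff(ids, pop_map$id)
  if (length(missing) > 0) {
    abort(sprintf("no population mapping for id '%s'", missing[1]))
  }

  out <- tibble(
    id = unname(ids),
    population = unname(pop_map$population[match(ids, pop_map$id)]),
    sequence = unname(toupper(as.character(seqs)))
  )
  validate_alignment(out)
  out
}

#' Write an alignment tibble to FASTA
#'
#' @param alignment A tibble with columns `id`, `population`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  validate_alignment(alignment)
  x <- Biostrings::BStringSet(setNames(alignment$sequence, alignment$id))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write a population map TSV for an alignment
#'
#' @inheritParams write_alignment_fasta
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(alignment, path) {
  validate_alignment(alignment)
  readr::write_tsv(alignment[, c("id", "population")], path)
  invisible(path)
}
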