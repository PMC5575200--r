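#' Derive a reproducible child seed from a master seed
#'
#' Counter-based seed splitting: every stochastic stage (each reference-table
#' row, each pseudo-observed dataset) gets its own seed as a deterministic
#' function of the master seed and a counter, so results do not depend on the
#' order in which rows are simulated or on how work is distributed across
#' workers.
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer counter (vectorised).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  # multiplicative hash mod the Mersenne prime 2^31 - 1; exact in doubles
  # because all intermediates stay below 2^53
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  x <- (s * 48271) %% m
  x <- (x * 69621 + (as.numeric(counter) %% m) * 16807 + 12345) %% m
  x <- (x * 48271) %% m
  as.integer(x + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
DNA_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# character sequence vector -> integer matrix (0..3, NA for N/-)
encode_sequences <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[1])
  chars <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  codes <- matrix(DNA_CODES[chars], nrow = n, ncol = L)
  codes
}

decode_sequences <- function(codes) {
  bases <- c("A", "C", "G", "T")
  apply(codes, 1, function(row) paste(bases[row + 1L], collapse = ""))
}

#' @noRd
validate_alignment <- function(alignment, arg = "alignment") {
  if (!is.data.frame(alignment)) {
    abort(sprintf("`%s` must be a data frame with columns id, population, sequence", arg))
  }
  need <- c("id", "population", "sequence")
  missing_cols <- setdiff(need, names(alignment))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(alignment) == 0) abort("no sequences in alignment")
  seqs <- toupper(alignment$sequence)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "ragged alignment: sequence lengths differ (%s)",
      paste(sort(unique(lens)), collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    abort(sprintf("sequence for id '%s' contains characters outside {A,C,G,T,N,-}",
                  alignment$id[which(bad)[1]]))
  }
  invisible(alignment)
}

alignment_length <- function(alignment) nchar(alignment$sequence[1])
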