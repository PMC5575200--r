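test_that("read_alignment attaches populations and rejects bad input", {
  fa <- write_toy_fasta(c("ACGTACGT", "ACGTACGA", "ACGTACGC"))
  map <- write_toy_map(paste0("s", 1:3), c("A", "A", "B"))
  aln <- read_alignment(fa, map)
  expect_equal(nrow(aln), 3)
  expect_equal(nchar(aln$sequence), rep(8, 3))
  expect_equal(aln$population, c("A", "A", "B"))

  # ragged alignment
  fa2 <- write_toy_fasta(c("ACGTACGT", "ACGTACG"))
  map2 <- write_toy_map(paste0("s", 1:2), c("A", "A"))
  expect_error(read_alignment(fa2, map2), "ragged")

  # empty FASTA
  fa3 <- tempfile(fileext = ".fasta"); file.create(fa3)
  expect_error(read_alignment(fa3, map2), "no sequences")

  # unmapped id is named in the error
  map3 <- write_toy_map("s1", "A")
  expect_error(read_alignment(fa, map3), "s2")
})

test_that("collapse_haplotypes groups identical sequences in first-appearance order", {
  ht <- collapse_haplotypes(toy_alignment(c("AAA", "AAA", "AAT")))
  expect_equal(sort(ht$counts$count), c(1L, 2L))
  expect_equal(ht$haplotypes$haplotype, c("H1", "H2"))
  expect_equal(ht$haplotypes$sequence[ht$haplotypes$haplotype == "H1"], "AAA")
  expect_equal(sum(ht$counts$count), 3)

  # five mutually distinct sequences -> five singletons
  ht5 <- collapse_haplotypes(toy_alignment(c("AA", "AT", "AG", "AC", "TA")))
  expect_equal(nrow(ht5$haplotypes), 5)
  expect_true(all(ht5$counts$count == 1))

  # case-insensitive; N/- match only themselves
  ht2 <- collapse_haplotypes(toy_alignment(c("acgt", "ACGT", "ACGN")))
  expect_equal(nrow(ht2$haplotypes), 2)

  # user label map overrides fresh labels
  ht3 <- collapse_haplotypes(toy_alignment(c("AAA", "AAT")),
                             label_map = c(AAT = "H9"))
  expect_setequal(ht3$haplotypes$haplotype, c("H1", "H9"))
})

test_that("haplotype partition is invariant to record order", {
  aln <- random_alignment(30, 12, seed = 7)
  aln$sequence <- aln$sequence |> substr(1, 3) # force duplicates
  perm <- withr::with_seed(1, sample(nrow(aln)))
  a <- collapse_haplotypes(aln)
  b <- collapse_haplotypes(aln[perm, ])
  part <- function(ht) {
    m <- merge(ht$counts, ht$haplotypes, by = "haplotype")
    m <- m[order(m$sequence), c("sequence", "count")]
    rownames(m) <- NULL
    m
  }
  expect_equal(part(a), part(b))
  # with a fixed label map the output is identical
  lm <- setNames(a$haplotypes$haplotype, a$haplotypes$sequence)
  a2 <- collapse_haplotypes(aln[perm, ], label_map = lm)
  expect_equal(dplyr::arrange(a$counts, haplotype),
               dplyr::arrange(a2$counts, haplotype))
})

test_that("total haplotype count is conserved on random inputs", {
  for (seed in 1:5) {
    n <- 10 + seed * 7
    aln <- random_alignment(n, 4, n_pops = 3, seed = seed)
    ht <- collapse_haplotypes(aln)
    expect_equal(sum(ht$counts$count), n)
  }
})

test_that("census totals and richness work on subsets", {
  aln <- toy_alignment(c("AA", "AA", "AA", "AA"), populations = "solo")
  ht <- collapse_haplotypes(aln)
  cs <- census(ht)
  expect_equal(cs$n_sequences[cs$population == "(all)"], 4)
  expect_equal(cs$n_haplotypes[cs$population == "(all)"], 1)
  expect_error(census(ht, "nope"), "unknown population")
})

test_that("the packaged worldwide table reproduces the published accounting", {
  tab <- load_table1_fixture()
  cs <- census(tab)
  expect_equal(cs$n_sequences[cs$population == "(all)"], 916)

  native <- census(tab, c("China", "Japan", "Republic of Korea"))
  expect_equal(native$n_sequences[native$population == "(all)"], 214)

  by_country <- vapply(
    c(China = 158L, Japan = 44L, `Republic of Korea` = 12L,
      `United States` = 108L, Canada = 51L, Switzerland = 223L,
      Italy = 40L, France = 139L, Hungary = 84L, Greece = 57L),
    identity, integer(1))
  for (ctry in names(by_country)) {
    cc <- census(tab, ctry)
    expect_equal(cc$n_sequences[cc$population == "(all)"],
                 unname(by_country[ctry]), label = ctry)
  }

  west <- census(tab, "Western US (post-2008)")
  expect_equal(west$n_haplotypes[west$population == "(all)"], 5)

  # spot checks against printed cells
  cnt <- tab$counts
  bud <- cnt[cnt$population == "Budapest", ]
  expect_equal(setNames(bud$count, bud$haplotype)[c("H1", "H3")],
               c(H1 = 83L, H3 = 1L))
  fr <- cnt[cnt$population == "Schiltigheim", ]
  expect_equal(sort(fr$count), c(1L, 2L, 136L))
  expect_true(all(cnt$count >= 0))

  # country-level view aggregates consistently
  tc <- load_table1_fixture(level = "country")
  expect_equal(sum(tc$counts$count), 916)
  expect_equal(sum(tc$counts$count[tc$counts$population == "China"]), 158)
})

test_that("the France locality collapses from sequences exactly as printed", {
  # 139 sequences: 1 of one haplotype, 136 of another, 2 of a third
  tab <- load_table1_fixture()
  seqs <- tab$haplotypes$sequence
  names(seqs) <- tab$haplotypes$haplotype
  fr <- rep(c(seqs[["H1"]], seqs[["H3"]], seqs[["H8"]]), c(1, 136, 2))
  ht <- collapse_haplotypes(toy_alignment(fr, populations = "Schiltigheim"))
  expect_equal(sort(ht$counts$count), c(1L, 2L, 136L))
  expect_equal(nrow(ht$haplotypes), 3)
})

test_that("haplotype table round-trips through CSV and FASTA", {
  ht <- collapse_haplotypes(toy_alignment(c("AAA", "AAT", "AAT")))
  csv <- tempfile(fileext = ".csv"); fa <- tempfile(fileext = ".fasta")
  write_haplotype_table(ht, csv, fa)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$H1, 1L)
  expect_equal(back$H2, 2L)
  seqs <- Biostrings::readBStringSet(fa)
  expect_equal(as.character(seqs[["H2"]]), "AAT")
})
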