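strip_gaps <- function(x) gsub("-", "", x, fixed = TRUE)

test_that("identical sequences align without gaps", {
  aln <- align_cdr3_set(rep("CLLGSISLGILSQ", 4))
  expect_equal(aln$length, 13)
  expect_true(all(aln$aligned == "CLLGSISLGILSQ"))
})

test_that("a two-sequence alignment is an optimal pairwise global alignment", {
  pairs <- list(c("CARFNRGGDYW", "CARARFDRGGDYW"),
                c("CQAWD_QPNVF", "CV_VF"),
                c("CSSYTS_QHSVF", "CSSYTSS_ALGAVF"))
  for (p in pairs) {
    aln <- align_cdr3_set(p)
    expect_equal(strip_gaps(aln$aligned), p)
    expect_equal(score_gapped_pair(aln$aligned[1], aln$aligned[2]),
                 nw_score_oracle(p[1], p[2]))
  }
})

test_that("SHM subclone CDR3s align with gaps only in the shorter rows", {
  seqs <- c("CARFNRGGDYW", "CARFDRGGDYW", "CARARFDRGGDYW")
  aln <- align_cdr3_set(seqs)
  expect_equal(aln$length, 13)
  expect_equal(strip_gaps(aln$aligned), seqs)
  gaps <- stringr::str_count(aln$aligned, stringr::fixed("-"))
  expect_equal(gaps, c(2, 2, 0))
})

test_that("gap stripping recovers every input (property over random sets)", {
  withr::with_seed(11, {
    for (i in 1:30) {
      n <- sample(2:8, 1)
      seqs <- vapply(seq_len(n), function(k) {
        paste(c("C", sample(c(LETTERS[1:20], "_", "*"), sample(5:15, 1),
                            replace = TRUE)), collapse = "")
      }, character(1))
      aln <- align_cdr3_set(seqs)
      expect_equal(strip_gaps(aln$aligned), seqs)
      expect_true(all(nchar(aln$aligned) == aln$length))
      expect_gte(aln$length, max(nchar(seqs)))
    }
  })
})

test_that("alignment is deterministic and error-checks its input", {
  seqs <- c("CARFNRGGDYW", "CARFDRGGDYW", "CARARFDRGGDYW")
  expect_identical(align_cdr3_set(seqs), align_cdr3_set(seqs))
  expect_error(align_cdr3_set(character()), "non-empty")
  expect_error(align_cdr3_set(c("CAW", "")), "non-empty")
})

test_that("position frequency matrix counts columns and calls the consensus", {
  one <- position_frequency_matrix(align_cdr3_set("CARW"))
  expect_equal(one$consensus, "CARW")
  aln <- align_cdr3_set(c("CAAW", "CAGW", "CAAW"))
  pfm <- position_frequency_matrix(aln)
  expect_equal(unname(colSums(pfm$counts)), rep(3, 4))  # columns sum to n
  expect_equal(unname(pfm$counts["A", 3]), 2)
  expect_equal(unname(pfm$counts["G", 3]), 1)
  expect_equal(pfm$consensus, "CAAW")
  # anchored cysteine: first column is 100% C
  expect_equal(unname(pfm$counts["C", 1]), 3)
})

test_that("consensus ties break alphabetically and the gap loses ties", {
  aln <- align_cdr3_set(c("CAW", "CGW"))
  pfm <- position_frequency_matrix(aln)
  expect_equal(substr(pfm$consensus, 2, 2), "A")  # A/G tie -> alphabetical
  aln2 <- align_cdr3_set(c("CARFFW", "CW"))
  pfm2 <- position_frequency_matrix(aln2)
  # every gap column here ties 1-1 with a residue: the residue must win
  expect_false(grepl("-", pfm2$consensus, fixed = TRUE))
})

test_that("CDR3 length distributions exclude the out-of-frame marker", {
  alcl <- alcl_samples()[[1]]
  expect_equal(cdr3_length_distribution(alcl, "dominant"),
               tibble::tibble(length = nchar("CSARGEQYF"), count = 1L))
  lens <- cdr3_length_distribution(list(
    repertoire_sample("a", tibble::tibble(
      locus = "IGL", v_gene = "IGLV3-1", d_gene = NA_character_,
      j_gene = "IGLJ6", junction_aa = "CQAWD_QPNVF",  # 10 residues + marker
      junction_nt = fake_nt(91), read_count = 100L)),
    repertoire_sample("b", tibble::tibble(
      locus = "IGH", v_gene = "IGHV1-2", d_gene = NA_character_,
      j_gene = "IGHJ4", junction_aa = "CARFNRGGDYW",
      junction_nt = fake_nt(92), read_count = 100L))), "dominant")
  expect_equal(lens, tibble::tibble(length = c(10L, 11L), count = c(1L, 1L)))
  expect_equal(nrow(cdr3_length_distribution(list())), 0)
  # counts sum to contributing clonotypes in "all" mode
  all_lens <- cdr3_length_distribution(ca46_sample(), "all")
  expect_equal(sum(all_lens$count), 3)
})

test_that("PFM and consensus exports are plain text round-trippable", {
  aln <- align_cdr3_set(c("CAAW", "CAGW", "CAAW"))
  pfm <- position_frequency_matrix(aln)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pfm(pfm, tf)
  tall <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(sum(tall$count), 3 * 4)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_consensus_fasta(c(s1 = pfm$consensus), fa)
  expect_equal(readLines(fa), c(">s1", "CAAW"))
})
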