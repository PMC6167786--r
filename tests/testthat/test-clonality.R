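simple_sample <- function(id, loci, reads, junction_aa = NULL) {
  n <- length(reads)
  loci <- rep_len(loci, n)
  repertoire_sample(id, tibble::tibble(
    locus = loci,
    v_gene = paste0(loci, "V1-", seq_len(n)),
    d_gene = NA_character_,
    j_gene = paste0(loci, "J1"),
    junction_aa = junction_aa %||% rep("CARGGW", n),
    junction_nt = fake_nt(seq_len(n) + 100),
    read_count = as.integer(reads)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("read filtering is inclusive at the threshold and idempotent", {
  s <- simple_sample("NAMALWA-like", "IGL", c(67629, 208, 120, 116))
  expect_equal(nrow(filter_clonotypes(s, 30)$clonotypes), 4)
  expect_equal(nrow(filter_clonotypes(simple_sample("x", "IGH", 29), 30)$clonotypes), 0)
  expect_equal(nrow(filter_clonotypes(simple_sample("x", "IGH", 30), 30)$clonotypes), 1)
  f <- filter_clonotypes(s, 200)
  expect_equal(filter_clonotypes(f, 200), f)
})

test_that("CPM is reads per million library reads and linear in reads", {
  expect_equal(round(compute_cpm(2517, 178.5e6), 2), 14.10)
  expect_equal(compute_cpm(0, 5e7), 0)
  expect_equal(compute_cpm(1e6, 1e9), 1000)
  expect_equal(compute_cpm(3 * 17L, 2e8), 3 * compute_cpm(17L, 2e8))
  expect_error(compute_cpm(10, 0), "positive")
})

test_that("clonotype fractions use the requested denominator and sum to one", {
  s <- simple_sample("S", c("IGH", "IGH", "IGL"), c(50, 30, 20))
  fr <- compute_fractions(s, "sample_wide")
  expect_equal(fr$fraction, c(0.5, 0.3, 0.2))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  pl <- compute_fractions(s, "per_locus")
  expect_equal(pl$fraction, c(50 / 80, 30 / 80, 1))
  expect_equal(sum(pl$fraction[pl$locus == "IGH"]), 1, tolerance = 1e-9)
  one <- compute_fractions(simple_sample("S", "IGH", 99), "sample_wide")
  expect_equal(one$fraction, 1)
  expect_error(compute_fractions(filter_clonotypes(s, 1e6)), "empty")
})

test_that("a sample-wide denominator reproduces published per-line fractions", {
  # dominant light-chain clone at 74.70% implies the heavy-chain subclone
  # rounds to 10.63% under the same denominator
  total <- round(15670 / 0.7470)
  s <- simple_sample("NALM-6-like", c("IGL", "IGL", "IGH", "IGL"),
                     c(15670, 2479, 2229, total - 15670 - 2479 - 2229))
  fr <- compute_fractions(s, "sample_wide")
  expect_equal(round_half_up(100 * fr$fraction[1:3], 2), c(74.70, 11.82, 10.63))
})

test_that("clonality categories follow the per-locus count tiers", {
  # six IGL rearrangements: oligo/polyclonal
  nudul <- simple_sample("NU-DUL-1-like", "IGL",
                         c(10266, 3738, 3005, 2974, 1180, 507))
  expect_equal(classify_clonality(nudul)$category, "oligo_or_polyclonal")
  # exactly two IGK clonotypes: biallelic or biclonal (within the IGK allowance)
  kms <- simple_sample("KMS-27-like", "IGK", c(625058, 382112))
  expect_equal(classify_clonality(kms)$category, "biallelic_or_biclonal")
  # four IGK clonotypes still within the ">4" allowance; five exceeds it
  expect_equal(classify_clonality(simple_sample("k4", "IGK", rep(100, 4)))$category,
               "biallelic_or_biclonal")
  expect_equal(classify_clonality(simple_sample("k5", "IGK", rep(100, 5)))$category,
               "oligo_or_polyclonal")
  # a single IGH clonotype is monoclonal; nothing retained is no_rearrangement
  expect_equal(classify_clonality(simple_sample("m", "IGH", 18169))$category,
               "monoclonal")
  empty <- classify_clonality(simple_sample("n", "IGH", 12))
  expect_equal(empty$category, "no_rearrangement")
  expect_equal(sum(empty$per_locus_counts), 0)
  expect_null(empty$dominant)
})

test_that("dominant clone, prominence and productivity flags are reported", {
  s <- simple_sample("S", c("IGK", "IGH"), c(9500, 300),
                     junction_aa = c("CQQRTNWPITF", "CARW"))
  call <- classify_clonality(s)
  expect_equal(call$dominant$locus, "IGK")
  expect_equal(call$dominant_fraction, 9500 / 9800)
  expect_true(call$prominent)
  expect_false(call$dominant_nonproductive)
  nonprod <- simple_sample("S2", "IGL", 5000, junction_aa = "CQSYD_AGVF")
  expect_true(classify_clonality(nonprod)$dominant_nonproductive)
})

test_that("light-chain-only flags dominant IGK/IGL without retained IGH", {
  lc <- simple_sample("LC-MM", c("IGK", "IGH"), c(382112, 12))
  expect_true(flag_light_chain_only(lc))
  hc <- simple_sample("KMS-12-BM-like", "IGH", 18169)
  expect_false(flag_light_chain_only(hc))
  expect_false(flag_light_chain_only(simple_sample("none", "IGH", 5)))
  expect_true(classify_clonality(lc)$light_chain_only)
})

test_that("calls are invariant to row order and to sub-threshold additions", {
  s <- simple_sample("S", c("IGL", "IGL", "IGH"), c(5000, 400, 90))
  shuffled <- s
  shuffled$clonotypes <- s$clonotypes[c(3, 1, 2), ]
  c1 <- classify_clonality(s)
  c2 <- classify_clonality(shuffled)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$dominant, c2$dominant)
  expect_equal(c1$dominant_fraction, c2$dominant_fraction)

  plus_noise <- s
  plus_noise$clonotypes <- dplyr::bind_rows(
    s$clonotypes,
    simple_sample("S", "TRA", 29)$clonotypes)
  c3 <- classify_clonality(plus_noise)
  expect_equal(c1$category, c3$category)
  expect_equal(c1$per_locus_counts, c3$per_locus_counts)
  expect_equal(c1$dominant_fraction, c3$dominant_fraction)
})

test_that("flattened calls carry per-locus counts and dominant fields", {
  calls <- clonality_calls(list(simple_sample("a", "IGH", 100),
                                simple_sample("b", "IGK", c(50, 40))))
  expect_equal(calls$category, c("monoclonal", "biallelic_or_biclonal"))
  expect_equal(calls$n_IGH, c(1L, 0L))
  expect_equal(calls$n_IGK, c(0L, 2L))
  expect_equal(calls$dominant_read_count, c(100L, 50L))
})
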