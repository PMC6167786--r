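test_that("edit distance matches published subclone examples", {
  expect_equal(edit_distance("CARFNRGGDYW", "CARFNRGGDYW"), 0L)
  expect_equal(edit_distance("CARFNRGGDYW", "CARFDRGGDYW"), 1L)
  expect_equal(edit_distance("CARFDRGGDYW", "CARARFDRGGDYW"), 2L)
  expect_equal(edit_distance("CARFNRGGDYW",
                             c("CARFDRGGDYW", "CARARFDRGGDYW")), c(1L, 3L))
})

test_that("edit distance agrees with the DP oracle and is a metric", {
  alphabet <- c(LETTERS[1:20], "_", "*")
  withr::with_seed(7, {
    for (i in 1:200) {
      trio <- vapply(1:3, function(k) {
        paste(sample(alphabet, sample(3:15, 1), replace = TRUE), collapse = "")
      }, character(1))
      d12 <- edit_distance(trio[1], trio[2])
      d13 <- edit_distance(trio[1], trio[3])
      d23 <- edit_distance(trio[2], trio[3])
      expect_equal(d12, dp_edit_distance(trio[1], trio[2]))
      expect_equal(d12, edit_distance(trio[2], trio[1]))  # symmetry
      expect_lte(d13, d12 + d23)                          # triangle inequality
      expect_equal(edit_distance(trio[1], trio[1]), 0L)
    }
  })
})

test_that("same-pattern clonotypes with similar CDR3s form one SHM cluster", {
  cl <- cluster_subclones(ca46_sample(), "IGH")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pattern, "shm_derived")
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$dominant_junction_aa, "CARFNRGGDYW")
  expect_lte(cl$max_edit_distance, 4L)

  nam <- cluster_subclones(filter_clonotypes(namalwa_sample(), 30), "IGL")
  expect_equal(nam$n_members, 4L)
  expect_equal(nam$pattern, "shm_derived")
})

test_that("many distinct patterns at one locus are labelled independent", {
  cl <- cluster_subclones(nudul1_sample(), "IGL")
  expect_equal(sum(cl$n_members), 6)
  expect_true(all(cl$pattern[cl$n_members == 1] == "independent"))
  expect_gt(length(unique(paste(cl$v_gene, cl$j_gene))), 2)
})

test_that("few patterns stay singleton; lone clonotypes are singleton clusters", {
  cl <- cluster_subclones(kms27_sample(), "IGK")
  expect_equal(cl$pattern, c("singleton", "singleton"))
  one <- cluster_subclones(ca46_sample(), "IGL")
  expect_equal(nrow(one), 0)
  s <- kms27_sample()
  s$clonotypes <- s$clonotypes[1, ]
  expect_equal(cluster_subclones(s, "IGK")$pattern, "singleton")
})

test_that("distant same-pattern members split off; clusters always partition", {
  s <- repertoire_sample("S", tibble::tibble(
    locus = "IGH", v_gene = "IGHV1-2", d_gene = "IGHD1-1", j_gene = "IGHJ4",
    junction_aa = c("CARFNRGGDYW", "CARFDRGGDYW", "CTTPLMEKWPHEAVYW"),
    junction_nt = fake_nt(61:63),
    read_count = c(1000L, 100L, 90L)))
  cl <- cluster_subclones(s, "IGH", max_edit = 3)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_members, c(2L, 1L))
  expect_equal(sum(cl$n_members), nrow(s$clonotypes))

  # order invariance
  s2 <- s
  s2$clonotypes <- s$clonotypes[c(3, 1, 2), ]
  expect_equal(cluster_subclones(s2, "IGH", max_edit = 3), cl)
})

test_that("junctions shared at solid depth across samples are fingerprints", {
  shared <- find_shared_junctions(alcl_samples(), match_on = "aa")
  expect_equal(nrow(shared), 1)
  expect_equal(shared$junction, "CLLGSISLGILSQ")
  expect_equal(shared$n_samples, 5L)
  expect_setequal(shared$sample_ids[[1]], paste0("ALCL", 1:5))
  expect_false(shared$suspected_contamination)
})

test_that("trace-level recurrent junctions are flagged as contamination", {
  base <- alcl_samples()
  contam <- lapply(seq_along(base), function(i) {
    s <- base[[i]]
    s$clonotypes <- dplyr::bind_rows(s$clonotypes, tibble::tibble(
      locus = "TRA", v_gene = "TRAV8-7", d_gene = NA_character_,
      j_gene = "TRAJ19", junction_aa = "CAGADRLQTGMRGAFDL",
      junction_nt = "TGTGCAGGAGCAGATCGACTGCAAACTGGGATGCGAGGAGCATTTGATCTT",
      read_count = sample(5:25, 1), cpm = NA_real_))
    s
  })
  shared <- find_shared_junctions(contam, match_on = "aa", low_read_ceiling = 30)
  expect_equal(nrow(shared), 2)
  expect_true(shared$suspected_contamination[shared$junction == "CAGADRLQTGMRGAFDL"])
  expect_false(shared$suspected_contamination[shared$junction == "CLLGSISLGILSQ"])
})

test_that("pairwise-distinct junctions produce no shared groups", {
  a <- repertoire_sample("A", tibble::tibble(
    locus = "IGH", v_gene = "IGHV1-2", d_gene = NA_character_,
    j_gene = "IGHJ4", junction_aa = "CARAAW", junction_nt = fake_nt(71),
    read_count = 100L))
  b <- repertoire_sample("B", tibble::tibble(
    locus = "IGH", v_gene = "IGHV1-2", d_gene = NA_character_,
    j_gene = "IGHJ4", junction_aa = "CARCCW", junction_nt = fake_nt(72),
    read_count = 100L))
  expect_equal(nrow(find_shared_junctions(list(a, b))), 0)
  expect_error(find_shared_junctions(list(a)), "two samples")
})
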