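test_that("point mutation of a junction is exact, bounded and seeded", {
  nt <- "TGTGCAAGATTTAATCGAGGAGGAGATTATTGG"
  expect_equal(mutate_junction(nt, 0, seed = 1), nt)
  m1 <- mutate_junction(nt, 1, seed = 2)
  expect_equal(sum(strsplit(nt, "")[[1]] != strsplit(m1, "")[[1]]), 1)
  m5 <- mutate_junction(nt, 5, seed = 3)
  expect_equal(sum(strsplit(nt, "")[[1]] != strsplit(m5, "")[[1]]), 5)
  expect_identical(mutate_junction(nt, 3, seed = 42),
                   mutate_junction(nt, 3, seed = 42))
  expect_error(mutate_junction("ACG", 4, seed = 1), "exceeds")
})

test_that("a degenerate monoclonal scenario emits exactly one true clone", {
  cfg <- generator_config("monoclonal", seed = 5, n_samples = 5,
                          shm_subclones = 0, noise_clones = 0,
                          p_nonproductive = 0)
  gen <- generate_repertoire(cfg)
  for (s in gen$samples) {
    kept <- filter_clonotypes(s, 30)$clonotypes
    expect_equal(nrow(kept), 1)
    expect_equal(classify_clonality(s)$category, "monoclonal")
    expect_true(is_productive(kept$junction_aa))
  }
  expect_true(all(gen$truth$true_category == "monoclonal"))
})

test_that("generation is reproducible given the seed", {
  cfg <- generator_config("oligoclonal", seed = 77, n_samples = 4,
                          shm_subclones = 2)
  g1 <- generate_repertoire(cfg)
  g2 <- generate_repertoire(cfg)
  expect_equal(g1$samples, g2$samples)
  expect_equal(g1$truth, g2$truth)
  g3 <- generate_repertoire(generator_config("oligoclonal", seed = 78,
                                             n_samples = 4, shm_subclones = 2))
  expect_false(identical(g1$samples, g3$samples))
})

test_that("SHM offspring share the dominant pattern within the edit bound", {
  cfg <- generator_config("monoclonal", seed = 9, n_samples = 10,
                          shm_subclones = 3, shm_mutations_range = c(1, 3),
                          noise_clones = 0)
  gen <- generate_repertoire(cfg)
  for (s in gen$samples) {
    lin <- gen$lineage[gen$lineage$sample_id == s$sample_id, ]
    expect_equal(nrow(lin), 3)
    ct <- s$clonotypes
    dom <- ct[ct$junction_nt == lin$parent_junction_nt[1], ]
    for (off_nt in lin$offspring_junction_nt) {
      off <- ct[ct$junction_nt == off_nt, ]
      expect_equal(off$v_gene, dom$v_gene)
      expect_equal(off$j_gene, dom$j_gene)
      expect_lte(edit_distance(off$junction_aa, dom$junction_aa), 3L)
    }
    # the whole family clusters as one SHM-derived group of size 4
    locus <- dom$locus
    cl <- cluster_subclones(filter_clonotypes(s, 30), locus)
    expect_equal(cl$pattern[1], "shm_derived")
    expect_equal(cl$n_members[1], 4L)
  }
})

test_that("truth labels equal an independent recount of the emitted table", {
  for (sc in c("monoclonal", "biallelic", "oligoclonal", "polyclonal",
               "non_lymphoid")) {
    cfg <- generator_config(sc, seed = 31, n_samples = 10, shm_subclones = 1)
    gen <- generate_repertoire(cfg)
    recount <- vapply(gen$samples, function(s) {
      kept <- filter_clonotypes(s, 30)$clonotypes
      if (nrow(kept) == 0) return("no_rearrangement")
      cnt <- table(factor(kept$locus, levels = REPERTOIRE_LOCI))
      if (any(cnt[c("IGH", "IGL", "TRA", "TRG", "TRD")] >= 3) ||
          any(cnt[c("IGK", "TRB")] > 4)) "oligo_or_polyclonal"
      else if (nrow(kept) == 1) "monoclonal" else "biallelic_or_biclonal"
    }, character(1))
    expect_equal(unname(recount), gen$truth$true_category)
  }
})

test_that("the dominant clone's fraction lands in the configured range", {
  cfg <- generator_config("oligoclonal", seed = 13, n_samples = 20,
                          dominant_fraction_range = c(0.6, 0.95),
                          noise_clones = 3)
  gen <- generate_repertoire(cfg)
  for (s in gen$samples) {
    fr <- compute_fractions(filter_clonotypes(s, 30), "sample_wide")
    expect_gte(max(fr$fraction), 0.6)
    expect_lte(max(fr$fraction), 0.95)
  }
})

test_that("noise and contamination clones stay below the read threshold", {
  cj <- list(locus = "TRA", v_gene = "TRAV8-7", j_gene = "TRAJ19",
             junction_nt = "TGTGCAGGAGCAGATCGACTGCAAACTGGGATGCGAGGAGCATTTGATCTT")
  cfg <- generator_config("non_lymphoid", seed = 21, n_samples = 6,
                          noise_clones = 4, contamination_junction = cj)
  gen <- generate_repertoire(cfg)
  for (s in gen$samples) {
    expect_true(all(s$clonotypes$read_count < 30))
    expect_true(cj$junction_nt %in% s$clonotypes$junction_nt)
  }
  expect_true(all(gen$truth$true_category == "no_rearrangement"))
  shared <- find_shared_junctions(gen$samples, match_on = "nt")
  hit <- shared[shared$junction == cj$junction_nt, ]
  expect_equal(hit$n_samples, 6L)
  expect_true(hit$suspected_contamination)
})

test_that("generated tables pass validation and round-trip through the TSV", {
  cfg <- generator_config("biallelic", seed = 55, n_samples = 3,
                          p_nonproductive = 0.5)
  gen <- generate_repertoire(cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(gen$samples, tf)
  expect_equal(unname(read_clonotype_table(tf)), unname(gen$samples))
  # junction_aa emitted by the generator is the package's own translation
  for (s in gen$samples) {
    expect_equal(s$clonotypes$junction_aa,
                 translate_junction(s$clonotypes$junction_nt))
  }
})

test_that("configs are validated", {
  expect_error(generator_config("monoclonal"), "seed")
  expect_error(generator_config("monoclonal", seed = 1,
                                n_clones_range = c(2, 3)), "n_clones_range")
  expect_error(generator_config("oligoclonal", seed = 1,
                                dominant_fraction_range = c(0.9, 0.5)))
})
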