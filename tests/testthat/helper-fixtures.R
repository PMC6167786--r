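# Fixtures built in code: published worked examples (reads, gene patterns
# and CDR3 amino-acid strings are the printed inputs; junction nucleotide
# strings are synthetic placeholders where only identity/distinctness
# matters downstream).

# Deterministic distinct ACGT strings (base-4 encoding of an integer).
fake_nt <- function(i, len = 12) {
  vapply(i, function(x) {
    digits <- integer(len)
    for (k in seq_len(len)) {
      digits[k] <- x %% 4
      x <- x %/% 4
    }
    paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
  }, character(1))
}

# Burkitt-lymphoma line with three same-pattern IGH clonotypes whose CDR3s
# differ by a few SHM edits from the dominant.
ca46_sample <- function() {
  repertoire_sample("CA46", tibble::tibble(
    locus = "IGH", v_gene = "IGHV5-51", d_gene = "IGHD5-12", j_gene = "IGHJ4",
    junction_aa = c("CARFNRGGDYW", "CARFDRGGDYW", "CARARFDRGGDYW"),
    junction_nt = fake_nt(1:3),
    read_count = c(9000L, 400L, 150L)))
}

# Burkitt-lymphoma line with four same-pattern IGL clonotypes: one dominant
# plus three barely expressed SHM subclones.
namalwa_sample <- function() {
  repertoire_sample("NAMALWA", tibble::tibble(
    locus = "IGL", v_gene = "IGLV4-60", d_gene = NA_character_,
    j_gene = "IGLJ3",
    junction_aa = c("CQTWGTGIWVF", "CQTWGTGLWVF", "CQTWGAGIWVF", "CQTWGTGIRVF"),
    junction_nt = fake_nt(11:14),
    read_count = c(67629L, 208L, 120L, 116L)))
}

# Unspecified B-cell lymphoma line with six IGL clonotypes across five
# distinct V-J patterns (independent oligoclonality).
nudul1_sample <- function() {
  repertoire_sample("NU-DUL-1", tibble::tibble(
    locus = "IGL",
    v_gene = c("IGLV1-40", "IGLV1-44", "IGLV4-60", "IGLV7-43", "IGLV1-44",
               "IGLV9-49"),
    d_gene = NA_character_,
    j_gene = c("IGLJ2", "IGLJ3", "IGLJ3", "IGLJ3", "IGLJ3", "IGLJ3"),
    junction_aa = c("CQSYDSSLSGWVF", "CAAWDDSLNGPVF", "CQTWGTGIWVF",
                    "CLLYYGGAQVF", "CTSYTSSSTLVF", "CGADHGSGSNFVF"),
    junction_nt = fake_nt(21:26),
    read_count = c(10266L, 3738L, 3005L, 2974L, 1180L, 507L)))
}

# Myeloma line expressing exactly two productive IGK rearrangements
# (biallelic expression), nothing else retained.
kms27_sample <- function() {
  repertoire_sample("KMS-27", tibble::tibble(
    locus = "IGK", v_gene = c("IGKV2-40", "IGKV1-39"),
    d_gene = NA_character_, j_gene = c("IGKJ4", "IGKJ1"),
    junction_aa = c("CMQRIEFPLTF", "CQQSYSTPRTF"),
    junction_nt = fake_nt(31:32),
    read_count = c(625058L, 382112L)))
}

# Five anaplastic large-cell lymphoma lines sharing one TRA junction
# (identity fingerprint) at solid read support.
alcl_samples <- function() {
  reads <- c(170L, 190L, 210L, 230L, 250L)
  lapply(1:5, function(i) {
    repertoire_sample(paste0("ALCL", i), tibble::tibble(
      locus = c("TRA", "TRB"),
      v_gene = c("TRAV40", "TRBV20-1"),
      d_gene = c(NA_character_, "TRBD1"),
      j_gene = c("TRAJ4", "TRBJ2-3"),
      junction_aa = c("CLLGSISLGILSQ", paste0("CSAR", strrep("G", i), "EQYF")),
      junction_nt = c("TGCCTCCTGGGGTCTATCAGCCTGGGAATCCTGTCACAA", fake_nt(40 + i)),
      read_count = c(reads[i], 500L)))
  })
}

# Published per-line clonotype annotations of blood-cancer lines (curated
# plain-text copy shipped with the package).
load_curated_blood_cancer_table <- function() {
  path <- system.file("extdata", "blood_cancer_nonproductive_clonotypes.tsv",
                      package = "repclonality")
  readr::read_tsv(path, col_types = readr::cols(
    read_count = "i", fraction_pct = "d", .default = "c"), na = "")
}

# Integer denominators consistent with a printed anchor fraction (percent,
# two decimals, half-up rounding).
candidate_totals <- function(anchor_reads, anchor_pct) {
  lo <- floor(anchor_reads * 100 / (anchor_pct + 0.005))
  hi <- ceiling(anchor_reads * 100 / (anchor_pct - 0.005))
  t <- lo:hi
  t[round_half_up(100 * anchor_reads / t, 2) == anchor_pct]
}
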