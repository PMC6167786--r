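# Scenario-controlled synthetic repertoire generator.
#
# Emulates the structure of MiXCR-style clonotype tables from lymphocyte
# cell-line RNA-seq: one (or few) dominant rearrangements carrying most of
# the receptor reads, optional somatic-hypermutation subclones sharing the
# dominant V-D-J pattern with slightly mutated junctions, a configurable
# rate of nonproductive junctions, trace-level (<30 reads) noise clones,
# and an optional recurrent contamination junction inserted into every
# sample. Each sample is emitted together with a ground-truth label whose
# category is recomputed from the emitted read counts by an independent
# recount, so truth always reflects what the table actually contains.

CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                paste0), c("T", "C", "A", "G"), paste0))
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)
TRP_CODON <- "TGG"
PHE_CODONS <- c("TTT", "TTC")
CYS_CODONS <- c("TGT", "TGC")

#' Generator configuration
#'
#' Defaults encode the study conditions the analysis assumes: a 30-read
#' retention threshold separating true clones from noise, dominant clones
#' carrying 60-95% of the receptor reads, SHM subclones within a few point
#' mutations of their parent, and RNA-seq libraries of ~1.5e8 reads.
#'
#' @param scenario `"monoclonal"` (one true clone), `"biallelic"` (two
#'   clones at one locus), `"oligoclonal"` (counts just past the per-locus
#'   oligoclonality rule), `"polyclonal"` (many clones across loci) or
#'   `"non_lymphoid"` (no true clones, noise only).
#' @param seed integer seed; every random draw of the generator flows from
#'   it (mandatory).
#' @param n_samples number of samples to generate.
#' @param loci candidate loci for true clones.
#' @param dominant_fraction_range `[lo, hi]` of the dominant clone's
#'   sample-wide read fraction among true clones.
#' @param n_clones_range range of true (>=30 read) clone counts; `NULL`
#'   selects the scenario default (monoclonal 1, biallelic 2, oligoclonal
#'   3-6 for IGH/IGL/TRA-family loci and 5-8 for IGK/TRB, polyclonal 10-25).
#' @param shm_subclones number of SHM offspring attached to the dominant
#'   clone (same V-D-J labels, mutated junction).
#' @param shm_mutations_range range of nucleotide point mutations per
#'   offspring.
#' @param p_nonproductive probability that a generated junction is made
#'   nonproductive (frameshift deletion or injected stop codon).
#' @param noise_clones number of trace clones with 1-29 reads per sample.
#' @param contamination_junction optional list
#'   `(locus, v_gene, j_gene, junction_nt)` inserted into every sample at
#'   1-29 reads, emulating recurrent cross-sample contamination.
#' @param total_rna_reads library size used as the CPM denominator.
#' @param sample_prefix prefix of generated sample ids.
#' @return a `generator_config` list.
#' @export
generator_config <- function(scenario = c("monoclonal", "biallelic",
                                          "oligoclonal", "polyclonal",
                                          "non_lymphoid"),
                             seed,
                             n_samples = 1L,
                             loci = c("IGH", "IGK", "IGL"),
                             dominant_fraction_range = c(0.60, 0.95),
                             n_clones_range = NULL,
                             shm_subclones = 0L,
                             shm_mutations_range = c(1L, 3L),
                             p_nonproductive = 0.1,
                             noise_clones = 2L,
                             contamination_junction = NULL,
                             total_rna_reads = 1.5e8,
                             sample_prefix = "SYN") {
  scenario <- match.arg(scenario)
  if (missing(seed)) rlang::abort("seed is mandatory")
  stopifnot(n_samples >= 1, all(loci %in% REPERTOIRE_LOCI),
            length(dominant_fraction_range) == 2,
            dominant_fraction_range[1] > 0,
            dominant_fraction_range[1] <= dominant_fraction_range[2],
            dominant_fraction_range[2] <= 1,
            shm_subclones >= 0,
            length(shm_mutations_range) == 2,
            shm_mutations_range[1] >= 1,
            shm_mutations_range[1] <= shm_mutations_range[2],
            p_nonproductive >= 0, p_nonproductive <= 1,
            noise_clones >= 0, total_rna_reads > 0)
  if (!is.null(n_clones_range)) {
    stopifnot(length(n_clones_range) == 2,
              n_clones_range[1] <= n_clones_range[2], n_clones_range[1] >= 0)
    fixed <- switch(scenario, monoclonal = c(1L, 1L), biallelic = c(2L, 2L),
                    non_lymphoid = c(0L, 0L), NULL)
    if (!is.null(fixed) && !identical(as.integer(n_clones_range), fixed)) {
      rlang::abort(sprintf("scenario '%s' requires n_clones_range c(%d, %d)",
                           scenario, fixed[1], fixed[2]))
    }
  }
  if (!is.null(contamination_junction)) {
    stopifnot(is.list(contamination_junction),
              all(c("locus", "v_gene", "j_gene", "junction_nt") %in%
                    names(contamination_junction)))
  }
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n_samples = as.integer(n_samples), loci = loci,
                 dominant_fraction_range = dominant_fraction_range,
                 n_clones_range = n_clones_range,
                 shm_subclones = as.integer(shm_subclones),
                 shm_mutations_range = as.integer(shm_mutations_range),
                 p_nonproductive = p_nonproductive,
                 noise_clones = as.integer(noise_clones),
                 contamination_junction = contamination_junction,
                 total_rna_reads = total_rna_reads,
                 sample_prefix = sample_prefix),
            class = "generator_config")
}

# Random in-frame junction: C anchor + random sense codons + W/F anchor.
random_junction_nt <- function(locus, aa_len = sample(9:17, 1)) {
  end <- if (locus %in% c("IGH", "TRB", "TRD", "TRG")) TRP_CODON
         else sample(PHE_CODONS, 1)
  paste0(sample(CYS_CODONS, 1),
         paste(sample(SENSE_CODONS, aa_len - 2, replace = TRUE), collapse = ""),
         end)
}

# Make a productive junction nonproductive: frameshift (delete 1-2 nt) or
# inject an internal stop codon.
make_nonproductive <- function(nt) {
  if (stats::runif(1) < 0.5) {
    k <- sample(1:2, 1)
    pos <- sample(seq_len(nchar(nt) - k), 1)
    paste0(substr(nt, 1, pos - 1), substr(nt, pos + k, nchar(nt)))
  } else {
    codon_i <- sample(2:(nchar(nt) %/% 3 - 1), 1)
    paste0(substr(nt, 1, (codon_i - 1) * 3), sample(STOP_CODONS, 1),
           substr(nt, codon_i * 3 + 1, nchar(nt)))
  }
}

draw_pattern <- function(locus) {
  list(v = sample(segment_vocabulary(locus, "V"), 1),
       d = if (locus %in% D_BEARING_LOCI)
         sample(segment_vocabulary(locus, "D"), 1) else NA_character_,
       j = sample(segment_vocabulary(locus, "J"), 1))
}

#' Point-mutate a junction sequence
#'
#' Substitutes exactly `n_mut` distinct positions (sampled without
#' replacement) to a different base — the point-mutation model used for
#' SHM offspring. Deterministic per seed; the caller's RNG state is left
#' untouched.
#'
#' @param junction_nt an A/C/G/T string.
#' @param n_mut number of substitutions (`0 <= n_mut <= nchar`).
#' @param seed integer seed.
#' @return the mutated string, at Hamming distance exactly `n_mut`.
#' @export
mutate_junction <- function(junction_nt, n_mut, seed) {
  stopifnot(is.character(junction_nt), length(junction_nt) == 1, n_mut >= 0)
  if (grepl("[^ACGT]", junction_nt)) rlang::abort("junction_nt must be A/C/G/T")
  if (n_mut > nchar(junction_nt)) {
    rlang::abort("n_mut exceeds junction length")
  }
  if (n_mut == 0) return(junction_nt)
  withr::with_seed(seed, {
    chars <- strsplit(junction_nt, "", fixed = TRUE)[[1]]
    pos <- sample(length(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}

# Integer partition of `total` over `n` parts, each >= floor_reads:
# floor plus Dirichlet(1)-distributed surplus, largest parts first.
partition_reads <- function(total, n, floor_reads = 30L) {
  if (n == 0) return(integer())
  surplus <- total - n * floor_reads
  if (surplus < 0) rlang::abort("residual read mass too small for the clone count")
  w <- stats::rexp(n)
  extra <- floor(surplus * w / sum(w))
  extra[1] <- extra[1] + (surplus - sum(extra))  # exact total
  sort(as.integer(floor_reads + extra), decreasing = TRUE)
}

# Independent recount of the clonality category implied by a clonotype
# table (the truth label); deliberately minimal and separate from
# classify_clonality().
truth_category <- function(tbl, min_reads = 30L) {
  kept <- tbl[tbl$read_count >= min_reads, , drop = FALSE]
  if (nrow(kept) == 0) return("no_rearrangement")
  cnt <- table(factor(kept$locus, levels = REPERTOIRE_LOCI))
  if (any(cnt[GEQ_OLIGO_LOCI] >= 3) || any(cnt[GT_OLIGO_LOCI] > 4)) {
    return("oligo_or_polyclonal")
  }
  if (nrow(kept) == 1) "monoclonal" else "biallelic_or_biclonal"
}

#' Generate synthetic repertoire samples with ground truth
#'
#' Reproducible given `config$seed`. See [generator_config()] for the
#' scenario semantics. SHM offspring always share the dominant clone's
#' V-D-J labels and sit within `shm_mutations_range` point mutations (hence
#' within that edit distance on the amino-acid level) of its junction.
#'
#' @param config a [generator_config()].
#' @return a list with `samples` (named list of `RepertoireSample`),
#'   `truth` (tibble: `sample_id`, `scenario`, `true_category`) and
#'   `lineage` (tibble mapping SHM offspring junctions to their parent).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    out <- lapply(seq_len(config$n_samples), function(i) {
      generate_one_sample(config, sprintf("%s%04d", config$sample_prefix, i))
    })
  })
  samples <- lapply(out, `[[`, "sample")
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  list(samples = samples,
       truth = purrr::map_dfr(out, `[[`, "truth"),
       lineage = purrr::map_dfr(out, `[[`, "lineage"))
}

generate_one_sample <- function(config, sample_id) {
  sc <- config$scenario
  n_true <- if (!is.null(config$n_clones_range)) {
    sample(config$n_clones_range[1]:config$n_clones_range[2], 1)
  } else NA_integer_

  rows <- list()
  lineage <- tibble::tibble(sample_id = character(),
                            offspring_junction_nt = character(),
                            parent_junction_nt = character())

  if (sc != "non_lymphoid") {
    if (sc == "polyclonal") {
      n_true <- if (is.na(n_true)) sample(10:25, 1) else n_true
      clone_loci <- sample(config$loci, n_true, replace = TRUE)
    } else {
      locus <- sample(config$loci, 1)
      if (is.na(n_true)) {
        n_true <- switch(sc,
          monoclonal = 1L,
          biallelic = 2L,
          oligoclonal = if (locus %in% GT_OLIGO_LOCI) sample(5:8, 1)
                        else sample(3:6, 1))
      }
      clone_loci <- rep(locus, n_true)
    }

    total_rep <- round(stats::rlnorm(1, log(2e4), 0.4))
    f <- stats::runif(1, config$dominant_fraction_range[1] + 1e-3,
                      config$dominant_fraction_range[2] - 1e-3)
    n_minor <- n_true - 1L + config$shm_subclones
    # the residual mass must accommodate a 30-read floor per minor clone
    total_rep <- max(total_rep, ceiling((30 * n_minor + 60) / (1 - f)))
    dom_reads <- as.integer(round(f * total_rep))
    minor_reads <- partition_reads(total_rep - dom_reads, n_minor)
    # keep the dominant genuinely dominant
    while (n_minor > 0 && minor_reads[1] >= dom_reads) {
      minor_reads <- partition_reads(total_rep - dom_reads, n_minor)
    }

    seen_nt <- character()
    new_junction <- function(locus) {
      repeat {
        nt <- random_junction_nt(locus)
        if (stats::runif(1) < config$p_nonproductive) nt <- make_nonproductive(nt)
        if (!nt %in% seen_nt) {
          seen_nt <<- c(seen_nt, nt)
          return(nt)
        }
      }
    }

    dom_pat <- draw_pattern(clone_loci[1])
    dom_nt <- new_junction(clone_loci[1])
    rows[[1]] <- tibble::tibble(
      locus = clone_loci[1], v_gene = dom_pat$v, d_gene = dom_pat$d,
      j_gene = dom_pat$j, junction_nt = dom_nt, read_count = dom_reads)

    ri <- 0L
    if (n_true > 1) {
      for (k in 2:n_true) {
        ri <- ri + 1L
        pat <- draw_pattern(clone_loci[k])
        rows[[length(rows) + 1]] <- tibble::tibble(
          locus = clone_loci[k], v_gene = pat$v, d_gene = pat$d,
          j_gene = pat$j, junction_nt = new_junction(clone_loci[k]),
          read_count = minor_reads[ri])
      }
    }
    if (config$shm_subclones > 0) {
      for (k in seq_len(config$shm_subclones)) {
        ri <- ri + 1L
        repeat {
          n_mut <- sample(config$shm_mutations_range[1]:config$shm_mutations_range[2], 1)
          mut <- mutate_junction(dom_nt, n_mut,
                                 seed = sample.int(.Machine$integer.max, 1))
          if (!mut %in% seen_nt) break
        }
        seen_nt <- c(seen_nt, mut)
        rows[[length(rows) + 1]] <- tibble::tibble(
          locus = clone_loci[1], v_gene = dom_pat$v, d_gene = dom_pat$d,
          j_gene = dom_pat$j, junction_nt = mut, read_count = minor_reads[ri])
        lineage <- dplyr::bind_rows(lineage, tibble::tibble(
          sample_id = sample_id, offspring_junction_nt = mut,
          parent_junction_nt = dom_nt))
      }
    }
  }

  if (config$noise_clones > 0) {
    for (k in seq_len(config$noise_clones)) {
      locus <- sample(REPERTOIRE_LOCI, 1)
      pat <- draw_pattern(locus)
      rows[[length(rows) + 1]] <- tibble::tibble(
        locus = locus, v_gene = pat$v, d_gene = pat$d, j_gene = pat$j,
        junction_nt = random_junction_nt(locus),
        read_count = sample(1:29, 1))
    }
  }
  if (!is.null(config$contamination_junction)) {
    cj <- config$contamination_junction
    rows[[length(rows) + 1]] <- tibble::tibble(
      locus = cj$locus, v_gene = cj$v_gene,
      d_gene = cj$d_gene %||% NA_character_, j_gene = cj$j_gene,
      junction_nt = cj$junction_nt, read_count = sample(1:29, 1))
  }

  tbl <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(locus = character(), v_gene = character(),
                   d_gene = character(), j_gene = character(),
                   junction_nt = character(), read_count = integer())
  if (nrow(tbl) > 0) {
    # drop accidental duplicate keys from noise/contamination collisions
    tbl <- tbl[!duplicated(clonotype_key(tbl)), , drop = FALSE]
    tbl$junction_aa <- translate_junction(tbl$junction_nt)
    tbl$cpm <- compute_cpm(tbl$read_count, config$total_rna_reads)
  }

  sample <- repertoire_sample(sample_id, tbl, cohort = config$scenario,
                              total_rna_reads = config$total_rna_reads)
  list(sample = sample,
       truth = tibble::tibble(sample_id = sample_id,
                              scenario = config$scenario,
                              true_category = truth_category(tbl)),
       lineage = lineage)
}
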