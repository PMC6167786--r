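#' Recognised receptor loci
#'
#' The seven human antigen-receptor loci handled by the package, in the fixed
#' order used for per-locus count vectors.
#' @export
REPERTOIRE_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRG", "TRD")

# Loci whose rearrangements carry a D segment.
D_BEARING_LOCI <- c("IGH", "TRB", "TRD")

# Mandatory per-clonotype columns, in native column order.
CLONOTYPE_COLUMNS <- c("locus", "v_gene", "d_gene", "j_gene",
                       "junction_nt", "junction_aa", "read_count", "cpm")

locus_from_gene <- function(gene) {
  pre <- substr(gene, 1, 3)
  ifelse(pre %in% REPERTOIRE_LOCI, pre, NA_character_)
}

#' Clonotype identity key
#'
#' A clonotype is identified by locus, V/D/J gene labels and the exact
#' junction nucleotide sequence; junctions differing by a single nucleotide
#' are distinct clonotypes.
#'
#' @param tbl a clonotype tibble (columns `locus`, `v_gene`, `d_gene`,
#'   `j_gene`, `junction_nt`).
#' @return character vector of keys, one per row.
#' @export
clonotype_key <- function(tbl) {
  d <- tbl$d_gene
  d[is.na(d)] <- ""
  paste(tbl$locus, tbl$v_gene, d, tbl$j_gene, tbl$junction_nt, sep = "|")
}

validate_clonotypes <- function(tbl, context = "clonotypes") {
  tbl <- tibble::as_tibble(tbl)
  missing <- setdiff(c("locus", "v_gene", "j_gene", "junction_nt", "read_count"),
                     names(tbl))
  if (length(missing) > 0) {
    abort_format(sprintf("%s: missing mandatory column(s): %s",
                         context, paste(missing, collapse = ", ")))
  }
  if (!"d_gene" %in% names(tbl)) tbl$d_gene <- NA_character_
  if (!"junction_aa" %in% names(tbl)) tbl$junction_aa <- NA_character_
  if (!"cpm" %in% names(tbl)) tbl$cpm <- NA_real_

  tbl$locus <- as.character(tbl$locus)
  bad_locus <- !tbl$locus %in% REPERTOIRE_LOCI
  if (any(bad_locus)) {
    abort_format(sprintf("%s: unknown locus value(s): %s", context,
                         paste(unique(tbl$locus[bad_locus]), collapse = ", ")))
  }
  for (col in c("v_gene", "d_gene", "j_gene")) {
    tbl[[col]] <- normalize_gene_name(as.character(tbl[[col]]))
  }

  # locus must agree with gene-name prefixes when those carry a locus prefix
  for (col in c("v_gene", "j_gene")) {
    implied <- locus_from_gene(tbl[[col]])
    clash <- !is.na(implied) & implied != tbl$locus
    if (any(clash)) {
      abort_format(sprintf(
        "%s: %s '%s' is inconsistent with locus '%s'", context, col,
        tbl[[col]][clash][1], tbl$locus[clash][1]))
    }
  }

  tbl$junction_nt <- toupper(as.character(tbl$junction_nt))
  tbl$junction_nt[is.na(tbl$junction_nt)] <- ""
  bad_nt <- grepl("[^ACGT]", tbl$junction_nt)
  if (any(bad_nt)) {
    abort_format(sprintf("%s: junction_nt contains non-ACGT characters (row %d: '%s')",
                         context, which(bad_nt)[1], tbl$junction_nt[bad_nt][1]))
  }
  empty_nt <- tbl$junction_nt == ""
  no_aa <- is.na(tbl$junction_aa) | tbl$junction_aa == ""
  if (any(empty_nt & no_aa)) {
    abort_format(sprintf("%s: row %d has neither junction_nt nor junction_aa",
                         context, which(empty_nt & no_aa)[1]))
  }

  tbl$read_count <- as.integer(tbl$read_count)
  if (anyNA(tbl$read_count) || any(tbl$read_count < 0)) {
    abort_format(sprintf("%s: read_count must be a non-negative integer", context))
  }
  tbl$cpm <- as.numeric(tbl$cpm)

  keys <- clonotype_key(tbl)
  if (anyDuplicated(keys)) {
    abort_format(sprintf("%s: duplicate clonotype key '%s' (merge by summing reads before construction)",
                         context, keys[duplicated(keys)][1]))
  }
  front <- intersect(CLONOTYPE_COLUMNS, names(tbl))
  tbl[, c(front, setdiff(names(tbl), front)), drop = FALSE]
}

#' Construct a repertoire sample
#'
#' A `RepertoireSample` holds one cell line's (or donor's) retained
#' clonotypes together with the CPM denominator and a cohort label.
#'
#' @param sample_id sample identifier.
#' @param clonotypes data frame of clonotypes; mandatory columns `locus`,
#'   `v_gene`, `j_gene`, `junction_nt`, `read_count`; `d_gene`,
#'   `junction_aa`, `cpm` and extras (e.g. `c_gene`) are kept when present.
#'   Junction amino-acid strings may carry the `_` (out-of-frame) and `*`
#'   (stop) markers.
#' @param cohort optional disease-type or population label.
#' @param total_rna_reads optional total RNA-seq read count of the library
#'   (the CPM denominator).
#' @return an object of class `RepertoireSample`.
#' @examples
#' s <- repertoire_sample("CA46", tibble::tibble(
#'   locus = "IGH", v_gene = "IGHV5-51", d_gene = "IGHD5-12",
#'   j_gene = "IGHJ4", junction_nt = "TGTGCCTGG", junction_aa = "CAW",
#'   read_count = 100L))
#' s
#' @export
repertoire_sample <- function(sample_id, clonotypes,
                              cohort = NA_character_,
                              total_rna_reads = NA_real_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1, !is.na(sample_id))
  total_rna_reads <- as.numeric(total_rna_reads)
  if (!is.na(total_rna_reads) && total_rna_reads <= 0) {
    rlang::abort("total_rna_reads must be positive")
  }
  structure(
    list(sample_id = sample_id,
         cohort = as.character(cohort),
         total_rna_reads = total_rna_reads,
         clonotypes = validate_clonotypes(clonotypes, context = sample_id)),
    class = "RepertoireSample")
}

#' @export
print.RepertoireSample <- function(x, ...) {
  cat(sprintf("<RepertoireSample> %s  (cohort: %s)\n", x$sample_id,
              ifelse(is.na(x$cohort), "-", x$cohort)))
  cat(sprintf("  %d clonotype(s), %s total RNA reads\n",
              nrow(x$clonotypes),
              ifelse(is.na(x$total_rna_reads), "unknown",
                     format(x$total_rna_reads, big.mark = ","))))
  tab <- table(x$clonotypes$locus)
  if (length(tab) > 0) {
    cat("  loci:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten repertoire samples into one clonotype table
#'
#' @param samples a `RepertoireSample` or a list of them.
#' @return a tibble with the per-clonotype columns plus `sample_id`,
#'   `total_rna_reads` and `cohort`.
#' @export
as_clonotype_tbl <- function(samples) {
  samples <- as_sample_list(samples)
  purrr::map_dfr(samples, function(s) {
    if (nrow(s$clonotypes) == 0) return(tibble::tibble())
    dplyr::mutate(s$clonotypes,
                  sample_id = s$sample_id,
                  total_rna_reads = s$total_rna_reads,
                  cohort = s$cohort,
                  .before = 1)
  })
}

as_sample_list <- function(samples) {
  if (inherits(samples, "RepertoireSample")) samples <- list(samples)
  if (!is.list(samples) || !all(vapply(samples, inherits, TRUE, "RepertoireSample"))) {
    rlang::abort("expected a RepertoireSample or a list of RepertoireSample objects")
  }
  stats::setNames(samples, vapply(samples, `[[`, "", "sample_id"))
}
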