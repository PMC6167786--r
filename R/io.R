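# Reading and writing clonotype tables.
#
# Native dialect: one TSV row per clonotype with columns
#   sample_id, locus, v_gene, d_gene, j_gene, junction_nt, junction_aa,
#   read_count, cpm, total_rna_reads, cohort
# d_gene absent is an empty cell (TRA/IGK/IGL/TRG rearrangements have no D).
# mixcr_like dialect: best-effort mapping of common MiXCR export column
# names (cloneCount, nSeqCDR3, aaSeqCDR3, bestVHit/allVHitsWithScore, ...);
# the tool's export columns are configurable, so the mapping accepts several
# synonyms per field and strips allele suffixes and alignment scores.

NATIVE_COLUMNS <- c("sample_id", "locus", "v_gene", "d_gene", "j_gene",
                    "junction_nt", "junction_aa", "read_count", "cpm",
                    "total_rna_reads", "cohort")

MIXCR_SYNONYMS <- list(
  sample_id   = c("sample_id", "sample", "sampleId"),
  locus       = c("locus", "chains", "chain"),
  v_gene      = c("bestVHit", "allVHitsWithScore", "bestVGene", "vHit", "v_call"),
  d_gene      = c("bestDHit", "allDHitsWithScore", "bestDGene", "dHit", "d_call"),
  j_gene      = c("bestJHit", "allJHitsWithScore", "bestJGene", "jHit", "j_call"),
  junction_nt = c("nSeqCDR3", "nSeqImputedCDR3", "junction", "targetSequences"),
  junction_aa = c("aaSeqCDR3", "aaSeqImputedCDR3", "junction_aa"),
  read_count  = c("cloneCount", "readCount", "count", "duplicate_count"),
  total_rna_reads = c("total_rna_reads", "totalReads"),
  cohort      = c("cohort")
)

# MiXCR hits look like "IGHV5-51*00(1234.5)"; keep the bare gene name.
strip_mixcr_hit <- function(x) {
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*$", "", x)
  sub("\\*.*$", "", x)
}

map_mixcr_columns <- function(tbl) {
  out <- tibble::tibble(.rows = nrow(tbl))
  for (field in names(MIXCR_SYNONYMS)) {
    hit <- intersect(MIXCR_SYNONYMS[[field]], names(tbl))
    if (length(hit) > 0) out[[field]] <- tbl[[hit[1]]]
  }
  for (col in intersect(c("v_gene", "d_gene", "j_gene"), names(out))) {
    out[[col]] <- strip_mixcr_hit(out[[col]])
  }
  out
}

#' Read a clonotype table
#'
#' Parses a TSV of clonotypes (one row per rearrangement) and assembles one
#' [repertoire_sample()] per distinct `sample_id`. Rows sharing an identity
#' key (locus, V, D, J, exact junction nucleotide sequence) are merged by
#' summing their read counts, keeping the first occurrence's other fields;
#' otherwise input order is preserved. Gzip input is handled by file
#' extension.
#'
#' @param source path to a TSV (optionally `.gz`) file, or a connection.
#' @param dialect `"native"` (the package's lossless column set) or
#'   `"mixcr_like"` (best-effort mapping of common MiXCR export columns;
#'   locus is derived from the V/J gene prefix when no chain column exists).
#' @return a named list of `RepertoireSample` objects, in order of first
#'   appearance.
#' @export
read_clonotype_table <- function(source, dialect = c("native", "mixcr_like")) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  if (dialect == "mixcr_like") tbl <- map_mixcr_columns(tbl)

  required <- c("sample_id", "v_gene", "j_gene", "junction_nt", "read_count")
  missing <- setdiff(required, names(tbl))
  if (!"locus" %in% names(tbl) && dialect == "native") missing <- c("locus", missing)
  if (length(missing) > 0) {
    abort_format(sprintf("missing mandatory column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) return(stats::setNames(list(), character()))

  tbl$.line <- seq_len(nrow(tbl)) + 1L  # +1 for the header line

  # reject rows with unparsable read counts
  reads <- suppressWarnings(as.numeric(tbl$read_count))
  bad <- is.na(reads)
  if (any(bad)) {
    rlang::warn(sprintf("rejected %d row(s) with unparsable read_count (line %s)",
                        sum(bad), paste(tbl$.line[bad], collapse = ", ")))
    tbl <- tbl[!bad, , drop = FALSE]
    reads <- reads[!bad]
  }
  tbl$read_count <- as.integer(round(reads))
  if (nrow(tbl) == 0) return(stats::setNames(list(), character()))

  for (col in c("v_gene", "d_gene", "j_gene")) {
    if (col %in% names(tbl)) tbl[[col]] <- normalize_gene_name(tbl[[col]])
  }
  if (!"d_gene" %in% names(tbl)) tbl$d_gene <- NA_character_
  if (!"locus" %in% names(tbl) || all(is.na(tbl$locus))) {
    tbl$locus <- dplyr::coalesce(locus_from_gene(tbl$v_gene),
                                 locus_from_gene(tbl$j_gene))
  }

  tbl$junction_nt <- toupper(dplyr::coalesce(tbl$junction_nt, ""))
  bad_nt <- grepl("[^ACGT]", tbl$junction_nt)
  if (any(bad_nt)) {
    abort_format(sprintf("junction_nt contains non-ACGT characters at line %d ('%s')",
                         tbl$.line[bad_nt][1], tbl$junction_nt[bad_nt][1]))
  }
  if (!"junction_aa" %in% names(tbl)) tbl$junction_aa <- NA_character_
  need_aa <- is.na(tbl$junction_aa) & tbl$junction_nt != ""
  if (any(need_aa)) tbl$junction_aa[need_aa] <- translate_junction(tbl$junction_nt[need_aa])

  # merge duplicate clonotype keys within a sample (sum reads, keep first row)
  tbl$.key <- paste(tbl$sample_id, clonotype_key(tbl), sep = "@")
  tbl <- tbl |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(read_count = sum(.data$read_count)) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.line)

  if (!"cpm" %in% names(tbl)) tbl$cpm <- NA_character_
  if (!"total_rna_reads" %in% names(tbl)) tbl$total_rna_reads <- NA_character_
  if (!"cohort" %in% names(tbl)) tbl$cohort <- NA_character_
  tbl$cpm <- suppressWarnings(as.numeric(tbl$cpm))
  tbl$total_rna_reads <- suppressWarnings(as.numeric(tbl$total_rna_reads))

  ids <- unique(tbl$sample_id)
  samples <- lapply(ids, function(id) {
    rows <- tbl[tbl$sample_id == id, , drop = FALSE]
    keep <- setdiff(names(rows),
                    c("sample_id", "total_rna_reads", "cohort", ".line", ".key"))
    repertoire_sample(
      sample_id = id,
      clonotypes = rows[, keep, drop = FALSE],
      cohort = rows$cohort[1],
      total_rna_reads = rows$total_rna_reads[1])
  })
  stats::setNames(samples, ids)
}

#' Write clonotype samples as a native-dialect TSV
#'
#' Inverse of [read_clonotype_table()]: reading the written file reproduces
#' the samples field-for-field. Absent D genes (and absent cohort /
#' `total_rna_reads`) are written as empty cells, never as `"NA"` text.
#'
#' @param samples a `RepertoireSample` or list of them.
#' @param sink output path (`.gz` compresses) or connection.
#' @return `sink`, invisibly.
#' @export
write_clonotype_table <- function(samples, sink) {
  samples <- as_sample_list(samples)
  flat <- as_clonotype_tbl(samples)
  if (nrow(flat) == 0) {
    flat <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(NATIVE_COLUMNS)), NATIVE_COLUMNS))
  } else {
    extra <- setdiff(names(flat), NATIVE_COLUMNS)
    flat <- flat[, c(NATIVE_COLUMNS, extra), drop = FALSE]
  }
  readr::write_tsv(flat, sink, na = "", progress = FALSE)
  invisible(sink)
}
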