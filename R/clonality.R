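# Clonotype filtering, CPM, clonal fractions and per-sample clonality calls.
#
# Classification tiers (counts of retained clonotypes per locus):
#   no retained clonotypes                       -> no_rearrangement
#   >=3 IGH, >=3 IGL, >=3 TRA (TRG/TRD likewise),
#     or >4 IGK, >4 TRB                          -> oligo_or_polyclonal
#   exactly one clonotype overall                -> monoclonal
#   otherwise                                    -> biallelic_or_biclonal
# The higher IGK/TRB allowance reflects biallelic + secondary-rearrangement
# capacity of those loci; two clonotypes at one locus may simply be the two
# alleles, hence the "biallelic_or_biclonal" wording.

GEQ_OLIGO_LOCI <- c("IGH", "IGL", "TRA", "TRG", "TRD")  # ">= threshold" family
GT_OLIGO_LOCI  <- c("IGK", "TRB")                        # "> threshold" family

#' Clonality thresholds
#'
#' @param min_reads minimum read support for a clonotype to be retained
#'   (default 30).
#' @param index_min_reads read support defining an "index" rearrangement in
#'   cohort-level summaries (default 100).
#' @param oligo_heavy_lambda per-locus clonotype count at which IGH/IGL/TRA
#'   (and TRG/TRD) call oligo/polyclonality, inclusive (default 3).
#' @param oligo_kappa_beta per-locus clonotype count that IGK/TRB must
#'   exceed (strictly) to call oligo/polyclonality (default 4).
#' @param cpm_noise_ceiling CPM below which a dominant rearrangement is
#'   regarded as baseline noise in non-lymphoid samples (default 0.5).
#' @return a `clonality_thresholds` list.
#' @export
clonality_thresholds <- function(min_reads = 30L, index_min_reads = 100L,
                                 oligo_heavy_lambda = 3L,
                                 oligo_kappa_beta = 4L,
                                 cpm_noise_ceiling = 0.5) {
  min_reads <- as.integer(min_reads)
  index_min_reads <- as.integer(index_min_reads)
  stopifnot(min_reads >= 0, index_min_reads >= min_reads,
            oligo_heavy_lambda >= 1, oligo_kappa_beta >= 1,
            cpm_noise_ceiling >= 0)
  structure(list(min_reads = min_reads,
                 index_min_reads = index_min_reads,
                 oligo_heavy_lambda = as.integer(oligo_heavy_lambda),
                 oligo_kappa_beta = as.integer(oligo_kappa_beta),
                 cpm_noise_ceiling = cpm_noise_ceiling),
            class = "clonality_thresholds")
}

#' Filter clonotypes by read support
#'
#' Retains exactly the clonotypes with `read_count >= min_reads`, preserving
#' order. Idempotent; an empty result is allowed.
#'
#' @param sample a `RepertoireSample`.
#' @param min_reads non-negative read threshold (default 30).
#' @return the filtered `RepertoireSample`.
#' @export
filter_clonotypes <- function(sample, min_reads = 30L) {
  stopifnot(inherits(sample, "RepertoireSample"), min_reads >= 0)
  sample$clonotypes <- sample$clonotypes[sample$clonotypes$read_count >= min_reads, ,
                                         drop = FALSE]
  sample
}

#' Clonal reads per million total RNA-seq reads
#'
#' CPM normalises a clonotype's read support by the sequencing depth of the
#' whole library: `read_count / total_rna_reads * 1e6`.
#'
#' @param read_count clonotype read counts.
#' @param total_rna_reads total RNA-seq reads of the library (positive).
#' @return numeric CPM values.
#' @examples
#' compute_cpm(2517, 178.5e6)
#' @export
compute_cpm <- function(read_count, total_rna_reads) {
  if (any(!is.finite(total_rna_reads) | total_rna_reads <= 0)) {
    rlang::abort("total_rna_reads must be positive")
  }
  read_count / total_rna_reads * 1e6
}

#' Clonotype read fractions
#'
#' Fraction of reads carried by each retained clonotype, either over the
#' whole sample (`sample_wide`, the denominator shared by all loci — the
#' convention of published per-line tables) or within each locus
#' (`per_locus`). Fractions are returned unrounded; display rounding is half
#' up to two decimals via [round_half_up()].
#'
#' @param sample a filtered `RepertoireSample` with at least one clonotype.
#' @param scope `"sample_wide"` or `"per_locus"`.
#' @return the clonotype tibble with an added `fraction` column.
#' @export
compute_fractions <- function(sample, scope = c("sample_wide", "per_locus")) {
  scope <- match.arg(scope)
  stopifnot(inherits(sample, "RepertoireSample"))
  tbl <- sample$clonotypes
  if (nrow(tbl) == 0) rlang::abort("cannot compute fractions of an empty sample")
  if (scope == "sample_wide") {
    tbl$fraction <- tbl$read_count / sum(tbl$read_count)
  } else {
    tbl <- tbl |>
      dplyr::group_by(.data$locus) |>
      dplyr::mutate(fraction = .data$read_count / sum(.data$read_count)) |>
      dplyr::ungroup()
  }
  tbl
}

# Dominant clonotype under the deterministic tie-break:
# read_count descending, then junction_nt ascending.
dominant_clonotype <- function(tbl) {
  if (nrow(tbl) == 0) return(NULL)
  ord <- order(-tbl$read_count, tbl$junction_nt)
  tbl[ord[1], , drop = FALSE]
}

#' Flag light-chain-only expression
#'
#' TRUE when the sample's dominant retained clonotype is a light chain (IGK
#' or IGL) while no IGH clonotype reaches `min_reads` — the expression
#' signature of light-chain multiple myeloma, where the heavy-chain locus is
#' deleted or silenced after rearrangement.
#'
#' @param sample a `RepertoireSample`.
#' @param thresholds a [clonality_thresholds()] object.
#' @return logical scalar.
#' @export
flag_light_chain_only <- function(sample, thresholds = clonality_thresholds()) {
  stopifnot(inherits(sample, "RepertoireSample"))
  kept <- filter_clonotypes(sample, thresholds$min_reads)$clonotypes
  dom <- dominant_clonotype(kept)
  if (is.null(dom)) return(FALSE)
  dom$locus %in% c("IGK", "IGL") && !any(kept$locus == "IGH")
}

#' Classify a sample's clonality
#'
#' Applies the read filter, counts retained clonotypes per locus and assigns
#' the clonality category (see the tier rules in
#' [clonality_thresholds()]). The dominant clonotype is the highest-read
#' retained clonotype (ties: lexicographically smallest junction); its
#' sample-wide fraction, `prominent` status (fraction > 0.90), productivity
#' and the light-chain-only flag are reported alongside.
#'
#' @param sample a `RepertoireSample`.
#' @param thresholds a [clonality_thresholds()] object.
#' @return a `clonality_call` list with elements `sample_id`,
#'   `per_locus_counts`, `category`, `dominant` (one-row tibble or `NULL`),
#'   `dominant_fraction`, `prominent`, `light_chain_only`,
#'   `dominant_nonproductive`.
#' @export
classify_clonality <- function(sample, thresholds = clonality_thresholds()) {
  stopifnot(inherits(sample, "RepertoireSample"),
            inherits(thresholds, "clonality_thresholds"))
  kept <- filter_clonotypes(sample, thresholds$min_reads)
  tbl <- kept$clonotypes
  counts <- vapply(REPERTOIRE_LOCI, function(l) sum(tbl$locus == l), integer(1))

  oligo <- any(counts[GEQ_OLIGO_LOCI] >= thresholds$oligo_heavy_lambda) ||
    any(counts[GT_OLIGO_LOCI] > thresholds$oligo_kappa_beta)
  category <- if (sum(counts) == 0) {
    "no_rearrangement"
  } else if (oligo) {
    "oligo_or_polyclonal"
  } else if (sum(counts) == 1) {
    "monoclonal"
  } else {
    "biallelic_or_biclonal"
  }

  dom <- dominant_clonotype(tbl)
  dom_frac <- NA_real_
  dom_nonprod <- NA
  if (!is.null(dom)) {
    fr <- compute_fractions(kept, "sample_wide")
    dom_frac <- fr$fraction[clonotype_key(fr) == clonotype_key(dom)][1]
    if (!is.na(dom$junction_aa) && dom$junction_aa != "") {
      dom_nonprod <- !is_productive(dom$junction_aa)
    }
  }

  structure(list(
    sample_id = sample$sample_id,
    per_locus_counts = counts,
    category = category,
    dominant = dom,
    dominant_fraction = dom_frac,
    prominent = isTRUE(dom_frac > 0.90),
    light_chain_only = flag_light_chain_only(sample, thresholds),
    dominant_nonproductive = dom_nonprod),
    class = "clonality_call")
}

#' @export
print.clonality_call <- function(x, ...) {
  cat(sprintf("<clonality_call> %s: %s\n", x$sample_id, x$category))
  cat("  counts:", paste(sprintf("%s=%d", names(x$per_locus_counts),
                                 x$per_locus_counts), collapse = " "), "\n")
  if (!is.null(x$dominant)) {
    cat(sprintf("  dominant: %s %s (%d reads, %.2f%%%s)\n",
                x$dominant$locus, x$dominant$junction_aa,
                x$dominant$read_count, 100 * x$dominant_fraction,
                if (x$prominent) ", prominent" else ""))
  }
  invisible(x)
}

#' Clonality calls for a set of samples, flattened
#'
#' @param samples a `RepertoireSample` or list of them.
#' @param thresholds a [clonality_thresholds()] object.
#' @return a tibble with one row per sample: category, per-locus counts
#'   (`n_IGH`, ...), dominant-clone fields and the boolean flags.
#' @export
clonality_calls <- function(samples, thresholds = clonality_thresholds()) {
  samples <- as_sample_list(samples)
  purrr::map_dfr(samples, function(s) {
    call <- classify_clonality(s, thresholds)
    dom <- call$dominant
    counts <- tibble::as_tibble_row(
      stats::setNames(as.list(call$per_locus_counts),
                      paste0("n_", names(call$per_locus_counts))))
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = call$sample_id,
        category = call$category,
        dominant_locus = if (is.null(dom)) NA_character_ else dom$locus,
        dominant_v_gene = if (is.null(dom)) NA_character_ else dom$v_gene,
        dominant_d_gene = if (is.null(dom)) NA_character_ else dom$d_gene,
        dominant_j_gene = if (is.null(dom)) NA_character_ else dom$j_gene,
        dominant_junction_aa = if (is.null(dom)) NA_character_ else dom$junction_aa,
        dominant_read_count = if (is.null(dom)) NA_integer_ else dom$read_count,
        dominant_fraction = call$dominant_fraction,
        prominent = call$prominent,
        light_chain_only = call$light_chain_only,
        dominant_nonproductive = call$dominant_nonproductive),
      counts)
  })
}
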