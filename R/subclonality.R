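# Subclone clustering and cross-sample junction fingerprinting.
#
# Same-pattern clonotypes (identical V-D-J labels) whose CDR3s sit within a
# small edit distance of the dominant member are interpreted as somatic-
# hypermutation offspring of that clone ("Pattern I"); same-locus clonotypes
# with distinct patterns beyond the biallelic allowance arose independently
# ("Pattern II"). The SHM label is a sequence-similarity heuristic, not a
# mutation-model test.

#' Levenshtein distance between amino-acid strings
#'
#' Unit-cost substitution/insertion/deletion edit distance, applied
#' elementwise with recycling. Marker characters (`_`, `*`) participate as
#' ordinary symbols.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @examples
#' edit_distance("CARFNRGGDYW", c("CARFDRGGDYW", "CARARFDRGGDYW"))
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  as.integer(mapply(function(x, y) drop(utils::adist(x, y)), a, b,
                    USE.NAMES = FALSE))
}

# Default SHM edit-distance ceiling: 4, or 30% of the dominant CDR3 length,
# whichever is larger.
default_max_edit <- function(dominant_aa) {
  max(4L, as.integer(ceiling(0.3 * nchar(dominant_aa))))
}

#' Cluster same-pattern clonotypes into subclone groups
#'
#' Clonotypes at one locus are grouped by exact V-D-J pattern. Within a
#' pattern group, members whose `junction_aa` lies within `max_edit` of the
#' group's dominant clonotype form one cluster (`shm_derived` when it has
#' two or more members); members beyond the threshold become their own
#' clusters. Single-member clusters are labelled `independent` when the
#' locus carries more distinct patterns than its biallelic allowance (2 for
#' IGH/IGL/TRA/TRG/TRD, 4 for IGK/TRB), else `singleton`. Clusters
#' partition the sample's clonotypes at the locus.
#'
#' @param sample a `RepertoireSample`, already filtered by read support.
#' @param locus one of [REPERTOIRE_LOCI].
#' @param max_edit maximum Levenshtein distance from the cluster dominant;
#'   `NULL` uses `max(4, ceiling(0.3 * nchar(dominant CDR3)))` per group.
#' @return a tibble with one row per cluster: pattern genes, `pattern`
#'   label, `n_members`, dominant CDR3/reads, `max_edit_distance`, and a
#'   `members` list-column of clonotype tibbles (ordered by read count
#'   descending).
#' @export
cluster_subclones <- function(sample, locus, max_edit = NULL) {
  stopifnot(inherits(sample, "RepertoireSample"),
            locus %in% REPERTOIRE_LOCI)
  tbl <- sample$clonotypes[sample$clonotypes$locus == locus, , drop = FALSE]
  empty <- tibble::tibble(
    sample_id = character(), locus = character(), v_gene = character(),
    d_gene = character(), j_gene = character(), pattern = character(),
    n_members = integer(), dominant_junction_aa = character(),
    dominant_read_count = integer(), max_edit_distance = integer(),
    members = list())
  if (nrow(tbl) == 0) return(empty)

  tbl <- tbl[order(-tbl$read_count, tbl$junction_nt), , drop = FALSE]
  d_for_key <- ifelse(is.na(tbl$d_gene), "", tbl$d_gene)
  pat <- paste(tbl$v_gene, d_for_key, tbl$j_gene, sep = "|")

  clusters <- list()
  for (p in unique(pat)) {
    grp <- tbl[pat == p, , drop = FALSE]
    dom <- grp[1, , drop = FALSE]
    me <- max_edit %||% default_max_edit(dom$junction_aa)
    d <- edit_distance(grp$junction_aa, dom$junction_aa)
    keep <- d <= me
    clusters[[length(clusters) + 1]] <-
      list(members = grp[keep, , drop = FALSE], dist = max(d[keep]))
    for (i in which(!keep)) {
      clusters[[length(clusters) + 1]] <-
        list(members = grp[i, , drop = FALSE], dist = 0L)
    }
  }

  n_patterns <- length(unique(pat))
  allowance <- if (locus %in% GT_OLIGO_LOCI) 4L else 2L
  out <- purrr::map_dfr(clusters, function(cl) {
    m <- cl$members
    tibble::tibble(
      sample_id = sample$sample_id,
      locus = locus,
      v_gene = m$v_gene[1], d_gene = m$d_gene[1], j_gene = m$j_gene[1],
      pattern = if (nrow(m) >= 2) "shm_derived"
                else if (n_patterns > allowance) "independent" else "singleton",
      n_members = nrow(m),
      dominant_junction_aa = m$junction_aa[1],
      dominant_read_count = m$read_count[1],
      max_edit_distance = as.integer(cl$dist),
      members = list(m))
  })
  out[order(-out$dominant_read_count, out$dominant_junction_aa), , drop = FALSE]
}

#' Find junctions shared across samples
#'
#' Groups clonotypes from two or more samples by (locus, V gene, J gene,
#' junction). A recurring junction supported by ample reads in several
#' samples is a genuine shared rearrangement (e.g. an identity fingerprint
#' of sibling cell lines); one seen at trace read counts nearly everywhere
#' is flagged as suspected cross-sample contamination or alignment noise.
#'
#' @param samples a list of two or more `RepertoireSample` objects.
#' @param match_on match junctions on amino-acid (`"aa"`) or nucleotide
#'   (`"nt"`) sequence.
#' @param low_read_ceiling groups whose reads fall below this ceiling in
#'   all, or all-but-one, member samples are flagged
#'   `suspected_contamination` (default 30).
#' @return a tibble sorted by the number of sharing samples (descending):
#'   key columns, `n_samples`, `sample_ids` and `reads` list-columns,
#'   `suspected_contamination`.
#' @export
find_shared_junctions <- function(samples, match_on = c("aa", "nt"),
                                  low_read_ceiling = 30L) {
  match_on <- match.arg(match_on)
  samples <- as_sample_list(samples)
  if (length(samples) < 2) rlang::abort("need at least two samples")
  flat <- as_clonotype_tbl(samples)
  empty <- tibble::tibble(
    locus = character(), v_gene = character(), j_gene = character(),
    junction = character(), n_samples = integer(), sample_ids = list(),
    reads = list(), suspected_contamination = logical())
  if (nrow(flat) == 0) return(empty)

  flat$junction <- if (match_on == "aa") flat$junction_aa else flat$junction_nt
  flat <- flat[!is.na(flat$junction) & flat$junction != "", , drop = FALSE]

  grouped <- flat |>
    dplyr::group_by(.data$locus, .data$v_gene, .data$j_gene, .data$junction,
                    .data$sample_id) |>
    dplyr::summarise(read_count = sum(.data$read_count), .groups = "drop_last") |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      sample_ids = list(.data$sample_id),
      reads = list(stats::setNames(.data$read_count, .data$sample_id)),
      .groups = "drop")
  grouped <- grouped[grouped$n_samples >= 2, , drop = FALSE]
  if (nrow(grouped) == 0) return(empty)

  grouped$suspected_contamination <- vapply(grouped$reads, function(r) {
    sum(r < low_read_ceiling) >= length(r) - 1L
  }, logical(1))
  grouped[order(-grouped$n_samples, grouped$junction), , drop = FALSE]
}
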