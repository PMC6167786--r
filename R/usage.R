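# Samples x gene-segment usage matrices for heatmap export.

#' Gene-segment usage matrix
#'
#' Builds a samples-by-segments matrix for one locus and segment class.
#' In `dominant` mode each row is one-hot on the segment used by the
#' sample's dominant clonotype at the locus; in `all_weighted` mode row
#' entries are read-count-weighted proportions over all retained
#' clonotypes. Either way each row sums to one. Samples with no retained
#' clonotype at the locus (or lacking the segment annotation) are omitted.
#'
#' @param samples a `RepertoireSample` or list of them (already filtered by
#'   read support).
#' @param segment_class `"V"`, `"D"`, `"J"` or `"C"` (`"C"` requires a
#'   `c_gene` column; rows lacking it are skipped with a warning).
#' @param locus one of [REPERTOIRE_LOCI].
#' @param mode `"dominant"` or `"all_weighted"`.
#' @return a `usage_matrix`: a numeric matrix (rows = samples, columns =
#'   built-in vocabulary order plus any extra observed segments) with
#'   attributes `mode`, `normalization`, `segment_class`, `locus`.
#' @export
segment_usage <- function(samples, segment_class = c("V", "D", "J", "C"),
                          locus, mode = c("dominant", "all_weighted")) {
  segment_class <- match.arg(segment_class)
  mode <- match.arg(mode)
  stopifnot(locus %in% REPERTOIRE_LOCI)
  samples <- as_sample_list(samples)
  col <- switch(segment_class, V = "v_gene", D = "d_gene", J = "j_gene",
                C = "c_gene")
  flat <- as_clonotype_tbl(samples)
  vocab <- segment_vocabulary(locus, segment_class)

  if (nrow(flat) > 0) {
    flat <- flat[flat$locus == locus, , drop = FALSE]
    if (!col %in% names(flat)) {
      if (nrow(flat) > 0) {
        rlang::warn(sprintf("no '%s' column; all rows skipped", col))
      }
      flat <- flat[0, , drop = FALSE]
      flat[[col]] <- character()
    } else if (anyNA(flat[[col]])) {
      rlang::warn(sprintf("skipped %d row(s) lacking %s annotation",
                          sum(is.na(flat[[col]])), col))
      flat <- flat[!is.na(flat[[col]]), , drop = FALSE]
    }
  }

  if (nrow(flat) == 0) {
    m <- matrix(numeric(), nrow = 0, ncol = length(vocab),
                dimnames = list(character(), vocab))
    return(new_usage_matrix(m, mode, segment_class, locus))
  }

  if (mode == "dominant") {
    flat <- flat |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::arrange(dplyr::desc(.data$read_count), .data$junction_nt,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::mutate(weight = 1)
  } else {
    flat <- flat |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(weight = .data$read_count / sum(.data$read_count)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$sample_id, segment = .data[[col]]) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  if (mode == "dominant") flat$segment <- flat[[col]]

  cols <- c(vocab, sort(setdiff(unique(flat$segment), vocab)))
  rows <- intersect(names(samples), unique(flat$sample_id))
  m <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  m[cbind(flat$sample_id, flat$segment)] <- flat$weight
  new_usage_matrix(m, mode, segment_class, locus)
}

new_usage_matrix <- function(m, mode, segment_class, locus,
                             normalization = "none") {
  structure(m, mode = mode, segment_class = segment_class, locus = locus,
            normalization = normalization,
            class = c("usage_matrix", class(m)))
}

#' Normalise a usage matrix for heatmap display
#'
#' `zscore` standardises each segment column across samples using the
#' population (n) standard deviation; constant columns map to all zeros.
#' `log2` applies `log2(value + pseudocount)` elementwise.
#'
#' @param m a `usage_matrix` (or plain matrix).
#' @param method `"zscore"` or `"log2"`.
#' @param pseudocount added before `log2`; must be positive when zeros are
#'   present.
#' @return the normalised `usage_matrix` (attribute `normalization` set).
#' @export
normalize_matrix <- function(m, method = c("zscore", "log2"), pseudocount = 1) {
  method <- match.arg(method)
  out <- unclass(m)
  if (method == "zscore") {
    if (nrow(out) > 0) {
      mu <- colMeans(out)
      sd_pop <- sqrt(colMeans(sweep(out, 2, mu)^2))
      out <- sweep(out, 2, mu)
      nz <- sd_pop > 0
      out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd_pop[nz], "/")
      out[, !nz] <- 0
    }
  } else {
    if (pseudocount <= 0 && any(out == 0)) {
      rlang::abort("pseudocount must be positive when zero values are present")
    }
    out <- log2(out + pseudocount)
  }
  new_usage_matrix(out,
                   mode = attr(m, "mode") %||% NA_character_,
                   segment_class = attr(m, "segment_class") %||% NA_character_,
                   locus = attr(m, "locus") %||% NA_character_,
                   normalization = method)
}

#' Mean usage per cohort
#'
#' Group-by mean of usage-matrix rows, e.g. population-level segment-usage
#' profiles. No significance testing is performed.
#'
#' @param m a `usage_matrix`.
#' @param cohorts character vector mapping row (sample) ids to cohort
#'   labels; either named by sample id or in row order.
#' @return a matrix with one row per cohort.
#' @export
aggregate_usage_by_cohort <- function(m, cohorts) {
  if (!is.null(names(cohorts))) cohorts <- cohorts[rownames(m)]
  stopifnot(length(cohorts) == nrow(m))
  rowsum(unclass(m), group = cohorts) / as.vector(table(cohorts)[sort(unique(cohorts))])
}

#' Write a usage matrix as TSV
#'
#' @param m a `usage_matrix` (or plain matrix with row names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_usage_matrix <- function(m, path) {
  tbl <- tibble::as_tibble(unclass(m), rownames = "sample_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
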