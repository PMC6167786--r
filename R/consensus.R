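# CDR3 multiple alignment (center-star), position frequency matrices and
# length distributions.
#
# CDR3s are short (typically 8-20 residues), so a deterministic center-star
# progressive alignment with identity scoring (match +1, mismatch 0,
# gap -1) is adequate for consensus/logo input; a full progressive aligner
# with guide trees would add nothing at these lengths.

# Needleman-Wunsch global alignment of two strings.
# Traceback preference on score ties: diagonal, then up (gap in b), then
# left (gap in a) - fixed so alignments are deterministic.
nw_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

#' Align a set of CDR3 sequences (center-star)
#'
#' The center is the sequence minimising the total pairwise edit distance
#' (ties: longest, then lexicographically smallest); every other sequence
#' is globally aligned to it (match +1, mismatch 0, gap -1) and gaps are
#' propagated into the growing alignment ("once a gap, always a gap").
#' Deterministic. With two sequences the result is exactly their pairwise
#' global alignment.
#'
#' @param seqs character vector of one or more non-empty amino-acid
#'   strings; `_` and `*` markers participate as ordinary symbols.
#' @return a `cdr3_alignment`: list with `sequences` (the inputs),
#'   `aligned` (equal-length gapped strings, `-` gaps, input order) and
#'   `length` (alignment length).
#' @examples
#' align_cdr3_set(c("CARFNRGGDYW", "CARFDRGGDYW", "CARARFDRGGDYW"))
#' @export
align_cdr3_set <- function(seqs) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0 || any(is.na(seqs) | seqs == "")) {
    rlang::abort("need at least one non-empty sequence")
  }
  if (length(seqs) == 1) {
    return(new_cdr3_alignment(seqs, seqs))
  }
  dmat <- utils::adist(seqs)
  total <- rowSums(dmat)
  ord <- order(total, -nchar(seqs), seqs)
  ci <- ord[1]
  center <- seqs[ci]

  # master: gapped center; rows: gapped members in input order (split chars)
  master <- strsplit(center, "", fixed = TRUE)[[1]]
  rows <- vector("list", length(seqs))
  rows[[ci]] <- master
  for (k in setdiff(seq_along(seqs), ci)) {
    p <- nw_align(center, seqs[k])
    pc <- strsplit(p$a, "", fixed = TRUE)[[1]]
    ps <- strsplit(p$b, "", fixed = TRUE)[[1]]
    merged <- merge_into_star(master, rows, pc, ps)
    master <- merged$master
    rows <- merged$rows
    rows[[k]] <- merged$newrow
  }
  new_cdr3_alignment(seqs, vapply(rows, paste, "", collapse = ""))
}

# Merge a pairwise (center, seq) alignment into the master alignment.
# master/rows carry earlier gaps; pc/ps is the new pair. Columns where only
# the master has a gap give the new row a gap; columns where only pc has a
# gap insert a gap column into master and all existing rows.
merge_into_star <- function(master, rows, pc, ps) {
  filled <- !vapply(rows, is.null, logical(1))
  nm <- length(master); np <- length(pc)
  i <- 1L; j <- 1L
  out_master <- character(0)
  out_rows <- rep(list(character(0)), length(rows))
  newrow <- character(0)
  push <- function(mch, rowfun, sch) {
    out_master <<- c(out_master, mch)
    for (k in which(filled)) out_rows[[k]] <<- c(out_rows[[k]], rowfun(k))
    newrow <<- c(newrow, sch)
  }
  while (i <= nm || j <= np) {
    if (i <= nm && master[i] == "-") {
      push("-", function(k) rows[[k]][i], "-"); i <- i + 1L
    } else if (j <= np && pc[j] == "-") {
      push("-", function(k) "-", ps[j]); j <- j + 1L
    } else {
      push(master[i], function(k) rows[[k]][i], ps[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  for (k in which(!filled)) out_rows[k] <- list(NULL)
  list(master = out_master, rows = out_rows, newrow = newrow)
}

new_cdr3_alignment <- function(sequences, aligned) {
  structure(list(sequences = sequences, aligned = aligned,
                 length = nchar(aligned[1])),
            class = "cdr3_alignment")
}

#' @export
print.cdr3_alignment <- function(x, ...) {
  cat(sprintf("<cdr3_alignment> %d sequence(s), length %d\n",
              length(x$aligned), x$length))
  writeLines(utils::head(x$aligned, 10))
  if (length(x$aligned) > 10) cat("...\n")
  invisible(x)
}

#' Position frequency matrix and consensus of an alignment
#'
#' Counts every symbol (including the gap `-`) per alignment column; the
#' consensus takes the most frequent symbol per column, breaking ties
#' alphabetically with the gap losing all ties. Column counts always sum
#' to the number of sequences.
#'
#' @param aln a `cdr3_alignment` from [align_cdr3_set()].
#' @return a `pfm`: list with `length`, `counts` (symbols x positions
#'   integer matrix) and `consensus` (string of alignment length).
#' @export
position_frequency_matrix <- function(aln) {
  stopifnot(inherits(aln, "cdr3_alignment"))
  chars <- do.call(rbind, strsplit(aln$aligned, "", fixed = TRUE))
  symbols <- sort(unique(as.vector(chars)))
  counts <- vapply(seq_len(ncol(chars)), function(j) {
    table(factor(chars[, j], levels = symbols))
  }, integer(length(symbols)))
  counts <- matrix(counts, nrow = length(symbols),
                   dimnames = list(symbols, seq_len(ncol(chars))))
  consensus <- vapply(seq_len(ncol(counts)), function(j) {
    col <- counts[, j]
    top <- names(col)[col == max(col)]
    if (length(top) > 1) top <- setdiff(top, "-")
    sort(top)[1]
  }, character(1))
  structure(list(length = ncol(counts), counts = counts,
                 consensus = paste(consensus, collapse = "")),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> length %d, consensus: %s\n", x$length, x$consensus))
  invisible(x)
}

#' CDR3 length distribution
#'
#' Counts CDR3 amino-acid lengths of either the dominant clonotype of each
#' sample or of all retained clonotypes. The out-of-frame marker `_` is an
#' annotation, not a residue, and is excluded from the length; a stop `*`
#' occupies a residue position and counts.
#'
#' @param samples a `RepertoireSample` or list of them (already filtered).
#' @param which `"dominant"` (one length per sample) or `"all"`.
#' @return a tibble with columns `length` and `count`; counts sum to the
#'   number of contributing clonotypes.
#' @export
cdr3_length_distribution <- function(samples, which = c("dominant", "all")) {
  which <- match.arg(which)
  samples <- as_sample_list(samples)
  flat <- as_clonotype_tbl(samples)
  if (nrow(flat) == 0) {
    return(tibble::tibble(length = integer(), count = integer()))
  }
  if (which == "dominant") {
    flat <- flat |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::arrange(dplyr::desc(.data$read_count), .data$junction_nt,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  flat <- flat[!is.na(flat$junction_aa) & flat$junction_aa != "", , drop = FALSE]
  len <- nchar(gsub("_", "", flat$junction_aa, fixed = TRUE))
  tab <- table(len)
  tibble::tibble(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Export a position frequency matrix as a tall TSV
#'
#' One row per (position, symbol) with a positive count — the input format
#' of sequence-logo tools.
#'
#' @param pfm a `pfm` from [position_frequency_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm"))
  tall <- tibble::tibble(
    position = rep(seq_len(ncol(pfm$counts)), each = nrow(pfm$counts)),
    symbol = rep(rownames(pfm$counts), times = ncol(pfm$counts)),
    count = as.vector(pfm$counts))
  readr::write_tsv(tall[tall$count > 0, ], path, progress = FALSE)
  invisible(path)
}

#' Write consensus sequence(s) as FASTA
#'
#' @param consensus named character vector of consensus strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  nm <- names(consensus) %||% paste0("consensus", seq_along(consensus))
  writeLines(as.vector(rbind(paste0(">", nm), unname(consensus))), path)
  invisible(path)
}
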