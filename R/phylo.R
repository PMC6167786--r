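# Poisson-corrected amino-acid distances and neighbor-joining trees.
#
# Distances are computed on one shared multiple alignment (consistent
# column homology), not on pairwise realignments. The NJ implementation is
# the classical Saitou-Nei agglomeration: at each step join the pair
# minimising Q = (n-2) d_ij - r_i - r_j, with a deterministic tie-break on
# the smallest (i, j) index pair; negative branch lengths are clamped to
# zero at serialization only, so the topology is unaffected.

#' Amino-acid p-distance between two aligned strings
#'
#' Proportion of mismatching columns among columns where neither string has
#' a gap.
#'
#' @param a,b equal-length gapped strings (rows of one alignment).
#' @return the p-distance in `[0, 1]`.
#' @export
pairwise_pdistance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) rlang::abort("aligned strings must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  comp <- av != "-" & bv != "-"
  if (!any(comp)) rlang::abort("no comparable (gap-free) columns")
  mean(av[comp] != bv[comp])
}

#' Poisson multiple-hit correction
#'
#' Converts an amino-acid p-distance into an estimated number of
#' substitutions per site under a Poisson model of replacement:
#' `d = -ln(1 - p)`. Monotone, convex, and `d >= p` on `[0, 1)`.
#'
#' @param p p-distances in `[0, 1)`.
#' @return corrected distances.
#' @examples
#' poisson_correct(c(0, 0.5, 0.9))
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) {
    rlang::abort("p must lie in [0, 1): a saturated distance (p = 1) has no finite correction")
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix over aligned CDR3s
#'
#' Saturated pairs (p = 1, no shared residue) have no finite correction;
#' they are set to the largest finite corrected distance in the matrix plus
#' 1.0, with a warning.
#'
#' @param aln a `cdr3_alignment`, or a character vector of equal-length
#'   gapped strings.
#' @param ids tip labels (default: names of the sequences, else `seq1`...).
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
cdr3_distance_matrix <- function(aln, ids = NULL) {
  seqs <- if (inherits(aln, "cdr3_alignment")) aln$aligned else aln
  stopifnot(is.character(seqs), length(seqs) >= 2)
  n <- length(seqs)
  ids <- ids %||% names(seqs) %||% paste0("seq", seq_len(n))
  if (anyDuplicated(ids)) rlang::abort("tip labels must be unique")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- pairwise_pdistance(seqs[i], seqs[j])
      if (p >= 1) {
        d[i, j] <- d[j, i] <- NA_real_
        saturated <- TRUE
      } else {
        d[i, j] <- d[j, i] <- poisson_correct(p)
      }
    }
  }
  if (saturated) {
    finite_max <- suppressWarnings(max(d, na.rm = TRUE))
    if (!is.finite(finite_max)) rlang::abort("all pairwise distances are saturated")
    rlang::warn(sprintf(
      "%d saturated pair(s) (p = 1) set to max finite distance + 1",
      sum(is.na(d)) / 2))
    d[is.na(d)] <- finite_max + 1
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining. For two taxa the single edge is
#' split at its midpoint; with three taxa the star lengths follow the
#' closed form `l_A = (d_AB + d_AC - d_BC) / 2` (and rotations). The tree
#' is serialized as an unrooted newick string with branch lengths to six
#' decimal places (negative lengths clamped to zero); `newick_full` keeps
#' full precision for numeric work such as additivity checks.
#'
#' @param D a symmetric numeric matrix (zero diagonal, finite entries) with
#'   row/column names as tip labels, or a [stats::dist].
#' @return an `nj_tree`: list with `newick`, `newick_full` and `ids`.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 2) rlang::abort("need at least two taxa")
  if (any(!is.finite(D))) rlang::abort("distance matrix must be finite")
  if (max(abs(D - t(D))) > 1e-9) rlang::abort("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) rlang::abort("diagonal must be zero")
  ids <- rownames(D) %||% paste0("t", seq_len(n))

  fmt6 <- function(x) sprintf("%.6f", pmax(x, 0))
  fmtf <- function(x) sprintf("%.17g", pmax(x, 0))
  disp <- as.list(ids)  # display newick fragments (6 d.p.)
  full <- as.list(ids)  # full-precision fragments
  m <- D

  while (nrow(m) > 3) {
    k <- nrow(m)
    r <- rowSums(m)
    Q <- (k - 2) * m - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, among the Q minima
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- m[i, j] - li
    disp_new <- sprintf("(%s:%s,%s:%s)", disp[[i]], fmt6(li), disp[[j]], fmt6(lj))
    full_new <- sprintf("(%s:%s,%s:%s)", full[[i]], fmtf(li), full[[j]], fmtf(lj))
    dk <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    rownames(m2) <- colnames(m2) <- c(rownames(m)[keep], "")
    m <- m2
    disp <- c(disp[keep], disp_new)
    full <- c(full[keep], full_new)
  }

  if (nrow(m) == 2) {
    h <- m[1, 2] / 2
    newick <- sprintf("(%s:%s,%s:%s);", disp[[1]], fmt6(h), disp[[2]], fmt6(h))
    newick_full <- sprintf("(%s:%s,%s:%s);", full[[1]], fmtf(h), full[[2]], fmtf(h))
  } else {
    la <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
    lb <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
    lc <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      disp[[1]], fmt6(la), disp[[2]], fmt6(lb), disp[[3]], fmt6(lc))
    newick_full <- sprintf("(%s:%s,%s:%s,%s:%s);",
                           full[[1]], fmtf(la), full[[2]], fmtf(lb), full[[3]], fmtf(lc))
  }
  structure(list(newick = newick, newick_full = newick_full, ids = ids),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("<nj_tree> %d tips\n%s\n", length(x$ids), x$newick))
  invisible(x)
}

#' Convert an `nj_tree` to an `ape::phylo` object
#'
#' @param tree an `nj_tree`.
#' @param precise use the full-precision branch lengths (default `TRUE`).
#' @return a `phylo` object.
#' @export
tree_as_phylo <- function(tree, precise = TRUE) {
  stopifnot(inherits(tree, "nj_tree"))
  ape::read.tree(text = if (precise) tree$newick_full else tree$newick)
}

#' Write a tree to a newick file
#'
#' @param tree an `nj_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "nj_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' Write a distance matrix as a square labelled TSV
#'
#' @param D symmetric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  tbl <- tibble::as_tibble(D, rownames = "id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
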