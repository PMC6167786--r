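# Independent oracles used to cross-check the implementation.

# Textbook dynamic-programming Levenshtein distance (unit costs).
dp_edit_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- 0:length(bv)
  for (i in seq_along(av)) {
    cur <- c(i, rep(0, length(bv)))
    for (j in seq_along(bv)) {
      cur[j + 1] <- min(prev[j] + (av[i] != bv[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(bv) + 1]
}

# Brute-force codon-table translation with the same marker convention,
# built on Biostrings' standard genetic code.
oracle_translate <- function(nt) {
  gc_tab <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    k <- n %/% 3
    aa <- if (k > 0) {
      codons <- substring(s, seq(1, 3 * k, 3), seq(3, 3 * k, 3))
      paste(unname(gc_tab[codons]), collapse = "")
    } else ""
    if (n %% 3 != 0) aa <- paste0(aa, "_")
    aa
  }, character(1), USE.NAMES = FALSE)
}

# Score-only Needleman-Wunsch (global, linear gap) for optimality checks.
nw_score_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- gap * (0:length(bv))
  for (i in seq_along(av)) {
    cur <- c(gap * i, rep(0, length(bv)))
    for (j in seq_along(bv)) {
      cur[j + 1] <- max(prev[j] + ifelse(av[i] == bv[j], match, mismatch),
                        prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[length(bv) + 1]
}

# Score of a gapped pair under the same scheme (gap-gap columns excluded).
score_gapped_pair <- function(ga, gb, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(ga, "", fixed = TRUE)[[1]]
  bv <- strsplit(gb, "", fixed = TRUE)[[1]]
  keep <- !(av == "-" & bv == "-")
  av <- av[keep]; bv <- bv[keep]
  sum(ifelse(av == "-" | bv == "-", gap,
             ifelse(av == bv, match, mismatch)))
}

# Random unrooted tree with positive branch lengths; its cophenetic matrix
# is additive by construction.
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.05, 1))
    ape::cophenetic.phylo(tr)
  })
}
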