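#' Round half away from zero
#'
#' Base [round()] rounds half to even; published clonotype tables round half
#' up, so display values use this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(10.625, 0.005), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Replace unicode dash variants (en/em/figure/hyphen) with ASCII "-".
# Published gene names mix dashes ("IGHV5–51" vs "IGHV5-51").
normalize_gene_name <- function(x) {
  out <- gsub("[‐‑‒–—−]", "-", x)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_format <- function(msg) {
  rlang::abort(msg, class = "repclonality_format_error")
}
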