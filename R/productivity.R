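# Junction translation and productivity calling.
#
# A rearrangement is nonproductive when its rendered CDR3 amino-acid string
# carries "_" (out-of-frame: junction length not a multiple of three) or "*"
# (stop codon inside the CDR3). Both markers can co-occur.

#' Translate a VDJ junction with frameshift/stop markers
#'
#' Translates full codons left-to-right with the standard genetic code
#' (stops rendered `*`). When the junction length is not a multiple of
#' three, the trailing incomplete codon is rendered as a single `_`
#' appended after the translated codons — the out-of-frame marker that
#' downstream productivity calling keys on.
#'
#' @param junction_nt character vector of A/C/G/T junction sequences
#'   (empty strings allowed, translating to empty strings).
#' @return character vector of marked amino-acid strings.
#' @examples
#' translate_junction(c("TGTGCCTGG", "TGTTAATGG", "TGTGCCTG"))
#' @export
translate_junction <- function(junction_nt) {
  stopifnot(is.character(junction_nt))
  bad <- regexpr("[^ACGT]", junction_nt)
  if (any(bad > 0, na.rm = TRUE)) {
    i <- which(bad > 0)[1]
    rlang::abort(sprintf(
      "junction_nt[%d] has a non-ACGT character at position %d ('%s')",
      i, bad[i], substr(junction_nt[i], bad[i], bad[i])))
  }
  vapply(junction_nt, function(nt) {
    n <- nchar(nt)
    k <- n %/% 3
    aa <- if (k > 0) {
      paste(seqinr::translate(seqinr::s2c(substr(nt, 1, 3 * k))), collapse = "")
    } else ""
    if (n %% 3 != 0) aa <- paste0(aa, "_")
    aa
  }, character(1), USE.NAMES = FALSE)
}

#' Classify junction productivity from the marker convention
#'
#' @param junction_aa character vector of rendered CDR3 amino-acid strings,
#'   possibly containing the `_` (out-of-frame) and `*` (stop) markers.
#' @return character vector with values `"productive"`, `"out_of_frame"`,
#'   `"stop_codon"` or `"out_of_frame_and_stop"`.
#' @examples
#' classify_productivity(c("CARDRRGEWPPSDYYYYYMDVW", "CSSYTSS_ALGAVF",
#'                         "CAREP*LELFDYW", "CARDRV*QL_PPPLRDYW"))
#' @export
classify_productivity <- function(junction_aa) {
  stopifnot(is.character(junction_aa))
  if (any(is.na(junction_aa) | junction_aa == "")) {
    rlang::abort("empty junction_aa: no junction to classify")
  }
  oof <- grepl("_", junction_aa, fixed = TRUE)
  stp <- grepl("*", junction_aa, fixed = TRUE)
  dplyr::case_when(
    oof & stp ~ "out_of_frame_and_stop",
    oof       ~ "out_of_frame",
    stp       ~ "stop_codon",
    TRUE      ~ "productive")
}

#' @rdname classify_productivity
#' @return for `is_productive`, a logical vector.
#' @export
is_productive <- function(junction_aa) {
  classify_productivity(junction_aa) == "productive"
}
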