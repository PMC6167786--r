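# Built-in germline gene-segment name vocabulary (human, IMGT-style names).
# Used to fix usage-matrix column order and to label simulated clonotypes.
# Names are labels only; no germline sequences are needed downstream.

SEGMENT_VOCABULARY <- list(
  IGH = list(
    V = c("IGHV1-2", "IGHV1-3", "IGHV1-8", "IGHV1-18", "IGHV1-24", "IGHV1-46",
          "IGHV1-69", "IGHV2-5", "IGHV2-26", "IGHV3-7", "IGHV3-9", "IGHV3-11",
          "IGHV3-15", "IGHV3-20", "IGHV3-21", "IGHV3-23", "IGHV3-30",
          "IGHV3-33", "IGHV3-48", "IGHV3-53", "IGHV4-34", "IGHV4-39",
          "IGHV4-59", "IGHV5-51", "IGHV6-1"),
    D = c("IGHD1-1", "IGHD1-20", "IGHD2-2", "IGHD2-8", "IGHD2-15", "IGHD2-21",
          "IGHD3-3", "IGHD3-10", "IGHD3-22", "IGHD4-17", "IGHD4-23",
          "IGHD5-12", "IGHD6-6", "IGHD6-13"),
    J = paste0("IGHJ", 1:6),
    C = c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1",
          "IGHA2", "IGHE")),
  IGK = list(
    V = c("IGKV1-5", "IGKV1-9", "IGKV1-12", "IGKV1-16", "IGKV1-17",
          "IGKV1-27", "IGKV1-33", "IGKV1-39", "IGKV2-24", "IGKV2-28",
          "IGKV2-29", "IGKV2-30", "IGKV2-40", "IGKV3-11", "IGKV3-15",
          "IGKV3-20", "IGKV3D-20", "IGKV4-1", "IGKV5-2", "IGKV6-21"),
    D = character(),
    J = paste0("IGKJ", 1:5),
    C = "IGKC"),
  IGL = list(
    V = c("IGLV1-36", "IGLV1-40", "IGLV1-44", "IGLV1-47", "IGLV1-51",
          "IGLV2-8", "IGLV2-11", "IGLV2-14", "IGLV2-23", "IGLV2-34",
          "IGLV3-1", "IGLV3-10", "IGLV3-19", "IGLV3-21", "IGLV3-25",
          "IGLV4-3", "IGLV4-60", "IGLV4-69", "IGLV5-45", "IGLV6-57",
          "IGLV7-43", "IGLV8-61", "IGLV9-49", "IGLV11-55"),
    D = character(),
    J = paste0("IGLJ", c(1, 2, 3, 6, 7)),
    C = paste0("IGLC", c(1, 2, 3, 6, 7))),
  TRA = list(
    V = c("TRAV1-1", "TRAV1-2", "TRAV2", "TRAV3", "TRAV4", "TRAV5", "TRAV6",
          "TRAV8-1", "TRAV8-2", "TRAV8-6", "TRAV8-7", "TRAV9-2", "TRAV10",
          "TRAV12-1", "TRAV13-1", "TRAV14DV4", "TRAV17", "TRAV19", "TRAV20",
          "TRAV21", "TRAV26-1", "TRAV29DV5", "TRAV38-1", "TRAV40", "TRAV41"),
    D = character(),
    J = c("TRAJ4", "TRAJ8", "TRAJ19", "TRAJ24", "TRAJ33", "TRAJ45",
          "TRAJ49", "TRAJ57"),
    C = "TRAC"),
  TRB = list(
    V = c("TRBV2", "TRBV3-1", "TRBV3-2", "TRBV4-1", "TRBV5-1", "TRBV6-1",
          "TRBV6-5", "TRBV7-2", "TRBV7-9", "TRBV9", "TRBV10-3", "TRBV11-2",
          "TRBV12-3", "TRBV13", "TRBV14", "TRBV15", "TRBV18", "TRBV19",
          "TRBV20-1", "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1", "TRBV30"),
    D = c("TRBD1", "TRBD2"),
    J = c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7)),
    C = c("TRBC1", "TRBC2")),
  TRG = list(
    V = paste0("TRGV", c(2, 3, 4, 5, 8, 9, 10, 11)),
    D = character(),
    J = c("TRGJ1", "TRGJ2", "TRGJP", "TRGJP1", "TRGJP2"),
    C = c("TRGC1", "TRGC2")),
  TRD = list(
    V = paste0("TRDV", 1:3),
    D = paste0("TRDD", 1:3),
    J = paste0("TRDJ", 1:4),
    C = "TRDC")
)

#' Built-in gene-segment vocabulary
#'
#' Fixed germline segment-name lists per locus and segment class. They
#' define the column order of usage matrices and the label pool of the
#' synthetic generator.
#'
#' @param locus one of [REPERTOIRE_LOCI].
#' @param segment_class `"V"`, `"D"`, `"J"` or `"C"`.
#' @return character vector of segment names (possibly empty: loci without
#'   a D segment).
#' @export
segment_vocabulary <- function(locus, segment_class = c("V", "D", "J", "C")) {
  segment_class <- match.arg(segment_class)
  stopifnot(locus %in% REPERTOIRE_LOCI)
  SEGMENT_VOCABULARY[[locus]][[segment_class]]
}
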