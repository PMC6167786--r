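# End-to-end pipeline runner: YAML (or list) config in, staged TSV/JSON/
# newick outputs out. Stages run in a fixed order (classify, subclones,
# fingerprint, usage, consensus, tree); each stage's files are written
# before the next stage starts, so disabling a downstream stage never
# changes upstream outputs. Runs are deterministic given the config (all
# randomness flows from the generator seed); the JSON report's timestamp is
# the only field that varies between identical reruns.

PIPELINE_STAGES <- c("classify", "subclones", "fingerprint", "usage",
                     "consensus", "tree")

#' Run the full repertoire analysis pipeline
#'
#' @param config path to a YAML file, or an equivalent nested list, with
#'   keys:
#'   \describe{
#'     \item{input}{`table:` path of a native-dialect clonotype TSV
#'       (`dialect:` may name `mixcr_like`), or}
#'     \item{generator}{[generator_config()] fields (`scenario`, `seed`,
#'       `n_samples`, ...) to simulate the input instead,}
#'     \item{output_dir}{directory for all outputs (created),}
#'     \item{thresholds}{optional [clonality_thresholds()] fields,}
#'     \item{fraction_scope}{`sample_wide` (default) or `per_locus`,}
#'     \item{stages}{optional subset of `classify, subclones, fingerprint,
#'       usage, consensus, tree`,}
#'     \item{subclones}{optional `locus`, `max_edit`,}
#'     \item{fingerprint}{optional `match_on`, `low_read_ceiling`,}
#'     \item{usage}{optional `locus`, `segment_class`, `mode`,
#'       `normalization` (`none`/`zscore`/`log2`),}
#'     \item{tree}{optional `min_tips` (default 3).}
#'   }
#' @return the run report (also written to `report.json`): per-sample
#'   clonality calls, stage output paths, per-sample errors, and metadata
#'   (config hash, seed, package version, timestamp).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config),
                     c("input", "generator", "output_dir", "thresholds",
                       "fraction_scope", "stages", "subclones", "fingerprint",
                       "usage", "consensus", "tree"))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (is.null(config$output_dir)) rlang::abort("config needs an output_dir")
  if (is.null(config$input) && is.null(config$generator)) {
    rlang::abort("config needs either an input table or a generator block")
  }
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- do.call(clonality_thresholds, config$thresholds %||% list())
  scope <- config$fraction_scope %||% "sample_wide"

  paths <- list()
  errors <- list()
  truth <- NULL

  if (!is.null(config$generator)) {
    gen_cfg <- do.call(generator_config, config$generator)
    gen <- generate_repertoire(gen_cfg)
    samples <- gen$samples
    truth <- gen$truth
    paths$clonotypes <- file.path(out_dir, "clonotypes.tsv")
    write_clonotype_table(samples, paths$clonotypes)
    paths$truth <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(gen$truth, paths$truth, progress = FALSE)
  } else {
    samples <- read_clonotype_table(config$input$table,
                                    dialect = config$input$dialect %||% "native")
  }

  filtered <- lapply(samples, filter_clonotypes, min_reads = th$min_reads)
  calls <- NULL

  if ("classify" %in% stages) {
    calls <- clonality_calls(samples, th)
    paths$clonality <- file.path(out_dir, "clonality_calls.tsv")
    readr::write_tsv(calls, paths$clonality, na = "", progress = FALSE)
    frac <- purrr::map_dfr(filtered, function(s) {
      if (nrow(s$clonotypes) == 0) return(tibble::tibble())
      dplyr::mutate(compute_fractions(s, scope), sample_id = s$sample_id,
                    .before = 1)
    })
    paths$fractions <- file.path(out_dir, "clonotype_fractions.tsv")
    readr::write_tsv(frac, paths$fractions, na = "", progress = FALSE)
  }

  if ("subclones" %in% stages) {
    sub_cfg <- config$subclones %||% list()
    loci <- sub_cfg$locus %||% REPERTOIRE_LOCI
    clusters <- purrr::map_dfr(filtered, function(s) {
      purrr::map_dfr(loci, function(l) {
        tryCatch(cluster_subclones(s, l, max_edit = sub_cfg$max_edit),
                 error = function(e) {
                   errors[[length(errors) + 1]] <<-
                     list(sample_id = s$sample_id, stage = "subclones",
                          message = conditionMessage(e))
                   tibble::tibble()
                 })
      })
    })
    paths$subclones <- file.path(out_dir, "subclone_clusters.tsv")
    readr::write_tsv(dplyr::select(clusters, -dplyr::any_of("members")),
                     paths$subclones, na = "", progress = FALSE)
  }

  if ("fingerprint" %in% stages && length(samples) >= 2) {
    fp_cfg <- config$fingerprint %||% list()
    shared <- find_shared_junctions(
      samples, match_on = fp_cfg$match_on %||% "aa",
      low_read_ceiling = fp_cfg$low_read_ceiling %||% th$min_reads)
    flat_shared <- shared |>
      dplyr::mutate(sample_ids = purrr::map_chr(.data$sample_ids, paste,
                                                collapse = ","),
                    reads = purrr::map_chr(.data$reads, function(r)
                      paste(r, collapse = ",")))
    paths$shared_junctions <- file.path(out_dir, "shared_junctions.tsv")
    readr::write_tsv(flat_shared, paths$shared_junctions, na = "",
                     progress = FALSE)
  }

  if ("usage" %in% stages) {
    us_cfg <- config$usage %||% list()
    us_loci <- us_cfg$locus %||% c("IGH", "IGK", "IGL")
    for (l in us_loci) {
      m <- segment_usage(filtered, segment_class = us_cfg$segment_class %||% "V",
                         locus = l, mode = us_cfg$mode %||% "dominant")
      norm <- us_cfg$normalization %||% "none"
      if (norm != "none") m <- normalize_matrix(m, norm)
      p <- file.path(out_dir, sprintf("usage_%s_%s.tsv", l,
                                      us_cfg$segment_class %||% "V"))
      write_usage_matrix(m, p)
      paths[[paste0("usage_", l)]] <- p
    }
  }

  dominants <- purrr::map_dfr(filtered, function(s) {
    dom <- dominant_clonotype(s$clonotypes)
    if (is.null(dom)) return(tibble::tibble())
    dplyr::mutate(dom, sample_id = s$sample_id, .before = 1)
  })

  if ("consensus" %in% stages && nrow(dominants) > 0) {
    aln <- align_cdr3_set(stats::setNames(dominants$junction_aa,
                                          dominants$sample_id))
    pfm <- position_frequency_matrix(aln)
    paths$pfm <- file.path(out_dir, "cdr3_pfm.tsv")
    write_pfm(pfm, paths$pfm)
    paths$consensus <- file.path(out_dir, "cdr3_consensus.fa")
    write_consensus_fasta(c(dominant_cdr3 = pfm$consensus), paths$consensus)
    lens <- cdr3_length_distribution(filtered, "dominant")
    paths$lengths <- file.path(out_dir, "cdr3_lengths.tsv")
    readr::write_tsv(lens, paths$lengths, progress = FALSE)
  }

  if ("tree" %in% stages) {
    min_tips <- (config$tree %||% list())$min_tips %||% 3
    if (nrow(dominants) >= max(2, min_tips)) {
      aln <- align_cdr3_set(stats::setNames(dominants$junction_aa,
                                            dominants$sample_id))
      D <- cdr3_distance_matrix(aln, ids = dominants$sample_id)
      paths$distances <- file.path(out_dir, "cdr3_distances.tsv")
      write_distance_matrix(D, paths$distances)
      tree <- neighbor_joining(D)
      paths$tree <- file.path(out_dir, "cdr3_nj.nwk")
      write_newick(tree, paths$tree)
    }
  }

  report <- list(
    n_samples = length(samples),
    sample_ids = names(samples),
    stages_run = stages,
    clonality = calls,
    truth = truth,
    outputs = paths,
    errors = errors,
    metadata = list(
      config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
      seed = (config$generator %||% list())$seed,
      thresholds = unclass(th),
      package_version = as.character(utils::packageVersion("repclonality")),
      timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(report)
}
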