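PIPELINE_DEFAULTS <- list(
  mutations = NULL,          # path to the mutation TSV (required)
  transcripts = NULL,        # path to GTF/BED12 (required for annotation)
  transcript_format = "gtf",
  segments = NULL,           # path to SEG (required for the missense analysis)
  output_dir = "aimut_output",
  min_dna_depth = 10,
  min_rna_depth = 10,
  hypermutation_rate = 10,
  exome_size_mb = 38,
  cn_low = -0.15,
  cn_high = 0.15,
  alpha = 1,
  beta = 1,
  bf_threshold = 10,
  nmd_boundary_inclusive = TRUE,
  min_events = 2,
  neglogp_cutoff = 2.5,
  seed = 1
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a flat YAML key-value file (or takes a named list), injects the
#' default thresholds (minimum depths 10/10, Bayes-factor threshold 10,
#' copy-neutral bounds -0.15/0.15, hypermutation rate 10/Mb, inclusive
#' 50-nt boundary) and rejects unknown keys and type mismatches,
#' reporting all problems together.
#'
#' @param config path to a YAML file, or a named list.
#' @return normalized configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  errors <- character(0)
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  for (key in unknown) {
    sug <- agrep(key, names(PIPELINE_DEFAULTS), max.distance = 0.4,
                 value = TRUE)
    errors <- c(errors, paste0("unknown key '", key, "'",
                               if (length(sug) > 0)
                                 paste0(" (did you mean: ",
                                        paste(sug, collapse = ", "), "?)")))
  }
  out <- PIPELINE_DEFAULTS
  for (key in intersect(names(config), names(PIPELINE_DEFAULTS))) {
    out[[key]] <- config[[key]]
  }
  num_keys <- c("min_dna_depth", "min_rna_depth", "hypermutation_rate",
                "exome_size_mb", "cn_low", "cn_high", "alpha", "beta",
                "bf_threshold", "min_events", "neglogp_cutoff", "seed")
  for (key in num_keys) {
    if (!is.numeric(out[[key]]) || length(out[[key]]) != 1) {
      errors <- c(errors, paste0("key '", key, "' must be a single number"))
    }
  }
  if (!is.logical(out$nmd_boundary_inclusive)) {
    errors <- c(errors, "key 'nmd_boundary_inclusive' must be true/false")
  }
  for (key in c("mutations", "transcripts", "segments", "output_dir",
                "transcript_format")) {
    if (!is.null(out[[key]]) &&
        (!is.character(out[[key]]) || length(out[[key]]) != 1)) {
      errors <- c(errors, paste0("key '", key, "' must be a single string"))
    }
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  out
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full allelic-imbalance pipeline
#'
#' Orchestrates the analysis end to end: read inputs, apply the
#' preprocessing funnel (depth filter, hypermutated-sample exclusion,
#' per-sample multi-mutant-gene discard), run the Bayes-factor AI test,
#' annotate truncating mutations for NMD sensitivity and splice-site
#' mutations for donor/acceptor position, run the copy-neutral missense
#' analysis (spectra, transition/transversion, per-gene enrichment,
#' ranked-list export) and write all tables plus a JSON run manifest to
#' the output directory. Rerunning with the same configuration and
#' inputs reproduces identical outputs (the manifest's timestamp
#' aside).
#'
#' @param config path to a YAML configuration or a named list
#'   (see [validate_config()]).
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$mutations)) {
    stop("[input] config must name a 'mutations' table", call. = FALSE)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "aimut",
                   version = as.character(utils::packageVersion("aimut")),
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   seed = cfg$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   input_checksums = list(), stages = list())
  for (key in c("mutations", "transcripts", "segments")) {
    if (!is.null(cfg[[key]])) {
      if (!file.exists(cfg[[key]])) {
        stop("[input] missing file for '", key, "': ", cfg[[key]],
             call. = FALSE)
      }
      manifest$input_checksums[[key]] <-
        unname(tools::md5sum(cfg[[key]]))
    }
  }

  stage_log("input", "reading mutation table ", cfg$mutations)
  records <- read_mutation_table(cfg$mutations)
  reports <- list()

  f <- filter_by_depth(records, cfg$min_dna_depth, cfg$min_rna_depth)
  records <- f$records; reports$depth <- f$report
  stage_log("depth", f$report$records_in, " -> ", f$report$records_out)

  f <- filter_hypermutated(records, cfg$hypermutation_rate,
                           cfg$exome_size_mb)
  records <- f$records; reports$hypermutation <- f$report
  stage_log("hypermutation", length(f$flagged_samples),
            " sample(s) excluded")

  f <- drop_multimutant_genes(records)
  records <- f$records; reports$multi_mutant <- f$report
  stage_log("multi_mutant", f$report$records_in, " -> ",
            f$report$records_out)

  params <- bf_params(cfg$alpha, cfg$beta, cfg$bf_threshold)
  results <- call_allelic_imbalance(records, params)
  stage_log("ai_test", nrow(results), " mutations tested")

  annotations <- NULL
  if (!is.null(cfg$transcripts)) {
    stage_log("annotate", "reading transcript models")
    models <- read_transcript_models(cfg$transcripts,
                                     cfg$transcript_format)
    ptc <- suppressWarnings(
      annotate_ptc_table(results, models, cfg$nmd_boundary_inclusive))
    splice <- suppressWarnings(
      classify_splice_site_table(results, models))
    write.table(ptc, file.path(cfg$output_dir, "ptc_annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(splice, file.path(cfg$output_dir, "splice_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    annotations <- merge(
      data.frame(key = record_key(results), stringsAsFactors = FALSE),
      ptc[, c("key", "region", "nmd_class")], by = "key", all.x = TRUE,
      sort = FALSE)
    stage_log("annotate", nrow(ptc), " PTC annotation(s), ",
              nrow(splice), " splice call(s)")
  }

  write_results(results, file.path(cfg$output_dir, "ai_results.tsv"),
                annotations = annotations, allow_empty = TRUE)
  summary <- category_summary(results, "category")
  write.table(summary, file.path(cfg$output_dir, "category_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(cfg$segments)) {
    stage_log("missense", "copy-neutral missense analysis")
    segments <- read_segments(cfg$segments)
    ms <- results[results$category == "missense", , drop = FALSE]
    f <- filter_copy_neutral(ms, segments, cfg$cn_low, cfg$cn_high)
    reports$copy_neutral <- f$report
    ms <- f$records
    if (nrow(ms) > 0) {
      spectra <- table(spectrum_class(ms$ref, ms$alt), ms$ai_class)
      write.table(as.data.frame(spectra),
                  file.path(cfg$output_dir, "missense_spectra.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tstv <- table(ts_tv(ms$ref, ms$alt), ms$ai_class)
      write.table(as.data.frame(tstv),
                  file.path(cfg$output_dir, "missense_tstv.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- gene_ai_enrichment(ms, "sig_pos_afd", cfg$min_events)
      write.table(enr,
                  file.path(cfg$output_dir, "missense_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      export_ranked_list(enr, file.path(cfg$output_dir,
                                        "missense_sig_pos.rnk"))
    }
  }

  write_funnel(reports, file.path(cfg$output_dir, "funnel.tsv"))
  manifest$stages <- lapply(reports, function(r) {
    list(stage = r$stage_name, records_in = r$records_in,
         records_out = r$records_out, n_removed = length(r$removed_ids))
  })
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "outputs in ", cfg$output_dir)
  invisible(cfg$output_dir)
}
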