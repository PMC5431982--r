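#' Filter report for one preprocessing stage
#'
#' Every filter returns, alongside the surviving records, a small audit
#' object recording how many records went in, how many came out and the
#' keys of the removed ones, so the whole preprocessing funnel can be
#' reconstructed.
#'
#' @param stage_name label for the stage.
#' @param records_in,records_out integer counts.
#' @param removed_ids character vector of removed record keys.
#' @return list of class `filter_report`.
#' @export
filter_report <- function(stage_name, records_in, records_out, removed_ids) {
  stopifnot(records_out == records_in - length(removed_ids),
            records_out >= 0)
  structure(list(stage_name = stage_name,
                 records_in = as.integer(records_in),
                 records_out = as.integer(records_out),
                 removed_ids = as.character(removed_ids)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d (removed %d)\n", x$stage_name,
              x$records_in, x$records_out, length(x$removed_ids)))
  invisible(x)
}

make_filtered <- function(stage, records, keep) {
  list(records = records[keep, , drop = FALSE],
       report = filter_report(stage, nrow(records), sum(keep),
                              record_key(records)[!keep]))
}

#' Filter mutations by sequencing depth
#'
#' Keeps mutations supported by at least `min_dna` reads in the exome
#' data and at least `min_rna` reads in the transcriptome data (total
#' depth = ref + alt; the bound is inclusive).
#'
#' @param records mutation data frame.
#' @param min_dna,min_rna minimum total read depths (default 10/10).
#' @return list with elements `records` (kept rows) and `report`
#'   (a [filter_report()]).
#' @export
filter_by_depth <- function(records, min_dna = 10, min_rna = 10) {
  stopifnot(min_dna >= 0, min_rna >= 0)
  keep <- (records$dna_ref + records$dna_alt) >= min_dna &
    (records$rna_ref + records$rna_alt) >= min_rna
  make_filtered("depth", records, keep)
}

#' Flag hypermutated samples
#'
#' A sample is flagged when its mutation count per megabase of captured
#' exome strictly exceeds `rate_threshold` (default 10 mutations/Mb).
#'
#' @param records mutation data frame.
#' @param rate_threshold mutations per Mb (strict `>`).
#' @param exome_size_mb captured exome size in Mb used as the rate
#'   denominator (default 38).
#' @return character vector of flagged sample ids.
#' @export
flag_hypermutated <- function(records, rate_threshold = 10,
                              exome_size_mb = 38) {
  stopifnot(exome_size_mb > 0)
  if (nrow(records) == 0) return(character(0))
  counts <- table(records$sample_id)
  names(counts)[as.numeric(counts) / exome_size_mb > rate_threshold]
}

#' Remove mutations from hypermutated samples
#'
#' Convenience wrapper combining [flag_hypermutated()] with record
#' removal and a funnel report.
#'
#' @inheritParams flag_hypermutated
#' @return list with `records`, `report` and `flagged_samples`.
#' @export
filter_hypermutated <- function(records, rate_threshold = 10,
                                exome_size_mb = 38) {
  flagged <- flag_hypermutated(records, rate_threshold, exome_size_mb)
  out <- make_filtered("hypermutation", records,
                       !(records$sample_id %in% flagged))
  out$flagged_samples <- flagged
  out
}

#' Discard genes with multiple mutations in the same sample
#'
#' Within each sample, every mutation of a gene carrying two or more
#' mutations in that sample is removed. A gene mutated once in each of
#' two samples is retained in both (per-sample scope).
#'
#' @param records mutation data frame.
#' @return list with `records` and `report`.
#' @export
drop_multimutant_genes <- function(records) {
  if (nrow(records) == 0) return(make_filtered("multi_mutant", records,
                                               logical(0)))
  gkey <- paste(records$sample_id, records$gene, sep = "\r")
  keep <- !(gkey %in% names(which(table(gkey) >= 2)))
  make_filtered("multi_mutant", records, keep)
}

#' Restrict mutations to copy-number-neutral segments
#'
#' Keeps mutations whose position falls inside a same-sample segment
#' with `low < log_ratio < high` (strict on both sides; defaults
#' -0.15/0.15). Mutations not covered by any segment of their sample are
#' removed.
#'
#' @param records mutation data frame.
#' @param segments copy-number segment data frame
#'   (see [read_segments()]).
#' @param low,high open-interval bounds on the log2 copy ratio.
#' @return list with `records` and `report`.
#' @export
filter_copy_neutral <- function(records, segments, low = -0.15,
                                high = 0.15) {
  stopifnot(low < high)
  if (nrow(records) == 0) {
    return(make_filtered("copy_neutral", records, logical(0)))
  }
  neutral <- segments[segments$log_ratio > low & segments$log_ratio < high,
                      , drop = FALSE]
  keep <- rep(FALSE, nrow(records))
  if (nrow(neutral) > 0) {
    mg <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
    sg <- GenomicRanges::GRanges(neutral$chrom,
                                 IRanges::IRanges(neutral$start, neutral$end))
    hits <- GenomicRanges::findOverlaps(mg, sg)
    same <- records$sample_id[S4Vectors::queryHits(hits)] ==
      neutral$sample_id[S4Vectors::subjectHits(hits)]
    keep[unique(S4Vectors::queryHits(hits)[same])] <- TRUE
  }
  make_filtered("copy_neutral", records, keep)
}

#' Write a preprocessing funnel to TSV
#'
#' @param reports list of [filter_report()] objects in stage order.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_funnel <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(stage = r$stage_name, records_in = r$records_in,
               records_out = r$records_out,
               n_removed = length(r$removed_ids))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
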