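#' @importFrom stats aggregate p.adjust rbeta rbinom rnbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' The six somatic mutation categories
#'
#' Category labels used throughout the package: four SNV classes
#' (nonsense, missense, splice_site, silent) and two indel classes
#' (frameshift, inframe).
#'
#' @export
MUTATION_CATEGORIES <- c("nonsense", "missense", "splice_site",
                         "silent", "frameshift", "inframe")

REQUIRED_MUTATION_COLUMNS <- c("sample_id", "gene", "chrom", "pos",
                               "ref", "alt", "category",
                               "dna_ref", "dna_alt", "rna_ref", "rna_alt")

#' Normalize mutation category labels
#'
#' Maps common spellings ("Nonsense", "Splice_Site", "splice-site", ...)
#' onto the canonical lower-case labels in [MUTATION_CATEGORIES].
#'
#' @param x character vector of category labels.
#' @return character vector of canonical labels.
#' @export
normalize_category <- function(x) {
  norm <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  bad <- !(norm %in% MUTATION_CATEGORIES) & !is.na(norm)
  if (any(bad)) {
    stop("unknown mutation category: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  norm
}

#' Unique key identifying a mutation record
#'
#' A mutation is identified by its sample and genomic position
#' (`sample:chrom:pos`). Keys are used in filter reports, ground-truth
#' tables and annotation joins.
#'
#' @param records mutation data frame with `sample_id`, `chrom`, `pos`.
#' @return character vector of keys.
#' @export
record_key <- function(records) {
  paste(records$sample_id, records$chrom, records$pos, sep = ":")
}

validate_mutation_table <- function(df) {
  missing <- setdiff(REQUIRED_MUTATION_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("pos", "dna_ref", "dna_alt", "rna_ref", "rna_alt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]]))) {
      stop("non-numeric value in column '", col, "' at row ",
           which(is.na(v) & !is.na(df[[col]]))[1], call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative value in column '", col, "' at row ",
           which(v < 0)[1], call. = FALSE)
    }
    df[[col]] <- as.integer(round(v))
  }
  df$category <- normalize_category(df$category)
  snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1
  if (any(snv & df$ref == df$alt)) {
    stop("ref and alt alleles identical at row ",
         which(snv & df$ref == df$alt)[1], call. = FALSE)
  }
  if ("ptc_cds_pos" %in% names(df)) {
    df$ptc_cds_pos <- suppressWarnings(as.integer(df$ptc_cds_pos))
  }
  df
}

#' Read a per-mutation allele-count table
#'
#' Reads a tab-separated mutation table with one row per somatic mutation,
#' carrying DNA (exome) and RNA (transcriptome) reference/alternate read
#' counts. Required columns: `sample_id`, `gene`, `chrom`, `pos`, `ref`,
#' `alt`, `category`, `dna_ref`, `dna_alt`, `rna_ref`, `rna_alt`.
#' Optional: `ptc_cds_pos` (1-based CDS position of a premature stop for
#' truncating mutations). Unknown extra columns are preserved untouched.
#'
#' @param path path to a TSV file.
#' @return data frame, one row per mutation, category normalized.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  validate_mutation_table(df)
}

#' Write a mutation table to TSV
#'
#' @param records mutation data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mutation_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments (SEG format)
#'
#' SEG files are tab-separated with columns sample, chromosome, start,
#' end, an optional number-of-markers column, and the segment mean
#' (log2 copy ratio). Column names are matched case-insensitively against
#' common SEG headers.
#'
#' @param path path to a SEG file.
#' @return data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `log_ratio`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  lut <- c(sample = "sample_id", id = "sample_id", sample_id = "sample_id",
           chrom = "chrom", chromosome = "chrom",
           start = "start", loc.start = "start", "loc_start" = "start",
           end = "end", loc.end = "end", "loc_end" = "end",
           seg.mean = "log_ratio", seg_mean = "log_ratio",
           segment_mean = "log_ratio", log_ratio = "log_ratio")
  nm <- tolower(names(df))
  hit <- nm %in% names(lut)
  names(df)[hit] <- unname(lut[nm[hit]])
  need <- c("sample_id", "chrom", "start", "end", "log_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("SEG file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  if (nrow(df) == 0) return(df)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$log_ratio <- as.numeric(df$log_ratio)
  if (any(df$start > df$end)) {
    stop("segment with start > end at row ",
         which(df$start > df$end)[1], call. = FALSE)
  }
  df
}

#' Write copy-number segments to SEG
#'
#' @param segments data frame as returned by [read_segments()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("sample_id", "chrom", "start", "end", "log_ratio")]
  names(out) <- c("sample", "chrom", "start", "end", "seg.mean")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("sample_id", "gene", "chrom", "pos", "category",
                    "dna_vaf", "rna_vaf", "afd", "log10_bf", "ai_class")

#' Write per-mutation allelic-imbalance results
#'
#' Writes the AI result table as TSV with a fixed leading column order
#' (sample, gene, chrom, pos, category, dna_vaf, rna_vaf, afd, log10_bf,
#' ai_class), followed by any annotation columns. Floating-point values
#' are rendered with 6 significant digits.
#'
#' @param results AI result data frame (see [call_allelic_imbalance()]).
#' @param path output path.
#' @param annotations optional data frame joined on `key` (or row order
#'   when no key column is present).
#' @param allow_empty allow writing a header-only file.
#' @return invisibly, the path.
#' @export
write_results <- function(results, path, annotations = NULL,
                          allow_empty = FALSE) {
  if (nrow(results) == 0 && !allow_empty) {
    stop("refusing to write empty result table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  out <- results
  if (!is.null(annotations) && nrow(out) > 0) {
    key <- record_key(out)
    akey <- if ("key" %in% names(annotations)) annotations$key else NULL
    if (!is.null(akey)) {
      idx <- match(key, akey)
      add <- annotations[idx, setdiff(names(annotations), "key"), drop = FALSE]
      rownames(add) <- NULL
      out <- cbind(out, add)
    } else {
      out <- cbind(out, annotations)
    }
  }
  dup <- duplicated(record_key(results))
  if (any(dup)) {
    warning("duplicate (sample, chrom, pos) rows written verbatim: ",
            sum(dup), " duplicate(s)", call. = FALSE)
  }
  lead <- intersect(RESULT_COLUMNS, names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return data frame.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE)
}
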