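#' Construct a transcript model
#'
#' A strand-aware exon/CDS structure used for all premature-termination-
#' codon (PTC) and splice-site geometry. Exons are stored in transcript
#' (5' to 3') order as 1-based inclusive genomic intervals; on the minus
#' strand the first exon is therefore the most 3' genomic interval.
#' `cds_start` and `cds_end` are the genomic positions of the first and
#' last coding base in translation order (so `cds_start > cds_end` on the
#' minus strand).
#'
#' @param transcript_id transcript identifier.
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with integer columns `start`, `end`
#'   (1-based inclusive genomic); any order, sorted internally.
#' @param cds_start,cds_end genomic positions of the translation start
#'   and stop (first and last coding base).
#' @param cds_sequence optional coding nucleotide string (A/C/G/T),
#'   length divisible by 3.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exons, cds_start, cds_end,
                             cds_sequence = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) == 0) stop("transcript has zero exons", call. = FALSE)
  if (any(exons$start > exons$end)) {
    stop("exon with start > end", call. = FALSE)
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id, call. = FALSE)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  tm <- structure(list(
    transcript_id = as.character(transcript_id),
    gene = as.character(gene),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    cds_sequence = cds_sequence
  ), class = "transcript_model")
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(tm$cds_start) || !in_exon(tm$cds_end)) {
    stop("CDS boundary outside exons in transcript ", transcript_id,
         call. = FALSE)
  }
  clen <- cds_length(tm)
  if (is.na(clen) || clen <= 0) {
    stop("CDS orientation inconsistent with strand in transcript ",
         transcript_id, call. = FALSE)
  }
  if (!is.null(cds_sequence)) {
    if (nchar(cds_sequence) != clen) {
      stop("cds_sequence length (", nchar(cds_sequence),
           ") does not match CDS span (", clen, ")", call. = FALSE)
    }
    if (clen %% 3 != 0) {
      stop("CDS length not divisible by 3 in transcript ", transcript_id,
           call. = FALSE)
    }
  }
  tm
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s, %d exon(s), CDS %d nt\n",
              x$transcript_id, x$gene, x$chrom,
              paste(range(c(x$exons$start, x$exons$end)), collapse = "-"),
              x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}

exon_lengths <- function(tm) tm$exons$end - tm$exons$start + 1L

#' Spliced (mature transcript) length in nucleotides
#' @param tm a `transcript_model`.
#' @return integer length.
#' @export
spliced_length <- function(tm) sum(exon_lengths(tm))

#' Map a genomic position to a spliced transcript coordinate
#'
#' Returns the 1-based position of `genomic_pos` along the mature
#' (spliced) transcript, counting from the 5' end in transcript
#' orientation. Intronic positions return `NA`; positions outside the
#' transcript's genomic span raise an error.
#'
#' @param tm a `transcript_model`.
#' @param genomic_pos integer genomic position (1-based).
#' @return integer transcript coordinate or `NA`.
#' @export
genomic_to_transcript <- function(tm, genomic_pos) {
  lo <- min(tm$exons$start); hi <- max(tm$exons$end)
  if (genomic_pos < lo || genomic_pos > hi) {
    stop("position ", genomic_pos, " outside span of transcript ",
         tm$transcript_id, call. = FALSE)
  }
  cum <- c(0L, cumsum(exon_lengths(tm)))
  for (i in seq_len(nrow(tm$exons))) {
    s <- tm$exons$start[i]; e <- tm$exons$end[i]
    if (genomic_pos >= s && genomic_pos <= e) {
      off <- if (tm$strand == "+") genomic_pos - s else e - genomic_pos
      return(cum[i] + off + 1L)
    }
  }
  NA_integer_
}

#' Map a spliced transcript coordinate back to a genomic position
#'
#' @param tm a `transcript_model`.
#' @param t_pos 1-based transcript coordinate.
#' @return integer genomic position.
#' @export
transcript_to_genomic <- function(tm, t_pos) {
  lens <- exon_lengths(tm)
  cum <- cumsum(lens)
  if (t_pos < 1 || t_pos > sum(lens)) {
    stop("transcript coordinate ", t_pos, " out of range", call. = FALSE)
  }
  i <- which(t_pos <= cum)[1]
  off <- t_pos - c(0L, cum)[i] - 1L
  if (tm$strand == "+") tm$exons$start[i] + off else tm$exons$end[i] - off
}

#' Transcript coordinates of the CDS boundaries
#'
#' @param tm a `transcript_model`.
#' @return integer vector `c(start, end)` in spliced coordinates.
#' @export
cds_transcript_span <- function(tm) {
  c(genomic_to_transcript(tm, tm$cds_start),
    genomic_to_transcript(tm, tm$cds_end))
}

#' CDS length in nucleotides
#' @param tm a `transcript_model`.
#' @return integer length, or `NA` if the CDS boundaries are intronic.
#' @export
cds_length <- function(tm) {
  span <- cds_transcript_span(tm)
  if (anyNA(span)) return(NA_integer_)
  span[2] - span[1] + 1L
}

validate_cds_within_exons <- function(chrom_ranges, exon_ranges, id) {
  # chrom_ranges/exon_ranges: data frames with start, end
  ex <- IRanges::IRanges(exon_ranges$start, exon_ranges$end)
  cds <- IRanges::IRanges(chrom_ranges$start, chrom_ranges$end)
  leftover <- IRanges::setdiff(cds, IRanges::intersect(cds, ex))
  if (length(leftover) > 0) {
    stop("CDS outside exon union in transcript ", id, call. = FALSE)
  }
  invisible(TRUE)
}

build_model_from_features <- function(tid, gene, chrom, strand,
                                      exon_df, cds_df) {
  validate_cds_within_exons(cds_df, exon_df, tid)
  if (strand == "+") {
    cds_start <- min(cds_df$start); cds_end <- max(cds_df$end)
  } else {
    cds_start <- max(cds_df$end); cds_end <- min(cds_df$start)
  }
  transcript_model(tid, gene, chrom, strand, exon_df, cds_start, cds_end)
}

#' Read transcript models from GTF or BED12
#'
#' GTF input must carry `exon` and `CDS` features with `gene_id` and
#' `transcript_id` attributes; BED12 input uses the thick range as the
#' CDS and the block name as both transcript and gene identifier (BED
#' 0-based half-open coordinates are converted to 1-based inclusive at
#' this boundary). When a gene has several transcripts, the one with the
#' longest CDS is kept and the choice is reported via `message()`.
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return named list mapping gene symbol to `transcript_model`.
#' @export
read_transcript_models <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  models <- list()
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    df$seqnames <- as.character(df$seqnames)
    df$strand <- as.character(df$strand)
    if (!all(c("gene_id", "transcript_id") %in% names(df))) {
      stop("GTF lacks gene_id/transcript_id attributes", call. = FALSE)
    }
    df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
    for (tid in unique(df$transcript_id)) {
      sub <- df[df$transcript_id == tid, , drop = FALSE]
      ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
      cds <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
      if (nrow(ex) == 0) stop("transcript ", tid, " has zero exons",
                              call. = FALSE)
      if (nrow(cds) == 0) next  # non-coding transcript: skip
      m <- build_model_from_features(tid, sub$gene_id[1], sub$seqnames[1],
                                     sub$strand[1], ex, cds)
      models[[length(models) + 1L]] <- m
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) stop("no records in BED file", call. = FALSE)
    blk <- rtracklayer::blocks(gr)
    for (i in seq_along(gr)) {
      tid <- gr$name[i]
      b <- as.data.frame(IRanges::ranges(blk[[i]]))
      thick <- gr$thick[i]
      cds_df <- data.frame(start = BiocGenerics::start(thick),
                           end = BiocGenerics::end(thick))
      m <- build_model_from_features(
        tid, tid, as.character(GenomicRanges::seqnames(gr)[i]),
        as.character(BiocGenerics::strand(gr)[i]),
        b[, c("start", "end")], cds_df)
      models[[length(models) + 1L]] <- m
    }
  }
  genes <- vapply(models, function(m) m$gene, character(1))
  keep <- list()
  for (g in unique(genes)) {
    cand <- models[genes == g]
    if (length(cand) > 1) {
      lens <- vapply(cand, cds_length, integer(1))
      pick <- which.max(lens)
      message("gene ", g, ": keeping transcript ",
              cand[[pick]]$transcript_id, " (longest CDS of ",
              length(cand), ")")
      cand <- cand[pick]
    }
    keep[[g]] <- cand[[1]]
  }
  keep
}

#' Write transcript models to GTF
#'
#' Emits one `exon` feature per exon and one `CDS` feature per coding
#' exon segment, in deterministic order (genes alphabetically, exons in
#' genomic order), so identical models produce byte-identical files.
#'
#' @param models named list of `transcript_model` (gene -> model).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_transcript_gtf <- function(models, path) {
  lines <- character(0)
  for (g in sort(names(models))) {
    m <- models[[g]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene,
                     m$transcript_id)
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    lines <- c(lines, sprintf("%s\taimut\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, ex$start, ex$end, m$strand, attrs))
    lo <- min(m$cds_start, m$cds_end); hi <- max(m$cds_start, m$cds_end)
    cs <- pmax(ex$start, lo); ce <- pmin(ex$end, hi)
    sel <- cs <= ce
    lines <- c(lines, sprintf("%s\taimut\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, cs[sel], ce[sel], m$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
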