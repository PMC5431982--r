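#' Map a genomic position to a 1-based CDS coordinate
#'
#' Strand-aware mapping through the spliced transcript. Positions in
#' introns or UTRs (inside the transcript span but outside the CDS)
#' return `NA`; positions outside the transcript span raise an error.
#'
#' @param tm a `transcript_model`.
#' @param genomic_pos integer genomic position.
#' @return 1-based CDS nucleotide position, or `NA` when not coding.
#' @export
map_genomic_to_cds <- function(tm, genomic_pos) {
  t_pos <- genomic_to_transcript(tm, genomic_pos)
  if (is.na(t_pos)) return(NA_integer_)
  span <- cds_transcript_span(tm)
  if (t_pos < span[1] || t_pos > span[2]) return(NA_integer_)
  t_pos - span[1] + 1L
}

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

#' Locate the premature stop created by a frameshift by re-translation
#'
#' Naive model: the reference CDS is edited at the variant position
#' (bases inserted or deleted according to the ref/alt allele lengths),
#' then codons are scanned from the translation start; the first stop
#' codon strictly upstream of the (shifted) normal stop is the PTC. The
#' returned position is the 1-based first base of that stop codon in
#' the mutant CDS, which the geometry code treats as the PTC position
#' in the original transcript frame (exact for deletions upstream
#' distances, off by at most the indel length otherwise).
#'
#' @param cds_sequence reference coding sequence (A/C/G/T string).
#' @param cds_pos 1-based CDS position of the variant's first base.
#' @param ref,alt reference and alternate alleles (indel-style: first
#'   base shared anchor).
#' @return integer PTC CDS position, or `NA` when no premature stop is
#'   created.
#' @export
retranslate_frameshift <- function(cds_sequence, cds_pos, ref, alt) {
  n <- nchar(cds_sequence)
  stopifnot(cds_pos >= 1, cds_pos <= n)
  # replace ref by alt starting at cds_pos
  left <- substr(cds_sequence, 1, cds_pos - 1)
  right_start <- cds_pos + nchar(ref)
  right <- if (right_start <= n) substr(cds_sequence, right_start, n) else ""
  mut <- paste0(left, alt, right)
  ncod <- nchar(mut) %/% 3
  if (ncod < 1) return(NA_integer_)
  starts <- seq(1, by = 3, length.out = ncod)
  codons <- substring(mut, starts, starts + 2)
  hit <- which(codons %in% GENETIC_STOPS)
  # ignore a stop that is simply the (possibly shifted) terminal codon
  hit <- hit[hit < ncod]
  if (length(hit) == 0) return(NA_integer_)
  starts[hit[1]]
}

#' Annotate a truncating mutation's premature termination codon
#'
#' Computes, in spliced (mature mRNA) coordinates, the geometry that
#' governs nonsense-mediated decay under the exon-junction-complex
#' model: the distance from the PTC to the 3'-most exon-exon junction,
#' to the start codon, and to the nearest downstream junction, plus a
#' region label and the resulting NMD class.
#'
#' For nonsense SNVs the PTC is the codon containing the mutated base
#' (the codon's first base anchors all distances). For frameshifts an
#' explicit `ptc_cds_pos` on the record is used when present; otherwise
#' the PTC is recovered by [retranslate_frameshift()] when the
#' transcript carries a `cds_sequence`.
#'
#' A PTC at least `50` nt upstream of the last exon-exon junction (and
#' not in the last exon) is classified NMD-sensitive; the boundary at
#' exactly 50 nt is included by default and controlled by
#' `boundary_inclusive`.
#'
#' @param record one-row mutation data frame (category `nonsense` or
#'   `frameshift`).
#' @param tm the gene's `transcript_model`.
#' @param boundary_inclusive treat exactly 50 nt as sensitive
#'   (default TRUE).
#' @return one-row data frame with columns `key`, `transcript_id`,
#'   `ptc_cds_pos`, `exon_index`, `dist_last_junction`,
#'   `dist_start_codon`, `dist_downstream_junction`, `region`,
#'   `nmd_class`.
#' @export
annotate_ptc <- function(record, tm, boundary_inclusive = TRUE) {
  if (!record$category %in% c("nonsense", "frameshift")) {
    stop("annotate_ptc applies to nonsense and frameshift mutations",
         call. = FALSE)
  }
  clen <- cds_length(tm)
  if (record$category == "nonsense") {
    cds_pos <- map_genomic_to_cds(tm, record$pos)
    if (is.na(cds_pos)) {
      stop("nonsense mutation at ", record$pos,
           " does not map into the CDS of ", tm$transcript_id,
           call. = FALSE)
    }
    ptc <- ((cds_pos - 1L) %/% 3L) * 3L + 1L
  } else {
    ptc <- if (!is.null(record$ptc_cds_pos)) record$ptc_cds_pos else NA
    if (is.null(ptc) || is.na(ptc)) {
      if (is.null(tm$cds_sequence)) {
        stop("frameshift record lacks ptc_cds_pos and transcript ",
             tm$transcript_id, " has no cds_sequence for re-translation",
             call. = FALSE)
      }
      cds_pos <- map_genomic_to_cds(tm, record$pos)
      if (is.na(cds_pos)) {
        stop("frameshift position does not map into the CDS", call. = FALSE)
      }
      ptc <- retranslate_frameshift(tm$cds_sequence, cds_pos,
                                    record$ref, record$alt)
      if (is.na(ptc)) {
        stop("no premature stop recovered by re-translation", call. = FALSE)
      }
    }
    ptc <- as.integer(ptc)
  }
  if (ptc < 1 || ptc > clen) {
    stop("PTC CDS position ", ptc, " outside CDS (length ", clen, ")",
         call. = FALSE)
  }
  span <- cds_transcript_span(tm)
  t_pos <- span[1] + ptc - 1L                  # spliced coordinate of PTC
  lens <- exon_lengths(tm)
  cum <- cumsum(lens)
  n_ex <- length(lens)
  exon_index <- which(t_pos <= cum)[1]
  # last exon-exon junction = 3' end of the penultimate exon, in spliced
  # coordinates; undefined for single-exon transcripts
  dist_last <- if (n_ex >= 2) cum[n_ex - 1L] - t_pos else NA_integer_
  dist_down <- if (exon_index < n_ex) cum[exon_index] - t_pos
               else NA_integer_
  sens_cut <- if (boundary_inclusive) 50L else 51L
  region <- if (exon_index == n_ex) {
    "last_exon"
  } else if (exon_index == n_ex - 1L) {
    if (dist_last >= sens_cut) "penultimate_ge50" else "penultimate_lt50"
  } else {
    "other"
  }
  nmd_class <- if (region != "last_exon" && !is.na(dist_last) &&
                   dist_last >= sens_cut) "sensitive" else "insensitive"
  data.frame(key = record_key(record),
             transcript_id = tm$transcript_id,
             ptc_cds_pos = as.integer(ptc),
             exon_index = as.integer(exon_index),
             dist_last_junction = as.integer(dist_last),
             dist_start_codon = as.integer(ptc - 1L),
             dist_downstream_junction = as.integer(dist_down),
             region = region,
             nmd_class = nmd_class,
             stringsAsFactors = FALSE)
}

#' Annotate all truncating mutations in a table
#'
#' Applies [annotate_ptc()] to every nonsense/frameshift record whose
#' gene has a transcript model; records that cannot be annotated (no
#' model, PTC unrecoverable) are skipped with a warning count.
#'
#' @param records mutation data frame.
#' @param models named list of `transcript_model` (gene -> model).
#' @param boundary_inclusive see [annotate_ptc()].
#' @return data frame of PTC annotations (possibly 0 rows).
#' @export
annotate_ptc_table <- function(records, models, boundary_inclusive = TRUE) {
  idx <- which(records$category %in% c("nonsense", "frameshift"))
  out <- list()
  n_skip <- 0L
  for (i in idx) {
    rec <- records[i, , drop = FALSE]
    tm <- models[[rec$gene]]
    if (is.null(tm)) { n_skip <- n_skip + 1L; next }
    ann <- tryCatch(annotate_ptc(rec, tm, boundary_inclusive),
                    error = function(e) NULL)
    if (is.null(ann)) { n_skip <- n_skip + 1L; next }
    out[[length(out) + 1L]] <- ann
  }
  if (n_skip > 0) {
    warning(n_skip, " truncating mutation(s) could not be annotated",
            call. = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(key = character(0), transcript_id = character(0),
                      ptc_cds_pos = integer(0), exon_index = integer(0),
                      dist_last_junction = integer(0),
                      dist_start_codon = integer(0),
                      dist_downstream_junction = integer(0),
                      region = character(0), nmd_class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Intronic splice-site positions of a transcript
#'
#' Internal helper returning, for every intron, the genomic positions of
#' the four canonical splice-site nucleotides in transcript orientation:
#' donor +1/+2 (expected G/T, the intron's first two bases) and acceptor
#' -2/-1 (expected A/G, its last two bases).
#'
#' @param tm a `transcript_model`.
#' @return data frame with columns `pos`, `side`, `offset`,
#'   `canonical_ref`.
#' @keywords internal
splice_site_positions <- function(tm) {
  n_ex <- nrow(tm$exons)
  if (n_ex < 2) {
    return(data.frame(pos = integer(0), side = character(0),
                      offset = integer(0), canonical_ref = character(0)))
  }
  rows <- list()
  for (i in seq_len(n_ex - 1L)) {
    if (tm$strand == "+") {
      don <- tm$exons$end[i] + 1:2          # first two intronic bases
      acc <- tm$exons$start[i + 1L] - 2:1   # last two intronic bases
      acc_off <- c(-2L, -1L)
    } else {
      don <- tm$exons$start[i] - 1:2
      acc <- tm$exons$end[i + 1L] + 2:1
      acc_off <- c(-2L, -1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pos = c(don, acc),
      side = c("donor_5prime", "donor_5prime",
               "acceptor_3prime", "acceptor_3prime"),
      offset = c(1L, 2L, acc_off),
      canonical_ref = c("G", "T", "A", "G"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify a splice-site mutation
#'
#' Assigns a splice-site mutation to the canonical donor (5', GT) or
#' acceptor (3', AG) dinucleotide, strand-aware: donor offsets +1/+2 are
#' the first and second intronic nucleotides after an exon end in
#' transcript orientation; acceptor offsets -2/-1 are the last two
#' intronic nucleotides before the next exon. `canonical_ref` is the
#' expected base in the transcript's sense orientation. Positions
#' deeper than 2 nt into an intron are rejected.
#'
#' @param record one-row mutation data frame (category `splice_site`).
#' @param tm the gene's `transcript_model`.
#' @return one-row data frame with columns `key`, `side`, `offset`,
#'   `canonical_ref`.
#' @export
classify_splice_site <- function(record, tm) {
  if (record$category != "splice_site") {
    stop("classify_splice_site applies to splice_site mutations",
         call. = FALSE)
  }
  sites <- splice_site_positions(tm)
  hit <- which(sites$pos == record$pos)
  if (length(hit) == 0) {
    stop("position ", record$pos, " is not within 2 nt of an intron ",
         "boundary of ", tm$transcript_id, call. = FALSE)
  }
  data.frame(key = record_key(record),
             side = sites$side[hit[1]],
             offset = sites$offset[hit[1]],
             canonical_ref = sites$canonical_ref[hit[1]],
             stringsAsFactors = FALSE)
}

#' Classify all splice-site mutations in a table
#'
#' @param records mutation data frame.
#' @param models named list of `transcript_model`.
#' @return data frame of splice-site calls (unclassifiable records are
#'   skipped with a warning count).
#' @export
classify_splice_site_table <- function(records, models) {
  idx <- which(records$category == "splice_site")
  out <- list(); n_skip <- 0L
  for (i in idx) {
    rec <- records[i, , drop = FALSE]
    tm <- models[[rec$gene]]
    call <- if (is.null(tm)) NULL else
      tryCatch(classify_splice_site(rec, tm), error = function(e) NULL)
    if (is.null(call)) { n_skip <- n_skip + 1L; next }
    out[[length(out) + 1L]] <- call
  }
  if (n_skip > 0) {
    warning(n_skip, " splice-site mutation(s) could not be classified",
            call. = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(key = character(0), side = character(0),
                      offset = integer(0), canonical_ref = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' First-exon features of PTC annotations
#'
#' Flags PTCs in the first exon and passes through the distance to the
#' start codon; a PTC close to the start codon tends to escape NMD.
#'
#' @param annotations data frame from [annotate_ptc_table()].
#' @return data frame with columns `key`, `in_first_exon`,
#'   `dist_start_codon`.
#' @export
first_exon_features <- function(annotations) {
  data.frame(key = annotations$key,
             in_first_exon = annotations$exon_index == 1L,
             dist_start_codon = annotations$dist_start_codon,
             stringsAsFactors = FALSE)
}
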