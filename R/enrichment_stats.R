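#' One-tailed paired t-test of RNA-VAF against DNA-VAF
#'
#' Tests whether the RNA-level mutant allele fraction is systematically
#' lower (`rna_less`, the NMD direction) or higher (`rna_greater`, the
#' intron-retention direction) than the DNA-level fraction, pairing the
#' two VAFs of each mutation.
#'
#' @param results AI result data frame with `dna_vaf` and `rna_vaf`.
#' @param direction `"rna_less"` or `"rna_greater"`.
#' @return list with elements `statistic` (t), `p_value` (one-tailed)
#'   and `df`.
#' @export
paired_vaf_test <- function(results, direction = c("rna_less",
                                                   "rna_greater")) {
  direction <- match.arg(direction)
  d <- results$rna_vaf - results$dna_vaf
  if (length(d) < 2) stop("need at least 2 paired observations",
                          call. = FALSE)
  if (sd(d) <= 10 * .Machine$double.eps * max(1, abs(mean(d)))) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  alt <- if (direction == "rna_less") "less" else "greater"
  tt <- stats::t.test(results$rna_vaf, results$dna_vaf, paired = TRUE,
                      alternative = alt)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Cell layout: row 1 = focal group (significant, non-significant),
#' row 2 = background (significant, non-significant). The `greater`
#' alternative tests enrichment of cell `a`. The p-value is computed
#' directly from the conditional hypergeometric distribution
#' ([stats::dhyper()]) over all tables with the observed margins:
#' `greater` sums the tail at and beyond `a`; `two_sided` sums every
#' table whose conditional probability does not exceed that of the
#' observed table (the same rule as [stats::fisher.test()], which this
#' function matches but is much faster to call in bulk).
#'
#' @param a,b,c_,d_ non-negative integer cells.
#' @param alternative `"two_sided"` or `"greater"`.
#' @return the exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_,
                             alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c_, d_)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  if (sum(cells) == 0) stop("all-zero contingency table", call. = FALSE)
  r1 <- a + b; r2 <- c_ + d_; k <- a + c_
  x <- max(0, k - r2):min(r1, k)
  d <- stats::dhyper(x, r1, r2, k)
  if (alternative == "greater") {
    sum(d[x >= a])
  } else {
    min(1, sum(d[d <= d[x == a] * (1 + 1e-7)]))
  }
}

#' Six-class mutation spectrum of an SNV
#'
#' Collapses the 12 possible substitutions onto the six strand-symmetric
#' classes (C:G>A:T, C:G>G:C, C:G>T:A, T:A>A:T, T:A>C:G, T:A>G:C): a
#' purine-reference substitution is reported as its reverse complement
#' (e.g. G>T and C>A are both C:G>A:T).
#'
#' @param ref,alt single-nucleotide characters (vectorized).
#' @return character vector of class labels.
#' @export
spectrum_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid nucleotide", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  pair <- c(C = "C:G", T = "T:A")
  partner <- c(A = "T", C = "G", G = "C", T = "A")
  sprintf("%s>%s:%s", pair[r], a, partner[a])
}

#' Transition / transversion class of an SNV
#'
#' @param ref,alt single-nucleotide characters (vectorized).
#' @return character vector: `"transition"` (A<->G, C<->T) or
#'   `"transversion"`.
#' @export
ts_tv <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid nucleotide", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[ref] == purine[alt], "transition", "transversion"))
}

#' Pearson chi-square test of independence
#'
#' Classic contingency-table test (no continuity correction, so the 2x2
#' statistic equals the squared two-proportion z statistic).
#'
#' @param counts matrix or table of class-by-group counts (at least
#'   2 rows and 2 columns).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Cumulative event-ratio curve
#'
#' For each bin edge `k * bin_width` (k = 1, 2, ...), counts all
#' observations with `value < edge` (cumulative, left-closed at 0,
#' right-open) and the events among them, and reports the event ratio.
#' This is the construction behind "sig-neg-AFD ratio versus distance"
#' curves where the x-axis is a cumulative scale marked every
#' `bin_width` units.
#'
#' @param values numeric covariate per mutation (e.g. distance in nt).
#' @param event_flags logical vector, same length.
#' @param bin_width positive bin width.
#' @param max_value largest edge to report (edges run up to the first
#'   multiple of `bin_width` >= `max_value`).
#' @return data frame with columns `bin_upper_edge`, `n_total`,
#'   `n_event`, `ratio` (`NA` where `n_total` is 0).
#' @export
cumulative_ratio_curve <- function(values, event_flags, bin_width,
                                   max_value = max(values)) {
  stopifnot(length(values) == length(event_flags), bin_width > 0)
  edges <- seq(bin_width, by = bin_width,
               length.out = max(1, ceiling(max_value / bin_width)))
  n_total <- vapply(edges, function(e) sum(values < e), integer(1))
  n_event <- vapply(edges, function(e) sum(event_flags[values < e]),
                    integer(1))
  data.frame(bin_upper_edge = edges, n_total = n_total,
             n_event = n_event,
             ratio = ifelse(n_total > 0, n_event / n_total, NA_real_))
}

#' Per-gene enrichment of an allelic-imbalance class
#'
#' For each gene, a one-sided Fisher's exact test on the 2x2 table
#' (gene focal-class, gene other; background focal-class, background
#' other) where the background is all other genes in the result set.
#' The score column `neg_log10_p` feeds the ranked-list export. A
#' Benjamini-Hochberg adjusted p-value is emitted alongside for
#' reference but is not used for filtering.
#'
#' @param results AI result data frame with `gene` and `ai_class`.
#' @param focal_class `"sig_pos_afd"` or `"sig_neg_afd"`.
#' @param min_events genes with fewer focal events are excluded from
#'   the report (default 1).
#' @return data frame with columns `gene`, `n_mutations`, `n_focal`,
#'   `p_fisher`, `neg_log10_p`, `p_bh`, sorted by descending
#'   `neg_log10_p` with alphabetical tie-break.
#' @export
gene_ai_enrichment <- function(results,
                               focal_class = c("sig_pos_afd",
                                               "sig_neg_afd"),
                               min_events = 1) {
  focal_class <- match.arg(focal_class)
  focal <- results$ai_class == focal_class
  genes <- sort(unique(results$gene))
  n_all <- nrow(results)
  n_focal_all <- sum(focal)
  rows <- lapply(genes, function(g) {
    in_g <- results$gene == g
    a <- sum(focal & in_g)
    b <- sum(!focal & in_g)
    cc <- n_focal_all - a
    dd <- (n_all - n_focal_all) - b
    data.frame(gene = g, n_mutations = a + b, n_focal = a,
               p_fisher = fisher_exact_2x2(a, b, cc, dd, "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_fisher, method = "BH")
  out <- out[out$n_focal >= min_events, , drop = FALSE]
  out$neg_log10_p <- -log10(out$p_fisher)
  out <- out[order(-out$neg_log10_p, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "n_mutations", "n_focal", "p_fisher", "neg_log10_p",
          "p_bh")]
}

#' Export a ranked gene list (.rnk style)
#'
#' Two tab-separated columns (gene, score) sorted by descending
#' `neg_log10_p`, ties broken alphabetically, suitable as a preranked
#' gene-set-enrichment input.
#'
#' @param enrichment data frame from [gene_ai_enrichment()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_ranked_list <- function(enrichment, path) {
  ord <- order(-enrichment$neg_log10_p, enrichment$gene)
  out <- enrichment[ord, c("gene", "neg_log10_p")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
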