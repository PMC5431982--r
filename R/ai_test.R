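#' Parameters of the allelic-imbalance Bayes-factor test
#'
#' The test compares, for each mutation, the DNA-level and RNA-level
#' mutant allele counts under two models: H1, independent binomial
#' proportions each with a Beta(alpha, beta) prior, versus H0, a single
#' shared proportion with the same prior. The Bayes factor BF10 is the
#' ratio of the two marginal likelihoods; a mutation is called
#' significant when BF10 strictly exceeds `bf_threshold`.
#'
#' @param alpha,beta Beta prior shapes (default uniform, Beta(1,1)).
#' @param bf_threshold Bayes-factor significance cutoff (default 10).
#' @return list of class `bf_params`.
#' @export
bf_params <- function(alpha = 1, beta = 1, bf_threshold = 10) {
  stopifnot(alpha > 0, beta > 0, bf_threshold > 0)
  structure(list(alpha = alpha, beta = beta,
                 bf_threshold = bf_threshold), class = "bf_params")
}

#' Variant allele frequency
#'
#' Fraction of reads supporting the mutant allele among all reads at the
#' site: `alt / (alt + ref)`.
#'
#' @param alt_count,ref_count non-negative integer read counts
#'   (vectorized).
#' @return numeric fraction(s) in \[0, 1\].
#' @export
compute_vaf <- function(alt_count, ref_count) {
  if (any(alt_count < 0) || any(ref_count < 0)) {
    stop("negative read count", call. = FALSE)
  }
  total <- alt_count + ref_count
  if (any(total == 0)) {
    stop("VAF undefined at zero total depth (depth-filter first)",
         call. = FALSE)
  }
  alt_count / total
}

#' Allelic fraction difference
#'
#' RNA-VAF minus DNA-VAF, in \[-1, 1\]. Positive values mean the mutant
#' allele is over-represented in the transcriptome relative to the
#' genome; negative values mean depletion of the mutant transcript.
#'
#' @param dna_vaf,rna_vaf fractions in \[0, 1\] (vectorized).
#' @return numeric difference(s).
#' @export
compute_afd <- function(dna_vaf, rna_vaf) {
  stopifnot(all(dna_vaf >= 0 & dna_vaf <= 1),
            all(rna_vaf >= 0 & rna_vaf <= 1))
  rna_vaf - dna_vaf
}

#' log10 Bayes factor for a DNA/RNA allele-count pair
#'
#' Closed-form conjugate computation. With counts (kD of nD) and
#' (kR of nR) and prior Beta(a, b), the marginal likelihoods are
#' products/sums of Beta functions (binomial coefficients cancel in the
#' ratio):
#' \deqn{BF_{10} = \frac{B(a+k_D, b+n_D-k_D)\,B(a+k_R, b+n_R-k_R)}
#'   {B(a,b)\,B(a+k_D+k_R, b+n_D+n_R-k_D-k_R)}}
#' Everything is computed in log space via `lbeta`.
#'
#' @param dna_alt,dna_total,rna_alt,rna_total integer counts
#'   (vectorized); totals must be positive and alt counts within totals.
#' @param params a [bf_params()] object.
#' @return numeric log10(BF10); positive values favor distinct DNA and
#'   RNA proportions.
#' @export
log10_bayes_factor <- function(dna_alt, dna_total, rna_alt, rna_total,
                               params = bf_params()) {
  if (any(dna_total <= 0) || any(rna_total <= 0)) {
    stop("totals must be positive", call. = FALSE)
  }
  if (any(dna_alt < 0) || any(rna_alt < 0) ||
      any(dna_alt > dna_total) || any(rna_alt > rna_total)) {
    stop("alt counts must lie in [0, total]", call. = FALSE)
  }
  a <- params$alpha; b <- params$beta
  log_m1 <- lbeta(a + dna_alt, b + dna_total - dna_alt) +
    lbeta(a + rna_alt, b + rna_total - rna_alt) - 2 * lbeta(a, b)
  log_m0 <- lbeta(a + dna_alt + rna_alt,
                  b + dna_total + rna_total - dna_alt - rna_alt) -
    lbeta(a, b)
  (log_m1 - log_m0) / log(10)
}

#' Classify a mutation's allelic-imbalance status
#'
#' `sig_pos_afd` when AFD > 0 and BF10 strictly exceeds the threshold;
#' `sig_neg_afd` when AFD < 0 and BF10 exceeds the threshold; otherwise
#' `no_sig` (including AFD exactly 0 and BF exactly at the threshold).
#'
#' @param dna_vaf,rna_vaf fractions (vectorized).
#' @param log10_bf log10 Bayes factor(s).
#' @param params a [bf_params()] object.
#' @return character vector of `"sig_pos_afd"`, `"sig_neg_afd"`,
#'   `"no_sig"`.
#' @export
classify_ai <- function(dna_vaf, rna_vaf, log10_bf,
                        params = bf_params()) {
  afd <- compute_afd(dna_vaf, rna_vaf)
  sig <- log10_bf > log10(params$bf_threshold)
  ifelse(sig & afd > 0, "sig_pos_afd",
         ifelse(sig & afd < 0, "sig_neg_afd", "no_sig"))
}

#' Run the allelic-imbalance test on a mutation table
#'
#' Computes DNA-VAF, RNA-VAF, AFD, the log10 Bayes factor and the AI
#' class for every record. Records must have positive DNA and RNA
#' depths (apply [filter_by_depth()] first).
#'
#' @param records mutation data frame.
#' @param params a [bf_params()] object.
#' @return the input data frame with columns `dna_vaf`, `rna_vaf`,
#'   `afd`, `log10_bf`, `ai_class` appended.
#' @export
call_allelic_imbalance <- function(records, params = bf_params()) {
  out <- records
  dna_total <- records$dna_ref + records$dna_alt
  rna_total <- records$rna_ref + records$rna_alt
  out$dna_vaf <- compute_vaf(records$dna_alt, records$dna_ref)
  out$rna_vaf <- compute_vaf(records$rna_alt, records$rna_ref)
  out$afd <- compute_afd(out$dna_vaf, out$rna_vaf)
  out$log10_bf <- log10_bayes_factor(records$dna_alt, dna_total,
                                     records$rna_alt, rna_total, params)
  out$ai_class <- classify_ai(out$dna_vaf, out$rna_vaf, out$log10_bf,
                              params)
  out
}

#' Summarize AI calls by group
#'
#' For each combination of the grouping columns, reports the number of
#' mutations, the counts of significantly positive/negative AFD calls
#' and the corresponding ratios (class count divided by group total,
#' matching the per-tumor-type "sig-neg-AFD ratio").
#'
#' @param results AI result data frame
#'   (from [call_allelic_imbalance()]).
#' @param group_keys character vector of column names to group by.
#' @return data frame with columns `<group_keys>`, `n`, `n_sig_pos`,
#'   `n_sig_neg`, `sig_pos_ratio`, `sig_neg_ratio`; empty groups are
#'   omitted.
#' @export
category_summary <- function(results, group_keys = "category") {
  stopifnot(all(group_keys %in% names(results)))
  if (nrow(results) == 0) {
    return(data.frame())
  }
  g <- interaction(results[group_keys], drop = TRUE, sep = "\r")
  n <- as.vector(table(g))
  pos <- as.vector(tapply(results$ai_class == "sig_pos_afd", g, sum))
  neg <- as.vector(tapply(results$ai_class == "sig_neg_afd", g, sum))
  keyvals <- do.call(rbind, strsplit(levels(g), "\r", fixed = TRUE))
  out <- as.data.frame(keyvals, stringsAsFactors = FALSE)
  names(out) <- group_keys
  out$n <- n
  out$n_sig_pos <- pos
  out$n_sig_neg <- neg
  out$sig_pos_ratio <- pos / n
  out$sig_neg_ratio <- neg / n
  rownames(out) <- NULL
  out
}

#' Depth-cutoff sensitivity grid
#'
#' Re-applies the depth filter over a grid of minimum DNA and RNA read
#' cutoffs and reports, per cutoff pair and mutation category, the
#' proportions of sig-pos-AFD, sig-neg-AFD and non-significant calls
#' (the three sum to 1 within each cell). VAFs and Bayes factors do not
#' depend on the cutoffs, so the test is run once on all records with
#' positive depth and only the filtering is repeated.
#'
#' @param records mutation data frame.
#' @param dna_cutoffs,rna_cutoffs integer vectors of minimum depths.
#' @param params a [bf_params()] object.
#' @return data frame with columns `min_dna`, `min_rna`, `category`,
#'   `n`, `sig_pos_ratio`, `sig_neg_ratio`, `no_sig_ratio`.
#' @export
threshold_grid <- function(records, dna_cutoffs = seq(0, 50, 10),
                           rna_cutoffs = seq(0, 50, 10),
                           params = bf_params()) {
  stopifnot(length(dna_cutoffs) > 0, length(rna_cutoffs) > 0)
  positive <- (records$dna_ref + records$dna_alt) > 0 &
    (records$rna_ref + records$rna_alt) > 0
  res <- call_allelic_imbalance(records[positive, , drop = FALSE], params)
  dna_total <- res$dna_ref + res$dna_alt
  rna_total <- res$rna_ref + res$rna_alt
  rows <- list()
  for (md in dna_cutoffs) {
    for (mr in rna_cutoffs) {
      sub <- res[dna_total >= md & rna_total >= mr, , drop = FALSE]
      if (nrow(sub) == 0) next
      s <- category_summary(sub, "category")
      s$min_dna <- md
      s$min_rna <- mr
      s$no_sig_ratio <- 1 - s$sig_pos_ratio - s$sig_neg_ratio
      rows[[length(rows) + 1L]] <- s[, c("min_dna", "min_rna", "category",
                                         "n", "sig_pos_ratio",
                                         "sig_neg_ratio", "no_sig_ratio")]
    }
  }
  do.call(rbind, rows)
}
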