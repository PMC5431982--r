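# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the Bayes-factor oracle integrates the
# marginal likelihoods numerically, the geometry oracle walks the
# spliced sequence nucleotide by nucleotide, and the Fisher oracle
# enumerates the hypergeometric support explicitly.

# log10 Bayes factor by 1-D numerical quadrature of the beta-binomial
# marginals (binomial coefficients cancel between numerator and
# denominator and are omitted on both sides).
quad_log10_bf <- function(kD, nD, kR, nR, a = 1, b = 1) {
  lik <- function(k, n) {
    integrate(function(p) p^k * (1 - p)^(n - k) * dbeta(p, a, b),
              0, 1, rel.tol = 1e-12)$value
  }
  m1 <- lik(kD, nD) * lik(kR, nR)
  m0 <- lik(kD + kR, nD + nR)
  log10(m1 / m0)
}

# Nucleotide-by-nucleotide spliced walk over a transcript model: builds
# the explicit genomic coordinate of every spliced position, then reads
# all PTC geometry off that vector by counting.
oracle_ptc_geometry <- function(tm, ptc_cds_pos) {
  walk <- integer(0)
  exon_of <- integer(0)
  for (i in seq_len(nrow(tm$exons))) {
    g <- tm$exons$start[i]:tm$exons$end[i]
    if (tm$strand == "-") g <- rev(g)
    walk <- c(walk, g)
    exon_of <- c(exon_of, rep(i, length(g)))
  }
  t_cds_start <- which(walk == tm$cds_start)
  t_pos <- t_cds_start + ptc_cds_pos - 1L
  n_ex <- nrow(tm$exons)
  exon_index <- exon_of[t_pos]
  dist_last <- if (n_ex >= 2) sum(exon_of <= n_ex - 1L) - t_pos
               else NA_integer_
  dist_down <- if (exon_index < n_ex) sum(exon_of <= exon_index) - t_pos
               else NA_integer_
  list(exon_index = exon_index,
       dist_last_junction = dist_last,
       dist_start_codon = ptc_cds_pos - 1L,
       dist_downstream_junction = dist_down,
       sensitive = !is.na(dist_last) && exon_index < n_ex &&
         dist_last >= 50L)
}

# Exhaustive hypergeometric enumeration for a 2x2 table: probabilities
# of every table with the observed margins via the factorial formula.
enum_fisher <- function(a, b, c_, d_, alternative = "two_sided") {
  r1 <- a + b; r2 <- c_ + d_; k <- a + c_; n <- r1 + r2
  xs <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(n, k)
  p <- exp(logp)
  obs <- p[xs == a]
  if (alternative == "greater") sum(p[xs >= a])
  else min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Random transcript models for property tests, built directly through
# the constructor (2-12 exons, random strand, CDS on codon boundaries).
random_transcript <- function(id = "TX1", gene = "G1", n_exons = NULL) {
  if (is.null(n_exons)) n_exons <- sample(2:12, 1)
  ex_len <- sample(60:400, n_exons, replace = TRUE)
  introns <- if (n_exons > 1) sample(50:2000, n_exons - 1L,
                                     replace = TRUE) else integer(0)
  start0 <- sample(1000:100000, 1)
  starts <- start0 + cumsum(c(0L, head(ex_len, -1) + introns))
  ends <- starts + ex_len - 1L
  strand <- sample(c("+", "-"), 1)
  L <- sum(ex_len)
  u <- sample(seq_len(max(1L, floor(0.15 * L))), 1)
  v <- sample(0:max(0L, floor(0.10 * L)), 1)
  cds_len <- 3L * ((L - u - v) %/% 3L)
  tm0 <- transcript_model(id, gene, "chrT", strand,
                          data.frame(start = starts, end = ends),
                          cds_start = if (strand == "+") starts[1]
                                      else ends[n_exons],
                          cds_end = if (strand == "+") ends[n_exons]
                                    else starts[1])
  g_start <- transcript_to_genomic(tm0, u + 1L)
  g_end <- transcript_to_genomic(tm0, u + cds_len)
  transcript_model(id, gene, "chrT",
                   strand, data.frame(start = starts, end = ends),
                   cds_start = g_start, cds_end = g_end)
}

# Mirror a transcript (and optionally a genomic position) through a
# pivot, flipping strand; all spliced-coordinate geometry must be
# invariant under this reflection.
reflect_transcript <- function(tm, pivot = 1e7) {
  ex <- data.frame(start = pivot - tm$exons$end,
                   end = pivot - tm$exons$start)
  transcript_model(tm$transcript_id, tm$gene, tm$chrom,
                   if (tm$strand == "+") "-" else "+",
                   ex,
                   cds_start = pivot - tm$cds_start,
                   cds_end = pivot - tm$cds_end,
                   cds_sequence = tm$cds_sequence)
}

# Minimal well-formed mutation row used by unit tests.
make_record <- function(sample_id = "S1", gene = "G1", chrom = "chr1",
                        pos = 100L, ref = "C", alt = "T",
                        category = "missense", dna_ref = 30L,
                        dna_alt = 20L, rna_ref = 30L, rna_alt = 20L,
                        ptc_cds_pos = NA_integer_) {
  data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
             pos = pos, ref = ref, alt = alt, category = category,
             dna_ref = dna_ref, dna_alt = dna_alt, rna_ref = rna_ref,
             rna_alt = rna_alt, ptc_cds_pos = ptc_cds_pos,
             stringsAsFactors = FALSE)
}
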