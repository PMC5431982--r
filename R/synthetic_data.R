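# Per-tumor-type mutation-category counts used as mixture weights.
# Rows: nonsense, missense, splice_site, silent, frameshift, inframe.
CATEGORY_COUNT_PRESETS <- list(
  BRCA = c(nonsense = 1129, missense = 14066, splice_site = 74,
           silent = 4281, frameshift = 800, inframe = 187),
  HNSC = c(nonsense = 1704, missense = 20308, splice_site = 117,
           silent = 7968, frameshift = 733, inframe = 246),
  KIRC = c(nonsense = 133, missense = 1896, splice_site = 8,
           silent = 728, frameshift = 540, inframe = 97),
  LUAD = c(nonsense = 1829, missense = 23091, splice_site = 147,
           silent = 8311, frameshift = 787, inframe = 280),
  STAD = c(nonsense = 563, missense = 9257, splice_site = 44,
           silent = 3581, frameshift = 581, inframe = 175)
)

#' Category mixture weights for a tumor-type preset
#'
#' Normalized mutation-category proportions (nonsense, missense,
#' splice-site, silent SNVs; frameshift and inframe indels) for the
#' five bundled tumor-type presets.
#'
#' @param preset one of `"BRCA"`, `"HNSC"`, `"KIRC"`, `"LUAD"`,
#'   `"STAD"`.
#' @return named numeric vector summing to 1.
#' @export
category_weights_preset <- function(preset = "BRCA") {
  counts <- CATEGORY_COUNT_PRESETS[[match.arg(preset,
                                              names(CATEGORY_COUNT_PRESETS))]]
  counts / sum(counts)
}

#' Configuration of the synthetic-cohort generator
#'
#' Fixes the study conditions of a simulated cohort: cohort and gene
#' panel size, the mutation-category mixture, the distribution of true
#' DNA-level mutant fractions, the strength of the NMD and
#' intron-retention allelic effects, sequencing depths and their
#' dispersion, the copy-number landscape and the hypermutator rate.
#'
#' The NMD effect is a per-transcript survival factor: an
#' NMD-sensitive truncating mutation's mutant transcripts survive at
#' rate `nmd_retention`, giving the RNA mutant fraction of
#' [rna_fraction_under_nmd()]. Splice-site mutations are up-weighted by
#' `splice_retention_boost` through the same odds transform (intron
#' retention stabilizes the mutant transcript).
#'
#' @param n_samples number of tumor samples (default 60).
#' @param n_genes number of genes in the simulated panel (default 400).
#' @param muts_per_sample mean somatic mutation count per non-
#'   hypermutated sample (default 40; Poisson).
#' @param category_weights named fractions over the six categories
#'   (default the BRCA preset).
#' @param dna_fraction_prior Beta shapes for the true DNA mutant
#'   fraction (default c(50, 50): clonal heterozygous mutations in a
#'   pure diploid genome, mean 0.5; tumor purity and subclonal
#'   structure are deliberately not modeled).
#' @param nmd_retention mutant-transcript survival factor for
#'   NMD-sensitive truncating mutations, in (0, 1] (default 0.25).
#' @param splice_retention_boost mutant odds multiplier for splice-site
#'   mutations, > 1 (default 2).
#' @param dna_depth,rna_depth mean sequencing depths (default 80/80).
#' @param depth_dispersion negative-binomial size parameter for depth
#'   draws (default 10; smaller = more uneven coverage).
#' @param neutral_cn_fraction fraction of copy-number segments that are
#'   copy-neutral (default 0.8).
#' @param hypermutator_fraction fraction of samples simulated as
#'   hypermutators (default 0.03).
#' @param exome_size_mb nominal captured exome size, used to pick
#'   hypermutator mutation counts (default 38).
#' @param seed integer random seed (default 1).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 60, n_genes = 400,
                              muts_per_sample = 40,
                              category_weights = category_weights_preset("BRCA"),
                              dna_fraction_prior = c(50, 50),
                              nmd_retention = 0.25,
                              splice_retention_boost = 2,
                              dna_depth = 80, rna_depth = 80,
                              depth_dispersion = 10,
                              neutral_cn_fraction = 0.8,
                              hypermutator_fraction = 0.03,
                              exome_size_mb = 38,
                              seed = 1) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1, cfg$n_genes >= 1,
            cfg$dna_depth > 0, cfg$rna_depth > 0,
            cfg$depth_dispersion > 0,
            cfg$nmd_retention > 0, cfg$nmd_retention <= 1,
            cfg$splice_retention_boost >= 1,
            cfg$neutral_cn_fraction >= 0, cfg$neutral_cn_fraction <= 1,
            cfg$hypermutator_fraction >= 0, cfg$hypermutator_fraction <= 1,
            all(sort(names(cfg$category_weights)) ==
                  sort(MUTATION_CATEGORIES)))
  if (abs(sum(cfg$category_weights) - 1) > 1e-9) {
    stop("category_weights must sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

# Run code under a local RNG state so the global stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

random_cds_sequence <- function(n_codons) {
  paste0(paste(sample(NON_STOP_CODONS, n_codons - 1L, replace = TRUE),
               collapse = ""), "TAA")
}

#' Simulate a panel of transcript models
#'
#' Generates `n_genes` protein-coding transcripts on five synthetic
#' chromosomes: 2-12 exons per gene, exon lengths 60-400 nt, intron
#' lengths 200-2,000 nt, random strand, a CDS covering at least 60% of
#' the spliced length (divisible by 3) and a random coding sequence
#' with no internal stop codon. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return named list mapping gene symbol (`GENE0001`, ...) to
#'   `transcript_model`.
#' @export
simulate_transcripts <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, {
    models <- list()
    chrom_cursor <- setNames(rep(1L, 5),
                             paste0("chr", 1:5))
    for (i in seq_len(config$n_genes)) {
      gene <- sprintf("GENE%04d", i)
      chrom <- paste0("chr", ((i - 1L) %% 5L) + 1L)
      n_ex <- sample(2:12, 1)
      ex_len <- sample(60:400, n_ex, replace = TRUE)
      introns <- if (n_ex > 1) sample(200:2000, n_ex - 1L,
                                      replace = TRUE) else integer(0)
      start <- chrom_cursor[[chrom]] + sample(5000:20000, 1)
      starts <- start + cumsum(c(0L, head(ex_len, -1) + introns))
      ends <- starts + ex_len - 1L
      chrom_cursor[[chrom]] <- ends[n_ex]
      strand <- sample(c("+", "-"), 1)
      L <- sum(ex_len)
      u <- sample(seq_len(max(1L, floor(0.15 * L))), 1)       # 5' UTR
      v <- sample(0:max(0L, floor(0.10 * L)), 1)              # 3' UTR
      cds_len <- 3L * ((L - u - v) %/% 3L)
      t_cds_start <- u + 1L
      t_cds_end <- t_cds_start + cds_len - 1L
      exdf <- data.frame(start = starts, end = ends)
      tm0 <- transcript_model(paste0("TX", substring(gene, 5)), gene,
                              chrom, strand, exdf,
                              cds_start = if (strand == "+") starts[1]
                                          else ends[n_ex],
                              cds_end = if (strand == "+") ends[n_ex]
                                        else starts[1])
      g_start <- transcript_to_genomic(tm0, t_cds_start)
      g_end <- transcript_to_genomic(tm0, t_cds_end)
      models[[gene]] <- transcript_model(
        tm0$transcript_id, gene, chrom, strand, exdf,
        cds_start = g_start, cds_end = g_end,
        cds_sequence = random_cds_sequence(cds_len %/% 3L))
    }
    models
  })
}

#' RNA mutant fraction under partial NMD
#'
#' If mutant transcripts survive nonsense-mediated decay at rate
#' `retention` while wildtype transcripts are unaffected, the expected
#' mutant allele fraction in RNA is
#' `retention * p / (retention * p + (1 - p))` for DNA fraction `p`.
#' `retention = 1` leaves the fraction unchanged; values > 1 act as an
#' up-weighting of the mutant allele (used for intron retention at
#' splice sites).
#'
#' @param p_dna true DNA-level mutant fraction(s) in \[0, 1\].
#' @param retention positive survival factor.
#' @return RNA-level mutant fraction(s).
#' @export
rna_fraction_under_nmd <- function(p_dna, retention) {
  stopifnot(all(p_dna >= 0 & p_dna <= 1), retention > 0)
  ifelse(p_dna == 1, 1,
         retention * p_dna / (retention * p_dna + (1 - p_dna)))
}

# Independent brute-force 50-nt-rule call used only to label ground
# truth: walks exon lengths, finds the exon holding the PTC and the
# spliced coordinate of the last junction.
brute_force_nmd_truth <- function(tm, ptc_cds_pos) {
  lens <- tm$exons$end - tm$exons$start + 1L
  offs <- 0L
  t_cds_start <- genomic_to_transcript(tm, tm$cds_start)
  t_pos <- t_cds_start + ptc_cds_pos - 1L
  walked <- 0L; exon_idx <- NA_integer_
  for (i in seq_along(lens)) {
    if (t_pos <= walked + lens[i]) { exon_idx <- i; break }
    walked <- walked + lens[i]
  }
  if (length(lens) < 2 || exon_idx == length(lens)) return(FALSE)
  last_junction <- sum(lens[seq_len(length(lens) - 1L)])
  (last_junction - t_pos) >= 50L
}

pick_cds_snv_pos <- function(tm) {
  clen <- cds_length(tm)
  cds_pos <- sample(seq_len(max(1L, clen - 3L)), 1)  # avoid the stop codon
  t_cds_start <- genomic_to_transcript(tm, tm$cds_start)
  g <- transcript_to_genomic(tm, t_cds_start + cds_pos - 1L)
  list(cds_pos = cds_pos, genomic = g)
}

#' Simulate a somatic-mutation cohort with known allelic-imbalance truth
#'
#' Places mutations of the six categories at category-appropriate
#' coordinates on the supplied transcript models, draws a true DNA
#' mutant fraction per mutation from the configured Beta prior, applies
#' the configured allelic effect (NMD depletion for truncating
#' mutations that the 50-nt rule marks sensitive on their transcript;
#' intron-retention up-weighting for splice-site mutations; none
#' otherwise), and emits binomial DNA/RNA read counts at
#' negative-binomial depths, copy-number segments (mostly neutral) and
#' a per-record ground-truth table. A configured fraction of samples
#' are hypermutators. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param transcripts named list of `transcript_model` from
#'   [simulate_transcripts()].
#' @return list with elements `mutations` (data frame),
#'   `segments` (data frame) and `truth` (data frame with columns
#'   `key`, `true_dna_fraction`, `true_rna_fraction`, `effect`,
#'   `nmd_sensitive_truth`).
#' @export
simulate_cohort <- function(config, transcripts) {
  validate_simulation_config(config)
  with_seed(config$seed + 1L, {
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    n_hyper <- round(config$hypermutator_fraction * config$n_samples)
    hyper <- if (n_hyper > 0) sample(samples, n_hyper) else character(0)
    genes <- names(transcripts)
    cats <- names(config$category_weights)
    mut_rows <- list(); truth_rows <- list()
    for (s in samples) {
      n_mut <- if (s %in% hyper) {
        # comfortably above the 10/Mb exclusion threshold
        ceiling(config$exome_size_mb * 10) + sample(50:150, 1)
      } else {
        stats::rpois(1, config$muts_per_sample)
      }
      if (n_mut == 0) next
      cat_draw <- sample(cats, n_mut, replace = TRUE,
                         prob = config$category_weights)
      gene_draw <- sample(genes, n_mut, replace = TRUE)
      used_pos <- character(0)
      for (j in seq_len(n_mut)) {
        tm <- transcripts[[gene_draw[j]]]
        for (attempt in 1:25) {  # redraw on (sample, chrom, pos) collision
          category <- cat_draw[j]
          ptc_cds_pos <- NA_integer_
          effect <- "none"; nmd_truth <- FALSE
          if (category %in% c("nonsense", "missense", "silent")) {
            loc <- pick_cds_snv_pos(tm)
            pos <- loc$genomic
            ref <- substr(tm$cds_sequence, loc$cds_pos, loc$cds_pos)
            alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
            if (category == "nonsense") {
              ptc_cds_pos <- ((loc$cds_pos - 1L) %/% 3L) * 3L + 1L
              nmd_truth <- brute_force_nmd_truth(tm, ptc_cds_pos)
              if (nmd_truth && config$nmd_retention < 1) effect <- "nmd"
            }
          } else if (category == "splice_site") {
            sites <- splice_site_positions(tm)
            if (nrow(sites) == 0) {  # single-exon gene: fall back to silent
              category <- "silent"
              loc <- pick_cds_snv_pos(tm)
              pos <- loc$genomic
              ref <- substr(tm$cds_sequence, loc$cds_pos, loc$cds_pos)
              alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
            } else {
              k <- sample(nrow(sites), 1)
              pos <- sites$pos[k]
              ref <- sites$canonical_ref[k]
              alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
              if (config$splice_retention_boost > 1) {
                effect <- "intron_retention"
              }
            }
          } else {  # frameshift or inframe indel
            loc <- pick_cds_snv_pos(tm)
            pos <- loc$genomic
            anchor <- substr(tm$cds_sequence, loc$cds_pos, loc$cds_pos)
            ins_len <- if (category == "frameshift") sample(1:2, 1) else 3L
            ref <- anchor
            alt <- paste0(anchor,
                          paste(sample(c("A", "C", "G", "T"), ins_len,
                                       replace = TRUE), collapse = ""))
            if (category == "frameshift") {
              ptc_cds_pos <- retranslate_frameshift(tm$cds_sequence,
                                                    loc$cds_pos, ref, alt)
              if (is.na(ptc_cds_pos)) {
                ptc_cds_pos <- cds_length(tm) - 2L  # runs to the stop codon
              }
              nmd_truth <- brute_force_nmd_truth(tm, ptc_cds_pos)
              if (nmd_truth && config$nmd_retention < 1) effect <- "nmd"
            }
          }
          pos_key <- paste(tm$chrom, pos)
          if (!pos_key %in% used_pos) break
        }
        used_pos <- c(used_pos, pos_key)
        p_dna <- rbeta(1, config$dna_fraction_prior[1],
                       config$dna_fraction_prior[2])
        p_rna <- switch(effect,
                        nmd = rna_fraction_under_nmd(p_dna,
                                                     config$nmd_retention),
                        intron_retention = rna_fraction_under_nmd(
                          p_dna, config$splice_retention_boost),
                        p_dna)
        dna_depth <- max(1L, rnbinom(1, mu = config$dna_depth,
                                     size = config$depth_dispersion))
        rna_depth <- max(1L, rnbinom(1, mu = config$rna_depth,
                                     size = config$depth_dispersion))
        dna_alt <- rbinom(1, dna_depth, p_dna)
        rna_alt <- rbinom(1, rna_depth, p_rna)
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          sample_id = s, gene = tm$gene, chrom = tm$chrom, pos = pos,
          ref = ref, alt = alt, category = category,
          dna_ref = dna_depth - dna_alt, dna_alt = dna_alt,
          rna_ref = rna_depth - rna_alt, rna_alt = rna_alt,
          ptc_cds_pos = ptc_cds_pos, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          key = paste(s, tm$chrom, pos, sep = ":"),
          true_dna_fraction = p_dna, true_rna_fraction = p_rna,
          effect = effect, nmd_sensitive_truth = nmd_truth,
          stringsAsFactors = FALSE)
      }
    }
    mutations <- do.call(rbind, mut_rows)
    truth <- do.call(rbind, truth_rows)
    segments <- simulate_segments(config, transcripts, samples)
    list(mutations = mutations, segments = segments, truth = truth)
  })
}

# Copy-number segments: per sample and chromosome, a small number of
# contiguous segments covering the full gene-bearing span; each segment
# is copy-neutral with probability neutral_cn_fraction.
simulate_segments <- function(config, transcripts, samples) {
  spans <- list()
  for (tm in transcripts) {
    lo <- min(tm$exons$start); hi <- max(tm$exons$end)
    old <- spans[[tm$chrom]]
    spans[[tm$chrom]] <- c(min(c(old[1], lo - 1000L)),
                           max(c(old[2], hi + 1000L)))
  }
  rows <- list()
  for (s in samples) {
    for (chrom in names(spans)) {
      span <- spans[[chrom]]
      n_seg <- sample(3:8, 1)
      cuts <- sort(sample(seq(span[1] + 1L, span[2] - 1L), n_seg - 1L))
      starts <- c(span[1], cuts + 1L)
      ends <- c(cuts, span[2])
      neutral <- runif(n_seg) < config$neutral_cn_fraction
      lr <- ifelse(neutral, runif(n_seg, -0.1, 0.1),
                   sample(c(-1, 1), n_seg, replace = TRUE) *
                     runif(n_seg, 0.2, 1.0))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, chrom = chrom, start = starts, end = ends,
        log_ratio = round(lr, 4), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
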