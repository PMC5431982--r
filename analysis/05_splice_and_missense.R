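#!/usr/bin/env Rscript

# Stage 5: splice-site and missense analyses.
#
# Splice-site mutations: classifies each into the canonical donor (GT)
# or acceptor (AG) dinucleotide and contrasts sig-pos-AFD (intron
# retention) rates between the two sides. Missense mutations: restricts
# to copy-number-neutral loci, then mutation spectra,
# transition/transversion composition, and per-gene enrichment of
# sig-pos-AFD events with a ranked-list export.

suppressMessages(library(aimut))

results <- read_results("results/ai_results.tsv")
models <- read_transcript_models("results/transcripts.gtf", "gtf")
segments <- read_segments("results/segments.seg")

## --- splice sites ----------------------------------------------------
splice <- classify_splice_site_table(results, models)
write.table(splice, "results/splice_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
res_sp <- merge(cbind(results, key = record_key(results)), splice,
                by = "key")
side_tab <- table(res_sp$side, res_sp$ai_class == "sig_pos_afd")
cat("sig-pos-AFD rate by splice side:\n")
print(prop.table(side_tab, 1), digits = 3)
if (all(dim(side_tab) == c(2, 2))) {
  p_side <- fisher_exact_2x2(side_tab["donor_5prime", "TRUE"],
                             side_tab["donor_5prime", "FALSE"],
                             side_tab["acceptor_3prime", "TRUE"],
                             side_tab["acceptor_3prime", "FALSE"],
                             "two_sided")
  cat(sprintf("donor vs acceptor contrast, Fisher p = %.3g\n", p_side))
}

## --- copy-neutral missense -------------------------------------------
ms <- results[results$category == "missense", ]
cn <- filter_copy_neutral(ms, segments)
cat(sprintf("\nmissense: %d of %d in copy-neutral segments\n",
            nrow(cn$records), nrow(ms)))
ms <- cn$records

spec <- table(spectrum_class(ms$ref, ms$alt), ms$ai_class)
write.table(as.data.frame(spec), "results/missense_spectra.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (ncol(spec) >= 2) {
  cs <- chisq_independence(spec)
  cat(sprintf("spectrum x AI-class chi-square p = %.3g\n", cs$p_value))
}

tstv <- table(ts_tv(ms$ref, ms$alt), ms$ai_class)
write.table(as.data.frame(tstv), "results/missense_tstv.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

enr <- gene_ai_enrichment(ms, "sig_pos_afd", min_events = 2)
write.table(enr, "results/missense_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_ranked_list(enr, "results/missense_sig_pos.rnk")
top <- enr[enr$neg_log10_p > 2.5, ]
cat(sprintf("genes above the -log10 p > 2.5 display threshold: %d\n",
            nrow(top)))
if (nrow(top) > 0) print(top, row.names = FALSE, digits = 3)
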