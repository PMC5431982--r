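#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# Generates a synthetic tumor cohort — transcript models, somatic
# mutations with DNA/RNA allele counts, copy-number segments and the
# ground-truth table — under the package's declared study conditions
# (BRCA-like category mixture, NMD retention 0.25, splice-site
# retention boost 2, mean depths 80/80). Everything downstream reads
# the files written here.

suppressMessages(library(aimut))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- simulation_config(n_samples = 160, muts_per_sample = 80,
                         n_genes = 300, seed = 1)
tx <- simulate_transcripts(cfg)
coh <- simulate_cohort(cfg, tx)

write_transcript_gtf(tx, file.path(out_dir, "transcripts.gtf"))
write_mutation_table(coh$mutations, file.path(out_dir, "mutations.tsv"))
write_segments(coh$segments, file.path(out_dir, "segments.seg"))
write.table(coh$truth, file.path(out_dir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d mutations in %d samples over %d genes\n",
            nrow(coh$mutations), cfg$n_samples, cfg$n_genes))
print(round(table(coh$mutations$category) / nrow(coh$mutations), 4))
cat(sprintf("truly NMD-affected truncating mutations: %d\n",
            sum(coh$truth$effect == "nmd")))
cat(sprintf("splice-site (intron-retention) mutations: %d\n",
            sum(coh$truth$effect == "intron_retention")))
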