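#!/usr/bin/env Rscript

# Stage 2: preprocessing funnel.
#
# Applies the depth filter (>= 10 reads in both exome and
# transcriptome), excludes hypermutated samples (> 10 mutations/Mb over
# a 38 Mb exome) and discards genes carrying several mutations in the
# same sample. Writes the filtered table and the funnel audit.

suppressMessages(library(aimut))

mut <- read_mutation_table("results/mutations.tsv")

f1 <- filter_by_depth(mut, 10, 10)
f2 <- filter_hypermutated(f1$records, 10, 38)
f3 <- drop_multimutant_genes(f2$records)

reports <- list(f1$report, f2$report, f3$report)
for (r in reports) print(r)
if (length(f2$flagged_samples) > 0) {
  cat("hypermutated sample(s):",
      paste(f2$flagged_samples, collapse = ", "), "\n")
}

write_mutation_table(f3$records, "results/mutations_filtered.tsv")
write_funnel(reports, "results/funnel.tsv")
cat(sprintf("retained %d of %d mutations\n", nrow(f3$records), nrow(mut)))
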