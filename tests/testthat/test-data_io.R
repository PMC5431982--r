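test_that("mutation table reading validates schema, counts and categories", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(make_record("S1", pos = 10L, category = "Nonsense"),
              make_record("S1", pos = 20L, category = "Splice_Site"),
              make_record("S2", pos = 30L, category = "missense"))
  write_mutation_table(df, path)
  got <- read_mutation_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$category, c("nonsense", "splice_site", "missense"))
  expect_equal(got$dna_alt, df$dna_alt)

  # round trip is the identity on the required columns
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(got, path2)
  expect_equal(read_mutation_table(path2), got)

  # missing column named in the error
  bad <- df[, setdiff(names(df), "rna_alt")]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "rna_alt")

  # negative count reported with its row
  bad <- df; bad$dna_alt[2] <- -2L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "negative.*row 2")

  # unknown category rejected
  bad <- df; bad$category[1] <- "readthrough"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "unknown mutation category")
})

test_that("extra columns survive a read/write round trip untouched", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- make_record()
  df$tumor_type <- "BRCA"
  df$note <- "hand-curated"
  write_mutation_table(df, path)
  got <- read_mutation_table(path)
  expect_equal(got$tumor_type, "BRCA")
  expect_equal(got$note, "hand-curated")
})

test_that("SEG reading maps headers, validates intervals, handles empties", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tseg.mean",
               "S1\tchr1\t1\t1000\t0.02"), path)
  seg <- read_segments(path)
  expect_equal(seg$log_ratio, 0.02)
  expect_equal(seg$sample_id, "S1")

  writeLines("sample\tchrom\tstart\tend\tseg.mean", path)
  expect_equal(nrow(read_segments(path)), 0)

  writeLines(c("sample\tchrom\tstart\tend\tseg.mean",
               "S1\tchr1\t1000\t1\t0.02"), path)
  expect_error(read_segments(path), "start > end")
})

test_that("result writing keeps column order, rounds to 6 significant digits,
           and round-trips class labels and VAFs", {
  set.seed(101)
  n <- 1000
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_record("S1", gene = sprintf("G%d", i), pos = i,
                dna_ref = sample(5:80, 1), dna_alt = sample(5:80, 1),
                rna_ref = sample(5:80, 1), rna_alt = sample(5:80, 1))
  }))
  res <- call_allelic_imbalance(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  got <- read_results(path)
  expect_equal(names(got)[1:10],
               c("sample_id", "gene", "chrom", "pos", "category",
                 "dna_vaf", "rna_vaf", "afd", "log10_bf", "ai_class"))
  expect_equal(got$ai_class, res$ai_class)
  expect_equal(got$dna_vaf, res$dna_vaf, tolerance = 1e-6)
  expect_equal(got$rna_vaf, res$rna_vaf, tolerance = 1e-6)

  # empty table needs the explicit flag
  expect_error(write_results(res[0, ], path), "allow_empty")
  write_results(res[0, ], path, allow_empty = TRUE)
  expect_equal(nrow(read_results(path)), 0)

  # duplicates written verbatim with a warning
  expect_warning(write_results(rbind(res[1, ], res[1, ]), path),
                 "duplicate")
  expect_equal(nrow(read_results(path)), 2)
})

test_that("GTF models order exons in transcript orientation and keep the
           longest CDS per gene", {
  path <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "G1"; transcript_id "T1";'
  attr2 <- 'gene_id "G1"; transcript_id "T2";'
  writeLines(c(
    sprintf("chr1\tx\texon\t100\t200\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\texon\t300\t400\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\texon\t500\t600\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\tCDS\t150\t200\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\tCDS\t300\t400\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\tCDS\t500\t550\t.\t-\t.\t%s", attr1),
    sprintf("chr1\tx\texon\t100\t200\t.\t-\t.\t%s", attr2),
    sprintf("chr1\tx\tCDS\t120\t140\t.\t-\t.\t%s", attr2)), path)
  suppressMessages(models <- read_transcript_models(path, "gtf"))
  expect_length(models, 1)
  tm <- models$G1
  expect_equal(tm$transcript_id, "T1")           # longest CDS wins
  expect_equal(tm$exons$start, c(500, 300, 100)) # minus strand: 3'-most first
  expect_equal(tm$cds_start, 550L)
  expect_equal(tm$cds_end, 150L)
})

test_that("BED12 blocks convert to 1-based inclusive internal coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  # chromStart 100, one block of 50 -> internal exon [101, 150]
  writeLines("chr1\t100\t150\tTX9\t0\t+\t109\t139\t0\t1\t50,\t0,", path)
  models <- read_transcript_models(path, "bed12")
  tm <- models$TX9
  expect_equal(tm$exons$start, 101)
  expect_equal(tm$exons$end, 150)
  expect_equal(tm$cds_start, 110L)
  expect_equal(tm$cds_end, 139L)
})

test_that("CDS straddling an intron is rejected as a model error", {
  path <- withr::local_tempfile(fileext = ".gtf")
  a <- 'gene_id "G1"; transcript_id "T1";'
  writeLines(c(
    sprintf("chr1\tx\texon\t100\t200\t.\t+\t.\t%s", a),
    sprintf("chr1\tx\texon\t300\t400\t.\t+\t.\t%s", a),
    sprintf("chr1\tx\tCDS\t150\t250\t.\t+\t.\t%s", a)), path)
  expect_error(read_transcript_models(path, "gtf"), "CDS outside exon")
})

test_that("GTF writing round-trips models through the GTF reader", {
  cfg <- simulation_config(n_genes = 20, n_samples = 2, seed = 5)
  models <- simulate_transcripts(cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_transcript_gtf(models, path)
  got <- read_transcript_models(path, "gtf")
  expect_setequal(names(got), names(models))
  for (g in names(models)) {
    expect_equal(got[[g]]$exons, models[[g]]$exons, info = g)
    expect_equal(got[[g]]$strand, models[[g]]$strand, info = g)
    expect_equal(got[[g]]$cds_start, models[[g]]$cds_start, info = g)
    expect_equal(got[[g]]$cds_end, models[[g]]$cds_end, info = g)
  }
})

test_that("minus-strand models always lead with the 3'-most genomic exon", {
  set.seed(77)
  for (i in 1:50) {
    tm <- random_transcript()
    if (tm$strand == "-") {
      expect_equal(tm$exons$start[1], max(tm$exons$start))
    } else {
      expect_equal(tm$exons$start[1], min(tm$exons$start))
    }
  }
})
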