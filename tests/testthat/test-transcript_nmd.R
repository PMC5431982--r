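two_exon_plus <- function() {
  # exon1 [101,150], exon2 [301,400]; CDS genomic 111..340
  transcript_model("T1", "G1", "chr1", "+",
                   data.frame(start = c(101L, 301L),
                              end = c(150L, 400L)),
                   cds_start = 111L, cds_end = 340L)
}

test_that("genomic positions map to CDS coordinates strand-awarely", {
  tm <- transcript_model("T1", "G1", "chr1", "+",
                         data.frame(start = 101L, end = 150L),
                         cds_start = 111L, cds_end = 140L)
  expect_equal(map_genomic_to_cds(tm, 111L), 1L)
  expect_equal(map_genomic_to_cds(tm, 140L), 30L)
  expect_true(is.na(map_genomic_to_cds(tm, 105L)))  # 5' UTR
  expect_error(map_genomic_to_cds(tm, 500L), "outside span")

  # minus-strand mirror: CDS runs 140 -> 111
  tr <- transcript_model("T1m", "G1", "chr1", "-",
                         data.frame(start = 101L, end = 150L),
                         cds_start = 140L, cds_end = 111L)
  expect_equal(map_genomic_to_cds(tr, 140L), 1L)
  expect_equal(map_genomic_to_cds(tr, 111L), 30L)

  # intronic positions are not in the CDS
  tm2 <- two_exon_plus()
  expect_true(is.na(map_genomic_to_cds(tm2, 200L)))
})

test_that("PTC annotation implements the 50-nt rule with an inclusive
           boundary and a last-exon escape", {
  tm <- two_exon_plus()
  # spliced: exon1 contributes 50 nt, junction at spliced position 50.
  # CDS starts at spliced 11. A PTC at CDS position p sits at spliced
  # 10 + p, so dist_last_junction = 40 - p.
  rec <- make_record("S1", gene = "G1", pos = 0L, category = "frameshift",
                     ptc_cds_pos = 1L)
  ann <- annotate_ptc(rec, tm)
  expect_equal(ann$dist_last_junction, 39L)
  expect_equal(ann$region, "penultimate_lt50")
  expect_equal(ann$nmd_class, "insensitive")

  # PTC in the last exon escapes NMD
  rec$ptc_cds_pos <- 60L
  ann <- annotate_ptc(rec, tm)
  expect_equal(ann$region, "last_exon")
  expect_equal(ann$nmd_class, "insensitive")
  expect_true(is.na(ann$dist_downstream_junction))

  # longer first exon: place the junction 50 nt beyond the PTC
  tm3 <- transcript_model("T3", "G1", "chr1", "+",
                          data.frame(start = c(101L, 301L),
                                     end = c(250L, 400L)),
                          cds_start = 111L, cds_end = 340L)
  # spliced junction at 150; CDS position p at spliced 10 + p
  rec$ptc_cds_pos <- 90L   # dist = 150 - 100 = 50: boundary case
  ann <- annotate_ptc(rec, tm3)
  expect_equal(ann$dist_last_junction, 50L)
  expect_equal(ann$nmd_class, "sensitive")
  expect_equal(ann$region, "penultimate_ge50")
  # with an exclusive boundary the same PTC escapes
  ann_ex <- annotate_ptc(rec, tm3, boundary_inclusive = FALSE)
  expect_equal(ann_ex$nmd_class, "insensitive")
  expect_equal(ann_ex$region, "penultimate_lt50")

  rec$ptc_cds_pos <- 60L   # dist = 80 >= 50: clearly sensitive
  ann <- annotate_ptc(rec, tm3)
  expect_equal(ann$nmd_class, "sensitive")
})

test_that("nonsense PTCs anchor on the codon start and frameshifts
           re-translate when no PTC is supplied", {
  tm <- transcript_model("T1", "G1", "chr1", "+",
                         data.frame(start = c(101L, 301L),
                                    end = c(250L, 400L)),
                         cds_start = 111L, cds_end = 340L,
                         cds_sequence = paste0(
                           strrep("ATG", 59), "TAA"))
  # SNV at genomic 125 -> CDS 15 -> codon 5 -> PTC CDS position 13
  rec <- make_record("S1", gene = "G1", pos = 125L, category = "nonsense")
  ann <- annotate_ptc(rec, tm)
  expect_equal(ann$ptc_cds_pos, 13L)
  expect_equal(ann$dist_start_codon, 12L)

  # frameshift with an explicit PTC uses it verbatim
  rec_fs <- make_record("S1", gene = "G1", pos = 125L,
                        category = "frameshift", ptc_cds_pos = 37L)
  expect_equal(annotate_ptc(rec_fs, tm)$ptc_cds_pos, 37L)

  # frameshift without a PTC on a transcript without sequence fails
  tm_noseq <- two_exon_plus()
  rec_fs$ptc_cds_pos <- NA_integer_
  expect_error(annotate_ptc(rec_fs, tm_noseq), "cds_sequence")

  # with a sequence, a 1-nt insertion into the ATG repeat shifts the
  # frame; the expected stop is found by independently translating the
  # edited sequence codon by codon
  seq0 <- paste0(strrep("ATG", 59), "TAA")
  ptc <- retranslate_frameshift(seq0, 15L, "G", "GTA")
  mut <- paste0(substr(seq0, 1, 14), "GTA", substr(seq0, 16, nchar(seq0)))
  codons <- substring(mut, seq(1, nchar(mut) - 2, 3),
                      seq(3, nchar(mut), 3))
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
  expect_equal(ptc, (stop_idx - 1) * 3 + 1)
  rec_fs2 <- make_record("S1", gene = "G1", pos = 125L, ref = "G",
                         alt = "GTA", category = "frameshift")
  rec_fs2$ptc_cds_pos <- NULL
  expect_equal(annotate_ptc(rec_fs2, tm)$ptc_cds_pos, ptc)
})

test_that("PTC geometry matches the brute-force spliced walk on 1,000
           random transcripts and is strand-reflection invariant", {
  set.seed(2024)
  for (i in seq_len(1000)) {
    tm <- random_transcript()
    clen <- cds_length(tm)
    ptc <- sample(seq_len(clen - 3L), 1)
    ptc <- ((ptc - 1L) %/% 3L) * 3L + 1L
    rec <- make_record("S1", gene = tm$gene, pos = 0L,
                       category = "frameshift", ptc_cds_pos = ptc)
    ann <- annotate_ptc(rec, tm)
    oracle <- oracle_ptc_geometry(tm, ptc)
    expect_equal(ann$exon_index, oracle$exon_index)
    expect_equal(ann$dist_last_junction, oracle$dist_last_junction)
    expect_equal(ann$dist_start_codon, oracle$dist_start_codon)
    expect_equal(ann$dist_downstream_junction,
                 oracle$dist_downstream_junction)
    expect_equal(ann$nmd_class == "sensitive", oracle$sensitive)

    # region labels partition: exactly one label applies
    expect_true(ann$region %in% c("last_exon", "penultimate_ge50",
                                  "penultimate_lt50", "other"))

    # reflection through a pivot flips strand but not the annotation
    refl <- reflect_transcript(tm)
    ann_r <- annotate_ptc(rec, refl)
    expect_equal(ann_r[, c("ptc_cds_pos", "exon_index",
                           "dist_last_junction", "dist_start_codon",
                           "dist_downstream_junction", "region",
                           "nmd_class")],
                 ann[, c("ptc_cds_pos", "exon_index",
                         "dist_last_junction", "dist_start_codon",
                         "dist_downstream_junction", "region",
                         "nmd_class")])
  }
})

test_that("splice-site classification assigns canonical donor/acceptor
           offsets strand-awarely and rejects deep intronic positions", {
  tm <- two_exon_plus()
  rec <- function(pos) make_record("S1", gene = "G1", pos = pos,
                                   category = "splice_site")
  d1 <- classify_splice_site(rec(151L), tm)
  expect_equal(d1$side, "donor_5prime")
  expect_equal(d1$offset, 1L)
  expect_equal(d1$canonical_ref, "G")
  d2 <- classify_splice_site(rec(152L), tm)
  expect_equal(d2$offset, 2L)
  expect_equal(d2$canonical_ref, "T")
  a1 <- classify_splice_site(rec(300L), tm)
  expect_equal(a1$side, "acceptor_3prime")
  expect_equal(a1$offset, -1L)
  expect_equal(a1$canonical_ref, "G")
  a2 <- classify_splice_site(rec(299L), tm)
  expect_equal(a2$offset, -2L)
  expect_equal(a2$canonical_ref, "A")
  expect_error(classify_splice_site(rec(155L), tm), "not within 2 nt")

  # minus-strand mirror gives the same calls
  refl <- reflect_transcript(tm)
  pivot <- 1e7
  for (pos in c(151L, 152L, 299L, 300L)) {
    orig <- classify_splice_site(rec(pos), tm)
    mirr <- classify_splice_site(rec(as.integer(pivot - pos)), refl)
    expect_equal(mirr$side, orig$side)
    expect_equal(mirr$offset, orig$offset)
    expect_equal(mirr$canonical_ref, orig$canonical_ref)
  }
})

test_that("first-exon features pass through distances and flag exon 1", {
  tm <- transcript_model("T1", "G1", "chr1", "+",
                         data.frame(start = c(101L, 301L),
                                    end = c(250L, 400L)),
                         cds_start = 111L, cds_end = 340L)
  rec <- make_record("S1", gene = "G1", pos = 0L, category = "frameshift",
                     ptc_cds_pos = 30L)
  ann <- annotate_ptc(rec, tm)
  fe <- first_exon_features(ann)
  expect_true(fe$in_first_exon)
  expect_equal(fe$dist_start_codon, 29L)

  # single-exon transcript: first exon and last exon simultaneously
  tm1 <- transcript_model("T2", "G2", "chr1", "+",
                          data.frame(start = 101L, end = 400L),
                          cds_start = 111L, cds_end = 340L)
  rec1 <- make_record("S1", gene = "G2", pos = 0L,
                      category = "frameshift", ptc_cds_pos = 30L)
  ann1 <- annotate_ptc(rec1, tm1)
  expect_equal(ann1$region, "last_exon")
  expect_equal(ann1$nmd_class, "insensitive")
  expect_true(first_exon_features(ann1)$in_first_exon)
})
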