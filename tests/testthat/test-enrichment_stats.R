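test_that("paired VAF test reproduces the hand-computed t statistic and
           respects its one-tailed orientation", {
  res <- data.frame(dna_vaf = c(0.5, 0.4, 0.6), rna_vaf = c(0.2, 0.1, 0.3))
  # differences are constant at -0.3: zero variance is an error
  expect_error(paired_vaf_test(res, "rna_less"), "zero variance")

  res$rna_vaf[3] <- 0.35
  # d = (-0.3, -0.3, -0.25): mean -0.283333, sd 0.0288675
  d <- res$rna_vaf - res$dna_vaf
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  out <- paired_vaf_test(res, "rna_less")
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, pt(t_hand, df = 2), tolerance = 1e-12)

  # positive mean difference makes the rna_less p exceed 0.5
  res_up <- data.frame(dna_vaf = c(0.2, 0.3, 0.1),
                       rna_vaf = c(0.5, 0.45, 0.3))
  expect_gt(paired_vaf_test(res_up, "rna_less")$p_value, 0.5)

  # swapping the pair flips the sign of t exactly
  sw <- data.frame(dna_vaf = res$rna_vaf, rna_vaf = res$dna_vaf)
  expect_equal(paired_vaf_test(sw, "rna_greater")$statistic,
               -out$statistic)

  expect_error(paired_vaf_test(res[1, ], "rna_less"), "at least 2")
})

test_that("exact 2x2 p-values equal hypergeometric enumeration and
           stats::fisher.test", {
  expect_equal(fisher_exact_2x2(3, 1, 10, 86, "greater"),
               enum_fisher(3, 1, 10, 86, "greater"), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5, "two_sided"), 1)
  # transposition leaves the two-sided p unchanged
  expect_equal(fisher_exact_2x2(3, 9, 2, 40, "two_sided"),
               fisher_exact_2x2(3, 2, 9, 40, "two_sided"),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")

  # independent cross-check against the stats implementation
  set.seed(31)
  for (i in 1:200) {
    cells <- sample(0:25, 4, replace = TRUE)
    if (sum(cells) == 0) next
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4],
                                  "two_sided"),
                 fisher.test(m)$p.value, tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4],
                                  "greater"),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("mutation spectra collapse the 12 substitutions onto 6
           strand-symmetric classes", {
  expect_equal(spectrum_class("C", "A"), "C:G>A:T")
  expect_equal(spectrum_class("G", "T"), "C:G>A:T")
  subs <- expand.grid(ref = c("A", "C", "G", "T"),
                      alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  classes <- spectrum_class(subs$ref, subs$alt)
  expect_equal(sort(unique(classes)),
               sort(c("C:G>A:T", "C:G>G:C", "C:G>T:A",
                      "T:A>A:T", "T:A>C:G", "T:A>G:C")))
  expect_true(all(table(classes) == 2))
  # reverse-complement invariance
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(spectrum_class(comp[subs$ref], comp[subs$alt]), classes)
  expect_error(spectrum_class("C", "N"), "invalid nucleotide")
})

test_that("transitions are exactly the four purine/pyrimidine-preserving
           substitutions", {
  expect_equal(ts_tv("C", "T"), "transition")
  expect_equal(ts_tv("C", "A"), "transversion")
  subs <- expand.grid(ref = c("A", "C", "G", "T"),
                      alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  expect_equal(sum(ts_tv(subs$ref, subs$alt) == "transition"), 4)
})

test_that("chi-square independence test matches its algebraic identities", {
  # outer product of margins: statistic 0, p 1
  m <- outer(c(10, 20), c(30, 70)) / 100
  out <- chisq_independence(m * 100)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  # 2x2 statistic equals the squared two-proportion z statistic
  tab <- matrix(c(12, 30, 25, 40), 2)
  out <- chisq_independence(tab)
  p1 <- tab[1, 1] / sum(tab[, 1]); p2 <- tab[1, 2] / sum(tab[, 2])
  pp <- sum(tab[1, ]) / sum(tab)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(tab[, 1]) +
                                           1 / sum(tab[, 2])))
  expect_equal(out$statistic, z^2, tolerance = 1e-12)

  # row permutation invariance
  expect_equal(chisq_independence(tab[2:1, ])$statistic, out$statistic)
  expect_error(chisq_independence(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("cumulative ratio curves count left-closed bins and match
           brute-force re-filtering", {
  curve <- cumulative_ratio_curve(c(5, 15, 25), c(TRUE, FALSE, TRUE),
                                  bin_width = 10, max_value = 30)
  expect_equal(curve$ratio, c(1 / 1, 1 / 2, 2 / 3))
  expect_equal(curve$bin_upper_edge, c(10, 20, 30))

  set.seed(8)
  values <- runif(500, 0, 300)
  flags <- runif(500) < 0.3
  curve <- cumulative_ratio_curve(values, flags, 10, 300)
  for (i in seq_len(nrow(curve))) {
    sel <- values < curve$bin_upper_edge[i]
    expect_equal(curve$n_total[i], sum(sel))
    expect_equal(curve$ratio[i], mean(flags[sel]))
  }
  # counts are non-decreasing along cumulative bins; the last bin is the
  # global event fraction
  expect_true(all(diff(curve$n_total) >= 0))
  expect_true(all(diff(curve$n_event) >= 0))
  expect_equal(curve$ratio[nrow(curve)], mean(flags))
})

test_that("per-gene enrichment tests each gene against all others and
           filters by focal-event count", {
  # gene X: 3 focal of 4; background: 10 focal of 96
  res <- data.frame(
    gene = c(rep("X", 4), rep(paste0("B", 1:96), 1)),
    ai_class = c(rep("sig_pos_afd", 3), "no_sig",
                 rep("sig_pos_afd", 10), rep("no_sig", 86)),
    stringsAsFactors = FALSE)
  enr <- gene_ai_enrichment(res, "sig_pos_afd", min_events = 1)
  x <- enr[enr$gene == "X", ]
  expect_equal(x$p_fisher, enum_fisher(3, 1, 10, 86, "greater"),
               tolerance = 1e-12)
  expect_equal(x$neg_log10_p, -log10(x$p_fisher))

  # zero-focal genes are excluded at min_events = 1
  expect_false(any(enr$n_focal == 0))
  expect_true(all(enr$p_fisher >= 0 & enr$p_fisher <= 1))

  # input order does not change the result
  perm <- res[sample(nrow(res)), ]
  expect_equal(gene_ai_enrichment(perm, "sig_pos_afd", 1), enr)
})

test_that("ranked list export orders by score with alphabetical
           tie-breaks and round-trips", {
  enr <- data.frame(gene = c("B", "A", "C"),
                    n_mutations = c(5, 5, 5), n_focal = c(3, 2, 1),
                    p_fisher = c(0.001, 0.01, 0.1),
                    neg_log10_p = c(3, 2, 1), p_bh = c(0.003, 0.015, 0.1))
  path <- withr::local_tempfile(fileext = ".rnk")
  export_ranked_list(enr, path)
  got <- read.delim(path, header = FALSE)
  expect_equal(got$V1, c("B", "A", "C"))
  expect_equal(got$V2, c(3, 2, 1))

  # equal scores: alphabetical
  enr$neg_log10_p <- c(2, 2, 2)
  export_ranked_list(enr, path)
  expect_equal(read.delim(path, header = FALSE)$V1, c("A", "B", "C"))
})
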