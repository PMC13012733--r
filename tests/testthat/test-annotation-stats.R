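test_that("decile profiles partition strata and flag deviant deciles exactly", {
  rec <- data.frame(frequency = (1:100) / 100,
                    flag = rep(c(TRUE, rep(FALSE, 9L)), 10L))
  prof <- suppressWarnings(decile_activity_profile(rec))  # perfect-fit ANOVA
  expect_equal(sum(prof$profile$n), 100L)
  expect_true(all(prof$profile$percent == 10))
  expect_true(all(prof$profile$p == 1))

  # one fully active decile against an overall rate of 10%
  rec2 <- data.frame(frequency = (1:100) / 100,
                     flag = c(rep(FALSE, 90L), rep(TRUE, 10L)))
  prof2 <- decile_activity_profile(rec2)
  top <- prof2$profile[prof2$profile$decile == 1L, ]  # decile 1 = highest freq
  expect_equal(top$n_flag, 10L)
  expect_lt(top$p, 1e-8)

  expect_warning(decile_activity_profile(
    data.frame(frequency = rep(0.5, 30L), flag = rep(c(TRUE, FALSE), 15L))),
    "collapsed")
})

test_that("threshold depletion matches the hypergeometric oracle", {
  rec <- data.frame(flag = rep(c(TRUE, FALSE), c(10L, 100L)),
                    iaf = c(rep(c(0.6, 0.2), c(1L, 9L)),
                            rep(c(0.6, 0.2), c(10L, 90L))))
  res <- threshold_depletion_test(rec, thresholds = 0.5)
  expect_equal(res$or, 1, tolerance = 1e-6)
  expect_equal(res$p, 1)

  # strong depletion: 0/10 flagged in the high-IAF margin
  rec2 <- data.frame(flag = rep(c(TRUE, FALSE), c(10L, 100L)),
                     iaf = c(rep(0.2, 10L), rep(c(0.6, 0.2), c(50L, 50L))))
  res2 <- threshold_depletion_test(rec2, thresholds = 0.5)
  expect_lt(res2$or, 0.3)
  # Fisher two-sided p equals the sum of hypergeometric outcomes no more
  # likely than the observed table (enumeration oracle)
  oracle <- sum_hyper_p(x = 0, m = 10, n = 100, k = 50)
  expect_equal(res2$p, oracle, tolerance = 1e-9)

  res3 <- threshold_depletion_test(rec2, thresholds = 0.05)  # empty low margin
  expect_true(res3$degenerate)
  expect_true(is.na(res3$or))
})

test_that("signed TSS distances are strand-aware with a documented tie rule", {
  seqs <- data.frame(contig = "c1", position = c(1500L, 1500L),
                     flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tss_plus <- data.frame(contig = "c1", position = 1000L, strand = "+")
  tss_minus <- data.frame(contig = "c1", position = 2000L, strand = "-")
  expect_equal(tss_distance_profile(seqs, tss_plus)$distances$distance,
               c(500, 500))
  expect_equal(tss_distance_profile(seqs, tss_minus)$distances$distance,
               c(500, 500))
  # equidistant: the upstream (negative) TSS wins and the tie is flagged
  both <- data.frame(contig = "c1", position = c(1000L, 2000L),
                     strand = c("+", "+"))
  prof <- tss_distance_profile(seqs, both)
  expect_equal(prof$distances$distance, c(-500, -500))
  expect_true(all(prof$distances$tss_tie))
  expect_error(tss_distance_profile(seqs, both[0L, ]), "empty TSS")

  # flipping every gene strand negates every signed distance
  set.seed(6)
  seqs2 <- data.frame(contig = "c1", position = sample(1000:9000, 20L),
                      flag = sample(c(TRUE, FALSE), 20L, replace = TRUE))
  tssN <- data.frame(contig = "c1", position = sample(1000:9000, 5L),
                     strand = "+")
  flipped <- tssN; flipped$strand <- "-"
  d1 <- tss_distance_profile(seqs2, tssN)$distances$distance
  d2 <- tss_distance_profile(seqs2, flipped)$distances$distance
  expect_equal(d1, -d2)
})

test_that("GC association computes exact fractions per source", {
  seqs <- data.frame(core_sequence = c("GGCC", "ATAT", "GCAT", "AATT"),
                     flag = c(TRUE, FALSE, TRUE, FALSE),
                     source = "DENISOVAN", stringsAsFactors = FALSE)
  res <- suppressWarnings(sequence_feature_tests(seqs))  # rank ties
  expect_equal(res$gc, c(1, 0, 0.5, 0))
  expect_equal(res$tests$median_gc_active, 0.75)
  expect_true(res$tests$p > 0 && res$tests$p <= 1)
})

test_that("haplotype concordance matches the textbook contingency computation", {
  ref <- tiny_reference(seed = 19L, len = 3000L)
  panel <- tiny_panel(c(600L, 650L, 1500L, 1550L, 2300L, 2350L), ref)
  oligos <- suppressMessages(design_oligos(panel, ref))
  # fabricate calls: all oligos active -> full concordance
  calls <- data.frame(oligo_id = oligos$oligo_id, is_active = TRUE,
                      stringsAsFactors = FALSE)
  conc <- haplotype_concordance(calls, oligos)
  expect_true(all(conc$class_table$percent == 100))
  expect_equal(conc$class_chisq, 0, tolerance = 1e-12)
  expect_equal(conc$aa_table$percent, c(100, 100))

  # mixed calls: chi-square equals the direct 2x3 formula on the output table
  set.seed(77)
  calls$is_active <- sample(c(TRUE, FALSE), nrow(calls), replace = TRUE)
  conc2 <- haplotype_concordance(calls, oligos)
  ct <- conc2$class_table[conc2$class_table$n > 0L, ]
  obs <- rbind(ct$n_concordant, ct$n - ct$n_concordant)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi_oracle <- sum((obs - expected)^2 / expected)
  expect_equal(conc2$class_chisq, chi_oracle, tolerance = 1e-9)
})

test_that("perfectly additive activities give slope and correlation of one", {
  ref <- tiny_reference(seed = 23L, len = 6000L)
  panel <- tiny_panel(c(600L, 650L, 1500L, 1550L, 2300L, 2350L,
                        3100L, 3150L, 3900L, 3950L), ref)
  oligos <- suppressMessages(design_oligos(panel, ref))
  # fabricate an ActivityMatrix whose haplotype medians equal the sum of
  # their constituents exactly
  set.seed(3)
  med <- matrix(stats::rnorm(nrow(oligos) * 2L), nrow(oligos), 2L,
                dimnames = list(oligos$oligo_id, c("r1", "r2")))
  sgl <- oligos$oligo_class == "SINGLE"
  scf <- archmpra:::parse_allele_config(oligos$allele_config)
  skey <- ifelse(sgl, paste(vapply(scf, function(x) x$snp_id[1L], character(1L)),
                            vapply(scf, function(x) x$state[1L], character(1L))), NA)
  sid <- stats::setNames(oligos$oligo_id[sgl], skey[sgl])
  for (i in which(!sgl)) {
    cf <- scf[[i]]
    med[i, ] <- colSums(med[sid[paste(cf$snp_id, cf$state)], , drop = FALSE])
  }
  act <- structure(list(oligo_median = med), class = "ActivityMatrix")
  calls <- data.frame(oligo_id = oligos$oligo_id, is_active = FALSE)
  add <- additivity_correlation(act, oligos, calls)
  expect_equal(add$r, 1, tolerance = 1e-9)
  expect_equal(add$slope, 1, tolerance = 1e-9)
  expect_length(add$outliers, 0L)
})
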