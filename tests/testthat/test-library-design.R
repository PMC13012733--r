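test_that("an isolated SNP yields two full-length single oligos centred on the variant", {
  ref <- tiny_reference()
  panel <- tiny_panel(500L, ref)
  oligos <- design_oligos(panel, ref)

  expect_equal(nrow(oligos), 2L)
  expect_true(all(oligos$oligo_class == "SINGLE"))
  expect_true(all(nchar(oligos$core_sequence) == 170L))
  expect_true(all(nchar(oligos$sequence) == 200L))
  ad <- mpra_adapters()
  expect_true(all(startsWith(oligos$sequence, ad[["adapter_5"]])))
  expect_true(all(endsWith(oligos$sequence, ad[["adapter_3"]])))

  # variant base at core offset 85 (0-based), flanks identical to reference
  m <- oligos$core_sequence[grepl("MODERN", oligos$allele_config)]
  a <- oligos$core_sequence[grepl("ARCHAIC", oligos$allele_config)]
  diffs <- which(strsplit(m, "")[[1L]] != strsplit(a, "")[[1L]])
  expect_equal(diffs, 86L)  # 1-based position of 0-based offset 85
  expect_equal(substr(m, 86L, 86L), panel$modern_allele)
  expect_equal(substr(a, 86L, 86L), panel$archaic_allele)
  expect_equal(oligos$start[1L], 500L - 85L)
  expect_equal(substr(ref[[1L]], oligos$start[1L] + 1L, oligos$start[1L] + 85L),
               substr(m, 1L, 85L))
})

test_that("SNP clusters yield 2^n haplotype oligos plus per-SNP singles", {
  ref <- tiny_reference(seed = 7L)
  panel2 <- tiny_panel(c(600L, 640L), ref)   # 40 bp apart
  o2 <- design_oligos(panel2, ref)
  expect_equal(sum(o2$oligo_class == "HAPLOTYPE") + length(attr(o2, "dropped")[
    grepl("region", attr(o2, "dropped"))]), 4L)
  expect_equal(sum(o2$oligo_class == "SINGLE") + sum(!grepl("region", attr(o2, "dropped"))), 4L)
  hap <- o2[o2$oligo_class == "HAPLOTYPE", ]
  expect_true(all(hap$start == hap$start[1L]))  # shared window
  expect_true(all(nchar(hap$core_sequence) == 170L))

  panel3 <- tiny_panel(c(600L, 640L, 680L), ref)
  o3 <- design_oligos(panel3, ref)
  expect_equal(sum(o3$oligo_class == "HAPLOTYPE") +
                 sum(grepl("region", attr(o3, "dropped"))), 8L)

  # allelic configurations are all distinct combinations
  cfg <- sort(hap$allele_config)
  expect_equal(length(unique(cfg)), nrow(hap))
})

test_that("restriction screening matches SfiI and BsiWI recognition rules", {
  flank <- strrep("A", 20L)
  expect_false(screen_restriction_sites(paste0(flank, "CGTACG", flank)))
  expect_false(screen_restriction_sites(paste0(flank, "GGCCATATAGGCC", flank)))
  # reverse complement of an SfiI match is itself an SfiI match
  expect_false(screen_restriction_sites(paste0(flank, revcomp_t("GGCCATATAGGCC"), flank)))
  expect_true(screen_restriction_sites("AAAAAAAA"))
  expect_true(screen_restriction_sites(paste0(flank, "GGCCATATAGGC", flank)))  # 4-bp spacer
  expect_error(screen_restriction_sites("ACGTN"), "non-ACGT")
  # designed oligos never contain a site
  b <- small_bundle(n_snps = 40L)
  expect_true(all(vapply(b$oligos$sequence, screen_restriction_sites, logical(1L))))
})

test_that("edge SNPs are skipped with a warning and bad reference bases error", {
  ref <- tiny_reference()
  panel <- tiny_panel(c(50L, 500L), ref)
  expect_warning(oligos <- design_oligos(panel, ref), "contig edge")
  expect_true(all(grepl("tsnp02", oligos$allele_config)))

  bad <- tiny_panel(500L, ref)
  bad$modern_allele <- setdiff(c("A", "C", "G", "T"),
                               c(bad$modern_allele, bad$archaic_allele))[1L]
  expect_error(design_oligos(bad, ref), "tsnp01")
})

test_that("design is order-independent and idempotent over the panel", {
  ref <- tiny_reference(seed = 11L)
  panel <- tiny_panel(c(400L, 800L, 840L, 1400L), ref)
  o1 <- design_oligos(panel, ref)
  o2 <- design_oligos(panel[sample(nrow(panel)), ], ref)
  expect_equal(o1[order(o1$oligo_id), ], o2[order(o2$oligo_id), ],
               ignore_attr = TRUE)
  o3 <- design_oligos(panel, ref)
  expect_identical(o1, o3)
})

test_that("scrambled controls pass all screens and are seed-deterministic", {
  ref <- tiny_reference(len = 3000L, seed = 3L)
  motifs <- list(make_test_motif("T1", "TGACGTCATG"),
                 make_test_motif("T2", "GGAAGTGAAAC"))
  s1 <- generate_scrambled_controls(12L, motifs = motifs, reference = ref, seed = 9L)
  s2 <- generate_scrambled_controls(12L, motifs = motifs, reference = ref, seed = 9L)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 12L)
  expect_true(all(nchar(s1$core_sequence) == 170L))
  expect_true(all(vapply(s1$sequence, screen_restriction_sites, logical(1L))))
  # no motif match at p < 1e-4
  for (m in motifs) {
    thr <- archmpra:::pwm_score_threshold(m, 1e-4)
    best <- vapply(s1$core_sequence, archmpra:::scan_max_score, numeric(1L), pwm = m)
    expect_true(all(best < thr))
  }
  # no exact 24-mer shared with the reference
  idx <- archmpra:::build_kmer_index(ref, 24L)
  expect_false(any(vapply(s1$core_sequence, archmpra:::shares_kmer,
                          logical(1L), kmer_index = idx, k = 24L)))
  expect_equal(nrow(generate_scrambled_controls(0L)), 0L)
})
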