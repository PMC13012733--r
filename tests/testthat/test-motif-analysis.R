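test_that("MEME files round-trip and pseudocounts renormalise columns", {
  motifs <- list(make_test_motif("M1", "ACGT"), make_test_motif("M2", "TTGACA"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- load_motifs(path)
  expect_length(back, 2L)
  expect_equal(back[[1L]]$motif_id, "M1")
  expect_equal(back[[1L]]$prob, motifs[[1L]]$prob, tolerance = 1e-5,
               ignore_attr = TRUE)

  # a column stored as given with pseudocount 0, renormalised with 0.01
  two <- list(list(motif_id = "P", prob = matrix(c(0.5, 0.25, 0.25, 0,
                                                   0.25, 0.25, 0.25, 0.25),
                                                 2L, 4L, byrow = TRUE),
                   background = rep(0.25, 4L)))
  write_meme(two, path)
  p0 <- load_motifs(path)[[1L]]$prob
  expect_equal(unname(p0[1L, ]), c(0.5, 0.25, 0.25, 0), tolerance = 1e-5)
  p1 <- load_motifs(path, pseudocount = 0.01)[[1L]]$prob
  expect_equal(unname(p1[1L, ]), (c(0.5, 0.25, 0.25, 0) + 0.01) / 1.04,
               tolerance = 1e-5)

  empty <- withr::local_tempfile(fileext = ".meme")
  writeLines("MEME version 4", empty)
  expect_length(load_motifs(empty), 0L)
})

test_that("log-odds scanning scores consensus runs and respects strand symmetry", {
  # all-A motif on an all-A sequence: 2 bits per column under uniform background
  allA <- make_test_motif("A4", "AAAA", strength = 1)
  sc <- archmpra:::scan_max_score(strrep("A", 10L), allA)
  expect_equal(sc, 4 * log2(1 / 0.25))

  pal <- make_test_motif("PAL", "ACGT", strength = 1)  # reverse-complement palindrome
  s_fwd <- archmpra:::scan_max_score(paste0("GG", "ACGT", "GG"), pal)
  s_rev <- archmpra:::scan_max_score(revcomp_t(paste0("GG", "ACGT", "GG")), pal)
  expect_equal(s_fwd, s_rev)
})

test_that("exact PWM p-values match closed forms and are monotone", {
  allA2 <- make_test_motif("A2", "AA", strength = 1)
  # score 4 bits is attained only by AA: p = 1/16 over all dinucleotides
  expect_equal(pwm_score_pvalue(allA2, 4), 1 / 16)
  # below the minimum achievable score the tail is everything
  m <- make_test_motif("M", "ACG")
  lo <- sum(apply(archmpra:::pwm_logodds(m), 1L, min))
  expect_equal(pwm_score_pvalue(m, lo - 1), 1)
  # monotone non-increasing in score
  scores <- seq(-10, 6, by = 0.37)
  ps <- vapply(scores, function(s) pwm_score_pvalue(m, s), numeric(1L))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("DP tail probabilities equal full enumeration for short motifs", {
  set.seed(31)
  g <- 0.01
  for (trial in 1:6) {
    L <- sample(2:8, 1L)
    prob <- matrix(stats::rgamma(4L * L, 1), L, 4L)
    prob <- prob / rowSums(prob)
    colnames(prob) <- c("A", "C", "G", "T")
    pwm <- list(motif_id = "R", prob = prob,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    Sint <- round(archmpra:::pwm_logodds(pwm) / g)
    # enumeration oracle over all 4^L sequences on the same integer grid
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    totals <- numeric(nrow(grid))
    for (j in seq_len(L)) totals <- totals + Sint[j, grid[, j]]
    probs <- rep(1 / 4^L, nrow(grid))
    for (t_int in sample(unique(totals), 5L)) {
      p_enum <- sum(probs[totals >= t_int])
      p_dp <- pwm_score_pvalue(pwm, t_int * g, granularity = g)
      expect_equal(p_dp, p_enum, tolerance = 1e-9)
    }
  }
})

test_that("allele scoring is confined to the central 40 bp window", {
  set.seed(5)
  core <- tiny_reference(len = 170L, seed = 5L)[[1L]]
  motif <- make_test_motif("W", "TGACGTCATG", strength = 1)
  plant <- function(seq, at) {  # at = 1-based start
    substr(seq, at, at + 9L) <- "TGACGTCATG"
    seq
  }
  # central window of a 170-mer covers 1-based positions 66..105
  inside <- plant(core, 80L)
  outside <- plant(core, 20L)
  hits_in <- score_alleles(inside, inside, list(motif))
  hits_out <- score_alleles(outside, outside, list(motif))
  expect_equal(hits_in$score_modern, 10 * 2)
  expect_lt(hits_out$score_modern, 10 * 2)
  # motif longer than the window is skipped with a warning
  long <- make_test_motif("L", strrep("A", 41L))
  expect_warning(h <- score_alleles(inside, inside, list(motif, long)),
                 "skipped")
  expect_equal(nrow(h), 1L)
})

test_that("differential binding keeps qualifying motifs and the largest |delta|", {
  hits <- data.frame(
    motif_id = c("a", "b", "c"),
    score_modern = c(10, 12, 8),
    score_archaic = c(10.5, 10, 8),
    p_modern = c(5e-5, 5e-4, 0.5),
    p_archaic = c(2e-4, 5e-5, 0.5),
    stringsAsFactors = FALSE
  )
  rec <- differential_binding(hits)
  expect_equal(rec$best_motif_id, "b")      # |delta| 2.0 beats 0.5
  expect_equal(rec$binding_delta, -2)
  # stringent/lenient thresholds: one allele must reach 1e-4
  none <- differential_binding(hits[3L, ])
  expect_null(none)
  weak <- hits[1L, ]; weak$p_modern <- 5e-4  # neither allele below 1e-4
  expect_null(differential_binding(weak))
})
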