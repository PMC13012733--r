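test_that("aggregate log ratios follow the summed-CPM arithmetic", {
  map <- data.frame(barcode = c("b1", "b2"), oligo_id = "o1")
  lib <- rep(1e6, 2L)
  # equal library sizes: y = log2(sum cDNA + 0.5) - log2(sum pDNA + 0.5)
  cdna <- matrix(c(20L, 11L, 20L, 11L), 2L, 2L)
  pdna <- matrix(c(4L, 3L, 4L, 3L), 2L, 2L)
  tab <- make_counts_table(cdna, pdna, map, lib_cdna = lib, lib_pdna = lib,
                           replicates = default_replicates()[1:2, ])
  ret <- list(map = map, barcodes = map$barcode)
  ag <- compute_aggregate_log_ratios(tab, ret)
  expect_equal(ag$y, rep(log2(31.5) - log2(7.5), 2L))
  expect_equal(ag$d, rep(log2(7.5), 2L))
  # with a unit pseudocount the sums give the round 32/8 ratio, y = 2
  ag1 <- compute_aggregate_log_ratios(tab, ret, pseudocount = 1)
  expect_equal(ag1$y, c(2, 2))

  # equal sums give y = 0; doubling the cDNA library lowers y by 1
  tab2 <- make_counts_table(cdna, cdna, map, lib_cdna = lib, lib_pdna = lib,
                            replicates = default_replicates()[1:2, ])
  expect_equal(compute_aggregate_log_ratios(tab2, ret)$y, c(0, 0))
  tab3 <- make_counts_table(cdna, cdna, map, lib_cdna = 2 * lib, lib_pdna = lib,
                            replicates = default_replicates()[1:2, ])
  expect_equal(compute_aggregate_log_ratios(tab3, ret)$y, c(-1, -1))
})

test_that("the allelic WLS fit matches the closed-form normal equations", {
  # constant shift between alleles: logfc is the negated archaic effect
  rows <- data.frame(y = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
                     allele = rep(c(0, 1), each = 5L),
                     background = rep(c(0, 0, 1, 1, 1), 2L))
  fit <- fit_weighted_allele_model(rows)
  expect_equal(fit$logfc, -1)

  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:14, 1L)
    rows <- data.frame(y = stats::rnorm(n),
                       allele = rep_len(c(0, 1), n),
                       background = stats::rbinom(n, 1L, 0.5))
    w <- stats::runif(n, 0.2, 3)
    fit <- fit_weighted_allele_model(rows, weights = w)
    X <- cbind(1, rows$allele)
    if (length(unique(rows$background)) > 1L) X <- cbind(X, rows$background)
    beta_oracle <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% rows$y)
    expect_equal(unname(fit$coefficients), drop(beta_oracle), tolerance = 1e-10)
    r <- rows$y - X %*% beta_oracle
    expect_equal(fit$s2, sum(w * r^2) / (n - ncol(X)), tolerance = 1e-10)
  }

  # constant background column is dropped, allele estimate unchanged
  rows$background <- 1
  expect_equal(fit_weighted_allele_model(rows)$logfc,
               -unname(stats::coef(stats::lm(y ~ allele, rows))["allele"]))
  # one allele missing: untestable
  rows$allele <- 0
  expect_null(fit_weighted_allele_model(rows))
})

test_that("variance moderation matches the plug-in formula and the limma oracle", {
  # posterior variance obeys (d0 s0^2 + df s^2) / (d0 + df)
  set.seed(71)
  s2h <- stats::rchisq(50L, 6L) / 6L
  sqh <- archmpra:::squeeze_variances(s2h, rep(6, 50L))
  expect_equal(sqh$s2_post,
               (sqh$d0 * sqh$s0_2 + 6 * s2h) / (sqh$d0 + 6))

  y <- seq(0.05, 4, length.out = 30L)
  expect_equal(vapply(vapply(y, archmpra:::trigamma_inverse, numeric(1L)),
                      trigamma, numeric(1L)),
               y, tolerance = 1e-6)

  set.seed(13)
  s2 <- stats::rchisq(200L, df = 5L) / 5L * 0.4
  df <- rep(7, 200L)
  ours <- archmpra:::squeeze_variances(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(ours$d0, ref$df.prior, tolerance = 0.02)
  expect_equal(ours$s0_2, ref$var.prior, tolerance = 0.02)
  expect_equal(ours$s2_post, ref$var.post, tolerance = 0.01)
})

test_that("moderated tests are calibrated under a planted null", {
  ks <- q_rate <- numeric(3L)
  for (s in 1:3) {
    set.seed(s)
    snp_rows <- lapply(1:200, function(i) {
      data.frame(y = stats::rnorm(10L, sd = 0.3),
                 d = stats::rnorm(10L, mean = 10, sd = 0.5),
                 allele = rep(c(0, 1), each = 5L),
                 background = rep(c(0, 0, 1, 1, 1), 2L))
    })
    names(snp_rows) <- sprintf("s%03d", 1:200)
    res <- moderate_and_test(snp_rows)
    ks[s] <- suppressWarnings(stats::ks.test(res$table$p, "punif")$statistic)
    q_rate[s] <- mean(res$table$q < 0.05)
  }
  expect_lt(mean(ks), 0.09)
  expect_lte(mean(q_rate), 0.02)
  expect_s3_class(res, "mpra_diff")
  expect_output(print(res), "prior df")

  # equal residual variances: moderated t approaches the ordinary t as the
  # prior degrees of freedom grow
  fits <- lapply(snp_rows, fit_weighted_allele_model)
  scaled <- Map(function(r, f) {
    X <- cbind(1, r$allele, r$background)
    fitted <- drop(X %*% f$coefficients)
    r$y <- fitted + (r$y - fitted) / sqrt(f$s2)
    r
  }, snp_rows, fits)
  out <- moderate_and_test(scaled)
  ord_t <- vapply(scaled, function(r) {
    f <- fit_weighted_allele_model(r)
    f$logfc / sqrt(f$s2 * f$v_allele)
  }, numeric(1L))
  expect_gt(out$d0, 50)  # near-identical variances push the prior df high
  ratio <- unname(out$table$t) / unname(ord_t[out$table$snp_id])
  expect_lt(stats::sd(ratio), 1e-3)     # proportional to the ordinary t
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("haplotype ANOVA honours the degenerate conventions and the consensus rule", {
  expect_equal(archmpra:::oneway_anova_p(list(c(1, 1, 1), c(2, 2, 2))), 0)
  expect_equal(archmpra:::oneway_anova_p(list(c(1, 2, 3), c(1, 2, 3))), 1)
  set.seed(55)
  g <- split(stats::rnorm(40L), rep(1:4, each = 10L))
  p <- archmpra:::oneway_anova_p(g)
  expect_equal(p, stats::anova(stats::lm(unlist(g) ~ factor(rep(1:4, each = 10L))))[["Pr(>F)"]][1L])

  b <- small_bundle("strong-effects", seed = 3L, n_snps = 80L)
  norm <- normalize_counts(b$counts)
  ret <- filter_library(norm)
  act <- compute_activity(norm, ret)
  hap <- test_haplotype_anova(act, b$oligos)
  expect_true(all(hap$table$differentially_active ==
                    (rowSums(!is.na(hap$q) & hap$q < 0.05) >= 2L)))
})

test_that("planted allelic effects are recovered with the right sign convention", {
  b <- small_bundle("strong-effects", seed = 9L, n_snps = 120L)
  norm <- normalize_counts(b$counts)
  ret <- filter_library(norm)
  act <- compute_activity(norm, ret)
  calls <- call_activity(act)$calls
  aggr <- compute_aggregate_log_ratios(b$counts, ret)
  d <- mpra_diff_test(aggr, b$oligos, b$replicates,
                      snps = archmpra:::snps_with_active_allele(b$oligos, calls))
  ev <- evaluate_differential(d$table, b$truth)
  expect_gte(ev$power, 0.7)
  expect_lte(ev$fdp, 0.1)
  expect_gte(ev$sign_concordance, 0.95)
  expect_equal(ev$slope, 1, tolerance = 0.1)
})
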