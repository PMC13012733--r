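# Precision-weighted allelic linear model with empirical-Bayes variance
# moderation for single-variant SNPs, and per-locus ANOVA for haplotype-like
# sequences.
#
# The allelic model follows the voom idea: oligo-level log ratios of summed
# counts are modelled by weighted least squares, with observation weights
# derived from a global mean-variance trend in pDNA abundance (element
# dosage), and residual variances are shrunk towards a common prior by
# moment-matching on the log-variances.

#' Aggregate log ratios of summed counts
#'
#' For every retained oligo and replicate, sums cDNA and pDNA counts across
#' the oligo's surviving barcodes and forms
#' \code{y = log2 CPM(cDNA sum) - log2 CPM(pDNA sum)} with a 0.5 aggregate
#' pseudocount; \code{d = log2 CPM(pDNA sum)} is kept as the precision
#' covariate.
#'
#' @param counts a \code{BarcodeCountTable}.
#' @param retained output of [filter_library()].
#' @param pseudocount aggregate pseudocount (default 0.5).
#' @return data frame: \code{oligo_id}, \code{replicate_id}, \code{y},
#'   \code{d}.
#' @export
compute_aggregate_log_ratios <- function(counts, retained, pseudocount = 0.5) {
  stopifnot(inherits(counts, "BarcodeCountTable"))
  map <- retained$map
  oligo_f <- factor(map$oligo_id)
  sum_c <- rowsum(counts$cdna[map$barcode, , drop = FALSE], oligo_f)
  sum_p <- rowsum(counts$pdna[map$barcode, , drop = FALSE], oligo_f)
  l2c <- log2(sweep(sum_c + pseudocount, 2L, counts$lib_cdna / 1e6, "/"))
  l2p <- log2(sweep(sum_p + pseudocount, 2L, counts$lib_pdna / 1e6, "/"))
  y <- l2c - l2p
  reps <- colnames(counts$cdna)
  data.frame(
    oligo_id = rep(rownames(y), times = length(reps)),
    replicate_id = rep(reps, each = nrow(y)),
    y = as.vector(y),
    d = as.vector(l2p),
    stringsAsFactors = FALSE
  )
}

#' Weighted least-squares fit of the allelic model for one SNP
#'
#' Regresses the aggregate log ratio on an intercept, the allelic state
#' (0 = modern, 1 = archaic) and the cell-line genetic background
#' (0 = European, 1 = Papuan), with the supplied observation weights. A
#' constant background column is dropped. The reported \code{logfc} is the
#' negated allele coefficient, so a negative value means the archaic allele
#' is the more active one.
#'
#' @param rows data frame with \code{y}, \code{allele}, \code{background}.
#' @param weights positive observation weights (default all 1).
#' @return list with \code{logfc}, \code{coefficients}, \code{s2} (residual
#'   variance), \code{df} (residual degrees of freedom), \code{v_allele}
#'   (unscaled variance of the allele coefficient), or NULL if the design is
#'   rank deficient for the allele effect.
#' @export
fit_weighted_allele_model <- function(rows, weights = rep(1, nrow(rows))) {
  if (nrow(rows) < 4L || length(unique(rows$allele)) < 2L) return(NULL)
  X <- cbind(intercept = 1, allele = rows$allele)
  if (length(unique(rows$background)) > 1L) {
    X <- cbind(X, background = rows$background)
  }
  fit <- stats::lm.wfit(X, rows$y, w = weights)
  df <- nrow(X) - fit$rank
  if (df < 1L || is.na(fit$coefficients["allele"])) return(NULL)
  rss <- sum(weights * fit$residuals^2)
  XtWX <- crossprod(X * sqrt(weights))
  v <- tryCatch(solve(XtWX)["allele", "allele"], error = function(e) NA_real_)
  if (!is.finite(v)) return(NULL)
  list(
    logfc = -unname(fit$coefficients["allele"]),
    coefficients = fit$coefficients,
    s2 = rss / df,
    df = df,
    v_allele = v
  )
}

# Solve trigamma(x) = y by Newton iteration (standard closed-form start).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# Empirical-Bayes variance shrinkage by moment-matching on log s^2.
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  post <- if (is.finite(d0)) {
    (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = post)
}

#' Moderated allelic tests across all SNPs
#'
#' Takes first-pass fits, estimates the global mean-variance trend (lowess of
#' the square-root residual standard deviation on mean pDNA abundance),
#' refits every SNP with precision weights from the trend, shrinks residual
#' variances with empirical-Bayes moment matching, and returns moderated
#' t-statistics, two-sided p-values and BH-adjusted q-values.
#'
#' This is the work-horse behind [mpra_diff_test()]; use that wrapper for the
#' oligo-table interface.
#'
#' @param snp_rows named list: per SNP, a data frame with \code{y}, \code{d},
#'   \code{allele}, \code{background}.
#' @param fdr FDR level for the differential-activity flag (default 0.05).
#' @return object of class \code{mpra_diff}; its \code{$table} has
#'   \code{snp_id}, \code{logfc}, \code{t}, \code{p}, \code{q},
#'   \code{is_differentially_active}.
#' @export
moderate_and_test <- function(snp_rows, fdr = 0.05) {
  if (length(snp_rows) < 10L) {
    stop("at least 10 testable SNPs are needed for hyperparameter estimation")
  }
  first <- lapply(snp_rows, function(rows) fit_weighted_allele_model(rows))
  testable <- !vapply(first, is.null, logical(1L))

  d_mean <- vapply(snp_rows[testable], function(r) mean(r$d), numeric(1L))
  sd_g <- sqrt(vapply(first[testable], `[[`, numeric(1L), "s2"))
  trend <- stats::lowess(d_mean, sqrt(sd_g), f = 0.5)

  refit <- lapply(snp_rows[testable], function(rows) {
    pred <- stats::approx(trend$x, trend$y, xout = rows$d, rule = 2L)$y
    w <- pmax(pred, 1e-4)^(-4)
    fit_weighted_allele_model(rows, weights = w)
  })
  ok <- !vapply(refit, is.null, logical(1L))
  refit <- refit[ok]
  s2 <- vapply(refit, `[[`, numeric(1L), "s2")
  df <- vapply(refit, `[[`, numeric(1L), "df")
  keep <- is.finite(s2)
  if (any(!keep)) warning(sum(!keep), " SNP(s) dropped with non-finite variance")
  refit <- refit[keep]
  s2 <- s2[keep]
  df <- df[keep]

  sq <- squeeze_variances(s2, df)
  logfc <- vapply(refit, `[[`, numeric(1L), "logfc")
  v <- vapply(refit, `[[`, numeric(1L), "v_allele")
  se <- sqrt(sq$s2_post * v)
  tstat <- logfc / se
  df_total <- if (is.finite(sq$d0)) sq$d0 + df else Inf
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- bh_adjust(p)

  table <- data.frame(
    snp_id = names(refit),
    logfc = logfc,
    t = tstat,
    p = p,
    q = q,
    is_differentially_active = q < fdr,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(
    table = table,
    d0 = sq$d0,
    s0_2 = sq$s0_2,
    trend = trend,
    n_untestable = sum(!testable) + sum(!ok),
    fdr = fdr
  ), class = "mpra_diff")
}

#' @export
print.mpra_diff <- function(x, ...) {
  cat("Moderated allelic differential-activity fit\n")
  cat("  SNPs tested:", nrow(x$table), " untestable:", x$n_untestable, "\n")
  cat(sprintf("  prior df d0 = %.2f, prior variance s0^2 = %.4g\n",
              x$d0, x$s0_2))
  cat("  differentially active (q <", x$fdr, "):",
      sum(x$table$is_differentially_active), "\n")
  invisible(x)
}

#' @export
summary.mpra_diff <- function(object, n = 10L, ...) {
  print(object)
  tab <- object$table[order(object$table$p), ]
  cat("\nTop SNPs by p-value:\n")
  print(utils::head(tab, n), row.names = FALSE)
  invisible(tab)
}

#' Differential activity between archaic and modern alleles
#'
#' Builds the per-SNP design from the oligo table (single-variant oligos
#' only), restricted to \code{snps} when given (typically the SNPs with at
#' least one active allele), and runs the precision-weighted moderated
#' analysis.
#'
#' @param aggregates output of [compute_aggregate_log_ratios()].
#' @param oligos oligo table from [design_oligos()].
#' @param replicates replicate descriptors.
#' @param snps optional character vector of SNP ids to test (default: all
#'   single-variant SNPs present in the aggregates).
#' @param fdr FDR level (default 0.05).
#' @return an object of class \code{mpra_diff} (see [moderate_and_test()]).
#' @export
mpra_diff_test <- function(aggregates, oligos, replicates = default_replicates(),
                           snps = NULL, fdr = 0.05) {
  single <- oligos[oligos$oligo_class == "SINGLE", , drop = FALSE]
  cfgs <- parse_allele_config(single$allele_config)
  snp_of <- vapply(cfgs, function(x) x$snp_id[1L], character(1L))
  state_of <- vapply(cfgs, function(x) x$state[1L], character(1L))
  if (is.null(snps)) snps <- unique(snp_of)

  bg <- stats::setNames(as.integer(replicates$ancestry == "PNG"),
                        replicates$replicate_id)
  aggr <- aggregates[aggregates$oligo_id %in% single$oligo_id, , drop = FALSE]
  aggr$snp_id <- snp_of[match(aggr$oligo_id, single$oligo_id)]
  aggr$allele <- as.integer(state_of[match(aggr$oligo_id, single$oligo_id)] == "ARCHAIC")
  aggr$background <- bg[aggr$replicate_id]

  snp_rows <- split(aggr[, c("y", "d", "allele", "background")],
                    factor(aggr$snp_id, levels = intersect(snps, aggr$snp_id)))
  moderate_and_test(snp_rows, fdr = fdr)
}

#' Per-locus ANOVA for haplotype-like sequences
#'
#' Within each replicate, performs a one-way ANOVA of barcode activities
#' across the allelic combinations of each haplotype region (groups with at
#' least two barcodes; at least two groups required). P-values are BH-adjusted
#' across regions within each replicate, and a region is differentially
#' active if adjusted p < \code{alpha} in at least \code{min_replicates}
#' replicates.
#'
#' @param act an \code{ActivityMatrix} from [compute_activity()].
#' @param oligos oligo table (haplotype oligos carry \code{region_id}).
#' @param alpha FDR level (default 0.05).
#' @param min_replicates consensus requirement (default 2).
#' @return list with \code{table} (region_id, n_significant,
#'   differentially_active), \code{p} and \code{q} (region x replicate).
#' @export
test_haplotype_anova <- function(act, oligos, alpha = 0.05,
                                 min_replicates = 2L) {
  stopifnot(inherits(act, "ActivityMatrix"))
  hap <- oligos[oligos$oligo_class == "HAPLOTYPE", , drop = FALSE]
  map <- act$map[act$map$oligo_id %in% hap$oligo_id, , drop = FALSE]
  if (nrow(map) == 0L) stop("no haplotype oligos in the activity matrix")
  map$region_id <- hap$region_id[match(map$oligo_id, hap$oligo_id)]
  regions <- unique(map$region_id)
  reps <- colnames(act$activity)

  pmat <- matrix(NA_real_, length(regions), length(reps),
                 dimnames = list(regions, reps))
  for (rg in regions) {
    sub <- map[map$region_id == rg, , drop = FALSE]
    for (r in seq_along(reps)) {
      vals <- act$activity[sub$barcode, r]
      groups <- split(vals, sub$oligo_id)
      groups <- groups[vapply(groups, length, integer(1L)) >= 2L]
      if (length(groups) < 2L) next
      pmat[rg, r] <- oneway_anova_p(groups)
    }
  }
  qmat <- apply(pmat, 2L, bh_adjust)
  dimnames(qmat) <- dimnames(pmat)
  sig <- !is.na(qmat) & qmat < alpha
  table <- data.frame(
    region_id = regions,
    n_significant = rowSums(sig),
    differentially_active = rowSums(sig) >= min_replicates,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(table = table, p = pmat, q = qmat)
}

# One-way fixed-effects ANOVA p-value with documented degenerate conventions:
# zero within-group variance gives p = 0 when group means differ and p = 1
# when they do not.
oneway_anova_p <- function(groups) {
  means <- vapply(groups, mean, numeric(1L))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  if (ssw == 0) {
    return(if (max(means) - min(means) > 0) 0 else 1)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = vapply(groups, length, integer(1L))))
  stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
}
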