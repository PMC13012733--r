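# Downstream statistics: allele-frequency decile profiles, depletion at IAF
# thresholds, TSS-distance profiles, GC association, haplotype concordance
# and additivity.

#' Allele-frequency decile activity profile
#'
#' Within each stratum (e.g. introgression source x allelic state), sequences
#' are ranked by frequency (stable rank, ties broken by input order) and split
#' into ten near-equal deciles; decile 1 holds the highest frequencies. Each
#' decile's active fraction is compared to the stratum-wide rate with an exact
#' two-sided binomial test, and a one-way ANOVA (F-test of the per-decile
#' percentages on decile number) assesses an overall frequency trend.
#'
#' @param records data frame with \code{frequency} in [0,1], logical
#'   \code{flag} (active or differentially active), and any stratifier
#'   columns.
#' @param stratify_by character vector of stratifier column names (default
#'   none: one stratum).
#' @return list with \code{profile} (per stratum x decile: n, n_flag,
#'   percent, binomial p, CI) and \code{anova_p}.
#' @export
decile_activity_profile <- function(records, stratify_by = character(0)) {
  stopifnot(all(records$frequency >= 0 & records$frequency <= 1))
  strata <- if (length(stratify_by)) {
    interaction(records[stratify_by], drop = TRUE, sep = "/")
  } else {
    factor(rep("all", nrow(records)))
  }
  out <- list()
  for (st in levels(strata)) {
    sub <- records[strata == st, , drop = FALSE]
    n_dec <- 10L
    n_distinct <- length(unique(sub$frequency))
    if (nrow(sub) < 10L || n_distinct < 10L) {
      n_dec <- max(1L, min(nrow(sub), n_distinct))
      warning("stratum ", st, " supports only ", n_dec,
              " frequency bins; deciles collapsed")
    }
    # rank 1 = highest frequency, so decile 1 = top frequencies
    rk <- rank(-sub$frequency, ties.method = "first")
    dec <- ceiling(rk * n_dec / nrow(sub))
    rate <- mean(sub$flag)
    rows <- lapply(seq_len(n_dec), function(k) {
      idx <- dec == k
      n <- sum(idx)
      n_flag <- sum(sub$flag[idx])
      bt <- stats::binom.test(n_flag, n, p = max(min(rate, 1 - 1e-12), 1e-12))
      data.frame(stratum = st, decile = k, n = n, n_flag = n_flag,
                 percent = 100 * n_flag / n, p = bt$p.value,
                 ci_lo = 100 * bt$conf.int[1L], ci_hi = 100 * bt$conf.int[2L],
                 stringsAsFactors = FALSE)
    })
    out[[st]] <- do.call(rbind, rows)
  }
  profile <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  anova_p <- if (length(unique(profile$decile)) > 1L) {
    fit <- stats::lm(percent ~ decile, data = profile)
    stats::anova(fit)[["Pr(>F)"]][1L]
  } else {
    NA_real_
  }
  list(profile = profile, anova_p = anova_p)
}

#' Depletion of differential activity at IAF thresholds
#'
#' For each threshold t, forms the 2x2 table of (flagged vs not) x
#' (IAF >= t vs IAF < t) and applies Fisher's exact test (two-sided).
#' Reports the conditional-MLE odds ratio with its 95% CI, alongside the
#' 0.5-corrected sample odds ratio for tables with zero cells.
#'
#' @param records data frame with logical \code{flag} and numeric \code{iaf}.
#' @param thresholds numeric IAF thresholds.
#' @return data frame per threshold: counts, \code{or}, \code{or_corrected},
#'   CI, \code{p}, and a \code{degenerate} flag for empty margins.
#' @export
threshold_depletion_test <- function(records, thresholds) {
  rows <- lapply(thresholds, function(t) {
    hi <- records$iaf >= t
    tab <- matrix(c(sum(records$flag & hi), sum(records$flag & !hi),
                    sum(!records$flag & hi), sum(!records$flag & !hi)),
                  nrow = 2L, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
    orc <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    if (degenerate) {
      data.frame(threshold = t, n_flag_hi = tab[1, 1], n_flag_lo = tab[1, 2],
                 n_other_hi = tab[2, 1], n_other_lo = tab[2, 2],
                 or = NA_real_, or_corrected = orc,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                 degenerate = TRUE)
    } else {
      ft <- stats::fisher.test(tab)
      data.frame(threshold = t, n_flag_hi = tab[1, 1], n_flag_lo = tab[1, 2],
                 n_other_hi = tab[2, 1], n_other_lo = tab[2, 2],
                 or = unname(ft$estimate), or_corrected = orc,
                 ci_lo = ft$conf.int[1L], ci_hi = ft$conf.int[2L],
                 p = ft$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Signed distance to the nearest TSS and distance-binned activity
#'
#' Distances are strand-aware: positive when the SNP lies downstream of the
#' gene's TSS. Ties between equidistant TSS resolve to the upstream one and
#' are flagged. Reports the per-bin active percentage with binomial tests
#' against the overall rate, a chi-square test of the active fraction within
#' vs beyond 1 kb, and (when an \code{allelic_state} column is present) a
#' logistic regression of activity on allelic state restricted to sequences
#' within 1 kb.
#'
#' @param sequences data frame with \code{contig}, \code{position} (SNP
#'   position, 0-based), logical \code{flag}, optional \code{allelic_state}.
#' @param tss data frame with \code{contig}, \code{position}, \code{strand}.
#' @param bins numeric break points for signed distances.
#' @return list with \code{distances}, \code{bin_profile}, \code{chisq_p},
#'   \code{logistic_p}.
#' @export
tss_distance_profile <- function(sequences, tss,
                                 bins = c(-Inf, -5000, -1000, -500, 0,
                                          500, 1000, 5000, Inf)) {
  if (nrow(tss) == 0L) stop("empty TSS set")
  dist <- numeric(nrow(sequences))
  tied <- logical(nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    cand <- tss[tss$contig == sequences$contig[i], , drop = FALSE]
    if (nrow(cand) == 0L) {
      dist[i] <- NA_real_
      next
    }
    d <- ifelse(cand$strand == "+",
                sequences$position[i] - cand$position,
                cand$position - sequences$position[i])
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1L) {
      tied[i] <- TRUE
      up <- best[d[best] < 0]
      best <- if (length(up)) up[1L] else best[1L]
    }
    dist[i] <- d[best]
  }
  distances <- data.frame(sequences, distance = dist, tss_tie = tied,
                          stringsAsFactors = FALSE)
  ok <- !is.na(dist)
  bin <- cut(dist[ok], breaks = bins)
  rate <- mean(sequences$flag[ok])
  bin_profile <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- bin == b
    n <- sum(idx)
    if (n == 0L) {
      return(data.frame(bin = b, n = 0L, n_flag = 0L, percent = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    n_flag <- sum(sequences$flag[ok][idx])
    bt <- stats::binom.test(n_flag, n, p = max(min(rate, 1 - 1e-12), 1e-12))
    data.frame(bin = b, n = n, n_flag = n_flag, percent = 100 * n_flag / n,
               p = bt$p.value, stringsAsFactors = FALSE)
  }))
  near <- abs(dist[ok]) <= 1000
  chisq_p <- if (length(unique(near)) > 1L) {
    suppressWarnings(stats::chisq.test(table(near, sequences$flag[ok]))$p.value)
  } else {
    NA_real_
  }
  logistic_p <- NA_real_
  if ("allelic_state" %in% names(sequences) && sum(near) > 2L) {
    subn <- distances[ok, ][near, , drop = FALSE]
    if (length(unique(subn$allelic_state)) > 1L) {
      fit <- stats::glm(flag ~ allelic_state, family = stats::binomial(),
                        data = subn)
      co <- summary(fit)$coefficients
      if (nrow(co) > 1L) logistic_p <- co[2L, 4L]
    }
  }
  list(distances = distances, bin_profile = bin_profile,
       chisq_p = chisq_p, logistic_p = logistic_p)
}

#' GC-content association with activity
#'
#' GC fraction of each core sequence; two-sided Wilcoxon rank-sum test of GC
#' in active vs inactive sequences, per introgression source.
#'
#' @param sequences data frame with \code{core_sequence}, logical \code{flag},
#'   and \code{source}.
#' @return list with \code{gc} (per-sequence fractions) and \code{tests}
#'   (per source: n, medians, Wilcoxon p).
#' @export
sequence_feature_tests <- function(sequences) {
  gc <- vapply(sequences$core_sequence, function(s) {
    b <- strsplit(s, "")[[1L]]
    mean(b %in% c("G", "C"))
  }, numeric(1L), USE.NAMES = FALSE)
  tests <- do.call(rbind, lapply(unique(sequences$source), function(src) {
    idx <- sequences$source == src
    g_act <- gc[idx & sequences$flag]
    g_in <- gc[idx & !sequences$flag]
    p <- if (length(g_act) > 0L && length(g_in) > 0L) {
      # GC fractions tie frequently; the normal approximation is intended
      suppressWarnings(stats::wilcox.test(g_act, g_in)$p.value)
    } else {
      NA_real_
    }
    data.frame(source = src, n_active = length(g_act), n_inactive = length(g_in),
               median_gc_active = stats::median(g_act),
               median_gc_inactive = stats::median(g_in),
               p = p, stringsAsFactors = FALSE)
  }))
  list(gc = gc, tests = tests)
}

# Helper: split haplotype oligos into the per-site states data frame, keeping
# only 2-SNP regions whose four single-variant oligos are all present.
eligible_pairs <- function(oligos, measured_oligos) {
  hap <- oligos[oligos$oligo_class == "HAPLOTYPE", , drop = FALSE]
  cfgs <- parse_allele_config(hap$allele_config)
  two <- vapply(cfgs, nrow, integer(1L)) == 2L
  hap <- hap[two, , drop = FALSE]
  cfgs <- cfgs[two]
  single <- oligos[oligos$oligo_class == "SINGLE", , drop = FALSE]
  scf <- parse_allele_config(single$allele_config)
  skey <- paste(vapply(scf, function(x) x$snp_id, character(1L)),
                vapply(scf, function(x) x$state, character(1L)))
  single_id <- stats::setNames(single$oligo_id, skey)

  rows <- lapply(seq_len(nrow(hap)), function(i) {
    cf <- cfgs[[i]]
    sid <- single_id[paste(cf$snp_id, cf$state)]
    if (anyNA(sid) || !all(sid %in% measured_oligos) ||
        !hap$oligo_id[i] %in% measured_oligos) {
      return(NULL)
    }
    data.frame(
      region_id = hap$region_id[i],
      hap_oligo = hap$oligo_id[i],
      state1 = cf$state[1L], state2 = cf$state[2L],
      single1 = unname(sid[1L]), single2 = unname(sid[2L]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Concordance between single-variant and haplotype-like activity
#'
#' Restricted to 2-SNP haplotype regions whose four constituent single-variant
#' oligos all survived filtering. Haplotype sequences carrying two archaic
#' alleles are excluded from the single-vs-haplotype comparison (no
#' single-variant counterpart exists); each remaining haplotype sequence is
#' paired with each constituent single-variant oligo carrying the same allele.
#' Reports per-class concordance (archaic-human, human-archaic, human-human)
#' with a chi-square test of homogeneity, and separately the concordance of
#' archaic-archaic sequences with the two one-archaic sequences of the same
#' region with its own chi-square test.
#'
#' @param calls activity calls (\code{oligo_id}, \code{is_active}), typically
#'   \code{call_activity(...)$calls}.
#' @param oligos oligo table.
#' @return list with \code{class_table}, \code{class_chisq},
#'   \code{class_chisq_p}, \code{aa_table}, \code{aa_chisq_p}.
#' @export
haplotype_concordance <- function(calls, oligos) {
  active <- stats::setNames(calls$is_active, calls$oligo_id)
  pairs <- eligible_pairs(oligos, calls$oligo_id)
  if (is.null(pairs)) {
    warning("no eligible single/haplotype pairs")
    return(list(class_table = NULL, class_chisq = NA_real_,
                class_chisq_p = NA_real_, aa_table = NULL,
                aa_chisq_p = NA_real_))
  }
  pairs$class <- paste0(substr(pairs$state1, 1L, 1L), substr(pairs$state2, 1L, 1L))

  one_arch <- pairs[pairs$class != "AA", , drop = FALSE]
  long <- rbind(
    data.frame(class = one_arch$class, hap = one_arch$hap_oligo,
               single = one_arch$single1, stringsAsFactors = FALSE),
    data.frame(class = one_arch$class, hap = one_arch$hap_oligo,
               single = one_arch$single2, stringsAsFactors = FALSE)
  )
  long$concordant <- active[long$hap] == active[long$single]
  class_label <- c(AM = "archaic-human", MA = "human-archaic", MM = "human-human")
  class_table <- do.call(rbind, lapply(names(class_label), function(cl) {
    sub <- long[long$class == cl, , drop = FALSE]
    data.frame(class = class_label[[cl]], n = nrow(sub),
               n_concordant = sum(sub$concordant),
               percent = 100 * mean(sub$concordant),
               stringsAsFactors = FALSE)
  }))
  usable <- class_table$n > 0L
  if (sum(usable) > 1L) {
    tab <- rbind(class_table$n_concordant[usable],
                 class_table$n[usable] - class_table$n_concordant[usable])
    if (any(rowSums(tab) == 0L)) {
      # every pair concordant (or none): no heterogeneity to test
      class_chisq <- 0
      class_chisq_p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      class_chisq <- unname(ct$statistic)
      class_chisq_p <- ct$p.value
    }
  } else {
    warning("fewer than two allelic-state classes; homogeneity test skipped")
    class_chisq <- NA_real_
    class_chisq_p <- NA_real_
  }

  # archaic-archaic vs one-archaic concordance, per region
  by_region <- split(pairs, pairs$region_id)
  aa_rows <- lapply(by_region, function(px) {
    aa <- px$hap_oligo[px$class == "AA"]
    if (!length(aa)) return(NULL)
    data.frame(
      vs_ah = if (any(px$class == "AM"))
        active[aa[1L]] == active[px$hap_oligo[px$class == "AM"][1L]] else NA,
      vs_ha = if (any(px$class == "MA"))
        active[aa[1L]] == active[px$hap_oligo[px$class == "MA"][1L]] else NA
    )
  })
  aa_df <- do.call(rbind, aa_rows)
  aa_table <- NULL
  aa_chisq_p <- NA_real_
  if (!is.null(aa_df)) {
    aa_table <- data.frame(
      comparison = c("archaic-archaic:archaic-human",
                     "archaic-archaic:human-archaic"),
      n = c(sum(!is.na(aa_df$vs_ah)), sum(!is.na(aa_df$vs_ha))),
      n_concordant = c(sum(aa_df$vs_ah, na.rm = TRUE),
                       sum(aa_df$vs_ha, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
    aa_table$percent <- 100 * aa_table$n_concordant / aa_table$n
    if (all(aa_table$n > 0L)) {
      tab <- rbind(aa_table$n_concordant, aa_table$n - aa_table$n_concordant)
      aa_chisq_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  list(class_table = class_table, class_chisq = class_chisq,
       class_chisq_p = class_chisq_p, aa_table = aa_table,
       aa_chisq_p = aa_chisq_p)
}

#' Additivity of haplotype activity
#'
#' For haplotype sequences whose constituent single-variant oligos are all
#' measured (archaic-archaic combinations excluded), compares the haplotype's
#' activity with the sum of the allele-matched single-variant activities:
#' per replicate, the singles' median barcode activities are summed, and the
#' median over replicates of that sum is regressed against the median over
#' replicates of the haplotype's per-replicate median activity. Haplotypes
#' called active while every matched constituent is inactive are flagged as
#' interaction candidates.
#'
#' @param act an \code{ActivityMatrix}.
#' @param oligos oligo table.
#' @param calls activity calls (\code{oligo_id}, \code{is_active}).
#' @return list with \code{table}, Pearson \code{r} and \code{p},
#'   regression \code{slope}, and \code{outliers} (haplotype oligo ids).
#' @export
additivity_correlation <- function(act, oligos, calls) {
  stopifnot(inherits(act, "ActivityMatrix"))
  active <- stats::setNames(calls$is_active, calls$oligo_id)
  pairs <- eligible_pairs(oligos, rownames(act$oligo_median))
  if (is.null(pairs)) {
    return(list(table = NULL, r = NA_real_, p = NA_real_, slope = NA_real_,
                outliers = character(0)))
  }
  pairs <- pairs[!(pairs$state1 == "ARCHAIC" & pairs$state2 == "ARCHAIC"), ,
                 drop = FALSE]
  med <- act$oligo_median
  hap_act <- apply(med[pairs$hap_oligo, , drop = FALSE], 1L, stats::median)
  summed <- apply(med[pairs$single1, , drop = FALSE] +
                    med[pairs$single2, , drop = FALSE], 1L, stats::median)
  ct <- stats::cor.test(summed, hap_act)
  slope <- unname(stats::coef(stats::lm(hap_act ~ summed))[2L])
  outlier <- active[pairs$hap_oligo] &
    !active[pairs$single1] & !active[pairs$single2]
  outlier[is.na(outlier)] <- FALSE
  table <- data.frame(
    region_id = pairs$region_id,
    hap_oligo = pairs$hap_oligo,
    hap_activity = unname(hap_act),
    summed_single_activity = unname(summed),
    outlier = unname(outlier),
    stringsAsFactors = FALSE
  )
  list(table = table, r = unname(ct$estimate), p = ct$p.value, slope = slope,
       outliers = pairs$hap_oligo[outlier])
}
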