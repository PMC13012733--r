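# Per-replicate activity testing, BH correction within replicate, the
# >= 2-replicate consensus rule, and ancestry-specific activity classes.

#' One-sided activity test for one oligo in one replicate
#'
#' One-sample t test (alternative: greater) of the oligo's barcode activities
#' against the replicate mean activity, treated as a known constant.
#' Conventions for degenerate inputs: fewer than two barcode activities gives
#' \code{NA} (untestable); zero variance gives p = 0 if the mean exceeds
#' \code{mu}, p = 1 if it falls below, and p = 0.5 if it equals \code{mu}.
#'
#' @param activities numeric barcode activities for one oligo.
#' @param mu replicate mean activity.
#' @return p-value in [0,1], or NA if untestable.
#' @export
test_activity_per_replicate <- function(activities, mu) {
  activities <- activities[is.finite(activities)]
  if (length(activities) < 2L) return(NA_real_)
  if (stats::sd(activities) == 0) {
    m <- mean(activities)
    return(if (m > mu) 0 else if (m < mu) 1 else 0.5)
  }
  stats::t.test(activities, mu = mu, alternative = "greater")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; NA inputs stay NA
#' and do not count towards the family size.
#'
#' @param pvals numeric p-values in [0,1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus activity calls and ancestry specificity
#'
#' An oligo is active if its BH-adjusted p-value is below \code{alpha} in at
#' least \code{min_replicates} replicates (untestable replicates count as not
#' significant). Specificity: EUR_SPECIFIC if significant in both European
#' replicates and in no Papuan replicate; PNG_SPECIFIC if significant in at
#' least two of the three Papuan replicates and in no European replicate;
#' otherwise SHARED if active, NONE if not.
#'
#' @param qmat oligo x replicate matrix of adjusted p-values (NA =
#'   untestable).
#' @param replicates replicate descriptors with \code{ancestry} in
#'   \{"EUR","PNG"\}, rows aligned to \code{qmat} columns.
#' @param alpha significance level (default 0.05).
#' @param min_replicates consensus requirement (default 2).
#' @return data frame: \code{oligo_id}, \code{n_significant},
#'   \code{is_active}, \code{specificity}.
#' @export
call_active <- function(qmat, replicates, alpha = 0.05, min_replicates = 2L) {
  if (!all(replicates$ancestry %in% c("EUR", "PNG"))) {
    stop("unknown ancestry label in replicates")
  }
  sig <- !is.na(qmat) & qmat < alpha
  n_sig <- rowSums(sig)
  active <- n_sig >= min_replicates
  eur <- replicates$ancestry == "EUR"
  png <- replicates$ancestry == "PNG"
  eur_all <- rowSums(sig[, eur, drop = FALSE]) == sum(eur)
  eur_none <- rowSums(sig[, eur, drop = FALSE]) == 0L
  png_none <- rowSums(sig[, png, drop = FALSE]) == 0L
  png_two <- rowSums(sig[, png, drop = FALSE]) >= 2L

  spec <- ifelse(eur_all & png_none, "EUR_SPECIFIC",
          ifelse(png_two & eur_none, "PNG_SPECIFIC",
          ifelse(active, "SHARED", "NONE")))
  data.frame(
    oligo_id = rownames(qmat),
    n_significant = n_sig,
    is_active = active,
    specificity = spec,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call active oligos from an activity matrix
#'
#' Runs the per-replicate one-sided activity test for every oligo, adjusts
#' p-values with Benjamini-Hochberg within each replicate (one family per
#' replicate), and applies the consensus and specificity rules.
#'
#' @param act an \code{ActivityMatrix} from [compute_activity()].
#' @param alpha FDR level (default 0.05).
#' @param min_replicates consensus requirement (default 2).
#' @return list with \code{calls} (see [call_active()]), \code{p} and \code{q}
#'   (oligo x replicate matrices).
#' @export
call_activity <- function(act, alpha = 0.05, min_replicates = 2L) {
  stopifnot(inherits(act, "ActivityMatrix"))
  oligo_f <- factor(act$map$oligo_id)
  oligos <- levels(oligo_f)
  reps <- colnames(act$activity)
  pmat <- matrix(NA_real_, length(oligos), length(reps),
                 dimnames = list(oligos, reps))
  for (r in seq_along(reps)) {
    by_oligo <- split(act$activity[, r], oligo_f)
    pmat[, r] <- vapply(by_oligo, test_activity_per_replicate,
                        numeric(1L), mu = act$mu[r])
  }
  qmat <- apply(pmat, 2L, bh_adjust)
  dimnames(qmat) <- dimnames(pmat)
  calls <- call_active(qmat, act$replicates, alpha = alpha,
                       min_replicates = min_replicates)
  list(calls = calls, p = pmat, q = qmat)
}
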