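# Ground-truth recovery metrics for the synthetic scenarios.

#' Sensitivity and false discovery proportion of activity calls
#'
#' An oligo is truly active when its planted activity is positive.
#'
#' @param calls activity calls (\code{oligo_id}, \code{is_active}).
#' @param truth ground truth from [simulate_ground_truth()].
#' @return list with \code{sensitivity}, \code{fdp}, \code{n_true},
#'   \code{n_called}.
#' @export
evaluate_activity_calls <- function(calls, truth) {
  beta <- truth$oligo$beta[match(calls$oligo_id, truth$oligo$oligo_id)]
  true_active <- beta > 0
  called <- calls$is_active
  tp <- sum(called & true_active)
  list(
    sensitivity = if (any(true_active)) tp / sum(true_active) else NA_real_,
    fdp = if (any(called)) sum(called & !true_active) / sum(called) else 0,
    n_true = sum(true_active),
    n_called = sum(called)
  )
}

#' Power, FDP and effect-size recovery of the allelic model
#'
#' Power is computed over tested SNPs with a true allelic |log2 FC| of at
#' least \code{min_effect}; false discoveries are flagged SNPs with a true
#' log fold change of zero. The slope and Pearson correlation come from
#' regressing the estimated on the true log fold changes over all tested
#' SNPs.
#'
#' @param table the \code{$table} of an \code{mpra_diff} fit.
#' @param truth ground truth.
#' @param min_effect minimum planted |log2 FC| counted for power (default 1).
#' @return list with \code{power}, \code{fdp}, \code{slope}, \code{r},
#'   \code{sign_concordance} (fraction of calls with |logfc| >= 0.5 whose
#'   estimated sign matches the truth).
#' @export
evaluate_differential <- function(table, truth, min_effect = 1) {
  tr <- truth$snp$true_logfc[match(table$snp_id, truth$snp$snp_id)]
  called <- table$is_differentially_active
  strong <- abs(tr) >= min_effect
  null_snp <- tr == 0
  big_call <- called & abs(table$logfc) >= 0.5
  list(
    power = if (any(strong)) mean(called[strong]) else NA_real_,
    fdp = if (any(called)) sum(called & null_snp) / sum(called) else 0,
    slope = if (stats::sd(tr) > 0)
      unname(stats::coef(stats::lm(table$logfc ~ tr))[2L]) else NA_real_,
    r = if (stats::sd(tr) > 0) stats::cor(table$logfc, tr) else NA_real_,
    sign_concordance = if (any(big_call))
      mean(sign(table$logfc[big_call]) == sign(tr[big_call])) else NA_real_
  )
}
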