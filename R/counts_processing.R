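# Normalisation, barcode/oligo filtering, and barcode-level activity.

#' Library-size normalise counts to log2 CPM
#'
#' \code{log2cpm = log2((count + pseudocount) * 1e6 / library_size)}.
#'
#' @param counts a \code{BarcodeCountTable}.
#' @param pseudocount added to every raw count before CPM (default 1).
#' @return list of class \code{mpra_norm} carrying \code{log2cpm_cdna},
#'   \code{log2cpm_pdna} (barcode x replicate matrices) and the input table.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "BarcodeCountTable"))
  if (any(counts$lib_cdna <= 0) || any(counts$lib_pdna <= 0)) {
    stop("library sizes must be positive")
  }
  l2 <- function(m, lib) {
    log2(sweep(m + pseudocount, 2L, lib / 1e6, "/"))
  }
  structure(list(
    log2cpm_cdna = l2(counts$cdna, counts$lib_cdna),
    log2cpm_pdna = l2(counts$pdna, counts$lib_pdna),
    counts = counts,
    pseudocount = pseudocount
  ), class = "mpra_norm")
}

#' Apply the barcode and oligo filters
#'
#' Removes barcodes whose mean pDNA log2 CPM across replicates (computed
#' without pseudocount, so the threshold keeps its published meaning) is below
#' \code{pdna_floor}, then removes oligos left with fewer than
#' \code{min_barcodes} surviving barcodes.
#'
#' @param norm output of [normalize_counts()].
#' @param pdna_floor mean pDNA log2 CPM floor (default -5).
#' @param min_barcodes minimum barcodes per retained oligo (default 10).
#' @return list with \code{barcodes} (retained barcode ids), \code{map}
#'   (retained barcode map), \code{n_barcodes_removed},
#'   \code{n_oligos_removed}.
#' @export
filter_library <- function(norm, pdna_floor = -5, min_barcodes = 10L) {
  stopifnot(inherits(norm, "mpra_norm"))
  counts <- norm$counts
  raw_l2 <- log2(sweep(counts$pdna, 2L, counts$lib_pdna / 1e6, "/"))
  mean_l2 <- rowMeans(raw_l2)  # a zero count gives -Inf, so the mean is -Inf
  pass_bc <- is.finite(mean_l2) & mean_l2 >= pdna_floor
  n_bc_removed <- sum(!pass_bc)

  map <- counts$map
  map_pass <- map[map$barcode %in% rownames(counts$pdna)[pass_bc], , drop = FALSE]
  tab <- table(map_pass$oligo_id)
  keep_oligos <- names(tab)[tab >= min_barcodes]
  n_oligo_removed <- length(unique(map$oligo_id)) - length(keep_oligos)
  map_keep <- map_pass[map_pass$oligo_id %in% keep_oligos, , drop = FALSE]
  if (nrow(map_keep) == 0L) stop("no barcodes survive filtering")
  list(
    barcodes = map_keep$barcode,
    map = map_keep,
    n_barcodes_removed = n_bc_removed,
    n_oligos_removed = n_oligo_removed
  )
}

#' Compute barcode-level and oligo-level activity
#'
#' Activity of a barcode in a replicate is its cDNA log2 CPM minus its pDNA
#' log2 CPM. Also computes the per-replicate mean activity over all retained
#' barcodes, the per-oligo per-replicate median barcode activity, and the
#' per-oligo summed-count activity (log2 of summed cDNA CPM minus log2 of
#' summed pDNA CPM, with a 0.5 aggregate pseudocount).
#'
#' @param norm output of [normalize_counts()].
#' @param retained output of [filter_library()].
#' @return list of class \code{ActivityMatrix}: \code{activity} (barcode x
#'   replicate), \code{mu} (per-replicate mean), \code{oligo_median},
#'   \code{oligo_summed} (oligo x replicate), \code{map}, \code{replicates}.
#' @export
compute_activity <- function(norm, retained) {
  stopifnot(inherits(norm, "mpra_norm"))
  bc <- retained$barcodes
  act <- norm$log2cpm_cdna[bc, , drop = FALSE] -
    norm$log2cpm_pdna[bc, , drop = FALSE]
  mu <- colMeans(act)

  map <- retained$map
  oligo_f <- factor(map$oligo_id)
  med <- apply(act, 2L, function(col) {
    vapply(split(col, oligo_f), stats::median, numeric(1L))
  })
  counts <- norm$counts
  sum_c <- rowsum(counts$cdna[bc, , drop = FALSE], oligo_f)
  sum_p <- rowsum(counts$pdna[bc, , drop = FALSE], oligo_f)
  summed <- log2(sweep(sum_c + 0.5, 2L, counts$lib_cdna / 1e6, "/")) -
    log2(sweep(sum_p + 0.5, 2L, counts$lib_pdna / 1e6, "/"))

  structure(list(
    activity = act,
    mu = mu,
    oligo_median = med,
    oligo_summed = summed,
    map = map,
    replicates = counts$replicates
  ), class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat("ActivityMatrix:", nrow(x$activity), "barcodes,",
      nrow(x$oligo_median), "oligos,", ncol(x$activity), "replicates\n")
  cat("replicate mean activity:",
      paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = ", "), "\n")
  invisible(x)
}
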