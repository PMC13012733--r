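# PWM scanning of allele pairs, exact score p-values by dynamic programming,
# and the differential binding score between archaic and modern alleles.

#' Read position weight matrices from a MEME minimal-format file
#'
#' @param path path to a MEME minimal-format motif file.
#' @param pseudocount uniform pseudocount added to every probability before
#'   per-column renormalisation (default 0).
#' @return list of motifs; each is a list with \code{motif_id}, \code{prob}
#'   (L x 4 probability matrix, columns A, C, G, T) and \code{background}
#'   (length-4 base probabilities).
#' @export
load_motifs <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  lines <- trimws(lines)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "\\s+")[[1L]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[c(2L, 4L, 6L, 8L)])
      names(vals) <- toks[c(1L, 3L, 5L, 7L)]
      background <- vals[BASES]
    }
  }

  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  for (i in seq_along(motif_at)) {
    id <- strsplit(lines[motif_at[i]], "\\s+")[[1L]][2L]
    hdr <- motif_at[i] + grep("^letter-probability matrix",
                              lines[seq(motif_at[i] + 1L, length(lines))])[1L]
    if (is.na(hdr)) stop("motif ", id, ": no letter-probability matrix header")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[seq(hdr + 1L, hdr + w)]
    mat <- t(vapply(seq_along(rows), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(rows[j], "\\s+")[[1L]]))
      if (length(v) != 4L || anyNA(v)) {
        stop("motif ", id, ": malformed probability row at line ", hdr + j)
      }
      v
    }, numeric(4L)))
    colnames(mat) <- BASES
    if (pseudocount > 0) {
      mat <- (mat + pseudocount) / (1 + 4 * pseudocount)
    }
    if (any(abs(rowSums(mat) - 1) > 1e-4)) {
      stop("motif ", id, ": columns do not sum to 1")
    }
    mat <- mat / rowSums(mat)
    motifs[[i]] <- list(motif_id = id, prob = mat, background = background)
  }
  motifs
}

#' Write motifs to a MEME minimal-format file
#'
#' @param motifs list of motifs as returned by [load_motifs()].
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", ""),
             con)
  bg <- if (length(motifs)) motifs[[1L]]$background else rep(0.25, 4)
  writeLines(c("Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$prob)), con)
    writeLines(apply(m$prob, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

# Log2-odds score matrix (L x 4, bits); zero probabilities score -Inf.
pwm_logodds <- function(pwm) {
  log2(sweep(pwm$prob, 2L, pwm$background, "/"))
}

# Maximum log2-odds score of a motif over all offsets of both strands.
scan_max_score <- function(sequence, pwm) {
  S <- pwm_logodds(pwm)
  L <- nrow(S)
  n <- nchar(sequence)
  if (L > n) return(-Inf)
  best <- -Inf
  for (strand_seq in c(sequence, revcomp(sequence))) {
    idx <- match(strsplit(strand_seq, "")[[1L]], BASES)
    for (off in seq_len(n - L + 1L)) {
      sc <- sum(S[cbind(seq_len(L), idx[off:(off + L - 1L)])])
      if (sc > best) best <- sc
    }
  }
  best
}

#' Exact PWM score p-value by dynamic programming
#'
#' Computes the probability that a random sequence drawn from the motif's
#' background distribution attains a log2-odds score at least as large as
#' \code{score}. Per-column scores are discretised at \code{granularity} bits
#' and the exact score distribution is built by convolution across columns;
#' the discretisation error on the p-value is bounded by the probability mass
#' within L x granularity of the threshold.
#'
#' @param pwm a motif (see [load_motifs()]).
#' @param score log2-odds score in bits.
#' @param granularity score bin width in bits (default 0.01).
#' @return tail probability in [0,1].
#' @export
pwm_score_pvalue <- function(pwm, score, granularity = 0.01) {
  stopifnot(granularity > 0)
  dist <- pwm_score_distribution(pwm, granularity)
  t_int <- round(score / granularity)
  idx <- t_int - dist$offset + 1L
  # below the smallest finite score the whole finite mass qualifies (this is
  # 1 unless some motif entries have zero probability and score -Inf)
  if (idx <= 1L) return(sum(dist$prob))
  if (idx > length(dist$prob)) return(0)
  sum(dist$prob[idx:length(dist$prob)])
}

# Discretised exact null score distribution: list(prob, offset) where
# prob[i] = P(integer score == offset + i - 1) under the background.
pwm_score_distribution <- function(pwm, granularity) {
  S <- pwm_logodds(pwm)
  Sint <- round(S / granularity)
  bg <- pwm$background
  dist <- 1
  offset <- 0L
  for (j in seq_len(nrow(Sint))) {
    col <- Sint[j, ]
    keep <- is.finite(col)
    if (!any(keep)) return(list(prob = numeric(0), offset = 0L))
    cmin <- min(col[keep])
    cmax <- max(col[keep])
    new <- numeric(length(dist) + (cmax - cmin))
    for (b in which(keep)) {
      sh <- col[b] - cmin
      new[(1L + sh):(length(dist) + sh)] <-
        new[(1L + sh):(length(dist) + sh)] + dist * bg[b]
    }
    dist <- new
    offset <- offset + as.integer(cmin)
  }
  list(prob = dist, offset = offset)
}

# Smallest score (bits) whose tail probability is below p_target; +Inf if the
# motif cannot reach that significance.
pwm_score_threshold <- function(pwm, p_target, granularity = 0.01) {
  dist <- pwm_score_distribution(pwm, granularity)
  if (!length(dist$prob)) return(Inf)
  tail_p <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail_p < p_target)
  if (!length(ok)) return(Inf)
  (dist$offset + ok[1L] - 1L) * granularity
}

#' Score both alleles of a SNP against a motif collection
#'
#' Each allele's core sequence is trimmed to its central 40 bp (the window
#' used for transcription-factor binding analysis) and scanned on both strands
#' at every offset; the per-motif maximum log2-odds score and its exact
#' p-value are recorded per allele.
#'
#' @param seq_modern,seq_archaic core sequences of the two alleles (>= 40 bp).
#' @param motifs motif collection from [load_motifs()].
#' @param window scan window width (default 40).
#' @param granularity p-value discretisation in bits.
#' @return data frame: \code{motif_id}, \code{score_modern}, \code{score_archaic},
#'   \code{p_modern}, \code{p_archaic}. Motifs longer than the window are
#'   skipped with a warning.
#' @export
score_alleles <- function(seq_modern, seq_archaic, motifs, window = 40L,
                          granularity = 0.01) {
  stop_if_not_dna(seq_modern, "modern sequence")
  stop_if_not_dna(seq_archaic, "archaic sequence")
  if (nchar(seq_modern) < window || nchar(seq_archaic) < window) {
    stop("core sequences must be at least ", window, " bp")
  }
  trim <- function(s) {
    st <- floor((nchar(s) - window) / 2)
    substr(s, st + 1L, st + window)
  }
  sm <- trim(seq_modern)
  sa <- trim(seq_archaic)
  keep <- vapply(motifs, function(m) nrow(m$prob) <= window, logical(1L))
  if (any(!keep)) warning(sum(!keep), " motif(s) longer than ", window, " bp skipped")
  motifs <- motifs[keep]
  res <- lapply(motifs, function(m) {
    s1 <- scan_max_score(sm, m)
    s2 <- scan_max_score(sa, m)
    data.frame(
      motif_id = m$motif_id,
      score_modern = s1,
      score_archaic = s2,
      p_modern = pwm_score_pvalue(m, s1, granularity),
      p_archaic = pwm_score_pvalue(m, s2, granularity),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Differential binding record for one SNP
#'
#' Retains motifs where one allele matches at p below the stringent threshold
#' and the other at p below the lenient threshold, computes the differential
#' binding score (archaic minus modern best score) per motif, and reports the
#' motif with the largest absolute score difference.
#'
#' @param hits data frame from [score_alleles()].
#' @param thresholds length-2 numeric: stringent and lenient p thresholds
#'   (default \code{c(1e-4, 1e-3)}).
#' @return one-row data frame (\code{best_motif_id}, \code{score_archaic},
#'   \code{score_modern}, \code{p_archaic}, \code{p_modern},
#'   \code{binding_delta}) or \code{NULL} if no motif qualifies.
#' @export
differential_binding <- function(hits, thresholds = c(1e-4, 1e-3)) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  pmin2 <- pmin(hits$p_modern, hits$p_archaic)
  pmax2 <- pmax(hits$p_modern, hits$p_archaic)
  qual <- pmin2 < thresholds[1L] & pmax2 < thresholds[2L]
  if (!any(qual)) return(NULL)
  h <- hits[qual, , drop = FALSE]
  delta <- h$score_archaic - h$score_modern
  best <- which.max(abs(delta))
  data.frame(
    best_motif_id = h$motif_id[best],
    score_archaic = h$score_archaic[best],
    score_modern = h$score_modern[best],
    p_archaic = h$p_archaic[best],
    p_modern = h$p_modern[best],
    binding_delta = delta[best],
    stringsAsFactors = FALSE
  )
}
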