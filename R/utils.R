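BASES <- c("A", "C", "G", "T")

#' @importFrom stats runif
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stop_if_not_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    stop(what, " contains non-ACGT characters", call. = FALSE)
  }
  invisible(x)
}

# Deterministic per-stage child seeds fanned out from one global seed.
# Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
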