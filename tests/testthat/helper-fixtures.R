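# Shared in-code fixtures: tiny reference/panel pairs, hand-built count
# tables, and synthetic motifs.

# A deterministic reference contig with given SNPs substituted in.
tiny_reference <- function(len = 2000L, seed = 42L, contig = "chr_t") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), contig)
}

# A small SNP panel on one contig. positions are 0-based; modern alleles are
# forced to match the reference.
tiny_panel <- function(positions, reference, contig = "chr_t",
                       source = "DENISOVAN", iaf = 0.3) {
  ref <- reference[[contig]]
  modern <- substring(ref, positions + 1L, positions + 1L)
  archaic <- vapply(modern, function(b) setdiff(c("A", "C", "G", "T"), b)[1L],
                    character(1L), USE.NAMES = FALSE)
  data.frame(
    snp_id = sprintf("tsnp%02d", seq_along(positions)),
    contig = contig,
    position = positions,
    modern_allele = modern,
    archaic_allele = archaic,
    source = source,
    iaf = iaf,
    stringsAsFactors = FALSE
  )
}

# Build a motif object directly from a consensus string.
make_test_motif <- function(id, consensus, strength = 0.97) {
  idx <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
  m <- matrix((1 - strength) / 3, length(idx), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(idx)) m[i, idx[i]] <- strength
  list(motif_id = id, prob = m, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

# Hand-built BarcodeCountTable from matrices.
make_counts_table <- function(cdna, pdna, map, lib_cdna = colSums(cdna),
                              lib_pdna = colSums(pdna),
                              replicates = default_replicates()[seq_len(ncol(cdna)), ]) {
  colnames(cdna) <- colnames(pdna) <- replicates$replicate_id
  rownames(cdna) <- rownames(pdna) <- map$barcode
  structure(list(
    cdna = cdna, pdna = pdna,
    lib_cdna = stats::setNames(lib_cdna, replicates$replicate_id),
    lib_pdna = stats::setNames(lib_pdna, replicates$replicate_id),
    map = map, replicates = replicates, seed = NA_integer_
  ), class = "BarcodeCountTable")
}

# Small end-to-end bundle, sized for test speed.
small_bundle <- function(scenario = "default", seed = 1L, n_snps = 150L, ...) {
  suppressMessages(make_fixtures(scenario, seed = seed,
                                 panel_config = list(n_snps = n_snps), ...))
}

# Two-sided Fisher p oracle: sum of hypergeometric outcomes no more likely
# than the observed one.
sum_hyper_p <- function(x, m, n, k) {
  probs <- stats::dhyper(0:m, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Independent reverse complement (character arithmetic only).
revcomp_t <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# Brute-force BH step-up oracle: p_(i) * m / i with cumulative minimum from
# the largest p downwards, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
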