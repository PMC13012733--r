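# Synthetic MPRA data with known ground truth: SNP panels on random reference
# contigs, barcode libraries, and negative-binomial cDNA/pDNA barcode counts.
#
# The default settings emulate the assay this package targets: 5 replicate
# libraries across 3 lymphoblastoid cell lines (2 European, 3 Papuan after one
# replicate drop), ~15% of SNPs in multi-SNP regions, introgressed allele
# frequencies >= 0.15, and 48 +/- 40 barcodes per oligo with a floor of 10.

#' Default replicate layout
#'
#' Five replicate libraries: two from a European LCL (GM12878) and three from
#' two Papuan LCLs (PNG22 twice, PNG8 once -- its first replicate is dropped,
#' mirroring a failed cDNA library).
#'
#' @return data frame with \code{replicate_id}, \code{cell_line},
#'   \code{ancestry}.
#' @export
default_replicates <- function() {
  data.frame(
    replicate_id = c("GM12878_1", "GM12878_2", "PNG22_1", "PNG22_2", "PNG8_2"),
    cell_line = c("GM12878", "GM12878", "PNG22", "PNG22", "PNG8"),
    ancestry = c("EUR", "EUR", "PNG", "PNG", "PNG"),
    stringsAsFactors = FALSE
  )
}

panel_defaults <- function() {
  list(
    n_snps = 850L,
    clustered_fraction = 0.15,
    denisovan_fraction = 0.55,
    cluster_sizes = c(2L, 3L, 4L),
    cluster_size_probs = c(0.875, 0.1, 0.025),
    iaf_min = 0.15,
    iaf_shape1 = 0.8,
    iaf_shape2 = 4,
    tss_within_1kb = 0.35,
    contig_length = 4000L,
    snp_anchor = 2000L,
    motif_plant = NULL  # list(motifs=, n=, seed offset handled globally)
  )
}

#' Simulate a SNP panel, TSS annotation and reference
#'
#' Each SNP unit (an isolated SNP or a cluster of 2-4 SNPs within 170 bp)
#' is placed on its own random reference contig with one strand-aware TSS at
#' a controlled distance, so downstream TSS-distance statistics can be
#' exercised without interference between units. Introgressed allele
#' frequencies are drawn from a truncated decreasing distribution on
#' [iaf_min, 1]. Optionally, transcription-factor motifs are written into the
#' reference around a subset of isolated SNPs so that one allele completes the
#' motif consensus and the other breaks it (\code{motif_plant = list(motifs =,
#' n =)}); these SNPs are recorded in the \code{meta$motif_snps} table.
#'
#' @param config named list overriding the defaults (panel size, clustered
#'   fraction, IAF distribution, TSS placement, motif planting).
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with \code{panel} (SNP data frame), \code{tss} (contig,
#'   position, strand, gene_id), \code{reference} (named character vector)
#'   and \code{meta}.
#' @export
simulate_snp_panel <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(panel_defaults(), config)
  if (cfg$clustered_fraction < 0 || cfg$clustered_fraction > 1) {
    stop("clustered fraction must lie in [0,1]")
  }
  set.seed(child_seed(seed, "snp_panel"))

  n <- cfg$n_snps
  n_clustered_target <- round(n * cfg$clustered_fraction)
  unit_sizes <- integer(0)
  assigned <- 0L
  while (assigned < n_clustered_target) {
    s <- sample(cfg$cluster_sizes, 1L, prob = cfg$cluster_size_probs)
    s <- min(s, n_clustered_target - assigned + 1L)
    if (s < 2L) break
    unit_sizes <- c(unit_sizes, s)
    assigned <- assigned + s
  }
  n_isolated <- n - assigned
  unit_sizes <- c(unit_sizes, rep(1L, n_isolated))
  unit_sizes <- sample(unit_sizes)  # shuffle cluster placement
  n_units <- length(unit_sizes)

  L <- cfg$contig_length
  anchor <- cfg$snp_anchor
  contigs <- sprintf("ctg%04d", seq_len(n_units))
  reference <- vapply(seq_len(n_units), function(i) random_dna(L), character(1L))
  names(reference) <- contigs

  panel <- vector("list", n_units)
  tss <- vector("list", n_units)
  snp_counter <- 0L
  for (i in seq_len(n_units)) {
    sz <- unit_sizes[i]
    offsets <- if (sz == 1L) 0L else cumsum(c(0L, sample(20:30, sz - 1L, replace = TRUE)))
    positions <- anchor + offsets
    ids <- sprintf("snp%05d", snp_counter + seq_len(sz))
    snp_counter <- snp_counter + sz
    src <- if (stats::runif(1L) < cfg$denisovan_fraction) "DENISOVAN" else "NEANDERTHAL"
    ref_bases <- substring(reference[i], positions + 1L, positions + 1L)
    archaic <- vapply(ref_bases, function(b) sample(setdiff(BASES, b), 1L),
                      character(1L), USE.NAMES = FALSE)
    iaf <- cfg$iaf_min + (1 - cfg$iaf_min) *
      stats::rbeta(sz, cfg$iaf_shape1, cfg$iaf_shape2)
    panel[[i]] <- data.frame(
      snp_id = ids, contig = contigs[i], position = positions,
      modern_allele = ref_bases, archaic_allele = archaic,
      source = src, iaf = iaf, stringsAsFactors = FALSE
    )
    near <- stats::runif(1L) < cfg$tss_within_1kb
    g <- if (near) sample(50:1000, 1L) else sample(1001:1800, 1L)
    side <- sample(c(-1L, 1L), 1L)
    tss[[i]] <- data.frame(
      contig = contigs[i],
      position = anchor + side * g,
      strand = sample(c("+", "-"), 1L),
      gene_id = sprintf("gene%04d", i),
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, panel)
  tss <- do.call(rbind, tss)
  meta <- list(seed = seed, config = cfg)

  if (!is.null(cfg$motif_plant)) {
    planted <- plant_motifs(panel, reference, cfg$motif_plant)
    panel <- planted$panel
    reference <- planted$reference
    meta$motif_snps <- planted$motif_snps
  }
  list(panel = panel, tss = tss, reference = reference, meta = meta)
}

# Write motif consensus sequences into the reference around isolated SNPs so
# that one allele carries the consensus base at a discriminating column and
# the other carries the least likely base.
plant_motifs <- function(panel, reference, plant) {
  motifs <- plant$motifs
  n_plant <- plant$n
  iso <- names(which(table(panel$contig) == 1L))
  cand <- panel$snp_id[panel$contig %in% iso]
  if (length(cand) < n_plant) stop("not enough isolated SNPs to plant motifs in")
  chosen <- sample(cand, n_plant)
  rec <- vector("list", n_plant)
  for (k in seq_len(n_plant)) {
    row <- which(panel$snp_id == chosen[k])
    m <- motifs[[sample(length(motifs), 1L)]]
    Lm <- nrow(m$prob)
    j <- ceiling(Lm / 2)  # discriminating column near the motif centre
    consensus <- BASES[apply(m$prob, 1L, which.max)]
    broken <- BASES[which.min(m$prob[j, ])]
    pos <- panel$position[row]
    ctg <- panel$contig[row]
    start <- pos - (j - 1L)
    refseq <- reference[[ctg]]
    for (i in seq_len(Lm)) {
      if (i != j) refseq <- substitute_base(refseq, start + i - 1L, consensus[i])
    }
    bound_allele <- sample(c("MODERN", "ARCHAIC"), 1L)
    if (bound_allele == "MODERN") {
      panel$modern_allele[row] <- consensus[j]
      panel$archaic_allele[row] <- broken
    } else {
      panel$modern_allele[row] <- broken
      panel$archaic_allele[row] <- consensus[j]
    }
    refseq <- substitute_base(refseq, pos, panel$modern_allele[row])
    reference[[ctg]] <- refseq
    rec[[k]] <- data.frame(snp_id = chosen[k], motif_id = m$motif_id,
                           bound_allele = bound_allele, stringsAsFactors = FALSE)
  }
  list(panel = panel, reference = reference,
       motif_snps = do.call(rbind, rec))
}

barcode_defaults <- function() {
  list(mean_barcodes = 48, sd_barcodes = 40, floor = 10L, drop_fraction = 0)
}

#' Simulate a barcode-to-oligo map
#'
#' Per-oligo barcode multiplicity follows a discretised log-normal matched to
#' the target mean and standard deviation, truncated below at \code{floor}.
#' A configurable fraction of oligos may instead receive fewer than
#' \code{floor} barcodes to exercise the downstream oligo filter. Barcodes are
#' unique random 15-mers.
#'
#' @param oligos oligo data frame (needs \code{oligo_id}).
#' @param config list overriding \code{mean_barcodes} (48), \code{sd_barcodes}
#'   (40), \code{floor} (10), \code{drop_fraction} (0).
#' @param seed integer seed.
#' @param barcode_length barcode length in bp (default 15).
#' @return data frame with \code{barcode}, \code{oligo_id}.
#' @export
simulate_barcode_library <- function(oligos, config = list(), seed = 1L,
                                     barcode_length = 15L) {
  stopifnot(nrow(oligos) > 0L)
  cfg <- utils::modifyList(barcode_defaults(), config)
  set.seed(child_seed(seed, "barcode_library"))
  n <- nrow(oligos)
  sigma2 <- log(1 + (cfg$sd_barcodes / cfg$mean_barcodes)^2)
  mu <- log(cfg$mean_barcodes) - sigma2 / 2
  m <- pmax(round(stats::rlnorm(n, mu, sqrt(sigma2))), cfg$floor)
  if (cfg$drop_fraction > 0) {
    low <- sample(n, round(n * cfg$drop_fraction))
    m[low] <- sample(seq_len(cfg$floor - 1L), length(low), replace = TRUE)
  }
  total <- sum(m)
  if (total > 4^barcode_length) {
    stop("requested barcodes exceed 4^", barcode_length)
  }
  barcodes <- make_unique_barcodes(total, barcode_length)
  data.frame(
    barcode = barcodes,
    oligo_id = rep(oligos$oligo_id, times = m),
    stringsAsFactors = FALSE
  )
}

make_unique_barcodes <- function(n, len) {
  draw <- function(k) {
    mat <- matrix(sample(BASES, k * len, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  bc <- unique(draw(n + ceiling(n * 0.01) + 10L))
  while (length(bc) < n) bc <- unique(c(bc, draw(n - length(bc) + 10L)))
  bc[seq_len(n)]
}

counts_defaults <- function() {
  list(
    mean_pdna = 200, mean_cdna = 200,
    dispersion_pdna = 0.05, dispersion_cdna = 0.15,
    abundance_shape = 4,       # Gamma barcode-abundance weights, mean 1
    baseline_log2 = 0,
    replicate_sd = 0.05,       # scalar per-replicate shift, log2 units
    unassigned_fraction = 0.1  # library-size remainder not in the count table
  )
}

#' Simulate barcode-level cDNA/pDNA counts
#'
#' Per barcode b of oligo o: pDNA counts are negative binomial with mean
#' proportional to a Gamma-distributed barcode abundance weight (shared across
#' replicates, reproducing the high cross-replicate pDNA correlation), and
#' cDNA counts are negative binomial with mean scaled by
#' \code{2^(baseline + beta_o + eps_r)}, where \code{beta_o} is the oligo's
#' true activity from the ground truth and \code{eps_r} a small per-replicate
#' shift. Library sizes equal the column sums plus a configurable unassigned
#' remainder.
#'
#' @param map barcode map from [simulate_barcode_library()].
#' @param truth ground truth from [simulate_ground_truth()] (uses
#'   \code{truth$oligo}).
#' @param replicates replicate descriptors (see [default_replicates()]).
#' @param config list overriding the count-model defaults.
#' @param seed integer seed.
#' @return a \code{BarcodeCountTable}: list with integer matrices \code{cdna}
#'   and \code{pdna} (barcode x replicate), library sizes \code{lib_cdna} and
#'   \code{lib_pdna}, the \code{map} and the \code{replicates} table.
#' @export
simulate_counts <- function(map, truth, replicates = default_replicates(),
                            config = list(), seed = 1L) {
  cfg <- utils::modifyList(counts_defaults(), config)
  if (cfg$dispersion_pdna < 0 || cfg$dispersion_cdna < 0) {
    stop("dispersions must be nonnegative")
  }
  beta <- truth$oligo$beta[match(map$oligo_id, truth$oligo$oligo_id)]
  if (anyNA(beta)) stop("ground truth must cover every oligo in the map")
  set.seed(child_seed(seed, "counts"))

  nb <- nrow(map)
  nr <- nrow(replicates)
  a_b <- stats::rgamma(nb, shape = cfg$abundance_shape, rate = cfg$abundance_shape)
  eps <- stats::rnorm(nr, 0, cfg$replicate_sd)

  rnb <- function(mu, phi) {
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  }
  pdna <- matrix(0L, nb, nr, dimnames = list(map$barcode, replicates$replicate_id))
  cdna <- pdna
  mu_p <- cfg$mean_pdna * a_b
  for (r in seq_len(nr)) {
    pdna[, r] <- rnb(mu_p, cfg$dispersion_pdna)
    mu_c <- cfg$mean_cdna * a_b * 2^(cfg$baseline_log2 + beta + eps[r])
    cdna[, r] <- rnb(mu_c, cfg$dispersion_cdna)
  }
  lib_p <- round(colSums(pdna) * (1 + cfg$unassigned_fraction))
  lib_c <- round(colSums(cdna) * (1 + cfg$unassigned_fraction))

  structure(list(
    cdna = cdna, pdna = pdna,
    lib_cdna = lib_c, lib_pdna = lib_p,
    map = map, replicates = replicates,
    seed = seed
  ), class = "BarcodeCountTable")
}

#' @export
print.BarcodeCountTable <- function(x, ...) {
  cat("BarcodeCountTable:", nrow(x$map), "barcodes,",
      length(unique(x$map$oligo_id)), "oligos,",
      nrow(x$replicates), "replicates\n")
  invisible(x)
}

truth_defaults <- function() {
  list(
    mode = "standard",          # standard | null | motif | additive
    fraction_active = 0.10,
    beta_range = c(1.5, 2.5),
    da_fraction = 0.5,          # of active single SNPs, fraction with allelic effect
    logfc_range = c(1, 2),
    motif_effect_range = c(1, 2),
    modern_active_prob = 0.4,   # additive mode: P(an allele contributes)
    contribution_range = c(0.5, 1.5),
    interaction_fraction = 0    # additive mode: pure-interaction regions
  )
}

#' Plant per-oligo activities and per-SNP allelic effects
#'
#' Modes: \code{"null"} (all activities zero), \code{"standard"} (a fraction
#' of single SNPs and haplotype regions active at beta in \code{beta_range};
#' a subset of active single SNPs get an allelic log2 fold change of at least
#' 1), \code{"motif"} (SNPs listed in \code{motif_snps} are differentially
#' active with the motif-bound allele more active), and \code{"additive"}
#' (per-site allele contributions; haplotype activity is the exact sum of the
#' matched single-variant activities, optionally with pure-interaction regions
#' whose haplotypes are active while every constituent allele is inert).
#'
#' The log fold change sign convention is negative when the archaic allele is
#' the more active one.
#'
#' @param oligos oligo table from [design_oligos()].
#' @param config list overriding [truth_defaults()].
#' @param seed integer seed.
#' @param motif_snps optional table from \code{simulate_snp_panel} metadata
#'   (\code{snp_id}, \code{bound_allele}) used in \code{"motif"} mode.
#' @return list with \code{oligo} (oligo_id, beta), \code{snp} (snp_id,
#'   true_logfc, motif_driven), \code{region} (region_id, interaction).
#' @export
simulate_ground_truth <- function(oligos, config = list(), seed = 1L,
                                  motif_snps = NULL) {
  cfg <- utils::modifyList(truth_defaults(), config)
  set.seed(child_seed(seed, "ground_truth"))

  beta <- stats::setNames(numeric(nrow(oligos)), oligos$oligo_id)
  single <- oligos[oligos$oligo_class == "SINGLE", , drop = FALSE]
  single_cfg <- parse_allele_config(single$allele_config)
  snp_ids <- vapply(single_cfg, function(x) x$snp_id[1L], character(1L))
  snps <- unique(snp_ids)
  snp_truth <- data.frame(snp_id = snps, true_logfc = 0, motif_driven = FALSE,
                          stringsAsFactors = FALSE)
  regions <- unique(stats::na.omit(oligos$region_id))
  region_truth <- data.frame(region_id = regions,
                             interaction = logical(length(regions)),
                             stringsAsFactors = FALSE)

  single_oligo_of <- function(snp, state) {
    single$oligo_id[snp_ids == snp &
                      vapply(single_cfg, function(x) x$state[1L], character(1L)) == state]
  }
  runifr <- function(n, r) stats::runif(n, r[1L], r[2L])

  if (cfg$mode == "null") {
    # all zero
  } else if (cfg$mode %in% c("standard", "motif")) {
    planted <- character(0)
    if (cfg$mode == "motif") {
      if (is.null(motif_snps)) stop("motif mode needs the motif_snps table")
      planted <- intersect(motif_snps$snp_id, snps)
      for (s in planted) {
        b_hi <- runifr(1L, cfg$beta_range)
        eff <- runifr(1L, cfg$motif_effect_range)
        bound <- motif_snps$bound_allele[motif_snps$snp_id == s]
        b_m <- if (bound == "MODERN") b_hi else b_hi - eff
        b_a <- if (bound == "ARCHAIC") b_hi else b_hi - eff
        beta[single_oligo_of(s, "MODERN")] <- b_m
        beta[single_oligo_of(s, "ARCHAIC")] <- b_a
        i <- match(s, snp_truth$snp_id)
        snp_truth$true_logfc[i] <- -(b_a - b_m)
        snp_truth$motif_driven[i] <- TRUE
      }
    }
    other <- setdiff(snps, planted)
    active <- sample(other, round(length(other) * cfg$fraction_active))
    for (s in active) {
      b_hi <- runifr(1L, cfg$beta_range)
      if (stats::runif(1L) < cfg$da_fraction) {
        m <- runifr(1L, cfg$logfc_range)
        hi_arch <- stats::runif(1L) < 0.5
        b_a <- if (hi_arch) b_hi else b_hi - m
        b_m <- if (hi_arch) b_hi - m else b_hi
      } else {
        b_a <- b_m <- b_hi
      }
      beta[single_oligo_of(s, "MODERN")] <- b_m
      beta[single_oligo_of(s, "ARCHAIC")] <- b_a
      snp_truth$true_logfc[match(s, snp_truth$snp_id)] <- -(b_a - b_m)
    }
    active_regions <- sample(regions, round(length(regions) * cfg$fraction_active))
    for (rg in active_regions) {
      ids <- oligos$oligo_id[!is.na(oligos$region_id) & oligos$region_id == rg]
      beta[ids] <- runifr(1L, cfg$beta_range)
    }
  } else if (cfg$mode == "additive") {
    # per-site, per-allele contributions; haplotype beta = sum over sites
    clustered_snps <- unique(unlist(lapply(
      parse_allele_config(oligos$allele_config[oligos$oligo_class == "HAPLOTYPE"]),
      function(x) x$snp_id)))
    contrib <- list()
    for (s in clustered_snps) {
      u <- vapply(c("MODERN", "ARCHAIC"), function(st) {
        if (stats::runif(1L) < cfg$modern_active_prob)
          runifr(1L, cfg$contribution_range) else 0
      }, numeric(1L))
      contrib[[s]] <- u
    }
    inter_regions <- sample(regions, round(length(regions) * cfg$interaction_fraction))
    region_truth$interaction <- region_truth$region_id %in% inter_regions
    inter_rows <- !is.na(oligos$region_id) & oligos$region_id %in% inter_regions
    inter_snps <- unique(unlist(lapply(
      parse_allele_config(oligos$allele_config[inter_rows]),
      function(x) x$snp_id)))
    for (s in inter_snps) contrib[[s]] <- c(MODERN = 0, ARCHAIC = 0)
    for (s in clustered_snps) {
      u <- contrib[[s]]
      beta[single_oligo_of(s, "MODERN")] <- u[["MODERN"]]
      beta[single_oligo_of(s, "ARCHAIC")] <- u[["ARCHAIC"]]
      snp_truth$true_logfc[match(s, snp_truth$snp_id)] <-
        -(u[["ARCHAIC"]] - u[["MODERN"]])
    }
    hap <- oligos[oligos$oligo_class == "HAPLOTYPE", , drop = FALSE]
    hap_cfg <- parse_allele_config(hap$allele_config)
    for (i in seq_len(nrow(hap))) {
      cfg_i <- hap_cfg[[i]]
      b <- sum(vapply(seq_len(nrow(cfg_i)), function(j) {
        contrib[[cfg_i$snp_id[j]]][[cfg_i$state[j]]]
      }, numeric(1L)))
      if (hap$region_id[i] %in% inter_regions) b <- b + 2
      beta[hap$oligo_id[i]] <- b
    }
    # isolated SNPs: standard activity assignment without allelic effects
    iso <- setdiff(snps, clustered_snps)
    for (s in sample(iso, round(length(iso) * cfg$fraction_active))) {
      beta[c(single_oligo_of(s, "MODERN"), single_oligo_of(s, "ARCHAIC"))] <-
        runifr(1L, cfg$beta_range)
    }
  } else {
    stop("unknown ground-truth mode: ", cfg$mode)
  }

  list(
    oligo = data.frame(oligo_id = names(beta), beta = unname(beta),
                       stringsAsFactors = FALSE),
    snp = snp_truth,
    region = region_truth
  )
}

# Parse "snp1:MODERN;snp2:ARCHAIC" allele configuration strings.
parse_allele_config <- function(x) {
  lapply(x, function(s) {
    if (is.na(s)) return(data.frame(snp_id = character(0), state = character(0)))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    data.frame(
      snp_id = vapply(parts, `[`, character(1L), 1L),
      state = vapply(parts, `[`, character(1L), 2L),
      stringsAsFactors = FALSE
    )
  })
}
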