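# Oligo library construction: single-variant and haplotype-like test sequences,
# adapter attachment, restriction screening, scrambled negative controls.

#' Synthesis adapter sequences
#'
#' 15 bp adapters attached to the 5' and 3' ends of every 170 bp core
#' sequence, giving the full 200 bp synthesis oligo.
#'
#' @export
mpra_adapters <- function() {
  c(adapter_5 = "ACTGGCCGCTTGACG", adapter_3 = "CACTGCGGCTCCTGC")
}

CORE_LEN <- 170L
VARIANT_OFFSET <- 85L  # 0-based offset of the variant within the core window

#' Validate a SNP panel
#'
#' A SNP panel is a data frame with one row per candidate variant:
#' \code{snp_id}, \code{contig}, \code{position} (0-based), \code{modern_allele},
#' \code{archaic_allele}, \code{source} ("DENISOVAN" or "NEANDERTHAL"),
#' \code{iaf} (introgressed allele frequency in [0,1]).
#'
#' @param panel data frame of SNP records.
#' @param require_iaf_min minimum introgressed allele frequency admitted to the
#'   test panel (default 0.15). Set to 0 to skip the check.
#' @return the validated panel, invisibly.
#' @export
validate_snp_panel <- function(panel, require_iaf_min = 0.15) {
  needed <- c("snp_id", "contig", "position", "modern_allele",
              "archaic_allele", "source", "iaf")
  miss <- setdiff(needed, names(panel))
  if (length(miss)) stop("SNP panel missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$snp_id)) stop("duplicate snp_id in panel")
  ok_base <- panel$modern_allele %in% BASES & panel$archaic_allele %in% BASES
  if (!all(ok_base)) stop("alleles must be single bases in A/C/G/T")
  if (any(panel$modern_allele == panel$archaic_allele)) {
    stop("modern and archaic alleles must differ")
  }
  if (!all(panel$source %in% c("DENISOVAN", "NEANDERTHAL"))) {
    stop("source must be DENISOVAN or NEANDERTHAL")
  }
  if (any(panel$iaf < 0 | panel$iaf > 1)) stop("iaf must lie in [0,1]")
  if (require_iaf_min > 0 && any(panel$iaf < require_iaf_min)) {
    stop("test-panel SNPs must have iaf >= ", require_iaf_min)
  }
  invisible(panel)
}

ref_as_character <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else if (is.character(reference)) {
    reference
  } else {
    stop("reference must be a named character vector or DNAStringSet")
  }
}

#' Screen a sequence for SfiI and BsiWI restriction sites
#'
#' Oligos carrying either recognition sequence would be cut and lost during
#' cloning, so they are excluded from the library. Recognition sequences are
#' GGCCNNNNNGGCC (SfiI) and CGTACG (BsiWI); both are reverse-complement
#' palindromic, so scanning one strand suffices.
#'
#' @param sequence uppercase ACGT string.
#' @return \code{TRUE} if the sequence is free of both sites.
#' @export
screen_restriction_sites <- function(sequence) {
  stop_if_not_dna(sequence)
  !grepl("GGCC[ACGT]{5}GGCC|CGTACG", sequence)
}

# Chain SNPs into haplotype regions: consecutive sites < 170 bp apart share a
# region. Returns an integer cluster index per row of the (sorted) panel.
chain_snps <- function(positions) {
  if (length(positions) == 0L) return(integer(0))
  gaps <- diff(positions)
  cumsum(c(1L, as.integer(gaps >= CORE_LEN)))
}

substitute_base <- function(core, offset0, base) {
  substr(core, offset0 + 1L, offset0 + 1L) <- base
  core
}

#' Design the oligo library for a SNP panel
#'
#' Every SNP yields two single-variant oligos (modern and archaic allele)
#' centred on the variant, with reference (modern) sequence at all flanking
#' positions — including any neighbouring variant sites. SNPs within 170 bp
#' of one another are additionally grouped into a haplotype region and yield
#' one oligo per allelic combination (2^n oligos for n sites), all on a
#' shared 170 bp window centred on the midpoint of the outermost sites.
#' Adapters are attached to give 200 bp synthesis sequences, and any oligo
#' containing an SfiI or BsiWI restriction site is dropped.
#'
#' @param snp_panel validated SNP panel (see [validate_snp_panel()]).
#' @param reference named character vector (or \code{DNAStringSet}) of contig
#'   sequences.
#' @param adapters length-2 character vector of 5' and 3' adapter sequences.
#' @param iaf_min minimum IAF enforced on the panel.
#' @return data frame of oligo records: \code{oligo_id}, \code{oligo_class}
#'   (SINGLE or HAPLOTYPE), \code{source}, \code{region_id}, \code{contig},
#'   \code{start}, \code{end} (0-based half-open), \code{allele_config}
#'   (semicolon list of \code{snp_id:state}), \code{core_sequence},
#'   \code{sequence} (full 200-mer). Oligos dropped by restriction screening
#'   are recorded in the \code{"dropped"} attribute.
#' @export
design_oligos <- function(snp_panel, reference, adapters = mpra_adapters(),
                          iaf_min = 0.15) {
  validate_snp_panel(snp_panel, require_iaf_min = iaf_min)
  reference <- ref_as_character(reference)
  snp_panel <- snp_panel[order(snp_panel$contig, snp_panel$position), , drop = FALSE]

  out <- list()
  for (ctg in unique(snp_panel$contig)) {
    if (!ctg %in% names(reference)) stop("contig not in reference: ", ctg)
    refseq <- reference[[ctg]]
    sub <- snp_panel[snp_panel$contig == ctg, , drop = FALSE]

    ref_base <- substring(refseq, sub$position + 1L, sub$position + 1L)
    bad <- which(ref_base != sub$modern_allele & ref_base != sub$archaic_allele)
    if (length(bad)) {
      stop("reference base matches neither allele for SNP ", sub$snp_id[bad[1L]])
    }

    # every SNP is tested in single-variant oligos on a modern background;
    # clustered SNPs additionally get the 2^n haplotype combinations
    cl <- chain_snps(sub$position)
    for (k in unique(cl)) {
      grp <- sub[cl == k, , drop = FALSE]
      for (j in seq_len(nrow(grp))) {
        out[[length(out) + 1L]] <- design_single(grp[j, , drop = FALSE],
                                                 refseq, ctg)
      }
      if (nrow(grp) > 1L) {
        out[[length(out) + 1L]] <- design_haplotype(grp, refseq, ctg)
      }
    }
  }
  oligos <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(oligos) || nrow(oligos) == 0L) {
    stop("no oligos could be designed from the panel")
  }

  oligos$sequence <- paste0(adapters[[1L]], oligos$core_sequence, adapters[[2L]])
  clean <- vapply(oligos$sequence, screen_restriction_sites, logical(1L),
                  USE.NAMES = FALSE)
  dropped <- oligos[!clean, , drop = FALSE]
  if (nrow(dropped)) {
    message(nrow(dropped), " oligo(s) dropped by restriction-site screening")
  }
  oligos <- oligos[clean, , drop = FALSE]
  rownames(oligos) <- NULL
  attr(oligos, "dropped") <- dropped$oligo_id
  oligos
}

design_single <- function(snp, refseq, ctg) {
  pos <- snp$position
  start <- pos - VARIANT_OFFSET
  end <- start + CORE_LEN
  if (start < 0L || end > nchar(refseq)) {
    warning("SNP ", snp$snp_id, " is within 85 bp of a contig edge; skipped")
    return(NULL)
  }
  core_ref <- substr(refseq, start + 1L, end)
  cores <- c(
    MODERN = substitute_base(core_ref, VARIANT_OFFSET, snp$modern_allele),
    ARCHAIC = substitute_base(core_ref, VARIANT_OFFSET, snp$archaic_allele)
  )
  data.frame(
    oligo_id = paste0(snp$snp_id, "_", c("M", "A")),
    oligo_class = "SINGLE",
    source = snp$source,
    region_id = NA_character_,
    contig = ctg,
    start = start,
    end = end,
    allele_config = paste0(snp$snp_id, ":", c("MODERN", "ARCHAIC")),
    core_sequence = unname(cores),
    stringsAsFactors = FALSE
  )
}

design_haplotype <- function(grp, refseq, ctg) {
  n <- nrow(grp)
  if (n > 6L) stop("haplotype region with more than 6 SNPs: ", grp$snp_id[1L])
  span <- max(grp$position) - min(grp$position)
  if (span > CORE_LEN - 4L) {
    stop("clustered SNPs spanning ", span,
         " bp cannot share a 170 bp window (region at ", grp$snp_id[1L], ")")
  }
  mid <- (min(grp$position) + max(grp$position)) %/% 2L
  start <- mid - VARIANT_OFFSET
  # keep every site >= 2 bp inside the window, and the window on the contig
  start <- min(start, min(grp$position) - 2L)
  start <- max(start, max(grp$position) + 3L - CORE_LEN, 0L)
  end <- start + CORE_LEN
  if (start < 0L || end > nchar(refseq) || any(grp$position < start + 2L) ||
      any(grp$position > end - 3L)) {
    warning("haplotype region at ", grp$snp_id[1L],
            " cannot be placed on the contig; skipped")
    return(NULL)
  }
  core_ref <- substr(refseq, start + 1L, end)
  region_id <- paste0("region_", ctg, "_", start)
  src <- unique(grp$source)
  src <- if (length(src) == 1L) src else "MIXED"

  states <- expand.grid(rep(list(c("MODERN", "ARCHAIC")), n),
                        stringsAsFactors = FALSE)
  combos <- lapply(seq_len(nrow(states)), function(i) {
    core <- core_ref
    st <- as.character(states[i, ])
    for (j in seq_len(n)) {
      base <- if (st[j] == "MODERN") grp$modern_allele[j] else grp$archaic_allele[j]
      core <- substitute_base(core, grp$position[j] - start, base)
    }
    data.frame(
      oligo_id = paste0(region_id, "_", paste(substr(st, 1L, 1L), collapse = "")),
      oligo_class = "HAPLOTYPE",
      source = src,
      region_id = region_id,
      contig = ctg,
      start = start,
      end = end,
      allele_config = paste(paste0(grp$snp_id, ":", st), collapse = ";"),
      core_sequence = core,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, combos)
}

#' Generate scrambled negative-control sequences
#'
#' Uniform-random sequences regenerated until they (i) contain no match to any
#' motif in the supplied collection at p < \code{motif_p}, (ii) share no exact
#' 24-mer with the reference genome on either strand, and (iii) pass the
#' restriction-site screen (with adapters attached).
#'
#' @param n number of controls.
#' @param length core sequence length (default 170).
#' @param motifs motif collection from [load_motifs()]; may be empty.
#' @param reference named character vector of contig sequences, or NULL to
#'   skip the genome-match screen.
#' @param seed integer seed; output is deterministic given the seed.
#' @param motif_p motif match p-value threshold (default 1e-4).
#' @param adapters adapter pair attached before restriction screening.
#' @return data frame of SCRAMBLED oligo records (same columns as
#'   [design_oligos()], with NA coordinates).
#' @export
generate_scrambled_controls <- function(n, length = 170L, motifs = list(),
                                        reference = NULL, seed = 1L,
                                        motif_p = 1e-4,
                                        adapters = mpra_adapters()) {
  stopifnot(n >= 0L, length > 0L)
  if (n == 0L) {
    return(data.frame(oligo_id = character(0), oligo_class = character(0),
                      source = character(0), region_id = character(0),
                      contig = character(0), start = integer(0), end = integer(0),
                      allele_config = character(0), core_sequence = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  set.seed(seed)
  thresholds <- vapply(motifs, function(m) pwm_score_threshold(m, motif_p),
                       numeric(1L))
  kmer_index <- if (!is.null(reference)) build_kmer_index(reference, 24L) else NULL

  cores <- character(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(1000L)) {
      cand <- random_dna(length)
      if (!screen_restriction_sites(paste0(adapters[[1L]], cand, adapters[[2L]]))) next
      if (length(motifs) &&
          any(vapply(seq_along(motifs), function(j) {
            scan_max_score(cand, motifs[[j]]) >= thresholds[j]
          }, logical(1L)))) next
      if (!is.null(kmer_index) && shares_kmer(cand, kmer_index, 24L)) next
      cores[i] <- cand
      break
    }
    if (cores[i] == "") {
      stop("could not generate a clean scrambled control after 1000 attempts; ",
           "consider a looser motif set")
    }
  }
  data.frame(
    oligo_id = sprintf("scrambled_%04d", seq_len(n)),
    oligo_class = "SCRAMBLED",
    source = "NONE",
    region_id = NA_character_,
    contig = NA_character_,
    start = NA_integer_,
    end = NA_integer_,
    allele_config = NA_character_,
    core_sequence = cores,
    sequence = paste0(adapters[[1L]], cores, adapters[[2L]]),
    stringsAsFactors = FALSE
  )
}

build_kmer_index <- function(reference, k) {
  reference <- ref_as_character(reference)
  kmers <- unlist(lapply(unname(reference), function(s) {
    both <- c(s, revcomp(s))
    unlist(lapply(both, function(x) {
      if (nchar(x) < k) return(character(0))
      starts <- seq_len(nchar(x) - k + 1L)
      substring(x, starts, starts + k - 1L)
    }))
  }))
  sort(unique(kmers))
}

shares_kmer <- function(sequence, kmer_index, k) {
  if (nchar(sequence) < k) return(FALSE)
  starts <- seq_len(nchar(sequence) - k + 1L)
  km <- substring(sequence, starts, starts + k - 1L)
  any(km %in% kmer_index)
}
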