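# Plain-text readers and writers mirroring the real-data input schema.

write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("#", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write the oligo library as TSV (and optionally FASTA)
#'
#' @param oligos oligo table from [design_oligos()].
#' @param path output TSV path.
#' @param fasta optional path for a FASTA of the full synthesis sequences.
#' @export
write_library <- function(oligos, path, fasta = NULL) {
  write_tsv(oligos, path)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(oligos$sequence)
    names(seqs) <- oligos$oligo_id
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) read_tsv(path)

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of contig sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*", "", names(seqs)))
}

#' Write a reference genome to FASTA
#'
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(unname(reference))
  names(seqs) <- names(reference)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write and read barcode count tables
#'
#' Long TSV with columns barcode, replicate_id, fraction, count; library
#' sizes and the generator seed are carried in comment header lines. Barcodes
#' present in the map but absent from the file are zeros (sparse TSVs omit
#' zero rows).
#'
#' @param counts a \code{BarcodeCountTable}.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  reps <- colnames(counts$cdna)
  long <- rbind(
    data.frame(barcode = rep(rownames(counts$cdna), length(reps)),
               replicate_id = rep(reps, each = nrow(counts$cdna)),
               fraction = "CDNA", count = as.vector(counts$cdna)),
    data.frame(barcode = rep(rownames(counts$pdna), length(reps)),
               replicate_id = rep(reps, each = nrow(counts$pdna)),
               fraction = "PDNA", count = as.vector(counts$pdna))
  )
  long <- long[long$count > 0L, , drop = FALSE]
  hdr <- c(
    paste("seed", counts$seed),
    paste("library_size CDNA", reps, counts$lib_cdna),
    paste("library_size PDNA", reps, counts$lib_pdna)
  )
  write_tsv(long, path, header_lines = hdr)
}

#' @rdname write_counts
#' @param map barcode map (barcode, oligo_id).
#' @param replicates replicate descriptors.
#' @export
read_counts <- function(path, map, replicates) {
  hdr <- grep("^#", readLines(path, n = 50L), value = TRUE)
  libs <- hdr[grepl("^#library_size", hdr)]
  parts <- strsplit(sub("^#", "", libs), " ")
  lib <- data.frame(
    fraction = vapply(parts, `[`, character(1L), 2L),
    replicate_id = vapply(parts, `[`, character(1L), 3L),
    size = as.numeric(vapply(parts, `[`, character(1L), 4L))
  )
  long <- read_tsv(path)
  reps <- replicates$replicate_id
  empty <- matrix(0L, nrow(map), length(reps),
                  dimnames = list(map$barcode, reps))
  fill <- function(frac) {
    m <- empty
    sub <- long[long$fraction == frac, , drop = FALSE]
    sub <- sub[sub$barcode %in% map$barcode, , drop = FALSE]
    m[cbind(sub$barcode, sub$replicate_id)] <- sub$count
    m
  }
  get_lib <- function(frac) {
    stats::setNames(lib$size[lib$fraction == frac][
      match(reps, lib$replicate_id[lib$fraction == frac])], reps)
  }
  seed_line <- hdr[grepl("^#seed", hdr)]
  structure(list(
    cdna = fill("CDNA"), pdna = fill("PDNA"),
    lib_cdna = get_lib("CDNA"), lib_pdna = get_lib("PDNA"),
    map = map, replicates = replicates,
    seed = if (length(seed_line)) as.integer(sub("^#seed ", "", seed_line[1L])) else NA_integer_
  ), class = "BarcodeCountTable")
}

#' Read and write pipeline configuration
#'
#' YAML key-value files; a config round-trips unchanged.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
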