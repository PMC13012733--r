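# End-to-end orchestration over synthetic or real-schema inputs.

#' Default analysis thresholds
#'
#' All printed constants of the analysis are defaults here, never hard-coded
#' downstream: count pseudocount, aggregate pseudocount, pDNA floor, minimum
#' barcodes per oligo, FDR level, replicate-consensus requirement, minimum
#' IAF, and the motif match p thresholds.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    pseudocount = 1,
    aggregate_pseudocount = 0.5,
    pdna_floor = -5,
    min_barcodes = 10L,
    fdr = 0.05,
    min_active_replicates = 2L,
    iaf_min = 0.15,
    motif_p_stringent = 1e-4,
    motif_p_lenient = 1e-3
  )
}

scenario_settings <- function(scenario) {
  switch(scenario,
    "null" = list(panel = list(), truth = list(mode = "null")),
    "default" = list(panel = list(),
                     truth = list(mode = "standard", fraction_active = 0.10,
                                  da_fraction = 0.09)),
    "strong-effects" = list(panel = list(),
                            truth = list(mode = "standard",
                                         fraction_active = 0.2,
                                         beta_range = c(2, 3),
                                         da_fraction = 0.5,
                                         logfc_range = c(1.5, 2.5))),
    "motif" = list(panel = list(n_snps = 400L,
                                motif_plant = list(n = 60L)),
                   truth = list(mode = "motif", fraction_active = 0.10)),
    "additive" = list(panel = list(clustered_fraction = 0.6),
                      truth = list(mode = "additive")),
    "interaction" = list(panel = list(clustered_fraction = 0.6),
                         truth = list(mode = "additive",
                                      interaction_fraction = 0.1)),
    stop("unknown scenario '", scenario, "'; options: null, default, ",
         "strong-effects, motif, additive, interaction")
  )
}

#' Generate a complete synthetic input bundle
#'
#' Scenarios: \code{"null"} (no activity anywhere), \code{"default"}
#' (~10% of SNPs and regions active at beta in [1.5, 2.5]; ~9% of active
#' single SNPs carry an allelic effect of at least 1 log2 unit, echoing the
#' differential-activity rate the assay reports), \code{"strong-effects"},
#' \code{"motif"} (differential activity planted through motif
#' creation/destruction), \code{"additive"} (haplotype activity is exactly the
#' sum of the constituent allele contributions), \code{"interaction"}
#' (additive plus regions whose haplotypes are active while every constituent
#' allele is inert).
#'
#' @param scenario scenario name.
#' @param seed integer seed; the bundle is byte-identical given the seed.
#' @param dir optional directory: when given, the full input bundle (library
#'   TSV + FASTA, barcode map, counts, TSS, ground truth, config YAML) is
#'   written there.
#' @param panel_config,barcode_config,counts_config,truth_config overrides
#'   merged on top of the scenario settings.
#' @param motifs motif collection used by the \code{"motif"} scenario
#'   (default: the bundled synthetic collection).
#' @return list with \code{panel}, \code{tss}, \code{reference},
#'   \code{oligos}, \code{map}, \code{counts}, \code{truth},
#'   \code{replicates}, \code{scenario}, \code{seed}.
#' @export
make_fixtures <- function(scenario = "default", seed = 1L, dir = NULL,
                          panel_config = list(), barcode_config = list(),
                          counts_config = list(), truth_config = list(),
                          motifs = NULL) {
  st <- scenario_settings(scenario)
  pcfg <- utils::modifyList(st$panel, panel_config)
  tcfg <- utils::modifyList(st$truth, truth_config)
  if (!is.null(pcfg$motif_plant)) {
    if (is.null(motifs)) {
      motifs <- load_motifs(system.file("extdata", "synthetic_motifs.meme",
                                        package = "archmpra"))
    }
    pcfg$motif_plant$motifs <- motifs
  }

  sim <- simulate_snp_panel(pcfg, seed = seed)
  oligos <- design_oligos(sim$panel, sim$reference)
  replicates <- default_replicates()
  truth <- simulate_ground_truth(oligos, tcfg, seed = seed,
                                 motif_snps = sim$meta$motif_snps)
  map <- simulate_barcode_library(oligos, barcode_config, seed = seed)
  counts <- simulate_counts(map, truth, replicates, counts_config, seed = seed)

  bundle <- list(
    scenario = scenario, seed = seed,
    panel = sim$panel, tss = sim$tss, reference = sim$reference,
    meta = sim$meta,
    oligos = oligos, map = map, counts = counts, truth = truth,
    replicates = replicates
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  hdr <- paste("seed", bundle$seed)
  write_tsv(bundle$panel, p("snp_panel.tsv"), hdr)
  write_tsv(bundle$tss, p("tss.tsv"), hdr)
  write_reference_fasta(bundle$reference, p("reference.fa"))
  write_library(bundle$oligos, p("library.tsv"), fasta = p("library.fa"))
  write_tsv(bundle$map, p("barcode_map.tsv"), hdr)
  write_counts(bundle$counts, p("counts.tsv"))
  write_tsv(bundle$truth$oligo, p("truth_oligo.tsv"), hdr)
  write_tsv(bundle$truth$snp, p("truth_snp.tsv"), hdr)
  write_tsv(bundle$replicates, p("replicates.tsv"), hdr)
  write_config(list(scenario = bundle$scenario, seed = bundle$seed),
               p("config.yaml"))
  invisible(dir)
}

#' Differential motif binding for a set of SNPs
#'
#' Scores the modern and archaic single-variant core sequences of each SNP
#' against the motif collection and reports the qualifying motif with the
#' largest absolute differential binding score.
#'
#' @param oligos oligo table.
#' @param snps SNP ids to score.
#' @param motifs motif collection.
#' @param thresholds stringent/lenient p thresholds.
#' @return data frame with one row per SNP that has a qualifying motif.
#' @export
motif_differential_analysis <- function(oligos, snps, motifs,
                                        thresholds = c(1e-4, 1e-3)) {
  single <- oligos[oligos$oligo_class == "SINGLE", , drop = FALSE]
  cfgs <- parse_allele_config(single$allele_config)
  snp_of <- vapply(cfgs, function(x) x$snp_id[1L], character(1L))
  state_of <- vapply(cfgs, function(x) x$state[1L], character(1L))
  rows <- lapply(snps, function(s) {
    m_id <- single$core_sequence[snp_of == s & state_of == "MODERN"]
    a_id <- single$core_sequence[snp_of == s & state_of == "ARCHAIC"]
    if (length(m_id) != 1L || length(a_id) != 1L) return(NULL)
    hits <- score_alleles(m_id, a_id, motifs)
    rec <- differential_binding(hits, thresholds)
    if (is.null(rec)) return(NULL)
    cbind(data.frame(snp_id = s, stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Stages: normalise, filter, barcode activity, activity calls, allelic
#' differential activity (single SNPs with at least one active allele),
#' haplotype ANOVA, motif differential binding (when motifs are supplied),
#' annotation statistics, and (when ground truth is present) a recovery
#' report. Every stage writes a TSV under \code{outdir} and logs counts
#' in/out. Deterministic given the bundle.
#'
#' @param bundle input bundle from [make_fixtures()] (or an equivalently
#'   shaped list loaded from real-schema files).
#' @param outdir output directory.
#' @param config analysis thresholds (see [default_config()]).
#' @param motifs optional motif collection for the motif stage.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(bundle, outdir, config = default_config(),
                         motifs = NULL) {
  config <- utils::modifyList(default_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  log_line("pipeline start: scenario=", bundle$scenario %||% "external",
           " seed=", bundle$seed %||% NA)

  norm <- normalize_counts(bundle$counts, pseudocount = config$pseudocount)
  retained <- filter_library(norm, pdna_floor = config$pdna_floor,
                             min_barcodes = config$min_barcodes)
  log_line("filter: ", retained$n_barcodes_removed, " barcodes and ",
           retained$n_oligos_removed, " oligos removed; ",
           nrow(retained$map), " barcode rows retained")

  act <- compute_activity(norm, retained)
  activity <- call_activity(act, alpha = config$fdr,
                            min_replicates = config$min_active_replicates)
  write_tsv(cbind(activity$calls,
                  q = round(activity$q[activity$calls$oligo_id, , drop = FALSE], 6)),
            file.path(outdir, "activity_calls.tsv"))
  log_line("activity: ", sum(activity$calls$is_active), " of ",
           nrow(activity$calls), " oligos called active")

  aggr <- compute_aggregate_log_ratios(bundle$counts, retained,
                                       pseudocount = config$aggregate_pseudocount)
  active_snps <- snps_with_active_allele(bundle$oligos, activity$calls)
  diff <- NULL
  if (length(active_snps) >= 10L) {
    diff <- mpra_diff_test(aggr, bundle$oligos, bundle$replicates,
                           snps = active_snps, fdr = config$fdr)
    write_tsv(diff$table, file.path(outdir, "differential_activity.tsv"))
    log_line("differential: ", sum(diff$table$is_differentially_active),
             " of ", nrow(diff$table), " SNPs differentially active")
  } else {
    log_line("differential: skipped (fewer than 10 SNPs with an active allele)")
  }

  hap <- NULL
  if (any(bundle$oligos$oligo_class == "HAPLOTYPE")) {
    hap <- test_haplotype_anova(act, bundle$oligos, alpha = config$fdr,
                                min_replicates = config$min_active_replicates)
    write_tsv(hap$table, file.path(outdir, "haplotype_anova.tsv"))
    log_line("haplotype: ", sum(hap$table$differentially_active), " of ",
             nrow(hap$table), " regions differentially active")
  }

  motif_res <- NULL
  if (!is.null(motifs) && !is.null(diff)) {
    motif_res <- motif_differential_analysis(
      bundle$oligos, diff$table$snp_id, motifs,
      thresholds = c(config$motif_p_stringent, config$motif_p_lenient))
    if (!is.null(motif_res)) {
      write_tsv(motif_res, file.path(outdir, "differential_binding.tsv"))
      log_line("motif: ", nrow(motif_res), " SNPs with a qualifying motif")
    }
  }

  stats_res <- annotation_stage(bundle, act, activity, diff, outdir, log_line)

  report <- NULL
  if (!is.null(bundle$truth)) {
    report <- recovery_report(bundle, activity, diff)
    write_tsv(report, file.path(outdir, "recovery_report.tsv"))
    log_line("recovery: ", paste(sprintf("%s=%.3f", report$metric, report$value),
                                 collapse = " "))
  }
  log_line("pipeline done")
  invisible(list(norm = norm, retained = retained, act = act,
                 activity = activity, aggregates = aggr, diff = diff,
                 hap = hap, motif = motif_res, stats = stats_res,
                 report = report))
}

# Single-variant SNPs with at least one active allele.
snps_with_active_allele <- function(oligos, calls) {
  single <- oligos[oligos$oligo_class == "SINGLE", , drop = FALSE]
  cfgs <- parse_allele_config(single$allele_config)
  snp_of <- vapply(cfgs, function(x) x$snp_id[1L], character(1L))
  active <- calls$oligo_id[calls$is_active]
  sort(unique(snp_of[single$oligo_id %in% active]))
}

annotation_stage <- function(bundle, act, activity, diff, outdir, log_line) {
  calls <- activity$calls
  single <- bundle$oligos[bundle$oligos$oligo_class == "SINGLE", , drop = FALSE]
  cfgs <- parse_allele_config(single$allele_config)
  snp_of <- vapply(cfgs, function(x) x$snp_id[1L], character(1L))
  state_of <- vapply(cfgs, function(x) x$state[1L], character(1L))
  measured <- single$oligo_id %in% calls$oligo_id
  rec <- data.frame(
    oligo_id = single$oligo_id[measured],
    snp_id = snp_of[measured],
    allelic_state = state_of[measured],
    source = single$source[measured],
    core_sequence = single$core_sequence[measured],
    stringsAsFactors = FALSE
  )
  rec$frequency <- bundle$panel$iaf[match(rec$snp_id, bundle$panel$snp_id)]
  rec$position <- bundle$panel$position[match(rec$snp_id, bundle$panel$snp_id)]
  rec$contig <- bundle$panel$contig[match(rec$snp_id, bundle$panel$snp_id)]
  rec$flag <- calls$is_active[match(rec$oligo_id, calls$oligo_id)]

  deciles <- decile_activity_profile(rec, stratify_by = c("source", "allelic_state"))
  write_tsv(deciles$profile, file.path(outdir, "iaf_decile_activity.tsv"))

  tssp <- tss_distance_profile(rec, bundle$tss)
  write_tsv(tssp$bin_profile, file.path(outdir, "tss_distance_profile.tsv"))

  gc <- sequence_feature_tests(rec)
  write_tsv(gc$tests, file.path(outdir, "gc_association.tsv"))

  depletion <- NULL
  if (!is.null(diff)) {
    da <- data.frame(
      snp_id = diff$table$snp_id,
      flag = diff$table$is_differentially_active,
      iaf = bundle$panel$iaf[match(diff$table$snp_id, bundle$panel$snp_id)]
    )
    depletion <- threshold_depletion_test(da, thresholds = c(0.3, 0.4, 0.5))
    write_tsv(depletion, file.path(outdir, "iaf_depletion.tsv"))
  }

  concordance <- NULL
  additivity <- NULL
  if (any(bundle$oligos$oligo_class == "HAPLOTYPE")) {
    concordance <- haplotype_concordance(calls, bundle$oligos)
    if (!is.null(concordance$class_table)) {
      write_tsv(concordance$class_table, file.path(outdir, "concordance.tsv"))
    }
    additivity <- additivity_correlation(act, bundle$oligos, calls)
    if (!is.null(additivity$table)) {
      write_tsv(additivity$table, file.path(outdir, "additivity.tsv"))
    }
  }
  log_line("annotation stats written")
  list(deciles = deciles, tss = tssp, gc = gc, depletion = depletion,
       concordance = concordance, additivity = additivity)
}

recovery_report <- function(bundle, activity, diff) {
  act_eval <- evaluate_activity_calls(activity$calls, bundle$truth)
  rows <- data.frame(metric = c("activity_sensitivity", "activity_fdp"),
                     value = c(act_eval$sensitivity, act_eval$fdp))
  if (!is.null(diff)) {
    de <- evaluate_differential(diff$table, bundle$truth)
    rows <- rbind(rows, data.frame(
      metric = c("differential_power", "differential_fdp",
                 "logfc_slope", "logfc_r"),
      value = c(de$power, de$fdp, de$slope, de$r)
    ))
  }
  rows
}
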