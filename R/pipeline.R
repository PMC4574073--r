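# Pipeline stage runners: each stage reads its inputs from the output
# directory (or produces them in order under run_all), writes TSV outputs
# with provenance headers, and fails with a distinct message when an
# upstream file is missing.

stage_path <- function(config, name) {
  outdir <- config$paths$outdir %||% "repeatcohort_out"
  file.path(outdir, name)
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  inform(sprintf(...))
}

#' Run the simulation stage
#'
#' Generates the synthetic cohort, writes per-genome FASTA files, the sample
#' sheet, the truth table and the expression/methylation tables.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @return Invisibly, the `tr_study` object.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- stage_path(config, "")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config$simulation, sequences = TRUE,
                          params = config$detection)
  write_genome_fasta(cohort_sequences(study$cohort),
                     stage_path(config, "genomes"))
  write_tsv_commented(study$cohort$samples,
                      stage_path(config, "sample_sheet.tsv"), config)
  write_tsv_commented(study$cohort$truth,
                      stage_path(config, "truth.tsv"), config)
  write_tsv_commented(study$expression,
                      stage_path(config, "expression.tsv"), config)
  write_tsv_commented(study$methylation,
                      stage_path(config, "methylation.tsv"), config)
  pw <- synthetic_pathways(unique(study$cohort$truth$gene_id),
                           seed = config$seed)
  write_tsv_commented(
    tibble(pathway = rep(names(pw), lengths(pw)), gene = unlist(pw)),
    stage_path(config, "pathways.tsv"), config)
  log_msg(config, "simulated %d genes x %d patients into %s",
          config$simulation$n_genes, config$simulation$n_patients, outdir)
  invisible(study)
}

#' Run repeat detection over all genomes
#'
#' Reads the per-genome FASTA files, applies the genome QC filter, and
#' writes one repeat-call table covering all passing genomes.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the repeat-call tibble.
#' @export
run_find_repeats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gdir <- stage_path(config, "genomes")
  if (!dir.exists(gdir)) {
    abort(sprintf("missing genomes directory: %s (run the simulate stage or point `paths$genomes` at FASTA input)", gdir))
  }
  paths <- list.files(gdir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (length(paths) == 0L) abort(sprintf("no FASTA files found in %s", gdir))
  seqs <- read_genome_fasta(paths)
  qc <- qc_genomes(seqs, config$qc$max_unaligned)
  failed <- setdiff(unique(seqs$genome_id), qc$passing)
  if (length(failed)) {
    log_msg(config, "QC removed %d genome(s): %s", length(failed),
            paste(failed, collapse = ", "))
  }
  write_tsv_commented(qc$qc, stage_path(config, "genome_qc.tsv"), config)
  seqs <- seqs[seqs$genome_id %in% qc$passing, ]
  calls <- detect_repeats(seqs, config$detection)
  write_tsv_commented(calls, stage_path(config, "repeat_calls.tsv"), config)
  log_msg(config, "detected %d repeats across %d genomes", nrow(calls),
          length(qc$passing))
  invisible(calls)
}

#' Run tumor-vs-matched-normal instability calling
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the pair-call table and the promoter and
#'   exon instability matrices.
#' @export
run_call_instability <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  calls <- read_tsv_commented(stage_path(config, "repeat_calls.tsv"))
  samples <- read_tsv_commented(stage_path(config, "sample_sheet.tsv"))
  qc <- read_tsv_commented(stage_path(config, "genome_qc.tsv"))
  samples <- samples[samples$genome_id %in% qc$genome_id[qc$pass], ]
  # keep only patients with both genomes passing QC
  complete <- samples |>
    count(.data$patient_id) |>
    filter(.data$n == 2L)
  samples <- samples[samples$patient_id %in% complete$patient_id, ]
  if (nrow(samples) == 0L) abort("no patient has both genomes passing QC.")
  pair_calls <- call_instability(
    calls, samples,
    max_shift = config$matching$max_shift,
    unstable_min_delta = config$matching$unstable_min_delta,
    match_revcomp = config$matching$match_revcomp)
  out <- pair_calls[, c("patient_id", "gene_id", "region", "status", "call",
                        "canonical", "period", "copies_a", "copies_b",
                        "start_a", "start_b", "score_a", "score_b")]
  write_tsv_commented(out, stage_path(config, "pair_calls.tsv"), config)
  mats <- list()
  for (rk in unique(pair_calls$region)) {
    m <- build_instability_matrix(pair_calls, region = rk,
                                  patients = unique(samples$patient_id))
    write_tsv_commented(m, stage_path(config, paste0("instability_matrix_",
                                                     rk, ".tsv")), config)
    mats[[rk]] <- m
  }
  log_msg(config, "called instability for %d patients", nrow(complete))
  invisible(list(pair_calls = pair_calls, matrices = mats))
}

#' Run the cohort statistics stage
#'
#' Builds tumor-normal and all-pairs normal-normal profiles, the
#' tumor-vs-normal and MSI-vs-MSS comparisons and the pathway enrichment
#' tests.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with profiles and test tables.
#' @export
run_cohort_stats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  calls_path <- stage_path(config, "repeat_calls.tsv")
  if (!file.exists(calls_path)) {
    abort(sprintf("missing repeat calls: %s (run the find-repeats stage first)",
                  calls_path))
  }
  calls <- read_tsv_commented(calls_path)
  samples <- read_tsv_commented(stage_path(config, "sample_sheet.tsv"))
  qc <- read_tsv_commented(stage_path(config, "genome_qc.tsv"))
  samples <- samples[samples$genome_id %in% qc$genome_id[qc$pass], ]
  pairs <- cohort_pairs(samples)
  profiles <- pair_profiles(calls, pairs,
                            max_shift = config$matching$max_shift,
                            unstable_min_delta = config$matching$unstable_min_delta)
  write_tsv_commented(profiles, stage_path(config, "pair_profiles.tsv"), config)
  tests <- list()
  for (rk in unique(profiles$region)) {
    for (metric in c("orphan", "unstable", "instability")) {
      t <- compare_cohorts(profiles, region = rk, metric = metric)
      tests[[length(tests) + 1]] <- tidy(t)
    }
  }
  tests <- bind_rows(tests)
  msi <- compare_msi(profiles)
  pw_path <- stage_path(config, "pathways.tsv")
  enr <- NULL
  if (file.exists(pw_path)) {
    pathways <- read_pathways(pw_path)
    universe <- unique(calls$gene_id)
    pwp <- pathway_profiles(calls, pairs, pathways, universe,
                            max_shift = config$matching$max_shift,
                            unstable_min_delta = config$matching$unstable_min_delta)
    enr <- pathway_enrichment(pwp)
    write_tsv_commented(enr, stage_path(config, "pathway_enrichment.tsv"), config)
  }
  write_tsv_commented(tests, stage_path(config, "cohort_tests.tsv"), config)
  write_tsv_commented(msi, stage_path(config, "msi_tests.tsv"), config)
  log_msg(config, "cohort statistics over %d pairs", nrow(pairs))
  invisible(list(profiles = profiles, tests = tests, msi = msi,
                 enrichment = enr))
}

#' Run the omics association stage
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a tibble of association results.
#' @export
run_assoc <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pc_path <- stage_path(config, "pair_calls.tsv")
  if (!file.exists(pc_path)) {
    abort(sprintf("missing pair calls: %s (run the call-instability stage first)",
                  pc_path))
  }
  pair_calls <- read_tsv_commented(pc_path)
  samples <- read_tsv_commented(stage_path(config, "sample_sheet.tsv"))
  expr <- read_tsv_commented(stage_path(config, "expression.tsv"))
  meth_path <- stage_path(config, "methylation.tsv")
  meth <- if (file.exists(meth_path)) read_tsv_commented(meth_path) else NULL
  results <- list()
  tumors <- samples$genome_id[samples$tissue == "tumor"]
  for (rk in unique(pair_calls$region)) {
    m <- build_instability_matrix(pair_calls, region = rk)
    # matrix columns are patient ids; expression columns are tumor genome ids
    pt <- samples$patient_id[match(tumors, samples$genome_id)]
    names(m) <- c("gene_id", tumors[match(names(m)[-1], pt)])
    res <- expression_association(m, expr)
    results[[length(results) + 1]] <- mutate(tidy(res), region = rk)
    if (!is.null(meth) && rk == "promoter") {
      res <- methylation_association(m, meth)
      results[[length(results) + 1]] <- mutate(tidy(res), region = rk)
    }
  }
  out <- bind_rows(results)
  write_tsv_commented(out, stage_path(config, "associations.tsv"), config)
  log_msg(config, "association tests written")
  invisible(out)
}

#' Run the full pipeline
#'
#' Simulation, repeat detection, instability calling, cohort statistics and
#' omics association in order, plus a one-file summary report.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list of stage outputs.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- run_simulate(config)
  calls <- run_find_repeats(config)
  inst <- run_call_instability(config)
  stats <- run_cohort_stats(config)
  assoc <- run_assoc(config)
  summary <- bind_rows(
    stats$tests,
    mutate(stats$msi, comparison = "msi_vs_mss")[, c("comparison", "test",
                                                     "statistic", "p_raw",
                                                     "p_adjusted")],
    assoc[, c("test", "statistic", "p_raw", "p_adjusted")]
  )
  write_tsv_commented(summary, stage_path(config, "summary.tsv"), config)
  log_msg(config, "pipeline complete: %s", stage_path(config, ""))
  invisible(list(study = study, calls = calls, instability = inst,
                 stats = stats, associations = assoc))
}
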