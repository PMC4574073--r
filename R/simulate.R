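# Synthetic paired tumor/normal cohorts with planted tandem repeats.
#
# The generator plants perfect repeat arrays into repeat-free random
# background, then derives per-patient germline alleles (private slippage,
# gain and loss at half rate, so two unrelated normals differ at roughly the
# configured rates) and a tumor genome per patient (somatic slippage at the
# tumor rate -- scaled up for MSI patients -- plus de-novo gains and losses).
# Every sequence difference is recorded in a truth table, one row per
# (gene, patient, region).

seed_stage <- function(config, stage) {
  (config$seed %% 599999L) * 3001L + stage
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_unit_weights <- function() {
  # heavily skewed to short units, as in genomic microsatellite surveys
  w <- numeric(100)
  w[1:6] <- c(0.45, 0.25, 0.10, 0.08, 0.05, 0.03)
  w[7:20] <- 0.04 / 14
  w
}

#' Simulation configuration for a paired tumor/normal cohort
#'
#' The defaults describe the study conditions the package is exercised under:
#' 35 patients of which 4 are MSI (microsatellite instable, i.e. mismatch
#' repair deficient), 200 genes with a 5,000 bp promoter and one exon
#' super-transcript each, tumor slippage at five times the normal-normal
#' rate, a tenfold slippage multiplier for MSI tumors, expression
#' downregulation (-1 on log2 rpkm) and a +0.1 methylation beta shift for
#' genes with promoter repeat instability.
#'
#' @param n_genes,n_patients,n_msi_patients Cohort dimensions.
#' @param promoter_length Promoter region length in bp.
#' @param exon_length_range Range the exon super-transcript length is drawn
#'   from (uniform), bp.
#' @param frac_genes_with_promoter_repeat,frac_genes_with_exon_repeat
#'   Fraction of genes with a planted repeat in the respective region.
#' @param unit_length_distribution Weights over unit lengths 1..100 bp.
#' @param copy_number_range Target range of planted repeat-unit counts; the
#'   lower end is raised per unit length so every planted array stays above
#'   the detectability minimum.
#' @param p_slippage_normal Per-locus probability that two independently
#'   drawn normal genomes differ in copy number (implemented as patient-
#'   private germline slippage at half this rate).
#' @param p_slippage_tumor Per-locus probability of a tumor-vs-matched-normal
#'   copy-number change.
#' @param msi_rate_multiplier Factor (>= 1) applied to `p_slippage_tumor`
#'   for MSI patients (capped at probability 1).
#' @param p_gain,p_loss Per-region probabilities of a tumor-specific de-novo
#'   repeat gain / repeat loss.
#' @param p_gain_normal,p_loss_normal Per-region germline gain / loss rates
#'   (halved per patient, like slippage), giving normal-normal pairs a
#'   non-degenerate orphan-repeat null.
#' @param expr_base_log2_mean,expr_base_log2_sd Baseline log2 rpkm
#'   distribution.
#' @param expr_effect_log2 Additive log2 shift for (gene, patient) cells with
#'   promoter repeat instability (negative = downregulation).
#' @param meth_base_beta,meth_base_sd,meth_effect_delta Methylation baseline
#'   beta value, its noise sd, and the shift for instability-bearing cells.
#' @param seed Integer seed; together with the config it fully determines
#'   all generator output.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 200L, n_patients = 35L, n_msi_patients = 4L,
                       promoter_length = 5000L,
                       exon_length_range = c(500L, 1500L),
                       frac_genes_with_promoter_repeat = 0.6,
                       frac_genes_with_exon_repeat = 0.4,
                       unit_length_distribution = default_unit_weights(),
                       copy_number_range = c(3L, 20L),
                       p_slippage_normal = 0.016,
                       p_slippage_tumor = 0.08,
                       msi_rate_multiplier = 10,
                       p_gain = 0.05, p_loss = 0.03,
                       p_gain_normal = 0.01, p_loss_normal = 0.006,
                       expr_base_log2_mean = 5, expr_base_log2_sd = 0.7,
                       expr_effect_log2 = -1,
                       meth_base_beta = 0.3, meth_base_sd = 0.05,
                       meth_effect_delta = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
    n_msi_patients = as.integer(n_msi_patients),
    promoter_length = as.integer(promoter_length),
    exon_length_range = as.integer(exon_length_range),
    frac_genes_with_promoter_repeat = frac_genes_with_promoter_repeat,
    frac_genes_with_exon_repeat = frac_genes_with_exon_repeat,
    unit_length_distribution = as.numeric(unit_length_distribution),
    copy_number_range = as.integer(copy_number_range),
    p_slippage_normal = p_slippage_normal,
    p_slippage_tumor = p_slippage_tumor,
    msi_rate_multiplier = msi_rate_multiplier,
    p_gain = p_gain, p_loss = p_loss,
    p_gain_normal = p_gain_normal, p_loss_normal = p_loss_normal,
    expr_base_log2_mean = expr_base_log2_mean,
    expr_base_log2_sd = expr_base_log2_sd,
    expr_effect_log2 = expr_effect_log2,
    meth_base_beta = meth_base_beta, meth_base_sd = meth_base_sd,
    meth_effect_delta = meth_effect_delta,
    seed = as.integer(seed)
  )
  probs <- c("frac_genes_with_promoter_repeat", "frac_genes_with_exon_repeat",
             "p_slippage_normal", "p_slippage_tumor", "p_gain", "p_loss",
             "p_gain_normal", "p_loss_normal")
  for (f in probs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", f))
    }
  }
  if (cfg$msi_rate_multiplier < 1) abort("`msi_rate_multiplier` must be >= 1.")
  if (cfg$promoter_length <= 0) abort("`promoter_length` must be positive.")
  if (cfg$n_msi_patients > cfg$n_patients) {
    abort("`n_msi_patients` cannot exceed `n_patients`.")
  }
  if (length(cfg$unit_length_distribution) != 100L ||
      any(cfg$unit_length_distribution < 0) ||
      sum(cfg$unit_length_distribution) <= 0) {
    abort("`unit_length_distribution` must be 100 non-negative weights summing > 0.")
  }
  if (length(cfg$exon_length_range) != 2L ||
      cfg$exon_length_range[1] > cfg$exon_length_range[2] ||
      cfg$exon_length_range[1] <= 0) {
    abort("`exon_length_range` must be a positive, ordered length-2 interval.")
  }
  if (length(cfg$copy_number_range) != 2L ||
      cfg$copy_number_range[1] > cfg$copy_number_range[2]) {
    abort("`copy_number_range` must be an ordered length-2 interval.")
  }
  if (cfg$meth_base_beta < 0 || cfg$meth_base_beta > 1) {
    abort("`meth_base_beta` must be in [0, 1].")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Cohort simulation config: %d genes x %d patients (%d MSI), seed %d\n",
              x$n_genes, x$n_patients, x$n_msi_patients, x$seed))
  cat(sprintf("  slippage normal %.3f / tumor %.3f (MSI x%.0f); gain %.3f / loss %.3f\n",
              x$p_slippage_normal, x$p_slippage_tumor, x$msi_rate_multiplier,
              x$p_gain, x$p_loss))
  cat(sprintf("  expression effect %+.2f log2, methylation effect %+.2f beta\n",
              x$expr_effect_log2, x$meth_effect_delta))
  invisible(x)
}

random_nt <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# a unit that is not itself a repetition of a shorter unit
random_primitive_unit <- function(p) {
  repeat {
    u <- random_nt(p)
    if (p == 1L) return(u)
    primitive <- TRUE
    for (d in seq_len(p - 1)) {
      if (p %% d != 0) next
      if (identical(strsplit(u, "")[[1]],
                    rep(strsplit(substr(u, 1, d), "")[[1]], p / d))) {
        primitive <- FALSE
        break
      }
    }
    if (primitive) return(u)
  }
}

# repeat-free random background (rejection sampled against the detector)
random_background <- function(n, params, max_tries = 25L) {
  for (i in seq_len(max_tries)) {
    bg <- random_nt(n)
    if (n < 2L) return(bg)
    if (nrow(find_tandem_repeats(bg, params, method = "seeded")) == 0L) return(bg)
  }
  abort("could not draw a repeat-free background window.")
}

min_detect_copies <- function(period, params) {
  min_len <- ceiling(params$min_score / params$match_weight)
  pmax(2L, as.integer(ceiling(min_len / period)))
}

# insert `copies` repetitions of `unit` into `background` after position
# `at` (0-based number of background characters preceding the array)
compose_region <- function(background, unit, copies, at) {
  ifelse(is.na(unit), background,
         paste0(substr(background, 1L, at),
                strrep(unit, ifelse(is.na(copies), 0L, copies)),
                substr(background, at + 1L, nchar(background))))
}

draw_planted_repeat <- function(region_length, config, params, max_tries = 50L) {
  wts <- config$unit_length_distribution
  for (i in seq_len(max_tries)) {
    p <- sample.int(100L, 1L, prob = wts)
    lo <- max(config$copy_number_range[1], min_detect_copies(p, params) + 1L)
    hi <- min(config$copy_number_range[2], floor(0.4 * region_length / p))
    if (lo > hi) next
    copies <- if (lo == hi) lo else sample(lo:hi, 1L)
    unit <- random_primitive_unit(p)
    return(list(unit = unit, period = p, copies = copies))
  }
  abort("planted repeats cannot fit in the configured region lengths.")
}

#' Generate reference regions with planted tandem repeats
#'
#' Builds one promoter and one exon super-transcript region per gene. For the
#' configured fraction of genes a perfect tandem repeat (random primitive
#' unit, unit length from the configured distribution, copy number above the
#' detectability minimum) is inserted at a random offset into repeat-free
#' random background. Composed regions are rejection-checked so that the
#' detector recovers exactly the planted repeat.
#'
#' @param config A [sim_config()].
#' @param params [detection_params()] used for the repeat-free background
#'   check.
#' @param backgrounds If `FALSE`, only the planted-repeat layout is drawn
#'   (no background sequences); enough for event-level studies, but such a
#'   reference cannot emit genome sequences.
#' @return A `tr_reference` object: a list with `regions` (tibble of per-
#'   region background, planted repeat description and region metadata) and
#'   the `config`.
#' @export
generate_reference <- function(config, params = detection_params(),
                               backgrounds = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(seed_stage(config, 1L), {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    grid <- tidyr::expand_grid(gene_id = genes,
                               region = c("promoter", "exon"))
    n <- nrow(grid)
    grid$region_length <- ifelse(
      grid$region == "promoter", config$promoter_length,
      sample(config$exon_length_range[1]:config$exon_length_range[2],
             n, replace = TRUE))
    frac <- ifelse(grid$region == "promoter",
                   config$frac_genes_with_promoter_repeat,
                   config$frac_genes_with_exon_repeat)
    grid$has_repeat <- runif(n) < frac
    grid$unit <- NA_character_
    grid$period <- NA_integer_
    grid$copies <- NA_integer_
    grid$start <- NA_integer_
    grid$background <- NA_character_
    for (i in seq_len(n)) {
      if (!grid$has_repeat[i]) {
        if (backgrounds) {
          grid$background[i] <- random_background(grid$region_length[i], params)
        }
        next
      }
      rp <- draw_planted_repeat(grid$region_length[i], config, params)
      arr_len <- rp$period * rp$copies
      bg_len <- grid$region_length[i] - arr_len
      at <- sample(0:bg_len, 1L)
      if (backgrounds) {
        ok <- FALSE
        for (try in 1:25) {
          bg <- random_background(bg_len, params)
          hits <- find_tandem_repeats(compose_region(bg, rp$unit, rp$copies, at),
                                      params, method = "seeded")
          if (nrow(hits) == 1L &&
              hits$canonical[1] == canonical_unit(rp$unit)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("could not embed a planted repeat cleanly.")
        grid$background[i] <- bg
      }
      grid$unit[i] <- rp$unit
      grid$period[i] <- rp$period
      grid$copies[i] <- rp$copies
      grid$start[i] <- at
    }
    grid$canonical <- ifelse(grid$has_repeat, canonical_unit(
      ifelse(is.na(grid$unit), "A", grid$unit)), NA_character_)
    structure(list(regions = as_tibble(grid), config = config,
                   params = params),
              class = "tr_reference")
  })
}

#' Reference region sequences
#'
#' Composes the reference sequence (background plus planted repeat) for every
#' region of a [generate_reference()] object.
#'
#' @param reference A `tr_reference`.
#' @return Tibble with `gene_id`, `region`, `sequence`.
#' @export
reference_sequences <- function(reference) {
  stopifnot(inherits(reference, "tr_reference"))
  r <- reference$regions
  tibble(gene_id = r$gene_id, region = r$region,
         sequence = compose_region(r$background, r$unit, r$copies, r$start))
}

# geometric number of repeat units gained/lost in one slippage event,
# mostly 1 (p = 0.5); direction symmetric, flipped upward when a loss of
# copies would push the array under the detectability minimum
slip_copies <- function(copies, period, params) {
  n <- length(copies)
  k <- rgeom(n, 0.5) + 1L
  up <- runif(n) < 0.5
  new <- ifelse(up, copies + k, copies - k)
  floor_c <- min_detect_copies(period, params)
  ifelse(new < floor_c, copies + k, new)
}

draw_gain <- function(region_length, config, params) {
  rp <- draw_planted_repeat(region_length, config, params)
  rp$at <- sample(0:region_length, 1L)
  rp
}

#' Generate a paired tumor/normal cohort from a reference
#'
#' Derives for each patient a normal genome (patient-private germline
#' slippage, gain and loss at half the configured normal-normal rates) and a
#' tumor genome (somatic slippage at `p_slippage_tumor`, multiplied by
#' `msi_rate_multiplier` for MSI patients and capped at 1; de-novo gains at
#' `p_gain` in regions with no repeat in the patient's normal; losses at
#' `p_loss` for repeats present in the normal). Copy-number changes add or
#' remove at least one full unit and never push an array under the
#' detectability minimum.
#'
#' @param reference A `tr_reference` from [generate_reference()].
#' @param config The [sim_config()] (defaults to the reference's config).
#' @param sequences If `TRUE`, per-genome region sequences are composed;
#'   event-level studies can skip this.
#' @return A `tr_cohort` object: list with `samples` (genome_id, patient_id,
#'   tissue, msi), `truth` (one row per gene x patient x region with the
#'   germline and somatic event and the allele present in each genome),
#'   `sequences` (or `NULL`), `reference` and `config`.
#' @export
generate_cohort <- function(reference, config = reference$config,
                            sequences = TRUE) {
  stopifnot(inherits(reference, "tr_reference"), inherits(config, "sim_config"))
  params <- reference$params
  with_seed_(seed_stage(config, 2L), {
    patients <- sprintf("P%03d", seq_len(config$n_patients))
    msi_idx <- sample.int(config$n_patients, config$n_msi_patients)
    msi <- seq_len(config$n_patients) %in% msi_idx
    samples <- tibble(
      genome_id = c(paste0(patients, "_N"), paste0(patients, "_T")),
      patient_id = rep(patients, 2L),
      tissue = rep(c("normal", "tumor"), each = config$n_patients),
      msi = rep(msi, 2L)
    ) |> arrange(.data$patient_id, .data$tissue)

    r <- reference$regions
    truth <- tidyr::expand_grid(
      idx = seq_len(nrow(r)),
      patient_id = patients
    )
    truth <- bind_cols(r[truth$idx, c("gene_id", "region", "region_length",
                                      "has_repeat", "unit", "period", "copies",
                                      "start")],
                       truth["patient_id"])
    names(truth)[names(truth) == "has_repeat"] <- "planted"
    names(truth)[names(truth) == "copies"] <- "ref_copies"
    truth$msi <- msi[match(truth$patient_id, patients)]
    nt <- nrow(truth)

    # germline layer (patient-private, half rate)
    g_loss <- truth$planted & (runif(nt) < config$p_loss_normal / 2)
    g_slip <- truth$planted & !g_loss & (runif(nt) < config$p_slippage_normal / 2)
    g_gain <- !truth$planted & (runif(nt) < config$p_gain_normal / 2)

    truth$normal_unit <- ifelse(truth$planted & !g_loss, truth$unit, NA_character_)
    truth$normal_period <- ifelse(truth$planted & !g_loss, truth$period, NA_integer_)
    truth$normal_copies <- ifelse(truth$planted & !g_loss, truth$ref_copies, NA_integer_)
    truth$normal_start <- ifelse(truth$planted & !g_loss, truth$start, NA_integer_)
    if (any(g_slip)) {
      truth$normal_copies[g_slip] <- slip_copies(truth$ref_copies[g_slip],
                                                 truth$period[g_slip], params)
    }
    for (i in which(g_gain)) {
      gn <- draw_gain(truth$region_length[i], config, params)
      truth$normal_unit[i] <- gn$unit
      truth$normal_period[i] <- gn$period
      truth$normal_copies[i] <- gn$copies
      truth$normal_start[i] <- gn$at
    }
    truth$germline_event <- dplyr::case_when(
      g_loss ~ "loss",
      g_slip ~ "copy_change",
      g_gain ~ "gain",
      TRUE ~ "none"
    )

    # somatic layer: tumor vs the patient's own normal
    present <- !is.na(truth$normal_unit)
    p_slip <- pmin(1, config$p_slippage_tumor *
                     ifelse(truth$msi, config$msi_rate_multiplier, 1))
    s_loss <- present & (runif(nt) < config$p_loss)
    s_slip <- present & !s_loss & (runif(nt) < p_slip)
    s_gain <- !present & (runif(nt) < config$p_gain)

    truth$tumor_unit <- ifelse(present & !s_loss, truth$normal_unit, NA_character_)
    truth$tumor_period <- ifelse(present & !s_loss, truth$normal_period, NA_integer_)
    truth$tumor_copies <- ifelse(present & !s_loss, truth$normal_copies, NA_integer_)
    truth$tumor_start <- ifelse(present & !s_loss, truth$normal_start, NA_integer_)
    if (any(s_slip)) {
      truth$tumor_copies[s_slip] <- slip_copies(truth$normal_copies[s_slip],
                                                truth$normal_period[s_slip], params)
    }
    for (i in which(s_gain)) {
      gn <- draw_gain(truth$region_length[i], config, params)
      truth$tumor_unit[i] <- gn$unit
      truth$tumor_period[i] <- gn$period
      truth$tumor_copies[i] <- gn$copies
      truth$tumor_start[i] <- gn$at
    }
    truth$event <- dplyr::case_when(
      s_loss ~ "loss",
      s_slip ~ "copy_change",
      s_gain ~ "gain",
      TRUE ~ "none"
    )

    seqs <- NULL
    if (sequences) {
      if (anyNA(r$background)) {
        abort("reference was generated with `backgrounds = FALSE`; cannot compose sequences.")
      }
      bg_all <- r$background[match(paste(truth$gene_id, truth$region),
                                   paste(r$gene_id, r$region))]
      normal_seq <- compose_region(bg_all, truth$normal_unit,
                                   truth$normal_copies, truth$normal_start)
      tumor_seq <- compose_region(bg_all, truth$tumor_unit,
                                  truth$tumor_copies, truth$tumor_start)
      seqs <- bind_rows(
        tibble(genome_id = paste0(truth$patient_id, "_N"),
               gene_id = truth$gene_id, region = truth$region,
               sequence = normal_seq),
        tibble(genome_id = paste0(truth$patient_id, "_T"),
               gene_id = truth$gene_id, region = truth$region,
               sequence = tumor_seq)
      ) |> arrange(.data$genome_id, .data$gene_id, .data$region)
    }

    truth <- as_tibble(truth[, c("gene_id", "patient_id", "region", "msi",
                                 "planted", "unit", "period", "ref_copies",
                                 "start", "germline_event", "normal_unit",
                                 "normal_period", "normal_copies",
                                 "normal_start", "event", "tumor_unit",
                                 "tumor_period", "tumor_copies",
                                 "tumor_start")])
    structure(list(samples = samples, truth = truth, sequences = seqs,
                   reference = reference, config = config),
              class = "tr_cohort")
  })
}

#' Repeat calls implied by a cohort's truth table
#'
#' Converts the truth table into the per-genome repeat-call table the
#' detector would produce on the (perfect) planted arrays. Used by
#' event-level power studies; sequence-level agreement between this table
#' and [detect_repeats()] output is established by the truth-recovery tests.
#'
#' @param cohort A `tr_cohort`.
#' @return Tibble with `genome_id`, `gene_id`, `region`, `start`, `period`,
#'   `unit`, `canonical`, `copy_number`, `score`.
#' @export
truth_repeat_calls <- function(cohort) {
  stopifnot(inherits(cohort, "tr_cohort"))
  t <- cohort$truth
  one <- function(side) {
    u <- t[[paste0(side, "_unit")]]
    keep <- !is.na(u)
    tibble(
      genome_id = paste0(t$patient_id[keep], if (side == "normal") "_N" else "_T"),
      gene_id = t$gene_id[keep], region = t$region[keep],
      start = t[[paste0(side, "_start")]][keep],
      period = t[[paste0(side, "_period")]][keep],
      unit = u[keep],
      canonical = canonical_unit(u[keep]),
      copy_number = as.numeric(t[[paste0(side, "_copies")]][keep]),
      score = 2L * t[[paste0(side, "_period")]][keep] *
        t[[paste0(side, "_copies")]][keep]
    )
  }
  bind_rows(one("normal"), one("tumor")) |>
    arrange(.data$genome_id, .data$gene_id, .data$region, .data$start)
}

#' Per-genome region sequences of a cohort
#'
#' @param cohort A `tr_cohort` generated with `sequences = TRUE`.
#' @return Tibble with `genome_id`, `gene_id`, `region`, `sequence`.
#' @export
cohort_sequences <- function(cohort) {
  stopifnot(inherits(cohort, "tr_cohort"))
  if (is.null(cohort$sequences)) {
    abort("cohort was generated with `sequences = FALSE`.")
  }
  cohort$sequences
}

instability_flags_from_truth <- function(truth, region = "promoter") {
  t <- truth[truth$region == region, ]
  tibble(gene_id = t$gene_id, patient_id = t$patient_id,
         instability = t$event != "none")
}

#' Generate a tumor expression table coupled to promoter instability
#'
#' Baseline rpkm values are log-normal (`2^N(mean, sd)` on log2 scale); for
#' every (gene, patient) cell whose promoter carries a somatic repeat
#' instability event in the truth table, the log2 value is shifted by
#' `expr_effect_log2`. All values are non-negative by construction.
#'
#' @param cohort A `tr_cohort` (or its truth tibble).
#' @param config A [sim_config()]; defaults to the cohort's.
#' @return Tibble: `gene_id` plus one column of rpkm per tumor genome.
#' @export
generate_expression <- function(cohort, config = NULL) {
  truth <- if (inherits(cohort, "tr_cohort")) cohort$truth else cohort
  config <- config %||% cohort$config
  stopifnot(inherits(config, "sim_config"))
  with_seed_(seed_stage(config, 3L), {
    flags <- instability_flags_from_truth(truth, "promoter")
    genes <- unique(flags$gene_id)
    patients <- unique(flags$patient_id)
    base <- matrix(rnorm(length(genes) * length(patients),
                         config$expr_base_log2_mean, config$expr_base_log2_sd),
                   nrow = length(genes))
    fl <- matrix(FALSE, length(genes), length(patients),
                 dimnames = list(genes, patients))
    fl[cbind(match(flags$gene_id, genes), match(flags$patient_id, patients))] <-
      flags$instability
    vals <- 2^(base + config$expr_effect_log2 * fl)
    out <- as_tibble(as.data.frame(vals))
    names(out) <- paste0(patients, "_T")
    bind_cols(tibble(gene_id = genes), out)
  })
}

#' Generate a tumor promoter methylation table coupled to instability
#'
#' Beta values are `meth_base_beta` plus Gaussian noise, shifted by
#' `meth_effect_delta` for (gene, patient) cells with promoter instability,
#' and clamped to the unit interval.
#'
#' @inheritParams generate_expression
#' @return Tibble: `gene_id` plus one beta-value column per tumor genome.
#' @export
generate_methylation <- function(cohort, config = NULL) {
  truth <- if (inherits(cohort, "tr_cohort")) cohort$truth else cohort
  config <- config %||% cohort$config
  stopifnot(inherits(config, "sim_config"))
  with_seed_(seed_stage(config, 4L), {
    flags <- instability_flags_from_truth(truth, "promoter")
    genes <- unique(flags$gene_id)
    patients <- unique(flags$patient_id)
    base <- matrix(rnorm(length(genes) * length(patients),
                         config$meth_base_beta, config$meth_base_sd),
                   nrow = length(genes))
    fl <- matrix(FALSE, length(genes), length(patients),
                 dimnames = list(genes, patients))
    fl[cbind(match(flags$gene_id, genes), match(flags$patient_id, patients))] <-
      flags$instability
    vals <- pmin(pmax(base + config$meth_effect_delta * fl, 0), 1)
    out <- as_tibble(as.data.frame(vals))
    names(out) <- paste0(patients, "_T")
    bind_cols(tibble(gene_id = genes), out)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generate_reference()], [generate_cohort()],
#' [generate_expression()] and [generate_methylation()].
#'
#' @param config A [sim_config()].
#' @param sequences Whether to compose per-genome sequences.
#' @param params [detection_params()] for the background rejection step.
#' @return A `tr_study` list with `reference`, `cohort`, `expression`,
#'   `methylation` and `config`.
#' @export
simulate_study <- function(config = sim_config(), sequences = TRUE,
                           params = detection_params()) {
  reference <- generate_reference(config, params)
  cohort <- generate_cohort(reference, config, sequences = sequences)
  structure(list(reference = reference, cohort = cohort,
                 expression = generate_expression(cohort),
                 methylation = generate_methylation(cohort),
                 config = config),
            class = "tr_study")
}

#' Synthetic pathway gene sets
#'
#' Draws disjoint gene sets mirroring the relative sizes of the five
#' cancer-associated signaling pathways used in the cohort analyses.
#'
#' @param gene_ids Character vector of all gene ids.
#' @param sizes Named integer vector of set sizes; the default scales the
#'   five-pathway proportions to about half the gene universe.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors.
#' @export
synthetic_pathways <- function(gene_ids,
                               sizes = NULL,
                               seed = 1L) {
  if (is.null(sizes)) {
    prop <- c(pathway_A = 113, pathway_B = 44, pathway_C = 98,
              pathway_D = 29, pathway_E = 87) / 371
    sizes <- pmax(round(prop * 0.5 * length(gene_ids)), 2L)
  }
  if (sum(sizes) > length(gene_ids)) abort("pathway sizes exceed the gene universe.")
  with_seed_(seed, {
    pool <- sample(gene_ids)
    out <- list()
    offset <- 0L
    for (nm in names(sizes)) {
      out[[nm]] <- sort(pool[(offset + 1):(offset + sizes[[nm]])])
      offset <- offset + sizes[[nm]]
    }
    out
  })
}
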