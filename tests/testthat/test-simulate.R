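# Synthetic cohort generator: determinism, planted-repeat fractions, the
# slippage/gain/loss event model, rate recovery, and the coupled
# expression/methylation effects.

test_that("identical config and seed give byte-identical output", {
  cfg <- tiny_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(reference_sequences(s1$reference),
                   reference_sequences(s2$reference))
  expect_identical(cohort_sequences(s1$cohort), cohort_sequences(s2$cohort))
  expect_identical(s1$cohort$truth, s2$cohort$truth)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$methylation, s2$methylation)
  # and FASTA serialization round-trips identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_fasta(cohort_sequences(s1$cohort), d1)
  write_genome_fasta(cohort_sequences(s2$cohort), d2)
  f <- list.files(d1)
  expect_identical(lapply(file.path(d1, f), readLines),
                   lapply(file.path(d2, f), readLines))
})

test_that("repeat fractions 1 and 0 plant everywhere and nowhere", {
  r1 <- generate_reference(tiny_config(seed = 2, n_genes = 10,
                                       frac_genes_with_promoter_repeat = 1,
                                       frac_genes_with_exon_repeat = 1),
                           backgrounds = FALSE)
  expect_true(all(r1$regions$has_repeat))
  r0 <- generate_reference(tiny_config(seed = 2,
                                       frac_genes_with_promoter_repeat = 0,
                                       frac_genes_with_exon_repeat = 0),
                           backgrounds = FALSE)
  expect_false(any(r0$regions$has_repeat))
})

test_that("zero somatic rates give identical tumors; loss rate 1 removes all", {
  cz <- tiny_config(seed = 3, p_slippage_tumor = 0, p_gain = 0, p_loss = 0,
                    p_slippage_normal = 0, p_gain_normal = 0, p_loss_normal = 0)
  coh <- generate_cohort(generate_reference(cz))
  expect_true(all(coh$truth$event == "none"))
  seqs <- cohort_sequences(coh)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(seqs, tissue = sub("^.*_", "", .data$genome_id),
                  patient = sub("_[NT]$", "", .data$genome_id)),
    id_cols = c("patient", "gene_id", "region"),
    names_from = "tissue", values_from = "sequence")
  expect_identical(wide$T, wide$N)

  cl <- tiny_config(seed = 3, frac_genes_with_promoter_repeat = 1,
                    frac_genes_with_exon_repeat = 1, p_loss = 1,
                    p_loss_normal = 0, p_gain_normal = 0, p_slippage_normal = 0)
  cohl <- generate_cohort(generate_reference(cl, backgrounds = FALSE),
                          sequences = FALSE)
  expect_true(all(cohl$truth$event == "loss"))
})

test_that("copy-change counts match the configured binomial rate", {
  # 200 planted promoter loci at slippage 0.2: Binomial(200, 0.2) bounds
  for (seed in c(5, 6, 7)) {
    cfg <- sim_config(n_genes = 200, n_patients = 1, n_msi_patients = 0,
                      frac_genes_with_promoter_repeat = 1,
                      frac_genes_with_exon_repeat = 0,
                      p_slippage_tumor = 0.2, p_loss = 0, p_gain = 0,
                      p_slippage_normal = 0, p_gain_normal = 0,
                      p_loss_normal = 0, seed = seed)
    coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                           sequences = FALSE)
    n_cc <- sum(coh$truth$event == "copy_change")
    bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.2)
    expect_gte(n_cc, bounds[1])
    expect_lte(n_cc, bounds[2])
  }
})

test_that("every somatic event is a real sequence difference and vice versa", {
  coh <- generate_cohort(generate_reference(tiny_config(seed = 19)))
  seqs <- cohort_sequences(coh)
  truth <- coh$truth
  for (i in seq_len(nrow(truth))) {
    sn <- seqs$sequence[seqs$genome_id == paste0(truth$patient_id[i], "_N") &
                          seqs$gene_id == truth$gene_id[i] &
                          seqs$region == truth$region[i]]
    st <- seqs$sequence[seqs$genome_id == paste0(truth$patient_id[i], "_T") &
                          seqs$gene_id == truth$gene_id[i] &
                          seqs$region == truth$region[i]]
    if (truth$event[i] == "none") {
      expect_identical(sn, st)
    } else {
      expect_false(identical(sn, st))
    }
  }
})

test_that("slippage changes whole units and respects the detectability floor", {
  cfg <- tiny_config(seed = 23, n_genes = 40, frac_genes_with_promoter_repeat = 1,
                     p_slippage_tumor = 0.5, p_loss = 0, p_gain = 0)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  cc <- coh$truth[coh$truth$event == "copy_change", ]
  expect_gt(nrow(cc), 0)
  delta <- cc$tumor_copies - cc$normal_copies
  expect_true(all(delta != 0))
  expect_true(all(delta == round(delta)))
  min_len <- 40  # score threshold / match weight
  expect_true(all(cc$tumor_copies * cc$tumor_period >= min_len))
})

test_that("MSI patients accumulate more copy changes than MSS patients", {
  rates <- sapply(1:5, function(seed) {
    cfg <- tiny_config(seed = seed, n_patients = 10, n_msi_patients = 3,
                       n_genes = 60, msi_rate_multiplier = 10)
    coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                           sequences = FALSE)
    t <- coh$truth
    per <- dplyr::summarise(dplyr::group_by(t, .data$patient_id, .data$msi),
                            n = sum(.data$event == "copy_change"),
                            .groups = "drop")
    c(msi = mean(per$n[per$msi]), mss = mean(per$n[!per$msi]))
  })
  expect_true(all(rates["msi", ] > rates["mss", ]))
})

test_that("expression shifts instability-bearing cells by the planted effect", {
  cfg <- tiny_config(seed = 31, n_genes = 100, n_patients = 20,
                     n_msi_patients = 0, expr_effect_log2 = -1,
                     expr_base_log2_sd = 0.3)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  expr <- generate_expression(coh)
  expect_true(all(as.matrix(expr[, -1]) >= 0))
  truth <- coh$truth[coh$truth$region == "promoter", ]
  flagged <- truth$event != "none"
  vals <- log2(as.matrix(expr[, -1]))
  v <- vals[cbind(match(truth$gene_id, expr$gene_id),
                  match(paste0(truth$patient_id, "_T"), names(expr)[-1]) )]
  # difference of group means recovers the planted -1 within CI
  est <- mean(v[flagged]) - mean(v[!flagged])
  se <- sqrt(stats::var(v[flagged]) / sum(flagged) +
               stats::var(v[!flagged]) / sum(!flagged))
  expect_lt(abs(est - (-1)), 4 * se)

  # null case: no systematic difference
  cfg0 <- tiny_config(seed = 31, n_genes = 100, n_patients = 20,
                      n_msi_patients = 0, expr_effect_log2 = 0,
                      expr_base_log2_sd = 0.3)
  coh0 <- generate_cohort(generate_reference(cfg0, backgrounds = FALSE),
                          sequences = FALSE)
  expr0 <- generate_expression(coh0)
  vals0 <- log2(as.matrix(expr0[, -1]))
  v0 <- vals0[cbind(match(truth$gene_id, expr0$gene_id),
                    match(paste0(truth$patient_id, "_T"), names(expr0)[-1]))]
  est0 <- mean(v0[flagged]) - mean(v0[!flagged])
  expect_lt(abs(est0), 4 * se)
})

test_that("methylation stays in [0, 1] and recovers the planted shift", {
  cfg <- tiny_config(seed = 37, n_genes = 150, n_patients = 20,
                     n_msi_patients = 0, meth_base_beta = 0.3,
                     meth_effect_delta = 0.2)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  meth <- generate_methylation(coh)
  m <- as.matrix(meth[, -1])
  expect_true(all(m >= 0 & m <= 1))
  truth <- coh$truth[coh$truth$region == "promoter", ]
  flagged <- truth$event != "none"
  v <- m[cbind(match(truth$gene_id, meth$gene_id),
               match(paste0(truth$patient_id, "_T"), names(meth)[-1]))]
  expect_lt(abs(mean(v[flagged]) - 0.5), 0.02)
  expect_lt(abs(mean(v[!flagged]) - 0.3), 0.02)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_slippage_tumor = 1.2), "probability")
  expect_error(sim_config(msi_rate_multiplier = 0.5), "msi_rate_multiplier")
  expect_error(sim_config(n_patients = 3, n_msi_patients = 5), "n_msi_patients")
  expect_error(sim_config(meth_base_beta = 1.4), "meth_base_beta")
  expect_error(sim_config(promoter_length = 0), "promoter_length")
  # planted repeats that cannot fit are rejected
  expect_error(
    generate_reference(tiny_config(seed = 1, promoter_length = 30L,
                                   exon_length_range = c(30L, 35L),
                                   frac_genes_with_promoter_repeat = 1),
                       backgrounds = FALSE),
    "cannot fit")
})

test_that("synthetic pathway sets are disjoint and sized as requested", {
  genes <- sprintf("g%03d", 1:200)
  pw <- synthetic_pathways(genes, seed = 4)
  expect_equal(length(pw), 5L)
  all_genes <- unlist(pw)
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_true(all(all_genes %in% genes))
})
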