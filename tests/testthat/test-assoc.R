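# Association of instability with expression and methylation.

mini_matrix <- function(flags) {
  # flags: named list gene -> logical vector over tumors T1..Tk
  k <- length(flags[[1]])
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = names(flags)),
    tibble::as_tibble(do.call(rbind, flags), .name_repair = "minimal"))
  names(out) <- c("gene_id", paste0("T", seq_len(k)))
  out
}

mini_table <- function(vals) {
  k <- length(vals[[1]])
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = names(vals)),
    tibble::as_tibble(do.call(rbind, vals), .name_repair = "minimal"))
  names(out) <- c("gene_id", paste0("T", seq_len(k)))
  out
}

test_that("group means follow the flag partition", {
  m <- mini_matrix(list(g1 = c(TRUE, FALSE, FALSE, FALSE)))
  e <- mini_table(list(g1 = c(2, 8, 8, 8)))
  gm <- gene_group_means(m, e)
  expect_equal(gm$mean_instability, 2)
  expect_equal(gm$mean_other, 8)
  expect_equal(gm$n_instability_tumors, 1L)
  expect_equal(gm$n_other_tumors, 3L)
  expect_equal(gm$log2_mean_instability, log2(2 + 1e-6))
})

test_that("genes flagged in all or no tumors are excluded and counted", {
  m <- mini_matrix(list(g1 = c(TRUE, FALSE), g2 = c(TRUE, TRUE)))
  e <- mini_table(list(g1 = c(1, 2), g2 = c(3, 4)))
  expect_message(gm <- gene_group_means(m, e), "excluded")
  expect_equal(gm$gene_id, "g1")
  expect_equal(attr(gm, "n_excluded"), 1L)
  expect_equal(nrow(gm) + attr(gm, "n_excluded"), nrow(m))
})

test_that("no overlapping tumors is an error", {
  m <- mini_matrix(list(g1 = c(TRUE, FALSE)))
  e <- mini_table(list(g1 = c(1, 2)))
  names(e) <- c("gene_id", "X1", "X2")
  expect_error(gene_group_means(m, e), "overlap")
})

test_that("methylation association validates the beta range", {
  m <- mini_matrix(list(g1 = c(TRUE, FALSE, FALSE)))
  bad <- mini_table(list(g1 = c(0.2, 1.4, 0.3)))
  expect_error(methylation_association(m, bad), "\\[0, 1\\]")
})

test_that("results are invariant to tumor column order", {
  cfg <- tiny_config(seed = 61, n_genes = 40, n_patients = 10)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, "promoter")
  names(m) <- c("gene_id", paste0(names(m)[-1], "_T"))
  expr <- generate_expression(coh)
  r1 <- suppressMessages(expression_association(m, expr))
  perm <- c(1, sample(2:ncol(expr)))
  r2 <- suppressMessages(expression_association(m, expr[, perm]))
  expect_equal(tidy(r1), tidy(r2))
})

test_that("planted expression downregulation is detected with direction", {
  cfg <- tiny_config(seed = 62, n_genes = 120, n_patients = 15,
                     expr_effect_log2 = -1)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, "promoter")
  names(m) <- c("gene_id", paste0(names(m)[-1], "_T"))
  res <- suppressMessages(expression_association(m, generate_expression(coh)))
  expect_equal(res$direction, "down_in_instability")
  expect_lt(res$p_raw, 0.01)
  # mean-of-logs alternative agrees on a strong planted effect
  res2 <- suppressMessages(
    expression_association(m, generate_expression(coh),
                           aggregate = "mean_of_log"))
  expect_equal(res2$direction, "down_in_instability")
})

test_that("planted methylation elevation is detected with direction", {
  cfg <- tiny_config(seed = 63, n_genes = 120, n_patients = 15,
                     meth_effect_delta = 0.1)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, "promoter")
  names(m) <- c("gene_id", paste0(names(m)[-1], "_T"))
  res <- suppressMessages(methylation_association(m, generate_methylation(coh)))
  expect_equal(res$direction, "up_in_instability")
  expect_lt(res$p_raw, 0.05)
})

test_that("pathway-scoped association recovers opposite planted directions", {
  # genome-wide effect -1; flip the sign inside a designated pathway by
  # editing the expression table according to the truth flags
  cfg <- tiny_config(seed = 64, n_genes = 100, n_patients = 15,
                     expr_effect_log2 = -1)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  expr <- generate_expression(coh)
  genes <- expr$gene_id
  up_set <- genes[1:30]
  truth <- coh$truth[coh$truth$region == "promoter", ]
  flag <- truth$event != "none" & truth$gene_id %in% up_set
  em <- as.matrix(expr[, -1])
  cells <- cbind(match(truth$gene_id[flag], genes),
                 match(paste0(truth$patient_id[flag], "_T"), colnames(em)))
  em[cells] <- em[cells] * 4  # +2 on log2: planted -1 becomes net +1
  expr[, -1] <- em
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, "promoter")
  names(m) <- c("gene_id", paste0(names(m)[-1], "_T"))
  res <- suppressMessages(
    expression_association(m, expr, scope = "pathway",
                           pathways = list(up = up_set,
                                           down = setdiff(genes, up_set))))
  expect_equal(res$direction[res$scope == "pathway:up"], "up_in_instability")
  expect_equal(res$direction[res$scope == "pathway:down"], "down_in_instability")
  expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))
})

test_that("tidy and glance expose the test fields", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), comparison = "demo")
  td <- tidy(r)
  expect_equal(td$p_raw, 0.1)
  expect_equal(td$comparison, "demo")
  expect_equal(glance(r)$method, "WRS")
  s <- signed_rank_test(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(tidy(s)$direction, "negative")
})
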