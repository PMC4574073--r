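# Association of per-gene repeat instability with expression / methylation:
# for each gene (with instability in at least one but not all tumors),
# compare its mean value in tumors where it shows instability against tumors
# where it does not, then test across genes with a paired signed-rank test.

#' Per-gene group means over instability-flagged tumors
#'
#' For every gene of an instability matrix, computes the mean of the omics
#' value (expression rpkm or methylation beta) over the tumors where the
#' gene shows repeat instability and over the remaining tumors, plus
#' `log2(mean + epsilon)` of both. Genes flagged in all or in no shared
#' tumor have an empty comparison group and are excluded (count reported in
#' the `n_excluded` attribute and via a message).
#'
#' @param matrix An [build_instability_matrix()] tibble (gene_id + one
#'   logical column per tumor).
#' @param table Omics tibble: `gene_id` plus one numeric column per tumor;
#'   column names must overlap the matrix's tumor columns.
#' @param epsilon Added to means before log2.
#' @return Tibble with `gene_id`, `n_instability_tumors`, `n_other_tumors`,
#'   `mean_instability`, `mean_other`, `log2_mean_instability`,
#'   `log2_mean_other`.
#' @export
gene_group_means <- function(matrix, table, epsilon = 1e-6) {
  stopifnot(is.data.frame(matrix), is.data.frame(table),
            "gene_id" %in% names(matrix), "gene_id" %in% names(table))
  tumors <- intersect(setdiff(names(matrix), "gene_id"),
                      setdiff(names(table), "gene_id"))
  if (length(tumors) == 0L) {
    abort("no overlapping tumor columns between instability matrix and omics table.")
  }
  genes <- intersect(matrix$gene_id, table$gene_id)
  M <- as.matrix(matrix[match(genes, matrix$gene_id), tumors])
  storage.mode(M) <- "logical"
  V <- as.matrix(table[match(genes, table$gene_id), tumors])
  storage.mode(V) <- "double"
  n_flag <- rowSums(M)
  n_other <- length(tumors) - n_flag
  keep <- n_flag >= 1L & n_other >= 1L
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    inform(sprintf("%d gene(s) excluded: instability in none or all tumors.",
                   n_excl))
  }
  mean_i <- rowSums(V * M) / n_flag
  mean_o <- rowSums(V * !M) / n_other
  LV <- log2(V + epsilon)
  out <- tibble(
    gene_id = genes,
    n_instability_tumors = as.integer(n_flag),
    n_other_tumors = as.integer(n_other),
    mean_instability = mean_i,
    mean_other = mean_o,
    log2_mean_instability = log2(mean_i + epsilon),
    log2_mean_other = log2(mean_o + epsilon),
    # mean-of-logs alternative: unbiased under a null with unequal group
    # sizes, unlike log-of-mean (see the methods vignette)
    mean_log2_instability = rowSums(LV * M) / n_flag,
    mean_log2_other = rowSums(LV * !M) / n_other
  )[keep, ]
  attr(out, "n_excluded") <- n_excl
  out
}

assoc_result <- function(test, scope, omics, n_genes, log_scale) {
  dir <- switch(test$direction,
                negative = "down_in_instability",
                positive = "up_in_instability",
                "none")
  structure(list(scope = scope, omics = omics, n_genes = n_genes,
                 test = "WSR", statistic = test$statistic,
                 p_raw = test$p_raw, p_adjusted = test$p_raw,
                 correction = "none", direction = dir,
                 log_scale = log_scale),
            class = "assoc_result")
}

#' Association of repeat instability with gene expression
#'
#' Implements the paired scheme: per gene, the binary-logarithm mean
#' expression in tumors where the gene shows instability versus tumors where
#' it does not; across genes, a two-sided Wilcoxon signed-rank test of these
#' paired log2 means. With `scope = "pathway"`, the test is run per pathway
#' gene set and Bonferroni-corrected over the number of pathways.
#'
#' @param matrix Instability matrix ([build_instability_matrix()]).
#' @param expression Expression tibble (`gene_id` + rpkm per tumor).
#' @param scope `"genome_wide"` or `"pathway"`.
#' @param pathways Named list of gene sets (required for pathway scope).
#' @param epsilon Added to means before log2.
#' @param aggregate `"log_of_mean"` (default: the binary logarithm of the
#'   group mean) or `"mean_of_log"` (group mean of per-tumor log2 values,
#'   which is calibrated under a true null when group sizes differ; see the
#'   methods vignette).
#' @return For genome-wide scope an `assoc_result`; for pathway scope a
#'   tibble with one row per pathway.
#' @export
expression_association <- function(matrix, expression,
                                   scope = c("genome_wide", "pathway"),
                                   pathways = NULL, epsilon = 1e-6,
                                   aggregate = c("log_of_mean", "mean_of_log")) {
  scope <- match.arg(scope)
  aggregate <- match.arg(aggregate)
  gm <- gene_group_means(matrix, expression, epsilon = epsilon)
  cols <- if (aggregate == "log_of_mean") {
    c("log2_mean_instability", "log2_mean_other")
  } else {
    c("mean_log2_instability", "mean_log2_other")
  }
  if (scope == "genome_wide") {
    t <- signed_rank_test(gm[[cols[1]]], gm[[cols[2]]])
    return(assoc_result(t, "genome_wide", "expression", nrow(gm), TRUE))
  }
  if (is.null(pathways)) abort("pathway scope requires `pathways`.")
  rows <- lapply(names(pathways), function(pw) {
    sub <- gm[gm$gene_id %in% pathways[[pw]], ]
    if (nrow(sub) == 0L) {
      return(tibble(scope = paste0("pathway:", pw), omics = "expression",
                    n_genes = 0L, statistic = NA_real_, p_raw = NA_real_,
                    direction = "none"))
    }
    t <- signed_rank_test(sub[[cols[1]]], sub[[cols[2]]])
    r <- assoc_result(t, paste0("pathway:", pw), "expression", nrow(sub), TRUE)
    tibble(scope = r$scope, omics = r$omics, n_genes = r$n_genes,
           statistic = r$statistic, p_raw = r$p_raw, direction = r$direction)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = length(pathways))
  out$correction <- "bonferroni"
  out
}

#' Association of repeat instability with promoter methylation
#'
#' Same paired scheme as [expression_association()] on methylation beta
#' values, without the log transform.
#'
#' @param matrix Instability matrix.
#' @param methylation Methylation tibble (`gene_id` + beta in `[0, 1]` per
#'   tumor).
#' @inheritParams expression_association
#' @return An `assoc_result`, or a per-pathway tibble for pathway scope.
#' @export
methylation_association <- function(matrix, methylation,
                                    scope = c("genome_wide", "pathway"),
                                    pathways = NULL) {
  scope <- match.arg(scope)
  vals <- as.matrix(methylation[, setdiff(names(methylation), "gene_id")])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("methylation beta values must lie in [0, 1].")
  }
  gm <- gene_group_means(matrix, methylation, epsilon = 0)
  if (scope == "genome_wide") {
    t <- signed_rank_test(gm$mean_instability, gm$mean_other)
    return(assoc_result(t, "genome_wide", "methylation", nrow(gm), FALSE))
  }
  if (is.null(pathways)) abort("pathway scope requires `pathways`.")
  rows <- lapply(names(pathways), function(pw) {
    sub <- gm[gm$gene_id %in% pathways[[pw]], ]
    if (nrow(sub) == 0L) {
      return(tibble(scope = paste0("pathway:", pw), omics = "methylation",
                    n_genes = 0L, statistic = NA_real_, p_raw = NA_real_,
                    direction = "none"))
    }
    t <- signed_rank_test(sub$mean_instability, sub$mean_other)
    r <- assoc_result(t, paste0("pathway:", pw), "methylation", nrow(sub), FALSE)
    tibble(scope = r$scope, omics = r$omics, n_genes = r$n_genes,
           statistic = r$statistic, p_raw = r$p_raw, direction = r$direction)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = length(pathways))
  out$correction <- "bonferroni"
  out
}
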