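# Box-plot summaries of pair profiles and association inputs.

#' Box plots of per-pair instability counts
#'
#' Mirrors the cohort comparison figures: the per-pair number of genes with
#' the chosen event, normal-normal pairs on the left, tumor-matched-normal
#' pairs on the right.
#'
#' @param profiles Tibble from [pair_profiles()].
#' @param region Region kind to plot.
#' @param metric `"instability"`, `"orphan"` or `"unstable"`.
#' @param mono Restrict to mononucleotide repeats?
#' @return A ggplot object.
#' @export
plot_pair_profiles <- function(profiles, region = "promoter",
                               metric = c("instability", "orphan", "unstable"),
                               mono = FALSE) {
  metric <- match.arg(metric)
  col <- profile_metric_column(metric, mono)
  pr <- profiles[profiles$region == region, ]
  pr$pair_class <- factor(pr$pair_class,
                          levels = c("normal_normal", "tumor_normal"))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$pair_class, y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("genes with %s%s repeats", if (mono) "mononucleotide " else "",
                  metric),
      title = sprintf("%s repeats, %s regions", metric, region)) +
    ggplot2::theme_minimal()
}

#' Box plots of per-gene mean omics values by instability group
#'
#' @param group_means Tibble from [gene_group_means()].
#' @param log_scale Plot the log2 means (expression) instead of the raw
#'   means (methylation)?
#' @return A ggplot object.
#' @export
plot_association <- function(group_means, log_scale = TRUE) {
  cols <- if (log_scale) {
    c("log2_mean_instability", "log2_mean_other")
  } else {
    c("mean_instability", "mean_other")
  }
  long <- tidyr::pivot_longer(group_means[, c("gene_id", cols)],
                              dplyr::all_of(cols),
                              names_to = "group", values_to = "value")
  long$group <- ifelse(grepl("instability", long$group),
                       "with instability", "without instability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (log_scale) "log2 mean expression" else "mean beta") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.instability_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"gene_id", names_to = "patient",
                              values_to = "instability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$gene_id,
                                     fill = .data$instability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "grey20")) +
    ggplot2::labs(x = "patient", y = "gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
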