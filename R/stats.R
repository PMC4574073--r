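# Rank-based cohort statistics: Wilcoxon rank-sum (two independent groups of
# per-pair counts) and signed-rank (paired per-gene means) tests, with
# Bonferroni correction over figure-level test families.

new_cohort_test <- function(comparison, test, statistic, n_a, n_b, p_raw,
                            exact, extra = list()) {
  structure(c(list(comparison = comparison, test = test,
                   statistic = unname(statistic), n_a = n_a, n_b = n_b,
                   p_raw = p_raw, p_adjusted = p_raw, correction = "none",
                   exact = exact), extra),
            class = "cohort_test")
}

#' Wilcoxon rank-sum test of two independent groups
#'
#' Two-sided test; the exact permutation distribution is used when the
#' smaller group has at most `exact_max_n` observations and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction. If all values across both groups are identical, p = 1.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param exact_max_n Largest min(n_a, n_b) for the exact branch.
#' @param comparison Optional label.
#' @return A `cohort_test` object; see [tidy.cohort_test()].
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_raw  # exact two-sided p = 0.1
#' @export
rank_sum_test <- function(values_a, values_b, exact_max_n = 8L,
                          comparison = NULL) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty.")
  if (anyNA(a) || anyNA(b)) abort("missing values are not allowed.")
  if (length(unique(c(a, b))) == 1L) {
    return(new_cohort_test(comparison, "WRS",
                           statistic = length(a) * length(b) / 2,
                           n_a = length(a), n_b = length(b),
                           p_raw = 1, exact = FALSE))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= exact_max_n
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  new_cohort_test(comparison, "WRS", ht$statistic, length(a), length(b),
                  min(1, ht$p.value), exact)
}

#' Wilcoxon signed-rank test of paired values
#'
#' Two-sided test on the differences `x - y` (or on `x` directly when `y` is
#' missing). Zero differences are dropped (signed-rank convention); the
#' exact distribution is used for at most `exact_max_n` nonzero untied
#' differences, otherwise the normal approximation with continuity
#' correction. All-zero differences give p = 1 and direction "none".
#'
#' @param x,y Numeric vectors of equal length (`y` optional).
#' @param exact_max_n Largest number of nonzero pairs for the exact branch.
#' @param comparison Optional label.
#' @return A `cohort_test` object with a `direction` field: `"negative"`,
#'   `"positive"` or `"none"`, the sign of the median nonzero difference.
#' @examples
#' signed_rank_test(1:6, c(2, 4, 6, 8, 10, 12))$p_raw  # 2 / 2^6 = 0.03125
#' @export
signed_rank_test <- function(x, y = NULL, exact_max_n = 25L, comparison = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) abort("missing values are not allowed.")
  if (length(d) == 0L) abort("need at least one pair.")
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(new_cohort_test(comparison, "WSR", statistic = 0,
                           n_a = length(d), n_b = length(d), p_raw = 1,
                           exact = FALSE, extra = list(direction = "none")))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- !ties && length(nz) <= exact_max_n
  ht <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  med <- median(nz)
  dir <- if (med < 0) "negative" else if (med > 0) "positive" else "none"
  new_cohort_test(comparison, "WSR", ht$statistic, length(d), length(d),
                  min(1, ht$p.value), exact, extra = list(direction = dir))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and caps at 1. Never
#' decreases a p-value.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 5)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1].")
  if (m < length(p)) abort("`m` must be at least the number of p-values.")
  pmin(1, p * m)
}

profile_metric_column <- function(metric, mono) {
  metric <- match.arg(metric, c("instability", "orphan", "unstable"))
  paste0(if (mono) "mono_" else "", "n_genes_", metric)
}

#' Compare tumor-normal against normal-normal pair profiles
#'
#' Wilcoxon rank-sum test of a per-pair gene count between the
#' tumor-matched-normal pairs and the pooled all-combinations normal-normal
#' pairs, for one region kind and event metric.
#'
#' @param profiles Profile tibble from [pair_profiles()] (needs
#'   `pair_class`).
#' @param region `"promoter"` or `"exon"`.
#' @param metric `"instability"`, `"orphan"` or `"unstable"`.
#' @param mono Restrict to mononucleotide repeats?
#' @return A `cohort_test` with group medians in `median_a` (tumor-normal)
#'   and `median_b` (normal-normal).
#' @export
compare_cohorts <- function(profiles, region = "promoter",
                            metric = c("instability", "orphan", "unstable"),
                            mono = FALSE) {
  metric <- match.arg(metric)
  col <- profile_metric_column(metric, mono)
  pr <- profiles[profiles$region == region, ]
  a <- pr[[col]][pr$pair_class == "tumor_normal"]
  b <- pr[[col]][pr$pair_class == "normal_normal"]
  if (length(a) == 0L || length(b) == 0L) {
    abort("profiles must contain both tumor_normal and normal_normal pairs.")
  }
  res <- rank_sum_test(a, b,
                       comparison = sprintf("tumor_normal vs normal_normal: %s %s%s",
                                            region, if (mono) "mono " else "", metric))
  res$median_a <- median(a)
  res$median_b <- median(b)
  res
}

#' Compare MSI against MSS tumors
#'
#' Wilcoxon rank-sum tests of per-pair instability gene counts between MSI
#' and MSS tumor-normal pairs, over a family of metrics (by default the four
#' panels: promoter/exon, any/mononucleotide instability), Bonferroni-
#' corrected over the family.
#'
#' @param profiles Profile tibble from [pair_profiles()]; tumor-normal rows
#'   must carry a logical `msi` flag.
#' @param metrics Data frame with columns `region`, `metric`, `mono`
#'   defining the family of panels.
#' @return Tibble with one row per panel: medians, statistic, `p_raw`,
#'   `p_adjusted` (Bonferroni, m = number of panels).
#' @export
compare_msi <- function(profiles,
                        metrics = tibble(
                          region = c("promoter", "promoter", "exon", "exon"),
                          metric = "instability",
                          mono = c(FALSE, TRUE, FALSE, TRUE))) {
  tn <- profiles[profiles$pair_class == "tumor_normal", ]
  if (nrow(tn) == 0L) abort("no tumor_normal pairs in profiles.")
  if (!any(tn$msi %in% TRUE) || !any(tn$msi %in% FALSE)) {
    abort("need at least one MSI and one MSS tumor-normal pair.")
  }
  rows <- vector("list", nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    col <- profile_metric_column(metrics$metric[i], metrics$mono[i])
    pr <- tn[tn$region == metrics$region[i], ]
    a <- pr[[col]][pr$msi %in% TRUE]
    b <- pr[[col]][pr$msi %in% FALSE]
    t <- rank_sum_test(a, b)
    rows[[i]] <- tibble(
      comparison = "msi_vs_mss", region = metrics$region[i],
      metric = metrics$metric[i], mono = metrics$mono[i], test = "WRS",
      statistic = t$statistic, n_a = t$n_a, n_b = t$n_b,
      median_a = median(a), median_b = median(b), p_raw = t$p_raw)
  }
  out <- bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = nrow(out))
  out$correction <- "bonferroni"
  out
}

#' Pathway-level enrichment of repeat instability
#'
#' For every pathway and event type (unstable / orphan), a Wilcoxon rank-sum
#' test of the per-pair proportion of pathway genes carrying that event,
#' tumor-normal versus normal-normal, Bonferroni-corrected over
#' (pathways x event types).
#'
#' @param pw_profiles Tibble from [pathway_profiles()].
#' @param event_types Character subset of `c("unstable", "orphan")`.
#' @return Tibble with one row per pathway and event type.
#' @export
pathway_enrichment <- function(pw_profiles,
                               event_types = c("unstable", "orphan")) {
  event_types <- match.arg(event_types, several.ok = TRUE)
  pws <- unique(pw_profiles$pathway)
  rows <- list()
  for (pw in pws) {
    pr <- pw_profiles[pw_profiles$pathway == pw, ]
    for (ev in event_types) {
      col <- paste0("prop_", ev)
      a <- pr[[col]][pr$pair_class == "tumor_normal"]
      b <- pr[[col]][pr$pair_class == "normal_normal"]
      if (length(a) == 0L || length(b) == 0L) {
        abort("pathway profiles must contain both pair classes.")
      }
      t <- rank_sum_test(a, b)
      rows[[length(rows) + 1]] <- tibble(
        pathway = pw, event = ev, test = "WRS", statistic = t$statistic,
        n_a = t$n_a, n_b = t$n_b, median_a = median(a), median_b = median(b),
        p_raw = t$p_raw)
    }
  }
  out <- bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = nrow(out))
  out$correction <- "bonferroni"
  out
}
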