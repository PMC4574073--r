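# Shared fixtures: random sequences with (optionally mutated) planted repeat
# arrays, small cohort configs, and exhaustive enumeration oracles for the
# rank-based tests.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_seq <- function(s, n_mut) {
  v <- strsplit(s, "")[[1]]
  i <- sample(length(v), n_mut)
  v[i] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
  paste(v, collapse = "")
}

# random background of length ~n, with probability `p_plant` carrying one
# planted repeat array (period 1..6, >= 45 bp, possibly with 1-2 point
# mutations)
planted_seq <- function(n, p_plant = 0.7, mutations = TRUE) {
  bg <- random_seq(n)
  if (runif(1) < p_plant) {
    p <- sample(1:6, 1)
    cp <- sample(ceiling(45 / p):ceiling(90 / p), 1)
    arr <- strrep(paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = ""), cp)
    if (mutates <- (mutations && runif(1) < 0.5)) arr <- mutate_seq(arr, sample(1:2, 1))
    at <- sample(0:(n - 10), 1)
    bg <- paste0(substr(bg, 1, at), arr, substr(bg, at + 1, nchar(bg)))
  }
  bg
}

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 12L, n_patients = 4L, n_msi_patients = 1L,
                   promoter_length = 600L, exon_length_range = c(300L, 500L),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled ranks to group A
wrs_enumerate <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  sets <- utils::combn(n, length(a))
  w_all <- apply(sets, 2, function(idx) sum(rank(seq_len(n))[idx])) -
    length(a) * (length(a) + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided Wilcoxon signed-rank p-value by enumerating every sign
# assignment of the nonzero differences
wsr_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# repeat-call tables for synthetic matching tests
fake_call <- function(gene = "g1", region = "promoter", start = 100L,
                      unit = "AC", copies = 25, score = NULL) {
  period <- nchar(unit)
  tibble::tibble(gene_id = gene, region = region, start = as.integer(start),
                 period = period, canonical = canonical_unit(unit),
                 copy_number = copies,
                 score = as.integer(score %||% (2 * period * copies)))
}

`%||%` <- rlang::`%||%`
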