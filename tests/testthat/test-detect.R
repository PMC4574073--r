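# Tandem repeat detection: wraparound alignment scoring, thresholds,
# canonicalization, and agreement between the seeded detector and the
# exhaustive reference search.

test_that("perfect arrays score and report as expected", {
  hits <- find_tandem_repeats(strrep("A", 40))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit, "A")
  expect_equal(hits$period, 1L)
  expect_equal(hits$copy_number, 40)
  expect_equal(hits$score, 80L)  # match weight 2 x 40 bp
  expect_equal(hits$identity, 1)
  expect_equal(hits$indel_fraction, 0)

  # 15 bp perfect array scores 30 < 80: not emitted
  expect_equal(nrow(find_tandem_repeats(strrep("ACG", 5))), 0L)

  # embedded in background, coordinates are region-relative and 0-based
  bg <- "GTCTTGCACTTGTCAATGCGGTAAGCTGGCATAACCACTGGA"
  s <- paste0(bg, strrep("ACGT", 12), bg)
  hits <- find_tandem_repeats(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, nchar(bg))
  expect_equal(hits$length, 48L)
  expect_equal(hits$canonical, "ACGT")
})

test_that("a single substitution keeps a 48 bp array above all thresholds", {
  arr <- strrep("ACGT", 12)
  substr(arr, 23, 23) <- "C"  # G -> C, one mismatch, not in the leading unit
  hits <- find_tandem_repeats(arr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 2L * 47L - 7L)      # 87
  expect_equal(hits$identity, 47 / 48)
  expect_gte(hits$identity, 0.90)
})

test_that("wraparound alignment scoring matches hand-computed cases", {
  # perfect array: score = 2 * k * p, identity 1, no indels
  r <- score_repeat_alignment(strrep("ACGT", 12), "ACGT")
  expect_equal(r$score, 96L)
  expect_equal(r$identity, 1)
  expect_equal(r$indel_fraction, 0)
  expect_equal(r$ref_units, 12)

  # 10 x "AC" with one A deleted: 19 matches, 1 deletion
  arr <- paste0(strrep("AC", 5), "C", strrep("AC", 4))
  r <- score_repeat_alignment(arr, "AC")
  expect_equal(r$score, 2L * 19L - 7L)  # 31
  expect_equal(r$identity, 19 / 20)
  expect_equal(r$indel_fraction, 1 / 9)
  expect_gt(r$indel_fraction, 0.10)     # boundary: fails the indel threshold

  # empty array aligns to zero units
  expect_equal(score_repeat_alignment("", "ACGT")$score, 0L)

  # one substitution costs match_weight + mismatch_penalty
  arr <- strrep("ACGT", 12)
  substr(arr, 23, 23) <- "C"
  expect_equal(score_repeat_alignment(arr, "ACGT")$score, 2L * 47L - 7L)
})

test_that("alignment score equals a plain-R DP on tiny cases", {
  # independent reference: full-matrix wraparound DP, score only
  r_dp <- function(arr, unit, mw = 2, xp = 7, ip = 7) {
    a <- strsplit(arr, "")[[1]]; u <- strsplit(unit, "")[[1]]
    L <- length(a); p <- length(u)
    D <- matrix(-Inf, L + 1, p)
    D[1, ] <- -ip * (seq_len(p) - 1)
    for (i in seq_len(L)) {
      for (j in seq_len(p)) {
        jp <- if (j == 1) p else j - 1
        sc <- if (a[i] == u[jp]) mw else -xp
        D[i + 1, j] <- max(D[i, jp] + sc, D[i, j] - ip)
      }
      for (pass in 1:2) {
        for (j in seq_len(p)) {
          jp <- if (j == 1) p else j - 1
          D[i + 1, j] <- max(D[i + 1, j], D[i + 1, jp] - ip)
        }
      }
    }
    D[L + 1, 1]
  }
  set.seed(101)
  for (case in 1:40) {
    p <- sample(1:4, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    arr <- substr(strrep(unit, 8), 1, sample(0:20, 1))
    if (runif(1) < 0.6 && nchar(arr) > 2) arr <- mutate_seq(arr, 1)
    expect_equal(score_repeat_alignment(arr, unit)$score, r_dp(arr, unit),
                 info = paste(arr, unit))
  }
})

test_that("canonical units are minimal rotations and idempotent", {
  expect_equal(canonical_unit(c("GAC", "A", "CACA")), c("ACG", "A", "ACAC"))
  set.seed(7)
  for (i in 1:25) {
    u <- random_seq(sample(1:8, 1))
    cu <- canonical_unit(u)
    # rotation-invariant
    r <- sample(nchar(u), 1)
    rot <- paste0(substr(u, r, nchar(u)), substr(u, 1, r - 1))
    expect_equal(canonical_unit(rot), cu)
    expect_equal(canonical_unit(cu), cu)
  }
  expect_error(canonical_unit(""), "non-empty")
})

test_that("mononucleotide classification uses the canonical unit length", {
  expect_equal(is_mononucleotide(c("A", "AC", "AAAT")), c(TRUE, FALSE, FALSE))
  hits <- find_tandem_repeats(strrep("A", 45))
  expect_true(is_mononucleotide(hits))
})

test_that("input validation rejects non-nucleotide characters, accepts empty", {
  expect_error(find_tandem_repeats("ACGTX"), "outside")
  expect_equal(nrow(find_tandem_repeats("")), 0L)
  expect_error(score_repeat_alignment("ACGT", ""), "non-empty")
})

test_that("N bases match nothing and N-rich repeats are discarded", {
  # poly-A with scattered Ns still detected while N fraction is small
  s <- paste0(strrep("A", 30), "N", strrep("A", 30))
  hits <- find_tandem_repeats(s)
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$identity, 1)
  # an array that is mostly N is not reported
  expect_equal(nrow(find_tandem_repeats(strrep("AN", 40))), 0L)
})

test_that("detector output equals the exhaustive reference search", {
  set.seed(202)
  pars <- detection_params(max_unit_length = 10)
  for (i in 1:60) {
    s <- planted_seq(sample(80:160, 1))
    a <- find_tandem_repeats(s, pars, method = "exhaustive")
    b <- find_tandem_repeats_brute(s, pars)
    expect_equal(as.data.frame(a), as.data.frame(b),
                 ignore_attr = TRUE, info = s)
  }
})

test_that("seeded search agrees with exhaustive search", {
  set.seed(303)
  pars <- detection_params(max_unit_length = 20)
  for (i in 1:30) {
    s <- planted_seq(sample(150:400, 1), p_plant = 0.8)
    a <- find_tandem_repeats(s, pars, method = "exhaustive")
    b <- find_tandem_repeats(s, pars, method = "seeded")
    expect_equal(as.data.frame(a), as.data.frame(b),
                 ignore_attr = TRUE, info = s)
  }
})

test_that("raising min_score or min_identity never adds repeats", {
  set.seed(404)
  for (i in 1:15) {
    s <- planted_seq(200, p_plant = 0.9)
    n_lo <- nrow(find_tandem_repeats(s, detection_params(min_score = 60)))
    n_hi <- nrow(find_tandem_repeats(s, detection_params(min_score = 100)))
    expect_gte(n_lo, n_hi)
    n_strict <- nrow(find_tandem_repeats(s, detection_params(min_identity = 0.98)))
    n_loose <- nrow(find_tandem_repeats(s, detection_params(min_identity = 0.90)))
    expect_gte(n_loose, n_strict)
  }
})

test_that("planted perfect repeats are fully recovered, background is clean", {
  set.seed(505)
  cfg <- tiny_config(seed = 17, frac_genes_with_promoter_repeat = 1,
                     frac_genes_with_exon_repeat = 1)
  ref <- generate_reference(cfg)
  seqs <- reference_sequences(ref)
  calls <- detect_repeats(seqs)
  # recall 1: every planted repeat found with the right canonical unit
  planted <- ref$regions[ref$regions$has_repeat, ]
  found <- dplyr::inner_join(
    planted, calls, by = c("gene_id", "region"), suffix = c("", ".call"))
  expect_equal(nrow(found), nrow(planted))
  expect_equal(found$canonical.call, canonical_unit(found$unit))
  # no detections beyond the planted loci (rejection-sampled background)
  expect_equal(nrow(calls), nrow(planted))
})
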