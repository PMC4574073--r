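# Repeat matching and instability classification between genome pairs.

test_that("positional window rule matches at 40 nt and splits at 60 nt", {
  a <- fake_call(start = 100)
  b40 <- fake_call(start = 140)
  m <- match_repeats(a, b40)
  expect_equal(nrow(m), 1L)
  expect_equal(m$status, "stable")

  b60 <- fake_call(start = 160)
  m <- match_repeats(a, b60)
  expect_equal(sort(m$status), c("orphan_a", "orphan_b"))
})

test_that("greedy matching picks the nearest candidate one-to-one", {
  # A has repeats at 100 and 130; B has one at 120: B pairs with 130
  a <- dplyr::bind_rows(fake_call(start = 100), fake_call(start = 130))
  b <- fake_call(start = 120)
  m <- match_repeats(a, b)
  matched <- m[m$status %in% c("stable", "unstable"), ]
  expect_equal(matched$start_a, 130L)
  expect_equal(m$status[m$start_a == 100 & !is.na(m$start_a)], "orphan_a")
})

test_that("matching requires equal canonical units within a gene", {
  a <- fake_call(unit = "AC", start = 100)
  b <- fake_call(unit = "CA", start = 110)  # same canonical rotation
  expect_equal(match_repeats(a, b)$status, "stable")
  b2 <- fake_call(unit = "AG", start = 110)
  expect_equal(sort(match_repeats(a, b2)$status), c("orphan_a", "orphan_b"))
  # no cross-gene matching
  b3 <- fake_call(gene = "g2", start = 100)
  m <- match_repeats(a, b3)
  expect_equal(sort(m$status), c("orphan_a", "orphan_b"))
})

test_that("reverse-complement units are distinct unless opted in", {
  a <- fake_call(unit = "AAC", start = 100)   # revcomp AAC = GTT
  b <- fake_call(unit = "GTT", start = 105)
  expect_equal(sort(match_repeats(a, b)$status), c("orphan_a", "orphan_b"))
  expect_equal(match_repeats(a, b, match_revcomp = TRUE)$status, "stable")
})

test_that("copy-number classification uses the one-unit threshold", {
  expect_equal(classify_match(10, 12), "unstable")
  expect_equal(classify_match(10, 10), "stable")
  expect_equal(classify_match(10, 10.4), "stable")   # delta 0.4 < 1
  expect_equal(classify_match(10, 11), "unstable")   # boundary: delta == 1
  expect_equal(classify_match(10, 10.4, unstable_min_delta = 0.3), "unstable")
  expect_equal(classify_match(NA, 10), "orphan_b")
  expect_equal(classify_match(10, NA), "orphan_a")
})

test_that("gene flags are unions over the gene's matches", {
  m <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", region = "promoter", status = "orphan_a",
                   canonical = "AC", mono = FALSE),
    tibble::tibble(gene_id = "g1", region = "promoter", status = "stable",
                   canonical = "A", mono = TRUE),
    tibble::tibble(gene_id = "g2", region = "promoter", status = "stable",
                   canonical = "AC", mono = FALSE),
    tibble::tibble(gene_id = "g3", region = "promoter", status = "unstable",
                   canonical = "A", mono = TRUE))
  fl <- gene_flags(m)
  g1 <- fl[fl$gene_id == "g1", ]
  expect_true(g1$has_orphan); expect_false(g1$has_unstable)
  expect_true(g1$has_instability); expect_false(g1$mono_has_orphan)
  g2 <- fl[fl$gene_id == "g2", ]
  expect_false(g2$has_instability)
  g3 <- fl[fl$gene_id == "g3", ]
  expect_true(g3$mono_has_unstable && g3$has_unstable && g3$mono_has_instability)
  # mono flags imply the general flags
  expect_true(all(!fl$mono_has_orphan | fl$has_orphan))
  expect_true(all(!fl$mono_has_unstable | fl$has_unstable))
})

test_that("matching is symmetric and conserves repeats", {
  set.seed(55)
  for (i in 1:20) {
    mk <- function() {
      n <- sample(0:4, 1)
      if (n == 0) return(fake_call()[0, ])
      dplyr::bind_rows(lapply(seq_len(n), function(k) {
        fake_call(gene = sample(c("g1", "g2"), 1),
                  start = sample(0:300, 1),
                  unit = sample(c("A", "AC", "AAG"), 1),
                  copies = sample(40:60, 1))
      }))
    }
    a <- mk(); b <- mk()
    m_ab <- match_repeats(a, b)
    m_ba <- match_repeats(b, a)
    # conservation: |a| + |b| = 2 * matched + orphans
    n_matched <- sum(m_ab$status %in% c("stable", "unstable"))
    n_orphan <- sum(startsWith(m_ab$status, "orphan"))
    expect_equal(nrow(a) + nrow(b), 2L * n_matched + n_orphan)
    # symmetry: statuses swap orphan labels
    swap <- c(stable = "stable", unstable = "unstable",
              orphan_a = "orphan_b", orphan_b = "orphan_a")
    expect_equal(sort(unname(swap[m_ab$status])), sort(m_ba$status))
  }
})

test_that("increasing the positional window never creates orphans", {
  set.seed(66)
  for (i in 1:10) {
    a <- dplyr::bind_rows(lapply(1:3, function(k)
      fake_call(start = sample(0:200, 1), copies = sample(40:50, 1))))
    b <- dplyr::bind_rows(lapply(1:3, function(k)
      fake_call(start = sample(0:200, 1), copies = sample(40:50, 1))))
    orphans <- sapply(c(10, 50, 100, 250), function(w)
      sum(startsWith(match_repeats(a, b, max_shift = w)$status, "orphan")))
    expect_true(all(diff(orphans) <= 0))
  }
})

test_that("vectorised cohort calling equals per-patient greedy matching", {
  set.seed(77)
  cfg <- tiny_config(seed = 44, n_patients = 6)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  calls <- truth_repeat_calls(coh)
  fast <- call_instability(calls, coh$samples)
  slow <- repeatcohort:::calls_matched(calls, coh$samples)
  key <- function(x) {
    x <- x[order(x$patient_id, x$gene_id, x$region, x$status, x$canonical), ]
    x[, c("patient_id", "gene_id", "region", "status", "canonical",
          "copies_a", "copies_b")]
  }
  expect_equal(as.data.frame(key(fast)), as.data.frame(key(slow)),
               ignore_attr = TRUE)
})

test_that("fast and matched pair profiling agree", {
  cfg <- tiny_config(seed = 45, n_patients = 5)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  calls <- truth_repeat_calls(coh)
  pairs <- cohort_pairs(coh$samples)
  fast <- repeatcohort:::profiles_fast(calls, pairs, 50, 1)
  slow <- repeatcohort:::profiles_matched(calls, pairs, 50, 1)
  expect_equal(as.data.frame(fast), as.data.frame(slow), ignore_attr = TRUE)
})

test_that("instability matrix marks exactly the truth-table events", {
  cfg <- tiny_config(seed = 47)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, region = "promoter")
  truth <- coh$truth[coh$truth$region == "promoter" & coh$truth$event != "none", ]
  for (i in seq_len(nrow(truth))) {
    expect_true(m[[truth$patient_id[i]]][m$gene_id == truth$gene_id[i]])
  }
  expect_equal(sum(as.matrix(m[, -1])), nrow(truth))
  # genes with no instability anywhere are dropped
  expect_true(all(rowSums(as.matrix(m[, -1])) > 0))
})

test_that("a zero-rate cohort yields an empty instability matrix", {
  cfg <- tiny_config(seed = 48, p_slippage_tumor = 0, p_gain = 0, p_loss = 0)
  coh <- generate_cohort(generate_reference(cfg, backgrounds = FALSE),
                         sequences = FALSE)
  pc <- call_instability(truth_repeat_calls(coh), coh$samples)
  m <- build_instability_matrix(pc, region = "promoter")
  expect_equal(nrow(m), 0L)
})
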