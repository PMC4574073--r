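#' Tandem repeat detection parameters
#'
#' Thresholds and alignment weights for [find_tandem_repeats()]. The defaults
#' select micro- and minisatellites with repeat units up to 100 nt, unit
#' identity of at least 90 %, adjacent-unit indel incidence of at most 10 %,
#' and a wraparound alignment score of at least 80 under +2/-7/-7
#' match/mismatch/indel weights (so a perfect array must span at least 40 bp).
#'
#' @param min_score Minimum wraparound alignment score for an emitted repeat.
#' @param max_unit_length Maximum repeat unit (period) length in bp, at most 100.
#' @param min_identity Minimum fraction of aligned unit positions that match
#'   the verification unit.
#' @param max_indel_fraction Maximum number of indels per adjacent-unit
#'   junction spanned by the array.
#' @param max_n_fraction Windows with a larger fraction of `N` (unaligned)
#'   bases are discarded.
#' @param match_weight,mismatch_penalty,indel_penalty Alignment weights;
#'   penalties are given as positive numbers and applied negatively.
#' @return A `detection_params` object (a validated list).
#' @examples
#' detection_params()
#' detection_params(min_score = 50)
#' @export
detection_params <- function(min_score = 80L, max_unit_length = 100L,
                             min_identity = 0.90, max_indel_fraction = 0.10,
                             max_n_fraction = 0.10, match_weight = 2L,
                             mismatch_penalty = 7L, indel_penalty = 7L) {
  p <- list(
    min_score = as.integer(min_score),
    max_unit_length = as.integer(max_unit_length),
    min_identity = as.numeric(min_identity),
    max_indel_fraction = as.numeric(max_indel_fraction),
    max_n_fraction = as.numeric(max_n_fraction),
    match_weight = as.integer(match_weight),
    mismatch_penalty = as.integer(mismatch_penalty),
    indel_penalty = as.integer(indel_penalty)
  )
  if (p$min_score <= 0) abort("`min_score` must be positive.")
  if (p$max_unit_length < 1 || p$max_unit_length > 100) {
    abort("`max_unit_length` must be in 1..100.")
  }
  for (f in c("min_identity", "max_indel_fraction", "max_n_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(sprintf("`%s` must be in [0, 1].", f))
  }
  if (p$match_weight <= 0 || p$mismatch_penalty < 0 || p$indel_penalty < 0) {
    abort("alignment weights must be positive (penalties given as positive numbers).")
  }
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Tandem repeat detection parameters\n")
  cat(sprintf("  score >= %d, period <= %d, identity >= %.2f, indels/junction <= %.2f\n",
              x$min_score, x$max_unit_length, x$min_identity, x$max_indel_fraction))
  cat(sprintf("  weights: match +%d, mismatch -%d, indel -%d; max N fraction %.2f\n",
              x$match_weight, x$mismatch_penalty, x$indel_penalty, x$max_n_fraction))
  invisible(x)
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single character string.")
  }
  s <- toupper(sequence)
  if (nchar(gsub("[ACGTN]", "", s)) > 0L) {
    abort("`sequence` contains characters outside {A, C, G, T, N}.")
  }
  s
}

repeat_columns <- function(df, gene_id = NA_character_, region = NA_character_) {
  tibble(
    gene_id = gene_id,
    region = region,
    start = as.integer(df$start),
    length = as.integer(df$length),
    period = as.integer(df$period),
    unit = as.character(df$unit),
    canonical = as.character(df$canonical),
    copy_number = as.numeric(df$copy_number),
    score = as.integer(df$score),
    identity = as.numeric(df$identity),
    indel_fraction = as.numeric(df$indel_fraction)
  )
}

#' Find tandem repeats in a nucleotide sequence
#'
#' Detects tandem repeat arrays whose wraparound alignment against cyclic
#' concatenations of the array's leading unit passes all thresholds in
#' `params`, then removes redundant overlapping interpretations (among
#' overlapping candidates with the same canonical unit only the best-scoring
#' is kept; candidates with different canonical units may co-exist if they
#' overlap by less than 50 % of the shorter).
#'
#' Coordinates are 0-based, half-open, relative to the supplied sequence.
#' `N` bases match nothing; arrays with more than `max_n_fraction` of `N`
#' are discarded.
#'
#' @param sequence A single string over A/C/G/T/N. An empty string yields an
#'   empty result.
#' @param params A [detection_params()] object.
#' @param method Candidate search strategy. `"exhaustive"` sweeps every
#'   (start, period) pair; `"seeded"` restricts starts to neighbourhoods of
#'   exact lag-p match runs, which is what makes 5 kb promoters tractable;
#'   `"auto"` (default) picks exhaustive while the full sweep is cheap.
#' @param gene_id,region Optional identifiers copied into the output.
#' @return A tibble with one row per repeat: `start`, `length`, `period`,
#'   `unit` (consensus pattern, the most common in-phase unit), `canonical`
#'   (lexicographically minimal rotation of `unit`), `copy_number`
#'   (= length / period), `score`, `identity` and `indel_fraction`, sorted by
#'   `start`.
#' @examples
#' find_tandem_repeats(strrep("A", 45))
#' find_tandem_repeats(strrep("ACG", 5))  # 15 bp, below the score threshold
#' @export
find_tandem_repeats <- function(sequence, params = detection_params(),
                                method = c("auto", "exhaustive", "seeded"),
                                gene_id = NA_character_, region = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(params, "detection_params"))
  s <- validate_sequence(sequence)
  if (nchar(s) == 0L) {
    return(repeat_columns(list(start = integer(), length = integer(),
                               period = integer(), unit = character(),
                               canonical = character(), copy_number = numeric(),
                               score = integer(), identity = numeric(),
                               indel_fraction = numeric()),
                          gene_id = character(), region = character()))
  }
  df <- rc_detect(s, params$min_score, params$max_unit_length,
                  params$min_identity, params$max_indel_fraction,
                  params$max_n_fraction, params$match_weight,
                  params$mismatch_penalty, params$indel_penalty, method)
  repeat_columns(df, gene_id = gene_id, region = region)
}

#' Detect repeats across a table of region sequences
#'
#' Maps [find_tandem_repeats()] over a tibble of region sequences, e.g. the
#' per-genome regions emitted by the cohort simulator or extracted by
#' [build_regions()].
#'
#' @param regions A tibble with columns `gene_id`, `region`, `sequence`, and
#'   optionally `genome_id`.
#' @inheritParams find_tandem_repeats
#' @return A tibble of repeat calls with identifier columns prepended.
#' @export
detect_repeats <- function(regions, params = detection_params(),
                           method = c("auto", "exhaustive", "seeded")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "detection_params"), is.data.frame(regions),
            all(c("gene_id", "region", "sequence") %in% names(regions)))
  has_genome <- "genome_id" %in% names(regions)
  out <- vector("list", nrow(regions))
  idx <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- validate_sequence(regions$sequence[[i]])
    if (nchar(s) == 0L) next
    df <- rc_detect(s, params$min_score, params$max_unit_length,
                    params$min_identity, params$max_indel_fraction,
                    params$max_n_fraction, params$match_weight,
                    params$mismatch_penalty, params$indel_penalty, method)
    if (nrow(df) == 0L) next
    out[[i]] <- df
    idx[[i]] <- rep.int(i, nrow(df))
  }
  keep <- !vapply(out, is.null, logical(1))
  grab <- function(col) unlist(lapply(out[keep], `[[`, col), use.names = FALSE)
  ridx <- unlist(idx[keep], use.names = FALSE)
  res <- repeat_columns(
    list(start = grab("start"), length = grab("length"),
         period = grab("period"), unit = grab("unit") %||% character(),
         canonical = grab("canonical") %||% character(),
         copy_number = grab("copy_number") %||% numeric(),
         score = grab("score") %||% integer(),
         identity = grab("identity") %||% numeric(),
         indel_fraction = grab("indel_fraction") %||% numeric()),
    gene_id = regions$gene_id[ridx] %||% character(),
    region = regions$region[ridx] %||% character())
  if (has_genome) {
    res$genome_id <- regions$genome_id[ridx] %||% character()
    res <- relocate(res, "genome_id")
  }
  res
}

#' Score an array against cyclic concatenations of a unit
#'
#' Global wraparound alignment of `array` against `unit` repeated a whole
#' number of times (the number of repetitions is chosen optimally, including
#' zero for an empty array). The score is the sum of +`match_weight` per
#' match and -`mismatch_penalty` / -`indel_penalty` per mismatch / indel;
#' `identity` is matches over aligned unit positions, and `indel_fraction`
#' is indels per adjacent-unit junction spanned.
#'
#' @param array Nucleotide string (may be empty).
#' @param unit Non-empty nucleotide string, at most `params$max_unit_length`
#'   characters.
#' @param params A [detection_params()] object supplying the weights.
#' @return A list with `score`, `identity`, `indel_fraction`, `matches`,
#'   `mismatches`, `insertions`, `deletions` and `ref_units` (number of unit
#'   copies consumed by the alignment).
#' @examples
#' score_repeat_alignment(strrep("AC", 10), "AC")
#' @export
score_repeat_alignment <- function(array, unit, params = detection_params()) {
  a <- if (nchar(array) == 0L) "" else validate_sequence(array)
  u <- validate_sequence(unit)
  if (nchar(u) == 0L) abort("`unit` must be non-empty.")
  if (nchar(u) > params$max_unit_length) {
    abort("`unit` is longer than `params$max_unit_length`.")
  }
  v <- rc_score(a, u, params$match_weight, params$mismatch_penalty,
                params$indel_penalty)
  ref <- v[["matches"]] + v[["mismatches"]] + v[["deletions"]]
  w <- ref / nchar(u)
  list(
    score = unname(v[["score"]]),
    identity = if (ref > 0) unname(v[["matches"]]) / ref else NA_real_,
    indel_fraction = if (ref > 0) {
      (v[["insertions"]] + v[["deletions"]]) / max(1, w - 1)
    } else NA_real_,
    matches = unname(v[["matches"]]),
    mismatches = unname(v[["mismatches"]]),
    insertions = unname(v[["insertions"]]),
    deletions = unname(v[["deletions"]]),
    ref_units = unname(w)
  )
}

#' Canonical form of a repeat unit
#'
#' The lexicographically minimal cyclic rotation, used so that repeats with
#' the same unit written in different phases ("GAC", "ACG", "CGA") compare
#' equal. Idempotent.
#'
#' @param unit Character vector of non-empty unit strings.
#' @return Character vector of canonical rotations.
#' @examples
#' canonical_unit(c("GAC", "A", "CACA"))
#' @export
canonical_unit <- function(unit) {
  if (!is.character(unit)) abort("`unit` must be a character vector.")
  if (any(is.na(unit)) || any(nchar(unit) == 0L)) {
    abort("units must be non-empty and non-missing.")
  }
  as.character(rc_canonical(unit))
}

#' Is a repeat a mononucleotide repeat?
#'
#' True for repeats whose canonical unit consists of a single base
#' (e.g. poly-A runs); an A-rich unit such as "AAAT" is not mononucleotide.
#'
#' @param x A repeat tibble from [find_tandem_repeats()] (uses its
#'   `canonical` column) or a character vector of units.
#' @return Logical vector.
#' @examples
#' is_mononucleotide(c("A", "AC", "AAAT"))
#' @export
is_mononucleotide <- function(x) {
  units <- if (is.data.frame(x)) x$canonical else canonical_unit(x)
  nchar(units) == 1L
}

#' Brute-force reference search for tandem repeats
#'
#' Enumerates every (start, length, period) window up to
#' `params$max_unit_length`, scores each with the wraparound alignment, and
#' applies the same thresholds and overlap resolution as
#' [find_tandem_repeats()]. Exponentially slower than the seeded detector,
#' intended as an exhaustive reference for short sequences.
#'
#' @inheritParams find_tandem_repeats
#' @return A tibble in the same format as [find_tandem_repeats()].
#' @export
find_tandem_repeats_brute <- function(sequence, params = detection_params(),
                                      gene_id = NA_character_,
                                      region = NA_character_) {
  s <- validate_sequence(sequence)
  if (nchar(s) == 0L) {
    return(find_tandem_repeats("", params, gene_id = gene_id, region = region))
  }
  df <- rc_brute_candidates(s, params$min_score, params$max_unit_length,
                            params$min_identity, params$max_indel_fraction,
                            params$max_n_fraction, params$match_weight,
                            params$mismatch_penalty, params$indel_penalty)
  resolved <- resolve_overlaps_r(as_tibble(df))
  repeat_columns(resolved, gene_id = gene_id, region = region)
}

# Plain-R overlap resolution used by the brute-force reference path; same
# documented rule as the C++ detector, written independently.
resolve_overlaps_r <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  ord <- order(-cands$score, cands$period, cands$start, cands$length,
               cands$canonical)
  cands <- cands[ord, ]
  kept <- integer(0)
  for (i in seq_len(nrow(cands))) {
    s1 <- cands$start[i]; e1 <- s1 + cands$length[i]
    ok <- TRUE
    for (k in kept) {
      s2 <- cands$start[k]; e2 <- s2 + cands$length[k]
      ov <- min(e1, e2) - max(s1, s2)
      if (ov <= 0) next
      if (cands$canonical[i] == cands$canonical[k]) { ok <- FALSE; break }
      if (2 * ov >= min(e1 - s1, e2 - s2)) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  res <- cands[kept, ]
  res[order(res$start, res$period), ]
}
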