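# Matching repeats between two genomes of the same gene region and
# classifying each as stable, unstable (copy-number variant) or orphan
# (present in only one genome -- a de-novo gain or a loss).

#' Match repeats between two genomes of the same regions
#'
#' Candidate pairs are repeats of the same gene region with equal canonical
#' unit whose starts lie within `max_shift` nucleotides. Pairs are accepted
#' greedily in order of increasing positional distance (ties: higher summed
#' score first, then lower `start` in genome A), one-to-one; unmatched
#' repeats become orphans. Matching never crosses gene boundaries.
#'
#' @param repeats_a,repeats_b Repeat-call tibbles (as from
#'   [detect_repeats()]) for the two genomes; must contain `gene_id`,
#'   `region`, `start`, `period`, `canonical`, `copy_number`, `score`.
#' @param max_shift Maximum positional variation of matched repeats, bp.
#' @param unstable_min_delta Minimum copy-number difference for a matched
#'   pair to be called unstable (in repeat units).
#' @param match_revcomp If `TRUE`, units are canonicalized over both strands
#'   before comparison.
#' @return A tibble of repeat matches: `gene_id`, `region`, `status`
#'   (stable / unstable / orphan_a / orphan_b), `canonical`, `period`,
#'   `mono`, `copies_a`, `copies_b`, `copy_delta`, `start_a`, `start_b`,
#'   `score_a`, `score_b`.
#' @examples
#' a <- tibble::tibble(gene_id = "g", region = "promoter", start = 100L,
#'                     period = 2L, canonical = "AC", copy_number = 25,
#'                     score = 100L)
#' b <- dplyr::mutate(a, start = 140L, copy_number = 27)
#' match_repeats(a, b)  # matched (distance 40 <= 50), unstable (delta 2)
#' @export
match_repeats <- function(repeats_a, repeats_b, max_shift = 50,
                          unstable_min_delta = 1, match_revcomp = FALSE) {
  need <- c("gene_id", "region", "start", "period", "canonical",
            "copy_number", "score")
  a <- prepare_calls(repeats_a, need, match_revcomp)
  b <- prepare_calls(repeats_b, need, match_revcomp)
  keys <- union(paste(a$gene_id, a$region), paste(b$gene_id, b$region))
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    ga <- a[paste(a$gene_id, a$region) == keys[i], ]
    gb <- b[paste(b$gene_id, b$region) == keys[i], ]
    out[[i]] <- match_one_region(ga, gb, max_shift, keys[i])
  }
  m <- bind_rows(out)
  if (nrow(m) == 0L) {
    return(tibble(gene_id = character(), region = character(),
                  status = character(), canonical = character(),
                  period = integer(), mono = logical(), copies_a = numeric(),
                  copies_b = numeric(), copy_delta = numeric(),
                  start_a = integer(), start_b = integer(),
                  score_a = integer(), score_b = integer()))
  }
  m$copy_delta <- m$copies_a - m$copies_b
  m$status <- classify_match(m$copies_a, m$copies_b, unstable_min_delta,
                             orphan = m$status)
  m[order(m$gene_id, m$region, pmin(m$start_a, m$start_b, na.rm = TRUE)), ]
}

prepare_calls <- function(x, need, match_revcomp) {
  stopifnot(is.data.frame(x))
  if (!"canonical" %in% names(x) && "unit" %in% names(x)) {
    x$canonical <- canonical_unit(x$unit)
  }
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("repeat calls lack columns: ", paste(missing, collapse = ", ")))
  }
  if (match_revcomp) x$canonical <- strand_canonical(x$canonical)
  x
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# canonical over both strands: the smaller of the canonical rotations of the
# unit and of its reverse complement
strand_canonical <- function(units) {
  pmin(canonical_unit(units), canonical_unit(revcomp_chr(units)))
}

match_one_region <- function(ga, gb, max_shift, key) {
  gene <- sub(" [^ ]*$", "", key)
  region <- sub("^.* ", "", key)
  na <- nrow(ga)
  nb <- nrow(gb)
  used_a <- rep(FALSE, na)
  used_b <- rep(FALSE, nb)
  rows <- list()
  if (na > 0 && nb > 0) {
    cand <- expand.grid(ia = seq_len(na), ib = seq_len(nb))
    cand <- cand[ga$canonical[cand$ia] == gb$canonical[cand$ib], , drop = FALSE]
    if (nrow(cand)) {
      cand$dist <- abs(ga$start[cand$ia] - gb$start[cand$ib])
      cand <- cand[cand$dist <= max_shift, , drop = FALSE]
      cand <- cand[order(cand$dist,
                         -(ga$score[cand$ia] + gb$score[cand$ib]),
                         ga$start[cand$ia]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        ia <- cand$ia[r]; ib <- cand$ib[r]
        if (used_a[ia] || used_b[ib]) next
        used_a[ia] <- TRUE; used_b[ib] <- TRUE
        rows[[length(rows) + 1]] <- tibble(
          gene_id = gene, region = region, status = "matched",
          canonical = ga$canonical[ia], period = ga$period[ia],
          copies_a = ga$copy_number[ia], copies_b = gb$copy_number[ib],
          start_a = ga$start[ia], start_b = gb$start[ib],
          score_a = ga$score[ia], score_b = gb$score[ib])
      }
    }
  }
  orphan <- function(g, side, used) {
    idx <- which(!used)
    if (!length(idx)) return(NULL)
    tibble(
      gene_id = gene, region = region,
      status = if (side == "a") "orphan_a" else "orphan_b",
      canonical = g$canonical[idx], period = g$period[idx],
      copies_a = if (side == "a") g$copy_number[idx] else NA_real_,
      copies_b = if (side == "b") g$copy_number[idx] else NA_real_,
      start_a = if (side == "a") g$start[idx] else NA_integer_,
      start_b = if (side == "b") g$start[idx] else NA_integer_,
      score_a = if (side == "a") g$score[idx] else NA_integer_,
      score_b = if (side == "b") g$score[idx] else NA_integer_)
  }
  res <- bind_rows(c(rows, list(orphan(ga, "a", used_a), orphan(gb, "b", used_b))))
  if (nrow(res)) res$mono <- nchar(res$canonical) == 1L
  res
}

#' Classify a repeat match
#'
#' One-sided matches are orphans; matched pairs whose copy numbers differ by
#' at least `unstable_min_delta` full units are unstable, otherwise stable.
#'
#' @param copies_a,copies_b Copy numbers (NA for an absent side).
#' @param unstable_min_delta Copy-number difference threshold, units.
#' @param orphan Optional character vector carrying pre-assigned
#'   `orphan_a` / `orphan_b` labels for one-sided entries.
#' @return Character vector of statuses.
#' @examples
#' classify_match(10, 12)   # unstable
#' classify_match(10, 10.4) # stable (delta 0.4 < 1)
#' @export
classify_match <- function(copies_a, copies_b, unstable_min_delta = 1,
                           orphan = NULL) {
  n <- max(length(copies_a), length(copies_b))
  copies_a <- rep_len(copies_a, n)
  copies_b <- rep_len(copies_b, n)
  out <- ifelse(is.na(copies_a) & !is.na(copies_b), "orphan_b",
         ifelse(!is.na(copies_a) & is.na(copies_b), "orphan_a",
         ifelse(abs(copies_a - copies_b) >= unstable_min_delta,
                "unstable", "stable")))
  # one-sided rows: which genome holds the repeat decides the orphan label
  if (!is.null(orphan)) {
    pre <- orphan %in% c("orphan_a", "orphan_b")
    out[pre] <- orphan[pre]
  } else {
    out[is.na(copies_a) & !is.na(copies_b)] <- "orphan_b"
    out[!is.na(copies_a) & is.na(copies_b)] <- "orphan_a"
  }
  if (any(is.na(copies_a) & is.na(copies_b))) {
    abort("a repeat match must have at least one side present.")
  }
  out
}

#' Per-gene instability flags from classified matches
#'
#' Aggregates a match table to one row per gene region: whether the gene has
#' any orphan repeat, any unstable repeat, either (instability), and the
#' mononucleotide-restricted counterparts. A gene counts once however many
#' qualifying repeats it carries.
#'
#' @param matches A tibble from [match_repeats()].
#' @return Tibble with `gene_id`, `region`, `has_orphan`, `has_unstable`,
#'   `has_instability` and `mono_*` counterparts.
#' @export
gene_flags <- function(matches) {
  stopifnot(is.data.frame(matches))
  if (nrow(matches) == 0L) {
    return(tibble(gene_id = character(), region = character(),
                  has_orphan = logical(), has_unstable = logical(),
                  has_instability = logical(), mono_has_orphan = logical(),
                  mono_has_unstable = logical(), mono_has_instability = logical()))
  }
  matches |>
    group_by(.data$gene_id, .data$region) |>
    summarise(
      has_orphan = any(startsWith(.data$status, "orphan")),
      has_unstable = any(.data$status == "unstable"),
      mono_has_orphan = any(startsWith(.data$status, "orphan") & .data$mono),
      mono_has_unstable = any(.data$status == "unstable" & .data$mono),
      .groups = "drop"
    ) |>
    mutate(has_instability = .data$has_orphan | .data$has_unstable,
           mono_has_instability = .data$mono_has_orphan | .data$mono_has_unstable) |>
    select("gene_id", "region", "has_orphan", "has_unstable", "has_instability",
           "mono_has_orphan", "mono_has_unstable", "mono_has_instability")
}

#' Call tumor-vs-matched-normal instability for a cohort
#'
#' For each patient, matches the tumor genome's repeats against the matched
#' normal's (per gene region) and aggregates to per-gene flags. Genome A is
#' the tumor, so `orphan_a` is a de-novo gain and `orphan_b` a loss.
#'
#' When every (genome, gene, region, canonical unit) carries at most one
#' repeat, an equivalent vectorised path is used; otherwise each patient is
#' matched with [match_repeats()].
#'
#' @param repeats Repeat calls for all genomes (column `genome_id`).
#' @param samples Sample sheet tibble (`genome_id`, `patient_id`, `tissue`).
#' @param max_shift,unstable_min_delta,match_revcomp See [match_repeats()].
#' @return Tibble of per-patient matches with `patient_id` and a `call`
#'   column mapping status to gain / loss / copy_change / none.
#' @export
call_instability <- function(repeats, samples, max_shift = 50,
                             unstable_min_delta = 1, match_revcomp = FALSE) {
  stopifnot(all(c("genome_id", "patient_id", "tissue") %in% names(samples)))
  repeats <- prepare_calls(repeats, c("genome_id", "gene_id", "region", "start",
                                      "period", "canonical", "copy_number",
                                      "score"), match_revcomp)
  single <- !anyDuplicated(paste(repeats$genome_id, repeats$gene_id,
                                 repeats$region, repeats$canonical))
  if (single) {
    return(calls_fast(repeats, samples, max_shift, unstable_min_delta))
  }
  calls_matched(repeats, samples, max_shift = max_shift,
                unstable_min_delta = unstable_min_delta)
}

# Vectorised tumor-vs-matched-normal calling over locus matrices; applicable
# when each (genome, gene, region, canonical unit) carries at most one
# repeat, in which case it agrees with the greedy per-patient matcher.
calls_fast <- function(repeats, samples, max_shift, unstable_min_delta) {
  patients <- unique(samples$patient_id)
  tum <- samples$genome_id[samples$tissue == "tumor"][
    match(patients, samples$patient_id[samples$tissue == "tumor"])]
  nor <- samples$genome_id[samples$tissue == "normal"][
    match(patients, samples$patient_id[samples$tissue == "normal"])]
  if (anyNA(tum) || anyNA(nor)) {
    abort("every patient needs exactly one tumor and one normal genome.")
  }
  genomes <- c(tum, nor)
  repeats <- repeats[repeats$genome_id %in% genomes, ]
  locus_key <- paste(repeats$gene_id, repeats$region, repeats$canonical,
                     sep = "\r")
  loci <- sort(unique(locus_key))
  L <- length(loci)
  li <- match(locus_key, loci)
  gi <- match(repeats$genome_id, genomes)
  pres <- matrix(FALSE, L, length(genomes))
  st <- matrix(NA_real_, L, length(genomes))
  cp <- matrix(NA_real_, L, length(genomes))
  sc <- matrix(NA_integer_, L, length(genomes))
  pres[cbind(li, gi)] <- TRUE
  st[cbind(li, gi)] <- repeats$start
  cp[cbind(li, gi)] <- repeats$copy_number
  sc[cbind(li, gi)] <- repeats$score
  parts <- strsplit(loci, "\r", fixed = TRUE)
  locus_gene <- vapply(parts, `[[`, character(1), 1L)
  locus_region <- vapply(parts, `[[`, character(1), 2L)
  locus_canon <- vapply(parts, `[[`, character(1), 3L)
  locus_period <- repeats$period[match(loci, locus_key)]
  np <- length(patients)
  it <- seq_len(np)
  in_ <- np + it
  pa <- pres[, it, drop = FALSE]   # tumor side = genome A
  pb <- pres[, in_, drop = FALSE]
  near <- pa & pb & abs(st[, it, drop = FALSE] - st[, in_, drop = FALSE]) <= max_shift
  emit <- function(which_mat, status) {
    idx <- which(which_mat, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    l <- idx[, 1]; pcol <- idx[, 2]
    is_a <- status != "orphan_b"
    is_b <- status != "orphan_a"
    tibble(
      patient_id = patients[pcol],
      gene_id = locus_gene[l], region = locus_region[l],
      status = status, canonical = locus_canon[l],
      period = locus_period[l],
      mono = nchar(locus_canon[l]) == 1L,
      copies_a = if (is_a) cp[cbind(l, pcol)] else NA_real_,
      copies_b = if (is_b) cp[cbind(l, pcol + np)] else NA_real_,
      start_a = if (is_a) as.integer(st[cbind(l, pcol)]) else NA_integer_,
      start_b = if (is_b) as.integer(st[cbind(l, pcol + np)]) else NA_integer_,
      score_a = if (is_a) sc[cbind(l, pcol)] else NA_integer_,
      score_b = if (is_b) sc[cbind(l, pcol + np)] else NA_integer_)
  }
  matched <- emit(near, "matched")
  if (!is.null(matched)) {
    matched$status <- ifelse(abs(matched$copies_a - matched$copies_b) >=
                               unstable_min_delta, "unstable", "stable")
  }
  calls <- bind_rows(
    matched,
    emit(pa & !near, "orphan_a"),   # tumor-only (or positionally distant)
    emit(pb & !near, "orphan_b")
  )
  if (nrow(calls) == 0L) {
    return(calls_matched(repeats, samples, max_shift = max_shift,
                         unstable_min_delta = unstable_min_delta))
  }
  calls$copy_delta <- calls$copies_a - calls$copies_b
  calls$call <- dplyr::case_when(
    calls$status == "orphan_a" ~ "gain",
    calls$status == "orphan_b" ~ "loss",
    calls$status == "unstable" ~ "copy_change",
    TRUE ~ "none"
  )
  arrange(calls, .data$patient_id, .data$gene_id, .data$region,
          pmin(.data$start_a, .data$start_b, na.rm = TRUE))
}

calls_matched <- function(repeats, samples, ...) {
  patients <- unique(samples$patient_id)
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    ids <- samples[samples$patient_id == patients[i], ]
    tid <- ids$genome_id[ids$tissue == "tumor"]
    nid <- ids$genome_id[ids$tissue == "normal"]
    if (length(tid) != 1L || length(nid) != 1L) {
      abort(sprintf("patient %s does not have exactly one tumor and one normal genome.",
                    patients[i]))
    }
    m <- match_repeats(repeats[repeats$genome_id == tid, ],
                       repeats[repeats$genome_id == nid, ], ...)
    if (nrow(m)) m$patient_id <- patients[i]
    out[[i]] <- m
  }
  calls <- bind_rows(out)
  if (nrow(calls)) {
    calls$call <- dplyr::case_when(
      calls$status == "orphan_a" ~ "gain",
      calls$status == "orphan_b" ~ "loss",
      calls$status == "unstable" ~ "copy_change",
      TRUE ~ "none"
    )
    calls <- relocate(calls, "patient_id")
  }
  calls
}

#' Build a gene-by-patient instability matrix
#'
#' Entry (gene, patient) is `TRUE` when the gene shows the requested flag in
#' that patient's tumor-vs-matched-normal comparison. Genes with no
#' instability in any patient are dropped: only genes with a repeat
#' instability in at least one patient enter the downstream association
#' analyses.
#'
#' @param calls Per-patient match table from [call_instability()].
#' @param region Region kind to use (`"promoter"` or `"exon"`).
#' @param flag One of `"instability"`, `"orphan"`, `"unstable"`.
#' @param patients Optional vector fixing the patient (column) set.
#' @return A tibble with `gene_id` and one logical column per patient,
#'   classed `instability_matrix`, with attributes `region` and `flag`.
#' @export
build_instability_matrix <- function(calls, region = "promoter",
                                     flag = c("instability", "orphan", "unstable"),
                                     patients = NULL) {
  flag <- match.arg(flag)
  patients <- patients %||% unique(calls$patient_id)
  fl <- calls[calls$region == region, ] |>
    group_by(.data$gene_id, .data$patient_id) |>
    summarise(
      value = switch(flag,
        orphan = any(startsWith(.data$status, "orphan")),
        unstable = any(.data$status == "unstable"),
        instability = any(.data$status != "stable")),
      .groups = "drop")
  genes <- sort(unique(fl$gene_id[fl$value]))
  m <- matrix(FALSE, length(genes), length(patients),
              dimnames = list(genes, patients))
  fl <- fl[fl$gene_id %in% genes, ]
  m[cbind(match(fl$gene_id, genes), match(fl$patient_id, patients))] <- fl$value
  out <- bind_cols(tibble(gene_id = genes),
                   as_tibble(as.data.frame(m, optional = TRUE)))
  names(out) <- c("gene_id", patients)
  structure(out, region = region, flag = flag,
            class = c("instability_matrix", class(out)))
}
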