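# Per-genome-pair instability profiles: counts of genes with orphan /
# unstable / any-instability repeats, overall and mononucleotide-only,
# for tumor-matched-normal pairs and for all unordered normal-normal pairs
# (the between-individual null).

#' Enumerate all unordered pairs of normal genomes
#'
#' @param genome_ids Character vector of at least two genome ids.
#' @return Tibble with `pair_id`, `genome_a`, `genome_b`, one row per
#'   unordered pair in deterministic order; 35 genomes yield 595 pairs.
#' @examples
#' nrow(enumerate_normal_pairs(paste0("N", 1:35)))  # choose(35, 2) = 595
#' @export
enumerate_normal_pairs <- function(genome_ids) {
  if (!is.character(genome_ids)) genome_ids <- as.character(genome_ids)
  if (length(genome_ids) < 2L) abort("need at least two genomes to form pairs.")
  if (anyDuplicated(genome_ids)) abort("genome ids must be unique.")
  cmb <- combn(genome_ids, 2L)
  tibble(pair_id = sprintf("NN%04d", seq_len(ncol(cmb))),
         genome_a = cmb[1, ], genome_b = cmb[2, ])
}

#' Build the pair table for a cohort
#'
#' One tumor-matched-normal pair per patient (genome A = tumor) plus all
#' unordered normal-normal pairs.
#'
#' @param samples Sample sheet tibble (`genome_id`, `patient_id`, `tissue`,
#'   `msi`).
#' @return Tibble with `pair_id`, `pair_class` (`tumor_normal` /
#'   `normal_normal`), `genome_a`, `genome_b`, `msi` (NA for normal pairs).
#' @export
cohort_pairs <- function(samples) {
  stopifnot(all(c("genome_id", "patient_id", "tissue") %in% names(samples)))
  tum <- samples[samples$tissue == "tumor", ]
  nor <- samples[samples$tissue == "normal", ]
  tn <- tibble(
    pair_id = paste0("TN_", tum$patient_id),
    pair_class = "tumor_normal",
    genome_a = tum$genome_id,
    genome_b = nor$genome_id[match(tum$patient_id, nor$patient_id)],
    msi = if ("msi" %in% names(tum)) tum$msi else NA
  )
  nn <- enumerate_normal_pairs(nor$genome_id)
  nn$pair_class <- "normal_normal"
  nn$msi <- NA
  bind_rows(tn, nn[, c("pair_id", "pair_class", "genome_a", "genome_b", "msi")])
}

#' Profile repeat instability for genome pairs
#'
#' For every pair, counts the genes (per region kind) with orphan repeats,
#' with unstable repeats, and with either, plus the mononucleotide-restricted
#' counterparts. When every (genome, gene, region, canonical unit) carries at
#' most one repeat -- as in simulated cohorts -- an equivalent vectorised
#' all-pairs path is used; otherwise each pair is matched with
#' [match_repeats()].
#'
#' @param repeats Repeat calls for all genomes (needs `genome_id`, `gene_id`,
#'   `region`, `start`, `period`, `canonical`, `copy_number`, `score`).
#' @param pairs Pair table as from [cohort_pairs()] or
#'   [enumerate_normal_pairs()] (needs `pair_id`, `genome_a`, `genome_b`;
#'   `pair_class` and `msi` are carried through).
#' @param max_shift,unstable_min_delta See [match_repeats()].
#' @return Tibble with one row per pair and region kind:
#'   `pair_id`, `pair_class`, `msi`, `region`, `n_genes_orphan`,
#'   `n_genes_unstable`, `n_genes_instability` and `mono_*` counterparts.
#' @export
pair_profiles <- function(repeats, pairs, max_shift = 50,
                          unstable_min_delta = 1) {
  stopifnot(all(c("pair_id", "genome_a", "genome_b") %in% names(pairs)))
  repeats <- prepare_calls(repeats, c("genome_id", "gene_id", "region", "start",
                                      "period", "canonical", "copy_number",
                                      "score"), FALSE)
  if (!"pair_class" %in% names(pairs)) pairs$pair_class <- NA_character_
  if (!"msi" %in% names(pairs)) pairs$msi <- NA
  single <- !anyDuplicated(paste(repeats$genome_id, repeats$gene_id,
                                 repeats$region, repeats$canonical))
  if (nrow(repeats) == 0L) return(empty_profiles())
  if (single) {
    profiles_fast(repeats, pairs, max_shift, unstable_min_delta)
  } else {
    profiles_matched(repeats, pairs, max_shift, unstable_min_delta)
  }
}

empty_profiles <- function() {
  tibble(pair_id = character(), pair_class = character(), msi = logical(),
         region = character(), n_genes_orphan = integer(),
         n_genes_unstable = integer(), n_genes_instability = integer(),
         mono_n_genes_orphan = integer(), mono_n_genes_unstable = integer(),
         mono_n_genes_instability = integer())
}

profile_columns <- function() {
  c("n_genes_orphan", "n_genes_unstable", "n_genes_instability",
    "mono_n_genes_orphan", "mono_n_genes_unstable", "mono_n_genes_instability")
}

# Vectorised all-pairs profiling over locus matrices. A locus is one
# (gene, region, canonical unit); with at most one repeat per genome at a
# locus the greedy matcher reduces to: both present within the positional
# window -> matched, otherwise every present side is an orphan.
profiles_fast <- function(repeats, pairs, max_shift, unstable_min_delta) {
  genomes <- sort(unique(c(pairs$genome_a, pairs$genome_b, repeats$genome_id)))
  locus_key <- paste(repeats$gene_id, repeats$region, repeats$canonical,
                     sep = "\r")
  loci <- sort(unique(locus_key))
  L <- length(loci)
  li <- match(locus_key, loci)
  gi <- match(repeats$genome_id, genomes)
  pres <- matrix(FALSE, L, length(genomes))
  st <- matrix(NA_real_, L, length(genomes))
  cp <- matrix(NA_real_, L, length(genomes))
  pres[cbind(li, gi)] <- TRUE
  st[cbind(li, gi)] <- repeats$start
  cp[cbind(li, gi)] <- repeats$copy_number
  parts <- strsplit(loci, "\r", fixed = TRUE)
  locus_gene <- vapply(parts, `[[`, character(1), 1L)
  locus_region <- vapply(parts, `[[`, character(1), 2L)
  locus_mono <- nchar(vapply(parts, `[[`, character(1), 3L)) == 1L

  ia <- match(pairs$genome_a, genomes)
  ib <- match(pairs$genome_b, genomes)
  pa <- pres[, ia, drop = FALSE]
  pb <- pres[, ib, drop = FALSE]
  both <- pa & pb
  near <- both & abs(st[, ia, drop = FALSE] - st[, ib, drop = FALSE]) <= max_shift
  orphan <- (pa != pb) | (both & !near)
  unstable <- near &
    abs(cp[, ia, drop = FALSE] - cp[, ib, drop = FALSE]) >= unstable_min_delta
  instab <- orphan | unstable

  count_genes <- function(flag, keep) {
    # number of genes with any flagged locus, per pair
    if (!any(keep)) return(rep(0L, ncol(flag)))
    f <- flag[keep, , drop = FALSE]
    g <- factor(locus_gene[keep])
    agg <- rowsum(f + 0L, g)
    as.integer(colSums(agg > 0L))
  }
  out <- list()
  for (rk in sort(unique(locus_region))) {
    in_rk <- locus_region == rk
    out[[rk]] <- tibble(
      pair_id = pairs$pair_id, pair_class = pairs$pair_class, msi = pairs$msi,
      region = rk,
      n_genes_orphan = count_genes(orphan, in_rk),
      n_genes_unstable = count_genes(unstable, in_rk),
      n_genes_instability = count_genes(instab, in_rk),
      mono_n_genes_orphan = count_genes(orphan, in_rk & locus_mono),
      mono_n_genes_unstable = count_genes(unstable, in_rk & locus_mono),
      mono_n_genes_instability = count_genes(instab, in_rk & locus_mono)
    )
  }
  arrange(bind_rows(out), .data$pair_id, .data$region)
}

profiles_matched <- function(repeats, pairs, max_shift, unstable_min_delta) {
  out <- vector("list", nrow(pairs))
  regions <- sort(unique(repeats$region))
  for (i in seq_len(nrow(pairs))) {
    m <- match_repeats(repeats[repeats$genome_id == pairs$genome_a[i], ],
                       repeats[repeats$genome_id == pairs$genome_b[i], ],
                       max_shift = max_shift,
                       unstable_min_delta = unstable_min_delta)
    fl <- gene_flags(m)
    per_region <- lapply(regions, function(rk) {
      f <- fl[fl$region == rk, ]
      tibble(pair_id = pairs$pair_id[i], pair_class = pairs$pair_class[i],
             msi = pairs$msi[i], region = rk,
             n_genes_orphan = sum(f$has_orphan),
             n_genes_unstable = sum(f$has_unstable),
             n_genes_instability = sum(f$has_instability),
             mono_n_genes_orphan = sum(f$mono_has_orphan),
             mono_n_genes_unstable = sum(f$mono_has_unstable),
             mono_n_genes_instability = sum(f$mono_has_instability))
    })
    out[[i]] <- bind_rows(per_region)
  }
  arrange(bind_rows(out), .data$pair_id, .data$region)
}

#' Profile a single genome pair
#'
#' @param repeats_a,repeats_b Repeat calls of the two genomes.
#' @inheritParams pair_profiles
#' @return One-pair profile tibble (one row per region kind present).
#' @export
profile_pair <- function(repeats_a, repeats_b, max_shift = 50,
                         unstable_min_delta = 1) {
  repeats_a$genome_id <- "a"
  repeats_b$genome_id <- "b"
  pair_profiles(bind_rows(repeats_a, repeats_b),
                tibble(pair_id = "pair", genome_a = "a", genome_b = "b"),
                max_shift = max_shift, unstable_min_delta = unstable_min_delta)
}

#' Per-pathway instability proportions for genome pairs
#'
#' For every pair and pathway, the proportion of pathway genes whose region
#' carries an unstable repeat, and the proportion with an orphan repeat. The
#' denominator is the number of pathway genes in the analyzed gene universe
#' (not only repeat-bearing genes).
#'
#' @inheritParams pair_profiles
#' @param pathways Named list of gene-id vectors.
#' @param universe Character vector of all analyzed genes; pathway genes
#'   outside it are dropped from the denominator.
#' @param region Region kind to profile (default promoter, as in the
#'   pathway-level promoter analyses).
#' @return Tibble: `pair_id`, `pair_class`, `msi`, `pathway`, `n_genes`,
#'   `prop_unstable`, `prop_orphan`.
#' @export
pathway_profiles <- function(repeats, pairs, pathways, universe,
                             region = "promoter", max_shift = 50,
                             unstable_min_delta = 1) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  repeats <- repeats[repeats$region == region, ]
  out <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pw <- intersect(pathways[[i]], universe)
    if (length(pw) == 0L) abort(sprintf("pathway %s has no genes in the universe.",
                                        names(pathways)[i]))
    prof <- pair_profiles(repeats[repeats$gene_id %in% pw, ], pairs,
                          max_shift = max_shift,
                          unstable_min_delta = unstable_min_delta)
    if (nrow(prof) == 0L) {
      prof <- tibble(pair_id = pairs$pair_id, pair_class = pairs$pair_class,
                     msi = pairs$msi, n_genes_orphan = 0L, n_genes_unstable = 0L)
    } else {
      prof <- prof[prof$region == region, ]
      # pairs with no repeat calls at all still count with zero proportions
      miss <- setdiff(pairs$pair_id, prof$pair_id)
      if (length(miss)) {
        add <- pairs[pairs$pair_id %in% miss, c("pair_id", "pair_class", "msi")]
        add$n_genes_orphan <- 0L
        add$n_genes_unstable <- 0L
        prof <- bind_rows(prof, add)
      }
    }
    out[[i]] <- tibble(
      pair_id = prof$pair_id, pair_class = prof$pair_class, msi = prof$msi,
      pathway = names(pathways)[i], n_genes = length(pw),
      prop_unstable = prof$n_genes_unstable / length(pw),
      prop_orphan = prof$n_genes_orphan / length(pw)
    )
  }
  arrange(bind_rows(out), .data$pathway, .data$pair_id)
}
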