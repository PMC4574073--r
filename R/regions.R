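# Building per-gene promoter and exon super-transcript regions from a
# reference genome and annotation, and the genome-level QC filter on
# unaligned (N) bases.

require_bioc <- function(pkgs) {
  for (p in pkgs) {
    if (!requireNamespace(p, quietly = TRUE)) {
      abort(sprintf("package `%s` is required for this operation.", p))
    }
  }
}

#' Build promoter and exon super-transcript regions
#'
#' For every gene: the promoter is the `promoter_length` bp immediately
#' upstream of the 5'-most transcription start across the gene's exons
#' (strand-aware, reverse-complemented for minus-strand genes, truncated at
#' the chromosome edge with a warning); the exon super-transcript is the
#' union of all exon intervals, merged and concatenated 5' to 3'. Genes with
#' exons on more than one chromosome (e.g. transposons) are excluded with a
#' warning.
#'
#' @param reference A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param annotation Exon annotation: a `GenomicRanges::GRanges` with a
#'   `gene_id` metadata column, or a path to a GFF3/GTF (exon features with a
#'   `gene_id` attribute) or BED file (name column = gene id). GFF 1-based
#'   coordinates are converted on read; all output coordinates are 0-based
#'   half-open.
#' @param promoter_length Promoter length in bp.
#' @return Tibble with `gene_id`, `region`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open promoter bounds, or super-transcript span),
#'   `n_intervals`, `length`, `truncated`, `sequence` (strand-oriented).
#' @export
build_regions <- function(reference, annotation, promoter_length = 5000L) {
  require_bioc(c("Biostrings", "GenomicRanges", "IRanges", "GenomeInfoDb",
                 "S4Vectors"))
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  gr <- read_annotation(annotation)
  genes <- unique(gr$gene_id)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- gr[gr$gene_id == genes[i]]
    chroms <- unique(as.character(GenomeInfoDb::seqnames(g)))
    if (length(chroms) > 1L) {
      warn(sprintf("gene %s annotated on multiple chromosomes (%s); excluded.",
                   genes[i], paste(chroms, collapse = ", ")))
      next
    }
    strand <- unique(as.character(BiocGenerics::strand(g)))
    strand <- if (all(strand == "-")) "-" else "+"
    chrom_len <- length(reference[[chroms]])
    # merged exon super-transcript (0-based half-open)
    red <- GenomicRanges::reduce(g)
    starts0 <- BiocGenerics::start(red) - 1L
    ends0 <- BiocGenerics::end(red)
    exon_seqs <- lapply(seq_along(red), function(k) {
      as.character(Biostrings::subseq(reference[[chroms]],
                                      starts0[k] + 1L, ends0[k]))
    })
    if (strand == "-") {
      exon_seq <- paste(rev(vapply(exon_seqs, revcomp_chr, character(1))),
                        collapse = "")
    } else {
      exon_seq <- paste(unlist(exon_seqs), collapse = "")
    }
    # promoter upstream of the 5'-most TSS
    if (strand == "+") {
      tss <- min(starts0)
      pstart <- max(0L, tss - promoter_length)
      pend <- tss
      pseq <- if (pend > pstart) {
        as.character(Biostrings::subseq(reference[[chroms]], pstart + 1L, pend))
      } else ""
    } else {
      tss <- max(ends0)
      pstart <- tss
      pend <- min(chrom_len, tss + promoter_length)
      pseq <- if (pend > pstart) {
        revcomp_chr(as.character(Biostrings::subseq(reference[[chroms]],
                                                    pstart + 1L, pend)))
      } else ""
    }
    truncated <- nchar(pseq) < promoter_length
    if (truncated) {
      warn(sprintf("promoter of gene %s truncated at a chromosome edge (%d bp).",
                   genes[i], nchar(pseq)))
    }
    out[[i]] <- tibble(
      gene_id = genes[i],
      region = c("promoter", "exon"),
      chrom = chroms, strand = strand,
      start = c(pstart, min(starts0)),
      end = c(pend, max(ends0)),
      n_intervals = c(1L, length(red)),
      length = c(nchar(pseq), nchar(exon_seq)),
      truncated = c(truncated, FALSE),
      sequence = c(toupper(pseq), toupper(exon_seq))
    )
  }
  bind_rows(out)
}

read_annotation <- function(annotation) {
  if (inherits(annotation, "GRanges")) {
    gr <- annotation
  } else if (is.character(annotation)) {
    require_bioc("rtracklayer")
    gr <- rtracklayer::import(annotation)
    if (grepl("\\.bed$", annotation, ignore.case = TRUE)) {
      gr$gene_id <- gr$name
    } else {
      gr <- gr[gr$type %in% c("exon", "Exon")]
    }
  } else {
    abort("`annotation` must be a GRanges or a GFF3/BED path.")
  }
  if (is.null(gr$gene_id)) abort("annotation lacks a `gene_id` attribute.")
  if (length(gr) == 0L) abort("annotation contains no exon features.")
  gr
}

#' Genome-level QC on unaligned bases
#'
#' A genome fails QC when the fraction of unaligned positions (encoded as
#' `N`) over all its promoter positions, or over all its exon positions,
#' exceeds `max_unaligned` (strictly more than; exactly the threshold
#' passes). Failing genomes are removed from all downstream analyses; a
#' genome missing its regions entirely also fails.
#'
#' @param sequences Tibble with `genome_id`, `gene_id`, `region`,
#'   `sequence`.
#' @param max_unaligned Maximum tolerated N fraction (default 0.10).
#' @return List with `passing` (character vector of genome ids) and `qc`
#'   (tibble: `genome_id`, `fraction_unaligned_promoters`,
#'   `fraction_unaligned_exons`, `pass`).
#' @export
qc_genomes <- function(sequences, max_unaligned = 0.10) {
  stopifnot(all(c("genome_id", "region", "sequence") %in% names(sequences)))
  qc <- sequences |>
    mutate(n_count = stringr::str_count(.data$sequence, "N"),
           len = nchar(.data$sequence)) |>
    group_by(.data$genome_id, .data$region) |>
    summarise(frac = sum(.data$n_count) / sum(.data$len), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "frac")
  for (col in c("promoter", "exon")) {
    if (!col %in% names(qc)) qc[[col]] <- NA_real_
  }
  qc <- tibble(
    genome_id = qc$genome_id,
    fraction_unaligned_promoters = qc$promoter,
    fraction_unaligned_exons = qc$exon
  )
  qc$pass <- !is.na(qc$fraction_unaligned_promoters) &
    !is.na(qc$fraction_unaligned_exons) &
    qc$fraction_unaligned_promoters <= max_unaligned &
    qc$fraction_unaligned_exons <= max_unaligned
  list(passing = qc$genome_id[qc$pass], qc = qc)
}
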