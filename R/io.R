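# File formats: per-genome region FASTA, sample sheet / truth / calls /
# matrix / profile / result TSVs, pathway sets (two-column TSV or GMT), and
# the pipeline configuration (YAML key-value file).

tool_version <- function() {
  as.character(utils::packageVersion("repeatcohort"))
}

config_hash <- function(config) {
  # hash the scientific configuration only, not filesystem paths
  cfg <- unclass_config(config)
  cfg$paths <- NULL
  rlang::hash(cfg)
}

#' Write a TSV with a provenance comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Optional config object; its hash is recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, config = NULL) {
  hdr <- sprintf("# repeatcohort %s%s", tool_version(),
                 if (!is.null(config)) paste0(" config_hash=", config_hash(config))
                 else "")
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path Input path.
#' @return Tibble.
#' @export
read_tsv_commented <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write per-genome region FASTA files
#'
#' One FASTA file per genome, record ids `geneID|region_kind`.
#'
#' @param sequences Tibble with `genome_id`, `gene_id`, `region`,
#'   `sequence`.
#' @param dir Output directory (created if needed).
#' @return Tibble with `genome_id` and `path`.
#' @export
write_genome_fasta <- function(sequences, dir) {
  require_bioc("Biostrings")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- unique(sequences$genome_id)
  paths <- character(length(genomes))
  for (i in seq_along(genomes)) {
    sub <- sequences[sequences$genome_id == genomes[i], ]
    set <- Biostrings::DNAStringSet(sub$sequence)
    names(set) <- paste0(sub$gene_id, "|", sub$region)
    paths[i] <- file.path(dir, paste0(genomes[i], ".fasta"))
    Biostrings::writeXStringSet(set, paths[i])
  }
  tibble(genome_id = genomes, path = paths)
}

#' Read per-genome region FASTA files
#'
#' @param paths FASTA paths; the genome id defaults to the file name without
#'   extension.
#' @param genome_ids Optional explicit genome ids.
#' @return Tibble with `genome_id`, `gene_id`, `region`, `sequence`.
#' @export
read_genome_fasta <- function(paths, genome_ids = NULL) {
  require_bioc("Biostrings")
  genome_ids <- genome_ids %||% sub("\\.(fa|fasta)$", "", basename(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) abort(sprintf("missing FASTA file: %s", paths[i]))
    set <- Biostrings::readDNAStringSet(paths[i])
    ids <- strsplit(names(set), "|", fixed = TRUE)
    out[[i]] <- tibble(
      genome_id = genome_ids[i],
      gene_id = vapply(ids, `[[`, character(1), 1L),
      region = vapply(ids, `[[`, character(1), 2L),
      sequence = unname(as.character(set))
    )
  }
  bind_rows(out)
}

#' Read pathway gene sets
#'
#' Accepts a two-column TSV (`pathway`, `gene`, with or without header) or a
#' GMT file (pathway, description, genes...).
#'
#' @param path Input path.
#' @return Named list of gene-id vectors.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing pathway file: %s", path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(out) <- vapply(parts, `[[`, character(1), 1L)
    return(out)
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_names = c("pathway", "gene"))
  if (identical(unname(tolower(unlist(df[1, ]))), c("pathway", "gene"))) {
    df <- df[-1, ]
  }
  split(df$gene, df$pathway)
}

#' Read / write the pipeline configuration
#'
#' The configuration is a YAML key-value file with top-level sections
#' `paths`, `detection`, `matching`, `qc`, `statistics`, `simulation`, and
#' scalar `seed` / `log_level`. Unknown keys are rejected; missing sections
#' fall back to package defaults. The object round-trips through
#' serialization unchanged.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list with `detection` ([detection_params()])
#'   and `simulation` ([sim_config()]) instantiated.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing config file: %s", path))
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` (or plain list) to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path, precision = 15L)
  invisible(path)
}

unclass_config <- function(config) {
  config <- unclass(config)
  config$detection <- unclass(config$detection)
  config$simulation <- unclass(config$simulation)
  config
}

as_pipeline_config <- function(raw) {
  known <- c("paths", "detection", "matching", "qc", "statistics",
             "simulation", "seed", "log_level")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  }
  seed <- raw$seed %||% 1L
  sim <- raw$simulation %||% list()
  if (is.null(sim$seed)) sim$seed <- seed
  cfg <- list(
    paths = raw$paths %||% list(),
    detection = do.call(detection_params, raw$detection %||% list()),
    matching = modifyList(list(max_shift = 50, unstable_min_delta = 1,
                               match_revcomp = FALSE),
                          raw$matching %||% list()),
    qc = modifyList(list(max_unaligned = 0.10), raw$qc %||% list()),
    statistics = modifyList(list(alpha = 0.05, wrs_exact_max_n = 8L,
                                 wsr_exact_max_n = 25L),
                            raw$statistics %||% list()),
    simulation = do.call(sim_config, sim),
    seed = as.integer(seed),
    log_level = raw$log_level %||% "info"
  )
  structure(cfg, class = "pipeline_config")
}

#' Default pipeline configuration
#'
#' @param outdir Output directory recorded in `paths`.
#' @param ... Overrides passed to [sim_config()].
#' @param seed Seed for both the simulation and the statistics stages.
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(outdir = "repeatcohort_out", seed = 1L, ...) {
  as_pipeline_config(list(
    paths = list(outdir = outdir),
    simulation = c(list(seed = seed), list(...)),
    seed = seed
  ))
}
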