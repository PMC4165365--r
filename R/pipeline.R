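# pipeline: configuration object and the detect -> quantify -> catalog
# orchestration.

#' Pipeline configuration
#'
#' All thresholds of the discovery/quantification pipeline with their
#' defaults; any can be overridden by name.  The config is serialized
#' alongside outputs for provenance.
#'
#' @param ... named overrides (unknown names are an error).
#' @return a named list of class `circ_config`.
#' @export
circ_config <- function(...) {
  cfg <- list(
    min_reads = 2L,        # junction support within a sample
    min_fraction = 0.10,   # catalog circular-fraction threshold
    min_samples = 2L,      # ... in at least this many samples
    max_span = 100000L,    # genomic span limit for a junction (nt)
    anchor_min = 20L,      # minimum exact split-segment length (nt)
    probe_len = 20L,       # quantification probe length (nt)
    window = 10L,          # splice-signal flanking window (nt)
    shift_max = 5L,        # breakpoint shift search range (nt)
    retention_window = 200L,  # intron-retention mate window (nt)
    maxlen_trans = 400L,   # trans-splicing test length cutoff (nt)
    cohorts = 1000L,       # permutation cohorts
    min_fpkm = 0.1,        # expressed-gene threshold
    max_mismatches = 2L,   # linear-pass mismatch allowance
    seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stopf("unknown config option(s): %s", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$min_reads > 0, cfg$min_fraction > 0, cfg$min_samples > 0,
            cfg$max_span > 0, cfg$probe_len > 0)
  structure(cfg, class = c("circ_config", "list"))
}

#' Run the discovery and quantification pipeline
#'
#' Stages, in order: PCR-duplicate collapse and linear pre-filter (per
#' sample), split alignment of unmapped reads, splice-signal refinement,
#' candidate calling (support >= `min_reads` within a sample), junction
#' probe counting over the full library, the catalog filter (GT-AG and
#' fraction >= `min_fraction` in >= `min_samples` samples) and catalog
#' assembly with exon models.  Deterministic given inputs and config.
#'
#' @param genome a `circ_genome`.
#' @param reads read data frame (all samples; `sample_id` column).
#' @param annotation optional `circ_annot` for exon models / classes.
#' @param config a [circ_config()].
#' @param out_dir optional directory: writes `candidates.tsv`,
#'   `counts.tsv`, `catalog.tsv` (+ BED12) and `config.tsv`.
#' @return list: `candidates`, `counts`, `catalog` (filtered junctions),
#'   `catalog_table`, `high_fraction`, `prefilter`.
#' @export
run_pipeline <- function(genome, reads, annotation = NULL,
                         config = circ_config(), out_dir = NULL) {
  stopifnot(inherits(genome, "circ_genome"), nrow(reads) > 0)
  pf <- linear_prefilter(reads, genome, max_mismatches = config$max_mismatches)
  alns <- find_split_alignments(pf$unmapped, genome,
                                anchor_min = config$anchor_min,
                                max_span = config$max_span)
  refined <- refine_splice_signal(alns, genome, window = config$window,
                                  shift_max = config$shift_max)
  cand <- call_candidates(refined, min_reads = config$min_reads)
  counts <- if (nrow(cand) > 0)
    count_junction_reads(cand, reads, genome, probe_len = config$probe_len)
  else NULL
  if (!is.null(counts)) {
    fl <- catalog_filter(cand, counts, min_fraction = config$min_fraction,
                         min_samples = config$min_samples)
    cat_tab <- build_catalog(fl$catalog, counts, annotation = annotation)
  } else {
    fl <- list(catalog = cand, high_fraction = character(0))
    cat_tab <- build_catalog(cand, data.frame(junction_id = character(0),
                                              sample_id = character(0),
                                              fraction = numeric(0)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cand, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(counts))
      utils::write.table(counts, file.path(out_dir, "counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_catalog(cat_tab, file.path(out_dir, "catalog.tsv"))
    utils::write.table(
      data.frame(option = names(config), value = unlist(lapply(config, as.character))),
      file.path(out_dir, "config.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(candidates = cand, counts = counts, catalog = fl$catalog,
       catalog_table = cat_tab, high_fraction = fl$high_fraction,
       prefilter = pf)
}
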