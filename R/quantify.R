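# quantify: junction probe counting, circular fractions, FPKM, abundance
# inference, catalog filters, exon-model and annotation-class assignment.

#' Circular fraction from junction counts
#'
#' `n_junction / (n_donor + n_acceptor - n_junction + 1)`: the share of a
#' locus's junction-informative reads that span the back-spliced junction,
#' with a +1 pseudocount in the denominator.  Vectorized; validates the
#' containment invariant `n_junction <= min(n_donor, n_acceptor)` (a
#' junction-spanning read contains both probes).
#'
#' @param n_donor,n_acceptor,n_junction non-negative integer counts.
#' @return numeric vector in `[0, 1)`.
#' @export
#' @examples
#' circular_fraction(12, 9, 5)   # 5/17
circular_fraction <- function(n_donor, n_acceptor, n_junction) {
  stopifnot(all(n_donor >= 0), all(n_acceptor >= 0), all(n_junction >= 0),
            all(n_junction <= n_donor), all(n_junction <= n_acceptor))
  n_junction / (n_donor + n_acceptor - n_junction + 1)
}

#' Junction probes for quantification
#'
#' The donor probe is the last `probe_len` exonic nt ending at the donor
#' end, the acceptor probe the first `probe_len` exonic nt from the acceptor
#' start, both in transcript orientation; the junction word is the
#' back-spliced concatenation donor-probe || acceptor-probe (reading along
#' the circle).  With an exon model the probes come from the spliced circle
#' sequence; without one they are genomic flanks.  Probes are truncated with
#' a warning when the circle is shorter than the probe.
#'
#' @param junction one-row junction data frame (`chrom`, `strand`,
#'   `acceptor_start`, `donor_end`).
#' @param genome a `circ_genome`.
#' @param exons optional exon data frame (`start`, `end`, forward coords)
#'   restricted to the circle.
#' @param probe_len probe length (nt).
#' @return list with `donor`, `acceptor`, `junction` strings and `truncated`
#'   flag.
#' @export
junction_probes <- function(junction, genome, exons = NULL, probe_len = 20) {
  strand <- if (junction$strand %in% c("+", "-")) junction$strand else "+"
  if (is.null(exons)) {
    exons <- data.frame(start = junction$acceptor_start, end = junction$donor_end)
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  segs <- vapply(seq_len(nrow(exons)), function(i)
    genome_fetch(genome, junction$chrom, exons$start[i], exons$end[i], "+"),
    character(1))
  circ <- paste(segs, collapse = "")
  if (strand == "-") circ <- revcomp_dna(circ)
  truncated <- nchar(circ) < probe_len
  p <- min(probe_len, nchar(circ))
  if (truncated)
    warnf("circle at %s:%d-%d shorter than probe; probes truncated to %d nt",
          junction$chrom, junction$acceptor_start, junction$donor_end, p)
  donor <- substr(circ, nchar(circ) - p + 1L, nchar(circ))
  acceptor <- substr(circ, 1L, p)
  list(donor = donor, acceptor = acceptor,
       junction = paste0(donor, acceptor), truncated = truncated)
}

#' Count junction-informative reads
#'
#' For each junction and sample, counts reads that contain the donor probe
#' with at least `probe_len` read nt remaining 3' of it (`n_donor`: "enough
#' sequence space for the other sequence"), reads containing the acceptor
#' probe with `probe_len` nt remaining 5' of it (`n_acceptor`), and reads
#' containing the full back-spliced junction word (`n_junction`).  Matching
#' is exact substring; both read orientations are tried; each read counts at
#' most once per tally.
#'
#' @param junctions junction data frame (requires `junction_id`, `chrom`,
#'   `strand`, `acceptor_start`, `donor_end`).
#' @param reads read data frame.
#' @param genome a `circ_genome`.
#' @param probe_len probe length.
#' @param exon_models optional named list (by `junction_id`) of circle exon
#'   data frames passed to [junction_probes()].
#' @return long data frame: `junction_id`, `sample_id`, `n_donor`,
#'   `n_acceptor`, `n_junction`, `fraction`.
#' @export
count_junction_reads <- function(junctions, reads, genome, probe_len = 20,
                                 exon_models = NULL) {
  samples <- sort(unique(reads$sample_id))
  seqs <- reads$seq
  rcs <- revcomp_dna(seqs)
  len <- nchar(seqs)
  sidx <- split(seq_along(seqs), reads$sample_id)
  out <- vector("list", nrow(junctions) * length(samples))
  k <- 0L
  space_ok_3p <- function(probe) {
    # first occurrence minimizes the end position, so it suffices to test it
    l1 <- stringi::stri_locate_first_fixed(seqs, probe)[, 2]
    l2 <- stringi::stri_locate_first_fixed(rcs, probe)[, 2]
    (!is.na(l1) & (len - l1) >= probe_len) | (!is.na(l2) & (len - l2) >= probe_len)
  }
  space_ok_5p <- function(probe) {
    l1 <- stringi::stri_locate_last_fixed(seqs, probe)[, 1]
    l2 <- stringi::stri_locate_last_fixed(rcs, probe)[, 1]
    (!is.na(l1) & (l1 - 1L) >= probe_len) | (!is.na(l2) & (l2 - 1L) >= probe_len)
  }
  for (i in seq_len(nrow(junctions))) {
    jid <- junctions$junction_id[i]
    pr <- junction_probes(junctions[i, , drop = FALSE], genome,
                          exons = exon_models[[jid]], probe_len = probe_len)
    d_ok <- space_ok_3p(pr$donor)
    a_ok <- space_ok_5p(pr$acceptor)
    j_ok <- stringi::stri_detect_fixed(seqs, pr$junction) |
            stringi::stri_detect_fixed(rcs, pr$junction)
    for (sm in samples) {
      ii <- sidx[[sm]]
      k <- k + 1L
      out[[k]] <- data.frame(
        junction_id = jid, sample_id = sm,
        n_donor = sum(d_ok[ii]), n_acceptor = sum(a_ok[ii]),
        n_junction = sum(j_ok[ii]), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$fraction <- circular_fraction(res$n_donor, res$n_acceptor, res$n_junction)
  res
}

#' Gene-level FPKM from mapped fragments
#'
#' A fragment is assigned to a gene when either mate's full-length placement
#' overlaps the union of the gene's exons; fragments overlapping several
#' genes count for each.  FPKM = fragments / (exonic kb x mapped fragments /
#' 1e6), per sample.
#'
#' @param annotation a `circ_annot` table.
#' @param placements placement data frame from [linear_prefilter()]
#'   (`read_id`, `sample_id`, `chrom`, `start`, `end`).
#' @return data frame `gene_id`, `sample_id`, `fragments`, `exonic_kb`,
#'   `fpkm`.
#' @export
gene_fpkm <- function(annotation, placements) {
  if (nrow(placements) == 0L) stopf("no mapped fragments: FPKM undefined")
  ex <- GenomicRanges::reduce(S4Vectors::split(
    GenomicRanges::GRanges(annotation$chrom,
                           IRanges::IRanges(annotation$start + 1L, annotation$end)),
    annotation$gene_id))
  exonic_kb <- sum(GenomicRanges::width(ex)) / 1000
  out <- list()
  for (sm in unique(placements$sample_id)) {
    pl <- placements[placements$sample_id == sm, , drop = FALSE]
    total <- length(unique(pl$read_id))
    if (total == 0L) stopf("sample %s has zero mapped fragments", sm)
    gr <- GenomicRanges::GRanges(pl$chrom, IRanges::IRanges(pl$start + 1L, pl$end))
    ov <- GenomicRanges::findOverlaps(gr, ex)
    frag_gene <- unique(data.frame(frag = pl$read_id[S4Vectors::queryHits(ov)],
                                   gene = names(ex)[S4Vectors::subjectHits(ov)]))
    counts <- table(factor(frag_gene$gene, levels = names(ex)))
    out[[sm]] <- data.frame(
      gene_id = names(ex), sample_id = sm,
      fragments = as.integer(counts),
      exonic_kb = as.numeric(exonic_kb),
      fpkm = as.numeric(counts) / (as.numeric(exonic_kb) * total / 1e6),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inferred circRNA abundance
#'
#' The inferred FPKM of a circRNA is its circular fraction times the FPKM of
#' the cognate gene (which includes both circular and linear isoforms); its
#' read weight is that product times the circRNA exonic length.
#'
#' @param fraction circular fraction(s).
#' @param gene_fpkm cognate gene FPKM(s).
#' @param exonic_length circRNA exonic length(s), nt.
#' @return data frame `inferred_fpkm`, `circ_read_weight`.
#' @export
infer_abundance <- function(fraction, gene_fpkm, exonic_length = NA_real_) {
  data.frame(inferred_fpkm = fraction * gene_fpkm,
             circ_read_weight = fraction * gene_fpkm * exonic_length)
}

#' Share of the transcriptome attributed to circRNAs
#'
#' Sum of circRNA read weights (fraction x gene FPKM x exonic length) over
#' the sum of gene FPKM x gene exonic length for expressed protein-coding
#' genes (FPKM >= `min_fpkm`).
#'
#' @param circ_weights circRNA read weights (one per circRNA).
#' @param gene_fpkm,gene_exonic_len per-gene FPKM and exonic length (nt).
#' @param gene_type per-gene type (only `protein_coding` genes enter the
#'   denominator).
#' @param min_fpkm expressed-gene threshold.
#' @return scalar share in `[0, 1]` (of exon-mapping reads).
#' @export
transcriptome_share <- function(circ_weights, gene_fpkm, gene_exonic_len,
                                gene_type = "protein_coding", min_fpkm = 0.1) {
  gene_type <- rep_len(gene_type, length(gene_fpkm))
  keep <- gene_fpkm >= min_fpkm & gene_type == "protein_coding"
  denom <- sum(gene_fpkm[keep] * gene_exonic_len[keep])
  if (denom <= 0) return(NA_real_)
  sum(circ_weights) / denom
}

#' Catalog filter
#'
#' Keeps GT-AG junctions whose circular fraction is at least `min_fraction`
#' in at least `min_samples` samples.  Also reports the high-fraction
#' sublist: junctions with fraction >= 0.5 in most (> half) of the samples
#' in which their transcript isoforms were detected (donor or acceptor
#' availability >= 1 read).
#'
#' @param junctions candidate data frame (needs `junction_id`,
#'   `signal_class`).
#' @param counts long count table from [count_junction_reads()].
#' @param min_fraction,min_samples catalog thresholds.
#' @return list: `catalog` (kept junctions), `high_fraction` (junction ids),
#'   `n_pass_samples` per junction.
#' @export
catalog_filter <- function(junctions, counts, min_fraction = 0.10, min_samples = 2) {
  np <- tapply(counts$fraction >= min_fraction, counts$junction_id, sum)
  det <- tapply(counts$n_donor + counts$n_acceptor >= 1, counts$junction_id, sum)
  hi <- tapply(counts$fraction >= 0.5 & (counts$n_donor + counts$n_acceptor >= 1),
               counts$junction_id, sum)
  n_pass <- as.integer(np[junctions$junction_id])
  n_pass[is.na(n_pass)] <- 0L
  keep <- junctions$signal_class == "GT-AG" & n_pass >= min_samples
  kept <- junctions[keep, , drop = FALSE]
  rownames(kept) <- NULL
  high <- names(hi)[!is.na(hi) & !is.na(det) & det > 0 & hi > det / 2]
  high <- intersect(high, kept$junction_id)
  list(catalog = kept, high_fraction = high,
       n_pass_samples = setNames(n_pass, junctions$junction_id))
}

#' Assign an exon model and annotation class to a junction
#'
#' Chooses a transcript whose exon boundaries include the acceptor start (as
#' an exon start) and the donor end (as an exon end); the circRNA exons are
#' that transcript's exons within the junction interval.  Ties go to the
#' transcript with most exons inside the interval, then the longest.  When
#' no transcript matches both boundaries the model is a single exon spanning
#' the interval.  The annotation class reflects CDS/UTR content of the
#' chosen exons, or antisense / lincRNA / intergenic overlap status.
#'
#' @param junction one-row junction data frame.
#' @param annotation a `circ_annot` table.
#' @return list: `exons` (data frame, forward coords), `transcript_id` (NA
#'   if unmatched), `annotation_class`, `exonic_length`.
#' @export
assign_exon_model <- function(junction, annotation) {
  acc <- junction$acceptor_start; don <- junction$donor_end
  ann <- annotation[annotation$chrom == junction$chrom, , drop = FALSE]
  same_strand <- if (junction$strand %in% c("+", "-")) ann$strand == junction$strand
                 else rep(TRUE, nrow(ann))
  sense <- ann[same_strand, , drop = FALSE]
  models <- if (nrow(sense)) split(sense, sense$transcript_id) else list()
  match_ok <- vapply(models, function(m)
    any(m$start == acc) && any(m$end == don), logical(1))
  tid <- NA_character_
  if (any(match_ok)) {
    cand <- models[match_ok]
    n_in <- vapply(cand, function(m) sum(m$start >= acc & m$end <= don), integer(1))
    tlen <- vapply(cand, function(m) sum(m$end - m$start), integer(1))
    ord <- order(-n_in, -tlen, names(cand))
    tid <- names(cand)[ord[1]]
    m <- cand[[ord[1]]]
    exons <- m[m$start >= acc & m$end <= don, c("start", "end"), drop = FALSE]
    cls <- .annotation_class_cds(m, exons)
  } else {
    exons <- data.frame(start = acc, end = don)
    # classify by overlap
    ov_sense <- nrow(sense) > 0 && any(sense$start < don & sense$end > acc)
    if (ov_sense) {
      hit <- sense[sense$start < don & sense$end > acc, , drop = FALSE]
      m <- split(hit, hit$transcript_id)[[1]]
      cls <- .annotation_class_cds(m, exons)
    } else {
      anti <- ann[!same_strand, , drop = FALSE]
      ov_anti <- nrow(anti) > 0 && any(anti$start < don & anti$end > acc)
      cls <- if (ov_anti) "antisense" else "intergenic"
    }
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  list(exons = exons, transcript_id = tid, annotation_class = cls,
       exonic_length = sum(exons$end - exons$start))
}

# CDS/UTR class of circle exons against a transcript model.
.annotation_class_cds <- function(m, exons) {
  gt <- m$gene_type[1]
  if (!is.na(gt) && gt %in% c("lincRNA", "lncRNA")) return("lincRNA")
  cs <- m$cds_start[1]; ce <- m$cds_end[1]
  if (is.na(cs) || is.na(ce)) {
    if (!is.na(gt) && gt != "protein_coding") return("noncoding-other")
    return("noncoding-other")
  }
  left_utr <- any(exons$start < cs)   # exon bases left of the CDS
  right_utr <- any(exons$end > ce)
  if (identical(m$strand[1], "-")) {  # 5' UTR is genomically right for minus genes
    tmp <- left_utr; left_utr <- right_utr; right_utr <- tmp
  }
  if (left_utr && right_utr) "both-UTR"
  else if (left_utr) "+5'UTR"
  else if (right_utr) "+3'UTR"
  else "CDS-only"
}

#' Build a circRNA catalog table
#'
#' Joins candidate junctions, their exon models and per-sample fractions
#' into the flat catalog serialized by [write_catalog()].
#'
#' @param junctions junction data frame (typically `catalog_filter()$catalog`).
#' @param counts long count table from [count_junction_reads()].
#' @param annotation optional `circ_annot` for exon models and classes.
#' @return catalog data frame: `circ_id`, coordinates, `exon_sizes`,
#'   `exon_starts` (comma strings, circle-relative), `exonic_length`,
#'   `annotation_class`, `frac_<sample>` columns.
#' @export
build_catalog <- function(junctions, counts, annotation = NULL) {
  samples <- sort(unique(counts$sample_id))
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, , drop = FALSE]
    if (!is.null(annotation)) {
      am <- assign_exon_model(j, annotation)
    } else {
      am <- list(exons = data.frame(start = j$acceptor_start, end = j$donor_end),
                 transcript_id = NA_character_, annotation_class = "intergenic",
                 exonic_length = j$donor_end - j$acceptor_start)
    }
    fr <- setNames(rep(NA_real_, length(samples)), samples)
    cc <- counts[counts$junction_id == j$junction_id, , drop = FALSE]
    fr[cc$sample_id] <- cc$fraction
    out <- data.frame(
      circ_id = j$junction_id, chrom = j$chrom, strand = j$strand,
      acceptor_start = j$acceptor_start, donor_end = j$donor_end,
      exon_sizes = paste(am$exons$end - am$exons$start, collapse = ","),
      exon_starts = paste(am$exons$start - j$acceptor_start, collapse = ","),
      exonic_length = am$exonic_length,
      annotation_class = am$annotation_class,
      transcript_id = am$transcript_id, stringsAsFactors = FALSE
    )
    for (sm in samples) out[[paste0("frac_", sm)]] <- fr[[sm]]
    out
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circ_id = character(0), chrom = character(0), strand = character(0),
               acceptor_start = integer(0), donor_end = integer(0),
               exon_sizes = character(0), exon_starts = character(0),
               exonic_length = integer(0), annotation_class = character(0),
               transcript_id = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Exon data frame of a catalog row (forward coords).
catalog_exons <- function(record) {
  sizes <- as.integer(strsplit(record$exon_sizes, ",")[[1]])
  starts <- as.integer(strsplit(record$exon_starts, ",")[[1]]) + record$acceptor_start
  data.frame(start = starts, end = starts + sizes)
}
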