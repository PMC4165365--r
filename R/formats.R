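# formats: readers/writers for external formats, one internal coordinate
# convention (0-based half-open, forward strand; strand stored separately).

#' Load a genome from FASTA
#'
#' Sequences are uppercased and names truncated at the first whitespace.
#' The result is a named character vector of class `"circ_genome"`; alphabet
#' is restricted to A/C/G/T/N.
#'
#' @param path path to a FASTA file (gzip transparently supported).
#' @return a `circ_genome` object.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stopf("empty FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) stopf("duplicate chromosome name in %s", path)
  as_genome(setNames(toupper(as.character(dss)), nm))
}

#' Construct a genome object from named sequences
#'
#' @param seqs named character vector of uppercase DNA sequences.
#' @return a `circ_genome` object.
#' @export
as_genome <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("genome sequences must have unique names")
  seqs <- toupper(seqs)
  bad <- stringi::stri_count_charclass(seqs, "[^ACGTN]")
  if (any(bad > 0L)) stopf("genome contains non-ACGTN characters")
  structure(seqs, class = "circ_genome")
}

#' @export
print.circ_genome <- function(x, ...) {
  cat(sprintf("<circ_genome> %d sequence(s), %s nt total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Fetch genomic sequence
#'
#' Coordinates are 0-based half-open on the forward strand; `strand = "-"`
#' returns the reverse complement (i.e. the transcript-orientation sequence).
#'
#' @param genome a `circ_genome`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return character scalar.
#' @export
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stopf("unknown chromosome: %s", chrom)
  n <- nchar(genome[[chrom]])
  if (start < 0 || end > n || start > end)
    stopf("fetch out of bounds: %s:%d-%d (len %d)", chrom, start, end, n)
  s <- substr0(genome[[chrom]], start, end)
  if (identical(strand, "-")) revcomp_dna(s) else s
}

new_annotation <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(df)))
  if (!"gene_type" %in% names(df)) df$gene_type <- "protein_coding"
  if (!"cds_start" %in% names(df)) df$cds_start <- NA_integer_
  if (!"cds_end" %in% names(df)) df$cds_end <- NA_integer_
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$cds_start <- as.integer(df$cds_start); df$cds_end <- as.integer(df$cds_end)
  stopifnot(all(df$strand %in% c("+", "-")), all(df$end > df$start))
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("circ_annot", "data.frame")
  df
}

#' Load exon annotation from GTF or BED12
#'
#' GTF `exon` features (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED12 blocks are used as-is.  GTF `CDS`
#' features, when present, define a per-transcript CDS span used for
#' annotation classes and codon-frame assignment.  Transcripts with zero
#' exons are skipped with a warning.
#'
#' @param path path to a `.gtf` or `.bed` file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return a `circ_annot` data frame with one row per exon and columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`,
#'   `gene_type`, `cds_start`, `cds_end`.
#' @export
load_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stopf("no exon features in %s", path)
    out <- data.frame(
      gene_id = as.character(ex$gene_id),
      transcript_id = as.character(ex$transcript_id),
      chrom = as.character(ex$seqnames),
      strand = as.character(ex$strand),
      start = ex$start - 1L,   # GTF 1-based inclusive -> 0-based half-open
      end = ex$end,
      gene_type = if ("gene_type" %in% names(ex)) as.character(ex$gene_type)
                  else if ("gene_biotype" %in% names(ex)) as.character(ex$gene_biotype)
                  else "protein_coding",
      stringsAsFactors = FALSE
    )
    cds <- df[df$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      cs <- tapply(cds$start - 1L, as.character(cds$transcript_id), min)
      ce <- tapply(cds$end, as.character(cds$transcript_id), max)
      out$cds_start <- as.integer(cs[out$transcript_id])
      out$cds_end <- as.integer(ce[out$transcript_id])
    }
    new_annotation(out)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stopf("no records in %s", path)
    blocks <- if (!is.null(gr$blocks)) gr$blocks else
      IRanges::IRangesList(lapply(GenomicRanges::width(gr), function(w) IRanges::IRanges(1L, w)))
    rows <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      cs <- GenomicRanges::start(gr)[i] - 1L  # back to 0-based chromStart
      nm <- if (!is.null(gr$name)) gr$name[i] else sprintf("rec%d", i)
      data.frame(
        gene_id = nm, transcript_id = nm,
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        start = cs + IRanges::start(b) - 1L,
        end = cs + IRanges::end(b),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    new_annotation(out)
  }
}

# Split an annotation into per-transcript exon models (list of data.frames).
transcript_models <- function(annot) {
  split(as.data.frame(annot), annot$transcript_id)
}

# GRanges of exons (for overlap machinery).
annot_granges <- function(annot) {
  GenomicRanges::GRanges(
    seqnames = annot$chrom,
    ranges = IRanges::IRanges(start = annot$start + 1L, end = annot$end),
    strand = annot$strand,
    gene_id = annot$gene_id, transcript_id = annot$transcript_id
  )
}

#' Write a circRNA catalog to TSV (with BED12 companion)
#'
#' One row per circRNA: id, coordinates, exon blocks (comma-separated sizes
#' and circle-relative starts), exonic length, annotation class and one
#' `frac_<sample>` column per sample.  A BED12 companion with the exon block
#' structure is written next to the TSV (`<path>.bed`) unless `bed = FALSE`.
#'
#' @param catalog a catalog data frame as produced by [build_catalog()].
#' @param path output TSV path.
#' @param bed also write the BED12 companion.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, bed = TRUE) {
  df <- as.data.frame(catalog)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed && nrow(df) > 0L) {
    sizes <- df$exon_sizes
    starts <- df$exon_starts
    bed12 <- data.frame(
      chrom = df$chrom, start = df$acceptor_start, end = df$donor_end,
      name = df$circ_id, score = 0L, strand = df$strand,
      thickStart = df$acceptor_start, thickEnd = df$donor_end,
      rgb = "0,0,0",
      blockCount = lengths(strsplit(sizes, ",")),
      blockSizes = sizes, blockStarts = starts
    )
    utils::write.table(bed12, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a circRNA catalog written by [write_catalog()]
#' @param path TSV path.
#' @return catalog data frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(exon_sizes = "character",
                                         exon_starts = "character"))
  df
}

#' Read a paired FASTQ library
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2 (`path2` may be `NULL`
#'   for single-end data); gzip supported.
#' @param sample_id sample label attached to every read.
#' @return a read data frame with columns `read_id`, `mate`, `seq`,
#'   `sample_id`.
#' @export
read_fastq_pair <- function(path1, path2 = NULL, sample_id = "s1") {
  rd <- function(p, mate) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    data.frame(
      read_id = sub("/[12]$", "", sub("\\s.*$", "", names(x))),
      mate = mate, seq = toupper(as.character(x)),
      sample_id = sample_id, stringsAsFactors = FALSE
    )
  }
  out <- rd(path1, 1L)
  if (!is.null(path2)) out <- rbind(out, rd(path2, 2L))
  rownames(out) <- NULL
  out
}

#' Write reads as a FASTQ pair (`/1`, `/2` read-name suffixes)
#'
#' @param reads read data frame (`read_id`, `mate`, `seq`).
#' @param path1,path2 output FASTQ paths; `path2` ignored when all reads are
#'   mate 1.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(reads, path1, path2 = NULL) {
  wr <- function(df, p, suffix) {
    if (is.null(p)) return(invisible(NULL))
    qual <- strrep("I", nchar(df$seq))
    lines <- as.vector(rbind(paste0("@", df$read_id, suffix),
                             df$seq, "+", qual))
    writeLines(lines, p)
  }
  wr(reads[reads$mate == 1L, , drop = FALSE], path1, "/1")
  if (any(reads$mate == 2L)) wr(reads[reads$mate == 2L, , drop = FALSE], path2, "/2")
  invisible(c(path1, path2))
}

#' Load a per-base conservation track from bedGraph
#'
#' @param path bedGraph path (0-based half-open intervals, `score` column).
#' @return data frame `chrom`, `start`, `end`, `score` (class
#'   `"circ_track"`); use [track_values()] to expand to per-base scores.
#' @export
load_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score), stringsAsFactors = FALSE
  )
  class(out) <- c("circ_track", "data.frame")
  out
}

#' Per-base values of a conservation track over an interval
#'
#' Positions without coverage are `NA`.  Scores are returned in forward
#' genomic orientation.
#'
#' @param track a track data frame (see [load_track()]).
#' @param chrom,start,end 0-based half-open query interval.
#' @return numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  v <- rep(NA_real_, end - start)
  tr <- track[track$chrom == chrom & track$end > start & track$start < end, , drop = FALSE]
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      a <- max(tr$start[i], start) - start
      b <- min(tr$end[i], end) - start
      if (b > a) v[(a + 1L):b] <- tr$score[i]
    }
  }
  v
}
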