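# mates: mate-read analyses -- trans-splicing discrimination, intron
# retention, poly(A)-selection comparison.

# Junction-spanning read ids for one junction (reads containing the
# back-spliced junction word in either orientation).
junction_spanning_reads <- function(junction, reads, genome, probe_len = 20,
                                    exons = NULL) {
  pr <- junction_probes(junction, genome, exons = exons, probe_len = probe_len)
  hit <- stringi::stri_detect_fixed(reads$seq, pr$junction) |
         stringi::stri_detect_fixed(revcomp_dna(reads$seq), pr$junction)
  unique(reads$read_id[hit])
}

#' Place and categorize the mates of junction-spanning reads
#'
#' Identifies reads spanning a junction's back-spliced word, maps each one's
#' mate full-length (contiguous, up to `max_mismatch` substitutions, both
#' orientations; ambiguous multi-placement mates are discarded) and assigns
#' exactly one category: `upstream_of_acceptor` / `downstream_of_donor`
#' (strictly outside the circle interval, labels on the annotated strand --
#' the trans-splicing signal), `inside_circle` (overlapping the junction's
#' own acceptor/donor exons), `neighbor_exon` (another exon inside the
#' circle), `intron` (inside the circle, intronic only), or `other`.
#'
#' @param junction one-row junction data frame.
#' @param reads paired read data frame.
#' @param genome a `circ_genome`.
#' @param exons exon model of the circle (forward coords); single-exon span
#'   by default.
#' @param probe_len junction probe length.
#' @param max_mismatch mate mapping mismatch allowance.
#' @return data frame `read_id`, `chrom`, `start`, `end`, `category`,
#'   `dist_acceptor`, `dist_donor` (signed genomic distances from the mate
#'   start/end to the junction boundaries).
#' @export
mate_placements <- function(junction, reads, genome, exons = NULL,
                            probe_len = 20, max_mismatch = 2) {
  if (!any(reads$mate == 2L)) stopf("mate analysis requires paired-end data")
  if (is.null(exons))
    exons <- data.frame(start = junction$acceptor_start, end = junction$donor_end)
  span_ids <- junction_spanning_reads(junction, reads, genome,
                                      probe_len = probe_len, exons = exons)
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      category = character(0), dist_acceptor = integer(0),
                      dist_donor = integer(0), stringsAsFactors = FALSE)
  if (length(span_ids) == 0L) return(empty)
  # the mate of a junction-spanning end: the other mate of the same fragment,
  # unless that end itself spans the junction word
  pr <- junction_probes(junction, genome, exons = exons, probe_len = probe_len)
  cand <- reads[reads$read_id %in% span_ids, , drop = FALSE]
  is_span <- stringi::stri_detect_fixed(cand$seq, pr$junction) |
             stringi::stri_detect_fixed(revcomp_dna(cand$seq), pr$junction)
  mates <- cand[!is_span, , drop = FALSE]
  if (nrow(mates) == 0L) return(empty)
  pl <- map_seqs_linear(mates$seq, genome, max_mismatch = max_mismatch)
  nh <- attr(pl, "n_hits")
  pl <- pl[nh[pl$seq_idx] == 1L, , drop = FALSE]  # unique placements only
  if (nrow(pl) == 0L) return(empty)
  acc <- junction$acceptor_start; don <- junction$donor_end
  minus <- identical(junction$strand, "-")
  own <- exons[c(1L, nrow(exons)), , drop = FALSE]   # acceptor + donor exons
  categ <- character(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    ch <- pl$chrom[i]; s <- pl$start[i]; e <- pl$end[i]
    if (ch != junction$chrom) { categ[i] <- "other"; next }
    if (e <= acc) {
      categ[i] <- if (minus) "downstream_of_donor" else "upstream_of_acceptor"
    } else if (s >= don) {
      categ[i] <- if (minus) "upstream_of_acceptor" else "downstream_of_donor"
    } else if (s >= acc && e <= don) {
      ov_own <- any(own$start < e & own$end > s)
      ov_nb <- any(exons$start < e & exons$end > s &
                     !(exons$start %in% own$start & exons$end %in% own$end))
      categ[i] <- if (ov_own) "inside_circle"
                  else if (ov_nb) "neighbor_exon"
                  else "intron"
    } else categ[i] <- "other"
  }
  data.frame(read_id = mates$read_id[pl$seq_idx], chrom = pl$chrom,
             start = pl$start, end = pl$end, category = categ,
             dist_acceptor = pl$start - acc, dist_donor = pl$end - don,
             stringsAsFactors = FALSE)
}

#' Trans-splicing test from mate reads
#'
#' For circRNAs shorter than `max_len` exonic nt (the fragment size bounds
#' how far a mate can reach), mates of junction-spanning reads that map
#' strictly upstream of the back-spliced acceptor or strictly downstream of
#' the donor are evidence of a linear trans-spliced product rather than a
#' circle: a circle has no outside.
#'
#' @param catalog catalog data frame (needs `circ_id`, coordinates,
#'   `exonic_length`, exon blocks).
#' @param reads paired read data frame.
#' @param genome a `circ_genome`.
#' @param max_len exonic-length cutoff (nt).
#' @param max_mismatch mate mapping mismatch allowance.
#' @return list: `per_junction` (circ_id, mates mapped, upstream, downstream,
#'   evidence), `placements` (all categorized mates), `total_evidence`.
#' @export
trans_splice_test <- function(catalog, reads, genome, max_len = 400,
                              max_mismatch = 2) {
  keep <- catalog$exonic_length < max_len
  cat2 <- catalog[keep, , drop = FALSE]
  per <- list(); placed <- list()
  for (i in seq_len(nrow(cat2))) {
    rec <- cat2[i, , drop = FALSE]
    j <- data.frame(junction_id = rec$circ_id, chrom = rec$chrom,
                    strand = rec$strand, acceptor_start = rec$acceptor_start,
                    donor_end = rec$donor_end, stringsAsFactors = FALSE)
    mp <- mate_placements(j, reads, genome, exons = catalog_exons(rec),
                          max_mismatch = max_mismatch)
    up <- sum(mp$category == "upstream_of_acceptor")
    dn <- sum(mp$category == "downstream_of_donor")
    per[[i]] <- data.frame(circ_id = rec$circ_id, n_mates = nrow(mp),
                           upstream = up, downstream = dn,
                           evidence = up + dn, stringsAsFactors = FALSE)
    if (nrow(mp)) placed[[length(placed) + 1L]] <- cbind(circ_id = rec$circ_id, mp)
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(circ_id = character(0), n_mates = integer(0),
               upstream = integer(0), downstream = integer(0),
               evidence = integer(0))
  list(per_junction = per,
       placements = if (length(placed)) do.call(rbind, placed) else NULL,
       total_evidence = sum(per$evidence))
}

#' Intron retention within circRNAs
#'
#' Mates of junction-spanning reads that do not map to the junction's own
#' exons are classified exon vs intron within `window`-nt genomic windows
#' downstream of the back-spliced acceptor and upstream of the donor
#' (transcript-oriented).  The retained fraction is intron mates /
#' (intron + neighbor-exon mates); `NA` when no informative mates exist.
#'
#' @param catalog catalog data frame.
#' @param reads paired read data frame.
#' @param genome a `circ_genome`.
#' @param window classification window (nt); matches the mean fragment size.
#' @param max_mismatch mate mapping mismatch allowance.
#' @return list: `retained_fraction`, `n_intron`, `n_exon`, `per_junction`.
#' @export
intron_retention <- function(catalog, reads, genome, window = 200,
                             max_mismatch = 2) {
  n_int <- 0L; n_ex <- 0L; per <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, , drop = FALSE]
    j <- data.frame(junction_id = rec$circ_id, chrom = rec$chrom,
                    strand = rec$strand, acceptor_start = rec$acceptor_start,
                    donor_end = rec$donor_end, stringsAsFactors = FALSE)
    exons <- catalog_exons(rec)
    mp <- mate_placements(j, reads, genome, exons = exons,
                          max_mismatch = max_mismatch)
    # the ~200-nt fragment size confines informative mates to the first
    # intron / neighboring exon from the back-spliced sites; `window` only
    # caps how far into the circle an intron mate may start
    own_edges <- c(exons$end[1], exons$start[nrow(exons)])
    in_win <- mp$start < own_edges[1] + window | mp$end > own_edges[2] - window
    inf <- mp$category %in% c("intron", "neighbor_exon") &
      (mp$category == "neighbor_exon" | in_win)
    ni <- sum(mp$category == "intron" & inf)
    ne <- sum(mp$category == "neighbor_exon" & inf)
    n_int <- n_int + ni; n_ex <- n_ex + ne
    per[[i]] <- data.frame(circ_id = rec$circ_id, n_intron = ni, n_exon = ne,
                           retained_fraction =
                             if (ni + ne > 0) ni / (ni + ne) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  list(retained_fraction = if (n_int + n_ex > 0) n_int / (n_int + n_ex) else NA_real_,
       n_intron = n_int, n_exon = n_ex,
       per_junction = if (length(per)) do.call(rbind, per) else NULL)
}

#' Compare circular fractions between non-poly(A) and poly(A) libraries
#'
#' Poly(A) selection depletes circles (no poly(A) tail) but not linear
#' trans-spliced products, so genuine circRNAs show fraction 0 in the
#' poly(A)-selected library while trans-spliced mimics stay positive in
#' both.
#'
#' @param junctions junction data frame.
#' @param counts_nonpolya,counts_polya count tables from
#'   [count_junction_reads()] on the two libraries.
#' @return list: `pairs` (junction_id, fraction_nonpolya, fraction_polya),
#'   `summary` (detected counts; junctions absent from both are excluded).
#' @export
polya_compare <- function(junctions, counts_nonpolya, counts_polya) {
  agg <- function(cc) {
    nd <- tapply(cc$n_donor, cc$junction_id, sum)
    na_ <- tapply(cc$n_acceptor, cc$junction_id, sum)
    nj <- tapply(cc$n_junction, cc$junction_id, sum)
    data.frame(junction_id = names(nd),
               fraction = circular_fraction(as.numeric(nd), as.numeric(na_),
                                            as.numeric(nj)),
               stringsAsFactors = FALSE)
  }
  a <- agg(counts_nonpolya); b <- agg(counts_polya)
  pairs <- data.frame(
    junction_id = junctions$junction_id,
    fraction_nonpolya = a$fraction[match(junctions$junction_id, a$junction_id)],
    fraction_polya = b$fraction[match(junctions$junction_id, b$junction_id)],
    stringsAsFactors = FALSE
  )
  pairs$fraction_nonpolya[is.na(pairs$fraction_nonpolya)] <- 0
  pairs$fraction_polya[is.na(pairs$fraction_polya)] <- 0
  det_a <- pairs$fraction_nonpolya > 0
  det_b <- pairs$fraction_polya > 0
  pairs <- pairs[det_a | det_b, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       summary = c(nonpolya = sum(pairs$fraction_nonpolya > 0),
                   polya = sum(pairs$fraction_polya > 0),
                   both = sum(pairs$fraction_nonpolya > 0 & pairs$fraction_polya > 0)))
}
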