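# translation: junction probes for ribosome-footprint (RPF) vs RNA-seq
# comparison, paralog-derived false-positive exclusion.

#' Build circular and linear junction probes for the translation test
#'
#' A 20-nt probe is taken across each of three junctions: the circular
#' junction (last 10 exonic nt of the donor exon + first 10 of the acceptor
#' exon, reading along the circle) and the two annotated linear junctions
#' overlapping it (donor exon to its downstream linear partner, upstream
#' linear partner to the acceptor exon).  circRNAs lacking an annotated
#' linear partner at either side (e.g. single-exon genes) are excluded with
#' `NULL`; an exon shorter than a half-probe skips the probe with a warning.
#'
#' @param record one catalog row (needs `transcript_id` assigned).
#' @param annotation a `circ_annot` table.
#' @param genome a `circ_genome`.
#' @param probe_len total probe length (half on each side).
#' @return list `circular`, `linear_donor`, `linear_acceptor`, `circ_id`, or
#'   `NULL` when the circRNA is ineligible.
#' @export
build_probes <- function(record, annotation, genome, probe_len = 20) {
  half <- probe_len %/% 2L
  if (is.na(record$transcript_id)) return(NULL)
  m <- transcript_models(annotation)[[record$transcript_id]]
  if (is.null(m)) return(NULL)
  acc <- record$acceptor_start; don <- record$donor_end
  inside <- which(m$start >= acc & m$end <= don)
  if (length(inside) == 0L) return(NULL)
  strand <- m$strand[1]
  # forward-coordinate neighbors; transcript orientation decides which is the
  # donor-side linear partner
  up <- m[m$end <= acc, , drop = FALSE]     # genomically left of the circle
  dn <- m[m$start >= don, , drop = FALSE]   # genomically right
  left_nb <- if (nrow(up)) up[nrow(up), ] else NULL
  right_nb <- if (nrow(dn)) dn[1L, ] else NULL
  if (is.null(left_nb) || is.null(right_nb)) return(NULL)
  fetch <- function(start, end) genome_fetch(genome, m$chrom[1], start, end, "+")
  exon_tail <- function(e) fetch(e$end - half, e$end)     # forward-left half
  exon_head <- function(e) fetch(e$start, e$start + half)
  ex <- m[inside, , drop = FALSE]
  if (any(ex$end - ex$start < half) ||
      left_nb$end - left_nb$start < half || right_nb$end - right_nb$start < half) {
    warnf("exon shorter than %d nt at %s; probe skipped", half, record$circ_id)
    return(NULL)
  }
  first_ex <- ex[1L, ]; last_ex <- ex[nrow(ex), ]
  if (strand == "+") {
    circular <- paste0(exon_tail(last_ex), exon_head(first_ex))
    linear_donor <- paste0(exon_tail(last_ex), exon_head(right_nb))
    linear_acceptor <- paste0(exon_tail(left_nb), exon_head(first_ex))
  } else {
    # transcript orientation: donor exon is the genomically-left circle exon
    circular <- revcomp_dna(paste0(exon_tail(last_ex), exon_head(first_ex)))
    linear_donor <- revcomp_dna(paste0(exon_tail(left_nb), exon_head(first_ex)))
    linear_acceptor <- revcomp_dna(paste0(exon_tail(last_ex), exon_head(right_nb)))
  }
  list(circ_id = record$circ_id, circular = circular,
       linear_donor = linear_donor, linear_acceptor = linear_acceptor)
}

# Reads containing a probe (either orientation), counted once per read.
.probe_hits <- function(seqs, rcs, probe) {
  sum(stringi::stri_detect_fixed(seqs, probe) |
        stringi::stri_detect_fixed(rcs, probe))
}

#' Count junction probes in a read library
#'
#' Exact substring counts (both orientations, once per read) for the
#' circular and two linear probes, plus the probe-count analog of the
#' circular fraction: circ / (linear_donor + linear_acceptor - circ + 1).
#'
#' @param probes probe set from [build_probes()].
#' @param reads read data frame.
#' @return one-row data frame `circ_id`, `n_linear_donor`, `n_circular`,
#'   `n_linear_acceptor`, `fraction`.
#' @export
probe_counts <- function(probes, reads) {
  seqs <- reads$seq; rcs <- revcomp_dna(seqs)
  nd <- .probe_hits(seqs, rcs, probes$linear_donor)
  nc <- .probe_hits(seqs, rcs, probes$circular)
  na_ <- .probe_hits(seqs, rcs, probes$linear_acceptor)
  data.frame(circ_id = probes$circ_id, n_linear_donor = nd, n_circular = nc,
             n_linear_acceptor = na_,
             fraction = nc / (nd + na_ - nc + 1), stringsAsFactors = FALSE)
}

#' Flag probes at risk of paralog-derived false positives
#'
#' A circular probe is flagged when its 20-mer occurs contiguously in the
#' genome (either orientation) -- a genuine junction word spans a
#' back-splice and should not -- or when its two half-words co-occur in
#' linear splice order elsewhere within `max_dist` nt, which an adjacent
#' paralogous gene could splice into a junction-identical read.
#'
#' @param probes probe set from [build_probes()] (or a list of them).
#' @param genome a `circ_genome`.
#' @param max_dist maximum half-word separation considered (nt).
#' @return logical vector, `TRUE` = paralog risk.
#' @export
paralog_filter <- function(probes, genome, max_dist = 100000) {
  if (!is.null(probes$circular)) probes <- list(probes)
  vapply(probes, function(pr) {
    w <- pr$circular
    half <- nchar(w) %/% 2L
    h1 <- substr(w, 1L, half)                 # donor-side half
    h2 <- substr(w, half + 1L, nchar(w))      # acceptor-side half
    for (chrom in names(genome)) {
      cs <- genome[[chrom]]
      if (stringi::stri_detect_fixed(cs, w) ||
          stringi::stri_detect_fixed(cs, revcomp_dna(w))) return(TRUE)
      # linear-order co-occurrence: h1 then h2 (forward) within max_dist
      p1 <- stringi::stri_locate_all_fixed(cs, h1, overlap = TRUE)[[1]]
      p2 <- stringi::stri_locate_all_fixed(cs, h2, overlap = TRUE)[[1]]
      if (!is.na(p1[1, 1]) && !is.na(p2[1, 1])) {
        for (e1 in p1[, 2]) {
          gap <- p2[, 1] - 1L - e1
          if (any(gap >= 0 & gap <= max_dist)) return(TRUE)
        }
      }
      # reverse-complement orientation: rc(h2) then rc(h1)
      q2 <- stringi::stri_locate_all_fixed(cs, revcomp_dna(h2), overlap = TRUE)[[1]]
      q1 <- stringi::stri_locate_all_fixed(cs, revcomp_dna(h1), overlap = TRUE)[[1]]
      if (!is.na(q1[1, 1]) && !is.na(q2[1, 1])) {
        for (e2 in q2[, 2]) {
          gap <- q1[, 1] - 1L - e2
          if (any(gap >= 0 & gap <= max_dist)) return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Translation test: RPF vs RNA-seq junction evidence
#'
#' Builds probes for every catalog circRNA with annotated linear partners,
#' counts them in the RNA-seq and RPF libraries and restricts the analysis
#' to circRNAs with RPF reads at both linear junctions.  The RNA-seq
#' circular fraction is computed with the standard containment-based
#' quantification formula (20-nt probes and the sequence-space rule); the
#' RPF fraction uses the probe-count analog, the only informative estimator
#' for ~30-nt footprints, and is exactly 0 when no footprint spans the
#' circular junction.  Paralog-risk probes are flagged and excluded from
#' translation claims.
#'
#' @param catalog catalog data frame with `transcript_id`.
#' @param annotation a `circ_annot` table.
#' @param genome a `circ_genome`.
#' @param rna_reads,rpf_reads read data frames.
#' @return data frame with RNA and RPF junction-word counts, `rna_fraction`
#'   (standard formula), `rpf_fraction` (probe formula), `eligible` and
#'   `paralog_risk` flags.
#' @export
translation_test <- function(catalog, annotation, genome, rna_reads, rpf_reads) {
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, , drop = FALSE]
    pr <- build_probes(rec, annotation, genome)
    if (is.null(pr)) next
    rna <- probe_counts(pr, rna_reads)
    rpf <- probe_counts(pr, rpf_reads)
    jx <- data.frame(junction_id = rec$circ_id, chrom = rec$chrom,
                     strand = rec$strand, acceptor_start = rec$acceptor_start,
                     donor_end = rec$donor_end, stringsAsFactors = FALSE)
    em <- setNames(list(catalog_exons(rec)), rec$circ_id)
    std <- count_junction_reads(jx, rna_reads, genome, exon_models = em)
    rows[[length(rows) + 1L]] <- data.frame(
      circ_id = pr$circ_id,
      rna_donor = rna$n_linear_donor, rna_circ = rna$n_circular,
      rna_acceptor = rna$n_linear_acceptor,
      rna_fraction = circular_fraction(sum(std$n_donor), sum(std$n_acceptor),
                                       sum(std$n_junction)),
      rpf_donor = rpf$n_linear_donor, rpf_circ = rpf$n_circular,
      rpf_acceptor = rpf$n_linear_acceptor, rpf_fraction = rpf$fraction,
      eligible = rpf$n_linear_donor > 0 & rpf$n_linear_acceptor > 0,
      paralog_risk = paralog_filter(pr, genome),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
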