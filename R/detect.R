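# detect: two-part split alignment of reads failing full-length alignment,
# GT-AG boundary refinement, candidate calling and the dinucleotide
# enrichment diagnostic.

#' Collapse PCR duplicates
#'
#' Identical sequences within a sample are collapsed to one representative
#' read before mapping; the number collapsed is kept in `dup_count`.
#'
#' @param reads read data frame.
#' @return deduplicated read data frame.
#' @export
dedupe_reads <- function(reads) {
  key <- paste(reads$sample_id, reads$seq, sep = "\r")
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  out$dup_count <- as.integer(table(key)[key[keep]])
  rownames(out) <- NULL
  out
}

# Full-length contiguous placement of sequences against the genome, both
# orientations, allowing up to max_mismatch substitutions.  Uses
# Biostrings::matchPDict; for max_mismatch > 0 the read is split into three
# trusted bands (pigeonhole: any hit with <= 2 mismatches has a clean band).
# Returns a data.frame of placements: seq_idx, chrom, strand, start, end
# (0-based half-open), n per seq in attribute "n_hits".
map_seqs_linear <- function(seqs, genome, max_mismatch = 2) {
  n_hits <- integer(length(seqs))
  out <- list()
  subjects <- lapply(unclass(genome), Biostrings::DNAString)
  widths <- nchar(seqs)
  clean <- !stringi::stri_detect_charclass(seqs, "[^ACGT]")
  for (w in unique(widths)) {
    idx <- which(widths == w & clean)
    if (length(idx) == 0L) next
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") seqs[idx] else revcomp_dna(seqs[idx])
      dpat <- Biostrings::DNAStringSet(pat)
      bands <- if (max_mismatch == 0L) list(c(1L, w)) else {
        b <- unique(pmin(w, c(0L, floor(w / 3), floor(2 * w / 3), w)))
        lapply(seq_len(length(b) - 1L), function(i) c(b[i] + 1L, b[i + 1L]))
      }
      hits <- list()
      for (bd in bands) {
        pd <- Biostrings::PDict(dpat, tb.start = bd[1], tb.end = bd[2])
        for (chrom in names(subjects)) {
          mi <- Biostrings::matchPDict(pd, subjects[[chrom]],
                                       max.mismatch = max_mismatch)
          si <- Biostrings::startIndex(mi)
          nz <- which(lengths(si) > 0L)
          if (length(nz)) {
            hits[[length(hits) + 1L]] <- data.frame(
              seq_idx = rep(idx[nz], lengths(si)[nz]), chrom = chrom,
              strand = ori, start = unlist(si[nz]) - 1L,
              stringsAsFactors = FALSE
            )
          }
        }
      }
      if (length(hits)) {
        h <- unique(do.call(rbind, hits))
        h$end <- h$start + w
        out[[length(out) + 1L]] <- h
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_idx = integer(0), chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  tab <- table(factor(res$seq_idx, levels = seq_along(seqs)))
  attr(res, "n_hits") <- as.integer(tab)
  rownames(res) <- NULL
  res
}

#' Linear pre-filter: split reads into mapped and unmapped sets
#'
#' Reads with any full-length contiguous alignment at up to `max_mismatches`
#' substitutions (either orientation) are removed from circRNA discovery;
#' PCR duplicates are collapsed first.  The mapped placements are retained
#' for FPKM computation.
#'
#' @param reads read data frame (`read_id`, `mate`, `seq`, `sample_id`).
#' @param genome a `circ_genome`.
#' @param max_mismatches mismatch allowance for the full-length pass.
#' @return list with `mapped` and `unmapped` read data frames (duplicates
#'   collapsed) and `placements` (read_id, mate, sample_id, chrom, strand,
#'   start, end, n_hits).
#' @export
linear_prefilter <- function(reads, genome, max_mismatches = 2) {
  dd <- dedupe_reads(reads)
  pl <- map_seqs_linear(dd$seq, genome, max_mismatch = max_mismatches)
  nh <- attr(pl, "n_hits")
  mapped <- nh > 0L
  placements <- cbind(
    dd[pl$seq_idx, c("read_id", "mate", "sample_id"), drop = FALSE],
    pl[, c("chrom", "strand", "start", "end")],
    n_hits = nh[pl$seq_idx]
  )
  rownames(placements) <- NULL
  list(mapped = dd[mapped, , drop = FALSE],
       unmapped = dd[!mapped, , drop = FALSE],
       placements = placements)
}

#' Find two-part split alignments indicative of back-splicing
#'
#' For each read (and its reverse complement) every breakpoint is considered
#' that splits it into a 5' and a 3' segment of at least `anchor_min` nt,
#' both matching the genome exactly (no mismatch or gap).  Only pairs on the
#' same chromosome, in reversed genomic order (the read's 5' segment
#' downstream of its 3' segment) and spanning at most `max_span` nt are
#' kept.  Breakpoints that slide across junction micro-homology map to the
#' same genomic placement and are reported once, with the sliding range in
#' `b_lo`/`b_hi`; a read with more than one distinct placement is discarded
#' as ambiguous.  Reads shorter than `max(40, 2 * anchor_min)` are skipped.
#'
#' @param reads read data frame of discovery candidates (typically the
#'   `unmapped` set from [linear_prefilter()]).
#' @param genome a `circ_genome`.
#' @param anchor_min minimum exact segment length (nt).
#' @param max_span maximum genomic span of a junction (nt).
#' @return data frame of split alignments: `read_id`, `sample_id`, `chrom`,
#'   `orientation`, `b` (representative breakpoint), `b_lo`, `b_hi` (full
#'   exact-match sliding range), `acceptor_start`, `donor_end` (0-based at
#'   breakpoint `b`).
#' @export
find_split_alignments <- function(reads, genome, anchor_min = 20, max_span = 100000) {
  min_len <- max(40L, 2L * anchor_min)
  empty <- data.frame(read_id = character(0), sample_id = character(0),
                      chrom = character(0), orientation = character(0),
                      b = integer(0), b_lo = integer(0), b_hi = integer(0),
                      acceptor_start = integer(0), donor_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    s0 <- reads$seq[r]
    L <- nchar(s0)
    if (L < min_len || grepl("[^ACGT]", s0)) next
    classes <- list()
    for (ori in c("+", "-")) {
      s <- if (ori == "+") s0 else revcomp_dna(s0)
      srev <- stringi::stri_reverse(s)
      pref <- substr(s, 1L, anchor_min)
      suff <- substr(s, L - anchor_min + 1L, L)
      for (chrom in names(genome)) {
        cs <- genome[[chrom]]
        p5 <- stringi::stri_locate_all_fixed(cs, pref, overlap = TRUE)[[1]]
        p3 <- stringi::stri_locate_all_fixed(cs, suff, overlap = TRUE)[[1]]
        if (is.na(p5[1, 1]) || is.na(p3[1, 1])) next
        g5s <- p5[, 1]  # 1-based starts of prefix-anchor occurrences
        g3e <- p3[, 2]  # 1-based ends of suffix-anchor occurrences
        e5 <- vapply(g5s, function(g)
          common_prefix_len(s, substr(cs, g, g + L - 1L)), integer(1))
        e3 <- vapply(g3e, function(g)
          common_prefix_len(srev, stringi::stri_reverse(substr(cs, max(1L, g - L + 1L), g))),
          integer(1))
        for (i in seq_along(g5s)) {
          for (j in seq_along(g3e)) {
            bmin <- max(anchor_min, L - e3[j])
            bmax <- min(e5[i], L - anchor_min)
            if (bmin > bmax) next
            span <- (g5s[i] - 1L) + L - g3e[j]  # donor_end - acceptor_start
            if (span <= 0L || span > max_span) next
            b_lo <- max(1L, L - e3[j])
            b_hi <- min(e5[i], L - 1L)
            b <- as.integer(floor((bmin + bmax) / 2))
            classes[[length(classes) + 1L]] <- data.frame(
              read_id = reads$read_id[r], sample_id = reads$sample_id[r],
              chrom = chrom, orientation = ori, b = b,
              b_lo = b_lo, b_hi = b_hi,
              acceptor_start = g3e[j] - (L - b),
              donor_end = (g5s[i] - 1L) + b, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    if (length(classes) == 1L) rows[[length(rows) + 1L]] <- classes[[1L]]
    # > 1 distinct genomic placement: ambiguous, discarded
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Splice-signal dinucleotides at a shifted junction (donor-downstream and
# acceptor-upstream windows on the forward genome).
.signal_class_at <- function(cs, acc, don) {
  n <- nchar(cs)
  if (acc < 2L || don + 2L > n) return(c(NA_character_, NA_character_))
  before <- substr0(cs, acc - 2L, acc)   # 2 nt left of the interval
  after <- substr0(cs, don, don + 2L)    # 2 nt right of the interval
  c(before, after)
}

#' Refine split alignments to splice signals
#'
#' Enumerates breakpoint shifts `s` (smallest |s| first, ties toward
#' negative) within the read's exact-match sliding range and at most
#' `shift_max` from the representative breakpoint, and picks the shift whose
#' junction is flanked by GT-AG splice signals: on the forward genome either
#' `AG ] junction [ GT` (plus-strand junction) or `AC ] junction [ CT`
#' (minus-strand).  Failing that, the minor-spliceosome AT-AC signature is
#' tried the same way; otherwise the junction is classified `other` at the
#' unshifted coordinates with strand `*`.  Junctions whose 10-nt flanking
#' windows contain `N` are classified `other`.
#'
#' @param alns split alignments from [find_split_alignments()].
#' @param genome a `circ_genome`.
#' @param window flanking window (nt) used for the N check.
#' @param shift_max maximum breakpoint shift considered.
#' @return data frame of refined junctions: `read_id`, `sample_id`, `chrom`,
#'   `strand`, `acceptor_start`, `donor_end`, `signal_class`.
#' @export
refine_splice_signal <- function(alns, genome, window = 10, shift_max = 5) {
  n <- nrow(alns)
  strand <- character(n); cls <- character(n)
  acc_out <- integer(n); don_out <- integer(n)
  for (r in seq_len(n)) {
    cs <- genome[[alns$chrom[r]]]
    acc0 <- alns$acceptor_start[r]; don0 <- alns$donor_end[r]
    shifts <- (alns$b_lo[r]:alns$b_hi[r]) - alns$b[r]
    shifts <- shifts[abs(shifts) <= shift_max]
    shifts <- shifts[order(abs(shifts), shifts)]
    found <- FALSE
    win_n <- grepl("N", paste0(
      substr0(cs, max(0L, acc0 - window), acc0),
      substr0(cs, don0, min(nchar(cs), don0 + window))
    ), fixed = TRUE)
    if (!win_n) {
      for (class_words in list(
        list(name = "GT-AG", plus = c("AG", "GT"), minus = c("AC", "CT")),
        list(name = "AT-AC", plus = c("AC", "AT"), minus = c("GT", "AT"))
      )) {
        for (s in shifts) {
          sig <- .signal_class_at(cs, acc0 + s, don0 + s)
          if (anyNA(sig)) next
          if (identical(sig, class_words$plus)) {
            strand[r] <- "+"; cls[r] <- class_words$name
            acc_out[r] <- acc0 + s; don_out[r] <- don0 + s
            found <- TRUE; break
          }
          if (identical(sig, class_words$minus)) {
            strand[r] <- "-"; cls[r] <- class_words$name
            acc_out[r] <- acc0 + s; don_out[r] <- don0 + s
            found <- TRUE; break
          }
        }
        if (found) break
      }
    }
    if (!found) {
      strand[r] <- "*"; cls[r] <- "other"
      acc_out[r] <- acc0; don_out[r] <- don0
    }
  }
  data.frame(read_id = alns$read_id, sample_id = alns$sample_id,
             chrom = alns$chrom, strand = strand,
             acceptor_start = acc_out, donor_end = don_out,
             signal_class = cls, stringsAsFactors = FALSE)
}

#' Aggregate refined junctions into candidates
#'
#' Junctions are grouped by (chrom, strand, acceptor_start, donor_end);
#' support is the number of distinct (duplicate-collapsed) reads per sample.
#' Candidates whose support is below `min_reads` in every sample are
#' dropped.  Non-GT-AG candidates are retained and flagged -- they feed the
#' splice-signal diagnostics -- but are excluded later by the catalog filter.
#'
#' @param refined refined junctions from [refine_splice_signal()].
#' @param min_reads minimum supporting reads within at least one sample.
#' @return candidate data frame with `junction_id`, coordinates,
#'   `signal_class`, one `support_<sample>` column per sample and
#'   `total_support`.
#' @export
call_candidates <- function(refined, min_reads = 2) {
  if (nrow(refined) == 0L)
    return(data.frame(junction_id = character(0), chrom = character(0),
                      strand = character(0), acceptor_start = integer(0),
                      donor_end = integer(0), signal_class = character(0),
                      total_support = integer(0), stringsAsFactors = FALSE))
  key <- paste(refined$chrom, refined$strand, refined$acceptor_start,
               refined$donor_end, refined$signal_class, sep = "\r")
  samples <- sort(unique(refined$sample_id))
  first <- !duplicated(key)
  out <- refined[first, c("chrom", "strand", "acceptor_start", "donor_end",
                          "signal_class"), drop = FALSE]
  out$junction_id <- sprintf("circ_%s_%d_%d_%s", out$chrom, out$acceptor_start,
                             out$donor_end, out$strand)
  sup <- matrix(0L, nrow(out), length(samples),
                dimnames = list(NULL, samples))
  tab <- table(key, refined$sample_id)
  sup[, colnames(tab)] <- as.integer(tab[key[first], , drop = FALSE])
  colnames(sup) <- paste0("support_", samples)
  out <- cbind(out[, c("junction_id", "chrom", "strand", "acceptor_start",
                       "donor_end", "signal_class")], sup)
  out$total_support <- as.integer(rowSums(sup))
  keep <- apply(sup, 1L, max) >= min_reads
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dinucleotide enrichment around candidate junctions
#'
#' For candidates with at least `min_support` junction-spanning reads, the
#' frequency of each of the 16 dinucleotides is tabulated at every offset of
#' the `window`-nt windows flanking the donor end (transcript-downstream)
#' and the acceptor start (transcript-upstream), strand-aware.  In genuine
#' back-spliced candidates GT dominates donor offset 0 and AG acceptor
#' offset `window - 2`.
#'
#' @param candidates candidate data frame from [call_candidates()].
#' @param genome a `circ_genome`.
#' @param window flanking window size (nt).
#' @param min_support diagnostic support threshold.
#' @return data frame `side` (donor/acceptor), `offset` (0-based within the
#'   window), `dinuc`, `freq`; frequencies sum to 1 within each side x
#'   offset.  Empty candidates give an empty table.
#' @export
dinucleotide_enrichment <- function(candidates, genome, window = 10, min_support = 5) {
  cand <- candidates[candidates$total_support >= min_support, , drop = FALSE]
  empty <- data.frame(side = character(0), offset = integer(0),
                      dinuc = character(0), freq = numeric(0))
  if (nrow(cand) == 0L) return(empty)
  don_win <- character(nrow(cand)); acc_win <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cs <- genome[[cand$chrom[i]]]
    acc <- cand$acceptor_start[i]; don <- cand$donor_end[i]
    minus <- identical(cand$strand[i], "-")
    left <- substr0(cs, max(0L, acc - window), acc)
    right <- substr0(cs, don, min(nchar(cs), don + window))
    if (minus) {  # transcript-downstream of the donor is left of the interval
      don_win[i] <- revcomp_dna(left)
      acc_win[i] <- revcomp_dna(right)
    } else {
      don_win[i] <- right
      acc_win[i] <- left
    }
  }
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  tab <- function(wins, side) {
    offs <- 0:(window - 2L)
    rows <- lapply(offs, function(o) {
      dn <- substr(wins, o + 1L, o + 2L)
      dn <- dn[nchar(dn) == 2L]
      ft <- table(factor(dn, levels = dinucs))
      data.frame(side = side, offset = o, dinuc = dinucs,
                 freq = as.numeric(ft) / max(1L, sum(ft)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(tab(don_win, "donor"), tab(acc_win, "acceptor"))
  rownames(out) <- NULL
  out
}
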