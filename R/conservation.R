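# conservation: ortholog enrichment, cross-species junction overlap classes,
# circular-fraction correlation, codon-position conservation tests.

#' Ortholog circRNA enrichment (2x2)
#'
#' Cross-tabulates, over one-to-one ortholog pairs, whether the gene in
#' species A (e.g. mouse) has a circRNA against whether its ortholog in
#' species B (human) has one; genes absent from the ortholog table are
#' excluded.
#'
#' @param genes_a_circ,genes_b_circ gene ids with catalog circRNAs in each
#'   species.
#' @param orthologs data frame with columns `gene_a`, `gene_b` (unique
#'   one-to-one pairs).
#' @return list: `table` (2x2), `prop_circ` (P(B circ | A circ)),
#'   `prop_nocirc`, `odds_ratio` (`NA` proportions for empty margins).
#' @export
ortholog_circ_enrichment <- function(genes_a_circ, genes_b_circ, orthologs) {
  stopifnot(!anyDuplicated(orthologs$gene_a), !anyDuplicated(orthologs$gene_b))
  a <- orthologs$gene_a %in% genes_a_circ
  b <- orthologs$gene_b %in% genes_b_circ
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)),
               dnn = c("a_circ", "b_circ"))
  p1 <- if (sum(a) > 0) sum(a & b) / sum(a) else NA_real_
  p0 <- if (sum(!a) > 0) sum(!a & b) / sum(!a) else NA_real_
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, prop_circ = p1, prop_nocirc = p0, odds_ratio = as.numeric(or))
}

#' Map a genomic position across species
#'
#' The coordinate map is a table of paired intervals (the role a liftOver
#' chain plays), applied per boundary: a position inside an A interval maps
#' by offset into the paired B interval, reversed when strands differ.
#'
#' @param map data frame: `chrom_a`, `start_a`, `end_a`, `strand_a`,
#'   `chrom_b`, `start_b`, `end_b`, `strand_b` (0-based half-open).
#' @param chrom,pos position in species A.
#' @return list `chrom`, `pos` (`NA` when unmappable).
#' @export
map_position <- function(map, chrom, pos) {
  hit <- which(map$chrom_a == chrom & map$start_a <= pos & pos <= map$end_a)
  if (length(hit) == 0L) return(list(chrom = NA_character_, pos = NA_integer_))
  m <- map[hit[1L], ]
  off <- pos - m$start_a
  p <- if (identical(m$strand_a, m$strand_b)) m$start_b + off else m$end_b - off
  list(chrom = m$chrom_b, pos = as.integer(p))
}

#' Cross-species overlap class of a junction
#'
#' `same_splice_sites` when both mapped boundaries coincide (within `tol`
#' nt) with a species-B circRNA's boundaries; `partial_overlap` when the
#' mapped interval overlaps a B circRNA interval; otherwise `no_overlap`.
#' Junctions with an unmappable boundary are reported as `unmappable`.
#'
#' @param junctions_a junction data frame in species A.
#' @param catalog_b catalog/junction data frame in species B (needs `chrom`,
#'   `acceptor_start`, `donor_end`).
#' @param map coordinate map (see [map_position()]).
#' @param tol boundary tolerance (nt).
#' @return character vector of classes, one per A junction.
#' @export
overlap_class <- function(junctions_a, catalog_b, map, tol = 2) {
  vapply(seq_len(nrow(junctions_a)), function(i) {
    j <- junctions_a[i, ]
    m1 <- map_position(map, j$chrom, j$acceptor_start)
    m2 <- map_position(map, j$chrom, j$donor_end)
    if (is.na(m1$pos) || is.na(m2$pos) || !identical(m1$chrom, m2$chrom))
      return("unmappable")
    lo <- min(m1$pos, m2$pos); hi <- max(m1$pos, m2$pos)
    cb <- catalog_b[catalog_b$chrom == m1$chrom, , drop = FALSE]
    if (nrow(cb) == 0L) return("no_overlap")
    same <- abs(cb$acceptor_start - lo) <= tol & abs(cb$donor_end - hi) <= tol
    if (any(same)) return("same_splice_sites")
    if (any(cb$acceptor_start < hi & cb$donor_end > lo)) return("partial_overlap")
    "no_overlap"
  }, character(1))
}

#' Circular-fraction correlation between conserved circRNA pairs
#'
#' Fractions are averaged per junction over the samples in which the
#' transcript was represented (donor and acceptor availability >= 1 read
#' each), then the two species' averages are compared by Spearman
#' correlation.
#'
#' @param pairs data frame `junction_a`, `junction_b` (conserved pairs; at
#'   least 3).
#' @param counts_a,counts_b count tables from [count_junction_reads()].
#' @return list: `rho`, `p_value`, `avg_a`, `avg_b`.
#' @export
cf_correlation <- function(pairs, counts_a, counts_b) {
  if (nrow(pairs) < 3) stopf("need >= 3 conserved pairs")
  avg <- function(cc, ids) {
    vapply(ids, function(j) {
      d <- cc[cc$junction_id == j & cc$n_donor >= 1 & cc$n_acceptor >= 1, ]
      if (nrow(d) == 0L) NA_real_ else mean(d$fraction)
    }, numeric(1))
  }
  a <- avg(counts_a, pairs$junction_a)
  b <- avg(counts_b, pairs$junction_b)
  ok <- !is.na(a) & !is.na(b)
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, avg_a = a, avg_b = b)
}

# Codon position (1/2/3) of each base of given coding exons, walking the
# spliced CDS in transcript orientation.  Returns, per exon row, integer
# vector of codon positions aligned with forward genomic order.
codon_positions <- function(exons, cds_start, cds_end, strand) {
  ex <- exons[order(exons$start), , drop = FALSE]
  ex$start <- pmax(ex$start, cds_start)
  ex$end <- pmin(ex$end, cds_end)
  ex <- ex[ex$end > ex$start, , drop = FALSE]
  if (nrow(ex) == 0L) return(list())
  ord <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  res <- vector("list", nrow(ex))
  offset <- 0L
  for (i in ord) {
    w <- ex$end[i] - ex$start[i]
    pos <- ((offset + seq_len(w) - 1L) %% 3L) + 1L
    res[[i]] <- if (strand == "+") pos else rev(pos)
    offset <- offset + w
  }
  lapply(seq_len(nrow(ex)), function(i)
    list(start = ex$start[i], end = ex$end[i], codon_pos = res[[i]]))
}

# Mean track score per codon position over a set of coding exons of one
# transcript; NULL when more than half of the bases lack track coverage.
exon_codon_means <- function(exons, chrom, cds_start, cds_end, strand, track,
                             max_missing = 0.5) {
  cps <- codon_positions(exons, cds_start, cds_end, strand)
  if (length(cps) == 0L) return(NULL)
  sc <- list(); cp <- list()
  for (e in cps) {
    v <- track_values(track, chrom, e$start, e$end)
    sc[[length(sc) + 1L]] <- v
    cp[[length(cp) + 1L]] <- e$codon_pos
  }
  v <- unlist(sc); p <- unlist(cp)
  if (mean(is.na(v)) > max_missing) return(NULL)
  vapply(1:3, function(k) mean(v[p == k], na.rm = TRUE), numeric(1))
}

#' Codon-position conservation: circular vs neighboring linear exons
#'
#' For each circRNA with an assigned coding transcript, computes the mean
#' conservation score at codon positions 1/2/3 within its coding exons and
#' within the nearest upstream and downstream coding exons of the same
#' transcript outside the circle, then compares the paired means per
#' position with a two-sided paired Mann-Whitney (Wilcoxon signed-rank)
#' test.  Exons with more than half of their bases uncovered by the track
#' are excluded.
#'
#' @param catalog catalog data frame with `transcript_id` assigned.
#' @param annotation a `circ_annot` table (CDS columns required).
#' @param track conservation track (see [load_track()]).
#' @return list: `per_circ` (means per position, circ and neighbor),
#'   `p_values` (length 3).
#' @export
codon_position_conservation <- function(catalog, annotation, track) {
  models <- transcript_models(annotation)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, , drop = FALSE]
    if (is.na(rec$transcript_id) || !rec$transcript_id %in% names(models)) next
    m <- models[[rec$transcript_id]]
    if (is.na(m$cds_start[1])) next
    inside <- m$start >= rec$acceptor_start & m$end <= rec$donor_end
    if (!any(inside)) next
    up <- m[m$end <= rec$acceptor_start, , drop = FALSE]
    dn <- m[m$start >= rec$donor_end, , drop = FALSE]
    nb <- rbind(if (nrow(up)) up[nrow(up), ], if (nrow(dn)) dn[1L, ])
    if (is.null(nb) || nrow(nb) == 0L) next
    cm <- exon_codon_means(m[inside, c("start", "end")], rec$chrom,
                           m$cds_start[1], m$cds_end[1], m$strand[1], track)
    nm <- exon_codon_means(nb[, c("start", "end")], rec$chrom,
                           m$cds_start[1], m$cds_end[1], m$strand[1], track)
    if (is.null(cm) || is.null(nm)) next
    rows[[length(rows) + 1L]] <- data.frame(
      circ_id = rec$circ_id,
      circ_pos1 = cm[1], circ_pos2 = cm[2], circ_pos3 = cm[3],
      nb_pos1 = nm[1], nb_pos2 = nm[2], nb_pos3 = nm[3],
      stringsAsFactors = FALSE
    )
  }
  per <- if (length(rows)) do.call(rbind, rows) else NULL
  pv <- rep(NA_real_, 3)
  if (!is.null(per) && nrow(per) >= 3) {
    for (k in 1:3) {
      x <- per[[paste0("circ_pos", k)]]
      y <- per[[paste0("nb_pos", k)]]
      pv[k] <- if (all(x == y)) 1 else
        stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
    }
  }
  list(per_circ = per, p_values = pv)
}

#' Conservation-matched control cohorts for the position-3 test
#'
#' Draws `n_cohorts` cohorts of linear coding exons whose binned
#' distribution of combined position-1&2 mean scores matches the circular
#' exon set's, and returns the null distribution of cohort position-3 means
#' together with the circular set's percentile among them.  Bins are
#' equal-width over the pooled range; under-filled bins fall back to
#' sampling with replacement (warned once).
#'
#' @param circ_stats data frame `mean12`, `mean3` for circular exons.
#' @param pool_stats same for the linear exon pool.
#' @param n_cohorts number of control cohorts.
#' @param n_bins matching bins.
#' @return list: `null_means`, `circ_mean`, `percentile`.
#' @export
matched_conservation_cohort <- function(circ_stats, pool_stats,
                                        n_cohorts = 1000, n_bins = 10) {
  rng <- range(c(circ_stats$mean12, pool_stats$mean12), finite = TRUE)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  cb <- cut(circ_stats$mean12, brk, labels = FALSE)
  pb <- cut(pool_stats$mean12, brk, labels = FALSE)
  need <- table(factor(cb, levels = seq_len(n_bins)))
  warned <- FALSE
  null_means <- vapply(seq_len(n_cohorts), function(cc) {
    idx <- integer(0)
    for (b in which(need > 0)) {
      avail <- which(pb == b)
      nb <- need[[b]]
      if (length(avail) == 0L) stopf("no pool exons in matching bin %d", b)
      if (length(avail) < nb && !warned) {
        warned <<- TRUE
        warnf("bin %d under-filled (%d < %d); sampling with replacement",
              b, length(avail), nb)
      }
      idx <- c(idx, sample(avail, nb, replace = length(avail) < nb))
    }
    mean(pool_stats$mean3[idx])
  }, numeric(1))
  circ_mean <- mean(circ_stats$mean3)
  list(null_means = null_means, circ_mean = circ_mean,
       percentile = 100 * mean(null_means < circ_mean))
}
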