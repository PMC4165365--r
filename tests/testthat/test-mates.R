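# Geometry used throughout: circle over exons 2..4 with exon lengths
# (40, 300, 40) and 200-nt introns.  With 100-nt reads and ~200-nt fragments
# the mate of a junction-spanning read clears the 40-nt boundary exon at the
# same rate whether the molecule is spliced (landing in the neighbor exon)
# or intron-retaining (landing in the intron), so the retained fraction is
# estimated without capture bias.
retention_world <- function(rate, fraction = 0.6, n_fragments = 3500,
                            strand = "+", seed = 1) {
  w <- build_gene_world(c(150, 40, 300, 40, 200), rep(200, 4),
                        strand = strand, seed = seed)
  nex <- 5
  circ <- if (strand == "+") data.frame(gene_id = "g1", first_exon = 2, last_exon = 4)
          else data.frame(gene_id = "g1", first_exon = 2, last_exon = 4)
  truth <- sim_truth(w$annotation, circles = circ, fraction = fraction,
                     intron_retention_rate = rate)
  reads <- sim_reads(w$genome, w$annotation, truth, n_fragments = n_fragments,
                     seed = seed + 1)
  cat_row <- truth_catalog_row(w, truth)
  list(world = w, truth = truth, reads = reads, catalog = cat_row)
}

# Catalog row straight from the simulator truth (exon model from annotation).
truth_catalog_row <- function(w, truth) {
  jt <- truth$junctions[1, ]
  m <- w$annotation[w$annotation$transcript_id == jt$transcript_id, ]
  ex <- m[m$start >= jt$acceptor_start & m$end <= jt$donor_end, ]
  data.frame(
    circ_id = jt$junction_id, chrom = jt$chrom, strand = jt$strand,
    acceptor_start = jt$acceptor_start, donor_end = jt$donor_end,
    exon_sizes = paste(ex$end - ex$start, collapse = ","),
    exon_starts = paste(ex$start - jt$acceptor_start, collapse = ","),
    exonic_length = sum(ex$end - ex$start), stringsAsFactors = FALSE
  )
}

test_that("mate categories partition mapped mates; pure circles have no outside mates", {
  rw <- retention_world(rate = 0, seed = 21)
  j <- data.frame(junction_id = rw$catalog$circ_id, chrom = rw$catalog$chrom,
                  strand = rw$catalog$strand,
                  acceptor_start = rw$catalog$acceptor_start,
                  donor_end = rw$catalog$donor_end)
  mp <- mate_placements(j, rw$reads, rw$world$genome,
                        exons = circkit:::catalog_exons(rw$catalog))
  expect_gt(nrow(mp), 20)
  expect_true(all(mp$category %in% c("inside_circle", "neighbor_exon", "intron",
                                     "upstream_of_acceptor", "downstream_of_donor",
                                     "other")))
  # a circle has no outside
  expect_equal(sum(mp$category %in% c("upstream_of_acceptor", "downstream_of_donor")), 0L)
  # single-end input is an error
  expect_error(mate_placements(j, rw$reads[rw$reads$mate == 1, ], rw$world$genome),
               "paired-end")
})

test_that("intron retention is recovered at rates 0, 0.2 and 1", {
  for (rate in c(0, 0.2, 1)) {
    rw <- retention_world(rate = rate, seed = 30 + round(rate * 10))
    ir <- intron_retention(rw$catalog, rw$reads, rw$world$genome)
    expect_gte(ir$n_intron + ir$n_exon, 100)
    if (rate == 0) expect_equal(ir$retained_fraction, 0)
    else if (rate == 1) expect_equal(ir$retained_fraction, 1)
    else expect_lt(abs(ir$retained_fraction - rate), 0.08)
  }
  # no informative mates -> NA
  rw0 <- retention_world(rate = 0, seed = 35)
  empty_reads <- rw0$reads[0, ]
  empty_reads <- rbind(empty_reads,
                       data.frame(read_id = "r", mate = 1:2,
                                  seq = strrep("A", 100), sample_id = "s1"))
  ir0 <- intron_retention(rw0$catalog, empty_reads, rw0$world$genome)
  expect_true(is.na(ir0$retained_fraction))
})

test_that("trans-spliced contaminants produce outside-mapping mates; circles do not", {
  w <- build_gene_world(c(200, 40, 40, 200), rep(200, 3), seed = 41)
  truth_trans <- sim_truth(w$annotation,
                           circles = data.frame(gene_id = "g1", first_exon = 2,
                                                last_exon = 3, kind = "trans"),
                           fraction = 0.6)
  reads_t <- sim_reads(w$genome, w$annotation, truth_trans,
                       n_fragments = 4000, seed = 42)
  cat_t <- truth_catalog_row(w, truth_trans)
  tt <- trans_splice_test(cat_t, reads_t, w$genome)
  expect_gt(tt$total_evidence, 0)
  expect_true(any(tt$per_junction$upstream > 0) || any(tt$per_junction$downstream > 0))

  # genuine circle of the same geometry: zero evidence
  rw <- retention_world(rate = 0, seed = 43)
  tc <- trans_splice_test(rw$catalog, rw$reads, rw$world$genome)
  expect_equal(tc$total_evidence, 0L)
  # length cutoff: circles >= max_len are not considered
  tl <- trans_splice_test(rw$catalog, rw$reads, rw$world$genome, max_len = 300)
  expect_equal(nrow(tl$per_junction), 0L)
})

test_that("poly(A) comparison: circles vanish, trans-spliced products persist", {
  w <- build_gene_world(c(200, 40, 40, 200, 180), rep(200, 4), seed = 51)
  circles <- data.frame(gene_id = c("g1", "g1"), first_exon = c(2, 4),
                        last_exon = c(3, 4), kind = c("circle", "trans"))
  # one gene cannot carry both; build two worlds instead
  w2 <- build_gene_world(c(200, 40, 40, 200), rep(200, 3), seed = 52)
  tr_circ <- sim_truth(w$annotation,
                       circles = data.frame(gene_id = "g1", first_exon = 2,
                                            last_exon = 3), fraction = 0.5)
  tr_trans <- sim_truth(w2$annotation,
                        circles = data.frame(gene_id = "g1", first_exon = 2,
                                             last_exon = 3, kind = "trans"),
                        fraction = 0.5)
  mk <- function(world, truth, polya, seed)
    sim_reads(world$genome, world$annotation, truth, n_fragments = 1500,
              polya_selected = polya, seed = seed)
  jx <- rbind(
    cbind(tr_circ$junctions[, c("junction_id", "chrom", "strand",
                                "acceptor_start", "donor_end")]),
    cbind(tr_trans$junctions[, c("junction_id", "chrom", "strand",
                                 "acceptor_start", "donor_end")])
  )
  jx$junction_id <- c("circ", "trans")
  count2 <- function(polya, seed) rbind(
    count_junction_reads(jx[1, ], mk(w, tr_circ, polya, seed), w$genome),
    count_junction_reads(jx[2, ], mk(w2, tr_trans, polya, seed + 1), w2$genome)
  )
  cc_non <- count2(FALSE, 60)
  cc_pa <- count2(TRUE, 62)
  pc <- polya_compare(jx, cc_non, cc_pa)
  pr <- pc$pairs
  expect_equal(pr$fraction_polya[pr$junction_id == "circ"], 0)
  expect_gt(pr$fraction_nonpolya[pr$junction_id == "circ"], 0.2)
  # a trans product presents its junction word once but two donor/acceptor
  # probe copies per molecule, so its expected fraction is f/(2+f) = 0.2
  expect_gte(pr$fraction_polya[pr$junction_id == "trans"], 0.1)
  expect_gte(pr$fraction_nonpolya[pr$junction_id == "trans"], 0.1)
  expect_equal(unname(pc$summary["both"]), 1L)
})
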