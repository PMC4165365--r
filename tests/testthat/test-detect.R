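test_that("duplicate collapse keeps one representative per sequence per sample", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:1000), mate = 1L,
    seq = rep("ACGTACGTACGT", 1000), sample_id = "s1"
  )
  dd <- dedupe_reads(reads)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$dup_count, 1000L)
  reads$sample_id <- rep(c("s1", "s2"), 500)
  expect_equal(nrow(dedupe_reads(reads)), 2L)
})

test_that("linear prefilter separates exonic reads from back-spliced reads", {
  w <- default_world()
  g <- w$sim$genome
  m <- w$sim$annotation[w$sim$annotation$transcript_id == "t1", ]
  exonic <- genome_fetch(g, m$chrom[1], m$start[1], m$start[1] + 60)
  jt <- w$truth$junctions[w$truth$junctions$transcript_id == "t1", ]
  pr <- junction_probes(jt, g, probe_len = 30)
  bs <- pr$junction  # 30 + 30 nt in back-spliced order
  reads <- data.frame(read_id = c("lin", "bs"), mate = 1L,
                      seq = c(exonic, bs), sample_id = "s1")
  pf <- linear_prefilter(reads, g)
  expect_equal(pf$mapped$read_id, "lin")
  expect_equal(pf$unmapped$read_id, "bs")
  expect_equal(pf$placements$chrom, m$chrom[1])
  # a read with 2 mismatches still maps; 3 mismatches does not
  mm <- exonic
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mm, 5, 5))[1]
  substr(mm, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(mm, 25, 25))[1]
  mm3 <- mm
  substr(mm3, 45, 45) <- setdiff(c("A", "C", "G", "T"), substr(mm3, 45, 45))[1]
  pf2 <- linear_prefilter(data.frame(read_id = c("m2", "m3"), mate = 1L,
                                     seq = c(mm, mm3), sample_id = "s1"), g)
  expect_equal(pf2$mapped$read_id, "m2")
  expect_equal(pf2$unmapped$read_id, "m3")
})

test_that("split alignment finds planted junctions at the exact break and obeys its rules", {
  set.seed(42)
  g <- as_genome(c(chr1 = rand_dna(10000), chr2 = rand_dna(2000)))
  # plant a junction: donor segment at 6000..6040, acceptor at 3000..3040
  don_seg <- genome_fetch(g, "chr1", 5960, 6000)
  acc_seg <- genome_fetch(g, "chr1", 3000, 3040)
  read <- paste0(don_seg, acc_seg)
  al <- find_split_alignments(
    data.frame(read_id = "r1", mate = 1L, seq = read, sample_id = "s1"), g)
  expect_equal(nrow(al), 1L)
  expect_equal(al$acceptor_start, 3000L)
  expect_equal(al$donor_end, 6000L)

  # reverse-complemented read gives the same forward-coordinate junction
  al_rc <- find_split_alignments(
    data.frame(read_id = "r1", mate = 1L, seq = revcomp_dna(read), sample_id = "s1"), g)
  expect_equal(al_rc$acceptor_start, 3000L)
  expect_equal(al_rc$donor_end, 6000L)

  # segments on different chromosomes: not emitted
  cross <- paste0(genome_fetch(g, "chr2", 100, 140), acc_seg)
  expect_equal(nrow(find_split_alignments(
    data.frame(read_id = "x", mate = 1L, seq = cross, sample_id = "s1"), g)), 0L)

  # duplicated donor segment -> two reversed-order placements -> ambiguous
  g2 <- as_genome(c(chr1 = paste0(unclass(g)[["chr1"]],
                                  substr(unclass(g)[["chr1"]], 5901, 6100))))
  al_amb <- find_split_alignments(
    data.frame(read_id = "r1", mate = 1L, seq = read, sample_id = "s1"), g2)
  expect_equal(nrow(al_amb), 0L)

  # span limit: > max_span is dropped
  near <- paste0(genome_fetch(g, "chr1", 4960, 5000), acc_seg)
  expect_equal(nrow(find_split_alignments(
    data.frame(read_id = "n", mate = 1L, seq = near, sample_id = "s1"),
    g, max_span = 1500)), 0L)
  expect_equal(nrow(find_split_alignments(
    data.frame(read_id = "n", mate = 1L, seq = near, sample_id = "s1"),
    g, max_span = 2100)), 1L)

  # reads shorter than 40 nt are skipped
  expect_equal(nrow(find_split_alignments(
    data.frame(read_id = "s", mate = 1L, seq = substr(read, 1, 39),
               sample_id = "s1"), g)), 0L)
})

test_that("splice-signal refinement picks GT-AG shifts, minor signals and strands", {
  # construct a genome where the breakpoint can slide: the 2 nt after the
  # donor end ("GT") also start the acceptor exon, so exact matching allows
  # shifts and only the signal pins the boundary
  set.seed(43)
  left_flank <- rand_dna(300)
  acc_exon <- paste0("GTC", rand_dna(117))
  mid <- rand_dna(200)
  don_exon <- paste0(rand_dna(118), "TT")
  g <- as_genome(c(chr1 = paste0(left_flank, "AG", acc_exon, mid, don_exon,
                                 "GTA", rand_dna(300))))
  acc <- 302L                    # after left_flank + AG
  don <- 302L + 120L + 200L + 120L
  read <- paste0(genome_fetch(g, "chr1", don - 60, don),
                 genome_fetch(g, "chr1", acc, acc + 60))
  al <- find_split_alignments(
    data.frame(read_id = "r", mate = 1L, seq = read, sample_id = "s1"), g)
  expect_equal(nrow(al), 1L)
  j <- refine_splice_signal(al, g)
  expect_equal(j$signal_class, "GT-AG")
  expect_equal(j$strand, "+")
  expect_equal(j$acceptor_start, acc)
  expect_equal(j$donor_end, don)
  # the 2-nt CA homology means b_lo..b_hi spans >1 breakpoint; the refined
  # coordinates must be the signal-consistent ones regardless of which
  # representative breakpoint was chosen
  expect_true(al$b_hi - al$b_lo >= 2)

  # refinement is idempotent: an alignment constructed at refined coords
  # refines to itself
  al2 <- al
  al2$acceptor_start <- j$acceptor_start
  al2$donor_end <- j$donor_end
  j2 <- refine_splice_signal(al2, g)
  expect_equal(j2$acceptor_start, j$acceptor_start)
  expect_equal(j2$donor_end, j$donor_end)

  # AT-AC minor-spliceosome signature
  g3 <- as_genome(c(chr1 = paste0(substr(unclass(g)[["chr1"]], 1, 300), "AC",
                                  acc_exon, mid, don_exon, "AT",
                                  substr(unclass(g)[["chr1"]], don + 3,
                                         nchar(unclass(g)[["chr1"]])))))
  al3 <- find_split_alignments(
    data.frame(read_id = "r", mate = 1L,
               seq = paste0(genome_fetch(g3, "chr1", don - 60, don),
                            genome_fetch(g3, "chr1", acc, acc + 60)),
               sample_id = "s1"), g3)
  j3 <- refine_splice_signal(al3, g3)
  expect_equal(j3$signal_class, "AT-AC")

  # minus-strand junctions (AC ... CT on the forward genome) get strand "-"
  w <- default_world()
  minus <- w$truth$junctions[w$truth$junctions$strand == "-", ][1, ]
  mread <- paste0(
    genome_fetch(w$sim$genome, minus$chrom, minus$donor_end - 50, minus$donor_end),
    genome_fetch(w$sim$genome, minus$chrom, minus$acceptor_start, minus$acceptor_start + 50)
  )
  alm <- find_split_alignments(
    data.frame(read_id = "m", mate = 1L, seq = mread, sample_id = "s1"),
    w$sim$genome)
  jm <- refine_splice_signal(alm, w$sim$genome)
  expect_equal(jm$signal_class, "GT-AG")
  expect_equal(jm$strand, "-")
})

test_that("candidate calling enforces the two-read rule and aggregates support", {
  w <- default_world()
  jt <- w$truth$junctions[1, ]
  mk <- function(id, off) {
    seq <- paste0(
      genome_fetch(w$sim$genome, jt$chrom, jt$donor_end - 40 - off, jt$donor_end),
      genome_fetch(w$sim$genome, jt$chrom, jt$acceptor_start, jt$acceptor_start + 40 + off)
    )
    data.frame(read_id = id, mate = 1L, seq = seq, sample_id = "s1")
  }
  reads3 <- rbind(mk("a", 0), mk("b", 3), mk("c", 6))
  al <- find_split_alignments(reads3, w$sim$genome)
  cand <- call_candidates(refine_splice_signal(al, w$sim$genome))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$support_s1, 3L)
  expect_equal(cand$acceptor_start, jt$acceptor_start)
  expect_equal(cand$donor_end, jt$donor_end)
  # one supporting read only: excluded
  al1 <- find_split_alignments(mk("a", 0), w$sim$genome)
  expect_equal(nrow(call_candidates(refine_splice_signal(al1, w$sim$genome))), 0L)
})

test_that("dinucleotide enrichment shows GT at donor offset 0, AG at acceptor end", {
  w <- default_world()
  res <- run_pipeline(w$sim$genome, w$reads, annotation = w$sim$annotation)
  enr <- dinucleotide_enrichment(res$candidates, w$sim$genome)
  gt0 <- enr[enr$side == "donor" & enr$offset == 0 & enr$dinuc == "GT", ]
  expect_equal(gt0$freq, 1)
  ag8 <- enr[enr$side == "acceptor" & enr$offset == 8 & enr$dinuc == "AG", ]
  expect_equal(ag8$freq, 1)
  # frequencies sum to one at every side x offset
  sums <- tapply(enr$freq, paste(enr$side, enr$offset), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # random positions give background-like (not signal-dominated) frequencies
  set.seed(44)
  fake <- res$candidates
  fake$acceptor_start <- fake$acceptor_start + 37L
  fake$donor_end <- fake$donor_end - 41L
  enr_bg <- dinucleotide_enrichment(fake, w$sim$genome)
  gt_bg <- enr_bg[enr_bg$side == "donor" & enr_bg$offset == 0 & enr_bg$dinuc == "GT", ]
  expect_lt(gt_bg$freq, 1)
  # empty candidate list: empty table
  expect_equal(nrow(dinucleotide_enrichment(res$candidates[0, ], w$sim$genome)), 0L)
})
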