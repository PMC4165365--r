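# Shared fixtures and independent oracles for the test suite.

# Cached default simulated world (genome + annotation + truth + reads).
.fixture_env <- new.env(parent = emptyenv())
default_world <- function() {
  if (is.null(.fixture_env$world)) {
    sim <- sim_genome(n_genes = 4, seed = 101)
    truth <- sim_truth(sim$annotation, samples = c("s1", "s2"), fraction = 0.5)
    reads <- rbind(
      sim_reads(sim$genome, sim$annotation, truth, "s1", n_fragments = 1200, seed = 102),
      sim_reads(sim$genome, sim$annotation, truth, "s2", n_fragments = 1200, seed = 103)
    )
    .fixture_env$world <- list(sim = sim, truth = truth, reads = reads)
  }
  .fixture_env$world
}

# Brute-force split-alignment oracle: enumerate every breakpoint and every
# exact occurrence of both segments; return unique junction placements
# (chrom, acceptor_start, donor_end) under the reversed-order / span rules.
# Independent of find_split_alignments (no anchors, no extension logic).
oracle_split <- function(seq, genome, anchor_min = 20, max_span = 100000) {
  hits <- list()
  for (ori in c("+", "-")) {
    s <- if (ori == "+") seq else revcomp_dna(seq)
    L <- nchar(s)
    if (L < max(40, 2 * anchor_min)) next
    for (b in anchor_min:(L - anchor_min)) {
      pre <- substr(s, 1, b)
      suf <- substr(s, b + 1, L)
      for (chrom in names(genome)) {
        cs <- genome[[chrom]]
        p5 <- stringi::stri_locate_all_fixed(cs, pre, overlap = TRUE)[[1]]
        p3 <- stringi::stri_locate_all_fixed(cs, suf, overlap = TRUE)[[1]]
        if (is.na(p5[1, 1]) || is.na(p3[1, 1])) next
        for (g5 in p5[, 1]) {
          for (g3 in p3[, 1]) {
            don <- (g5 - 1) + b          # 0-based exclusive end of 5' segment
            acc <- g3 - 1                # 0-based start of 3' segment
            span <- don - acc
            if (span > 0 && span <= max_span) {
              hits[[length(hits) + 1]] <- data.frame(
                chrom = chrom, orientation = ori,
                don_base = don - b, acc_base = acc - b,
                stringsAsFactors = FALSE
              )
            }
          }
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  unique(do.call(rbind, hits))   # shift families collapse on (don-b, acc-b)
}

# Sliding-window seed-site oracle: classify every window of the sequence
# directly by string equality (8mer > 7mer-m8 > 7mer-A1 precedence).
# Vectorized over window positions; independent of the stringi search used
# by the implementation.
oracle_count_sites <- function(seq, words) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 7) return(list(n8mer = 0L, n7mer_m8 = 0L, n7mer_a1 = 0L, total = 0L))
  i <- 1:(n - 6)
  w7 <- substring(s, i, i + 6)
  nxt <- substring(s, i + 7, i + 7)       # "" at the last window
  prv <- substring(s, i - 1, i - 1)       # "" at the first window
  is_m8 <- w7 == words$w7mer_m8
  n8 <- sum(is_m8 & nxt == "A")
  n78 <- sum(is_m8 & nxt != "A")
  is_a1 <- w7 == words$w7mer_a1 & !is_m8 &
    (i == 1L | prv != substr(words$w7mer_m8, 1, 1))
  n7a1 <- sum(is_a1)
  list(n8mer = as.integer(n8), n7mer_m8 = as.integer(n78),
       n7mer_a1 = as.integer(n7a1), total = as.integer(n8 + n78 + n7a1))
}

# Fragments needed for a target read coverage of the linear transcriptome.
fragments_for_coverage <- function(annotation, coverage, read_length = 100) {
  tx_nt <- sum(annotation$end - annotation$start)
  ceiling(coverage * tx_nt / (2 * read_length))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Single-gene world with exact exon/intron geometry (canonical splice
# signals on the requested strand), for mate/translation tests.
build_gene_world <- function(exon_lens, intron_lens, strand = "+",
                             flank = 300, seed = 1) {
  set.seed(seed)
  stopifnot(length(intron_lens) == length(exon_lens) - 1)
  pieces <- rand_dna(flank)
  pos <- flank
  rows <- list()
  for (i in seq_along(exon_lens)) {
    rows[[i]] <- data.frame(gene_id = "g1", transcript_id = "t1",
                            chrom = "chrT", strand = strand,
                            start = pos, end = pos + exon_lens[i])
    pieces <- c(pieces, rand_dna(exon_lens[i]))
    pos <- pos + exon_lens[i]
    if (i < length(exon_lens)) {
      body <- rand_dna(intron_lens[i] - 4)
      pieces <- c(pieces, if (strand == "+") paste0("GT", body, "AG")
                          else paste0("CT", body, "AC"))
      pos <- pos + intron_lens[i]
    }
  }
  pieces <- c(pieces, rand_dna(flank))
  ann <- do.call(rbind, rows)
  ann$gene_type <- "protein_coding"
  ann$cds_start <- min(ann$start)
  ann$cds_end <- max(ann$end)
  list(genome = as_genome(c(chrT = paste(pieces, collapse = ""))),
       annotation = circkit:::new_annotation(ann))
}

# Hand-built annotation: gA (one exon), gB (3 exons, CDS 120..420 so exon 1
# carries 5'UTR), gC overlapping gB's first exon.
new_annotation_for_test <- function() {
  circkit:::new_annotation(data.frame(
    gene_id = c("gA", "gB", "gB", "gB", "gC"),
    transcript_id = c("tA", "tB", "tB", "tB", "tC"),
    chrom = "chr1", strand = "+",
    start = c(10L, 100L, 200L, 350L, 90L),
    end = c(60L, 150L, 250L, 420L, 110L),
    gene_type = "protein_coding",
    cds_start = c(NA, 120L, 120L, 120L, NA),
    cds_end = c(NA, 420L, 420L, 420L, NA),
    stringsAsFactors = FALSE
  ))
}
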