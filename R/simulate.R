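# simulate: synthetic genomes, linear+circular transcript mixtures with known
# circular fractions, paired-end fragments and RPF-like reads, plus ground
# truth for recovery tests.

#' Simulate a multi-gene genome with canonical splice signals
#'
#' Generates random DNA genes on one chromosome, each with `exons_per_gene`
#' exons separated by introns that carry canonical major-spliceosome signals:
#' on the annotated strand every intron starts `GT` and ends `AG` (for minus
#' genes the forward genome therefore reads `CT ... AC`).  All exons are
#' flagged coding (the whole transcript span is the CDS), which is what the
#' downstream translation and conservation modules assume of the simulated
#' world.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene (scalar or vector recycled per gene).
#' @param exon_len_range,intron_len_range integer ranges (min, max) sampled
#'   uniformly.
#' @param intergenic nt of random DNA between genes (and at both chromosome
#'   ends).
#' @param strands gene strands; default alternates `+`/`-`.
#' @param chrom chromosome name.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return `list(genome, annotation)` with a [as_genome()] object and a
#'   `circ_annot` exon table (one transcript per gene).
#' @export
sim_genome <- function(n_genes = 6, exons_per_gene = 4,
                       exon_len_range = c(80, 300),
                       intron_len_range = c(150, 400),
                       intergenic = 500, strands = NULL,
                       chrom = "chr1", seed = NULL) {
  stopifnot(n_genes > 0, all(exons_per_gene > 0),
            all(exon_len_range > 0), all(intron_len_range >= 4))
  if (!is.null(seed)) set.seed(seed)
  nex <- rep_len(exons_per_gene, n_genes)
  if (is.null(strands)) strands <- rep_len(c("+", "-"), n_genes)
  strands <- rep_len(strands, n_genes)

  pieces <- character(0)
  pos <- 0L
  rows <- list()
  add <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add(random_dna(intergenic))
  for (g in seq_len(n_genes)) {
    n <- nex[g]
    elen <- exon_len_range[1] - 1L +
      sample.int(exon_len_range[2] - exon_len_range[1] + 1L, n, replace = TRUE)
    ilen <- if (n > 1) intron_len_range[1] - 1L +
      sample.int(intron_len_range[2] - intron_len_range[1] + 1L, n - 1L, replace = TRUE)
    else integer(0)
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%d", g), transcript_id = sprintf("t%d", g),
        chrom = chrom, strand = strands[g],
        start = pos, end = pos + elen[i], stringsAsFactors = FALSE
      )
      add(random_dna(elen[i]))
      if (i < n) {
        body <- random_dna(ilen[i] - 4L)
        intr <- if (strands[g] == "+") paste0("GT", body, "AG")
                else paste0("CT", body, "AC")
        add(intr)
      }
    }
    add(random_dna(intergenic))
  }
  genome <- as_genome(setNames(paste(pieces, collapse = ""), chrom))
  annot <- do.call(rbind, rows)
  # whole transcript treated as coding
  spans <- lapply(split(annot, annot$transcript_id), function(d) c(min(d$start), max(d$end)))
  annot$cds_start <- vapply(annot$transcript_id, function(t) spans[[t]][1], numeric(1))
  annot$cds_end <- vapply(annot$transcript_id, function(t) spans[[t]][2], numeric(1))
  annot$gene_type <- "protein_coding"
  list(genome = genome, annotation = new_annotation(annot))
}

#' Declare the simulated circular (or trans-spliced) truth
#'
#' Picks, for each listed gene, a run of consecutive exons (in transcript
#' order) that back-splice into a circle, and assigns each junction a true
#' circular fraction per sample.  `kind = "trans"` marks a junction as a
#' trans-splicing contaminant instead: the simulator then emits a linear,
#' polyadenylated exon-shuffled transcript whose seam is read-identical to
#' the back-spliced junction -- the positive control for the mate-pair and
#' poly(A) discrimination tests.
#'
#' @param annotation a `circ_annot` table.
#' @param circles data frame with columns `gene_id`, `first_exon`,
#'   `last_exon` (1-based indices in transcript order) and optionally `kind`
#'   (`"circle"` or `"trans"`).  Default: every gene with >= 3 exons circles
#'   its internal exons `2 .. n-1`.
#' @param samples sample ids.
#' @param fraction true circular fraction(s): scalar, per-junction vector, or
#'   junction x sample matrix.
#' @param intron_retention_rate probability that a circular molecule retains
#'   its internal introns (molecule-level).
#' @return a `circ_truth` list: `junctions` (with 0-based `acceptor_start`,
#'   `donor_end`), `fractions` (long junction x sample), `samples`,
#'   `intron_retention_rate`.
#' @export
sim_truth <- function(annotation, circles = NULL, samples = "s1",
                      fraction = 0.5, intron_retention_rate = 0) {
  models <- transcript_models(annotation)
  if (is.null(circles)) {
    gl <- unique(annotation[, c("gene_id", "transcript_id")])
    nex <- vapply(gl$transcript_id, function(t) nrow(models[[t]]), integer(1))
    gl <- gl[nex >= 3, , drop = FALSE]
    circles <- data.frame(gene_id = gl$gene_id, first_exon = 2L,
                          last_exon = nex[nex >= 3] - 1L)
  }
  if (is.null(circles$kind)) circles$kind <- "circle"
  juncs <- lapply(seq_len(nrow(circles)), function(i) {
    gene <- circles$gene_id[i]
    tid <- unique(annotation$transcript_id[annotation$gene_id == gene])[1]
    m <- models[[tid]]
    n <- nrow(m)
    fe <- circles$first_exon[i]; le <- circles$last_exon[i]
    stopifnot(fe >= 1, le <= n, fe <= le)
    # transcript-order index -> forward-order row
    fwd <- if (m$strand[1] == "+") seq_len(n) else rev(seq_len(n))
    rows <- fwd[fe:le]
    L <- min(m$start[rows]); R <- max(m$end[rows])
    data.frame(junction_id = sprintf("true_%s", gene), gene_id = gene,
               transcript_id = tid, chrom = m$chrom[1], strand = m$strand[1],
               acceptor_start = L, donor_end = R,
               first_exon = fe, last_exon = le, kind = circles$kind[i],
               stringsAsFactors = FALSE)
  })
  juncs <- do.call(rbind, juncs)
  nj <- nrow(juncs); ns <- length(samples)
  fr <- if (is.matrix(fraction)) fraction else matrix(rep_len(fraction, nj), nj, ns)
  stopifnot(all(fr >= 0), all(fr <= 1), nrow(fr) == nj, ncol(fr) == ns)
  fractions <- data.frame(
    junction_id = rep(juncs$junction_id, ns),
    sample_id = rep(samples, each = nj),
    fraction = as.vector(fr), stringsAsFactors = FALSE
  )
  structure(list(junctions = juncs, fractions = fractions, samples = samples,
                 intron_retention_rate = intron_retention_rate),
            class = "circ_truth")
}

# Spliced sequence of transcript exons (transcript order), rows in forward order.
spliced_seq <- function(genome, m, rows = seq_len(nrow(m))) {
  segs <- vapply(rows, function(i)
    genome_fetch(genome, m$chrom[i], m$start[i], m$end[i], "+"), character(1))
  s <- paste(segs, collapse = "")
  if (m$strand[1] == "-") revcomp_dna(s) else s
}

# Transcript-order forward row indices of the exons in a circle.
circle_rows <- function(m, first_exon, last_exon) {
  n <- nrow(m)
  fwd <- if (m$strand[1] == "+") seq_len(n) else rev(seq_len(n))
  fwd[first_exon:last_exon]
}

# Spliced circle sequence in transcript orientation (acceptor exon first).
circle_seq <- function(genome, m, first_exon, last_exon) {
  rows <- sort(circle_rows(m, first_exon, last_exon))
  spliced_seq(genome, m, rows)
}

#' Simulate paired-end RNA-seq reads for one sample
#'
#' Fragments are drawn from a template pool: the spliced linear transcript of
#' every gene, plus for each true junction either (i) a circular template
#' realized as 3 tandem copies of the spliced circle sequence (so fragments
#' can start anywhere, including across the back-spliced seam) or (ii) for
#' `kind = "trans"`, a linear exon-shuffled transcript.  Template sampling
#' weights are molarity x (template length - mean fragment length + 1), i.e.
#' equal fragment-start density per nt across isoforms, with molarity odds
#' `fraction : (1 - fraction)`; the tandem template then presents two
#' junction seams per molecule against one donor + one acceptor site per
#' linear molecule, which makes the circular-fraction estimator unbiased for
#' the molar fraction.  With `polya_selected = TRUE` circular templates are
#' excluded (circles lack poly(A) tails); trans-spliced contaminants, being
#' linear, remain.
#'
#' @param genome,annotation simulated genome and exon table.
#' @param truth a `circ_truth` object.
#' @param sample_id which sample's fractions to use (must be in
#'   `truth$samples`).
#' @param n_fragments number of fragments (2 reads each).
#' @param read_length read length (>= 40 for discovery).
#' @param fragment_mean,fragment_sd fragment length distribution
#'   (Normal(200, 30) by default, clamped to `[read_length, template]`).
#' @param polya_selected simulate a poly(A)-selected library.
#' @param error_rate per-base substitution rate (0 by default; the split
#'   alignment stage is exact).
#' @param seed RNG seed.
#' @return read data frame (`read_id`, `mate`, `seq`, `sample_id`) with the
#'   originating template in attribute `"templates"`.
#' @export
sim_reads <- function(genome, annotation, truth, sample_id = NULL,
                      n_fragments = 2000, read_length = 100,
                      fragment_mean = 200, fragment_sd = 30,
                      polya_selected = FALSE, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_id <- sample_id %||% truth$samples[1]
  stopifnot(sample_id %in% truth$samples)
  models <- transcript_models(annotation)
  fr <- truth$fractions[truth$fractions$sample_id == sample_id, , drop = FALSE]
  jt <- truth$junctions
  rr <- truth$intron_retention_rate

  templates <- list(); molarity <- numeric(0); tnames <- character(0)
  push <- function(name, s, m) {
    templates[[length(templates) + 1L]] <<- s
    molarity[length(molarity) + 1L] <<- m
    tnames[length(tnames) + 1L] <<- name
  }
  for (tid in names(models)) {
    m <- models[[tid]]
    ji <- which(jt$transcript_id == tid)
    f <- if (length(ji)) sum(fr$fraction[match(jt$junction_id[ji], fr$junction_id)]) else 0
    push(paste0("lin_", tid), spliced_seq(genome, m), 1 - f)
    for (j in ji) {
      fj <- fr$fraction[match(jt$junction_id[j], fr$junction_id)]
      if (fj <= 0) next
      if (jt$kind[j] == "circle") {
        if (polya_selected) next
        cs <- circle_seq(genome, m, jt$first_exon[j], jt$last_exon[j])
        if (rr < 1) push(paste0("circ_", jt$junction_id[j]), strrep(cs, 3L), fj * (1 - rr))
        if (rr > 0) {
          ret <- genome_fetch(genome, jt$chrom[j], jt$acceptor_start[j],
                              jt$donor_end[j], jt$strand[j])
          push(paste0("circret_", jt$junction_id[j]), strrep(ret, 3L), fj * rr)
        }
      } else {  # trans-spliced linear contaminant, carries poly(A)
        n <- nrow(m)
        fwd <- if (m$strand[1] == "+") seq_len(n) else rev(seq_len(n))
        tord <- c(fwd[1:jt$last_exon[j]], fwd[jt$first_exon[j]:n])
        segs <- vapply(tord, function(i) {
          s <- genome_fetch(genome, m$chrom[i], m$start[i], m$end[i], "+")
          if (m$strand[1] == "-") revcomp_dna(s) else s
        }, character(1))
        # minus-strand transcript order walks forward rows right-to-left, and
        # each segment must be in transcript orientation
        push(paste0("trans_", jt$junction_id[j]), paste(segs, collapse = ""), fj)
      }
    }
  }
  len <- nchar(unlist(templates))
  w <- molarity * pmax(1, len - fragment_mean + 1)
  if (all(w <= 0)) stopf("no template has positive weight")
  ti <- sample.int(length(templates), n_fragments, replace = TRUE, prob = w)
  fl <- pmin(len[ti], pmax(read_length, round(rnorm(n_fragments, fragment_mean, fragment_sd))))
  st <- floor(runif(n_fragments) * (len[ti] - fl + 1))  # 0-based
  tpl <- unlist(templates)[ti]
  r1 <- stringi::stri_sub(tpl, st + 1L, length = read_length)
  r2 <- revcomp_dna(stringi::stri_sub(tpl, st + fl - read_length + 1L, length = read_length))
  if (error_rate > 0) {
    r1 <- mutate_seqs(r1, error_rate)
    r2 <- mutate_seqs(r2, error_rate)
  }
  ids <- sprintf("%s_frag%06d", sample_id, seq_len(n_fragments))
  out <- data.frame(
    read_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n_fragments),
    seq = c(r1, r2), sample_id = sample_id, stringsAsFactors = FALSE
  )
  attr(out, "templates") <- rep(tnames[ti], 2L)
  out
}

# Random substitutions at the given per-base rate.
mutate_seqs <- function(seqs, rate) {
  n <- nchar(seqs)
  k <- stats::rbinom(length(seqs), n, rate)
  hit <- which(k > 0)
  for (i in hit) {
    pos <- sample.int(n[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

#' Simulate ribosome-protected fragments (RPF)
#'
#' Short reads drawn exclusively from spliced linear transcripts: by
#' construction no RPF read ever spans a back-spliced junction, which is the
#' empirical behavior the translation module tests for.
#'
#' @param genome,annotation simulated genome and exon table.
#' @param n_reads number of RPF reads.
#' @param read_length RPF length (~30 nt).
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return read data frame (`mate` is always 1).
#' @export
sim_rpf <- function(genome, annotation, n_reads = 2000, read_length = 30,
                    sample_id = "rpf", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  models <- transcript_models(annotation)
  tpl <- vapply(models, function(m) spliced_seq(genome, m), character(1))
  len <- nchar(tpl)
  keep <- len >= read_length
  tpl <- tpl[keep]; len <- len[keep]
  ti <- sample.int(length(tpl), n_reads, replace = TRUE, prob = len - read_length + 1)
  st <- floor(runif(n_reads) * (len[ti] - read_length + 1))
  data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n_reads)), mate = 1L,
    seq = stringi::stri_sub(tpl[ti], st + 1L, length = read_length),
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}
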