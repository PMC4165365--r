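# mirna: canonical seed-site counting on concatenated circRNA exons,
# composition-preserving permuted-word null cohorts, RBP/AGO2 cluster
# analyses.

#' Canonical target words of a miRNA family
#'
#' From the mature miRNA sequence (RNA or DNA alphabet): the 7mer-m8 word is
#' the DNA reverse complement of the seed (miRNA positions 2-8), the 8mer
#' appends an `A` (opposite miRNA position 1), and the 7mer-A1 is the
#' reverse complement of positions 2-7 plus the `A`.
#'
#' @param mature mature miRNA sequence (>= 8 nt).
#' @param family optional family name carried through.
#' @return list: `family`, `seed`, `w8mer`, `w7mer_m8`, `w7mer_a1`.
#' @export
#' @examples
#' site_words("UGGAAGACUAGUGAUUUUGUUGU", "miR-7")  # 8mer GTCTTCCA
site_words <- function(mature, family = NA_character_) {
  m <- rna_to_dna(mature)
  if (nchar(m) < 8L) stopf("mature sequence shorter than 8 nt")
  seed <- substr(m, 2L, 8L)
  w78 <- revcomp_dna(seed)
  list(family = family, seed = seed,
       w8mer = paste0(w78, "A"), w7mer_m8 = w78,
       w7mer_a1 = paste0(revcomp_dna(substr(m, 2L, 7L)), "A"))
}

#' Count canonical miRNA sites in a sequence
#'
#' Scans every position of the (concatenated exonic) sequence and classifies
#' each seed-region match as exactly one site type, 8mer taking precedence
#' over 7mer-m8 over 7mer-A1.  Sites are not counted across the circular
#' junction unless `wrap_junction = TRUE`, which appends the first 7 nt to
#' the end for circle-aware scanning.
#'
#' @param seq DNA sequence (5' to 3' of the transcript).
#' @param words site words from [site_words()].
#' @param wrap_junction scan across the circular junction.
#' @return list of counts: `n8mer`, `n7mer_m8`, `n7mer_a1`, `total`.
#' @export
count_sites <- function(seq, words, wrap_junction = FALSE) {
  s <- toupper(seq)
  if (wrap_junction && nchar(s) >= 7L) s <- paste0(s, substr(s, 1L, 7L))
  n <- nchar(s)
  m8 <- stringi::stri_locate_all_fixed(s, words$w7mer_m8, overlap = TRUE)[[1]]
  n8 <- 0L; n78 <- 0L
  if (!is.na(m8[1, 1])) {
    nxt <- substr(rep(s, nrow(m8)), m8[, 2] + 1L, m8[, 2] + 1L)
    n8 <- sum(nxt == "A")
    n78 <- nrow(m8) - n8
  }
  a1 <- stringi::stri_locate_all_fixed(s, words$w7mer_a1, overlap = TRUE)[[1]]
  n7a1 <- 0L
  if (identical(words$w7mer_a1, words$w7mer_m8)) {
    # degenerate repetitive seed: the A1 word is the m8 word, every
    # occurrence is already classified by the m8 scan
    a1 <- matrix(NA_integer_, 1, 2)
  }
  if (!is.na(a1[1, 1])) {
    # an A1 word preceded by the m8-position match is part of an 8mer
    prev <- substr(rep(s, nrow(a1)), a1[, 1] - 1L, a1[, 1] - 1L)
    n7a1 <- sum(a1[, 1] == 1L | prev != substr(words$w7mer_m8, 1L, 1L))
  }
  list(n8mer = as.integer(n8), n7mer_m8 = as.integer(n78),
       n7mer_a1 = as.integer(n7a1),
       total = as.integer(n8 + n78 + n7a1))
}

#' Seed-site tallies for circRNAs x miRNA families
#'
#' @param seqs named character vector of concatenated circRNA exonic
#'   sequences.
#' @param families data frame `family`, `mature` (and optionally `tier`).
#' @param wrap_junction see [count_sites()].
#' @return long data frame `circ_id`, `family`, `n8mer`, `n7mer_m8`,
#'   `n7mer_a1`, `total`.
#' @export
count_sites_tally <- function(seqs, families, wrap_junction = FALSE) {
  out <- list()
  for (f in seq_len(nrow(families))) {
    w <- site_words(families$mature[f], families$family[f])
    for (i in seq_along(seqs)) {
      ct <- count_sites(seqs[[i]], w, wrap_junction = wrap_junction)
      out[[length(out) + 1L]] <- data.frame(
        circ_id = names(seqs)[i] %||% as.character(i), family = w$family,
        n8mer = ct$n8mer, n7mer_m8 = ct$n7mer_m8, n7mer_a1 = ct$n7mer_a1,
        total = ct$total, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# All distinct permutations of a character multiset (n <= ~8).
.multiset_perms <- function(chars) {
  chars <- sort(chars)
  n <- length(chars)
  if (n <= 1L) return(matrix(chars, nrow = 1))
  out <- list()
  for (c0 in unique(chars)) {
    rest <- chars[-match(c0, chars)]
    sub <- .multiset_perms(rest)
    out[[length(out) + 1L]] <- cbind(c0, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

.cg_count <- function(x) stringi::stri_count_fixed(x, "CG", overlap = TRUE)

#' Valid composition-preserving permutations of an 8mer site
#'
#' Enumerates the distinct permutations of the 8mer word that preserve its
#' mononucleotide composition, preserve the number of CG dinucleotides
#' (counted on the linear word) and end in `A` (the 3'-most nucleotide of a
#' canonical 8mer site).  The original word is always a member; degenerate
#' words (e.g. `AAAAAAAA`) may have no alternative.
#'
#' @param w8 an 8-nt site word ending in `A`.
#' @return character vector of valid words (includes `w8`).
#' @export
permute_site_word <- function(w8) {
  stopifnot(nchar(w8) == 8L)
  if (substr(w8, 8L, 8L) != "A") stopf("8mer site must end in A: %s", w8)
  chars <- strsplit(substr(w8, 1L, 7L), "")[[1]]
  perms <- .multiset_perms(chars)
  cand <- unique(paste0(apply(perms, 1L, paste, collapse = ""), "A"))
  cand[.cg_count(cand) == .cg_count(w8)]
}

#' Permuted-word null cohorts
#'
#' For each of `n_cohorts` cohorts, every family's 8mer is replaced by a
#' uniformly sampled valid permutation (see [permute_site_word()]); the
#' 7mer words are recomputed from the permuted 8mer (7mer-m8 = first 7 nt,
#' 7mer-A1 = last 7 nt).  A family with no alternative permutation keeps
#' its original word with a warning.
#'
#' @param families data frame `family`, `mature`.
#' @param n_cohorts number of null cohorts.
#' @param seed RNG seed.
#' @return list of cohorts; each is a list of word sets as returned by
#'   [site_words()] (with permuted words).
#' @export
permuted_cohorts <- function(families, n_cohorts = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- lapply(seq_len(nrow(families)), function(f)
    site_words(families$mature[f], families$family[f]))
  # control words are permutations *other than* the site itself (a null that
  # could redraw the original word could never be exceeded)
  valid <- lapply(base, function(w) setdiff(permute_site_word(w$w8mer), w$w8mer))
  for (f in seq_along(valid)) {
    if (length(valid[[f]]) == 0L) {
      warnf("family %s has no alternative permutation; keeping original word",
            base[[f]]$family)
    }
  }
  lapply(seq_len(n_cohorts), function(cc) {
    lapply(seq_along(base), function(f) {
      w8 <- if (length(valid[[f]]) >= 1L) sample(valid[[f]], 1L) else base[[f]]$w8mer
      list(family = base[[f]]$family, seed = base[[f]]$seed, w8mer = w8,
           w7mer_m8 = substr(w8, 1L, 7L), w7mer_a1 = substr(w8, 2L, 8L))
    })
  })
}

#' Null distribution of seed-site totals from permuted cohorts
#'
#' Re-runs site counting with each permuted cohort and returns the null
#' totals per circRNA x family together with the across-cohort maximum
#' envelope (the upper limit a genuine sponge must exceed).
#'
#' @param seqs named character vector of circRNA sequences.
#' @param families data frame `family`, `mature`.
#' @param n_cohorts,seed see [permuted_cohorts()].
#' @param wrap_junction see [count_sites()].
#' @return list: `observed` (tally data frame), `null_totals` (array circ x
#'   family x cohort), `envelope` (circ x family max over cohorts).
#' @export
null_site_distribution <- function(seqs, families, n_cohorts = 1000,
                                   seed = NULL, wrap_junction = FALSE) {
  obs <- count_sites_tally(seqs, families, wrap_junction = wrap_junction)
  cohorts <- permuted_cohorts(families, n_cohorts, seed = seed)
  ncirc <- length(seqs); nfam <- nrow(families)
  ids <- names(seqs) %||% as.character(seq_len(ncirc))
  nt <- array(0L, c(ncirc, nfam, n_cohorts),
              dimnames = list(ids, families$family, NULL))
  for (cc in seq_len(n_cohorts)) {
    for (f in seq_len(nfam)) {
      w <- cohorts[[cc]][[f]]
      for (i in seq_len(ncirc)) {
        nt[i, f, cc] <- count_sites(seqs[[i]], w, wrap_junction)$total
      }
    }
  }
  env <- apply(nt, c(1, 2), max)
  list(observed = obs, null_totals = nt, envelope = env)
}

#' Crosslink-cluster density: circular vs neighboring exons
#'
#' Density is the number of clusters overlapping an exon set per exonic kb.
#' Each circRNA's coding-exon density is compared with that of its
#' neighboring linear coding exons by a paired two-sided Mann-Whitney
#' (Wilcoxon signed-rank) test; circRNAs without neighbor exons are
#' excluded.
#'
#' @param clusters data frame `chrom`, `start`, `end` (0-based half-open
#'   crosslink cluster intervals).
#' @param circ_exons,neighbor_exons named lists (by circ id) of exon data
#'   frames (`chrom` attached or passed per-exon row).
#' @return list: `per_circ` (densities), `p_value`.
#' @export
cluster_density_compare <- function(clusters, circ_exons, neighbor_exons) {
  dens <- function(ex) {
    if (is.null(ex) || nrow(ex) == 0L) return(NA_real_)
    kb <- sum(ex$end - ex$start) / 1000
    hit <- 0L
    for (i in seq_len(nrow(clusters))) {
      if (any(clusters$chrom[i] == ex$chrom &
                clusters$start[i] < ex$end & clusters$end[i] > ex$start))
        hit <- hit + 1L
    }
    hit / kb
  }
  ids <- intersect(names(circ_exons), names(neighbor_exons))
  per <- data.frame(
    circ_id = ids,
    circ_density = vapply(circ_exons[ids], dens, numeric(1)),
    neighbor_density = vapply(neighbor_exons[ids], dens, numeric(1)),
    stringsAsFactors = FALSE
  )
  per <- per[!is.na(per$circ_density) & !is.na(per$neighbor_density), , drop = FALSE]
  p <- if (nrow(per) < 3) NA_real_
  else if (all(per$circ_density == per$neighbor_density)) 1
  else stats::wilcox.test(per$circ_density, per$neighbor_density,
                          paired = TRUE, exact = FALSE)$p.value
  list(per_circ = per, p_value = p)
}

#' Assign crosslink clusters to miRNA families
#'
#' A cluster overlapping a circRNA's exons is assigned to family `f` when
#' the cluster's sequence (in the circRNA's strand orientation) contains any
#' of `f`'s three site words; a cluster containing words of several families
#' counts for each.
#'
#' @param clusters cluster data frame (`chrom`, `start`, `end`).
#' @param catalog catalog data frame.
#' @param genome a `circ_genome`.
#' @param families data frame `family`, `mature`.
#' @return long data frame `circ_id`, `family`, `n_clusters`.
#' @export
assign_clusters_to_family <- function(clusters, catalog, genome, families) {
  words <- lapply(seq_len(nrow(families)), function(f)
    site_words(families$mature[f], families$family[f]))
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, , drop = FALSE]
    ex <- catalog_exons(rec)
    ov <- clusters$chrom == rec$chrom &
      vapply(seq_len(nrow(clusters)), function(k)
        any(clusters$start[k] < ex$end & clusters$end[k] > ex$start), logical(1))
    cl <- clusters[ov, , drop = FALSE]
    cseq <- vapply(seq_len(nrow(cl)), function(k)
      genome_fetch(genome, cl$chrom[k], cl$start[k], cl$end[k], rec$strand),
      character(1))
    for (w in words) {
      nhit <- sum(vapply(cseq, function(s)
        stringi::stri_detect_fixed(s, w$w8mer) ||
          stringi::stri_detect_fixed(s, w$w7mer_m8) ||
          stringi::stri_detect_fixed(s, w$w7mer_a1), logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        circ_id = rec$circ_id, family = w$family, n_clusters = nhit,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
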