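# specificity: Jensen-Shannon cell-type specificity against an
# expression-matched linear-junction cohort; circular-fraction matrix.

# Shannon entropy in bits with 0 log 0 := 0.
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence (base-2 logs) between two distributions.
.jsd2 <- function(p, q) {
  .entropy2((p + q) / 2) - (.entropy2(p) + .entropy2(q)) / 2
}

#' Jensen-Shannon cell-type specificity score
#'
#' `max_t (1 - sqrt(JSD(p, e_t)))` where `p` is the normalized expression
#' profile over samples and `e_t` the indicator distribution of sample `t`;
#' JSD uses base-2 logarithms, so the score lies in `[0, 1]` and equals 1
#' exactly for single-sample profiles.
#'
#' @param x non-negative expression values across samples (counts); an
#'   all-zero profile returns `NA`.
#' @return scalar score in `[0, 1]`.
#' @export
#' @examples
#' js_specificity(c(1, 0, 0))    # 1
#' js_specificity(c(1, 1))       # ~0.4421
js_specificity <- function(x) {
  stopifnot(all(x >= 0), length(x) >= 2)
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  p <- x / s
  best <- 0
  for (t in seq_along(p)) {
    e <- numeric(length(p)); e[t] <- 1
    best <- max(best, 1 - sqrt(max(0, .jsd2(p, e))))
  }
  best
}

#' Specificity scores for a matrix of profiles
#' @param mat features x samples non-negative matrix.
#' @return numeric vector (NA for all-zero rows).
#' @export
specificity_scores <- function(mat) {
  apply(mat, 1L, function(x) if (sum(x) <= 0) NA_real_ else js_specificity(x))
}

#' Expression-matched linear control cohort
#'
#' Samples linear junctions so that the histogram of total junction-spanning
#' reads (unit-width `log2(total + 1)` bins) matches the circRNA set's
#' histogram bin for bin; sampling is without replacement, falling back to
#' with-replacement (with a warning) in bins with too few linear candidates.
#'
#' @param circ_totals total junction-spanning reads per circRNA.
#' @param linear_totals totals for the linear junction pool.
#' @return integer indices into the linear pool (length =
#'   `length(circ_totals)`).
#' @export
matched_linear_cohort <- function(circ_totals, linear_totals) {
  bin <- function(x) floor(log2(x + 1))
  cb <- bin(circ_totals); lb <- bin(linear_totals)
  picks <- integer(0)
  for (b in sort(unique(cb))) {
    need <- sum(cb == b)
    avail <- which(lb == b)
    if (length(avail) == 0L) {
      # empty bin: fall back to the nearest populated expression bin
      nb <- unique(lb)[which.min(abs(unique(lb) - b))]
      warnf("no linear candidates in expression bin %d; using nearest bin %d", b, nb)
      avail <- which(lb == nb)
    }
    if (length(avail) >= need) {
      picks <- c(picks, sample(avail, need))
    } else {
      warnf("bin %d has %d linear candidates for %d circRNAs; sampling with replacement",
            b, length(avail), need)
      picks <- c(picks, sample(avail, need, replace = TRUE))
    }
  }
  picks
}

#' Compare circRNA and matched-linear specificity distributions
#'
#' @param circ_mat,linear_mat features x samples count matrices (circular
#'   and linear junction-spanning reads).
#' @return list: `circ_scores`, `control_scores`, `cohort` (indices),
#'   `p_value` (two-sided Mann-Whitney).
#' @export
specificity_comparison <- function(circ_mat, linear_mat) {
  ct <- rowSums(circ_mat); lt <- rowSums(linear_mat)
  keep <- ct > 0
  cohort <- matched_linear_cohort(ct[keep], lt)
  cs <- specificity_scores(circ_mat[keep, , drop = FALSE])
  ls <- specificity_scores(linear_mat[cohort, , drop = FALSE])
  p <- stats::wilcox.test(cs, ls, exact = FALSE)$p.value
  list(circ_scores = cs, control_scores = ls, cohort = cohort, p_value = p)
}

#' Circular-fraction matrix across samples
#'
#' Restricts to junctions whose donor and acceptor availability are each
#' supported by at least `min_avail` reads in every sample, and returns the
#' junction x sample fraction matrix with pairwise Spearman correlations
#' between samples.
#'
#' @param counts long count table from [count_junction_reads()].
#' @param min_avail per-site availability threshold (reads).
#' @return list: `matrix` (fractions), `spearman` (sample x sample rho),
#'   `median_rho` (off-diagonal median).
#' @export
cf_matrix <- function(counts, min_avail = 5) {
  ok <- counts$n_donor >= min_avail & counts$n_acceptor >= min_avail
  keep_j <- names(which(tapply(ok, counts$junction_id, all)))
  samples <- sort(unique(counts$sample_id))
  if (length(keep_j) == 0L) {
    warnf("no junction passes the availability filter")
    m <- matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples))
    return(list(matrix = m, spearman = NULL, median_rho = NA_real_))
  }
  cc <- counts[counts$junction_id %in% keep_j, , drop = FALSE]
  m <- matrix(NA_real_, length(keep_j), length(samples),
              dimnames = list(keep_j, samples))
  m[cbind(match(cc$junction_id, keep_j), match(cc$sample_id, samples))] <- cc$fraction
  rho <- if (length(samples) >= 2 && nrow(m) >= 2)
    stats::cor(m, method = "spearman") else NULL
  med <- if (!is.null(rho) && length(samples) > 1)
    stats::median(rho[lower.tri(rho)]) else NA_real_
  list(matrix = m, spearman = rho, median_rho = med)
}
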