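test_that("site words derive from the seed by reverse complement", {
  w <- site_words("UGGAAGACUAGUGAUUUUGUUGU", "miR-7")
  expect_equal(w$seed, "GGAAGAC")
  expect_equal(w$w7mer_m8, "GTCTTCC")
  expect_equal(w$w8mer, "GTCTTCCA")
  expect_equal(w$w7mer_a1, "TCTTCCA")
  # poly-U seed gives poly-A complements
  wu <- site_words("AUUUUUUUGG")
  expect_equal(wu$w7mer_m8, "AAAAAAA")
  expect_equal(wu$w8mer, "AAAAAAAA")
  expect_error(site_words("UGGAAGA"), "8 nt")
  # deterministic
  expect_identical(site_words("UGGAAGACUAGUGAUUUUGUUGU"),
                   site_words("UGGAAGACUAGUGAUUUUGUUGU"))
})

test_that("site classes are mutually exclusive with 8mer precedence", {
  w <- site_words("UGGAAGACUAGUGAUUUUGUUGU", "miR-7")
  expect_equal(count_sites("GTCTTCCA", w)[c("n8mer", "n7mer_m8", "n7mer_a1")],
               list(n8mer = 1L, n7mer_m8 = 0L, n7mer_a1 = 0L))
  expect_equal(count_sites("GTCTTCCG", w)$n7mer_m8, 1L)
  expect_equal(count_sites("GTCTTCCG", w)$total, 1L)
  expect_equal(count_sites("TTCTTCCA", w)[c("n8mer", "n7mer_m8", "n7mer_a1")],
               list(n8mer = 0L, n7mer_m8 = 0L, n7mer_a1 = 1L))
  # junction wrap: site split across the circle start/end
  circ <- paste0("TCCAGGGGGGGGGGGGGGGGTCT")   # ...GTCT + TCCA... wraps to GTCTTCCA?
  expect_equal(count_sites(circ, w)$total, 0L)
  expect_equal(count_sites(circ, w, wrap_junction = TRUE)$total, 1L)
})

test_that("count_sites equals the sliding-window oracle on random sequences", {
  set.seed(111)
  fams <- data.frame(
    family = sprintf("fam%d", 1:4),
    mature = c("UGGAAGACUAGUGAUUUUGUUGU", "UAAGGCACGCGGUGAAUGCC",
               "AUUUUUUUGGAA", "UCCCUGAGACCCUAACUUGUGA")
  )
  for (f in seq_len(nrow(fams))) {
    w <- site_words(fams$mature[f], fams$family[f])
    for (r in 1:25) {
      s <- rand_dna(300)
      # salt with site words to exercise all classes
      if (r %% 3 == 0) s <- paste0(s, w$w8mer, rand_dna(5), w$w7mer_a1)
      if (r %% 4 == 0) s <- paste0(w$w7mer_m8, "G", s)
      got <- count_sites(s, w)
      exp <- oracle_count_sites(s, w)
      expect_identical(got[c("n8mer", "n7mer_m8", "n7mer_a1", "total")],
                       exp[c("n8mer", "n7mer_m8", "n7mer_a1", "total")])
    }
  }
})

test_that("permuted words preserve composition, CG count and the terminal A", {
  for (w8 in c("GTCTTCCA", "ACGCGCCA", "GGCCAATA")) {
    perms <- permute_site_word(w8)
    expect_true(w8 %in% perms)
    srt <- function(x) paste(sort(strsplit(x, "")[[1]]), collapse = "")
    cg <- function(x) stringi::stri_count_fixed(x, "CG", overlap = TRUE)
    expect_true(all(vapply(perms, srt, "") == srt(w8)))
    expect_true(all(vapply(perms, cg, 0L) == cg(w8)))
    expect_true(all(substr(perms, 8, 8) == "A"))
  }
  # spec'd example candidate is valid for the miR-7 8mer
  expect_true("TCTCTGCA" %in% permute_site_word("GTCTTCCA"))
  # degenerate word: only itself; cohorts fall back with a warning
  expect_equal(permute_site_word("AAAAAAAA"), "AAAAAAAA")
  fams <- data.frame(family = "polyU", mature = "AUUUUUUUUU")
  expect_warning(co <- permuted_cohorts(fams, n_cohorts = 2, seed = 1),
                 "no alternative")
  expect_equal(co[[1]][[1]]$w8mer, "AAAAAAAA")
  # reproducible under a fixed seed; derived 7mers recomputed from the 8mer
  fams2 <- data.frame(family = "miR-7", mature = "UGGAAGACUAGUGAUUUUGUUGU")
  c1 <- permuted_cohorts(fams2, n_cohorts = 5, seed = 9)
  c2 <- permuted_cohorts(fams2, n_cohorts = 5, seed = 9)
  expect_identical(c1, c2)
  for (k in 1:5) {
    wk <- c1[[k]][[1]]
    expect_equal(wk$w7mer_m8, substr(wk$w8mer, 1, 7))
    expect_equal(wk$w7mer_a1, substr(wk$w8mer, 2, 8))
  }
})

test_that("planted sites exceed the permuted-cohort envelope (sponge detection)", {
  set.seed(112)
  fams <- data.frame(family = c("miR-7", "ctrl"),
                     mature = c("UGGAAGACUAGUGAUUUUGUUGU",
                                "UAAGGCACGCGGUGAAUGCC"))
  w7 <- site_words(fams$mature[1])
  sponge <- paste0(rand_dna(100),
                   paste(vapply(1:15, function(i) paste0(w7$w8mer, rand_dna(20)),
                                ""), collapse = ""),
                   rand_dna(100))
  plain <- rand_dna(nchar(sponge))
  seqs <- c(sponge = sponge, plain = plain)
  nd <- null_site_distribution(seqs, fams, n_cohorts = 100, seed = 7)
  obs_sponge <- nd$observed$total[nd$observed$circ_id == "sponge" &
                                    nd$observed$family == "miR-7"]
  expect_gte(obs_sponge, 15L)
  expect_gt(obs_sponge, nd$envelope["sponge", "miR-7"])
  # the plain sequence stays within the envelope
  obs_plain <- nd$observed$total[nd$observed$circ_id == "plain" &
                                   nd$observed$family == "miR-7"]
  expect_lte(obs_plain, max(2L, nd$envelope["plain", "miR-7"] + 1L))
})

test_that("cluster density and cluster-to-family assignment find a planted sponge", {
  # 12 synthetic circles, each with one exon set and one neighbor set
  ids <- sprintf("c%02d", 1:12)
  circ_ex <- lapply(1:12, function(i)
    data.frame(chrom = "chr1", start = i * 10000L, end = i * 10000L + 500L))
  nb_ex <- lapply(1:12, function(i)
    data.frame(chrom = "chr1", start = i * 10000L + 2000L,
               end = i * 10000L + 2500L))
  names(circ_ex) <- ids; names(nb_ex) <- ids
  # clusters only inside circles: circ density exceeds neighbor density
  clusters <- do.call(rbind, lapply(circ_ex, function(ex)
    data.frame(chrom = ex$chrom[1], start = ex$start[1] + 5L,
               end = ex$start[1] + 35L)))
  cd <- cluster_density_compare(clusters, circ_ex, nb_ex)
  expect_true(all(cd$per_circ$circ_density > cd$per_circ$neighbor_density))
  expect_lt(cd$p_value, 0.05)
  # empty track: all densities zero
  cd0 <- cluster_density_compare(clusters[0, ], circ_ex, nb_ex)
  expect_true(all(cd0$per_circ$circ_density == 0))
  expect_equal(cd0$p_value, 1)

  # cluster-to-family assignment: a cluster covering a planted word counts
  w <- default_world()
  res <- run_pipeline(w$sim$genome, w$reads, annotation = w$sim$annotation)
  cat_tab <- res$catalog_table
  expect_gt(nrow(cat_tab), 1)
  fams <- data.frame(family = c("miR-7", "ctrl"),
                     mature = c("UGGAAGACUAGUGAUUUUGUUGU",
                                "UAAGGCACGCGGUGAAUGCC"))
  wmir <- site_words(fams$mature[1])
  rec <- cat_tab[1, ]
  ex1 <- circkit:::catalog_exons(rec)
  # plant the 8mer inside the first exon of the first circle
  g <- unclass(w$sim$genome)
  pos <- ex1$start[1] + 10L
  word <- if (rec$strand == "-") revcomp_dna(wmir$w8mer) else wmir$w8mer
  substr(g[[rec$chrom]], pos + 1L, pos + 8L) <- word
  g2 <- as_genome(g)
  clus <- data.frame(chrom = rec$chrom, start = pos - 4L, end = pos + 12L)
  asg <- assign_clusters_to_family(clus, cat_tab, g2, fams)
  expect_equal(asg$n_clusters[asg$circ_id == rec$circ_id & asg$family == "miR-7"], 1L)
  expect_equal(sum(asg$n_clusters[asg$circ_id != rec$circ_id]), 0L)
})
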