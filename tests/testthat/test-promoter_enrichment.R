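test_that("upstream extraction is strand-aware and clip-flagged", {
  contig <- random_dna_seq(8000)
  genome <- c(c1 = contig)
  plus <- gene_model("gp", "c1", "+", cbind(5000L, 5300L),
                     cbind(5000L, 5300L))
  ps <- extract_upstream(genome, list(plus), L = 2000L)
  expect_equal(ps$promoters[["gp"]], substr(contig, 3001, 5000))
  expect_equal(ps$bed$start, 3000)
  expect_equal(ps$bed$end, 5000)

  minus <- gene_model("gm", "c1", "-", cbind(2000L, 2300L),
                      cbind(2000L, 2300L))     # tss = 2299
  psm <- extract_upstream(genome, list(minus), L = 2000L)
  expect_equal(psm$promoters[["gm"]],
               reverse_complement(substr(contig, 2301, 4300)))

  near <- gene_model("gn", "c1", "+", cbind(500L, 800L), cbind(500L, 800L))
  psn <- extract_upstream(genome, list(near), L = 2000L)
  expect_equal(nchar(psn$promoters[["gn"]]), 500L)
  expect_equal(psn$clipped, "gn")

  edge <- gene_model("ge", "c1", "+", cbind(0L, 300L), cbind(0L, 300L))
  expect_warning(
    out <- extract_upstream(genome, list(edge, plus), L = 2000L),
    "zero upstream")
  expect_false("ge" %in% names(out$promoters))
})

test_that("motif scanning honours IUPAC, overlaps and palindromes", {
  motifs <- data.frame(
    motif_id = c("pal", "iupacN", "polyA"),
    iupac = c("CACGTG", "CANNTG", "AAA"))
  seqs <- c(g1 = paste0("TTTTT", "CACGTG", "TTTTT"),
            g2 = paste0("TTTTT", "CAGGTG", "TTTTT"),
            g3 = "AAAATTTTTTTTTT")
  sc <- scan_motifs(seqs, motifs, both_strands = TRUE)
  expect_equal(sc$counts["g1", "pal"], 1L)      # palindrome counted once
  expect_equal(sc$counts["g2", "iupacN"], 1L)   # N matches any base
  expect_equal(sc$counts["g3", "polyA"], 2L +
                 naive_iupac_count("AAAATTTTTTTTTT", "AAA") - 2L)
  expect_equal(sc$counts["g3", "polyA"],
               naive_iupac_count(seqs[["g3"]], "AAA"))
  expect_true(sc$presence["g1", "pal"])
  # overlap convention in isolation: AAA in AAAA on one strand = 2
  one <- scan_motifs(c(g = "AAAA"), data.frame(motif_id = "m",
                                               iupac = "AAA"),
                     both_strands = FALSE)
  expect_equal(unname(one$counts["g", "m"]), 2L)
  # sequence N matches only motif letter N
  nseq <- c(g = "CANTG")
  expect_equal(unname(scan_motifs(nseq, data.frame(motif_id = "m",
                                                   iupac = "CANTG"),
                                  FALSE)$counts[1, 1]), 1L)
  expect_equal(unname(scan_motifs(nseq, data.frame(motif_id = "m",
                                                   iupac = "CAATG"),
                                  FALSE)$counts[1, 1]), 0L)
})

test_that("motif scanning equals the brute-force matcher", {
  set.seed(127)
  motifs <- data.frame(motif_id = paste0("M", 1:8),
                       iupac = c("CACGTG", "CANNTG", "WTTGAC", "RYSWKM",
                                 "AAA", "GATCGATC", "BDHV", "TTGACY"))
  seqs <- setNames(vapply(1:20, function(i) random_dna_seq(300),
                          character(1)), paste0("g", 1:20))
  sc <- scan_motifs(seqs, motifs, both_strands = TRUE)
  for (g in names(seqs)) for (m in seq_len(nrow(motifs)))
    expect_equal(sc$counts[g, m],
                 naive_iupac_count(seqs[[g]], motifs$iupac[m]),
                 label = paste(g, motifs$motif_id[m]))
})

test_that("scanning is strand-symmetric under both_strands", {
  set.seed(131)
  motifs <- data.frame(motif_id = paste0("M", 1:4),
                       iupac = c("CACGTG", "TTGACY", "RYSWKM", "GATC"))
  seqs <- setNames(vapply(1:10, function(i) random_dna_seq(400),
                          character(1)), paste0("g", 1:10))
  fwd <- scan_motifs(seqs, motifs, both_strands = TRUE)
  rc <- scan_motifs(setNames(reverse_complement(seqs), names(seqs)),
                    motifs, both_strands = TRUE)
  expect_equal(fwd$counts, rc$counts)
})

test_that("exact binomial tail matches closed forms and enumeration", {
  pres <- matrix(c(rep(TRUE, 5), rep(c(TRUE, FALSE), 5)), ncol = 1,
                 dimnames = list(paste0("g", 1:15), "m"))
  # x = 5, n = 5, p0 = 0.5 (background = the 10 alternating genes)
  en <- binomial_enrichment(pres[, , drop = FALSE],
                            group = paste0("g", 1:5),
                            background = paste0("g", 1:15))
  # p0 here is 10/15; check directly against the summation oracle
  expect_equal(en$p_value, binom_tail_sum(5, 5, 10 / 15), tolerance = 1e-12)

  p <- stats::pbinom(4, 5, 0.5, lower.tail = FALSE)
  expect_equal(p, 0.03125)                 # the 0.5^5 identity

  # x = 0 with alternative greater has p = 1
  pres0 <- matrix(c(rep(FALSE, 3), rep(TRUE, 6)), ncol = 1,
                  dimnames = list(paste0("g", 1:9), "m"))
  en0 <- binomial_enrichment(pres0, paste0("g", 1:3), paste0("g", 1:9))
  expect_equal(en0$p_value, 1)

  # random grid against direct summation with exact coefficients
  set.seed(137)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.99)
    expect_equal(stats::pbinom(x - 1, n, p0, lower.tail = FALSE),
                 binom_tail_sum(x, n, p0), tolerance = 1e-12)
  }
})

test_that("binomial p-value is monotone in x and handles degenerate p0", {
  n <- 12; p0 <- 0.3
  pv <- vapply(0:n, function(x)
    stats::pbinom(x - 1, n, p0, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(pv) <= 0))

  ids <- paste0("g", 1:6)
  none <- matrix(FALSE, 6, 1, dimnames = list(ids, "m"))
  e <- binomial_enrichment(none, ids[1:2], ids)
  expect_equal(e$p_value, 1)               # p0 = 0, x = 0
  expect_identical(e$note, "")
  all_true <- matrix(TRUE, 6, 1, dimnames = list(ids, "m"))
  e3 <- binomial_enrichment(all_true, ids[1:2], ids)
  expect_equal(e3$p_value, 1)              # p0 = 1
  expect_error(binomial_enrichment(none, character(0), ids), "empty group")
  expect_error(binomial_enrichment(none, "gX", ids), "subset")
})

test_that("BH adjustment equals the textbook step-up", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(139)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_pvalues(p), bh_step_up(p))
  }
  expect_identical(adjust_pvalues(c(0.5, 0.01), "none"), c(0.5, 0.01))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("tissue report collects significant motifs with their carriers", {
  set.seed(149)
  ids <- paste0("g", 1:60)
  pres <- matrix(runif(60 * 2) < 0.1, 60, 2,
                 dimnames = list(ids, c("Menr", "Mnull")))
  groups <- list(leaf = ids[1:8], root = ids[9:16])
  pres[groups$leaf, "Menr"] <- TRUE
  pres[groups$root, "Menr"] <- TRUE
  enr <- lapply(groups, function(g)
    binomial_enrichment(pres, g, ids, adjust = "none"))
  rep_tab <- tissue_motif_report(enr, pres, groups)
  expect_equal(nrow(rep_tab), 2L)          # same motif in both tissues
  expect_setequal(rep_tab$tissue, c("leaf", "root"))
  expect_equal(rep_tab$motif_id, c("Menr", "Menr"))
  expect_identical(rep_tab$genes[rep_tab$tissue == "leaf"],
                   paste(sort(groups$leaf), collapse = ","))

  null_enr <- lapply(groups, function(g)
    binomial_enrichment(pres[, "Mnull", drop = FALSE], g, ids))
  empty <- tissue_motif_report(null_enr, pres, groups)
  expect_equal(nrow(empty), 0L)
})

test_that("planted enriched motifs surface in their tissue's report", {
  cfg <- simulation_config(seed = 151, n_genes = 80,
                           specific_fraction = 10 / 80,
                           planted_motifs = data.frame(
                             motif_id = "M0001", p0 = 0.05, p1 = 0.95))
  pm <- simulate_promoters(cfg, motifs = data.frame(
    motif_id = c("M0001", "M0002"),
    iupac = c("GTACGATCGT", "CCGATTACGG")))
  sc <- scan_motifs(pm$promoters, pm$motifs)
  enr <- list(leaf = binomial_enrichment(sc, pm$group,
                                         names(pm$promoters),
                                         adjust = "none"))
  tab <- tissue_motif_report(enr, sc, list(leaf = pm$group))
  expect_true("M0001" %in% tab$motif_id)
})
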