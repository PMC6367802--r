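test_that("generators are seed-deterministic, byte for byte", {
  cfg <- simulation_config(seed = 5, n_genes = 12, n_proteins = 20,
                           n_true_family = 14, motif_catalog_size = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in c("genome.fa", "genes.gff3", "proteins.fa", "promoters.fa",
              "motifs.tsv", "fpkm.tsv", "truth/introns.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed must change the genome
  d3 <- withr::local_tempdir()
  write_simulation(simulation_config(seed = 6, n_genes = 12,
                                     n_proteins = 20, n_true_family = 14,
                                     motif_catalog_size = 10), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("all mass on the zero-intron class gives intron-less genes", {
  cfg <- simulation_config(seed = 3, n_genes = 15,
                           intron_count_weights = c(1, 0, 0, 0, 0, 0))
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$truth), 0L)
  expect_true(all(vapply(gm$models, function(g) nrow(g$exons), integer(1))
                  == 1L))
})

test_that("intron-count census matches the configured class weights", {
  cfg <- simulation_config(seed = 17, n_genes = 2000)
  gm <- simulate_gene_models(cfg)
  per_gene <- vapply(gm$models, function(g)
    nrow(introns_from_genemodel(g)), integer(1))
  cls <- ifelse(per_gene >= 5, "5+", as.character(per_gene))
  obs <- table(factor(cls, levels = names(cfg$intron_count_weights)))
  # binomial CI per class, Bonferroni-split over the 6 simultaneous classes
  # so the familywise level stays at 99%
  alpha <- 0.01 / 6
  for (k in names(cfg$intron_count_weights)) {
    ci <- qbinom(c(alpha / 2, 1 - alpha / 2), 2000,
                 cfg$intron_count_weights[[k]])
    expect_gte(obs[[k]], ci[1])
    expect_lte(obs[[k]], ci[2])
  }
})

test_that("generated gene models satisfy the CDS and truth contracts", {
  gm <- simulate_gene_models(simulation_config(seed = 9, n_genes = 40))
  for (g in gm$models) expect_equal(cds_length(g) %% 3L, 0L)
  obs <- introns_from_genemodels(gm$models)
  obs <- obs[order(obs$gene_id, obs$k), ]
  tru <- gm$truth[order(gm$truth$gene_id, gm$truth$k), ]
  expect_equal(obs$k, tru$k)
  expect_equal(obs$aa_position, as.integer(tru$aa_position))
  expect_equal(obs$phase, as.integer(tru$phase))
})

test_that("true-family proteins carry all four motifs; decoys do not", {
  cfg <- simulation_config(seed = 13, n_proteins = 60, n_true_family = 36)
  ps <- simulate_protein_set(cfg)
  tru <- ps$truth
  for (i in which(tru$is_family)[1:5]) {
    hits <- scan_signatures(ps$proteins[[i]])
    expect_true(all(lengths(hits) >= 1L))
    expect_true(nchar(ps$proteins[[i]]) >= 450 &&
                  nchar(ps$proteins[[i]]) <= 600)
  }
  heme_miss <- which(tru$reason == "missing_heme")
  for (i in heme_miss)
    expect_length(scan_signatures(ps$proteins[[i]])$heme, 0L)
  # full truth-table comparison: perfect sensitivity and specificity
  calls <- filter_candidates(ps$proteins)
  expect_identical(calls$passed, tru$is_family)
})

test_that("promoter planting honours rates, overlap-free truth and p1 = 1", {
  catalog <- data.frame(motif_id = c("M0001", "M0002"),
                        iupac = c("GTACGATCGT", "TTGACCGTAC"))
  cfg <- simulation_config(seed = 23, n_genes = 40,
                           specific_fraction = 10 / 40,
                           planted_motifs = data.frame(
                             motif_id = "M0001", p0 = 0, p1 = 1))
  pm <- simulate_promoters(cfg, motifs = catalog)
  expect_length(pm$promoters, 40L)
  expect_true(all(nchar(pm$promoters) == cfg$promoter_length))
  # every group promoter contains the planted motif
  sc <- scan_motifs(pm$promoters, pm$motifs)
  expect_true(all(sc$presence[pm$group, "M0001"]))
  # p0 = 0: no background gene in the planted-truth table
  expect_true(all(pm$planted$gene_id %in% pm$group))
  # never-planted motif occurs only by (rare for a 10-mer) chance
  expect_lte(sum(sc$presence[, "M0002"]), 3L)

  # p0 = p1 = 0 plants nothing
  cfg0 <- simulation_config(seed = 23, n_genes = 10,
                            planted_motifs = data.frame(
                              motif_id = "M0001", p0 = 0, p1 = 0))
  expect_equal(nrow(simulate_promoters(cfg0, motifs = catalog)$planted), 0L)
})

test_that("background presence rate matches planting + random occurrence", {
  motif <- "GTACGATCGT"                       # non-degenerate, non-palindromic
  n_bg <- 5000L
  p0 <- 0.1
  cfg <- simulation_config(seed = 29, n_genes = n_bg,
                           specific_fraction = 0,
                           planted_motifs = data.frame(
                             motif_id = "M0001", p0 = p0, p1 = p0))
  pm <- simulate_promoters(cfg, motifs = data.frame(motif_id = "M0001",
                                                    iupac = motif))
  sc <- scan_motifs(pm$promoters, pm$motifs)
  # closed-form random occurrence (Poisson approximation, both strands)
  L <- cfg$promoter_length
  mu <- 2 * (L - nchar(motif) + 1) / 4^nchar(motif)
  p_expect <- 1 - (1 - p0) * exp(-mu)
  obs <- sum(sc$presence[, "M0001"])
  ci <- qbinom(c(0.005, 0.995), n_bg, p_expect)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("expression planting is recoverable at fold 100 and null at 1", {
  cfg <- simulation_config(seed = 31, n_genes = 200)
  ex <- simulate_expression(cfg)
  expect_identical(ex$fpkm, simulate_expression(cfg)$fpkm)  # determinism
  calls <- tissue_specificity(ex$fpkm)
  planted <- ex$truth$specific
  expect_gte(mean(calls$specific[planted]), 0.95)
  # recovered top tissue is the designated one
  expect_identical(calls$top_tissue[planted], ex$truth$tissue[planted])

  cfg1 <- simulation_config(seed = 31, n_genes = 400, fpkm_fold = 1)
  ex1 <- simulate_expression(cfg1)
  c1 <- tissue_specificity(ex1$fpkm)
  # fold 1: planted genes behave like background, no systematic excess
  r_planted <- mean(c1$specific[ex1$truth$specific])
  r_bg <- mean(c1$specific[!ex1$truth$specific])
  expect_lt(abs(r_planted - r_bg), 0.1)
})

test_that("alignment simulation follows its substitution model", {
  # zero-length branches: all leaves identical
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment_on_tree(tr, 50, seed = 7)
  expect_length(unique(aln), 1L)

  # two leaves: observed p-distance within 3 sigma of the closed form
  tr2 <- ape::read.tree(text = "(A:0.3,B:0.5);")
  aln2 <- simulate_alignment_on_tree(tr2, 10000, seed = 19)
  p_exp <- expected_pdist(c(0.3, 0.5))
  p_obs <- mean(strsplit(aln2[["A"]], "")[[1]] !=
                  strsplit(aln2[["B"]], "")[[1]])
  sigma <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * sigma)

  # six-leaf tree: NJ on simulated distances recovers the true topology
  set.seed(37)
  cs <- random_additive_case(6)
  cs$tree$edge.length <- pmin(cs$tree$edge.length, 0.8)
  aln6 <- simulate_alignment_on_tree(cs$tree, 20000, seed = 41)
  rec <- nj_tree(protein_distances(aln6, "poisson"))
  expect_equal(phangorn::RF.dist(ape::unroot(rec), cs$tree), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(intron_count_weights = rep(0.2, 6)))
  expect_error(simulation_config(
    conserved_sites = data.frame(mean_position = 460, phase = 1,
                                 jitter = 5)), "beyond the shortest")
  expect_error(simulation_config(planted_motifs = data.frame(
    motif_id = "M0001", p0 = 0.5, p1 = 0.2)))
})
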