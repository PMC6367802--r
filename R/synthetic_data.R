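# Synthetic-data generators with known ground truth.
#
# The generators emulate the shape of a plant genome-wide P450 survey: gene
# models with 0-14 introns concentrated at 1-2 introns, a protein pool in
# which the true family members carry all four signature motifs at 450-600
# aa, promoters with group-elevated motif planting over a uniform i.i.d.
# background (which keeps the analytic random-occurrence probability of a
# motif computable for test oracles), and log-normal FPKM with designated
# tissue-specific genes.  Every generator is fully determined by the config
# seed and emits a machine-readable truth table.

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data layer.  The defaults are the
#' study conditions the package models: 233 family genes among 300
#' proteins, the intron-number class weights of a tomato-sized P450 census
#' (23/108/37/4/30/31 genes with 0/1/2/3/4/5+ introns), two conserved
#' phase-1 insertion sites, 2-kb promoters, a 946-motif catalog, 19
#' tissues and a 73/233 tissue-specific fraction.
#'
#' @param seed integer master seed (< 2^29); fully determines all outputs.
#' @param n_genes number of family gene models.
#' @param n_proteins total proteins in the mining pool.
#' @param n_true_family how many of `n_proteins` are true family members.
#' @param intron_count_weights probability vector over intron-number
#'   classes `0,1,2,3,4,5+` (must sum to 1).
#' @param conserved_sites data.frame (`mean_position`, `phase`, `jitter`)
#'   of planted conserved insertion sites, protein coordinates.
#' @param site_spacing minimum same-phase spacing between planted sites
#'   (aa); keeps sites recoverable by window clustering.
#' @param intron_length_range genomic intron lengths (nt), sampled
#'   uniformly.
#' @param protein_length_range amino-acid lengths of family proteins,
#'   sampled uniformly.
#' @param promoter_length promoter length L in nt (default 2000).
#' @param motif_catalog_size number of motifs in the synthetic catalog.
#' @param planted_motifs data.frame (`motif_id`, `p0`, `p1`): per-gene
#'   Bernoulli planting rates for background (`p0`) and group (`p1`)
#'   genes; requires `p1 >= p0`.
#' @param n_tissues number of expression tissues (>= 2).
#' @param specific_fraction fraction of genes made tissue-specific.
#' @param fpkm_fold fold factor applied to a specific gene's designated
#'   tissue.
#' @param fpkm_lognormal_params `c(mu, sigma)` of the log-normal FPKM
#'   noise.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 233L,
    n_proteins = 300L,
    n_true_family = 233L,
    intron_count_weights = c(`0` = 23, `1` = 108, `2` = 37, `3` = 4,
                             `4` = 30, `5+` = 31) / 233,
    conserved_sites = data.frame(mean_position = c(150, 250),
                                 phase = c(1L, 1L), jitter = c(15, 15)),
    site_spacing = 80,
    intron_length_range = c(80L, 500L),
    protein_length_range = c(450L, 600L),
    promoter_length = 2000L,
    motif_catalog_size = 946L,
    planted_motifs = data.frame(motif_id = c("M0001", "M0002", "M0003"),
                                p0 = 0.1, p1 = 0.9),
    n_tissues = 19L,
    specific_fraction = 73 / 233,
    fpkm_fold = 100,
    fpkm_lognormal_params = c(mu = 1, sigma = 1.5)) {
  stopifnot(seed == as.integer(seed), seed >= 0L, seed < 2^29,
            n_genes >= 1L, n_proteins >= n_true_family,
            n_true_family >= 0L,
            length(intron_count_weights) == 6L,
            all(intron_count_weights >= 0),
            abs(sum(intron_count_weights) - 1) < 1e-9,
            all(c("mean_position", "phase", "jitter") %in%
                  names(conserved_sites)),
            all(conserved_sites$phase %in% 0:2),
            all(conserved_sites$jitter >= 0),
            site_spacing > 0,
            length(intron_length_range) == 2L,
            intron_length_range[1] >= 1L,
            diff(intron_length_range) >= 0,
            length(protein_length_range) == 2L,
            protein_length_range[1] >= 50L,
            diff(protein_length_range) >= 0,
            promoter_length >= 20L,
            motif_catalog_size >= 1L,
            all(c("motif_id", "p0", "p1") %in% names(planted_motifs)),
            all(planted_motifs$p0 >= 0 & planted_motifs$p0 <= 1),
            all(planted_motifs$p1 >= planted_motifs$p0),
            all(planted_motifs$p1 <= 1),
            n_tissues >= 2L,
            specific_fraction >= 0, specific_fraction <= 1,
            fpkm_fold > 0,
            length(fpkm_lognormal_params) == 2L,
            fpkm_lognormal_params[2] > 0)
  bad <- conserved_sites$mean_position + conserved_sites$jitter >
    protein_length_range[1] - 10
  if (any(bad))
    stopf("conserved site at %g aa lies beyond the shortest protein",
          conserved_sites$mean_position[bad][1L])
  names(intron_count_weights) <- c("0", "1", "2", "3", "4", "5+")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_proteins = as.integer(n_proteins),
              n_true_family = as.integer(n_true_family),
              intron_count_weights = intron_count_weights,
              conserved_sites = conserved_sites,
              site_spacing = site_spacing,
              intron_length_range = as.integer(intron_length_range),
              protein_length_range = as.integer(protein_length_range),
              promoter_length = as.integer(promoter_length),
              motif_catalog_size = as.integer(motif_catalog_size),
              planted_motifs = planted_motifs,
              n_tissues = as.integer(n_tissues),
              specific_fraction = specific_fraction,
              fpkm_fold = fpkm_fold,
              fpkm_lognormal_params = fpkm_lognormal_params)
  class(cfg) <- "simulation_config"
  cfg
}

DNA_BASES <- c("A", "C", "G", "T")

# fast i.i.d. uniform DNA of length n as a single string
random_dna <- function(n) {
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)])
}

random_protein <- function(n) {
  codes <- utf8ToInt(paste(AA_ALPHABET, collapse = ""))
  intToUtf8(codes[sample.int(20L, n, replace = TRUE)])
}

# Deterministic insertion-site catalog: config conserved sites first, then
# background sites on a per-phase grid spaced site_spacing apart, phases
# cycling 0/1/2, skipping grid points within site_spacing of a same-phase
# conserved site.  Background sites jitter by at most 10 aa.
site_catalog <- function(config) {
  cs <- config$conserved_sites
  cons <- data.frame(site_id = paste0("S", seq_len(nrow(cs))),
                     mean_position = cs$mean_position, phase = cs$phase,
                     jitter = cs$jitter, conserved_planted = TRUE,
                     stringsAsFactors = FALSE)
  lo <- 25
  hi <- config$protein_length_range[1] - 50
  grid <- lapply(0:2, function(ph) {
    pos <- seq(lo, hi, by = config$site_spacing)
    near <- vapply(pos, function(p)
      any(cs$phase == ph & abs(cs$mean_position - p) < config$site_spacing),
      logical(1))
    pos[!near]
  })
  idx <- c(0L, 0L, 0L)
  bg <- list()
  repeat {
    advanced <- FALSE
    for (ph in 0:2) {
      if (idx[ph + 1L] < length(grid[[ph + 1L]])) {
        idx[ph + 1L] <- idx[ph + 1L] + 1L
        bg[[length(bg) + 1L]] <- data.frame(
          site_id = NA_character_,
          mean_position = grid[[ph + 1L]][idx[ph + 1L]],
          phase = ph, jitter = 10, conserved_planted = FALSE,
          stringsAsFactors = FALSE)
        advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  cat_df <- rbind(cons, do.call(rbind, bg))
  cat_df$site_id <- paste0("S", seq_len(nrow(cat_df)))
  cat_df
}

#' Simulate a genome with intron-bearing gene models
#'
#' Each gene sits on its own contig with 2.1-kb flanks, a random strand and
#' exons equal to its CDS.  Intron counts are drawn from the configured
#' class weights (the `5+` class draws uniformly from 5..14); a gene with m
#' introns carries the first m sites of the deterministic site catalog
#' (conserved sites first), each jittered within its window, so the truth
#' table pins every intron to a site id, amino-acid position and phase.
#'
#' @param config a [simulation_config()].
#' @return list: `genome` (named character vector), `models` (named list of
#'   [gene_model()]), `truth` (data.frame gene_id/site_id/aa_position/
#'   phase/k), `catalog` (site catalog with an `n_genes` column and the
#'   expected `conserved` flag: jitter within window and >= 2 genes).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  catalog <- site_catalog(config)
  classes <- names(config$intron_count_weights)
  n <- config$n_genes
  drawn <- sample(classes, n, replace = TRUE,
                  prob = config$intron_count_weights)
  m_of <- integer(n)
  is5 <- drawn == "5+"
  m_of[!is5] <- as.integer(drawn[!is5])
  m_of[is5] <- sample(5:14, sum(is5), replace = TRUE)
  if (max(m_of) > nrow(catalog))
    stopf("intron count %d exceeds the %d-site catalog", max(m_of),
          nrow(catalog))
  plr <- config$protein_length_range
  ilr <- config$intron_length_range
  genome <- character(n)
  models <- vector("list", n)
  truth <- list()
  gene_ids <- sprintf("g%04d", seq_len(n))
  contig_ids <- sprintf("ctg%04d", seq_len(n))
  flank <- 2100L
  for (i in seq_len(n)) {
    L <- sample(plr[1]:plr[2], 1L)
    m <- m_of[i]
    strand <- sample(c("+", "-"), 1L)
    if (m > 0L) {
      st <- catalog[seq_len(m), , drop = FALSE]
      aa <- st$mean_position + vapply(st$jitter, function(j)
        if (j <= 0) 0 else sample(seq(-j, j), 1L), numeric(1))
      aa <- as.integer(round(aa))
      k <- sort(3L * (aa - 1L) + st$phase)
      truth[[i]] <- data.frame(
        gene_id = gene_ids[i], site_id = st$site_id,
        aa_position = aa, phase = st$phase,
        k = 3L * (aa - 1L) + st$phase, stringsAsFactors = FALSE)
    } else {
      k <- integer(0)
    }
    seg_len <- diff(c(0L, k, 3L * L))
    intron_len <- if (m > 0L)
      sample(ilr[1]:ilr[2], m, replace = TRUE) else integer(0)
    # plus-strand layout, then mirror for minus strand
    starts <- integer(m + 1L); ends <- integer(m + 1L)
    pos <- flank
    for (s in seq_len(m + 1L)) {
      starts[s] <- pos
      ends[s] <- pos + seg_len[s]
      pos <- ends[s] + if (s <= m) intron_len[s] else 0L
    }
    clen <- pos + flank
    if (strand == "-") {
      tmp <- clen - ends
      ends <- clen - starts
      starts <- tmp
      o <- order(starts); starts <- starts[o]; ends <- ends[o]
    }
    exons <- cbind(starts, ends)
    models[[i]] <- gene_model(gene_ids[i], contig_ids[i], strand,
                              exons = exons, cds = exons)
    genome[i] <- random_dna(clen)
  }
  names(genome) <- contig_ids
  names(models) <- gene_ids
  truth <- if (length(truth) > 0L)
    do.call(rbind, truth) else
      data.frame(gene_id = character(0), site_id = character(0),
                 aa_position = integer(0), phase = integer(0),
                 k = integer(0))
  catalog$n_genes <- vapply(catalog$site_id, function(s)
    length(unique(truth$gene_id[truth$site_id == s])), integer(1))
  catalog$conserved <- catalog$n_genes >= 2L
  list(genome = genome, models = models, truth = truth,
       catalog = catalog[catalog$n_genes > 0L, , drop = FALSE])
}

# instantiate one signature pattern as a concrete peptide
instantiate_signature <- function(name) {
  r <- function() sample(AA_ALPHABET, 1L)
  switch(name,
    heme = paste0("F", r(), r(), "G", r(), "R", r(), "C", r(), "G"),
    i_helix = paste0(sample(c("A", "G"), 1L), "G", r(), "DT"),
    k_helix = paste0("E", r(), r(), "R"),
    perf = paste0("PER", sample(c("F", "W"), 1L)),
    stopf("unknown signature %s", name))
}

# overwrite part of a string in place
implant <- function(s, piece, at) {   # at: 1-based
  paste0(substr(s, 1L, at - 1L), piece,
         substr(s, at + nchar(piece), nchar(s)))
}

#' Simulate a protein pool with known family membership
#'
#' True family members carry all four signature motifs (I-helix, K-helix,
#' PERF/W and heme, implanted in that N-to-C order at ~50/65/78/90% of the
#' length) and lengths uniform in the configured range.  Decoys cycle
#' through six defect types: too short, too long, or missing one of the
#' four motifs (re-sampled until the motif is genuinely absent).
#'
#' @param config a [simulation_config()].
#' @return list: `proteins` (named character vector) and `truth`
#'   (data.frame protein_id/is_family/reason).
#' @export
simulate_protein_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  plr <- config$protein_length_range
  profiles <- signature_profiles()
  anchors <- c(i_helix = 0.50, k_helix = 0.65, perf = 0.78, heme = 0.90)
  build <- function(L, omit = NULL) {
    for (try in 1:100) {
      s <- random_protein(L)
      for (nm in setdiff(names(anchors), omit)) {
        at <- max(2L, round(anchors[[nm]] * L) + sample(-10:10, 1L))
        s <- implant(s, instantiate_signature(nm), at)
      }
      if (is.null(omit) ||
          length(scan_signatures(s, profiles[omit])[[1L]]) == 0L)
        return(s)
    }
    stopf("could not build a decoy lacking %s", omit)
  }
  n_true <- config$n_true_family
  n_decoy <- config$n_proteins - n_true
  defect <- rep(c("short", "long", "missing_heme", "missing_i_helix",
                  "missing_k_helix", "missing_perf"),
                length.out = n_decoy)
  ids <- sprintf("p%04d", seq_len(config$n_proteins))
  proteins <- character(config$n_proteins)
  reason <- character(config$n_proteins)
  for (i in seq_len(n_true)) {
    proteins[i] <- build(sample(plr[1]:plr[2], 1L))
    reason[i] <- "family"
  }
  for (j in seq_len(n_decoy)) {
    i <- n_true + j
    proteins[i] <- switch(defect[j],
      short = build(sample(200:(plr[1] - 1L), 1L)),
      long = build(sample((plr[2] + 1L):(plr[2] + 100L), 1L)),
      build(sample(plr[1]:plr[2], 1L),
            omit = sub("^missing_", "", defect[j])))
    reason[i] <- defect[j]
  }
  names(proteins) <- ids
  list(proteins = proteins,
       truth = data.frame(protein_id = ids,
                          is_family = reason == "family",
                          reason = reason, stringsAsFactors = FALSE))
}

# one random IUPAC consensus motif: mostly ACGT with occasional degeneracy
random_motif <- function() {
  len <- sample(6:10, 1L)
  paste0(vapply(seq_len(len), function(.) {
    if (runif(1) < 0.85) sample(DNA_BASES, 1L)
    else sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                1L)
  }, character(1)), collapse = "")
}

# concrete instance of an IUPAC motif (N instantiated as a plain base)
instantiate_motif <- function(iupac) {
  paste0(vapply(strsplit(iupac, "")[[1L]], function(ch) {
    ex <- strsplit(IUPAC_EXPANSION[[ch]], "")[[1L]]
    sample(setdiff(ex, "N"), 1L)
  }, character(1)), collapse = "")
}

#' Simulate promoters with planted motif occurrences
#'
#' Background sequence is i.i.d. uniform A/C/G/T.  For each planted motif
#' each gene independently receives one concrete occurrence with
#' probability `p1` (group genes) or `p0` (background genes), inserted at a
#' uniform random position on a uniform random strand; placements
#' overlapping an earlier plant are re-drawn so the truth table stays
#' exact.  Additional catalog motifs are never planted and occur only by
#' chance.
#'
#' @param config a [simulation_config()].
#' @param gene_ids promoter gene ids; default `g0001..` up to
#'   `config$n_genes`.
#' @param group character vector of group gene ids; default the first
#'   `round(specific_fraction * n)` genes.
#' @param motifs optional catalog data.frame (`motif_id`, `iupac`) to use
#'   instead of a freshly generated one; lets callers pin the planted
#'   motif's length and degeneracy (short motifs have appreciable chance
#'   background presence in a 2-kb promoter).
#' @return list: `promoters` (named character vector), `motifs` (catalog
#'   data.frame motif_id/iupac/source), `planted` (data.frame gene_id/
#'   motif_id/position/strand), `group`.
#' @export
simulate_promoters <- function(config, gene_ids = NULL, group = NULL,
                               motifs = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  L <- config$promoter_length
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d",
                                             seq_len(config$n_genes))
  if (is.null(group))
    group <- gene_ids[seq_len(round(config$specific_fraction *
                                      length(gene_ids)))]
  stopifnot(all(group %in% gene_ids))
  catalog <- if (!is.null(motifs)) {
    stopifnot(all(c("motif_id", "iupac") %in% names(motifs)))
    if (is.null(motifs$source)) motifs$source <- "synthetic"
    motifs[c("motif_id", "iupac", "source")]
  } else data.frame(
    motif_id = sprintf("M%04d", seq_len(config$motif_catalog_size)),
    iupac = vapply(seq_len(config$motif_catalog_size),
                   function(.) random_motif(), character(1)),
    source = "synthetic", stringsAsFactors = FALSE)
  pm <- config$planted_motifs
  if (!all(pm$motif_id %in% catalog$motif_id))
    stopf("planted motif ids must be catalog ids (M0001..)")
  if (any(nchar(catalog$iupac[match(pm$motif_id, catalog$motif_id)]) > L))
    stopf("planted motif longer than the promoter")
  seqs <- stats::setNames(
    vapply(gene_ids, function(.) random_dna(L), character(1)), gene_ids)
  occupied <- stats::setNames(
    rep(list(matrix(numeric(0), ncol = 2L)), length(gene_ids)), gene_ids)
  planted <- list()
  for (r in seq_len(nrow(pm))) {
    iupac <- catalog$iupac[catalog$motif_id == pm$motif_id[r]]
    w <- nchar(iupac)
    for (g in gene_ids) {
      rate <- if (g %in% group) pm$p1[r] else pm$p0[r]
      if (runif(1) >= rate) next
      inst <- instantiate_motif(iupac)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") inst <- reverse_complement(inst)
      occ <- occupied[[g]]
      placed <- FALSE
      for (try in 1:100) {
        at <- sample.int(L - w + 1L, 1L)            # 1-based start
        if (nrow(occ) == 0L ||
            all(at + w - 1L < occ[, 1] | at > occ[, 2])) {
          seqs[[g]] <- implant(seqs[[g]], inst, at)
          occupied[[g]] <- rbind(occ, c(at, at + w - 1L))
          planted[[length(planted) + 1L]] <- data.frame(
            gene_id = g, motif_id = pm$motif_id[r], position = at - 1L,
            strand = strand, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("could not place motif %s in gene %s without overlap",
              pm$motif_id[r], g)
    }
  }
  planted <- if (length(planted) > 0L) do.call(rbind, planted) else
    data.frame(gene_id = character(0), motif_id = character(0),
               position = integer(0), strand = character(0))
  list(promoters = seqs, motifs = catalog, planted = planted,
       group = group)
}

#' Simulate a tissue FPKM matrix with planted specific genes
#'
#' Non-specific genes draw i.i.d. log-normal FPKM per tissue.  Each planted
#' specific gene has one designated tissue set to `fpkm_fold` times the
#' mean FPKM of its other tissues, so the fold factor is directly the
#' tissue-versus-rest enrichment: at fold 1 the designated tissue sits at
#' the gene's own baseline (no systematic specificity), at fold 100 the
#' gene concentrates `100/(100 + n_tissues - 1)` of its signal there.
#'
#' @param config a [simulation_config()].
#' @param gene_ids gene ids; default `g0001..` up to `config$n_genes`.
#' @return list: `fpkm` (genes x tissues matrix) and `truth` (data.frame
#'   gene_id/specific/tissue).
#' @export
simulate_expression <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d",
                                             seq_len(config$n_genes))
  n <- length(gene_ids)
  t <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(t))
  mu <- config$fpkm_lognormal_params[[1]]
  sigma <- config$fpkm_lognormal_params[[2]]
  m <- matrix(stats::rlnorm(n * t, mu, sigma), n, t,
              dimnames = list(gene_ids, tissues))
  n_spec <- round(config$specific_fraction * n)
  spec_tissue <- rep(NA_character_, n)
  if (n_spec > 0L) {
    for (i in seq_len(n_spec)) {
      tis <- ((i - 1L) %% t) + 1L
      m[i, tis] <- config$fpkm_fold * mean(m[i, -tis])
      spec_tissue[i] <- tissues[tis]
    }
  }
  list(fpkm = m,
       truth = data.frame(gene_id = gene_ids,
                          specific = !is.na(spec_tissue),
                          tissue = spec_tissue, stringsAsFactors = FALSE))
}

#' Simulate a protein alignment along a tree
#'
#' The root sequence is i.i.d. uniform over the 20 amino acids; along each
#' branch every site independently substitutes, with probability
#' `1 - exp(-rate * branch_length)`, to a residue drawn uniformly from the
#' other 19.  Leaves are returned gap-free, so the result is a (trivially
#' aligned) alignment block for distance and NJ validation.
#'
#' @param tree a binary [ape::phylo] tree with branch lengths.
#' @param length number of alignment columns.
#' @param rate substitution rate multiplier (default 1, i.e. branch length
#'   is the expected number of substitutions scale).
#' @param seed optional integer seed.
#' @return named character vector of leaf sequences (an alignment block).
#' @export
simulate_alignment_on_tree <- function(tree, length, rate = 1,
                                       seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            length >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ntip <- base::length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(20L, length, replace = TRUE)
  # preorder: parents always precede children in ape's cladewise edges
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    p <- 1 - exp(-rate * el[e])
    s <- seqs[[par]]
    hit <- which(runif(length) < p)
    if (base::length(hit) > 0L)
      s[hit] <- ((s[hit] - 1L +
                    sample.int(19L, base::length(hit), replace = TRUE))
                 %% 20L) + 1L
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(AA_ALPHABET[seqs[[i]]], collapse = ""), character(1))
  stats::setNames(out, tree$tip.label)
}

#' Write a full synthetic dataset to disk
#'
#' Runs all generators under one config and writes `genome.fa`,
#' `genes.gff3`, `proteins.fa`, `promoters.fa`, `motifs.tsv`, `fpkm.tsv`,
#' truth sidecars under `truth/` and a `metadata.tsv` recording the seed.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(file.path(dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  gm <- simulate_gene_models(config)
  pr <- simulate_protein_set(config)
  pm <- simulate_promoters(config, gene_ids = names(gm$models))
  ex <- simulate_expression(config, gene_ids = names(gm$models))
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fa"),
    promoters = file.path(dir, "promoters.fa"),
    motifs = file.path(dir, "motifs.tsv"),
    fpkm = file.path(dir, "fpkm.tsv"),
    introns_truth = file.path(dir, "truth", "introns.tsv"),
    sites_truth = file.path(dir, "truth", "sites.tsv"),
    proteins_truth = file.path(dir, "truth", "proteins.tsv"),
    planted_truth = file.path(dir, "truth", "planted_motifs.tsv"),
    expression_truth = file.path(dir, "truth", "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"))
  write_fasta(gm$genome, paths[["genome"]])
  write_gff3(gm$models, paths[["gff"]])
  write_fasta(pr$proteins, paths[["proteins"]])
  write_fasta(pm$promoters, paths[["promoters"]])
  utils::write.table(pm$motifs, paths[["motifs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(ex$fpkm, paths[["fpkm"]])
  for (p in list(c("introns_truth", "truth"), c("sites_truth", "catalog")))
    utils::write.table(gm[[p[2]]], paths[[p[1]]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(pr$truth, paths[["proteins_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pm$planted, paths[["planted_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ex$truth, paths[["expression_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(key = c("seed", "package"),
               value = c(config$seed, "cypminer")),
    paths[["metadata"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
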