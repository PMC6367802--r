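# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (sliding windows, direct summation,
# textbook formulas) and independent of the package's implementation paths.

# ---- brute-force pattern matchers ------------------------------------------

# parse a degenerate protein pattern into a list of allowed-character sets
parse_protein_pattern <- function(pattern) {
  out <- list()
  i <- 1L
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      set <- character(0)
      while (chars[j] != "]") { set <- c(set, chars[j]); j <- j + 1L }
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <-
        if (chars[i] == "x") "ANY" else chars[i]
      i <- i + 1L
    }
  }
  out
}

# 0-based overlapping match starts by explicit sliding window
naive_protein_scan <- function(seq, pattern) {
  sets <- parse_protein_pattern(pattern)
  w <- length(sets)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < w) return(integer(0))
  hits <- integer(0)
  for (s in 0:(length(chars) - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      allowed <- sets[[j]]
      if (!identical(allowed, "ANY") && !(chars[s + j] %in% allowed)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

# per-sequence count of one oriented IUPAC pattern, positionwise
naive_iupac_count_one <- function(chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  w <- length(pat)
  L <- length(chars)
  if (L < w) return(0L)
  n <- 0L
  for (s in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(chars[s + j] %in% IUPAC_SETS[[pat[j]]])) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}

RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")

naive_revcomp <- function(x) {
  paste(rev(RC_MAP[strsplit(x, "")[[1]]]), collapse = "")
}

# both-strand count with the palindromic-consensus convention
naive_iupac_count <- function(seq, iupac, both_strands = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- naive_iupac_count_one(chars, iupac)
  if (both_strands) {
    rc <- naive_revcomp(iupac)
    if (rc != iupac) n <- n + naive_iupac_count_one(chars, rc)
  }
  n
}

# ---- statistical oracles ----------------------------------------------------

# upper-tail binomial probability by direct summation of exact terms
binom_tail_sum <- function(x, n, p0) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  k <- x:n
  sum(choose(n, k) * p0^k * (1 - p0)^(n - k))
}

# textbook Benjamini-Hochberg step-up with monotonicity enforcement
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# expected p-distance between two leaves of the simulation substitution
# model: along each branch b a site substitutes with prob 1 - exp(-b) to a
# uniform other residue, so the identity coefficient multiplies as
# (20 exp(-b) - 1) / 19 and P(differ) = (19/20) (1 - prod).
expected_pdist <- function(branch_lengths) {
  19 / 20 * (1 - prod((20 * exp(-branch_lengths) - 1) / 19))
}

# ---- fixtures ---------------------------------------------------------------

# random unrooted binary tree with positive branch lengths + its additive
# distance matrix (labels sorted for deterministic tie-breaking)
random_additive_case <- function(ntaxa) {
  tr <- ape::unroot(ape::rtree(ntaxa, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.15, 2)
  d <- ape::cophenetic.phylo(tr)
  labs <- sort(rownames(d))
  list(tree = tr, d = d[labs, labs])
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a two-exon plus-strand gene with k coding nt before its single intron
two_exon_gene <- function(k, total_cds = NULL, gene_id = "g1",
                          strand = "+") {
  if (is.null(total_cds)) total_cds <- k + (3 - k %% 3) %% 3 + 3
  stopifnot(total_cds %% 3 == 0, k < total_cds)
  ex <- rbind(c(0L, k), c(k + 100L, k + 100L + (total_cds - k)))
  gene_model(gene_id, "c1", strand, exons = ex, cds = ex)
}

# mirror a gene model to the other strand within a contig of length clen
mirror_gene <- function(g, clen) {
  ex <- cbind(clen - g$exons[, 2], clen - g$exons[, 1])
  cd <- cbind(clen - g$cds[, 2], clen - g$cds[, 1])
  o <- order(ex[, 1])
  gene_model(g$gene_id, g$contig_id, if (g$strand == "+") "-" else "+",
             exons = ex[o, , drop = FALSE],
             cds = cd[order(cd[, 1]), , drop = FALSE])
}

# hand-built insertion_sites object (for degenerate cases the clusterer
# cannot produce, e.g. mixed-phase sites)
manual_sites <- function(members) {
  sites <- do.call(rbind, lapply(split(members, members$site_id),
    function(m) data.frame(
      site_id = m$site_id[1], phase = m$phase[1], n_introns = nrow(m),
      n_genes = length(unique(m$gene_id)),
      mean_position = mean(m$aa_position),
      min_position = min(m$aa_position),
      max_position = max(m$aa_position), stringsAsFactors = FALSE)))
  out <- list(sites = sites[order(sites$site_id), ],
              members = members)
  class(out) <- "insertion_sites"
  out
}
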