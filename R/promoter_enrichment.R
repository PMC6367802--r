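# Promoter analysis: upstream extraction, IUPAC consensus motif scanning and
# exact binomial over-representation tests against the genome background.

# IUPAC nucleotide code.  A motif letter N matches any base including a
# literal N in the sequence; a non-N motif letter never matches sequence N.
IUPAC_EXPANSION <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

# IUPAC motif -> perl regex of character classes
iupac_regex <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1L]]
  bad <- setdiff(letters, names(IUPAC_EXPANSION))
  if (length(bad) > 0L)
    stopf("invalid IUPAC letter(s) in motif %s: %s", motif,
          paste(unique(bad), collapse = ""))
  paste0(vapply(letters, function(ch) {
    ex <- IUPAC_EXPANSION[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

#' Extract upstream promoter regions
#'
#' For a `+` strand gene the promoter is `genome[max(0, tss - L), tss)`; for
#' a `-` strand gene it is the reverse complement of
#' `genome[tss + 1, min(contig_end, tss + 1 + L))`.  Promoters clipped by a
#' contig edge are kept (and flagged); genes with zero upstream sequence are
#' excluded with a warning.  A BED6 table of the extracted genomic windows
#' is returned for audit.
#'
#' @param genome named character vector of contig sequences.
#' @param models list of [gene_model()] objects.
#' @param L upstream length in nt (default 2000).
#' @return list of class `promoter_set`: `promoters` (named character
#'   vector, promoter sense 5'->3'), `bed` (data.frame with BED6 columns
#'   chrom/start/end/name/score/strand) and `clipped` (character vector of
#'   gene ids shorter than `L`).
#' @export
extract_upstream <- function(genome, models, L = 2000L) {
  stopifnot(is.character(genome), !is.null(names(genome)), L >= 1L)
  proms <- character(0); bed <- list(); clipped <- character(0)
  for (g in models) {
    if (!g$contig_id %in% names(genome))
      stopf("contig %s of gene %s absent from genome", g$contig_id,
            g$gene_id)
    clen <- nchar(genome[[g$contig_id]])
    if (g$strand == "+") {
      s <- max(0L, g$tss - L); e <- g$tss
    } else {
      s <- g$tss + 1L; e <- min(clen, g$tss + 1L + L)
    }
    if (e <= s) {
      warnf("gene %s has zero upstream sequence; excluded", g$gene_id)
      next
    }
    seq <- substr(genome[[g$contig_id]], s + 1L, e)   # 0-based -> substr
    if (g$strand == "-") seq <- reverse_complement(seq)
    if (e - s < L) clipped <- c(clipped, g$gene_id)
    proms[[g$gene_id]] <- seq
    bed[[length(bed) + 1L]] <- data.frame(
      chrom = g$contig_id, start = s, end = e, name = g$gene_id,
      score = ".", strand = g$strand, stringsAsFactors = FALSE)
  }
  if (length(proms) == 0L) stopf("no promoters extracted")
  out <- list(promoters = proms, bed = do.call(rbind, bed),
              clipped = clipped)
  class(out) <- "promoter_set"
  attr(out, "L") <- as.integer(L)
  out
}

#' Scan promoters for IUPAC consensus motifs
#'
#' Counts every (overlapping) match start of each motif in each promoter;
#' with `both_strands` the reverse-complement pattern is scanned too and the
#' counts added.  A motif whose reverse complement equals itself (a
#' palindromic consensus such as `CACGTG` or `CANNTG`) is scanned once, so
#' a single genomic occurrence counts once.  Presence is `count >= 1`.
#'
#' @param promoters a `promoter_set` from [extract_upstream()], or a named
#'   character vector of sequences.
#' @param motifs data.frame with columns `motif_id` and `iupac` (see
#'   [read_motif_table()]).
#' @param both_strands scan both strands (default TRUE).
#' @return list of class `presence_matrix`: `counts` and `presence`
#'   (genes x motifs matrices) plus a `both_strands` attribute.
#' @export
scan_motifs <- function(promoters, motifs, both_strands = TRUE) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$promoters
  stopifnot(is.character(promoters), !is.null(names(promoters)),
            all(c("motif_id", "iupac") %in% names(motifs)))
  seqs <- toupper(promoters)
  counts <- matrix(0L, length(seqs), nrow(motifs),
                   dimnames = list(names(seqs), motifs$motif_id))
  for (m in seq_len(nrow(motifs))) {
    pat <- toupper(motifs$iupac[m])
    pats <- pat
    if (both_strands) {
      rc <- reverse_complement(pat)
      if (rc != pat) pats <- c(pat, rc)
    }
    for (p in pats) {
      rx <- paste0("(?=", iupac_regex(p), ")")
      hits <- gregexpr(rx, seqs, perl = TRUE)
      counts[, m] <- counts[, m] +
        vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h),
               integer(1))
    }
  }
  out <- list(counts = counts, presence = counts >= 1L)
  class(out) <- "presence_matrix"
  attr(out, "both_strands") <- both_strands
  out
}

#' Exact one-sample binomial over-representation test
#'
#' For each motif, the background proportion `p0` is the fraction of
#' background genes whose promoter contains the motif; the test asks
#' whether the `x` of `n` group genes carrying it is consistent with `p0`.
#' The `greater` alternative uses the exact upper tail
#' `P(X >= x), X ~ Binomial(n, p0)`; small groups are the norm here, so no
#' normal approximation is used.  Degenerate backgrounds are handled
#' analytically: `p0 = 0` gives p = 1 when `x = 0` and is otherwise flagged
#' `background_absent` (p reported as 0); `p0 = 1` gives p = 1.
#'
#' @param presence a `presence_matrix` from [scan_motifs()], or a logical
#'   genes x motifs matrix.
#' @param group character vector of group gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two_sided"`.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param adjust multiple-testing adjustment for the q-value column:
#'   `"BH"` (default) or `"none"`.
#' @return data.frame with one row per motif: `motif_id`, `n`, `x`, `p0`,
#'   `p_value`, `q_value`, `significant`, `note`.
#' @export
binomial_enrichment <- function(presence, group, background,
                                alternative = c("greater", "two_sided"),
                                alpha = 0.05, adjust = c("BH", "none")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  if (inherits(presence, "presence_matrix")) presence <- presence$presence
  stopifnot(is.matrix(presence), is.logical(presence))
  if (length(group) == 0L) stopf("empty group")
  if (!all(group %in% background))
    stopf("group is not a subset of background")
  missing_ids <- setdiff(background, rownames(presence))
  if (length(missing_ids) > 0L)
    stopf("gene(s) absent from presence matrix: %s",
          paste(utils::head(missing_ids, 5L), collapse = ", "))
  n <- length(group)
  res <- lapply(colnames(presence), function(m) {
    p0 <- sum(presence[background, m]) / length(background)
    x <- sum(presence[group, m])
    note <- ""
    if (p0 == 0) {
      p <- if (x == 0L) 1 else { note <- "background_absent"; 0 }
    } else if (p0 == 1) {
      p <- 1
      if (alternative == "two_sided" && x < n)
        p <- stats::binom.test(x, n, p0, "two.sided")$p.value
    } else if (alternative == "greater") {
      p <- stats::pbinom(x - 1L, n, p0, lower.tail = FALSE)
    } else {
      p <- stats::binom.test(x, n, p0, "two.sided")$p.value
    }
    data.frame(motif_id = m, n = n, x = x, p0 = p0, p_value = p,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- adjust_pvalues(out$p_value, adjust)
  out$significant <- out$q_value <= alpha
  out[c("motif_id", "n", "x", "p0", "p_value", "q_value", "significant",
        "note")]
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up with monotonicity enforcement (via
#' [stats::p.adjust()]) or pass-through.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param method `"BH"` or `"none"`.
#' @return adjusted p-values, same length and order as input.
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  if (method == "none") return(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' Tissue-specific over-represented motif report
#'
#' Combines per-tissue enrichment tables into the classic "tissue-specific
#' genes with over-represented promoter motifs" summary: one row per
#' (tissue, significant motif), listing the group genes whose promoter
#' carries the motif.  Rows are ordered by tissue, then q-value, then motif
#' id.
#'
#' @param enrichments named list (tissue -> data.frame from
#'   [binomial_enrichment()]).
#' @param presence a `presence_matrix` or logical matrix.
#' @param groups named list (tissue -> character vector of group gene ids).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `tissue`, `motif_id`, `x`, `n`,
#'   `p_value`, `q_value`, `genes`.
#' @export
tissue_motif_report <- function(enrichments, presence, groups,
                                alpha = 0.05) {
  if (inherits(presence, "presence_matrix")) presence <- presence$presence
  stopifnot(is.list(enrichments), !is.null(names(enrichments)),
            identical(sort(names(enrichments)), sort(names(groups))))
  rows <- lapply(names(enrichments), function(tis) {
    e <- enrichments[[tis]]
    e <- e[e$q_value <= alpha, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    genes <- vapply(e$motif_id, function(m) {
      carriers <- groups[[tis]][presence[groups[[tis]], m]]
      paste(sort(carriers), collapse = ",")
    }, character(1))
    data.frame(tissue = tis, motif_id = e$motif_id, x = e$x, n = e$n,
               p_value = e$p_value, q_value = e$q_value,
               genes = unname(genes), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tissue = character(0), motif_id = character(0),
                      x = integer(0), n = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      genes = character(0)))
  out[order(out$tissue, out$q_value, out$motif_id), , drop = FALSE]
}
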