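# The gene_model class: one gene's exon/CDS architecture on a contig.
#
# Intervals are 0-based half-open matrices with columns start/end, sorted and
# non-overlapping.  A gene carries exactly one transcript: multi-isoform
# models are out of scope for a gene-level family survey.

#' Construct a gene model
#'
#' A `gene_model` holds one gene's strand, exon and CDS intervals on a contig
#' plus its transcription start.  It is the substrate of intron projection
#' ([introns_from_genemodel()]) and promoter extraction
#' ([extract_upstream()]).
#'
#' @param gene_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column integer matrices (start, end), 0-based
#'   half-open, genomic (left-to-right) order.  `cds` must lie within the
#'   exon union and its total length must be divisible by 3.
#' @param tss transcription start, 0-based genomic position.  Defaults to the
#'   leftmost exon coordinate on `+` and the rightmost covered base on `-`.
#' @return object of class `gene_model`.
#' @examples
#' gene_model("g1", "c1", "+", exons = cbind(0L, 9L), cds = cbind(0L, 9L))
#' @export
gene_model <- function(gene_id, contig_id, strand, exons, cds, tss = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(contig_id), length(contig_id) == 1L)
  if (!strand %in% c("+", "-"))
    stopf("gene %s: strand must be '+' or '-'", gene_id)
  exons <- as_interval_matrix(exons, gene_id, "exon")
  cds   <- as_interval_matrix(cds, gene_id, "CDS")
  if (!intervals_within(cds, exons))
    stopf("gene %s: CDS intervals not contained in exon union", gene_id)
  len <- sum(cds[, 2] - cds[, 1])
  if (len == 0L) stopf("gene %s: zero-length CDS", gene_id)
  if (len %% 3L != 0L)
    stopf("gene %s: total CDS length %d not divisible by 3", gene_id, len)
  if (is.null(tss))
    tss <- if (strand == "+") min(exons[, 1]) else max(exons[, 2]) - 1L
  structure(
    list(gene_id = gene_id, contig_id = contig_id, strand = strand,
         exons = exons, cds = cds, tss = as.integer(tss)),
    class = "gene_model")
}

# validate/sort a 2-column interval matrix; non-overlapping required
as_interval_matrix <- function(x, gene_id, what) {
  x <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (any(is.na(x)) || any(x[, 2] <= x[, 1]))
    stopf("gene %s: invalid %s interval", gene_id, what)
  x <- x[order(x[, 1]), , drop = FALSE]
  if (nrow(x) > 1L && any(x[-1L, 1] < x[-nrow(x), 2]))
    stopf("gene %s: overlapping %s intervals", gene_id, what)
  x
}

# is every interval of a contained in some interval of b?
intervals_within <- function(a, b) {
  all(vapply(seq_len(nrow(a)), function(i) {
    any(b[, 1] <= a[i, 1] & a[i, 2] <= b[, 2])
  }, logical(1)))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d exon(s), CDS %d nt, tss %d\n",
              x$gene_id, x$contig_id, x$strand, nrow(x$exons),
              sum(x$cds[, 2] - x$cds[, 1]), x$tss))
  invisible(x)
}

#' Total CDS length of a gene model (nt)
#' @param g a `gene_model`.
#' @return integer number of coding nucleotides.
#' @export
cds_length <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  sum(g$cds[, 2] - g$cds[, 1])
}
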