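# Readers/writers for the standard formats touched by the pipeline.
#
# Conventions: all internal coordinates are 0-based half-open.  GFF3 is
# 1-based inclusive and BED is 0-based half-open; conversion happens only in
# the functions below.  Every reader/writer pair is a round-trip identity on
# valid inputs.

#' Read a FASTA file into a named character vector
#'
#' Handles plain genomes, protein sets and aligned FASTA alike.  Sequences
#' are uppercased; wrapped lines are concatenated; record order is preserved.
#' The record identifier is the header up to the first whitespace.
#'
#' @param path path to an existing FASTA file.
#' @return named character vector of sequences.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stopf("duplicate FASTA ID(s): %s", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = as.integer(width))
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' IUPAC-aware (R complements to Y etc.), so it applies to degenerate motif
#' consensus strings as well as plain sequence.
#'
#' @param x character vector of DNA/IUPAC strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read gene models from a GFF3 file
#'
#' Expects the standard gene/mRNA/exon/CDS hierarchy linked by `Parent`
#' attributes.  One [gene_model()] is produced per mRNA; when a gene carries
#' several mRNAs only the first is kept, with a warning (the pipeline is
#' gene-level and isoform-free).  Coordinates are converted from GFF3
#' 1-based inclusive to internal 0-based half-open.
#'
#' @param path path to a GFF3 file.
#' @return list of `gene_model` objects, named by gene id.
#' @seealso [write_gff3()]
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) > 0L) p[[1L]] else NA_character_, character(1))
  start0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  mrna <- which(type == "mRNA")
  if (length(mrna) == 0L) stopf("no mRNA features in %s", path)
  if (anyNA(parent[mrna]))
    stopf("mRNA feature without Parent link in %s", path)
  # one mRNA per gene: keep first occurrence
  first <- !duplicated(parent[mrna])
  if (!all(first))
    warnf("%d gene(s) with multiple mRNAs; keeping the first of each",
          sum(!first))
  mrna <- mrna[first]

  seg <- which(type %in% c("exon", "CDS"))
  if (anyNA(parent[seg]))
    stopf("exon/CDS feature without Parent link in %s", path)
  models <- lapply(mrna, function(i) {
    mid <- id[i]
    kids <- seg[parent[seg] == mid]
    ex <- kids[type[kids] == "exon"]
    cd <- kids[type[kids] == "CDS"]
    if (length(ex) == 0L) stopf("mRNA %s has no exon features", mid)
    if (length(cd) == 0L) stopf("mRNA %s has no CDS features", mid)
    gene_model(gene_id = parent[i], contig_id = contig[i],
               strand = strand[i],
               exons = cbind(start0[ex], end0[ex]),
               cds = cbind(start0[cd], end0[cd]))
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write gene models to GFF3
#'
#' Emits the gene/mRNA/exon/CDS hierarchy with correct CDS phase columns,
#' converting from internal 0-based half-open to GFF3 1-based inclusive.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(models, gff3_rows)
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start1, end = df$end1),
    strand = df$strand)
  gr$source <- "cypminer"
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# one gene's GFF3 feature rows (1-based inclusive) as a data.frame
gff3_rows <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  ex <- g$exons; cd <- g$cds
  # CDS phase: bases to skip to reach a codon start, in transcription order
  ord <- if (g$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
  lens <- (cd[, 2] - cd[, 1])[ord]
  before <- cumsum(c(0L, lens[-length(lens)]))
  phase <- integer(nrow(cd))
  phase[ord] <- (3L - before %% 3L) %% 3L
  span <- c(min(ex[, 1]), max(ex[, 2]))
  tid <- paste0(g$gene_id, ".t1")
  data.frame(
    contig = g$contig_id,
    start1 = c(span[1], span[1], ex[, 1], cd[, 1]) + 1L,
    end1 = c(span[2], span[2], ex[, 2], cd[, 2]),
    strand = g$strand,
    type = c("gene", "mRNA", rep("exon", nrow(ex)), rep("CDS", nrow(cd))),
    ID = c(g$gene_id, tid,
           paste0(tid, ".exon", seq_len(nrow(ex))),
           paste0(tid, ".cds", seq_len(nrow(cd)))),
    Parent = c(NA, g$gene_id, rep(tid, nrow(ex) + nrow(cd))),
    phase = c(NA, NA, rep(NA, nrow(ex)), phase),
    stringsAsFactors = FALSE)
}

#' Write a phylogenetic tree in newick format
#'
#' Thin wrapper around [ape::write.tree()]; branch lengths and any node
#' support labels are preserved.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path path to a newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("newick file not found: %s", path)
  ape::read.tree(path)
}

#' Read/write a labelled numeric matrix as TSV
#'
#' Row labels live in the first column (header `id`); remaining columns are
#' numeric.  Used for FPKM matrices, identity matrices and presence tables.
#'
#' @param path file path.
#' @return `read_tsv_matrix`: a numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_tsv_matrix
#' @param m numeric matrix with dimnames.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif catalog TSV
#'
#' Expected columns: `motif_id`, `iupac`, and optionally `source`.  Motifs
#' are validated against the IUPAC nucleotide alphabet and must be at least
#' 4 nt long.
#'
#' @param path TSV path.
#' @return data.frame with columns motif_id, iupac, source.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif_id", "iupac") %in% names(df)))
    stopf("motif table must have columns motif_id and iupac")
  if (is.null(df$source)) df$source <- "unknown"
  df$iupac <- toupper(df$iupac)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", df$iupac) | nchar(df$iupac) < 4L
  if (any(bad))
    stopf("invalid motif(s): %s", paste(df$motif_id[bad], collapse = ", "))
  df[c("motif_id", "iupac", "source")]
}
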