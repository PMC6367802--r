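# Intron evolution: projection of introns onto protein coordinates,
# cross-gene insertion-site clustering, conserved-intron calling, censuses
# and family x site gain/loss matrices.
#
# Conventions.  For an intron with k coding nucleotides 5' of its junction,
# phase = k mod 3 (0 between codons, 1 after the first base, 2 after the
# second) and aa_position = floor(k/3) + 1, i.e. the 1-based index of the
# codon containing or immediately following the intron.  The single formula
# covers all three phases.

#' Project a gene model's introns onto protein coordinates
#'
#' Walks consecutive CDS segments in transcription order (strand-aware) and
#' emits one record per inter-segment junction.  Introns lying entirely in
#' UTR never separate CDS segments and are therefore excluded.  Adjacent
#' CDS segments with no genomic gap are merged first.
#'
#' @param g a [gene_model()].
#' @return data.frame with columns `gene_id`, `intron_index` (1-based, in
#'   transcription order), `k` (coding nucleotides upstream), `aa_position`
#'   and `phase`.  Zero rows for a single-segment CDS.
#' @export
introns_from_genemodel <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  cds <- g$cds
  if (sum(cds[, 2] - cds[, 1]) == 0L) stopf("gene %s: zero CDS length",
                                            g$gene_id)
  # merge genomically adjacent segments: no intron between them
  if (nrow(cds) > 1L) {
    keep <- which(cds[-1L, 1] > cds[-nrow(cds), 2])
    starts <- cds[c(1L, keep + 1L), 1]
    ends <- cds[c(keep, nrow(cds)), 2]
    cds <- cbind(starts, ends)
  }
  m <- nrow(cds)
  if (m < 2L)
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      k = integer(0), aa_position = integer(0),
                      phase = integer(0)))
  lens <- cds[, 2] - cds[, 1]
  if (g$strand == "-") lens <- rev(lens)      # transcription order
  k <- cumsum(lens)[-m]
  data.frame(gene_id = g$gene_id,
             intron_index = seq_len(m - 1L),
             k = as.integer(k),
             aa_position = as.integer(k %/% 3L + 1L),
             phase = as.integer(k %% 3L),
             stringsAsFactors = FALSE)
}

#' Collect intron records from many gene models
#' @param models list of [gene_model()] objects.
#' @return row-bound data.frame of [introns_from_genemodel()] results.
#' @export
introns_from_genemodels <- function(models) {
  do.call(rbind, c(lapply(models, introns_from_genemodel),
                   list(make.row.names = FALSE)))
}

#' Cluster introns into cross-gene insertion sites
#'
#' Within each phase class, single-linkage clustering of amino-acid
#' positions with link threshold `window`: two introns of the same phase
#' fall in the same site when they can be chained through gaps of at most
#' `window` aa.  Sites are numbered `I1..In` by ascending mean position
#' across all phases.  Clustering is per-phase because the conserved-intron
#' definition requires phase identity; cross-phase merging would create
#' sites that could never be called conserved.
#'
#' @param introns data.frame with at least `gene_id`, `aa_position`,
#'   `phase` (as from [introns_from_genemodels()]).
#' @param window link threshold in amino acids (default 45).
#' @return list of class `insertion_sites` with two data.frames:
#'   `sites` (`site_id`, `phase`, `n_introns`, `n_genes`, `mean_position`,
#'   `min_position`, `max_position`) and `members` (`site_id`, `gene_id`,
#'   `aa_position`, `phase`).
#' @export
cluster_insertion_sites <- function(introns, window = 45) {
  stopifnot(window > 0,
            all(c("gene_id", "aa_position", "phase") %in% names(introns)))
  if (nrow(introns) == 0L) stopf("no introns to cluster")
  introns <- introns[order(introns$phase, introns$aa_position,
                           introns$gene_id), , drop = FALSE]
  key <- integer(nrow(introns))
  next_id <- 0L
  for (ph in sort(unique(introns$phase))) {
    sel <- which(introns$phase == ph)
    pos <- introns$aa_position[sel]
    brk <- c(0L, which(diff(pos) > window), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      next_id <- next_id + 1L
      key[sel[(brk[b] + 1L):brk[b + 1L]]] <- next_id
    }
  }
  means <- tapply(introns$aa_position, key, mean)
  ord <- order(as.numeric(means), as.integer(names(means)))
  site_of <- stats::setNames(seq_along(ord), names(means)[ord])
  introns$site_id <- paste0("I", site_of[as.character(key)])
  sites <- do.call(rbind, lapply(seq_along(ord), function(s) {
    mem <- introns[introns$site_id == paste0("I", s), , drop = FALSE]
    data.frame(site_id = paste0("I", s),
               phase = mem$phase[1L],
               n_introns = nrow(mem),
               n_genes = length(unique(mem$gene_id)),
               mean_position = mean(mem$aa_position),
               min_position = min(mem$aa_position),
               max_position = max(mem$aa_position),
               stringsAsFactors = FALSE)
  }))
  out <- list(sites = sites,
              members = introns[, c("site_id", "gene_id", "aa_position",
                                    "phase")])
  class(out) <- "insertion_sites"
  attr(out, "window") <- window
  out
}

#' Flag conserved insertion sites
#'
#' A site is conserved when every member intron lies within `window` amino
#' acids of the site's mean position, all members share one intron phase
#' (when `require_same_phase`), and at least `min_genes` distinct genes
#' carry it.
#'
#' @param sites an `insertion_sites` object from
#'   [cluster_insertion_sites()].
#' @param window conservation window in amino acids (default 45).
#' @param min_genes minimum distinct genes per conserved site (default 2).
#' @param require_same_phase require uniform phase (default TRUE).
#' @return the `insertion_sites` object with a logical `conserved` column
#'   added to `$sites`.
#' @export
call_conserved <- function(sites, window = 45, min_genes = 2L,
                           require_same_phase = TRUE) {
  stopifnot(inherits(sites, "insertion_sites"))
  tab <- sites$sites
  mem <- sites$members
  conserved <- logical(nrow(tab))
  for (s in seq_len(nrow(tab))) {
    m <- mem[mem$site_id == tab$site_id[s], , drop = FALSE]
    within <- all(abs(m$aa_position - tab$mean_position[s]) <= window)
    same_phase <- !require_same_phase || length(unique(m$phase)) == 1L
    enough <- length(unique(m$gene_id)) >= min_genes
    conserved[s] <- within && same_phase && enough
  }
  sites$sites$conserved <- conserved
  sites
}

#' Intron-number census
#'
#' Counts genes per intron-number class `{0, 1, 2, 3, 4, 5+}` and reports
#' percentages (two decimals, half-up).  When gene models are supplied the
#' phase composition of all introns is reported as well.
#'
#' @param x either a list of [gene_model()] objects or a numeric vector of
#'   per-gene intron counts.
#' @return list of class `intron_census`: `class_counts`, `percentages`,
#'   `total_genes`, `phase_counts` (NULL for count-vector input),
#'   `min_introns`, `max_introns`.
#' @export
intron_census <- function(x) {
  if (is.numeric(x)) {
    counts <- as.integer(x)
    phase_counts <- NULL
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    recs <- lapply(x, introns_from_genemodel)
    counts <- vapply(recs, nrow, integer(1))
    all_introns <- do.call(rbind, recs)
    phase_counts <- table(factor(all_introns$phase, levels = 0:2))
  }
  if (length(counts) == 0L) stopf("no genes in census input")
  cls <- ifelse(counts >= 5L, "5+", as.character(counts))
  class_counts <- table(factor(cls, levels = c("0", "1", "2", "3", "4",
                                               "5+")))
  out <- list(class_counts = class_counts,
              percentages = percent_share(as.numeric(class_counts),
                                          length(counts)),
              total_genes = length(counts),
              phase_counts = phase_counts,
              min_introns = min(counts),
              max_introns = max(counts))
  names(out$percentages) <- names(class_counts)
  class(out) <- "intron_census"
  out
}

#' @export
print.intron_census <- function(x, ...) {
  cat(sprintf("<intron_census> %d genes, %d-%d introns\n", x$total_genes,
              x$min_introns, x$max_introns))
  for (k in names(x$class_counts))
    cat(sprintf("  %-2s introns: %4d genes (%.2f%%)\n", k,
                x$class_counts[[k]], x$percentages[[k]]))
  invisible(x)
}

#' Family-by-site intron presence (gain/loss) matrix
#'
#' A cell is 1 when any gene of the family carries an intron at the site.
#' Complementary rows between two columns are the signature of reciprocal
#' gain/loss between families.
#'
#' @param sites an `insertion_sites` object.
#' @param group_labels named character vector mapping every gene id in the
#'   site membership to its family label.
#' @return integer 0/1 matrix, families x sites; rows sorted by family
#'   label, columns by site number.
#' @export
gain_loss_matrix <- function(sites, group_labels) {
  stopifnot(inherits(sites, "insertion_sites"))
  mem <- sites$members
  missing_genes <- setdiff(unique(mem$gene_id), names(group_labels))
  if (length(missing_genes) > 0L)
    stopf("unlabeled gene(s): %s", paste(missing_genes, collapse = ", "))
  fams <- sort(unique(unname(group_labels)))
  site_ids <- sites$sites$site_id[
    order(as.integer(sub("^I", "", sites$sites$site_id)))]
  m <- matrix(0L, length(fams), length(site_ids),
              dimnames = list(fams, site_ids))
  fam_of <- unname(group_labels[mem$gene_id])
  for (r in seq_len(nrow(mem)))
    m[fam_of[r], mem$site_id[r]] <- 1L
  m
}

#' Text-art intron map
#'
#' One line per gene with phase symbols at (scaled) amino-acid positions:
#' `|` phase 0, `[` phase 1, `]` phase 2 — the bracket notation of
#' classical intron-map figures.
#'
#' @param introns data.frame as from [introns_from_genemodels()].
#' @param width map width in characters (default 80).
#' @return character vector of lines, named by gene id.
#' @export
intron_map_text <- function(introns, width = 80L) {
  stopifnot(all(c("gene_id", "aa_position", "phase") %in% names(introns)))
  sym <- c(`0` = "|", `1` = "[", `2` = "]")
  maxpos <- max(introns$aa_position)
  genes <- unique(introns$gene_id)
  lines <- vapply(genes, function(g) {
    m <- introns[introns$gene_id == g, , drop = FALSE]
    chars <- rep("-", width)
    at <- pmax(1L, pmin(width, round(m$aa_position / maxpos * width)))
    chars[at] <- sym[as.character(m$phase)]
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(lines, genes)
}
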