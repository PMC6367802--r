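# Expression profiling: FPKM-based expressed / tissue-specific calls,
# heatmap matrix preparation and Livak 2^-ddCt relative quantification.

check_fpkm <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) >= 2L,
            !is.null(rownames(m)), !is.null(colnames(m)))
  if (any(!is.finite(m)) || any(m < 0))
    stopf("FPKM matrix must be finite and non-negative")
  m
}

#' Call expressed genes from an FPKM matrix
#'
#' A gene is expressed when its maximum FPKM across tissues reaches the
#' threshold `T`.  The summary reports the count and the percentage of
#' input genes (two decimals, half-up).
#'
#' @param m numeric FPKM matrix, genes x tissues.
#' @param T FPKM threshold (default 2).
#' @return list: `expressed` (character vector of gene ids), `n_expressed`,
#'   `total_genes`, `percentage`.
#' @export
call_expressed <- function(m, T = 2) {
  m <- check_fpkm(m)
  stopifnot(T >= 0)
  expressed <- rownames(m)[apply(m, 1L, max) >= T]
  list(expressed = expressed,
       n_expressed = length(expressed),
       total_genes = nrow(m),
       percentage = percent_share(length(expressed), nrow(m)))
}

#' Tissue-specificity calls
#'
#' For each gene: the top tissue (argmax FPKM, ties broken by the
#' lexicographically smallest tissue label), the specificity score
#' `s = max / total` (0 for an all-zero gene), and the specific flag
#' `expressed AND s >= s_star`.  "Highly expressed in a specific tissue"
#' is thus formalized with two knobs: the expressed threshold `T` and the
#' concentration cutoff `s_star`.
#'
#' @param m numeric FPKM matrix, genes x tissues.
#' @param s_star specificity cutoff in `[1/n_tissues, 1]` (default 0.5).
#' @param T expressed threshold, as in [call_expressed()].
#' @return data.frame with `gene_id`, `expressed`, `top_tissue`, `score`,
#'   `specific`.
#' @export
tissue_specificity <- function(m, s_star = 0.5, T = 2) {
  m <- check_fpkm(m)
  lab_order <- order(colnames(m))
  res <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    total <- sum(v)
    mx <- max(v)
    top <- colnames(m)[lab_order][which.max(v[lab_order])]
    s <- if (total == 0) 0 else mx / total
    data.frame(gene_id = rownames(m)[i], expressed = mx >= T,
               top_tissue = top, score = s,
               specific = mx >= T && s >= s_star,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Prepare a heatmap matrix
#'
#' Optional `ln(x + 1)` transform followed by optional per-row centering
#' and unit-variance scaling — the defaults of common clustering/heatmap
#' front-ends.  Constant rows cannot be variance-scaled; they are centered
#' to zero and listed in the `constant_rows` attribute.
#'
#' @param m numeric FPKM matrix, genes x tissues.
#' @param transform `"ln1p"` (default) or `"none"`.
#' @param row_scaling `"unit_variance"` (default) or `"none"`.
#' @return transformed numeric matrix with the same dimnames.
#' @export
heatmap_matrix <- function(m, transform = c("ln1p", "none"),
                           row_scaling = c("unit_variance", "none")) {
  transform <- match.arg(transform)
  row_scaling <- match.arg(row_scaling)
  m <- check_fpkm(m)
  out <- if (transform == "ln1p") log(m + 1) else m
  constant <- character(0)
  if (row_scaling == "unit_variance") {
    for (i in seq_len(nrow(out))) {
      v <- out[i, ]
      s <- stats::sd(v)
      if (s == 0) {
        out[i, ] <- 0
        constant <- c(constant, rownames(out)[i])
      } else {
        out[i, ] <- (v - mean(v)) / s
      }
    }
  }
  attr(out, "constant_rows") <- constant
  out
}

#' Livak 2^-ddCt relative expression
#'
#' Input rows are qPCR measurements of one gene in one tissue: target-gene
#' and reference-gene (housekeeping) Ct values, optionally with a
#' `bio_rep` column.  Technical replicates (duplicate rows of the same
#' gene/tissue/bio_rep) are averaged first; then per biological replicate
#' `dCt = Ct_target - Ct_reference`.  The fold change of a tissue is
#' `2^-(ddCt)` with `ddCt = mean dCt(tissue) - mean dCt(calibrator)`, so
#' the calibrator tissue itself is exactly 1.  The reported `fold_sd` is
#' the standard deviation of per-biological-replicate folds computed
#' against the calibrator mean.
#'
#' @param records data.frame with columns `gene`, `tissue`, `ct_target`,
#'   `ct_reference` and optionally `bio_rep`.
#' @param calibrator calibrator tissue name; must be measured for every
#'   gene.
#' @return data.frame with `gene`, `tissue`, `n_bio`, `delta_ct`,
#'   `delta_delta_ct`, `fold`, `fold_sd`.
#' @export
ddct_fold_change <- function(records, calibrator) {
  need <- c("gene", "tissue", "ct_target", "ct_reference")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (is.null(records$bio_rep)) records$bio_rep <- 1L
  bad <- !is.finite(records$ct_target) | !is.finite(records$ct_reference) |
    records$ct_target <= 0 | records$ct_reference <= 0
  if (any(bad))
    stopf("missing or non-positive Ct for gene %s in tissue %s",
          records$gene[bad][1L], records$tissue[bad][1L])
  # technical replicates -> one Ct pair per gene/tissue/bio_rep
  agg <- stats::aggregate(records[c("ct_target", "ct_reference")],
                          by = records[c("gene", "tissue", "bio_rep")],
                          FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  out <- list()
  for (g in unique(agg$gene)) {
    a <- agg[agg$gene == g, , drop = FALSE]
    cal <- a$dct[a$tissue == calibrator]
    if (length(cal) == 0L)
      stopf("gene %s has no calibrator tissue '%s' measurement", g,
            calibrator)
    cal_mean <- mean(cal)
    for (tis in unique(a$tissue)) {
      dct <- a$dct[a$tissue == tis]
      ddct <- mean(dct) - cal_mean
      rep_folds <- 2^-(dct - cal_mean)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, tissue = tis, n_bio = length(dct),
        delta_ct = mean(dct), delta_delta_ct = ddct, fold = 2^-ddct,
        fold_sd = if (length(rep_folds) > 1L) stats::sd(rep_folds)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
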