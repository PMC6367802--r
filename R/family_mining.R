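# Family mining: P450 signature motifs, identity/conservation statistics and
# family/subfamily grouping.
#
# Plant P450s carry four diagnostic motifs: the heme-binding domain around an
# invariant cysteine near the C terminus, the I-helix oxygen-binding groove,
# the K-helix ExxR salt bridge and the PERF/W domain.  A full-length family
# member has all four plus a length in a configurable window (450-600 aa for
# the tomato-sized survey this package models).

#' Default P450 signature profiles
#'
#' Degenerate protein patterns written with fixed residues, `x` wildcards and
#' square-bracket alternatives.  These are minimal consensus patterns
#' consistent with published P450 sequence logos — the heme motif keeps its
#' invariant cysteine, the I-helix its (A/G)GxDT core, the K-helix its ExxR
#' salt bridge and the PERF/W domain its PER[FW] core.  All four are
#' user-overridable: pass your own named vector wherever a `profiles`
#' argument is accepted.
#'
#' @return named character vector with entries `heme`, `i_helix`, `k_helix`,
#'   `perf`.
#' @export
signature_profiles <- function() {
  c(heme = "FxxGxRxCxG",
    i_helix = "[AG]GxDT",
    k_helix = "ExxR",
    perf = "PER[FW]")
}

# degenerate protein pattern -> perl regex (x wildcard, [..] alternatives)
protein_pattern_regex <- function(pattern) {
  if (!grepl("^(\\[[A-Z]+\\]|[A-Zx])+$", pattern))
    stopf("invalid signature pattern: %s", pattern)
  gsub("x", ".", pattern, fixed = TRUE)
}

# overlapping match start positions (0-based) of a perl regex in one string
overlapping_starts <- function(regex, s) {
  m <- gregexpr(paste0("(?=", regex, ")"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a protein for signature motifs
#'
#' Reports every (overlapping) match start of each profile pattern.
#'
#' @param protein a single ungapped amino-acid sequence.
#' @param profiles named character vector of degenerate patterns; defaults to
#'   [signature_profiles()].
#' @return named list mapping profile name to an integer vector of 0-based
#'   match start positions (empty when the motif is absent).
#' @examples
#' scan_signatures("MKTFSAGRRICLGAAPERW")[c("heme", "perf")]
#' @export
scan_signatures <- function(protein, profiles = signature_profiles()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (grepl("-", protein, fixed = TRUE))
    stopf("scan_signatures() requires an ungapped sequence")
  lapply(as.list(profiles), function(p)
    overlapping_starts(protein_pattern_regex(p), protein))
}

#' Filter proteins to full-length family candidates
#'
#' A candidate passes when all four signature motifs are present and its
#' length lies within `length_bounds`.  Exact duplicate sequences are
#' collapsed to one call (redundancy removal); removed duplicates are listed
#' in the `duplicates` attribute of the result.
#'
#' @param proteins named character vector of ungapped protein sequences.
#' @param profiles signature patterns, see [signature_profiles()].
#' @param length_bounds inclusive `(min, max)` amino-acid length bounds.
#' @return data.frame with one row per retained protein: `protein_id`,
#'   `length`, one hit-count column per profile, `passed` and `fail_reasons`
#'   (comma-joined, empty when passed).  Attribute `duplicates` is a
#'   data.frame of (kept, removed) id pairs.
#' @export
filter_candidates <- function(proteins, profiles = signature_profiles(),
                              length_bounds = c(450L, 600L)) {
  stopifnot(length(length_bounds) == 2L,
            length_bounds[1] <= length_bounds[2])
  if (length(proteins) == 0L) {
    out <- data.frame(protein_id = character(0), length = integer(0),
                      passed = logical(0), fail_reasons = character(0))
    attr(out, "duplicates") <- data.frame(kept = character(0),
                                          removed = character(0))
    return(out)
  }
  stopifnot(!is.null(names(proteins)))
  dup <- duplicated(unname(proteins))
  dup_tab <- data.frame(
    kept = names(proteins)[match(proteins[dup], proteins)],
    removed = names(proteins)[dup],
    stringsAsFactors = FALSE)
  kept <- proteins[!dup]

  hits <- lapply(kept, scan_signatures, profiles = profiles)
  counts <- t(vapply(hits, lengths, integer(length(profiles))))
  colnames(counts) <- names(profiles)
  len <- nchar(kept)
  miss <- counts == 0L
  reasons <- apply(miss, 1L, function(m)
    if (!any(m)) "" else
      paste(paste0("missing_", names(profiles)[m]), collapse = ","))
  bad_len <- len < length_bounds[1] | len > length_bounds[2]
  reasons <- ifelse(bad_len,
                    ifelse(reasons == "", "length",
                           paste(reasons, "length", sep = ",")),
                    reasons)
  out <- data.frame(protein_id = names(kept), length = as.integer(len),
                    counts, passed = reasons == "", fail_reasons = reasons,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "duplicates") <- dup_tab
  out
}

# ---- alignment statistics ---------------------------------------------------

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# named character vector of equal-length gapped sequences -> char matrix
alignment_matrix <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 2L,
            !is.null(names(alignment)))
  if (length(unique(nchar(alignment))) != 1L)
    stopf("alignment records have unequal gapped lengths")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Pairwise percent identity of an alignment
#'
#' `identity(i, j)` is `100 * matches / comparable`, where comparable
#' positions are the aligned columns in which neither sequence has a gap.
#' Pairs with zero comparable columns are `NA` and listed in the
#' `undefined_pairs` attribute.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @return symmetric numeric matrix (diagonal 100) of percent identities.
#' @seealso [protein_distances()]; on gap-free alignments
#'   `identity = 100 * (1 - p_distance)`.
#' @export
identity_matrix <- function(alignment) {
  M <- alignment_matrix(alignment)
  n <- nrow(M)
  out <- matrix(100, n, n, dimnames = list(names(alignment),
                                           names(alignment)))
  undef <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- M[i, ] != "-" & M[j, ] != "-"
    nc <- sum(comp)
    v <- if (nc == 0L) NA_real_ else 100 * sum(M[i, comp] == M[j, comp]) / nc
    if (nc == 0L) undef[[length(undef) + 1L]] <- c(i, j)
    out[i, j] <- out[j, i] <- v
  }
  attr(out, "undefined_pairs") <- if (length(undef) > 0L)
    do.call(rbind, undef) else NULL
  out
}

#' Per-column residue frequencies and information content
#'
#' For each aligned column the gap-excluded residue distribution and its
#' information content `log2(20) - H` in bits, where `H` is the Shannon
#' entropy of that distribution — the quantity a sequence-logo renderer
#' draws as total letter height.  All-gap columns get `NA` information and
#' are flagged.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @return list with `frequencies` (20 x n_columns matrix, columns summing
#'   to 1) and `information` (numeric vector, bits; `NA` for all-gap
#'   columns).
#' @export
column_conservation <- function(alignment) {
  M <- alignment_matrix(alignment)
  nc <- ncol(M)
  freq <- matrix(0, length(AA_ALPHABET), nc,
                 dimnames = list(AA_ALPHABET, NULL))
  info <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- M[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      info[j] <- NA_real_
      next
    }
    tab <- table(factor(col, levels = AA_ALPHABET))
    p <- as.numeric(tab) / length(col)
    freq[, j] <- p
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    info[j] <- log2(20) - h
  }
  list(frequencies = freq, information = info)
}

#' Pairwise evolutionary distances from an alignment
#'
#' `p_distance` is the mismatch fraction over comparable (gap-free in both)
#' columns; `poisson` applies the multiple-hit correction `-ln(1 - p)`,
#' infinite (and flagged) when `p >= 1`.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param model `"p_distance"` or `"poisson"`.
#' @return symmetric numeric distance matrix with zero diagonal; attribute
#'   `model` records the choice, attribute `undefined_pairs` any pair with
#'   no comparable columns.
#' @export
protein_distances <- function(alignment,
                              model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  idm <- identity_matrix(alignment)
  p <- 1 - idm / 100
  d <- if (model == "poisson") {
    ifelse(p >= 1, Inf, -log(1 - p))
  } else p
  diag(d) <- 0
  attr(d, "model") <- model
  attr(d, "undefined_pairs") <- attr(idm, "undefined_pairs")
  d
}

#' Family and subfamily assignment by identity thresholds
#'
#' Single-linkage clustering of the percent-identity matrix at the family
#' threshold and again at the (higher) subfamily threshold, following the
#' P450 nomenclature convention of ~40% identity for family and ~55% for
#' subfamily membership.  Because both partitions come from the same
#' single-linkage dendrogram, subfamilies nest exactly within families.
#' Cluster labels are numbered by decreasing cluster size, ties broken by
#' the lexicographically smallest member id.
#'
#' @param identity percent-identity matrix from [identity_matrix()].
#' @param family_cut,subfamily_cut percent-identity thresholds (defaults 40
#'   and 55).
#' @return data.frame with `protein_id`, `family` (e.g. `"F1"`) and
#'   `subfamily` (e.g. `"F1.S2"`).
#' @export
assign_groups <- function(identity, family_cut = 40, subfamily_cut = 55) {
  stopifnot(is.matrix(identity), nrow(identity) == ncol(identity),
            family_cut <= subfamily_cut)
  if (anyNA(identity)) stopf("identity matrix contains undefined pairs")
  d <- stats::as.dist(100 - identity)
  hc <- stats::hclust(d, method = "single")
  fam <- relabel_clusters(stats::cutree(hc, h = 100 - family_cut), "F")
  sub_raw <- stats::cutree(hc, h = 100 - subfamily_cut)
  ids <- rownames(identity)
  sub <- character(length(ids))
  for (f in unique(fam)) {
    sel <- fam == f
    sub[sel] <- paste0(f, ".", relabel_clusters(sub_raw[sel], "S"))
  }
  data.frame(protein_id = ids, family = unname(fam),
             subfamily = sub, stringsAsFactors = FALSE)
}

# deterministic cluster labels: by size desc, then smallest member id
relabel_clusters <- function(cl, prefix) {
  ids <- names(cl)
  info <- data.frame(cluster = unique(cl))
  info$size <- vapply(info$cluster, function(k) sum(cl == k), integer(1))
  info$first <- vapply(info$cluster, function(k) min(ids[cl == k]),
                       character(1))
  info <- info[order(-info$size, info$first), ]
  new <- stats::setNames(paste0(prefix, seq_len(nrow(info))), info$cluster)
  stats::setNames(new[as.character(cl)], ids)
}
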