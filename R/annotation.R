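# Reference-based annotation of cells and peaks: binned-control module
# scoring, thresholded argmax labelling, majority labelling of peaks, and
# Pearson-correlation matching of peak profiles to spatial reference
# domains.

#' Module score with expression-binned control genes
#'
#' Genes are ranked by mean expression across cells and cut into `n_bins`
#' bins of (near-)equal size; for every gene of the set, `n_ctrl` control
#' genes are drawn from the non-set genes of its bin (with replacement when
#' the pool holds fewer than `n_ctrl`, and falling back to the whole bin
#' when the set fills it). The score of a cell is the mean expression of the
#' set genes minus the mean expression of the pooled controls. This is a
#' self-contained variant of binned-control gene-set scoring; numerical
#' equality with other implementations is not promised.
#'
#' @param e Genes x cells expression matrix.
#' @param gene_set Character vector; at least one member must be in `e`.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls drawn per set gene (default 100).
#' @param seed Seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(e, gene_set, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  e <- .check_expression(e)
  gene_set <- intersect(unique(gene_set), rownames(e))
  if (length(gene_set) == 0L) stop("no gene of the set is present")
  n_bins <- min(as.integer(n_bins), nrow(e))
  avg <- rowMeans(e)
  ord <- order(avg, rownames(e))
  bin_of <- integer(nrow(e))
  bin_of[ord] <- if (n_bins == 1L) 1L
    else as.integer(cut(seq_along(ord), breaks = n_bins, labels = FALSE))
  names(bin_of) <- rownames(e)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  controls <- character(0)
  for (g in gene_set) {
    # controls are expression-matched non-set genes; fall back to the whole
    # bin when the set fills it
    pool <- setdiff(rownames(e)[bin_of == bin_of[[g]]], gene_set)
    if (length(pool) == 0L) pool <- rownames(e)[bin_of == bin_of[[g]]]
    replace <- length(pool) < n_ctrl
    controls <- c(controls, sample(pool, n_ctrl, replace = replace))
  }
  set_mean <- colMeans(e[gene_set, , drop = FALSE])
  ctrl_mean <- colMeans(e[controls, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Thresholded argmax labelling from a score matrix
#'
#' A cell receives the label of its highest-scoring column iff that score
#' strictly exceeds `threshold`; ties at the maximum, or a maximum at or
#' below the threshold, give `NA`.
#'
#' @param scores Cells x labels score matrix.
#' @param threshold Minimum winning score (exclusive).
#' @return Named character vector of labels (or `NA`).
#' @export
assign_labels <- function(scores, threshold = 0) {
  scores <- as.matrix(scores)
  stopifnot(is.finite(threshold), !is.null(colnames(scores)))
  out <- apply(scores, 1L, function(row) {
    top <- max(row)
    if (!is.finite(top) || top <= threshold) return(NA_character_)
    hits <- which(row == top)
    if (length(hits) > 1L) NA_character_ else colnames(scores)[hits]
  })
  stats::setNames(as.character(out), rownames(scores))
}

#' Majority label per peak
#'
#' The supporting fraction of a peak is the fraction of member cells with a
#' non-`NA` label. A peak is labelled `NA` unless strictly more than half
#' its cells are labelled; otherwise it takes the modal non-`NA` label,
#' with modal ties resolving to `NA`.
#'
#' @param cell_labels Named per-cell labels (may contain `NA`).
#' @param peaks A `peak_assignment` (from [find_peaks()] /
#'   [triage_cluster()]) or a named per-cell peak-id vector (`"NONE"` for
#'   unassigned cells).
#' @return Data frame: peak, label, supporting_fraction, n_cells.
#' @export
peak_majority_label <- function(cell_labels, peaks) {
  peak_labels <- if (inherits(peaks, "peak_assignment")) peaks$labels else peaks
  if (!setequal(names(cell_labels), names(peak_labels)))
    stop("cell universes of labels and peaks differ")
  cell_labels <- cell_labels[names(peak_labels)]
  ids <- setdiff(unique(peak_labels), "NONE")
  rows <- lapply(sort(ids), function(pk) {
    members <- cell_labels[peak_labels == pk]
    if (length(members) == 0L) stop("empty peak ", pk)
    frac <- mean(!is.na(members))
    lab <- NA_character_
    if (frac > 0.5) {
      tab <- table(members[!is.na(members)])
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) == 1L) lab <- winners
    }
    data.frame(peak = pk, label = lab, supporting_fraction = frac,
               n_cells = length(members), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Match peak expression profiles to spatial reference domains
#'
#' Computes per-peak mean expression over a marker gene union, drops peaks
#' with fewer than `min_peak_cells` cells and genes expressed in less than
#' `min_expr_frac` of the cells of any retained peak, then reports the
#' Pearson correlation of every (peak, domain) profile pair and the
#' best-matching domain per peak.
#'
#' @param e Genes x cells expression matrix.
#' @param peaks A `peak_assignment` or named per-cell peak-id vector.
#' @param domain_profiles Genes x domains reference expression matrix.
#' @param markers Marker gene union to correlate over.
#' @param min_peak_cells Minimum cells for a peak to be retained.
#' @param min_expr_frac Minimum expressed fraction per retained peak.
#' @return List with `r` (peaks x domains Pearson matrix), `best` (named
#'   best-domain per peak), `genes_used`.
#' @export
spatial_correlate <- function(e, peaks, domain_profiles, markers,
                              min_peak_cells = 20L, min_expr_frac = 0.05) {
  e <- .check_expression(e)
  peak_labels <- if (inherits(peaks, "peak_assignment")) peaks$labels else peaks
  domain_profiles <- as.matrix(domain_profiles)
  genes <- intersect(intersect(unique(markers), rownames(e)),
                     rownames(domain_profiles))
  ids <- setdiff(unique(peak_labels), "NONE")
  sizes <- table(peak_labels)[ids]
  ids <- ids[sizes >= min_peak_cells]
  if (length(ids) == 0L) stop("no peak passes the size filter")
  expr_frac <- sapply(ids, function(pk) {
    cells <- names(peak_labels)[peak_labels == pk]
    rowMeans(e[genes, cells, drop = FALSE] > 0)
  })
  keep_gene <- apply(expr_frac >= min_expr_frac, 1L, all)
  genes <- genes[keep_gene]
  if (length(genes) < 3L) stop("fewer than 3 genes survive the filters")
  profiles <- sapply(ids, function(pk) {
    cells <- names(peak_labels)[peak_labels == pk]
    rowMeans(e[genes, cells, drop = FALSE])
  })
  r <- stats::cor(profiles, domain_profiles[genes, , drop = FALSE],
                  method = "pearson")
  best <- colnames(r)[apply(r, 1L, which.max)]
  list(r = r, best = stats::setNames(best, rownames(r)), genes_used = genes)
}
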