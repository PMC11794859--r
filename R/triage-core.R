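# Repressive-tendency machinery: RTS tables, the discordance-score (DS)
# transform, per-cell RTS weights, top-k DS gene lists, Jaccard similarity
# and the complete-linkage peak dendrogram.
#
# The RTS is a per-gene, non-negative score derived upstream from the
# breadth of H3K27me3 repressive-chromatin domains across many tissues;
# genes with broad domains tend to be cell-identity regulators. Multiplying
# a gene's expression by its RTS gives the discordance score, which ranks
# genes by predicted regulatory importance for the cell group at hand.

#' Construct an RTS table
#'
#' @param x Named numeric vector mapping gene id to a non-negative
#'   repressive tendency score.
#' @return A named numeric vector of class `rts_table`.
#' @export
rts_table <- function(x) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicate gene ids in RTS table")
  if (any(!is.finite(x)) || any(x < 0)) stop("RTS values must be finite and >= 0")
  structure(x, class = "rts_table")
}

.check_expression <- function(e) {
  e <- as.matrix(e)
  if (is.null(rownames(e))) stop("expression matrix needs gene rownames")
  if (any(!is.finite(e)) || any(e < 0))
    stop("expression values must be finite and >= 0")
  e
}

#' TRIAGE discordance transform
#'
#' Multiplies each gene's expression row by its repressive tendency score.
#' Genes absent from the RTS table get a discordance score of 0 (their
#' count is reported via attribute `n_missing_rts`).
#'
#' @param e Genes x groups (or genes x cells) non-negative expression matrix.
#' @param r An [rts_table()].
#' @return Matrix of discordance scores, same shape and dimnames as `e`.
#' @export
discordance_transform <- function(e, r) {
  e <- .check_expression(e)
  stopifnot(inherits(r, "rts_table"))
  w <- unclass(r)[rownames(e)]
  missing <- is.na(w)
  if (all(missing)) stop("no gene overlap between expression and RTS table")
  w[missing] <- 0
  ds <- e * w
  attr(ds, "n_missing_rts") <- sum(missing)
  ds
}

#' Per-cell repressive-tendency weights
#'
#' Each cell is weighted by the highest RTS among the genes it expresses
#' (expression strictly above `expr_threshold`). Cells expressing no
#' RTS-covered gene get weight 0 with a warning.
#'
#' @param e Genes x cells expression matrix.
#' @param r An [rts_table()].
#' @param expr_threshold Expression above this counts as "expressed".
#' @return Named numeric vector of per-cell weights.
#' @export
cell_rts <- function(e, r, expr_threshold = 0) {
  e <- .check_expression(e)
  stopifnot(inherits(r, "rts_table"))
  w <- unclass(r)[rownames(e)]
  if (all(is.na(w))) stop("no gene overlap between expression and RTS table")
  w[is.na(w)] <- 0
  expressed <- e > expr_threshold
  out <- apply(expressed * w, 2L, max)
  if (any(out == 0))
    warning(sum(out == 0), " cell(s) express no RTS-covered gene; weight 0")
  stats::setNames(as.numeric(out), colnames(e))
}

#' Top-k genes by discordance score
#'
#' Ranks genes by DS (expression times RTS) in descending order, breaking
#' ties lexicographically by gene id, and returns the first `k`.
#'
#' @param expr Named numeric vector of group-mean expression per gene.
#' @param r An [rts_table()].
#' @param k Number of genes to return (default 100).
#' @return Character vector of `k` gene ids.
#' @export
top_ds_genes <- function(expr, r, k = 100L) {
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  ds <- discordance_transform(matrix(expr, ncol = 1,
                                     dimnames = list(names(expr), "g")), r)[, 1]
  if (k > length(ds)) stop("k exceeds the number of genes with a defined DS")
  ord <- order(-ds, names(ds))
  names(ds)[ord][seq_len(k)]
}

#' Pairwise Jaccard similarity between gene lists
#'
#' @param lists Named list of non-empty gene id vectors (one per peak).
#' @return Symmetric matrix with unit diagonal, entries
#'   `|A intersect B| / |A union B|`.
#' @export
jaccard_matrix <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  if (any(lengths(lists) == 0L)) stop("empty gene list")
  sets <- lapply(lists, unique)
  n <- length(sets)
  j <- matrix(1, n, n, dimnames = list(names(lists), names(lists)))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      inter <- length(intersect(sets[[a]], sets[[b]]))
      j[a, b] <- j[b, a] <- inter / length(union(sets[[a]], sets[[b]]))
    }
  }
  j
}

#' Complete-linkage dendrogram over peak similarity profiles
#'
#' Computes Euclidean distances between the rows of a Jaccard similarity
#' matrix and clusters them agglomeratively with complete linkage.
#'
#' @param j Symmetric Jaccard matrix with unit diagonal (e.g. from
#'   [jaccard_matrix()]).
#' @return An `hclust` object; merge heights are non-decreasing.
#' @export
peak_dendrogram <- function(j) {
  j <- as.matrix(j)
  if (nrow(j) != ncol(j) || !isTRUE(all.equal(j, t(j), tolerance = 1e-8)))
    stop("Jaccard matrix must be symmetric")
  stats::hclust(stats::dist(j, method = "euclidean"), method = "complete")
}

#' Write a dendrogram as a Newick string
#'
#' @param h An `hclust` object (e.g. from [peak_dendrogram()]).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
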