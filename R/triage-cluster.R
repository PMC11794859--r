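# TRIAGE-Cluster: repressive-tendency-weighted kernel density estimation on
# a 2-D embedding, density contour levelling, per-level spatial clustering,
# and leaf-peak identification in the resulting containment forest.
#
# The intent: rather than tuning a graph-clustering resolution, cell types
# are defined as local maxima ("peaks") of the RTS-weighted density over
# the embedding. The weighted density is split into ascending contour
# levels; the super-threshold cells at each level are spatially clustered;
# a peak is a cluster whose branch never splits at any higher level.

.check_embedding <- function(emb) {
  emb <- as.matrix(emb)
  if (ncol(emb) != 2L) stop("embedding must have exactly 2 columns")
  if (any(!is.finite(emb))) stop("embedding coordinates must be finite")
  if (is.null(rownames(emb))) rownames(emb) <- sprintf("cell%05d", seq_len(nrow(emb)))
  emb
}

#' Weighted Gaussian kernel density over a 2-D embedding
#'
#' Evaluates, at every cell position, the weighted sum of bivariate Gaussian
#' kernels centred on all cells. The kernel covariance is the (weighted)
#' sample covariance of the coordinates scaled by `bandwidth^2`, and the
#' weights are normalised to sum to one, so uniform weights reproduce the
#' unweighted estimate exactly.
#'
#' @param emb Cells x 2 coordinate matrix.
#' @param weights Per-cell non-negative weights, not all zero. Default
#'   uniform.
#' @param bandwidth Covariance scaling factor (default 0.25).
#' @return A `density_field` list: `density` (named per-cell values),
#'   `bandwidth`, and `kernel_cov` (the 2x2 kernel covariance used).
#' @export
weighted_kde <- function(emb, weights = NULL, bandwidth = 0.25) {
  emb <- .check_embedding(emb)
  n <- nrow(emb)
  if (n < 3L) stop("need at least 3 cells")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights >= 0))
  if (sum(weights) == 0) stop("all-zero weights")
  w <- weights / sum(weights)
  # maximum-likelihood (population) weighted covariance: keeps the density
  # exactly invariant under duplicating cells with split weights
  cov_est <- tryCatch(stats::cov.wt(emb, wt = w, method = "ML")$cov,
                      error = function(e) NULL)
  singular <- is.null(cov_est) || !all(is.finite(cov_est)) ||
    det(cov_est) <= .Machine$double.eps
  if (singular) {
    warning("singular coordinate covariance; falling back to diagonal")
    v <- apply(emb, 2L, stats::var)
    v[v <= 0 | !is.finite(v)] <- 1
    cov_est <- diag(v)
  }
  sigma <- cov_est * bandwidth^2
  sigma_inv <- solve(sigma)
  norm_const <- 1 / (2 * pi * sqrt(det(sigma)))
  # N(x_i; x_j, sigma) for all pairs via the Mahalanobis quadratic form
  q11 <- sigma_inv[1, 1]; q12 <- sigma_inv[1, 2]; q22 <- sigma_inv[2, 2]
  dx <- outer(emb[, 1], emb[, 1], "-")
  dy <- outer(emb[, 2], emb[, 2], "-")
  quad <- q11 * dx^2 + 2 * q12 * dx * dy + q22 * dy^2
  dens <- as.numeric(exp(-0.5 * quad) %*% w) * norm_const
  structure(list(density = stats::setNames(dens, rownames(emb)),
                 bandwidth = bandwidth, kernel_cov = sigma),
            class = "density_field")
}

#' Contour thresholds for a density field
#'
#' `n_levels` thresholds equally spaced strictly between the minimum and
#' maximum density (both endpoints excluded), mirroring default contour-plot
#' behaviour.
#'
#' @param d A `density_field` from [weighted_kde()], or a numeric vector of
#'   densities.
#' @param n_levels Number of thresholds (default 10).
#' @return Strictly increasing numeric vector of length `n_levels`.
#' @export
contour_levels <- function(d, n_levels = 10L) {
  dens <- if (inherits(d, "density_field")) d$density else d
  lo <- min(dens); hi <- max(dens)
  if (hi <= lo) stop("constant density field; no contour levels")
  lo + seq_len(n_levels) * (hi - lo) / (n_levels + 1)
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Core points have at least `min_samples` neighbours (themselves included)
#' within radius `eps`; clusters are the connected components of core
#' points plus any border points within `eps` of a core; remaining points
#' are noise (cluster 0).
#'
#' @param coords Points x 2 coordinate matrix.
#' @param eps Neighbourhood radius.
#' @param min_samples Minimum neighbourhood size (self-inclusive) for a
#'   core point.
#' @return Integer cluster labels (0 = noise), one per row of `coords`.
#' @export
dbscan_cluster <- function(coords, eps, min_samples = 5L) {
  stopifnot(eps > 0, min_samples >= 1L)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  labels <- integer(n)          # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      reach <- which(nbr[p, ])
      for (r2 in reach) {
        if (labels[r2] == 0L) {
          labels[r2] <- cl
          if (core[r2]) queue <- c(queue, r2)
        }
      }
    }
  }
  labels
}

#' Spatial clusters among super-threshold cells at one contour level
#'
#' @param emb Cells x 2 embedding.
#' @param d A `density_field` (or numeric densities) aligned with `emb`.
#' @param threshold Density threshold; only cells with density >= threshold
#'   are clustered.
#' @param eps,min_samples DBSCAN parameters.
#' @return Named list of cell-id vectors, one per cluster (noise cells are
#'   in no cluster); empty list when no cell passes the threshold.
#' @export
level_clusters <- function(emb, d, threshold, eps = 0.25, min_samples = 5L) {
  emb <- .check_embedding(emb)
  dens <- if (inherits(d, "density_field")) d$density else d
  stopifnot(length(dens) == nrow(emb))
  keep <- which(dens >= threshold)
  if (length(keep) == 0L) return(list())
  labels <- dbscan_cluster(emb[keep, , drop = FALSE], eps = eps,
                           min_samples = min_samples)
  ids <- rownames(emb)[keep]
  out <- split(ids, labels)
  out[names(out) != "0"]
}

#' Identify density peaks from per-level clusterings
#'
#' Builds a containment forest linking each cluster at level `l` to the
#' cluster at level `l - 1` holding the plurality of its cells. A peak is
#' the topmost cluster of a branch that never splits at any higher level
#' (a chain of the forest); its membership is the cell set at its birth
#' level. Peaks smaller than `min_peak_cells` are dropped.
#'
#' @param clusterings List (ascending threshold order) of per-level cluster
#'   lists as returned by [level_clusters()].
#' @param min_peak_cells Minimum member count for a surviving peak.
#' @param all_cells Optional character vector of the full cell universe,
#'   used to mark non-peak cells.
#' @return A `peak_assignment` list: `labels` (named per-cell peak id or
#'   `"NONE"`), and `peaks` (data frame: peak id, birth level, n_cells).
#' @export
find_peaks <- function(clusterings, min_peak_cells = 20L, all_cells = NULL) {
  n_levels <- length(clusterings)
  nodes <- list()   # each: level, index-in-level, cells, parent (node id or NA)
  node_id <- function(level, idx) sprintf("L%02d.%d", level, idx)
  for (lev in seq_len(n_levels)) {
    cls <- clusterings[[lev]]
    for (i in seq_along(cls)) {
      cells <- cls[[i]]
      parent <- NA_character_
      if (lev > 1L && length(clusterings[[lev - 1L]])) {
        overlaps <- vapply(clusterings[[lev - 1L]],
                           function(p) length(intersect(cells, p)), integer(1))
        if (max(overlaps) > 0L)
          parent <- node_id(lev - 1L, which.max(overlaps))
      }
      nodes[[node_id(lev, i)]] <- list(level = lev, cells = cells,
                                       parent = parent)
    }
  }
  if (length(nodes)) {
    children <- split(names(nodes),
                      vapply(nodes, function(n) ifelse(is.na(n$parent), "", n$parent), ""))
    n_children <- function(id) length(children[[id]])
    # a node is chain-like iff its subtree never has two children anywhere
    chain <- new.env()
    is_chain <- function(id) {
      if (!is.null(chain[[id]])) return(chain[[id]])
      kids <- children[[id]]
      res <- if (length(kids) == 0L) TRUE
      else if (length(kids) > 1L) FALSE
      else is_chain(kids[[1]])
      chain[[id]] <- res
      res
    }
    peak_nodes <- Filter(function(id) {
      if (!is_chain(id)) return(FALSE)
      par <- nodes[[id]]$parent
      is.na(par) || !is_chain(par)
    }, names(nodes))
  } else {
    peak_nodes <- character(0)
  }
  peak_cells <- lapply(peak_nodes, function(id) nodes[[id]]$cells)
  keep <- lengths(peak_cells) >= min_peak_cells
  peak_nodes <- peak_nodes[keep]
  peak_cells <- peak_cells[keep]
  ord <- order(vapply(peak_nodes, function(id) nodes[[id]]$level, integer(1)),
               -lengths(peak_cells))
  peak_nodes <- peak_nodes[ord]
  peak_cells <- peak_cells[ord]
  ids <- sprintf("peak_%02d", seq_along(peak_nodes))
  if (is.null(all_cells))
    all_cells <- unique(unlist(lapply(clusterings, unlist), use.names = FALSE))
  labels <- stats::setNames(rep("NONE", length(all_cells)), all_cells)
  for (i in seq_along(ids)) labels[peak_cells[[i]]] <- ids[i]
  peaks <- data.frame(
    peak = ids,
    birth_level = vapply(peak_nodes, function(id) nodes[[id]]$level, integer(1)),
    n_cells = lengths(peak_cells), row.names = NULL)
  structure(list(labels = labels, peaks = peaks), class = "peak_assignment")
}

#' End-to-end TRIAGE-Cluster
#'
#' Composes [cell_rts()], [weighted_kde()], [contour_levels()],
#' [level_clusters()] per level, and [find_peaks()].
#'
#' @param e Genes x cells expression matrix (cells must match `emb`).
#' @param r An [rts_table()].
#' @param emb Cells x 2 embedding with rownames matching `colnames(e)`.
#' @param bandwidth KDE covariance scaling factor (default 0.25).
#' @param n_levels Number of contour levels (default 10).
#' @param eps DBSCAN radius; defaults to `bandwidth` (same length scale as
#'   the smoothing).
#' @param min_samples DBSCAN core-point neighbourhood size (default 5).
#' @param min_peak_cells Minimum surviving peak size (default 20).
#' @param weights Optional per-cell weights overriding `cell_rts(e, r)`.
#' @return A `peak_assignment` with an extra `provenance` element recording
#'   all parameters.
#' @export
triage_cluster <- function(e, r, emb, bandwidth = 0.25, n_levels = 10L,
                           eps = bandwidth, min_samples = 5L,
                           min_peak_cells = 20L, weights = NULL) {
  emb <- .check_embedding(emb)
  if (is.null(weights)) {
    e <- .check_expression(e)
    if (!setequal(colnames(e), rownames(emb)))
      stop("expression and embedding cover different cells")
    e <- e[, rownames(emb), drop = FALSE]
    weights <- cell_rts(e, r)
  }
  field <- weighted_kde(emb, weights, bandwidth = bandwidth)
  levels <- contour_levels(field, n_levels = n_levels)
  clusterings <- lapply(levels, function(t)
    level_clusters(emb, field, t, eps = eps, min_samples = min_samples))
  pa <- find_peaks(clusterings, min_peak_cells = min_peak_cells,
                   all_cells = rownames(emb))
  pa$density <- field$density
  pa$levels <- levels
  pa$provenance <- list(bandwidth = bandwidth, n_levels = n_levels,
                        eps = eps, min_samples = min_samples,
                        min_peak_cells = min_peak_cells)
  pa
}
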