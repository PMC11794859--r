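# Demultiplexing of cell x barcode count matrices.
#
# Two rules are provided. `max_count_assign` is the simple pilot rule: the
# barcode with the highest count names the sample, all-zero cells are
# Negative and tied maxima are Doublets. `quantile_threshold_demux` is a
# fully specified quantile-cutoff method in the style of hashing
# demultiplexers: counts are CLR-transformed, cells grouped by k-medoids,
# and a negative-binomial background per barcode sets a positivity
# threshold at its q-quantile.

LABEL_NEGATIVE <- "Negative"
LABEL_DOUBLET <- "Doublet"

.check_count_matrix <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty count matrix")
  if (is.null(rownames(m))) rownames(m) <- sprintf("cell%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("BC%02d", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(m))) stop("duplicate barcode ids")
  if (any(!is.finite(m)) || any(m < 0)) stop("counts must be finite and >= 0")
  m
}

#' Assign samples by the maximum-count rule
#'
#' Per cell: an all-zero row is `Negative`; a unique argmax names the
#' sample; a maximum shared by two or more barcodes is a `Doublet`.
#'
#' @param m Cells x barcodes non-negative count matrix (cells in rows).
#' @return Named character vector of per-cell labels (barcode id,
#'   `"Negative"` or `"Doublet"`).
#' @export
max_count_assign <- function(m) {
  m <- .check_count_matrix(m)
  labels <- apply(m, 1L, function(row) {
    top <- max(row)
    if (top == 0) return(LABEL_NEGATIVE)
    hits <- which(row == top)
    if (length(hits) > 1L) LABEL_DOUBLET else colnames(m)[hits]
  })
  stats::setNames(as.character(labels), rownames(m))
}

# Centred log-ratio transform per barcode column, pseudocount 1.
.clr_by_barcode <- function(m) {
  lg <- log1p(m)
  sweep(lg, 2L, colMeans(lg), "-")
}

#' Quantile-threshold demultiplexing
#'
#' CLR-normalises counts per barcode, partitions cells into
#' `n_barcodes + 1` groups by k-medoids clustering of the CLR matrix, and
#' for each barcode fits a negative-binomial background (method of moments;
#' Poisson fallback when variance <= mean) to the raw counts of the group
#' with the lowest mean for that barcode. A cell is positive for a barcode
#' when its raw count strictly exceeds the background `q`-quantile. Zero
#' positives gives `Negative`, one the barcode id, two or more `Doublet`.
#'
#' @param m Cells x barcodes count matrix; needs at least 2 barcodes and
#'   `2 * n_barcodes` cells.
#' @param q Background quantile cutoff (default 0.99).
#' @param seed Seed controlling the k-medoids sampling.
#' @return Named character vector of labels with attribute `thresholds`
#'   (per-barcode positivity cutoffs).
#' @export
quantile_threshold_demux <- function(m, q = 0.99, seed = 1L) {
  m <- .check_count_matrix(m)
  n_bc <- ncol(m)
  if (n_bc < 2L) stop("need at least 2 barcodes")
  if (nrow(m) < 2L * n_bc) stop("need at least 2 * n_barcodes cells")
  stopifnot(q >= 0, q <= 1)
  clr <- .clr_by_barcode(m)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  k <- n_bc + 1L
  groups <- cluster::clara(clr, k = k, samples = 10,
                           pamLike = TRUE)$clustering
  thresholds <- numeric(n_bc)
  for (b in seq_len(n_bc)) {
    grp_means <- tapply(m[, b], groups, mean)
    bg_group <- as.integer(names(grp_means)[which.min(grp_means)])
    bg <- m[groups == bg_group, b]
    mu <- mean(bg)
    v <- stats::var(bg)
    if (mu == 0) {
      warning(sprintf("all-zero background for barcode %s; threshold 0",
                      colnames(m)[b]))
      thresholds[b] <- 0
    } else if (is.na(v) || v <= mu) {
      thresholds[b] <- stats::qpois(q, lambda = mu)
    } else {
      size <- mu^2 / (v - mu)
      thresholds[b] <- stats::qnbinom(q, size = size, mu = mu)
    }
  }
  names(thresholds) <- colnames(m)
  pos <- sweep(m, 2L, thresholds, ">")
  n_pos <- rowSums(pos)
  labels <- character(nrow(m))
  labels[n_pos == 0L] <- LABEL_NEGATIVE
  labels[n_pos >= 2L] <- LABEL_DOUBLET
  single <- which(n_pos == 1L)
  labels[single] <- colnames(m)[apply(pos[single, , drop = FALSE], 1L, which)]
  labels <- stats::setNames(labels, rownames(m))
  attr(labels, "thresholds") <- thresholds
  labels
}

#' Agreement between two demultiplexing label vectors
#'
#' The sum of double positives (both methods assign the same sample label)
#' and double negatives (both `Negative`), divided by the total number of
#' cells. Doublet calls never count toward agreement.
#'
#' @param a,b Named per-cell label vectors over the same cells.
#' @return Fraction in `[0, 1]`.
#' @export
agreement <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || length(a) != length(b))
    stop("label vectors must cover the same cells")
  b <- b[names(a)]
  both_neg <- a == LABEL_NEGATIVE & b == LABEL_NEGATIVE
  sample_label <- !(a %in% c(LABEL_NEGATIVE, LABEL_DOUBLET)) &
    !(b %in% c(LABEL_NEGATIVE, LABEL_DOUBLET))
  both_pos <- sample_label & a == b
  (sum(both_pos) + sum(both_neg)) / length(a)
}

#' Quality-control thresholds for per-cell metrics
#'
#' All bounds are optional and inclusive at both ends ("between X and Y"
#' is read as a closed interval).
#'
#' @param min_counts,max_counts Library-size bounds (reads).
#' @param min_genes,max_genes Detected-feature bounds.
#' @param max_mito_frac Maximum mitochondrial read fraction.
#' @param min_ribo_frac,max_ribo_frac Ribosomal read fraction bounds.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_counts = NULL, max_counts = NULL,
                          min_genes = NULL, max_genes = NULL,
                          max_mito_frac = NULL,
                          min_ribo_frac = NULL, max_ribo_frac = NULL) {
  t <- list(min_counts = min_counts, max_counts = max_counts,
            min_genes = min_genes, max_genes = max_genes,
            max_mito_frac = max_mito_frac,
            min_ribo_frac = min_ribo_frac, max_ribo_frac = max_ribo_frac)
  pairs <- list(c("min_counts", "max_counts"), c("min_genes", "max_genes"),
                c("min_ribo_frac", "max_ribo_frac"))
  for (p in pairs) {
    if (!is.null(t[[p[1]]]) && !is.null(t[[p[2]]]) && t[[p[1]]] > t[[p[2]]])
      stop(sprintf("%s exceeds %s", p[1], p[2]))
  }
  for (f in c("max_mito_frac", "min_ribo_frac", "max_ribo_frac")) {
    if (!is.null(t[[f]]) && (t[[f]] < 0 || t[[f]] > 1))
      stop(f, " must lie in [0, 1]")
  }
  structure(t, class = "qc_thresholds")
}

# metric column and direction for each active bound
.qc_rules <- data.frame(
  bound = c("min_counts", "max_counts", "min_genes", "max_genes",
            "max_mito_frac", "min_ribo_frac", "max_ribo_frac"),
  column = c("n_counts", "n_counts", "n_genes", "n_genes",
             "mito_frac", "ribo_frac", "ribo_frac"),
  dir = c("min", "max", "min", "max", "max", "min", "max"),
  code = c("COUNTS_LOW", "COUNTS_HIGH", "GENES_LOW", "GENES_HIGH",
           "MITO", "RIBO_LOW", "RIBO_HIGH"),
  stringsAsFactors = FALSE)

#' Apply transcriptome quality-control filters
#'
#' A cell is kept iff it satisfies every active bound; rejection codes
#' enumerate all violated bounds.
#'
#' @param metrics Data frame with a `cell_id` column plus whichever of
#'   `n_counts`, `n_genes`, `mito_frac`, `ribo_frac` the active bounds
#'   reference.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `kept` (cell ids) and `rejections` (named list of
#'   violation-code vectors for rejected cells).
#' @export
apply_qc_filters <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"), "cell_id" %in% names(metrics))
  active <- .qc_rules[!vapply(thresholds[.qc_rules$bound], is.null, TRUE), ,
                      drop = FALSE]
  missing_cols <- setdiff(unique(active$column), names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks columns needed by active bounds: ",
         paste(missing_cols, collapse = ", "))
  codes <- rep(list(character(0)), nrow(metrics))
  for (i in seq_len(nrow(active))) {
    x <- metrics[[active$column[i]]]
    lim <- thresholds[[active$bound[i]]]
    bad <- if (active$dir[i] == "min") x < lim else x > lim
    for (j in which(bad)) codes[[j]] <- c(codes[[j]], active$code[i])
  }
  names(codes) <- metrics$cell_id
  kept <- metrics$cell_id[lengths(codes) == 0L]
  list(kept = kept, rejections = codes[lengths(codes) > 0L])
}
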