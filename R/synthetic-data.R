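# Synthetic-data generators emulating every input the pipeline needs:
# barcode count matrices with known sample of origin, multi-type expression
# with planted embedding blobs and high-RTS markers, and block-structured
# epigenetic breadth matrices with planted gene modules. Each generator is
# bit-reproducible under a fixed seed and returns the ground truth beside
# the data.
#
# Count emission uses Poisson draws for barcode reads and negative-binomial
# draws for expression; simple noise models sufficient for recovery tests,
# not a claim about real data.

#' Simulate a cell x barcode count matrix with known truth
#'
#' Singlet cells draw `Poisson(signal_mean)` on their true barcode and
#' `Poisson(ambient_mean)` on every other; doublets carry signal on two
#' distinct barcodes; negatives carry ambient counts only.
#'
#' @param n_cells Number of cells.
#' @param barcode_ids Barcode labels; default a panel of 8 hashtag-style
#'   tags mirroring an 8-sample hashing design.
#' @param signal_mean Mean on-target count (default 200).
#' @param ambient_mean Mean off-target/background count (default 2).
#' @param doublet_rate,negative_rate Class fractions; must sum to <= 1.
#' @param seed Integer seed.
#' @return List with `counts` (cells x barcodes), `truth` (data frame:
#'   cell_id, class, barcode, barcode2) and `params`.
#' @export
simulate_barcode_counts <- function(n_cells = 2000L,
                                    barcode_ids = sprintf("HTO%02d", 1:8),
                                    signal_mean = 200, ambient_mean = 2,
                                    doublet_rate = 0.05,
                                    negative_rate = 0.02, seed = 1L) {
  stopifnot(doublet_rate >= 0, negative_rate >= 0,
            doublet_rate + negative_rate <= 1)
  n_bc <- length(barcode_ids)
  if (n_bc < 2L && doublet_rate > 0)
    stop("doublets need at least 2 barcodes")
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  cls <- sample(c("singlet", "doublet", "negative"), n_cells, replace = TRUE,
                prob = c(1 - doublet_rate - negative_rate, doublet_rate,
                         negative_rate))
  counts <- matrix(stats::rpois(n_cells * n_bc, ambient_mean),
                   nrow = n_cells, ncol = n_bc,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                   barcode_ids))
  bc1 <- rep(NA_character_, n_cells)
  bc2 <- rep(NA_character_, n_cells)
  for (i in seq_len(n_cells)) {
    if (cls[i] == "negative") next
    picks <- sample(n_bc, if (cls[i] == "doublet") 2L else 1L)
    counts[i, picks] <- counts[i, picks] + stats::rpois(length(picks),
                                                        signal_mean)
    bc1[i] <- barcode_ids[picks[1]]
    if (length(picks) > 1L) bc2[i] <- barcode_ids[picks[2]]
  }
  list(counts = counts,
       truth = data.frame(cell_id = rownames(counts), class = cls,
                          barcode = bc1, barcode2 = bc2,
                          stringsAsFactors = FALSE),
       params = list(n_cells = n_cells, barcode_ids = barcode_ids,
                     signal_mean = signal_mean, ambient_mean = ambient_mean,
                     doublet_rate = doublet_rate,
                     negative_rate = negative_rate, seed = seed))
}

# negative-binomial draw parameterised by mean and dispersion (size)
.rnbinom_mean <- function(n, mu, size) {
  if (mu <= 0) return(integer(n))
  stats::rnbinom(n, size = size, mu = mu)
}

#' Simulate typed expression with a planted 2-D embedding and RTS table
#'
#' Each cell type gets `cells_per_type` cells placed as an isotropic
#' Gaussian blob around its centre, `markers_per_type` marker genes with
#' high mean expression in that type and low elsewhere, and an RTS table
#' assigning `marker_rts` to markers and `background_rts` to all other
#' genes.
#'
#' @param n_types Number of planted cell types.
#' @param cells_per_type Cells per type.
#' @param n_genes Total genes (must hold all markers).
#' @param markers_per_type Markers per type.
#' @param blob_centres Optional n_types x 2 matrix; default equally spaced
#'   on a circle of radius `6 * blob_sd * n_types / (2 * pi)` scaled so
#'   centres sit at least `10 * blob_sd` apart.
#' @param blob_sd Blob standard deviation in embedding units.
#' @param marker_rts,background_rts RTS values for marker / other genes.
#' @param marker_mean,ambient_mean,background_mean Negative-binomial means
#'   for markers in their own type, markers elsewhere, and non-marker
#'   genes.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List with `expression` (genes x cells), `embedding`
#'   (cells x 2), `rts` ([rts_table()]), `truth` (cell_id, type) and
#'   `params`.
#' @export
simulate_typed_expression <- function(n_types = 3L, cells_per_type = 300L,
                                      n_genes = 200L, markers_per_type = 5L,
                                      blob_centres = NULL, blob_sd = 0.5,
                                      marker_rts = 1.0, background_rts = 0.1,
                                      marker_mean = 20, ambient_mean = 0.2,
                                      background_mean = 1, dispersion = 2,
                                      seed = 1L) {
  stopifnot(n_types * markers_per_type <= n_genes)
  if (is.null(blob_centres)) {
    # centres on a circle whose chord between neighbours is 10 * blob_sd
    radius <- (10 * blob_sd) / (2 * sin(pi / max(n_types, 2)))
    ang <- 2 * pi * (seq_len(n_types) - 1) / n_types
    blob_centres <- cbind(radius * cos(ang), radius * sin(ang))
  }
  blob_centres <- as.matrix(blob_centres)
  stopifnot(nrow(blob_centres) == n_types, ncol(blob_centres) == 2L)
  if (n_types >= 2L) {
    dc <- as.matrix(stats::dist(blob_centres))
    if (min(dc[upper.tri(dc)]) < 2 * blob_sd)
      warning("blob centres closer than 2 * blob_sd; peaks may merge")
  }
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  n_cells <- n_types * cells_per_type
  type <- rep(seq_len(n_types), each = cells_per_type)
  emb <- blob_centres[type, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * 2, sd = blob_sd), ncol = 2)
  rownames(emb) <- sprintf("cell%05d", seq_len(n_cells))
  colnames(emb) <- c("dim1", "dim2")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  marker_idx <- matrix(seq_len(n_types * markers_per_type),
                       nrow = n_types, byrow = TRUE)
  expr <- matrix(0, nrow = n_genes, ncol = n_cells,
                 dimnames = list(genes, rownames(emb)))
  for (g in seq_len(n_genes)) {
    owner <- which(apply(marker_idx, 1L, function(ix) g %in% ix))
    mu <- if (length(owner)) ifelse(type == owner, marker_mean, ambient_mean)
          else rep(background_mean, n_cells)
    expr[g, ] <- stats::rnbinom(n_cells, size = dispersion, mu = mu)
  }
  rts <- rep(background_rts, n_genes)
  rts[seq_len(n_types * markers_per_type)] <- marker_rts
  names(rts) <- genes
  list(expression = expr, embedding = emb, rts = rts_table(rts),
       truth = data.frame(cell_id = rownames(emb),
                          type = sprintf("type%02d", type),
                          stringsAsFactors = FALSE),
       params = list(n_types = n_types, cells_per_type = cells_per_type,
                     n_genes = n_genes, markers_per_type = markers_per_type,
                     blob_centres = blob_centres, blob_sd = blob_sd,
                     marker_rts = marker_rts, background_rts = background_rts,
                     marker_mean = marker_mean, ambient_mean = ambient_mean,
                     background_mean = background_mean,
                     dispersion = dispersion, seed = seed))
}

#' Simulate a block-structured epigenetic breadth matrix
#'
#' Each of `n_modules` modules gets a prototype row drawn with spread
#' `between_sd` around a common baseline over the cell types; member genes
#' are the prototype plus `Gaussian(0, within_sd^2)` noise, floored at 0 so
#' values remain valid breadths.
#'
#' @param n_modules Number of planted gene modules.
#' @param genes_per_module Genes per module.
#' @param n_celltypes Number of cell-type columns.
#' @param within_sd Within-module noise standard deviation.
#' @param between_sd Between-module prototype spread; must exceed
#'   `within_sd`.
#' @param baseline Baseline breadth added to every prototype (default 10).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x cell types), `truth` (gene, module)
#'   and `params`.
#' @export
simulate_epigenetic_matrix <- function(n_modules = 3L, genes_per_module = 40L,
                                       n_celltypes = 10L, within_sd = 0.5,
                                       between_sd = 3, baseline = 10,
                                       seed = 1L) {
  stopifnot(between_sd > within_sd)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  protos <- matrix(stats::rnorm(n_modules * n_celltypes, mean = baseline,
                                sd = between_sd),
                   nrow = n_modules)
  n_genes <- n_modules * genes_per_module
  module <- rep(seq_len(n_modules), each = genes_per_module)
  m <- protos[module, , drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_celltypes, sd = within_sd),
           nrow = n_genes)
  m <- pmax(m, 0)
  rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(m) <- sprintf("celltype%02d", seq_len(n_celltypes))
  list(matrix = m,
       truth = data.frame(gene = rownames(m),
                          module = sprintf("module%02d", module),
                          stringsAsFactors = FALSE),
       params = list(n_modules = n_modules,
                     genes_per_module = genes_per_module,
                     n_celltypes = n_celltypes, within_sd = within_sd,
                     between_sd = between_sd, baseline = baseline,
                     seed = seed))
}
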