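# Gene-program parsing over an epigenetic reference basis.
#
# A gene list (typically the top discordance-score genes of a cell peak) is
# projected onto the principal components of a gene x cell-type
# repressive-mark (H3K27me3) breadth matrix; each component represents a
# recurring deposition pattern. The projected scores are clustered with a
# Gaussian mixture model whose component count is chosen by BIC; programs
# are kept only when their members share significantly many
# protein-protein-interaction edges, and kept programs are annotated by
# hypergeometric term enrichment with Benjamini-Hochberg control.

#' Fit a principal-component basis on an epigenetic breadth matrix
#'
#' PCA on the gene rows (cell types as features), mean-centred per feature.
#' The retained component count is either fixed (`n_components`) or the
#' smallest number whose cumulative explained variance reaches `cum_var`.
#'
#' @param m Genes x cell-types matrix of repressive-mark breadth values.
#' @param cum_var Cumulative explained-variance target in `(0, 1]`
#'   (default 0.96); ignored when `n_components` is given.
#' @param n_components Optional fixed component count.
#' @return An `epigenetic_basis` list: `loadings` (cell types x all
#'   components), `center`, `var_fraction`, `n_selected`.
#' @export
fit_basis <- function(m, cum_var = 0.96, n_components = NULL) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 cell types")
  if (is.null(rownames(m))) stop("epigenetic matrix needs gene rownames")
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  vf <- pca$sdev^2 / sum(pca$sdev^2)
  if (is.null(n_components)) {
    if (cum_var <= 0 || cum_var > 1) stop("cum_var must lie in (0, 1]")
    n_selected <- which(cumsum(vf) >= cum_var - 1e-12)[1]
    if (is.na(n_selected)) n_selected <- length(vf)
  } else {
    n_selected <- as.integer(n_components)
    stopifnot(n_selected >= 1L, n_selected <= ncol(pca$rotation))
  }
  structure(list(loadings = pca$rotation, center = pca$center,
                 var_fraction = vf, n_selected = n_selected),
            class = "epigenetic_basis")
}

#' Project genes onto an epigenetic basis
#'
#' @param genes Gene ids to project; ids absent from `m` are dropped with a
#'   warning.
#' @param m The epigenetic matrix the basis was fitted on (or one with the
#'   same cell-type columns).
#' @param b An `epigenetic_basis` from [fit_basis()].
#' @return Genes x selected-components score matrix.
#' @export
project_genes <- function(genes, m, b) {
  stopifnot(inherits(b, "epigenetic_basis"))
  m <- as.matrix(m)
  found <- genes %in% rownames(m)
  if (!any(found)) stop("no input gene found in the epigenetic matrix")
  if (!all(found))
    warning(sum(!found), " gene(s) absent from the epigenetic matrix; dropped")
  rows <- m[genes[found], , drop = FALSE]
  centred <- sweep(rows, 2L, b$center, "-")
  centred %*% b$loadings[, seq_len(b$n_selected), drop = FALSE]
}

#' Cluster projected gene scores with a Gaussian mixture, selecting k by BIC
#'
#' Fits full-covariance Gaussian mixtures for every `k` in `k_range`
#' (falling back to a diagonal-covariance model when the full model is not
#' estimable) and picks the `k` minimising BIC. Genes are hard-assigned by
#' maximum posterior.
#'
#' @param scores Genes x components score matrix (e.g. [project_genes()]).
#' @param k_range Candidate component counts (default `1:10`).
#' @param seed Seed for reproducibility of the fit.
#' @return List with `assignment` (named integer cluster per gene),
#'   `k` (chosen component count), `bic` (named trace, lower is better),
#'   `posterior` (genes x k matrix), `model` (mclust model name).
#' @export
gmm_bic_cluster <- function(scores, k_range = 1:10, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < max(k_range))
    stop("fewer genes than the largest candidate k")
  genes <- rownames(scores)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(n))
  # degenerate input: no variance anywhere -> a single component
  if (all(apply(scores, 2L, stats::var) < .Machine$double.eps)) {
    bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
    bic[as.character(1L)] <- 0
    return(list(assignment = stats::setNames(rep(1L, n), genes), k = 1L,
                bic = bic, posterior = matrix(1, n, 1), model = "degenerate"))
  }
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  models <- if (ncol(scores) == 1L) c("V", "E") else c("VVV", "VVI", "VII", "EII")
  grid <- mclust::mclustBIC(scores, G = k_range, modelNames = models,
                            verbose = FALSE)
  # per k, the best estimable covariance structure; BIC is then comparable
  # across k (mclust convention: larger is better)
  per_k <- vapply(as.character(k_range), function(kk) {
    row <- grid[kk, ]
    if (all(!is.finite(row))) return(c(NA_real_, NA_real_))
    best <- which.max(replace(row, !is.finite(row), -Inf))
    c(row[best], best)
  }, numeric(2))
  mclust_bic <- per_k[1, ]
  if (all(!is.finite(mclust_bic))) stop("no GMM fit succeeded for any k")
  best_idx <- which.max(mclust_bic)
  k <- k_range[best_idx]
  model <- models[per_k[2, best_idx]]
  # Mclust() resolves mclustBIC in the caller's frame; bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(scores, G = k, modelNames = model, verbose = FALSE)
  post <- fit$z
  if (is.null(post)) post <- matrix(1, n, 1)
  assignment <- apply(post, 1L, which.max)
  list(assignment = stats::setNames(as.integer(assignment), genes),
       k = k,
       bic = stats::setNames(-mclust_bic, k_range),
       posterior = post, model = model)
}

# Upper-tail hypergeometric probability P(X >= obs), inclusive of the
# observed value. Population of size `total` with `successes` marked;
# `drawn` draws without replacement.
.hyper_upper <- function(obs, successes, total, drawn) {
  stats::phyper(obs - 1, successes, total - successes, drawn,
                lower.tail = FALSE)
}

#' Protein-protein-interaction filter for a gene program
#'
#' One-tailed (upper) hypergeometric test of the number of PPI edges
#' observed inside the program. The population is all unordered gene pairs
#' over the background; successes are background edges; draws are the
#' program's internal pairs.
#'
#' @param program Character vector of program genes (subset of background).
#' @param edges Two-column matrix or data frame of undirected edges within
#'   the background.
#' @param background Character vector of background genes.
#' @param alpha_ppi Significance cutoff (default 0.001).
#' @return List with `p`, `kept` (`p < alpha_ppi`), `n_edges_observed`,
#'   `n_pairs_drawn`.
#' @export
ppi_filter <- function(program, edges, background, alpha_ppi = 0.001) {
  background <- unique(background)
  program <- unique(program)
  if (!all(program %in% background))
    stop("program genes must be a subset of the background")
  if (length(program) < 2L)
    return(list(p = 1, kept = FALSE, n_edges_observed = 0L, n_pairs_drawn = 0L))
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  in_bg <- edges[, 1] %in% background & edges[, 2] %in% background &
    edges[, 1] != edges[, 2]
  edges <- edges[in_bg, , drop = FALSE]
  # canonical unordered form, deduplicated
  key <- ifelse(edges[, 1] < edges[, 2],
                paste(edges[, 1], edges[, 2]),
                paste(edges[, 2], edges[, 1]))
  key <- unique(key)
  n_bg_edges <- length(key)
  total_pairs <- choose(length(background), 2)
  drawn <- choose(length(program), 2)
  parts <- strsplit(key, " ", fixed = TRUE)
  inside <- vapply(parts, function(p) all(p %in% program), logical(1))
  obs <- sum(inside)
  p <- .hyper_upper(obs, n_bg_edges, total_pairs, drawn)
  list(p = p, kept = p < alpha_ppi,
       n_edges_observed = obs, n_pairs_drawn = drawn)
}

#' Hypergeometric term enrichment with BH correction
#'
#' Per term, the upper-tail hypergeometric probability of the observed
#' overlap between the program and the term's gene set (both intersected
#' with the background); p-values are Benjamini-Hochberg adjusted across
#' all tested terms and terms with `fdr < alpha_fdr` are flagged.
#'
#' @param program Character vector of program genes (subset of background).
#' @param terms Named list of term gene sets, or a two-column data frame
#'   (term, gene).
#' @param background Character vector of background genes.
#' @param alpha_fdr FDR cutoff (default 0.01).
#' @return Data frame: term, n_term, overlap, p, fdr, kept; one row per
#'   term, in the input term order.
#' @export
term_enrich <- function(program, terms, background, alpha_fdr = 0.01) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  program <- unique(program)
  if (!all(program %in% background))
    stop("program genes must be a subset of the background")
  if (is.data.frame(terms)) terms <- split(terms[[2]], terms[[1]])
  term_sets <- lapply(terms, function(g) intersect(unique(g), background))
  overlap <- vapply(term_sets, function(g) length(intersect(g, program)),
                    integer(1))
  n_term <- lengths(term_sets)
  p <- mapply(function(k, K) .hyper_upper(k, K, length(background),
                                          length(program)),
              overlap, n_term)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(term = names(term_sets), n_term = n_term, overlap = overlap,
             p = as.numeric(p), fdr = as.numeric(fdr),
             kept = fdr < alpha_fdr, row.names = NULL)
}

#' Parse a gene list into co-regulated programs
#'
#' End-to-end composition: project the genes onto an epigenetic basis,
#' cluster the scores with a BIC-selected Gaussian mixture, apply the PPI
#' edge filter per program, and annotate kept programs by term enrichment.
#'
#' @param genes Input gene list.
#' @param m Genes x cell-types epigenetic breadth matrix.
#' @param basis Optional pre-fitted basis; default [fit_basis()] on `m`.
#' @param edges Optional PPI edge list (two columns); when `NULL` the PPI
#'   filter is skipped and all programs are kept.
#' @param terms Optional term -> gene sets for enrichment.
#' @param background Background gene universe for the tests; default all
#'   rownames of `m`.
#' @param k_range,seed Passed to [gmm_bic_cluster()].
#' @param alpha_ppi,alpha_fdr Test cutoffs.
#' @return List with `programs` (list of gene vectors), `ppi` (per-program
#'   filter results), `kept` (logical), `enrichment` (per kept program),
#'   `gmm` (the [gmm_bic_cluster()] result).
#' @export
parse_gene_programs <- function(genes, m, basis = NULL, edges = NULL,
                                terms = NULL, background = NULL,
                                k_range = 1:10, seed = 1L,
                                alpha_ppi = 0.001, alpha_fdr = 0.01) {
  m <- as.matrix(m)
  if (is.null(basis)) basis <- fit_basis(m)
  if (is.null(background)) background <- rownames(m)
  scores <- project_genes(genes, m, basis)
  gmm <- gmm_bic_cluster(scores, k_range = k_range, seed = seed)
  programs <- split(names(gmm$assignment), gmm$assignment)
  names(programs) <- sprintf("program_%02d", as.integer(names(programs)))
  if (is.null(edges)) {
    ppi <- NULL
    kept <- rep(TRUE, length(programs))
  } else {
    ppi <- lapply(programs, ppi_filter, edges = edges,
                  background = background, alpha_ppi = alpha_ppi)
    kept <- vapply(ppi, `[[`, logical(1), "kept")
  }
  names(kept) <- names(programs)
  enrichment <- NULL
  if (!is.null(terms)) {
    enrichment <- lapply(programs[kept], term_enrich, terms = terms,
                         background = background, alpha_fdr = alpha_fdr)
  }
  list(programs = programs, ppi = ppi, kept = kept,
       enrichment = enrichment, gmm = gmm)
}
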