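# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and first-principles formulas only.

# Hamming distance by explicit position loop.
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

# Composition-filter scanner by explicit loops (no rle, no regex).
oracle_filter_scan <- function(seq, stop_codons = c("TAA", "TAG", "TGA"),
                               max_homopolymer = 3L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  codes <- character(0)
  if (paste0(ch[1:3], collapse = "") %in% stop_codons)
    codes <- c(codes, "START_STOP")
  if (paste0(ch[(n - 2):n], collapse = "") %in% stop_codons)
    codes <- c(codes, "END_STOP")
  run <- 1L
  homopolymer <- FALSE
  for (i in 2:n) {
    if (ch[i] == ch[i - 1]) run <- run + 1L else run <- 1L
    if (run > max_homopolymer) homopolymer <- TRUE
  }
  if (homopolymer) codes <- c(codes, "HOMOPOLYMER")
  codes
}

# Upper-tail hypergeometric P(X >= obs) by exhaustive enumeration of all
# C(total, drawn) draws from a population whose first `successes` items are
# marked. Feasible for total <= 15.
oracle_hyper_enum <- function(obs, successes, total, drawn) {
  if (drawn == 0) return(as.numeric(obs <= 0))
  draws <- utils::combn(total, drawn)
  hits <- colSums(draws <= successes)
  mean(hits >= obs)
}

# Weighted bivariate Gaussian KDE by explicit double loop, with the
# maximum-likelihood weighted covariance assembled from its definition.
oracle_weighted_kde <- function(emb, w) {
  w <- w / sum(w)
  mu <- c(sum(w * emb[, 1]), sum(w * emb[, 2]))
  S <- matrix(0, 2, 2)
  for (i in seq_len(nrow(emb))) {
    d <- emb[i, ] - mu
    S <- S + w[i] * (d %*% t(d))
  }
  sigma <- S * 0.25^2
  si <- solve(sigma)
  nc <- 1 / (2 * pi * sqrt(det(sigma)))
  dens <- numeric(nrow(emb))
  for (i in seq_len(nrow(emb))) {
    acc <- 0
    for (j in seq_len(nrow(emb))) {
      d <- emb[i, ] - emb[j, ]
      acc <- acc + w[j] * exp(-0.5 * as.numeric(t(d) %*% si %*% d))
    }
    dens[i] <- acc * nc
  }
  dens
}

# DBSCAN by breadth-first search from first principles.
oracle_dbscan <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  core <- sapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_samples)
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        for (q in which(d[p, ] <= eps)) {
          if (labels[q] == 0L) {
            labels[q] <- cl
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  labels
}

# Naive agglomerative complete-linkage: repeatedly merge the two clusters
# with the smallest maximum inter-point distance, recording merge heights.
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best) { best <- link; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Adjusted Rand index between two label vectors (via mclust, which is not
# on the code path of any clustering routine under test except the GMM).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Deterministic random DNA strings for property tests.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
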