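two_blob_embedding <- function(n_per = 60, gap = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  emb <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, gap, sd), rnorm(n_per, 0, sd)))
  rownames(emb) <- sprintf("c%03d", seq_len(2 * n_per))
  emb
}

test_that("weighted_kde matches the double-loop kernel-sum oracle", {
  set.seed(2)
  emb <- two_blob_embedding(25, seed = 2)
  w <- runif(nrow(emb))
  f <- weighted_kde(emb, w, bandwidth = 0.25)
  expect_equal(unname(f$density), oracle_weighted_kde(emb, w),
               tolerance = 1e-10)
  expect_true(all(f$density >= 0))
})

test_that("uniform weights reproduce the unweighted estimate exactly", {
  emb <- two_blob_embedding(40, seed = 3)
  f_w <- weighted_kde(emb, rep(0.7, nrow(emb)))
  f_u <- weighted_kde(emb)
  expect_lt(max(abs(f_w$density - f_u$density)), 1e-12)
})

test_that("density is invariant to duplicating all cells with halved weights", {
  emb <- two_blob_embedding(20, seed = 4)
  w <- runif(nrow(emb))
  f1 <- weighted_kde(emb, w)
  emb2 <- rbind(emb, emb)
  rownames(emb2) <- sprintf("c%03d", seq_len(nrow(emb2)))
  f2 <- weighted_kde(emb2, c(w, w) / 2)
  expect_equal(unname(f2$density[seq_len(nrow(emb))]), unname(f1$density),
               tolerance = 1e-12)
})

test_that("concentrating weight on one cluster raises its density above the other", {
  emb <- two_blob_embedding(25, seed = 5)
  w <- c(rep(1, 25), rep(0, 25))
  f <- weighted_kde(emb, w)
  expect_gt(min(f$density[1:25]), max(f$density[26:50]))
  expect_error(weighted_kde(emb, rep(0, 50)), "all-zero")
  expect_error(weighted_kde(emb[1:2, ]), "at least 3")
})

test_that("contour_levels spaces thresholds equally, excluding both endpoints", {
  expect_equal(contour_levels(c(0, 10), n_levels = 10), (1:10) * 10 / 11)
  expect_equal(contour_levels(c(2, 4), n_levels = 1), 3)
  set.seed(6)
  lv <- contour_levels(runif(100), n_levels = 10)
  expect_true(all(diff(lv) > 0))
  expect_error(contour_levels(rep(1, 5)), "constant")
})

test_that("dbscan_cluster agrees with a breadth-first-search oracle", {
  set.seed(9)
  for (rep in 1:5) {
    coords <- matrix(runif(80 * 2, 0, 4), ncol = 2)
    ours <- dbscan_cluster(coords, eps = 0.5, min_samples = 4)
    ref <- oracle_dbscan(coords, eps = 0.5, min_samples = 4)
    expect_identical(ours == 0, ref == 0)             # same noise set
    expect_equal(ari(ours[ours > 0], ref[ours > 0]), 1)  # same partition
  }
})

test_that("level_clusters separates blobs, respects thresholds, and chains connect", {
  emb <- two_blob_embedding(40, gap = 10, seed = 10)
  f <- weighted_kde(emb)
  cls <- level_clusters(emb, f, threshold = min(f$density), eps = 1,
                        min_samples = 4)
  expect_length(cls, 2L)
  expect_length(level_clusters(emb, f, threshold = max(f$density) * 1.01), 0L)
  # all cells within eps of a chain form one cluster
  chain <- cbind(seq(0, 5, by = 0.4), 0)
  rownames(chain) <- sprintf("p%02d", seq_len(nrow(chain)))
  cls_chain <- level_clusters(chain, rep(1, nrow(chain)), threshold = 0.5,
                              eps = 0.5, min_samples = 2)
  expect_length(cls_chain, 1L)
  expect_length(cls_chain[[1]], nrow(chain))
})

test_that("find_peaks returns one peak per planted blob with nested levels", {
  sim <- simulate_typed_expression(n_types = 2, cells_per_type = 150, seed = 11)
  f <- weighted_kde(sim$embedding, rep(1, nrow(sim$embedding)))
  lv <- contour_levels(f)
  clusterings <- lapply(lv, function(t)
    level_clusters(sim$embedding, f, t, eps = 0.25, min_samples = 5))
  # every clustered cell at a level sits above that level's threshold
  for (l in seq_along(lv)[-1]) {
    expect_true(all(vapply(clusterings[[l]], function(cl)
      sum(f$density[cl] >= lv[l]) == length(cl), logical(1))))
  }
  pa <- find_peaks(clusterings, min_peak_cells = 20,
                   all_cells = rownames(sim$embedding))
  expect_identical(nrow(pa$peaks), 2L)
  assigned <- pa$labels != "NONE"
  expect_equal(ari(pa$labels[assigned], sim$truth$type[assigned]), 1)
  # peaks are disjoint by construction of the labels vector; every peak's
  # cells exceed its birth-level threshold
  for (i in seq_len(nrow(pa$peaks))) {
    cells <- names(pa$labels)[pa$labels == pa$peaks$peak[i]]
    expect_true(all(f$density[cells] >= lv[pa$peaks$birth_level[i]]))
  }
})

test_that("a blob below the size filter yields no peak", {
  set.seed(13)
  emb <- cbind(rnorm(10, 0, 0.3), rnorm(10, 0, 0.3))
  rownames(emb) <- sprintf("c%02d", 1:10)
  f <- weighted_kde(emb)
  lv <- contour_levels(f)
  clusterings <- lapply(lv, function(t)
    level_clusters(emb, f, t, eps = 0.5, min_samples = 3))
  pa <- find_peaks(clusterings, min_peak_cells = 20, all_cells = rownames(emb))
  expect_identical(nrow(pa$peaks), 0L)
  expect_true(all(pa$labels == "NONE"))
})

test_that("triage_cluster recovers planted types end-to-end and is order-invariant", {
  sim <- simulate_typed_expression(n_types = 3, cells_per_type = 200, seed = 14)
  pa <- triage_cluster(sim$expression, sim$rts, sim$embedding)
  expect_identical(nrow(pa$peaks), 3L)
  assigned <- pa$labels != "NONE"
  truth <- setNames(sim$truth$type, sim$truth$cell_id)
  expect_gte(ari(pa$labels[assigned], truth[names(pa$labels)[assigned]]), 0.95)
  # permuting cell order leaves the partition unchanged (up to relabelling)
  perm <- sample(ncol(sim$expression))
  pa2 <- triage_cluster(sim$expression[, perm], sim$rts,
                        sim$embedding[perm, ])
  common <- names(pa$labels)
  expect_equal(ari(pa$labels[common], pa2$labels[common]), 1)
  expect_identical(sort(unname(table(pa$labels))), sort(unname(table(pa2$labels))))
})

test_that("uniform RTS reduces the pipeline to spatial density peaks", {
  sim <- simulate_typed_expression(n_types = 2, cells_per_type = 150,
                                   marker_rts = 0.5, background_rts = 0.5,
                                   seed = 15)
  pa_rts <- triage_cluster(sim$expression, sim$rts, sim$embedding)
  pa_unif <- triage_cluster(NULL, NULL, sim$embedding,
                            weights = rep(1, nrow(sim$embedding)))
  expect_identical(pa_rts$peaks$n_cells, pa_unif$peaks$n_cells)
  expect_equal(ari(pa_rts$labels, pa_unif$labels), 1)
})

test_that("doubling the bandwidth never increases the peak count on two blobs", {
  for (seed in c(21, 22, 23)) {
    emb <- two_blob_embedding(80, gap = 6, seed = seed)
    n_peaks <- vapply(c(0.25, 0.5), function(bw) {
      pa <- triage_cluster(NULL, NULL, emb, bandwidth = bw, eps = 0.5,
                           min_peak_cells = 10,
                           weights = rep(1, nrow(emb)))
      nrow(pa$peaks)
    }, integer(1))
    expect_lte(n_peaks[2], n_peaks[1])
  }
})
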