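test_that("fit_basis selects components by cumulative variance or fixed count", {
  set.seed(3)
  # rank-2 matrix: two orthogonal patterns mixed across 30 genes
  u <- matrix(rnorm(30 * 2), ncol = 2)
  v <- matrix(rnorm(2 * 6), nrow = 2)
  m <- u %*% v
  rownames(m) <- sprintf("g%02d", 1:30)
  colnames(m) <- sprintf("ct%d", 1:6)
  b <- fit_basis(m, cum_var = 0.99)
  expect_identical(b$n_selected, 2L)
  expect_true(all(diff(b$var_fraction) <= 1e-12))
  expect_gte(sum(b$var_fraction[seq_len(b$n_selected)]), 0.99 - 1e-9)
  b1 <- fit_basis(m, n_components = 1)
  expect_identical(b1$n_selected, 1L)
  # full reconstruction reproduces the centred matrix
  centred <- sweep(m, 2, b$center, "-")
  scores_full <- centred %*% b$loadings
  expect_equal(scores_full %*% t(b$loadings), centred, tolerance = 1e-8)
  expect_error(fit_basis(m, cum_var = 0), "cum_var")
  expect_error(fit_basis(m[, 1, drop = FALSE]), "2 cell types")
})

test_that("project_genes matches the explicit loading product and handles misses", {
  sim <- simulate_epigenetic_matrix(n_modules = 2, genes_per_module = 10,
                                    n_celltypes = 5, seed = 4)
  b <- fit_basis(sim$matrix, cum_var = 0.9)
  genes <- rownames(sim$matrix)[1:5]
  sc <- project_genes(genes, sim$matrix, b)
  for (g in genes) {
    manual <- as.numeric((sim$matrix[g, ] - b$center) %*%
                         b$loadings[, seq_len(b$n_selected), drop = FALSE])
    expect_equal(unname(sc[g, ]), manual, tolerance = 1e-10)
  }
  # a gene equal to the feature means projects to the origin
  m2 <- rbind(sim$matrix, meanrow = colMeans(sim$matrix))
  b2 <- fit_basis(m2[-nrow(m2), ], cum_var = 0.9)
  b2$center <- colMeans(m2[-nrow(m2), ])
  sc0 <- project_genes("meanrow", m2, b2)
  expect_equal(unname(sc0[1, ]), rep(0, b2$n_selected), tolerance = 1e-8)
  expect_warning(project_genes(c(genes, "nope"), sim$matrix, b), "absent")
  expect_error(project_genes(c("no1", "no2"), sim$matrix, b), "no input gene")
})

test_that("gmm_bic_cluster recovers planted score clouds and degenerates sanely", {
  set.seed(5)
  centres <- rbind(c(0, 0), c(12, 0), c(0, 12))
  scores <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 2), ncol = 2), 2, centres[k, ], "+")))
  rownames(scores) <- sprintf("g%03d", 1:120)
  fit <- gmm_bic_cluster(scores, seed = 5)
  expect_identical(fit$k, 3L)
  expect_equal(ari(fit$assignment, rep(1:3, each = 40)), 1)
  expect_length(fit$bic, 10L)
  expect_identical(unname(which.min(fit$bic)), 3L)
  # identical rows collapse to a single component
  same <- matrix(1, nrow = 15, ncol = 2,
                 dimnames = list(sprintf("g%02d", 1:15), NULL))
  fit1 <- gmm_bic_cluster(same)
  expect_identical(fit1$k, 1L)
  expect_error(gmm_bic_cluster(scores[1:5, ], k_range = 1:10), "fewer genes")
})

test_that("gmm means are recovered within half a cluster sd at 6-sigma separation", {
  for (seed in 1:5) {
    set.seed(seed)
    centres <- rbind(c(0, 0), c(6, 0), c(3, 6 * sqrt(3) / 2))
    scores <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(30 * 2, sd = 1), ncol = 2), 2, centres[k, ], "+")))
    fit <- gmm_bic_cluster(scores, seed = seed)
    expect_identical(fit$k, 3L)
    grp_means <- t(sapply(split(seq_len(90), fit$assignment), function(ix)
      colMeans(scores[ix, , drop = FALSE])))
    err <- apply(centres, 1, function(ct)
      min(sqrt(rowSums(sweep(grp_means, 2, ct, "-")^2))))
    expect_true(all(err < 0.5))
  }
})

test_that("hypergeometric tails match exhaustive enumeration on small populations", {
  # term enrichment: every (N, K, n, k) over a grid with N <= 15
  for (N in c(8, 12, 15)) {
    bg <- sprintf("g%02d", seq_len(N))
    for (K in c(2, 5)) {
      for (n in c(3, 6)) {
        term <- bg[seq_len(K)]
        prog <- bg[seq_len(n)]
        res <- term_enrich(prog, list(t = term), bg)
        k_obs <- length(intersect(term, prog))
        expect_equal(res$p, oracle_hyper_enum(k_obs, K, N, n),
                     tolerance = 1e-10,
                     label = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("ppi_filter tests edge counts against the pair-sampling frame", {
  bg <- sprintf("g%02d", 1:12)
  prog <- bg[1:4]
  edges <- t(combn(prog, 2))                       # all 6 program pairs
  res <- ppi_filter(prog, edges, bg)
  # oracle over the pair population: C(12,2)=66 pairs, 6 successes, 6 drawn
  expect_equal(res$p, oracle_hyper_enum(6, 6, 66, 6) , tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  expect_true(res$kept)
  # zero observed edges -> inclusive upper tail is 1
  far_edges <- rbind(c("g09", "g10"), c("g11", "g12"))
  res0 <- ppi_filter(prog, far_edges, bg)
  expect_equal(res0$p, 1)
  expect_false(res0$kept)
  # duplicate and reversed edges are counted once
  dup <- rbind(edges, edges[, 2:1])
  expect_equal(ppi_filter(prog, dup, bg)$p, res$p)
  # degenerate program
  expect_equal(ppi_filter(bg[1], edges, bg)$p, 1)
  expect_error(ppi_filter(c("zz", bg[1]), edges, bg), "subset")
})

test_that("term enrichment applies BH within the tested term set", {
  bg <- sprintf("g%02d", 1:15)
  prog <- bg[1:5]
  terms <- list(hit = bg[1:5], part = bg[4:9], miss = bg[10:15])
  res <- term_enrich(prog, terms, bg)
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_equal(res$p[res$term == "miss"], 1)
  # permutation invariance of the kept set
  res_perm <- term_enrich(prog, terms[c(3, 1, 2)], bg)
  expect_setequal(res$term[res$kept], res_perm$term[res_perm$kept])
  # a single tested term gets fdr == p
  res1 <- term_enrich(prog, terms["hit"], bg)
  expect_equal(res1$fdr, res1$p)
  expect_error(term_enrich(prog, terms, character(0)), "empty background")
})

test_that("parse_gene_programs composes projection, GMM, PPI filter and enrichment", {
  sim <- simulate_epigenetic_matrix(seed = 6)
  genes <- rownames(sim$matrix)
  modules <- split(genes, sim$truth$module)
  # PPI edges densely connect module 1, sparsely elsewhere
  edges <- t(combn(modules[[1]], 2))
  terms <- list(mod1 = modules[[1]], mod2 = modules[[2]])
  res <- parse_gene_programs(genes, sim$matrix, edges = edges, terms = terms,
                             seed = 6)
  expect_identical(res$gmm$k, 3L)
  expect_equal(ari(res$gmm$assignment, sim$truth$module), 1)
  kept_programs <- res$programs[res$kept]
  expect_length(kept_programs, 1L)
  expect_setequal(kept_programs[[1]], modules[[1]])
  enr <- res$enrichment[[1]]
  expect_true(enr$kept[enr$term == "mod1"])
  expect_false(enr$kept[enr$term == "mod2"])
})
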