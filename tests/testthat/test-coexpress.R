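test_that("signed adjacency separates anti-correlated genes", {
  s <- seq(-1, 1, length.out = 12)
  v <- rbind(g1 = s, g2 = -s, g3 = s + 0.01 * seq_len(12))
  colnames(v) <- sprintf("s%02d", 1:12)
  A <- signed_adjacency(toy_lcpm(v), soft_power = 12)
  expect_equal(A["g1", "g2"], 0, tolerance = 1e-12)
  expect_equal(A["g1", "g1"], 1)
  expect_true(all(A >= 0 & A <= 1 + 1e-12))
  expect_equal(A, t(A))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(n_genes = 400, n_samples_per_group = 20, n_modules = 2,
                    module_size = 50, de_fraction = 0, seed = 7)
  ex <- simulate_expression(cfg)
  lc <- log_cpm(ex$data)
  # generator check: within-module correlation near the intended ~0.7
  m1 <- names(ex$truth$module_assignment)[ex$truth$module_assignment == 1]
  cc <- cor(t(lc$values[m1, ]))
  expect_gt(median(cc[upper.tri(cc)]), 0.5)
  mods <- detect_modules(lc, min_module_size = 30)
  ari <- mclust::adjustedRandIndex(mods$labels, ex$truth$module_assignment)
  expect_gte(ari, 0.8)
})

test_that("pure-noise expression yields no module of qualifying size", {
  n_with_module <- vapply(1:50, function(s) {
    cfg <- sim_config(n_genes = 300, n_samples_per_group = 10,
                      n_modules = 0, de_fraction = 0, seed = 500 + s)
    ex <- simulate_expression(cfg)
    mods <- detect_modules(log_cpm(ex$data), min_module_size = 30)
    any(mods$labels > 0)
  }, logical(1))
  expect_gte(mean(!n_with_module), 0.9)
})

test_that("module eigengene is the oriented first principal component", {
  set.seed(9)
  base <- rnorm(16)
  v <- matrix(rep(base, each = 6), 6, byrow = FALSE) * runif(6, 0.5, 2)
  rownames(v) <- sprintf("g%d", 1:6)
  colnames(v) <- sprintf("s%02d", 1:16)
  labels <- setNames(rep(1L, 6), rownames(v))
  me <- module_eigengene(toy_lcpm(v), labels)
  expect_equal(abs(cor(me[1, ], base)), 1, tolerance = 1e-8)
  expect_equal(sum(me[1, ]^2), 1, tolerance = 1e-12)  # unit norm
  expect_gt(cor(me[1, ], colMeans(t(scale(t(v))))), 0)

  # flipping all genes flips the eigengene
  me2 <- module_eigengene(toy_lcpm(-v), labels)
  expect_equal(me2[1, ], -me[1, ], tolerance = 1e-8)

  # PC1 variance dominates PC2 (brute-force eigendecomposition oracle)
  cfg <- sim_config(n_genes = 120, n_samples_per_group = 10, n_modules = 1,
                    module_size = 40, de_fraction = 0, seed = 11)
  ex <- simulate_expression(cfg)
  lc <- log_cpm(ex$data)
  mod <- names(ex$truth$module_assignment)[ex$truth$module_assignment == 1]
  std <- t(scale(t(lc$values[mod, ])))
  ev <- eigen(crossprod(std), symmetric = TRUE)$values
  expect_gte(ev[1], ev[2])
  me3 <- module_eigengene(lc, ex$truth$module_assignment)
  expect_equal(sum((std %*% me3[1, ])^2), ev[1], tolerance = 1e-6)
})

test_that("module membership kME/MMP behave like a Spearman test", {
  set.seed(13)
  n <- 20
  eig <- matrix(rnorm(n), 1, dimnames = list("M1", sprintf("s%02d", 1:n)))
  v <- rbind(g1 = eig[1, ], g2 = rnorm(n))
  colnames(v) <- colnames(eig)
  lc <- toy_lcpm(v)
  mm <- module_membership(lc, eig)
  expect_equal(mm$kme["g1", "M1"], 1)
  expect_lt(mm$mmp["g1", "M1"], 1e-10)

  # rank-then-Pearson equals direct Spearman
  expect_equal(mm$kme["g2", "M1"],
               cor(v["g2", ], eig[1, ], method = "spearman"))

  # independent noise genes: MMP ~ uniform (discrete ranks, so check the
  # realized rejection rates rather than a continuous KS statistic)
  v2 <- matrix(rnorm(1000 * n), 1000,
               dimnames = list(sprintf("g%04d", 1:1000), colnames(eig)))
  mm2 <- module_membership(toy_lcpm(v2), eig)
  expect_lt(abs(mean(mm2$mmp[, 1] < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(mm2$mmp[, 1] < 0.5) - 0.5), 0.06)

  expect_error(module_membership(toy_lcpm(v[, 1:3, drop = FALSE]), eig[, 1:3,
    drop = FALSE]), ">= 4 samples")
})

test_that("hub ranking follows intramodular connectivity", {
  # star topology: center correlated with all, leaves mutually independent
  set.seed(15)
  n <- 30
  center <- rnorm(n)
  leaves <- sapply(1:5, function(i) 0.7 * center + rnorm(n, 0, 0.7))
  v <- t(cbind(hub = center, leaves))
  rownames(v) <- c("hub", sprintf("leaf%d", 1:5))
  colnames(v) <- sprintf("s%02d", 1:n)
  lc <- toy_lcpm(v)
  A <- signed_adjacency(lc, 6)
  labels <- setNames(rep(1L, 6), rownames(v))
  ms <- structure(list(labels = labels, adjacency = A,
                       k_in = rowSums(A) - diag(A)), class = "module_set")
  ranked <- hub_genes(ms, 1L, 3)
  expect_equal(ranked$gene[1], "hub")

  expect_warning(all6 <- hub_genes(ms, 1L, 10), "module size")
  expect_equal(nrow(all6), 6L)

  # brute-force k_in oracle on a 10-gene instance
  v2 <- matrix(rnorm(10 * 12), 10,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
  lc2 <- toy_lcpm(v2)
  mods <- suppressWarnings(detect_modules(lc2, soft_power = 2,
                                          min_module_size = 2,
                                          merge_height = 1))
  A2 <- mods$adjacency
  for (g in names(mods$labels)) {
    m <- mods$labels[[g]]
    if (m == 0) next
    sel <- names(mods$labels)[mods$labels == m]
    expect_equal(mods$k_in[[g]], sum(A2[g, setdiff(sel, g)]),
                 tolerance = 1e-12)
  }
})
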