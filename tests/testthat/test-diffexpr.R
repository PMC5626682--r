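test_that("log-CPM matches its defining formula", {
  # count 0 in a sample of library size 1e6
  m <- matrix(c(0L, 1000000L, 10L, 999990L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- toy_counts(m, c("tumor", "control"))
  lc <- log_cpm(x, pseudocount = 0.5)
  expect_equal(lc$values["g1", "s1"], log2(0.5 / ((1e6 + 1) / 1e6)),
               tolerance = 1e-12)
  expect_equal(lc$values["g1", "s1"], -1.0000014, tolerance = 1e-6)

  # 2x2 toy vs hand computation
  m2 <- matrix(c(3L, 7L, 20L, 30L), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc2 <- log_cpm(toy_counts(m2, c("tumor", "control")), 0.5)
  hand <- log2((m2 + 0.5) / rep((colSums(m2) + 1) / 1e6, each = 2))
  expect_equal(lc2$values, hand)

  # doubling a sample's counts preserves the CPM profile (ratios), up to
  # the vanishing pseudocount effect
  m3 <- matrix(rpois(40, 50) + 1L, 10,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  x3 <- toy_counts(m3, rep(c("tumor", "control"), 2))
  m3d <- m3; m3d[, 1] <- m3d[, 1] * 2L
  x3d <- toy_counts(m3d, rep(c("tumor", "control"), 2))
  d <- log_cpm(x3d, 1e-9)$values[, 1] - log_cpm(x3, 1e-9)$values[, 1]
  expect_lt(max(abs(d)), 1e-6)

  expect_error(log_cpm(toy_counts(matrix(0L, 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))), c("tumor", "control"))),
    "all-zero")
})

test_that("fit_de calls direction per contract and rejects bad designs", {
  set.seed(4)
  v <- matrix(rnorm(100 * 10), 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:10)))
  v[1, ] <- rep(c(1, 2, 3, 4, 5), 2)  # identical across groups
  lc <- toy_lcpm(v, rep(c("tumor", "control"), each = 5))
  lc$values[1, ] <- c(1:5, 1:5)
  de <- fit_de(lc)
  expect_equal(de$logFC[de$gene == "g001"], 0, tolerance = 1e-12)
  expect_equal(de$direction[de$gene == "g001"], "ns")
  expect_true(all(de$fdr >= de$p))
  expect_true(all(de$direction[de$fdr <= 0.01 & de$logFC >= 0] == "up"))

  lc$samples$dup <- lc$samples$group  # collinear covariate
  expect_error(fit_de(lc, covariates = "dup"), "collinear")
})

test_that("fit_de recovers planted effects and controls false discoveries", {
  cfg <- sim_config(n_genes = 2000, n_samples_per_group = 20,
                    de_logfc_mean = 2, seed = 8)
  ex <- simulate_expression(cfg)
  de <- fit_de(log_cpm(ex$data), covariates = c("sex", "platform"))
  truth <- ex$truth$de_genes
  called <- de$gene[de$fdr <= 0.01]
  sens <- mean(names(truth) %in% called)
  expect_gte(sens, 0.9)

  # all-null simulation: realized false-discovery proportion small
  cfg0 <- sim_config(n_genes = 2000, n_samples_per_group = 20,
                     de_fraction = 0, n_modules = 0, seed = 12)
  ex0 <- simulate_expression(cfg0)
  de0 <- fit_de(log_cpm(ex0$data))
  expect_lte(mean(de0$fdr <= 0.01), 0.03)
  # null p-values approximately uniform
  expect_gt(ks.test(de0$p, "punif")$p.value, 0.01)
})

test_that("exon flattening splits bins at every isoform boundary", {
  gm <- data.frame(gene = "gA", isoform = c("i1", "i2"),
                   start = c(1, 1), end = c(100, 150))
  bins <- flatten_exons(gm)
  expect_equal(bins$start, c(1, 101))
  expect_equal(bins$end, c(100, 150))

  gm2 <- data.frame(gene = "gB", isoform = rep(c("i1", "i2"), each = 2),
                    start = c(1, 200, 1, 200), end = c(50, 300, 50, 300))
  bins2 <- flatten_exons(gm2)
  expect_equal(bins2$start, c(1, 200))
  expect_equal(bins2$end, c(50, 300))

  # 3-isoform toy vs brute-force segmentation over all boundaries
  gm3 <- data.frame(gene = "gC",
                    isoform = c("i1", "i1", "i2", "i2", "i3"),
                    start = c(1, 60, 1, 90, 30),
                    end = c(50, 80, 40, 120, 100))
  bins3 <- flatten_exons(gm3)
  pts <- sort(unique(c(gm3$start, gm3$end + 1)))
  brute <- NULL
  for (i in seq_len(length(pts) - 1)) {
    s <- pts[i]; e <- pts[i + 1] - 1
    covered <- any(gm3$start <= s & gm3$end >= e)
    if (covered) brute <- rbind(brute, c(s, e))
  }
  # merge brute segments only where no boundary separates them: disjoin
  # keeps boundary-split pieces, so compare coverage and boundaries
  expect_equal(sum(bins3$end - bins3$start + 1), sum(brute[, 2] - brute[, 1] + 1))
  expect_true(all(bins3$start %in% pts))
  expect_true(all((bins3$end + 1) %in% pts))
  # disjoint and ordered
  expect_true(all(diff(bins3$start) > 0))
  expect_true(all(bins3$start[-1] > bins3$end[-nrow(bins3)]))

  gm4 <- data.frame(gene = "gD", isoform = "i1",
                    start = c(1, 40), end = c(50, 90))
  expect_error(flatten_exons(gm4), "overlapping exons within isoform")
})

test_that("relative exonic usage obeys its normalization identity", {
  v <- matrix(5, 4, 2, dimnames = list(paste0("gA:bin", 1:4), c("s1", "s2")))
  lc <- toy_lcpm(v)
  rel <- relative_exon_usage(lc)
  expect_equal(unname(rel), matrix(-2, 4, 2))  # equal x -> -log2(N)

  v1 <- matrix(3.7, 1, 2, dimnames = list("gB:bin1", c("s1", "s2")))
  expect_warning(rel1 <- relative_exon_usage(toy_lcpm(v1)), "single exon")
  expect_equal(unname(rel1), matrix(0, 1, 2))

  set.seed(6)
  v2 <- matrix(rnorm(10, 4, 2), 5, 2,
               dimnames = list(paste0("gC:bin", 1:5), c("s1", "s2")))
  rel2 <- relative_exon_usage(toy_lcpm(v2))
  expect_equal(unname(colSums(2^rel2)), c(1, 1), tolerance = 1e-12)
})

test_that("Simes combination matches its formula and BH equivalence", {
  expect_equal(simes_p(c(0.01, 0.02, 0.9)), 0.03)
  expect_equal(simes_p(0.2), 0.2)
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(2:10, 1))
    expect_equal(simes_p(p), min(p.adjust(p, "BH")))
  }
})

test_that("exon-usage test finds planted shifts and is null on flat genes", {
  # all exons identical -> usage logFC exactly 0, F p-value 1
  v <- matrix(rnorm(8), 4, 8, byrow = TRUE)
  v <- v[rep(1:2, each = 2), ]          # 2 genes x 2 identical exons
  rownames(v) <- c("gA:bin1", "gA:bin2", "gB:bin1", "gB:bin2")
  colnames(v) <- sprintf("s%d", 1:8)
  lc <- toy_lcpm(v, rep(c("tumor", "control"), each = 4))
  res <- test_exon_usage(lc)
  expect_equal(res$exons$usage_logFC, rep(0, 4), tolerance = 1e-12)
  expect_equal(res$genes$F_p, c(1, 1))

  # planted usage-shift genes recovered by Simes FDR
  cfg <- sim_config(n_genes = 300, n_samples_per_group = 20,
                    splice_fraction = 0.1, usage_shift = 0.25, seed = 14)
  ex <- simulate_exon_counts(cfg, 4)
  res2 <- test_exon_usage(log_cpm(ex$data))
  hit <- res2$genes$gene[res2$genes$simes_fdr < 0.05]
  sens <- mean(ex$truth$splice_genes$gene %in% hit)
  expect_gte(sens, 0.8)
  # invariant: simes_p >= min p / n_exons
  m <- merge(res2$genes,
             aggregate(p ~ gene, res2$exons, min), by = "gene")
  expect_true(all(m$simes_p >= m$p / m$n_exons - 1e-12))
})
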