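test_that("variant burden averages over all samples", {
  samples <- sprintf("t%02d", 1:26)
  # 258 SNVs + 20 non-SNVs spread over the cohort
  set.seed(51)
  v <- data.frame(sample = sample(samples, 278, replace = TRUE),
                  gene = sprintf("g%03d", 1:278), somatic = TRUE)
  bd <- variant_burden(v, samples)
  expect_equal(bd$total, 278)
  expect_equal(bd$mean_reported, 10.7)
  expect_equal(bd$mean * 26, bd$total)   # exact bookkeeping

  expect_equal(variant_burden(v[0, ], sprintf("s%d", 1:5))$mean_reported, 0)
  v3 <- data.frame(sample = "s1", gene = c("a", "b", "c"), somatic = TRUE)
  expect_equal(variant_burden(v3, c("s1", "s2", "s3"))$mean_reported, 1)
})

test_that("recurrence requires distinct samples", {
  v <- data.frame(sample = c("s1", "s1", "s2", "s3"),
                  gene = c("gA", "gA", "gB", "gB"),
                  somatic = c(TRUE, TRUE, TRUE, TRUE))
  rec <- recurrent_genes(v, min_samples = 2)
  expect_equal(rec$gene, "gB")          # gA hit twice in one sample only
  expect_equal(recurrent_genes(v, min_samples = 1)$gene, c("gB", "gA"))

  cfg <- sim_config(n_genes = 300, n_samples_per_group = 10,
                    n_recurrent_genes = 4, seed = 53)
  ex <- simulate_expression(cfg)
  mv <- simulate_marks_and_variants(cfg, ex$truth)
  rec2 <- recurrent_genes(mv$variants, min_samples = 2)
  expect_setequal(rec2$gene, mv$truth$recurrent_genes)
})

test_that("gene-set enrichment of flagged genes uses the exact tail", {
  universe <- sprintf("g%04d", 1:1000)
  annot <- universe[1:50]
  flagged <- c(universe[1:5], universe[900:901])  # 5 of 7 in annotation
  rec <- geneset_fisher(flagged, annot, universe)
  expect_equal(rec$fold_enrichment, 5 * 1000 / (7 * 50), tolerance = 1e-12)
  expect_equal(rec$p, oracle_one_sided(5, 7, 50, 1000), tolerance = 1e-10)

  # overlap at expectation is not significant
  set.seed(55)
  flagged2 <- sample(universe, 100)     # expect 5 of 50 annot genes
  rec2 <- geneset_fisher(flagged2, annot, universe)
  expect_gt(rec2$p, 0.05)

  rec3 <- geneset_fisher(flagged, universe, universe)
  expect_equal(rec3$fold_enrichment, 1)  # annotation = universe
})

test_that("panel coverage counts variant or CNV hits with round-half-up", {
  samples <- sprintf("s%02d", 1:26)
  coords <- data.frame(gene = c("MEN1", "EZH2"), chrom = c("chr11", "chr7"),
                       start = c(100, 200), end = c(199, 299))
  v <- data.frame(sample = samples[1:12], gene = "MEN1")
  seg <- data.frame(sample = samples[13:22], chrom = "chr7", start = 150,
                    end = 250, class = "gain", log2ratio = 0.4)
  cov <- epigene_coverage(v, seg, coords, c("MEN1", "EZH2"), samples)
  expect_equal(cov$n_hit, 22)
  expect_equal(cov$percent, 85L)         # 22/26 = 84.6 -> 85

  cov0 <- epigene_coverage(v[0, ], seg[0, ], coords, "MEN1", samples)
  expect_equal(cov0$percent, 0L)

  # 3-sample hand enumeration: s1 variant, s2 CNV overlap, s3 nothing
  s3 <- c("s1", "s2", "s3")
  v3 <- data.frame(sample = "s1", gene = "MEN1")
  seg3 <- data.frame(sample = c("s2", "s3"), chrom = c("chr11", "chr11"),
                     start = c(150, 500), end = c(160, 600),
                     class = c("cnLOH", "loss"), log2ratio = 0)
  cov3 <- epigene_coverage(v3, seg3, coords, "MEN1", s3)
  expect_equal(unname(rowSums(cov3$hits) > 0), c(TRUE, TRUE, FALSE))
  expect_equal(cov3$percent, 67L)        # 2/3 = 66.7 -> 67

  expect_error(epigene_coverage(v3, seg3, coords, "NOCOORD", s3),
               "without coordinates")
})

test_that("CNV recurrence tracks report per-bin sample fractions", {
  lens <- c(chrA = 5e6, chrB = 3e6)
  seg <- data.frame(sample = "s1", chrom = "chrA", start = 1, end = 5e6,
                    class = "gain", log2ratio = 1)
  tr <- cnv_recurrence_track(seg, n_samples = 1, bin = 1e6,
                             chrom_lengths = lens)
  expect_equal(tr$gain[tr$chrom == "chrA"], rep(1, 5))
  expect_equal(tr$gain[tr$chrom == "chrB"], rep(0, 3))
  # bins tile each chromosome without overlap
  a <- tr[tr$chrom == "chrA", ]
  expect_equal(a$start, seq(1, 5e6, by = 1e6))
  expect_equal(a$end, a$start + 1e6 - 1)

  seg5 <- data.frame(sample = sprintf("s%d", 1:5), chrom = "chrB",
                     start = 1.5e6, end = 1.7e6, class = "loss",
                     log2ratio = -1)
  tr5 <- cnv_recurrence_track(seg5, n_samples = 26, bin = 1e6,
                              chrom_lengths = lens)
  hit <- tr5[tr5$chrom == "chrB" & tr5$start == 1e6 + 1, ]
  expect_equal(hit$loss, 5 / 26)         # ~0.192: one 20% track line

  tr0 <- cnv_recurrence_track(seg[0, ], 5, 1e6, lens)
  expect_true(all(tr0[, c("gain", "loss", "cnLOH")] == 0))

  bad <- data.frame(sample = "s1", chrom = "chrB", start = 1, end = 4e6,
                    class = "gain", log2ratio = 1)
  expect_error(cnv_recurrence_track(bad, 1, 1e6, lens),
               "beyond chromosome length")
})
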