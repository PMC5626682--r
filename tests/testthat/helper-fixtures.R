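# Small in-code fixtures shared across test files.

# A count_data bundle built directly (no file round-trip).
toy_counts <- function(counts, groups, ...) {
  samples <- data.frame(sample = colnames(counts), group = groups, ...,
                        stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples), class = "count_data")
}

# A log_cpm-like object from an explicit value matrix (for tests that
# control expression values exactly rather than counts).
toy_lcpm <- function(values, groups = rep(c("tumor", "control"),
                                          length.out = ncol(values))) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  structure(list(values = values, lib_sizes = rep(1e6, ncol(values)),
                 samples = data.frame(sample = colnames(values),
                                      group = groups,
                                      stringsAsFactors = FALSE)),
            class = "log_cpm")
}

# Write a counts + metadata TSV pair, returning the two paths.
write_toy_count_files <- function(counts, groups, dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  cp <- file.path(dir, "counts.tsv")
  mp <- file.path(dir, "meta.tsv")
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(df, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(counts), group = groups)
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  c(counts = cp, meta = mp)
}

# Minimal allele-count row constructor.
allele_row <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                       sample = "s1", group = "tumor", ref_count = 20,
                       alt_count = 20) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample = sample, group = group, ref_count = ref_count,
             alt_count = alt_count, stringsAsFactors = FALSE)
}

# Independent minlike two-sided oracle built from log-binomials only
# (does not use dhyper, fisher.test, or the package path).
oracle_two_sided <- function(k, n_sig, n_tgt, N) {
  lo <- max(0, n_sig + n_tgt - N)
  hi <- min(n_sig, n_tgt)
  lp <- vapply(lo:hi, function(x)
    lchoose(n_sig, x) + lchoose(N - n_sig, n_tgt - x) - lchoose(N, n_tgt),
    0)
  p <- exp(lp)
  obs <- p[k - lo + 1]
  sum(p[p <= obs * (1 + 1e-7)])
}

oracle_one_sided <- function(k, n_sig, n_tgt, N) {
  lo <- max(0, n_sig + n_tgt - N)
  hi <- min(n_sig, n_tgt)
  lp <- vapply(lo:hi, function(x)
    lchoose(n_sig, x) + lchoose(N - n_sig, n_tgt - x) - lchoose(N, n_tgt),
    0)
  sum(exp(lp)[(lo:hi) >= k])
}

# Balanced tumor/control per-locus table at proportion p (beta-binomial
# when rho > 0); used by the quasi-binomial calibration checks.
sim_loci_table <- function(n_loci, S, depth, p, rho = 0, seed = 1) {
  # balanced tumor/control table; identical generation per group
  set.seed(seed)
  rows <- list()
  for (g in c("tumor", "control")) for (s in seq_len(S)) {
    pp <- if (rho > 0) {
      a <- p * (1 / rho - 1); b <- (1 - p) * (1 / rho - 1)
      rbeta(n_loci, a, b)
    } else rep(p, n_loci)
    y <- rbinom(n_loci, depth, pp)
    rows[[paste(g, s)]] <- data.frame(
      chrom = "chr1", pos = seq_len(n_loci), ref = "A", alt = "T",
      sample = paste0(g, s), group = g, ref_count = y,
      alt_count = depth - y, stringsAsFactors = FALSE)
  }
  filter_ase_sites(do.call(rbind, rows), min_depth = 30)
}
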