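#' Synthetic-study configuration
#'
#' Parameters of the synthetic two-group study bundle. Counts follow a
#' negative-binomial model (Var = mu + alpha * mu^2) whose log2 mean is
#' baseline + group effect (the planted log fold change for DE genes) +
#' a shared per-module Gaussian latent factor (loading 1 for members) +
#' a log-normal library-size offset. Allele counts realize the reference
#' bias mechanistically: alternate-allele reads are dropped independently
#' with probability \code{2 - 1/ref_bias}, so a configured bias of 0.54
#' corresponds to an alt-read loss of ~0.148 and an expected null
#' reference fraction 0.5 / (0.5 + 0.5 * 0.852) = 0.54.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples in each of the tumor and control groups.
#' @param n_modules,module_size Planted co-expression modules (gene blocks).
#' @param de_fraction Fraction of genes with a planted group effect.
#' @param de_logfc_mean Magnitude of planted log2 fold changes (sign random).
#' @param nb_dispersion Negative-binomial dispersion alpha.
#' @param latent_factor_sd SD of the per-module shared factor (log2 scale).
#' @param lib_size_sd SD (log scale) of log-normal library-size factors.
#' @param splice_fraction Fraction of genes with a planted exon-usage shift.
#' @param usage_shift Shift in the affected exon's relative share
#'   (control share + shift in tumor).
#' @param mark_prob_in_updeg Probability an up-regulated DE gene carries the
#'   planted repressive mark.
#' @param mark_prob_background Probability any other gene carries it.
#' @param n_ase_sites Number of simulated heterozygous loci.
#' @param ase_depth_mean Poisson mean of per-sample read depth at a locus.
#' @param ase_depth_floor Lower bound applied to simulated depths.
#' @param ase_samples_per_group Samples per group carrying each locus.
#' @param ref_bias Expected null reference-allele fraction realized by the
#'   alt-read dropout mechanism.
#' @param n_ase_signal Number of loci with planted allelic imbalance.
#' @param ase_signal_fraction True reference fraction at planted loci.
#' @param ag_fraction Fraction of loci given A/G (or T/C) alleles, to
#'   exercise the RNA-editing exclusion filter.
#' @param n_recurrent_genes Genes planted as recurrently mutated (>= 2 tumors).
#' @param n_background_variants Singleton variants scattered over other genes.
#' @param seed Integer seed; a fixed seed yields a byte-identical bundle.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000, n_samples_per_group = 20,
                       n_modules = 4, module_size = 50,
                       de_fraction = 0.15, de_logfc_mean = 2,
                       nb_dispersion = 0.1, latent_factor_sd = 0.8,
                       lib_size_sd = 0.3,
                       splice_fraction = 0.05, usage_shift = 0.25,
                       mark_prob_in_updeg = 0.9, mark_prob_background = 0.1,
                       n_ase_sites = 5000, ase_depth_mean = 60,
                       ase_depth_floor = 30, ase_samples_per_group = 5,
                       ref_bias = 0.54, n_ase_signal = 100,
                       ase_signal_fraction = 0.8, ag_fraction = 0.1,
                       n_recurrent_genes = 5, n_background_variants = 30,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("de_fraction", "splice_fraction", "mark_prob_in_updeg",
             "mark_prob_background", "ref_bias", "ase_signal_fraction",
             "ag_fraction")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a probability in [0, 1]")
  if (ase_depth_mean < 1) stop("ase_depth_mean must be >= 1")
  if (ref_bias <= 0.5) stop("ref_bias must exceed 0.5 for a dropout mechanism")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

sample_sheet <- function(cfg) {
  n <- cfg$n_samples_per_group
  data.frame(sample = c(sprintf("tum%02d", seq_len(n)),
                        sprintf("ctl%02d", seq_len(n))),
             group = rep(c("tumor", "control"), each = n),
             sex = rep(rep(c("M", "F"), length.out = n), 2L),
             platform = rep(rep(c("p1", "p2"), each = ceiling(n / 2))[seq_len(n)], 2L),
             stringsAsFactors = FALSE)
}

#' Simulate a gene-level count matrix with planted truth
#'
#' @param cfg A [sim_config()].
#' @return List with \code{data} (a \code{count_data}) and \code{truth}
#'   (planted log fold changes \code{de_genes}, module labels
#'   \code{module_assignment} with 0 for background, and the per-sample
#'   library factors).
#' @export
simulate_expression <- function(cfg) {
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("module_size * n_modules exceeds n_genes")
  set.seed(stage_seed(cfg$seed, "expression"))
  genes <- gene_ids(cfg$n_genes)
  meta <- sample_sheet(cfg)
  ns <- nrow(meta)

  modules <- integer(cfg$n_genes)
  if (cfg$n_modules > 0)
    modules[seq_len(cfg$n_modules * cfg$module_size)] <-
      rep(seq_len(cfg$n_modules), each = cfg$module_size)
  names(modules) <- genes

  n_de <- floor(cfg$de_fraction * cfg$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(cfg$n_genes, n_de)) else integer()
  lfc <- numeric(cfg$n_genes)
  lfc[de_idx] <- cfg$de_logfc_mean * sample(c(-1, 1), n_de, replace = TRUE)

  base <- stats::runif(cfg$n_genes, 3, 9)
  lib <- exp(stats::rnorm(ns, 0, cfg$lib_size_sd))
  lib <- lib / mean(lib)
  tumor <- as.numeric(meta$group == "tumor")

  factors <- matrix(0, max(cfg$n_modules, 1L), ns)
  if (cfg$n_modules > 0)
    factors <- matrix(stats::rnorm(cfg$n_modules * ns, 0, cfg$latent_factor_sd),
                      cfg$n_modules, ns)

  logmu <- outer(base, rep(1, ns)) + outer(lfc, tumor)
  for (m in seq_len(cfg$n_modules))
    logmu[modules == m, ] <- sweep(logmu[modules == m, , drop = FALSE], 2,
                                   factors[m, ], `+`)
  mu <- sweep(2^logmu, 2, lib, `*`)
  counts <- matrix(
    if (cfg$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else stats::rpois(length(mu), mu),
    nrow(mu), ncol(mu), dimnames = list(genes, meta$sample))

  de <- lfc[de_idx]
  names(de) <- genes[de_idx]
  list(data = count_data(counts, meta),
       truth = list(de_genes = de, module_assignment = modules,
                    lib_factors = stats::setNames(lib, meta$sample)))
}

#' Simulate exon-bin counts with planted usage shifts
#'
#' Gene totals are drawn from the same negative-binomial model in both
#' groups (no group effect), then split multinomially across exon bins.
#' For splicing-truth genes the first bin's relative share moves from its
#' baseline by \code{usage_shift} in the tumor group, with the remaining
#' bins rescaled, so total gene counts are distribution-matched between
#' groups while usage differs.
#'
#' @param cfg A [sim_config()].
#' @param n_exons_per_gene Number of exon bins per gene (>= 2).
#' @return List with \code{data} (\code{count_data} over exon bins, ids
#'   \code{gene:binK}) and \code{truth} (\code{splice_genes}: shifted bin
#'   and shift size per planted gene).
#' @export
simulate_exon_counts <- function(cfg, n_exons_per_gene = 4) {
  if (n_exons_per_gene < 2) stop("n_exons_per_gene must be >= 2")
  set.seed(stage_seed(cfg$seed, "exon"))
  genes <- gene_ids(cfg$n_genes)
  meta <- sample_sheet(cfg)
  ns <- nrow(meta)
  E <- n_exons_per_gene

  n_spl <- if (cfg$usage_shift > 0) floor(cfg$splice_fraction * cfg$n_genes) else 0L
  spl_idx <- if (n_spl > 0) sort(sample.int(cfg$n_genes, n_spl)) else integer()

  base <- stats::runif(cfg$n_genes, 6, 10)   # deeper than gene sim: usage needs depth
  lib <- exp(stats::rnorm(ns, 0, cfg$lib_size_sd))
  lib <- lib / mean(lib)
  mu <- sweep(2^outer(base, rep(1, ns)), 2, lib, `*`)
  totals <- matrix(
    if (cfg$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else stats::rpois(length(mu), mu),
    nrow(mu), ncol(mu))

  share0 <- rep(1 / E, E)
  share_shift <- c(share0[1L] + cfg$usage_shift,
                   rep((1 - share0[1L] - cfg$usage_shift) / (E - 1), E - 1))
  tumor <- meta$group == "tumor"

  counts <- matrix(0L, cfg$n_genes * E, ns)
  rownames(counts) <- paste0(rep(genes, each = E), ":bin", rep(seq_len(E), cfg$n_genes))
  colnames(counts) <- meta$sample
  for (g in seq_len(cfg$n_genes)) {
    rows <- (g - 1L) * E + seq_len(E)
    for (s in seq_len(ns)) {
      sh <- if (g %in% spl_idx && tumor[s]) share_shift else share0
      counts[rows, s] <- stats::rmultinom(1L, totals[g, s], sh)[, 1L]
    }
  }
  spl <- data.frame(gene = genes[spl_idx], bin = rep(1L, n_spl),
                    shift = rep(cfg$usage_shift, n_spl),
                    stringsAsFactors = FALSE)
  list(data = count_data(counts, meta), truth = list(splice_genes = spl))
}

#' Simulate per-sample allele counts with a mechanistic reference bias
#'
#' Null loci are simulated at true allelic fraction 0.5 and each
#' alternate-allele read is then discarded independently with probability
#' \code{alt_loss} (default \code{2 - 1/ref_bias}), which yields an
#' expected observed reference fraction of \code{1 / (2 - alt_loss)}.
#' Planted imbalanced loci draw reference reads directly at their true
#' fraction. Allele letters are drawn from non-A/G, non-T/C pairs except
#' for a configurable fraction of A/G (T/C) loci that exercise the
#' editing-exclusion filter.
#'
#' @param cfg A [sim_config()].
#' @param alt_loss Alt-read dropout probability; default derived from
#'   \code{cfg$ref_bias}.
#' @return List with \code{data} (an \code{allele_counts} data.frame) and
#'   \code{truth} (\code{ase_loci}: true reference fraction per locus;
#'   \code{signal_loci}; \code{ag_loci}).
#' @export
simulate_allele_counts <- function(cfg, alt_loss = 2 - 1 / cfg$ref_bias) {
  set.seed(stage_seed(cfg$seed, "allele"))
  if (cfg$ase_depth_mean < 30)
    warning("ase_depth_mean below 30 reads: most sites will fail depth filtering")
  n <- cfg$n_ase_sites
  chrom <- paste0("chr", sample.int(22, n, replace = TRUE))
  pos <- sample.int(1e8, n)
  locus <- paste0(chrom, ":", pos)

  n_ag <- round(cfg$ag_fraction * n)
  is_ag <- c(rep(TRUE, n_ag), rep(FALSE, n - n_ag))[sample.int(n)]
  pairs_ok <- list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    p <- if (is_ag[i]) list(c("A", "G"), c("T", "C"))[[sample.int(2, 1)]]
    else pairs_ok[[sample.int(4, 1)]]
    if (stats::runif(1) < 0.5) p <- rev(p)
    ref[i] <- p[1L]; alt[i] <- p[2L]
  }

  sig_pool <- which(!is_ag)
  n_sig <- min(cfg$n_ase_signal, length(sig_pool))
  sig_idx <- if (n_sig > 0) sort(sample(sig_pool, n_sig)) else integer()
  true_frac <- rep(1 / (2 - alt_loss), n)
  true_frac[sig_idx] <- cfg$ase_signal_fraction
  names(true_frac) <- locus

  S <- cfg$ase_samples_per_group
  samples <- c(sprintf("tum%02d", seq_len(S)), sprintf("ctl%02d", seq_len(S)))
  groups <- rep(c("tumor", "control"), each = S)
  rows <- vector("list", 2L * S)
  for (j in seq_along(samples)) {
    depth <- pmax(stats::rpois(n, cfg$ase_depth_mean), cfg$ase_depth_floor)
    is_sig <- seq_len(n) %in% sig_idx
    refc <- integer(n); altc <- integer(n)
    r0 <- stats::rbinom(n, depth, ifelse(is_sig, cfg$ase_signal_fraction, 0.5))
    refc <- r0
    altc <- ifelse(is_sig, depth - r0,
                   stats::rbinom(n, depth - r0, 1 - alt_loss))
    rows[[j]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            sample = samples[j], group = groups[j],
                            ref_count = refc, alt_count = as.integer(altc),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- validate_allele_counts(tab)
  list(data = tab,
       truth = list(ase_loci = true_frac, signal_loci = locus[sig_idx],
                    ag_loci = locus[is_ag]))
}

#' Simulate mark signatures, a somatic-variant table and CNV segments
#'
#' Binary mark signatures are statistically coupled to DE direction: the
#' planted repressive mark contains each up-regulated DE gene with
#' probability \code{mark_prob_in_updeg} and any other gene with
#' probability \code{mark_prob_background}; the planted active mark is
#' coupled to down-regulated DE genes the same way; a null mark includes
#' every gene at the background rate. Two proliferation-style signatures
#' sample genes of planted module 1. The variant table plants
#' \code{n_recurrent_genes} genes mutated in 2-3 distinct tumors plus
#' singleton background variants; the segment table plants a recurrent
#' chr7 gain (~40\% of tumors) and chr11 loss (~20\%).
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return List with \code{signatures} (named list), \code{variants}
#'   (data.frame), \code{segments} (\code{segment_table}) and
#'   \code{truth} (recurrent genes/regions, signature membership).
#' @export
simulate_marks_and_variants <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "marks"))
  genes <- names(truth$module_assignment)
  up <- names(truth$de_genes)[truth$de_genes > 0]
  down <- names(truth$de_genes)[truth$de_genes < 0]

  couple <- function(fg) {
    inc <- ifelse(genes %in% fg, cfg$mark_prob_in_updeg, cfg$mark_prob_background)
    genes[stats::runif(length(genes)) < inc]
  }
  mod1 <- genes[truth$module_assignment == 1L]
  prolif <- function() {
    s <- c(mod1[stats::runif(length(mod1)) < 0.8],
           setdiff(genes, mod1)[stats::runif(length(genes) - length(mod1)) < 0.02])
    unique(s)
  }
  signatures <- list(
    repressive_mark = couple(up),
    active_mark = couple(down),
    null_mark = genes[stats::runif(length(genes)) < cfg$mark_prob_background],
    prolif_human = prolif(),
    prolif_mouse = prolif())
  signatures <- Filter(length, signatures)

  n_t <- cfg$n_samples_per_group
  tumors <- sprintf("tum%02d", seq_len(n_t))
  rec <- if (cfg$n_recurrent_genes > 0) sample(genes, cfg$n_recurrent_genes) else character()
  eff <- c("missense", "nonsense", "splice", "indel", "mnv")
  vrows <- list()
  for (g in rec) {
    n_hit <- if (n_t >= 3) sample(2:3, 1L) else 2L
    hit <- sample(tumors, n_hit)
    for (s in hit)
      vrows[[length(vrows) + 1L]] <- data.frame(
        sample = s, gene = g, chrom = paste0("chr", sample.int(22, 1L)),
        pos = sample.int(1e8, 1L), ref = "A", alt = "T",
        effect = sample(eff, 1L), somatic = TRUE, stringsAsFactors = FALSE)
  }
  # background singletons hit distinct genes so planted recurrence is the
  # only recurrence in the bundle
  bg <- setdiff(genes, rec)
  n_bgv <- min(cfg$n_background_variants, length(bg))
  bg_genes <- if (n_bgv > 0) sample(bg, n_bgv) else character()
  for (g in bg_genes) {
    vrows[[length(vrows) + 1L]] <- data.frame(
      sample = sample(tumors, 1L), gene = g,
      chrom = paste0("chr", sample.int(22, 1L)), pos = sample.int(1e8, 1L),
      ref = "C", alt = "G", effect = sample(eff, 1L), somatic = TRUE,
      stringsAsFactors = FALSE)
  }
  variants <- if (length(vrows)) do.call(rbind, vrows) else
    data.frame(sample = character(), gene = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               effect = character(), somatic = logical())

  gain_samples <- sample(tumors, ceiling(0.4 * n_t))
  loss_samples <- sample(tumors, ceiling(0.2 * n_t))
  seg <- rbind(
    if (length(gain_samples))
      data.frame(sample = gain_samples, chrom = "chr7", start = 1,
                 end = 5e7, class = "gain", log2ratio = 0.5),
    if (length(loss_samples))
      data.frame(sample = loss_samples, chrom = "chr11", start = 1,
                 end = 4e7, class = "loss", log2ratio = -0.5),
    data.frame(sample = sample(tumors, 5, replace = TRUE),
               chrom = paste0("chr", sample(2:6, 5, replace = TRUE)),
               start = 1e6, end = 2e6, class = "normal", log2ratio = 0))
  class(seg) <- c("segment_table", "data.frame")

  list(signatures = signatures, variants = variants, segments = seg,
       truth = list(recurrent_genes = rec,
                    recurrent_regions = data.frame(
                      chrom = c("chr7", "chr11"), start = c(1, 1),
                      end = c(5e7, 4e7), class = c("gain", "loss"),
                      frac = c(length(gain_samples), length(loss_samples)) / n_t),
                    mark_membership = signatures))
}

#' Approximate chromosome lengths for the human autosomes
#'
#' GRCh37-scale lengths rounded to the nearest Mb; used as the default
#' genome table for copy-number recurrence tracks.
#' @return Named numeric vector of lengths in bp for chr1..chr22.
#' @export
default_chrom_lengths <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  stats::setNames(mb * 1e6, paste0("chr", 1:22))
}
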