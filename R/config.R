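#' Study-level analysis configuration
#'
#' Collects every threshold and tuning constant the pipeline applies, with
#' defaults matching the study design this package implements: differential
#' expression called at FDR <= 1\%, signature/module enrichment and
#' allele-specific expression at FDR < 5\%, over-/under-enrichment fold
#' cutoffs of 2 and 0.6, a 201-gene sliding window (100 flanking genes each
#' side), an FDR-score cap of 50, a 30-read minimum depth for
#' allele-specific sites, a signed-network soft power of 12, a 30-gene
#' minimum module size, and 1 Mb copy-number recurrence bins.
#'
#' @param fdr_de FDR threshold for differential expression calls.
#' @param fdr_enrich FDR threshold for enrichment significance.
#' @param fdr_ase FDR threshold for allele-specific expression calls.
#' @param over_fold Fold-enrichment above which a significant record is
#'   called over-enriched (strict inequality).
#' @param under_fold Fold-enrichment below which a significant record is
#'   called under-enriched (strict inequality).
#' @param window_flank Number of flanking genes on each side of the
#'   sliding window (window width is \code{2 * window_flank + 1}).
#' @param fdr_score_cap Maximum absolute value of the FDR score.
#' @param min_ase_depth Minimum read depth supporting an allele-specific
#'   expression site.
#' @param soft_power Soft-threshold exponent for the signed co-expression
#'   adjacency.
#' @param min_module_size Smallest gene count retained as a module.
#' @param merge_height Static tree-cut height on topological-overlap
#'   dissimilarity.
#' @param cnv_bin Genomic bin width in bp for copy-number recurrence
#'   tracks.
#' @param seed Integer seed controlling all randomized stages.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(fdr_de = 0.01, fdr_enrich = 0.05, fdr_ase = 0.05,
                         over_fold = 2.0, under_fold = 0.6,
                         window_flank = 100, fdr_score_cap = 50,
                         min_ase_depth = 30, soft_power = 12,
                         min_module_size = 30, merge_height = 0.99,
                         cnv_bin = 1e6, seed = 1L) {
  cfg <- list(fdr_de = fdr_de, fdr_enrich = fdr_enrich, fdr_ase = fdr_ase,
              over_fold = over_fold, under_fold = under_fold,
              window_flank = as.integer(window_flank),
              fdr_score_cap = fdr_score_cap,
              min_ase_depth = as.integer(min_ase_depth),
              soft_power = soft_power,
              min_module_size = as.integer(min_module_size),
              merge_height = merge_height,
              cnv_bin = as.numeric(cnv_bin), seed = as.integer(seed))
  for (f in c("fdr_de", "fdr_enrich", "fdr_ase")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must be a fraction in (0, 1), got %s", f, v))
  }
  if (!(cfg$over_fold > 1 && cfg$under_fold < 1 && cfg$under_fold > 0))
    stop("need over_fold > 1 > under_fold > 0")
  if (cfg$window_flank < 1L) stop("window_flank must be >= 1")
  if (cfg$fdr_score_cap <= 0) stop("fdr_score_cap must be positive")
  if (cfg$soft_power < 1) stop("soft_power must be >= 1")
  if (cfg$merge_height <= 0 || cfg$merge_height > 1)
    stop("merge_height must be in (0, 1]")
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("study_config:\n")
  for (n in names(x)) cat(sprintf("  %-16s %s\n", n, format(x[[n]])))
  invisible(x)
}

# Stable 32-bit hash of a string; used to derive per-stage seed substreams
# so a stage's stream does not depend on which stages ran before it.
stage_seed <- function(seed, stage) {
  h <- 5381
  for (k in utf8ToInt(stage)) h <- (h * 33 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                ""), sep = "=", collapse = ";")
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483647
  sprintf("%08x", h)
}
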