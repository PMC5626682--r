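#' log2 counts-per-million
#'
#' \code{value[g,s] = log2((count[g,s] + pseudocount) /
#' ((libsize_s + 2 * pseudocount) / 1e6))} with \code{libsize_s} the raw
#' column sum (effective library size taken as the raw total).
#'
#' @param x A \code{count_data} object.
#' @param pseudocount Positive offset guarding zero counts (default 0.5).
#' @return A list of class \code{"log_cpm"}: \code{values} (gene x sample
#'   matrix), \code{lib_sizes}, and the sample sheet.
#' @export
log_cpm <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_data"), pseudocount > 0)
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x$counts)[lib == 0], collapse = ", "))
  vals <- log2(sweep(x$counts + pseudocount, 2, (lib + 2 * pseudocount) / 1e6, `/`))
  structure(list(values = vals, lib_sizes = lib, samples = x$samples),
            class = "log_cpm")
}

# Shared least-squares machinery: fits every row of `values` on design X,
# moderates per-row residual variance toward the grand mean with prior df
# d0, and returns the contrast column's coefficient, se and t.
lm_fit_moderated <- function(values, X, coef_name, prior_df = 4) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[-keep], collapse = ", "))
  }
  n <- ncol(values)
  p <- ncol(X)
  d <- n - p
  if (d < 1) stop("no residual degrees of freedom (need more samples)")
  beta <- t(qr.coef(qrX, t(values)))
  fitted <- beta %*% t(X)
  res <- values - fitted
  sigma2 <- rowSums(res^2) / d
  s2_0 <- mean(sigma2)
  s2_post <- (prior_df * s2_0 + d * sigma2) / (prior_df + d)
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  cgg <- XtXinv[coef_name, coef_name]
  se <- sqrt(cgg * s2_post)
  list(coef = beta[, coef_name], se = se, s2_post = s2_post,
       df = d + prior_df, unscaled_sd = sqrt(cgg))
}

build_design <- function(samples, covariates = NULL) {
  samples$group <- factor(samples$group, levels = c("control", "tumor"))
  fml <- stats::as.formula(paste(c("~ group", covariates), collapse = " + "))
  X <- stats::model.matrix(fml, data = samples)
  colnames(X)[colnames(X) == "grouptumor"] <- "group"
  X
}

#' Gene-level differential expression (tumor vs control)
#'
#' Per-gene least-squares fit of log-CPM on group plus covariates, with the
#' per-gene residual variance shrunk toward the grand mean variance using a
#' prior of \code{prior_df} degrees of freedom; moderated t statistics,
#' Benjamini-Hochberg FDR, and direction calls (\code{up} for
#' \code{fdr <= fdr_de} with logFC >= 0, \code{down} for negative logFC,
#' otherwise \code{ns}).
#'
#' @param lcpm A [log_cpm()] object.
#' @param covariates Character vector of metadata columns to adjust for.
#' @param prior_df Prior degrees of freedom for variance moderation.
#' @param fdr_de FDR threshold for direction calls.
#' @return data.frame of class \code{"de_result"}: gene, logFC, t, p, fdr,
#'   direction.
#' @export
fit_de <- function(lcpm, covariates = NULL, prior_df = 4, fdr_de = 0.01) {
  stopifnot(inherits(lcpm, "log_cpm"))
  if (length(unique(lcpm$samples$group)) < 2)
    stop("need both groups present")
  if (min(table(lcpm$samples$group)) < 2)
    stop("need >= 2 samples per group")
  X <- build_design(lcpm$samples, covariates)
  fit <- lm_fit_moderated(lcpm$values, X, "group", prior_df)
  t <- fit$coef / fit$se
  p <- 2 * stats::pt(-abs(t), df = fit$df)
  fdr <- stats::p.adjust(p, "BH")
  dir <- ifelse(fdr > fdr_de, "ns", ifelse(fit$coef >= 0, "up", "down"))
  out <- data.frame(gene = rownames(lcpm$values), logFC = fit$coef,
                    t = t, p = p, fdr = fdr, direction = dir,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flatten isoform exons into disjoint counting bins
#'
#' Splits overlapping exons from different isoforms of a gene at every exon
#' boundary, producing disjoint bins that cover the union of the input
#' exons; bins are numbered in 5'-to-3' (ascending-coordinate) order.
#'
#' @param gene_models data.frame with columns \code{gene, isoform, start,
#'   end} (1-based inclusive, one chromosome per gene).
#' @return data.frame with \code{gene, bin, start, end}.
#' @export
flatten_exons <- function(gene_models) {
  need <- c("gene", "isoform", "start", "end")
  stopifnot(all(need %in% names(gene_models)))
  out <- lapply(split(gene_models, gene_models$gene), function(gm) {
    for (iso in split(gm, gm$isoform)) {
      ir <- IRanges::IRanges(iso$start, iso$end)
      if (sum(IRanges::width(IRanges::reduce(ir))) < sum(IRanges::width(ir)))
        stop("overlapping exons within isoform '", iso$isoform[1L],
             "' of gene '", gm$gene[1L], "'")
    }
    bins <- IRanges::disjoin(IRanges::IRanges(gm$start, gm$end))
    data.frame(gene = gm$gene[1L], bin = seq_along(bins),
               start = IRanges::start(bins), end = IRanges::end(bins),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

exon_gene_of <- function(ids) sub(":[^:]*$", "", ids)

#' Relative exonic usage
#'
#' For exon-level log-CPM values x, the relative usage of exon i within its
#' gene is \code{rel_i = log2(2^x_i / sum_j 2^x_j)} over the gene's exons,
#' so per gene \code{sum_j 2^rel_j = 1}. Single-exon genes get rel = 0 (with
#' a warning), as forced by the formula.
#'
#' @param exon_lcpm A [log_cpm()] object over exon bins with ids of the
#'   form \code{gene:bin}.
#' @return Matrix of relative usages, same shape as the input values.
#' @export
relative_exon_usage <- function(exon_lcpm) {
  x <- exon_lcpm$values
  gene <- exon_gene_of(rownames(x))
  pow <- 2^x
  tot <- rowsum(pow, gene)
  if (any(table(gene) == 1L))
    warning("gene(s) with a single exon: relative usage is identically 0")
  rel <- log2(pow / tot[gene, , drop = FALSE])
  dimnames(rel) <- dimnames(x)
  rel
}

#' Simes combination of per-feature p-values
#'
#' \code{min_k (m * p_(k) / k)} over the ordered p-values, capped at 1.
#'
#' @param p Numeric vector of p-values.
#' @return The Simes combined p-value.
#' @export
simes_p <- function(p) {
  p <- sort(p)
  m <- length(p)
  min(1, min(m * p / seq_len(m)))
}

#' Differential exon usage with gene-level Simes combination
#'
#' Fits the moderated linear model at the exon level, then tests whether
#' exonic log fold changes differ within a gene: each exon's usage logFC
#' is its logFC minus the mean logFC of the gene's other exons, with a
#' moderated t-test per exon; an F-test for heterogeneity of exon logFCs
#' per gene; and the Simes combination of the per-exon p-values into a
#' genewise p, BH-adjusted across genes.
#'
#' @param exon_lcpm A [log_cpm()] object over exon bins (\code{gene:bin} ids).
#' @param covariates Metadata columns to adjust for.
#' @param prior_df Prior degrees of freedom for variance moderation.
#' @return List with \code{exons} (exon, gene, bin, usage_logFC, t, p) and
#'   \code{genes} (gene, n_exons, F, F_p, simes_p, simes_fdr). Genes with a
#'   single exon are skipped with a message.
#' @export
test_exon_usage <- function(exon_lcpm, covariates = NULL, prior_df = 4) {
  stopifnot(inherits(exon_lcpm, "log_cpm"))
  X <- build_design(exon_lcpm$samples, covariates)
  fit <- lm_fit_moderated(exon_lcpm$values, X, "group", prior_df)
  ids <- rownames(exon_lcpm$values)
  gene <- exon_gene_of(ids)
  nex <- table(gene)
  skipped <- names(nex)[nex < 2L]
  if (length(skipped))
    message(length(skipped), " gene(s) with < 2 exons skipped")

  exon_rows <- list(); gene_rows <- list()
  for (g in names(nex)[nex >= 2L]) {
    sel <- which(gene == g)
    b <- fit$coef[sel]
    se <- fit$se[sel]
    k <- length(sel)
    usage <- (b - (sum(b) - b) / (k - 1))
    vuse <- se^2 + (rep(sum(se^2), k) - se^2) / (k - 1)^2
    tt <- usage / sqrt(vuse)
    pp <- 2 * stats::pt(-abs(tt), df = fit$df)
    w <- 1 / se^2
    wm <- sum(w * b) / sum(w)
    Fstat <- sum(w * (b - wm)^2) / (k - 1)
    Fp <- stats::pf(Fstat, k - 1, fit$df, lower.tail = FALSE)
    exon_rows[[g]] <- data.frame(exon = ids[sel], gene = g,
                                 bin = sub("^.*:", "", ids[sel]),
                                 usage_logFC = usage, t = tt, p = pp,
                                 stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(gene = g, n_exons = k, F = Fstat, F_p = Fp,
                                 simes_p = simes_p(pp), stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  genes <- do.call(rbind, gene_rows)
  rownames(exons) <- rownames(genes) <- NULL
  genes$simes_fdr <- stats::p.adjust(genes$simes_p, "BH")
  list(exons = exons, genes = genes)
}
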