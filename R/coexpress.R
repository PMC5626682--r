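#' Signed co-expression adjacency
#'
#' \code{a_ij = ((1 + cor_ij) / 2)^beta}: perfectly anti-correlated genes
#' get adjacency 0, so correlation sign is preserved in the network.
#'
#' @param lcpm A [log_cpm()] object.
#' @param soft_power Soft-threshold exponent beta (>= 1).
#' @param correlation "pearson" or "spearman".
#' @return Symmetric gene x gene adjacency matrix in [0, 1].
#' @export
signed_adjacency <- function(lcpm, soft_power = 12,
                             correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  stopifnot(soft_power >= 1)
  cc <- stats::cor(t(lcpm$values), method = correlation)
  ((1 + cc) / 2)^soft_power
}

# Topological overlap dissimilarity of a signed adjacency (diagonal ignored).
tom_dissimilarity <- function(A) {
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  1 - tom
}

#' Detect signed co-expression modules
#'
#' Builds the signed adjacency, converts it to topological-overlap
#' dissimilarity, clusters by average-linkage hierarchical clustering with
#' a single static tree cut at \code{merge_height}, and drops clusters
#' smaller than \code{min_module_size} to the unassigned label 0. Modules
#' are labelled 1, 2, ... in decreasing size order. Constant-expression
#' genes are removed with a warning (their correlation is undefined).
#'
#' @param lcpm A [log_cpm()] object (>= 8 samples).
#' @param soft_power,correlation Passed to [signed_adjacency()].
#' @param min_module_size Smallest cluster retained as a module.
#' @param merge_height Static cut height on TOM dissimilarity in (0, 1].
#' @return A list of class \code{"module_set"}: \code{labels} (named
#'   integer, 0 = unassigned), \code{eigengenes} (module x sample, each
#'   row unit-norm), \code{kme} and \code{mmp} (gene x module Spearman
#'   correlation and its two-sided p), \code{k_in} (intramodular
#'   connectivity), and the adjacency.
#' @export
detect_modules <- function(lcpm, soft_power = 12,
                           correlation = c("pearson", "spearman"),
                           min_module_size = 30, merge_height = 0.99) {
  stopifnot(inherits(lcpm, "log_cpm"))
  if (ncol(lcpm$values) < 8) stop("need >= 8 samples for module detection")
  sds <- apply(lcpm$values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) removed")
    lcpm$values <- lcpm$values[sds > 0, , drop = FALSE]
  }
  A <- signed_adjacency(lcpm, soft_power, correlation)
  diss <- tom_dissimilarity(A)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = merge_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(raw))
  names(labels) <- rownames(lcpm$values)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  }
  me <- module_eigengene(lcpm, labels)
  mm <- module_membership(lcpm, me)
  k_in <- numeric(length(labels))
  names(k_in) <- names(labels)
  for (m in setdiff(unique(labels), 0L)) {
    sel <- which(labels == m)
    sub <- A[sel, sel, drop = FALSE]
    k_in[sel] <- rowSums(sub) - diag(sub)
  }
  structure(list(labels = labels, eigengenes = me, kme = mm$kme,
                 mmp = mm$mmp, k_in = k_in, adjacency = A,
                 params = list(soft_power = soft_power,
                               correlation = correlation,
                               min_module_size = min_module_size,
                               merge_height = merge_height)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sz <- table(x$labels[x$labels > 0])
  cat(sprintf("module_set: %d genes, %d modules (sizes: %s), %d unassigned\n",
              length(x$labels), length(sz), paste(sz, collapse = ", "),
              sum(x$labels == 0)))
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' module's standardized gene x sample expression block (each gene scaled
#' to mean 0, sd 1 across samples), sign-oriented so that its correlation
#' with the module's average standardized profile is positive. Rows are
#' unit-norm. A single-gene module's eigengene is that gene's standardized
#' profile (normalized).
#'
#' @param lcpm A [log_cpm()] object.
#' @param labels Named integer module labels (0 = unassigned, skipped).
#' @return Matrix module x sample; rownames \code{M1, M2, ...}.
#' @export
module_eigengene <- function(lcpm, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  ns <- ncol(lcpm$values)
  if (!length(mods))
    return(matrix(numeric(0), 0, ns,
                  dimnames = list(NULL, colnames(lcpm$values))))
  me <- matrix(0, length(mods), ns,
               dimnames = list(paste0("M", mods), colnames(lcpm$values)))
  for (i in seq_along(mods)) {
    block <- lcpm$values[names(labels)[labels == mods[i]], , drop = FALSE]
    std <- t(scale(t(block)))
    if (nrow(std) == 1L) {
      v <- std[1L, ] / sqrt(sum(std[1L, ]^2))
    } else {
      v <- svd(std, nu = 0, nv = 1)$v[, 1L]
    }
    avg <- colMeans(std)
    if (stats::cor(v, avg) < 0) v <- -v
    me[i, ] <- v
  }
  me
}

#' Module membership: kME and membership p-values
#'
#' kME is the Spearman correlation of each gene's profile with each module
#' eigengene; the module-membership p-value (MMP) is the two-sided
#' significance of that correlation, by the t approximation with n - 2
#' degrees of freedom (an exact Spearman p is used when n <= 10).
#' Membership is computed for all genes in the network against every
#' eigengene.
#'
#' @param lcpm A [log_cpm()] object (>= 4 samples).
#' @param eigengenes Matrix from [module_eigengene()].
#' @return List with matrices \code{kme} and \code{mmp} (gene x module).
#' @export
module_membership <- function(lcpm, eigengenes) {
  n <- ncol(lcpm$values)
  if (n < 4) stop("need >= 4 samples for a usable Spearman p-value")
  if (nrow(eigengenes) == 0)
    return(list(kme = matrix(0, nrow(lcpm$values), 0),
                mmp = matrix(0, nrow(lcpm$values), 0)))
  rg <- t(apply(lcpm$values, 1, rank))
  re <- t(apply(eigengenes, 1, rank))
  kme <- stats::cor(t(rg), t(re))
  dimnames(kme) <- list(rownames(lcpm$values), rownames(eigengenes))
  if (n <= 10) {
    mmp <- kme
    for (g in seq_len(nrow(kme))) for (m in seq_len(ncol(kme)))
      mmp[g, m] <- suppressWarnings(stats::cor.test(
        lcpm$values[g, ], eigengenes[m, ], method = "spearman")$p.value)
  } else {
    r <- pmin(pmax(kme, -1 + 1e-12), 1 - 1e-12)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    mmp <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(kme = kme, mmp = mmp)
}

#' Hub genes by intramodular connectivity
#'
#' Ranks a module's genes by \code{k_in(i) = sum_{j in module, j != i}
#' a_ij} (descending; ties broken lexicographically by gene id).
#'
#' @param modules A \code{module_set}.
#' @param module Module id (integer as in \code{labels}).
#' @param top_n Number of genes to return; if larger than the module, the
#'   whole module is returned with a warning.
#' @return data.frame with \code{gene, k_in} in rank order.
#' @export
hub_genes <- function(modules, module, top_n = 20) {
  sel <- names(modules$labels)[modules$labels == module]
  if (!length(sel)) stop("module ", module, " does not exist")
  if (top_n > length(sel)) {
    warning("top_n exceeds module size; returning the whole module")
    top_n <- length(sel)
  }
  k <- modules$k_in[sel]
  ord <- order(-k, sel)
  data.frame(gene = sel[ord][seq_len(top_n)],
             k_in = unname(k[ord][seq_len(top_n)]),
             stringsAsFactors = FALSE)
}
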