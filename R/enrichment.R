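#' Exact hypergeometric p-value for a 2x2 overlap table
#'
#' One-sided: \code{P[X >= k]} where X is hypergeometric with \code{n_sig}
#' marked genes among \code{N}, drawing \code{n_tgt}. Two-sided: the sum
#' of the probabilities of all tables with the same margins whose
#' probability does not exceed the observed one (the "minlike" convention
#' of the standard exact test), with a relative tolerance of 1e-7 on the
#' comparison. Vectorized over \code{k}.
#'
#' @param k Observed overlap count(s).
#' @param n_sig,n_tgt,N Fixed margins: signature size, target size,
#'   universe size.
#' @param sided \code{"two"} or \code{"one_greater"}.
#' @return Numeric vector of p-values.
#' @export
hypergeom_p <- function(k, n_sig, n_tgt, N, sided = c("two", "one_greater")) {
  sided <- match.arg(sided)
  if (sided == "one_greater")
    return(stats::phyper(k - 1, n_sig, N - n_sig, n_tgt, lower.tail = FALSE))
  lo <- max(0L, n_sig + n_tgt - N)
  hi <- min(n_sig, n_tgt)
  if (any(k < lo | k > hi))
    stop("overlap k outside the feasible range [", lo, ", ", hi,
         "] for the given margins")
  support <- lo:hi
  d <- stats::dhyper(support, n_sig, N - n_sig, n_tgt)
  ds <- sort(d)
  cd <- cumsum(ds)
  obs <- d[match(k, support)]
  idx <- findInterval(obs * (1 + 1e-7), ds)
  pmin(1, cd[pmax(idx, 1L)])
}

#' Fisher-exact projection of gene signatures onto target sets
#'
#' For every signature x target pair, counts the 2x2 overlap within the
#' gene universe and computes the exact hypergeometric p-value: one-sided
#' \code{P[X >= k]} for over-representation, or two-sided by summing the
#' probabilities of all tables at most as probable as the observed one.
#' The odds ratio is \code{(k * d) / (b * c)} on the 2x2, with a Haldane
#' 0.5 correction applied only when a zero cell would make it undefined
#' (the correction never affects the p-value). Fold enrichment is
#' \code{k * N / (n_sig * n_tgt)}. BH FDR is computed jointly across all
#' records of the call.
#'
#' @param signatures Named list of character vectors (or one vector).
#' @param targets Named list of character vectors (e.g. module gene lists,
#'   DEG classes).
#' @param universe Character vector: the background gene set; signatures
#'   and targets are intersected with it before counting.
#' @param sided \code{"two"} or \code{"one_greater"}.
#' @return data.frame of class \code{"enrichment_records"} with columns
#'   signature, target, k, n_sig, n_tgt, N, odds_ratio, fold_enrichment,
#'   p, fdr.
#' @export
fisher_projection <- function(signatures, targets, universe,
                              sided = c("two", "one_greater")) {
  sided <- match.arg(sided)
  if (!is.list(signatures)) signatures <- list(signature = signatures)
  if (!is.list(targets)) targets <- list(target = targets)
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  rows <- list()
  for (sn in names(signatures)) {
    sig <- intersect(signatures[[sn]], universe)
    if (!length(sig))
      stop("signature '", sn, "' is empty after intersection with the universe")
    for (tn in names(targets)) {
      tgt <- intersect(targets[[tn]], universe)
      k <- length(intersect(sig, tgt))
      n_sig <- length(sig); n_tgt <- length(tgt)
      b <- n_sig - k; cc <- n_tgt - k; d <- N - n_sig - n_tgt + k
      p <- hypergeom_p(k, n_sig, n_tgt, N, sided)
      if (k == 0 || b == 0 || cc == 0 || d == 0) {
        or <- ((k + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        or <- (k * d) / (b * cc)
      }
      fold <- if (n_tgt > 0) k * N / (n_sig * n_tgt) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sn, target = tn, k = k, n_sig = n_sig, n_tgt = n_tgt,
        N = N, odds_ratio = or, fold_enrichment = fold, p = min(1, p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Classify enrichment records as over / under / not significant
#'
#' \code{over} iff fold enrichment strictly exceeds \code{over_fold} at
#' \code{fdr < fdr_cut}; \code{under} iff fold is strictly below
#' \code{under_fold} at the same FDR; otherwise \code{ns}. Boundary values
#' (fold exactly at a cutoff) are \code{ns}.
#'
#' @param records From [fisher_projection()].
#' @param over_fold,under_fold Fold cutoffs (defaults 2 and 0.6).
#' @param fdr_cut FDR threshold (default 0.01).
#' @return The records with a \code{call} column added.
#' @export
classify_enrichment <- function(records, over_fold = 2, under_fold = 0.6,
                                fdr_cut = 0.01) {
  records$call <- ifelse(
    records$fdr < fdr_cut & records$fold_enrichment > over_fold, "over",
    ifelse(records$fdr < fdr_cut & records$fold_enrichment < under_fold,
           "under", "ns"))
  records
}

#' Capped FDR-score transform
#'
#' Maps each two-sided enrichment record to a signed score:
#' \code{-log2(FDR)} for over-enrichment (odds ratio > 1), \code{log2(FDR)}
#' for under-enrichment (odds ratio < 1), 0 whenever FDR > \code{alpha}
#' (default 0.05), with absolute value capped at \code{cap} (default 50).
#' FDR = 0 maps to the cap with the appropriate sign; a significant record
#' with odds ratio exactly 1 has no direction and scores 0.
#'
#' @param records From [fisher_projection()] (two-sided).
#' @param cap Maximum absolute score.
#' @param alpha Significance threshold above which scores are zeroed.
#' @return The records with an \code{fdr_score} column added.
#' @export
fdr_score <- function(records, cap = 50, alpha = 0.05) {
  stopifnot(cap > 0)
  s <- sign(records$odds_ratio - 1)
  mag <- ifelse(records$fdr <= 0, cap, pmin(cap, -log2(records$fdr)))
  records$fdr_score <- ifelse(records$fdr > alpha, 0, s * mag)
  records
}

#' Reshape scored records into a signature x target matrix
#' @param records Records with an \code{fdr_score} column.
#' @return Numeric matrix, signatures as rows, targets as columns.
#' @export
fdr_score_matrix <- function(records) {
  sigs <- unique(records$signature)
  tgts <- unique(records$target)
  m <- matrix(0, length(sigs), length(tgts), dimnames = list(sigs, tgts))
  for (i in seq_len(nrow(records)))
    m[records$signature[i], records$target[i]] <- records$fdr_score[i]
  m
}
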