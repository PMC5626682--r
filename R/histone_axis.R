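#' Rank genes along a differential-expression axis
#'
#' Orders the DE-tested universe along one axis for mark-track
#' visualization. The default mode \code{"signed_significance"} sorts by
#' \code{sign(logFC) * (-log10 fdr)} ascending (most significant
#' down-regulated genes at the left end, most significant up-regulated at
#' the right), ties broken by logFC then gene id. Mode
#' \code{"literal_blocks"} places genes with logFC >= 0 first, ranked
#' ascending by \code{-log10 fdr}, followed by genes with logFC < 0 ranked
#' descending.
#'
#' @param de A \code{de_result} data.frame from [fit_de()].
#' @param order_mode \code{"signed_significance"} or \code{"literal_blocks"}.
#' @return A list of class \code{"ranked_axis"}: \code{genes} (ordered),
#'   \code{logFC}, \code{fdr}, \code{neglog10_fdr}, \code{direction}.
#' @export
rank_genes <- function(de, order_mode = c("signed_significance", "literal_blocks")) {
  order_mode <- match.arg(order_mode)
  if (any(!is.finite(de$fdr))) stop("non-finite FDR in DE results")
  nl <- -log10(pmax(de$fdr, .Machine$double.xmin))
  ord <- if (order_mode == "signed_significance") {
    s <- sign(de$logFC) * nl
    order(s, de$logFC, de$gene)
  } else {
    up <- de$logFC >= 0
    c(which(up)[order(nl[up], de$gene[up])],
      which(!up)[order(-nl[!up], de$gene[!up])])
  }
  structure(list(genes = de$gene[ord], logFC = de$logFC[ord],
                 fdr = de$fdr[ord], neglog10_fdr = nl[ord],
                 direction = de$direction[ord], order_mode = order_mode),
            class = "ranked_axis")
}

#' Binary mark track along a ranked axis
#'
#' @param axis A \code{ranked_axis}.
#' @param signature Character vector of marked genes.
#' @return Integer vector: 1 where the axis gene is in the signature.
#' @export
mark_track <- function(axis, signature) {
  as.integer(axis$genes %in% signature)
}

#' Sliding-window mean of a binary track
#'
#' \code{curve[i]} is the mean of the track over positions
#' \code{[i - flank, i + flank]}, truncated at the track ends; interior
#' windows contain exactly \code{2 * flank + 1} entries. With the default
#' flank of 100 the interior window spans 201 genes.
#'
#' @param track Numeric/binary vector (length >= 2).
#' @param flank Flanking positions on each side (>= 1).
#' @return Numeric vector of window means, same length as the track.
#' @export
sliding_window_curve <- function(track, flank = 100) {
  L <- length(track)
  if (L < 2) stop("track must have length >= 2")
  stopifnot(flank >= 1)
  cs <- cumsum(c(0, track))
  i <- seq_len(L)
  lo <- pmax(i - flank, 1L)
  hi <- pmin(i + flank, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' One-sided enrichment of a signature among up-regulated genes
#'
#' Takes the up-DEG set from the axis direction calls and delegates to
#' [fisher_projection()] with the one-sided "greater" alternative against
#' the axis universe.
#'
#' @param axis A \code{ranked_axis}.
#' @param signature Character vector of marked genes.
#' @param name Signature label for the output record.
#' @return A one-row \code{enrichment_records} data.frame.
#' @export
axis_enrichment <- function(axis, signature, name = "signature") {
  up <- axis$genes[axis$direction == "up"]
  sigs <- list(signature)
  names(sigs) <- name
  fisher_projection(sigs, list(up_deg = up), axis$genes,
                    sided = "one_greater")
}

#' Assemble the full axis table (tracks and curves per signature)
#'
#' @param axis A \code{ranked_axis}.
#' @param signatures Named list of gene sets.
#' @param flank Sliding-window flank.
#' @return data.frame: gene, logFC, fdr, direction, then one track and one
#'   curve column per signature.
#' @export
axis_table <- function(axis, signatures, flank = 100) {
  out <- data.frame(gene = axis$genes, logFC = axis$logFC, fdr = axis$fdr,
                    neglog10_fdr = axis$neglog10_fdr,
                    direction = axis$direction, stringsAsFactors = FALSE)
  for (nm in names(signatures)) {
    tr <- mark_track(axis, signatures[[nm]])
    out[[paste0("track_", nm)]] <- tr
    out[[paste0("curve_", nm)]] <- sliding_window_curve(tr, flank)
  }
  out
}
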