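#' Per-sample somatic variant burden
#'
#' Counts protein-altering somatic variants per sample (samples with zero
#' variants still count toward the denominator) and reports the cohort
#' mean rounded to one decimal, e.g. 278 variants over 26 exomes gives
#' 10.7 per exome.
#'
#' @param variants data.frame with columns \code{sample} and
#'   \code{somatic} (logical).
#' @param samples Character vector of all cohort samples (defines the
#'   denominator).
#' @return List: \code{per_sample} (named counts), \code{total},
#'   \code{mean} (exact), \code{mean_reported} (1 decimal).
#' @export
variant_burden <- function(variants, samples) {
  stopifnot(length(samples) >= 1)
  v <- variants[variants$somatic, , drop = FALSE]
  counts <- stats::setNames(integer(length(samples)), samples)
  if (nrow(v)) {
    tb <- table(factor(v$sample, levels = samples))
    counts[names(tb)] <- as.integer(tb)
  }
  total <- sum(counts)
  list(per_sample = counts, total = total,
       mean = total / length(samples),
       mean_reported = round(total / length(samples), 1))
}

#' Recurrently mutated genes
#'
#' Genes mutated in at least \code{min_samples} distinct samples (a gene
#' hit twice in one sample counts once). Somatic variants only unless
#' \code{include_germline = TRUE}.
#'
#' @param variants data.frame with \code{sample, gene, somatic}.
#' @param min_samples Minimum distinct mutated samples (default 2).
#' @param include_germline Also count non-somatic variants.
#' @return data.frame \code{gene, n_samples}, descending count.
#' @export
recurrent_genes <- function(variants, min_samples = 2,
                            include_germline = FALSE) {
  v <- if (include_germline) variants else
    variants[variants$somatic, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(gene = character(), n_samples = integer()))
  u <- unique(v[, c("gene", "sample")])
  tb <- table(u$gene)
  tb <- tb[tb >= min_samples]
  out <- data.frame(gene = names(tb), n_samples = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of a gene list in an annotation set
#'
#' One-sided Fisher projection of a flagged gene list (e.g. recurrently
#' mutated genes) onto an annotation panel (e.g. a curated
#' epigenetic-regulator database) within a gene universe. Thin wrapper
#' over [fisher_projection()].
#'
#' @param genes Character vector of flagged genes.
#' @param annotation Character vector: the annotation set.
#' @param universe Background gene universe.
#' @return A one-row \code{enrichment_records} data.frame.
#' @export
geneset_fisher <- function(genes, annotation, universe) {
  fisher_projection(list(flagged = genes), list(annotation = annotation),
                    universe, sided = "one_greater")
}

#' Panel coverage by variants and/or CNV segments
#'
#' A sample "hits" a panel gene if it carries a variant in that gene or a
#' gain/loss/cnLOH segment overlapping the gene's coordinates. Returns the
#' sample x gene hit matrix and the fraction of samples with at least one
#' hit, reported as an integer percent with round-half-up (22 of 26 gives
#' 85\%).
#'
#' @param variants data.frame with \code{sample, gene}.
#' @param segments A \code{segment_table} (classes other than
#'   gain/loss/cnLOH are ignored).
#' @param gene_coords data.frame \code{gene, chrom, start, end} (1-based
#'   inclusive) for every panel gene.
#' @param panel Character vector of panel genes.
#' @param samples Character vector of all cohort samples.
#' @return List: \code{hits} (logical sample x gene matrix),
#'   \code{n_hit}, \code{fraction}, \code{percent} (integer).
#' @export
epigene_coverage <- function(variants, segments, gene_coords, panel, samples) {
  miss <- setdiff(panel, gene_coords$gene)
  if (length(miss))
    stop("panel gene(s) without coordinates: ", paste(miss, collapse = ", "))
  hits <- matrix(FALSE, length(samples), length(panel),
                 dimnames = list(samples, panel))
  v <- variants[variants$gene %in% panel & variants$sample %in% samples, ,
                drop = FALSE]
  if (nrow(v)) hits[cbind(v$sample, v$gene)] <- TRUE
  seg <- segments[segments$class %in% c("gain", "loss", "cnLOH") &
                    segments$sample %in% samples, , drop = FALSE]
  if (nrow(seg)) {
    for (g in panel) {
      gc <- gene_coords[gene_coords$gene == g, ][1L, ]
      ov <- seg$chrom == gc$chrom & seg$start <= gc$end & seg$end >= gc$start
      if (any(ov)) hits[unique(seg$sample[ov]), g] <- TRUE
    }
  }
  n_hit <- sum(rowSums(hits) > 0)
  frac <- n_hit / length(samples)
  list(hits = hits, n_hit = n_hit, fraction = frac,
       percent = as.integer(floor(100 * frac + 0.5)))
}

#' Copy-number recurrence track
#'
#' Tiles each chromosome into fixed-width bins and, per bin and CNV class
#' (gain, loss, cnLOH), reports the fraction of samples with at least one
#' overlapping segment of that class (any overlap of >= 1 bp counts; a
#' sample counts once per bin per class).
#'
#' @param segments A \code{segment_table}.
#' @param n_samples Cohort size (denominator).
#' @param bin Bin width in bp (default 1 Mb).
#' @param chrom_lengths Named vector of chromosome lengths
#'   (default [default_chrom_lengths()]).
#' @return data.frame: chrom, start, end (1-based inclusive bins), gain,
#'   loss, cnLOH (fractions in [0, 1]).
#' @export
cnv_recurrence_track <- function(segments, n_samples, bin = 1e6,
                                 chrom_lengths = default_chrom_lengths()) {
  classes <- c("gain", "loss", "cnLOH")
  seg <- segments[segments$class %in% classes, , drop = FALSE]
  bad <- !(seg$chrom %in% names(chrom_lengths))
  if (any(bad)) stop("segment on unknown chromosome: ",
                     paste(unique(seg$chrom[bad]), collapse = ", "))
  over <- seg$end > chrom_lengths[seg$chrom]
  if (any(over))
    stop("segment beyond chromosome length at row ", which(over)[1L])
  rows <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[ch]], by = bin)
    ends <- pmin(starts + bin - 1, chrom_lengths[[ch]])
    tab <- data.frame(chrom = ch, start = starts, end = ends,
                      gain = 0, loss = 0, cnLOH = 0,
                      stringsAsFactors = FALSE)
    sc <- seg[seg$chrom == ch, , drop = FALSE]
    for (cl in classes) {
      s <- sc[sc$class == cl, , drop = FALSE]
      if (!nrow(s)) next
      for (b in seq_along(starts)) {
        ov <- s$start <= ends[b] & s$end >= starts[b]
        tab[[cl]][b] <- length(unique(s$sample[ov])) / n_samples
      }
    }
    rows[[ch]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
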