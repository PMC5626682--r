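#' Read a count matrix with sample metadata
#'
#' The count file is TSV with feature identifiers (genes or exon bins) in
#' the first column and one column per sample. The metadata file is TSV
#' with one row per sample and at least the columns \code{sample} and
#' \code{group}; further columns (e.g. \code{sex}, \code{platform}) are
#' carried along as covariates. Metadata rows are reordered to match the
#' count-matrix column order.
#'
#' @param path Path to the counts TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return A list of class \code{"count_data"} with elements
#'   \code{counts} (numeric matrix, features x samples) and
#'   \code{samples} (data.frame aligned to the columns of \code{counts}).
#' @export
read_counts <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("counts file needs an id column plus >= 1 sample")
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature identifiers: ", paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("count at row '%s', column '%s' is not a nonnegative integer",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  for (col in c("sample", "group"))
    if (!col %in% names(meta)) stop("metadata lacks required column '", col, "'")
  missing <- setdiff(colnames(m), meta$sample)
  if (length(missing))
    stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = m, samples = meta), class = "count_data")
}

count_data <- function(counts, samples) {
  stopifnot(is.matrix(counts), ncol(counts) == nrow(samples),
            all(colnames(counts) == samples$sample))
  structure(list(counts = counts, samples = samples), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("count_data: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))), collapse = ", ")))
  invisible(x)
}

#' Write a count_data bundle to TSV files
#'
#' Inverse of [read_counts()]; round-trips exactly.
#'
#' @param x A \code{count_data} object.
#' @param path,metadata_path Output paths for the counts and metadata TSVs.
#' @export
write_counts <- function(x, path, metadata_path) {
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' Each GMT line is: name, description, then tab-separated member genes.
#' Members are deduplicated; empty signatures and duplicated names are
#' rejected.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per signature).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT signature '", parts[1L], "' has an empty member list")
    nm <- parts[1L]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT signature '", nm, "' has an empty member list")
    if (nm %in% names(sets)) stop("duplicated signature name '", nm, "'")
    sets[[nm]] <- members
  }
  sets
}

#' Write gene signatures to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read per-sample per-locus allele counts
#'
#' TSV with columns \code{chrom, pos, ref, alt, sample, group, ref_count,
#' alt_count}; positions are 1-based; alleles must be single uppercase
#' A/C/G/T and ref must differ from alt.
#'
#' @param path Path to the allele-count TSV.
#' @return A data.frame of class \code{"allele_counts"}.
#' @export
read_allele_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          sample = "character",
                                          group = "character"))
  need <- c("chrom", "pos", "ref", "alt", "sample", "group",
            "ref_count", "alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("allele counts lack column(s): ", paste(miss, collapse = ", "))
  validate_allele_counts(tab)
}

validate_allele_counts <- function(tab) {
  bad <- !(tab$ref %in% c("A", "C", "G", "T")) | !(tab$alt %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-ACGT allele at row ", which(bad)[1L])
  if (any(tab$ref == tab$alt))
    stop("ref equals alt at row ", which(tab$ref == tab$alt)[1L])
  cnt <- c(tab$ref_count, tab$alt_count)
  if (any(!is.finite(cnt) | cnt < 0 | cnt != round(cnt)))
    stop("allele counts must be nonnegative integers")
  class(tab) <- c("allele_counts", "data.frame")
  tab
}

#' Read copy-number segments (SEG)
#'
#' TSV with columns \code{sample, chrom, start, end, class, log2ratio};
#' coordinates 1-based inclusive; class one of gain, loss, cnLOH, normal,
#' undecided. Overlapping segments within a sample are allowed and
#' retained.
#'
#' @param path Path to the SEG file.
#' @return A data.frame of class \code{"segment_table"}.
#' @export
read_segments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "chrom", "start", "end", "class", "log2ratio")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("segment table lacks column(s): ", paste(miss, collapse = ", "))
  known <- c("gain", "loss", "cnLOH", "normal", "undecided")
  bad <- setdiff(unique(tab$class), known)
  if (length(bad)) stop("unknown segment class: ", paste(bad, collapse = ", "))
  if (any(tab$start > tab$end))
    stop("segment with start > end at row ", which(tab$start > tab$end)[1L])
  class(tab) <- c("segment_table", "data.frame")
  tab
}

#' Read a BED3 region mask
#'
#' BED intervals are 0-based half-open. Intervals are sorted and merged per
#' chromosome on read, so the mask is always in canonical form.
#'
#' @param path Path to a BED3 file (may be empty: no site is excluded).
#' @return A data.frame of class \code{"region_mask"} with columns
#'   \code{chrom, start, end} (0-based half-open).
#' @export
read_mask <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(region_mask(data.frame(chrom = character(), start = numeric(),
                                  end = numeric())))
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED mask needs >= 3 columns")
  region_mask(data.frame(chrom = as.character(tab[[1L]]),
                         start = as.numeric(tab[[2L]]),
                         end = as.numeric(tab[[3L]])))
}

#' Construct a region mask from intervals
#' @param df data.frame with chrom, start, end (0-based half-open).
#' @return Merged, sorted \code{region_mask}.
#' @export
region_mask <- function(df) {
  if (nrow(df) && any(df$start >= df$end))
    stop("mask interval with start >= end at row ", which(df$start >= df$end)[1L])
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_mask", "data.frame")
  out
}

#' Test positions for mask membership
#' @param mask A \code{region_mask}.
#' @param chrom,pos Vectors of chromosome labels and 1-based positions.
#' @return Logical vector: TRUE where the position falls in the mask.
#' @export
in_mask <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    mi <- mask[mask$chrom == ch, , drop = FALSE]
    if (!nrow(mi)) next
    sel <- chrom == ch
    ir <- IRanges::IRanges(start = mi$start + 1, end = mi$end)
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

# TSV writer for pipeline outputs: '#' header lines record provenance.
write_stage_tsv <- function(df, path, cfg = NULL, stage = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(sprintf("# intgen %s stage=%s config=%s seed=%d",
                       as.character(utils::packageVersion("intgen")),
                       stage %||% "NA", config_hash(cfg), cfg$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
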