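pipeline_stages <- c("simulate", "de", "splice", "network", "project",
                     "axis", "ase", "burden", "cnv_tracks")

stage_needs <- list(
  de = "counts.tsv", splice = "exon_counts.tsv", network = "counts.tsv",
  project = c("modules.tsv", "de_results.tsv", "signatures.gmt"),
  axis = c("de_results.tsv", "signatures.gmt"),
  ase = "allele_counts.tsv", burden = "variants.tsv",
  cnv_tracks = "segments.seg")

require_inputs <- function(outdir, stage) {
  for (f in stage_needs[[stage]] %||% character()) {
    if (!file.exists(file.path(outdir, f))) {
      producer <- if (f %in% c("modules.tsv")) "network"
      else if (f %in% c("de_results.tsv")) "de" else "simulate"
      stop("stage '", stage, "' needs ", f, "; run stage '", producer,
           "' first")
    }
  }
}

#' Run the integrative pipeline on a synthetic study bundle
#'
#' Executes the requested stages in order: \code{simulate} writes the
#' synthetic bundle (counts, exon counts, metadata, allele counts,
#' signatures, variants, segments, truth); \code{de} and \code{splice} fit
#' the gene- and exon-level models; \code{network} detects signed
#' co-expression modules; \code{project} computes the two-sided Fisher
#' projection and FDR-score matrix of every signature onto every module;
#' \code{axis} builds the DE-ranked axis with mark tracks, sliding-window
#' curves and the one-sided up-DEG enrichment; \code{ase} estimates the
#' empirical null fraction and runs the quasi-binomial test per group;
#' \code{burden} and \code{cnv_tracks} summarize variants and segments.
#' Stages are deterministic given the configuration seed; rerunning with
#' the same seed reproduces byte-identical outputs.
#'
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stage names, or \code{"all"}.
#' @param cfg A [study_config()].
#' @param sim A [sim_config()]; defaults to one seeded from \code{cfg}.
#' @return The run manifest (invisibly), also written to
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(outdir, stages = "all", cfg = study_config(),
                         sim = sim_config(seed = cfg$seed)) {
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = stages, config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   version = as.character(utils::packageVersion("intgen")),
                   outputs = list())
  emit <- function(df, name, stage) {
    write_stage_tsv(df, file.path(outdir, name), cfg, stage)
    manifest$outputs[[name]] <<- stage
  }

  for (stage in stages) {
    require_inputs(outdir, stage)
    if (stage == "simulate") {
      expr <- simulate_expression(sim)
      exon <- simulate_exon_counts(sim)
      ase <- simulate_allele_counts(sim)
      mv <- simulate_marks_and_variants(sim, expr$truth)
      write_counts(expr$data, file.path(outdir, "counts.tsv"),
                   file.path(outdir, "metadata.tsv"))
      write_counts(exon$data, file.path(outdir, "exon_counts.tsv"),
                   file.path(outdir, "exon_metadata.tsv"))
      utils::write.table(ase$data, file.path(outdir, "allele_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_sets(mv$signatures, file.path(outdir, "signatures.gmt"))
      utils::write.table(mv$variants, file.path(outdir, "variants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(mv$segments, file.path(outdir, "segments.seg"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      file.create(file.path(outdir, "mask.bed"))
      truth <- list(de_genes = as.list(expr$truth$de_genes),
                    module_assignment = as.list(expr$truth$module_assignment),
                    splice_genes = exon$truth$splice_genes,
                    ase_signal_loci = ase$truth$signal_loci,
                    recurrent_genes = mv$truth$recurrent_genes,
                    recurrent_regions = mv$truth$recurrent_regions)
      jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      for (f in c("counts.tsv", "exon_counts.tsv", "metadata.tsv",
                  "allele_counts.tsv", "signatures.gmt", "variants.tsv",
                  "segments.seg", "truth.json", "mask.bed"))
        manifest$outputs[[f]] <- "simulate"
    } else if (stage == "de") {
      x <- read_counts(file.path(outdir, "counts.tsv"),
                       file.path(outdir, "metadata.tsv"))
      de <- fit_de(log_cpm(x), covariates = c("sex", "platform"),
                   fdr_de = cfg$fdr_de)
      emit(de, "de_results.tsv", stage)
    } else if (stage == "splice") {
      x <- read_counts(file.path(outdir, "exon_counts.tsv"),
                       file.path(outdir, "exon_metadata.tsv"))
      lc <- log_cpm(x)
      usage <- test_exon_usage(lc, covariates = c("sex", "platform"))
      emit(usage$exons, "exon_usage.tsv", stage)
      emit(usage$genes, "splice_genes.tsv", stage)
    } else if (stage == "network") {
      x <- read_counts(file.path(outdir, "counts.tsv"),
                       file.path(outdir, "metadata.tsv"))
      mods <- detect_modules(log_cpm(x), soft_power = cfg$soft_power,
                             min_module_size = cfg$min_module_size,
                             merge_height = cfg$merge_height)
      own <- paste0("M", mods$labels)
      kme_own <- mmp_own <- rep(NA_real_, length(mods$labels))
      has <- own %in% rownames(mods$eigengenes)
      idx <- cbind(names(mods$labels)[has], own[has])
      kme_own[has] <- mods$kme[idx]
      mmp_own[has] <- mods$mmp[idx]
      emit(data.frame(gene = names(mods$labels), module = mods$labels,
                      kme = kme_own, mmp = mmp_own, k_in = mods$k_in,
                      stringsAsFactors = FALSE), "modules.tsv", stage)
      emit(data.frame(module = rownames(mods$eigengenes), mods$eigengenes,
                      check.names = FALSE), "eigengenes.tsv", stage)
      if (any(mods$labels == 1L))
        emit(hub_genes(mods, 1L, min(20L, sum(mods$labels == 1L))),
             "hub_genes.tsv", stage)
    } else if (stage == "project") {
      modtab <- utils::read.delim(file.path(outdir, "modules.tsv"),
                                  comment.char = "#")
      de <- utils::read.delim(file.path(outdir, "de_results.tsv"),
                              comment.char = "#")
      sigs <- read_gene_sets(file.path(outdir, "signatures.gmt"))
      universe <- modtab$gene
      targets <- split(modtab$gene, paste0("M", modtab$module))
      targets <- targets[names(targets) != "M0"]
      targets$up_deg <- de$gene[de$direction == "up"]
      targets$down_deg <- de$gene[de$direction == "down"]
      rec <- fisher_projection(sigs, targets, universe, sided = "two")
      rec <- classify_enrichment(rec, cfg$over_fold, cfg$under_fold,
                                 cfg$fdr_de)
      rec <- fdr_score(rec, cfg$fdr_score_cap, cfg$fdr_enrich)
      emit(rec, "enrichment.tsv", stage)
      m <- fdr_score_matrix(rec)
      emit(data.frame(signature = rownames(m), m, check.names = FALSE),
           "fdr_score_matrix.tsv", stage)
    } else if (stage == "axis") {
      de <- utils::read.delim(file.path(outdir, "de_results.tsv"),
                              comment.char = "#")
      sigs <- read_gene_sets(file.path(outdir, "signatures.gmt"))
      ax <- rank_genes(de)
      emit(axis_table(ax, sigs, cfg$window_flank), "axis.tsv", stage)
      enr <- do.call(rbind, lapply(names(sigs), function(nm)
        axis_enrichment(ax, sigs[[nm]], nm)))
      enr$fdr <- stats::p.adjust(enr$p, "BH")
      emit(enr, "axis_enrichment.tsv", stage)
    } else if (stage == "ase") {
      tab <- read_allele_counts(file.path(outdir, "allele_counts.tsv"))
      mask <- read_mask(file.path(outdir, "mask.bed"))
      tab <- filter_ase_sites(tab, mask, cfg$min_ase_depth)
      res <- do.call(rbind, lapply(c("tumor", "control"), function(g) {
        p0 <- estimate_null_fraction(tab, g)
        quasibinomial_test(tab, p0, g, cfg$fdr_ase)
      }))
      emit(res, "ase_results.tsv", stage)
    } else if (stage == "burden") {
      v <- utils::read.delim(file.path(outdir, "variants.tsv"),
                             comment.char = "#")
      samples <- sprintf("tum%02d", seq_len(sim$n_samples_per_group))
      bd <- variant_burden(v, samples)
      emit(data.frame(sample = names(bd$per_sample),
                      n_variants = as.integer(bd$per_sample)),
           "burden.tsv", stage)
      emit(recurrent_genes(v), "recurrent_genes.tsv", stage)
    } else if (stage == "cnv_tracks") {
      seg <- read_segments(file.path(outdir, "segments.seg"))
      tr <- cnv_recurrence_track(seg, sim$n_samples_per_group, cfg$cnv_bin)
      emit(tr, "cnv_tracks.tsv", stage)
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
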