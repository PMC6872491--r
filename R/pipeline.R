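## End-to-end orchestration: configuration with the published decision
## constants as defaults, staged execution over a directory of samples,
## per-sample JSON reports, cohort summary and a reproducibility manifest.

#' Pipeline configuration
#'
#' All thresholds default to the published decision constants: purity QC
#' 0.20; WGD major-allele ploidy 1.5 over >= 50% of >= 11 autosomes;
#' biallelic offset 0.5; MSI score 4; amplification rings 1.4x/2x/3x sample
#' ploidy; homozygous deletion 0.5; TMB 10/Mb; SMG q 0.01; signature
#' filters 5%/300 variants; fragile sites > 500 kb with > 30% of deletions
#' sized 20 kb - 1 Mb; hotspot margin 5 nt. Overrides are recorded in the
#' run manifest.
#'
#' @param ... named overrides of any default.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    purity_qc_threshold = 0.20,
    wgd_major_threshold = 1.5,
    wgd_fraction_threshold = 0.5,
    wgd_min_autosomes = 11L,
    biallelic_offset = 0.5,
    msi_threshold = 4,
    amp_factor_low = 1.4,
    amp_factor_moderate = 2,
    amp_factor_high = 3,
    homdel_threshold = 0.5,
    tmb_threshold = 10,
    smg_q_threshold = 0.01,
    signature_min_fraction = 0.05,
    signature_min_load = 300,
    fragile_min_length = 5e5,
    fragile_min_rate = 0.3,
    fragile_size_min = 2e4,
    fragile_size_max = 1e6,
    hotspot_margin = 5L,
    subclonal_ccf = 0.85,
    loh_threshold = 0.25,
    min_clonality_variants = 50L,
    peel_min_support = 5L,
    peel_support_fraction = 0.02,
    gc_threshold = 0.25,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg$overridden <- names(ov)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full interpretation pipeline over a directory of samples
#'
#' Input layout: one subdirectory per sample as written by
#' [write_sample()]. Stages run in order: purity/ploidy fitting and QC;
#' variant annotation (MNV merging, variant ploidy, clonality);
#' MSI/TMB/signatures; cohort dN/dS, panel and copy-number peaks; driver
#' catalogue; actionability; reporting. Every stage's output is written
#' under `output_dir`, together with a run manifest carrying the config
#' hash and seeds.
#'
#' @param input_dir directory of sample subdirectories.
#' @param output_dir output directory (created).
#' @param genome a `genome_model`.
#' @param fixtures a `fixture_resources`.
#' @param config a `pipeline_config`.
#' @return invisible list of per-sample results (also written to disk).
#' @export
run_pipeline <- function(input_dir, output_dir, genome, fixtures,
                         config = pipeline_config()) {
  dirs <- list.dirs(input_dir, recursive = FALSE)
  if (!length(dirs)) stop("no sample directories found in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- .stage("load", lapply(dirs, function(d) {
    for (f in c("segments.tsv", "somatic.vcf", "truth.json"))
      if (!file.exists(file.path(d, f)))
        stop("missing input file: ", file.path(d, f))
    meta <- jsonlite::fromJSON(file.path(d, "truth.json"))
    list(dir = d,
         sample_id = meta$sample_id, patient_id = meta$patient_id,
         sex = meta$sex %||% "male", doid = as.character(meta$doid %||% NA),
         segments = read_segments(file.path(d, "segments.tsv")),
         somatic = read_somatic_vcf(file.path(d, "somatic.vcf")),
         germline = if (file.exists(file.path(d, "germline.vcf")))
           read_germline_vcf(file.path(d, "germline.vcf")) else NULL,
         svs = if (file.exists(file.path(d, "svs.tsv")))
           read_svs(file.path(d, "svs.tsv")) else NULL)
  }))

  ## stage: purity/ploidy + QC -------------------------------------------
  fits <- .stage("purity_ploidy", lapply(samples, function(s) {
    fit_purity_ploidy(s$segments, sex = s$sex,
                      n_somatic = nrow(s$somatic),
                      gc = s$segments$gc,
                      gc_threshold = config$gc_threshold)
  }))
  purity_tab <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    purity = vapply(fits, `[[`, 0, "purity"),
    ploidy = vapply(fits, `[[`, 0, "ploidy"),
    wgd = vapply(fits, `[[`, TRUE, "wgd"),
    duplicated_autosomes = vapply(fits, `[[`, 0L, "duplicated_autosomes"),
    n_somatic = vapply(samples, function(s) nrow(s$somatic), 0L),
    gc_metric = vapply(fits, `[[`, 0, "gc_metric"),
    stringsAsFactors = FALSE)
  keep <- .stage("sample_qc",
                 apply_sample_qc(purity_tab,
                                 purity_threshold = config$purity_qc_threshold,
                                 gc_threshold = config$gc_threshold))
  utils::write.table(
    merge(purity_tab,
          keep[, c("sample_id", "qc_status"), drop = FALSE],
          by = "sample_id", all.x = TRUE),
    file.path(output_dir, "purity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  idx_keep <- match(keep$sample_id, purity_tab$sample_id)
  samples <- samples[idx_keep]
  fits <- fits[idx_keep]

  ## stage: variant annotation -------------------------------------------
  ann <- .stage("variant_annotation", lapply(seq_along(samples), function(i) {
    s <- samples[[i]]; fit <- fits[[i]]
    v <- merge_mnvs(s$somatic)
    segi <- .segment_at(fit$segments, v$chrom, v$pos - 1L)
    cn <- fit$segments$cn[segi]
    cn[is.na(cn)] <- fit$ploidy
    nc <- .normal_cn(v$chrom, s$sex)
    pa <- annotate_variant_ploidy(v$vaf, fit$purity, cn, nc,
                                  config$biallelic_offset)
    v$cn <- pa$cn
    v$variant_ploidy <- pa$variant_ploidy
    v$biallelic <- pa$biallelic
    cl <- suppressWarnings(
      fit_clonality(v$variant_ploidy,
                    subclonal_ccf = config$subclonal_ccf,
                    min_variants = config$min_clonality_variants))
    v$subclonal_prob <- cl$subclonal_prob
    list(variants = v, clonality = cl)
  }))

  ## stage: MSI / TMB / signatures ---------------------------------------
  scores <- .stage("msi_tmb_signatures", lapply(seq_along(samples),
                                                function(i) {
    v <- ann[[i]]$variants
    msi <- compute_msi(v, genome, threshold = config$msi_threshold)
    tmb <- compute_tmb(v, genome, threshold = config$tmb_threshold)
    sg <- fit_signatures(context_counts(v), fixtures$signature_matrix,
                         min_fraction = config$signature_min_fraction,
                         min_load = config$signature_min_load)
    list(msi = msi, tmb = tmb, signatures = sg)
  }))

  ## stage: cohort dN/dS, panel, peaks -----------------------------------
  coding <- do.call(rbind, lapply(seq_along(samples), function(i) {
    v <- ann[[i]]$variants
    v <- v[!is.na(v$gene) & !is.na(v$consequence), , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    data.frame(sample = samples[[i]]$sample_id, gene = v$gene,
               consequence = v$consequence, context = v$context,
               stringsAsFactors = FALSE)
  }))
  dnds <- NULL
  if (!is.null(coding) && any(coding$consequence == "synonymous")) {
    dnds <- .stage("dnds", run_dnds(coding, genome,
                                    significance = config$smg_q_threshold))
  }
  curated <- fixtures$gene_panel[, c("gene", "role")]
  panel <- .stage("gene_panel",
                  build_gene_panel(dnds, curated = curated,
                                   significance = config$smg_q_threshold))
  gene_cn_all <- .stage("gene_cn", do.call(rbind, lapply(
    seq_along(samples), function(i) {
      g <- gene_exonic_cn(fits[[i]]$segments, genome)
      g$sample <- samples[[i]]$sample_id
      g$sample_ploidy <- fits[[i]]$ploidy
      g
    })))
  peaks <- .stage("cn_peaks", find_cn_peaks(
    cn_events(gene_cn_all, amp_factor = config$amp_factor_high,
              homdel_threshold = config$homdel_threshold),
    genome, n_samples = length(samples), panel_genes = panel$gene,
    min_support = config$peel_min_support,
    support_fraction = config$peel_support_fraction,
    fragile_min_length = config$fragile_min_length,
    fragile_min_rate = config$fragile_min_rate,
    fragile_size_range = c(config$fragile_size_min,
                           config$fragile_size_max)))
  utils::write.table(peaks, file.path(output_dir, "peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage: driver catalogue ---------------------------------------------
  tmbs <- vapply(scores, function(x) x$tmb$tmb, numeric(1))
  mean_tmb <- mean(tmbs)
  # genes whose included TSG variants are predominantly biallelic
  biallelic_genes <- local({
    pooled <- do.call(rbind, lapply(ann, function(a) {
      v <- a$variants
      v[!is.na(v$gene), c("gene", "biallelic"), drop = FALSE]
    }))
    tsg <- panel$gene[panel$role == "tsg"]
    pooled <- pooled[pooled$gene %in% tsg, , drop = FALSE]
    if (nrow(pooled) == 0) character(0) else {
      fr <- tapply(pooled$biallelic, pooled$gene, mean)
      names(fr)[fr > 0.5]
    }
  })
  catalogue <- .stage("driver_catalogue", do.call(rbind, lapply(
    seq_along(samples), function(i) {
      s <- samples[[i]]; fit <- fits[[i]]
      v <- ann[[i]]$variants
      pts <- call_point_drivers(v, panel, dnds, tmbs[i], mean_tmb,
                                hotspots = fixtures$hotspots,
                                biallelic_genes = biallelic_genes,
                                hotspot_margin = config$hotspot_margin)
      gcn <- gene_cn_all[gene_cn_all$sample == s$sample_id, ]
      cnf <- call_cn_and_fusion_drivers(gcn, s$svs, peaks, panel,
                                        fixtures$known_fusions, genome,
                                        fit$ploidy,
                                        amp_factor = config$amp_factor_high,
                                        homdel_threshold =
                                          config$homdel_threshold)
      germ <- call_germline_drivers(s$germline, fit$segments, v,
                                    fit$purity,
                                    panel_genes = fixtures$germline_panel,
                                    sex = s$sex,
                                    loh_threshold = config$loh_threshold)
      if (nrow(germ)) {
        germ$hotspot <- FALSE
        germ$fragile_site <- FALSE
        germ$biallelic <- germ$allele_status == "wildtype_lost" |
          germ$second_hit
        germ$subclonal_prob <- 0
        germ <- germ[, c("gene", "class", "variant", "likelihood",
                         "biallelic", "hotspot", "fragile_site",
                         "subclonal_prob")]
      } else germ <- .empty_drivers()
      msi_ev <- if (scores[[i]]$msi$status == "MSI")
        data.frame(gene = "MSI", class = "MSI", variant = "genome",
                   likelihood = 1, biallelic = FALSE, hotspot = FALSE,
                   fragile_site = FALSE, subclonal_prob = 0,
                   stringsAsFactors = FALSE) else .empty_drivers()
      out <- rbind(pts, cnf, germ, msi_ev)
      if (nrow(out)) out$sample <- s$sample_id
      out
    })))
  if (!is.null(catalogue) && nrow(catalogue))
    utils::write.table(catalogue, file.path(output_dir, "drivers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: actionability -------------------------------------------------
  action <- .stage("actionability", lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    cat_i <- if (!is.null(catalogue) && nrow(catalogue))
      catalogue[catalogue$sample == s$sample_id, , drop = FALSE]
      else .empty_drivers()
    m <- match_actionable_events(cat_i, scores[[i]]$msi$status == "MSI",
                                 fixtures$knowledgebase, s$doid,
                                 fixtures$ontology)
    rank_and_report(m)
  }))

  ## stage: report --------------------------------------------------------
  results <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    list(sample_id = s$sample_id, patient_id = s$patient_id,
         fit = fits[[i]], clonality = ann[[i]]$clonality,
         variants = ann[[i]]$variants, msi = scores[[i]]$msi,
         tmb = scores[[i]]$tmb, signatures = scores[[i]]$signatures,
         drivers = if (!is.null(catalogue) && nrow(catalogue))
           catalogue[catalogue$sample == s$sample_id, , drop = FALSE]
           else .empty_drivers(),
         actionability = action[[i]])
  })
  .stage("report", write_report(results, output_dir))

  manifest <- list(
    package_version = as.character(utils::packageVersion("somascape")),
    config = unclass(config),
    config_hash = text_md5(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE)),
    n_samples = length(samples),
    sample_ids = vapply(samples, `[[`, "", "sample_id"),
    outputs = list.files(output_dir))
  manifest$manifest_hash <- text_md5(jsonlite::toJSON(manifest,
                                                      auto_unbox = TRUE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Write per-sample JSON reports and a cohort summary TSV
#'
#' @param results list of per-sample result lists (see [run_pipeline()]).
#' @param output_dir output directory.
#' @return invisible `output_dir`.
#' @export
write_report <- function(results, output_dir) {
  dir.create(file.path(output_dir, "reports"), showWarnings = FALSE,
             recursive = TRUE)
  rows <- lapply(results, function(r) {
    drv <- r$drivers
    rep_json <- list(
      sample_id = r$sample_id, patient_id = r$patient_id,
      purity = r$fit$purity, ploidy = r$fit$ploidy, wgd = r$fit$wgd,
      duplicated_autosomes = r$fit$duplicated_autosomes,
      qc_status = r$fit$qc_status,
      msi = list(score = r$msi$score, status = r$msi$status),
      tmb = list(tmb = r$tmb$tmb, eligible = r$tmb$eligible),
      subclonal_fraction = r$clonality$subclonal_fraction,
      signatures = as.list(r$signatures$reported),
      drivers = if (nrow(drv)) drv[, c("gene", "class", "variant",
                                       "likelihood", "biallelic",
                                       "hotspot")] else list(),
      actionability = list(
        actionable = r$actionability$actionable,
        best_level = r$actionability$best_level,
        on_label = r$actionability$best_on_label,
        treatments = if (nrow(r$actionability$treatments))
          r$actionability$treatments else list(),
        excluded = if (nrow(r$actionability$excluded))
          r$actionability$excluded else list()))
    jsonlite::write_json(rep_json,
                         file.path(output_dir, "reports",
                                   paste0(r$sample_id, ".json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    data.frame(sample_id = r$sample_id, purity = r$fit$purity,
               ploidy = r$fit$ploidy, wgd = r$fit$wgd,
               qc = r$fit$qc_status, msi = r$msi$status, tmb = r$tmb$tmb,
               tmb_eligible = r$tmb$eligible,
               subclonal_fraction = r$clonality$subclonal_fraction,
               n_drivers = nrow(drv),
               driver_burden = sum(drv$likelihood),
               actionable = r$actionability$actionable,
               best_level = r$actionability$best_level %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(output_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output_dir)
}
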