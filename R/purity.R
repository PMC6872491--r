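## Purity/ploidy estimation from segment BAF + depth-ratio observations,
## allele-specific copy-number assignment, WGD calling, CNA classification
## and sample QC.
##
## Degeneracy note: a sample at purity p with states {(M, m)} is
# observationally identical to one at purity p/(1-p) with states
# {(M+1, m+1)} whenever every minor allele of the latter is valid; LOH
# segments (m = 0) break the downward alias, and the lowest-ploidy
# solution is preferred among near-tied scores.
#
# Model: for a segment of total tumour copy number c, major allele M and
## germline copy number nc, the expected observations at purity p and sample
## ploidy Psi are
##   depth ratio  r = (p c + nc (1-p)) / (p Psi + 2 (1-p))
##   BAF          b = (p M + (1-p)) / (p c + 2 (1-p))       [autosomes]
## The fit grid-searches (p, Psi), inverts the mixture per segment, snaps to
## the nearest allele-specific integer state, and scores the deviation.

#' Fit tumour purity and ploidy from segment observations
#'
#' Grid search over purity x candidate sample ploidy. Each segment's
#' implied real-valued total and major copy number is computed by inverting
#' the mixture model, snapped to the nearest non-negative integer
#' allele-specific state, and scored by SNP-count-weighted squared BAF
#' deviation plus length-weighted squared depth-ratio deviation, with a
#' small integer-attraction term. Among grid points whose score lies within
#' `tie_tolerance` of the optimum, the lowest-ploidy (then lowest-purity)
#' solution is returned: this resolves the exact purity/ploidy aliasing of
#' mixture models towards the parsimonious profile while leaving genuinely
#' resolved fits (for example whole-genome duplications anchored by LOH
#' segments) untouched. Sample ploidy is recomputed as the length-weighted
#' mean fitted copy number.
#'
#' When the score surface is flat in purity (no aberrant segment), the
#' lowest grid purity achieving the optimum is reported and the fit is
#' flagged `purity_unreliable`.
#'
#' @param segments segment observation data frame: chrom, start, end, baf
#'   (folded or major-allele fraction; NA when uninformative), baf_count,
#'   depth_ratio.
#' @param sex "male" or "female" (sets germline copy number on X/Y).
#' @param purity_grid,ploidy_grid search grids.
#' @param max_cn maximum modelled integer copy number.
#' @param baf_weight,ratio_weight,integer_penalty score weights.
#' @param tie_tolerance relative score factor within which solutions count
#'   as tied; the best-fitting member of the lowest-ploidy tied family
#'   wins. Covers both the purity/ploidy aliasing and the state-doubling
#'   degeneracy near purity 1, where doubled profiles overfit noise by a
#'   bounded factor.
#' @param n_somatic number of somatic variants observed for the sample
#'   (used only for QC flagging).
#' @param gc optional per-segment GC fraction (for the GC-bias QC metric).
#' @param gc_threshold absolute residual-vs-GC slope above which QC fails.
#' @return object of class `purity_fit` with elements `purity`, `ploidy`,
#'   `score`, `wgd`, `duplicated_autosomes`, `qc_status`,
#'   `purity_unreliable`, `gc_metric` and `segments` (fitted allele-specific
#'   copy numbers).
#' @export
fit_purity_ploidy <- function(segments, sex = "male",
                              purity_grid = seq(0.08, 1.00, by = 0.01),
                              ploidy_grid = seq(1.0, 8.0, by = 0.02),
                              max_cn = 20, baf_weight = 1, ratio_weight = 1,
                              integer_penalty = 0.005, tie_tolerance = 6,
                              n_somatic = NA_integer_, gc = NULL,
                              gc_threshold = 0.25) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  seg <- segments
  seg$baf[!is.na(seg$baf)] <- pmax(seg$baf[!is.na(seg$baf)],
                                   1 - seg$baf[!is.na(seg$baf)])
  informative <- !is.na(seg$baf) & seg$baf_count > 0
  if (!any(informative)) stop("no segments with informative heterozygous SNPs")

  nc <- .normal_cn(seg$chrom, sex)
  use <- nc == 2                       # fit the grid on diploid-normal segments
  L <- as.double(seg$end - seg$start)
  wl <- L / sum(L[use])
  wb <- ifelse(informative, seg$baf_count, 0)
  wb <- wb / sum(wb[use])
  r <- seg$depth_ratio
  b <- seg$baf

  surface <- matrix(NA_real_, nrow = length(purity_grid),
                    ncol = length(ploidy_grid))
  for (pi in seq_along(purity_grid)) {
    p <- purity_grid[pi]
    denom <- p * ploidy_grid + 2 * (1 - p)          # length = n ploidy
    # implied CN: outer over (ploidy, segment)
    cn_imp <- (outer(denom, r[use]) - 2 * (1 - p)) / p
    cn_imp <- pmin(pmax(cn_imp, 0), max_cn)
    sig <- p * cn_imp + 2 * (1 - p)
    bu <- b[use]
    maj_imp <- sweep(sig, 2, bu, "*")
    maj_imp <- (maj_imp - (1 - p)) / p
    maj_imp[, is.na(bu)] <- cn_imp[, is.na(bu)] / 2
    min_imp <- cn_imp - maj_imp
    m_int <- pmin(pmax(round(min_imp), 0), max_cn)
    M_int <- pmin(pmax(round(maj_imp), m_int), max_cn)
    c_int <- M_int + m_int
    ebaf <- (p * M_int + (1 - p)) / pmax(p * c_int + 2 * (1 - p), 1e-9)
    ebaf <- pmax(ebaf, 1 - ebaf)
    eratio <- sweep(p * c_int + 2 * (1 - p), 1, denom, "/")
    dev_b <- sweep((sweep(ebaf, 2, bu, "-"))^2, 2, wb[use], "*")
    dev_b[, is.na(bu)] <- 0
    dev_r <- sweep((sweep(eratio, 2, r[use], "-"))^2, 2, wl[use], "*")
    dev_i <- sweep((cn_imp - c_int)^2, 2, wl[use], "*")
    surface[pi, ] <- rowSums(baf_weight * dev_b + ratio_weight * dev_r +
                               integer_penalty * dev_i)
  }
  min_score <- min(surface)
  # candidate solutions: all grid points fitting within the relative tie
  # window of the optimum (alias families fit equally well up to noise;
  # wrong solutions score an order of magnitude worse)
  tied <- which(surface <= tie_tolerance * min_score + 1e-12, arr.ind = TRUE)
  # restrict to the lowest-ploidy family and take its best-fitting member
  psi_t <- ploidy_grid[tied[, 2]]
  tied <- tied[psi_t <= min(psi_t) + 0.5, , drop = FALSE]
  j <- which.min(surface[tied])
  pick <- tied[j, ]
  p <- purity_grid[pick[1]]
  psi_c <- ploidy_grid[pick[2]]
  best <- list(score = surface[pick[1], pick[2]])
  fitted <- .assign_copy_number(seg, p, psi_c, sex, max_cn)
  ploidy <- sum(fitted$cn * L) / sum(L)

  # flatness check: a fully balanced diploid-looking genome cannot identify
  # purity; detect it from the fitted states rather than the score surface
  aberrant <- any(abs(fitted$cn - 2) > 0.25 | fitted$minor < 0.25)
  purity_unreliable <- !aberrant
  if (purity_unreliable) p <- purity_grid[1]

  gc_metric <- NA_real_
  if (!is.null(gc) && length(gc) == nrow(seg)) {
    eratio_fit <- expected_depth_ratio(p, fitted$cn, ploidy, nc)
    resid <- seg$depth_ratio - eratio_fit
    ok <- is.finite(resid) & is.finite(gc)
    gc_metric <- if (sum(ok) > 2)
      abs(unname(stats::coef(stats::lm(resid[ok] ~ gc[ok],
                                       weights = L[ok]))[2])) else NA_real_
  }

  qc <- "PASS"
  if (!is.na(n_somatic) && n_somatic == 0) qc <- "FAIL_NO_SOMATIC"
  else if (p < 0.20) qc <- "FAIL_PURITY"
  else if (!is.na(gc_metric) && gc_metric > gc_threshold) qc <- "FAIL_GC"

  cn_seg <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                       cn = fitted$cn, major = fitted$major,
                       minor = fitted$minor, stringsAsFactors = FALSE)
  wgd <- call_wgd(cn_seg, autosomes = NULL)

  structure(list(purity = p, ploidy = ploidy, score = best$score,
                 wgd = wgd$wgd, duplicated_autosomes = wgd$count,
                 qc_status = qc, purity_unreliable = purity_unreliable,
                 gc_metric = gc_metric, sex = sex, segments = cn_seg,
                 n_somatic = n_somatic),
            class = "purity_fit")
}

# real-valued allele-specific copy number per segment at fixed purity; total
# CN from the depth ratio, major from BAF, both lightly pulled to integers
.assign_copy_number <- function(seg, p, psi, sex, max_cn = 20) {
  nc <- .normal_cn(seg$chrom, sex)
  denom <- p * psi + 2 * (1 - p)
  cn <- (seg$depth_ratio * denom - nc * (1 - p)) / p
  cn <- pmin(pmax(cn, 0), max_cn)
  b <- ifelse(is.na(seg$baf), NA_real_, pmax(seg$baf, 1 - seg$baf))
  major <- ifelse(is.na(b), cn / 2,
                  (b * (p * cn + 2 * (1 - p)) - (1 - p)) / p)
  major <- pmin(pmax(major, cn / 2), cn)
  minor <- cn - major
  list(cn = cn, major = major, minor = minor)
}

#' Call whole-genome duplication from fitted copy-number segments
#'
#' An autosome counts as duplicated when the fraction of its covered length
#' with major allele ploidy > 1.5 is at least 50%; WGD is called when at
#' least `min_autosomes` autosomes are duplicated.
#'
#' @param cn_segments data.frame with chrom, start, end, major (as in a
#'   `purity_fit`'s `segments`).
#' @param autosomes character vector of autosome names; defaults to
#'   chr1..chr22.
#' @param major_threshold major-allele ploidy threshold.
#' @param fraction_threshold duplicated length fraction per autosome.
#' @param min_autosomes duplicated-autosome count needed for a WGD call.
#' @return list with `wgd` (logical) and `count` (duplicated autosomes).
#' @export
call_wgd <- function(cn_segments, autosomes = NULL, major_threshold = 1.5,
                     fraction_threshold = 0.5, min_autosomes = 11L) {
  if (nrow(cn_segments) == 0) stop("empty segment list")
  if (is.null(autosomes)) autosomes <- paste0("chr", 1:22)
  seg <- cn_segments[cn_segments$chrom %in% autosomes, ]
  count <- 0L
  for (a in unique(seg$chrom)) {
    s <- seg[seg$chrom == a, ]
    L <- sum(as.double(s$end - s$start))
    dup <- sum(as.double(s$end - s$start)[s$major > major_threshold])
    if (L > 0 && dup / L >= fraction_threshold) count <- count + 1L
  }
  list(wgd = count >= min_autosomes, count = count)
}

#' Classify per-gene copy-number alteration categories
#'
#' Loss ring: homozygous deletion when minimum exonic copy number < 0.5;
#' otherwise LOH (minor allele ploidy below the LOH threshold) split into
#' significant loss (copy number < 0.6 x sample ploidy) versus near
#' copy-neutral LOH. Gain ring: high-level amplification when copy number
#' > 3 x sample ploidy, moderate when > 2 x, low when > 1.4 x. Chromosome-Y
#' loss is reported separately for male samples when Y copy number < 0.5.
#'
#' @param cn_segments fitted copy-number segments (chrom, start, end, cn,
#'   minor).
#' @param genome a `genome_model` (gene/exon coordinates).
#' @param sample_ploidy fitted sample ploidy.
#' @param sex sample sex.
#' @param loh_threshold minor-allele ploidy below which a locus is LOH.
#' @param homdel_threshold,sig_loss_factor,amp_factors decision constants.
#' @return data.frame: gene, min_exonic_cn, min_exonic_minor, loss_category,
#'   gain_category; attribute `y_loss` (logical or NA).
#' @export
classify_cna_categories <- function(cn_segments, genome, sample_ploidy,
                                    sex = "male", loh_threshold = 0.25,
                                    homdel_threshold = 0.5,
                                    sig_loss_factor = 0.6,
                                    amp_factors = c(low = 1.4, moderate = 2,
                                                    high = 3)) {
  gx <- gene_exonic_cn(cn_segments, genome)
  loss <- ifelse(gx$min_exonic_cn < homdel_threshold, "homozygous_deletion",
          ifelse(gx$min_exonic_minor < loh_threshold &
                   gx$min_exonic_cn < sig_loss_factor * sample_ploidy,
                 "loh_significant_loss",
          ifelse(gx$min_exonic_minor < loh_threshold, "loh_copy_neutral",
                 "none")))
  gain <- ifelse(gx$min_exonic_cn > amp_factors["high"] * sample_ploidy,
                 "amp_high",
          ifelse(gx$min_exonic_cn > amp_factors["moderate"] * sample_ploidy,
                 "amp_moderate",
          ifelse(gx$min_exonic_cn > amp_factors["low"] * sample_ploidy,
                 "amp_low", "none")))
  out <- data.frame(gene = gx$gene, min_exonic_cn = gx$min_exonic_cn,
                    min_exonic_minor = gx$min_exonic_minor,
                    loss_category = unname(loss), gain_category = unname(gain),
                    stringsAsFactors = FALSE)
  y_loss <- NA
  if (sex == "male") {
    ys <- cn_segments[cn_segments$chrom == "chrY", ]
    if (nrow(ys) > 0) {
      Ly <- as.double(ys$end - ys$start)
      y_loss <- (sum(ys$cn * Ly) / sum(Ly)) < homdel_threshold
    }
  }
  attr(out, "y_loss") <- y_loss
  out
}

#' Minimum exonic copy number (and minor allele ploidy) per gene
#'
#' @param cn_segments fitted copy-number segments.
#' @param genome a `genome_model`.
#' @return data.frame: gene, chrom, min_exonic_cn, min_exonic_minor,
#'   del_size (length of the overlapping segment at the minimum, used for
#'   fragile-site sizing).
#' @export
gene_exonic_cn <- function(cn_segments, genome) {
  ge <- genome$genes
  out <- data.frame(gene = ge$gene, chrom = ge$chrom,
                    min_exonic_cn = NA_real_, min_exonic_minor = NA_real_,
                    del_size = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ge))) {
    seg <- cn_segments[cn_segments$chrom == ge$chrom[i] &
                         cn_segments$end > ge$start[i] &
                         cn_segments$start < ge$end[i], ]
    if (nrow(seg) == 0) next
    st <- ge$exon_starts[[i]]; en <- ge$exon_ends[[i]]
    hit <- vapply(seq_len(nrow(seg)), function(k)
      any(en > seg$start[k] & st < seg$end[k]), logical(1))
    if (!any(hit)) { # gene entirely intronic over these segments: use span
      hit <- rep(TRUE, nrow(seg))
    }
    seg <- seg[hit, ]
    j <- which.min(seg$cn)
    out$min_exonic_cn[i] <- seg$cn[j]
    out$min_exonic_minor[i] <- min(seg$minor)
    out$del_size[i] <- seg$end[j] - seg$start[j]
  }
  out
}

#' Filter a cohort's per-sample results by quality control
#'
#' Removes samples with zero somatic variants, fitted purity < 0.20 or a
#' GC-bias metric above threshold; for patients with several passing
#' biopsies, keeps the highest-purity one.
#'
#' @param cohort data.frame with columns sample_id, patient_id, purity,
#'   n_somatic and optionally gc_metric.
#' @param purity_threshold exclusion bound (strict `<`).
#' @param gc_threshold GC metric bound (strict `>` excludes).
#' @return the filtered data.frame, with an added `qc_status` column.
#' @export
apply_sample_qc <- function(cohort, purity_threshold = 0.20,
                            gc_threshold = 0.25) {
  stopifnot(all(c("sample_id", "patient_id", "purity", "n_somatic") %in%
                  names(cohort)))
  gc <- if ("gc_metric" %in% names(cohort)) cohort$gc_metric else NA_real_
  status <- ifelse(cohort$n_somatic == 0, "FAIL_NO_SOMATIC",
            ifelse(cohort$purity < purity_threshold, "FAIL_PURITY",
            ifelse(!is.na(gc) & gc > gc_threshold, "FAIL_GC", "PASS")))
  cohort$qc_status <- status
  keep <- cohort[status == "PASS", ]
  # highest-purity biopsy per patient
  keep <- keep[order(keep$patient_id, -keep$purity), ]
  keep <- keep[!duplicated(keep$patient_id), ]
  keep[order(keep$sample_id), ]
}

## ---- purity_fit methods -------------------------------------------------

#' @export
print.purity_fit <- function(x, ...) {
  cat(sprintf("purity_fit: purity %.2f%s, ploidy %.2f, WGD %s (%d autosomes duplicated), QC %s\n",
              x$purity, if (x$purity_unreliable) " (unreliable)" else "",
              x$ploidy, if (x$wgd) "yes" else "no",
              x$duplicated_autosomes, x$qc_status))
  invisible(x)
}

#' @export
summary.purity_fit <- function(object, ...) {
  seg <- object$segments
  L <- as.double(seg$end - seg$start)
  loh <- sum(L[seg$minor < 0.25 & seg$chrom %in% paste0("chr", 1:22)]) /
    sum(L[seg$chrom %in% paste0("chr", 1:22)])
  out <- list(purity = object$purity, ploidy = object$ploidy,
              score = object$score, wgd = object$wgd,
              duplicated_autosomes = object$duplicated_autosomes,
              qc_status = object$qc_status, loh_fraction = loh,
              n_segments = nrow(seg))
  class(out) <- "summary.purity_fit"
  out
}

#' @export
print.summary.purity_fit <- function(x, ...) {
  cat(sprintf(paste0("Purity/ploidy fit over %d segments\n",
                     "  purity: %.2f   ploidy: %.2f   fit score: %.4g\n",
                     "  WGD: %s (%d duplicated autosomes)\n",
                     "  autosomal LOH fraction: %.1f%%   QC: %s\n"),
              x$n_segments, x$purity, x$ploidy, x$score,
              if (x$wgd) "yes" else "no", x$duplicated_autosomes,
              100 * x$loh_fraction, x$qc_status))
  invisible(x)
}

#' @export
coef.purity_fit <- function(object, ...) {
  c(purity = object$purity, ploidy = object$ploidy)
}

#' Expected segment observations under a fitted purity/ploidy model
#'
#' @param object a `purity_fit`.
#' @param newdata optional segment data frame (chrom, start, end); defaults
#'   to the fitted segments.
#' @param ... unused.
#' @return data.frame with expected `baf` and `depth_ratio` per segment.
#' @export
predict.purity_fit <- function(object, newdata = NULL, ...) {
  seg <- newdata %||% object$segments
  if (is.null(seg$cn)) {
    idx <- .segment_at(object$segments, seg$chrom,
                       pmax(seg$start, 0))
    seg$cn <- object$segments$cn[idx]
    seg$major <- object$segments$major[idx]
    seg$minor <- object$segments$minor[idx]
  }
  nc <- .normal_cn(seg$chrom, object$sex)
  data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
             baf = expected_baf(object$purity, seg$major, seg$minor),
             depth_ratio = expected_depth_ratio(object$purity, seg$cn,
                                                object$ploidy, nc))
}

#' Plot a fitted copy-number profile
#'
#' Total and minor-allele copy number along the genome, one panel.
#'
#' @param x a `purity_fit`.
#' @param ... passed to [plot()].
#' @export
plot.purity_fit <- function(x, ...) {
  seg <- x$segments
  ord <- order(match(seg$chrom, unique(seg$chrom)), seg$start)
  seg <- seg[ord, ]
  offs <- c(0, cumsum(tapply(seg$end, match(seg$chrom, unique(seg$chrom)),
                             max)))
  xs <- offs[match(seg$chrom, unique(seg$chrom))]
  plot(NULL, xlim = c(0, max(xs + seg$end)), ylim = c(0, max(seg$cn) + 1),
       xlab = "genome position", ylab = "copy number",
       main = sprintf("purity %.2f, ploidy %.2f", x$purity, x$ploidy), ...)
  graphics::segments(xs + seg$start, seg$cn, xs + seg$end, seg$cn,
                     lwd = 2, col = "firebrick")
  graphics::segments(xs + seg$start, seg$minor, xs + seg$end, seg$minor,
                     lwd = 2, col = "steelblue")
  graphics::abline(h = x$ploidy, lty = 3)
  invisible(x)
}
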