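## Variant ploidy, biallelic status, MNV merging, clonal/subclonal mixture
## modelling and multi-biopsy sharing.

#' Annotate a variant with ploidy and biallelic status
#'
#' Variant ploidy is the absolute number of chromatids carrying the variant,
#' obtained by adjusting the observed VAF by the purity and multiplying by
#' the local copy number: v = VAF * (p * CN + nc * (1 - p)) / p, with
#' germline copy number nc (2 on autosomes; per-sex on X/Y). The variant is
#' biallelic (no wild type remaining) iff v > CN - 0.5.
#'
#' @param vaf observed variant allele fraction (vectorised).
#' @param purity tumour purity in (0, 1].
#' @param cn local total copy number.
#' @param normal_cn germline copy number at the locus.
#' @param biallelic_offset offset below CN at the biallelic boundary.
#' @return data.frame with `variant_ploidy`, `cn` and `biallelic`.
#' @export
annotate_variant_ploidy <- function(vaf, purity, cn, normal_cn = 2,
                                    biallelic_offset = 0.5) {
  if (any(purity <= 0)) stop("purity must be > 0")
  stopifnot(all(cn >= 0), all(vaf >= 0 & vaf <= 1))
  v <- variant_ploidy_from_vaf(vaf, purity, cn, normal_cn)
  data.frame(variant_ploidy = v, cn = cn,
             biallelic = v > cn - biallelic_offset)
}

#' Merge phased adjacent SNVs into multi-nucleotide variants
#'
#' Runs of SNVs at strictly consecutive positions (gap 0) sharing a phase
#' set merge into a single MNV; unphased or non-adjacent SNVs are left
#' unchanged. Reports counts by MNV length as an attribute.
#'
#' @param variants somatic variant data frame with `phase_set`.
#' @return variant data frame with merged MNV rows (type "MNV"); attribute
#'   `mnv_length_counts`.
#' @export
merge_mnvs <- function(variants) {
  if (nrow(variants) == 0) {
    attr(variants, "mnv_length_counts") <- table(integer(0))
    return(variants)
  }
  snv <- which(variants$type == "SNV" & !is.na(variants$phase_set))
  if (!length(snv)) {
    attr(variants, "mnv_length_counts") <- table(integer(0))
    return(variants)
  }
  cand <- variants[snv, ]
  ord <- order(cand$phase_set, cand$chrom, cand$pos)
  cand <- cand[ord, ]
  new_run <- c(TRUE, !(cand$phase_set[-1] == cand$phase_set[-nrow(cand)] &
                         cand$chrom[-1] == cand$chrom[-nrow(cand)] &
                         cand$pos[-1] == cand$pos[-nrow(cand)] + 1L))
  run_id <- cumsum(new_run)
  merged <- lapply(split(seq_len(nrow(cand)), run_id), function(ix) {
    if (length(ix) == 1) return(cand[ix, ])
    first <- cand[ix[1], ]
    first$ref <- paste(cand$ref[ix], collapse = "")
    first$alt <- paste(cand$alt[ix], collapse = "")
    first$type <- "MNV"
    first$alt_count <- as.integer(round(mean(cand$alt_count[ix])))
    first$depth <- as.integer(round(mean(cand$depth[ix])))
    first$vaf <- first$alt_count / first$depth
    first
  })
  merged <- do.call(rbind, merged)
  out <- rbind(variants[-snv, ], merged)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  lens <- nchar(merged$ref[merged$type == "MNV"])
  attr(out, "mnv_length_counts") <- table(lens)
  out
}

#' Fit the clonal/subclonal structure of one sample's somatic ploidies
#'
#' Somatic variant ploidies are fitted with a Gaussian mixture (EM, BIC
#' model selection over 1-5 components via mclust). Peaks whose location is
#' below `subclonal_ccf * 1` in ploidy space are marked subclonal; each
#' variant receives a posterior membership probability, and the sample
#' subclonal fraction is the mean per-variant subclonal probability (equal
#' to the total weight of the subclonal peaks at the EM fixed point).
#' With fewer than `min_variants` variants a single clonal peak is returned
#' with a warning.
#'
#' @param variant_ploidy numeric vector of somatic variant ploidies.
#' @param subclonal_ccf CCF boundary below which a peak is subclonal.
#' @param max_peaks maximum number of mixture components.
#' @param min_variants minimum variants for mixture fitting.
#' @return object of class `clonality_fit`: `peaks` (location, weight,
#'   sd, is_subclonal), `subclonal_prob` per variant, `subclonal_fraction`.
#' @export
fit_clonality <- function(variant_ploidy, subclonal_ccf = 0.85,
                          max_peaks = 5L, min_variants = 50L) {
  v <- variant_ploidy[is.finite(variant_ploidy)]
  if (!length(v)) stop("no variant ploidies supplied")
  if (length(v) < min_variants) {
    warning("fewer than ", min_variants,
            " variants; returning a single clonal peak")
    peaks <- data.frame(location = mean(v), weight = 1, sd = stats::sd(v),
                        is_subclonal = FALSE)
    return(structure(list(peaks = peaks,
                          subclonal_prob = rep(0, length(variant_ploidy)),
                          subclonal_fraction = 0, n = length(v),
                          bic = NA_real_),
                     class = "clonality_fit"))
  }
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(v, G = seq_len(max_peaks), modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, length(mu))
  # recompute responsibilities from the fitted parameters so that mixture
  # weights equal mean membership probabilities exactly
  pro <- fit$parameters$pro
  dens <- vapply(seq_along(mu), function(k)
    pro[k] * stats::dnorm(v, mu[k], pmax(sdv[k], 1e-6)), numeric(length(v)))
  dens <- matrix(dens, nrow = length(v))
  z <- dens / pmax(rowSums(dens), 1e-300)
  weight <- colMeans(z)
  is_sub <- mu < subclonal_ccf
  sub_prob_v <- rowSums(z[, is_sub, drop = FALSE])
  sub_prob <- rep(NA_real_, length(variant_ploidy))
  sub_prob[is.finite(variant_ploidy)] <- sub_prob_v
  peaks <- data.frame(location = unname(mu), weight = unname(weight),
                      sd = unname(sdv), is_subclonal = unname(is_sub))
  structure(list(peaks = peaks, subclonal_prob = sub_prob,
                 subclonal_fraction = mean(sub_prob_v), n = length(v),
                 bic = fit$bic),
            class = "clonality_fit")
}

#' @export
print.clonality_fit <- function(x, ...) {
  cat(sprintf("clonality_fit: %d variants, %d peak(s), subclonal fraction %.3f\n",
              x$n, nrow(x$peaks), x$subclonal_fraction))
  invisible(x)
}

#' @export
summary.clonality_fit <- function(object, ...) {
  cat(sprintf("Clonality mixture over %d somatic variant ploidies\n",
              object$n))
  print(transform(object$peaks, location = round(location, 3),
                  weight = round(weight, 3), sd = round(sd, 3)))
  cat(sprintf("Sample subclonal fraction: %.3f\n",
              object$subclonal_fraction))
  invisible(object)
}

#' Posterior subclonal probability for new variant ploidies
#'
#' @param object a `clonality_fit`.
#' @param newdata numeric vector of variant ploidies.
#' @param ... unused.
#' @return numeric vector of subclonal probabilities.
#' @export
predict.clonality_fit <- function(object, newdata, ...) {
  pk <- object$peaks
  dens <- vapply(seq_len(nrow(pk)), function(k)
    pk$weight[k] * stats::dnorm(newdata, pk$location[k],
                                pmax(pk$sd[k], 1e-6)),
    numeric(length(newdata)))
  dens <- matrix(dens, nrow = length(newdata))
  rowSums(dens[, pk$is_subclonal, drop = FALSE]) /
    pmax(rowSums(dens), 1e-300)
}

#' Histogram of variant ploidies with fitted mixture peaks
#' @param x a `clonality_fit`.
#' @param v optional raw variant ploidies to draw the histogram from.
#' @param ... passed to [graphics::hist()].
#' @export
plot.clonality_fit <- function(x, v = NULL, ...) {
  pk <- x$peaks
  if (!is.null(v)) {
    graphics::hist(v, breaks = 60, freq = FALSE,
                   main = "somatic variant ploidy", xlab = "variant ploidy",
                   ...)
    xs <- seq(min(v), max(v), length.out = 400)
    dens <- rowSums(vapply(seq_len(nrow(pk)), function(k)
      pk$weight[k] * stats::dnorm(xs, pk$location[k], pmax(pk$sd[k], 1e-6)),
      numeric(length(xs))))
    graphics::lines(xs, dens, col = "firebrick", lwd = 2)
  }
  graphics::abline(v = pk$location,
                   col = ifelse(pk$is_subclonal, "steelblue", "grey40"),
                   lty = 2)
  invisible(x)
}

#' Compare variant sharing between two biopsies of one patient
#'
#' Variant identity is keyed on (chrom, pos, ref, alt). For each clonality
#' class (clonal: subclonal probability <= 0.5; subclonal otherwise) the
#' shared fraction is computed over the union of the class across both
#' biopsies.
#'
#' @param a,b annotated somatic variant data frames, each carrying a
#'   `subclonal_prob` column.
#' @param patient_a,patient_b patient identifiers (must match).
#' @return list with `shared_clonal` and `shared_subclonal` fractions.
#' @export
compare_biopsies <- function(a, b, patient_a = "P", patient_b = "P") {
  if (!identical(patient_a, patient_b))
    stop("biopsies come from different patients")
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  cls <- function(df) ifelse(df$subclonal_prob > 0.5, "subclonal", "clonal")
  ka <- key(a); kb <- key(b)
  ca <- cls(a); cb <- cls(b)
  frac <- function(class) {
    ua <- ka[ca == class]; ub <- kb[cb == class]
    un <- union(ua, ub)
    if (!length(un)) return(NA_real_)
    length(intersect(ua, ub)) / length(un)
  }
  list(shared_clonal = frac("clonal"), shared_subclonal = frac("subclonal"))
}
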