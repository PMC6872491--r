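## Microsatellite instability scoring and tumour mutational burden.

#' Classify an MSI score
#'
#' @param count qualifying indel count.
#' @param mb genome size in megabases.
#' @param threshold score above which (strictly) the sample is MSI.
#' @return list with `score` and `status` ("MSI"/"MSS").
#' @export
msi_classify <- function(count, mb, threshold = 4) {
  if (mb <= 0) stop("genome size must be positive")
  score <- count / mb
  list(score = score, status = if (score > threshold) "MSI" else "MSS")
}

#' Compute microsatellite-instability status of a sample
#'
#' Counts indels whose locus overlaps a homopolymer run of five or more
#' bases or a 2-4 bp-unit repeat with four or more units, per variant,
#' normalised per megabase of genome; score > 4 is MSI.
#'
#' @param variants somatic variant data frame (`type == "INDEL"` rows are
#'   considered; positions 1-based).
#' @param genome a `genome_model` (microsatellite annotation and size).
#' @param threshold MSI decision threshold on the score.
#' @return object of class `msi_result`: list with `qualifying_indels`,
#'   `genome_mb`, `score`, `status`.
#' @export
compute_msi <- function(variants, genome, threshold = 4) {
  mb <- genome_mb(genome)
  if (mb <= 0) stop("zero-length genome")
  ms <- genome$microsatellites
  qual_ms <- ms[(ms$unit_length == 1 & ms$repeat_count >= 5) |
                  (ms$unit_length %in% 2:4 & ms$repeat_count >= 4), ]
  ind <- variants[variants$type == "INDEL", , drop = FALSE]
  n_qual <- 0L
  if (nrow(ind) > 0 && nrow(qual_ms) > 0) {
    for (cn in unique(ind$chrom)) {
      mi <- qual_ms[qual_ms$chrom == cn, ]
      if (nrow(mi) == 0) next
      pos0 <- ind$pos[ind$chrom == cn] - 1L       # back to 0-based
      ord <- order(mi$start)
      f <- findInterval(pos0, mi$start[ord])
      ok <- f >= 1 & pos0 < mi$end[ord][pmax(f, 1)]
      n_qual <- n_qual + sum(ok)
    }
  }
  cl <- msi_classify(n_qual, mb, threshold)
  structure(list(qualifying_indels = n_qual, genome_mb = mb,
                 score = cl$score, status = cl$status),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("MSI: %d qualifying indels over %.1f Mb -> score %.2f/Mb (%s)\n",
              x$qualifying_indels, x$genome_mb, x$score, x$status))
  invisible(x)
}

#' Tumour mutational burden and immunotherapy-eligibility flag
#'
#' TMB counts SNVs, MNVs and indels per megabase of genome; the eligibility
#' flag requires TMB strictly greater than the threshold (10 mutations per
#' megabase by default).
#'
#' @param variants somatic variant data frame, or an integer count.
#' @param genome a `genome_model`, or a numeric genome size in Mb.
#' @param threshold eligibility bound (strict `>`).
#' @return list with `n_mutations`, `genome_mb`, `tmb`, `eligible`.
#' @export
compute_tmb <- function(variants, genome, threshold = 10) {
  n <- if (is.data.frame(variants))
    sum(variants$type %in% c("SNV", "MNV", "INDEL")) else as.numeric(variants)
  mb <- if (inherits(genome, "genome_model")) genome_mb(genome)
        else as.numeric(genome)
  tmb <- n / mb
  list(n_mutations = n, genome_mb = mb, tmb = tmb,
       eligible = tmb > threshold)
}
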