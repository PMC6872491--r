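#' Derive a reproducible child seed from a master seed
#'
#' Deterministic linear-congruential derivation so that per-sample simulations
#' are independent of each other and of how many samples precede them.
#' Result always lies in \code{[1, 2^31 - 2]}.
#'
#' @param master integer master seed.
#' @param i non-negative integer stream index.
#' @return integer seed.
#' @export
derive_seed <- function(master, i) {
  stopifnot(is.numeric(master), is.numeric(i))
  x <- (abs(as.double(master)) %% 2147483629) + 1
  for (k in seq_len(2)) x <- (x * 48271 + 7919 * (as.double(i) + 1)) %% 2147483629
  as.integer(x %% 2147483628 + 1)
}

# tumour/normal mixture denominator: p*CN_tumour + normal_cn*(1-p)
mixture_denom <- function(purity, cn, normal_cn = 2) {
  purity * cn + normal_cn * (1 - purity)
}

#' Expected B-allele frequency of germline heterozygous SNPs
#'
#' Under the purity/copy-number mixture, a germline heterozygous SNP whose B
#' allele lies on the major haplotype has expected allele fraction
#' (p * major + (1 - p)) / (p * CN + 2 (1 - p)).
#'
#' @param purity tumour purity in (0, 1].
#' @param major,minor allele-specific tumour copy number.
#' @return expected BAF (major-allele fraction, >= 0.5 when major >= minor).
#' @export
expected_baf <- function(purity, major, minor) {
  num <- purity * major + (1 - purity)
  den <- mixture_denom(purity, major + minor, 2)
  ifelse(den <= 0, 0.5, num / den)
}

#' Expected tumour/normal depth ratio of a segment
#'
#' The ratio is normalised so that its genome-length-weighted mean is 1 for a
#' tumour of the given sample ploidy.
#'
#' @param purity tumour purity.
#' @param cn total tumour copy number of the segment.
#' @param sample_ploidy length-weighted mean tumour copy number.
#' @param normal_cn copy number of the matched normal at the locus (2 for
#'   autosomes, 1 for male X/Y).
#' @return expected depth ratio.
#' @export
expected_depth_ratio <- function(purity, cn, sample_ploidy, normal_cn = 2) {
  mixture_denom(purity, cn, normal_cn) / mixture_denom(purity, sample_ploidy, 2)
}

# variant ploidy inversion used throughout: v = VAF * (p*CN + nc*(1-p)) / p
variant_ploidy_from_vaf <- function(vaf, purity, cn, normal_cn = 2) {
  vaf * mixture_denom(purity, cn, normal_cn) / purity
}

# expected VAF at variant ploidy v (chromatids * CCF)
expected_vaf <- function(v, purity, cn, normal_cn = 2) {
  pmin(1, pmax(0, purity * v / mixture_denom(purity, cn, normal_cn)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable per-file md5 hash over text content (manifest use)
text_md5 <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}
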