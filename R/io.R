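## Standard-format I/O: minimal VCF 4.2 writer for simulated variants,
## TSV segment/SV tables, JSON truth files. Internal coordinates are
## 0-based half-open; VCF and the variant data frames are 1-based.

#' Write a somatic variant table as minimal VCF 4.2
#'
#' @param variants somatic variant data frame (as produced by
#'   [simulate_sample()]).
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(variants, path, sample_id = "TUMOUR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somascape",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "##INFO=<ID=PHS,Number=1,Type=String,Description=\"Phase set\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=AC2,Number=1,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Total depth\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  )
  info <- sprintf("TYPE=%s;AC2=%d;DP2=%d%s%s%s%s",
                  variants$type, variants$alt_count, variants$depth,
                  ifelse(is.na(variants$context), "",
                         paste0(";TNC=", variants$context)),
                  ifelse(is.na(variants$phase_set), "",
                         paste0(";PHS=", variants$phase_set)),
                  ifelse(is.na(variants$gene), "",
                         paste0(";GENE=", variants$gene)),
                  ifelse(is.na(variants$consequence), "",
                         paste0(";CSQ=", variants$consequence)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", variants$chrom,
                  variants$pos, variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write germline variants as minimal VCF 4.2
#'
#' @param variants germline variant data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_germline_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somascape",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=GT2,Number=1,Type=String,Description=\"Germline genotype\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=TAC,Number=1,Type=Integer,Description=\"Tumour alt count\">",
    "##INFO=<ID=TDP,Number=1,Type=Integer,Description=\"Tumour depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (is.null(variants) || nrow(variants) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- sprintf("GENE=%s;GT2=%s;CLNSIG=%s%s%s", variants$gene,
                  variants$genotype, variants$clnsig,
                  ifelse(is.na(variants$tumour_alt), "",
                         sprintf(";TAC=%d", variants$tumour_alt)),
                  ifelse(is.na(variants$tumour_depth), "",
                         sprintf(";TDP=%d", variants$tumour_depth)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", variants$chrom,
                  variants$pos, variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.info_field <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(?:^|;)", key, "=[^;]*"), info)),
         function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[1])
                     else NA_character_,
         character(1), USE.NAMES = FALSE)
}

#' Read a somatic VCF written by [write_somatic_vcf()]
#'
#' @param path VCF path.
#' @return somatic variant data frame.
#' @export
read_somatic_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) return(.empty_somatic())
  info <- fx$INFO
  ac <- as.integer(.info_field(info, "AC2"))
  dp <- as.integer(.info_field(info, "DP2"))
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF,
             alt = fx$ALT, type = .info_field(info, "TYPE"),
             alt_count = ac, depth = dp, vaf = ac / dp,
             phase_set = .info_field(info, "PHS"),
             gene = .info_field(info, "GENE"),
             consequence = .info_field(info, "CSQ"),
             context = .info_field(info, "TNC"), stringsAsFactors = FALSE)
}

#' Read a germline VCF written by [write_germline_vcf()]
#'
#' @param path VCF path.
#' @return germline variant data frame, or NULL when empty.
#' @export
read_germline_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) return(NULL)
  info <- fx$INFO
  ta <- as.integer(.info_field(info, "TAC"))
  td <- as.integer(.info_field(info, "TDP"))
  data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF,
             alt = fx$ALT, gene = .info_field(info, "GENE"),
             genotype = .info_field(info, "GT2"),
             clnsig = .info_field(info, "CLNSIG"), tumour_alt = ta,
             tumour_depth = td, tumour_vaf = ta / td,
             stringsAsFactors = FALSE)
}

#' Write a simulated sample's observables and truth to a directory
#'
#' Files: `segments.tsv`, `somatic.vcf`, `germline.vcf`, `svs.tsv`,
#' `truth.json`.
#'
#' @param sample a `tumour_sample`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- sample$segments
  seg$baf <- ifelse(is.na(seg$baf), 0, round(seg$baf, 6))
  seg$depth_ratio <- round(seg$depth_ratio, 6)
  seg$gc <- round(seg$gc, 4)
  utils::write.table(seg, file.path(dir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_somatic_vcf(sample$somatic, file.path(dir, "somatic.vcf"),
                    sample$truth$sample_id)
  write_germline_vcf(sample$germline, file.path(dir, "germline.vcf"))
  utils::write.table(sample$svs, file.path(dir, "svs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sample$truth
  truth$segments <- truth$segments
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(dir)
}

#' Read segment observations from a TSV file
#'
#' @param path TSV with columns chrom, start, end, baf, baf_count,
#'   depth_ratio (and optionally gc).
#' @return segment observation data frame.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  seg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "baf", "baf_count", "depth_ratio")
  stopifnot(all(need %in% names(seg)))
  seg$baf[seg$baf_count == 0] <- NA_real_
  seg
}

#' Read an SV breakpoint table from TSV
#' @param path TSV path.
#' @return SV data frame.
#' @export
read_svs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
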