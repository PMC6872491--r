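## Genome model: chromosomes, gene models with synthetic coding sequence,
## and microsatellite annotation. Coordinates are 0-based half-open
## internally; VCF output is 1-based.

GRCH37_CHROM_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

# curated gene layout of the synthetic genome: real driver-gene names placed
# on their real chromosomes, plus neutral filler genes.  role is the truth
# label used by the generator; is_panel marks the curated somatic panel.
.gene_catalogue <- function() {
  onc <- data.frame(
    gene = c("KRAS", "PIK3CA", "BRAF", "NRAS", "EGFR", "ERBB2", "MYC",
             "CCND1", "MDM2", "TERT", "AR", "CTNNB1", "KIT", "ALK", "ERG",
             "RET"),
    chrom = c("chr12", "chr3", "chr7", "chr1", "chr7", "chr17", "chr8",
              "chr11", "chr12", "chr5", "chrX", "chr3", "chr4", "chr2",
              "chr21", "chr10"),
    role = "oncogene", is_panel = TRUE, stringsAsFactors = FALSE
  )
  tsg <- data.frame(
    gene = c("TP53", "CDKN2A", "PTEN", "APC", "RB1", "SMAD4", "ARID1A",
             "ATM", "BRCA1", "BRCA2", "VHL", "STK11", "MSH2", "MLH1",
             "MSH6", "PMS2", "MUTYH", "MEN1", "NF2", "CHEK2", "BAP1",
             "TSC1", "TSC2", "WT1", "BMPR1A", "SDHB", "SDHC", "SDHD",
             "SDHAF2"),
    chrom = c("chr17", "chr9", "chr10", "chr5", "chr13", "chr18", "chr1",
              "chr11", "chr17", "chr13", "chr3", "chr19", "chr2", "chr3",
              "chr2", "chr7", "chr1", "chr11", "chr22", "chr22", "chr3",
              "chr9", "chr16", "chr11", "chr10", "chr1", "chr1", "chr11",
              "chr11"),
    role = "tsg", is_panel = TRUE, stringsAsFactors = FALSE
  )
  other <- data.frame(
    gene = c("TMPRSS2", "FHIT", "DMD"),
    chrom = c("chr21", "chr3", "chrX"),
    role = "none", is_panel = FALSE, stringsAsFactors = FALSE
  )
  rbind(onc, tsg, other)
}

#' Germline predisposition high-confidence gene panel
#'
#' The 25 cancer-related genes of the ACMG secondary-findings reporting
#' guidelines (v2.0) plus four curated genes (CDKN2A, CHEK2, BAP1, ATM).
#'
#' @return character vector of 29 gene symbols.
#' @export
germline_panel_genes <- function() {
  acmg25 <- c("APC", "RET", "BMPR1A", "SMAD4", "BRCA1", "BRCA2", "MLH1",
              "MSH2", "MSH6", "PMS2", "MEN1", "MUTYH", "NF2", "PTEN", "RB1",
              "SDHAF2", "SDHB", "SDHC", "SDHD", "STK11", "TP53", "TSC1",
              "TSC2", "VHL", "WT1")
  c(acmg25, "CDKN2A", "CHEK2", "BAP1", "ATM")
}

.CODONS61 <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.random_cds <- function(n_codons) {
  paste(sample(.CODONS61, n_codons, replace = TRUE), collapse = "")
}

# split `total` into n parts each >= minimum, deterministically random
.partition <- function(total, n, minimum) {
  if (n == 1) return(total)
  slack <- total - n * minimum
  stopifnot(slack >= 0)
  cuts <- sort(sample.int(slack + 1, n - 1, replace = TRUE) - 1)
  minimum + diff(c(0, cuts, slack))
}

#' Build the synthetic genome model
#'
#' A scaled human-like genome: 22 autosomes plus X and Y at 1/`scale` of
#' GRCh37 lengths (default 1/30, roughly 103 Mb), carrying a curated set of
#' real driver-gene names at synthetic coordinates, neutral filler genes, and
#' a microsatellite annotation (homopolymers and 2-4 bp unit repeats).
#' Every gene has a synthetic coding sequence so that variant consequences
#' and dN/dS opportunity can be computed exactly. Fully deterministic given
#' `seed`.
#'
#' @param seed integer seed controlling gene structure, coding sequence and
#'   microsatellite placement.
#' @param scale divisor applied to GRCh37 chromosome lengths; `scale = 1`
#'   gives a full-length genome.
#' @param n_filler_genes number of neutral filler genes (`GENE001`, ...).
#' @param n_microsatellites number of annotated microsatellite loci.
#' @return an object of class `genome_model`: list with elements
#'   `chromosomes` (name, length, is_autosome), `genes` (data frame with
#'   exon list-columns and `cds` strings) and `microsatellites`.
#' @export
mini_genome <- function(seed = 7777L, scale = 30, n_filler_genes = 30L,
                        n_microsatellites = 3000L) {
  withr::with_seed(seed, {
    chroms <- data.frame(
      name = names(GRCH37_CHROM_LENGTHS),
      length = as.integer(floor(GRCH37_CHROM_LENGTHS / scale)),
      stringsAsFactors = FALSE
    )
    chroms$is_autosome <- !chroms$name %in% c("chrX", "chrY")

    cat_df <- .gene_catalogue()
    if (n_filler_genes > 0) {
      fill <- data.frame(
        gene = sprintf("GENE%03d", seq_len(n_filler_genes)),
        chrom = sample(chroms$name[chroms$is_autosome], n_filler_genes,
                       replace = TRUE),
        role = "none", is_panel = FALSE, stringsAsFactors = FALSE
      )
      cat_df <- rbind(cat_df, fill)
    }

    # structural parameters per gene
    n <- nrow(cat_df)
    cat_df$span <- ifelse(cat_df$gene == "FHIT", 700000L,
                   ifelse(cat_df$gene == "DMD", 800000L,
                          as.integer(sample(15000:40000, n, replace = TRUE))))
    cat_df$n_exons <- ifelse(cat_df$gene %in% c("FHIT", "DMD"), 9L,
                             sample(3:8, n, replace = TRUE))
    cat_df$n_codons <- ifelse(cat_df$gene %in% c("FHIT", "DMD"), 301L,
                              sample(300:500, n, replace = TRUE))
    cat_df$coding_len <- cat_df$n_codons * 3L

    # deterministic placement: genes evenly spaced along each chromosome
    cat_df$start <- NA_integer_
    for (cn in unique(cat_df$chrom)) {
      idx <- which(cat_df$chrom == cn)
      L <- chroms$length[chroms$name == cn]
      anchors <- floor(L * seq_along(idx) / (length(idx) + 1))
      cat_df$start[idx] <- as.integer(anchors)
      # keep spans on-chromosome
      over <- cat_df$start[idx] + cat_df$span[idx] >= L
      cat_df$start[idx][over] <- pmax(0L, L - cat_df$span[idx][over] - 1L)
    }
    cat_df$end <- cat_df$start + cat_df$span
    cat_df$strand <- sample(c("+", "-"), n, replace = TRUE)

    exon_starts <- vector("list", n)
    exon_ends <- vector("list", n)
    cds <- character(n)
    for (i in seq_len(n)) {
      ne <- cat_df$n_exons[i]
      ex_len <- .partition(cat_df$coding_len[i], ne, 30)
      intron_total <- cat_df$span[i] - cat_df$coding_len[i]
      introns <- if (ne > 1) .partition(intron_total, ne - 1, 200) else integer(0)
      st <- integer(ne); en <- integer(ne)
      pos <- cat_df$start[i]
      for (e in seq_len(ne)) {
        st[e] <- pos
        en[e] <- pos + ex_len[e]
        pos <- en[e] + if (e < ne) introns[e] else 0L
      }
      exon_starts[[i]] <- st
      exon_ends[[i]] <- en
      cds[i] <- .random_cds(cat_df$n_codons[i])
    }
    cat_df$exon_starts <- exon_starts
    cat_df$exon_ends <- exon_ends
    cat_df$cds <- cds
    cat_df$coding_start <- cat_df$start
    cat_df$coding_end <- cat_df$end
    cat_df$length_bp <- cat_df$end - cat_df$start
    cat_df$is_germline_panel <- cat_df$gene %in% germline_panel_genes()

    # microsatellites: homopolymers (unit 1, >=5 repeats) and short tandem
    # repeats (unit 2-4, >=4 repeats), plus a sprinkle of sub-threshold loci
    ms_chrom <- sample(chroms$name, n_microsatellites, replace = TRUE,
                       prob = chroms$length)
    unit <- sample(c(1L, 1L, 1L, 2L, 3L, 4L), n_microsatellites, replace = TRUE)
    reps <- ifelse(unit == 1L, sample(4:20, n_microsatellites, replace = TRUE),
                   sample(3:12, n_microsatellites, replace = TRUE))
    ms_len <- unit * reps
    ms_start <- vapply(seq_len(n_microsatellites), function(i) {
      L <- chroms$length[chroms$name == ms_chrom[i]]
      as.integer(sample.int(L - ms_len[i] - 1L, 1L))
    }, integer(1))
    ms <- data.frame(chrom = ms_chrom, start = ms_start,
                     end = ms_start + ms_len, unit_length = unit,
                     repeat_count = reps, stringsAsFactors = FALSE)
    ms <- ms[order(ms$chrom, ms$start), ]
    rownames(ms) <- NULL

    g <- structure(list(chromosomes = chroms, genes = cat_df,
                        microsatellites = ms, seed = seed, scale = scale),
                   class = "genome_model")
    validate_genome(g)
    g
  })
}

#' Validate a genome model's structural invariants
#'
#' Checks chromosome lengths, gene and microsatellite coordinates, exon
#' ordering/disjointness, and coding length consistency. Errors on violation.
#'
#' @param genome a `genome_model`.
#' @return the genome, invisibly.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  ch <- genome$chromosomes
  stopifnot(all(ch$length > 0))
  len <- stats::setNames(ch$length, ch$name)
  ge <- genome$genes
  stopifnot(all(ge$chrom %in% ch$name),
            all(ge$start >= 0), all(ge$end <= len[ge$chrom]),
            all(ge$length_bp == ge$end - ge$start))
  for (i in seq_len(nrow(ge))) {
    st <- ge$exon_starts[[i]]; en <- ge$exon_ends[[i]]
    stopifnot(all(en > st), !is.unsorted(st, strictly = TRUE),
              all(st[-1] >= en[-length(en)]),     # disjoint, ordered
              st[1] >= ge$start[i], en[length(en)] <= ge$end[i],
              sum(en - st) == ge$coding_len[i],
              nchar(ge$cds[i]) == ge$coding_len[i])
  }
  ms <- genome$microsatellites
  stopifnot(all(ms$chrom %in% ch$name), all(ms$start >= 0),
            all(ms$end <= len[ms$chrom]),
            all(ms$unit_length %in% 1:4), all(ms$repeat_count >= 3))
  invisible(genome)
}

#' Total genome size in megabases
#' @param genome a `genome_model`.
#' @return numeric, Mb.
#' @export
genome_mb <- function(genome) sum(as.double(genome$chromosomes$length)) / 1e6

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb (1/%s of GRCh37), %d genes, %d microsatellites\n",
              nrow(x$chromosomes), genome_mb(x), format(x$scale),
              nrow(x$genes), nrow(x$microsatellites)))
  invisible(x)
}

## ---- gene coordinate helpers -------------------------------------------

# exon table for one gene: data.frame(start, end, cds_offset)
.gene_exons <- function(genome, gene) {
  i <- match(gene, genome$genes$gene)
  stopifnot(!is.na(i))
  st <- genome$genes$exon_starts[[i]]; en <- genome$genes$exon_ends[[i]]
  data.frame(start = st, end = en,
             cds_offset = cumsum(c(0L, (en - st)[-length(st)])))
}

# map a 0-based genomic position to 0-based CDS index (NA if intronic/outside)
genomic_to_cds <- function(genome, gene, pos) {
  ex <- .gene_exons(genome, gene)
  out <- rep(NA_integer_, length(pos))
  for (e in seq_len(nrow(ex))) {
    hit <- pos >= ex$start[e] & pos < ex$end[e]
    out[hit] <- ex$cds_offset[e] + (pos[hit] - ex$start[e])
  }
  out
}

# map 0-based CDS index to 0-based genomic position
cds_to_genomic <- function(genome, gene, cds_pos) {
  ex <- .gene_exons(genome, gene)
  out <- rep(NA_integer_, length(cds_pos))
  for (e in seq_len(nrow(ex))) {
    w <- ex$end[e] - ex$start[e]
    hit <- cds_pos >= ex$cds_offset[e] & cds_pos < ex$cds_offset[e] + w
    out[hit] <- ex$start[e] + (cds_pos[hit] - ex$cds_offset[e])
  }
  out
}

# TRUE when a 0-based genomic position lies within `margin` bp of an internal
# exon/intron boundary on the intron side (essential splice site)
is_splice_site <- function(genome, gene, pos, margin = 2L) {
  ex <- .gene_exons(genome, gene)
  ne <- nrow(ex)
  if (ne < 2) return(rep(FALSE, length(pos)))
  don <- ex$end[-ne]      # intron starts (donor side)
  acc <- ex$start[-1]     # intron ends (acceptor side)
  out <- rep(FALSE, length(pos))
  for (k in seq_along(don)) {
    out <- out | (pos >= don[k] & pos < don[k] + margin) |
                 (pos >= acc[k] - margin & pos < acc[k])
  }
  out
}
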