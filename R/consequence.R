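## Coding consequence classification and trinucleotide-context machinery.
## Contexts follow the standard 96-type convention: six pyrimidine-centred
## substitution classes x 16 flanking-base combinations, written "A[C>T]G".

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 trinucleotide substitution contexts
#'
#' @return character vector of the 96 context labels in canonical order.
#' @export
context96_levels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (f5 in .BASES) for (f3 in .BASES) {
    out <- c(out, paste0(f5, "[", s, "]", f3))
  }
  out
}

# canonical context label from an upstream base, ref, alt, downstream base;
# purine refs are reverse-complemented onto the pyrimidine strand
context96_label <- function(up, ref, alt, down) {
  pur <- ref %in% c("A", "G")
  u <- ifelse(pur, .COMPLEMENT[down], up)
  d <- ifelse(pur, .COMPLEMENT[up], down)
  r <- ifelse(pur, .COMPLEMENT[ref], ref)
  a <- ifelse(pur, .COMPLEMENT[alt], alt)
  paste0(u, "[", r, ">", a, "]", d)
}

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Enumerate every possible coding SNV of a genome
#'
#' For every gene, CDS position and alternative base, records the coding
#' consequence (synonymous, missense or nonsense) and the 96-type
#' trinucleotide context. This table is both the mutational "opportunity"
#' used by the dN/dS test and the sampling frame of the neutral coding
#' simulator. CDS edges are padded with 'A' for context purposes.
#'
#' @param genome a `genome_model`.
#' @return data.frame with columns gene, cds_pos (0-based), ref, alt,
#'   consequence, context.
#' @export
coding_site_table <- function(genome) {
  gc <- .genetic_code()
  res <- vector("list", nrow(genome$genes))
  for (i in seq_len(nrow(genome$genes))) {
    cds <- genome$genes$cds[i]
    L <- nchar(cds)
    s <- strsplit(cds, "")[[1]]
    up <- c("A", s[-L])
    down <- c(s[-1], "A")
    codon_idx <- (seq_len(L) - 1L) %/% 3L
    wp <- (seq_len(L) - 1L) %% 3L          # position within codon, 0..2
    codons <- substring(cds, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
    ref_aa <- gc[codons]
    out_alt <- vector("list", 4L)
    for (b in seq_along(.BASES)) {
      alt <- .BASES[b]
      keep <- s != alt
      mcod <- codons
      substr(mcod, wp + 1L, wp + 1L) <- alt
      alt_aa <- gc[mcod]
      cons <- ifelse(alt_aa == ref_aa, "synonymous",
                     ifelse(alt_aa == "*", "nonsense", "missense"))
      out_alt[[b]] <- data.frame(
        gene = genome$genes$gene[i],
        cds_pos = (seq_len(L) - 1L)[keep],
        ref = s[keep], alt = alt,
        consequence = cons[keep],
        context = context96_label(up[keep], s[keep], alt, down[keep]),
        stringsAsFactors = FALSE
      )
    }
    res[[i]] <- do.call(rbind, out_alt)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify a single coding SNV
#'
#' @param genome a `genome_model`.
#' @param gene gene symbol.
#' @param cds_pos 0-based CDS position.
#' @param alt alternative base.
#' @return list with `ref`, `consequence` and `context`.
#' @export
classify_coding_snv <- function(genome, gene, cds_pos, alt) {
  i <- match(gene, genome$genes$gene)
  stopifnot(!is.na(i), cds_pos >= 0, cds_pos < genome$genes$coding_len[i])
  cds <- genome$genes$cds[i]
  L <- nchar(cds)
  ref <- substr(cds, cds_pos + 1L, cds_pos + 1L)
  stopifnot(ref != alt)
  ci <- cds_pos %/% 3L
  codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
  mcod <- codon
  substr(mcod, cds_pos %% 3L + 1L, cds_pos %% 3L + 1L) <- alt
  gc <- .genetic_code()
  cons <- if (gc[mcod] == gc[codon]) "synonymous"
          else if (gc[mcod] == "*") "nonsense" else "missense"
  up <- if (cds_pos == 0) "A" else substr(cds, cds_pos, cds_pos)
  down <- if (cds_pos == L - 1) "A" else substr(cds, cds_pos + 2L, cds_pos + 2L)
  list(ref = ref, consequence = cons,
       context = context96_label(up, ref, alt, down))
}

# number of essential splice-site (position, alt) opportunities per gene:
# 2 intronic bases on each side of each internal boundary, 3 alts each
splice_opportunity <- function(genome, gene) {
  i <- match(gene, genome$genes$gene)
  ne <- genome$genes$n_exons[i]
  if (ne < 2) return(0L)
  as.integer((ne - 1L) * 4L * 3L)
}
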