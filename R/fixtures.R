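## Fixture resources: reference-style inputs that real pipelines take from
## external knowledgebases (COSMIC signatures, hotspot lists, known fusions,
## clinical evidence, disease ontology). All generated in code so that the
## stack runs without any download; content is synthetic but structurally
## faithful.

#' Generate fixture resources for the interpretation stack
#'
#' Builds, deterministically from `seed`:
#' \itemize{
#'   \item a 96 x 30 mutational signature matrix (columns sum to 1),
#'   \item a hotspot list (one or two recurrent codons per panel oncogene),
#'   \item a known-fusion list (5'/3' pairs plus promiscuous 3' partners),
#'   \item a germline predisposition panel (25 ACMG cancer genes + CDKN2A,
#'         CHEK2, BAP1, ATM),
#'   \item a clinical-evidence knowledgebase in a common data model,
#'   \item a small disease-ontology (DOID-style) parent table.
#' }
#'
#' @param genome a `genome_model` (hotspots are placed on its genes).
#' @param seed integer seed.
#' @return object of class `fixture_resources` (a named list).
#' @export
make_fixture_resources <- function(genome, seed = 424242L) {
  withr::with_seed(seed, {
    sig <- .make_signature_matrix(30L)
    hotspots <- .make_hotspots(genome)
    fusions <- list(
      pairs = data.frame(
        five_gene = c("TMPRSS2", "GENE001", "GENE002"),
        three_gene = c("ERG", "ALK", "BRAF"),
        stringsAsFactors = FALSE
      ),
      promiscuous_three = c("ERG", "ALK", "BRAF")
    )
    kb <- .make_knowledgebase()
    ontology <- .make_ontology()
    structure(list(
      site_table = coding_site_table(genome),
      signature_matrix = sig,
      hotspots = hotspots,
      known_fusions = fusions,
      germline_panel = germline_panel_genes(),
      knowledgebase = kb,
      ontology = ontology,
      gene_panel = genome$genes[genome$genes$is_panel,
                                c("gene", "chrom", "role", "is_panel")],
      seed = seed
    ), class = "fixture_resources")
  })
}

# sparse Dirichlet-like signature profiles; columns L1-normalised
.make_signature_matrix <- function(n_sig = 30L) {
  ctx <- context96_levels()
  m <- matrix(0, nrow = 96, ncol = n_sig,
              dimnames = list(ctx, paste0("S", seq_len(n_sig))))
  for (j in seq_len(n_sig)) {
    x <- stats::rgamma(96, shape = 0.08)
    # give each signature a few dominant peaks so profiles are well separated
    peaks <- sample.int(96, 4L)
    x[peaks] <- x[peaks] + stats::rgamma(4, shape = 3, rate = 0.5)
    m[, j] <- x / sum(x)
  }
  m
}

# one or two hotspot codons per panel oncogene, with genomic coordinates
.make_hotspots <- function(genome) {
  onc <- genome$genes[genome$genes$role == "oncogene", ]
  rows <- list()
  for (i in seq_len(nrow(onc))) {
    k <- sample(1:2, 1)
    codons <- sort(sample.int(onc$n_codons[i] - 2L, k))
    cds_pos <- (codons - 1L) * 3L + 1L       # middle base of the codon
    gpos <- cds_to_genomic(genome, onc$gene[i], cds_pos)
    rows[[i]] <- data.frame(gene = onc$gene[i], chrom = onc$chrom[i],
                            pos = gpos, cds_pos = cds_pos,
                            codon = codons, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# evidence knowledgebase in the common data model; includes C-level records
# (must be dropped on load), a cross-source duplicate, and a resistance
# record sharing a drug with a sensitivity record
.make_knowledgebase <- function() {
  rec <- function(gene, class, detail, drug, level, direction, doid, source) {
    data.frame(gene = gene, event_class = class, detail = detail,
               drug = drug, level = level, direction = direction,
               doid = doid, source = source, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    rec("BRAF", "mutation", "hotspot", "vemurafenib", "A", "sensitivity",
        "8923", "cgi"),
    rec("BRAF", "mutation", "hotspot", "vemurafenib", "A", "sensitivity",
        "8923", "civic"),                       # duplicate across sources
    rec("KRAS", "mutation", "", "cetuximab", "A", "resistance", "9256", "cgi"),
    rec("EGFR", "amplification", "", "cetuximab", "A", "sensitivity",
        "9256", "onco"),
    rec("EGFR", "mutation", "hotspot", "erlotinib", "A", "sensitivity",
        "1324", "civic"),
    rec("ERBB2", "amplification", "", "trastuzumab", "A", "sensitivity",
        "1612", "onco"),
    rec("PIK3CA", "mutation", "hotspot", "alpelisib", "B", "sensitivity",
        "1612", "civic"),
    rec("PTEN", "deletion", "", "capivasertib", "B", "sensitivity",
        "162", "civic"),
    rec("CDKN2A", "deletion", "", "palbociclib", "B", "sensitivity",
        "162", "cgi"),
    rec("ALK", "fusion", "", "crizotinib", "A", "sensitivity", "1324", "onco"),
    rec("TMPRSS2-ERG", "fusion", "", "ets-inhibitor", "B", "sensitivity",
        "10283", "civic"),
    rec("MSI", "MSI", "", "pembrolizumab", "A", "sensitivity", "162", "onco"),
    rec("KRAS", "amplification", "", "experimental-x", "C", "sensitivity",
        "162", "cgi"),                          # C level: dropped on load
    rec("MDM2", "amplification", "", "experimental-y", "D", "sensitivity",
        "162", "civic")                         # D level: dropped on load
  ))
}

# DOID-style ontology: child -> parent edges, rooted at "162" (cancer)
.make_ontology <- function() {
  data.frame(
    id     = c("1612", "3458", "1324", "3908", "9256", "10283", "8923",
               "4159", "3459"),
    parent = c("162",  "1612", "162",  "1324", "162",  "162",   "4159",
               "162",  "1612"),
    name   = c("breast cancer", "breast lobular carcinoma", "lung cancer",
               "non-small cell lung carcinoma", "colorectal cancer",
               "prostate cancer", "skin melanoma", "skin cancer",
               "breast ductal carcinoma"),
    stringsAsFactors = FALSE
  )
}

#' Test whether one disease-ontology term is the same as or a descendant of
#' another
#'
#' @param id query DOID (character).
#' @param ancestor candidate ancestor DOID.
#' @param ontology ontology edge table (columns `id`, `parent`).
#' @return logical.
#' @export
doid_is_a <- function(id, ancestor, ontology) {
  if (is.na(id) || is.na(ancestor)) return(FALSE)
  cur <- id
  seen <- character(0)
  while (length(cur) == 1 && !cur %in% seen) {
    if (cur == ancestor) return(TRUE)
    seen <- c(seen, cur)
    cur <- ontology$parent[match(cur, ontology$id)]
    if (is.na(cur)) return(FALSE)
  }
  FALSE
}

#' Write fixture resources to plain-text files
#'
#' @param fx a `fixture_resources` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_resources <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(context = rownames(fx$signature_matrix),
                           as.data.frame(fx$signature_matrix)),
                     file.path(dir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$hotspots, file.path(dir, "hotspots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$known_fusions$pairs, file.path(dir, "known_fusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(fx$germline_panel, file.path(dir, "germline_panel.txt"))
  jsonlite::write_json(fx$knowledgebase, file.path(dir, "knowledgebase.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.table(fx$ontology, file.path(dir, "ontology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$gene_panel, file.path(dir, "gene_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
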