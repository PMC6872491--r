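## Clinical actionability: knowledgebase in a common evidence model,
## biomarker matching with disease-ontology label status, resistance
## exclusion and per-sample ranking.

#' Load and normalise a clinical-evidence knowledgebase
#'
#' Records are normalised to the common data model (gene, event class,
#' detail, drug, evidence level, direction, disease-ontology id); only A
#' and B level records are retained, and duplicates across sources are
#' collapsed.
#'
#' @param x a data.frame of records, or a path to a JSON/TSV fixture file.
#' @return data.frame of evidence records.
#' @export
load_knowledgebase <- function(x) {
  kb <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::fromJSON(x)
    else utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  } else x
  if (nrow(kb) == 0) return(kb)
  need <- c("gene", "event_class", "detail", "drug", "level", "direction",
            "doid")
  stopifnot(all(need %in% names(kb)))
  bad <- !kb$level %in% c("A", "B", "C", "D", "E")
  if (any(bad)) stop("unknown evidence level token: ",
                     paste(unique(kb$level[bad]), collapse = ", "))
  kb <- kb[kb$level %in% c("A", "B"), , drop = FALSE]
  kb$doid <- as.character(kb$doid)
  key <- do.call(paste, kb[need])
  kb <- kb[!duplicated(key), need, drop = FALSE]
  rownames(kb) <- NULL
  kb
}

#' Match a sample's driver events against the knowledgebase
#'
#' Every sensitivity record matching an event is returned; matching
#' granularity is exact detail > gene + event class > gene, most specific
#' wins per (event, drug). MSI samples gain a level-A match from the MSI
#' biomarker. A match is on-label when the sample's disease-ontology id is
#' the record's id or one of its descendants; samples without an ontology
#' id get off-label matches with a warning.
#'
#' @param catalogue sample driver catalogue (gene, class, variant,
#'   hotspot).
#' @param msi_status TRUE when the sample is MSI.
#' @param kb knowledgebase from [load_knowledgebase()].
#' @param doid sample disease-ontology id (character or NA).
#' @param ontology ontology edge table.
#' @return data.frame of matches: biomarker, drug, level, direction,
#'   on_label.
#' @export
match_actionable_events <- function(catalogue, msi_status, kb, doid,
                                    ontology) {
  if (is.null(doid) || is.na(doid)) {
    warning("sample has no disease-ontology id; all matches off-label")
    doid <- NA_character_
  }
  class_map <- c(point = "mutation", amplification = "amplification",
                 homozygous_deletion = "deletion", fusion = "fusion")
  rows <- list()
  consider <- function(rec, biomarker) {
    on <- if (is.na(doid)) FALSE else doid_is_a(doid, rec$doid, ontology)
    rows[[length(rows) + 1]] <<- data.frame(
      biomarker = biomarker, drug = rec$drug, level = rec$level,
      direction = rec$direction, on_label = on, stringsAsFactors = FALSE)
  }
  if (!is.null(catalogue) && nrow(catalogue)) {
    for (i in seq_len(nrow(catalogue))) {
      ev <- catalogue[i, ]
      ecl <- class_map[ev$class]
      if (is.na(ecl)) next
      # fusions are recorded either under the pair name or the 3' partner
      gene_keys <- unique(c(ev$gene, strsplit(ev$gene, "-")[[1]]))
      cand <- kb[kb$gene %in% gene_keys & kb$event_class == ecl, ,
                 drop = FALSE]
      if (nrow(cand) == 0) next
      # specificity: exact detail match beats class-level beats gene-level
      spec <- ifelse(nzchar(cand$detail) &
                       ((cand$detail == "hotspot" & isTRUE(ev$hotspot)) |
                          cand$detail == ev$variant), 2L,
                     ifelse(!nzchar(cand$detail), 1L, 0L))
      cand <- cand[spec > 0, , drop = FALSE]
      spec <- spec[spec > 0]
      if (nrow(cand) == 0) next
      for (drug in unique(cand$drug)) {
        sub <- cand[cand$drug == drug, , drop = FALSE]
        best <- which.max(spec[cand$drug == drug])
        consider(sub[best, ], paste0(ev$gene, ":", ev$class))
      }
    }
  }
  if (isTRUE(msi_status)) {
    msi_rec <- kb[kb$event_class == "MSI", , drop = FALSE]
    for (i in seq_len(nrow(msi_rec))) consider(msi_rec[i, ], "MSI")
  }
  if (!length(rows))
    return(data.frame(biomarker = character(0), drug = character(0),
                      level = character(0), direction = character(0),
                      on_label = logical(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Rank matches and report the sample's actionability call
#'
#' Treatments whose sensitivity evidence is countered by resistance
#' evidence from another biomarker in the same sample at the same or
#' higher evidence level are excluded as non-actionable. Remaining
#' sensitivity matches are ranked A on-label > A off-label > B on-label >
#' B off-label and the best is reported. The ranking is a total order, so
#' the result is invariant to the order of the match list.
#'
#' @param matches match table from [match_actionable_events()].
#' @return object of class `actionability_call`: `best_level`,
#'   `best_on_label`, `actionable` (logical), `treatments` (ranked
#'   sensitivity matches), `excluded` (drug + reason).
#' @export
rank_and_report <- function(matches) {
  sens <- matches[matches$direction == "sensitivity", , drop = FALSE]
  res <- matches[matches$direction == "resistance", , drop = FALSE]
  lvl_rank <- c(A = 2L, B = 1L)
  excluded <- data.frame(drug = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(sens) && nrow(res)) {
    drop <- logical(nrow(sens))
    for (i in seq_len(nrow(sens))) {
      r <- res[res$drug == sens$drug[i] &
                 res$biomarker != sens$biomarker[i], , drop = FALSE]
      if (nrow(r) && max(lvl_rank[r$level]) >= lvl_rank[sens$level[i]]) {
        drop[i] <- TRUE
        excluded <- rbind(excluded, data.frame(
          drug = sens$drug[i],
          reason = sprintf("resistance evidence at level %s",
                           r$level[which.max(lvl_rank[r$level])]),
          stringsAsFactors = FALSE))
      }
    }
    sens <- sens[!drop, , drop = FALSE]
  }
  excluded <- unique(excluded)
  if (nrow(sens) == 0)
    return(structure(list(best_level = NA_character_, best_on_label = NA,
                          actionable = FALSE, treatments = sens,
                          excluded = excluded),
                     class = "actionability_call"))
  score <- lvl_rank[sens$level] * 2L + as.integer(sens$on_label)
  ord <- order(-score, sens$drug, sens$biomarker)
  sens <- sens[ord, , drop = FALSE]
  rownames(sens) <- NULL
  structure(list(best_level = sens$level[1],
                 best_on_label = sens$on_label[1], actionable = TRUE,
                 treatments = sens, excluded = excluded),
            class = "actionability_call")
}

#' @export
print.actionability_call <- function(x, ...) {
  if (!x$actionable) {
    cat("actionability_call: no actionable treatment\n")
  } else {
    cat(sprintf("actionability_call: level %s %s; %d treatment(s), %d excluded\n",
                x$best_level,
                if (x$best_on_label) "on-label" else "off-label",
                nrow(x$treatments), nrow(x$excluded)))
  }
  invisible(x)
}
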