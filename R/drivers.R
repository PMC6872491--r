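## Driver catalogue: gene panel construction, TSG/oncogene role
## classification, GISTIC-like copy-number peak peel-off, per-sample driver
## calling across variant classes with likelihood scores, germline
## predisposition assessment, co-occurrence testing and burden summaries.

#' Build the candidate driver-gene panel
#'
#' Union of cohort significantly mutated genes (q < `significance`),
#' externally curated significantly mutated genes, and curated cancer
#' genes, with provenance flags; every member receives a TSG/oncogene role.
#'
#' @param dnds a `dnds_result` (cohort SMGs), or NULL.
#' @param external_smg character vector (external SMG list).
#' @param curated data.frame with columns `gene` and `role` (curated
#'   cancer-gene list with known roles).
#' @param role_features optional per-gene feature data.frame for
#'   [classify_gene_role()] (genes without curated role).
#' @param role_model fitted role classifier from [train_role_classifier()].
#' @param significance SMG inclusion cut-off.
#' @return data.frame: gene, smg_cohort, smg_external, curated, role,
#'   role_prob.
#' @export
build_gene_panel <- function(dnds = NULL, external_smg = character(0),
                             curated = NULL, role_features = NULL,
                             role_model = NULL, significance = 0.01) {
  cohort <- if (!is.null(dnds))
    unique(dnds$table$gene[!is.na(dnds$table$q) &
                             dnds$table$q < significance]) else character(0)
  cur_genes <- if (!is.null(curated)) curated$gene else character(0)
  genes <- sort(unique(c(cohort, external_smg, cur_genes)))
  if (!length(genes))
    return(data.frame(gene = character(0), smg_cohort = logical(0),
                      smg_external = logical(0), curated = logical(0),
                      role = character(0), role_prob = numeric(0),
                      stringsAsFactors = FALSE))
  role <- rep(NA_character_, length(genes))
  prob <- rep(NA_real_, length(genes))
  if (!is.null(curated)) {
    m <- match(genes, curated$gene)
    role[!is.na(m)] <- curated$role[m[!is.na(m)]]
    prob[!is.na(m)] <- 1
  }
  need <- which(is.na(role))
  if (length(need) && !is.null(role_features) && !is.null(role_model)) {
    f <- role_features[match(genes[need], role_features$gene), ]
    ok <- !is.na(f$gene)
    if (any(ok)) {
      cls <- classify_gene_role(f[ok, ], role_model)
      role[need[ok]] <- cls$role
      prob[need[ok]] <- cls$prob
    }
  }
  role[is.na(role)] <- "tsg"        # conservative default for unlabelled genes
  prob[is.na(prob)] <- 0.5
  data.frame(gene = genes, smg_cohort = genes %in% cohort,
             smg_external = genes %in% external_smg,
             curated = genes %in% cur_genes, role = role, role_prob = prob,
             stringsAsFactors = FALSE)
}

#' Train the TSG/oncogene role classifier
#'
#' Logistic regression on per-gene mutation features: fraction of
#' truncating variants, concentration of missense variants at the modal
#' codon, fraction of biallelic events, and in-frame indel fraction.
#' Trained on a synthetic labelled gene set emulating curated annotation.
#'
#' @param n training-set size.
#' @param seed integer seed (model is deterministic given the seed).
#' @return fitted `glm` object (family binomial; response 1 = TSG).
#' @export
train_role_classifier <- function(n = 400L, seed = 99L) {
  d <- simulate_role_training(n, seed)
  stats::glm(is_tsg ~ frac_truncating + missense_concentration +
               biallelic_fraction + inframe_fraction,
             family = stats::binomial(), data = d)
}

#' Simulate a labelled gene feature set for role classification
#'
#' TSGs show high truncating and biallelic fractions with dispersed
#' missense; oncogenes show concentrated missense hotspots, few
#' truncations, and in-frame indels.
#'
#' @param n number of genes.
#' @param seed integer seed.
#' @return data.frame of features with `is_tsg` labels.
#' @export
simulate_role_training <- function(n = 400L, seed = 99L) {
  withr::with_seed(seed, {
    is_tsg <- stats::runif(n) < 0.5
    rb <- function(t, a1, b1, a0, b0)
      stats::rbeta(n, ifelse(t, a1, a0), ifelse(t, b1, b0))
    # overlapping feature distributions: no single feature separates roles
    data.frame(
      gene = sprintf("TRAIN%04d", seq_len(n)),
      frac_truncating = rb(is_tsg, 4, 4, 1.2, 7),
      missense_concentration = rb(is_tsg, 2, 5, 4.5, 3),
      biallelic_fraction = rb(is_tsg, 4.5, 3, 2, 5),
      inframe_fraction = rb(is_tsg, 1, 9, 2, 6),
      is_tsg = is_tsg, stringsAsFactors = FALSE)
  })
}

#' Classify gene role (TSG vs oncogene) from mutation features
#'
#' @param features data.frame with the four feature columns of
#'   [simulate_role_training()].
#' @param model fitted classifier from [train_role_classifier()].
#' @return data.frame with `role` ("tsg"/"oncogene") and `prob`
#'   (probability of the assigned role).
#' @export
classify_gene_role <- function(features, model) {
  if (is.null(model)) stop("role classifier has not been trained")
  p_tsg <- stats::predict(model, newdata = features, type = "response")
  data.frame(role = ifelse(p_tsg >= 0.5, "tsg", "oncogene"),
             prob = ifelse(p_tsg >= 0.5, p_tsg, 1 - p_tsg))
}

## ---- copy-number peak peel-off -----------------------------------------

#' Find focal amplification/deletion peaks by iterative peel-off
#'
#' Per chromosome and direction: the gene with maximal supporting-sample
#' count seeds a peak; the peak extends over the maximal contiguous run of
#' genes carrying events in all of the seed's supporting samples; a single
#' target gene is chosen by curation rules (panel gene in peak, else
#' shortest gene fully inside the peak, else the seed); the supporting
#' samples' events on that chromosome are peeled off and the search
#' repeats until support falls below `max(min_support, support_fraction *
#' n_samples)`. Amplification events require min exonic CN > 3 x sample
#' ploidy; deletions require < 0.5 and exclude chromosome Y.
#'
#' @param events data.frame of per-sample gene events: sample, gene, chrom,
#'   direction ("amp"/"del"), and optionally del_size.
#' @param genome a `genome_model` (gene order along chromosomes).
#' @param n_samples cohort size (for the support threshold).
#' @param panel_genes character vector used by the curation rules.
#' @param min_support,support_fraction peel-off stopping rule.
#' @param fragile_min_length,fragile_min_rate,fragile_size_range
#'   fragile-site annotation constants (gene length > 500 kb and > 30% of
#'   its deletions sized 20 kb - 1 Mb).
#' @return data.frame of peaks: chrom, direction, start, end, target_gene,
#'   support, fragile_site.
#' @export
find_cn_peaks <- function(events, genome, n_samples,
                          panel_genes = character(0), min_support = 5L,
                          support_fraction = 0.02,
                          fragile_min_length = 5e5, fragile_min_rate = 0.3,
                          fragile_size_range = c(2e4, 1e6)) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(chrom = character(0), direction = character(0),
                      start = integer(0), end = integer(0),
                      target_gene = character(0), support = integer(0),
                      fragile_site = logical(0), stringsAsFactors = FALSE))
  thr <- max(min_support, ceiling(support_fraction * n_samples))
  ge <- genome$genes[order(match(genome$genes$chrom,
                                 genome$chromosomes$name),
                           genome$genes$start), ]
  peaks <- list()
  for (dir in c("amp", "del")) {
    ev_d <- events[events$direction == dir, ]
    if (dir == "del") ev_d <- ev_d[ev_d$chrom != "chrY", ]
    for (cn in unique(ev_d$chrom)) {
      gorder <- ge$gene[ge$chrom == cn]
      ev <- ev_d[ev_d$chrom == cn, ]
      repeat {
        if (nrow(ev) == 0) break
        support <- table(factor(ev$gene, levels = gorder))
        if (max(support) < thr) break
        seed <- gorder[which.max(support)]      # leftmost maximal gene
        seed_samples <- unique(ev$sample[ev$gene == seed])
        has_all <- vapply(gorder, function(g)
          all(seed_samples %in% ev$sample[ev$gene == g]), logical(1))
        si <- match(seed, gorder)
        lo <- si; hi <- si
        while (lo > 1 && has_all[lo - 1]) lo <- lo - 1
        while (hi < length(gorder) && has_all[hi + 1]) hi <- hi + 1
        peak_genes <- gorder[lo:hi]
        target <- .curate_peak_target(peak_genes, panel_genes, ge)
        gi <- match(peak_genes, ge$gene)
        fragile <- FALSE
        if (dir == "del") {
          tlen <- ge$length_bp[match(target, ge$gene)]
          sizes <- ev$del_size[ev$gene == target]
          sizes <- sizes[!is.na(sizes)]
          rate <- if (length(sizes))
            mean(sizes >= fragile_size_range[1] &
                   sizes <= fragile_size_range[2]) else 0
          fragile <- tlen > fragile_min_length & rate > fragile_min_rate
        }
        peaks[[length(peaks) + 1]] <- data.frame(
          chrom = cn, direction = dir, start = min(ge$start[gi]),
          end = max(ge$end[gi]), target_gene = target,
          support = length(seed_samples), fragile_site = fragile,
          stringsAsFactors = FALSE)
        ev <- ev[!ev$sample %in% seed_samples, ]     # peel off
      }
    }
  }
  if (!length(peaks))
    return(data.frame(chrom = character(0), direction = character(0),
                      start = integer(0), end = integer(0),
                      target_gene = character(0), support = integer(0),
                      fragile_site = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, peaks)
  out <- out[order(out$direction, -out$support), ]
  rownames(out) <- NULL
  out
}

# curation priority: panel gene in peak > shortest gene fully inside peak >
# peak seed (the gene at the support maximum, first element)
.curate_peak_target <- function(peak_genes, panel_genes, gene_table) {
  inpanel <- peak_genes[peak_genes %in% panel_genes]
  if (length(inpanel)) return(inpanel[1])
  gi <- match(peak_genes, gene_table$gene)
  peak_genes[which.min(gene_table$length_bp[gi])]
}

#' Per-sample copy-number driver events from fitted gene copy numbers
#'
#' @param gene_cn per-sample output of [gene_exonic_cn()], with a `sample`
#'   column and the sample's ploidy in `sample_ploidy`.
#' @param amp_factor high-level amplification bound (x sample ploidy,
#'   strict >).
#' @param homdel_threshold homozygous-deletion bound (strict <).
#' @return event data.frame for [find_cn_peaks()].
#' @export
cn_events <- function(gene_cn, amp_factor = 3, homdel_threshold = 0.5) {
  empty <- data.frame(sample = character(0), gene = character(0),
                      chrom = character(0), direction = character(0),
                      del_size = numeric(0), stringsAsFactors = FALSE)
  if (is.null(gene_cn) || nrow(gene_cn) == 0) return(empty)
  amp <- gene_cn[!is.na(gene_cn$min_exonic_cn) &
                   gene_cn$min_exonic_cn >
                     amp_factor * gene_cn$sample_ploidy, ]
  del <- gene_cn[!is.na(gene_cn$min_exonic_cn) &
                   gene_cn$min_exonic_cn < homdel_threshold, ]
  rbind(
    empty,
    if (nrow(amp)) data.frame(sample = amp$sample, gene = amp$gene,
                              chrom = amp$chrom, direction = "amp",
                              del_size = NA_real_, stringsAsFactors = FALSE),
    if (nrow(del)) data.frame(sample = del$sample, gene = del$gene,
                              chrom = del$chrom, direction = "del",
                              del_size = if ("del_size" %in% names(del))
                                del$del_size else NA_real_,
                              stringsAsFactors = FALSE))
}

## ---- point-mutation drivers --------------------------------------------

#' Call point-mutation driver events for one sample
#'
#' Inclusion rules: missense and in-frame indels for panel oncogenes;
#' nonsynonymous and essential-splice point mutations for panel TSGs;
#' recurrent TERT-promoter mutations as the only non-coding class. The
#' driver likelihood is E / (E + P_sample), where E is the gene/class
#' driver excess (observed - expected) from the cohort dN/dS fit and
#' P_sample the expected passenger count scaled by the sample's mutational
#' burden relative to the cohort mean. The likelihood is raised to at least
#' `override` for oncogene variants at or within `hotspot_margin`
#' nucleotides of a known hotspot, and for biallelic TSG variants in genes
#' with a high biallelic driver fraction.
#'
#' @param variants one sample's annotated variants (gene, consequence,
#'   chrom, pos, plus `biallelic` and `subclonal_prob` columns).
#' @param panel gene panel from [build_gene_panel()].
#' @param dnds cohort `dnds_result`.
#' @param sample_tmb this sample's TMB (mutations/Mb).
#' @param cohort_mean_tmb cohort mean TMB (burden reference).
#' @param hotspots hotspot table (gene, chrom, pos).
#' @param biallelic_genes genes whose drivers are predominantly biallelic
#'   (the biallelic override applies there).
#' @param hotspot_margin nt distance for the hotspot override.
#' @param override floor applied by the overrides.
#' @return data.frame of driver events: gene, class, variant, likelihood,
#'   biallelic, hotspot.
#' @export
call_point_drivers <- function(variants, panel, dnds, sample_tmb,
                               cohort_mean_tmb, hotspots = NULL,
                               biallelic_genes = character(0),
                               hotspot_margin = 5L, override = 0.99) {
  v <- variants[!is.na(variants$gene) & variants$gene %in% panel$gene, ,
                drop = FALSE]
  if (nrow(v) == 0)
    return(.empty_drivers())
  role <- panel$role[match(v$gene, panel$gene)]
  if (anyNA(role)) stop("panel missing role for gene(s): ",
                        paste(unique(v$gene[is.na(role)]), collapse = ", "))
  inframe <- v$consequence %in% "inframe_indel"
  keep_onc <- role == "oncogene" &
    (v$consequence %in% "missense" | inframe)
  keep_tsg <- role == "tsg" &
    v$consequence %in% c("missense", "nonsense", "splice", "inframe_indel",
                         "frameshift")
  keep_tert <- v$gene == "TERT" & v$consequence %in% "promoter"
  v <- v[keep_onc | keep_tsg | keep_tert, , drop = FALSE]
  if (nrow(v) == 0) return(.empty_drivers())
  role <- panel$role[match(v$gene, panel$gene)]

  cls_map <- c(missense = "missense", inframe_indel = "indel",
               frameshift = "indel", nonsense = "nonsense",
               splice = "splice", promoter = "missense")
  dn_class <- unname(cls_map[v$consequence])
  if (!is.null(dnds)) {
    tab <- dnds$table
    key <- paste(tab$gene, tab$class)
    m <- match(paste(v$gene, dn_class), key)
    obs <- ifelse(is.na(m), 0, tab$observed[m])
    expd <- ifelse(is.na(m), 0, tab$expected[m])
  } else {
    # no cohort excess estimate: only hotspot/biallelic evidence can
    # promote a variant
    obs <- expd <- rep(0, nrow(v))
  }
  E <- pmax(obs - expd, 0)
  burden <- if (cohort_mean_tmb > 0) sample_tmb / cohort_mean_tmb else 1
  P <- expd * burden
  lik <- ifelse(E + P > 0, E / (E + P), 0)

  is_hot <- rep(FALSE, nrow(v))
  if (!is.null(hotspots) && nrow(hotspots)) {
    for (i in seq_len(nrow(v))) {
      hs <- hotspots[hotspots$gene == v$gene[i], ]
      if (nrow(hs))
        is_hot[i] <- any(hs$chrom == v$chrom[i] &
                           abs(hs$pos + 1 - v$pos[i]) <= hotspot_margin)
    }
  }
  hot_override <- is_hot & role == "oncogene"
  bial <- if ("biallelic" %in% names(v)) v$biallelic else FALSE
  bial_override <- role == "tsg" & bial & v$gene %in% biallelic_genes
  lik[hot_override | bial_override] <-
    pmax(lik[hot_override | bial_override], override)
  lik[v$consequence %in% "promoter"] <-
    pmax(lik[v$consequence %in% "promoter"], override)

  data.frame(gene = v$gene, class = "point",
             variant = paste0(v$chrom, ":", v$pos, v$ref, ">", v$alt),
             likelihood = pmin(pmax(lik, 0), 1),
             biallelic = bial & role == "tsg", hotspot = is_hot,
             fragile_site = FALSE,
             subclonal_prob = v$subclonal_prob %||% NA_real_,
             stringsAsFactors = FALSE)
}

.empty_drivers <- function() {
  data.frame(gene = character(0), class = character(0),
             variant = character(0), likelihood = numeric(0),
             biallelic = logical(0), hotspot = logical(0),
             fragile_site = logical(0), subclonal_prob = numeric(0),
             stringsAsFactors = FALSE)
}

## ---- copy-number and fusion drivers ------------------------------------

#' Call amplification, deletion and fusion driver events for one sample
#'
#' Amplification drivers: minimum exonic copy number > `amp_factor` x
#' sample ploidy in significantly amplified target genes or panel
#' oncogenes. Deletion drivers: minimum exonic copy number <
#' `homdel_threshold` in significantly deleted target genes or panel TSGs.
#' Fusions are classified as in-frame coding (known 5'/3' pair or
#' promiscuous 3' partner, breakpoints in introns with matching coding
#' phase), cis-activating (breakpoint repositioning regulatory sequence
#' into the 5' region of a promiscuous partner), or in-frame intragenic
#' exon deletion (deleted exon length divisible by 3).
#'
#' @param gene_cn this sample's [gene_exonic_cn()] table plus
#'   `sample_ploidy`.
#' @param svs SV breakpoint table.
#' @param peaks peak table from [find_cn_peaks()] (may be empty).
#' @param panel gene panel.
#' @param known_fusions fixture list (pairs, promiscuous_three).
#' @param genome a `genome_model`.
#' @param sample_ploidy fitted sample ploidy.
#' @param amp_factor,homdel_threshold decision constants.
#' @return driver event data.frame.
#' @export
call_cn_and_fusion_drivers <- function(gene_cn, svs, peaks, panel,
                                       known_fusions, genome, sample_ploidy,
                                       amp_factor = 3,
                                       homdel_threshold = 0.5) {
  out <- list()
  amp_targets <- unique(c(peaks$target_gene[peaks$direction == "amp"],
                          panel$gene[panel$role == "oncogene"]))
  del_targets <- unique(c(peaks$target_gene[peaks$direction == "del"],
                          panel$gene[panel$role == "tsg"]))
  amp <- gene_cn[!is.na(gene_cn$min_exonic_cn) &
                   gene_cn$min_exonic_cn > amp_factor * sample_ploidy &
                   gene_cn$gene %in% amp_targets, ]
  if (nrow(amp))
    out[[length(out) + 1]] <- data.frame(
      gene = amp$gene, class = "amplification",
      variant = sprintf("CN=%.1f", amp$min_exonic_cn), likelihood = 1,
      biallelic = FALSE, hotspot = FALSE, fragile_site = FALSE,
      subclonal_prob = 0, stringsAsFactors = FALSE)
  del <- gene_cn[!is.na(gene_cn$min_exonic_cn) &
                   gene_cn$min_exonic_cn < homdel_threshold &
                   gene_cn$chrom != "chrY" &
                   gene_cn$gene %in% del_targets, ]
  if (nrow(del)) {
    frag <- if (!is.null(peaks) && nrow(peaks))
      peaks$fragile_site[match(del$gene, peaks$target_gene)]
      else rep(NA, nrow(del))
    frag[is.na(frag)] <- FALSE
    out[[length(out) + 1]] <- data.frame(
      gene = del$gene, class = "homozygous_deletion",
      variant = sprintf("CN=%.2f", del$min_exonic_cn), likelihood = 1,
      biallelic = TRUE, hotspot = FALSE, fragile_site = frag,
      subclonal_prob = 0, stringsAsFactors = FALSE)
  }
  fus <- classify_fusions(svs, genome, known_fusions)
  if (nrow(fus))
    out[[length(out) + 1]] <- data.frame(
      gene = fus$name, class = "fusion", variant = fus$subtype,
      likelihood = 1, biallelic = FALSE, hotspot = FALSE,
      fragile_site = FALSE, subclonal_prob = 0, stringsAsFactors = FALSE)
  if (!length(out)) return(.empty_drivers())
  do.call(rbind, out)
}

#' Classify SV breakpoints into fusion driver subtypes
#'
#' @param svs SV table (chrom1, pos1, orient1, chrom2, pos2, orient2, type).
#' @param genome a `genome_model`.
#' @param known_fusions fixture list with `pairs` and `promiscuous_three`.
#' @return data.frame: name, five_gene, three_gene, subtype (one of
#'   "in_frame_coding", "cis_activating", "intragenic_deletion").
#' @export
classify_fusions <- function(svs, genome, known_fusions) {
  res <- list()
  if (is.null(svs) || nrow(svs) == 0)
    return(data.frame(name = character(0), five_gene = character(0),
                      three_gene = character(0), subtype = character(0),
                      stringsAsFactors = FALSE))
  ge <- genome$genes
  gene_at <- function(chrom, pos) {
    hit <- which(ge$chrom == chrom & ge$start <= pos & ge$end > pos)
    if (length(hit)) ge$gene[hit[1]] else NA_character_
  }
  intron_phase <- function(gene, pos) {
    ex <- .gene_exons(genome, gene)
    ne <- nrow(ex)
    if (ne < 2) return(NA_integer_)
    for (k in seq_len(ne - 1)) {
      if (pos >= ex$end[k] && pos < ex$start[k + 1])
        return(sum(ex$end[seq_len(k)] - ex$start[seq_len(k)]) %% 3L)
    }
    NA_integer_
  }
  pair_known <- function(a, b) {
    kp <- known_fusions$pairs
    any(kp$five_gene == a & kp$three_gene == b)
  }
  for (i in seq_len(nrow(svs))) {
    s <- svs[i, ]
    ga <- gene_at(s$chrom1, s$pos1)
    gb <- gene_at(s$chrom2, s$pos2)
    # intragenic exon deletion
    if (!is.na(ga) && !is.na(gb) && ga == gb && s$type == "DEL") {
      ex <- .gene_exons(genome, ga)
      del_cov <- ex$start >= s$pos1 & ex$end <= s$pos2
      if (any(del_cov) &&
          sum((ex$end - ex$start)[del_cov]) %% 3L == 0L) {
        res[[length(res) + 1]] <- data.frame(
          name = ga, five_gene = ga, three_gene = ga,
          subtype = "intragenic_deletion", stringsAsFactors = FALSE)
      }
      next
    }
    # in-frame coding fusion: both breakends intronic, phases match,
    # pair known or 3' partner promiscuous
    if (!is.na(ga) && !is.na(gb) && ga != gb) {
      pa <- intron_phase(ga, s$pos1)
      pb <- intron_phase(gb, s$pos2)
      if (!is.na(pa) && !is.na(pb) && pa == pb &&
          (pair_known(ga, gb) ||
             gb %in% known_fusions$promiscuous_three)) {
        res[[length(res) + 1]] <- data.frame(
          name = paste0(ga, "-", gb), five_gene = ga, three_gene = gb,
          subtype = "in_frame_coding", stringsAsFactors = FALSE)
        next
      }
    }
    # cis-activating: breakend in the 5' regulatory window of a
    # promiscuous partner, partner end outside that gene
    gi <- which(ge$gene %in% known_fusions$promiscuous_three)
    for (k in gi) {
      win_lo <- max(0, ge$start[k] - 10000)
      in_window <- (s$chrom2 == ge$chrom[k] & s$pos2 >= win_lo &
                      s$pos2 < ge$start[k]) |
                   (s$chrom1 == ge$chrom[k] & s$pos1 >= win_lo &
                      s$pos1 < ge$start[k])
      if (in_window && (is.na(ga) || ga != ge$gene[k])) {
        res[[length(res) + 1]] <- data.frame(
          name = ge$gene[k], five_gene = NA_character_,
          three_gene = ge$gene[k], subtype = "cis_activating",
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(res))
    return(data.frame(name = character(0), five_gene = character(0),
                      three_gene = character(0), subtype = character(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, res))
}

## ---- germline predisposition -------------------------------------------

#' Assess germline predisposition variants against the tumour
#'
#' Restricted to the high-confidence panel (25 ACMG cancer genes plus
#' CDKN2A, CHEK2, BAP1, ATM). Each pathogenic variant is annotated with its
#' germline genotype, whether a second somatic hit exists in the same gene,
#' and whether the wild-type or the variant allele was lost by a copy
#' number alteration: at an LOH locus (minor allele ploidy below
#' `loh_threshold`), a tumour variant ploidy above CN - 0.5 means the wild
#' type was lost; a tumour variant ploidy below 0.5 means the variant
#' itself was lost.
#'
#' @param germline germline variant data frame (gene, genotype, clnsig,
#'   tumour_vaf, chrom, pos).
#' @param cn_segments fitted tumour copy-number segments.
#' @param somatic this sample's somatic variants (for second hits).
#' @param purity fitted tumour purity.
#' @param panel_genes high-confidence panel.
#' @param sex sample sex.
#' @param loh_threshold minor-ploidy LOH bound.
#' @return driver event data.frame with columns gene, class, variant,
#'   likelihood, genotype, second_hit, allele_status ("wildtype_lost",
#'   "variant_lost", "heterozygous_retained").
#' @export
call_germline_drivers <- function(germline, cn_segments, somatic, purity,
                                  panel_genes = germline_panel_genes(),
                                  sex = "male", loh_threshold = 0.25) {
  if (is.null(germline) || nrow(germline) == 0)
    return(data.frame(gene = character(0), class = character(0),
                      variant = character(0), likelihood = numeric(0),
                      genotype = character(0), second_hit = logical(0),
                      allele_status = character(0), stringsAsFactors = FALSE))
  g <- germline[germline$clnsig == "Pathogenic" &
                  germline$gene %in% panel_genes, , drop = FALSE]
  if (nrow(g) == 0)
    return(call_germline_drivers(NULL, cn_segments, somatic, purity))
  idx <- .segment_at(cn_segments, g$chrom, g$pos - 1L)
  cn <- cn_segments$cn[idx]
  minor <- cn_segments$minor[idx]
  nc <- .normal_cn(g$chrom, sex)
  v <- variant_ploidy_from_vaf(g$tumour_vaf, purity, cn, nc)
  loh <- !is.na(minor) & minor < loh_threshold
  status <- ifelse(!loh, "heterozygous_retained",
            ifelse(v > cn - 0.5, "wildtype_lost",
            ifelse(v < 0.5, "variant_lost", "heterozygous_retained")))
  second <- vapply(g$gene, function(gg)
    any(!is.na(somatic$gene) & somatic$gene == gg &
          somatic$consequence %in% c("missense", "nonsense", "splice",
                                     "frameshift", "inframe_indel")),
    logical(1))
  data.frame(gene = g$gene, class = "germline",
             variant = paste0(g$chrom, ":", g$pos, g$ref, ">", g$alt),
             likelihood = 1, genotype = g$genotype,
             second_hit = unname(second), allele_status = unname(status),
             stringsAsFactors = FALSE)
}

## ---- co-occurrence and summaries ---------------------------------------

#' Pairwise driver co-occurrence testing
#'
#' For every pair of driver genes, builds the 2 x 2 sample table and runs a
#' two-sided Fisher exact test, BH-corrected, with a signed direction
#' (co-occurring when the odds ratio exceeds 1, mutually exclusive
#' otherwise).
#'
#' @param catalogue cohort driver catalogue (columns sample, gene).
#' @param samples character vector of all cohort sample ids.
#' @return data.frame: gene_a, gene_b, n_both, n_a_only, n_b_only,
#'   n_neither, odds_ratio, direction, p, q.
#' @export
driver_cooccurrence <- function(catalogue, samples) {
  genes <- sort(unique(catalogue$gene))
  if (length(genes) < 2)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      n_both = integer(0), n_a_only = integer(0),
                      n_b_only = integer(0), n_neither = integer(0),
                      odds_ratio = numeric(0), direction = character(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  has <- vapply(genes, function(g)
    samples %in% catalogue$sample[catalogue$gene == g], logical(length(samples)))
  has <- matrix(has, nrow = length(samples))
  rows <- list()
  for (i in seq_len(length(genes) - 1)) for (j in (i + 1):length(genes)) {
    tab <- table(factor(has[, i], levels = c(TRUE, FALSE)),
                 factor(has[, j], levels = c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = genes[i], gene_b = genes[j], n_both = tab[1, 1],
      n_a_only = tab[1, 2], n_b_only = tab[2, 1], n_neither = tab[2, 2],
      odds_ratio = unname(ft$estimate),
      direction = if (ft$estimate > 1) "co_occurring" else "exclusive",
      p = ft$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Summarise driver burden per sample
#'
#' Driver burden is the sum of driver likelihoods; subclonal driver burden
#' is the sum of subclonal probability x driver likelihood.
#'
#' @param catalogue driver catalogue with columns sample, class,
#'   likelihood, subclonal_prob.
#' @return data.frame per sample: driver_burden, subclonal_driver_burden,
#'   and per-class burdens.
#' @export
summarize_driver_counts <- function(catalogue) {
  if (nrow(catalogue) == 0)
    return(data.frame(sample = character(0), driver_burden = numeric(0),
                      subclonal_driver_burden = numeric(0),
                      stringsAsFactors = FALSE))
  sp <- catalogue$subclonal_prob
  sp[is.na(sp)] <- 0
  agg <- function(x, f) tapply(x, catalogue$sample, f)
  out <- data.frame(sample = names(agg(catalogue$likelihood, sum)),
                    driver_burden = as.numeric(agg(catalogue$likelihood, sum)),
                    subclonal_driver_burden =
                      as.numeric(tapply(sp * catalogue$likelihood,
                                        catalogue$sample, sum)),
                    stringsAsFactors = FALSE)
  for (cls in unique(catalogue$class)) {
    sel <- catalogue$class == cls
    b <- tapply(catalogue$likelihood[sel], catalogue$sample[sel], sum)
    out[[paste0("burden_", cls)]] <- as.numeric(b[out$sample])
    out[[paste0("burden_", cls)]][is.na(out[[paste0("burden_", cls)]])] <- 0
  }
  rownames(out) <- NULL
  out
}
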