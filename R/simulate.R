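## Synthetic tumour-sample generator: ground truth plus observable data
## (segment BAF/depth summaries, somatic and germline variants, SV table).
## Observed VAFs are binomial draws at negative-binomial per-site depth under
## the purity/copy-number mixture; segment BAF and depth ratio derive from
## the same mixture.

#' Tumour simulation configuration
#'
#' Defaults emulate the sequencing design of a deep tumour/normal WGS pair
#' (106x tumour, 38x normal) on the scaled genome. `clones` must contain
#' exactly one clone with cancer-cell fraction 1; subclone CCFs are
#' restricted to (0.1, 0.9) so that clonal/subclonal truth is unambiguous.
#'
#' @param purity tumour purity in (0, 1].
#' @param sex "male" or "female".
#' @param wgd simulate a whole-genome-duplicated profile.
#' @param clones data.frame with columns `ccf` and `fraction` (mixture
#'   weights over variants, summing to 1).
#' @param n_snv,n_indel,n_mnv background somatic variant counts.
#' @param n_coding_snv neutral coding SNVs (drawn from the genome's coding
#'   site table when `fixtures` carry one; they feed cohort dN/dS).
#' @param n_sv background structural-variant count.
#' @param signature_mix named numeric vector of signature weights.
#' @param tumour_depth,normal_depth mean sequencing depths.
#' @param nb_size negative-binomial size (overdispersion) for per-site depth.
#' @param gc_bias_amplitude amplitude of multiplicative GC depth bias.
#' @param het_snp_per_kb density of informative germline heterozygous SNPs.
#' @param msi_target qualifying-indel density (per Mb) injected via
#'   [inject_msi()]; 0 adds none.
#' @param error_rate uniform sequencing error rate added to expected VAF.
#' @param segment_profile optional data.frame(chrom, start, end, major,
#'   minor) overriding the generated profile.
#' @param planted list of planted truth events; see [simulate_sample()].
#' @return object of class `tumour_sim_config`.
#' @export
tumour_sim_config <- function(purity = 0.65, sex = "male", wgd = FALSE,
                              clones = data.frame(ccf = 1, fraction = 1),
                              n_snv = 400L, n_indel = 40L, n_mnv = 5L,
                              n_sv = 8L, n_coding_snv = 25L,
                              signature_mix = c(S1 = 0.7, S5 = 0.3),
                              tumour_depth = 106, normal_depth = 38,
                              nb_size = 10, gc_bias_amplitude = 0,
                              het_snp_per_kb = 0.67, msi_target = 0,
                              error_rate = 0, segment_profile = NULL,
                              planted = list()) {
  if (!is.numeric(purity) || purity <= 0 || purity > 1)
    stop("purity must lie in (0, 1]")
  stopifnot(is.data.frame(clones), all(c("ccf", "fraction") %in% names(clones)))
  if (any(clones$ccf > 1)) stop("clone CCF must not exceed 1")
  if (sum(clones$ccf == 1) != 1)
    stop("exactly one clone must have CCF 1.0")
  sub <- clones$ccf[clones$ccf < 1]
  if (length(sub) && any(sub <= 0.1 | sub >= 0.9))
    stop("subclone CCFs must lie in (0.1, 0.9)")
  stopifnot(abs(sum(clones$fraction) - 1) < 1e-9)
  if (msi_target < 0) stop("msi_target must be >= 0")
  stopifnot(tumour_depth > 0, normal_depth > 0, nb_size >= 0)
  structure(list(purity = purity, sex = sex, wgd = wgd, clones = clones,
                 n_snv = as.integer(n_snv), n_indel = as.integer(n_indel),
                 n_mnv = as.integer(n_mnv), n_sv = as.integer(n_sv),
                 n_coding_snv = as.integer(n_coding_snv),
                 signature_mix = signature_mix,
                 tumour_depth = tumour_depth, normal_depth = normal_depth,
                 nb_size = nb_size, gc_bias_amplitude = gc_bias_amplitude,
                 het_snp_per_kb = het_snp_per_kb, msi_target = msi_target,
                 error_rate = error_rate, segment_profile = segment_profile,
                 planted = planted),
            class = "tumour_sim_config")
}

# normal (germline) copy number at a locus
.normal_cn <- function(chrom, sex) {
  ifelse(chrom == "chrY", ifelse(sex == "male", 1, 0),
         ifelse(chrom == "chrX", ifelse(sex == "male", 1, 2), 2))
}

## ---- segment-profile construction --------------------------------------

.base_state <- function(chrom, sex, wgd) {
  nc <- .normal_cn(chrom, sex)
  if (nc == 2) { if (wgd) c(2, 2) else c(1, 1) }
  else if (nc == 1) { if (wgd) c(2, 0) else c(1, 0) }
  else c(0, 0)
}

# aberrant allele-specific states and their relative frequencies; non-WGD
# tumours are dominated by losses and single-copy gains, WGD tumours by
# deviations around the doubled (2,2) baseline
.aberrant_pool <- function(wgd) {
  if (wgd)
    list(states = list(c(2, 1), c(3, 2), c(4, 2), c(2, 0), c(3, 1),
                       c(4, 1), c(3, 3)),
         weights = c(0.25, 0.2, 0.15, 0.15, 0.1, 0.05, 0.1))
  else
    list(states = list(c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(2, 2),
                       c(3, 2), c(4, 2)),
         weights = c(0.25, 0.15, 0.3, 0.1, 0.1, 0.05, 0.05))
}

.generate_segment_profile <- function(genome, config) {
  rows <- list()
  pool <- .aberrant_pool(config$wgd)
  for (i in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$name[i]
    L <- genome$chromosomes$length[i]
    nc <- .normal_cn(chrom, config$sex)
    if (nc == 0) next
    base <- .base_state(chrom, config$sex, config$wgd)
    nseg <- sample(2:4, 1)
    bp <- sort(sample.int(L - 1L, nseg - 1L))
    st <- c(0L, bp); en <- c(bp, L)
    for (s in seq_len(nseg)) {
      state <- base
      if (nc == 2 && stats::runif(1) < 0.3)
        state <- pool$states[[sample.int(length(pool$states), 1,
                                         prob = pool$weights)]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = st[s], end = en[s],
        major = state[1], minor = state[2], stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  # identifiability: realistic profiles carry LOH somewhere; force one
  aut <- prof$chrom %in% genome$chromosomes$name[genome$chromosomes$is_autosome]
  if (!any(prof$minor[aut] == 0 & prof$major[aut] >= 1)) {
    k <- which(aut)[1]
    prof$major[k] <- if (config$wgd) 2 else 1
    prof$minor[k] <- 0
  }
  prof
}

# carve an interval with a fixed allele-specific state into a profile
.carve_segment <- function(prof, chrom, start, end, major, minor) {
  out <- list()
  for (i in seq_len(nrow(prof))) {
    r <- prof[i, ]
    if (r$chrom != chrom || r$end <= start || r$start >= end) {
      out[[length(out) + 1]] <- r
      next
    }
    if (r$start < start) {
      left <- r; left$end <- start
      out[[length(out) + 1]] <- left
    }
    if (r$end > end) {
      right <- r; right$start <- end
      out[[length(out) + 1]] <- right
    }
  }
  out[[length(out) + 1]] <- data.frame(chrom = chrom, start = start,
                                       end = end, major = major,
                                       minor = minor, stringsAsFactors = FALSE)
  prof <- do.call(rbind, out)
  prof <- prof[prof$end > prof$start, ]
  prof[order(match(prof$chrom, unique(prof$chrom)), prof$start), ]
}

.gene_interval <- function(genome, gene, margin = 0L) {
  i <- match(gene, genome$genes$gene)
  stopifnot(!is.na(i))
  g <- genome$genes[i, ]
  L <- genome$chromosomes$length[match(g$chrom, genome$chromosomes$name)]
  list(chrom = g$chrom, start = max(0L, g$start - margin),
       end = min(L, g$end + margin))
}

## ---- observation simulators --------------------------------------------

.sim_depth <- function(n, mu, nb_size) {
  d <- if (nb_size > 0) stats::rnbinom(n, mu = mu, size = nb_size)
       else stats::rpois(n, mu)
  pmax(1L, d)
}

# simulate observed (alt_count, depth, vaf) for variants with variant ploidy v
.sim_vaf <- function(purity, cn, normal_cn, v, tumour_depth, sample_ploidy,
                     nb_size, error_rate = 0) {
  mu <- tumour_depth * mixture_denom(purity, cn, normal_cn) /
    mixture_denom(purity, sample_ploidy, 2)
  d <- .sim_depth(length(v), pmax(mu, 1e-3), nb_size)
  ev <- expected_vaf(v, purity, cn, normal_cn)
  ev <- ev * (1 - error_rate) + error_rate / 3
  a <- stats::rbinom(length(v), d, ev)
  data.frame(alt_count = a, depth = d, vaf = a / d)
}

# locate each (chrom, pos) in a segment profile; returns row index
.segment_at <- function(prof, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    pr <- which(prof$chrom == cn)
    if (!length(pr)) next
    f <- findInterval(pos[sel], prof$start[pr])
    ok <- f >= 1 & pos[sel] < prof$end[pr][pmax(f, 1)]
    idx[sel[ok]] <- pr[f[ok]]
  }
  idx
}

# draw trinucleotide contexts (and implied ref/alt) from a signature mixture
.draw_contexts <- function(n, signature_mix, signature_matrix) {
  ctx_levels <- rownames(signature_matrix)
  if (is.null(signature_matrix) || n == 0)
    return(data.frame(context = character(0), ref = character(0),
                      alt = character(0)))
  w <- signature_mix / sum(signature_mix)
  sig <- sample(names(w), n, replace = TRUE, prob = w)
  ctx <- vapply(sig, function(s)
    sample(ctx_levels, 1, prob = signature_matrix[, s]), character(1))
  ref <- substr(ctx, 3, 3)
  alt <- substr(ctx, 5, 5)
  # half the events are placed on the complementary strand
  flip <- stats::runif(n) < 0.5
  ref[flip] <- .COMPLEMENT[ref[flip]]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  data.frame(context = unname(ctx), ref = unname(ref), alt = unname(alt),
             stringsAsFactors = FALSE)
}

.empty_somatic <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), type = character(0), alt_count = integer(0),
             depth = integer(0), vaf = numeric(0), phase_set = character(0),
             gene = character(0), consequence = character(0),
             context = character(0), stringsAsFactors = FALSE)
}

## ---- main generator ----------------------------------------------------

#' Simulate one synthetic tumour sample
#'
#' Generates ground truth (allele-specific segment profile, clone structure,
#' planted driver events) and observable data: segment BAF/depth-ratio
#' summaries, somatic small variants with binomially sampled VAFs, germline
#' variants, and an SV breakpoint table.
#'
#' `config$planted` may contain: `hotspots` (oncogene symbols receiving a
#' clonal hotspot missense SNV), `biallelic_tsg` (TSGs receiving LOH plus a
#' clonal nonsense SNV), `amplifications`, `homozygous_deletions` (gene
#' symbols), `fusions` (data.frame five_gene/three_gene), `intragenic_dels`,
#' `cis_fusions` (3' gene symbols), `tert_promoter` (logical) and `germline`
#' (data.frame gene/loh/second_hit with loh one of "none", "wildtype",
#' "variant").
#'
#' @param genome a `genome_model`.
#' @param config a `tumour_sim_config`.
#' @param seed integer seed; identical seeds give identical samples.
#' @param fixtures optional `fixture_resources` (required for hotspot
#'   planting and signature-context draws).
#' @param sample_id,patient_id,cancer_type,doid sample metadata.
#' @return object of class `tumour_sample`: list with `truth`, `segments`,
#'   `somatic`, `germline`, `svs`.
#' @export
simulate_sample <- function(genome, config = tumour_sim_config(), seed = 1L,
                            fixtures = NULL, sample_id = "SAMPLE01",
                            patient_id = sample_id,
                            cancer_type = "breast cancer", doid = "1612") {
  stopifnot(inherits(genome, "genome_model"),
            inherits(config, "tumour_sim_config"))
  if (nrow(genome$chromosomes) == 0) stop("empty genome")
  p <- config$purity
  pl <- config$planted
  withr::with_seed(seed, {
    prof <- config$segment_profile %||% .generate_segment_profile(genome, config)

    ## planted copy-number carve-outs
    psi0 <- sum((prof$major + prof$minor) * (prof$end - prof$start)) /
      sum(prof$end - prof$start)
    for (g in pl$amplifications %||% character(0)) {
      iv <- .gene_interval(genome, g, margin = 10000L)
      amp_cn <- ceiling(3 * psi0) + 3
      prof <- .carve_segment(prof, iv$chrom, iv$start, iv$end, amp_cn - 1, 1)
    }
    for (g in pl$homozygous_deletions %||% character(0)) {
      iv <- .gene_interval(genome, g,
                           margin = as.integer(sample(10000:120000, 1)))
      prof <- .carve_segment(prof, iv$chrom, iv$start, iv$end, 0, 0)
    }
    for (g in pl$biallelic_tsg %||% character(0)) {
      iv <- .gene_interval(genome, g, margin = 50000L)
      prof <- .carve_segment(prof, iv$chrom, iv$start, iv$end, 1, 0)
    }
    glp <- pl$germline
    if (!is.null(glp)) {
      for (k in seq_len(nrow(glp))) {
        if (glp$loh[k] %in% c("wildtype", "variant")) {
          iv <- .gene_interval(genome, glp$gene[k], margin = 50000L)
          prof <- .carve_segment(prof, iv$chrom, iv$start, iv$end, 1, 0)
        }
      }
    }

    seg_len <- prof$end - prof$start
    cn <- prof$major + prof$minor
    psi <- sum(cn * seg_len) / sum(seg_len)

    ## segment observables
    nc_seg <- .normal_cn(prof$chrom, config$sex)
    gc <- stats::runif(nrow(prof), 0.35, 0.60)
    eratio <- expected_depth_ratio(p, cn, psi, nc_seg) *
      (1 + config$gc_bias_amplitude * (gc - 0.475) / 0.125)
    # ratio noise from read sampling: gamma with shape ~ effective read
    # count over the segment (capped by the per-site NB overdispersion)
    shape <- pmax(20, seg_len * config$tumour_depth / 500)
    ratio_obs <- stats::rgamma(nrow(prof), shape = shape,
                               rate = shape / pmax(eratio, 1e-6))
    baf_count <- ifelse(nc_seg == 2,
                        pmax(0L, round(seg_len / 1000 * config$het_snp_per_kb)),
                        0L)
    ebaf <- expected_baf(p, prof$major, prof$minor)
    site_depth <- pmax(1, config$tumour_depth *
                         mixture_denom(p, cn, nc_seg) /
                         mixture_denom(p, psi, 2))
    reads <- pmax(1, round(baf_count * site_depth))
    baf_obs <- ifelse(baf_count > 0,
                      stats::rbinom(nrow(prof), reads, ebaf) / reads, NA_real_)
    segments <- data.frame(chrom = prof$chrom, start = prof$start,
                           end = prof$end, baf = baf_obs,
                           baf_count = baf_count, depth_ratio = ratio_obs,
                           gc = gc, stringsAsFactors = FALSE)

    ## background somatic SNVs
    som <- list()
    n_snv <- config$n_snv
    if (n_snv > 0) {
      chroms <- genome$chromosomes
      ci <- sample.int(nrow(chroms), n_snv, replace = TRUE,
                       prob = chroms$length)
      pos <- vapply(ci, function(i) sample.int(chroms$length[i], 1L),
                    integer(1))
      chrom <- chroms$name[ci]
      segi <- .segment_at(prof, chrom, pos)
      ok <- !is.na(segi)
      chrom <- chrom[ok]; pos <- pos[ok]; segi <- segi[ok]
      m <- length(pos)
      ccf <- sample(config$clones$ccf, m, replace = TRUE,
                    prob = config$clones$fraction)
      major <- prof$major[segi]; minor <- prof$minor[segi]
      cnv <- major + minor
      dup_frac <- if (config$wgd) 0.4 else 0.1
      mult <- ifelse(ccf == 1 & major >= 2 & stats::runif(m) < dup_frac,
                     major, 1)
      keep <- cnv > 0
      chrom <- chrom[keep]; pos <- pos[keep]; segi <- segi[keep]
      ccf <- ccf[keep]; mult <- mult[keep]; cnv <- cnv[keep]
      m <- length(pos)
      v <- ccf * mult
      ncv <- .normal_cn(chrom, config$sex)
      obs <- .sim_vaf(p, cnv, ncv, v, config$tumour_depth, psi,
                      config$nb_size, config$error_rate)
      if (!is.null(fixtures)) {
        ctx <- .draw_contexts(m, config$signature_mix,
                              fixtures$signature_matrix)
      } else {
        ref <- sample(.BASES, m, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1),
                      character(1))
        ctx <- data.frame(context = NA_character_, ref = ref, alt = alt,
                          stringsAsFactors = FALSE)
      }
      som[[length(som) + 1]] <- data.frame(
        chrom = chrom, pos = as.integer(pos + 1L), ref = ctx$ref,
        alt = ctx$alt, type = "SNV", alt_count = obs$alt_count,
        depth = obs$depth, vaf = obs$vaf, phase_set = NA_character_,
        gene = NA_character_, consequence = NA_character_,
        context = ctx$context, ccf_truth = ccf, mult_truth = mult,
        stringsAsFactors = FALSE)
    }

    ## phased MNV runs (adjacent SNVs sharing a phase set)
    if (config$n_mnv > 0) {
      rows <- list()
      for (k in seq_len(config$n_mnv)) {
        len <- sample(c(2L, 2L, 2L, 2L, 3L), 1)
        i <- sample.int(nrow(genome$chromosomes), 1,
                        prob = genome$chromosomes$length)
        chrom <- genome$chromosomes$name[i]
        pos0 <- sample.int(genome$chromosomes$length[i] - len, 1L)
        segi <- .segment_at(prof, chrom, pos0)
        if (is.na(segi) || prof$major[segi] + prof$minor[segi] == 0) next
        cnv <- prof$major[segi] + prof$minor[segi]
        ncv <- .normal_cn(chrom, config$sex)
        obs <- .sim_vaf(p, rep(cnv, len), rep(ncv, len), rep(1, len),
                        config$tumour_depth, psi, config$nb_size,
                        config$error_rate)
        ref <- sample(.BASES, len, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1),
                      character(1))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = as.integer(pos0 + seq_len(len)), ref = ref,
          alt = alt, type = "SNV", alt_count = obs$alt_count,
          depth = obs$depth, vaf = obs$vaf,
          phase_set = sprintf("PS%03d", k), gene = NA_character_,
          consequence = NA_character_, context = NA_character_,
          ccf_truth = 1, mult_truth = 1, stringsAsFactors = FALSE)
      }
      if (length(rows)) som[[length(som) + 1]] <- do.call(rbind, rows)
    }

    ## background indels (fraction at microsatellites)
    if (config$n_indel > 0) {
      ni <- config$n_indel
      at_ms <- stats::runif(ni) < 0.4
      ms <- genome$microsatellites
      rows <- list()
      for (k in seq_len(ni)) {
        if (at_ms[k] && nrow(ms) > 0) {
          j <- sample.int(nrow(ms), 1)
          chrom <- ms$chrom[j]; pos0 <- ms$start[j]
        } else {
          i <- sample.int(nrow(genome$chromosomes), 1,
                          prob = genome$chromosomes$length)
          chrom <- genome$chromosomes$name[i]
          pos0 <- sample.int(genome$chromosomes$length[i] - 2L, 1L)
        }
        segi <- .segment_at(prof, chrom, pos0)
        if (is.na(segi) || prof$major[segi] + prof$minor[segi] == 0) next
        cnv <- prof$major[segi] + prof$minor[segi]
        ncv <- .normal_cn(chrom, config$sex)
        obs <- .sim_vaf(p, cnv, ncv, 1, config$tumour_depth, psi,
                        config$nb_size, config$error_rate)
        del <- stats::runif(1) < 0.5
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = as.integer(pos0 + 1L),
          ref = if (del) "AT" else "A", alt = if (del) "A" else "AT",
          type = "INDEL", alt_count = obs$alt_count, depth = obs$depth,
          vaf = obs$vaf, phase_set = NA_character_, gene = NA_character_,
          consequence = NA_character_, context = NA_character_,
          ccf_truth = 1, mult_truth = 1, stringsAsFactors = FALSE)
      }
      if (length(rows)) som[[length(som) + 1]] <- do.call(rbind, rows)
    }

    ## neutral background coding SNVs (feed cohort dN/dS)
    if (config$n_coding_snv > 0 && !is.null(fixtures$site_table)) {
      st <- fixtures$site_table
      sub <- sub(".*\\[(.>.)\\].*", "\\1", st$context)
      w <- ifelse(sub %in% c("C>T", "T>C"), 3, 1)
      nct <- stats::rpois(1, config$n_coding_snv)
      if (nct > 0) {
        ci <- sample.int(nrow(st), nct, replace = TRUE, prob = w)
        gpos <- vapply(ci, function(k)
          as.integer(cds_to_genomic(genome, st$gene[k], st$cds_pos[k])),
          integer(1))
        chrom <- genome$genes$chrom[match(st$gene[ci], genome$genes$gene)]
        segi <- .segment_at(prof, chrom, gpos)
        ok <- !is.na(segi) & (prof$major[segi] + prof$minor[segi]) > 0
        if (any(ok)) {
          ci <- ci[ok]; gpos <- gpos[ok]; chrom <- chrom[ok]
          segi <- segi[ok]
          cnv <- prof$major[segi] + prof$minor[segi]
          ncv <- .normal_cn(chrom, config$sex)
          obs <- .sim_vaf(p, cnv, ncv, rep(1, length(ci)),
                          config$tumour_depth, psi, config$nb_size,
                          config$error_rate)
          som[[length(som) + 1]] <- data.frame(
            chrom = chrom, pos = as.integer(gpos + 1L), ref = st$ref[ci],
            alt = st$alt[ci], type = "SNV", alt_count = obs$alt_count,
            depth = obs$depth, vaf = obs$vaf, phase_set = NA_character_,
            gene = st$gene[ci], consequence = st$consequence[ci],
            context = st$context[ci], ccf_truth = 1, mult_truth = 1,
            stringsAsFactors = FALSE)
        }
      }
    }

    ## planted coding drivers
    planted_truth <- list()
    plant_coding <- function(gene, want, label) {
      i <- match(gene, genome$genes$gene)
      stopifnot(!is.na(i))
      cds_len <- genome$genes$coding_len[i]
      hit <- NULL
      if (label == "hotspot" && !is.null(fixtures)) {
        hs <- fixtures$hotspots[fixtures$hotspots$gene == gene, ]
        cand <- if (nrow(hs)) hs$cds_pos[1] else NULL
      } else cand <- NULL
      tries <- c(cand, sample.int(cds_len, min(300L, cds_len)) - 1L)
      for (cp in tries) {
        for (alt in sample(.BASES)) {
          ref <- substr(genome$genes$cds[i], cp + 1, cp + 1)
          if (ref == alt) next
          cl <- classify_coding_snv(genome, gene, cp, alt)
          if (cl$consequence == want) { hit <- list(cds_pos = cp, alt = alt,
                                                    cl = cl); break }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) stop("could not plant ", want, " in ", gene)
      gpos <- cds_to_genomic(genome, gene, hit$cds_pos)
      chrom <- genome$genes$chrom[i]
      segi <- .segment_at(prof, chrom, gpos)
      cnv <- prof$major[segi] + prof$minor[segi]
      mult <- if (label == "biallelic") cnv else 1
      ncv <- .normal_cn(chrom, config$sex)
      obs <- .sim_vaf(p, cnv, ncv, mult, config$tumour_depth, psi,
                      config$nb_size, config$error_rate)
      data.frame(chrom = chrom, pos = as.integer(gpos + 1L),
                 ref = hit$cl$ref, alt = hit$alt, type = "SNV",
                 alt_count = obs$alt_count, depth = obs$depth, vaf = obs$vaf,
                 phase_set = NA_character_, gene = gene,
                 consequence = hit$cl$consequence, context = hit$cl$context,
                 ccf_truth = 1, mult_truth = mult, stringsAsFactors = FALSE)
    }
    for (g in pl$hotspots %||% character(0)) {
      row <- plant_coding(g, "missense", "hotspot")
      som[[length(som) + 1]] <- row
      planted_truth$hotspots <- rbind(planted_truth$hotspots,
                                      cbind(row[c("gene", "chrom", "pos")],
                                            class = "point"))
    }
    for (g in pl$biallelic_tsg %||% character(0)) {
      row <- plant_coding(g, "nonsense", "biallelic")
      som[[length(som) + 1]] <- row
      planted_truth$biallelic_tsg <- rbind(planted_truth$biallelic_tsg,
                                           cbind(row[c("gene", "chrom", "pos")],
                                                 class = "point"))
    }
    if (isTRUE(pl$tert_promoter)) {
      i <- match("TERT", genome$genes$gene)
      gpos <- max(0L, genome$genes$start[i] - 100L)
      chrom <- genome$genes$chrom[i]
      segi <- .segment_at(prof, chrom, gpos)
      cnv <- prof$major[segi] + prof$minor[segi]
      obs <- .sim_vaf(p, cnv, .normal_cn(chrom, config$sex), 1,
                      config$tumour_depth, psi, config$nb_size,
                      config$error_rate)
      som[[length(som) + 1]] <- data.frame(
        chrom = chrom, pos = as.integer(gpos + 1L), ref = "C", alt = "T",
        type = "SNV", alt_count = obs$alt_count, depth = obs$depth,
        vaf = obs$vaf, phase_set = NA_character_, gene = "TERT",
        consequence = "promoter", context = NA_character_, ccf_truth = 1,
        mult_truth = 1, stringsAsFactors = FALSE)
    }

    ## somatic second hits for planted germline events
    if (!is.null(glp)) {
      for (k in seq_len(nrow(glp))) {
        if (isTRUE(glp$second_hit[k])) {
          row <- plant_coding(glp$gene[k], "nonsense", "second_hit")
          som[[length(som) + 1]] <- row
        }
      }
    }

    somatic <- if (length(som)) do.call(rbind, som) else .empty_somatic()
    rownames(somatic) <- NULL

    ## germline variants
    germ <- list()
    if (!is.null(glp)) {
      for (k in seq_len(nrow(glp))) {
        g <- glp$gene[k]
        i <- match(g, genome$genes$gene)
        cp <- sample.int(genome$genes$coding_len[i], 1L) - 1L
        ref <- substr(genome$genes$cds[i], cp + 1, cp + 1)
        alt <- sample(setdiff(.BASES, ref), 1)
        gpos <- cds_to_genomic(genome, g, cp)
        chrom <- genome$genes$chrom[i]
        segi <- .segment_at(prof, chrom, gpos)
        cnv <- prof$major[segi] + prof$minor[segi]
        minor <- prof$minor[segi]
        copies <- switch(glp$loh[k],
                         wildtype = cnv,       # variant haplotype retained
                         variant = 0,          # variant haplotype lost
                         minor)                # untouched heterozygous locus
        ncv <- .normal_cn(chrom, config$sex)
        ev <- (p * copies + (1 - p) * 1) / mixture_denom(p, cnv, ncv)
        d <- .sim_depth(1, config$tumour_depth *
                          mixture_denom(p, cnv, ncv) /
                          mixture_denom(p, psi, 2), config$nb_size)
        a <- stats::rbinom(1, d, min(1, max(0, ev)))
        germ[[length(germ) + 1]] <- data.frame(
          chrom = chrom, pos = as.integer(gpos + 1L), ref = ref, alt = alt,
          gene = g, genotype = "HET", clnsig = "Pathogenic",
          tumour_alt = a, tumour_depth = d, tumour_vaf = a / d,
          stringsAsFactors = FALSE)
      }
    }
    # benign background germline variants
    nonpanel <- genome$genes$gene[!genome$genes$is_germline_panel]
    for (g in sample(nonpanel, min(5, length(nonpanel)))) {
      i <- match(g, genome$genes$gene)
      cp <- sample.int(genome$genes$coding_len[i], 1L) - 1L
      ref <- substr(genome$genes$cds[i], cp + 1, cp + 1)
      gpos <- cds_to_genomic(genome, g, cp)
      germ[[length(germ) + 1]] <- data.frame(
        chrom = genome$genes$chrom[i], pos = as.integer(gpos + 1L),
        ref = ref, alt = sample(setdiff(.BASES, ref), 1), gene = g,
        genotype = "HET", clnsig = "Benign", tumour_alt = NA_integer_,
        tumour_depth = NA_integer_, tumour_vaf = NA_real_,
        stringsAsFactors = FALSE)
    }
    germline <- if (length(germ)) do.call(rbind, germ) else NULL

    ## structural variants
    svs <- .simulate_svs(genome, config, prof)

    msi_status_truth <- FALSE
    # truth WGD flag: the duplication rule applied to the truth profile
    wgd_truth <- call_wgd(data.frame(chrom = prof$chrom, start = prof$start,
                                     end = prof$end, major = prof$major,
                                     stringsAsFactors = FALSE))$wgd
    truth <- list(sample_id = sample_id, patient_id = patient_id,
                  cancer_type = cancer_type, doid = doid, sex = config$sex,
                  purity = p, ploidy = psi, wgd = wgd_truth,
                  segments = prof, clones = config$clones,
                  tumour_depth = config$tumour_depth,
                  nb_size = config$nb_size,
                  planted = c(pl, list(resolved = planted_truth)),
                  msi_status = msi_status_truth, seed = seed)
    smp <- structure(list(truth = truth, segments = segments,
                          somatic = somatic, germline = germline, svs = svs),
                     class = "tumour_sample")
    if (config$msi_target > 0)
      smp <- inject_msi(smp, config$msi_target, genome)
    smp
  })
}

# SV breakpoints: planted fusions (phase-compatible), cis-activating events,
# intragenic exon deletions, plus random background SVs
.simulate_svs <- function(genome, config, prof) {
  pl <- config$planted
  rows <- list()
  add <- function(c1, p1, o1, c2, p2, o2, type) {
    rows[[length(rows) + 1]] <<- data.frame(
      chrom1 = c1, pos1 = as.integer(p1), orient1 = o1, chrom2 = c2,
      pos2 = as.integer(p2), orient2 = o2, type = type,
      stringsAsFactors = FALSE)
  }
  exon_phases <- function(gene) {
    i <- match(gene, genome$genes$gene)
    ex <- .gene_exons(genome, gene)
    cumsum(ex$end - ex$start) %% 3          # phase after each exon
  }
  fus <- pl$fusions
  if (!is.null(fus)) {
    for (k in seq_len(nrow(fus))) {
      a <- fus$five_gene[k]; b <- fus$three_gene[k]
      exa <- .gene_exons(genome, a); exb <- .gene_exons(genome, b)
      pha <- exon_phases(a); phb <- c(0, exon_phases(b))
      pick <- NULL
      for (ia in seq_len(nrow(exa) - 1)) {
        ib <- which(phb[seq_len(nrow(exb) - 1)] == pha[ia])
        if (length(ib)) { pick <- c(ia, ib[1]); break }
      }
      if (is.null(pick)) pick <- c(1L, 1L)
      ia <- pick[1]; ib <- pick[2]
      p1 <- (exa$end[ia] + exa$start[ia + 1]) %/% 2
      p2 <- (exb$end[ib] + exb$start[ib + 1]) %/% 2
      add(genome$genes$chrom[match(a, genome$genes$gene)], p1, "+",
          genome$genes$chrom[match(b, genome$genes$gene)], p2, "-", "BND")
    }
  }
  for (b in pl$cis_fusions %||% character(0)) {
    i <- match(b, genome$genes$gene)
    p2 <- max(0L, genome$genes$start[i] - 5000L)
    j <- sample.int(nrow(genome$chromosomes), 1)
    add(genome$chromosomes$name[j],
        sample.int(genome$chromosomes$length[j], 1), "+",
        genome$genes$chrom[i], p2, "-", "BND")
  }
  for (g in pl$intragenic_dels %||% character(0)) {
    ex <- .gene_exons(genome, g)
    lens <- ex$end - ex$start
    ok <- which(lens %% 3 == 0 & seq_along(lens) > 1 &
                  seq_along(lens) < length(lens))
    e <- if (length(ok)) ok[1] else 2L
    chrom <- genome$genes$chrom[match(g, genome$genes$gene)]
    add(chrom, (ex$end[e - 1] + ex$start[e]) %/% 2, "+",
        chrom, (ex$end[e] + ex$start[e + 1]) %/% 2, "-", "DEL")
  }
  if (config$n_sv > 0) {
    for (k in seq_len(config$n_sv)) {
      i <- sample.int(nrow(genome$chromosomes), 1,
                      prob = genome$chromosomes$length)
      L <- genome$chromosomes$length[i]
      p1 <- sample.int(L - 100000L, 1)
      add(genome$chromosomes$name[i], p1, "+",
          genome$chromosomes$name[i],
          p1 + sample.int(80000L, 1) + 1000L, "-",
          sample(c("DEL", "DUP"), 1))
    }
  }
  if (!length(rows))
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      orient1 = character(0), chrom2 = character(0),
                      pos2 = integer(0), orient2 = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inject microsatellite-instability indels into a simulated sample
#'
#' Adds Poisson(`target_score` x genome Mb) single-base indels at qualifying
#' microsatellite loci (homopolymers of five or more bases, or 2-4 bp unit
#' repeats with four or more units), so that the downstream qualifying-indel
#' density matches `target_score` within Poisson error.
#'
#' @param sample a `tumour_sample`.
#' @param target_score target qualifying-indel density in indels per Mb.
#' @param genome the `genome_model` the sample was simulated on.
#' @return the modified `tumour_sample`.
#' @export
inject_msi <- function(sample, target_score, genome) {
  if (target_score < 0) stop("target_score must be >= 0")
  if (target_score == 0) return(sample)
  ms <- genome$microsatellites
  qual <- ms[(ms$unit_length == 1 & ms$repeat_count >= 5) |
               (ms$unit_length %in% 2:4 & ms$repeat_count >= 4), ]
  if (nrow(qual) == 0) stop("genome has no qualifying microsatellites")
  n <- stats::rpois(1, target_score * genome_mb(genome))
  if (n == 0) return(sample)
  truth <- sample$truth
  prof <- truth$segments
  j <- sample.int(nrow(qual), n, replace = TRUE)
  chrom <- qual$chrom[j]
  pos0 <- qual$start[j]
  segi <- .segment_at(prof, chrom, pos0)
  cnv <- prof$major[segi] + prof$minor[segi]
  cnv[is.na(cnv)] <- 2
  cnv[cnv == 0] <- 2    # place on diploid background if locus deleted
  ncv <- .normal_cn(chrom, truth$sex)
  obs <- .sim_vaf(truth$purity, cnv, ncv, 1, truth$tumour_depth %||% 106,
                  truth$ploidy, truth$nb_size %||% 10)
  del <- stats::runif(n) < 0.5
  rows <- data.frame(
    chrom = chrom, pos = as.integer(pos0 + 1L),
    ref = ifelse(del, "AA", "A"), alt = ifelse(del, "A", "AA"),
    type = "INDEL", alt_count = obs$alt_count, depth = obs$depth,
    vaf = obs$vaf, phase_set = NA_character_, gene = NA_character_,
    consequence = NA_character_, context = NA_character_, ccf_truth = 1,
    mult_truth = 1, stringsAsFactors = FALSE)
  sample$somatic <- rbind(sample$somatic, rows)
  sample$truth$msi_injected <- n
  sample$truth$msi_status <- (n / genome_mb(genome)) > 4
  sample
}

#' Simulate a cohort of synthetic tumour samples
#'
#' Per-sample seeds are derived deterministically from the master seed, so a
#' cohort is reproducible and individual samples can be regenerated in
#' isolation.
#'
#' @param genome a `genome_model`.
#' @param n number of samples (>= 1).
#' @param config a `tumour_sim_config`, or a function `(i) -> config` giving
#'   per-sample configurations.
#' @param seed master seed.
#' @param fixtures optional `fixture_resources`.
#' @param cancer_type,doid cohort metadata applied to every sample.
#' @return list of `tumour_sample` objects.
#' @export
simulate_cohort <- function(genome, n, config = tumour_sim_config(),
                            seed = 1L, fixtures = NULL,
                            cancer_type = "breast cancer", doid = "1612") {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    cfg <- if (is.function(config)) config(i) else config
    simulate_sample(genome, cfg, seed = derive_seed(seed, i),
                    fixtures = fixtures,
                    sample_id = sprintf("S%03d", i),
                    patient_id = sprintf("P%03d", i),
                    cancer_type = cancer_type, doid = doid)
  })
}

#' Simulate two biopsies of one patient with controlled variant sharing
#'
#' Builds two samples whose somatic SNV sets share a specified number of
#' clonal and subclonal variants (by genomic identity), with the remainder
#' private to each biopsy. Used to study clonality-resolved variant sharing
#' between independent lesions of one patient.
#'
#' @param genome a `genome_model`.
#' @param config a `tumour_sim_config` applied to both biopsies (its clone
#'   table must contain one clonal and at least one subclonal clone).
#' @param n_shared_clonal,n_private_clonal,n_shared_subclonal,n_private_subclonal
#'   variant counts.
#' @param seed integer seed.
#' @return list of two `tumour_sample` objects (same `patient_id`).
#' @export
simulate_biopsy_pair <- function(genome, config = tumour_sim_config(),
                                 n_shared_clonal = 200L,
                                 n_private_clonal = 50L,
                                 n_shared_subclonal = 30L,
                                 n_private_subclonal = 70L, seed = 1L) {
  sub_ccf <- config$clones$ccf[config$clones$ccf < 1]
  sub_ccf <- if (length(sub_ccf)) sub_ccf[1] else 0.4
  withr::with_seed(seed, {
    draw_pos <- function(n) {
      ci <- sample.int(nrow(genome$chromosomes), n, replace = TRUE,
                       prob = genome$chromosomes$length)
      data.frame(chrom = genome$chromosomes$name[ci],
                 pos = vapply(ci, function(i)
                   sample.int(genome$chromosomes$length[i], 1L), integer(1)),
                 stringsAsFactors = FALSE)
    }
    shared_c <- draw_pos(n_shared_clonal)
    shared_s <- draw_pos(n_shared_subclonal)
    make_biopsy <- function(b) {
      priv_c <- draw_pos(n_private_clonal)
      priv_s <- draw_pos(n_private_subclonal)
      base <- simulate_sample(genome,
                              tumour_sim_config(purity = config$purity,
                                                sex = config$sex,
                                                n_snv = 0L, n_indel = 0L,
                                                n_mnv = 0L, n_sv = 0L),
                              seed = derive_seed(seed, b),
                              sample_id = sprintf("PAIR_B%d", b),
                              patient_id = "PAIR")
      prof <- base$truth$segments
      psi <- base$truth$ploidy
      mk <- function(df, ccf) {
        if (nrow(df) == 0) return(NULL)
        segi <- .segment_at(prof, df$chrom, df$pos)
        ok <- !is.na(segi) & (prof$major[segi] + prof$minor[segi]) > 0
        df <- df[ok, ]; segi <- segi[ok]
        cnv <- prof$major[segi] + prof$minor[segi]
        ncv <- .normal_cn(df$chrom, config$sex)
        obs <- .sim_vaf(config$purity, cnv, ncv, rep(ccf, nrow(df)),
                        config$tumour_depth, psi, config$nb_size)
        data.frame(chrom = df$chrom, pos = as.integer(df$pos + 1L),
                   ref = "C", alt = "T", type = "SNV",
                   alt_count = obs$alt_count, depth = obs$depth,
                   vaf = obs$vaf, phase_set = NA_character_,
                   gene = NA_character_, consequence = NA_character_,
                   context = NA_character_, ccf_truth = ccf, mult_truth = 1,
                   stringsAsFactors = FALSE)
      }
      base$somatic <- do.call(rbind, Filter(Negate(is.null), list(
        mk(shared_c, 1), mk(priv_c, 1),
        mk(shared_s, sub_ccf), mk(priv_s, sub_ccf))))
      base
    }
    list(make_biopsy(1), make_biopsy(2))
  })
}
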