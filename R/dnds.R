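## Simplified dN/dS driver-gene test: per-trinucleotide-context mutation
## rates estimated from synonymous sites, expected nonsynonymous counts via
## per-gene opportunity counting, and a per-gene/per-class Poisson test of
## observed against expected under neutrality (dN/dS = 1), BH-corrected.
## No covariates or negative-binomial shrinkage.

#' Simplified dN/dS test for significantly mutated genes
#'
#' Per-context mutation rates are estimated cohort-wide from synonymous
#' variants (count / opportunity per 96-type context). Expected missense and
#' nonsense counts per gene follow from the gene's opportunity spectrum;
#' expected essential-splice counts use the global mean per-site rate times
#' the gene's splice opportunity; expected coding-indel counts distribute
#' the cohort's coding indel total by coding length. Each gene x class is
#' tested with a two-sided Poisson test against its expectation and
#' BH-corrected across genes within class; genes with q below
#' `significance` in any class are flagged significant.
#'
#' @param variants cohort variant data frame with columns `gene`,
#'   `consequence` (synonymous/missense/nonsense/splice/indel_coding) and
#'   `context` for SNVs.
#' @param genome a `genome_model`.
#' @param site_table optional precomputed [coding_site_table()] (saves time
#'   across repeated calls).
#' @param significance q-value cut-off for the significant-gene flag.
#' @return object of class `dnds_result`: `table` (gene, class, observed,
#'   expected, dnds, p, q, significant), `global` (per-class totals),
#'   `significant_genes`.
#' @export
run_dnds <- function(variants, genome, site_table = NULL,
                     significance = 0.01) {
  if (nrow(variants) == 0) stop("empty cohort")
  st <- site_table %||% coding_site_table(genome)
  lev <- context96_levels()

  syn <- variants[variants$consequence %in% "synonymous", ]
  if (nrow(syn) == 0) stop("no synonymous variants; rates unidentifiable")

  syn_obs_ctx <- table(factor(syn$context, levels = lev))
  opp <- table(factor(st$gene, levels = unique(st$gene)),
               factor(st$context, levels = lev),
               factor(st$consequence,
                      levels = c("synonymous", "missense", "nonsense")))
  syn_opp_ctx <- colSums(opp[, , "synonymous"])
  rate <- as.numeric(syn_obs_ctx) / pmax(as.numeric(syn_opp_ctx), 1)
  rate_global <- sum(syn_obs_ctx) / max(sum(syn_opp_ctx), 1)

  genes <- rownames(opp)
  exp_mis <- as.numeric(opp[, , "missense"] %*% rate)
  exp_non <- as.numeric(opp[, , "nonsense"] %*% rate)
  # per-gene synonymous expectation (for the global dN/dS denominator)
  exp_syn <- as.numeric(opp[, , "synonymous"] %*% rate)

  splice_opp <- vapply(genes, function(g) splice_opportunity(genome, g),
                       integer(1))
  exp_spl <- rate_global * splice_opp

  ind <- variants[variants$consequence %in% "indel_coding", ]
  clen <- genome$genes$coding_len[match(genes, genome$genes$gene)]
  exp_ind <- nrow(ind) * clen / sum(clen)

  obs_count <- function(df, cls) {
    tab <- table(factor(df$gene[df$consequence == cls], levels = genes))
    as.integer(tab)
  }
  obs <- list(missense = obs_count(variants, "missense"),
              nonsense = obs_count(variants, "nonsense"),
              splice = obs_count(variants, "splice"),
              indel = {
                tab <- table(factor(ind$gene, levels = genes))
                as.integer(tab)
              })
  expd <- list(missense = exp_mis, nonsense = exp_non, splice = exp_spl,
               indel = exp_ind)

  rows <- list()
  for (cls in names(obs)) {
    o <- obs[[cls]]; e <- expd[[cls]]
    p <- rep(NA_real_, length(o))
    testable <- e > 0
    p[testable] <- vapply(which(testable), function(i)
      stats::poisson.test(o[i], T = e[i])$p.value, numeric(1))
    q <- rep(NA_real_, length(o))
    q[testable] <- stats::p.adjust(p[testable], method = "BH")
    rows[[cls]] <- data.frame(gene = genes, class = cls, observed = o,
                              expected = e, dnds = ifelse(e > 0, o / e, NA),
                              p = p, q = q,
                              significant = !is.na(q) & q < significance,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  glob <- do.call(rbind, lapply(names(obs), function(cls)
    data.frame(class = cls, observed = sum(obs[[cls]]),
               expected = sum(expd[[cls]]),
               dnds = sum(obs[[cls]]) / max(sum(expd[[cls]]), 1e-12),
               stringsAsFactors = FALSE)))
  sig <- sort(unique(tab$gene[tab$significant]))
  structure(list(table = tab, global = glob, significant_genes = sig,
                 rate = stats::setNames(rate, lev),
                 rate_global = rate_global, significance = significance,
                 n_variants = nrow(variants), exp_syn = exp_syn),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dnds_result: %d variants, %d significant gene(s) at q < %g\n",
              x$n_variants, length(x$significant_genes), x$significance))
  print(x$global, row.names = FALSE)
  invisible(x)
}

#' Simulate a cohort of coding mutations
#'
#' Draws coding SNVs from the genome's full site table with per-site weights
#' given by a trinucleotide context profile (transitions elevated by
#' default), so that selection is absent and dN/dS is 1 by construction.
#' Essential-splice and coding-indel mutations are added at the neutral
#' per-site rate. A missense excess can be injected into one gene to
#' emulate positive selection.
#'
#' @param genome a `genome_model`.
#' @param n_samples cohort size.
#' @param muts_per_sample mean coding mutations per sample.
#' @param seed integer seed.
#' @param site_table optional precomputed [coding_site_table()].
#' @param excess optional list(gene=, fold=) injecting a `fold`-times
#'   missense excess into `gene`.
#' @param context_weight named numeric weights applied per context class
#'   (defaults elevate C>T and T>C transitions threefold).
#' @return variant data frame with columns sample, gene, consequence,
#'   context.
#' @export
simulate_coding_cohort <- function(genome, n_samples, muts_per_sample = 30,
                                   seed = 1L, site_table = NULL,
                                   excess = NULL,
                                   context_weight = NULL) {
  st <- site_table %||% coding_site_table(genome)
  withr::with_seed(seed, {
    sub <- sub(".*\\[(.>.)\\].*", "\\1", st$context)
    w <- rep(1, nrow(st))
    cw <- context_weight %||% c("C>T" = 3, "T>C" = 3)
    for (s in names(cw)) w[sub == s] <- cw[[s]]
    n_snv <- stats::rpois(1, n_samples * muts_per_sample * 0.93)
    idx <- sample.int(nrow(st), n_snv, replace = TRUE, prob = w)
    snv <- data.frame(sample = sprintf("S%03d", sample.int(n_samples, n_snv,
                                                           replace = TRUE)),
                      gene = st$gene[idx], consequence = st$consequence[idx],
                      context = st$context[idx], stringsAsFactors = FALSE)
    # essential splice sites at the mean per-site rate
    genes <- unique(st$gene)
    spl_opp <- vapply(genes, function(g) splice_opportunity(genome, g),
                      integer(1))
    mean_rate <- n_snv * mean(w) / sum(w)      # per (site, alt) draw rate
    n_spl <- stats::rpois(1, mean_rate * sum(spl_opp))
    spl <- if (n_spl > 0) data.frame(
      sample = sprintf("S%03d", sample.int(n_samples, n_spl, replace = TRUE)),
      gene = sample(genes, n_spl, replace = TRUE, prob = spl_opp),
      consequence = "splice", context = NA_character_,
      stringsAsFactors = FALSE) else NULL
    # coding indels uniform per coding bp
    n_ind <- stats::rpois(1, n_samples * muts_per_sample * 0.05)
    clen <- genome$genes$coding_len[match(genes, genome$genes$gene)]
    ind <- if (n_ind > 0) data.frame(
      sample = sprintf("S%03d", sample.int(n_samples, n_ind, replace = TRUE)),
      gene = sample(genes, n_ind, replace = TRUE, prob = clen),
      consequence = "indel_coding", context = NA_character_,
      stringsAsFactors = FALSE) else NULL
    out <- rbind(snv, spl, ind)
    if (!is.null(excess)) {
      gsel <- st$gene == excess$gene & st$consequence == "missense"
      base <- sum(w[gsel]) / sum(w) * n_snv     # neutral missense expectation
      n_x <- stats::rpois(1, (excess$fold - 1) * base)
      if (n_x > 0) {
        xi <- sample(which(gsel), n_x, replace = TRUE, prob = w[gsel])
        out <- rbind(out, data.frame(
          sample = sprintf("S%03d", sample.int(n_samples, n_x,
                                               replace = TRUE)),
          gene = st$gene[xi], consequence = st$consequence[xi],
          context = st$context[xi], stringsAsFactors = FALSE))
      }
    }
    rownames(out) <- NULL
    out
  })
}
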