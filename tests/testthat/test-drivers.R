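fake_dnds <- function(tab) structure(list(table = tab), class = "dnds_result")

test_that("gene panel is the union of sources with q-gated cohort SMGs", {
  dn <- fake_dnds(data.frame(
    gene = c("G1", "G2", "G3", "G4"), class = "missense",
    observed = 5, expected = 1, dnds = 5, p = 0.001,
    q = c(0.001, 0.005, 0.02, 0.5),
    significant = c(TRUE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
  curated <- data.frame(gene = c("C1", "C2", "C3", "C4", "C5"),
                        role = "tsg", stringsAsFactors = FALSE)
  p <- build_gene_panel(dn, external_smg = c("E1", "E2", "E3", "E4"),
                        curated = curated)
  expect_equal(nrow(p), 2 + 4 + 5)           # disjoint 2 + 4 + 5
  expect_false("G3" %in% p$gene)             # q = 0.02 excluded
  # overlapping lists deduplicate
  p2 <- build_gene_panel(dn, external_smg = c("G1", "C1"), curated = curated)
  expect_equal(anyDuplicated(p2$gene), 0)
  expect_true(p2$smg_cohort[p2$gene == "G1"] &&
                p2$smg_external[p2$gene == "G1"])
  expect_true(all(!is.na(p$role)))
})

test_that("role classifier separates feature extremes and held-out genes", {
  model <- train_role_classifier(seed = 99)
  tsg_like <- data.frame(frac_truncating = 0.9,
                         missense_concentration = 0.1,
                         biallelic_fraction = 0.9, inframe_fraction = 0.02)
  onc_like <- data.frame(frac_truncating = 0.05,
                         missense_concentration = 0.9,
                         biallelic_fraction = 0.1, inframe_fraction = 0.3)
  expect_identical(classify_gene_role(tsg_like, model)$role, "tsg")
  expect_identical(classify_gene_role(onc_like, model)$role, "oncogene")
  held <- simulate_role_training(n = 300, seed = 1234)
  pred <- classify_gene_role(held, model)
  acc <- mean((pred$role == "tsg") == held$is_tsg)
  expect_gte(acc, 0.9)
  expect_error(classify_gene_role(tsg_like, NULL), "not.*trained")
})

test_that("point-driver inclusion rules follow gene role", {
  g <- test_genome()
  panel <- data.frame(gene = c("KRAS", "TP53"),
                      role = c("oncogene", "tsg"), stringsAsFactors = FALSE)
  mkv <- function(gene, csq) data.frame(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T", gene = gene,
    consequence = csq, biallelic = FALSE, subclonal_prob = 0,
    stringsAsFactors = FALSE)
  dn <- fake_dnds(data.frame(gene = "KRAS", class = "missense",
                             observed = 10, expected = 2, dnds = 5,
                             p = 1e-5, q = 1e-4, significant = TRUE))
  # synonymous variants never enter the catalogue
  expect_equal(nrow(call_point_drivers(mkv("KRAS", "synonymous"), panel, dn,
                                       1, 1)), 0)
  # nonsense in an oncogene is not an inclusion class; in a TSG it is
  expect_equal(nrow(call_point_drivers(mkv("KRAS", "nonsense"), panel, dn,
                                       1, 1)), 0)
  expect_equal(nrow(call_point_drivers(mkv("TP53", "nonsense"), panel, dn,
                                       1, 1)), 1)
  expect_equal(nrow(call_point_drivers(mkv("KRAS", "missense"), panel, dn,
                                       1, 1)), 1)
  # unknown panel role errors
  bad_panel <- data.frame(gene = "KRAS", role = NA_character_)
  expect_error(call_point_drivers(mkv("KRAS", "missense"), bad_panel, dn,
                                  1, 1), "role")
})

test_that("driver likelihood is E/(E+P), monotone in burden, with overrides", {
  fx <- test_fixtures()
  panel <- data.frame(gene = "KRAS", role = "oncogene",
                      stringsAsFactors = FALSE)
  dn <- fake_dnds(data.frame(gene = "KRAS", class = "missense",
                             observed = 20, expected = 5, dnds = 4,
                             p = 1e-6, q = 1e-5, significant = TRUE))
  v <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "T",
                  gene = "KRAS", consequence = "missense",
                  biallelic = FALSE, subclonal_prob = 0,
                  stringsAsFactors = FALSE)
  lik <- function(tmb) call_point_drivers(v, panel, dn, tmb, 1)$likelihood
  # brute-force evaluation of the declared formula
  E <- 20 - 5
  expect_equal(lik(1), E / (E + 5 * 1))
  expect_equal(lik(100), E / (E + 5 * 100))
  expect_lt(lik(100), lik(1))
  burdens <- c(0.5, 1, 2, 5, 20, 100)
  ls <- vapply(burdens, lik, numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_true(all(ls >= 0 & ls <= 1))
  # hotspot override: a variant at a fixture hotspot is promoted to >= 0.99
  hs <- fx$hotspots[fx$hotspots$gene == "KRAS", ][1, ]
  vh <- v
  vh$chrom <- hs$chrom
  vh$pos <- as.integer(hs$pos + 1)
  out <- call_point_drivers(vh, panel, dn, 100, 1, hotspots = fx$hotspots)
  expect_gte(out$likelihood, 0.99)
  expect_true(out$hotspot)
  # within 5 nt still counts; 6 nt away does not
  vh$pos <- as.integer(hs$pos + 1 + 5)
  expect_gte(call_point_drivers(vh, panel, dn, 100, 1,
                                hotspots = fx$hotspots)$likelihood, 0.99)
  vh$pos <- as.integer(hs$pos + 1 + 6)
  expect_lt(call_point_drivers(vh, panel, dn, 100, 1,
                               hotspots = fx$hotspots)$likelihood, 0.99)
  # biallelic TSG override in predominantly-biallelic genes
  panel2 <- data.frame(gene = "TP53", role = "tsg")
  dn2 <- fake_dnds(data.frame(gene = "TP53", class = "nonsense",
                              observed = 3, expected = 2.9, dnds = 1,
                              p = 0.5, q = 0.5, significant = FALSE))
  vb <- v
  vb$gene <- "TP53"; vb$consequence <- "nonsense"; vb$biallelic <- TRUE
  expect_gte(call_point_drivers(vb, panel2, dn2, 1, 1,
                                biallelic_genes = "TP53")$likelihood, 0.99)
  expect_lt(call_point_drivers(vb, panel2, dn2, 1, 1)$likelihood, 0.99)
})

test_that("copy-number driver calls apply the strict published bounds", {
  g <- test_genome()
  panel <- data.frame(gene = c("EGFR", "CDKN2A"),
                      role = c("oncogene", "tsg"), stringsAsFactors = FALSE)
  kf <- test_fixtures()$known_fusions
  gcn <- data.frame(gene = c("EGFR", "CDKN2A"), chrom = c("chr7", "chr9"),
                    min_exonic_cn = c(7, 0.2), min_exonic_minor = 0,
                    del_size = c(NA, 5e4), stringsAsFactors = FALSE)
  drv <- call_cn_and_fusion_drivers(gcn, NULL, NULL, panel, kf, g,
                                    sample_ploidy = 2)
  expect_setequal(drv$class, c("amplification", "homozygous_deletion"))
  expect_true(drv$biallelic[drv$class == "homozygous_deletion"])
  # CN 6.0 at ploidy 2 is not > 3x; CN 0.5 is not < 0.5
  gcn2 <- data.frame(gene = c("EGFR", "CDKN2A"), chrom = c("chr7", "chr9"),
                     min_exonic_cn = c(6, 0.5), min_exonic_minor = 0,
                     del_size = NA_real_, stringsAsFactors = FALSE)
  expect_equal(nrow(call_cn_and_fusion_drivers(gcn2, NULL, NULL, panel, kf,
                                               g, 2)), 0)
})

test_that("fusion classification follows exon-phase arithmetic", {
  g <- test_genome()
  fx <- test_fixtures()
  # generator-planted known pair with compatible phases -> in-frame coding
  s <- simulate_sample(g, tumour_sim_config(
    n_snv = 0, n_indel = 0, n_mnv = 0, n_sv = 0, n_coding_snv = 0,
    planted = list(fusions = data.frame(five_gene = "TMPRSS2",
                                        three_gene = "ERG"))), seed = 19)
  cl <- classify_fusions(s$svs, g, fx$known_fusions)
  expect_true(any(cl$subtype == "in_frame_coding" & cl$name == "TMPRSS2-ERG"))
  # planted intragenic exon deletion with length divisible by 3
  s2 <- simulate_sample(g, tumour_sim_config(
    n_snv = 0, n_indel = 0, n_mnv = 0, n_sv = 0, n_coding_snv = 0,
    planted = list(intragenic_dels = "CTNNB1")), seed = 20)
  cl2 <- classify_fusions(s2$svs, g, fx$known_fusions)
  ex <- somascape:::.gene_exons(g, "CTNNB1")
  lens <- ex$end - ex$start
  internal_inframe <- any(lens[-c(1, length(lens))] %% 3 == 0)
  if (internal_inframe) {
    expect_true(any(cl2$subtype == "intragenic_deletion"))
  }
  # 5' regulatory repositioning of a promiscuous partner -> cis-activating
  s3 <- simulate_sample(g, tumour_sim_config(
    n_snv = 0, n_indel = 0, n_mnv = 0, n_sv = 0, n_coding_snv = 0,
    planted = list(cis_fusions = "ALK")), seed = 21)
  cl3 <- classify_fusions(s3$svs, g, fx$known_fusions)
  expect_true(any(cl3$subtype == "cis_activating" & cl3$name == "ALK"))
  # an unknown pair with incompatible context yields nothing
  sv_bad <- data.frame(chrom1 = "chr1", pos1 = 10L, orient1 = "+",
                       chrom2 = "chr2", pos2 = 10L, orient2 = "-",
                       type = "BND", stringsAsFactors = FALSE)
  expect_equal(nrow(classify_fusions(sv_bad, g, fx$known_fusions)), 0)
})

test_that("germline assessment tracks which allele is lost", {
  g <- test_genome()
  p <- 0.8
  seg_loh <- flat_cn_segments(g, 1, 0)
  seg_het <- flat_cn_segments(g, 1, 1)
  i <- match("BRCA2", g$genes$gene)
  mkg <- function(tvaf) data.frame(
    chrom = g$genes$chrom[i], pos = g$genes$start[i] + 5L, ref = "A",
    alt = "T", gene = "BRCA2", genotype = "HET", clnsig = "Pathogenic",
    tumour_alt = NA, tumour_depth = NA, tumour_vaf = tvaf,
    stringsAsFactors = FALSE)
  no_som <- data.frame(gene = character(0), consequence = character(0))
  # allele-ploidy bookkeeping oracle: v = tvaf * (p*CN + 2(1-p)) / p
  tv_wt_lost <- (p * 1 + (1 - p)) / (p * 1 + 2 * (1 - p))   # variant kept
  tv_var_lost <- (1 - p) / (p * 1 + 2 * (1 - p))            # variant lost
  out <- call_germline_drivers(mkg(tv_wt_lost), seg_loh, no_som, p)
  expect_identical(out$allele_status, "wildtype_lost")
  out2 <- call_germline_drivers(mkg(tv_var_lost), seg_loh, no_som, p)
  expect_identical(out2$allele_status, "variant_lost")
  out3 <- call_germline_drivers(mkg(0.5), seg_het, no_som, p)
  expect_identical(out3$allele_status, "heterozygous_retained")
  # somatic second hit in the same gene
  som <- data.frame(gene = "BRCA2", consequence = "nonsense")
  expect_true(call_germline_drivers(mkg(0.5), seg_het, som, p)$second_hit)
  # variants outside the high-confidence panel are not reported
  glv <- mkg(0.5); glv$gene <- "GENE001"
  expect_equal(nrow(call_germline_drivers(glv, seg_het, no_som, p)), 0)
  # benign variants are not reported
  glb <- mkg(0.5); glb$clnsig <- "Benign"
  expect_equal(nrow(call_germline_drivers(glb, seg_het, no_som, p)), 0)
})

test_that("driver co-occurrence matches exact hypergeometric enumeration", {
  samples <- sprintf("S%02d", 1:20)
  catalogue <- rbind(
    data.frame(sample = samples[1:10], gene = "A"),
    data.frame(sample = samples[11:20], gene = "B"))
  co <- driver_cooccurrence(catalogue, samples)
  expect_identical(co$direction, "exclusive")
  # enumeration oracle: P(tables at least as extreme) under fixed margins
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(0, 10, 10, 10) + 1e-12])
  expect_equal(co$p, p_exact, tolerance = 1e-9)
  # perfectly co-occurring genes point the other way
  cat2 <- rbind(data.frame(sample = samples[1:10], gene = "A"),
                data.frame(sample = samples[1:10], gene = "B"))
  expect_identical(driver_cooccurrence(cat2, samples)$direction,
                   "co_occurring")
  # single gene -> empty table
  expect_equal(nrow(driver_cooccurrence(catalogue[1:5, ], samples)), 0)
})

test_that("independent genes are rarely significant in co-occurrence tests", {
  withr::with_seed(6, {
    samples <- sprintf("S%03d", 1:60)
    catalogue <- do.call(rbind, lapply(LETTERS[1:6], function(gn)
      data.frame(sample = sample(samples, 25), gene = gn)))
    co <- driver_cooccurrence(catalogue, samples)
    expect_lte(sum(co$q < 0.05), 1)
  })
})

test_that("driver burden summaries are exact sums", {
  catalogue <- data.frame(
    sample = c("S1", "S1", "S2"), gene = c("A", "B", "A"),
    class = c("point", "amplification", "point"),
    likelihood = c(1, 0.5, 0.8), subclonal_prob = c(0, 0, 0.25),
    stringsAsFactors = FALSE)
  s <- summarize_driver_counts(catalogue)
  expect_equal(s$driver_burden[s$sample == "S1"], 1.5)
  expect_equal(s$subclonal_driver_burden[s$sample == "S1"], 0)
  expect_equal(s$subclonal_driver_burden[s$sample == "S2"], 0.25 * 0.8)
  # brute-force oracle over a random catalogue
  withr::with_seed(12, {
    rc <- data.frame(sample = sample(c("X", "Y", "Z"), 50, replace = TRUE),
                     gene = sample(LETTERS, 50, replace = TRUE),
                     class = "point", likelihood = runif(50),
                     subclonal_prob = runif(50), stringsAsFactors = FALSE)
    s2 <- summarize_driver_counts(rc)
    for (sm in unique(rc$sample)) {
      sel <- rc$sample == sm
      expect_equal(s2$driver_burden[s2$sample == sm],
                   sum(rc$likelihood[sel]))
      expect_equal(s2$subclonal_driver_burden[s2$sample == sm],
                   sum(rc$likelihood[sel] * rc$subclonal_prob[sel]))
    }
  })
})
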