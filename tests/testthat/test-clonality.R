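test_that("variant ploidy inversion matches the closed form", {
  # p = 1, CN 2, VAF 0.5 -> one chromatid, not biallelic
  a <- annotate_variant_ploidy(0.5, 1, 2)
  expect_equal(a$variant_ploidy, 1)
  expect_false(a$biallelic)
  # p = 0.5, CN 4, VAF 1/3 -> v = 2
  expect_equal(annotate_variant_ploidy(1 / 3, 0.5, 4)$variant_ploidy, 2)
  # LOH: CN 1, p = 1, VAF 1 -> v = 1 > 0.5 -> biallelic
  expect_true(annotate_variant_ploidy(1, 1, 1)$biallelic)
  expect_error(annotate_variant_ploidy(0.5, 0, 2), "purity")
})

test_that("biallelic rule is exact over a grid of (v, CN)", {
  for (cn in c(1, 2, 3, 4)) {
    v <- seq(0, cn + 1, by = 0.05)
    p <- 0.8
    vaf <- pmin(1, p * v / (p * cn + 2 * (1 - p)))
    ann <- annotate_variant_ploidy(vaf, p, cn)
    expect_equal(ann$biallelic, ann$variant_ploidy > cn - 0.5)
  }
})

test_that("ploidy inversion round-trips through simulated VAFs", {
  withr::with_seed(5, {
    p <- 0.6; cn <- 3; v <- 2
    d <- rnbinom(3000, mu = 100, size = 10) + 1
    vaf <- rbinom(3000, d, p * v / (p * cn + 2 * (1 - p))) / d
    vhat <- annotate_variant_ploidy(vaf, p, cn)$variant_ploidy
    expect_lt(abs(mean(vhat) - v), 3 * sd(vhat) / sqrt(3000))
  })
})

test_that("phased adjacent SNVs merge into MNVs", {
  mk <- function(pos, ps) data.frame(
    chrom = "chr1", pos = pos, ref = "A", alt = "T", type = "SNV",
    alt_count = 30L, depth = 100L, vaf = 0.3, phase_set = ps,
    gene = NA_character_, consequence = NA_character_,
    context = NA_character_, stringsAsFactors = FALSE)
  # adjacent, same phase set -> dinucleotide MNV
  m <- merge_mnvs(mk(c(100L, 101L), "PS1"))
  expect_equal(nrow(m), 1)
  expect_identical(m$type, "MNV")
  expect_equal(nchar(m$ref), 2)
  # different phase sets -> unmerged
  m2 <- merge_mnvs(mk(c(100L, 101L), c("PS1", "PS2")))
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$type == "SNV"))
  # exhaustive toy: three adjacent plus one distant in one phase set
  m3 <- merge_mnvs(mk(c(100L, 101L, 102L, 200L), "PS1"))
  expect_equal(sort(nchar(m3$ref)), c(1, 3))
  expect_equal(as.integer(attr(m3, "mnv_length_counts")["3"]), 1L)
  # unphased variants never merge
  m4 <- merge_mnvs(mk(c(100L, 101L), NA_character_))
  expect_equal(nrow(m4), 2)
})

test_that("clonality mixture separates clonal from subclonal variants", {
  withr::with_seed(8, {
    p <- 0.8; cn <- 2
    n <- 1500
    is_sub <- runif(n) < 0.3
    v_true <- ifelse(is_sub, 0.4, 1)
    d <- rnbinom(n, mu = 100, size = 10) + 1
    vaf <- rbinom(n, d, p * v_true / (p * cn + 2 * (1 - p))) / d
    v <- annotate_variant_ploidy(vaf, p, cn)$variant_ploidy
    cl <- fit_clonality(v)
    expect_lt(abs(cl$subclonal_fraction - mean(is_sub)), 0.05)
    # probabilities are probabilities and the sample fraction is their mean
    expect_true(all(cl$subclonal_prob >= 0 & cl$subclonal_prob <= 1))
    expect_lt(abs(cl$subclonal_fraction - mean(cl$subclonal_prob)), 1e-6)
    expect_lt(abs(sum(cl$peaks$weight) - 1), 1e-6)
    # most truly subclonal variants receive high subclonal probability
    expect_gt(mean(cl$subclonal_prob[is_sub] > 0.5), 0.9)
  })
})

test_that("single clonal population gives a near-zero subclonal fraction", {
  withr::with_seed(9, {
    d <- rnbinom(500, mu = 100, size = 10) + 1
    vaf <- rbinom(500, d, 0.5) / d
    cl <- fit_clonality(annotate_variant_ploidy(vaf, 1, 2)$variant_ploidy)
    expect_lt(cl$subclonal_fraction, 0.02)
    expect_false(any(cl$peaks$is_subclonal & cl$peaks$weight > 0.05))
  })
})

test_that("small variant sets fall back to a single clonal peak", {
  expect_warning(cl <- fit_clonality(rep(1, 10)), "single clonal peak")
  expect_equal(nrow(cl$peaks), 1)
  expect_equal(cl$subclonal_fraction, 0)
  expect_error(fit_clonality(numeric(0)), "no variant ploidies")
})

test_that("biopsy sharing fractions follow variant identity by clonality class", {
  mk <- function(pos, sub) data.frame(
    chrom = "chr1", pos = pos, ref = "A", alt = "T",
    subclonal_prob = ifelse(sub, 0.9, 0.05), stringsAsFactors = FALSE)
  a <- mk(1:10, rep(c(FALSE, TRUE), each = 5))
  expect_equal(compare_biopsies(a, a),
               list(shared_clonal = 1, shared_subclonal = 1))
  b <- mk(11:20, rep(c(FALSE, TRUE), each = 5))
  expect_equal(compare_biopsies(a, b),
               list(shared_clonal = 0, shared_subclonal = 0))
  expect_error(compare_biopsies(a, b, "P1", "P2"), "different patients")
})

test_that("generated biopsy pairs recover the planted sharing structure", {
  g <- test_genome()
  cfg <- tumour_sim_config(purity = 0.8,
                           clones = data.frame(ccf = c(1, 0.4),
                                               fraction = c(0.7, 0.3)))
  pr <- simulate_biopsy_pair(g, cfg, n_shared_clonal = 300,
                             n_private_clonal = 0, n_shared_subclonal = 0,
                             n_private_subclonal = 150, seed = 13)
  annotate <- function(s) {
    f <- fit_purity_ploidy(s$segments)
    v <- s$somatic
    segs <- f$segments
    cn <- vapply(seq_len(nrow(v)), function(i) {
      s2 <- segs[segs$chrom == v$chrom[i] & segs$start <= v$pos[i] - 1 &
                   segs$end > v$pos[i] - 1, ]
      if (nrow(s2)) s2$cn[1] else f$ploidy
    }, numeric(1))
    v$variant_ploidy <- annotate_variant_ploidy(v$vaf, f$purity,
                                                cn)$variant_ploidy
    cl <- fit_clonality(v$variant_ploidy)
    v$subclonal_prob <- cl$subclonal_prob
    v
  }
  a <- annotate(pr[[1]]); b <- annotate(pr[[2]])
  sh <- compare_biopsies(a, b)
  expect_gt(sh$shared_clonal, 0.9)          # all clonal variants shared
  expect_lt(sh$shared_subclonal, 0.1)       # all subclonal variants private
})
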