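test_that("a fully balanced diploid genome yields the degenerate fit", {
  g <- test_genome()
  ch <- g$chromosomes[g$chromosomes$is_autosome, ]
  seg <- data.frame(chrom = ch$name, start = 0L, end = ch$length,
                    baf = 0.5, baf_count = 1000L, depth_ratio = 1,
                    stringsAsFactors = FALSE)
  f <- fit_purity_ploidy(seg)
  expect_true(f$purity_unreliable)
  expect_equal(f$purity, 0.08)             # lowest grid value
  expect_lt(abs(f$ploidy - 2), 0.05)
  expect_true(all(abs(f$segments$cn - 2) < 0.1))
})

test_that("purity and ploidy are recovered from simulated tumours", {
  g <- test_genome()
  ok <- logical(6)
  set.seed(31)
  for (i in seq_along(ok)) {
    pu <- runif(1, 0.25, 0.95)
    s <- simulate_sample(g, tumour_sim_config(purity = pu, wgd = i %% 2 == 0,
                                              n_snv = 50, n_indel = 0,
                                              n_mnv = 0, n_coding_snv = 0),
                         seed = 300 + i)
    f <- fit_purity_ploidy(s$segments)
    ok[i] <- abs(f$purity - pu) <= 0.03 &&
      abs(f$ploidy - s$truth$ploidy) <= 0.1
    # allele-sum and length-weighted-ploidy invariants
    expect_true(all(abs(f$segments$major + f$segments$minor -
                          f$segments$cn) < 1e-6))
    L <- as.double(f$segments$end - f$segments$start)
    expect_lt(abs(f$ploidy - sum(f$segments$cn * L) / sum(L)), 1e-6)
  }
  expect_gte(sum(ok), 5)
})

test_that("low-purity samples fail QC", {
  g <- test_genome()
  s <- simulate_sample(g, tumour_sim_config(purity = 0.10, n_snv = 50,
                                            n_indel = 0, n_mnv = 0,
                                            n_coding_snv = 0), seed = 77)
  f <- fit_purity_ploidy(s$segments, n_somatic = nrow(s$somatic))
  expect_lt(f$purity, 0.20)
  expect_identical(f$qc_status, "FAIL_PURITY")
})

test_that("segments without informative SNPs are rejected", {
  seg <- data.frame(chrom = "chr1", start = 0L, end = 10^6, baf = NA_real_,
                    baf_count = 0L, depth_ratio = 1)
  expect_error(fit_purity_ploidy(seg), "informative")
})

test_that("WGD calling applies the duplicated-autosome rule exactly", {
  expect_error(call_wgd(data.frame()), "empty")
  all22 <- flat_cn_segments(test_genome(), 2, 2)
  w <- call_wgd(all22)
  expect_true(w$wgd)
  expect_equal(w$count, 22)
  expect_true(call_wgd(wgd_profile(11))$wgd)
  expect_false(call_wgd(wgd_profile(10))$wgd)
  none <- flat_cn_segments(test_genome(), 1, 1)
  w0 <- call_wgd(none)
  expect_false(w0$wgd)
  expect_equal(w0$count, 0)
})

test_that("WGD call is invariant to segment subdivision", {
  prof <- wgd_profile(13)
  half <- do.call(rbind, lapply(seq_len(nrow(prof)), function(i) {
    r <- prof[i, ]; mid <- (r$start + r$end) %/% 2
    rbind(transform(r, end = mid), transform(r, start = mid))
  }))
  expect_identical(call_wgd(prof), call_wgd(half))
})

test_that("an autosome duplicated on less than half its length does not count", {
  g <- test_genome()
  L <- g$chromosomes$length[1]
  seg <- data.frame(chrom = "chr1", start = c(0L, floor(0.6 * L)),
                    end = c(floor(0.6 * L), L), cn = c(2, 3),
                    major = c(1, 2), minor = 1)
  expect_equal(call_wgd(seg)$count, 0)
  seg$major <- c(2, 1)                     # duplicated on 60% of the length
  expect_equal(call_wgd(seg)$count, 1)
})

test_that("CNA categories reproduce the ring definitions", {
  g <- test_genome()
  # whole genome at CN 1 (1,0), ploidy 2 -> LOH with significant loss
  cats <- classify_cna_categories(flat_cn_segments(g, 1, 0), g, 2)
  expect_true(all(cats$loss_category == "loh_significant_loss"))
  # copy-neutral LOH: CN 2.0 with minor 0
  cats <- classify_cna_categories(flat_cn_segments(g, 2, 0), g, 2)
  expect_true(all(cats$loss_category == "loh_copy_neutral"))
  # CN 3.0 at ploidy 2 -> low-level amplification only
  cats <- classify_cna_categories(flat_cn_segments(g, 2, 1), g, 2)
  expect_true(all(cats$gain_category == "amp_low"))
  # homozygous deletion ring
  cats <- classify_cna_categories(flat_cn_segments(g, 0, 0), g, 2)
  expect_true(all(cats$loss_category == "homozygous_deletion"))
  # male Y loss flag
  expect_true(attr(cats, "y_loss"))
  cats2 <- classify_cna_categories(flat_cn_segments(g, 1, 1), g, 2)
  expect_false(attr(cats2, "y_loss"))
})

test_that("sample QC filters and keeps the highest-purity biopsy", {
  cohort <- data.frame(
    sample_id = c("A1", "B1", "B2", "C1", "D1"),
    patient_id = c("A", "B", "B", "C", "D"),
    purity = c(0.5, 0.35, 0.62, 0.19, 0.4),
    n_somatic = c(100L, 50L, 80L, 60L, 0L),
    stringsAsFactors = FALSE)
  keep <- apply_sample_qc(cohort)
  expect_setequal(keep$sample_id, c("A1", "B2"))
  expect_identical(keep$qc_status, rep("PASS", 2))
  allpass <- cohort[c(1, 3), ]
  expect_setequal(apply_sample_qc(allpass)$sample_id, allpass$sample_id)
})

test_that("purity_fit methods summarise the model", {
  g <- test_genome()
  s <- simulate_sample(g, tumour_sim_config(purity = 0.7, n_snv = 30,
                                            n_indel = 0, n_mnv = 0,
                                            n_coding_snv = 0), seed = 41)
  f <- fit_purity_ploidy(s$segments, n_somatic = nrow(s$somatic))
  expect_named(coef(f), c("purity", "ploidy"))
  expect_output(print(f), "purity_fit")
  expect_output(print(summary(f)), "LOH fraction")
  pred <- predict(f)
  expect_equal(nrow(pred), nrow(f$segments))
  expect_true(all(is.finite(pred$depth_ratio)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
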