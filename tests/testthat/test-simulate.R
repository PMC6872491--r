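test_that("configuration validation rejects impossible tumours", {
  expect_error(tumour_sim_config(purity = 0), "purity")
  expect_error(tumour_sim_config(purity = 1.2), "purity")
  expect_error(tumour_sim_config(
    clones = data.frame(ccf = c(1, 1.2), fraction = c(0.5, 0.5))), "CCF")
  expect_error(tumour_sim_config(
    clones = data.frame(ccf = c(0.5, 0.4), fraction = c(0.5, 0.5))),
    "exactly one clone")
  expect_error(tumour_sim_config(msi_target = -1), "msi_target")
})

test_that("pure diploid tumours concentrate VAF near 0.5", {
  g <- test_genome()
  prof <- do.call(rbind, lapply(seq_len(nrow(g$chromosomes)), function(i)
    data.frame(chrom = g$chromosomes$name[i], start = 0L,
               end = g$chromosomes$length[i], major = 1, minor = 1)))
  prof <- prof[!prof$chrom %in% c("chrX", "chrY"), ]
  s <- simulate_sample(g, tumour_sim_config(purity = 1, sex = "female",
                                            segment_profile = prof,
                                            n_snv = 100, n_indel = 0,
                                            n_mnv = 0, n_coding_snv = 0),
                       seed = 7)
  snv <- s$somatic[s$somatic$type == "SNV", ]
  expect_gt(nrow(snv), 50)
  expect_lt(abs(mean(snv$vaf) - 0.5), 3 * 0.05 / sqrt(nrow(snv)) + 0.005)
})

test_that("observed VAF and BAF follow the purity/copy-number mixture", {
  g <- test_genome()
  # one segment at (2,0), purity 0.6: expected het-SNP BAF
  #   (0.6*2 + 0.4*1) / (0.6*2 + 0.4*2) = 0.8
  expect_equal(expected_baf(0.6, 2, 0), 0.8)
  prof <- data.frame(chrom = "chr1", start = 0L,
                     end = g$chromosomes$length[1], major = 2, minor = 0)
  s <- simulate_sample(g, tumour_sim_config(purity = 0.6,
                                            segment_profile = prof,
                                            n_snv = 400, n_indel = 0,
                                            n_mnv = 0, n_coding_snv = 0),
                       seed = 3)
  seg <- s$segments
  expect_lt(abs(seg$baf[1] - 0.8), 0.01)    # Monte-Carlo mean of many SNPs
  # VAF of clonal single-copy variants: p*v / (p*CN + 2(1-p)) = 0.6/2 = 0.3
  snv <- s$somatic[s$somatic$mult_truth == 1, ]
  se <- sqrt(0.3 * 0.7 / 106) / sqrt(nrow(snv))
  expect_lt(abs(mean(snv$vaf) - 0.3), 3 * se + 0.01)
  # depth ratio expectation: CN 2 everywhere -> ratio 1
  expect_lt(abs(seg$depth_ratio[1] - 1), 0.01)
})

test_that("identical seeds give byte-identical sample files", {
  g <- test_genome()
  fx <- test_fixtures()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- tumour_sim_config(n_snv = 50, n_indel = 10)
  write_sample(simulate_sample(g, cfg, seed = 11, fixtures = fx), d1)
  write_sample(simulate_sample(g, cfg, seed = 11, fixtures = fx), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  d3 <- withr::local_tempdir()
  write_sample(simulate_sample(g, cfg, seed = 12, fixtures = fx), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "somatic.vcf"))),
                         unname(tools::md5sum(file.path(d3, "somatic.vcf")))))
})

test_that("MSI injection hits the target qualifying-indel density", {
  g <- test_genome()
  s <- simulate_sample(g, tumour_sim_config(n_snv = 0, n_indel = 0,
                                            n_mnv = 0, n_coding_snv = 0),
                       seed = 5)
  expect_identical(inject_msi(s, 0, g)$somatic, s$somatic)
  withr::with_seed(21, {
    s12 <- inject_msi(s, 12, g)
    n <- s12$truth$msi_injected
    lambda <- 12 * genome_mb(g)
    expect_lt(abs(n - lambda), 4 * sqrt(lambda))  # Poisson mean check
    m <- compute_msi(s12$somatic, g)
    expect_identical(m$status, "MSI")
    expect_lt(abs(m$score - 12), 1.5)
  })
  expect_error(inject_msi(s, -3, g), "target_score")
})

test_that("cohort seeds derive deterministically and n = 1 matches a single sample", {
  g <- test_genome()
  fx <- test_fixtures()
  cfg <- tumour_sim_config(n_snv = 30, n_indel = 5)
  coh <- simulate_cohort(g, 1, cfg, seed = 9, fixtures = fx)
  solo <- simulate_sample(g, cfg, seed = derive_seed(9, 1), fixtures = fx,
                          sample_id = "S001", patient_id = "P001")
  expect_identical(coh[[1]]$somatic, solo$somatic)
  expect_error(simulate_cohort(g, 0, cfg), "n must be")
  expect_equal(derive_seed(9, 1), derive_seed(9, 1))
  expect_false(derive_seed(9, 1) == derive_seed(9, 2))
  expect_true(derive_seed(.Machine$integer.max, 10^6) < 2^31)
})

test_that("fixture resources are structurally sound", {
  fx <- test_fixtures()
  expect_equal(dim(fx$signature_matrix), c(96, 30))
  expect_true(all(abs(colSums(fx$signature_matrix) - 1) < 1e-9))
  expect_true(all(fx$signature_matrix >= 0))
  kb <- fx$knowledgebase
  # at least one resistance record sharing a drug with a sensitivity record
  shared <- intersect(kb$drug[kb$direction == "resistance"],
                      kb$drug[kb$direction == "sensitivity"])
  expect_gt(length(shared), 0)
  expect_true(all(fx$hotspots$gene %in% test_genome()$genes$gene))
  d <- withr::local_tempdir()
  write_fixture_resources(fx, d)
  expect_true(all(c("signatures.tsv", "hotspots.tsv", "knowledgebase.json",
                    "ontology.tsv") %in% list.files(d)))
})
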