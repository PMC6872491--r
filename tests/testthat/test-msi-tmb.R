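test_that("MSI score classification is strict at the published boundary", {
  # 12,400 qualifying indels on 3,100 Mb -> score 4.0 -> MSS (strict >)
  expect_identical(msi_classify(12400, 3100)$status, "MSS")
  expect_identical(msi_classify(12500, 3100)$status, "MSI")
  expect_equal(msi_classify(12400, 3100)$score, 4)
  expect_error(msi_classify(10, 0), "positive")
})

test_that("MSI scorer counts only qualifying microsatellite overlaps", {
  g <- test_genome()
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      type = character(0))
  m0 <- compute_msi(empty, g)
  expect_equal(m0$score, 0)
  expect_identical(m0$status, "MSS")
  n <- 600L
  m <- compute_msi(ms_indels(g, n), g)
  expect_equal(m$qualifying_indels, n)
  # indels at non-qualifying loci (short homopolymers) do not count
  ms <- g$microsatellites
  nonq <- ms[ms$unit_length == 1 & ms$repeat_count == 4, ]
  expect_gt(nrow(nonq), 0)   # the default genome annotates sub-threshold runs
  bad <- data.frame(chrom = nonq$chrom, pos = nonq$start + 1L, ref = "AA",
                    alt = "A", type = "INDEL", stringsAsFactors = FALSE)
  expect_equal(compute_msi(bad, g)$qualifying_indels, 0)
})

test_that("MSI scorer agrees with a brute-force overlap count", {
  g <- test_genome()
  withr::with_seed(17, {
    ms <- g$microsatellites
    n <- 300
    near <- sample(nrow(ms), n, replace = TRUE)
    offset <- sample(-3:6, n, replace = TRUE)     # some inside, some outside
    ind <- data.frame(chrom = ms$chrom[near],
                      pos = ms$start[near] + offset + 1L,
                      type = "INDEL", stringsAsFactors = FALSE)
    qual <- ms[(ms$unit_length == 1 & ms$repeat_count >= 5) |
                 (ms$unit_length %in% 2:4 & ms$repeat_count >= 4), ]
    brute <- sum(vapply(seq_len(n), function(i)
      any(qual$chrom == ind$chrom[i] & ind$pos[i] - 1 >= qual$start &
            ind$pos[i] - 1 < qual$end), logical(1)))
    expect_equal(compute_msi(ind, g)$qualifying_indels, brute)
  })
})

test_that("TMB and the eligibility flag use the strict 10/Mb rule", {
  t0 <- compute_tmb(0, 3100)
  expect_equal(t0$tmb, 0)
  expect_false(t0$eligible)
  expect_false(compute_tmb(31000, 3100)$eligible)   # exactly 10/Mb
  expect_true(compute_tmb(40000, 3100)$eligible)
  g <- test_genome()
  v <- data.frame(type = c("SNV", "MNV", "INDEL", "SNV"))
  expect_equal(compute_tmb(v, g)$n_mutations, 4)
})
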