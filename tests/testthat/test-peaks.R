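# hand-enumerable event matrices: expected peel-off outcomes derived
# manually from the definition (argmax support, contiguous extension over
# genes shared by all supporting samples, peel, repeat)

chr7_genes <- function() {
  g <- test_genome()
  ge <- g$genes[g$genes$chrom == "chr7", ]
  ge$gene[order(ge$start)]
}

ev_row <- function(sample, gene, direction = "amp", del_size = NA_real_) {
  g <- test_genome()
  data.frame(sample = sample, gene = gene,
             chrom = g$genes$chrom[match(gene, g$genes$gene)],
             direction = direction, del_size = del_size,
             stringsAsFactors = FALSE)
}

test_that("a planted focal peak amid broad gains resolves to the focal gene", {
  genes7 <- chr7_genes()
  focal <- do.call(rbind, lapply(sprintf("S%02d", 1:6), ev_row,
                                 gene = "EGFR"))
  broad <- do.call(rbind, lapply(sprintf("S%02d", 7:9), function(s)
    do.call(rbind, lapply(genes7, ev_row, sample = s))))
  pk <- find_cn_peaks(rbind(focal, broad), test_genome(), n_samples = 50,
                      panel_genes = "EGFR")
  expect_equal(nrow(pk), 1)
  expect_identical(pk$target_gene, "EGFR")
  expect_equal(pk$support, 9)
})

test_that("two independent peaks on one chromosome are returned in support order", {
  genes7 <- chr7_genes()
  a <- genes7[1]; b <- genes7[3]
  ev <- rbind(
    do.call(rbind, lapply(sprintf("A%02d", 1:7), ev_row, gene = a)),
    do.call(rbind, lapply(sprintf("B%02d", 1:5), ev_row, gene = b)))
  pk <- find_cn_peaks(ev, test_genome(), n_samples = 50)
  expect_equal(nrow(pk), 2)
  expect_identical(pk$target_gene, c(a, b))
  expect_equal(pk$support, c(7, 5))
})

test_that("peel-off output is invariant to event-row order", {
  genes7 <- chr7_genes()
  ev <- rbind(
    do.call(rbind, lapply(sprintf("A%02d", 1:7), ev_row, gene = genes7[1])),
    do.call(rbind, lapply(sprintf("B%02d", 1:6), ev_row, gene = genes7[2])))
  pk1 <- find_cn_peaks(ev, test_genome(), n_samples = 60)
  pk2 <- find_cn_peaks(ev[rev(seq_len(nrow(ev))), ], test_genome(),
                       n_samples = 60)
  expect_identical(pk1, pk2)
})

test_that("removing a peak's supporting samples removes the peak on re-run", {
  genes7 <- chr7_genes()
  ev <- rbind(
    do.call(rbind, lapply(sprintf("A%02d", 1:7), ev_row, gene = genes7[1])),
    do.call(rbind, lapply(sprintf("B%02d", 1:6), ev_row, gene = genes7[2])))
  pk <- find_cn_peaks(ev, test_genome(), n_samples = 60)
  top <- pk$target_gene[1]
  supporting <- unique(ev$sample[ev$gene == top])
  pk2 <- find_cn_peaks(ev[!ev$sample %in% supporting, ], test_genome(),
                       n_samples = 60)
  expect_false(top %in% pk2$target_gene)
})

test_that("support below the stopping rule yields no peaks", {
  ev <- do.call(rbind, lapply(sprintf("S%d", 1:4), ev_row, gene = "EGFR"))
  pk <- find_cn_peaks(ev, test_genome(), n_samples = 50)
  expect_equal(nrow(pk), 0)
  expect_equal(nrow(find_cn_peaks(ev[0, ], test_genome(), 50)), 0)
})

test_that("fragile-site annotation requires length and deletion-size rate", {
  g <- test_genome()
  expect_gt(g$genes$length_bp[match("FHIT", g$genes$gene)], 5e5)
  mk_dels <- function(n_in_range, n_total) {
    sizes <- c(rep(5e4, n_in_range), rep(5e6, n_total - n_in_range))
    do.call(rbind, lapply(seq_len(n_total), function(i)
      ev_row(sprintf("S%02d", i), "FHIT", "del", sizes[i])))
  }
  pk_hi <- find_cn_peaks(mk_dels(7, 20), g, n_samples = 40)   # 35% in range
  expect_true(pk_hi$fragile_site[pk_hi$target_gene == "FHIT"])
  pk_lo <- find_cn_peaks(mk_dels(6, 20), g, n_samples = 40)   # exactly 30%
  expect_false(pk_lo$fragile_site[pk_lo$target_gene == "FHIT"])
  # a short gene never qualifies regardless of deletion sizes
  short <- do.call(rbind, lapply(sprintf("S%02d", 1:20), function(s)
    ev_row(s, "TP53", "del", 5e4)))
  pk_s <- find_cn_peaks(short, g, n_samples = 40)
  expect_false(any(pk_s$fragile_site))
})

test_that("deletion peaks exclude chromosome Y", {
  g <- test_genome()
  # DMD lies on chrX; build a fake Y gene event set via AR (chrX) vs none
  ev <- do.call(rbind, lapply(sprintf("S%02d", 1:8), function(s)
    ev_row(s, "AR", "del", 3e4)))
  ev$chrom <- "chrY"
  expect_equal(nrow(find_cn_peaks(ev, g, n_samples = 40)), 0)
})
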