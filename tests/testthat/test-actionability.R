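kb_rec <- function(gene = "EGFR", class = "mutation", detail = "",
                   drug = "drugX", level = "A", direction = "sensitivity",
                   doid = "162") {
  data.frame(gene = gene, event_class = class, detail = detail, drug = drug,
             level = level, direction = direction, doid = doid,
             stringsAsFactors = FALSE)
}

test_that("knowledgebase loading keeps only A/B levels and deduplicates", {
  kb <- rbind(kb_rec(level = "A"), kb_rec(level = "C", drug = "drugC"),
              kb_rec(level = "A"))                       # duplicate
  out <- load_knowledgebase(kb)
  expect_equal(nrow(out), 1)
  expect_error(load_knowledgebase(kb_rec(level = "Z")), "unknown evidence")
  expect_equal(nrow(load_knowledgebase(kb_rec()[0, ])), 0)
  # JSON round trip via the fixture writer
  fx <- test_fixtures()
  d <- withr::local_tempdir()
  write_fixture_resources(fx, d)
  kb2 <- load_knowledgebase(file.path(d, "knowledgebase.json"))
  expect_true(all(kb2$level %in% c("A", "B")))
  expect_lt(nrow(kb2), nrow(fx$knowledgebase))   # C/D records dropped
})

test_that("MSI samples gain a level-A match and label status uses the ontology", {
  fx <- test_fixtures()
  kb <- load_knowledgebase(fx$knowledgebase)
  m <- match_actionable_events(NULL, TRUE, kb, "9256", fx$ontology)
  expect_true(any(m$biomarker == "MSI" & m$level == "A"))
  # descendant DOID is on-label: breast lobular carcinoma under breast cancer
  cat1 <- data.frame(gene = "ERBB2", class = "amplification",
                     variant = "CN=8", hotspot = FALSE,
                     stringsAsFactors = FALSE)
  m2 <- match_actionable_events(cat1, FALSE, kb, "3458", fx$ontology)
  expect_true(m2$on_label[m2$drug == "trastuzumab"])
  # unrelated tumour type: off-label
  m3 <- match_actionable_events(cat1, FALSE, kb, "1324", fx$ontology)
  expect_false(m3$on_label[m3$drug == "trastuzumab"])
  # missing ontology id warns and matches off-label
  expect_warning(m4 <- match_actionable_events(cat1, FALSE, kb, NA,
                                               fx$ontology), "off-label")
  expect_false(any(m4$on_label))
  # MSS sample with no events matches nothing
  expect_equal(nrow(match_actionable_events(NULL, FALSE, kb, "162",
                                            fx$ontology)), 0)
})

test_that("resistance exclusion follows the same-or-higher-level rule exactly", {
  mk_match <- function(sens_level, res_level, on = TRUE) {
    m <- data.frame(biomarker = "EGFR:point", drug = "drugX",
                    level = sens_level, direction = "sensitivity",
                    on_label = on, stringsAsFactors = FALSE)
    if (!is.na(res_level))
      m <- rbind(m, data.frame(biomarker = "KRAS:point", drug = "drugX",
                               level = res_level, direction = "resistance",
                               on_label = on, stringsAsFactors = FALSE))
    m
  }
  # exhaustive (sensitivity level x resistance level x label) truth table
  cases <- expand.grid(sens = c("A", "B"), res = c(NA, "A", "B"),
                       on = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    call <- rank_and_report(mk_match(cs$sens, cs$res, cs$on))
    excluded <- !is.na(cs$res) &&
      (cs$res == "A" || (cs$res == "B" && cs$sens == "B"))
    expect_identical(call$actionable, !excluded,
                     info = paste(cs$sens, cs$res, cs$on))
    if (!excluded) {
      expect_identical(call$best_level, cs$sens)
      expect_identical(call$best_on_label, cs$on)
    } else {
      expect_equal(nrow(call$excluded), 1)
    }
  }
  # resistance from the same biomarker does not exclude
  m <- mk_match("A", NA)
  m <- rbind(m, data.frame(biomarker = "EGFR:point", drug = "drugX",
                           level = "A", direction = "resistance",
                           on_label = TRUE, stringsAsFactors = FALSE))
  expect_true(rank_and_report(m)$actionable)
})

test_that("ranking is a total order invariant to permutation", {
  m <- data.frame(
    biomarker = c("a", "b", "c", "d"), drug = c("w", "x", "y", "z"),
    level = c("B", "A", "B", "A"), direction = "sensitivity",
    on_label = c(TRUE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  call <- rank_and_report(m)
  # A on-label > A off-label > B on-label > B off-label
  expect_identical(call$best_level, "A")
  expect_true(call$best_on_label)
  expect_identical(call$treatments$drug, c("z", "x", "w", "y"))
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    expect_identical(rank_and_report(m[perm, ]), call)
  }
  # {B on-label, A off-label} -> best is A off-label
  m2 <- m[m$drug %in% c("w", "x"), ]
  call2 <- rank_and_report(m2)
  expect_identical(call2$best_level, "A")
  expect_false(call2$best_on_label)
})

test_that("adding resistance evidence never raises the reported level", {
  withr::with_seed(14, {
    for (k in 1:20) {
      n <- sample(1:4, 1)
      m <- data.frame(
        biomarker = sprintf("b%d", seq_len(n)),
        drug = sample(c("d1", "d2"), n, replace = TRUE),
        level = sample(c("A", "B"), n, replace = TRUE),
        direction = "sensitivity",
        on_label = sample(c(TRUE, FALSE), n, replace = TRUE),
        stringsAsFactors = FALSE)
      base <- rank_and_report(m)
      res <- data.frame(biomarker = "bR",
                        drug = sample(c("d1", "d2"), 1),
                        level = sample(c("A", "B"), 1),
                        direction = "resistance", on_label = TRUE,
                        stringsAsFactors = FALSE)
      with_res <- rank_and_report(rbind(m, res))
      rank_of <- function(call) {
        if (!call$actionable) return(0)
        c(B = 1, A = 2)[call$best_level] * 2 + call$best_on_label
      }
      expect_lte(rank_of(with_res), rank_of(base))
    }
  })
})
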