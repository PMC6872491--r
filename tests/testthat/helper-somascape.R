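# Shared fixtures: the default scaled genome and fixture resources are
# expensive enough to build once per test run.

test_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- mini_genome()
    g
  }
})

test_fixtures <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_fixture_resources(test_genome())
    fx
  }
})

# a copy-number segment table with k fully duplicated autosomes at (2,1)
# and the rest at (1,1)
wgd_profile <- function(k, genome = test_genome()) {
  ch <- genome$chromosomes
  aut <- ch[ch$is_autosome, ]
  data.frame(chrom = aut$name, start = 0L, end = aut$length,
             cn = ifelse(seq_len(nrow(aut)) <= k, 3, 2),
             major = ifelse(seq_len(nrow(aut)) <= k, 2, 1),
             minor = 1, stringsAsFactors = FALSE)
}

# single-segment-per-chromosome copy-number table at a fixed state
flat_cn_segments <- function(genome, major, minor) {
  ch <- genome$chromosomes
  data.frame(chrom = ch$name, start = 0L, end = ch$length,
             cn = major + minor, major = major, minor = minor,
             stringsAsFactors = FALSE)
}

# qualifying-indel variant table of a given size placed on microsatellites
ms_indels <- function(genome, n) {
  ms <- genome$microsatellites
  qual <- ms[(ms$unit_length == 1 & ms$repeat_count >= 5) |
               (ms$unit_length %in% 2:4 & ms$repeat_count >= 4), ]
  j <- rep_len(seq_len(nrow(qual)), n)
  data.frame(chrom = qual$chrom[j], pos = qual$start[j] + 1L, ref = "AA",
             alt = "A", type = "INDEL", stringsAsFactors = FALSE)
}
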