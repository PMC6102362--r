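make_contig_with <- function(left, insert, right) {
  c(ctg = paste0(left, insert, right))
}

test_that("tandem satellite arrays are chained into blocks with unit counts", {
  set.seed(51)
  monomer <- random_dna(528)
  arr <- strrep(monomer, 10)
  seqs <- make_contig_with(random_dna(5000), arr, random_dna(5000))
  blocks <- detect_satellite_blocks(seqs, monomer)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_units, 10)
  expect_lt(abs(blocks$start - 5000), 30)
  expect_lt(abs(blocks$end - (5000 + 5280)), 30)

  ## no monomer similarity anywhere -> empty
  none <- detect_satellite_blocks(c(ctg = random_dna(20000)), monomer)
  expect_equal(nrow(none), 0)
  expect_error(detect_satellite_blocks(seqs, ""), "empty monomer")
})

test_that("satellite unit counts are position-invariant and strand-symmetric", {
  set.seed(52)
  monomer <- random_dna(528)
  arr <- strrep(monomer, 6)
  s1 <- make_contig_with(random_dna(2000), arr, random_dna(12000))
  s2 <- make_contig_with(random_dna(11000), arr, random_dna(3000))
  b1 <- detect_satellite_blocks(s1, monomer)
  b2 <- detect_satellite_blocks(s2, monomer)
  expect_equal(b1$n_units, b2$n_units)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s1[["ctg"]])))
  b3 <- detect_satellite_blocks(c(ctg = rc), monomer)
  expect_equal(nrow(b3), nrow(b1))
  expect_equal(b3$n_units, b1$n_units)
  expect_equal(b3$start, nchar(rc) - b1$end)
})

test_that("diverged satellite blocks keep unit-count recall against the ledger", {
  sim <- generate_locus_pair(small_sim_config(seed = 12))
  blocks <- detect_satellite_blocks(sim$assembly_a$contigs,
                                    sim$satellite_profile)
  planted <- sum(vapply(Filter(function(x) x$genotype == "genoA",
                               sim$ledger$satellites),
                        function(x) x$n_units, 1))
  expect_gte(sum(blocks$n_units), ceiling(0.9 * planted))
  expect_lte(sum(blocks$n_units), planted + 1)
})

test_that("intact and solo LTR elements are classified through their TSDs", {
  set.seed(53)
  ltr <- random_dna(300)
  lib <- c(fam1 = ltr)
  tsd <- random_dna(5)
  intact <- paste0(tsd, ltr, random_dna(2000), ltr, tsd)
  solo <- paste0(tsd, ltr, tsd)
  bare <- ltr  # no TSD anywhere
  seqs <- c(ctg = paste0(random_dna(4000), intact, random_dna(20000),
                         solo, random_dna(20000), bare, random_dna(4000)))
  el <- detect_ltr_elements(seqs, lib)
  expect_equal(sum(el$classification == "intact"), 1)
  expect_equal(sum(el$classification == "solo"), 1)
  expect_equal(sum(el$classification == "truncated"), 1)
  it <- el[el$classification == "intact", ]
  expect_equal(it$tsd_len, 5)
  expect_equal(it$tsd, tsd)
  expect_false(is.na(el$tsd[el$classification == "solo"]))
  expect_error(detect_ltr_elements(seqs, character(0)), "empty LTR")
})

test_that("the I/S ratio summarises intact versus solo counts", {
  el <- data.frame(classification = c(rep("intact", 6), rep("solo", 5)))
  rs <- compute_is_ratio(el)
  expect_equal(rs$is_ratio, 1.2)
  expect_true(rs$is_defined)

  none <- compute_is_ratio(data.frame(classification = rep("intact", 3)))
  expect_false(none$is_defined)
  expect_true(is.na(none$is_ratio))
})

test_that("planted LTR landscapes are recovered exactly", {
  sim <- generate_locus_pair(small_sim_config(seed = 13))
  for (asm in list(sim$assembly_a, sim$assembly_b)) {
    el <- detect_ltr_elements(asm$contigs, sim$ltr_library)
    rs <- compute_is_ratio(el)
    expect_equal(rs$n_intact, 2)
    expect_equal(rs$n_solo, 1)
    expect_equal(rs$is_ratio, 2)
  }
})
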