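test_that("NG86 site and difference counting matches hand enumeration", {
  ## four-fold degenerate glycine codon: third position fully synonymous
  aln <- align_coding_pair("GGA", "GGA")
  sc <- ng86_sites_and_diffs(aln)
  expect_equal(sc$S, 1)
  expect_equal(sc$N, 2)
  expect_equal(sc$Sd, 0)
  expect_equal(sc$Nd, 0)

  ## one synonymous third-position change in a glycine run
  sc2 <- ng86_sites_and_diffs(align_coding_pair("GGTGGAGGG", "GGCGGAGGG"))
  expect_equal(sc2$S, 3)
  expect_equal(sc2$N, 6)
  expect_equal(sc2$Sd, 1)
  expect_equal(sc2$Nd, 0)
})

test_that("NG86 counts agree with the brute-force pathway oracle", {
  set.seed(101)
  for (rep in 1:60) {
    rc <- random_codons(sample(1:3, 1))
    if (length(rc$a) == 0) next
    aln <- structure(list(gene_a = "a", gene_b = "b",
                          codons_a = rc$a, codons_b = rc$b,
                          n_cols = length(rc$a), n_gapped_cols = 0L,
                          identity = NA_real_, method = "direct"),
                     class = "codon_alignment")
    got <- ng86_sites_and_diffs(aln)
    want <- oracle_ng86(rc$a, rc$b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction follows the closed form and flags saturation", {
  sc <- structure(list(S = 3, N = 6, Sd = 1, Nd = 0, n_codons = 3),
                  class = "site_counts")
  est <- compute_ka_ks(sc)
  expect_equal(est$ps, 1 / 3)
  expect_equal(est$ks, -0.75 * log(1 - 4 / 9), tolerance = 1e-12)
  expect_equal(est$ka, 0)
  expect_false(est$saturated)

  sat <- compute_ka_ks(structure(list(S = 4, N = 8, Sd = 3.2, Nd = 0,
                                      n_codons = 4), class = "site_counts"))
  expect_true(sat$saturated_ks)
  expect_true(is.na(sat$ks))

  undef <- compute_ka_ks(structure(list(S = 0, N = 6, Sd = 0, Nd = 1,
                                        n_codons = 2), class = "site_counts"))
  expect_true(is.na(undef$ks))
  expect_false(undef$saturated_ks)
})

test_that("Ka/Ks estimates are symmetric and zero on identity", {
  set.seed(7)
  orf <- random_orf(120)
  div <- mutate_to_target_ks(orf, 0.2, "proportional")
  ab <- kaks_pair(orf, div)
  ba <- kaks_pair(div, orf)
  expect_equal(ab$ks, ba$ks, tolerance = 1e-12)
  expect_equal(ab$ka, ba$ka, tolerance = 1e-12)
  expect_equal(ab$identity, ba$identity, tolerance = 1e-12)

  self <- kaks_pair(orf, orf)
  expect_equal(self$ks, 0)
  expect_equal(self$ka, 0)
  expect_equal(self$identity, 1)
})

test_that("Ks is strictly increasing in the synonymous proportion", {
  ps <- seq(0.02, 0.70, by = 0.04)
  ks <- vapply(ps, function(p) {
    compute_ka_ks(structure(list(S = 100, N = 200, Sd = 100 * p, Nd = 0,
                                 n_codons = 100), class = "site_counts"))$ks
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks >= ps))  # correction inflates the raw proportion
})

test_that("protein-guided alignment handles identity, stops, and codon indels", {
  set.seed(11)
  a <- random_orf(100)
  aln <- align_coding_pair(a, a)
  expect_equal(aln$n_cols, 100)
  expect_equal(aln$identity, 1)
  expect_equal(aln$method, "protein")

  ## single codon insertion: back-mapping checked against a tiny NW oracle
  b20 <- random_orf(20)
  ins <- paste0(substr(b20, 1, 30), "GCA", substr(b20, 31, 60))
  aln2 <- align_coding_pair(b20, ins)
  expect_equal(aln2$n_cols, 20)
  expect_equal(aln2$n_gapped_cols, 1)
  nw <- oracle_protein_nw(translate_cds(b20), translate_cds(ins))
  expect_equal(sum(nw[, 1] == "-" | nw[, 2] == "-"), 1)
  expect_equal(aln2$identity, 1)

  ## premature stops are aligned as stop symbols, not dropped
  ps <- a
  substr(ps, 61, 63) <- "TGA"
  aln3 <- align_coding_pair(a, ps)
  expect_equal(aln3$method, "protein")
  expect_equal(aln3$n_cols, 100)
  sc <- ng86_sites_and_diffs(aln3)
  ## premature and terminal stop columns both excluded from counting
  expect_equal(sc$n_codons, 98)
})

test_that("frameshifted pseudogenes fall back to nucleotide-guided codon pairing", {
  set.seed(12)
  a <- random_orf(120)
  fs <- paste0(substr(a, 1, 179), substr(a, 181, nchar(a)))  # 1-bp deletion
  aln <- align_coding_pair(a, fs)
  expect_equal(aln$method, "nucleotide")
  expect_gt(aln$identity, 0.99)
  est <- compute_ka_ks(ng86_sites_and_diffs(aln))
  expect_lt(est$ks, 0.01)  # homologous bases stay paired across the indel
})

test_that("synonymous-only simulated divergence yields Ka exactly zero", {
  set.seed(13)
  orf <- random_orf(150)
  mut <- mutate_to_target_ks(orf, 0.08, "synonymous_only")
  expect_equal(translate_cds(mut), translate_cds(orf))
  r <- kaks_pair(orf, mut)
  expect_identical(r$ka, 0)
  expect_gte(r$ks, 0.06)
})
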