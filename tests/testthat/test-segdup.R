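test_that("hard masking blanks exactly the selected feature spans", {
  set.seed(61)
  cds <- random_orf(200)
  contig <- paste0(random_dna(1000), cds, random_dna(1000))
  asm <- genotype_assembly("g", c(c1 = contig), data.frame(
    feature_id = "cnl1", type = "gene", contig_id = "c1",
    start = 1000L, end = 1000L + nchar(cds), strand = "+",
    gene_class = "CNL", subfamily = "CNL1", status = "intact",
    cds = cds, stringsAsFactors = FALSE))
  masked <- mask_features(asm, "CNL")
  expect_equal(nchar(masked[["c1"]]), nchar(contig))
  expect_equal(substr(masked[["c1"]], 1001, 1000 + nchar(cds)),
               strrep("N", nchar(cds)))
  expect_equal(substr(masked[["c1"]], 1, 1000), substr(contig, 1, 1000))
  ## no features of the class -> unchanged
  expect_identical(mask_features(asm, "satellite_DNA")[["c1"]], contig)
  expect_error(mask_features(asm, "nonsense"), "unknown feature class")
})

test_that("segmental duplications obey the identity/length thresholds", {
  set.seed(62)
  dup600 <- random_dna(600)
  dup450 <- random_dna(450)
  big <- random_dna(2000)
  big92 <- mutate_noncoding(big, 0.075)
  seqs <- c(ctg = paste0(random_dna(3000), dup600, random_dna(3000), dup450,
                         random_dna(3000), big, random_dna(3000), dup600,
                         random_dna(3000), dup450, random_dna(3000), big92,
                         random_dna(3000)))
  sd <- detect_segmental_duplications(seqs)
  expect_true(nrow(sd) >= 2)
  lens <- sd$end_1 - sd$start_1
  expect_true(any(abs(lens - 600) < 30))        # 600-bp copy found
  expect_false(any(abs(lens - 450) < 30))       # 450-bp copy rejected
  hit92 <- sd[which.max(lens), ]
  expect_gte(hit92$end_1 - hit92$start_1, 1900)
  oracle_id <- global_nt_identity(big, big92)
  expect_lt(abs(hit92$identity - oracle_id), 0.02)
  expect_true(all(sd$identity > 0.90))
  expect_true(all(sd$length >= 500))
})

test_that("self-comparison is symmetric and excludes trivial self-hits", {
  set.seed(63)
  dup <- random_dna(800)
  s1 <- c(a = paste0(random_dna(2000), dup, random_dna(2000)))
  s2 <- c(b = paste0(random_dna(1500), dup, random_dna(2500)))
  ab <- detect_segmental_duplications(s1, s2)
  ba <- detect_segmental_duplications(s2, s1)
  expect_equal(ab[order(ab$start_1), ], ba[order(ba$start_1), ])
  self <- detect_segmental_duplications(c(s1, s2))
  expect_true(all(!(self$contig_1 == self$contig_2 &
                    self$start_1 == self$start_2)))
})

test_that("windowed identity profiles match their closed-form cases", {
  ident <- windowed_identity_profile(strrep("ACGT", 50), strrep("ACGT", 50))
  expect_true(all(ident$identity == 1))
  expect_true(all(ident$fill))

  a <- strrep("AC", 100)
  b <- strrep("AG", 100)  # strictly alternating match/mismatch
  alt <- windowed_identity_profile(a, b)
  expect_true(all(alt$identity == 0.5))
  expect_false(any(alt$fill))
  expect_equal(length(alt$identity), 200 - 10 + 1)
  expect_error(windowed_identity_profile("ACGTACGT", "ACGTACGT"),
               "shorter than one window")
  expect_error(windowed_identity_profile("ACGT", "ACG"), "equal length")
})

test_that("a planted 80%-identity segment fills inside and not outside", {
  set.seed(64)
  seg_a <- random_dna(400)
  seg_b <- strsplit(seg_a, "")[[1]]
  at <- round((seq_len(80) - 0.5) * 400 / 80)
  for (p in at) seg_b[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                           seg_b[p]), 1)
  a <- paste0(random_dna(300), seg_a, random_dna(300))
  b <- paste0(random_dna(300), paste(seg_b, collapse = ""), random_dna(300))
  prof <- windowed_identity_profile(a, b)
  inside <- prof$positions >= 310 & prof$positions <= 680
  outside <- prof$positions < 280 | prof$positions > 700
  expect_true(all(prof$fill[inside]))
  expect_lt(mean(prof$fill[outside]), 0.05)
})

test_that("junction changepoints and microhomology match the exhaustive oracle", {
  set.seed(65)
  for (m in c(0, 3, 8, 12)) {
    p <- plant_junction(random_dna(6000), random_dna(4000), "NHEJ",
                        params = list(m = c(m, m)))
    rj <- resolve_junction(p$hybrid, p$donor, p$recipient)
    for (side in c("X", "Y")) {
      orc <- oracle_junction(p$hybrid, p$donor, p$recipient, p$tract,
                             p$donor_tract, side)
      expect_equal(rj[[side]]$microhomology_m, orc$m, info = paste(side, m))
      expect_equal(rj[[side]]$microhomology_m, m)
      expect_equal(rj[[side]]$position, orc$position)
    }
  }
})

test_that("repair-pathway classification separates NHEJ, HR, and ambiguity", {
  cfg <- analysis_config()
  jc <- function(m, tlen = NA, tid = NA, drop_out = NA) {
    structure(list(junction_id = "X", position = 100L,
                   microhomology_m = m, transition_len = tlen,
                   transition_identity = tid,
                   identity_drop = c(outside = drop_out, inside = 1),
                   recipient_available = !is.na(m)),
              class = "junction_call")
  }
  expect_identical(classify_repair_pathway(jc(3), cfg), "NHEJ")
  expect_identical(classify_repair_pathway(jc(0, 130, 0.80), cfg), "HR")
  ## transition below both thresholds does not rescue an HR call
  expect_identical(classify_repair_pathway(jc(0, 40, 0.65), cfg), "NHEJ")
  expect_identical(classify_repair_pathway(jc(14), cfg), "ambiguous")
  ## degraded mode: no recipient, abrupt drop -> NHEJ
  expect_identical(classify_repair_pathway(jc(NA, drop_out = 0.3), cfg),
                   "NHEJ")
  expect_identical(classify_repair_pathway(jc(NA, drop_out = 0.9), cfg),
                   "ambiguous")
})

test_that("planted HR junctions resolve to HR with measured transitions", {
  set.seed(66)
  p <- plant_junction(random_dna(6000), random_dna(4000), "HR",
                      params = list(transition_len = c(130, 70),
                                    transition_identity = c(0.80, 0.75)))
  rj <- resolve_junction(p$hybrid, p$donor, p$recipient)
  expect_identical(rj$X$repair_class, "HR")
  expect_identical(rj$Y$repair_class, "HR")
  expect_lt(abs(rj$X$transition_len - 130), 15)
  expect_lt(abs(rj$X$transition_identity - 0.80), 0.06)
})

test_that("masked spans attract no segmental-duplication hits", {
  set.seed(67)
  cds <- random_orf(400)  # 1200 bp, duplicated below
  contig <- paste0(random_dna(2000), cds, random_dna(2000), cds,
                   random_dna(2000))
  asm <- genotype_assembly("g", c(c1 = contig), data.frame(
    feature_id = c("g1", "g2"), type = "gene", contig_id = "c1",
    start = c(2000L, 2000L + nchar(cds) + 2000L),
    end = c(2000L + nchar(cds), 2000L + 2 * nchar(cds) + 2000L),
    strand = "+", gene_class = "CNL", subfamily = "CNL1",
    status = "intact", cds = cds, stringsAsFactors = FALSE))
  unmasked <- detect_segmental_duplications(asm$contigs)
  expect_gte(nrow(unmasked), 1)
  masked <- detect_segmental_duplications(mask_features(asm, "CNL"))
  expect_equal(nrow(masked), 0)
})
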