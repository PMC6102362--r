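test_that("gene status follows the annotation-level pseudogene rule", {
  set.seed(41)
  clean <- random_orf(50)
  expect_identical(classify_gene_status(clean), "intact")
  stopm <- clean
  substr(stopm, 31, 33) <- "TGA"
  expect_identical(classify_gene_status(stopm), "pseudogene")
  fs <- paste0(substr(clean, 1, 40), substr(clean, 42, nchar(clean)))
  expect_identical(classify_gene_status(fs), "pseudogene")
  seg <- sub("^ATG", "GTG", clean)
  expect_identical(classify_gene_status(seg), "segment")
})

test_that("subfamily assignment applies the exemplar identity threshold", {
  set.seed(42)
  e1 <- random_dna(600)
  e2 <- random_dna(600)
  refs <- c(CNL1 = e1, CNL3_4 = e2)
  mutate_exact <- function(seq, k) {
    v <- strsplit(seq, "")[[1]]
    pos <- round(seq(1, length(v), length.out = k))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  expect_identical(assign_subfamily(e1, refs)$subfamily, "CNL1")
  near <- mutate_exact(e1, 150)  # 75% identity to CNL1
  expect_identical(assign_subfamily(near, refs)$subfamily, "CNL1")
  far <- mutate_exact(e1, 185)   # ~69% identity: below the 72% threshold
  res <- assign_subfamily(far, refs)
  expect_identical(res$subfamily, "none")
  expect_error(assign_subfamily(e1, character(0)), "named vector")
})

test_that("threshold calibration takes the maximum anchor Ks and rejects bad anchors", {
  set.seed(43)
  anchors <- stats::setNames(replicate(4, random_orf(200)),
                             paste0("a", 1:4))
  targets <- c(0.01, 0.02, 0.04, 0.005)
  partners <- stats::setNames(mapply(mutate_to_target_ks, anchors, targets,
                                     MoreArgs = list(mode = "synonymous_only")),
                              paste0("b", 1:4))
  pairing <- data.frame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4))
  cal <- calibrate_ks_threshold(anchors, partners, pairing)
  expect_equal(cal$threshold, max(cal$anchor_pairs$ks))
  expect_equal(cal$ks_mean, mean(cal$anchor_pairs$ks))
  expect_lt(abs(cal$anchor_pairs$ks[3] - 0.04), 0.012)

  ident <- calibrate_ks_threshold(anchors, anchors, data.frame(
    gene_a = paste0("a", 1:4), gene_b = paste0("a", 1:4)))
  expect_equal(ident$threshold, 0)
  expect_equal(ident$ks_mean, 0)

  expect_error(calibrate_ks_threshold(anchors, partners, pairing[1, ]),
               "at least 2")
  broken <- partners
  substr(broken[["b1"]], 31, 33) <- "TAA"
  expect_error(calibrate_ks_threshold(anchors, broken, pairing), "intact")
})

test_that("collinear blocks chain conserved anchor order and break on violations", {
  set.seed(44)
  cds <- stats::setNames(replicate(5, random_orf(100)), paste0("g", 1:5))
  a <- toy_assembly("A", cds)
  b_ok <- toy_assembly("B", stats::setNames(cds, paste0("h", 1:5)))
  pairs <- data.frame(gene_a = paste0("g", 1:5), gene_b = paste0("h", 1:5))
  res <- build_collinear_blocks(a, b_ok, pairs)
  expect_equal(nrow(res$blocks), 1)
  expect_equal(res$blocks$n_anchors, 5)
  ## block extends outward to the contig ends (no conflicting anchors)
  expect_equal(res$blocks$start_a, 0)
  expect_equal(res$blocks$end_a, nchar(a$contigs[["c1"]]))

  ## ABCDE vs ACBDE: order break at the B/C swap forces >= 2 blocks
  b_swap <- toy_assembly("B", stats::setNames(cds, paste0("h", 1:5)),
                         order = c(1, 3, 2, 4, 5))
  res2 <- build_collinear_blocks(a, b_swap, pairs)
  expect_gte(nrow(res2$blocks), 2)
})

test_that("identical assemblies give only orthologs and an empty event catalog", {
  sim <- generate_locus_pair(null_sim_config(seed = 6))
  rb <- run_pipeline(sim$assembly_a, sim$assembly_b)
  expect_equal(rb$calibration$threshold, 0)
  n_genes <- nrow(assembly_genes(sim$assembly_a, c("CNL", "TNL")))
  expect_equal(sum(rb$pairs$relation == "ortholog"), n_genes)
  expect_equal(sum(rb$pairs$relation == "recent_paralog"), 0)
  expect_equal(nrow(rb$events$losses), 0)
  expect_equal(nrow(rb$events$recent_duplications), 0)
  expect_equal(nrow(rb$events$pseudogenizations), 0)
})

test_that("a seeded simulation's event ledger is recovered by the pipeline", {
  sim <- generate_locus_pair(small_sim_config(seed = 11))
  rb <- run_pipeline(sim$assembly_a, sim$assembly_b,
                     satellite_profile = sim$satellite_profile,
                     ltr_library = sim$ltr_library)
  led <- sim$ledger

  planted <- sort(vapply(led$losses, `[[`, "", "surviving_counterpart"))
  expect_identical(sort(rb$events$losses$evidence_gene), planted)
  ## no gene is both loss evidence and an ortholog
  orth <- rb$pairs[rb$pairs$relation == "ortholog", ]
  expect_length(intersect(rb$events$losses$evidence_gene,
                          c(orth$gene_a, orth$gene_b)), 0)

  dup <- led$duplications[[1]]
  expect_equal(rb$events$recent_duplications$source, dup$source)
  expect_equal(rb$events$recent_duplications$copy, dup$copy)

  want_timing <- sort(paste(
    vapply(led$pseudogenizations, `[[`, "", "gene"),
    vapply(led$pseudogenizations, `[[`, "", "timing")))
  got_timing <- sort(paste(sub("^geno[AB]_", "", rb$events$pseudogenizations$gene_a),
                           rb$events$pseudogenizations$timing))
  expect_identical(got_timing, want_timing)
})
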