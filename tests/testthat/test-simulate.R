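test_that("null simulation yields two identical assemblies and an empty ledger", {
  sim <- generate_locus_pair(null_sim_config(seed = 5))
  expect_identical(unname(sim$assembly_a$contigs),
                   unname(sim$assembly_b$contigs))
  strip <- function(asm) {
    ft <- asm$features
    ft$feature_id <- sub("^geno[AB]_", "", ft$feature_id)
    ft$contig_id <- NULL
    ft
  }
  expect_equal(strip(sim$assembly_a), strip(sim$assembly_b))
  expect_length(sim$ledger$losses, 0)
  expect_length(sim$ledger$pseudogenizations, 0)
  expect_length(sim$ledger$duplications, 0)
  expect_length(sim$ledger$ltr, 0)
  expect_length(sim$ledger$segdups, 0)
})

test_that("the same seed reproduces byte-identical FASTA/GFF3 outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_locus_pair(generate_locus_pair(small_sim_config(seed = 8)), d1)
  write_locus_pair(generate_locus_pair(small_sim_config(seed = 8)), d2)
  for (f in c("genoA.fasta", "genoB.fasta", "ledger.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  strip_date <- function(x) x[!grepl("^##date", x)]
  for (f in c("genoA.gff3", "genoB.gff3"))
    expect_identical(strip_date(readLines(file.path(d1, f))),
                     strip_date(readLines(file.path(d2, f))), info = f)
})

test_that("gene counts are conserved: ancestral - losses + duplications", {
  cfg <- small_sim_config(seed = 9)
  sim <- generate_locus_pair(cfg)
  ancestral <- cfg$n_anchor_genes + sum(cfg$n_cnl_per_subfamily) + cfg$n_tnl
  n_a <- nrow(assembly_genes(sim$assembly_a))
  n_b <- nrow(assembly_genes(sim$assembly_b))
  expect_equal(n_a, ancestral - cfg$n_losses_per_lineage[["A"]] +
                 cfg$n_recent_duplications[["A"]])
  expect_equal(n_b, ancestral - cfg$n_losses_per_lineage[["B"]] +
                 cfg$n_recent_duplications[["B"]])
})

test_that("mutate_to_target_ks honours its contract", {
  set.seed(31)
  orf <- random_orf(111)
  expect_identical(mutate_to_target_ks(orf, 0), orf)
  expect_error(mutate_to_target_ks(orf, 0.8), "saturation")
  expect_error(mutate_to_target_ks("ATGTAA", 0.1), "too short")

  mut <- mutate_to_target_ks(orf, 0.1, "synonymous_only")
  expect_identical(translate_cds(mut), translate_cds(orf))

  prop <- mutate_to_target_ks(orf, 0.2, "proportional", ka_ks = 0.3)
  st <- classify_gene_status(prop)
  expect_identical(st, "intact")  # no stops ever introduced
})

test_that("simulated divergence recovers the target Ks without bias", {
  set.seed(32)
  orf <- random_orf(333)  # 999 bp
  ks <- vapply(1:8, function(i) {
    kaks_pair(orf, mutate_to_target_ks(orf, 0.05))$ks
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.05), 0.01)
})

test_that("planted NHEJ junctions have engineered microhomology and clean flanks", {
  set.seed(33)
  R <- random_dna(6000)
  D <- random_dna(4000)
  p0 <- plant_junction(R, D, "NHEJ", params = list(m = c(0, 0)))
  ## blunt junction: hybrid flanks equal recipient left / donor right exactly
  b <- p0$tract[1]
  expect_identical(substr(p0$hybrid, 1, b), substr(p0$recipient, 1, b))
  expect_identical(substr(p0$hybrid, b + 1, b + 50),
                   substr(p0$donor, p0$donor_tract[1] + 1,
                          p0$donor_tract[1] + 50))
  p3 <- plant_junction(R, D, "NHEJ", params = list(m = c(3, 5)))
  expect_equal(p3$truth$X$m, 3)
  expect_equal(p3$truth$Y$m, 5)
})

test_that("planted HR transitions realize their target identity windows", {
  set.seed(34)
  p <- plant_junction(random_dna(6000), random_dna(4000), "HR",
                      params = list(transition_len = c(130, 80),
                                    transition_identity = c(0.8, 0.75)))
  expect_equal(p$truth$X$transition_len, 130)
  expect_lt(abs(p$truth$X$transition_identity - 0.8), 0.03)
  expect_equal(p$truth$Y$transition_len, 80)
})
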