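## Reduced simulation configuration for fast unit tests: same event
## machinery, smaller locus.

small_sim_config <- function(seed = 1, ...) {
  sim_config(n_anchor_genes = 4L,
             n_cnl_per_subfamily = c(CNL1 = 3L, CNL3_4 = 3L),
             n_tnl = 0L,
             n_losses_per_lineage = c(A = 1L, B = 1L),
             n_pseudogenization_shared = 1L,
             n_pseudogenization_lineage = c(A = 1L, B = 1L),
             n_recent_duplications = c(A = 1L, B = 0L),
             n_segdups = c(A = 1L, B = 0L),
             n_intact_ltr = 2L,
             n_solo_ltr = 1L,
             n_satellite_blocks = 1L,
             satellite_units_range = c(4L, 6L),
             spacer_len_mean = 4000L,
             seed = seed,
             ...)
}

null_sim_config <- function(seed = 1) {
  sim_config(n_anchor_genes = 4L,
             n_cnl_per_subfamily = c(CNL1 = 3L, CNL3_4 = 3L),
             n_tnl = 0L,
             anchor_ks_mean = 0,
             n_losses_per_lineage = c(A = 0L, B = 0L),
             n_pseudogenization_shared = 0L,
             n_pseudogenization_lineage = c(A = 0L, B = 0L),
             n_recent_duplications = c(A = 0L, B = 0L),
             n_segdups = c(A = 0L, B = 0L),
             n_intact_ltr = 0L,
             n_solo_ltr = 0L,
             n_satellite_blocks = 0L,
             spacer_len_mean = 3000L,
             seed = seed)
}

## a hand-built assembly: anchors at given order positions on one contig
toy_assembly <- function(genotype_id, anchor_cds, order = seq_along(anchor_cds),
                         gap = 2000L) {
  ids <- names(anchor_cds)
  n <- length(ids)
  lens <- nchar(anchor_cds)
  starts <- integer(n)
  pos <- gap
  contig <- strrep("A", gap)
  for (k in order) {
    starts[k] <- nchar(contig)
    contig <- paste0(contig, anchor_cds[[k]], strrep("A", gap))
  }
  features <- data.frame(
    feature_id = ids, type = "gene",
    contig_id = "c1", start = starts, end = starts + lens,
    strand = "+", gene_class = "low_copy", subfamily = "none",
    status = "intact", cds = unname(anchor_cds),
    stringsAsFactors = FALSE)
  genotype_assembly(genotype_id, stats::setNames(contig, "c1"), features)
}
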