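## Analysis configuration: every numeric rule the pipeline applies, with the
## cluster-comparison defaults.

#' Analysis configuration
#'
#' Bundles the thresholds the comparative pipeline applies.  Defaults encode
#' the operational rules for a two-haplotype NL-cluster comparison:
#' orthologs must lie in a collinear block, fall below the anchor-calibrated
#' Ks threshold and share at least 96\% nucleotide identity; subfamily
#' membership needs 72\% identity to an exemplar; segmental duplications are
#' local alignments of more than 90\% identity over at least 500 bp; VISTA-
#' style identity profiles use 10-bp windows filled at 70\%; the satellite
#' monomer is 528 bp.
#'
#' @param ortholog_identity_min Minimum nucleotide identity within an
#'   ortholog pair (fraction).
#' @param subfamily_identity_min Minimum identity to an exemplar for
#'   subfamily assignment.
#' @param sd_identity_min,sd_length_min Segmental-duplication thresholds:
#'   identity must exceed `sd_identity_min` over at least `sd_length_min` bp.
#' @param window_size,window_identity_min Sliding-window size (bp) and fill
#'   threshold for identity profiles.
#' @param microhomology_max_nhej Longest junction microhomology still read
#'   as NHEJ (bp).
#' @param transition_min_len,transition_min_identity Minimum length (bp) and
#'   donor-recipient identity of a homologous transition region for an HR
#'   call.
#' @param tsd_len_range Length range (bp) of target-site duplications
#'   checked when classifying LTR elements.
#' @param satellite_monomer_len Satellite monomer length (bp).
#' @param satellite_identity_min Minimum identity of a monomer match.
#' @param ltr_identity_min Minimum identity of an LTR-library hit.
#' @param ltr_element_size_range Allowed span (bp) of a full LTR element
#'   (paired LTRs plus internal region).
#' @param anchor_identity_min Minimum identity for pairing low-copy anchors
#'   across genotypes.
#' @param random_seed Seed recorded in reports; all pipeline randomness (none
#'   in the analysis itself, but simulators honour it) flows from here.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(ortholog_identity_min = 0.96,
                            subfamily_identity_min = 0.72,
                            sd_identity_min = 0.90,
                            sd_length_min = 500L,
                            window_size = 10L,
                            window_identity_min = 0.70,
                            microhomology_max_nhej = 10L,
                            transition_min_len = 50L,
                            transition_min_identity = 0.70,
                            tsd_len_range = c(4L, 6L),
                            satellite_monomer_len = 528L,
                            satellite_identity_min = 0.70,
                            ltr_identity_min = 0.75,
                            ltr_element_size_range = c(1000L, 15000L),
                            anchor_identity_min = 0.90,
                            random_seed = 1L) {
  cfg <- list(ks_model = "NG86+JC",
              ortholog_identity_min = ortholog_identity_min,
              subfamily_identity_min = subfamily_identity_min,
              sd_identity_min = sd_identity_min,
              sd_length_min = as.integer(sd_length_min),
              window_size = as.integer(window_size),
              window_identity_min = window_identity_min,
              microhomology_max_nhej = as.integer(microhomology_max_nhej),
              transition_min_len = as.integer(transition_min_len),
              transition_min_identity = transition_min_identity,
              tsd_len_range = as.integer(tsd_len_range),
              satellite_monomer_len = as.integer(satellite_monomer_len),
              satellite_identity_min = satellite_identity_min,
              ltr_identity_min = ltr_identity_min,
              ltr_element_size_range = as.integer(ltr_element_size_range),
              anchor_identity_min = anchor_identity_min,
              random_seed = as.integer(random_seed))
  fracs <- c("ortholog_identity_min", "subfamily_identity_min",
             "sd_identity_min", "window_identity_min",
             "transition_min_identity", "satellite_identity_min",
             "ltr_identity_min", "anchor_identity_min")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("analysis_config: ", f, " must be in [0, 1]")
  lens <- c("sd_length_min", "window_size", "transition_min_len",
            "satellite_monomer_len")
  for (l in lens)
    if (cfg[[l]] <= 0L) stop("analysis_config: ", l, " must be positive")
  if (cfg$tsd_len_range[1] > cfg$tsd_len_range[2] || cfg$tsd_len_range[1] < 1L)
    stop("analysis_config: invalid tsd_len_range")
  structure(cfg, class = "analysis_config")
}
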