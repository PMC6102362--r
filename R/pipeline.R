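## End-to-end comparative pipeline: calibrate -> blocks -> pairs -> events
## -> repeats -> segmental duplications -> junctions.

## retrieve, in the other genotype, the putative recipient molecule for a
## hybrid tract: both hybrid flanks must map close together (i.e. without
## the inserted tract between them)
.retrieve_recipient <- function(flank_left, flank_right, other_contigs,
                                tract_len) {
  hits <- blastn_hits(c(L = flank_left, R = flank_right), other_contigs,
                      task = "megablast")
  if (nrow(hits) == 0) return(NULL)
  hl <- hits[hits$qid == "L", , drop = FALSE]
  hr <- hits[hits$qid == "R", , drop = FALSE]
  if (nrow(hl) == 0 || nrow(hr) == 0) return(NULL)
  hl <- hl[which.max(hl$bitscore), ]
  hr <- hr[which.max(hr$bitscore), ]
  if (hl$sid != hr$sid || hl$strand != hr$strand) return(NULL)
  gap <- hr$sstart - hl$send
  if (is.na(gap) || gap < -200 || gap > 0.5 * tract_len) return(NULL)
  ctg <- other_contigs[[hl$sid]]
  s <- max(1L, hl$sstart - 200L)
  e <- min(nchar(ctg), hr$send + 200L)
  seq <- substr(ctg, s, e)
  if (hl$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  list(seq = seq, contig = hl$sid, start = s - 1L, end = e, gap = gap)
}

.resolve_sd_junctions <- function(sd_row, assembly, other_assembly, config) {
  ctg <- assembly$contigs
  flank <- 800L
  try_copy <- function(cs, os) {
    contig <- ctg[[cs$contig]]
    h0 <- max(1L, cs$start - 2000L + 1L)
    h1 <- min(nchar(contig), cs$end + 2000L)
    hybrid <- substr(contig, h0, h1)
    dctg <- ctg[[os$contig]]
    d0 <- max(1L, os$start - flank + 1L)
    d1 <- min(nchar(dctg), os$end + flank)
    donor <- substr(dctg, d0, d1)
    fl_l <- substr(contig, max(1L, cs$start - 700L + 1L), cs$start)
    fl_r <- substr(contig, cs$end + 1L, min(nchar(contig), cs$end + 700L))
    rec <- .retrieve_recipient(fl_l, fl_r, other_assembly$contigs,
                               cs$end - cs$start)
    calls <- resolve_junction(hybrid, donor,
                              recipient = if (is.null(rec)) NULL else rec$seq,
                              config = config,
                              tract = c(cs$start - h0 + 1L, cs$end - h0 + 1L))
    list(calls = calls, recipient_found = !is.null(rec))
  }
  c1 <- list(contig = sd_row$contig_1, start = sd_row$start_1,
             end = sd_row$end_1)
  c2 <- list(contig = sd_row$contig_2, start = sd_row$start_2,
             end = sd_row$end_2)
  r1 <- try_copy(c1, c2)
  r2 <- try_copy(c2, c1)
  ## the copy whose flanks map contiguously in the other genotype is the
  ## hybrid (its recipient pre-dates the insertion)
  if (r1$recipient_found && !r2$recipient_found)
    list(hybrid_copy = 1L, res = r1)
  else if (r2$recipient_found && !r1$recipient_found)
    list(hybrid_copy = 2L, res = r2)
  else list(hybrid_copy = 2L, res = r2)
}

#' Run the full comparative pipeline on two annotated assemblies
#'
#' Executes, in order: anchor pairing and Ks-threshold calibration,
#' collinear-block delineation, gene-status classification, homolog-pair
#' classification, event inference (losses, recent duplications,
#' pseudogenization timing), repeat-landscape annotation (satellite blocks,
#' LTR elements, I/S ratio), segmental-duplication detection on masked
#' sequence, and breakpoint-junction resolution with repair-pathway
#' classification.
#'
#' @param assembly_a,assembly_b Validated [genotype_assembly()] objects;
#'   both must carry at least two pairable `low_copy` anchor genes.
#' @param config An [analysis_config()].
#' @param satellite_profile Satellite monomer consensus (named character
#'   vector or scalar); `NULL` skips satellite annotation.
#' @param ltr_library Named character vector of exemplar LTR sequences;
#'   `NULL` skips LTR annotation.
#' @return An object of class `result_bundle` with elements
#'   `calibration`, `blocks`, `pairs`, `events`, `repeats` (one
#'   `repeat_summary` per genotype), `segdups`, `junctions`, `config`.
#' @export
run_pipeline <- function(assembly_a, assembly_b,
                         config = analysis_config(),
                         satellite_profile = NULL, ltr_library = NULL) {
  for (asm in list(assembly_a, assembly_b)) {
    validate_genotype_assembly(asm)
    if (length(asm$contigs) == 0 || sum(asm$features$type == "gene") == 0)
      stop("run_pipeline: empty assembly '", asm$genotype_id, "'")
  }
  id_a <- assembly_a$genotype_id
  id_b <- assembly_b$genotype_id

  ## 1. calibration
  anchor_pairing <- pair_anchors(assembly_a, assembly_b, config)
  if (nrow(anchor_pairing) < 2)
    stop("run_pipeline: fewer than 2 anchor ortholog pairs; cannot ",
         "calibrate the Ks threshold")
  cds_a <- stats::setNames(assembly_genes(assembly_a)$cds,
                           assembly_genes(assembly_a)$feature_id)
  cds_b <- stats::setNames(assembly_genes(assembly_b)$cds,
                           assembly_genes(assembly_b)$feature_id)
  calibration <- calibrate_ks_threshold(cds_a, cds_b,
                                        anchor_pairing[, c("gene_a", "gene_b")])

  ## 2. collinear blocks
  blocks <- build_collinear_blocks(assembly_a, assembly_b, anchor_pairing)

  ## 3-4. homolog pairs (statuses are derived per gene inside the tables)
  pairs <- classify_homolog_pairs(assembly_a, assembly_b, blocks,
                                  calibration, config)

  ## 5. event catalog
  events <- infer_event_catalog(pairs, blocks, assembly_a, assembly_b)

  ## 6. repeat landscape
  repeats <- list()
  sat_by_geno <- list()
  for (asm in list(assembly_a, assembly_b)) {
    sats <- if (!is.null(satellite_profile))
      detect_satellite_blocks(asm$contigs, satellite_profile, config)
    else NULL
    ltrs <- if (!is.null(ltr_library))
      detect_ltr_elements(asm$contigs, ltr_library, config)
    else data.frame(classification = character(0))
    repeats[[asm$genotype_id]] <- compute_is_ratio(ltrs, sats)
    sat_by_geno[[asm$genotype_id]] <- sats
  }

  ## 7. segmental duplications on masked sequence
  segdups <- list()
  junctions <- list()
  assemblies <- list(assembly_a, assembly_b)
  names(assemblies) <- c(id_a, id_b)
  for (g in names(assemblies)) {
    asm <- assemblies[[g]]
    other <- assemblies[[setdiff(names(assemblies), g)]]
    masked <- mask_features(asm, classes = c("CNL", "TNL"),
                            extra_intervals = sat_by_geno[[g]])
    sd <- detect_segmental_duplications(masked, NULL, config)
    if (nrow(sd)) {
      sd$genotype <- g
      sd$within_genotype <- TRUE
      segdups[[g]] <- sd
      for (k in seq_len(nrow(sd))) {
        jr <- .resolve_sd_junctions(sd[k, ], asm, other, config)
        for (side in c("X", "Y")) {
          call <- jr$res$calls[[side]]
          junctions[[length(junctions) + 1L]] <- data.frame(
            genotype = g, sd_index = k, hybrid_copy = jr$hybrid_copy,
            junction_id = side, position = call$position,
            microhomology_m = call$microhomology_m,
            transition_len = call$transition_len,
            transition_identity = call$transition_identity,
            identity_outside = call$identity_drop[["outside"]],
            identity_inside = call$identity_drop[["inside"]],
            repair_class = call$repair_class,
            recipient_available = call$recipient_available,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  segdups <- if (length(segdups)) do.call(rbind, segdups) else
    data.frame()
  rownames(segdups) <- NULL
  junctions <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame()

  structure(list(genotype_a = id_a, genotype_b = id_b,
                 calibration = calibration, blocks = blocks, pairs = pairs,
                 events = events, repeats = repeats, segdups = segdups,
                 junctions = junctions, config = config),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("result_bundle:", x$genotype_a, "vs", x$genotype_b, "\n")
  cat("  Ks threshold:", format(x$calibration$threshold, digits = 4),
      "(mean", format(x$calibration$ks_mean, digits = 4), ")\n")
  cat("  blocks:", nrow(x$blocks$blocks),
      "| ortholog pairs:", sum(x$pairs$relation == "ortholog"),
      "| recent paralog pairs:", sum(x$pairs$relation == "recent_paralog"),
      "\n")
  cat("  losses:", nrow(x$events$losses),
      "| pseudogenization events:", nrow(x$events$pseudogenizations), "\n")
  for (g in names(x$repeats)) {
    r <- x$repeats[[g]]
    cat("  ", g, ": intact LTR ", r$n_intact, ", solo ", r$n_solo,
        ", I/S ", format(r$is_ratio, digits = 3), "\n", sep = "")
  }
  cat("  segdups:", if (is.null(nrow(x$segdups))) 0 else nrow(x$segdups),
      "\n")
  invisible(x)
}
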