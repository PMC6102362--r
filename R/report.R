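## Deterministic TSV + JSON reporting of a result bundle.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.sorted <- function(df, cols) {
  cols <- intersect(cols, names(df))
  if (nrow(df) == 0 || length(cols) == 0) return(df)
  df[do.call(order, df[cols]), , drop = FALSE]
}

#' Write the pipeline report
#'
#' Emits deterministic TSV tables (calibration, blocks, pairs, events,
#' repeats, segdups, junctions) and one JSON summary.  Row ordering is
#' fixed by (genotype, contig, start, id), so writing the same bundle
#' twice produces byte-identical files; an empty bundle yields headers-only
#' tables and a valid JSON summary.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_event_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  .write_tsv(.sorted(bundle$calibration$anchor_pairs, c("gene_a", "gene_b")),
             p("calibration.tsv"))
  blk <- bundle$blocks$blocks
  if (is.null(blk)) blk <- data.frame()
  .write_tsv(.sorted(blk, c("contig_a", "start_a", "block_id")),
             p("blocks.tsv"))
  .write_tsv(.sorted(bundle$pairs, c("scope", "gene_a", "gene_b")),
             p("pairs.tsv"))

  ev <- bundle$events
  losses <- ev$losses
  dups <- ev$recent_duplications
  pseudo <- ev$pseudogenizations
  events_tab <- rbind(
    if (nrow(losses)) data.frame(event_type = "loss",
                                 lineage = losses$lineage,
                                 gene_a = losses$evidence_gene,
                                 gene_b = NA_character_,
                                 detail = paste0("evidence_in:",
                                                 losses$evidence_genotype),
                                 stringsAsFactors = FALSE),
    if (nrow(dups)) data.frame(event_type = "recent_duplication",
                               lineage = dups$genotype,
                               gene_a = dups$source, gene_b = dups$copy,
                               detail = paste0("ks:", signif(dups$ks, 4)),
                               stringsAsFactors = FALSE),
    if (nrow(pseudo)) data.frame(event_type = "pseudogenization",
                                 lineage = pseudo$timing,
                                 gene_a = pseudo$gene_a,
                                 gene_b = pseudo$gene_b,
                                 detail = paste0(pseudo$status_a, "/",
                                                 pseudo$status_b),
                                 stringsAsFactors = FALSE))
  if (is.null(events_tab))
    events_tab <- data.frame(event_type = character(0),
                             lineage = character(0), gene_a = character(0),
                             gene_b = character(0), detail = character(0))
  .write_tsv(.sorted(events_tab, c("event_type", "lineage", "gene_a")),
             p("events.tsv"))

  rep_rows <- list()
  for (g in sort(names(bundle$repeats))) {
    r <- bundle$repeats[[g]]
    el <- r$ltr_elements
    if (!is.null(el) && nrow(el) && "contig_id" %in% names(el))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        genotype = g, kind = "LTR", contig_id = el$contig_id,
        start = el$start, end = el$end,
        classification = el$classification,
        n_units = NA_integer_, stringsAsFactors = FALSE)
    sb <- r$satellite_blocks
    if (!is.null(sb) && nrow(sb))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        genotype = g, kind = "satellite", contig_id = sb$contig_id,
        start = sb$start, end = sb$end, classification = "block",
        n_units = sb$n_units, stringsAsFactors = FALSE)
  }
  repeats_tab <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(genotype = character(0), kind = character(0),
               contig_id = character(0), start = integer(0),
               end = integer(0), classification = character(0),
               n_units = integer(0))
  .write_tsv(.sorted(repeats_tab, c("genotype", "contig_id", "start")),
             p("repeats.tsv"))

  sd <- bundle$segdups
  if (is.null(sd) || nrow(sd) == 0)
    sd <- data.frame(genotype = character(0), contig_1 = character(0),
                     start_1 = integer(0), end_1 = integer(0),
                     contig_2 = character(0), start_2 = integer(0),
                     end_2 = integer(0), strand = character(0),
                     length = integer(0), identity = numeric(0),
                     within_genotype = logical(0))
  .write_tsv(.sorted(sd, c("genotype", "contig_1", "start_1")),
             p("segdups.tsv"))

  jn <- bundle$junctions
  if (is.null(jn) || nrow(jn) == 0)
    jn <- data.frame(genotype = character(0), sd_index = integer(0),
                     hybrid_copy = integer(0), junction_id = character(0),
                     position = integer(0), microhomology_m = integer(0),
                     transition_len = integer(0),
                     transition_identity = numeric(0),
                     identity_outside = numeric(0),
                     identity_inside = numeric(0),
                     repair_class = character(0),
                     recipient_available = logical(0))
  .write_tsv(.sorted(jn, c("genotype", "sd_index", "junction_id")),
             p("junctions.tsv"))

  smry <- list(
    genotypes = c(bundle$genotype_a, bundle$genotype_b),
    ks_model = bundle$config$ks_model,
    random_seed = bundle$config$random_seed,
    ks_threshold = bundle$calibration$threshold,
    anchor_ks_mean = bundle$calibration$ks_mean,
    n_anchor_pairs = nrow(bundle$calibration$anchor_pairs),
    n_blocks = nrow(blk),
    n_ortholog_pairs = sum(bundle$pairs$relation == "ortholog"),
    n_recent_paralog_pairs = sum(bundle$pairs$relation == "recent_paralog"),
    losses_by_lineage = as.list(table(bundle$events$losses$lineage)),
    n_recent_duplications = nrow(bundle$events$recent_duplications),
    pseudogenization_timing =
      as.list(table(bundle$events$pseudogenizations$timing)),
    intact_counts = bundle$events$intact_counts,
    is_ratio = lapply(bundle$repeats, function(r)
      list(n_intact = r$n_intact, n_solo = r$n_solo,
           is_ratio = r$is_ratio)),
    n_segdups = nrow(sd),
    junction_repair_classes = as.list(table(jn$repair_class)))
  jsonlite::write_json(smry, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file.path(out_dir,
                      c("calibration.tsv", "blocks.tsv", "pairs.tsv",
                        "events.tsv", "repeats.tsv", "segdups.tsv",
                        "junctions.tsv", "summary.json")))
}
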