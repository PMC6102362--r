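## Satellite monomer blocks, LTR retroelements, and the intact/solo-LTR
## (I/S) ratio -- a proxy for local unequal intra-strand recombination
## intensity.

#' Detect tandem satellite blocks by monomer matching
#'
#' Scans both strands for matches to the monomer consensus at or above the
#' configured identity (default 0.70) covering at least half a monomer,
#' then chains matches separated by less than one monomer length into
#' blocks.  The unit count of a block is its number of chained monomer
#' matches.
#'
#' @param seqs Named character vector of contig sequences.
#' @param monomer_profile Monomer consensus (character scalar, or named
#'   character vector whose first element is used).
#' @param config An [analysis_config()].
#' @return Data frame of blocks: `contig_id`, `start`, `end` (0-based
#'   half-open), `n_units`, `mean_unit_identity`.
#' @export
detect_satellite_blocks <- function(seqs, monomer_profile,
                                    config = analysis_config()) {
  if (length(monomer_profile) == 0 || !nzchar(monomer_profile[[1]]))
    stop("detect_satellite_blocks: empty monomer profile")
  monomer <- toupper(monomer_profile[[1]])
  mlen <- config$satellite_monomer_len
  hits <- blastn_hits(c(monomer = monomer), seqs, task = "blastn")
  hits <- hits[hits$pident >= config$satellite_identity_min &
               hits$length >= mlen / 2, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), n_units = integer(0),
                      mean_unit_identity = numeric(0)))
  hits <- .prune_overlaps(hits)
  out <- list()
  for (ctg in sort(unique(hits$sid))) {
    h <- hits[hits$sid == ctg, , drop = FALSE]
    h <- h[order(h$sstart), , drop = FALSE]
    gap_break <- c(FALSE, h$sstart[-1] - h$send[-nrow(h)] >= mlen)
    block <- cumsum(gap_break)
    for (b in unique(block)) {
      hb <- h[block == b, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg, start = min(hb$sstart) - 1L, end = max(hb$send),
        n_units = nrow(hb), mean_unit_identity = mean(hb$pident),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$start), , drop = FALSE]
}

.find_tsd <- function(contig_seq, start0, end0, tsd_range, slack = 2L) {
  ## exact direct repeat immediately flanking [start0, end0) (0-based);
  ## element edges may be off by a base or two, so allow a small slack
  shifts <- order(abs(seq(-slack, slack)))
  deltas <- seq(-slack, slack)[shifts]
  for (dl in deltas) for (dr in deltas) {
    s0 <- start0 + dl
    e0 <- end0 + dr
    for (l in rev(seq(tsd_range[1], tsd_range[2]))) {
      if (s0 - l < 0 || e0 + l > nchar(contig_seq) || s0 >= e0) next
      left <- substr(contig_seq, s0 - l + 1L, s0)
      right <- substr(contig_seq, e0 + 1L, e0 + l)
      if (left == right) return(left)
    }
  }
  NA_character_
}

#' Annotate LTR retroelements and classify them intact / solo / truncated
#'
#' Finds intervals similar to exemplar LTRs, pairs two same-orientation
#' hits whose combined span falls within the element-size window into a
#' candidate intact element, and demands an exact target-site duplication
#' (TSD, length within `tsd_len_range`) flanking the element.  A lone LTR
#' hit with its own flanking TSD is a solo-LTR (the relic of unequal
#' recombination between an element's two LTRs); a lone hit without a TSD
#' is reported truncated.
#'
#' @param seqs Named character vector of contig sequences.
#' @param ltr_library Named character vector of exemplar LTR sequences.
#' @param config An [analysis_config()].
#' @return Data frame of elements: `element_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`, `classification`, `tsd`,
#'   `tsd_len`, `family_hit`, `ltr1_start`, `ltr1_end`, `ltr2_start`,
#'   `ltr2_end` (NA for unpaired).
#' @export
detect_ltr_elements <- function(seqs, ltr_library,
                                config = analysis_config()) {
  if (length(ltr_library) == 0)
    stop("detect_ltr_elements: empty LTR exemplar library")
  hits <- blastn_hits(ltr_library, seqs, task = "blastn")
  min_len <- max(80L, round(0.5 * min(nchar(ltr_library))))
  hits <- hits[hits$pident >= config$ltr_identity_min &
               hits$length >= min_len, , drop = FALSE]
  ## project trimmed local hits back to full-exemplar boundaries, so TSD
  ## checks see the true element edges even when the hit ends are eroded
  if (nrow(hits)) {
    qlen <- nchar(ltr_library)[hits$qid]
    ext_l <- ifelse(hits$strand == "+", hits$qstart - 1L, qlen - hits$qend)
    ext_r <- ifelse(hits$strand == "+", qlen - hits$qend, hits$qstart - 1L)
    hits$sstart <- pmax(1L, hits$sstart - ext_l)
    hits$send <- hits$send + ext_r
  }
  cols <- data.frame(element_id = character(0), contig_id = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), classification = character(0),
                     tsd = character(0), tsd_len = integer(0),
                     family_hit = character(0),
                     ltr1_start = integer(0), ltr1_end = integer(0),
                     ltr2_start = integer(0), ltr2_end = integer(0))
  if (nrow(hits) == 0) return(cols)
  hits <- .prune_overlaps(hits)
  win <- config$ltr_element_size_range
  out <- list()
  n_el <- 0L
  for (ctg in sort(unique(hits$sid))) {
    h <- hits[hits$sid == ctg, , drop = FALSE]
    h <- h[order(h$sstart), , drop = FALSE]
    used <- logical(nrow(h))
    cseq <- seqs[[ctg]]
    emit <- function(class, s0, e0, strand, tsd, fam, l1, l2) {
      n_el <<- n_el + 1L
      out[[length(out) + 1L]] <<- data.frame(
        element_id = sprintf("LTRel_%03d", n_el), contig_id = ctg,
        start = s0, end = e0, strand = strand, classification = class,
        tsd = tsd, tsd_len = if (is.na(tsd)) NA_integer_ else nchar(tsd),
        family_hit = fam,
        ltr1_start = l1[1], ltr1_end = l1[2],
        ltr2_start = if (is.null(l2)) NA_integer_ else l2[1],
        ltr2_end = if (is.null(l2)) NA_integer_ else l2[2],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(h))) {
      if (used[i]) next
      paired <- FALSE
      for (j in seq_len(nrow(h))) {
        if (j <= i || used[j] || h$strand[j] != h$strand[i]) next
        span <- h$send[j] - h$sstart[i] + 1L
        if (span < win[1]) next
        if (span > win[2]) break
        s0 <- h$sstart[i] - 1L
        e0 <- h$send[j]
        tsd <- .find_tsd(cseq, s0, e0, config$tsd_len_range)
        if (is.na(tsd)) next
        ltr_i <- substr(cseq, h$sstart[i], h$send[i])
        ltr_j <- substr(cseq, h$sstart[j], h$send[j])
        if (global_nt_identity(ltr_i, ltr_j) < 0.7) next
        emit("intact", s0, e0, h$strand[i], tsd, h$qid[i],
             c(h$sstart[i] - 1L, h$send[i]),
             c(h$sstart[j] - 1L, h$send[j]))
        used[i] <- used[j] <- TRUE
        paired <- TRUE
        break
      }
      if (paired) next
      s0 <- h$sstart[i] - 1L
      e0 <- h$send[i]
      tsd <- .find_tsd(cseq, s0, e0, config$tsd_len_range)
      emit(if (is.na(tsd)) "truncated" else "solo",
           s0, e0, h$strand[i], tsd, h$qid[i], c(s0, e0), NULL)
      used[i] <- TRUE
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig_id, res$start), , drop = FALSE]
}

#' Intact/solo-LTR ratio and repeat summary
#'
#' The I/S ratio (intact LTR retrotransposons over solo-LTRs) indexes the
#' local intensity of unequal intra-strand homologous recombination: solo-
#' LTRs are the scars such recombination leaves.  The ratio is undefined
#' (flagged, not an error) when no solo-LTR is present.
#'
#' @param ltr_elements Data frame from [detect_ltr_elements()].
#' @param satellite_blocks Optional data frame from
#'   [detect_satellite_blocks()], carried into the summary.
#' @return An object of class `repeat_summary`: `n_intact`, `n_solo`,
#'   `n_truncated`, `is_ratio` (NA when undefined), `is_defined`, plus the
#'   input tables.
#' @examples
#' el <- data.frame(classification = c(rep("intact", 6), rep("solo", 5)))
#' compute_is_ratio(el)$is_ratio
#' @export
compute_is_ratio <- function(ltr_elements, satellite_blocks = NULL) {
  n_intact <- sum(ltr_elements$classification == "intact")
  n_solo <- sum(ltr_elements$classification == "solo")
  n_trunc <- sum(ltr_elements$classification == "truncated")
  structure(list(
    n_intact = n_intact, n_solo = n_solo, n_truncated = n_trunc,
    is_ratio = if (n_solo > 0) n_intact / n_solo else NA_real_,
    is_defined = n_solo > 0,
    ltr_elements = ltr_elements,
    satellite_blocks = satellite_blocks),
    class = "repeat_summary")
}
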