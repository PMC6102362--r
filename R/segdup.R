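## Segmental-duplication detection on repeat-masked sequence, breakpoint
## junction resolution against donor and recipient molecules, and
## NHEJ-versus-HR repair-pathway classification.

.maskable_classes <- c("CNL", "TNL", "low_copy", "other",
                       "satellite_DNA", "LTR_retrotransposon", "solo_LTR",
                       "truncated_LTR")

#' Hard-mask feature classes in an assembly
#'
#' Replaces every base of the selected features with `N`; sequence lengths
#' (and hence coordinates) are unchanged.  Gene features are selected by
#' `gene_class`, repeat features by their `type`.
#'
#' @param assembly A [genotype_assembly()].
#' @param classes Character vector of gene classes and/or repeat types to
#'   mask (e.g. `c("CNL", "satellite_DNA")`).
#' @param extra_intervals Optional data frame (`contig_id`, `start`, `end`,
#'   0-based half-open) of additional intervals to mask, e.g. satellite
#'   blocks detected de novo rather than annotated.
#' @return Named character vector of masked contig sequences.
#' @export
mask_features <- function(assembly, classes = c("CNL", "satellite_DNA"),
                          extra_intervals = NULL) {
  unknown <- setdiff(classes, .maskable_classes)
  if (length(unknown))
    stop("mask_features: unknown feature class(es): ",
         paste(unknown, collapse = ", "))
  ft <- assembly$features
  sel <- (ft$type == "gene" & ft$gene_class %in% classes) |
    (ft$type %in% classes)
  iv <- ft[sel, c("contig_id", "start", "end"), drop = FALSE]
  if (!is.null(extra_intervals) && nrow(extra_intervals))
    iv <- rbind(iv, extra_intervals[, c("contig_id", "start", "end")])
  seqs <- assembly$contigs
  for (k in seq_len(nrow(iv))) {
    ctg <- iv$contig_id[k]
    s <- iv$start[k]
    e <- iv$end[k]
    substr(seqs[[ctg]], s + 1L, e) <- strrep("N", e - s)
  }
  seqs
}

#' Detect segmental duplications
#'
#' Local-alignment search for duplicated tracts passing the operational
#' definition: more than `sd_identity_min` nucleotide identity over at
#' least `sd_length_min` bp (defaults 90\% / 500 bp).  Inputs should be
#' masked with [mask_features()] first, so satellite arrays and NL genes do
#' not masquerade as duplications.  With one sequence set the search is a
#' self-comparison (trivial self-matches removed); copy pairs are
#' canonicalized so `detect_segmental_duplications(a, b)` and `(b, a)`
#' agree.
#'
#' @param seqs_1 Named character vector of (masked) sequences.
#' @param seqs_2 Optional second set; `NULL` means self-comparison.
#' @param config An [analysis_config()].
#' @return Data frame of duplications: `contig_1`, `start_1`, `end_1`,
#'   `contig_2`, `start_2`, `end_2` (0-based half-open), `strand`,
#'   `length`, `identity`.
#' @export
detect_segmental_duplications <- function(seqs_1, seqs_2 = NULL,
                                          config = analysis_config()) {
  self_mode <- is.null(seqs_2)
  hits <- blastn_hits(seqs_1, if (self_mode) seqs_1 else seqs_2,
                      task = "blastn", dust = FALSE)
  empty <- data.frame(contig_1 = character(0), start_1 = integer(0),
                      end_1 = integer(0), contig_2 = character(0),
                      start_2 = integer(0), end_2 = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0))
  if (nrow(hits) == 0) return(empty)
  hits <- hits[hits$pident > config$sd_identity_min &
               hits$length >= config$sd_length_min, , drop = FALSE]
  if (self_mode) {
    triv <- hits$qid == hits$sid & hits$qstart == hits$sstart &
      hits$qend == hits$send
    hits <- hits[!triv, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(empty)
  ## canonical copy order: (contig, start) lexicographic
  q_first <- hits$qid < hits$sid |
    (hits$qid == hits$sid & hits$qstart <= hits$sstart)
  sd <- data.frame(
    contig_1 = ifelse(q_first, hits$qid, hits$sid),
    start_1 = ifelse(q_first, hits$qstart, hits$sstart) - 1L,
    end_1 = ifelse(q_first, hits$qend, hits$send),
    contig_2 = ifelse(q_first, hits$sid, hits$qid),
    start_2 = ifelse(q_first, hits$sstart, hits$qstart) - 1L,
    end_2 = ifelse(q_first, hits$send, hits$qend),
    strand = hits$strand, length = hits$length, identity = hits$pident,
    stringsAsFactors = FALSE)
  sd <- unique(sd)
  ## merge overlapping symmetric duplicates of the same event
  key <- paste(sd$contig_1, sd$contig_2, sd$strand)
  keep <- rep(TRUE, nrow(sd))
  ord <- order(-sd$length)
  for (a in ord) {
    if (!keep[a]) next
    for (b in ord) {
      if (a == b || !keep[b] || key[a] != key[b]) next
      ov1 <- min(sd$end_1[a], sd$end_1[b]) - max(sd$start_1[a], sd$start_1[b])
      ov2 <- min(sd$end_2[a], sd$end_2[b]) - max(sd$start_2[a], sd$start_2[b])
      if (ov1 > 0 && ov2 > 0) keep[b] <- FALSE
    }
  }
  sd <- sd[keep, , drop = FALSE]
  sd <- sd[order(sd$contig_1, sd$start_1, sd$contig_2, sd$start_2), ,
           drop = FALSE]
  rownames(sd) <- NULL
  sd
}

#' Sliding-window identity profile of an alignment
#'
#' VISTA-style identity track: the fraction of matching bases in each
#' sliding window of `window_size` bp (default 10, step 1) over two
#' equal-length, indel-free aligned sequences, with a fill mask at
#' `window_identity_min` (default 0.70).
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (character
#'   scalars, indels removed).
#' @param config An [analysis_config()].
#' @param step Window step in bp.
#' @return An object of class `identity_profile`: `window_size`, `step`,
#'   `positions` (1-based window starts), `identity`, `fill`.
#' @export
windowed_identity_profile <- function(aligned_a, aligned_b,
                                      config = analysis_config(),
                                      step = 1L) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("windowed_identity_profile: aligned sequences must have equal length")
  w <- config$window_size
  n <- nchar(aligned_a)
  if (n < w)
    stop("windowed_identity_profile: aligned length shorter than one window")
  m <- strsplit(toupper(aligned_a), "")[[1]] ==
    strsplit(toupper(aligned_b), "")[[1]]
  cm <- c(0, cumsum(m))
  starts <- seq(1L, n - w + 1L, by = step)
  ident <- (cm[starts + w] - cm[starts]) / w
  structure(list(window_size = w, step = as.integer(step),
                 positions = starts, identity = ident,
                 fill = ident >= config$window_identity_min),
            class = "identity_profile")
}

.match_vec <- function(a, b) {
  strsplit(a, "")[[1]] == strsplit(b, "")[[1]]
}

## locate `piece` inside `whole` by ungapped local alignment; returns the
## offset o such that whole[i] ~ piece[i + o], plus the matched range
.locate <- function(piece, whole) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(piece), Biostrings::DNAString(whole),
    substitutionMatrix = sm, gapOpening = 12, gapExtension = 4,
    type = "local")
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  list(piece_start = ps, piece_end = pe, whole_start = ss, whole_end = se,
       offset = ss - ps, score = Biostrings::score(aln))
}

#' Resolve the breakpoint junctions of a duplicated tract
#'
#' A segmental duplication turns a broken recipient molecule into a hybrid:
#' recipient sequence up to junction X, the duplicated donor tract, then
#' recipient sequence again after junction Y.  For each junction this
#' locates the changepoint maximizing the summed per-base agreement of the
#' hybrid with the recipient on one side and the donor on the other
#' (leftmost on ties), measures the microhomology (the maximal run of bases
#' on which donor and recipient agree spanning the changepoint), searches
#' for a homologous transition region (the maximal interval around the
#' junction in which donor-recipient windowed identity stays at or above
#' `window_identity_min`), and reports the identity drop in 200-bp windows
#' just inside versus outside the duplicated tract.  Without a recipient
#' the analysis degrades to hybrid-versus-donor only: junction positions
#' come from the donor-similarity boundary, microhomology is unavailable,
#' and the transition search uses the donor flank beyond the boundary.
#'
#' @param hybrid Sequence carrying the duplication (character scalar).
#' @param donor Donor molecule: the duplicated tract in its original
#'   context.
#' @param recipient Homolog of the unbroken recipient molecule, or `NULL`
#'   when none is available.
#' @param config An [analysis_config()].
#' @param tract Optional c(start, end), 0-based half-open, of the
#'   duplicated tract in `hybrid` (e.g. from
#'   [detect_segmental_duplications()]); located by alignment when absent.
#' @param scan_radius Changepoint scan half-width (bp) around each
#'   junction.
#' @return A list of two `junction_call` objects (`X`, `Y`), each with
#'   `junction_id`, `position` (1-based, last base left of the switch),
#'   `microhomology_m`, `transition_len`, `transition_identity`,
#'   `identity_drop` (outside/inside), `repair_class`,
#'   `recipient_available`.
#' @export
resolve_junction <- function(hybrid, donor, recipient = NULL,
                             config = analysis_config(), tract = NULL,
                             scan_radius = 400L) {
  hybrid <- toupper(hybrid)
  donor <- toupper(donor)
  if (!is.null(recipient)) recipient <- toupper(recipient)
  loc <- .locate(donor, hybrid)
  if (is.null(tract)) {
    hs <- loc$whole_start
    he <- loc$whole_end
  } else {
    hs <- tract[1] + 1L
    he <- tract[2]
  }
  oD <- loc$piece_start - loc$whole_start  # hybrid[i] ~ donor[i + oD]
  nH <- nchar(hybrid)
  nD <- nchar(donor)
  hyb <- strsplit(hybrid, "")[[1]]
  don <- strsplit(donor, "")[[1]]
  rec <- if (!is.null(recipient)) strsplit(recipient, "")[[1]] else NULL
  nR <- length(rec)

  one_junction <- function(side) {
    boundary <- if (side == "X") hs else he
    win0 <- max(1L, boundary - scan_radius)
    win1 <- min(nH, boundary + scan_radius)
    idx <- win0:win1
    call <- list(junction_id = side, position = NA_integer_,
                 microhomology_m = NA_integer_,
                 transition_len = NA_integer_,
                 transition_identity = NA_real_,
                 identity_drop = c(outside = NA_real_, inside = NA_real_),
                 repair_class = "ambiguous",
                 recipient_available = !is.null(rec))
    oR <- NA_integer_
    if (!is.null(rec)) {
      ## map the recipient onto the hybrid flank outside the tract
      fl0 <- if (side == "X") max(1L, hs - 1200L) else he - 150L
      fl1 <- if (side == "X") min(nH, hs + 150L) else min(nH, he + 1200L)
      flank <- substr(hybrid, fl0, fl1)
      lr <- .locate(flank, recipient)
      oR <- lr$whole_start - (fl0 + lr$piece_start - 1L)
    }
    if (!is.null(rec) && !is.na(oR)) {
      okR <- idx + oR >= 1 & idx + oR <= nR
      okD <- idx + oD >= 1 & idx + oD <= nD
      ok <- okR & okD
      if (sum(ok) > 50) {
        jdx <- idx[ok]
        mR <- hyb[jdx] == rec[jdx + oR]
        mD <- hyb[jdx] == don[jdx + oD]
        n <- length(jdx)
        if (side == "X") {
          score <- c(0, cumsum(mR)) + rev(c(0, cumsum(rev(mD))))
        } else {
          score <- c(0, cumsum(mD)) + rev(c(0, cumsum(rev(mR))))
        }
        j <- which.max(score) - 1L  # 0..n : bases 1..j left of switch
        pos <- if (j == 0L) jdx[1] - 1L else jdx[j]
        call$position <- pos
        ## microhomology: run of donor==recipient agreement spanning pos
        agree <- rec[jdx + oR] == don[jdx + oD]
        jj <- match(pos, jdx)
        m <- 0L
        if (!is.na(jj)) {
          k <- jj
          while (k >= 1 && agree[k]) { m <- m + 1L; k <- k - 1L }
          k <- jj + 1L
          while (k <= n && agree[k]) { m <- m + 1L; k <- k + 1L }
        }
        call$microhomology_m <- m
        ## transition: run of >=70% donor-recipient windowed identity at pos
        tr <- .transition_run(agree, jj, config)
        if (!is.null(tr)) {
          call$transition_len <- tr$len
          call$transition_identity <- tr$identity
        }
        call$identity_drop <- .identity_drop(mD, jj, side)
      }
    } else {
      ## degraded mode: hybrid-versus-donor only
      pos <- if (side == "X") hs - 1L else he
      call$position <- pos
      okD <- idx + oD >= 1 & idx + oD <= nD
      jdx <- idx[okD]
      mD <- hyb[jdx] == don[jdx + oD]
      jj <- match(pos, jdx)
      if (!is.na(jj)) {
        ## donor similarity extending beyond the homology boundary
        outside <- if (side == "X") rev(mD[seq_len(jj)]) else
          mD[jj:length(mD)]
        tr <- .transition_run(outside, 1L, config)
        if (!is.null(tr) && tr$len > config$window_size) {
          call$transition_len <- tr$len
          call$transition_identity <- tr$identity
        }
        call$identity_drop <- .identity_drop(mD, jj, side)
      }
    }
    call$repair_class <- classify_repair_pathway(call, config)
    structure(call, class = "junction_call")
  }
  list(X = one_junction("X"), Y = one_junction("Y"))
}

## maximal run of windows >= threshold containing (or adjacent to) anchor
.transition_run <- function(agree, anchor, config) {
  w <- config$window_size
  n <- length(agree)
  if (is.na(anchor) || n < w) return(NULL)
  cm <- c(0, cumsum(agree))
  starts <- seq_len(n - w + 1L)
  wid <- (cm[starts + w] - cm[starts]) / w
  pass <- wid >= config$window_identity_min
  if (!any(pass)) return(NULL)
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  best <- NULL
  for (r in which(runs$values)) {
    s <- begins[r]
    e <- ends[r] + w - 1L  # last covered position
    if (anchor >= s - w && anchor <= e + w) {
      len <- e - s + 1L
      if (is.null(best) || len > best$len) {
        best <- list(len = len,
                     identity = (cm[e + 1] - cm[s]) / (e - s + 1L),
                     from = s, to = e)
      }
    }
  }
  best
}

.identity_drop <- function(mD, anchor, side) {
  if (is.na(anchor)) return(c(outside = NA_real_, inside = NA_real_))
  n <- length(mD)
  if (side == "X") {
    out_idx <- max(1L, anchor - 200L):anchor
    in_idx <- min(n, anchor + 1L):min(n, anchor + 200L)
  } else {
    in_idx <- max(1L, anchor - 200L):anchor
    out_idx <- min(n, anchor + 1L):min(n, anchor + 200L)
  }
  c(outside = mean(mD[out_idx]), inside = mean(mD[in_idx]))
}

#' Classify the repair pathway at a resolved junction
#'
#' HR when a homologous transition region of at least `transition_min_len`
#' bp at `transition_min_identity` identity spans the junction (donor
#' similarity extending beyond the homology boundary); NHEJ when the
#' microhomology is at most `microhomology_max_nhej` bp and no qualifying
#' transition exists; otherwise ambiguous.  Without a recipient (no
#' microhomology measurement) an abrupt identity drop with no transition
#' region is read as NHEJ.
#'
#' @param call A `junction_call` from [resolve_junction()].
#' @param config An [analysis_config()].
#' @return `"HR"`, `"NHEJ"`, or `"ambiguous"`.
#' @export
classify_repair_pathway <- function(call, config = analysis_config()) {
  has_transition <- !is.na(call$transition_len) &&
    call$transition_len >= config$transition_min_len &&
    !is.na(call$transition_identity) &&
    call$transition_identity >= config$transition_min_identity
  if (has_transition) return("HR")
  m <- call$microhomology_m
  if (!is.na(m)) {
    if (m <= config$microhomology_max_nhej) return("NHEJ")
    return("ambiguous")
  }
  ## degraded mode: abrupt drop outside the tract, no transition
  drop <- call$identity_drop["outside"]
  if (!is.na(drop) && drop <= 0.6) return("NHEJ")
  "ambiguous"
}
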