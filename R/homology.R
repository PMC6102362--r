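## Ks-threshold calibration from low-copy anchors, collinear-block
## delineation, homolog-pair classification and lineage-resolved event
## inference.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Classify gene status from its coding sequence
#'
#' Operational annotation-level rule: a CDS is `intact` when it starts with
#' ATG, its length is a multiple of 3 and it has no premature stop codon;
#' `pseudogene` when it starts with ATG but carries a premature stop and/or
#' a frameshift (length not divisible by 3); and `segment` when it does not
#' start with ATG at all.
#'
#' @param cds Character vector of coding sequences.
#' @return Character vector of `"intact"`, `"pseudogene"`, `"segment"`.
#' @examples
#' classify_gene_status(c("ATGAAATAA", "ATGTAAAAATAA", "GTGAAATAA"))
#' @export
classify_gene_status <- function(cds) {
  vapply(toupper(cds), function(x) {
    if (is.na(x) || nchar(x) < 3) return("segment")
    if (substr(x, 1, 3) != "ATG") return("segment")
    if (nchar(x) %% 3L != 0L) return("pseudogene")
    cod <- split_codons(x)
    internal <- cod[-length(cod)]
    if (any(internal %in% .stop_codons)) return("pseudogene")
    "intact"
  }, character(1), USE.NAMES = FALSE)
}

#' Global nucleotide identity between two sequences
#'
#' Needleman-Wunsch global alignment identity (matches over alignment
#' length, internal gaps counted against), as reported by classic global
#' aligners.
#'
#' @param a,b Nucleotide sequences (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @export
global_nt_identity <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Assign a gene to an NL subfamily by exemplar identity
#'
#' Computes the global nucleotide identity of the gene's CDS to every
#' exemplar and assigns the subfamily of the best-matching exemplar when
#' that identity reaches `subfamily_identity_min` (default 0.72); below the
#' threshold, or on an exact tie between subfamilies, the gene stays
#' unassigned (`"none"`).
#'
#' @param cds The gene's coding sequence (character scalar).
#' @param reference_set Named character vector of exemplar sequences; names
#'   are subfamily labels (repeated names allowed for several exemplars per
#'   subfamily).
#' @param config An [analysis_config()].
#' @return A list with `subfamily` and the per-subfamily best `identity`.
#' @export
assign_subfamily <- function(cds, reference_set, config = analysis_config()) {
  if (length(reference_set) == 0 || is.null(names(reference_set)))
    stop("assign_subfamily: reference_set must be a named vector of exemplars")
  ident <- vapply(reference_set, function(r) global_nt_identity(cds, r),
                  numeric(1))
  by_fam <- tapply(ident, names(reference_set), max)
  best <- max(by_fam)
  winners <- names(by_fam)[by_fam == best]
  fam <- if (best >= config$subfamily_identity_min && length(winners) == 1L)
    winners else "none"
  list(subfamily = fam, identity = by_fam)
}

#' Calibrate the orthology Ks threshold from low-copy anchor pairs
#'
#' Computes the NG86 Ks for each anchor ortholog pair and sets the
#' orthology threshold to the maximum anchor Ks: any homolog pair below it
#' diverged no earlier than the anchors, i.e. no earlier than the
#' gene-pool split the anchors date.
#'
#' @param anchors_a,anchors_b Named character vectors of anchor CDSs (all
#'   must be intact: non-pseudogenized, non-truncated).
#' @param anchor_pairing Data frame with columns `gene_a`, `gene_b` naming
#'   the ortholog pairs.
#' @return An object of class `threshold_calibration`: the per-pair table
#'   (`anchor_pairs` with `ks`), `ks_mean`, `ks_max` and
#'   `threshold` (= `ks_max`).
#' @export
calibrate_ks_threshold <- function(anchors_a, anchors_b, anchor_pairing) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(anchor_pairing)))
  if (nrow(anchor_pairing) < 2)
    stop("calibrate_ks_threshold: need at least 2 anchor ortholog pairs")
  st_a <- classify_gene_status(anchors_a[anchor_pairing$gene_a])
  st_b <- classify_gene_status(anchors_b[anchor_pairing$gene_b])
  if (any(st_a != "intact") || any(st_b != "intact"))
    stop("calibrate_ks_threshold: anchors must be intact ",
         "(non-pseudogenized, non-truncated)")
  tab <- kaks_table(anchor_pairing, anchors_a, anchors_b)
  if (any(tab$saturated))
    stop("calibrate_ks_threshold: saturated anchor Ks; anchors unusable ",
         "for calibration")
  structure(list(anchor_pairs = tab,
                 ks_mean = mean(tab$ks),
                 ks_max = max(tab$ks),
                 threshold = max(tab$ks)),
            class = "threshold_calibration")
}

#' Pair low-copy anchors across two genotypes
#'
#' Reciprocal-best pairing of `low_copy` genes by global nucleotide
#' identity, used to feed [calibrate_ks_threshold()] and
#' [build_collinear_blocks()] when no explicit pairing is supplied.
#'
#' @param assembly_a,assembly_b [genotype_assembly()] objects.
#' @param config An [analysis_config()]; pairs below
#'   `anchor_identity_min` are discarded.
#' @return Data frame with columns `gene_a`, `gene_b`, `identity`.
#' @export
pair_anchors <- function(assembly_a, assembly_b, config = analysis_config()) {
  ga <- assembly_genes(assembly_a, "low_copy")
  gb <- assembly_genes(assembly_b, "low_copy")
  if (nrow(ga) == 0 || nrow(gb) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0)))
  idm <- matrix(0, nrow(ga), nrow(gb), dimnames = list(ga$feature_id,
                                                       gb$feature_id))
  prof <- .kmer_profiles(c(ga$cds, gb$cds))
  na <- nrow(ga)
  for (i in seq_len(nrow(ga)))
    for (j in seq_len(nrow(gb))) {
      sim <- .kmer_sim(prof, i, na + j, nchar(ga$cds[i]), nchar(gb$cds[j]))
      idm[i, j] <- if (sim >= 0.2)
        global_nt_identity(ga$cds[i], gb$cds[j])
      else sim^(1 / 8)
    }
  pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0))
  repeat {
    best <- which(idm == max(idm), arr.ind = TRUE)
    if (nrow(best) == 0 || max(idm) < config$anchor_identity_min) break
    i <- best[1, 1]; j <- best[1, 2]
    pairs <- rbind(pairs, data.frame(gene_a = rownames(idm)[i],
                                     gene_b = colnames(idm)[j],
                                     identity = idm[i, j]))
    idm[i, ] <- -1
    idm[, j] <- -1
    if (all(idm < 0)) break
  }
  pairs[order(pairs$gene_a), , drop = FALSE]
}

## shared 8-mer fraction between two sequences; (sim)^(1/8) approximates
## the nucleotide identity, so pairs that cannot reach an identity floor
## can be screened out before full alignment
.kmer_profiles <- function(cds_vec, k = 8L) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(cds_vec),
                                       width = k)
}

.kmer_sim <- function(prof, i, j, len_i, len_j, k = 8L) {
  sum(pmin(prof[i, ], prof[j, ])) / (min(len_i, len_j) - k + 1L)
}

.gene_positions <- function(assembly, ids) {
  ft <- assembly$features
  idx <- match(ids, ft$feature_id)
  if (anyNA(idx))
    stop("unknown gene id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  data.frame(contig = ft$contig_id[idx], start = ft$start[idx],
             end = ft$end[idx], strand = ft$strand[idx],
             stringsAsFactors = FALSE)
}

#' Delineate collinear blocks from anchor ortholog pairs
#'
#' Chains anchor pairs whose order along both genotypes is conserved (in the
#' same or fully reversed orientation); a chain breaks where the order is
#' violated or the pairs change contig.  Block spans run from the first to
#' the last member anchor, extended outward to the nearer of the contig end
#' or the next conflicting anchor.
#'
#' @param assembly_a,assembly_b [genotype_assembly()] objects.
#' @param anchor_pairs Data frame with `gene_a`, `gene_b` (e.g. from
#'   [pair_anchors()]).
#' @return A list with `blocks` (one row per block: spans in both
#'   genotypes, orientation, anchor count) and `anchor_pairs` (the input
#'   with a `block_id` column).
#' @export
build_collinear_blocks <- function(assembly_a, assembly_b, anchor_pairs) {
  if (nrow(anchor_pairs) == 0) {
    warning("build_collinear_blocks: no anchors; no blocks")
    return(list(blocks = data.frame(), anchor_pairs = anchor_pairs))
  }
  pa <- .gene_positions(assembly_a, anchor_pairs$gene_a)
  pb <- .gene_positions(assembly_b, anchor_pairs$gene_b)
  ord <- order(pa$contig, pa$start)
  ap <- anchor_pairs[ord, , drop = FALSE]
  pa <- pa[ord, , drop = FALSE]
  pb <- pb[ord, , drop = FALSE]
  n <- nrow(ap)
  ## rank of each paired anchor along genotype B (per contig)
  rank_b <- integer(n)
  for (ctg in unique(pb$contig)) {
    sel <- pb$contig == ctg
    rank_b[sel] <- rank(pb$start[sel])
  }
  block_id <- integer(n)
  cur <- 1L
  dir <- 0L
  block_id[1] <- cur
  for (i in seq_len(n)[-1]) {
    same_ctg <- pa$contig[i] == pa$contig[i - 1] &&
      pb$contig[i] == pb$contig[i - 1]
    step <- rank_b[i] - rank_b[i - 1]
    ok <- same_ctg && abs(step) == 1L && (dir == 0L || step == dir)
    if (ok) {
      block_id[i] <- cur
      dir <- step
    } else {
      cur <- cur + 1L
      block_id[i] <- cur
      dir <- 0L
    }
  }
  span_one <- function(pos, members, contig_len, all_pos) {
    ctg <- pos$contig[members][1]
    s <- min(pos$start[members])
    e <- max(pos$end[members])
    others <- setdiff(which(pos$contig == ctg), members)
    left <- others[pos$end[others] <= s]
    right <- others[pos$start[others] >= e]
    start <- if (length(left)) max(pos$end[left]) else 0L
    end <- if (length(right)) min(pos$start[right]) else contig_len[[ctg]]
    c(start = start, end = end)
  }
  len_a <- nchar(assembly_a$contigs)
  len_b <- nchar(assembly_b$contigs)
  blocks <- do.call(rbind, lapply(seq_len(cur), function(b) {
    members <- which(block_id == b)
    sa <- span_one(pa, members, len_a, pa)
    sb <- span_one(pb, members, len_b, pb)
    orient <- if (length(members) > 1 &&
                  rank_b[members[2]] < rank_b[members[1]])
      "reversed" else "same"
    data.frame(block_id = b, n_anchors = length(members),
               contig_a = pa$contig[members][1], start_a = sa["start"],
               end_a = sa["end"],
               contig_b = pb$contig[members][1], start_b = sb["start"],
               end_b = sb["end"], orientation = orient,
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  ap$block_id <- block_id
  list(blocks = blocks, anchor_pairs = ap)
}

.block_of_genes <- function(genes, blocks, side) {
  if (nrow(genes) == 0 || is.null(blocks) || nrow(blocks) == 0)
    return(rep(NA_integer_, nrow(genes)))
  ctg_col <- paste0("contig_", side)
  s_col <- paste0("start_", side)
  e_col <- paste0("end_", side)
  mid <- (genes$start + genes$end) / 2
  vapply(seq_len(nrow(genes)), function(i) {
    hit <- which(blocks[[ctg_col]] == genes$contig_id[i] &
                 blocks[[s_col]] <= mid[i] & mid[i] < blocks[[e_col]])
    if (length(hit)) blocks$block_id[hit[1]] else NA_integer_
  }, integer(1))
}

#' Classify homolog pairs as ortholog, recent paralog, or ancient
#'
#' Within each subfamily, computes Ks, Ka and nucleotide identity for every
#' cross-genotype gene pair lying in the same collinear block and for every
#' within-genotype pair.  A cross pair is an ortholog when its Ks falls
#' below the calibrated threshold, its identity reaches
#' `ortholog_identity_min`, and it wins reciprocal-best matching by Ks
#' (ties broken toward higher identity and flagged).  A within-genotype
#' pair below the threshold is a recent paralog.  Everything else,
#' including saturated pairs, is ancient.
#'
#' @param assembly_a,assembly_b [genotype_assembly()] objects.
#' @param blocks Result of [build_collinear_blocks()].
#' @param calibration A `threshold_calibration`.
#' @param config An [analysis_config()].
#' @param gene_classes Gene classes entered into the comparison.
#' @return Data frame with one row per computed pair: ids, scope
#'   (`"cross"` or the genotype id), subfamily, `block_id`, `ks`, `ka`,
#'   `identity`, `saturated`, `relation`, `tied`.
#' @export
classify_homolog_pairs <- function(assembly_a, assembly_b, blocks,
                                   calibration,
                                   config = analysis_config(),
                                   gene_classes = c("CNL", "TNL")) {
  thr <- calibration$threshold
  ga <- assembly_genes(assembly_a, gene_classes)
  gb <- assembly_genes(assembly_b, gene_classes)
  ga$block <- .block_of_genes(ga, blocks$blocks, "a")
  gb$block <- .block_of_genes(gb, blocks$blocks, "b")
  rows <- list()

  ## cross-genotype candidates: same subfamily, shared block; the shared-
  ## 8-mer screen skips full alignment for pairs that cannot reach the
  ## ortholog identity floor
  prof_ab <- if (nrow(ga) + nrow(gb) > 0) .kmer_profiles(c(ga$cds, gb$cds))
  n_a <- nrow(ga)
  for (i in seq_len(nrow(ga))) {
    for (j in seq_len(nrow(gb))) {
      if (is.na(ga$block[i]) || is.na(gb$block[j])) next
      if (ga$block[i] != gb$block[j]) next
      if (ga$subfamily[i] != gb$subfamily[j]) next
      sim <- .kmer_sim(prof_ab, i, n_a + j, nchar(ga$cds[i]),
                       nchar(gb$cds[j]))
      if (sim < 0.40) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ga$feature_id[i], gene_b = gb$feature_id[j],
          scope = "cross", subfamily = ga$subfamily[i],
          block_id = ga$block[i], ks = NA_real_, ka = NA_real_,
          identity = sim^(1 / 8), saturated = FALSE, screened = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      r <- kaks_pair(ga$cds[i], gb$cds[j], ga$feature_id[i], gb$feature_id[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ga$feature_id[i], gene_b = gb$feature_id[j],
        scope = "cross", subfamily = ga$subfamily[i],
        block_id = ga$block[i], ks = r$ks, ka = r$ka,
        identity = r$identity, saturated = r$saturated, screened = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  cross <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               scope = character(0), subfamily = character(0),
               block_id = integer(0), ks = numeric(0), ka = numeric(0),
               identity = numeric(0), saturated = logical(0),
               screened = logical(0))
  cross$relation <- "ancient"
  cross$tied <- FALSE
  cand <- which(!cross$saturated & !is.na(cross$ks) & cross$ks <= thr &
                cross$identity >= config$ortholog_identity_min)
  if (length(cand)) {
    ## reciprocal-best by Ks, ties toward higher identity (flagged)
    cc <- cross[cand, ]
    ord <- order(cc$ks, -cc$identity)
    used_a <- character(0)
    used_b <- character(0)
    for (k in ord) {
      if (cc$gene_a[k] %in% used_a || cc$gene_b[k] %in% used_b) next
      idx <- cand[k]
      cross$relation[idx] <- "ortholog"
      tie <- sum(abs(cc$ks - cc$ks[k]) < 1e-12 &
                 (cc$gene_a == cc$gene_a[k] | cc$gene_b == cc$gene_b[k])) > 1
      cross$tied[idx] <- tie
      used_a <- c(used_a, cc$gene_a[k])
      used_b <- c(used_b, cc$gene_b[k])
    }
  }

  ## within-genotype pairs; a shared-8-mer screen skips full alignment for
  ## pairs too diverged to fall below the Ks threshold (a sub-threshold Ks
  ## implies ~94%+ identity, far above the screen's ~89% floor)
  within_rows <- function(g, label) {
    out <- list()
    if (nrow(g) < 2) return(out)
    prof <- .kmer_profiles(g$cds)
    for (i in seq_len(nrow(g) - 1)) {
      for (j in (i + 1):nrow(g)) {
        if (g$subfamily[i] != g$subfamily[j]) next
        sim <- .kmer_sim(prof, i, j, nchar(g$cds[i]), nchar(g$cds[j]))
        if (sim < 0.40) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = g$feature_id[i], gene_b = g$feature_id[j],
            scope = label, subfamily = g$subfamily[i],
            block_id = NA_integer_, ks = NA_real_, ka = NA_real_,
            identity = sim^(1 / 8), saturated = FALSE,
            relation = "ancient", tied = FALSE, screened = TRUE,
            stringsAsFactors = FALSE)
          next
        }
        r <- kaks_pair(g$cds[i], g$cds[j], g$feature_id[i], g$feature_id[j])
        ## a frame-uncertain Ks (both members frameshifted) cannot support
        ## a sub-threshold call on its own; demand corroborating identity
        ks_trust <- !isTRUE(r$aln$frame_uncertain) ||
          r$identity >= config$ortholog_identity_min
        rel <- if (!r$saturated && !is.na(r$ks) && r$ks <= thr && ks_trust)
          "recent_paralog" else "ancient"
        out[[length(out) + 1L]] <- data.frame(
          gene_a = g$feature_id[i], gene_b = g$feature_id[j],
          scope = label, subfamily = g$subfamily[i],
          block_id = if (!is.na(g$block[i]) && identical(g$block[i], g$block[j]))
            g$block[i] else NA_integer_,
          ks = r$ks, ka = r$ka, identity = r$identity,
          saturated = r$saturated, relation = rel, tied = FALSE,
          screened = FALSE, stringsAsFactors = FALSE)
      }
    }
    out
  }
  wr <- c(within_rows(ga, assembly_a$genotype_id),
          within_rows(gb, assembly_b$genotype_id))
  pairs <- rbind(cross, if (length(wr)) do.call(rbind, wr))
  rownames(pairs) <- NULL
  pairs
}

#' Infer the lineage-resolved event catalog
#'
#' Applies the comparative rules: a gene inside a collinear block with
#' neither an ortholog nor a recent paralog witnesses the loss of its
#' counterpart in the other lineage; a recent-paralog pair in which exactly
#' one member has an ortholog is a lineage-specific duplication from that
#' member; an ortholog pair with both members pseudogenized was
#' pseudogenized before the lineages split (`shared`), with exactly one, a
#' lineage-specific event.  Genes outside any block are reported as
#' unresolved, not guessed.
#'
#' @param pairs Output of [classify_homolog_pairs()].
#' @param blocks Output of [build_collinear_blocks()].
#' @param assembly_a,assembly_b [genotype_assembly()] objects.
#' @param gene_classes Gene classes considered.
#' @return An object of class `event_catalog` with `losses`,
#'   `recent_duplications`, `pseudogenizations`, `intact_counts` and
#'   `unresolved`.
#' @export
infer_event_catalog <- function(pairs, blocks, assembly_a, assembly_b,
                                gene_classes = c("CNL", "TNL")) {
  ga <- assembly_genes(assembly_a, gene_classes)
  gb <- assembly_genes(assembly_b, gene_classes)
  ga$block <- .block_of_genes(ga, blocks$blocks, "a")
  gb$block <- .block_of_genes(gb, blocks$blocks, "b")
  id_a <- assembly_a$genotype_id
  id_b <- assembly_b$genotype_id
  orth <- pairs[pairs$relation == "ortholog", , drop = FALSE]
  rp <- pairs[pairs$relation == "recent_paralog", , drop = FALSE]
  paired <- c(orth$gene_a, orth$gene_b, rp$gene_a, rp$gene_b)

  loss_rows <- function(g, genotype, other) {
    solo <- g[!(g$feature_id %in% paired), , drop = FALSE]
    inb <- solo[!is.na(solo$block), , drop = FALSE]
    if (nrow(inb) == 0)
      return(data.frame(evidence_gene = character(0),
                        evidence_genotype = character(0),
                        lineage = character(0), block_id = integer(0)))
    data.frame(evidence_gene = inb$feature_id, evidence_genotype = genotype,
               lineage = other, block_id = inb$block,
               stringsAsFactors = FALSE)
  }
  losses <- rbind(loss_rows(ga, id_a, id_b), loss_rows(gb, id_b, id_a))

  un_a <- ga$feature_id[is.na(ga$block) & !(ga$feature_id %in% paired)]
  un_b <- gb$feature_id[is.na(gb$block) & !(gb$feature_id %in% paired)]
  unresolved <- rbind(
    data.frame(gene = un_a, genotype = rep(id_a, length(un_a)),
               stringsAsFactors = FALSE),
    data.frame(gene = un_b, genotype = rep(id_b, length(un_b)),
               stringsAsFactors = FALSE))

  dup_rows <- lapply(seq_len(nrow(rp)), function(k) {
    a_has <- rp$gene_a[k] %in% c(orth$gene_a, orth$gene_b)
    b_has <- rp$gene_b[k] %in% c(orth$gene_a, orth$gene_b)
    src <- if (a_has && !b_has) rp$gene_a[k]
    else if (b_has && !a_has) rp$gene_b[k] else NA_character_
    cpy <- if (is.na(src)) NA_character_
    else setdiff(c(rp$gene_a[k], rp$gene_b[k]), src)
    data.frame(source = src, copy = cpy, genotype = rp$scope[k],
               ks = rp$ks[k], stringsAsFactors = FALSE)
  })
  recent_duplications <- if (length(dup_rows)) do.call(rbind, dup_rows) else
    data.frame(source = character(0), copy = character(0),
               genotype = character(0), ks = numeric(0))

  status_of <- function(g, ids) g$status[match(ids, g$feature_id)]
  st_a <- status_of(ga, orth$gene_a)
  st_b <- status_of(gb, orth$gene_b)
  timing <- ifelse(st_a == "pseudogene" & st_b == "pseudogene", "shared",
            ifelse(st_a == "pseudogene" & st_b != "pseudogene",
                   paste0(id_a, "_specific"),
            ifelse(st_b == "pseudogene" & st_a != "pseudogene",
                   paste0(id_b, "_specific"), "none")))
  pseudo <- data.frame(gene_a = orth$gene_a, gene_b = orth$gene_b,
                       status_a = st_a, status_b = st_b, timing = timing,
                       stringsAsFactors = FALSE)
  pseudo <- pseudo[pseudo$timing != "none", , drop = FALSE]

  intact_counts <- list(
    both = sum(st_a == "intact" & st_b == "intact"),
    only_a = sum(st_a == "intact" & st_b != "intact"),
    only_b = sum(st_b == "intact" & st_a != "intact"))

  structure(list(losses = losses,
                 recent_duplications = recent_duplications,
                 pseudogenizations = pseudo,
                 intact_counts = intact_counts,
                 unresolved = unresolved),
            class = "event_catalog")
}
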