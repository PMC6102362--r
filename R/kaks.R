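## Codon-aware pairwise alignment and Nei-Gojobori (1986) Ka/Ks estimation
## with Jukes-Cantor multiple-hit correction.

.subtel_cache <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
ng86_tables <- function() {
  if (!is.null(.subtel_cache$ng86)) return(.subtel_cache$ng86)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- Biostrings::GENETIC_CODE[codons]
  is_stop <- aa == "*"

  ## Synonymous site fraction per sense codon: at each position, the fraction
  ## of the 3 alternative bases giving the same amino acid.  A change to a
  ## stop codon is counted as nonsynonymous.
  syn_sites <- rep(NA_real_, 64)
  names(syn_sites) <- codons
  neighbours <- function(codon, pos) {
    b <- strsplit(codon, "")[[1]]
    out <- character(0)
    for (nb in setdiff(bases, b[pos])) {
      b2 <- b
      b2[pos] <- nb
      out <- c(out, paste(b2, collapse = ""))
    }
    out
  }
  for (i in seq_along(codons)) {
    if (is_stop[i]) next
    s <- 0
    for (pos in 1:3) {
      nb <- neighbours(codons[i], pos)
      s <- s + sum(aa[nb] == aa[i] & aa[nb] != "*") / 3
    }
    syn_sites[i] <- s
  }

  ## Pairwise synonymous/nonsynonymous difference counts, averaged over all
  ## minimal mutational pathways.  Pathways passing through a stop codon are
  ## excluded; when every pathway is blocked, all observed differences are
  ## counted as nonsynonymous.
  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_along(codons)) {
    if (is_stop[i]) next
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_along(codons)) {
      if (is_stop[j]) next
      cj <- strsplit(codons[j], "")[[1]]
      dpos <- which(ci != cj)
      k <- length(dpos)
      if (k == 0) {
        sd_mat[i, j] <- 0
        nd_mat[i, j] <- 0
        next
      }
      syn_tot <- 0
      non_tot <- 0
      n_ok <- 0
      for (ord in perms[[as.character(k)]]) {
        cur <- ci
        syn <- 0
        non <- 0
        ok <- TRUE
        for (step in seq_len(k)) {
          p <- dpos[ord[step]]
          nxt <- cur
          nxt[p] <- cj[p]
          cod_a <- paste(cur, collapse = "")
          cod_b <- paste(nxt, collapse = "")
          if (aa[cod_b] == "*" && step < k) { # intermediate stop
            ok <- FALSE
            break
          }
          if (aa[cod_a] == aa[cod_b]) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        if (ok) {
          syn_tot <- syn_tot + syn
          non_tot <- non_tot + non
          n_ok <- n_ok + 1
        }
      }
      if (n_ok > 0) {
        sd_mat[i, j] <- syn_tot / n_ok
        nd_mat[i, j] <- non_tot / n_ok
      } else {
        sd_mat[i, j] <- 0
        nd_mat[i, j] <- k
      }
    }
  }
  .subtel_cache$ng86 <- list(codons = codons, aa = aa, is_stop = is_stop,
                             syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .subtel_cache$ng86
}

split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Globally aligns two CDSs and returns the gap-free codon columns on which
#' NG86 site and difference counting operates.  When both sequences are in
#' frame (length divisible by 3) the alignment is protein-guided: conceptual
#' translations (premature stops kept as `*`) are aligned with BLOSUM62 and
#' affine gap penalties, and the protein alignment is back-mapped onto
#' codons.  When either sequence carries a frameshift (length not divisible
#' by 3, as in many annotated pseudogenes) the alignment falls back to a
#' global nucleotide alignment, and codon columns are read in the frame of
#' the in-frame member (or of the first sequence when both are shifted), so
#' that homologous bases stay paired across the indel.
#'
#' @param cds_a,cds_b Coding nucleotide sequences (character scalars,
#'   uppercase A/C/G/T), unspliced of introns, strand-resolved.
#' @param gene_a,gene_b Identifiers carried through to the result.
#' @param gap_opening,gap_extension Affine gap penalties for the guide
#'   alignment.
#' @return An object of class `codon_alignment`: gene ids, the paired codon
#'   vectors (`codons_a`, `codons_b`), the number of gapped codon columns,
#'   the overall nucleotide identity over aligned ungapped columns, and the
#'   guide method used (`"protein"` or `"nucleotide"`).
#' @examples
#' a <- "ATGGGTGGAGGGTAA"
#' align_coding_pair(a, a)$identity
#' @export
align_coding_pair <- function(cds_a, cds_b, gene_a = "a", gene_b = "b",
                              gap_opening = 10, gap_extension = 0.5) {
  stopifnot(is.character(cds_a), is.character(cds_b))
  if (nchar(cds_a) < 3 || nchar(cds_b) < 3)
    stop("align_coding_pair: both coding sequences must be at least one codon long")
  cds_a <- toupper(cds_a)
  cds_b <- toupper(cds_b)
  in_frame <- c(nchar(cds_a) %% 3L == 0L, nchar(cds_b) %% 3L == 0L)
  if (all(in_frame)) {
    res <- .align_protein_guided(cds_a, cds_b, gap_opening, gap_extension)
    method <- "protein"
  } else {
    res <- .align_nucleotide_guided(cds_a, cds_b, in_frame,
                                    gap_opening, gap_extension)
    method <- "nucleotide"
  }
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = res$codons_a, codons_b = res$codons_b,
                 n_cols = length(res$codons_a),
                 n_gapped_cols = res$n_gapped,
                 identity = res$identity, method = method,
                 ## with both sequences frameshifted no common true reading
                 ## frame exists; site classification is then unreliable
                 frame_uncertain = !any(in_frame)),
            class = "codon_alignment")
}

## table-driven conceptual translation (stops kept as "*")
translate_cds <- function(cds) {
  tb <- ng86_tables()
  aa <- tb$aa[match(split_codons(cds), tb$codons)]
  if (anyNA(aa)) stop("translate_cds: non-ACGT codon")
  paste(aa, collapse = "")
}

.align_protein_guided <- function(cds_a, cds_b, gap_opening, gap_extension) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
  ap <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  as <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  ia <- cumsum(ap != "-")
  ib <- cumsum(as != "-")
  keep <- ap != "-" & as != "-"
  codons_a <- cod_a[ia[keep]]
  codons_b <- cod_b[ib[keep]]
  n_gapped <- sum(xor(ap == "-", as == "-"))
  identity <- .codon_identity(codons_a, codons_b)
  list(codons_a = codons_a, codons_b = codons_b,
       n_gapped = n_gapped, identity = identity)
}

.align_nucleotide_guided <- function(cds_a, cds_b, in_frame,
                                     gap_opening, gap_extension) {
  ## EDNAFULL-style scoring: mismatches must stay cheaper than the gap
  ## pair that could hide them, or diverged pairs shred into gap columns
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds_a), Biostrings::DNAString(cds_b),
    substitutionMatrix = sm, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  ap <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ref_is_a <- if (in_frame[1]) TRUE else if (in_frame[2]) FALSE else TRUE
  ref <- if (ref_is_a) ap else as_
  oth <- if (ref_is_a) as_ else ap
  both <- ref != "-" & oth != "-"
  identity <- if (any(both)) mean(ap[both] == as_[both]) else 0
  ## read codons in the reference frame
  ref_pos <- cumsum(ref != "-")
  n_codon <- sum(ref != "-") %/% 3L
  codons_r <- character(0)
  codons_o <- character(0)
  n_gapped <- 0L
  col_of <- match(seq_len(n_codon * 3L), ifelse(ref != "-", ref_pos, NA))
  for (k in seq_len(n_codon)) {
    cols <- col_of[(3L * k - 2L):(3L * k)]
    if (any(oth[cols] == "-")) {
      n_gapped <- n_gapped + 1L
      next
    }
    codons_r <- c(codons_r, paste(ref[cols], collapse = ""))
    codons_o <- c(codons_o, paste(oth[cols], collapse = ""))
  }
  if (ref_is_a) list(codons_a = codons_r, codons_b = codons_o,
                     n_gapped = n_gapped, identity = identity)
  else list(codons_a = codons_o, codons_b = codons_r,
            n_gapped = n_gapped, identity = identity)
}

.codon_identity <- function(codons_a, codons_b) {
  if (length(codons_a) == 0) return(0)
  a <- unlist(strsplit(codons_a, ""))
  b <- unlist(strsplit(codons_b, ""))
  mean(a == b)
}

#' NG86 synonymous/nonsynonymous site and difference counts
#'
#' For every gap-free codon column, each codon position contributes a
#' synonymous-site fraction equal to the number of the 3 possible single-base
#' changes that preserve the amino acid, divided by 3; changes to stop codons
#' count as nonsynonymous.  Sites are averaged over the two sequences.
#' Differences in codons separated by more than one change are averaged over
#' all minimal mutational pathways, excluding pathways through stop codons
#' (when all pathways are blocked the differences count as nonsynonymous).
#' Columns containing a stop codon in either sequence, including the
#' terminal stop, are excluded from counting.
#'
#' @param aln A `codon_alignment` from [align_coding_pair()].
#' @return An object of class `site_counts` with fields `S`, `N`
#'   (fractional site counts), `Sd`, `Nd` (difference counts), and
#'   `n_codons` (codon columns actually counted).
#' @examples
#' ng86_sites_and_diffs(align_coding_pair("GGTGGAGGG", "GGCGGAGGG"))
#' @export
ng86_sites_and_diffs <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tb <- ng86_tables()
  ia <- match(aln$codons_a, tb$codons)
  ib <- match(aln$codons_b, tb$codons)
  if (anyNA(ia) || anyNA(ib))
    stop("ng86_sites_and_diffs: non-ACGT codon in alignment")
  keep <- !tb$is_stop[ia] & !tb$is_stop[ib]
  ia <- ia[keep]
  ib <- ib[keep]
  if (length(ia) == 0)
    stop("ng86_sites_and_diffs: no countable (stop-free, ungapped) codon columns")
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- sum(tb$sd[cbind(ia, ib)])
  Nd <- sum(tb$nd[cbind(ia, ib)])
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(ia)),
            class = "site_counts")
}

#' Jukes-Cantor-corrected Ka and Ks from NG86 site counts
#'
#' `ps = Sd/S` and `pn = Nd/N` are corrected as
#' `K = -(3/4) * log(1 - (4/3) * p)`; a proportion at or above 3/4 is beyond
#' the correction's reach and sets the corresponding `saturated` flag (the
#' distance is returned as `NA`, not an error).
#'
#' @param counts A `site_counts` object from [ng86_sites_and_diffs()].
#' @return An object of class `ks_estimate` with `ps`, `pn`, `ks`, `ka`,
#'   `saturated_ks`, `saturated_ka` and the overall `saturated` flag.
#' @examples
#' compute_ka_ks(structure(list(S = 3, N = 6, Sd = 1, Nd = 0, n_codons = 3),
#'                         class = "site_counts"))
#' @export
compute_ka_ks <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  jc <- function(p) {
    if (is.na(p)) return(list(k = NA_real_, sat = FALSE))
    if (p >= 0.75) return(list(k = NA_real_, sat = TRUE))
    list(k = -0.75 * log(1 - 4 * p / 3), sat = FALSE)
  }
  ps <- if (counts$S > 0) counts$Sd / counts$S else NA_real_
  pn <- if (counts$N > 0) counts$Nd / counts$N else NA_real_
  ks <- jc(ps)
  ka <- jc(pn)
  structure(list(ps = ps, pn = pn, ks = ks$k, ka = ka$k,
                 saturated_ks = ks$sat, saturated_ka = ka$sat,
                 saturated = ks$sat || ka$sat),
            class = "ks_estimate")
}

#' One-call Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper chaining [align_coding_pair()],
#' [ng86_sites_and_diffs()] and [compute_ka_ks()].
#'
#' @inheritParams align_coding_pair
#' @return A list with the alignment (`aln`), counts (`counts`), estimate
#'   (`est`), and the scalar shortcuts `ks`, `ka`, `identity`, `saturated`.
#' @export
kaks_pair <- function(cds_a, cds_b, gene_a = "a", gene_b = "b") {
  aln <- align_coding_pair(cds_a, cds_b, gene_a, gene_b)
  counts <- ng86_sites_and_diffs(aln)
  est <- compute_ka_ks(counts)
  list(aln = aln, counts = counts, est = est,
       ks = est$ks, ka = est$ka, identity = aln$identity,
       saturated = est$saturated)
}

#' Batch Ka/Ks over a table of sequence pairs
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param cds_a,cds_b Named character vectors of coding sequences indexed by
#'   the ids in `pairs` (may be the same vector).
#' @return `pairs` with columns `identity`, `S`, `N`, `Sd`, `Nd`, `ks`,
#'   `ka`, `saturated` appended.
#' @export
kaks_table <- function(pairs, cds_a, cds_b = cds_a) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  n <- nrow(pairs)
  out <- cbind(pairs,
               identity = numeric(n), S = numeric(n), N = numeric(n),
               Sd = numeric(n), Nd = numeric(n),
               ks = NA_real_, ka = NA_real_, saturated = logical(n))
  for (i in seq_len(n)) {
    r <- kaks_pair(cds_a[[pairs$gene_a[i]]], cds_b[[pairs$gene_b[i]]],
                   pairs$gene_a[i], pairs$gene_b[i])
    out$identity[i] <- r$identity
    out$S[i] <- r$counts$S
    out$N[i] <- r$counts$N
    out$Sd[i] <- r$counts$Sd
    out$Nd[i] <- r$counts$Nd
    out$ks[i] <- r$ks
    out$ka[i] <- r$ka
    out$saturated[i] <- r$saturated
  }
  out
}
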