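## Two-genotype locus simulator with a ground-truth event ledger.
##
## An ancestral subtelomeric locus (low-copy anchor genes interleaved with
## two CNL subfamily arrays and a couple of TNLs, separated by intergenic
## spacers) is evolved into two descendant genotypes: neutral divergence
## calibrated on the anchors, lineage-specific gene losses,
## pseudogenizations (premature stop or 1-bp frameshift), segmental
## duplications with engineered NHEJ/HR junctions, LTR retroelement
## insertions with target-site duplications, solo-LTRs, and satellite
## monomer arrays.  Every planted event is recorded in a ledger the
## analysis pipeline can be scored against.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_bases <- c("A", "C", "G", "T")

#' Random nucleotide sequence
#'
#' @param n Length in bp.
#' @return Character scalar of uniformly random A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(.sim_bases, n, replace = TRUE), collapse = "")
}

#' Random open reading frame
#'
#' ATG start, uniformly random sense codons, TAA stop.
#'
#' @param n_codons Total codon count including start and stop.
#' @return Character scalar of length `3 * n_codons`.
#' @export
random_orf <- function(n_codons) {
  tb <- ng86_tables()
  sense <- tb$codons[!tb$is_stop & tb$codons != "ATG"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Neutral substitution process for non-coding (or constraint-free) sequence
#'
#' Applies uniform substitutions at a per-site probability, each site
#' changed to one of the 3 alternative bases uniformly (Jukes-Cantor
#' compatible).  Positions in `protect` are left untouched (e.g. a
#' pseudogene's start codon and its planted lesion, which define its
#' annotation class).
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param rate Per-site substitution probability.
#' @param protect Integer positions exempt from mutation.
#' @return The mutated sequence.
#' @export
mutate_noncoding <- function(seq, rate, protect = integer(0)) {
  n <- nchar(seq)
  if (n == 0 || rate <= 0) return(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- setdiff(sample.int(n, k), protect)
  if (length(pos) == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  for (p in pos) {
    v[p] <- sample(setdiff(.sim_bases, v[p]), 1)
  }
  paste(v, collapse = "")
}

#' Simulation configuration for a two-genotype locus pair
#'
#' Defaults describe the study conditions the analysis is built for: 12
#' low-copy anchor ortholog pairs at a mean silent divergence (Ks) of
#' 0.0177 with a slowest-to-fastest spread whose maximum is about 2.8 times
#' the mean; two CNL subfamilies of 15 ancestral members each (paralog
#' backbone divergence Ks 0.10-0.60); 6 + 3 lineage-specific losses; 4
#' shared and 7 + 6 lineage-specific pseudogenizations; one recent ectopic
#' duplication; 2 + 1 segmental duplications with mixed NHEJ/HR junctions;
#' and, per genotype, 10 intact LTR retroelements, 5 solo-LTRs and 2
#' tandem satellite blocks of 528-bp monomers.
#'
#' @param n_anchor_genes Number of low-copy anchor genes.
#' @param n_cnl_per_subfamily Named counts of ancestral CNLs per subfamily.
#' @param n_tnl Number of TNL genes.
#' @param anchor_ks_mean Mean pairwise anchor Ks (the silent-site
#'   divergence between the two gene pools).
#' @param anchor_ks_relmax Ratio of the largest anchor-pair divergence to
#'   the mean (rate heterogeneity across anchors).
#' @param cnl_background_ks Range of per-paralog backbone divergence.
#' @param cnl_ka_ks Ka/Ks ratio applied when CNLs diverge proportionally.
#' @param n_losses_per_lineage Named counts (`A`, `B`) of lineage-specific
#'   CNL losses.
#' @param n_pseudogenization_shared Pseudogenizations planted in the
#'   ancestor (shared by both descendants).
#' @param n_pseudogenization_lineage Named counts of lineage-specific
#'   pseudogenizations.
#' @param n_recent_duplications Named counts of post-divergence ectopic CNL
#'   duplications.
#' @param recent_dup_ks Extra divergence of a recent duplicate from its
#'   source.
#' @param n_segdups Named counts of segmental duplications per lineage.
#' @param segdup_len Length of each duplicated tract (bp).
#' @param segdup_repair_mix Sampling weights for NHEJ vs HR junctions.
#' @param nhej_m_range Microhomology range (bp) for NHEJ junctions.
#' @param hr_transition_range Transition-region length range (bp) for HR
#'   junctions.
#' @param hr_identity_range Transition-region identity range for HR
#'   junctions.
#' @param n_intact_ltr,n_solo_ltr LTR element counts per genotype.
#' @param n_satellite_blocks Satellite blocks per genotype.
#' @param satellite_units_range Units per satellite block.
#' @param satellite_unit_divergence Per-unit divergence from the monomer
#'   consensus.
#' @param monomer_len Satellite monomer length (bp).
#' @param ltr_len,ltr_internal_len LTR and internal-region lengths (bp).
#' @param ltr_divergence Per-element divergence from the family exemplar.
#' @param tsd_len_range Target-site duplication length range (bp).
#' @param anchor_cds_len,cnl_cds_len,tnl_cds_len CDS lengths (bp, multiples
#'   of 3).
#' @param spacer_len_mean Mean intergenic spacer length (bp).
#' @param genotype_ids Labels of the two descendant genotypes.
#' @param seed Seed for the single random generator driving the whole
#'   simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_anchor_genes = 12L,
                       n_cnl_per_subfamily = c(CNL1 = 15L, CNL3_4 = 15L),
                       n_tnl = 2L,
                       anchor_ks_mean = 0.0177,
                       anchor_ks_relmax = 2.79,
                       cnl_background_ks = c(0.10, 0.60),
                       cnl_ka_ks = 0.2,
                       n_losses_per_lineage = c(A = 6L, B = 3L),
                       n_pseudogenization_shared = 4L,
                       n_pseudogenization_lineage = c(A = 7L, B = 6L),
                       n_recent_duplications = c(A = 1L, B = 0L),
                       recent_dup_ks = 0.005,
                       n_segdups = c(A = 2L, B = 1L),
                       segdup_len = 2000L,
                       segdup_repair_mix = c(NHEJ = 0.5, HR = 0.5),
                       nhej_m_range = c(0L, 8L),
                       hr_transition_range = c(80L, 180L),
                       hr_identity_range = c(0.75, 0.90),
                       n_intact_ltr = 10L,
                       n_solo_ltr = 5L,
                       n_satellite_blocks = 2L,
                       satellite_units_range = c(6L, 12L),
                       satellite_unit_divergence = 0.15,
                       monomer_len = 528L,
                       ltr_len = 300L,
                       ltr_internal_len = 2000L,
                       ltr_divergence = 0.08,
                       tsd_len_range = c(4L, 6L),
                       anchor_cds_len = 1200L,
                       cnl_cds_len = 900L,
                       tnl_cds_len = 900L,
                       spacer_len_mean = 6500L,
                       genotype_ids = c("genoA", "genoB"),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (anchor_ks_mean < 0 || anchor_ks_mean * anchor_ks_relmax >= 0.75)
    stop("sim_config: anchor divergence must stay below JC saturation")
  counts <- c(n_anchor_genes, n_cnl_per_subfamily, n_tnl,
              n_losses_per_lineage, n_pseudogenization_shared,
              n_pseudogenization_lineage, n_recent_duplications, n_segdups,
              n_intact_ltr, n_solo_ltr, n_satellite_blocks)
  if (any(counts < 0)) stop("sim_config: counts must be non-negative")
  n_cnl <- sum(n_cnl_per_subfamily)
  need <- sum(n_losses_per_lineage) + n_pseudogenization_shared +
    sum(n_pseudogenization_lineage) + sum(n_recent_duplications)
  if (need > n_cnl)
    stop("sim_config: planted CNL events (", need,
         ") exceed ancestral CNL count (", n_cnl, ")")
  structure(cfg, class = "sim_config")
}

## ---------------------------------------------------------------------
## targeted coding-sequence divergence

#' Mutate a CDS until its NG86 Ks versus the original reaches a target
#'
#' Introduces single-base substitutions, drawn uniformly over sites and
#' over the 3 alternative bases (Jukes-Cantor-compatible), until the NG86 +
#' JC Ks estimate of mutated-versus-original first reaches the target.
#' `synonymous_only` accepts only amino-acid-preserving changes (the
#' protein is untouched); `proportional` also accepts nonsynonymous changes
#' with probability `ka_ks`.  Substitutions creating stop codons are never
#' accepted, the start and terminal codons are left alone, and pre-existing
#' internal stop codons (pseudogenes) are immutable and uncounted, matching
#' the estimator's treatment of stop columns.
#'
#' @param cds A coding sequence (length a multiple of 3, at least 3
#'   codons).
#' @param target_ks Target Ks (must lie below the JC saturation bound
#'   0.75).
#' @param mode `"synonymous_only"` or `"proportional"`.
#' @param ka_ks Acceptance probability of nonsynonymous changes in
#'   proportional mode.
#' @param max_iter Attempt budget; exhaustion raises a simulation error
#'   (the target is unreachable, e.g. for an ultra-short CDS).
#' @return The mutated CDS (character scalar).
#' @export
mutate_to_target_ks <- function(cds, target_ks,
                                mode = c("synonymous_only", "proportional"),
                                ka_ks = 0.2, max_iter = NULL) {
  mode <- match.arg(mode)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("mutate_to_target_ks: cds length must be a multiple of 3")
  if (nchar(cds) < 9L)
    stop("mutate_to_target_ks: cds too short")
  if (target_ks <= 0) return(cds)
  if (target_ks >= 0.75)
    stop("mutate_to_target_ks: target_ks is beyond JC saturation")
  tb <- ng86_tables()
  orig <- split_codons(cds)
  n <- length(orig)
  ia <- match(orig, tb$codons)
  ib <- ia
  countable <- !tb$is_stop[ia]
  countable[n] <- countable[n] && !tb$is_stop[ia[n]]
  mutable <- which(countable)
  mutable <- setdiff(mutable, c(1L, n))
  if (length(mutable) == 0)
    stop("mutate_to_target_ks: no mutable codons")
  cnt <- which(countable)
  syn_orig <- sum(tb$syn_sites[ia[cnt]])
  syn_cur <- syn_orig
  Sd <- 0
  Nd <- 0
  ks_now <- function() {
    S <- (syn_orig + syn_cur) / 2
    if (S <= 0) return(0)
    ps <- Sd / S
    if (ps >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * ps / 3)
  }
  if (is.null(max_iter)) max_iter <- 400L * n
  it <- 0L
  while (ks_now() < target_ks) {
    it <- it + 1L
    if (it > max_iter)
      stop("mutate_to_target_ks: target Ks ", target_ks,
           " unreachable for this CDS")
    c_i <- if (length(mutable) == 1L) mutable else sample(mutable, 1L)
    pos <- sample.int(3L, 1L)
    cod <- tb$codons[ib[c_i]]
    base_old <- substr(cod, pos, pos)
    base_new <- sample(setdiff(.sim_bases, base_old), 1L)
    new_cod <- cod
    substr(new_cod, pos, pos) <- base_new
    j <- match(new_cod, tb$codons)
    if (tb$is_stop[j]) next
    if (tb$aa[j] != tb$aa[ib[c_i]]) {
      if (mode == "synonymous_only") next
      if (stats::runif(1) > ka_ks) next
    }
    ks_prev <- ks_now()
    last <- c(c_i, ib[c_i])
    Sd <- Sd + tb$sd[ia[c_i], j] - tb$sd[ia[c_i], ib[c_i]]
    Nd <- Nd + tb$nd[ia[c_i], j] - tb$nd[ia[c_i], ib[c_i]]
    syn_cur <- syn_cur + tb$syn_sites[j] - tb$syn_sites[ib[c_i]]
    ib[c_i] <- j
    ## crossing the target: keep whichever state estimates closer, so the
    ## realized Ks is unbiased rather than carrying the overshoot of a
    ## discrete substitution step
    if (ks_now() >= target_ks) {
      if (abs(ks_prev - target_ks) < abs(ks_now() - target_ks)) {
        jj <- last[2]
        Sd <- Sd + tb$sd[ia[c_i], jj] - tb$sd[ia[c_i], ib[c_i]]
        Nd <- Nd + tb$nd[ia[c_i], jj] - tb$nd[ia[c_i], ib[c_i]]
        syn_cur <- syn_cur + tb$syn_sites[jj] - tb$syn_sites[ib[c_i]]
        ib[c_i] <- jj
      }
      break
    }
  }
  paste(tb$codons[ib], collapse = "")
}

## premature stop (50%) or 1-bp deletion frameshift (50%)
.pseudogenize <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (stats::runif(1) < 0.5 && n > 10L) {
    i <- sample(seq(5L, n - 5L), 1L)
    substr(cds, 3L * i - 2L, 3L * i) <- "TAA"
    list(cds = cds, lesion = "premature_stop",
         lesion_pos = (3L * i - 2L):(3L * i))
  } else {
    p <- sample(seq(15L, nchar(cds) - 15L), 1L)
    list(cds = paste0(substr(cds, 1L, p - 1L),
                      substr(cds, p + 1L, nchar(cds))),
         lesion = "frameshift", lesion_pos = integer(0))
  }
}

## ---------------------------------------------------------------------
## junction planting

.force_mismatch <- function(vec, i, against) {
  if (i < 1 || i > length(vec)) return(vec)
  if (vec[i] == against)
    vec[i] <- sample(setdiff(.sim_bases, against), 1L)
  vec
}

## evenly spaced mismatch positions so every sliding 10-bp window keeps the
## target identity
.homogenize <- function(target_bases, identity) {
  t <- length(target_bases)
  out <- target_bases
  nmis <- round((1 - identity) * t)
  if (nmis <= 0) return(list(seq = out, mismatch_at = integer(0)))
  at <- unique(pmin(pmax(round((seq_len(nmis) - 0.5) * t / nmis), 1L), t))
  for (k in at)
    out[k] <- sample(setdiff(.sim_bases, target_bases[k]), 1L)
  list(seq = out, mismatch_at = at)
}

#' Plant a segmental-duplication event with engineered junctions
#'
#' Builds the hybrid molecule of a duplicative double-strand-break repair
#' event: recipient sequence up to the break, a duplicated donor tract,
#' then recipient sequence again, with the X (left) and Y (right) junctions
#' engineered as either NHEJ (a microhomology of `m` bases shared by donor
#' and recipient exactly at the junction, flanked by forced mismatches) or
#' HR (a transition region in which the donor flank is homogenized toward
#' the recipient at a target identity, mismatches spread evenly so windowed
#' identity never dips below the global value).  The donor molecule is
#' returned with the engineered bases so genome and truth stay consistent.
#'
#' @param recipient_seq The unbroken recipient molecule (character
#'   scalar).
#' @param donor_seq The donor molecule; the duplicated tract is an
#'   internal window of it.
#' @param repair_type `"NHEJ"` or `"HR"`, length 1 (both junctions) or 2
#'   (X, Y).
#' @param params Optional list: `break_pos`, `donor_start`, `donor_end`
#'   (1-based), `m` (NHEJ microhomology, recycled to 2), `transition_len`,
#'   `transition_identity` (HR, recycled to 2).
#' @return A list: `hybrid`, `donor` (engineered), `recipient`, `tract`
#'   (0-based half-open span of the duplicated tract in the hybrid), and
#'   `truth` — per-junction type, canonical changepoint `position`
#'   (1-based, leftmost of the tie interval), `m` or
#'   `transition_len`/`transition_identity` (realized).
#' @export
plant_junction <- function(recipient_seq, donor_seq, repair_type,
                           params = list()) {
  R <- strsplit(toupper(recipient_seq), "")[[1]]
  D <- strsplit(toupper(donor_seq), "")[[1]]
  nR <- length(R)
  nD <- length(D)
  types <- rep(repair_type, length.out = 2L)
  if (!all(types %in% c("NHEJ", "HR")))
    stop("plant_junction: repair_type must be NHEJ or HR")
  b <- params$break_pos %||% (nR %/% 2L)
  ds <- params$donor_start %||% max(401L, nD %/% 4L)
  de <- params$donor_end %||% (nD - 400L)
  if (de - ds + 1L < 200L)
    stop("plant_junction: donor shorter than the requested duplication span")
  m <- rep(params$m %||% 3L, length.out = 2L)
  tl <- rep(params$transition_len %||% 130L, length.out = 2L)
  ti <- rep(params$transition_identity %||% 0.80, length.out = 2L)
  guard <- max(m, tl) + 5L
  if (b - guard < 1L || b + guard > nR || ds - guard < 1L ||
      de + guard > nD)
    stop("plant_junction: break or donor span too close to a sequence end")

  truth <- list()
  ## --- junction X (left) ---
  if (types[1] == "NHEJ") {
    mx <- m[1]
    if (mx > 0) D[ds:(ds + mx - 1L)] <- R[(b - mx + 1L):b]
    D <- .force_mismatch(D, ds - 1L, R[b - mx])
    D <- .force_mismatch(D, ds + mx, R[b + 1L])
    dxs <- ds + mx
    truth$X <- list(type = "NHEJ", m = mx, position = b - mx)
  } else {
    tx <- tl[1]
    hg <- .homogenize(R[(b - tx + 1L):b], ti[1])
    D[(ds - tx):(ds - 1L)] <- hg$seq
    dxs <- ds
    real_id <- mean(D[(ds - tx):(ds - 1L)] == R[(b - tx + 1L):b])
    truth$X <- list(type = "HR", position = b, transition_len = tx,
                    transition_identity = real_id)
  }
  ## --- junction Y (right) ---
  if (types[2] == "NHEJ") {
    my <- m[2]
    if (my > 0) D[(de - my + 1L):de] <- R[(b + 1L):(b + my)]
    D <- .force_mismatch(D, de - my, R[b])
    D <- .force_mismatch(D, de + 1L, R[b + my + 1L])
    dye <- de - my
    truth$Y <- list(type = "NHEJ", m = my)
  } else {
    ty <- tl[2]
    hg <- .homogenize(R[(b + 1L):(b + ty)], ti[2])
    D[(de + 1L):(de + ty)] <- hg$seq
    dye <- de
    real_id <- mean(D[(de + 1L):(de + ty)] == R[(b + 1L):(b + ty)])
    truth$Y <- list(type = "HR", transition_len = ty,
                    transition_identity = real_id)
  }
  ins_len <- dye - dxs + 1L
  jy <- b + ins_len
  truth$Y$position <- jy
  hybrid <- paste(c(R[1:b], D[dxs:dye], R[(b + 1L):nR]), collapse = "")
  list(hybrid = hybrid,
       donor = paste(D, collapse = ""),
       recipient = paste(R, collapse = ""),
       tract = c(b, b + ins_len),          # 0-based half-open, in hybrid
       donor_tract = c(dxs - 1L, dye),     # 0-based half-open, in donor
       truth = truth)
}

## ---------------------------------------------------------------------
## locus assembly machinery

.new_part <- function(kind, id, seq, ...) {
  c(list(kind = kind, id = id, seq = seq), list(...))
}

.part_index <- function(parts, id) {
  for (i in seq_along(parts)) if (parts[[i]]$id == id) return(i)
  NA_integer_
}

## split a spacer at `offset` (bases kept on the left), duplicating `tsd`
## bases of the right side on both flanks of the inserted parts
.insert_into_spacer <- function(parts, spacer_id, new_parts, tsd_len = 0L) {
  i <- .part_index(parts, spacer_id)
  sp <- parts[[i]]
  n <- nchar(sp$seq)
  offset <- n %/% 2L
  left <- substr(sp$seq, 1L, offset)
  right <- substr(sp$seq, offset + 1L, n)
  tsd <- if (tsd_len > 0L) substr(right, 1L, tsd_len) else ""
  left_part <- .new_part("spacer", paste0(sp$id, "l"), paste0(left, tsd))
  right_part <- .new_part("spacer", paste0(sp$id, "r"), right)
  parts <- append(parts[-i], c(list(left_part), new_parts,
                               list(right_part)), after = i - 1L)
  list(parts = parts, tsd = tsd)
}

.gene_roster <- function(cfg) {
  roster <- list()
  add <- function(id, class, subfam, len)
    roster[[length(roster) + 1L]] <<- list(id = id, class = class,
                                           subfamily = subfam, len = len)
  n_anc <- cfg$n_anchor_genes
  fams <- names(cfg$n_cnl_per_subfamily)
  cnl_ids <- lapply(seq_along(fams), function(f)
    sprintf("%s_%02d", tolower(gsub("/", "", fams[f])),
            seq_len(cfg$n_cnl_per_subfamily[f])))
  tnl_ids <- if (cfg$n_tnl > 0) sprintf("tnl_%02d", seq_len(cfg$n_tnl))
  else character(0)
  ## interleave: anchor islands separated by CNL array chunks
  chunks <- function(ids, k) {
    out <- rep(list(character(0)), max(k, 1L))
    if (length(ids) == 0 || k == 0) return(out)
    grp <- cut(seq_along(ids), k, labels = FALSE)
    for (g in unique(grp)) out[[g]] <- ids[grp == g]
    out
  }
  n_isl <- max(n_anc, 1L)
  ch <- lapply(cnl_ids, chunks, k = n_isl)
  for (i in seq_len(n_isl)) {
    if (i <= n_anc) add(sprintf("anc_%02d", i), "low_copy", "none",
                        cfg$anchor_cds_len)
    for (f in seq_along(fams))
      for (id in ch[[f]][[i]]) add(id, "CNL", fams[f], cfg$cnl_cds_len)
    if (length(tnl_ids) >= 1 && i == max(1L, n_isl %/% 3L))
      add(tnl_ids[1], "TNL", "TNL7", cfg$tnl_cds_len)
    if (length(tnl_ids) >= 2 && i == max(2L, 2L * (n_isl %/% 3L)))
      add(tnl_ids[2], "TNL", "TNL7", cfg$tnl_cds_len)
  }
  roster
}

#' Generate a simulated two-genotype locus pair with its event ledger
#'
#' Builds the ancestral locus, evolves the two descendant genotypes under
#' the configured event counts, and returns the two annotated assemblies
#' together with the ground-truth ledger, the satellite monomer consensus
#' and the LTR exemplar used (the libraries a real analysis would take as
#' input).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `locus_pair_sim`: `assembly_a`, `assembly_b`
#'   ([genotype_assembly()]), `ledger`, `satellite_profile`,
#'   `ltr_library`, `config`.
#' @export
generate_locus_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genoA <- cfg$genotype_ids[1]
  genoB <- cfg$genotype_ids[2]

  ## --- ancestral gene sequences ---
  roster <- .gene_roster(cfg)
  fams <- names(cfg$n_cnl_per_subfamily)
  seeds <- stats::setNames(
    lapply(c(fams, if (cfg$n_tnl > 0) "TNL7"), function(f)
      random_orf(if (f == "TNL7") cfg$tnl_cds_len %/% 3L
                 else cfg$cnl_cds_len %/% 3L)),
    c(fams, if (cfg$n_tnl > 0) "TNL7"))
  gene_seq <- list()
  for (g in roster) {
    gene_seq[[g$id]] <- if (g$class == "low_copy") {
      random_orf(g$len %/% 3L)
    } else {
      bg <- stats::runif(1, cfg$cnl_background_ks[1], cfg$cnl_background_ks[2])
      mutate_to_target_ks(seeds[[g$subfamily]], bg, "proportional",
                          ka_ks = cfg$cnl_ka_ks)
    }
  }
  strands <- stats::setNames(sample(c("+", "-"), length(roster),
                                    replace = TRUE),
                             vapply(roster, `[[`, "", "id"))

  ## --- event gene assignment (disjoint CNL sets) ---
  cnl_ids <- vapply(Filter(function(g) g$class == "CNL", roster),
                    `[[`, "", "id")
  perm <- if (length(cnl_ids)) sample(cnl_ids) else character(0)
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    out
  }
  shared_pseudo <- take(cfg$n_pseudogenization_shared)
  loss_set <- list(A = take(cfg$n_losses_per_lineage[["A"]]),
                   B = take(cfg$n_losses_per_lineage[["B"]]))
  pseudo_set <- list(A = take(cfg$n_pseudogenization_lineage[["A"]]),
                     B = take(cfg$n_pseudogenization_lineage[["B"]]))
  dup_src <- list(A = take(cfg$n_recent_duplications[["A"]]),
                  B = take(cfg$n_recent_duplications[["B"]]))

  ## shared (ancestral) pseudogenization; the start codon and the planted
  ## lesion stay protected during later neutral evolution, so the
  ## annotation class of both descendants reflects the ancestral event
  shared_lesions <- character(0)
  shared_protect <- list()
  for (id in shared_pseudo) {
    ps <- .pseudogenize(gene_seq[[id]])
    gene_seq[[id]] <- ps$cds
    shared_lesions[id] <- ps$lesion
    shared_protect[[id]] <- c(1:3, ps$lesion_pos)
  }

  ## --- anchor divergence profile: mean 1, max anchor_ks_relmax ---
  n_anc <- cfg$n_anchor_genes
  anchor_targets <- numeric(0)
  if (n_anc > 0) {
    if (n_anc == 1) {
      w <- 1
    } else {
      w_rest <- seq(0.15, 1.6, length.out = n_anc - 1L)
      w_rest <- w_rest * stats::runif(n_anc - 1L, 0.9, 1.1)
      w_rest <- w_rest * (n_anc - cfg$anchor_ks_relmax) / sum(w_rest)
      w <- c(w_rest, cfg$anchor_ks_relmax)
      w <- sample(w)  # shuffle which anchor is fastest
    }
    anchor_targets <- stats::setNames(cfg$anchor_ks_mean * w,
                                      sprintf("anc_%02d", seq_len(n_anc)))
  }

  ## --- repeat libraries ---
  monomer <- random_dna(cfg$monomer_len)
  ltr_exemplar <- random_dna(cfg$ltr_len)

  ## --- ancestral part list ---
  parts0 <- list()
  spn <- 0L
  add_spacer <- function(parts) {
    spn <<- spn + 1L
    len <- round(stats::runif(1, 0.8, 1.2) * cfg$spacer_len_mean)
    c(parts, list(.new_part("spacer", sprintf("sp%03d", spn),
                            random_dna(len))))
  }
  parts0 <- add_spacer(parts0)
  for (g in roster) {
    parts0 <- c(parts0, list(.new_part("gene", g$id, gene_seq[[g$id]],
                                       gene_class = g$class,
                                       subfamily = g$subfamily,
                                       strand = strands[[g$id]])))
    parts0 <- add_spacer(parts0)
  }
  spacer_ids <- vapply(Filter(function(p) p$kind == "spacer", parts0),
                       `[[`, "", "id")

  ledger <- list(losses = list(), pseudogenizations = list(),
                 duplications = list(), ltr = list(), satellites = list(),
                 segdups = list())
  for (id in shared_pseudo)
    ledger$pseudogenizations[[length(ledger$pseudogenizations) + 1L]] <-
      list(gene = id, timing = "shared", lesion = shared_lesions[[id]])

  ## --- evolve one lineage ---
  evolve <- function(lineage) {
    geno <- if (lineage == "A") genoA else genoB
    parts <- parts0
    half <- cfg$anchor_ks_mean / 2
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (p$kind == "spacer") {
        parts[[i]]$seq <- mutate_noncoding(p$seq, half)
      } else if (p$gene_class == "low_copy") {
        parts[[i]]$seq <- mutate_to_target_ks(p$seq,
                                              anchor_targets[[p$id]] / 2,
                                              "synonymous_only")
      } else if (p$id %in% shared_pseudo) {
        parts[[i]]$seq <- mutate_noncoding(p$seq, half,  # neutral pseudogene
                                           protect = shared_protect[[p$id]])
      } else {
        parts[[i]]$seq <- mutate_to_target_ks(p$seq, half, "proportional",
                                              ka_ks = cfg$cnl_ka_ks)
      }
    }
    ## lineage-specific pseudogenization
    for (id in pseudo_set[[lineage]]) {
      i <- .part_index(parts, id)
      ps <- .pseudogenize(parts[[i]]$seq)
      parts[[i]]$seq <- ps$cds
      ledger$pseudogenizations[[length(ledger$pseudogenizations) + 1L]] <<-
        list(gene = id, timing = paste0(geno, "_specific"),
             lesion = ps$lesion)
    }
    ## lineage-specific losses (gene plus 1 kb of each flank)
    for (id in loss_set[[lineage]]) {
      i <- .part_index(parts, id)
      if (i > 1 && parts[[i - 1]]$kind == "spacer") {
        s <- parts[[i - 1]]$seq
        parts[[i - 1]]$seq <- substr(s, 1L, max(100L, nchar(s) - 1000L))
      }
      if (i < length(parts) && parts[[i + 1]]$kind == "spacer") {
        s <- parts[[i + 1]]$seq
        parts[[i + 1]]$seq <- substr(s, min(nchar(s) - 99L, 1001L), nchar(s))
      }
      parts <- parts[-i]
      other <- if (lineage == "A") genoB else genoA
      ledger$losses[[length(ledger$losses) + 1L]] <<-
        list(gene = id, lineage = geno,
             surviving_counterpart = paste0(other, "_", id))
    }
    ## host spacers for insertions (chosen on the ancestral spacer grid)
    n_ltr <- cfg$n_intact_ltr + cfg$n_solo_ltr
    avail <- spacer_ids
    ltr_hosts <- character(0)
    if (n_ltr > 0) {
      idx <- unique(round(seq(2, length(avail) - 1, length.out = n_ltr)))
      if (length(idx) < n_ltr)
        stop("sim_config: too few spacers for the requested LTR count")
      ltr_hosts <- avail[idx]
      avail <- setdiff(avail, ltr_hosts)
    }
    free <- sample(avail)
    grab <- function(k) {
      if (k == 0) return(character(0))
      if (k > length(free)) stop("sim_config: not enough free spacers")
      out <- free[seq_len(k)]
      free <<- free[-seq_len(k)]
      out
    }
    sat_hosts <- grab(cfg$n_satellite_blocks)
    n_sd <- cfg$n_segdups[[lineage]]
    sd_donor_hosts <- grab(n_sd)
    sd_recip_hosts <- grab(n_sd)
    dup_hosts <- grab(length(dup_src[[lineage]]))

    ## recent ectopic duplication(s)
    for (k in seq_along(dup_src[[lineage]])) {
      src <- dup_src[[lineage]][k]
      i <- .part_index(parts, src)
      copy_seq <- mutate_to_target_ks(parts[[i]]$seq, cfg$recent_dup_ks,
                                      "proportional", ka_ks = cfg$cnl_ka_ks)
      copy_id <- paste0(src, "_dup")
      np <- .new_part("gene", copy_id, copy_seq,
                      gene_class = parts[[i]]$gene_class,
                      subfamily = parts[[i]]$subfamily,
                      strand = sample(c("+", "-"), 1))
      parts <- .insert_into_spacer(parts, dup_hosts[k], list(np))$parts
      ledger$duplications[[length(ledger$duplications) + 1L]] <<-
        list(genotype = geno, source = paste0(geno, "_", src),
             copy = paste0(geno, "_", copy_id))
    }
    ## LTR elements
    if (n_ltr > 0) {
      classes <- sample(c(rep("intact", cfg$n_intact_ltr),
                          rep("solo", cfg$n_solo_ltr)))
      for (k in seq_len(n_ltr)) {
        ltr <- mutate_noncoding(ltr_exemplar, cfg$ltr_divergence)
        eseq <- if (classes[k] == "intact")
          paste0(ltr, random_dna(cfg$ltr_internal_len), ltr) else ltr
        eid <- sprintf("ltr%02d", k)
        tsd_len <- sample(seq(cfg$tsd_len_range[1], cfg$tsd_len_range[2]), 1L)
        np <- .new_part("ltr", eid, eseq, ltr_class = classes[k],
                        ltr_len = nchar(ltr))
        ins <- .insert_into_spacer(parts, ltr_hosts[k], list(np), tsd_len)
        parts <- ins$parts
        ledger$ltr[[length(ledger$ltr) + 1L]] <<-
          list(genotype = geno, element = eid, class = classes[k],
               tsd = ins$tsd)
      }
    }
    ## satellite blocks
    for (k in seq_along(sat_hosts)) {
      n_units <- sample(seq(cfg$satellite_units_range[1],
                            cfg$satellite_units_range[2]), 1L)
      units <- vapply(seq_len(n_units), function(u)
        mutate_noncoding(monomer, cfg$satellite_unit_divergence), "")
      np <- .new_part("satellite", sprintf("sat%02d", k),
                      paste(units, collapse = ""), n_units = n_units)
      parts <- .insert_into_spacer(parts, sat_hosts[k], list(np))$parts
      ledger$satellites[[length(ledger$satellites) + 1L]] <<-
        list(genotype = geno, block = sprintf("sat%02d", k),
             n_units = n_units)
    }
    ## segmental duplications with engineered junctions
    for (k in seq_len(n_sd)) {
      di <- .part_index(parts, sd_donor_hosts[k])
      dseq <- parts[[di]]$seq
      wlen <- cfg$segdup_len + 800L
      w0 <- max(1L, (nchar(dseq) - wlen) %/% 2L)
      window <- substr(dseq, w0, w0 + wlen - 1L)
      types <- sample(names(cfg$segdup_repair_mix), 2L, replace = TRUE,
                      prob = cfg$segdup_repair_mix)
      ri <- .part_index(parts, sd_recip_hosts[k])
      pj <- plant_junction(parts[[ri]]$seq, window, types,
                           params = list(
                             donor_start = 401L,
                             donor_end = wlen - 400L,
                             m = sample(seq(cfg$nhej_m_range[1],
                                            cfg$nhej_m_range[2]), 2L,
                                        replace = TRUE),
                             transition_len = sample(
                               seq(cfg$hr_transition_range[1],
                                   cfg$hr_transition_range[2]), 2L,
                               replace = TRUE),
                             transition_identity = stats::runif(
                               2L, cfg$hr_identity_range[1],
                               cfg$hr_identity_range[2])))
      ## write the engineered donor window back into its spacer
      substr(dseq, w0, w0 + wlen - 1L) <- pj$donor
      parts[[di]]$seq <- dseq
      parts[[ri]]$seq <- pj$hybrid
      ledger$segdups[[length(ledger$segdups) + 1L]] <<-
        list(genotype = geno, event = sprintf("%s_sd%02d", geno, k),
             donor_part = sd_donor_hosts[k], donor_offset = w0 + 400L,
             recipient_part = sd_recip_hosts[k],
             tract_offset = pj$tract, length = diff(pj$tract),
             junctions = pj$truth)
    }
    list(parts = parts, geno = geno)
  }

  lin <- list(A = evolve("A"), B = evolve("B"))

  ## --- assemble contigs and feature tables ---
  build_assembly <- function(lr) {
    geno <- lr$geno
    ctg <- paste0(geno, "_ctg1")
    offs <- 0L
    seq_parts <- character(0)
    rows <- list()
    for (p in lr$parts) {
      len <- nchar(p$seq)
      s <- offs
      e <- offs + len
      if (p$kind == "gene") {
        fwd <- if (p$strand == "+") p$seq else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(p$seq)))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = paste0(geno, "_", p$id), type = "gene",
          contig_id = ctg, start = s, end = e, strand = p$strand,
          gene_class = p$gene_class, subfamily = p$subfamily,
          status = classify_gene_status(p$seq), cds = p$seq,
          stringsAsFactors = FALSE)
        seq_parts <- c(seq_parts, fwd)
      } else {
        if (p$kind == "ltr") {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = paste0(geno, "_", p$id),
            type = if (p$ltr_class == "intact") "LTR_retrotransposon"
            else "solo_LTR",
            contig_id = ctg, start = s, end = e, strand = "+",
            gene_class = NA_character_, subfamily = NA_character_,
            status = NA_character_, cds = NA_character_,
            stringsAsFactors = FALSE)
        } else if (p$kind == "satellite") {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = paste0(geno, "_", p$id), type = "satellite_DNA",
            contig_id = ctg, start = s, end = e, strand = "+",
            gene_class = NA_character_, subfamily = NA_character_,
            status = NA_character_, cds = NA_character_,
            stringsAsFactors = FALSE)
        }
        seq_parts <- c(seq_parts, p$seq)
      }
      offs <- e
    }
    contig <- stats::setNames(paste(seq_parts, collapse = ""), ctg)
    genotype_assembly(geno, contig,
                      if (length(rows)) do.call(rbind, rows)
                      else empty_features())
  }
  asm_a <- build_assembly(lin$A)
  asm_b <- build_assembly(lin$B)

  ## absolute coordinates for planted segdups
  part_offset <- function(lr, part_id) {
    offs <- 0L
    for (p in lr$parts) {
      if (p$id == part_id) return(offs)
      offs <- offs + nchar(p$seq)
    }
    NA_integer_
  }
  for (k in seq_along(ledger$segdups)) {
    sd <- ledger$segdups[[k]]
    lr <- if (sd$genotype == genoA) lin$A else lin$B
    doff <- part_offset(lr, sd$donor_part)
    roff <- part_offset(lr, sd$recipient_part)
    ledger$segdups[[k]]$donor_span <- c(doff + sd$donor_offset - 1L,
                                        doff + sd$donor_offset - 1L +
                                          sd$length)
    ledger$segdups[[k]]$copy_span <- roff + sd$tract_offset
    for (j in c("X", "Y"))
      ledger$segdups[[k]]$junctions[[j]]$position_abs <-
        roff + sd$junctions[[j]]$position
  }
  ledger$config <- list(seed = cfg$seed, anchor_ks_mean = cfg$anchor_ks_mean,
                        anchor_targets = as.list(anchor_targets),
                        genotype_ids = cfg$genotype_ids)

  structure(list(assembly_a = asm_a, assembly_b = asm_b, ledger = ledger,
                 satellite_profile = stats::setNames(monomer, "monomer"),
                 ltr_library = stats::setNames(ltr_exemplar, "ltr_exemplar"),
                 config = cfg),
            class = "locus_pair_sim")
}

#' Write a simulated locus pair to disk
#'
#' Emits per-genotype FASTA + GFF3 (consumed unchanged by
#' [read_annotated_assembly()]), the satellite monomer and LTR exemplar
#' FASTAs, and the ground-truth ledger as JSON.
#'
#' @param sim A `locus_pair_sim` from [generate_locus_pair()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_locus_pair <- function(sim, out_dir) {
  stopifnot(inherits(sim, "locus_pair_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sim$config$genotype_ids
  paths <- c()
  for (side in c("a", "b")) {
    asm <- sim[[paste0("assembly_", side)]]
    fa <- file.path(out_dir, paste0(asm$genotype_id, ".fasta"))
    gf <- file.path(out_dir, paste0(asm$genotype_id, ".gff3"))
    write_genotype_assembly(asm, fa, gf)
    paths <- c(paths, stats::setNames(c(fa, gf),
                                      paste0(asm$genotype_id,
                                             c("_fasta", "_gff3"))))
  }
  sat <- file.path(out_dir, "satellite_monomer.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$satellite_profile), sat)
  ltr <- file.path(out_dir, "ltr_library.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$ltr_library), ltr)
  led <- file.path(out_dir, "ledger.json")
  jsonlite::write_json(sim$ledger, led, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, satellite = sat, ltr_library = ltr, ledger = led)
  invisible(paths)
}
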