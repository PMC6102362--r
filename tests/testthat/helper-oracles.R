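## Independent oracles the implementation is checked against.  These are
## deliberately written as direct enumerations, sharing no code with the
## package internals.

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

## brute-force NG86 site and difference counts for paired codon vectors
oracle_ng86 <- function(codons_a, codons_b) {
  aa_of <- function(codon) unname(.oracle_gc[codon])
  is_stop <- function(codon) aa_of(codon) == "*"

  syn_sites_of <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (nb in .oracle_bases) {
        if (substr(codon, pos, pos) == nb) next
        alt <- codon
        substr(alt, pos, pos) <- nb
        if (!is_stop(alt) && aa_of(alt) == aa_of(codon)) s <- s + 1 / 3
      }
    }
    s
  }

  ## enumerate every ordering of the differing positions recursively
  paths <- function(cur, target, remaining) {
    if (length(remaining) == 0) return(list(list(syn = 0, non = 0, ok = TRUE)))
    out <- list()
    for (k in seq_along(remaining)) {
      p <- remaining[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      blocked <- is_stop(nxt) && length(remaining) > 1
      step_syn <- !blocked && aa_of(cur) == aa_of(nxt)
      rest <- paths(nxt, target, remaining[-k])
      for (r in rest) {
        out[[length(out) + 1]] <- list(
          syn = r$syn + as.integer(!blocked && step_syn),
          non = r$non + as.integer(!blocked && !step_syn),
          ok = r$ok && !blocked)
      }
    }
    out
  }

  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    ca <- codons_a[i]
    cb <- codons_b[i]
    if (is_stop(ca) || is_stop(cb)) next
    S <- S + (syn_sites_of(ca) + syn_sites_of(cb)) / 2
    N <- N + (3 - syn_sites_of(ca) + 3 - syn_sites_of(cb)) / 2
    dpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(dpos) == 0) next
    pl <- paths(ca, cb, dpos)
    valid <- Filter(function(p) p$ok, pl)
    if (length(valid) > 0) {
      Sd <- Sd + mean(vapply(valid, `[[`, 0, "syn"))
      Nd <- Nd + mean(vapply(valid, `[[`, 0, "non"))
    } else {
      Nd <- Nd + length(dpos)  # all pathways stop-blocked
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

## simple Needleman-Wunsch protein aligner (linear gap penalty variant used
## only on tiny cases, as an independent back-mapping check)
oracle_protein_nw <- function(pa, pb, gap = -8) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(pb, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n)
  M[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m)
    M[i + 1, j + 1] <- max(M[i, j] + B[a[i], b[j]],
                           M[i, j + 1] + gap, M[i + 1, j] + gap)
  ## traceback
  i <- n; j <- m; cols <- list()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && M[i + 1, j + 1] == M[i, j] + B[a[i], b[j]]) {
      cols[[length(cols) + 1]] <- c(a[i], b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && M[i + 1, j + 1] == M[i, j + 1] + gap) {
      cols[[length(cols) + 1]] <- c(a[i], "-"); i <- i - 1
    } else {
      cols[[length(cols) + 1]] <- c("-", b[j]); j <- j - 1
    }
  }
  do.call(rbind, rev(cols))
}

## exhaustive flank-scan junction oracle: evaluates every candidate split
## point directly and measures microhomology by explicit outward scanning
oracle_junction <- function(hybrid, donor, recipient, tract, donor_tract,
                            side, radius = 350L) {
  H <- strsplit(hybrid, "")[[1]]
  D <- strsplit(donor, "")[[1]]
  R <- strsplit(recipient, "")[[1]]
  L <- tract[2] - tract[1]
  oD <- donor_tract[1] - tract[1]
  oR <- if (side == "X") 0L else -L
  center <- if (side == "X") tract[1] else tract[2]
  cand <- max(1L, center - radius):min(length(H), center + radius)
  okR <- cand + oR >= 1 & cand + oR <= length(R)
  okD <- cand + oD >= 1 & cand + oD <= length(D)
  cand <- cand[okR & okD]
  mR <- H[cand] == R[cand + oR]
  mD <- H[cand] == D[cand + oD]
  score <- vapply(seq_along(cand), function(k) {
    left <- seq_along(cand) <= k
    if (side == "X") sum(mR[left]) + sum(mD[!left])
    else sum(mD[left]) + sum(mR[!left])
  }, numeric(1))
  best_k <- which.max(score)
  pos <- cand[best_k]
  agree <- R[cand + oR] == D[cand + oD]
  m <- 0L
  k <- best_k
  while (k >= 1 && agree[k]) { m <- m + 1L; k <- k - 1L }
  k <- best_k + 1L
  while (k <= length(cand) && agree[k]) { m <- m + 1L; k <- k + 1L }
  list(position = pos, m = m)
}

random_codons <- function(n, include_multi_hit = TRUE) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  a <- sample(sense, n, replace = TRUE)
  b <- vapply(a, function(cod) {
    k <- sample(0:3, 1)
    if (k == 0 || !include_multi_hit && k > 1) return(cod)
    pos <- sample(1:3, k)
    for (p in pos) {
      alt <- sample(setdiff(.oracle_bases, substr(cod, p, p)), 1)
      substr(cod, p, p) <- alt
    }
    cod
  }, "", USE.NAMES = FALSE)
  ## keep sense codons only (the estimator excludes stop columns)
  keep <- .oracle_gc[b] != "*"
  list(a = a[keep], b = b[keep])
}
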