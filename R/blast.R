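## Thin wrapper around the NCBI BLAST+ blastn binary, the field-standard
## engine for the homology searches this package performs (satellite and
## LTR annotation, segmental-duplication detection).

blastn_available <- function() nzchar(Sys.which("blastn"))

#' Run blastn between two in-memory sequence sets
#'
#' @param query,subject Named character vectors of nucleotide sequences.
#' @param task blastn task (`"blastn"` allows diverged, short-word matches;
#'   `"megablast"` is faster for near-identical sequences).
#' @param evalue E-value cutoff.
#' @param dust Low-complexity filtering; disabled by default because
#'   satellite arrays are intentionally repetitive.
#' @return Data frame of hits: `qid`, `sid`, `pident` (fraction), `length`,
#'   `qstart`, `qend`, `sstart`, `send` (1-based, `sstart <= send`),
#'   `strand`, `bitscore`.  Zero-row frame when nothing matches.
#' @keywords internal
blastn_hits <- function(query, subject, task = "blastn", evalue = 1e-5,
                        dust = FALSE) {
  if (!blastn_available())
    stop("blastn not found on PATH; NCBI BLAST+ is required for this step")
  qf <- tempfile(fileext = ".fa")
  sf <- tempfile(fileext = ".fa")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(query), qf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(subject), sf)
  fmt <- "6 qseqid sseqid pident length qstart qend sstart send bitscore"
  args <- c("-task", task, "-query", qf, "-subject", sf,
            "-evalue", format(evalue, scientific = TRUE),
            "-outfmt", shQuote(fmt))
  if (!dust) args <- c(args, "-dust", "no", "-soft_masking", "false")
  out <- suppressWarnings(system2("blastn", args, stdout = TRUE, stderr = FALSE))
  empty <- data.frame(qid = character(0), sid = character(0),
                      pident = numeric(0), length = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), bitscore = numeric(0))
  if (length(out) == 0) return(empty)
  con <- textConnection(out)
  on.exit(close(con), add = TRUE)
  df <- utils::read.table(con, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("qid", "sid", "pident", "length",
                                        "qstart", "qend", "sstart", "send",
                                        "bitscore"))
  df$strand <- ifelse(df$sstart <= df$send, "+", "-")
  flip <- df$strand == "-"
  tmp <- df$sstart[flip]
  df$sstart[flip] <- df$send[flip]
  df$send[flip] <- tmp
  df$pident <- df$pident / 100
  df[, c("qid", "sid", "pident", "length", "qstart", "qend",
         "sstart", "send", "strand", "bitscore")]
}

## Keep the best-scoring of mutually overlapping subject intervals
## (overlap fraction relative to the shorter interval).
.prune_overlaps <- function(df, max_overlap = 0.5) {
  if (nrow(df) < 2) return(df)
  ord <- order(-df$bitscore)
  keep <- logical(nrow(df))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (df$sid[i] != df$sid[j]) next
      ov <- min(df$send[i], df$send[j]) - max(df$sstart[i], df$sstart[j]) + 1
      if (ov > max_overlap * min(df$send[i] - df$sstart[i] + 1,
                                 df$send[j] - df$sstart[j] + 1)) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}
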