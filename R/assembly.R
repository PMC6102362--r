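## Genotype assembly container: contig sequences plus typed features.
## Internal coordinates are 0-based half-open; all file IO is 1-based
## inclusive per the GFF3 specification.

.feature_columns <- c("feature_id", "type", "contig_id", "start", "end",
                      "strand", "gene_class", "subfamily", "status", "cds")

empty_features <- function() {
  data.frame(feature_id = character(0), type = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), gene_class = character(0),
             subfamily = character(0), status = character(0),
             cds = character(0), stringsAsFactors = FALSE)
}

#' Construct a validated genotype assembly
#'
#' One genotype's view of the locus: contig sequences plus gene and repeat
#' features anchored on them.
#'
#' @param genotype_id Genotype label (e.g. `"G19833"`).
#' @param contigs Named character vector of contig nucleotide sequences.
#' @param features Data frame with columns `feature_id`, `type`
#'   (`"gene"` or a repeat type), `contig_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `gene_class` (`CNL`, `TNL`,
#'   `low_copy`, `other`), `subfamily` (`CNL1`, `CNL3_4`, `TNL7`, `none`),
#'   `status` (`intact`, `pseudogene`, `segment`) and `cds` (spliced,
#'   strand-resolved coding sequence; `NA` for repeats).
#' @return An object of class `genotype_assembly`.
#' @export
genotype_assembly <- function(genotype_id, contigs, features = empty_features()) {
  stopifnot(is.character(genotype_id), length(genotype_id) == 1L,
            is.character(contigs), !is.null(names(contigs)))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  missing <- setdiff(.feature_columns, names(features))
  for (m in missing) features[[m]] <- rep(NA_character_, nrow(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features <- features[, .feature_columns]
  obj <- structure(list(genotype_id = genotype_id, contigs = contigs,
                        features = features),
                   class = "genotype_assembly")
  validate_genotype_assembly(obj)
}

#' @rdname genotype_assembly
#' @param x A `genotype_assembly`.
#' @export
validate_genotype_assembly <- function(x) {
  stopifnot(inherits(x, "genotype_assembly"))
  ft <- x$features
  if (nrow(ft) == 0) return(invisible(x))
  if (anyDuplicated(ft$feature_id))
    stop("genotype_assembly: duplicated feature ids in genotype '",
         x$genotype_id, "'")
  unknown <- setdiff(unique(ft$contig_id), names(x$contigs))
  if (length(unknown))
    stop("genotype_assembly: features reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  if (!all(ft$strand %in% c("+", "-")))
    stop("genotype_assembly: strands must be '+' or '-'")
  clen <- nchar(x$contigs)[ft$contig_id]
  bad <- ft$start < 0L | ft$end > clen | ft$start >= ft$end
  if (any(bad))
    stop("genotype_assembly: feature(s) outside contig bounds: ",
         paste(ft$feature_id[bad], collapse = ", "))
  genes <- ft[ft$type == "gene", ]
  if (any(is.na(genes$cds)) || any(nchar(genes$cds) == 0))
    stop("genotype_assembly: every gene needs a non-empty cds")
  invisible(x)
}

#' @export
print.genotype_assembly <- function(x, ...) {
  cat("genotype_assembly '", x$genotype_id, "': ", length(x$contigs),
      " contig(s), ", sum(nchar(x$contigs)), " bp, ",
      nrow(x$features), " feature(s) (",
      sum(x$features$type == "gene"), " genes)\n", sep = "")
  invisible(x)
}

#' Gene features of an assembly
#'
#' @param assembly A `genotype_assembly`.
#' @param gene_class Optional filter on gene class.
#' @return The gene rows of the feature table.
#' @export
assembly_genes <- function(assembly, gene_class = NULL) {
  g <- assembly$features[assembly$features$type == "gene", , drop = FALSE]
  if (!is.null(gene_class)) g <- g[g$gene_class %in% gene_class, , drop = FALSE]
  g
}

#' Extract a strand-resolved subsequence from a contig
#'
#' @param assembly A `genotype_assembly`.
#' @param contig_id Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"` (minus returns the reverse complement).
#' @return Character scalar.
#' @export
contig_slice <- function(assembly, contig_id, start, end, strand = "+") {
  seq <- substr(assembly$contigs[[contig_id]], start + 1L, end)
  if (strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}
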