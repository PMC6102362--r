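## FASTA/GFF3 input and output for annotated genotype assemblies.

.default_class_map <- c(gene_class = "gene_class", subfamily = "subfamily")

#' Read an annotated genotype assembly from FASTA + GFF3
#'
#' Loads contig sequences and the typed features describing them.  Gene rows
#' (GFF3 type `gene`) carry their class and subfamily in attributes named by
#' `class_map`; the coding sequence is taken from `CDS` child rows when
#' present (spliced in genomic order, strand-resolved), otherwise from the
#' gene span itself.  Gene status (intact / pseudogene / segment) is derived
#' from the CDS with [classify_gene_status()].  GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param fasta_path Path to the contig FASTA.
#' @param gff3_path Path to the GFF3 annotation; must reference the same
#'   contig ids as the FASTA.
#' @param genotype_id Label for the genotype; defaults to the FASTA
#'   basename.
#' @param class_map Named character vector mapping the fields `gene_class`
#'   and `subfamily` to the GFF3 attribute names that carry them.
#' @return A validated [genotype_assembly()].
#' @export
read_annotated_assembly <- function(fasta_path, gff3_path,
                                    genotype_id = NULL,
                                    class_map = .default_class_map) {
  if (is.null(genotype_id))
    genotype_id <- tools::file_path_sans_ext(basename(fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(as.character(seqs),
                             sub("\\s.*$", "", names(seqs)))
  gr <- rtracklayer::import(gff3_path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  unknown <- setdiff(unique(df$seqnames), names(contigs))
  if (length(unknown))
    stop("read_annotated_assembly: GFF3 references contig(s) absent from FASTA: ",
         paste(unknown, collapse = ", "))
  over <- df$end > nchar(contigs)[df$seqnames]
  if (any(over))
    stop("read_annotated_assembly: feature(s) extend beyond contig end: ",
         paste(utils::head(df$ID[over]), collapse = ", "))
  df$strand[!df$strand %in% c("+", "-")] <- "+"

  is_cds <- df$type == "CDS"
  cds_rows <- df[is_cds, , drop = FALSE]
  main <- df[!is_cds, , drop = FALSE]
  if (nrow(main) == 0)
    return(genotype_assembly(genotype_id, contigs))

  attr_or_na <- function(rows, name) {
    if (name %in% names(rows)) as.character(rows[[name]])
    else rep(NA_character_, nrow(rows))
  }
  feature_id <- attr_or_na(main, "ID")
  if (anyNA(feature_id))
    feature_id[is.na(feature_id)] <-
      sprintf("%s_f%04d", main$type[is.na(feature_id)], which(is.na(feature_id)))

  asm <- list(contigs = contigs)  # minimal stand-in for contig_slice
  class(asm) <- "genotype_assembly"
  splice_cds <- function(gene_id, row) {
    kids <- if (nrow(cds_rows) && "Parent" %in% names(cds_rows))
      cds_rows[vapply(cds_rows$Parent, function(p) gene_id %in% unlist(p),
                      logical(1)), , drop = FALSE]
    else cds_rows[0, , drop = FALSE]
    if (nrow(kids) == 0)
      return(contig_slice(asm, row$seqnames, row$start - 1L, row$end,
                          row$strand))
    kids <- kids[order(kids$start), , drop = FALSE]
    joined <- paste(substring(contigs[[row$seqnames]], kids$start, kids$end),
                    collapse = "")
    if (row$strand == "-")
      joined <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(joined)))
    joined
  }
  cds <- rep(NA_character_, nrow(main))
  is_gene <- main$type == "gene"
  for (i in which(is_gene))
    cds[i] <- splice_cds(feature_id[i], main[i, , drop = FALSE])

  features <- data.frame(
    feature_id = feature_id,
    type = main$type,
    contig_id = main$seqnames,
    start = main$start - 1L,
    end = main$end,
    strand = main$strand,
    gene_class = attr_or_na(main, class_map[["gene_class"]]),
    subfamily = attr_or_na(main, class_map[["subfamily"]]),
    status = NA_character_,
    cds = cds,
    stringsAsFactors = FALSE)
  features$status[is_gene] <- classify_gene_status(features$cds[is_gene])
  features$gene_class[is_gene & is.na(features$gene_class)] <- "other"
  features$subfamily[is_gene & is.na(features$subfamily)] <- "none"
  genotype_assembly(genotype_id, contigs, features)
}

#' Write a genotype assembly as FASTA + GFF3
#'
#' Inverse of [read_annotated_assembly()]: internal 0-based half-open
#' intervals are written as GFF3 1-based inclusive coordinates, with
#' `gene_class`, `subfamily` and `status` as attributes.  Rows are ordered
#' by (contig, start, feature id) so repeated writes of the same assembly
#' are byte-identical.
#'
#' @param assembly A [genotype_assembly()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotype_assembly <- function(assembly, fasta_path, gff3_path) {
  stopifnot(inherits(assembly, "genotype_assembly"))
  seqs <- Biostrings::DNAStringSet(assembly$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path)
  ft <- assembly$features
  ft <- ft[order(ft$contig_id, ft$start, ft$feature_id), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = ft$contig_id,
    ranges = IRanges::IRanges(start = ft$start + 1L, end = ft$end),
    strand = ft$strand)
  gr$source <- "subtelscope"
  gr$type <- ft$type
  gr$ID <- ft$feature_id
  gr$gene_class <- ft$gene_class
  gr$subfamily <- ft$subfamily
  gr$status <- ft$status
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}
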