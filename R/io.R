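# Readers/writers for the package's external formats.

#' Write the genome as FASTA
#'
#' @param genome An `rrbs_genome`.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), path)
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path FASTA path.
#' @param genes Optional gene table to attach.
#' @return An `rrbs_genome`.
#' @export
read_genome_fasta <- function(path, genes = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(x)
  names(contigs) <- sub("\\s.*$", "", names(x))
  structure(list(contigs = contigs,
                 genes = if (is.null(genes)) data.table() else genes,
                 spec = NULL),
            class = "rrbs_genome")
}

#' Write genes as BED6
#'
#' BED's native 0-based half-open convention; name = gene_id, score =
#' expression count when supplied (raw counts, which may exceed BED's nominal
#' 0-1000 score range - a documented dialect), strand column used.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @param expression Optional expression table (`gene_id`, `count`).
#' @export
write_genes_bed <- function(genes, path, expression = NULL) {
  score <- if (is.null(expression)) 0L else
    expression$count[match(genes$gene_id, expression$gene_id)]
  bed <- data.table(chrom = genes$contig, chromStart = genes$start,
                    chromEnd = genes$end, name = genes$gene_id,
                    score = score, strand = genes$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 gene file written by [write_genes_bed()]
#'
#' @param path BED path.
#' @return Gene data.table with the derived `tss` column.
#' @export
read_genes_bed <- function(path) {
  bed <- fread(path, sep = "\t",
               col.names = c("chrom", "chromStart", "chromEnd", "name",
                             "score", "strand"))
  data.table(gene_id = bed$name, contig = bed$chrom, start = bed$chromStart,
             end = bed$chromEnd, strand = bed$strand,
             tss = ifelse(bed$strand == "-", bed$chromEnd - 1L, bed$chromStart))
}

#' Write the truth methylome as TSV (contig, pos, m)
#'
#' @param truth A `methylome_truth`.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  fwrite(truth$sites, path, sep = "\t")
  invisible(path)
}

#' Read a truth methylome TSV
#'
#' @param path Path written by [write_truth_tsv()].
#' @param active_genes Optional active-gene ids to attach.
#' @return A `methylome_truth`.
#' @export
read_truth_tsv <- function(path, active_genes = character(0)) {
  sites <- fread(path, sep = "\t")
  structure(list(sites = sites, active_genes = active_genes),
            class = "methylome_truth")
}

#' Write an expression table as TSV (gene_id, count, class)
#'
#' @param expression Expression data.table.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expression, path) {
  fwrite(expression, path, sep = "\t")
  invisible(path)
}

#' Write QC summary as JSON
#'
#' Records the non-CpG methylation percentage and site counts at the 10x and
#' 100x coverage thresholds.
#'
#' @param calls A `cpg_calls`.
#' @param path Output path.
#' @export
write_qc_json <- function(calls, path) {
  stopifnot(inherits(calls, "cpg_calls"))
  qc <- list(
    non_cpg_methylation_percent = calls$qc$non_cpg_methylation_percent,
    non_cpg_total = calls$qc$non_cpg_total,
    sites_min_cov_10 = nrow(filter_by_coverage(calls, 10L)),
    sites_min_cov_100 = nrow(filter_by_coverage(calls, 100L)))
  jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
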