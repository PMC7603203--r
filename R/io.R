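# File-format plumbing: FASTA via Biostrings, InterProScan-style domain
# TSV, and GFF3 gene features via rtracklayer.

#' Read and write protein FASTA
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param proteins Named character vector (or `AAStringSet`).
#' @export
write_fasta <- function(proteins, path) {
  if (!is(proteins, "AAStringSet")) {
    proteins <- Biostrings::AAStringSet(unlist(proteins))
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' Read and write domain annotations
#'
#' InterProScan-style tab-separated annotations, no header, columns:
#' `protein_id`, `source_db`, `accession`, `start`, `end`, `description`.
#' Coordinates are 1-based inclusive.
#'
#' @param path TSV file path.
#' @return `read_domains()` returns a data frame with the columns above.
#' @export
read_domains <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("protein_id", "source_db", "accession",
                                 "start", "end", "description"),
                   quote = "")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_domains
#' @param domains Domain annotation data frame.
#' @export
write_domains <- function(domains, path) {
  cols <- c("protein_id", "source_db", "accession", "start", "end",
            "description")
  stopifnot(all(cols %in% names(domains)))
  write.table(domains[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 file and returns its `gene` features as a plain table.
#' Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene_", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene features to GFF3
#'
#' @param features Data frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff_genes <- function(features, path, source = "tpsinv") {
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- features$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
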