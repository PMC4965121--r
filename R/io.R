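# File-format plumbing. Standard formats go through Biostrings (FASTA/FASTQ)
# and rtracklayer (GFF3); collapsed tags use the ">t000001_x5" count-header
# FASTA dialect common to sRNA pipelines; truth sidecars and summary tables
# are plain TSV.

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `quality` (constant "I", Phred 40, when absent).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read or write collapsed tags as count-header FASTA
#'
#' Headers use the `>t000001_x5` dialect (tag id, `_x`, redundant count).
#'
#' @param tags data.frame from [collapse_tags()].
#' @param path file path.
#' @return `read_tag_fasta()` returns the tags data.frame.
#' @export
write_tag_fasta <- function(tags, path) {
  writeLines(paste0(">", tags$tag_id, "_x", tags$count, "\n", tags$sequence), path)
  invisible(path)
}

#' @rdname write_tag_fasta
#' @export
read_tag_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(x), regexec("^(\\S+)_x(\\d+)$", names(x)))
  if (any(lengths(m) != 3L)) stop("tag FASTA headers must look like 'id_xCOUNT'")
  out <- data.frame(tag_id = vapply(m, `[`, character(1), 2L),
                    sequence = unname(as.character(x)),
                    count = as.integer(vapply(m, `[`, character(1), 3L)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write genome scaffolds or transcripts as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read or write feature annotations as GFF3
#'
#' Annotations are GRanges with a `type` column (rRNA, tRNA, snRNA, snoRNA,
#' exon, intron, repeat), 1-based inclusive coordinates.
#'
#' @param gr GRanges of features.
#' @param path GFF3 path.
#' @export
write_gff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write a data.frame as a TSV file
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#'
#' @param path TSV path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
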