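# External interfaces: FASTA/FASTQ via Biostrings, tab-separated tables
# with one-line headers for libraries, counts, trajectories, enrichment
# records, motif matches, and fluorescence samples.

#' Write reads as FASTA or FASTQ
#'
#' FASTQ records carry a constant Q30 quality placeholder; the analysis
#' never consumes qualities.
#'
#' @param reads Character vector of reads (e.g. from [gen_reads()]).
#' @param path Output file path; format chosen by `format`.
#' @param format `"fastq"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(as.character(reads))
  names(x) <- sprintf("read_%06d", seq_along(reads))
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(strrep("?", nchar(reads))) # Q30
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path Input file; `.fastq`/`.fq` extensions are read as FASTQ,
#'   anything else as FASTA.
#' @return Character vector of sequences, named by record id.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq"
              else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read promoters from FASTA
#'
#' Record ids become promoter (gene) names.
#'
#' @param path FASTA file of promoter sequences.
#' @return Named character vector.
#' @export
read_promoters <- function(path) read_sequences(path, format = "fasta")

#' Write promoters to FASTA
#'
#' @param promoters Named character vector of promoter sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(unlist(as_named_sequences(promoters, "promoters")))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant library as tab-separated text
#' @param library A `selseq_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) write_tsv(library, path)

#' Write a count table as tab-separated text
#'
#' Columns: sequence, count, frequency; header lines are ordinary columns
#' repeated per row is avoided — metadata goes in the file name chosen by
#' the caller.
#'
#' @param table A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  counts <- as_counts(table, "table")
  write_tsv(data.frame(sequence = names(counts), count = as.double(counts),
                       frequency = as.double(counts) / sum(counts),
                       stringsAsFactors = FALSE), path)
}

#' Write a selection trajectory in long format
#'
#' One row per (time point, variant) with a positive count.
#'
#' @param trajectory A `selection_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  rows <- lapply(seq_along(trajectory), function(t) {
    pop <- trajectory[[t]]
    keep <- pop$counts > 0
    data.frame(time_point = t - 1L, sequence = names(pop$counts)[keep],
               count = as.double(pop$counts[keep]), strain = pop$strain,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Write a per-cell fluorescence sample as tab-separated text
#' @param sample A `fluorescence_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluorescence <- function(sample, path) {
  write_tsv(data.frame(condition = sample$condition,
                       fluorescence = sample$values,
                       background_mean = sample$background_mean,
                       stringsAsFactors = FALSE), path)
}
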