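# File interfaces: FASTA/FASTQ via Biostrings, plain TSV tables, minimal
# SAM emission of transposon hits.

#' Read raw small-RNA reads from FASTQ or FASTA
#'
#' The format is inferred from the file extension (`.fastq`/`.fq` versus
#' `.fasta`/`.fa`/`.fna`). Sequences are uppercased.
#'
#' @param path Path to the reads file.
#' @return A tibble with columns `id`, `sequence`, `quality` (`NA` for
#'   FASTA input).
#' @export
read_raw_reads <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("fastq", "fq")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- NA_character_
  }
  tibble::tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = unname(toupper(as.character(x))),
    quality = unname(qual)
  )
}

#' Read genome and transposon references from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` suitable for
#'   [build_index()].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble::tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = unname(toupper(as.character(x)))
  )
}

#' Write a simulated library and its ground truth to disk
#'
#' Writes the raw reads as FASTQ (constant placeholder qualities, Phred+33)
#' and the ground truth as a TSV with columns `read_id`, `source`,
#' `strand`, `true_insert`, `adapter_start`.
#'
#' @param library A `pirna_library` from [simulate_library()].
#' @param fastq_path,truth_path Output paths (`truth_path = NULL` skips the
#'   ground-truth table).
#' @return `fastq_path`, invisibly.
#' @export
write_library_fastq <- function(library, fastq_path, truth_path = NULL) {
  stopifnot(inherits(library, "pirna_library"))
  x <- Biostrings::DNAStringSet(library$reads$sequence)
  names(x) <- library$reads$id
  q <- Biostrings::BStringSet(library$reads$quality)
  Biostrings::writeXStringSet(x, fastq_path, format = "fastq", qualities = q)
  if (!is.null(truth_path)) {
    write_tsv_plain(library$truth, truth_path)
  }
  invisible(fastq_path)
}

#' Write reference sequences to FASTA
#'
#' @param references A `pirna_references` object.
#' @param genome_path,transposons_path Output FASTA paths.
#' @return Invisibly, the two paths.
#' @export
write_references_fasta <- function(references, genome_path,
                                   transposons_path) {
  stopifnot(inherits(references, "pirna_references"))
  g <- Biostrings::DNAStringSet(references$genome)
  names(g) <- "genome"
  Biostrings::writeXStringSet(g, genome_path, format = "fasta")
  t <- Biostrings::DNAStringSet(references$transposons$sequence)
  names(t) <- references$transposons$id
  Biostrings::writeXStringSet(t, transposons_path, format = "fasta")
  invisible(c(genome_path, transposons_path))
}

#' Write trimmed inserts to FASTA
#'
#' @param trimmed Trimmed-read tibble (`id`, `insert`) or a `trim_result`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_inserts_fasta <- function(trimmed, path) {
  if (inherits(trimmed, "trim_result")) trimmed <- trimmed$trimmed
  x <- Biostrings::DNAStringSet(trimmed$insert)
  names(x) <- trimmed$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write transposon hits as SAM
#'
#' Emits a minimal, valid SAM file: `@SQ` header lines per reference, flag
#' 0/16 for plus/minus strand, full-length match CIGAR, `NM:i:0` (the
#' mapper is zero-mismatch). The SEQ column carries the reference-oriented
#' sequence, per SAM convention.
#'
#' @param hits Hit tibble from [map_library()].
#' @param trimmed Trimmed-read tibble providing each read's insert.
#' @param references Reference set used for mapping (tibble or named
#'   character vector), for `@SQ` lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_hits_sam <- function(hits, trimmed, references, path) {
  if (inherits(trimmed, "trim_result")) trimmed <- trimmed$trimmed
  seqs <- reference_vector(references)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)), con)
  if (nrow(hits) > 0) {
    insert <- trimmed$insert[match(hits$read_id, trimmed$id)]
    seq_out <- ifelse(hits$strand == "-", revcomp(insert), insert)
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:0",
      hits$read_id, ifelse(hits$strand == "-", 16L, 0L), hits$reference_id,
      hits$start + 1L, nchar(seq_out), seq_out
    ), con)
  }
  invisible(path)
}

# deterministic TSV writer used for all tabular artifacts
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = NA))
}
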