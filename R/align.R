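# Zero-mismatch, strand-aware mapping of 23-30 nt inserts.
#
# References are indexed by their forward-strand k-mers (k = 23, the minimum
# query length); a query is looked up by its first k-mer (and by the first
# k-mer of its reverse complement for minus-strand hits) and every candidate
# site is verified over the full query length. This reports ALL perfect
# hits, on both strands, across all references. Coordinates are 0-based,
# half-open, in reference coordinates regardless of strand.

#' Build an exact k-mer index over a reference set
#'
#' Stores every forward-strand `key_length`-mer of every reference together
#' with its origin; windows containing `N` are skipped. Reverse-complement
#' matching is handled at query time, so the index holds forward windows
#' only.
#'
#' @param references A tibble with columns `id` and `sequence`, a named
#'   character vector, or a `pirna_references` component (e.g.
#'   `refs$transposons`).
#' @param key_length k-mer length, at most the shortest query (default 23,
#'   the minimum piRNA length).
#' @return An object of class `exact_index`.
#' @export
#' @examples
#' idx <- build_index(c(chr1 = "ACGTACGTACGTACGTACGTACGTACGT"))
#' idx
build_index <- function(references, key_length = 23L) {
  key_length <- as.integer(key_length)
  if (is.na(key_length) || key_length < 1L || key_length > 30L) {
    stop("key_length must lie in 1..30", call. = FALSE)
  }
  seqs <- reference_vector(references)
  assert_dna(seqs, "reference sequences")

  per_ref <- purrr::map2(names(seqs), unname(seqs), function(id, s) {
    L <- nchar(s)
    if (L < key_length) {
      return(tibble::tibble(kmer = character(0), reference_id = character(0),
                            start0 = integer(0)))
    }
    starts <- seq_len(L - key_length + 1L)
    kmers <- substring(s, starts, starts + key_length - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    tibble::tibble(kmer = kmers[keep], reference_id = id,
                   start0 = starts[keep] - 1L)
  })
  structure(
    list(
      kmers = dplyr::bind_rows(per_ref),
      key_length = key_length,
      references = seqs
    ),
    class = "exact_index"
  )
}

#' @export
print.exact_index <- function(x, ...) {
  cat(sprintf("<exact_index> %d references, %d stored %d-mers\n",
              length(x$references), nrow(x$kmers), x$key_length))
  invisible(x)
}

# normalise the accepted reference representations to a named character
# vector
reference_vector <- function(references) {
  if (inherits(references, "pirna_references")) {
    stop(paste("pass a single reference set, e.g. references$transposons or",
               "c(genome = references$genome)"), call. = FALSE)
  }
  if (is.data.frame(references)) {
    stopifnot(all(c("id", "sequence") %in% names(references)))
    seqs <- references$sequence
    names(seqs) <- references$id
  } else {
    seqs <- references
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("references must carry unique ids/names", call. = FALSE)
    }
  }
  if (anyDuplicated(names(seqs))) {
    stop("reference ids must be unique", call. = FALSE)
  }
  seqs
}

#' Map inserts to a reference set with zero mismatches
#'
#' Returns every position, on both strands of every reference, at which a
#' query matches exactly. A minus-strand hit means the insert equals the
#' reverse complement of the reference slice; its coordinates are reported
#' on the reference's forward strand, 0-based and half-open. Queries
#' containing `N` return no hits (an `N` can never match under a
#' no-mismatch policy).
#'
#' @param inserts Character vector of query sequences, each 23-30 nt (use
#'   `trimmed$insert` from [trim_and_filter()]).
#' @param index An [build_index()] result.
#' @param query_id Optional identifiers propagated to the output's
#'   `read_id` column (defaults to the element index).
#' @return A tibble with columns `read_id`, `reference_id`, `start`, `end`,
#'   `strand`, one row per hit.
#' @export
#' @examples
#' idx <- build_index(c(ref = "AAACCCGGGTTTAAACCCGGGTTTACGTACGT"))
#' map_exact(substr("AAACCCGGGTTTAAACCCGGGTTTACGTACGT", 2, 27), idx)
map_exact <- function(inserts, index, query_id = NULL) {
  stopifnot(inherits(index, "exact_index"))
  if (length(inserts) == 0L) return(empty_hits())
  inserts <- unname(inserts)
  assert_dna(inserts, "inserts")
  lens <- nchar(inserts)
  if (any(lens < 23L | lens > 30L)) {
    stop("inserts must be 23-30 nt long", call. = FALSE)
  }
  if (is.null(query_id)) query_id <- as.character(seq_along(inserts))

  k <- index$key_length
  refs <- index$references

  lookup <- function(queries, qidx) {
    # candidate sites from the index on the first k-mer, then full-length
    # verification against the reference slice
    q <- tibble::tibble(
      .q = qidx,
      kmer = substr(queries, 1L, k),
      qlen = nchar(queries),
      qseq = queries
    )
    cand <- dplyr::inner_join(q, index$kmers, by = "kmer",
                              relationship = "many-to-many")
    if (nrow(cand) == 0L) return(cand[0, ])
    ref_len <- nchar(refs)[match(cand$reference_id, names(refs))]
    cand <- cand[cand$start0 + cand$qlen <= ref_len, ]
    if (nrow(cand) == 0L) return(cand)
    slice <- substring(refs[cand$reference_id], cand$start0 + 1L,
                       cand$start0 + cand$qlen)
    cand[slice == cand$qseq, ]
  }

  has_n <- grepl("N", inserts, fixed = TRUE)
  qidx <- which(!has_n)
  fwd <- lookup(inserts[qidx], qidx)
  rcq <- revcomp(inserts[qidx])
  rev <- lookup(rcq, qidx)

  hits <- dplyr::bind_rows(
    tibble::tibble(
      read_id = query_id[fwd$.q], reference_id = fwd$reference_id,
      start = fwd$start0, end = fwd$start0 + fwd$qlen, strand = "+"
    ),
    tibble::tibble(
      read_id = query_id[rev$.q], reference_id = rev$reference_id,
      start = rev$start0, end = rev$start0 + rev$qlen, strand = "-"
    )
  )
  dplyr::arrange(hits, match(.data$read_id, query_id), .data$reference_id,
                 .data$start, .data$strand)
}

empty_hits <- function() {
  tibble::tibble(read_id = character(0), reference_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
}

#' Map a trimmed library to genome and transposon references
#'
#' Maps every insert, with zero mismatches, to the genome (recording only
#' whether each read has at least one perfect genome hit — the count of
#' such distinct reads is the sequencing-depth denominator for RPM
#' normalisation) and, independently, to the transposon set (recording all
#' hits). Identical insert sequences are collapsed before mapping and
#' re-expanded afterwards; results are identical to mapping each read
#' separately.
#'
#' @param trimmed Tibble of trimmed reads (`id`, `insert`), from
#'   [trim_and_filter()].
#' @param genome_index,transposon_index [build_index()] results for the
#'   genome and the transposon consensus set.
#' @return A list of class `map_result`:
#'   * `reads` — tibble (`id`, `insert`, `genome_mapped` flag);
#'   * `genome_mapped_total` — number of distinct reads with >= 1 perfect
#'     genome hit (a multi-mapping read counts once);
#'   * `hits` — tibble of all transposon hits (`read_id`, `reference_id`,
#'     `start`, `end`, `strand`).
#' @export
map_library <- function(trimmed, genome_index, transposon_index) {
  stopifnot(is.data.frame(trimmed),
            all(c("id", "insert") %in% names(trimmed)),
            inherits(genome_index, "exact_index"),
            inherits(transposon_index, "exact_index"))
  if (nrow(trimmed) == 0L) {
    return(structure(
      list(reads = tibble::tibble(id = character(0), insert = character(0),
                                  genome_mapped = logical(0)),
           genome_mapped_total = 0L, hits = empty_hits()),
      class = "map_result"
    ))
  }

  uniq <- unique(trimmed$insert)
  g_hits <- map_exact(uniq, genome_index, query_id = uniq)
  mapped_seq <- unique(g_hits$read_id)
  reads <- tibble::tibble(
    id = trimmed$id,
    insert = trimmed$insert,
    genome_mapped = trimmed$insert %in% mapped_seq
  )

  t_hits <- map_exact(uniq, transposon_index, query_id = uniq)
  # re-expand collapsed sequences to per-read hits
  expanded <- dplyr::inner_join(
    dplyr::select(reads, "id", "insert"),
    dplyr::rename(t_hits, insert = "read_id"),
    by = "insert", relationship = "many-to-many"
  )
  hits <- tibble::tibble(
    read_id = expanded$id,
    reference_id = expanded$reference_id,
    start = expanded$start,
    end = expanded$end,
    strand = expanded$strand
  )

  structure(
    list(reads = reads,
         genome_mapped_total = sum(reads$genome_mapped),
         hits = hits),
    class = "map_result"
  )
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf(
    "<map_result> %d reads, %d perfect genome-mappers, %d transposon hits on %d reads\n",
    nrow(x$reads), x$genome_mapped_total, nrow(x$hits),
    length(unique(x$hits$read_id))
  ))
  invisible(x)
}
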