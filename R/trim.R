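# 3' adapter identification and removal.
#
# The trimmer scans each read left to right for the leftmost position at
# which the read suffix matches a prefix of the adapter with at most
# `max_mismatches` mismatches, requiring at least `min_overlap` overlapping
# bases (so an adapter truncated by the cycle window is still found, while
# spurious 1-2 nt tail matches are not). N bases count as mismatches.

# Vectorised scan over a character vector; returns 0-based adapter start and
# mismatch count (NA/NA when no acceptable occurrence exists).
adapter_scan <- function(sequences, adapter, max_mismatches = 2L,
                         min_overlap = 6L) {
  n <- length(sequences)
  if (n == 0L) {
    return(list(adapter_start = integer(0), mismatches = integer(0)))
  }
  packed <- seq_byte_matrix(sequences)
  bytes <- packed$bytes
  widths <- packed$widths
  maxw <- nrow(bytes)
  a <- charToRaw(adapter)
  alen <- length(a)

  best_start <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  unresolved <- rep(TRUE, n)

  for (p in 0:(maxw - min_overlap)) {
    overlap <- min(alen, maxw - p)
    if (overlap < min_overlap) break
    idx <- which(unresolved & widths - p >= min_overlap)
    if (length(idx) == 0L) next
    block <- bytes[(p + 1L):(p + overlap), idx, drop = FALSE]
    raw_mm <- .colSums(block != a[seq_len(overlap)], overlap, length(idx))
    # padded positions beyond a read's end always miscompare; remove them
    pad <- pmax(0L, (p + overlap) - widths[idx])
    mm <- raw_mm - pad
    hit <- mm <= max_mismatches
    if (any(hit)) {
      found <- idx[hit]
      best_start[found] <- p
      best_mm[found] <- as.integer(mm[hit])
      unresolved[found] <- FALSE
    }
    if (!any(unresolved)) break
  }
  list(adapter_start = best_start, mismatches = best_mm)
}

#' Locate a 3' adapter in reads
#'
#' Finds, for each sequence, the leftmost 0-based position at which the
#' adapter (or an adapter prefix of at least `min_overlap` nt, when the
#' adapter runs off the end of the read) occurs with at most
#' `max_mismatches` substitutions. `N` bases count as mismatches. When
#' several positions qualify, the smallest wins (the shortest insert), the
#' standard adapter-trimming convention.
#'
#' @param sequences Character vector of read sequences (uppercase A/C/G/T/N).
#' @param adapter Adapter sequence (uppercase A/C/G/T), at least
#'   `min_overlap` nt.
#' @param max_mismatches Maximum substitutions tolerated in the overlap
#'   (default 2).
#' @param min_overlap Minimum read/adapter overlap in nt (default 6).
#' @return A tibble with one row per input sequence: `adapter_start`
#'   (0-based offset, NA if no occurrence) and `mismatches`.
#' @export
#' @examples
#' find_adapter("ACGTACGTACGTACGTACGTACGTATCGTATGCCGT", default_adapter())
find_adapter <- function(sequences, adapter, max_mismatches = 2L,
                         min_overlap = 6L) {
  if (length(sequences) == 0L) {
    return(tibble::tibble(adapter_start = integer(0),
                          mismatches = integer(0)))
  }
  assert_dna(sequences, "sequences")
  assert_dna(adapter, "adapter", allow_n = FALSE)
  if (length(adapter) != 1L || nchar(adapter) < min_overlap) {
    stop("adapter must be a single sequence of at least min_overlap nt",
         call. = FALSE)
  }
  stopifnot(max_mismatches >= 0, min_overlap >= 1)
  res <- adapter_scan(sequences, adapter, as.integer(max_mismatches),
                      as.integer(min_overlap))
  tibble::as_tibble(res)
}

#' Trim 3' adapters and keep 23-30 nt inserts
#'
#' Removes the 3' adapter from each read (tolerating up to `max_mismatches`
#' substitutions), discards reads without an adapter occurrence, and keeps
#' inserts whose length lies within `[min_len, max_len]` (both bounds
#' inclusive). Reads whose adapter sits at position 0 (an empty insert) are
#' counted as too short. Malformed records (empty or non-A/C/G/T/N
#' sequences) are counted and skipped with a warning.
#'
#' @param reads A data frame of raw reads with columns `id` and `sequence`
#'   (e.g. from [read_raw_reads()] or a [simulate_library()] result's
#'   `reads` element).
#' @param adapter 3' adapter sequence (default [default_adapter()]).
#' @param max_mismatches Maximum adapter mismatches (default 2).
#' @param min_len,max_len Inclusive insert length bounds (defaults 23 and
#'   30 nt, the piRNA size range).
#' @param min_overlap Minimum read/adapter overlap (default 6).
#' @return A list of class `trim_result`:
#'   * `trimmed` — tibble of kept reads (`id`, `insert`, `adapter_start`,
#'     `adapter_mismatches`);
#'   * `tallies` — tibble (`category`, `count`) over
#'     `kept`, `no_adapter`, `too_short`, `too_long`, `malformed`;
#'     the counts always sum to the number of input reads.
#' @export
#' @examples
#' refs <- generate_references(n_transposons = 2, length_range = c(300, 400),
#'                             genome_length = 4000, seed = 1)
#' models <- transposon_models(refs)
#' lib <- simulate_library(refs, models,
#'                         library_config(n_pirna_reads = 50,
#'                                        n_background_reads = 5,
#'                                        n_junk_reads = 5, seed = 2))
#' res <- trim_and_filter(lib$reads)
#' res$tallies
trim_and_filter <- function(reads,
                            adapter = default_adapter(),
                            max_mismatches = 2L,
                            min_len = 23L,
                            max_len = 30L,
                            min_overlap = 6L) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)),
            min_len >= 1, max_len >= min_len)
  n <- nrow(reads)
  seqs <- reads$sequence

  malformed <- is.na(seqs) | !grepl("^[ACGTN]+$", seqs)
  if (any(malformed)) {
    warning(sprintf("skipping %d malformed read record(s)", sum(malformed)),
            call. = FALSE)
  }
  valid <- which(!malformed)

  hit <- find_adapter(seqs[valid], adapter, max_mismatches, min_overlap)
  insert_len <- hit$adapter_start  # 0-based start == insert length
  kept_idx <- !is.na(insert_len) & insert_len >= min_len &
    insert_len <= max_len

  no_adapter <- sum(is.na(insert_len))
  too_short <- sum(!is.na(insert_len) & insert_len < min_len)
  too_long <- sum(!is.na(insert_len) & insert_len > max_len)

  kv <- valid[kept_idx]
  trimmed <- tibble::tibble(
    id = reads$id[kv],
    insert = substr(seqs[kv], 1L, insert_len[kept_idx]),
    adapter_start = as.integer(insert_len[kept_idx]),
    adapter_mismatches = hit$mismatches[kept_idx]
  )

  tallies <- tibble::tibble(
    category = c("kept", "no_adapter", "too_short", "too_long", "malformed"),
    count = c(nrow(trimmed), no_adapter, too_short, too_long, sum(malformed))
  )
  stopifnot(sum(tallies$count) == n)

  structure(list(trimmed = trimmed, tallies = tallies),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("<trim_result>\n")
  print(x$tallies)
  invisible(x)
}
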