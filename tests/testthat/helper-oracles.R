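# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately share no code with the implementation: plain character-level
# loops over every candidate position.

# Leftmost adapter occurrence by direct position-by-position mismatch
# counting; returns c(start0, mismatches) or NULL.
oracle_find_adapter <- function(seq, adapter, max_mm = 2, min_overlap = 6) {
  w <- nchar(seq)
  alen <- nchar(adapter)
  if (w < min_overlap) return(NULL)
  for (p in 0:(w - min_overlap)) {
    overlap <- min(alen, w - p)
    if (overlap < min_overlap) next
    s <- strsplit(substr(seq, p + 1, p + overlap), "")[[1]]
    a <- strsplit(substr(adapter, 1, overlap), "")[[1]]
    mm <- sum(s != a)
    if (mm <= max_mm) return(c(p, mm))
  }
  NULL
}

# All zero-mismatch hits of `insert` against named reference sequences,
# both strands, by exhaustive offset scan. Returns a data.frame
# (reference_id, start, end, strand), 0-based half-open.
oracle_map_exact <- function(insert, refs) {
  out <- list()
  len <- nchar(insert)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(insert))
  )
  for (id in names(refs)) {
    ref <- refs[[id]]
    L <- nchar(ref)
    if (L < len) next
    for (s0 in 0:(L - len)) {
      slice <- substr(ref, s0 + 1, s0 + len)
      if (slice == insert) {
        out[[length(out) + 1]] <- data.frame(
          reference_id = id, start = s0, end = s0 + len, strand = "+"
        )
      }
      if (slice == rc) {
        out[[length(out) + 1]] <- data.frame(
          reference_id = id, start = s0, end = s0 + len, strand = "-"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small reference set + models for fast end-to-end tests.
tiny_refs <- function(n_transposons = 4, seed = 11) {
  generate_references(
    n_transposons = n_transposons, length_range = c(300, 500),
    genome_length = 3000 + n_transposons * 600, seed = seed
  )
}

tiny_library <- function(refs, preset = "wt-ovary", n_pirna = 3000,
                         n_background = 300, n_junk = 60, seed = 5,
                         error_rate = 0, ...) {
  models <- transposon_models(refs, preset = preset, ...)
  cfg <- library_config(
    n_pirna_reads = n_pirna, n_background_reads = n_background,
    n_junk_reads = n_junk, error_rate = error_rate, seed = seed
  )
  simulate_library(refs, models, cfg)
}

profile_from_counts <- function(library_id, counts, genome_mapped_total) {
  structure(
    list(
      library_id = library_id,
      genome_mapped_total = genome_mapped_total,
      transposons = rpm_normalize(counts, genome_mapped_total),
      one_u_bias = NA_real_, one_u_bias_all_reads = NA_real_,
      antisense_bias = NA_real_
    ),
    class = "library_profile"
  )
}
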