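# Synthetic small-RNA library generator with per-read ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: 23-30 nt piRNA inserts drawn from transposon consensus sequences
# (with configurable per-transposon abundance, antisense fraction and 5'-U
# probability), genome-background inserts, adapterless junk reads, a ligated
# 3' adapter, a fixed sequencing cycle window, and optional per-base
# substitution errors. All randomness flows from one seeded R Mersenne-
# Twister stream, so identical inputs give byte-identical outputs.

#' Generate a transposon consensus set and a genome harbouring it
#'
#' Builds `n_transposons` random consensus sequences and a genome in which
#' each consensus is embedded verbatim (`n_transposon_copies_in_genome`
#' times), separated by random unique background sequence. Because every
#' copy is verbatim, every read derived from a consensus also maps perfectly
#' to the genome, which keeps the reads-per-million denominator (perfect
#' genome-mapping reads) well defined.
#'
#' @param n_transposons Number of consensus sequences (default 121, the size
#'   of a well-annotated transposon reference set for the silkworm).
#' @param length_range Length bounds (nt) for each consensus, sampled
#'   uniformly; consensus lengths of a few hundred to a few thousand nt are
#'   typical of transposable-element families.
#' @param genome_length Total genome length in nt. Must be large enough to
#'   host all copies plus at least 100 nt of background between and around
#'   them.
#' @param n_transposon_copies_in_genome Verbatim copies of each consensus
#'   embedded in the genome.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return An object of class `pirna_references`: a list with
#'   * `transposons` — tibble with `id` and `sequence`;
#'   * `genome` — a single genome sequence (character scalar);
#'   * `copies` — tibble of embedded copy coordinates (`transposon_id`,
#'     `start`, `end`, 1-based inclusive, forward strand);
#'   * `background` — tibble of genome intervals free of any copy, from
#'     which background reads are drawn.
#' @export
#' @examples
#' refs <- generate_references(n_transposons = 3, length_range = c(300, 400),
#'                             genome_length = 5000, seed = 1)
#' refs$transposons
generate_references <- function(n_transposons = 121,
                                length_range = c(800, 2000),
                                genome_length = 400000,
                                n_transposon_copies_in_genome = 1,
                                seed = 1) {
  stopifnot(n_transposons >= 1, n_transposon_copies_in_genome >= 1,
            length(length_range) == 2, length_range[1] >= 300,
            length_range[2] >= length_range[1])
  set.seed(as.integer(seed))

  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n_transposons,
               replace = TRUE)
  ids <- sprintf("TE%03d", seq_len(n_transposons))
  consensus <- random_dna(lens)

  n_copies <- n_transposons * n_transposon_copies_in_genome
  copy_of <- sample(rep(seq_len(n_transposons), n_transposon_copies_in_genome))
  min_spacer <- 100L
  copies_total <- sum(lens[copy_of])
  needed <- copies_total + (n_copies + 1L) * min_spacer
  if (genome_length < needed) {
    stop(sprintf(
      "genome_length = %d cannot host %d transposon copies (%d nt) plus %d nt of background; need at least %d",
      genome_length, n_copies, copies_total, (n_copies + 1L) * min_spacer,
      needed
    ), call. = FALSE)
  }

  extra <- genome_length - copies_total - (n_copies + 1L) * min_spacer
  spacer_len <- min_spacer +
    as.integer(stats::rmultinom(1, extra, rep(1, n_copies + 1L)))
  spacers <- random_dna(spacer_len)

  # interleave spacer, copy, spacer, copy, ..., spacer
  pieces <- character(2L * n_copies + 1L)
  pieces[seq(1L, 2L * n_copies + 1L, by = 2L)] <- spacers
  pieces[seq(2L, 2L * n_copies, by = 2L)] <- consensus[copy_of]
  genome <- paste(pieces, collapse = "")

  piece_len <- nchar(pieces)
  piece_end <- cumsum(piece_len)
  piece_start <- piece_end - piece_len + 1L
  copy_idx <- seq(2L, 2L * n_copies, by = 2L)
  spacer_idx <- seq(1L, 2L * n_copies + 1L, by = 2L)

  structure(
    list(
      transposons = tibble::tibble(id = ids, sequence = consensus),
      genome = genome,
      copies = tibble::tibble(
        transposon_id = ids[copy_of],
        start = piece_start[copy_idx],
        end = piece_end[copy_idx]
      ),
      background = tibble::tibble(
        start = piece_start[spacer_idx],
        end = piece_end[spacer_idx]
      ),
      seed = as.integer(seed)
    ),
    class = "pirna_references"
  )
}

#' @export
print.pirna_references <- function(x, ...) {
  cat(sprintf(
    "<pirna_references> %d transposons (%d-%d nt), genome %d nt, %d embedded copies\n",
    nrow(x$transposons), min(nchar(x$transposons$sequence)),
    max(nchar(x$transposons$sequence)), nchar(x$genome), nrow(x$copies)
  ))
  invisible(x)
}

#' Attach generative parameters to a transposon reference set
#'
#' Builds the per-transposon generative model used by
#' [simulate_library()]: an abundance weight plus the library-wide antisense
#' fraction and 5'-U probability taken from a preset (see
#' [pirna_presets()]) or supplied directly. Default abundance weights follow
#' a Zipf-like power law over the id order (weight of the i-th transposon
#' proportional to `i^-zipf_exponent`), emulating the heavy-tailed abundance
#' spectrum of transposon piRNAs, under which only the more abundant
#' families clear a fixed RPM threshold.
#'
#' @param references A `pirna_references` object (or a tibble with an `id`
#'   column).
#' @param preset One of `"wt-ovary"`, `"kg-ovary"`; ignored for fields
#'   overridden below.
#' @param abundance_weights Optional numeric vector (recycled or named by
#'   transposon id) overriding the Zipf weights.
#' @param zipf_exponent Power-law exponent for the default weights.
#' @param antisense_fraction,u_probability Optional scalar overrides of the
#'   preset values.
#' @return A tibble with columns `id`, `abundance_weight`,
#'   `antisense_fraction`, `u_probability`.
#' @export
#' @examples
#' refs <- generate_references(n_transposons = 4, length_range = c(300, 400),
#'                             genome_length = 6000, seed = 1)
#' transposon_models(refs, preset = "wt-ovary")
transposon_models <- function(references,
                              preset = "wt-ovary",
                              abundance_weights = NULL,
                              zipf_exponent = 1.5,
                              antisense_fraction = NULL,
                              u_probability = NULL) {
  ids <- if (inherits(references, "pirna_references")) {
    references$transposons$id
  } else {
    references$id
  }
  n <- length(ids)
  params <- preset_params(preset)
  af <- antisense_fraction %||% params$antisense_fraction
  up <- u_probability %||% params$u_probability
  stopifnot(af >= 0, af <= 1, up >= 0, up <= 1)

  w <- if (is.null(abundance_weights)) {
    seq_len(n)^(-zipf_exponent)
  } else if (!is.null(names(abundance_weights))) {
    unname(abundance_weights[ids])
  } else {
    rep_len(abundance_weights, n)
  }
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("abundance weights must be non-negative with a positive sum",
         call. = FALSE)
  }

  tibble::tibble(
    id = ids,
    abundance_weight = w,
    antisense_fraction = af,
    u_probability = up
  )
}

#' Scale abundance weights of selected transposons
#'
#' Multiplies the abundance weights of `ids` by `factor`, e.g. to emulate a
#' mutant library in which designated piRNA families are depleted (a factor
#' of 0.6 encodes a 40% drop in relative expression).
#'
#' @param models Model tibble from [transposon_models()].
#' @param ids Transposon ids to scale.
#' @param factor Positive multiplier.
#' @return The model tibble with updated weights.
#' @export
scale_abundance <- function(models, ids, factor) {
  stopifnot(is.numeric(factor), factor >= 0)
  missing <- setdiff(ids, models$id)
  if (length(missing) > 0) {
    stop("unknown transposon id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  models$abundance_weight[models$id %in% ids] <-
    models$abundance_weight[models$id %in% ids] * factor
  models
}

#' Configuration of one simulated sequencing library
#'
#' @param n_pirna_reads Transposon-derived piRNA reads.
#' @param n_background_reads Genome-background reads (inserts drawn from
#'   genome regions free of transposon copies; they map perfectly to the
#'   genome but to no transposon).
#' @param n_junk_reads Reads carrying no adapter occurrence within the
#'   trimmer's mismatch tolerance (they are discarded at the trim stage).
#' @param adapter 3' adapter sequence ligated after each insert (default
#'   [default_adapter()]).
#' @param cycle_length Sequencing read length in cycles (default 36).
#' @param insert_length_weights Named numeric vector of sampling weights
#'   over insert lengths 23-30 nt. The default peaks at 27 nt, the typical
#'   mode of ovarian piRNA length distributions.
#' @param error_rate Per-base substitution probability applied to the
#'   finished read (insert plus adapter), in `[0, 1)`.
#' @param seed Integer seed for the library's RNG stream.
#' @return A validated `library_config` object (a list).
#' @export
library_config <- function(n_pirna_reads = 200000,
                           n_background_reads = 20000,
                           n_junk_reads = 5000,
                           adapter = default_adapter(),
                           cycle_length = 36,
                           insert_length_weights = NULL,
                           error_rate = 0,
                           seed = 1) {
  if (is.null(insert_length_weights)) {
    insert_length_weights <- c(
      `23` = 2, `24` = 3, `25` = 5, `26` = 8,
      `27` = 10, `28` = 8, `29` = 4, `30` = 2
    )
  }
  lens <- as.integer(names(insert_length_weights))
  if (anyNA(lens) || any(lens < 23L) || any(lens > 30L)) {
    stop("insert_length_weights must be named by lengths within 23..30",
         call. = FALSE)
  }
  if (any(insert_length_weights < 0) || sum(insert_length_weights) <= 0) {
    stop("insert_length_weights must be non-negative with a positive sum",
         call. = FALSE)
  }
  assert_dna(adapter, "adapter", allow_n = FALSE)
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt", call. = FALSE)
  stopifnot(
    n_pirna_reads >= 0, n_background_reads >= 0, n_junk_reads >= 0,
    error_rate >= 0, error_rate < 1
  )
  max_len <- max(lens[insert_length_weights > 0])
  if (cycle_length < max_len) {
    stop("cycle_length must be at least the maximum insert length",
         call. = FALSE)
  }
  structure(
    list(
      n_pirna_reads = as.integer(n_pirna_reads),
      n_background_reads = as.integer(n_background_reads),
      n_junk_reads = as.integer(n_junk_reads),
      adapter = adapter,
      cycle_length = as.integer(cycle_length),
      insert_length_weights = insert_length_weights,
      error_rate = error_rate,
      seed = as.integer(seed)
    ),
    class = "library_config"
  )
}

# sample insert lengths from the configured weight table
sample_insert_lengths <- function(n, weights) {
  lens <- as.integer(names(weights))
  if (length(lens) == 1L) return(rep(lens, n))
  sample(lens, n, replace = TRUE, prob = weights)
}

# First base of the insert that a window (start, start+len-1) of `cons`
# would produce on the given strand, without materialising the insert.
insert_first_base <- function(cons, start, len, minus) {
  out <- substr(cons, start, start)
  if (any(minus)) {
    out[minus] <- complement_base(
      substr(cons[minus], start[minus] + len[minus] - 1L,
             start[minus] + len[minus] - 1L)
    )
  }
  out
}

#' Simulate a small-RNA sequencing library with ground truth
#'
#' Builds raw reads the way the sequencer would see them: each piRNA read is
#' a 23-30 nt insert sampled from a transposon consensus (reverse-
#' complemented for antisense reads, with the 5' base forced to U/T with the
#' model's `u_probability`), followed by the ligated 3' adapter, truncated
#' to `cycle_length`, with optional per-base substitution errors applied
#' last (so adapter copies can carry mismatches). Background reads take
#' their inserts from genome regions free of transposon copies; junk reads
#' are random sequences guaranteed to contain no adapter occurrence within
#' the trimmer's tolerance (2 mismatches, 6 nt minimum overlap).
#'
#' 5'-U forcing resamples the insert start position (up to 50 attempts)
#' until the first insert base meets the target, so the insert still matches
#' the consensus exactly and remains perfectly mappable; in the rare case no
#' attempt succeeds, the first base is substituted instead.
#'
#' @param references A `pirna_references` object.
#' @param models Model tibble from [transposon_models()].
#' @param config A [library_config()] object.
#' @return An object of class `pirna_library`: a list with
#'   * `reads` — tibble (`id`, `sequence`, `quality`), the raw library;
#'   * `truth` — tibble (`read_id`, `source`, `strand`, `true_insert`,
#'     `adapter_start`), per-read ground truth; `true_insert` is the insert
#'     after 5'-forcing but before sequencing errors, and `adapter_start`
#'     is the 0-based offset of the adapter in the read (NA for junk);
#'   * `config` — the configuration used.
#' @export
#' @examples
#' refs <- generate_references(n_transposons = 2, length_range = c(300, 400),
#'                             genome_length = 4000, seed = 1)
#' models <- transposon_models(refs, preset = "wt-ovary")
#' cfg <- library_config(n_pirna_reads = 100, n_background_reads = 10,
#'                       n_junk_reads = 5, seed = 7)
#' lib <- simulate_library(refs, models, cfg)
#' lib$reads
simulate_library <- function(references, models, config) {
  stopifnot(inherits(references, "pirna_references"),
            inherits(config, "library_config"))
  if (nrow(models) == 0L) stop("models must be non-empty", call. = FALSE)
  if (!all(models$id %in% references$transposons$id)) {
    stop("models reference transposons absent from the reference set",
         call. = FALSE)
  }
  set.seed(config$seed)

  lens_requested <- as.integer(names(config$insert_length_weights))
  max_len <- max(lens_requested[config$insert_length_weights > 0])
  cons_len <- nchar(references$transposons$sequence)
  if (min(cons_len) < max_len) {
    stop("insert length exceeds the shortest consensus length",
         call. = FALSE)
  }

  pirna <- simulate_pirna_reads(references, models, config)
  background <- simulate_background_reads(references, config)
  junk <- simulate_junk_reads(config)

  insert <- c(pirna$insert, background$insert)
  n_real <- length(insert)
  n_junk <- config$n_junk_reads

  # ligate adapter, pad with random downstream sequence if the window is
  # longer than insert+adapter, truncate to the cycle window
  reads_real <- if (n_real == 0L) character(0) else
    paste0(insert, config$adapter)
  short <- nchar(reads_real) < config$cycle_length
  if (any(short)) {
    reads_real[short] <- paste0(
      reads_real[short],
      random_dna(config$cycle_length - nchar(reads_real[short]))
    )
  }
  reads_real <- substr(reads_real, 1L, config$cycle_length)

  sequences <- c(reads_real, junk)
  if (config$error_rate > 0 && length(sequences) > 0) {
    sequences <- apply_substitution_errors(sequences, config$error_rate)
  }

  n <- n_real + n_junk
  ids <- sprintf("read%07d", seq_len(n))
  reads <- tibble::tibble(
    id = ids,
    sequence = sequences,
    quality = strrep("I", nchar(sequences))
  )
  truth <- tibble::tibble(
    read_id = ids,
    source = c(pirna$source, background$source, rep("junk", n_junk)),
    strand = c(pirna$strand, background$strand, rep(NA_character_, n_junk)),
    true_insert = c(insert, rep(NA_character_, n_junk)),
    adapter_start = c(nchar(insert), rep(NA_integer_, n_junk))
  )

  structure(
    list(reads = reads, truth = truth, config = config),
    class = "pirna_library"
  )
}

#' @export
print.pirna_library <- function(x, ...) {
  tab <- table(factor(x$truth$source %in% c("genome", "junk"),
                      levels = c(FALSE, TRUE)))
  cat(sprintf(
    "<pirna_library> %d reads (%d transposon-derived, %d genome background, %d junk), %d-cycle, seed %d\n",
    nrow(x$reads), sum(!x$truth$source %in% c("genome", "junk")),
    sum(x$truth$source == "genome"), sum(x$truth$source == "junk"),
    x$config$cycle_length, x$config$seed
  ))
  invisible(x)
}

simulate_pirna_reads <- function(references, models, config) {
  n <- config$n_pirna_reads
  if (n == 0L) {
    return(list(insert = character(0), source = character(0),
                strand = character(0)))
  }
  cons_all <- references$transposons$sequence
  names(cons_all) <- references$transposons$id

  pick <- sample.int(nrow(models), n, replace = TRUE,
                     prob = models$abundance_weight)
  tid <- models$id[pick]
  cons <- unname(cons_all[tid])
  clen <- nchar(cons)
  minus <- stats::runif(n) < models$antisense_fraction[pick]
  len <- sample_insert_lengths(n, config$insert_length_weights)
  want_u <- stats::runif(n) < models$u_probability[pick]
  pos_max <- clen - len + 1L

  start <- 1L + as.integer(floor(stats::runif(n) * pos_max))
  first <- insert_first_base(cons, start, len, minus)
  ok <- (first == "T") == want_u
  tries <- 0L
  while (!all(ok) && tries < 50L) {
    i <- which(!ok)
    start[i] <- 1L + as.integer(floor(stats::runif(length(i)) * pos_max[i]))
    first[i] <- insert_first_base(cons[i], start[i], len[i], minus[i])
    ok[i] <- (first[i] == "T") == want_u[i]
    tries <- tries + 1L
  }

  window <- substr(cons, start, start + len - 1L)
  insert <- window
  if (any(minus)) insert[minus] <- revcomp(window[minus])

  # fallback for reads whose 5' target was never met by resampling: force
  # the first base by substitution (such reads will not map exactly)
  if (!all(ok)) {
    i <- which(!ok)
    repl <- ifelse(want_u[i], "T",
                   sample(c("A", "C", "G"), length(i), replace = TRUE))
    substr(insert[i], 1L, 1L) <- repl
  }

  list(insert = insert, source = tid,
       strand = ifelse(minus, "-", "+"))
}

simulate_background_reads <- function(references, config) {
  n <- config$n_background_reads
  if (n == 0L) {
    return(list(insert = character(0), source = character(0),
                strand = character(0)))
  }
  bg <- references$background
  len <- sample_insert_lengths(n, config$insert_length_weights)
  width <- bg$end - bg$start + 1L
  # intervals shorter than the longest insert cannot host every read; pick
  # intervals weighted by the positions available to a 30-nt insert
  avail <- pmax(width - 30L + 1L, 0L)
  iv <- sample.int(nrow(bg), n, replace = TRUE, prob = avail)
  pos_max <- width[iv] - len + 1L
  start <- bg$start[iv] + as.integer(floor(stats::runif(n) * pos_max))
  window <- substr(rep(references$genome, n), start, start + len - 1L)
  minus <- stats::runif(n) < 0.5
  insert <- window
  if (any(minus)) insert[minus] <- revcomp(window[minus])
  list(insert = insert, source = rep("genome", n),
       strand = ifelse(minus, "-", "+"))
}

simulate_junk_reads <- function(config) {
  n <- config$n_junk_reads
  if (n == 0L) return(character(0))
  reads <- random_dna(rep(config$cycle_length, n))
  # reject candidates in which the trimmer would find the adapter
  repeat {
    hit <- adapter_scan(reads, config$adapter,
                        max_mismatches = 2L, min_overlap = 6L)
    bad <- !is.na(hit$adapter_start)
    if (!any(bad)) break
    reads[bad] <- random_dna(rep(config$cycle_length, sum(bad)))
  }
  reads
}

apply_substitution_errors <- function(sequences, error_rate) {
  widths <- nchar(sequences)
  total <- sum(widths)
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(sequences)
  pos <- sample.int(total, n_err)
  # map flat positions to (read, offset)
  ends <- cumsum(widths)
  read_idx <- findInterval(pos - 1L, ends) + 1L
  offset <- pos - c(0L, ends)[read_idx]
  old <- substr(sequences[read_idx], offset, offset)
  shift <- sample.int(3L, n_err, replace = TRUE)
  new <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
  for (k in seq_len(n_err)) {
    substr(sequences[read_idx[k]], offset[k], offset[k]) <- new[k]
  }
  sequences
}
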