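# Per-library piRNA statistics: strand-aware transposon read counts, RPM
# normalisation against perfect genome-mapping reads, the abundant-
# transposon filter, 5'-U (1U) bias and antisense strand bias.

#' Count distinct reads per transposon and strand
#'
#' A read counts at most once per (transposon, strand) however many
#' positions it hits; a read hitting several transposons counts towards each
#' of them.
#'
#' @param hits Hit tibble from [map_library()] (`read_id`, `reference_id`,
#'   `strand`).
#' @return A tibble with columns `transposon_id`, `sense_reads`,
#'   `antisense_reads`.
#' @export
count_transposon_reads <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("read_id", "reference_id", "strand") %in% names(hits)))
  hits |>
    dplyr::distinct(.data$read_id, .data$reference_id, .data$strand) |>
    dplyr::count(.data$reference_id, .data$strand) |>
    tidyr::pivot_wider(names_from = "strand", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"+" %in% names(d)) d$`+` <- 0L
      if (!"-" %in% names(d)) d$`-` <- 0L
      d
    })() |>
    dplyr::transmute(
      transposon_id = .data$reference_id,
      sense_reads = .data$`+`,
      antisense_reads = .data$`-`
    ) |>
    dplyr::arrange(.data$transposon_id)
}

#' Normalise counts to reads per million (RPM)
#'
#' `rpm = 1e6 * reads / genome_mapped_total`, where the denominator is the
#' number of distinct reads in the library that map perfectly to the genome
#' (the sequencing-depth proxy). Full floating precision is retained.
#'
#' @param counts Count tibble from [count_transposon_reads()].
#' @param genome_mapped_total Positive count of perfect genome-mapping
#'   reads.
#' @return The input tibble with `sense_rpm` and `antisense_rpm` columns
#'   added.
#' @export
rpm_normalize <- function(counts, genome_mapped_total) {
  if (!is.numeric(genome_mapped_total) || genome_mapped_total <= 0) {
    stop("genome_mapped_total must be positive (empty library?)",
         call. = FALSE)
  }
  dplyr::mutate(
    counts,
    sense_rpm = 1e6 * .data$sense_reads / genome_mapped_total,
    antisense_rpm = 1e6 * .data$antisense_reads / genome_mapped_total
  )
}

#' 5'-uridine (1U) bias of transposon-mapped reads
#'
#' The percentage of distinct transposon-mapped reads whose insert begins
#' with T (U in the RNA). The denominator is transposon-mapped reads; pass
#' `hits = NULL` to compute the same statistic over all reads in `trimmed`
#' (e.g. all genome-mapped reads), the alternative denominator.
#'
#' @param trimmed Trimmed-read tibble (`id`, `insert`).
#' @param hits Transposon hit tibble from [map_library()], or NULL.
#' @return Percentage in `[0, 100]`.
#' @export
one_u_bias <- function(trimmed, hits = NULL) {
  ids <- if (is.null(hits)) trimmed$id else unique(hits$read_id)
  inserts <- trimmed$insert[match(ids, trimmed$id)]
  inserts <- inserts[!is.na(inserts)]
  if (length(inserts) == 0L) {
    stop("1U bias is undefined: no transposon-mapped reads", call. = FALSE)
  }
  100 * mean(substr(inserts, 1L, 1L) == "T")
}

#' Pooled antisense strand bias
#'
#' The ratio of antisense to sense transposon-mapped reads, pooled over all
#' transposons (one scalar per library) — not a mean of per-transposon
#' ratios, which would be undefined for transposons lacking sense reads.
#'
#' @param counts Count tibble from [count_transposon_reads()].
#' @return Non-negative ratio.
#' @export
antisense_bias <- function(counts) {
  s <- sum(counts$sense_reads)
  a <- sum(counts$antisense_reads)
  if (s == 0L) {
    stop("antisense bias is undefined: no sense transposon reads",
         call. = FALSE)
  }
  a / s
}

#' Profile one library
#'
#' Combines trimming and mapping output into the library's statistics:
#' per-transposon sense/antisense read counts and RPM, the 1U bias (over
#' transposon-mapped reads, with the all-trimmed-reads variant exposed for
#' comparison) and the pooled antisense bias.
#'
#' @param trimmed Trimmed-read tibble (`id`, `insert`) or a `trim_result`.
#' @param mapping A [map_library()] result.
#' @param library_id Label for the library.
#' @return An object of class `library_profile` with elements `library_id`,
#'   `genome_mapped_total`, `transposons` (count + RPM tibble),
#'   `one_u_bias`, `one_u_bias_all_reads`, `antisense_bias`. Use [tidy()]
#'   for the per-transposon table and [glance()] for the one-row library
#'   summary.
#' @export
profile_library <- function(trimmed, mapping, library_id = "library") {
  if (inherits(trimmed, "trim_result")) trimmed <- trimmed$trimmed
  stopifnot(inherits(mapping, "map_result"))
  counts <- count_transposon_reads(mapping$hits)
  transposons <- rpm_normalize(counts, mapping$genome_mapped_total)
  structure(
    list(
      library_id = library_id,
      genome_mapped_total = mapping$genome_mapped_total,
      transposons = transposons,
      one_u_bias = one_u_bias(trimmed, mapping$hits),
      one_u_bias_all_reads = one_u_bias(trimmed, hits = NULL),
      antisense_bias = antisense_bias(counts)
    ),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf(
    "<library_profile> %s: %d genome-mapped reads, %d transposons, 1U bias %.1f%%, antisense bias %.2f\n",
    x$library_id, x$genome_mapped_total, nrow(x$transposons),
    x$one_u_bias, x$antisense_bias
  ))
  invisible(x)
}

#' @rdname tidy.library_profile
#' @method glance library_profile
#' @export
glance.library_profile <- function(x, ...) {
  tibble::tibble(
    library_id = x$library_id,
    genome_mapped_total = x$genome_mapped_total,
    n_transposons = nrow(x$transposons),
    one_u_bias = x$one_u_bias,
    one_u_bias_all_reads = x$one_u_bias_all_reads,
    antisense_bias = x$antisense_bias
  )
}

#' Tidiers for library profiles
#'
#' `tidy()` returns the per-transposon count/RPM table with the library id
#' attached; `glance()` returns the one-row library-level summary.
#'
#' @param x A `library_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy library_profile
#' @export
tidy.library_profile <- function(x, ...) {
  dplyr::mutate(x$transposons, library_id = x$library_id, .before = 1)
}

#' Transposons exceeding an RPM threshold
#'
#' Returns the transposons whose total (sense + antisense) RPM strictly
#' exceeds `threshold_rpm` in the given profile — "more than 500 RPM" means
#' a total RPM of exactly 500 is excluded. Used to restrict relative-
#' expression comparisons to abundantly piRNA-producing transposons in the
#' baseline (wild-type) library.
#'
#' @param profile A `library_profile` (the baseline library) or its
#'   [tidy()] tibble.
#' @param threshold_rpm Threshold in reads per million (default 500).
#' @return Character vector of transposon ids.
#' @export
filter_abundant <- function(profile, threshold_rpm = 500) {
  tab <- if (inherits(profile, "library_profile")) {
    profile$transposons
  } else {
    profile
  }
  total <- tab$sense_rpm + tab$antisense_rpm
  tab$transposon_id[total > threshold_rpm]
}
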