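# Mutant-versus-wild-type relative expression of transposon piRNAs:
# per-transposon RE (baseline = 1), three-band classification, replicate
# summaries (mean +/- sample SD), percent reduction, and a pooled-variance
# two-sample t test for replicate comparisons.

#' Relative expression against a baseline
#'
#' `re = sample_rpm / baseline_rpm`, so the baseline library sits at 1.
#' Where the baseline RPM is 0 the ratio is undefined and `NA` is returned
#' (never a fabricated number). Vectorised.
#'
#' @param sample_rpm,baseline_rpm Non-negative RPM values.
#' @return Numeric vector of RE values with `NA` where undefined.
#' @export
#' @examples
#' relative_expression(c(240, 400, 10), c(400, 400, 0))
relative_expression <- function(sample_rpm, baseline_rpm) {
  stopifnot(is.numeric(sample_rpm), is.numeric(baseline_rpm))
  ifelse(baseline_rpm > 0, sample_rpm / baseline_rpm, NA_real_)
}

#' Classify relative expression into heat-map bands
#'
#' Three bands with inclusive middle bounds: `reduced` when `re < lower`,
#' `unchanged` when `lower <= re <= upper`, `elevated` when `re > upper`.
#' The defaults 0.6 and 1.6 match the published heat-map colour scheme
#' (both boundary values fall in the unchanged band).
#'
#' @param re Numeric vector of non-negative RE values (`NA` allowed and
#'   propagated).
#' @param lower,upper Band boundaries (defaults 0.6 and 1.6).
#' @return Factor with levels `reduced`, `unchanged`, `elevated`.
#' @export
#' @examples
#' classify_band(c(0.59, 0.6, 1.0, 1.6, 1.61))
classify_band <- function(re, lower = 0.6, upper = 1.6) {
  stopifnot(lower < upper)
  if (any(re < 0, na.rm = TRUE)) {
    stop("relative expression cannot be negative", call. = FALSE)
  }
  band <- ifelse(re < lower, "reduced",
                 ifelse(re <= upper, "unchanged", "elevated"))
  factor(band, levels = c("reduced", "unchanged", "elevated"))
}

#' Compare sample profiles to a baseline
#'
#' Computes, per transposon and strand class (sense, antisense, total RPM),
#' the relative expression of each sample library against the baseline and
#' its band. When several baseline profiles are supplied their mean RPM is
#' the baseline.
#'
#' @param samples A `library_profile` or list of them (the mutant
#'   replicates).
#' @param baseline A `library_profile` or list of them (the wild-type
#'   baseline; a list is averaged).
#' @param transposon_ids Optional restriction to a transposon subset, e.g.
#'   from [filter_abundant()] on the baseline.
#' @param lower,upper Band boundaries passed to [classify_band()].
#' @return A tibble with columns `transposon_id`, `strand_class`,
#'   `library_id`, `re`, `band`.
#' @export
compare_profiles <- function(samples, baseline, transposon_ids = NULL,
                             lower = 0.6, upper = 1.6) {
  samples <- as_profile_list(samples)
  baseline <- as_profile_list(baseline)

  base_long <- dplyr::bind_rows(lapply(baseline, profile_long)) |>
    dplyr::group_by(.data$transposon_id, .data$strand_class) |>
    dplyr::summarise(baseline_rpm = mean(.data$rpm), .groups = "drop")

  out <- lapply(samples, function(p) {
    profile_long(p) |>
      dplyr::full_join(base_long, by = c("transposon_id", "strand_class")) |>
      dplyr::mutate(
        library_id = p$library_id,
        rpm = dplyr::coalesce(.data$rpm, 0),
        baseline_rpm = dplyr::coalesce(.data$baseline_rpm, 0)
      )
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(transposon_ids)) {
    out <- dplyr::filter(out, .data$transposon_id %in% transposon_ids)
  }
  out |>
    dplyr::mutate(
      re = relative_expression(.data$rpm, .data$baseline_rpm),
      band = classify_band(.data$re, lower, upper)
    ) |>
    dplyr::select("transposon_id", "strand_class", "library_id", "re",
                  "band") |>
    dplyr::arrange(.data$transposon_id, .data$strand_class,
                   .data$library_id)
}

as_profile_list <- function(x) {
  if (inherits(x, "library_profile")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                   "library_profile")))
  x
}

# long per-transposon RPM with sense/antisense/total strand classes
profile_long <- function(profile) {
  t <- profile$transposons
  tibble::tibble(
    transposon_id = rep(t$transposon_id, 3L),
    strand_class = rep(c("sense", "antisense", "total"),
                       each = nrow(t)),
    rpm = c(t$sense_rpm, t$antisense_rpm, t$sense_rpm + t$antisense_rpm)
  )
}

#' Mean and sample standard deviation of replicate values
#'
#' @param values Numeric vector of replicate measurements.
#' @return A tibble with `mean`, `sd` (divisor `n - 1`; `NA` when fewer
#'   than two values) and `n`.
#' @export
#' @examples
#' summarize_replicates(c(2, 4))
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  tibble::tibble(
    mean = if (n > 0) mean(values) else NA_real_,
    sd = if (n >= 2) stats::sd(values) else NA_real_,
    n = n
  )
}

#' Percent reduction relative to baseline
#'
#' `100 * (1 - mean_re)`; negative values indicate overexpression.
#'
#' @param mean_re Mean relative expression.
#' @return Percentage.
#' @export
#' @examples
#' percent_reduction(0.6)
percent_reduction <- function(mean_re) {
  100 * (1 - mean_re)
}

#' Summarise a comparison over replicates
#'
#' Collapses a [compare_profiles()] table over sample libraries: per
#' transposon and strand class, the mean and sample SD of RE, the replicate
#' count, and the percent reduction of the mean.
#'
#' @param comparison Tibble from [compare_profiles()].
#' @return A tibble with columns `transposon_id`, `strand_class`,
#'   `mean_re`, `sd_re`, `n`, `percent_reduction`.
#' @export
summarize_comparison <- function(comparison) {
  comparison |>
    dplyr::group_by(.data$transposon_id, .data$strand_class) |>
    dplyr::summarise(
      mean_re = mean(.data$re[!is.na(.data$re)]),
      sd_re = ifelse(sum(!is.na(.data$re)) >= 2,
                     stats::sd(.data$re[!is.na(.data$re)]), NA_real_),
      n = sum(!is.na(.data$re)),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_reduction = percent_reduction(.data$mean_re))
}

#' Pooled-variance two-sample t test
#'
#' Classical Student's t with pooled variance and a two-sided p value,
#' for comparing replicate relative-expression values between conditions.
#' Degenerate inputs are handled explicitly: with zero pooled variance the
#' p value is 1 when the group means are equal, and 0 (flagged by `t =
#' Inf`) when they differ.
#'
#' @param values_a,values_b Numeric vectors with at least two values each.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' two_sample_t(c(2.1, 1.9, 2.0), c(1.0, 1.1, 0.9))
two_sample_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values", call. = FALSE)
  pooled_var <- ((na - 1) * stats::var(values_a) +
                   (nb - 1) * stats::var(values_b)) / (na + nb - 2)
  if (pooled_var == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(tibble::tibble(
      statistic = if (same) 0 else Inf * sign(mean(values_a) - mean(values_b)),
      df = na + nb - 2,
      p_value = if (same) 1 else 0
    ))
  }
  fit <- stats::t.test(values_a, values_b, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}
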