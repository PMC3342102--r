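#' Generative presets for ovarian piRNA libraries
#'
#' Parameter presets encoding the published bias statistics of silkworm
#' ovarian transposon piRNAs. The 5'-uridine probability equals the reported
#' 1U bias, and the antisense fraction is `r / (1 + r)` where `r` is the
#' reported pooled antisense/sense ratio, so that libraries simulated under a
#' preset reproduce those statistics in expectation:
#'
#' * `wt-ovary` — wild-type ovary: 1U bias 73%, antisense bias 3.5.
#' * `kg-ovary` — masculinized (KG-line) ovary: 1U bias 69%, antisense
#'   bias 3.7.
#'
#' The `reduced_factor` column carries the abundance scaling applied to
#' piRNAs reported as depleted in the mutant ovary: a factor of 0.6, i.e. a
#' 40% reduction in relative expression.
#'
#' @return A tibble with columns `preset`, `u_probability`,
#'   `antisense_fraction`, and `reduced_factor`.
#' @export
#' @examples
#' pirna_presets()
pirna_presets <- function() {
  ratio_wt <- 3.5
  ratio_kg <- 3.7
  tibble::tibble(
    preset = c("wt-ovary", "kg-ovary"),
    u_probability = c(0.73, 0.69),
    antisense_fraction = c(ratio_wt / (1 + ratio_wt), ratio_kg / (1 + ratio_kg)),
    reduced_factor = c(NA_real_, 0.6)
  )
}

preset_params <- function(preset) {
  p <- pirna_presets()
  row <- p[p$preset == preset, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown preset '%s'; see pirna_presets()", preset),
         call. = FALSE)
  }
  row
}

#' Default 3' adapter sequence
#'
#' The adapter used by the original sequencing kit is unpublished; the
#' generator and the trimmer default to this fixed 20-mer stand-in (the
#' classic Illumina small-RNA 3' adapter prefix), which behaves like any
#' ligated 3' adapter would: it follows the insert and is truncated by the
#' 36-cycle read window.
#'
#' @return A 20-character adapter sequence.
#' @export
default_adapter <- function() {
  "TCGTATGCCGTCTTCTGCTT"
}
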