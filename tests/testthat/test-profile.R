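make_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    read_id = vapply(rows, `[[`, character(1), 1),
    reference_id = vapply(rows, `[[`, character(1), 2),
    start = 0L,
    end = 25L,
    strand = vapply(rows, `[[`, character(1), 3)
  )
}

test_that("a read counts once per transposon-strand, once per transposon hit", {
  # one read, two positions on the same transposon, same strand
  h1 <- make_hits(c("r1", "teA", "+"), c("r1", "teA", "+"))
  c1 <- count_transposon_reads(h1)
  expect_equal(c1$sense_reads[c1$transposon_id == "teA"], 1L)

  # one read antisense on two transposons counts for both
  h2 <- make_hits(c("r1", "teA", "-"), c("r1", "teB", "-"))
  c2 <- count_transposon_reads(h2)
  expect_equal(c2$antisense_reads, c(1L, 1L))
  expect_equal(c2$sense_reads, c(0L, 0L))
})

test_that("RPM normalisation is exact arithmetic and rejects empty libraries", {
  counts <- tibble::tibble(transposon_id = c("a", "b", "c"),
                           sense_reads = c(500L, 0L, 37L),
                           antisense_reads = c(0L, 0L, 0L))
  r <- rpm_normalize(counts, 1e6)
  expect_equal(r$sense_rpm, c(500, 0, 37))
  r2 <- rpm_normalize(counts, 123456)
  expect_equal(r2$sense_rpm[3], 1e6 * 37 / 123456)
  # counts are recoverable from RPM exactly (up to floating rounding)
  expect_equal(round(r2$sense_rpm * 123456 / 1e6), counts$sense_reads)
  expect_error(rpm_normalize(counts, 0), "positive")
})

test_that("the abundance filter is strict at the threshold and monotone", {
  counts <- tibble::tibble(
    transposon_id = c("at500", "just_over", "below"),
    sense_reads = c(300L, 300L, 10L),
    antisense_reads = c(200L, 201L, 10L)
  )
  prof <- profile_from_counts("wt", counts, 1e6)
  expect_identical(filter_abundant(prof, 500), "just_over")
  # monotonicity: raising the threshold never enlarges the subset
  thresholds <- c(0, 10, 100, 500, 501, 1000)
  sizes <- vapply(thresholds,
                  function(t) length(filter_abundant(prof, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("1U bias is a hand-countable percentage over mapped reads", {
  trimmed <- tibble::tibble(
    id = c("r1", "r2", "r3", "r4", "r5"),
    insert = c("TAAAAAAAAAAAAAAAAAAAAAA", "GAAAAAAAAAAAAAAAAAAAAAA",
               "TCCAAAAAAAAAAAAAAAAAAAA", "ACCAAAAAAAAAAAAAAAAAAAA",
               "TGGAAAAAAAAAAAAAAAAAAAA")
  )
  hits <- make_hits(c("r1", "teA", "+"), c("r2", "teA", "+"),
                    c("r3", "teB", "-"), c("r4", "teB", "-"),
                    # r5 maps twice but is one distinct read
                    c("r5", "teA", "+"), c("r5", "teB", "+"))
  expect_equal(one_u_bias(trimmed, hits), 100 * 3 / 5)
  # r5 dropped from the mapped set: 2 of 4 start with T
  expect_equal(one_u_bias(trimmed, hits[1:4, ]), 50)
  # all-reads denominator
  expect_equal(one_u_bias(trimmed), 60)
  expect_error(one_u_bias(trimmed, hits[0, ]), "undefined")
})

test_that("antisense bias pools counts rather than averaging ratios", {
  counts <- tibble::tibble(
    transposon_id = c("a", "b"),
    sense_reads = c(20L, 0L),       # a per-transposon mean would be undefined
    antisense_reads = c(50L, 20L)
  )
  expect_equal(antisense_bias(counts), 70 / 20)  # pooled 3.5
  eq <- tibble::tibble(transposon_id = "a", sense_reads = 5L,
                       antisense_reads = 5L)
  expect_equal(antisense_bias(eq), 1)
  none <- tibble::tibble(transposon_id = "a", sense_reads = 0L,
                         antisense_reads = 5L)
  expect_error(antisense_bias(none), "undefined")
})

test_that("profiles recover the generator's parameters on synthetic data", {
  refs <- tiny_refs(n_transposons = 5, seed = 61)
  u <- 0.7
  af <- 0.75
  n <- 20000
  lib <- tiny_library(refs, n_pirna = n, n_background = 2000, n_junk = 100,
                      seed = 17, u_probability = u, antisense_fraction = af)
  tr <- trim_and_filter(lib$reads, lib$config$adapter)
  gi <- build_index(c(genome = refs$genome))
  ti <- build_index(refs$transposons)
  mp <- map_library(tr$trimmed, gi, ti)
  prof <- profile_library(tr, mp, "syn")

  # counts equal ground-truth per-transposon per-strand tallies
  truth <- lib$truth[!lib$truth$source %in% c("genome", "junk"), ]
  want <- as.data.frame(table(truth$source, truth$strand))
  for (i in seq_len(nrow(want))) {
    row <- prof$transposons[prof$transposons$transposon_id ==
                              want$Var1[i], ]
    col <- if (want$Var2[i] == "+") row$sense_reads else row$antisense_reads
    expect_equal(col, want$Freq[i])
  }

  # denominator is all non-junk reads; RPM identity holds
  expect_equal(prof$genome_mapped_total, n + 2000)
  expect_equal(prof$transposons$sense_rpm,
               1e6 * prof$transposons$sense_reads /
                 prof$genome_mapped_total)

  # bias statistics estimate the generative parameters
  expect_lt(abs(prof$one_u_bias / 100 - u), 3 * sqrt(u * (1 - u) / n))
  ab <- prof$antisense_bias
  expect_lt(abs(ab / (1 + ab) - af), 3 * sqrt(af * (1 - af) / n))

  # tidiers
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_true(all(td$library_id == "syn"))
  gl <- glance(prof)
  expect_equal(gl$genome_mapped_total, prof$genome_mapped_total)
  expect_equal(gl$one_u_bias, prof$one_u_bias)
})
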