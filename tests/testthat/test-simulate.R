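test_that("reference generation embeds every consensus verbatim in the genome", {
  refs <- tiny_refs(n_transposons = 2, seed = 3)
  for (i in seq_len(nrow(refs$transposons))) {
    expect_true(grepl(refs$transposons$sequence[i], refs$genome,
                      fixed = TRUE))
  }
  # every 25-nt window of each consensus occurs in the genome
  cons <- refs$transposons$sequence[1]
  starts <- seq_len(nchar(cons) - 25 + 1)
  windows <- substring(cons, starts, starts + 24)
  expect_true(all(vapply(windows, grepl, logical(1), x = refs$genome,
                         fixed = TRUE)))
  # copy coordinates decode to the consensus
  cp <- refs$copies
  sl <- substring(refs$genome, cp$start, cp$end)
  expect_identical(
    sl, refs$transposons$sequence[match(cp$transposon_id,
                                        refs$transposons$id)]
  )
})

test_that("reference generation is deterministic and rejects tight genomes", {
  a <- generate_references(n_transposons = 3, length_range = c(300, 400),
                           genome_length = 6000, seed = 42)
  b <- generate_references(n_transposons = 3, length_range = c(300, 400),
                           genome_length = 6000, seed = 42)
  expect_identical(a, b)
  expect_error(
    generate_references(n_transposons = 3, length_range = c(400, 400),
                        genome_length = 1300, seed = 1),
    "cannot host"
  )
})

test_that("a 121-family reference set carries 121 distinct ids", {
  refs <- generate_references(n_transposons = 121,
                              length_range = c(300, 320),
                              genome_length = 60000, seed = 2)
  expect_length(unique(refs$transposons$id), 121L)
})

test_that("simulated libraries respect counts, determinism and ground truth", {
  refs <- tiny_refs(seed = 7)
  lib <- tiny_library(refs, n_pirna = 500, n_background = 50, n_junk = 20,
                      seed = 9)
  expect_identical(nrow(lib$reads), 570L)
  expect_identical(nrow(lib$truth), 570L)
  expect_identical(sum(lib$truth$source == "junk"), 20L)
  expect_identical(sum(lib$truth$source == "genome"), 50L)

  # same config twice -> byte-identical
  lib2 <- tiny_library(refs, n_pirna = 500, n_background = 50, n_junk = 20,
                       seed = 9)
  expect_identical(lib, lib2)

  # non-junk reads start with their true insert and carry the adapter there
  nj <- lib$truth[lib$truth$source != "junk", ]
  reads <- lib$reads$sequence[match(nj$read_id, lib$reads$id)]
  expect_identical(substr(reads, 1, nchar(nj$true_insert)), nj$true_insert)
  expect_identical(nj$adapter_start, nchar(nj$true_insert))
  adapter <- lib$config$adapter
  tail_len <- pmin(nchar(adapter),
                   lib$config$cycle_length - nj$adapter_start)
  expect_identical(
    substr(reads, nj$adapter_start + 1, nj$adapter_start + tail_len),
    substr(rep(adapter, nrow(nj)), 1, tail_len)
  )
})

test_that("degenerate generator settings pin 5' base and strand", {
  refs <- tiny_refs(seed = 13)
  lib_u1 <- tiny_library(refs, n_pirna = 400, n_background = 0, n_junk = 0,
                         seed = 3, u_probability = 1, antisense_fraction = 0)
  expect_true(all(substr(lib_u1$truth$true_insert, 1, 1) == "T"))
  expect_true(all(lib_u1$truth$strand == "+"))

  lib_u0 <- tiny_library(refs, n_pirna = 400, n_background = 0, n_junk = 0,
                         seed = 3, u_probability = 0, antisense_fraction = 1)
  expect_true(all(substr(lib_u0$truth$true_insert, 1, 1) != "T"))
  expect_true(all(lib_u0$truth$strand == "-"))
})

test_that("empirical generator fractions converge to the configured values", {
  refs <- tiny_refs(n_transposons = 6, seed = 21)
  n <- 100000
  u <- 0.73
  af <- 3.5 / 4.5
  lib <- tiny_library(refs, n_pirna = n, n_background = 0, n_junk = 0,
                      seed = 4, u_probability = u, antisense_fraction = af)
  one_u <- mean(substr(lib$truth$true_insert, 1, 1) == "T")
  expect_lt(abs(one_u - u), 3 * sqrt(u * (1 - u) / n))
  anti <- mean(lib$truth$strand == "-")
  expect_lt(abs(anti - af), 3 * sqrt(af * (1 - af) / n))

  # per-transposon read shares track the abundance weights
  models <- transposon_models(refs, u_probability = u,
                              antisense_fraction = af)
  share <- models$abundance_weight / sum(models$abundance_weight)
  obs <- as.vector(table(factor(lib$truth$source,
                                levels = models$id))) / n
  expect_true(all(abs(obs - share) <
                    3 * sqrt(share * (1 - share) / n) + 1e-12))
})

test_that("junk reads carry no adapter within the trimming tolerance", {
  refs <- tiny_refs(seed = 31)
  lib <- tiny_library(refs, n_pirna = 0, n_background = 0, n_junk = 300,
                      seed = 8)
  hit <- find_adapter(lib$reads$sequence, lib$config$adapter,
                      max_mismatches = 2, min_overlap = 6)
  expect_true(all(is.na(hit$adapter_start)))
})

test_that("substitution errors hit roughly error_rate of all bases", {
  refs <- tiny_refs(seed = 17)
  rate <- 0.02
  lib0 <- tiny_library(refs, n_pirna = 2000, n_background = 0, n_junk = 0,
                       seed = 6, error_rate = 0)
  lib1 <- tiny_library(refs, n_pirna = 2000, n_background = 0, n_junk = 0,
                       seed = 6, error_rate = rate)
  b0 <- strsplit(paste(lib0$reads$sequence, collapse = ""), "")[[1]]
  b1 <- strsplit(paste(lib1$reads$sequence, collapse = ""), "")[[1]]
  expect_length(b1, length(b0))
  obs <- mean(b0 != b1)
  expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / length(b0)))
})

test_that("generator rejects inserts longer than the shortest consensus", {
  refs <- tiny_refs(seed = 19)
  models <- transposon_models(refs)
  short_refs <- refs
  short_refs$transposons$sequence[1] <-
    substr(short_refs$transposons$sequence[1], 1, 25)
  expect_error(
    simulate_library(short_refs, models,
                     library_config(n_pirna_reads = 10,
                                    n_background_reads = 0,
                                    n_junk_reads = 0, seed = 1)),
    "consensus length"
  )
})

test_that("model construction validates weights and presets", {
  refs <- tiny_refs(seed = 23)
  expect_error(transposon_models(refs, preset = "nonsense"), "preset")
  expect_error(transposon_models(refs, abundance_weights = c(-1, 1, 1, 1)),
               "non-negative")
  m <- transposon_models(refs, preset = "kg-ovary")
  expect_equal(m$u_probability[1], 0.69)
  expect_equal(m$antisense_fraction[1], 3.7 / 4.7, tolerance = 1e-12)
  m2 <- scale_abundance(m, refs$transposons$id[2], 0.6)
  expect_equal(m2$abundance_weight[2], m$abundance_weight[2] * 0.6)
  expect_error(scale_abundance(m, "nope", 0.5), "unknown")
})
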