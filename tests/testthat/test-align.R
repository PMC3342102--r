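test_that("build_index stores exactly the forward k-mer windows", {
  set.seed(51)
  ref <- c(r1 = random_seq(100))
  idx <- build_index(ref, key_length = 23)
  expect_equal(nrow(idx$kmers), 78L)  # 100 - 23 + 1
  # membership: every stored key decodes to the reference substring
  expect_identical(
    idx$kmers$kmer,
    substring(ref, idx$kmers$start0 + 1, idx$kmers$start0 + 23)
  )
  # determinism
  expect_identical(idx$kmers, build_index(ref, key_length = 23)$kmers)
  # N windows are skipped
  refn <- c(r1 = paste0(random_seq(30), "N", random_seq(30)))
  idxn <- build_index(refn, key_length = 23)
  expect_false(any(grepl("N", idxn$kmers$kmer)))
  expect_equal(nrow(idxn$kmers), sum(!grepl(
    "N", substring(refn, 1:(61 - 22), 23:61))))
  expect_error(build_index(ref, key_length = 0), "1..30")
  expect_error(build_index(ref, key_length = 31), "1..30")
})

test_that("map_exact finds forward, reverse and absent matches", {
  set.seed(62)
  ref <- c(chr = random_seq(200))
  idx <- build_index(ref)
  insert <- substr(ref, 11, 35)  # reference[10:35), 0-based
  hit <- map_exact(insert, idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 10L)
  expect_equal(hit$end, 35L)
  expect_equal(hit$strand, "+")

  rc_hit <- map_exact(revcomp(insert), idx)
  expect_equal(nrow(rc_hit), 1L)
  expect_equal(rc_hit$start, 10L)
  expect_equal(rc_hit$end, 35L)
  expect_equal(rc_hit$strand, "-")

  mutated <- insert
  substr(mutated, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mutated, 13, 13))[1]
  expect_equal(nrow(map_exact(mutated, idx)), 0L)

  # inserts containing N never match
  with_n <- insert
  substr(with_n, 2, 2) <- "N"
  expect_equal(nrow(map_exact(with_n, idx)), 0L)

  expect_error(map_exact(random_seq(22), idx), "23-30")
  expect_error(map_exact(random_seq(31), idx), "23-30")
})

test_that("map_exact equals the naive both-strand scan on random cases", {
  set.seed(73)
  for (case in seq_len(1000)) {
    refs <- setNames(
      vapply(1:2, function(i) random_seq(sample(40:90, 1)), character(1)),
      c("a", "b")
    )
    idx <- build_index(refs)
    len <- sample(23:30, 1)
    insert <- if (case %% 2 == 0) {
      # planted: guaranteed at least one occurrence
      src <- refs[[sample(1:2, 1)]]
      s0 <- sample(0:(nchar(src) - len), 1)
      x <- substr(src, s0 + 1, s0 + len)
      if (case %% 4 == 0) revcomp(x) else x
    } else {
      random_seq(len)
    }
    got <- map_exact(insert, idx)
    want <- oracle_map_exact(insert, as.list(refs))
    got_key <- sort(paste(got$reference_id, got$start, got$end, got$strand))
    want_key <- sort(paste(want$reference_id, want$start, want$end,
                           want$strand))
    expect_identical(got_key, want_key)
  }
})

test_that("strand involution: reverse-complementing a query swaps strands only", {
  set.seed(84)
  ref <- c(chr = random_seq(500))
  idx <- build_index(ref)
  for (i in 1:20) {
    len <- sample(23:30, 1)
    s0 <- sample(0:(500 - len), 1)
    q <- substr(ref, s0 + 1, s0 + len)
    fwd <- map_exact(q, idx)
    rev <- map_exact(revcomp(q), idx)
    flip <- ifelse(fwd$strand == "+", "-", "+")
    expect_identical(
      sort(paste(fwd$reference_id, fwd$start, fwd$end, flip)),
      sort(paste(rev$reference_id, rev$start, rev$end, rev$strand))
    )
  }
})

test_that("map_library counts distinct genome-mapping reads, not hits", {
  set.seed(95)
  core <- random_seq(30)
  # genome with the same 30-mer planted twice: a multi-mapper counts once
  genome <- c(genome = paste0(random_seq(60), core, random_seq(60), core,
                              random_seq(60)))
  te <- tibble::tibble(id = c("teA", "teB"),
                       sequence = c(paste0(random_seq(20), core,
                                           random_seq(20)),
                                    paste0(core, random_seq(40))))
  gi <- build_index(genome)
  ti <- build_index(te)
  trimmed <- tibble::tibble(id = c("x", "y"),
                            insert = c(core, random_seq(25)))
  mp <- map_library(trimmed, gi, ti)
  expect_equal(mp$genome_mapped_total, 1L)
  expect_identical(mp$reads$genome_mapped, c(TRUE, FALSE))
  # read x hits both transposons, one hit record per (transposon, position)
  expect_setequal(unique(mp$hits$reference_id), c("teA", "teB"))
  expect_true(all(mp$hits$read_id == "x"))

  empty <- map_library(trimmed[0, ], gi, ti)
  expect_equal(empty$genome_mapped_total, 0L)
  expect_equal(nrow(empty$hits), 0L)
})

test_that("error-free synthetic libraries map back to source and strand", {
  refs <- tiny_refs(seed = 55)
  lib <- tiny_library(refs, n_pirna = 1200, n_background = 120, n_junk = 30,
                      seed = 16)
  tr <- trim_and_filter(lib$reads, lib$config$adapter)
  gi <- build_index(c(genome = refs$genome))
  ti <- build_index(refs$transposons)
  mp <- map_library(tr$trimmed, gi, ti)

  # every non-junk read maps perfectly to the genome
  expect_true(all(mp$reads$genome_mapped))
  expect_equal(mp$genome_mapped_total, nrow(tr$trimmed))

  # per-read transposon source and strand are recovered
  truth <- lib$truth[lib$truth$source != "genome" &
                       lib$truth$source != "junk", ]
  hit_src <- dplyr::inner_join(mp$hits, truth,
                               by = c("read_id" = "read_id"))
  same <- hit_src[hit_src$reference_id == hit_src$source, ]
  expect_setequal(same$read_id, truth$read_id)
  expect_true(all(same$strand.x == same$strand.y))
})
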