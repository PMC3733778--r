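test_that("sampling weights follow length over rank, normalized", {
  one <- make_tset(500)
  m1 <- build_sampling_model(one, 1)
  expect_equal(unname(m1$weights), 1.0)

  # equal lengths: weight of rank i is (1/i) / H_n regardless of permutation
  ts <- make_tset(rep(100L, 4))
  m <- build_sampling_model(ts, 5)
  h <- sum(1 / 1:4)
  expect_equal(unname(m$weights), (1 / 1:4) / h, tolerance = 1e-12)

  # unequal lengths: hand-normalized l_i / i in permutation order
  ts3 <- make_tset(c(300L, 100L, 200L))
  m3 <- build_sampling_model(ts3, 2)
  len <- setNames(ts3$transcripts$length, ts3$transcripts$transcript_id)
  raw <- len[m3$permutation] / seq_along(m3$permutation)
  expect_equal(unname(m3$weights), unname(raw / sum(raw)), tolerance = 1e-12)
  expect_equal(sum(m3$weights), 1.0)
  expect_setequal(m3$permutation, ts3$transcripts$transcript_id)
  # a known order check: lengths (300,100,200) at ranks 1..3 give
  # weights proportional to (300, 50, 66.67) i.e. (0.72, 0.12, 0.16)
  w <- c(300, 100 / 2, 200 / 3); w <- w / sum(w)
  expect_equal(round(w, 2), c(0.72, 0.12, 0.16))

  expect_error(build_sampling_model(
    structure(list(transcripts = data.frame()), class = "transcript_set")),
    "empty")
})

test_that("the same seed fixes the permutation across models", {
  ts <- generate_transcriptome(50, seed = 3)
  expect_identical(build_sampling_model(ts, 9)$permutation,
                   build_sampling_model(ts, 9)$permutation)
})

test_that("read lengths: resampled minimum, whole-transcript cap, moments", {
  lm400 <- read_length_model(400)
  expect_equal(lm400$sd, 100)
  expect_equal(lm400$min_len, 100)

  set.seed(1)
  # short transcript: every draw above 50 is replaced by the whole transcript
  l <- draw_read_lengths(lm400, rep(50L, 1000))
  expect_true(all(l == 50L))

  set.seed(2)
  l <- draw_read_lengths(lm400, rep(1000000L, 20000))
  expect_true(all(l >= 100L))
  # resampling at 3 sigma below the mean shifts the mean by < 0.4
  expect_lt(abs(mean(l) - 400), 3 * 100 / sqrt(20000) + 0.5)
  expect_equal(sd(l) / 400, 0.25, tolerance = 0.02)
})

test_that("substitution errors: identity, forced mutation, rate and positions", {
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  r0 <- apply_substitution_errors(seq, 0)
  expect_identical(r0$mutated, seq)
  expect_length(r0$error_positions, 0L)

  r1 <- apply_substitution_errors(seq, 1)
  a <- strsplit(seq, "")[[1]]; b <- strsplit(r1$mutated, "")[[1]]
  expect_true(all(a != b))
  expect_true(all(b %in% c("A", "C", "G", "T")))

  set.seed(4)
  long <- paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE), collapse = "")
  r <- apply_substitution_errors(long, 0.1)
  la <- strsplit(long, "")[[1]]; lb <- strsplit(r$mutated, "")[[1]]
  mism <- which(la != lb) - 1L
  expect_identical(mism, r$error_positions)
  p_hat <- length(mism) / 200000
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 200000))
})

test_that("single read from a short transcript spans the whole transcript", {
  ts <- make_tset(200)
  m <- build_sampling_model(ts, 1)
  rs <- simulate_reads(ts, m, read_length_model(400), 1, 0.015, seed = 1)
  expect_equal(rs$reads$start, 0L)
  expect_equal(rs$reads$end, 200L)
})

test_that("provenance round trip: reference + recorded errors reproduce reads", {
  ts <- generate_transcriptome(20, seed = 5)
  m <- build_sampling_model(ts, 5)
  rs <- simulate_reads(ts, m, read_length_model(300), 400, 0.02, seed = 6)
  r <- rs$reads
  ref <- substring(ts$sequences[r$transcript_id], r$start + 1L, r$end)
  for (i in seq_len(nrow(r))) {
    rc <- strsplit(ref[i], "")[[1]]
    sc <- strsplit(rs$sequences[[r$read_id[i]]], "")[[1]]
    offs <- rs$error_positions[[r$read_id[i]]] + 1L
    if (length(offs)) {
      expect_true(all(rc[offs] != sc[offs]))
      expect_identical(rc[-offs], sc[-offs])
      expect_true(all(offs >= 1L & offs <= r$length[i]))
    } else {
      expect_identical(rc, sc)
    }
  }
  # mean mismatch fraction near the configured rate
  mism <- sum(lengths(rs$error_positions)) / sum(r$length)
  expect_lt(abs(mism - 0.02), 3 * sqrt(0.02 * 0.98 / sum(r$length)))
})

test_that("simulation is deterministic and per-read draws stable in n_reads", {
  ts <- generate_transcriptome(30, seed = 7)
  m <- build_sampling_model(ts, 7)
  lm <- read_length_model(250)
  a <- simulate_reads(ts, m, lm, 300, 0.015, seed = 11)
  b <- simulate_reads(ts, m, lm, 300, 0.015, seed = 11)
  expect_identical(a$reads, b$reads)
  expect_identical(a$sequences, b$sequences)
  # independent streams: the first 150 reads agree when n_reads doubles
  c150 <- simulate_reads(ts, m, lm, 150, 0.015, seed = 11)
  expect_identical(a$reads[1:150, ], c150$reads)
})

test_that("observed transcript counts match the sampling weights (chi-square)", {
  ts <- make_tset(c(400L, 250L, 150L, 600L, 300L))
  m <- build_sampling_model(ts, 13)
  rs <- simulate_reads(ts, m, read_length_model(100), 20000, 0, seed = 13,
                       sequences = FALSE)
  obs <- table(factor(rs$reads$transcript_id, levels = names(m$weights)))
  pval <- suppressWarnings(
    stats::chisq.test(as.integer(obs), p = unname(m$weights))$p.value)
  expect_gt(pval, 0.001)
})

test_that("provenance TSV round trips, including empty error lists", {
  ts <- generate_transcriptome(5, seed = 1)
  m <- build_sampling_model(ts, 1)
  rs <- simulate_reads(ts, m, read_length_model(200), 50, 0.01, seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  write_provenance(rs, tsv)
  back <- read_provenance(tsv)
  expect_equal(back$read_id, rs$reads$read_id)
  expect_equal(back$start, rs$reads$start)
  expect_equal(back$end, rs$reads$end)
  expect_identical(back$error_offsets,
                   unname(rs$error_positions[rs$reads$read_id]))
  # FASTQ/FASTA writers produce parseable records of matching width
  fq <- tempfile(fileext = ".fastq")
  write_reads(rs, fq, "fastq")
  parsed <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(parsed), 50L)
  expect_equal(as.character(parsed), rs$sequences, ignore_attr = TRUE)
})
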