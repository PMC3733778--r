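test_that("overlap components: clear overlap, abutment, transitive chain", {
  # arguments are parallel start and end vectors of half-open intervals
  # [0,100) and [50,150) share 50 bases
  expect_equal(overlap_components(list(c(0L, 50L), c(100L, 150L))), c(1L, 1L))
  # disjoint [0,50) and [100,150)
  expect_equal(overlap_components(list(c(0L, 100L), c(50L, 150L))), c(1L, 2L))
  # half-open abutment [0,100), [100,200) shares zero bases
  expect_equal(overlap_components(list(c(0L, 100L), c(100L, 200L))), c(1L, 2L))
  # one-base chain [0,100), [99,150), [149,300) joins all three transitively
  expect_equal(overlap_components(list(c(0L, 99L, 149L), c(100L, 150L, 300L))),
               c(1L, 1L, 1L))
  expect_error(overlap_components(list(c(10L), c(10L))), "half-open")
})

test_that("sweep components equal the brute-force closure oracle", {
  set.seed(42)
  for (rep in 1:150) {
    n <- sample(2:60, 1)
    mo <- sample(c(1L, 1L, 25L, 40L), 1)
    s <- sample.int(500, n, replace = TRUE) - 1L
    e <- s + sample.int(120, n, replace = TRUE)
    got <- overlap_components(list(s, e), mo)
    want <- brute_components(s, e, mo)
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1L))
  }
})

test_that("single read becomes an error-corrected singleton", {
  ts <- make_tset(300)
  rs <- make_readset(ts, "t01", 10L, 110L, mutate_at = list(c(5L, 50L)))
  a <- perfect_assemble(rs, ts)
  expect_equal(nrow(a$contigs), 0L)
  expect_equal(nrow(a$singletons), 1L)
  expect_identical(unname(a$singleton_seqs),
                   unname(substring(ts$sequences["t01"], 11L, 110L)))
})

test_that("overlapping erroneous reads give a reference-consensus contig", {
  ts <- make_tset(300)
  rs <- make_readset(ts, c("t01", "t01"), c(0L, 50L), c(100L, 150L),
                     mutate_at = list(3L, 7L))
  a <- perfect_assemble(rs, ts)
  expect_equal(nrow(a$contigs), 1L)
  expect_equal(a$contigs$span_start, 0L)
  expect_equal(a$contigs$span_end, 150L)
  expect_identical(unname(a$contig_seqs),
                   unname(substring(ts$sequences["t01"], 1L, 150L)))
  expect_equal(a$contigs$n_reads, 2L)
  expect_equal(a$contigs$read_bases, 200L)
  expect_setequal(a$contig_members[[1]], rs$reads$read_id)
})

test_that("assembly output never differs from the reference", {
  ts <- generate_transcriptome(40, seed = 8)
  m <- build_sampling_model(ts, 8)
  rs <- simulate_reads(ts, m, read_length_model(300), 2000, 0.03, seed = 9)
  a <- perfect_assemble(rs, ts)
  co <- a$contigs
  expect_identical(unname(a$contig_seqs[co$contig_id]),
                   unname(substring(ts$sequences[co$source_transcript],
                                    co$span_start + 1L, co$span_end)))
  si <- a$singletons
  expect_identical(unname(a$singleton_seqs[si$read_id]),
                   unname(substring(ts$sequences[si$source_transcript],
                                    si$start + 1L, si$end)))
  # each read is in exactly one contig or one singleton
  placed <- c(unlist(a$contig_members, use.names = FALSE), si$read_id)
  expect_setequal(placed, rs$reads$read_id)
  expect_equal(anyDuplicated(placed), 0L)
})

test_that("adding reads only merges components, never splits them", {
  ts <- generate_transcriptome(5, seed = 10)
  m <- build_sampling_model(ts, 10)
  rs <- simulate_reads(ts, m, read_length_model(200), 400, 0, seed = 12)
  r <- rs$reads
  tx <- names(which.max(table(r$transcript_id)))
  idx <- which(r$transcript_id == tx)
  half <- idx[seq_len(length(idx) %/% 2)]
  sub <- overlap_components(list(r$start[half], r$end[half]))
  super <- overlap_components(list(r$start[idx], r$end[idx]))[
    match(half, idx)]
  expect_true(partition_refines(sub, super))
})

test_that("saturating depth collapses a transcript to one full contig", {
  ts <- make_tset(2000)
  m <- build_sampling_model(ts, 1)
  # ~50x coverage of a single transcript
  rs <- simulate_reads(ts, m, read_length_model(400), 250, 0.015, seed = 21)
  a <- perfect_assemble(rs, ts)
  expect_equal(nrow(a$contigs), 1L)
  expect_equal(nrow(a$singletons), 0L)
  # uniform placement leaves the terminal bases under-covered, so the span
  # need not touch the very last base; at 50x it covers essentially all of it
  expect_gte(a$contigs$length, 0.99 * 2000)
})

test_that("degradation knobs reduce joins and gate small components", {
  ts <- make_tset(500)
  # chain of 3 reads with 20-base overlaps
  rs <- make_readset(ts, rep("t01", 3), c(0L, 80L, 160L), c(100L, 180L, 260L))
  a1 <- perfect_assemble(rs, ts)
  expect_equal(nrow(a1$contigs), 1L)
  a40 <- perfect_assemble(rs, ts, min_overlap = 40L)
  expect_equal(nrow(a40$contigs), 0L)
  expect_equal(nrow(a40$singletons), 3L)
  amin <- perfect_assemble(rs, ts, min_reads = 4L)
  expect_equal(nrow(amin$contigs), 0L)
  expect_equal(nrow(amin$singletons), 3L)
  expect_equal(amin$label, "degraded")
})

test_that("assembly round trips through FASTA + membership, external ingestion", {
  ts <- generate_transcriptome(10, seed = 14)
  m <- build_sampling_model(ts, 14)
  rs <- simulate_reads(ts, m, read_length_model(250), 300, 0.01, seed = 15)
  a <- perfect_assemble(rs, ts)
  fa <- tempfile(fileext = ".fa"); mb <- tempfile(fileext = ".tsv")
  write_assembly(a, fa, mb)
  b <- read_assembly(fa, mb, readset = rs, label = "roundtrip")
  expect_setequal(b$contigs$contig_id, a$contigs$contig_id)
  expect_equal(nrow(b$singletons), nrow(a$singletons))
  bc <- b$contigs[match(a$contigs$contig_id, b$contigs$contig_id), ]
  expect_equal(bc$n_reads, a$contigs$n_reads)
  expect_equal(bc$read_bases, a$contigs$read_bases)
  expect_identical(unname(b$contig_seqs[a$contigs$contig_id]),
                   unname(a$contig_seqs))
  # unknown provenance is rejected
  rs_bad <- rs
  rs_bad$reads$transcript_id[1] <- "nope"
  expect_error(perfect_assemble(rs_bad, ts), "absent")
})
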