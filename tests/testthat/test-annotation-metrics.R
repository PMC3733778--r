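write_hits_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

test_that("tabular hit parsing: cutoff, top match, ties, coordinates", {
  slen <- c(P1 = 200L, P2 = 300L)
  empty <- write_hits_file(list())
  ht <- parse_tabular_hits(empty, "forward", 1e-6, slen)
  expect_equal(nrow(ht$hits), 0L)

  rows <- list(
    c("q1", "P1", "98.0", "100", "2", "0", "1", "300", "1", "100", "1e-10", "180"),
    c("q1", "P2", "99.0", "120", "1", "0", "1", "360", "1", "120", "1e-20", "220"),
    c("q2", "P1", "95.0", "50", "3", "0", "10", "159", "50", "1", "1e-3", "90"))
  ht <- parse_tabular_hits(write_hits_file(rows), "forward", 1e-6, slen)
  # q1 keeps the smaller e-value; q2's 1e-3 misses the 1e-6 cutoff
  expect_equal(ht$hits$query_id, "q1")
  expect_equal(ht$hits$subject_id, "P2")
  # 1-based inclusive becomes 0-based half-open
  expect_equal(ht$hits$q_start, 0L)
  expect_equal(ht$hits$q_end, 360L)
  expect_equal(ht$hits$subject_length, 300L)

  # equal e-values: higher bitscore wins; then lexicographic subject
  ties <- list(
    c("q1", "P2", "98", "100", "0", "0", "1", "300", "1", "100", "1e-10", "150"),
    c("q1", "P1", "98", "100", "0", "0", "1", "300", "1", "100", "1e-10", "180"))
  ht2 <- parse_tabular_hits(write_hits_file(ties), "forward", 1e-6, slen)
  expect_equal(ht2$hits$subject_id, "P1")

  # reversed subject coordinates (minus strand dialect) are normalized
  minus <- list(
    c("q1", "P1", "98", "100", "0", "0", "1", "300", "100", "1", "1e-10", "180"))
  ht3 <- parse_tabular_hits(write_hits_file(minus), "forward", 1e-6, slen)
  expect_equal(ht3$hits$s_start, 0L)
  expect_equal(ht3$hits$s_end, 100L)

  bad <- write_hits_file(list(c("q1", "P1", "98")))
  expect_error(parse_tabular_hits(bad, "forward", 1e-6, slen), "line 1")
  expect_error(
    parse_tabular_hits(write_hits_file(rows), "forward", 1e-6, c(P9 = 5L)),
    "unknown subject")
})

test_that("true annotation records provenance spans and transcript lengths", {
  ts <- make_tset(400L)
  rs <- make_readset(ts, "t01", 10L, 110L)
  a <- perfect_assemble(rs, ts)
  tt <- true_annotation_table(a, ts)
  expect_equal(tt$hits$subject_id, "t01")
  expect_equal(tt$hits$s_start, 10L)
  expect_equal(tt$hits$s_end, 110L)
  expect_equal(tt$hits$subject_length, 400L)
  # perfect assembly: unique true annotations == distinct sampled transcripts
  ts2 <- generate_transcriptome(25, seed = 19)
  m <- build_sampling_model(ts2, 19)
  rs2 <- simulate_reads(ts2, m, read_length_model(250), 500, 0.01, seed = 20)
  a2 <- perfect_assemble(rs2, ts2)
  tt2 <- true_annotation_table(a2, ts2)
  expect_equal(unique_annotation_count(tt2, unigene_ids_for_test(a2)),
               length(unique(rs2$reads$transcript_id)))
})

test_that("unique and singleton-only annotation counting", {
  h <- rbind(make_hit("c1", "P1"), make_hit("c2", "P1"),
             make_hit("s1", "P1"), make_hit("s2", "P2"))
  tab <- make_hit_table(h)
  expect_equal(unique_annotation_count(tab, c("c1", "c2")), 1L)
  expect_equal(unique_annotation_count(tab, character(0)), 0L)
  expect_equal(unique_annotation_count(tab, c("c1", "c2", "s1", "s2")), 2L)
  expect_equal(singleton_only_annotations(tab, c("c1", "c2"), c("s1", "s2")), 1L)
  h2 <- rbind(make_hit("s1", "P1"), make_hit("s2", "P2"),
              make_hit("c1", "P2"), make_hit("c2", "P3"))
  expect_equal(singleton_only_annotations(make_hit_table(h2),
                                          c("c1", "c2"), c("s1", "s2")), 1L)
})

test_that("ortholog hit ratio under both conventions", {
  # match covering the whole subject
  full <- make_hit("c1", "P1", q = c(0L, 300L), s = c(0L, 100L),
                   subject_length = 100L, unit = "aa")
  expect_equal(unname(ortholog_hit_ratio(full)), 1.0)
  # 300 nt of contig matching residues 1-100 of a 200-aa protein
  half <- make_hit("c1", "P1", q = c(0L, 300L), s = c(0L, 100L),
                   subject_length = 200L, unit = "aa")
  expect_equal(unname(ortholog_hit_ratio(half, "subject_span")), 0.5)
  expect_equal(unname(ortholog_hit_ratio(half, "query_bases")), 0.5)
  # query-bases convention may exceed 1 when the transcript has expanded
  expanded <- make_hit("c1", "P1", q = c(0L, 360L), s = c(0L, 100L),
                       subject_length = 100L, unit = "aa")
  expect_equal(unname(ortholog_hit_ratio(expanded, "query_bases")), 1.2)
  expect_equal(unname(ortholog_hit_ratio(expanded, "subject_span")), 1.0)
})

test_that("OHR error: identity gives 1; contraction is normalized away", {
  self <- make_hit_table(make_hit("u1", "Ps", q = c(0L, 300L), s = c(0L, 100L),
                                  subject_length = 100L, unit = "aa"))
  expect_equal(ohr_error(self, self)$raw_error, 1.0)
  expect_equal(ohr_error(self, self)$normalized_error, 1.0)
  # distant ortholog contracted to 0.8x, same matched region:
  # raw = 1/0.8 = 1.25, normalized = 1.0
  dist <- make_hit_table(make_hit("u1", "Pd", q = c(0L, 300L), s = c(0L, 80L),
                                  subject_length = 80L, unit = "aa"))
  err <- ohr_error(self, dist)
  expect_equal(err$raw_error, 1.25)
  expect_equal(err$normalized_error, 1.0)
  # only queries present in both tables are scored
  both <- make_hit_table(rbind(
    make_hit("u1", "Pd", subject_length = 80L),
    make_hit("u9", "Px", subject_length = 50L)))
  expect_equal(ohr_error(self, both)$query_id, "u1")
})

test_that("full-length perfect contig scores OHR exactly 1 on its self reference", {
  ts <- make_tset(600L, utr5 = 60L, utr3 = 120L)
  rs <- make_readset(ts, c("t01", "t01"), c(0L, 200L), c(400L, 600L))
  a <- perfect_assemble(rs, ts)
  rf <- derive_reference_set(ts, "self", unit = "aa")
  fwd <- annotate_by_provenance(a, ts, rf)
  expect_equal(unname(ortholog_hit_ratio(fwd)), 1.0)
  expect_equal(unname(ortholog_hit_ratio(fwd, "query_bases")), 1.0)
})

test_that("reciprocal best hits: definition, asymmetry, bound", {
  fwd <- make_hit_table(rbind(make_hit("u1", "P1"), make_hit("u2", "P2"),
                              make_hit("s1", "P3")))
  rev <- make_hit_table(rbind(make_hit("P1", "u1"), make_hit("P2", "u9"),
                              make_hit("P3", "s1")), direction = "reverse")
  out <- reciprocal_best_hits(fwd, rev, contig_ids = c("u1", "u2"),
                              singleton_ids = "s1")
  expect_setequal(out$pairs$query_id, c("u1", "s1"))
  expect_equal(unname(out$rbh_count["contigs"]), 1L)
  expect_equal(unname(out$rbh_count["unigenes"]), 2L)
  expect_equal(unname(out$pct_annotated_with_rbh["contigs"]), 50)
  expect_lte(max(out$rbh_count), min(nrow(fwd$hits), nrow(rev$hits)))
})

test_that("collapse factors count best-hitting references per sequence", {
  rev <- make_hit_table(rbind(make_hit("P1", "c1"), make_hit("P2", "c1"),
                              make_hit("P3", "c2")), direction = "reverse")
  cr <- collapse_factors(rev, c("c1", "c2"))
  expect_equal(unname(cr$cf[c("c1", "c2")]), c(2L, 1L))
  expect_equal(cr$average_cf, 1.5)
  expect_equal(cr$reverse_rarefaction, 3L)
  # conservation: reverse rarefaction equals reverse-annotated refs in scope
  expect_equal(cr$reverse_rarefaction,
               sum(rev$hits$subject_id %in% c("c1", "c2")))
  # scope restriction drops out-of-scope subjects
  cr1 <- collapse_factors(rev, "c1")
  expect_equal(cr1$reverse_rarefaction, 2L)
})

test_that("paralog-free perfect assembly has collapse factor 1 everywhere", {
  ts <- generate_transcriptome(25, isoform_rate = 0, seed = 22)
  m <- build_sampling_model(ts, 22)
  rs <- simulate_reads(ts, m, read_length_model(300), 2500, 0.01, seed = 23)
  a <- perfect_assemble(rs, ts)
  rf <- derive_reference_set(ts, "self")
  rev <- reverse_annotate_by_provenance(a, ts, rf, "unigenes")
  cr <- collapse_factors(rev, unigene_ids_for_test(a))
  expect_true(all(cr$cf == 1L))
  expect_equal(cr$average_cf, 1.0)
})

test_that("provenance annotator: UTR-only sequences stay unannotated, scopes differ", {
  ts <- make_tset(1000L, utr5 = 100L, utr3 = 200L)
  rf <- derive_reference_set(ts, "self", unit = "aa")
  # one read entirely inside the 5' UTR, one spanning the CDS
  rs <- make_readset(ts, c("t01", "t01"), c(0L, 300L), c(90L, 700L))
  a <- perfect_assemble(rs, ts)
  fwd <- annotate_by_provenance(a, ts, rf)
  expect_equal(nrow(fwd$hits), 1L)
  expect_equal(fwd$hits$subject_id, "p_t01")
  # annotation-count dominance: unigenes see at least what contigs see
  ts2 <- generate_transcriptome(30, seed = 24)
  m <- build_sampling_model(ts2, 24)
  rs2 <- simulate_reads(ts2, m, read_length_model(250), 600, 0.01, seed = 25)
  a2 <- perfect_assemble(rs2, ts2)
  rf2 <- derive_reference_set(ts2, "self")
  fwd2 <- annotate_by_provenance(a2, ts2, rf2)
  expect_gte(unique_annotation_count(fwd2, unigene_ids_for_test(a2)),
             unique_annotation_count(fwd2, a2$contigs$contig_id))
})
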