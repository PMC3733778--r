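# Hand-built fixtures and independent oracles used across the suite.

# Minimal transcript_set: one single-exon gene per transcript, with exact
# lengths and UTRs under the test's control.
make_tset <- function(lengths, utr5 = 0L, utr3 = 0L, seed = 1L) {
  n <- length(lengths)
  ids <- sprintf("t%02d", seq_len(n))
  gids <- sprintf("g%02d", seq_len(n))
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  names(seqs) <- ids
  utr5 <- rep_len(as.integer(utr5), n)
  utr3 <- rep_len(as.integer(utr3), n)
  exon_ids <- paste0(gids, "_e01")
  structure(list(
    transcripts = data.frame(transcript_id = ids, gene_id = gids,
                             family_id = NA_character_,
                             length = as.integer(lengths),
                             utr5_len = utr5, utr3_len = utr3,
                             stringsAsFactors = FALSE),
    sequences = seqs,
    exons = setNames(as.list(exon_ids), ids),
    exon_lengths = setNames(as.integer(lengths), exon_ids),
    genes = setNames(as.list(ids), gids),
    paralog_families = list(),
    params = list(paralog_spec = list(identity = 0.9))
  ), class = "transcript_set")
}

# Minimal read_set from explicit provenance coordinates; sequences are exact
# reference substrings (no errors) unless mutate_at gives per-read 0-based
# offsets to corrupt.
make_readset <- function(tset, transcript_id, start, end, mutate_at = NULL) {
  n <- length(transcript_id)
  ids <- sprintf("r%03d", seq_len(n))
  seqs <- substring(tset$sequences[transcript_id], start + 1L, end)
  errs <- rep(list(integer(0)), n)
  if (!is.null(mutate_at)) {
    for (i in seq_len(n)) {
      for (off in mutate_at[[i]]) {
        ch <- substring(seqs[i], off + 1L, off + 1L)
        substr(seqs[i], off + 1L, off + 1L) <- setdiff(c("A", "C", "G", "T"), ch)[1]
      }
      errs[[i]] <- as.integer(mutate_at[[i]])
    }
  }
  structure(list(
    reads = data.frame(read_id = ids, transcript_id = transcript_id,
                       start = as.integer(start), end = as.integer(end),
                       length = as.integer(end - start),
                       stringsAsFactors = FALSE),
    sequences = setNames(unname(seqs), ids),
    error_positions = setNames(errs, ids),
    params = list(n_reads = n, mean_len = mean(end - start),
                  error_rate = 0, seed = 0L)
  ), class = "read_set")
}

# Fraction of positions at which two equal-length strings agree — the simple
# aligned identity counter used to verify paralog divergence.
aligned_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

# Brute-force O(n^2) transitive-closure oracle for interval components:
# full pairwise overlap matrix, then breadth-first closure from each seed.
brute_components <- function(starts, ends, min_overlap = 1L) {
  n <- length(starts)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    pmin(ends[i], ends[j]) - pmax(starts[i], starts[j]) >= min_overlap)
  diag(adj) <- TRUE
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      members <- logical(n)
      frontier <- i
      while (length(frontier)) {
        members[frontier] <- TRUE
        nbrs <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
        frontier <- nbrs[!members[nbrs]]
      }
      comp[members] <- cid
    }
  }
  comp
}

# The same partition under possibly different labels?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1L)
}

# Build a hit_table row directly (0-based half-open spans).
make_hit <- function(query, subject, q = c(0L, 100L), s = c(0L, 100L),
                     subject_length = 100L, unit = "nt",
                     evalue = 1e-20, bitscore = 100) {
  data.frame(query_id = query, subject_id = subject,
             q_start = q[1], q_end = q[2], s_start = s[1], s_end = s[2],
             evalue = evalue, bitscore = bitscore,
             subject_length = as.integer(subject_length),
             subject_unit = unit, stringsAsFactors = FALSE)
}

make_hit_table <- function(hits, direction = "forward", cutoff = 1e-6) {
  structure(list(direction = direction, hits = hits, evalue_cutoff = cutoff),
            class = "hit_table")
}

unigene_ids_for_test <- function(assembly) {
  c(assembly$contigs$contig_id, assembly$singletons$read_id)
}

scope_coverages_for_test <- function(assembly) {
  assembly$contigs$read_bases / assembly$contigs$length
}

# Partition refinement check: reads in one component of the subset must stay
# together in the superset (adding reads only merges, never splits).
partition_refines <- function(sub_comp, super_comp) {
  all(tapply(super_comp, sub_comp, function(x) length(unique(x))) == 1L)
}
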