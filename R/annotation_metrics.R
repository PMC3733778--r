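new_hit_table <- function(hits, direction, cutoff) {
  structure(list(direction = direction, hits = hits, evalue_cutoff = cutoff),
            class = "hit_table")
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             subject_length = integer(0), subject_unit = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table (%s): %d best hits to %d subjects, e-value cutoff %g\n",
              x$direction, nrow(x$hits), length(unique(x$hits$subject_id)),
              x$evalue_cutoff))
  invisible(x)
}

#' Parse a 12-column BLAST-style tabular hit file into a best-hit table
#'
#' Expects the standard tabular dialect (`-outfmt 6`): qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore. Rows above
#' the e-value cutoff are dropped; for each query the minimum-e-value row is
#' kept, ties broken by higher bitscore then lexicographically smaller
#' subject id (BLAST output order is not stable, so tie-breaking must be
#' deterministic). Coordinates are converted from 1-based inclusive to
#' 0-based half-open.
#'
#' @param path Tabular hit file.
#' @param direction `"forward"` (assembly vs reference) or `"reverse"`
#'   (reference vs assembly).
#' @param evalue_cutoff Maximum e-value retained (default 1e-6).
#' @param subject_lengths Named vector mapping subject id to its length.
#' @param subject_unit `"aa"` or `"nt"` for the subjects.
#' @return A `hit_table` with at most one hit per query.
#' @export
parse_tabular_hits <- function(path, direction = c("forward", "reverse"),
                               evalue_cutoff = 1e-6, subject_lengths,
                               subject_unit = c("aa", "nt")) {
  direction <- match.arg(direction)
  subject_unit <- match.arg(subject_unit)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(new_hit_table(empty_hits(), direction, evalue_cutoff))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad))
    stop(sprintf("malformed hit row at line %d: expected 12 tab-separated columns",
                 bad[1]), call. = FALSE)
  m <- do.call(rbind, fields)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   q1 = as.integer(m[, 7]), q2 = as.integer(m[, 8]),
                   s1 = as.integer(m[, 9]), s2 = as.integer(m[, 10]),
                   evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(df)) {
    ord <- order(df$query_id, df$evalue, -df$bitscore, df$subject_id)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$query_id), , drop = FALSE]
  }
  miss <- setdiff(df$subject_id, names(subject_lengths))
  if (length(miss))
    stop("unknown subject length for: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  hits <- data.frame(query_id = df$query_id, subject_id = df$subject_id,
                     q_start = pmin(df$q1, df$q2) - 1L,
                     q_end = pmax(df$q1, df$q2),
                     s_start = pmin(df$s1, df$s2) - 1L,
                     s_end = pmax(df$s1, df$s2),
                     evalue = df$evalue, bitscore = df$bitscore,
                     subject_length = as.integer(subject_lengths[df$subject_id]),
                     subject_unit = subject_unit, stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  new_hit_table(hits, direction, evalue_cutoff)
}

# one row per unigene: id, source_transcript, span_start, span_end, length
unigene_table <- function(assembly) {
  co <- assembly$contigs
  si <- assembly$singletons
  rbind(data.frame(id = co$contig_id, source_transcript = co$source_transcript,
                   span_start = co$span_start, span_end = co$span_end,
                   length = co$length, stringsAsFactors = FALSE),
        data.frame(id = si$read_id, source_transcript = si$source_transcript,
                   span_start = si$start, span_end = si$end,
                   length = si$length, stringsAsFactors = FALSE))
}

#' True (provenance-based) annotation of an assembly
#'
#' Annotates each contig and singleton to the transcript its constituent
#' reads were sourced from — the zero-distance, error-free annotation oracle
#' against which similarity-based annotation can be compared. Requires
#' provenance, so it is not computable for external assemblies ingested
#' without membership information.
#'
#' @param assembly An `assembly` with known source transcripts.
#' @param tset The `transcript_set` (supplies subject lengths).
#' @return A forward `hit_table` whose subjects are transcript ids.
#' @export
true_annotation_table <- function(assembly, tset) {
  u <- unigene_table(assembly)
  if (anyNA(u$source_transcript))
    stop("true annotation requires read provenance for every sequence",
         call. = FALSE)
  tx_len <- setNames(tset$transcripts$length, tset$transcripts$transcript_id)
  hits <- data.frame(query_id = u$id, subject_id = u$source_transcript,
                     q_start = 0L, q_end = u$length,
                     s_start = u$span_start, s_end = u$span_end,
                     evalue = 0, bitscore = 2 * u$length,
                     subject_length = as.integer(tx_len[u$source_transcript]),
                     subject_unit = "nt", stringsAsFactors = FALSE)
  new_hit_table(hits, "forward", 1e-6)
}

#' Forward annotation of an assembly against a reference set (provenance oracle)
#'
#' A lightweight stand-in for a BLASTX-style search on synthetic data: each
#' unigene is matched to the ortholog of its source transcript, with the
#' matched region being the overlap of the unigene span with the transcript's
#' CDS (mapped into reference coordinates; divided by three for amino-acid
#' references). Unigenes whose CDS overlap is shorter than `min_match` bases
#' — e.g. UTR-only singletons — receive no hit, which is what makes annotation
#' rates informative. Real BLAST tabular files parsed with
#' [parse_tabular_hits()] can be used interchangeably everywhere a
#' `hit_table` is consumed.
#'
#' @param assembly An `assembly` with provenance.
#' @param tset The `transcript_set`.
#' @param refset A `reference_set` for the same transcriptome.
#' @param min_match Minimum matched CDS length in nucleotides (default 30).
#' @return A forward `hit_table` (subjects are reference ids). Subject spans
#'   are clipped to the reference length; query spans are not, so the
#'   paper-literal matched-base OHR convention remains available.
#' @export
annotate_by_provenance <- function(assembly, tset, refset, min_match = 30L) {
  u <- unigene_table(assembly)
  tx <- tset$transcripts
  idx <- match(u$source_transcript, tx$transcript_id)
  u5 <- tx$utr5_len[idx]; L <- tx$length[idx]; u3 <- tx$utr3_len[idx]
  ov_s <- pmax(u$span_start, u5)
  ov_e <- pmin(u$span_end, L - u3)
  m_nt <- ov_e - ov_s
  ref <- unname(refset$ortholog_map[u$source_transcript])
  keep <- !is.na(ref) & m_nt >= min_match
  u <- u[keep, , drop = FALSE]
  ov_s <- ov_s[keep]; ov_e <- ov_e[keep]; m_nt <- m_nt[keep]
  u5 <- u5[keep]; ref <- ref[keep]
  if (nrow(u) == 0L)
    return(new_hit_table(empty_hits(), "forward", 1e-6))

  div <- if (refset$unit == "aa") 3L else 1L
  m_units <- m_nt %/% div
  s0 <- (ov_s - u5) %/% div
  s1 <- s0 + m_units
  Lr <- setNames(refset$refs$length, refset$refs$ref_id)[ref]
  s0c <- pmin(s0, Lr)
  s1c <- pmin(s1, Lr)
  keep2 <- m_units >= 1L & (s1c - s0c) >= 1L
  hits <- data.frame(query_id = u$id, subject_id = ref,
                     q_start = ov_s - u$span_start, q_end = ov_e - u$span_start,
                     s_start = as.integer(s0c), s_end = as.integer(s1c),
                     evalue = 10^(-pmin(180, m_units)),
                     bitscore = 2 * m_units,
                     subject_length = as.integer(Lr),
                     subject_unit = refset$unit,
                     stringsAsFactors = FALSE)[keep2, , drop = FALSE]
  rownames(hits) <- NULL
  new_hit_table(hits, "forward", 1e-6)
}

# identity proxy between two transcripts of the same synthetic transcriptome:
# 1 for the same transcript; shared-exon length fraction for isoforms of one
# gene; the family identity parameter for paralogous genes; 0 otherwise.
transcript_identity <- function(tset, t1, t2) {
  if (t1 == t2) return(1)
  tx <- tset$transcripts
  g1 <- tx$gene_id[match(t1, tx$transcript_id)]
  g2 <- tx$gene_id[match(t2, tx$transcript_id)]
  if (g1 == g2) {
    shared <- intersect(tset$exons[[t1]], tset$exons[[t2]])
    return(sum(tset$exon_lengths[shared]) /
             max(tx$length[match(c(t1, t2), tx$transcript_id)]))
  }
  f1 <- tx$family_id[match(t1, tx$transcript_id)]
  f2 <- tx$family_id[match(t2, tx$transcript_id)]
  if (!is.na(f1) && !is.na(f2) && f1 == f2)
    return(tset$params$paralog_spec$identity)
  0
}

#' Reverse annotation of a reference set against an assembly (provenance oracle)
#'
#' A TBLASTN-style search stand-in: each reference sequence is matched to the
#' best unigene among those sourced from its own transcript, from sibling
#' isoforms of the same gene, or from paralogous genes of the same family.
#' Candidates are scored by matched CDS length times a sequence-identity
#' proxy (shared-exon fraction for isoforms, the family identity parameter
#' for paralogs), so a reference whose own transcript is poorly assembled can
#' best-hit a paralog's contig — exactly the collapse signal the collapse
#' factor measures.
#'
#' @param assembly An `assembly` with provenance.
#' @param tset The `transcript_set`.
#' @param refset The `reference_set`.
#' @param scope Match against `"unigenes"` or `"contigs"` only.
#' @param min_match Minimum matched CDS length (nt) for a candidate.
#' @param min_identity Minimum identity proxy for a candidate.
#' @return A reverse `hit_table`: queries are reference ids, subjects are
#'   unigene ids.
#' @export
reverse_annotate_by_provenance <- function(assembly, tset, refset,
                                           scope = c("unigenes", "contigs"),
                                           min_match = 30L, min_identity = 0.3) {
  scope <- match.arg(scope)
  u <- unigene_table(assembly)
  if (scope == "contigs") u <- u[u$id %in% assembly$contigs$contig_id, , drop = FALSE]
  tx <- tset$transcripts
  idx <- match(u$source_transcript, tx$transcript_id)
  ov_s <- pmax(u$span_start, tx$utr5_len[idx])
  ov_e <- pmin(u$span_end, tx$length[idx] - tx$utr3_len[idx])
  u$m_nt <- pmax(0L, ov_e - ov_s)
  u_by_tx <- split(seq_len(nrow(u)), u$source_transcript)

  gene_of <- setNames(tx$gene_id, tx$transcript_id)
  fam_of <- setNames(tx$family_id, tx$transcript_id)
  tx_by_gene <- split(tx$transcript_id, tx$gene_id)
  gene_by_fam <- tset$paralog_families

  div <- if (refset$unit == "aa") 3L else 1L
  rows <- vector("list", nrow(refset$refs))
  for (i in seq_len(nrow(refset$refs))) {
    t_r <- refset$refs$source_transcript[i]
    related <- tx_by_gene[[gene_of[t_r]]]
    fam <- fam_of[t_r]
    if (!is.na(fam))
      related <- unique(c(related,
                          unlist(tx_by_gene[gene_by_fam[[fam]]], use.names = FALSE)))
    cand <- unlist(u_by_tx[intersect(related, names(u_by_tx))], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    ident <- vapply(u$source_transcript[cand], function(t_u)
      transcript_identity(tset, t_u, t_r), 0)
    ok <- u$m_nt[cand] >= min_match & ident >= min_identity
    cand <- cand[ok]; ident <- ident[ok]
    if (length(cand) == 0L) next
    score <- u$m_nt[cand] * ident
    best <- cand[order(-score, u$id[cand])][1]
    m_units <- u$m_nt[best] %/% div
    Lr <- refset$refs$length[i]
    rows[[i]] <- data.frame(
      query_id = refset$refs$ref_id[i], subject_id = u$id[best],
      q_start = 0L, q_end = as.integer(min(m_units, Lr)),
      s_start = 0L, s_end = u$m_nt[best],
      evalue = 10^(-pmin(180, m_units)), bitscore = 2 * m_units,
      subject_length = u$length[best], subject_unit = "nt",
      stringsAsFactors = FALSE)
  }
  hits <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)]) else empty_hits()
  rownames(hits) <- NULL
  new_hit_table(hits, "reverse", 1e-6)
}

#' Count distinct annotations among a set of sequences
#'
#' @param table A forward `hit_table`.
#' @param scope_ids Sequence ids defining the scope (contigs, unigenes, ...).
#' @return Number of distinct subject ids hit by queries in scope.
#' @export
unique_annotation_count <- function(table, scope_ids) {
  h <- table$hits
  length(unique(h$subject_id[h$query_id %in% scope_ids]))
}

#' Annotations present only in singletons
#'
#' @param table A forward `hit_table`.
#' @param contig_ids,singleton_ids Ids of the two unigene classes.
#' @return Count of subjects hit by singletons but by no contig.
#' @export
singleton_only_annotations <- function(table, contig_ids, singleton_ids) {
  h <- table$hits
  length(setdiff(unique(h$subject_id[h$query_id %in% singleton_ids]),
                 unique(h$subject_id[h$query_id %in% contig_ids])))
}

#' Ortholog hit ratio
#'
#' The fraction of the best-matched reference sequence covered by a unigene's
#' match; values near 1 indicate a fully assembled transcript. Two
#' conventions are available. `"subject_span"` (default) divides the matched
#' subject span by the subject length — unit-safe and bounded by 1 for a
#' single HSP. `"query_bases"` divides the matched query bases (over 3 for
#' amino-acid subjects) by the subject length — the literal matched-base
#' formulation, which can exceed 1 when the query transcript has expanded
#' relative to the reference; this is the convention the OHR-error
#' decomposition relies on.
#'
#' @param hits A `hit_table` or its `hits` data frame.
#' @param convention `"subject_span"` or `"query_bases"`.
#' @return Named numeric vector of OHRs, one per query.
#' @export
ortholog_hit_ratio <- function(hits, convention = c("subject_span", "query_bases")) {
  convention <- match.arg(convention)
  h <- if (inherits(hits, "hit_table")) hits$hits else hits
  ohr <- if (convention == "subject_span") {
    (h$s_end - h$s_start) / h$subject_length
  } else {
    div <- ifelse(h$subject_unit == "aa", 3, 1)
    ((h$q_end - h$q_start) / div) / h$subject_length
  }
  setNames(ohr, h$query_id)
}

#' OHR error and normalized OHR error
#'
#' For each query annotated in both a same-species (`self_table`) and a
#' distant (`distant_table`) reference, the raw OHR error is
#' OHR_distant / OHR_self: deviations from 1 mix true match-quality loss with
#' evolutionary length change of the ortholog. The normalized error rescales
#' by the reference length ratio, cancelling the length change and isolating
#' match quality (for matched regions of equal query extent it reduces to the
#' matched-span ratio, so values above 1 indicate genuine over-matching
#' rather than ortholog contraction). OHRs use the matched-query-bases
#' convention.
#'
#' @param self_table Forward `hit_table` vs the zero-distance reference.
#' @param distant_table Forward `hit_table` vs the diverged reference.
#' @return Data frame with `query_id`, `raw_error`, `normalized_error`,
#'   `length_ratio` (distant / self reference length); one row per query
#'   annotated in both tables.
#' @export
ohr_error <- function(self_table, distant_table) {
  s <- self_table$hits
  d <- distant_table$hits
  common <- intersect(s$query_id, d$query_id)
  s <- s[match(common, s$query_id), , drop = FALSE]
  d <- d[match(common, d$query_id), , drop = FALSE]
  ohr_s <- ortholog_hit_ratio(s, "query_bases")
  ohr_d <- ortholog_hit_ratio(d, "query_bases")
  lr <- d$subject_length / s$subject_length
  raw <- unname(ohr_d / ohr_s)
  data.frame(query_id = common, raw_error = raw,
             normalized_error = raw * lr, length_ratio = lr,
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits
#'
#' A unigene u and reference p form an RBH when u's best forward hit is p and
#' p's best reverse hit is u — strong evidence of orthology. Counts and the
#' percentage of forward-annotated sequences having an RBH are reported per
#' scope when contig/singleton ids are supplied.
#'
#' @param forward Forward `hit_table` (unigene -> reference).
#' @param reverse Reverse `hit_table` (reference -> unigene).
#' @param contig_ids,singleton_ids Optional scope definitions.
#' @return List with `pairs` (data frame `query_id`, `subject_id`),
#'   `rbh_count` and `pct_annotated_with_rbh` (named by scope).
#' @export
reciprocal_best_hits <- function(forward, reverse,
                                 contig_ids = NULL, singleton_ids = NULL) {
  f <- forward$hits
  r <- reverse$hits
  back <- setNames(r$subject_id, r$query_id)
  is_rbh <- !is.na(back[f$subject_id]) & back[f$subject_id] == f$query_id
  pairs <- data.frame(query_id = f$query_id[is_rbh],
                      subject_id = f$subject_id[is_rbh],
                      stringsAsFactors = FALSE)
  scopes <- if (is.null(contig_ids)) list(all = unique(f$query_id))
            else list(contigs = contig_ids,
                      unigenes = c(contig_ids, singleton_ids))
  count <- vapply(scopes, function(ids) sum(pairs$query_id %in% ids), 0L)
  annotated <- vapply(scopes, function(ids) sum(f$query_id %in% ids), 0L)
  pct <- ifelse(annotated > 0, 100 * count / annotated, NA_real_)
  list(pairs = pairs, rbh_count = count,
       pct_annotated_with_rbh = setNames(as.numeric(pct), names(scopes)))
}

#' Collapse factors and reverse rarefaction
#'
#' The collapse factor of a sequence is the number of reference sequences
#' whose best (reverse) hit is that sequence; CF > 1 suggests paralogous or
#' isoform reads collapsed into one consensus. Summing CFs gives the reverse
#' rarefaction — a reference-side estimate of transcript discovery, equal to
#' the number of reverse-annotated references hitting the scope.
#'
#' @param reverse A reverse `hit_table`.
#' @param scope_ids Sequence ids to restrict to (contigs or unigenes).
#' @return A `collapse_report`: list with `cf` (named integer, sequences with
#'   CF >= 1 only), `average_cf`, `reverse_rarefaction`.
#' @export
collapse_factors <- function(reverse, scope_ids) {
  h <- reverse$hits
  h <- h[h$subject_id %in% scope_ids, , drop = FALSE]
  cf <- table(h$subject_id)
  cf <- setNames(as.integer(cf), names(cf))
  structure(list(cf = cf,
                 average_cf = if (length(cf)) mean(cf) else NA_real_,
                 reverse_rarefaction = sum(cf)),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf("collapse_report: %d sequences hit, average CF %.3f, reverse rarefaction %d\n",
              length(x$cf), x$average_cf, x$reverse_rarefaction))
  invisible(x)
}
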