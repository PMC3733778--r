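#' Connected components of intervals under an overlap threshold
#'
#' Two half-open intervals are connected when they share at least
#' `min_overlap` bases (for the default 1 this is any non-empty intersection;
#' abutting intervals share zero bases and are not connected). Components are
#' the transitive closure of this relation, computed by a sort-and-sweep
#' (O(n log n) for `min_overlap = 1`; a union-find sweep over the active set
#' otherwise, since with a higher threshold a short interval may fail to
#' connect even when lying inside the current span).
#'
#' @param intervals Two-column matrix or data frame of 0-based half-open
#'   `(start, end)` pairs.
#' @param min_overlap Minimum shared bases required to connect (>= 1).
#' @return Integer vector of component ids (1-based, numbered by leftmost
#'   span start), parallel to the input rows.
#' @export
overlap_components <- function(intervals, min_overlap = 1L) {
  s <- as.integer(intervals[[1]])
  e <- as.integer(intervals[[2]])
  if (any(e <= s)) stop("intervals must be half-open with end > start",
                        call. = FALSE)
  n <- length(s)
  if (n == 0L) return(integer(0))
  oo <- order(s, e)
  so <- s[oo]; eo <- e[oo]
  comp_sorted <- integer(n)
  if (min_overlap <= 1L) {
    hi <- cummax(eo)
    breaks <- c(TRUE, so[-1L] >= hi[-n])
    comp_sorted <- cumsum(breaks)
  } else {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    active <- integer(0)
    for (i in seq_len(n)) {
      # an active interval can still connect to i (or anything later) only
      # if it reaches at least min_overlap bases past so[i]
      active <- active[eo[active] >= so[i] + min_overlap]
      hits <- active[pmin(eo[active], eo[i]) - so[i] >= min_overlap]
      for (h in hits) {
        rh <- find(h); ri <- find(i)
        if (rh != ri) parent[max(rh, ri)] <- min(rh, ri)
      }
      active <- c(active, i)
    }
    roots <- vapply(seq_len(n), find, 0L)
    comp_sorted <- match(roots, unique(roots))
  }
  out <- integer(n)
  out[oo] <- comp_sorted
  out
}

#' Build a perfect assembly from read provenance
#'
#' Reads are grouped by source transcript; within each transcript, every set
#' of reads overlapping by at least `min_overlap` bases (transitively) forms
#' one component. Components of two or more reads become contigs whose
#' consensus is the reference substring spanning the union of member read
#' intervals — i.e. free of sequencing error by construction. Single-read
#' components become singletons whose sequence is likewise error-corrected
#' from the reference. Reads from different isoforms of one gene are never
#' co-assembled, so at saturating depth the contig count converges to the
#' transcript count.
#'
#' `min_overlap = 1` with `min_reads = 2` is the perfect assembler. The two
#' knobs degrade it in controlled ways for consistency testing: raising
#' `min_overlap` refuses short true overlaps (fewer joins), and raising
#' `min_reads` emulates a singleton-heavy assembler that only assembles
#' well-covered components, leaving the reads of smaller components as
#' individual singletons — the signature (fewer but longer contigs, many
#' singletons) of real transcriptome assemblers on skewed expression data.
#'
#' @param readset A `read_set`.
#' @param tset The `transcript_set` the reads were simulated from.
#' @param min_overlap Minimum overlap in bases to join two reads (default 1).
#' @param min_reads Minimum component size output as a contig (default 2);
#'   reads of smaller components become singletons.
#' @param label Assembly label stored in the result.
#' @return An `assembly`: list with `contigs` (data frame: `contig_id`,
#'   `source_transcript`, `span_start`, `span_end`, `length`, `n_reads`,
#'   `read_bases`), `contig_seqs`, `contig_members` (named list of read ids),
#'   `singletons` (data frame: `read_id`, `source_transcript`, `start`,
#'   `end`, `length`), `singleton_seqs`, `label`.
#' @export
perfect_assemble <- function(readset, tset, min_overlap = 1L, min_reads = 2L,
                             label = if (min_overlap == 1L && min_reads == 2L)
                                       "perfect" else "degraded") {
  min_reads <- max(2L, as.integer(min_reads))
  r <- readset$reads
  unknown <- setdiff(unique(r$transcript_id), tset$transcripts$transcript_id)
  if (length(unknown))
    stop("reads reference transcripts absent from the transcript set: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)

  by_tx <- split(seq_len(nrow(r)), r$transcript_id)
  contig_rows <- list()
  contig_members <- list()
  singleton_idx <- integer(0)

  for (tx in names(by_tx)) {
    idx <- by_tx[[tx]]
    comp <- overlap_components(list(r$start[idx], r$end[idx]), min_overlap)
    for (ci in seq_len(max(comp))) {
      m <- idx[comp == ci]
      if (length(m) < min_reads) {
        singleton_idx <- c(singleton_idx, m)
      } else {
        key <- sprintf("%s.c%d", tx, ci)
        contig_rows[[key]] <- data.frame(
          contig_id = key, source_transcript = tx,
          span_start = min(r$start[m]), span_end = max(r$end[m]),
          n_reads = length(m), read_bases = sum(r$length[m]),
          stringsAsFactors = FALSE)
        contig_members[[key]] <- r$read_id[m]
      }
    }
  }

  if (length(contig_rows)) {
    contigs <- do.call(rbind, contig_rows)
    rownames(contigs) <- NULL
    contigs$length <- contigs$span_end - contigs$span_start
    contigs <- contigs[, c("contig_id", "source_transcript", "span_start",
                           "span_end", "length", "n_reads", "read_bases")]
    contig_seqs <- setNames(
      substring(tset$sequences[contigs$source_transcript],
                contigs$span_start + 1L, contigs$span_end),
      contigs$contig_id)
  } else {
    contigs <- data.frame(contig_id = character(0),
                          source_transcript = character(0),
                          span_start = integer(0), span_end = integer(0),
                          length = integer(0), n_reads = integer(0),
                          read_bases = integer(0), stringsAsFactors = FALSE)
    contig_seqs <- character(0)
  }

  singles <- r[singleton_idx, c("read_id", "transcript_id", "start", "end",
                                "length")]
  names(singles)[2] <- "source_transcript"
  rownames(singles) <- NULL
  singleton_seqs <- setNames(
    substring(tset$sequences[singles$source_transcript],
              singles$start + 1L, singles$end),
    singles$read_id)

  structure(list(contigs = contigs, contig_seqs = contig_seqs,
                 contig_members = contig_members,
                 singletons = singles, singleton_seqs = singleton_seqs,
                 label = label, min_overlap = as.integer(min_overlap)),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly '%s': %d contigs, %d singletons (%d unigenes)\n",
              x$label, nrow(x$contigs), nrow(x$singletons),
              nrow(x$contigs) + nrow(x$singletons)))
  if (nrow(x$contigs))
    cat(sprintf("  contig bp %d, mean length %.0f, mean reads/contig %.1f\n",
                sum(x$contigs$length), mean(x$contigs$length),
                mean(x$contigs$n_reads)))
  invisible(x)
}

unigene_ids <- function(assembly) {
  c(assembly$contigs$contig_id, assembly$singletons$read_id)
}

scope_ids <- function(assembly, scope = c("unigenes", "contigs")) {
  scope <- match.arg(scope)
  if (scope == "contigs") assembly$contigs$contig_id else unigene_ids(assembly)
}

#' Write an assembly (FASTA + membership TSV)
#'
#' The membership table has one row per sequence: `sequence_id`, `type`
#' (`contig`/`singleton`), `source_transcript`, `span_start`, `span_end`,
#' `read_ids` (comma-joined). The same shape is accepted back by
#' [read_assembly()], so externally produced assemblies can enter the metric
#' suite.
#'
#' @param assembly An `assembly`.
#' @param fasta,membership_tsv Output paths (`NULL` to skip).
#' @export
write_assembly <- function(assembly, fasta = NULL, membership_tsv = NULL) {
  if (!is.null(fasta))
    write_fasta(c(assembly$contig_seqs, assembly$singleton_seqs), fasta, "dna")
  if (!is.null(membership_tsv)) {
    co <- assembly$contigs
    si <- assembly$singletons
    df <- rbind(
      data.frame(sequence_id = co$contig_id,
                 type = rep("contig", nrow(co)),
                 source_transcript = co$source_transcript,
                 span_start = co$span_start, span_end = co$span_end,
                 read_ids = as.character(
                   vapply(assembly$contig_members[co$contig_id],
                          paste, "", collapse = ",")),
                 stringsAsFactors = FALSE),
      data.frame(sequence_id = si$read_id,
                 type = rep("singleton", nrow(si)),
                 source_transcript = si$source_transcript,
                 span_start = si$start, span_end = si$end,
                 read_ids = si$read_id, stringsAsFactors = FALSE))
    write_tsv(df, membership_tsv)
  }
  invisible(c(fasta, membership_tsv))
}

#' Ingest an external assembly (FASTA plus optional membership TSV)
#'
#' Any assembler's output can enter the metric suite this way. Without a
#' membership table only sequence-intrinsic metrics (lengths, N50, counts)
#' are computable. A read listed under several sequences is tolerated and
#' counted once for read-usage percentages. Sequences with two or more member
#' reads are treated as contigs; the rest as singletons.
#'
#' @param fasta Assembly FASTA path.
#' @param membership_tsv Optional TSV with columns `sequence_id`, `type`,
#'   `read_ids` (comma-joined) and optionally `source_transcript`,
#'   `span_start`, `span_end`.
#' @param readset Optional `read_set`, used to compute per-contig read base
#'   counts (sum of full read lengths when spans are absent).
#' @param label Assembly label.
#' @return An `assembly` with `label = "external"` semantics.
#' @export
read_assembly <- function(fasta, membership_tsv = NULL, readset = NULL,
                          label = "external") {
  seqs <- read_fasta(fasta, "dna")
  ids <- names(seqs)
  members <- setNames(vector("list", length(ids)), ids)
  type <- rep("contig", length(ids))
  src <- rep(NA_character_, length(ids))
  span_s <- rep(NA_integer_, length(ids))
  span_e <- rep(NA_integer_, length(ids))

  if (!is.null(membership_tsv)) {
    mb <- read_tsv(membership_tsv, colClasses = c(read_ids = "character"))
    mb <- mb[mb$sequence_id %in% ids, , drop = FALSE]
    rid <- strsplit(mb$read_ids, ",", fixed = TRUE)
    members[mb$sequence_id] <- rid
    if ("type" %in% names(mb)) {
      type[match(mb$sequence_id, ids)] <- mb$type
    } else {
      type[match(mb$sequence_id, ids)] <-
        ifelse(lengths(rid) >= 2L, "contig", "singleton")
    }
    for (col in c("source_transcript", "span_start", "span_end")) {
      if (col %in% names(mb)) {
        v <- mb[[col]][match(ids, mb$sequence_id)]
        if (col == "source_transcript") src <- v
        if (col == "span_start") span_s <- as.integer(v)
        if (col == "span_end") span_e <- as.integer(v)
      }
    }
  }

  is_contig <- type == "contig"
  n_reads <- vapply(members, function(m) length(unique(m)), 0L)
  read_bases <- rep(NA_integer_, length(ids))
  if (!is.null(readset)) {
    rl <- setNames(readset$reads$length, readset$reads$read_id)
    read_bases <- vapply(members, function(m)
      as.integer(sum(rl[unique(m)], na.rm = TRUE)), 0L)
  }

  contigs <- data.frame(contig_id = ids[is_contig],
                        source_transcript = src[is_contig],
                        span_start = span_s[is_contig],
                        span_end = span_e[is_contig],
                        length = nchar(seqs[is_contig]),
                        n_reads = n_reads[is_contig],
                        read_bases = read_bases[is_contig],
                        stringsAsFactors = FALSE)
  sing_member <- vapply(members[!is_contig], function(m)
    if (length(m)) m[1] else NA_character_, "")
  singletons <- data.frame(read_id = ids[!is_contig],
                           source_transcript = src[!is_contig],
                           start = span_s[!is_contig],
                           end = span_e[!is_contig],
                           length = nchar(seqs[!is_contig]),
                           stringsAsFactors = FALSE)
  rownames(contigs) <- rownames(singletons) <- NULL

  structure(list(contigs = contigs, contig_seqs = seqs[is_contig],
                 contig_members = members[is_contig],
                 singletons = singletons, singleton_seqs = seqs[!is_contig],
                 label = label, min_overlap = NA_integer_),
            class = "assembly")
}
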