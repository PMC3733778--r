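#' Build the rank power-law, length-weighted sampling model
#'
#' Transcripts are placed in one fixed random permutation; the transcript at
#' (1-based) permutation position i is sampled with probability proportional
#' to l(t_i)/i, where l() is transcript length in bases. The same model (and
#' hence the same permutation) is meant to be reused across all sequencing
#' depths and read lengths of an experiment, so that expression ranks are
#' comparable between ladder points.
#'
#' @param tset A `transcript_set`.
#' @param seed Integer seed fixing the permutation.
#' @return A `sampling_model`: list with `permutation` (transcript ids in rank
#'   order) and `weights` (named, normalized selection probabilities in
#'   permutation order).
#' @export
build_sampling_model <- function(tset, seed = 1L) {
  tx <- tset$transcripts
  if (nrow(tx) == 0L) stop("empty transcript set", call. = FALSE)
  perm <- with_seed(seed, sample(tx$transcript_id))
  len <- setNames(tx$length, tx$transcript_id)[perm]
  w <- len / seq_along(perm)
  w <- w / sum(w)
  structure(list(permutation = perm, weights = setNames(w, perm), seed = seed),
            class = "sampling_model")
}

#' @export
print.sampling_model <- function(x, ...) {
  cat(sprintf("sampling_model: %d transcripts, top weight %.3g (rank 1), bottom %.3g\n",
              length(x$permutation), x$weights[1], x$weights[length(x$weights)]))
  invisible(x)
}

#' Read length model
#'
#' Read lengths are drawn from a normal distribution with standard deviation
#' and minimum both equal to 25% of the mean, the minimum being enforced by
#' resampling (draws below the minimum are redrawn, not clamped, so no
#' probability mass piles up at the cutoff). A draw longer than the source
#' transcript is replaced by the transcript length (the whole transcript is
#' sequenced).
#'
#' @param mean_len Mean read length in bases.
#' @param sd,min_len Optional overrides; default `mean_len / 4` for both.
#' @return A `read_length_model` list.
#' @export
read_length_model <- function(mean_len, sd = mean_len / 4, min_len = mean_len / 4) {
  stopifnot(mean_len >= 1)
  structure(list(mean_len = mean_len, sd = sd, min_len = min_len),
            class = "read_length_model")
}

#' Draw read lengths (resampled truncated normal, transcript-limited)
#'
#' Uses the current RNG state. Draws are rounded to integers and redrawn while
#' below `min_len`; each is then capped at its transcript's length.
#'
#' @param model A [read_length_model()].
#' @param transcript_len Integer vector of source transcript lengths (recycled
#'   against `n`).
#' @param n Number of draws (default `length(transcript_len)`).
#' @return Integer vector of read lengths.
#' @export
draw_read_lengths <- function(model, transcript_len, n = length(transcript_len)) {
  stopifnot(all(transcript_len >= 1))
  transcript_len <- rep_len(as.integer(transcript_len), n)
  l <- as.integer(round(rnorm(n, model$mean_len, model$sd)))
  bad <- which(l < model$min_len)
  while (length(bad)) {
    l[bad] <- as.integer(round(rnorm(length(bad), model$mean_len, model$sd)))
    bad <- bad[l[bad] < model$min_len]
  }
  pmin(l, transcript_len)
}

#' Apply uniform substitution errors to a sequence
#'
#' Each base is independently mutated with probability `p`, uniformly to one
#' of the three remaining bases (a mutated base therefore always differs from
#' the original, and the realized mismatch rate equals `p`). Uses the current
#' RNG state.
#'
#' @param sequence A single ACGT string.
#' @param p Per-base substitution probability in [0, 1].
#' @return List with `mutated` (string) and `error_positions` (0-based
#'   integer offsets of the substituted bases).
#' @export
apply_substitution_errors <- function(sequence, p) {
  stopifnot(p >= 0, p <= 1)
  n <- nchar(sequence)
  idx <- which(runif(n) < p)
  if (length(idx) && !all(strsplit(sequence, "")[[1]][idx] %in% DNA_BASES))
    stop("sequence contains non-ACGT bases", call. = FALSE)
  list(mutated = substitute_bases(sequence, idx),
       error_positions = idx - 1L)
}

#' Simulate EST/cDNA sequencing with full provenance
#'
#' Draws `n_reads` reads: the source transcript of each read is chosen i.i.d.
#' from the sampling model's rank power-law weights; its length from the
#' resampled truncated normal of `length_model` (capped at the transcript
#' length); its start uniformly over valid placements; substitution errors at
#' `error_rate` per base. Four independent RNG streams (transcript choice,
#' length, placement, errors) are derived from `seed`, so per-read draws do
#' not shift when `n_reads` changes.
#'
#' @param tset A `transcript_set`.
#' @param model A `sampling_model` built from `tset`.
#' @param length_model A [read_length_model()].
#' @param n_reads Number of reads (>= 1).
#' @param error_rate Per-base substitution probability (default 0.015).
#' @param seed Integer seed.
#' @param sequences If `FALSE`, only coordinates and provenance are generated
#'   (no base strings, no errors); useful for very deep samplings where only
#'   counts or lengths are needed.
#' @return A `read_set`: list with `reads` (data frame: `read_id`,
#'   `transcript_id`, `start`, `end`, `length`; 0-based half-open
#'   coordinates), `sequences` (named character or `NULL`),
#'   `error_positions` (named list of 0-based offsets or `NULL`), `params`.
#' @export
simulate_reads <- function(tset, model, length_model, n_reads,
                           error_rate = 0.015, seed = 1L, sequences = TRUE) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) stop("`n_reads` must be >= 1", call. = FALSE)
  stopifnot(inherits(model, "sampling_model"))
  tx_len <- setNames(tset$transcripts$length, tset$transcripts$transcript_id)

  tx <- with_seed(seed + 1L,
    sample(names(model$weights), n_reads, replace = TRUE,
           prob = model$weights))
  tl <- unname(tx_len[tx])
  len <- with_seed(seed + 2L, draw_read_lengths(length_model, tl, n_reads))
  start <- with_seed(seed + 3L,
    as.integer(floor(runif(n_reads) * (tl - len + 1L))))
  end <- start + len

  reads <- data.frame(read_id = sprintf("read%07d", seq_len(n_reads)),
                      transcript_id = tx, start = start, end = end,
                      length = len, stringsAsFactors = FALSE)

  seqs <- NULL
  errs <- NULL
  if (sequences) {
    raw <- substring(tset$sequences[tx], start + 1L, end)
    if (error_rate > 0) {
      mutated <- raw
      errs <- with_seed(seed + 4L, {
        e <- vector("list", n_reads)
        for (i in seq_len(n_reads)) {
          idx <- which(runif(len[i]) < error_rate)
          if (length(idx)) mutated[i] <- substitute_bases(raw[i], idx)
          e[[i]] <- idx - 1L
        }
        e
      })
      raw <- mutated
    } else {
      errs <- rep(list(integer(0)), n_reads)
    }
    seqs <- setNames(raw, reads$read_id)
    names(errs) <- reads$read_id
  }

  structure(list(reads = reads, sequences = seqs, error_positions = errs,
                 params = list(n_reads = n_reads,
                               mean_len = length_model$mean_len,
                               error_rate = error_rate, seed = seed)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, mean length %.1f bp, error rate %.3f%s\n",
              nrow(x$reads), mean(x$reads$length), x$params$error_rate,
              if (is.null(x$sequences)) " (coordinates only)" else ""))
  invisible(x)
}

#' Write simulated reads as FASTA or FASTQ
#'
#' FASTQ output uses a uniform placeholder quality character.
#'
#' @param readset A `read_set` with sequences.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param quality_char Placeholder quality for FASTQ (default `"I"`).
#' @export
write_reads <- function(readset, path, format = c("fasta", "fastq"),
                        quality_char = "I") {
  format <- match.arg(format)
  if (is.null(readset$sequences))
    stop("read set has no sequences (simulated with sequences = FALSE)",
         call. = FALSE)
  xs <- Biostrings::DNAStringSet(readset$sequences)
  if (format == "fasta") {
    Biostrings::writeXStringSet(xs, path)
  } else {
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(xs), function(w)
      strrep(quality_char, w), ""))
    Biostrings::writeXStringSet(xs, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Write / read the read-provenance table
#'
#' Columns: `read_id`, `transcript_id`, `start`, `end`, `strand`,
#' `error_offsets` (comma-joined 0-based offsets; empty allowed).
#'
#' @param readset A `read_set`.
#' @param path TSV path.
#' @return `write_provenance`: the path, invisibly. `read_provenance`: a data
#'   frame with `error_offsets` parsed into a list column.
#' @export
write_provenance <- function(readset, path) {
  r <- readset$reads
  offs <- if (is.null(readset$error_positions)) rep("", nrow(r))
          else vapply(readset$error_positions[r$read_id],
                      paste, "", collapse = ",")
  write_tsv(data.frame(read_id = r$read_id, transcript_id = r$transcript_id,
                       start = r$start, end = r$end, strand = "+",
                       error_offsets = offs, stringsAsFactors = FALSE),
            path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  df <- read_tsv(path, colClasses = c(error_offsets = "character"))
  df$error_offsets <- lapply(strsplit(df$error_offsets, ",", fixed = TRUE),
                             function(x) as.integer(x[nzchar(x)]))
  df
}
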