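DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute the bases of `seq` at 1-based positions `idx`, each uniformly to
# one of the three remaining bases. Returns the mutated string.
substitute_bases <- function(seq, idx) {
  if (length(idx) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- DNA_BASES[(match(chars[idx], DNA_BASES) - 1L + shift) %% 4L + 1L]
  paste(chars, collapse = "")
}

# Point-mutate a whole sequence at per-site rate `rate` (DNA alphabet unless
# `alphabet` given); used for paralog families and diverged references.
mutate_sequence <- function(seq, rate, alphabet = DNA_BASES) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(chars)) < rate)
  if (length(idx)) {
    k <- length(alphabet)
    shift <- sample.int(k - 1L, length(idx), replace = TRUE)
    chars[idx] <- alphabet[(match(chars[idx], alphabet) - 1L + shift) %% k + 1L]
  }
  paste(chars, collapse = "")
}

#' Write named sequences to a FASTA file
#'
#' Thin wrapper around [Biostrings::writeXStringSet()] accepting a plain named
#' character vector of nucleotide or amino-acid sequences.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file path.
#' @param type `"dna"` or `"aa"`.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "aa"), width = 70L) {
  type <- match.arg(type)
  xs <- if (type == "dna") Biostrings::DNAStringSet(sequences)
        else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(xs, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  xs <- if (type == "dna") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(xs)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
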