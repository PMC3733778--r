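metric_row <- function(metric, scope, value, units, label) {
  data.frame(metric = metric, scope = scope, assembly = label,
             value = as.numeric(value), units = units,
             stringsAsFactors = FALSE)
}

#' Aggregate assembly statistics
#'
#' Emits the basic output-size metrics: contig and singleton counts, percent
#' of reads incorporated into contigs (distinct reads in contigs divided by
#' total reads sequenced, x100 — a read listed under several sequences counts
#' once), base pairs in contigs, total assembly base pairs (contigs plus
#' singletons) and percent of assembly base pairs in contigs.
#'
#' @param assembly An `assembly`.
#' @param readset The `read_set` the assembly was built from.
#' @return Long-format data frame of metric records (`metric`, `scope`,
#'   `assembly`, `value`, `units`).
#' @export
aggregate_stats <- function(assembly, readset) {
  lab <- assembly$label
  used <- unique(unlist(assembly$contig_members, use.names = FALSE))
  missing <- setdiff(used, readset$reads$read_id)
  if (length(missing))
    stop("assembly references reads absent from the read set: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  n_total <- nrow(readset$reads)
  bp_contigs <- sum(assembly$contigs$length)
  bp_total <- bp_contigs + sum(assembly$singletons$length)
  rbind(
    metric_row("contig_count", "contigs", nrow(assembly$contigs), "count", lab),
    metric_row("singleton_count", "unigenes", nrow(assembly$singletons), "count", lab),
    metric_row("unigene_count", "unigenes",
               nrow(assembly$contigs) + nrow(assembly$singletons), "count", lab),
    metric_row("pct_reads_in_contigs", "contigs",
               100 * length(used) / n_total, "%", lab),
    metric_row("bp_in_contigs", "contigs", bp_contigs, "bp", lab),
    metric_row("total_bp", "unigenes", bp_total, "bp", lab),
    metric_row("pct_bp_in_contigs", "contigs",
               if (bp_total > 0) 100 * bp_contigs / bp_total else 0, "%", lab))
}

#' N50 length
#'
#' The length at which, walking sequences from longest to shortest, the
#' cumulative length first reaches at least half the total.
#'
#' @param lengths Non-empty vector of positive sequence lengths.
#' @return The N50 length (an element of `lengths`).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("N50 of an empty length set", call. = FALSE)
  stopifnot(all(lengths >= 1))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

scope_lengths <- function(assembly, scope) {
  if (scope == "contigs") assembly$contigs$length
  else c(assembly$contigs$length, assembly$singletons$length)
}

scope_coverages <- function(assembly, scope) {
  cov <- assembly$contigs$read_bases / assembly$contigs$length
  if (scope == "contigs") cov
  else c(cov, rep(1.0, nrow(assembly$singletons)))
}

#' Length, coverage and N50 statistics for a scope
#'
#' Coverage of a contig is the number of read bases incorporated divided by
#' its length; singletons are assigned coverage 1.0 and their corrected read
#' length. Both the unweighted and the length-weighted mean coverage are
#' emitted (the appropriate averaging convention is a judgment call, so both
#' are reported).
#'
#' @param assembly An `assembly`.
#' @param scope `"contigs"` or `"unigenes"`.
#' @return Long-format metric data frame; zero-length scope gives an empty
#'   frame with a warning.
#' @export
length_and_coverage_stats <- function(assembly, scope = c("unigenes", "contigs")) {
  scope <- match.arg(scope)
  lab <- assembly$label
  len <- scope_lengths(assembly, scope)
  if (length(len) == 0L) {
    warning("no sequences in scope '", scope, "'", call. = FALSE)
    return(metric_row(character(0), character(0), numeric(0), character(0),
                      character(0)))
  }
  cov <- scope_coverages(assembly, scope)
  out <- rbind(
    metric_row("mean_length", scope, mean(len), "bp", lab),
    metric_row("median_length", scope, median(len), "bp", lab),
    metric_row("n50_length", scope, n50(len), "bp", lab))
  if (!anyNA(cov)) {
    out <- rbind(out,
      metric_row("mean_coverage", scope, mean(cov), "x", lab),
      metric_row("median_coverage", scope, median(cov), "x", lab),
      metric_row("length_weighted_mean_coverage", scope,
                 sum(cov * len) / sum(len), "x", lab))
  }
  out
}

#' Coefficient of variation of per-sequence read counts
#'
#' Sample standard deviation divided by mean of the number of reads used per
#' sequence — a scale-invariant dispersion measure of how unevenly reads are
#' spread over the assembly. Singletons count one read in the unigene scope.
#'
#' @param assembly An `assembly`.
#' @param scope `"contigs"` or `"unigenes"`.
#' @return A single numeric; `NA` with a warning when the scope holds fewer
#'   than two sequences.
#' @export
read_count_cov <- function(assembly, scope = c("unigenes", "contigs")) {
  scope <- match.arg(scope)
  counts <- assembly$contigs$n_reads
  if (scope == "unigenes") counts <- c(counts, rep(1L, nrow(assembly$singletons)))
  if (length(counts) < 2L) {
    warning("read-count COV undefined for fewer than 2 sequences", call. = FALSE)
    return(NA_real_)
  }
  sd(counts) / mean(counts)
}

#' Read usage by transcript abundance bin
#'
#' Transcripts are binned by sampling-weight quantile (bin 1 = rarest); for
#' each bin the percentage of its reads incorporated into contigs is
#' reported. Requires read provenance, so it is not computable for external
#' assemblies ingested without a membership table.
#'
#' @param assembly An `assembly` whose contig members are known.
#' @param readset The `read_set`.
#' @param model The `sampling_model` used for simulation.
#' @param n_bins Number of abundance bins.
#' @return Data frame with `bin`, `n_reads`, `pct_reads_assembled`.
#' @export
read_usage_by_abundance_bin <- function(assembly, readset, model, n_bins = 10L) {
  w <- model$weights
  edges <- quantile(w, probs = seq(0, 1, length.out = n_bins + 1L))
  bin_of_tx <- setNames(pmin(n_bins, findInterval(w, edges, rightmost.closed = TRUE)),
                        names(w))
  used <- unique(unlist(assembly$contig_members, use.names = FALSE))
  r <- readset$reads
  in_contig <- r$read_id %in% used
  bin <- bin_of_tx[r$transcript_id]
  tot <- tapply(rep(1L, nrow(r)), bin, sum)
  asm <- tapply(as.integer(in_contig), bin, sum)
  out <- data.frame(bin = as.integer(names(tot)),
                    n_reads = as.integer(tot),
                    pct_reads_assembled = 100 * as.integer(asm) / as.integer(tot))
  rownames(out) <- NULL
  out[order(out$bin), , drop = FALSE]
}
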