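#' Construct a metric series over a sequencing ladder
#'
#' @param metric Metric name.
#' @param scope `"contigs"` or `"unigenes"`.
#' @param ladder `"depth"` or `"length"`.
#' @param x Strictly increasing ladder values (>= 3 points).
#' @param perfect Metric values for the perfect assembly at each `x`.
#' @param other Optional values for the comparison assembly.
#' @param better `"higher"`, `"lower"`, or `"toward_target"` (supply
#'   `target`).
#' @param target Target value for `better = "toward_target"` (e.g. the true
#'   transcript count for contig counts).
#' @return A `metric_series` object.
#' @export
metric_series <- function(metric, scope, ladder, x, perfect, other = NULL,
                          better = c("higher", "lower", "toward_target"),
                          target = NULL) {
  better <- match.arg(better)
  if (length(x) < 3L || length(x) != length(perfect))
    stop("a metric series needs >= 3 ladder points with one value each",
         call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  if (!is.null(other) && length(other) != length(x))
    stop("`other` must align with `x`", call. = FALSE)
  if (better == "toward_target" && is.null(target))
    stop("`toward_target` requires `target`", call. = FALSE)
  structure(list(metric = metric, scope = scope, ladder = ladder, x = x,
                 perfect = perfect, other = other, better = better,
                 target = target),
            class = "metric_series")
}

#' Classify the trend of a value series
#'
#' Labels a series `increasing`, `decreasing`, `flat` or `non_monotone`.
#' Steps within `rel_tol * max(|values|)` of zero are treated as ties, so
#' near-constant wiggle does not break monotonicity; with `rel_tol = 0` the
#' classification is strict.
#'
#' @param values Numeric vector (>= 3 values).
#' @param rel_tol Relative tolerance for treating a step as zero.
#' @return One of `"increasing"`, `"decreasing"`, `"flat"`, `"non_monotone"`.
#' @export
trend <- function(values, rel_tol = 0.01) {
  if (length(values) < 3L)
    stop("trend classification needs at least 3 values", call. = FALSE)
  tol <- rel_tol * max(abs(values), 0)
  steps <- diff(values)
  if (all(abs(steps) <= tol)) return("flat")
  if (all(steps >= -tol)) return("increasing")
  if (all(steps <= tol)) return("decreasing")
  "non_monotone"
}

#' Is the perfect assembly weakly better at every ladder point?
#'
#' Applies the series' better-direction pointwise: `higher`/`lower` compare
#' values directly; `toward_target` compares absolute deviation from the
#' target (e.g. contig count versus the true transcript count).
#'
#' @param series A [metric_series()] with `other` present.
#' @return Logical.
#' @export
consistent_over <- function(series) {
  if (is.null(series$other))
    stop("consistency requires a comparison assembly series", call. = FALSE)
  p <- series$perfect; o <- series$other
  switch(series$better,
         higher = all(p >= o),
         lower = all(p <= o),
         toward_target = all(abs(p - series$target) <= abs(o - series$target)))
}

trends_compatible <- function(t1, t2) {
  if (t1 == "non_monotone" || t2 == "non_monotone") return(FALSE)
  !((t1 == "increasing" && t2 == "decreasing") ||
    (t1 == "decreasing" && t2 == "increasing"))
}

#' Classify a metric's consistency over depth and read-length ladders
#'
#' A metric is *consistent* over a ladder when the perfect assembly scores
#' weakly better than the comparison assembly at every point; it is *fully
#' consistent* when it is consistent over both ladders and the perfect
#' series trends monotonically in compatible directions on both (flat counts
#' as compatible with either direction), so that comparisons are unambiguous
#' across all tested depths and read lengths.
#'
#' @param depth_series,length_series [metric_series()] objects for the same
#'   metric and scope.
#' @param rel_tol Relative trend tolerance (see [trend()]).
#' @return One-row data frame: `metric`, `scope`, `trend_depth`,
#'   `consistent_depth`, `trend_length`, `consistent_length`,
#'   `fully_consistent`.
#' @export
classify_consistency <- function(depth_series, length_series, rel_tol = 0.01) {
  if (depth_series$metric != length_series$metric ||
      depth_series$scope != length_series$scope)
    stop("depth and length series describe different metrics", call. = FALSE)
  td <- trend(depth_series$perfect, rel_tol)
  tl <- trend(length_series$perfect, rel_tol)
  cd <- if (is.null(depth_series$other)) NA else consistent_over(depth_series)
  cl <- if (is.null(length_series$other)) NA else consistent_over(length_series)
  fully <- isTRUE(cd) && isTRUE(cl) && trends_compatible(td, tl)
  data.frame(metric = depth_series$metric, scope = depth_series$scope,
             trend_depth = td, consistent_depth = cd,
             trend_length = tl, consistent_length = cl,
             fully_consistent = fully, stringsAsFactors = FALSE)
}

#' Better-direction registry for the bundled metrics
#'
#' Declares, per metric, which direction indicates higher assembly quality —
#' a judgment each evaluation must make explicitly, recorded here so it is
#' auditable and overridable. `toward_target` metrics (counts that should
#' approach a known truth, such as the transcript count) fall back to
#' `higher` when no target is available.
#'
#' @return Data frame with `metric`, `better`, `target` (`"transcript_count"`
#'   or `NA`).
#' @export
metric_registry <- function() {
  reg <- rbind(
    c("contig_count", "toward_target", "transcript_count"),
    c("singleton_count", "lower", NA),
    c("unigene_count", "toward_target", "transcript_count"),
    c("pct_reads_in_contigs", "higher", NA),
    c("bp_in_contigs", "higher", NA),
    c("total_bp", "higher", NA),
    c("pct_bp_in_contigs", "higher", NA),
    c("mean_length", "higher", NA),
    c("median_length", "higher", NA),
    c("n50_length", "higher", NA),
    c("mean_coverage", "higher", NA),
    c("median_coverage", "higher", NA),
    c("length_weighted_mean_coverage", "higher", NA),
    c("read_count_cov", "higher", NA),
    c("unique_annotations", "higher", NA),
    c("unique_true_annotations", "higher", NA),
    c("pct_annotated", "higher", NA),
    c("singleton_only_annotations", "higher", NA),
    c("mean_ohr", "higher", NA),
    c("median_ohr", "higher", NA),
    c("mean_ohr_true", "higher", NA),
    c("rbh_count", "higher", NA),
    c("pct_annotated_with_rbh", "higher", NA),
    c("mean_cf", "lower", NA),
    c("reverse_rarefaction", "higher", NA))
  out <- data.frame(metric = reg[, 1], better = reg[, 2], target = reg[, 3],
                    stringsAsFactors = FALSE)
  out
}
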