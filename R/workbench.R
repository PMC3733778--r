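#' Compute the full metric table for one assembly
#'
#' Gathers aggregate, length/coverage/N50, read-count dispersion and — when a
#' transcript set (and optionally a reference set) is supplied — the
#' annotation metrics: unique and true-annotation counts, singleton-only
#' annotations, percent annotated, ortholog hit ratios, reciprocal best
#' hits, collapse factors and reverse rarefaction, each over the contig and
#' unigene scopes.
#'
#' @param assembly An `assembly`.
#' @param readset The `read_set` it was built from.
#' @param tset Optional `transcript_set` (enables provenance/true
#'   annotation).
#' @param refset Optional `reference_set` (enables similarity-style
#'   annotation metrics via the provenance oracle).
#' @param min_match Minimum matched CDS length for the annotators.
#' @return Long-format data frame of metric records.
#' @export
metric_table <- function(assembly, readset, tset = NULL, refset = NULL,
                         min_match = 30L) {
  lab <- assembly$label
  out <- list(aggregate_stats(assembly, readset))
  for (sc in c("contigs", "unigenes")) {
    if (sc == "contigs" && nrow(assembly$contigs) == 0L) next
    out[[length(out) + 1L]] <- length_and_coverage_stats(assembly, sc)
    cov <- suppressWarnings(read_count_cov(assembly, sc))
    if (!is.na(cov))
      out[[length(out) + 1L]] <- metric_row("read_count_cov", sc, cov, "ratio", lab)
  }

  if (!is.null(tset)) {
    cid <- assembly$contigs$contig_id
    sid <- assembly$singletons$read_id
    true_tab <- true_annotation_table(assembly, tset)
    for (sc in c("contigs", "unigenes")) {
      ids <- scope_ids(assembly, sc)
      out[[length(out) + 1L]] <- rbind(
        metric_row("unique_true_annotations", sc,
                   unique_annotation_count(true_tab, ids), "count", lab),
        metric_row("mean_ohr_true", sc,
                   mean(ortholog_hit_ratio(
                     true_tab$hits[true_tab$hits$query_id %in% ids, ,
                                   drop = FALSE])), "ratio", lab))
    }

    if (!is.null(refset)) {
      fwd <- annotate_by_provenance(assembly, tset, refset, min_match)
      # one reverse search against the full unigene set; scope restriction
      # happens at counting time in collapse_factors()
      rev_uni <- reverse_annotate_by_provenance(assembly, tset, refset,
                                                "unigenes", min_match)
      rbh <- reciprocal_best_hits(fwd, rev_uni, cid, sid)
      for (sc in c("contigs", "unigenes")) {
        ids <- scope_ids(assembly, sc)
        h <- fwd$hits[fwd$hits$query_id %in% ids, , drop = FALSE]
        cf <- collapse_factors(rev_uni, ids)
        rows <- rbind(
          metric_row("unique_annotations", sc,
                     unique_annotation_count(fwd, ids), "count", lab),
          metric_row("pct_annotated", sc,
                     if (length(ids)) 100 * nrow(h) / length(ids) else NA,
                     "%", lab),
          metric_row("rbh_count", sc, rbh$rbh_count[[sc]], "count", lab),
          metric_row("pct_annotated_with_rbh", sc,
                     rbh$pct_annotated_with_rbh[[sc]], "%", lab),
          metric_row("reverse_rarefaction", sc, cf$reverse_rarefaction,
                     "count", lab))
        if (nrow(h))
          rows <- rbind(rows,
            metric_row("mean_ohr", sc, mean(ortholog_hit_ratio(h)), "ratio", lab),
            metric_row("median_ohr", sc, median(ortholog_hit_ratio(h)), "ratio", lab))
        if (!is.na(cf$average_cf))
          rows <- rbind(rows, metric_row("mean_cf", sc, cf$average_cf, "ratio", lab))
        out[[length(out) + 1L]] <- rows
      }
      out[[length(out) + 1L]] <- metric_row(
        "singleton_only_annotations", "unigenes",
        singleton_only_annotations(fwd, cid, sid), "count", lab)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a long-format metric table
#'
#' @param metrics Metric data frame from [metric_table()].
#' @param path TSV path.
#' @export
write_metrics <- function(metrics, path) write_tsv(metrics, path)

#' @rdname write_metrics
#' @export
read_metrics <- function(path) read_tsv(path)

validate_ladder_config <- function(config) {
  for (fld in c("depths", "lengths"))
    if (length(config[[fld]]) == 0L || any(config[[fld]] <= 0) ||
        any(diff(config[[fld]]) <= 0))
      stop("`", fld, "` must be a non-empty, positive, increasing ladder",
           call. = FALSE)
  if (is.null(config$tset) && is.null(config$fixture))
    stop("config needs either `tset` or `fixture` parameters", call. = FALSE)
  invisible(config)
}

#' Run a depth/read-length ladder experiment end to end
#'
#' Orchestrates fixture generation, read simulation, perfect (and degraded)
#' assembly, metric computation and consistency classification. One sampling
#' permutation, built once from `seed`, is reused across every ladder point
#' so expression ranks stay comparable. The depth ladder varies read count at
#' a fixed mean read length; the length ladder varies mean read length at a
#' fixed depth. The comparison ("other") assembler is the perfect assembler
#' with its minimum overlap requirement raised (default 40 bp), a controlled
#' degradation standing in for an imperfect assembler.
#'
#' @param config List with: `tset` (a `transcript_set`) or `fixture`
#'   (arguments to [generate_transcriptome()]); `depths` (read counts);
#'   `lengths` (mean read lengths); `fixed_depth` (reads for the length
#'   ladder); `mean_len` (read length for the depth ladder, default 400);
#'   `error_rate` (default 0.015); `seed`; `other_min_reads` (default 4,
#'   singleton-heavy degradation knob); `other_min_overlap` (default 40,
#'   `NULL` disables the comparison assembler); `reference` (arguments to
#'   [derive_reference_set()], default a diverged set) or `NULL` to skip
#'   annotation metrics; `outdir` (`NULL` for in-memory only); `write_reads`
#'   (write per-point FASTA/provenance, default `FALSE` — metric TSVs and the
#'   verdict matrix are always written when `outdir` is set).
#' @return List with `tset`, `model`, `refset`, `points` (per-point metric
#'   tables and parameters), `verdicts` (the consistency matrix) and `paths`.
#' @export
run_ladder <- function(config) {
  config$mean_len <- config$mean_len %||% 400
  config$error_rate <- config$error_rate %||% 0.015
  config$seed <- config$seed %||% 1L
  config$other_min_overlap <- if (!("other_min_overlap" %in% names(config)))
    40L else config$other_min_overlap
  validate_ladder_config(config)
  seed <- as.integer(config$seed)

  tset <- config$tset %||% do.call(generate_transcriptome, config$fixture)
  refset <- NULL
  if (!("reference" %in% names(config))) {
    config$reference <- list(mode = "diverged", sub_rate = 0.05,
                             expansion_dist = list(p_expand = 0.3,
                                                   factor_range = c(0.7, 1.3)),
                             seed = seed + 17L)
  }
  if (!is.null(config$reference))
    refset <- do.call(derive_reference_set, c(list(tset = tset), config$reference))
  model <- build_sampling_model(tset, seed)

  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  points <- list()
  grid <- rbind(
    data.frame(ladder = "depth", x = config$depths,
               n_reads = config$depths, mean_len = config$mean_len),
    data.frame(ladder = "length", x = config$lengths,
               n_reads = config$fixed_depth %||% config$depths[1],
               mean_len = config$lengths))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    point_seed <- seed + 101L * k
    rs <- simulate_reads(tset, model, read_length_model(g$mean_len),
                         g$n_reads, config$error_rate, point_seed)
    asms <- list(perfect = perfect_assemble(rs, tset))
    if (!is.null(config$other_min_overlap))
      asms$other <- perfect_assemble(rs, tset,
                                     min_overlap = config$other_min_overlap,
                                     min_reads = config$other_min_reads %||% 4L,
                                     label = "other")
    mt <- do.call(rbind, lapply(asms, metric_table, readset = rs,
                                tset = tset, refset = refset))
    rownames(mt) <- NULL
    key <- sprintf("%s_%g", g$ladder, g$x)
    if (!is.null(outdir)) {
      pdir <- file.path(outdir, key)
      dir.create(pdir, showWarnings = FALSE)
      write_metrics(mt, file.path(pdir, "metrics.tsv"))
      if (isTRUE(config$write_reads)) {
        write_reads(rs, file.path(pdir, "reads.fasta"))
        write_provenance(rs, file.path(pdir, "provenance.tsv"))
        for (nm in names(asms))
          write_assembly(asms[[nm]],
                         file.path(pdir, sprintf("assembly_%s.fasta", nm)),
                         file.path(pdir, sprintf("assembly_%s_members.tsv", nm)))
      }
    }
    points[[key]] <- list(ladder = g$ladder, x = g$x, n_reads = g$n_reads,
                          mean_len = g$mean_len, seed = point_seed,
                          metrics = mt)
  }

  verdicts <- ladder_verdicts(points, n_transcripts = nrow(tset$transcripts))
  paths <- NULL
  if (!is.null(outdir)) {
    write_tsv(verdicts, file.path(outdir, "verdicts.tsv"))
    writeLines(verdict_report(verdicts), file.path(outdir, "report.md"))
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.tsv"]
    manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    paths <- list(outdir = outdir,
                  verdicts = file.path(outdir, "verdicts.tsv"),
                  manifest = file.path(outdir, "manifest.tsv"))
  }
  list(tset = tset, model = model, refset = refset, points = points,
       verdicts = verdicts, paths = paths)
}

# assemble metric_series objects from per-point metric tables and classify
ladder_verdicts <- function(points, n_transcripts = NULL, rel_tol = 0.01) {
  reg <- metric_registry()
  series_for <- function(ladder, metric, scope) {
    pts <- points[vapply(points, function(p) p$ladder == ladder, TRUE)]
    if (length(pts) < 3L) return(NULL)
    x <- vapply(pts, function(p) as.numeric(p$x), 0)
    get_val <- function(p, label) {
      m <- p$metrics
      v <- m$value[m$metric == metric & m$scope == scope & m$assembly == label]
      if (length(v) == 1L) v else NA_real_
    }
    perfect <- vapply(pts, get_val, 0, label = "perfect")
    other <- vapply(pts, get_val, 0, label = "other")
    if (anyNA(perfect)) return(NULL)
    if (anyNA(other)) other <- NULL
    r <- reg[reg$metric == metric, , drop = FALSE]
    better <- if (nrow(r)) r$better else "higher"
    target <- NULL
    if (identical(better, "toward_target")) {
      if (!is.null(n_transcripts) && identical(r$target, "transcript_count"))
        target <- n_transcripts
      else better <- "higher"
    }
    ord <- order(x)
    metric_series(metric, scope, ladder, x[ord], perfect[ord],
                  if (is.null(other)) NULL else other[ord], better, target)
  }
  combos <- unique(do.call(rbind, lapply(points, function(p)
    p$metrics[, c("metric", "scope")])))
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    ds <- series_for("depth", combos$metric[i], combos$scope[i])
    ls <- series_for("length", combos$metric[i], combos$scope[i])
    if (is.null(ds) || is.null(ls)) next
    rows[[length(rows) + 1L]] <- classify_consistency(ds, ls, rel_tol)
  }
  if (length(rows) == 0L)
    return(data.frame(metric = character(0), scope = character(0),
                      trend_depth = character(0), consistent_depth = logical(0),
                      trend_length = character(0), consistent_length = logical(0),
                      fully_consistent = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

verdict_report <- function(verdicts) {
  mark <- function(x) ifelse(is.na(x), "?", ifelse(x, "yes", "no"))
  c("# Metric trends and consistency", "",
    "| Metric | Scope | Trend by depth | Consistent over depths | Trend by length | Consistent over lengths | Fully consistent |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s |",
            verdicts$metric, verdicts$scope, verdicts$trend_depth,
            mark(verdicts$consistent_depth), verdicts$trend_length,
            mark(verdicts$consistent_length), mark(verdicts$fully_consistent)))
}
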