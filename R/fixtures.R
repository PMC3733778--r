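#' Generate a synthetic transcriptome with isoforms, paralogs and UTRs
#'
#' Builds a transcript set with the structural features that drive
#' transcriptome assembly evaluation: genes composed of exons, alternatively
#' spliced isoforms produced by exon skipping (so isoforms of one gene share
#' sequence), paralog families derived by mutating a common ancestral gene,
#' untranslated regions flanking a central CDS, and heavy-tailed (log-normal)
#' transcript lengths. The generator is a stand-in for a real curated
#' transcript set; its distributions are synthetic and labelled as such.
#'
#' @param n_genes Number of genes (>= 1). Paralog family members count
#'   against this total.
#' @param isoform_rate Fraction of genes (with >= 3 exons) given a second
#'   (and occasionally third) isoform by internal exon skipping.
#' @param paralog_spec List with `n_families`, `family_size` and `identity`
#'   (target pairwise sequence identity within a family, in (0,1)).
#' @param length_model List with `meanlog`, `sdlog` (log-normal parameters
#'   for primary transcript length) and `min_len` (floor, >= 1).
#' @param utr_frac Total fraction of each transcript that is untranslated,
#'   split 1/3 to the 5' end and 2/3 to the 3' end.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A `transcript_set`: list with `transcripts` (data frame:
#'   `transcript_id`, `gene_id`, `family_id`, `length`, `utr5_len`,
#'   `utr3_len`), `sequences` (named character), `exons` (per-transcript
#'   ordered exon-id lists), `genes`, `paralog_families`, `params`.
#' @export
generate_transcriptome <- function(n_genes,
                                   isoform_rate = 0.3,
                                   paralog_spec = list(n_families = 0L,
                                                       family_size = 3L,
                                                       identity = 0.9),
                                   length_model = list(meanlog = log(2000) - 0.65^2 / 2,
                                                       sdlog = 0.65,
                                                       min_len = 300L),
                                   utr_frac = 0.3,
                                   seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("`n_genes` must be an integer >= 1", call. = FALSE)
  if (isoform_rate < 0 || isoform_rate > 1)
    stop("`isoform_rate` must lie in [0, 1]", call. = FALSE)
  nf <- as.integer(paralog_spec$n_families %||% 0L)
  fs <- as.integer(paralog_spec$family_size %||% 3L)
  fid <- paralog_spec$identity %||% 0.9
  if (nf > 0L && (fid <= 0 || fid >= 1))
    stop("paralog `identity` must lie in (0, 1)", call. = FALSE)
  if (nf * fs > n_genes)
    stop("paralog families require more genes than `n_genes`", call. = FALSE)
  min_len <- as.integer(length_model$min_len %||% 1L)
  if (min_len < 1L) stop("`min_len` must be >= 1", call. = FALSE)
  if (utr_frac < 0 || utr_frac >= 1)
    stop("`utr_frac` must lie in [0, 1)", call. = FALSE)

  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    family_of <- rep(NA_character_, n_genes)
    if (nf > 0L)
      family_of[seq_len(nf * fs)] <- rep(sprintf("fam%03d", seq_len(nf)), each = fs)

    # per-site mutation rate from a common ancestor giving ~`fid` pairwise
    # identity between two independently mutated copies
    par_rate <- (1 - fid) / 2

    tx_rows <- vector("list", n_genes)
    tx_seqs <- list()
    tx_exons <- list()
    exon_len <- list()
    fam_exon_seqs <- list()   # cached ancestral exon sequences per family

    for (g in seq_len(n_genes)) {
      gid <- gene_ids[g]
      fam <- family_of[g]

      if (!is.na(fam) && !is.null(fam_exon_seqs[[fam]])) {
        anc <- fam_exon_seqs[[fam]]
      } else {
        L <- max(min_len,
                 as.integer(round(rlnorm(1, length_model$meanlog, length_model$sdlog))))
        n_ex <- max(2L, min(12L, as.integer(round(L / 400))))
        # partition L into n_ex exon widths, each >= 30 bp
        base <- 30L * n_ex
        if (base >= L) { n_ex <- max(2L, L %/% 30L); base <- 30L * n_ex }
        props <- rexp(n_ex); props <- props / sum(props)
        widths <- 30L + as.integer(floor(props * (L - base)))
        widths[n_ex] <- widths[n_ex] + (L - sum(widths))
        anc <- vapply(widths, random_dna, "")
        if (!is.na(fam)) fam_exon_seqs[[fam]] <- anc
      }
      # every family member (including the first) is an independently
      # mutated copy of the cached ancestor, so pairwise identity is the
      # same for all member pairs
      exon_seq <- if (is.na(fam)) anc
                  else vapply(anc, mutate_sequence, "", rate = par_rate)
      n_ex <- length(exon_seq)
      exon_ids <- sprintf("%s_e%02d", gid, seq_len(n_ex))
      names(exon_seq) <- exon_ids
      exon_len[[gid]] <- setNames(nchar(exon_seq), exon_ids)

      # isoform structures: transcript 1 keeps all exons; alternative
      # isoforms each skip one distinct internal exon
      iso_sets <- list(seq_len(n_ex))
      if (n_ex >= 3L && runif(1) < isoform_rate) {
        n_alt <- sample(1:2, 1)
        skip <- sample(2:(n_ex - 1L), min(n_alt, n_ex - 2L))
        for (s in skip) iso_sets[[length(iso_sets) + 1L]] <- setdiff(seq_len(n_ex), s)
      }

      rows <- vector("list", length(iso_sets))
      for (j in seq_along(iso_sets)) {
        keep <- iso_sets[[j]]
        tid <- sprintf("%s.t%d", gid, j)
        seq <- paste(exon_seq[keep], collapse = "")
        len <- nchar(seq)
        u5 <- as.integer(round(len * utr_frac / 3))
        u3 <- as.integer(round(len * utr_frac * 2 / 3))
        while (u5 + u3 >= len - 3L) { u5 <- u5 %/% 2L; u3 <- u3 %/% 2L }
        rows[[j]] <- data.frame(transcript_id = tid, gene_id = gid,
                                family_id = fam, length = len,
                                utr5_len = u5, utr3_len = u3,
                                stringsAsFactors = FALSE)
        tx_seqs[[tid]] <- seq
        tx_exons[[tid]] <- exon_ids[keep]
      }
      tx_rows[[g]] <- do.call(rbind, rows)
    }

    transcripts <- do.call(rbind, tx_rows)
    rownames(transcripts) <- NULL
    genes <- split(transcripts$transcript_id, transcripts$gene_id)
    fams <- split(gene_ids[!is.na(family_of)], family_of[!is.na(family_of)])

    structure(list(
      transcripts = transcripts,
      sequences = unlist(tx_seqs),
      exons = tx_exons,
      exon_lengths = unlist(unname(exon_len)),
      genes = genes,
      paralog_families = fams,
      params = list(n_genes = n_genes, isoform_rate = isoform_rate,
                    paralog_spec = list(n_families = nf, family_size = fs,
                                        identity = fid),
                    length_model = length_model, utr_frac = utr_frac,
                    seed = seed)
    ), class = "transcript_set")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transcript_set <- function(x, ...) {
  tx <- x$transcripts
  n_iso <- sum(lengths(x$genes) > 1L)
  cat(sprintf("transcript_set: %d transcripts, %d genes (%d alternatively spliced), %d paralog families\n",
              nrow(tx), length(x$genes), n_iso, length(x$paralog_families)))
  cat(sprintf("  total length %d bp; mean %.0f bp; range %d-%d bp\n",
              sum(tx$length), mean(tx$length), min(tx$length), max(tx$length)))
  invisible(x)
}

# CDS nucleotide sequences (UTRs trimmed), named by transcript id.
cds_sequences <- function(tset) {
  tx <- tset$transcripts
  s <- substring(tset$sequences[tx$transcript_id],
                 tx$utr5_len + 1L, tx$length - tx$utr3_len)
  names(s) <- tx$transcript_id
  s
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

#' Derive a reference (protein or nucleotide) set from a transcriptome
#'
#' Produces the reference dataset a transcriptome assembly would be annotated
#' against: either the transcripts' own CDS regions (`mode = "self"`, a
#' zero-evolutionary-distance reference with all expansion factors exactly 1),
#' or a diverged relative (`mode = "diverged"`) produced by point
#' substitutions at `sub_rate` plus, with probability `p_expand`, terminal
#' truncation or extension by a factor drawn from `factor_range`. The realized
#' length ratio (reference length / ancestral length) is recorded per
#' reference as `expansion_factor`, emulating evolutionary expansion or
#' contraction of orthologs.
#'
#' @param tset A `transcript_set`.
#' @param mode `"self"` or `"diverged"`.
#' @param sub_rate Per-residue substitution rate in [0, 1).
#' @param expansion_dist List with `p_expand` and `factor_range` (positive
#'   length-2 numeric).
#' @param unit `"aa"` (conceptual translation of the CDS, length = CDS/3
#'   floored) or `"nt"`.
#' @param seed Integer seed.
#' @return A `reference_set`: list with `refs` (data frame: `ref_id`,
#'   `source_transcript`, `length`, `expansion_factor`), `sequences`,
#'   `ortholog_map` (transcript_id -> ref_id), `unit`, `mode`.
#' @export
derive_reference_set <- function(tset,
                                 mode = c("self", "diverged"),
                                 sub_rate = 0.1,
                                 expansion_dist = list(p_expand = 0,
                                                       factor_range = c(0.7, 1.3)),
                                 unit = c("aa", "nt"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (sub_rate < 0 || sub_rate >= 1)
    stop("`sub_rate` must lie in [0, 1)", call. = FALSE)
  fr <- expansion_dist$factor_range %||% c(0.7, 1.3)
  p_expand <- expansion_dist$p_expand %||% 0
  if (any(fr <= 0)) stop("`factor_range` must be positive", call. = FALSE)

  cds <- cds_sequences(tset)
  cds <- cds[nchar(cds) >= 3L]
  if (unit == "aa") {
    trimmed <- substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                             no.init.codon = TRUE))
    base <- chartr("*", "X", aa)
    alphabet <- AA_ALPHABET
  } else {
    base <- cds
    alphabet <- DNA_BASES
  }
  names(base) <- names(cds)

  ref_ids <- paste0("p_", names(base))
  anc_len <- nchar(base)

  seqs <- base
  factors <- rep(1.0, length(base))
  if (mode == "diverged") {
    div <- with_seed(seed, {
      out <- vapply(base, mutate_sequence, "", rate = sub_rate,
                    alphabet = alphabet)
      expand <- runif(length(out)) < p_expand
      f <- ifelse(expand, runif(length(out), fr[1], fr[2]), 1.0)
      new_len <- pmax(1L, as.integer(round(anc_len * f)))
      for (i in which(new_len != anc_len)) {
        if (new_len[i] < anc_len[i]) {
          out[i] <- substring(out[i], 1L, new_len[i])
        } else {
          extra <- paste(sample(alphabet, new_len[i] - anc_len[i],
                                replace = TRUE), collapse = "")
          out[i] <- paste0(out[i], extra)
        }
      }
      list(seqs = out, factors = new_len / anc_len)
    })
    seqs <- div$seqs
    factors <- unname(div$factors)
  }

  names(seqs) <- ref_ids
  refs <- data.frame(ref_id = ref_ids,
                     source_transcript = names(base),
                     length = nchar(seqs),
                     expansion_factor = factors,
                     stringsAsFactors = FALSE)
  ortholog_map <- setNames(ref_ids, names(base))

  structure(list(refs = refs, sequences = seqs, ortholog_map = ortholog_map,
                 unit = unit, mode = mode,
                 params = list(sub_rate = sub_rate,
                               expansion_dist = list(p_expand = p_expand,
                                                     factor_range = fr),
                               seed = seed)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set (%s, %s): %d references, mean length %.0f %s\n",
              x$mode, x$unit, nrow(x$refs), mean(x$refs$length), x$unit))
  if (x$mode == "diverged")
    cat(sprintf("  expansion factors: %d != 1, range %.2f-%.2f\n",
                sum(x$refs$expansion_factor != 1),
                min(x$refs$expansion_factor), max(x$refs$expansion_factor)))
  invisible(x)
}

#' Ground-truth table for a synthetic transcriptome
#'
#' @param tset A `transcript_set`.
#' @param refset Optional `reference_set`; adds the ortholog `ref_id` column.
#' @return Data frame with one row per transcript.
#' @export
transcript_truth <- function(tset, refset = NULL) {
  out <- tset$transcripts
  if (!is.null(refset))
    out$ref_id <- unname(refset$ortholog_map[out$transcript_id])
  out
}

#' Write a transcript set (FASTA + ground-truth TSV)
#'
#' @param tset A `transcript_set`.
#' @param fasta,truth_tsv Output paths (either may be `NULL` to skip).
#' @param refset Optional `reference_set` for the truth table.
#' @param width FASTA wrap width.
#' @return Invisibly, the paths written.
#' @export
write_transcriptome <- function(tset, fasta = NULL, truth_tsv = NULL,
                                refset = NULL, width = 70L) {
  if (!is.null(fasta)) write_fasta(tset$sequences, fasta, "dna", width)
  if (!is.null(truth_tsv)) write_tsv(transcript_truth(tset, refset), truth_tsv)
  invisible(c(fasta, truth_tsv))
}

#' Write a reference set as FASTA
#'
#' @param refset A `reference_set`.
#' @param path Output path.
#' @param width FASTA wrap width.
#' @export
write_reference_set <- function(refset, path, width = 70L) {
  write_fasta(refset$sequences, path,
              if (refset$unit == "aa") "aa" else "dna", width)
}
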