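#' Per-amplicon read counts from alignments
#'
#' A read is attributed to the amplicon whose insert interval contains its
#' alignment midpoint; unattributable reads are dropped and counted in the
#' `unassigned` attribute.
#'
#' @param alignment_sets named list of [map_reads()] results (one per
#'   sample), or a single result.
#' @param panel an [amplicon_panel()].
#' @return a `read_count_table`: data.table with `amplicon_id`, `multiplex`
#'   and one count column per sample.
#' @export
counts_from_alignments <- function(alignment_sets, panel) {
  if (data.table::is.data.table(alignment_sets)) {
    alignment_sets <- list(sample1 = alignment_sets)
  }
  if (is.null(names(alignment_sets))) {
    names(alignment_sets) <- paste0("sample", seq_along(alignment_sets))
  }
  a <- panel$amplicons
  out <- data.table::data.table(amplicon_id = a$id, multiplex = a$multiplex)
  unassigned <- integer(length(alignment_sets))
  names(unassigned) <- names(alignment_sets)
  for (s in names(alignment_sets)) {
    aln <- alignment_sets[[s]]
    aln <- aln[aln$mapped & !aln$multi, ]
    counts <- stats::setNames(rep(0L, nrow(a)), a$id)
    if (nrow(aln)) {
      span <- vapply(aln$ops, function(o) ops_ref_span(parse_ops(o)), 0L)
      mid <- aln$ref_start + span %/% 2L
      ids <- vapply(mid, function(p) {
        hit <- which(a$fwd_primer_end <= p & p < a$rev_primer_start)
        if (length(hit)) a$id[hit[1]] else NA_character_
      }, "")
      unassigned[s] <- sum(is.na(ids))
      tt <- table(ids[!is.na(ids)])
      counts[names(tt)] <- as.integer(tt)
    } else {
      warning("sample ", s, " has no usable alignments; all-zero counts")
    }
    out[[s]] <- as.integer(counts)
  }
  structure(out, unassigned = unassigned, class = c("read_count_table",
                                                    class(out)))
}

#' Build a read-count table from a plain matrix/data.frame
#'
#' @param counts matrix or data.frame, rows = amplicons, columns = samples.
#' @param panel an [amplicon_panel()] supplying the multiplex grouping.
#' @return a `read_count_table`.
#' @export
read_count_table <- function(counts, panel) {
  a <- panel$amplicons
  counts <- as.data.frame(counts)
  if (nrow(counts) != nrow(a)) stop("counts rows must match panel amplicons")
  if (any(counts < 0)) stop("read counts must be >= 0")
  out <- data.table::data.table(amplicon_id = a$id, multiplex = a$multiplex)
  for (s in names(counts)) out[[s]] <- as.integer(counts[[s]])
  structure(out, class = c("read_count_table", class(out)))
}

#' Write / read a read-count table as TSV
#' @param counts a `read_count_table`.
#' @param path file path.
#' @return `path` / a data.table (attach a panel with [read_count_table()]).
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) data.table::fread(path, sep = "\t")

#' Dosage quotients of a test sample against reference samples
#'
#' Per amplicon i in multiplex m: DQ = (RC_i / sum_m RC)_test divided by the
#' mean over reference samples of (RC_i / sum_m RC)_ref. Normalisation is
#' strictly within-multiplex, so DQ is invariant to per-sample sequencing
#' depth; DQ approximates copy_number / 2.
#'
#' @param counts a `read_count_table` (or data.table with `amplicon_id`,
#'   `multiplex` and sample columns).
#' @param test test sample column name.
#' @param refs character vector of reference sample column names (samples
#'   with normal copy number; three by default in the workflow).
#' @return data.table with `amplicon_id`, `multiplex`, `dq`.
#' @export
compute_dq <- function(counts, test, refs) {
  if (!length(refs)) stop("refs must be non-empty")
  miss <- setdiff(c(test, refs), names(counts))
  if (length(miss)) stop("unknown sample columns: ", paste(miss, collapse = ", "))
  out <- data.table::data.table(amplicon_id = counts$amplicon_id,
                                multiplex = counts$multiplex,
                                dq = NA_real_)
  for (m in unique(counts$multiplex)) {
    sel <- counts$multiplex == m
    if (sum(sel) < 2L) {
      warning("multiplex ", m, " has fewer than 2 amplicons; DQ uninformative")
    }
    tot_test <- sum(counts[[test]][sel])
    if (tot_test == 0) stop("zero total count in sample ", test,
                            " multiplex ", m)
    rel_test <- counts[[test]][sel] / tot_test
    rel_ref <- rowMeans(vapply(refs, function(r) {
      tot <- sum(counts[[r]][sel])
      if (tot == 0) stop("zero total count in sample ", r, " multiplex ", m)
      counts[[r]][sel] / tot
    }, numeric(sum(sel))))
    out$dq[sel] <- rel_test / rel_ref
  }
  out
}

#' Default DQ classification bands
#'
#' Deletion at DQ <= 0.70, normal in `[0.80, 1.20]`, duplication at
#' DQ >= 1.35; gaps between bands are classified ambiguous. The bands
#' bracket the empirically observed ranges (deletions 0.55-0.63, normal
#' 0.81-1.2, duplications around 1.45) with guard gaps.
#'
#' @return named list of cutoffs.
#' @export
dq_bands <- function() {
  list(deletion_max = 0.70, normal_min = 0.80, normal_max = 1.20,
       duplication_min = 1.35)
}

#' Classify dosage quotients into copy-number classes
#'
#' Per-amplicon class from the bands; the per-exon call requires all
#' amplicons covering an exon to agree (disagreement yields `ambiguous`).
#'
#' @param dq data.table from [compute_dq()].
#' @param panel an [amplicon_panel()].
#' @param model an [exon_model()] (optional; exon calls skipped if NULL).
#' @param bands list from [dq_bands()].
#' @return list with `amplicons` (`dq` plus `class`) and `exons`
#'   (per-exon calls, NULL when no model given).
#' @export
classify_dq <- function(dq, panel, model = NULL, bands = dq_bands()) {
  cls <- vapply(dq$dq, function(x) {
    if (is.na(x)) "ambiguous"
    else if (x <= bands$deletion_max) "deletion"
    else if (x >= bands$duplication_min) "duplication"
    else if (x >= bands$normal_min && x <= bands$normal_max) "normal"
    else "ambiguous"
  }, "")
  amp <- data.table::copy(dq)
  amp$class <- cls
  exons <- NULL
  if (!is.null(model)) {
    cov <- exon_intervals(panel, model)
    exons <- do.call(rbind, lapply(seq_len(nrow(cov)), function(i) {
      ids <- strsplit(cov$amplicon_ids[i], ",")[[1]]
      ids <- ids[nzchar(ids)]
      if (!length(ids)) {
        return(data.frame(label = cov$label[i], call = "uncovered",
                          mean_dq = NA_real_))
      }
      k <- amp$class[match(ids, amp$amplicon_id)]
      call <- if (length(unique(k)) == 1L) k[1] else "ambiguous"
      data.frame(label = cov$label[i], call = call,
                 mean_dq = mean(amp$dq[match(ids, amp$amplicon_id)]))
    }))
  }
  list(amplicons = amp, exons = exons)
}
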