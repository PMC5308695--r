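#' Build a pileup from alignments
#'
#' One column per covered panel position. Soft-clipped bases are excluded;
#' multi-mapping and unmapped reads are excluded; insertions are attributed
#' to the column left of the inserted bases and deletions to their first
#' deleted base (interior deleted columns count toward depth only). The
#' per-read context quality of a column is the mean Phred of the read bases
#' within two read positions of it.
#'
#' @param alignments data.table from [map_reads()], sorted by `ref_start`.
#' @param panel an [amplicon_panel()].
#' @return a `pileup` object: list with `tab` (long data.table with columns
#'   `pos`, `type` in base/ins/del/gap, `allele`, `strand`, `read_start`,
#'   `ctxq`) and `panel`.
#' @export
build_pileup <- function(alignments, panel) {
  a <- alignments[alignments$mapped & !alignments$multi, ]
  if (!nrow(a)) {
    return(structure(list(tab = data.table::data.table(
      pos = integer(), type = character(), allele = character(),
      strand = character(), read_start = integer(), read_end = integer(),
      ctxq = numeric()),
      panel = panel), class = "pileup"))
  }
  if (is.unsorted(a$ref_start)) {
    stop("alignments must be sorted by position; see order(ref_start)")
  }
  n <- nrow(a)
  acc_pos <- vector("list", n); acc_type <- vector("list", n)
  acc_allele <- vector("list", n); acc_strand <- character(n)
  acc_start <- integer(n); acc_end <- integer(n); acc_ctx <- vector("list", n)
  for (i in seq_len(n)) {
    sq <- a$seq[i]
    q <- char_to_phred(a$qual[i])
    L <- length(q)
    # windowed mean quality (+-2 read positions)
    cs <- cumsum(c(0, q))
    lo <- pmax(seq_len(L) - 2L, 1L)
    hi <- pmin(seq_len(L) + 2L, L)
    ctx <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    if (grepl("^([0-9]+[MX])+$", a$ops[i])) {
      # common case: gap- and clip-free alignment
      acc_pos[[i]] <- a$ref_start[i] + seq_len(L) - 1L
      acc_type[[i]] <- rep("base", L)
      acc_allele[[i]] <- strsplit(sq, "")[[1]]
      acc_ctx[[i]] <- ctx
      acc_strand[i] <- a$strand[i]
      acc_start[i] <- a$ref_start[i]
      acc_end[i] <- a$ref_start[i] + L
      next
    }
    tab <- parse_ops(a$ops[i])
    w <- ops_walk(tab, a$ref_start[i])
    pos_i <- w$aligned$ref_pos
    rp <- w$aligned$read_pos + 1L
    type_i <- rep("base", length(pos_i))
    allele_i <- substring(sq, rp, rp)
    ctx_i <- ctx[rp]
    if (nrow(w$ins)) {
      pos_i <- c(pos_i, w$ins$ref_pos_left)
      type_i <- c(type_i, rep("ins", nrow(w$ins)))
      allele_i <- c(allele_i, substring(sq, w$ins$read_pos + 1L,
                                        w$ins$read_pos + w$ins$len))
      ctx_i <- c(ctx_i, ctx[pmin(w$ins$read_pos + 1L, L)])
    }
    if (nrow(w$del)) {
      # context quality of the read base immediately left of the deletion
      idx <- pmax(1L, findInterval(w$del$ref_pos - 1L, w$aligned$ref_pos))
      del_ctx <- if (nrow(w$aligned)) ctx[w$aligned$read_pos[idx] + 1L] else NA_real_
      gaps <- unlist(mapply(function(p, l) p + seq_len(l) - 1L,
                            w$del$ref_pos, w$del$len, SIMPLIFY = FALSE))
      gap_ctx <- rep(rep(del_ctx, length.out = nrow(w$del)), w$del$len)
      pos_i <- c(pos_i, w$del$ref_pos, as.integer(gaps))
      type_i <- c(type_i, rep("del", nrow(w$del)), rep("gap", length(gaps)))
      allele_i <- c(allele_i, as.character(w$del$len), rep("-", length(gaps)))
      ctx_i <- c(ctx_i, rep(del_ctx, length.out = nrow(w$del)), gap_ctx)
    }
    acc_pos[[i]] <- pos_i
    acc_type[[i]] <- type_i
    acc_allele[[i]] <- allele_i
    acc_ctx[[i]] <- ctx_i
    acc_strand[i] <- a$strand[i]
    acc_start[i] <- a$ref_start[i]
    acc_end[i] <- a$ref_start[i] + ops_ref_span(tab)
  }
  reps <- lengths(acc_pos)
  tab <- data.table::data.table(
    pos = unlist(acc_pos), type = unlist(acc_type),
    allele = unlist(acc_allele),
    strand = rep(acc_strand, reps),
    read_start = rep(acc_start, reps),
    read_end = rep(acc_end, reps),
    ctxq = unlist(acc_ctx))
  data.table::setkey(tab, pos)
  structure(list(tab = tab, panel = panel), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup>", length(unique(x$tab$pos)), "columns,",
      nrow(x$tab), "records\n")
  invisible(x)
}

#' Summarise one pileup column
#'
#' @param pile a [build_pileup()] result.
#' @param pos 0-based reference position.
#' @return list with `pos`, `ref_base`, `depth`, `base_counts` (by allele
#'   and strand), `insertion_events`, `deletion_events` and `start_positions`.
#' @export
pileup_column <- function(pile, pos) {
  p0 <- as.integer(pos)
  tb <- pile$tab[J(p0), nomatch = NULL] # keyed by pos
  ref_base <- substr(pile$panel$reference$sequence, pos + 1L, pos + 1L)
  base <- tb[tb$type == "base", ]
  list(
    pos = pos, ref_base = ref_base,
    depth = sum(tb$type %in% c("base", "gap")),
    base_counts = if (nrow(base)) table(base$allele, base$strand) else table(character()),
    insertion_events = table(tb$allele[tb$type == "ins"]),
    deletion_events = table(tb$allele[tb$type == "del"]),
    start_positions = split(base$read_start, base$allele)
  )
}

# Required read span per reference position for witnessing an indel there:
# the whole homopolymer run containing the position (and the run starting
# one base right, for insertion anchors) plus one anchor base on each side.
# Returns 0-based bounds: a read witnesses position p (0-based) when
# read_start <= lo[p+1] - 1 and read_end >= hi[p+1].
run_span_bounds <- function(refseq) {
  ch <- strsplit(refseq, "")[[1]]
  run_id <- cumsum(c(TRUE, ch[-1] != ch[-length(ch)]))
  run_end_of <- stats::ave(seq_along(run_id), run_id, FUN = max) # 1-based
  run_start_of <- stats::ave(seq_along(run_id), run_id, FUN = min)
  list(lo = pmin(run_start_of, c(run_start_of[-1], length(ch) + 1L)) - 1L,
       hi = pmax(run_end_of, c(run_end_of[-1], 0L)) + 1L)
}

# Per-position 1-bp/2-bp indel event fractions of one pileup. The
# denominator is the homopolymer-spanning depth: only reads that cover the
# whole run containing the position (plus one anchor base on each side) can
# witness an indel there, so reads ending inside the run are excluded --
# otherwise they dilute every indel VAF at run positions.
indel_fractions <- function(pile) {
  tb <- pile$tab
  if (!nrow(tb)) {
    return(data.table::data.table(pos = integer(), depth = integer(),
                                  f_ins = numeric(), f_del = numeric(),
                                  f_ins2 = numeric()))
  }
  refseq <- pile$panel$reference$sequence
  sb <- run_span_bounds(refseq)
  span_lo <- sb$lo; span_hi <- sb$hi
  pos <- NULL; type <- NULL; allele <- NULL # NSE notes
  cov <- tb[type %in% c("base", "gap"), ]
  cov_depth <- cov[, .(depth = sum(read_start <= span_lo[pos + 1L] - 1L &
                                     read_end >= span_hi[pos + 1L])),
                   by = pos]
  # insertion events live between pileup column p and p+1; report them at
  # p+1 (the first base of the run they extend) so that a run's insertion
  # and deletion fractions share one position
  ins1 <- tb[type == "ins" & nchar(allele) == 1L, .(n_ins = .N),
             by = .(pos = pos + 1L)]
  ins2 <- tb[type == "ins" & nchar(allele) == 2L, .(n_ins2 = .N),
             by = .(pos = pos + 1L)]
  del1 <- tb[type == "del" & allele == "1", .(n_del = .N), by = pos]
  out <- Reduce(function(x, y) merge(x, y, by = "pos", all.x = TRUE),
                list(cov_depth, ins1, ins2, del1))
  for (col in c("n_ins", "n_ins2", "n_del")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out$f_ins <- ifelse(out$depth > 0, out$n_ins / out$depth, 0)
  out$f_ins2 <- ifelse(out$depth > 0, out$n_ins2 / out$depth, 0)
  out$f_del <- ifelse(out$depth > 0, out$n_del / out$depth, 0)
  out[, c("pos", "depth", "f_ins", "f_del", "f_ins2"), with = FALSE]
}
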