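#' Aligner configuration
#'
#' Defaults follow the two-stage mapping design: a 20 nt key from both read
#' ends (first and last 4 nt excluded) searched with at most 2 mismatches on
#' both strands; candidate starts within <5 nt combined; Smith-Waterman with
#' match 10, mismatch -8, indel -9 (flat, no open/extend distinction); a
#' rearrangement rescoring pass with match 100, mismatch 30, deletion 10,
#' insertion 1 per base, an indel run longer than 5 counting as a single
#' match.
#'
#' @param key_length seed key length.
#' @param key_skip bases excluded from each read end before the key.
#' @param key_max_mismatch maximum substitutions allowed in a key hit.
#' @param cluster_distance candidate starts closer than this are combined.
#' @param sw_match,sw_mismatch,sw_indel Smith-Waterman scores.
#' @param re_match,re_mismatch,re_del,re_ins rearrangement scores (all
#'   non-negative; higher is better).
#' @param re_long_indel_len indel runs longer than this score as one match.
#' @param window_pad reference padding around a candidate start for the SW
#'   window.
#' @param rescue_min_clip minimum soft-clip length eligible for long-deletion
#'   rescue.
#' @param rescue_max_gap furthest deletion length bridged by clip rescue.
#' @param unmapped_floor_frac reads whose rearrangement score is below this
#'   fraction of the perfect-read score are reported unmapped.
#' @return an `aligner_config` list.
#' @export
aligner_config <- function(key_length = 20L, key_skip = 4L,
                           key_max_mismatch = 2L, cluster_distance = 5L,
                           sw_match = 10, sw_mismatch = -8, sw_indel = -9,
                           re_match = 100, re_mismatch = 30, re_del = 10,
                           re_ins = 1, re_long_indel_len = 5L,
                           window_pad = 30L, rescue_min_clip = 8L,
                           rescue_max_gap = 60L,
                           unmapped_floor_frac = 0.6) {
  stopifnot(key_length >= 8L, re_match >= 0, re_mismatch >= 0, re_del >= 0,
            re_ins >= 0, sw_match > 0, sw_mismatch < 0, sw_indel < 0)
  structure(as.list(environment()), class = "aligner_config")
}

#' Build a BWT (FM) index of the reference
#'
#' Supports exact interval queries; inexact search is backtracking over at
#' most `key_max_mismatch` substitutions.
#'
#' @param ref an [reference()] object (or plain DNA string).
#' @return a `bwt_index` object.
#' @export
build_index <- function(ref) {
  seq <- if (inherits(ref, "ampliscan_reference")) ref$sequence else toupper(ref)
  idx <- cpp_fm_build(seq)
  idx$length <- nchar(seq)
  class(idx) <- "bwt_index"
  idx
}

#' Search a query in a BWT index with bounded mismatches
#'
#' @param index a [build_index()] result.
#' @param query DNA string.
#' @param max_mismatch maximum substitutions.
#' @return sorted 0-based start positions of approximate occurrences.
#' @export
fm_search <- function(index, query, max_mismatch = 0L) {
  cpp_fm_search(index, toupper(query), as.integer(max_mismatch))
}

#' Find candidate alignment start positions for a read
#'
#' Extracts the two seed keys (`read[key_skip .. key_skip+key_length)` and
#' the mirror key at the 3' end, 0-based), searches each on both strands
#' with at most `key_max_mismatch` substitutions, and converts each hit to
#' the implied full-read start.
#'
#' @param read read sequence.
#' @param index [build_index()] of the panel reference.
#' @param cfg [aligner_config()].
#' @return data.frame with columns `start` (implied 0-based read start on
#'   the forward reference), `strand`, `key` (`"5p"`/`"3p"`); zero rows when
#'   no key hits. Reads shorter than `2*key_skip + key_length` yield an
#'   object with attribute `reason = "too_short"`.
#' @export
find_seed_hits <- function(read, index, cfg = aligner_config()) {
  L <- nchar(read)
  empty <- data.frame(start = integer(), strand = character(), key = character())
  if (L < 2L * cfg$key_skip + cfg$key_length) {
    attr(empty, "reason") <- "too_short"
    return(empty)
  }
  rc <- revcomp(read)
  out <- list()
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") read else rc
    off5 <- cfg$key_skip
    off3 <- L - cfg$key_skip - cfg$key_length
    for (key in c("5p", "3p")) {
      off <- if (key == "5p") off5 else off3
      q <- substr(rd, off + 1L, off + cfg$key_length)
      hits <- fm_search(index, q, cfg$key_max_mismatch)
      if (length(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          start = hits - off, strand = strand, key = key)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[res$start > -cfg$key_length & res$start < index$length, , drop = FALSE]
}

#' Combine nearby candidate starts (single linkage)
#'
#' Starts on the same strand closer than `cluster_distance` are chained into
#' one group; the group representative is the minimum start.
#'
#' @param hits data.frame from [find_seed_hits()].
#' @param cfg [aligner_config()].
#' @return data.frame with columns `start` (representative) and `strand`.
#' @export
cluster_starts <- function(hits, cfg = aligner_config()) {
  if (!nrow(hits)) return(data.frame(start = integer(), strand = character()))
  out <- list()
  for (s in unique(hits$strand)) {
    st <- sort(unique(hits$start[hits$strand == s]))
    grp <- cumsum(c(TRUE, diff(st) >= cfg$cluster_distance))
    reps <- as.integer(tapply(st, grp, min))
    out[[s]] <- data.frame(start = reps, strand = s)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Smith-Waterman local alignment
#'
#' Standard local dynamic programming with flat per-base indel penalty and
#' deterministic tie-breaks; unaligned read ends are reported as soft clips.
#'
#' @param read read sequence (oriented).
#' @param window reference window.
#' @param cfg [aligner_config()].
#' @return list with `score`, `ops` (M/X/I/D/S run-length string) and
#'   `window_offset` (0-based window position of the first aligned base).
#' @export
smith_waterman <- function(read, window, cfg = aligner_config()) {
  cpp_sw(read, window, cfg$sw_match, cfg$sw_mismatch, cfg$sw_indel)
}

#' Rearrangement score of an alignment
#'
#' `re_match` per matched base, `re_mismatch` per mismatched base; every
#' base of an indel run longer than `re_long_indel_len` scores as a match
#' (long true indels beat mismatch or split-deletion scatter), shorter runs
#' score per base (`re_del`/`re_ins`). Soft clips contribute 0.
#'
#' @param ops ops string or parsed ops table.
#' @param cfg [aligner_config()].
#' @return numeric score.
#' @export
re_score <- function(ops, cfg = aligner_config()) {
  tab <- if (is.character(ops)) parse_ops(ops) else ops
  sc <- 0
  for (k in seq_len(nrow(tab))) {
    op <- tab$op[k]; len <- tab$len[k]
    sc <- sc + switch(op,
      M = cfg$re_match * len,
      X = cfg$re_mismatch * len,
      D = if (len > cfg$re_long_indel_len) cfg$re_match * len else cfg$re_del * len,
      I = if (len > cfg$re_long_indel_len) cfg$re_match * len else cfg$re_ins * len,
      S = 0)
  }
  sc
}

# left-shift indel runs within repeats/homopolymers; preserves the SW score
# and the read sequence implied by the alignment. ref here is the full
# reference string; ref_start the 0-based position of the first aligned base.
left_shift_indels <- function(ops, read, ref, ref_start) {
  tab <- parse_ops(ops)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    # recompute positions
    refp <- ref_start
    readp <- 0L
    k <- 1L
    while (k <= nrow(tab)) {
      op <- tab$op[k]; len <- tab$len[k]
      if ((op == "D" || op == "I") && k > 1L && tab$op[k - 1L] == "M" &&
          tab$len[k - 1L] >= 1L) {
        if (op == "D") {
          ok <- substr(ref, refp, refp) == substr(ref, refp + len, refp + len)
          # ref[refp-1] (1-based refp) vs ref[refp+len-1]
        } else {
          ok <- substr(read, readp, readp) == substr(read, readp + len, readp + len)
        }
        if (ok) {
          tab$len[k - 1L] <- tab$len[k - 1L] - 1L
          # the column vacated on the right becomes M again
          if (k < nrow(tab) && tab$op[k + 1L] == "M") {
            tab$len[k + 1L] <- tab$len[k + 1L] + 1L
          } else {
            tab <- rbind(tab[seq_len(k), , drop = FALSE],
                         data.frame(op = "M", len = 1L),
                         if (k < nrow(tab)) tab[(k + 1L):nrow(tab), , drop = FALSE])
          }
          if (tab$len[k - 1L] == 0L) tab <- tab[-(k - 1L), , drop = FALSE]
          if (op == "D") ref_start <- ref_start # first aligned base unchanged
          changed <- TRUE
          break
        }
      }
      if (op %in% c("M", "X", "I", "S")) readp <- readp + len
      if (op %in% c("M", "X", "D")) refp <- refp + len
      k <- k + 1L
    }
  }
  list(ops = ops_string(tab$op, tab$len), ref_start = ref_start)
}

# Locate a clipped read segment in a reference region, tolerating sparse
# mismatches: a 12-mer from the anchored end of the clip is matched exactly,
# the rest compared base-wise with at most max(1, len/20) mismatches.
# anchor_end = "left" anchors the clip's first bases (trailing clip),
# "right" its last bases (leading clip). Returns 0-based offset of the clip
# within `region` plus the per-base match vector, or NULL.
locate_clip <- function(clip, region, anchor_end = c("left", "right")) {
  anchor_end <- match.arg(anchor_end)
  clen <- nchar(clip)
  alen <- min(12L, clen)
  max_mm <- max(1L, clen %/% 20L)
  anchor <- if (anchor_end == "left") substr(clip, 1L, alen) else
    substr(clip, clen - alen + 1L, clen)
  cch <- strsplit(clip, "")[[1]]
  hits <- gregexpr(anchor, region, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  best <- NULL
  for (h in hits) {
    off <- if (anchor_end == "left") h - 1L else h - 1L - (clen - alen)
    if (off < 0L || off + clen > nchar(region)) next
    rch <- strsplit(substr(region, off + 1L, off + clen), "")[[1]]
    m <- cch == rch
    if (sum(!m) <= max_mm) {
      cand <- list(offset = off, match = m)
      # smallest gap preferred: leftmost hit for trailing (left-anchored)
      # search region, rightmost for leading
      if (anchor_end == "left") { best <- cand; break }
      best <- cand
    }
  }
  best
}

# convert a long terminal soft clip into deletion + match when the clipped
# sequence occurs nearby in the reference (read spans a large deletion)
rescue_long_clips <- function(ops, read, ref, ref_start, cfg) {
  tab <- parse_ops(ops)
  n <- nrow(tab)
  improved <- FALSE
  # trailing clip
  if (n >= 1L && tab$op[n] == "S" && tab$len[n] >= cfg$rescue_min_clip) {
    clen <- tab$len[n]
    clip <- substr(read, nchar(read) - clen + 1L, nchar(read))
    aln_end <- ref_start + ops_ref_span(tab) # 0-based, one past last aligned
    search <- substr(ref, aln_end + 2L, aln_end + 1L + cfg$rescue_max_gap + clen)
    hit <- locate_clip(clip, search, "left")
    if (!is.null(hit) && hit$offset >= 0L) {
      d <- hit$offset + 1L # deletion length
      cand <- rbind(tab[-n, , drop = FALSE],
                    data.frame(op = c("D", ifelse(hit$match, "M", "X")),
                               len = c(d, rep(1L, clen))))
      if (re_score(cand, cfg) >= re_score(tab, cfg)) {
        tab <- parse_ops(ops_string(cand$op, cand$len))
        improved <- TRUE
      }
    }
  }
  # leading clip
  n <- nrow(tab)
  if (n >= 1L && tab$op[1] == "S" && tab$len[1] >= cfg$rescue_min_clip) {
    clen <- tab$len[1]
    clip <- substr(read, 1L, clen)
    lo <- max(0L, ref_start - cfg$rescue_max_gap - clen - 1L)
    search <- substr(ref, lo + 1L, ref_start) # up to base before aligned start
    hit <- locate_clip(clip, search, "right")
    if (!is.null(hit)) {
      clip_start <- lo + hit$offset # 0-based
      d <- ref_start - (clip_start + clen)
      if (d >= 1L) {
        cand <- rbind(data.frame(op = c(ifelse(hit$match, "M", "X"), "D"),
                                 len = c(rep(1L, clen), d)),
                      tab[-1L, , drop = FALSE])
        if (re_score(cand, cfg) >= re_score(tab, cfg)) {
          tab <- parse_ops(ops_string(cand$op, cand$len))
          ref_start <- clip_start
          improved <- TRUE
        }
      }
    }
  }
  list(ops = ops_string(tab$op, tab$len), ref_start = ref_start,
       improved = improved)
}

# Trim mismatch-dense alignment ends back to the last confident anchor (an
# M run of >= anchor_len) so that rescue_long_clips can try to re-anchor
# them across a large deletion. Returns NULL when both ends are clean.
trim_noisy_ends <- function(tab, anchor_len = 12L, min_x = 3L) {
  n <- nrow(tab)
  anchors <- which(tab$op == "M" & tab$len >= anchor_len)
  if (!length(anchors)) return(NULL)
  changed <- FALSE
  # tail
  a <- max(anchors)
  if (a < n) {
    tail_idx <- (a + 1L):n
    if (sum(tab$len[tail_idx][tab$op[tail_idx] == "X"]) >= min_x) {
      clip <- sum(tab$len[tail_idx][tab$op[tail_idx] %in% c("M", "X", "I", "S")])
      tab <- rbind(tab[seq_len(a), , drop = FALSE],
                   data.frame(op = "S", len = clip))
      changed <- TRUE
    }
  }
  # head
  n <- nrow(tab)
  anchors <- which(tab$op == "M" & tab$len >= anchor_len)
  b <- min(anchors)
  if (b > 1L) {
    head_idx <- seq_len(b - 1L)
    if (sum(tab$len[head_idx][tab$op[head_idx] == "X"]) >= min_x) {
      clip <- sum(tab$len[head_idx][tab$op[head_idx] %in% c("M", "X", "I", "S")])
      ref_gain <- sum(tab$len[head_idx][tab$op[head_idx] %in% c("M", "X", "D")])
      tab <- rbind(data.frame(op = "S", len = clip),
                   tab[b:nrow(tab), , drop = FALSE])
      attr(tab, "ref_shift") <- ref_gain
      changed <- TRUE
    }
  }
  if (!changed) return(NULL)
  tab
}

#' Rearrange an alignment to optimise gaps and mismatches
#'
#' Applies the linear-time rewrite pass: indels are left-shifted within
#' repeats (tie-break: leftmost placement), and long terminal soft clips are
#' re-anchored across large deletions when that raises the rearrangement
#' score (an indel run longer than `re_long_indel_len` counts as one match,
#' which is what makes a genuine long deletion preferable to mismatch or
#' clip scatter).
#'
#' @param ops ops string from [smith_waterman()].
#' @param read oriented read sequence.
#' @param ref full reference sequence string.
#' @param ref_start 0-based reference position of the first aligned base.
#' @param cfg [aligner_config()].
#' @return list with `ops`, `ref_start`, `re_score`.
#' @export
rearrange_alignment <- function(ops, read, ref, ref_start,
                                cfg = aligner_config()) {
  if (!grepl("[IDS]", ops)) {
    return(list(ops = ops, ref_start = ref_start,
                re_score = re_score(ops, cfg)))
  }
  r <- if (grepl("S", ops, fixed = TRUE)) {
    rescue_long_clips(ops, read, ref, ref_start, cfg)
  } else list(ops = ops, ref_start = ref_start)
  # merge fragmented indel runs (flat-penalty DP splits long deletions
  # across accidental interior matches)
  if (length(gregexpr("[ID]", r$ops)[[1]]) >= 2L &&
      gregexpr("[ID]", r$ops)[[1]][1] != -1L) {
    m <- merge_adjacent_indels(r$ops, read, ref, r$ref_start, cfg,
                               max_gap = cfg$re_long_indel_len)
    r$ops <- m$ops
  }
  # mismatch-dense ends (reads crossing a deletion the DP bridged as
  # mismatch scatter): trim back to the last clean anchor and try to
  # re-anchor the clip across a deletion; adopt only on score improvement
  trimmed <- trim_noisy_ends(parse_ops(r$ops))
  if (!is.null(trimmed)) {
    shift <- attr(trimmed, "ref_shift")
    t_start <- r$ref_start + if (is.null(shift)) 0L else shift
    t_ops <- ops_string(trimmed$op, trimmed$len)
    r2 <- rescue_long_clips(t_ops, read, ref, t_start, cfg)
    if (r2$improved && re_score(r2$ops, cfg) > re_score(r$ops, cfg)) {
      r <- list(ops = r2$ops, ref_start = r2$ref_start)
    }
  }
  sh <- if (grepl("[ID]", r$ops)) {
    left_shift_indels(r$ops, read, ref, r$ref_start)
  } else list(ops = r$ops, ref_start = r$ref_start)
  list(ops = sh$ops, ref_start = sh$ref_start,
       re_score = re_score(sh$ops, cfg))
}

#' Soft-clip primer-derived alignment bases
#'
#' If an alignment overlaps the forward/reverse primer interval of the
#' amplicon containing its midpoint, the overlapping aligned prefix/suffix
#' is converted to soft clips and the aligned span shrinks accordingly
#' (primer bases are synthetic and could mask real variants).
#'
#' @param aln one-row alignment (list/data.frame with `ref_start`, `ops`).
#' @param panel an [amplicon_panel()].
#' @return updated list with `ops` and `ref_start`.
#' @export
soft_clip_primers <- function(aln, panel) {
  tab <- parse_ops(aln$ops)
  span <- ops_ref_span(tab)
  mid <- aln$ref_start + span %/% 2L
  a <- panel$amplicons
  hit <- which(a$start <= mid & mid < a$end)
  if (!length(hit)) return(list(ops = aln$ops, ref_start = aln$ref_start))
  clip_lo <- a$fwd_primer_end[hit[1]] # columns < clip_lo are primer
  clip_hi <- a$rev_primer_start[hit[1]] # columns >= clip_hi are primer
  if (aln$ref_start >= clip_lo && aln$ref_start + span <= clip_hi) {
    return(list(ops = aln$ops, ref_start = aln$ref_start)) # inside insert
  }
  refp <- aln$ref_start
  ops_out <- character(0)
  len_out <- integer(0)
  new_start <- NA_integer_
  for (k in seq_len(nrow(tab))) {
    op <- tab$op[k]; len <- tab$len[k]
    if (op %in% c("S", "I")) {
      # keep; insertions flanked by primer columns become part of the clip
      at_primer <- refp < clip_lo || refp > clip_hi
      ops_out <- c(ops_out, if (op == "I" && at_primer) "S" else op)
      len_out <- c(len_out, len)
      next
    }
    if (op == "D") {
      in_primer <- refp + len <= clip_lo || refp >= clip_hi
      if (!in_primer) {
        ops_out <- c(ops_out, "D"); len_out <- c(len_out, len)
        if (is.na(new_start)) new_start <- new_start # D cannot open alignment
      }
      refp <- refp + len
      next
    }
    # M or X: split by primer boundaries
    cols <- refp + seq_len(len) - 1L
    primer <- cols < clip_lo | cols >= clip_hi
    r <- rle(primer)
    at <- 0L
    for (g in seq_along(r$lengths)) {
      gl <- r$lengths[g]
      if (r$values[g]) {
        ops_out <- c(ops_out, "S"); len_out <- c(len_out, gl)
      } else {
        ops_out <- c(ops_out, op); len_out <- c(len_out, gl)
        if (is.na(new_start)) new_start <- refp + at
      }
      at <- at + gl
    }
    refp <- refp + len
  }
  # drop D runs stranded at the clipped edges
  tab2 <- data.frame(op = ops_out, len = len_out)
  # leading: S* then possibly D -> drop that D
  first_core <- which(!tab2$op %in% c("S"))[1]
  while (!is.na(first_core) && tab2$op[first_core] == "D") {
    tab2 <- tab2[-first_core, , drop = FALSE]
    first_core <- which(!tab2$op %in% c("S"))[1]
  }
  last_core <- rev(which(!tab2$op %in% c("S")))[1]
  while (!is.na(last_core) && tab2$op[last_core] == "D") {
    tab2 <- tab2[-last_core, , drop = FALSE]
    last_core <- rev(which(!tab2$op %in% c("S")))[1]
  }
  if (is.na(new_start)) new_start <- aln$ref_start # fully clipped
  list(ops = ops_string(tab2$op, tab2$len), ref_start = new_start)
}

str_rev <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Spliced two-frame alignment bridging a large deletion: the read's 5' key
# anchors a prefix frame at s1 and the 3' key a suffix frame at s2 = s1 + d;
# the best split point maximises total matches over both frames (O(L) with
# cumulative sums). Returns NULL when the frames do not fit the reference.
bridge_clusters <- function(read, refseq, s1, s2) {
  L <- nchar(read)
  if (s1 < 0L || s2 + L > nchar(refseq)) return(NULL)
  rch <- strsplit(read, "")[[1]]
  r1 <- strsplit(substr(refseq, s1 + 1L, s1 + L), "")[[1]]
  r2 <- strsplit(substr(refseq, s2 + 1L, s2 + L), "")[[1]]
  m1 <- rch == r1
  m2 <- rch == r2
  c1 <- cumsum(m1); c2 <- cumsum(m2)
  ks <- seq_len(L - 1L)
  k <- ks[which.max(c1[ks] + (c2[L] - c2[ks]))]
  op <- c(ifelse(m1[seq_len(k)], "M", "X"), "D",
          ifelse(m2[(k + 1L):L], "M", "X"))
  len <- c(rep(1L, k), s2 - s1, rep(1L, L - k))
  list(ops = ops_string(op, len), ref_start = s1)
}

# allocation-light seed search + clustering used by map_reads; equivalent to
# find_seed_hits() followed by cluster_starts()
seed_clusters_fast <- function(sq, rc, index, cfg) {
  L <- nchar(sq)
  off5 <- cfg$key_skip
  off3 <- L - cfg$key_skip - cfg$key_length
  starts <- integer(0)
  strands <- character(0)
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") sq else rc
    for (off in unique(c(off5, off3))) {
      q <- substr(rd, off + 1L, off + cfg$key_length)
      hits <- cpp_fm_search(index, q, cfg$key_max_mismatch)
      if (length(hits)) {
        starts <- c(starts, hits - off)
        strands <- c(strands, rep(strand, length(hits)))
      }
    }
  }
  keep <- starts > -cfg$key_length & starts < index$length
  starts <- starts[keep]; strands <- strands[keep]
  out_s <- integer(0); out_str <- character(0)
  for (strand in c("+", "-")) {
    st <- sort(unique(starts[strands == strand]))
    if (!length(st)) next
    grp <- cumsum(c(TRUE, diff(st) >= cfg$cluster_distance))
    reps <- st[!duplicated(grp)] # sorted: first of each group = min
    out_s <- c(out_s, reps)
    out_str <- c(out_str, rep(strand, length(reps)))
  }
  list(start = out_s, strand = out_str)
}

#' Map a read set against a panel
#'
#' Full per-read pipeline: seed key search, start clustering,
#' Smith-Waterman per cluster, rearrangement rescoring, best-cluster choice
#' by rearrangement score (ties flagged multi-mapping and excluded from
#' variant calling), primer soft-clipping, unmapped floor.
#'
#' @param reads a read set (data.table with `id`, `seq`, `qual`) or a FASTQ
#'   path.
#' @param panel an [amplicon_panel()].
#' @param cfg [aligner_config()].
#' @param index optional prebuilt [build_index()] of the panel reference.
#' @return data.table of alignments: `read_id`, `mapped`, `reason`, `multi`,
#'   `ref_start`, `strand`, `ops`, `seq`/`qual` (oriented to the forward
#'   reference strand), `sw_score`, `re_score`, `nm`.
#' @export
map_reads <- function(reads, panel, cfg = aligner_config(), index = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (!nrow(reads)) stop("empty read set")
  if (any(!nzchar(reads$seq))) {
    stop("malformed read record at index ", which(!nzchar(reads$seq))[1])
  }
  if (is.null(index)) index <- build_index(panel$reference)
  refseq <- panel$reference$sequence
  reflen <- panel$reference$length
  rcs <- revcomp(reads$seq)
  rcq <- str_rev(reads$qual)
  n <- nrow(reads)
  out <- vector("list", n)
  amp <- panel$amplicons
  for (i in seq_len(n)) {
    sq <- reads$seq[i]
    L <- nchar(sq)
    if (L < 2L * cfg$key_skip + cfg$key_length) {
      out[[i]] <- aln_row(reads$id[i], FALSE, "too_short")
      next
    }
    cl <- seed_clusters_fast(sq, rcs[i], index, cfg)
    if (!length(cl$start)) {
      out[[i]] <- aln_row(reads$id[i], FALSE, "no_seed")
      next
    }
    best <- NULL
    best_score <- -Inf
    tie <- FALSE
    consider <- function(ra, strand, sw_score) {
      if (ra$re_score > best_score + 1e-9) {
        best_score <<- ra$re_score
        best <<- list(strand = strand, sw_score = sw_score, ra = ra,
                      oriented = if (strand == "+") sq else rcs[i],
                      qual = if (strand == "+") reads$qual[i] else rcq[i])
        tie <<- FALSE
      } else if (abs(ra$re_score - best_score) <= 1e-9 &&
                 !is.null(best) && ra$ref_start != best$ra$ref_start) {
        tie <<- TRUE
      }
    }
    for (k in seq_along(cl$start)) {
      strand <- cl$strand[k]
      oriented <- if (strand == "+") sq else rcs[i]
      s <- cl$start[k]
      win_lo <- max(0L, s - cfg$window_pad)
      win_hi <- min(reflen, s + L + cfg$window_pad)
      window <- substr(refseq, win_lo + 1L, win_hi)
      sw <- smith_waterman(oriented, window, cfg)
      if (sw$score <= 0) next
      ref_start <- win_lo + sw$window_offset
      ra <- rearrange_alignment(sw$ops, oriented, refseq, ref_start, cfg)
      consider(ra, strand, sw$score)
    }
    # same-strand cluster pairs a large deletion apart: spliced candidate
    for (strand in unique(cl$strand)) {
      ss <- sort(cl$start[cl$strand == strand])
      if (length(ss) < 2L) next
      oriented <- if (strand == "+") sq else rcs[i]
      for (u in seq_len(length(ss) - 1L)) {
        for (v in (u + 1L):length(ss)) {
          d <- ss[v] - ss[u]
          if (d < 1L || d > cfg$rescue_max_gap) next
          br <- bridge_clusters(oriented, refseq, ss[u], ss[v])
          if (is.null(br)) next
          ra <- rearrange_alignment(br$ops, oriented, refseq, br$ref_start, cfg)
          consider(ra, strand, NA_real_)
        }
      }
    }
    if (is.null(best)) {
      out[[i]] <- aln_row(reads$id[i], FALSE, "no_alignment")
      next
    }
    if (best_score < cfg$unmapped_floor_frac * cfg$re_match * L) {
      out[[i]] <- aln_row(reads$id[i], FALSE, "low_score")
      next
    }
    clipped <- soft_clip_primers(
      list(ops = best$ra$ops, ref_start = best$ra$ref_start), panel)
    out[[i]] <- list(
      read_id = reads$id[i], mapped = TRUE, reason = "",
      multi = tie, ref_start = as.integer(clipped$ref_start),
      strand = best$strand, ops = clipped$ops,
      seq = best$oriented, qual = best$qual,
      sw_score = best$sw_score, re_score = best_score,
      nm = ops_nm_str(clipped$ops))
  }
  data.table::rbindlist(out, fill = TRUE)
}

aln_row <- function(id, mapped, reason) {
  list(read_id = id, mapped = mapped, reason = reason,
       multi = FALSE, ref_start = NA_integer_,
       strand = NA_character_, ops = NA_character_,
       seq = NA_character_, qual = NA_character_,
       sw_score = NA_real_, re_score = NA_real_,
       nm = NA_integer_)
}

#' Write alignments as SAM
#'
#' Emits a valid SAM file with `@SQ` from the panel reference; internal
#' M/X ops are folded into SAM `M` and the edit distance carried in `NM`.
#'
#' @param alignments data.table from [map_reads()].
#' @param panel an [amplicon_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, panel, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", panel$reference$name,
                  "\tLN:", panel$reference$length),
           "@PG\tID:ampliscan\tPN:ampliscan")
  recs <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    if (!a$mapped) {
      return(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   "*", "*", sep = "\t"))
    }
    flag <- if (a$strand == "-") 16L else 0L
    cigar <- gsub("X", "M", a$ops)
    tab <- parse_ops(cigar)
    cigar <- ops_string(tab$op, tab$len)
    paste(a$read_id, flag, panel$reference$name, a$ref_start + 1L,
          if (a$multi) 0L else 60L, cigar, "*", 0L, 0L, a$seq, a$qual,
          paste0("NM:i:", a$nm), sep = "\t")
  }, "")
  writeLines(c(hdr, recs), path)
  invisible(path)
}
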