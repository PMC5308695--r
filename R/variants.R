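#' Calling mode configuration
#'
#' Germline calling uses a 25% allelic ratio for SNVs and indels with a
#' minimum depth of 50x; somatic (FFPE) calling uses a 10% variant
#' frequency threshold with a minimum depth of 100x. The 25% indel
#' detection limit is retained as the reliability threshold of the
#' homopolymer filters.
#'
#' @param name `"germline"` or `"somatic"`.
#' @return a `calling_mode` list with `name`, `min_depth`, `min_vaf`,
#'   `indel_detection_limit`.
#' @export
calling_mode <- function(name = c("germline", "somatic")) {
  name <- match.arg(name)
  if (name == "germline") {
    structure(list(name = name, min_depth = 50L, min_vaf = 0.25,
                   indel_detection_limit = 0.25), class = "calling_mode")
  } else {
    structure(list(name = name, min_depth = 100L, min_vaf = 0.10,
                   indel_detection_limit = 0.25), class = "calling_mode")
  }
}

#' Filter cascade configuration
#'
#' Thresholds: depth test significance 5% (alpha), insertion overrun 20
#' percentage points, deletion displacement 30 points, HP percentage 25%,
#' strand bias 35 points, and the Q10 context-quality floor below which
#' reads are ignored by the strand-bias tally.
#'
#' @param depth_test_alpha,insertion_overrun,deletion_displacement,hp_percentage,strand_bias
#'   thresholds in (0,1).
#' @param context_quality_floor Phred floor for strand-informative reads.
#' @param min_informative_strand reads required on the empty strand before
#'   the one-strand-only rule fires.
#' @return a `filter_config` list.
#' @export
filter_config <- function(depth_test_alpha = 0.05, insertion_overrun = 0.20,
                          deletion_displacement = 0.30, hp_percentage = 0.25,
                          strand_bias = 0.35, context_quality_floor = 10,
                          min_informative_strand = 5L) {
  stopifnot(depth_test_alpha > 0, depth_test_alpha < 1,
            hp_percentage > 0, hp_percentage < 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Call candidate variants from a pileup
#'
#' Emits a candidate when depth reaches the mode's minimum and the allele
#' fraction reaches the mode's VAF threshold (boundary inclusive). Zygosity
#' is annotated het below VAF 0.75, hom otherwise. Candidates carry the
#' per-strand quality-screened counts and wild-type/mutant read start
#' position multisets the filter cascade needs.
#'
#' @param pile a [build_pileup()] result.
#' @param mode a [calling_mode()].
#' @param cfg a [filter_config()] (supplies the context-quality floor used
#'   for the strand tallies).
#' @return data.table of candidates; zero rows when nothing reaches the
#'   thresholds.
#' @export
call_candidates <- function(pile, mode = calling_mode("germline"),
                            cfg = filter_config()) {
  tb <- pile$tab
  empty <- data.table::data.table(
    pos = integer(), vcf_pos = integer(), hp_pos = integer(),
    type = character(),
    ref = character(), alt = character(), event_len = integer(),
    vaf = numeric(),
    depth = integer(), alt_count = integer(), zygosity = character(),
    hp_context = integer(), vaf_fwd = numeric(), vaf_rev = numeric(),
    alt_fwd = integer(), alt_rev = integer(), n_fwd = integer(),
    n_rev = integer(), f_ins_sample = numeric(), f_del_sample = numeric(),
    f_ins2_sample = numeric(), start_wt = list(), start_mut = list())
  if (!nrow(tb)) return(empty)
  refseq <- pile$panel$reference$sequence
  hp <- hp_run_lengths(refseq)
  pos <- NULL; type <- NULL; allele <- NULL # data.table NSE
  depth_tab <- tb[type %in% c("base", "gap"), .(depth = .N), by = pos]
  depth_of <- stats::setNames(depth_tab$depth, depth_tab$pos)
  frac <- indel_fractions(pile)
  span_of <- stats::setNames(frac$depth, frac$pos)
  f_of <- function(p, col) {
    i <- match(p, frac$pos)
    if (is.na(i)) 0 else frac[[col]][i]
  }
  # candidate events: SNVs (base != ref), insertions, deletions
  ref_at <- function(p) substr(refseq, p + 1L, p + 1L)
  ev <- tb[type %in% c("base", "ins", "del"),
           .(count = .N), by = .(pos, type, allele)]
  ev <- ev[!(type == "base" & allele == vapply(pos, ref_at, "")), ]
  out <- list()
  sb <- run_span_bounds(refseq)
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]
    typ <- switch(ev$type[i], base = "SNV", ins = "insertion", del = "deletion")
    hp_pos0 <- if (typ == "insertion") p + 1L else p
    # indel VAFs are computed against the homopolymer-spanning depth (see
    # indel_fractions); SNVs against the plain column depth
    d <- if (typ == "SNV") depth_of[as.character(p)]
         else span_of[as.character(hp_pos0)]
    if (is.na(d) || d < mode$min_depth) next
    vaf <- min(1, ev$count[i] / d)
    if (vaf < mode$min_vaf) next
    rows <- tb[pos == p & type == ev$type[i] & allele == ev$allele[i], ]
    wt_rows <- tb[pos == p & type == "base" & allele == ref_at(p), ]
    if (typ != "SNV") {
      # rank-test groups must both be able to witness the indel: restrict
      # both groups to run-spanning reads
      spans <- function(df) df[df$read_start <= sb$lo[hp_pos0 + 1L] - 1L &
                                 df$read_end >= sb$hi[hp_pos0 + 1L], ]
      wt_rows <- spans(wt_rows)
      rows <- spans(rows)
    }
    qrows <- rows[!is.na(rows$ctxq) & rows$ctxq >= cfg$context_quality_floor, ]
    qcov <- tb[pos == p & type %in% c("base", "gap") &
                 !is.na(ctxq) & ctxq >= cfg$context_quality_floor, ]
    if (typ != "SNV") {
      # strand tallies for indels use the spanning coverage only
      qcov <- qcov[qcov$read_start <= sb$lo[hp_pos0 + 1L] - 1L &
                     qcov$read_end >= sb$hi[hp_pos0 + 1L], ]
    }
    n_fwd <- sum(qcov$strand == "+")
    n_rev <- sum(qcov$strand == "-")
    alt_fwd <- sum(qrows$strand == "+")
    alt_rev <- sum(qrows$strand == "-")
    # hp_pos: the run-level position the homopolymer filters refer to (first
    # base of the run an indel modifies); insertions are emitted at the
    # pileup anchor column p but modify the run starting at p+1
    if (typ == "SNV") {
      ref <- ref_at(p); alt <- ev$allele[i]; elen <- 1L; vcf_pos <- p
      hp_pos <- p
    } else if (typ == "insertion") {
      ref <- ref_at(p); alt <- paste0(ref, ev$allele[i])
      elen <- nchar(ev$allele[i]); vcf_pos <- p
      hp_pos <- p + 1L
    } else {
      elen <- as.integer(ev$allele[i])
      # VCF-style: anchor base before the first deleted base; `pos` keeps
      # the event column (first deleted base) for the pileup-level filters
      vcf_pos <- p - 1L
      ref <- substr(refseq, p, p + elen)
      alt <- substr(refseq, p, p)
      hp_pos <- p
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      pos = p, vcf_pos = vcf_pos, hp_pos = hp_pos, type = typ,
      ref = ref, alt = alt, event_len = elen,
      vaf = vaf, depth = as.integer(d), alt_count = ev$count[i],
      zygosity = if (vaf < 0.75) "het" else "hom",
      hp_context = hp[hp_pos + 1L],
      vaf_fwd = if (n_fwd > 0) alt_fwd / n_fwd else NA_real_,
      vaf_rev = if (n_rev > 0) alt_rev / n_rev else NA_real_,
      alt_fwd = alt_fwd, alt_rev = alt_rev, n_fwd = n_fwd, n_rev = n_rev,
      f_ins_sample = f_of(hp_pos, "f_ins"),
      f_del_sample = f_of(hp_pos, "f_del"),
      f_ins2_sample = f_of(hp_pos, "f_ins2"),
      start_wt = list(wt_rows$read_start), start_mut = list(rows$read_start))
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, pos)
  res[]
}

#' Build the homopolymer error database from wild-type samples
#'
#' Per position, the 1-bp insertion, 1-bp deletion and 2-bp insertion event
#' fractions averaged across the wild-type samples (positions a sample does
#' not cover do not contribute to its average). Positions where the
#' averaged 1-bp indel frequency reaches 10% are flagged high-error; below
#' that the platform error is considered reliable.
#'
#' @param pileups list of [build_pileup()] results (>= 2 samples).
#' @param panel an [amplicon_panel()].
#' @return data.table with `pos`, `f_ins`, `f_del`, `f_ins2`, `high_error`.
#' @export
build_hp_database <- function(pileups, panel) {
  if (length(pileups) < 2L) stop("need at least 2 wild-type samples")
  per <- lapply(pileups, indel_fractions)
  all_tab <- data.table::rbindlist(per)
  pos <- NULL
  db <- all_tab[, .(f_ins = mean(f_ins), f_del = mean(f_del),
                    f_ins2 = mean(f_ins2)), by = pos]
  db$high_error <- pmax(db$f_ins, db$f_del) >= 0.10
  data.table::setorder(db, pos)
  db[]
}

hp_db_lookup <- function(db, p) {
  i <- match(p, db$pos)
  if (is.na(i)) {
    list(f_ins = 0, f_del = 0, f_ins2 = 0, high_error = FALSE)
  } else {
    as.list(db[i, ])
  }
}

#' Write / read a homopolymer error database as TSV
#'
#' @param db database from [build_hp_database()].
#' @param path file path.
#' @return `path` / the database.
#' @export
write_hp_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hp_database
#' @export
read_hp_database <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Mann-Whitney U test
#'
#' U is the number of pairs where x exceeds y (ties count one half),
#' computed from midranks. The p-value is exact (null distribution of U)
#' for untied samples with combined n <= 20, otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#' Two-sided.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  N <- m + n
  if (!has_ties && N <= 20) {
    p <- 2 * min(stats::pwilcox(U, m, n),
                 1 - stats::pwilcox(U - 1, m, n))
    p <- min(1, p)
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p_value = p)
}

#' Depth test filter
#'
#' Compares the read start position distributions of wild-type and mutant
#' reads at the variant column with the Mann-Whitney U test; a significant
#' difference marks the variant as a fragmentation artefact. Fewer than 3
#' reads in either group passes by default (the rank test is meaningless
#' and the depth/VAF gates already apply).
#'
#' @param v one-row candidate (from [call_candidates()]).
#' @param cfg a [filter_config()].
#' @return list with `pass` and `p_value`.
#' @export
filter_depth_test <- function(v, cfg = filter_config(),
                              cluster_distance = 5L) {
  wt <- v$start_wt[[1]]
  mut <- v$start_mut[[1]]
  if (length(wt) < 3L || length(mut) < 3L) {
    return(list(pass = TRUE, p_value = NA_real_))
  }
  # enzymatic fragmentation gives a few well-defined start sites; group
  # starts within <5 nt (the seed clustering distance) so that the 1-bp
  # boundary jitter an indel carrier's shorter fragments produce does not
  # register as an artefact, then rank the group memberships
  st <- sort(unique(c(wt, mut)))
  grp_id <- cumsum(c(TRUE, diff(st) >= cluster_distance))
  cl <- stats::setNames(grp_id, st)
  p <- mann_whitney_u(cl[as.character(wt)], cl[as.character(mut)])$p_value
  list(pass = p >= cfg$depth_test_alpha, p_value = p)
}

#' Strand bias filter
#'
#' Reads whose context quality is below the Q10 floor are excluded from the
#' tallies (done at candidate construction). Fails when the variant is seen
#' on exactly one strand while the empty strand has at least
#' `min_informative_strand` informative reads, or when the per-strand VAFs
#' differ by more than the threshold.
#'
#' @inheritParams filter_depth_test
#' @return list with `pass` and `statistic` (the VAF difference).
#' @export
filter_strand_bias <- function(v, cfg = filter_config()) {
  one_strand <- (v$alt_fwd == 0L && v$alt_rev > 0L && v$n_fwd >= cfg$min_informative_strand) ||
    (v$alt_rev == 0L && v$alt_fwd > 0L && v$n_rev >= cfg$min_informative_strand)
  diff <- if (!is.na(v$vaf_fwd) && !is.na(v$vaf_rev)) {
    abs(v$vaf_fwd - v$vaf_rev)
  } else NA_real_
  fail <- one_strand || (!is.na(diff) && diff > cfg$strand_bias)
  list(pass = !fail, statistic = diff)
}

#' Insertion overrun filter
#'
#' Applies only at high-error database positions (low-error positions
#' auto-pass: their indel frequencies are reliable). A true 1-bp insertion
#' must exceed the database insertion frequency by at least the overrun
#' margin AND show elevated 2-bp insertion frequency relative to the
#' database.
#'
#' @param v one-row insertion candidate.
#' @param db [build_hp_database()] result.
#' @param cfg a [filter_config()].
#' @return list with `pass` and `statistic` (the frequency margin).
#' @export
filter_insertion_overrun <- function(v, db, cfg = filter_config()) {
  e <- hp_db_lookup(db, if (!is.null(v$hp_pos)) v$hp_pos else v$pos)
  if (!e$high_error) return(list(pass = TRUE, statistic = NA_real_))
  margin <- v$f_ins_sample - e$f_ins
  pass <- margin >= cfg$insertion_overrun && v$f_ins2_sample > e$f_ins2
  list(pass = pass, statistic = margin)
}

#' Deletion displacement filter
#'
#' Applies only at high-error positions. A true 1-bp deletion shifts the
#' deletion share r = f_del/(f_del + f_ins) upward relative to the database
#' while the insertion frequency decreases.
#'
#' @param v one-row deletion candidate.
#' @inheritParams filter_insertion_overrun
#' @return list with `pass` and `statistic` (the share shift).
#' @export
filter_deletion_displacement <- function(v, db, cfg = filter_config()) {
  e <- hp_db_lookup(db, if (!is.null(v$hp_pos)) v$hp_pos else v$pos)
  if (!e$high_error) return(list(pass = TRUE, statistic = NA_real_))
  r_sample <- ratio_or_zero(v$f_del_sample, v$f_del_sample + v$f_ins_sample)
  r_db <- ratio_or_zero(e$f_del, e$f_del + e$f_ins)
  shift <- r_sample - r_db
  pass <- shift >= cfg$deletion_displacement && v$f_ins_sample < e$f_ins
  list(pass = pass, statistic = shift)
}

ratio_or_zero <- function(num, den) if (den > 0) num / den else 0

#' HP percentage filter
#'
#' Corrects an indel's frequency by the HP-opposite term: the deficit of
#' the opposite event (insertion for a deletion and vice versa) in the
#' sample relative to the database. corrected = f_event - max(0,
#' f_opposite_db - f_opposite_sample); the variant passes when the
#' corrected frequency reaches the HP-percentage threshold (boundary
#' inclusive).
#'
#' @param v one-row indel candidate.
#' @inheritParams filter_insertion_overrun
#' @return list with `pass` and `corrected_vaf`.
#' @export
filter_hp_percentage <- function(v, db, cfg = filter_config()) {
  e <- hp_db_lookup(db, if (!is.null(v$hp_pos)) v$hp_pos else v$pos)
  if (v$type == "deletion") {
    hp_opposite <- e$f_ins - v$f_ins_sample
    f_event <- v$f_del_sample
  } else {
    hp_opposite <- e$f_del - v$f_del_sample
    f_event <- v$f_ins_sample
  }
  corrected <- f_event - max(0, hp_opposite)
  list(pass = corrected >= cfg$hp_percentage, corrected_vaf = corrected)
}

#' Variant rearrangement tool
#'
#' Finds non-homopolymer indel candidates longer than one base with allele
#' frequency below the indel detection limit and re-examines the reads near
#' them: adjacent same-type indel runs separated by at most two aligned
#' bases are merged into one longer indel when the merged alignment's
#' rearrangement score is at least the original's. VAFs are recomputed and
#' the candidate list re-emitted.
#'
#' @param candidates data.table from [call_candidates()].
#' @param alignments data.table from [map_reads()] (sorted by position).
#' @param panel an [amplicon_panel()].
#' @param mode a [calling_mode()].
#' @param cfg an [aligner_config()] (for the rearrangement scores).
#' @param fcfg a [filter_config()].
#' @return list with `candidates` (re-called) and `alignments` (updated).
#' @export
variant_rearrangement_tool <- function(candidates, alignments, panel,
                                       mode = calling_mode("germline"),
                                       cfg = aligner_config(),
                                       fcfg = filter_config()) {
  targets <- candidates[candidates$type != "SNV" &
                          candidates$event_len > 1L &
                          candidates$hp_context < 3L &
                          candidates$vaf < mode$indel_detection_limit, ]
  if (!nrow(targets)) {
    return(list(candidates = candidates, alignments = alignments))
  }
  aln <- data.table::copy(alignments)
  refseq <- panel$reference$sequence
  touched <- FALSE
  for (t in seq_len(nrow(targets))) {
    win <- c(targets$pos[t] - (targets$event_len[t] + 5L),
             targets$pos[t] + 2L * (targets$event_len[t] + 5L))
    near <- which(aln$mapped & !aln$multi &
                    aln$ref_start <= win[2] &
                    aln$ref_start + nchar(aln$seq) >= win[1])
    for (i in near) {
      mr <- merge_adjacent_indels(aln$ops[i], aln$seq[i], refseq,
                                  aln$ref_start[i], cfg)
      if (mr$changed) {
        data.table::set(aln, i, "ops", mr$ops)
        data.table::set(aln, i, "nm", ops_nm(parse_ops(mr$ops)))
        touched <- TRUE
      }
    }
  }
  if (!touched) return(list(candidates = candidates, alignments = alignments))
  pile <- build_pileup(aln[order(aln$ref_start)], panel)
  list(candidates = call_candidates(pile, mode, fcfg), alignments = aln)
}

# merge same-type indel runs separated by <=2 aligned columns when the
# rewritten ops score at least as high under the rearrangement matrix
merge_adjacent_indels <- function(ops, read, ref, ref_start, cfg,
                                  max_gap = 2L) {
  tab <- parse_ops(ops)
  changed <- FALSE
  repeat {
    idx <- which(tab$op %in% c("I", "D"))
    done <- TRUE
    for (a in idx) {
      # look for the next indel of same type within <=max_gap aligned columns
      b <- a + 1L
      gap <- 0L
      while (b <= nrow(tab) && tab$op[b] %in% c("M", "X") && gap + tab$len[b] <= max_gap) {
        gap <- gap + tab$len[b]
        b <- b + 1L
      }
      if (b > nrow(tab) || tab$op[b] != tab$op[a] || b == a + 1L) next
      total <- tab$len[a] + tab$len[b]
      k <- gap
      # locate read/ref offsets of the group start
      offs <- ops_offsets(tab, ref_start)
      if (tab$op[a] == "D") {
        # total ref consumption stays total + k; the k read bases realign
        # either before or after the merged deletion
        ref_lo <- offs$ref[a] # 0-based first ref base of run a
        seg_read <- read_bases_between(tab, read, a, b)
        cand1 <- splice_rows(tab, a, b, list(
          data.frame(op = "D", len = total),
          mx_rows(seg_read, substr(ref, ref_lo + total + 1L,
                                   ref_lo + total + k))))
        cand2 <- splice_rows(tab, a, b, list(
          mx_rows(seg_read, substr(ref, ref_lo + 1L, ref_lo + k)),
          data.frame(op = "D", len = total)))
      } else {
        seg_read <- read_bases_between(tab, read, a, b)
        ref_lo <- offs$ref[a]
        group_read <- paste0(ins_bases(tab, read, a), seg_read,
                             ins_bases(tab, read, b))
        refk <- substr(ref, ref_lo + 1L, ref_lo + k)
        cand1 <- splice_rows(tab, a, b, list(
          mx_rows(substr(group_read, 1L, k), refk),
          data.frame(op = "I", len = total)))
        cand2 <- splice_rows(tab, a, b, list(
          data.frame(op = "I", len = total),
          mx_rows(substr(group_read, nchar(group_read) - k + 1L,
                         nchar(group_read)), refk)))
      }
      sc0 <- re_score(tab, cfg)
      sc1 <- if (!is.null(cand1)) re_score(cand1, cfg) else -Inf
      sc2 <- if (!is.null(cand2)) re_score(cand2, cfg) else -Inf
      if (max(sc1, sc2) >= sc0) {
        tab <- if (sc2 >= sc1) cand2 else cand1
        changed <- TRUE
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(ops = ops_string(tab$op, tab$len), changed = changed)
}

# 0-based ref/read offset of the start of each ops row
ops_offsets <- function(tab, ref_start) {
  refp <- integer(nrow(tab)); readp <- integer(nrow(tab))
  r <- ref_start; q <- 0L
  for (k in seq_len(nrow(tab))) {
    refp[k] <- r; readp[k] <- q
    if (tab$op[k] %in% c("M", "X", "D")) r <- r + tab$len[k]
    if (tab$op[k] %in% c("M", "X", "I", "S")) q <- q + tab$len[k]
  }
  list(ref = refp, read = readp)
}

read_bases_between <- function(tab, read, a, b) {
  if (b <= a + 1L) return("")
  offs <- ops_offsets(tab, 0L)
  lo <- offs$read[a + 1L]
  hi <- offs$read[b] # start of run b
  substr(read, lo + 1L, hi)
}

ins_bases <- function(tab, read, k) {
  if (tab$op[k] != "I") return("")
  offs <- ops_offsets(tab, 0L)
  substr(read, offs$read[k] + 1L, offs$read[k] + tab$len[k])
}

mx_rows <- function(read_seg, ref_seg) {
  if (!nzchar(read_seg)) return(data.frame(op = character(), len = integer()))
  rch <- strsplit(read_seg, "")[[1]]
  fch <- strsplit(ref_seg, "")[[1]]
  if (length(fch) < length(rch)) fch <- c(fch, rep("N", length(rch) - length(fch)))
  data.frame(op = ifelse(rch == fch[seq_along(rch)], "M", "X"),
             len = 1L)
}

splice_rows <- function(tab, a, b, repl) {
  repl <- do.call(rbind, repl)
  out <- rbind(
    if (a > 1L) tab[seq_len(a - 1L), , drop = FALSE],
    repl,
    if (b < nrow(tab)) tab[(b + 1L):nrow(tab), , drop = FALSE])
  # re-run-length-encode
  parse_ops(ops_string(out$op, out$len))
}

#' Run the platform filter cascade
#'
#' Illumina data passes unfiltered (variants are accepted as called);
#' ion-torrent data runs the cascade in order depth test, insertion
#' overrun, deletion displacement, HP percentage, strand bias. SNVs are
#' exempt from the three indel filters. Failed variants are retained with
#' their filter flags for visual-inspection export; survivors are flagged
#' `PASS`.
#'
#' @param candidates data.table from [call_candidates()].
#' @param db [build_hp_database()] result (required for iontorrent).
#' @param cfg a [filter_config()].
#' @param platform `"illumina"` or `"iontorrent"`.
#' @param pathogenic optional character vector of `pos:ref:alt` keys (or
#'   logical vector) tagging pathogenic variants for the audit table.
#' @return list with `candidates` (flag columns and `filter` added) and
#'   `audit` (survivor counts after each filter, total and pathogenic).
#' @export
run_cascade <- function(candidates, db = NULL, cfg = filter_config(),
                        platform = c("iontorrent", "illumina"),
                        pathogenic = NULL) {
  platform <- match.arg(platform)
  cand <- data.table::copy(candidates)
  n <- nrow(cand)
  is_path <- pathogenic_mask(cand, pathogenic)
  filters <- c("depth_test", "insertion_overrun", "deletion_displacement",
               "hp_percentage", "strand_bias")
  if (platform == "illumina" || n == 0L) {
    cand$filter <- rep("PASS", n)
    audit <- data.table::data.table(
      stage = c("total", if (platform == "iontorrent") filters),
      total = n, pathogenic = sum(is_path))
    return(list(candidates = cand, audit = audit))
  }
  if (is.null(db)) stop("iontorrent cascade requires a homopolymer error database")
  pass <- matrix(TRUE, n, length(filters), dimnames = list(NULL, filters))
  stat <- matrix(NA_real_, n, length(filters), dimnames = list(NULL, filters))
  for (i in seq_len(n)) {
    v <- cand[i, ]
    r <- filter_depth_test(v, cfg)
    pass[i, 1] <- r$pass; stat[i, 1] <- r$p_value
    if (v$type == "insertion") {
      r <- filter_insertion_overrun(v, db, cfg)
      pass[i, 2] <- r$pass; stat[i, 2] <- r$statistic
    }
    if (v$type == "deletion") {
      r <- filter_deletion_displacement(v, db, cfg)
      pass[i, 3] <- r$pass; stat[i, 3] <- r$statistic
    }
    if (v$type != "SNV") {
      r <- filter_hp_percentage(v, db, cfg)
      pass[i, 4] <- r$pass; stat[i, 4] <- r$corrected_vaf
    }
    r <- filter_strand_bias(v, cfg)
    pass[i, 5] <- r$pass; stat[i, 5] <- r$statistic
  }
  surviving <- rep(TRUE, n)
  audit_total <- integer(length(filters) + 1L)
  audit_path <- integer(length(filters) + 1L)
  audit_total[1] <- n
  audit_path[1] <- sum(is_path)
  for (k in seq_along(filters)) {
    surviving <- surviving & pass[, k]
    audit_total[k + 1L] <- sum(surviving)
    audit_path[k + 1L] <- sum(surviving & is_path)
  }
  first_fail <- apply(pass, 1L, function(z) {
    w <- which(!z)
    if (length(w)) paste(filters[w], collapse = ";") else "PASS"
  })
  cand$filter <- first_fail
  for (k in seq_along(filters)) {
    cand[[paste0("pass_", filters[k])]] <- pass[, k]
    cand[[paste0("stat_", filters[k])]] <- stat[, k]
  }
  audit <- data.table::data.table(stage = c("total", filters),
                                  total = audit_total,
                                  pathogenic = audit_path)
  list(candidates = cand, audit = audit)
}

pathogenic_mask <- function(cand, pathogenic) {
  if (is.null(pathogenic)) return(rep(FALSE, nrow(cand)))
  if (is.logical(pathogenic)) return(pathogenic)
  keys <- paste(cand$pos, cand$ref, cand$alt, sep = ":")
  keys %in% pathogenic
}
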