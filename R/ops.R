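# Internal representation of alignment operations.
#
# An ops string is a CIGAR-like run-length encoding over the alphabet
#   M  aligned, read base equals reference base
#   X  aligned, read base differs from reference base
#   I  insertion to the reference (consumes read only)
#   D  deletion from the reference (consumes reference only)
#   S  soft clip (consumes read only; never internal)
# M/X are kept distinct internally; SAM emission folds X into M and carries
# the edit distance in NM.

OPS_READ_CONSUMING <- c("M", "X", "I", "S")
OPS_REF_CONSUMING <- c("M", "X", "D")

parse_ops <- function(ops) {
  if (is.null(ops) || !nzchar(ops)) {
    return(data.frame(op = character(), len = integer()))
  }
  lens <- regmatches(ops, gregexpr("[0-9]+", ops))[[1]]
  ops_ <- regmatches(ops, gregexpr("[MXIDS]", ops))[[1]]
  if (length(lens) != length(ops_)) {
    stop("malformed ops string: ", ops)
  }
  data.frame(op = ops_, len = as.integer(lens))
}

ops_string <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]
  len <- len[keep]
  if (!length(op)) return("")
  # merge adjacent runs of identical type
  new_run <- c(TRUE, op[-1] != op[-length(op)])
  grp <- cumsum(new_run)
  len <- rowsum(len, grp)[, 1]
  op <- op[new_run]
  paste0(len, op, collapse = "")
}

ops_read_len <- function(tab) sum(tab$len[tab$op %in% OPS_READ_CONSUMING])

ops_ref_span <- function(tab) sum(tab$len[tab$op %in% OPS_REF_CONSUMING])

ops_nm <- function(tab) sum(tab$len[tab$op %in% c("X", "I", "D")])

# edit distance straight from an ops string (no data.frame allocation)
ops_nm_str <- function(ops) {
  toks <- regmatches(ops, gregexpr("[0-9]+[XID]", ops))[[1]]
  if (!length(toks)) return(0L)
  sum(as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' @noRd
ops_validate <- function(ops, read_len) {
  tab <- parse_ops(ops)
  if (ops_read_len(tab) != read_len) {
    stop("ops consume ", ops_read_len(tab), " read bases, read has ", read_len)
  }
  invisible(tab)
}

# Expand an ops table into per-base records used by the pileup builder.
# Returns list(aligned = data.frame(ref_pos, read_pos, op),
#              ins = data.frame(ref_pos_left, read_pos, len),
#              del = data.frame(ref_pos, len)) with 0-based coordinates;
# ref_pos of an insertion is the reference column LEFT of the inserted bases.
ops_walk <- function(tab, ref_start) {
  n <- nrow(tab)
  ref <- ref_start
  readp <- 0L
  al_ref <- integer(0); al_read <- integer(0); al_op <- character(0)
  ins_ref <- integer(0); ins_read <- integer(0); ins_len <- integer(0)
  del_ref <- integer(0); del_len <- integer(0)
  for (k in seq_len(n)) {
    op <- tab$op[k]; len <- tab$len[k]
    if (op == "M" || op == "X") {
      al_ref <- c(al_ref, ref + 0:(len - 1L))
      al_read <- c(al_read, readp + 0:(len - 1L))
      al_op <- c(al_op, rep(op, len))
      ref <- ref + len; readp <- readp + len
    } else if (op == "I") {
      ins_ref <- c(ins_ref, ref - 1L)
      ins_read <- c(ins_read, readp)
      ins_len <- c(ins_len, len)
      readp <- readp + len
    } else if (op == "D") {
      del_ref <- c(del_ref, ref)
      del_len <- c(del_len, len)
      ref <- ref + len
    } else if (op == "S") {
      readp <- readp + len
    }
  }
  list(
    aligned = data.frame(ref_pos = al_ref, read_pos = al_read, op = al_op),
    ins = data.frame(ref_pos_left = ins_ref, read_pos = ins_read, len = ins_len),
    del = data.frame(ref_pos = del_ref, len = del_len)
  )
}

# reference sequence implied by an alignment (for consistency checks)
ops_implied_read <- function(ops, window, window_offset, read) {
  tab <- parse_ops(ops)
  ref <- window_offset
  readp <- 0L
  out <- character(0)
  for (k in seq_len(nrow(tab))) {
    op <- tab$op[k]; len <- tab$len[k]
    if (op %in% c("M", "X", "I", "S")) {
      out <- c(out, substr(read, readp + 1L, readp + len))
      readp <- readp + len
    }
    if (op %in% c("M", "X", "D")) ref <- ref + len
  }
  paste0(out, collapse = "")
}

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
         function(ch) paste(rev(ch), collapse = ""), "")
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(round(q), 0L), 60L) + 33L, multiple = FALSE)
}

char_to_phred <- function(s) utf8ToInt(s) - 33L
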