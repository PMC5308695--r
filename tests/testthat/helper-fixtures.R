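# Shared fixtures, built in code at load time (no binary files).

# small cached panels so individual tests don't pay generation cost
.fix <- new.env()

fix_panel <- function(n_amplicons = 2L, n_multiplex = 1L, seed = 3L,
                      hp_len = 0L, chunks = 5L) {
  key <- paste(n_amplicons, n_multiplex, seed, hp_len, chunks, sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- synthetic_panel(n_amplicons, n_multiplex, seed = seed,
                                   hp_len = hp_len,
                                   chunks_per_amplicon = chunks)
  }
  .fix[[key]]
}

# hand-built alignment rows compatible with build_pileup()
fake_aln <- function(ref_start, ops, seq, qual = NULL, strand = "+",
                     id = NULL) {
  n <- length(ops)
  if (is.null(qual)) qual <- vapply(nchar(seq), function(L)
    paste(rep("I", L), collapse = ""), "")
  data.table::data.table(
    read_id = if (is.null(id)) sprintf("r%03d", seq_len(n)) else id,
    mapped = TRUE, reason = "", multi = FALSE,
    ref_start = as.integer(ref_start), strand = strand, ops = ops,
    seq = seq, qual = qual, sw_score = NA_real_, re_score = NA_real_,
    nm = vapply(ops, ampliscan:::ops_nm_str, 0L))
}

# error-free reads cut straight from the reference (for aligner tests)
exact_reads <- function(panel, n, read_len = 80L, seed = 1L) {
  set.seed(seed)
  a <- panel$amplicons
  refseq <- panel$reference$sequence
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(nrow(a), 1L)
    lo <- a$start[k]
    hi <- a$end[k] - read_len
    s <- sample(seq.int(lo, max(lo, hi)), 1L)
    strand <- sample(c("+", "-"), 1L)
    tmpl <- substr(refseq, s + 1L, s + read_len)
    data.table::data.table(
      id = sprintf("x%05d", i),
      seq = if (strand == "+") tmpl else ampliscan:::revcomp(tmpl),
      qual = paste(rep("I", read_len), collapse = ""),
      amplicon_id = a$id[k], molecule_id = i, strand = strand,
      true_start = s, mol_offset = 0L, template_len = read_len)
  })
  data.table::rbindlist(rows)
}
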