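# Synthetic panel construction.
#
# The generator builds amplicons as runs of site-free sequence chunks joined
# by cyclically alternating MseI/Csp6I/FspBI sites. With chunk lengths of
# 50-62 bp this guarantees that a combined digest yields fragments inside
# the 50-300 bp size-selection window and a single-enzyme digest yields
# fragments of at most ~200 bp, so a 100 bp read taken from either fragment
# end covers every position (no structural coverage holes).

random_chunk <- function(len, sites) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (!any(vapply(sites, function(p) grepl(p, s, fixed = TRUE), TRUE))) {
      return(s)
    }
  }
}

#' Build a synthetic amplicon panel
#'
#' Generates a random reference with controlled restriction-site spacing and
#' tiles it with `n_amplicons` amplicons (20 bp primers at both ends)
#' assigned round-robin to `n_multiplex` multiplex groups. Each amplicon
#' covers one synthetic exon (its insert inset by 5 bp), giving amplicon
#' lengths of roughly 280-460 bp, inside the 186-812 bp range a multiplex
#' PCR panel of this kind produces. Optionally a run of `hp_len` identical
#' bases is embedded in the first amplicon's insert so that homopolymer
#' behaviour is exercised.
#'
#' @param n_amplicons number of amplicons.
#' @param n_multiplex number of multiplex groups.
#' @param seed integer seed.
#' @param chunks_per_amplicon chunks (of 50-62 bp) per amplicon insert.
#' @param hp_len length of the embedded homopolymer run (0 to disable).
#' @param gene gene label.
#' @return list with `panel` (an [amplicon_panel()]) and `exons`
#'   (an [exon_model()]); the embedded homopolymer run's 0-based interval is
#'   attached as attribute `hp_interval` when present.
#' @export
synthetic_panel <- function(n_amplicons = 9L, n_multiplex = 1L, seed = 1L,
                            chunks_per_amplicon = 5L, hp_len = 8L,
                            gene = "GENE1") {
  set.seed(seed)
  enz <- restriction_enzymes()
  sites <- vapply(enz, `[[`, "", "recognition")
  amp_seqs <- character(n_amplicons)
  hp_interval <- NULL
  cyc <- 0L
  for (i in seq_len(n_amplicons)) {
    parts <- character(0)
    for (k in seq_len(chunks_per_amplicon)) {
      chunk <- random_chunk(sample(50:62, 1L), sites)
      if (i == 1L && k == 2L && hp_len > 0L) {
        # embed one long homopolymer mid-chunk (retry on site clash)
        at <- 20L
        repeat {
          flank <- c(substr(chunk, at, at), substr(chunk, at + 1L, at + 1L))
          base <- sample(setdiff(c("A", "C", "G", "T"), flank), 1L)
          run <- strrep(base, hp_len)
          cand <- paste0(substr(chunk, 1, at), run,
                         substr(chunk, at + 1L, nchar(chunk)))
          if (!any(vapply(sites, function(p) grepl(p, cand, fixed = TRUE), TRUE))) {
            chunk <- cand
            hp_offset_in_amp <- 20L + sum(nchar(parts)) + at
            hp_interval <- c(hp_offset_in_amp, hp_offset_in_amp + hp_len)
            break
          }
          chunk <- random_chunk(sample(50:62, 1L), sites)
        }
      }
      parts <- c(parts, chunk)
      if (k < chunks_per_amplicon) {
        cyc <- cyc + 1L
        parts <- c(parts, sites[(cyc - 1L) %% length(sites) + 1L])
      }
    }
    primer_f <- random_chunk(20L, sites)
    primer_r <- random_chunk(20L, sites)
    amp_seqs[i] <- paste0(primer_f, paste(parts, collapse = ""), primer_r)
  }
  spacers <- vapply(seq_len(n_amplicons + 1L),
                    function(i) random_chunk(12L, sites), "")
  refseq <- paste0(spacers[1],
                   paste0(amp_seqs, spacers[-1], collapse = ""))
  ref <- reference("panelref", refseq)
  starts <- 12L + c(0L, cumsum(nchar(amp_seqs) + 12L))[seq_len(n_amplicons)]
  amp <- data.frame(
    id = sprintf("amp%02d", seq_len(n_amplicons)),
    gene = gene,
    multiplex = sprintf("mux%d", (seq_len(n_amplicons) - 1L) %% n_multiplex + 1L),
    start = starts,
    end = starts + nchar(amp_seqs),
    fwd_primer_end = starts + 20L,
    rev_primer_start = starts + nchar(amp_seqs) - 20L,
    exons_covered = sprintf("ex%d", seq_len(n_amplicons))
  )
  panel <- amplicon_panel(ref, amp)
  exons <- exon_model(gene, data.frame(
    label = sprintf("ex%d", seq_len(n_amplicons)),
    start = amp$fwd_primer_end + 5L,
    end = amp$rev_primer_start - 5L
  ))
  if (!is.null(hp_interval)) {
    hp_interval <- hp_interval + starts[1]
  }
  structure(list(panel = panel, exons = exons), hp_interval = hp_interval)
}

#' Positions of homopolymer runs on the panel reference
#'
#' @param panel an [amplicon_panel()].
#' @param min_len minimum run length.
#' @return data.frame with 0-based `start`, `end`, `base`, `len`.
#' @export
homopolymer_runs <- function(panel, min_len = 3L) {
  r <- rle(strsplit(panel$reference$sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             base = r$values[keep], len = r$lengths[keep])
}
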