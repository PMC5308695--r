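#' Restriction enzyme with a 4-base recognition site
#'
#' The library-construction model fragments amplicons with 4-cutter enzymes
#' that leave 5' TA overhangs; fragmentation is modelled on the top strand
#' only (a cut at `cut_offset` within every occurrence of the recognition
#' site).
#'
#' @param name enzyme name.
#' @param recognition 4-mer recognition sequence (top strand).
#' @param cut_offset top-strand cut position within the site, in 0..4.
#' @return an `enzyme` object.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) != 4L || grepl("[^ACGT]", recognition)) {
    stop("recognition site must be a 4-mer over ACGT")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > 4L) stop("cut_offset must be in 0..4")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' Built-in fragmentation enzymes
#'
#' MseI (T^TAA), Csp6I (G^TAC) and FspBI (C^TAG); all three cut after the
#' first base of their site and so leave a TA 5' overhang, which is why the
#' downstream fragment of every internal junction starts with "TA".
#'
#' @return named list of [enzyme()] objects.
#' @export
restriction_enzymes <- function() {
  list(
    MseI = enzyme("MseI", "TTAA", 1L),
    Csp6I = enzyme("Csp6I", "GTAC", 1L),
    FspBI = enzyme("FspBI", "CTAG", 1L)
  )
}

#' Digest a sequence with restriction enzymes (top-strand model)
#'
#' Cuts at every occurrence of any recognition site, at that enzyme's
#' `cut_offset`. Fragments are returned 5' to 3' with their 0-based start
#' offsets; their concatenation equals the input (the digestion is total and
#' lossless). A sequence with no site yields a single fragment.
#'
#' @param sequence DNA string over ACGT.
#' @param enzymes list of [enzyme()] objects.
#' @return data.frame with columns `fragment` and `start_offset`.
#' @export
digest <- function(sequence, enzymes) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("sequence contains characters outside ACGT")
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  cuts <- integer(0)
  for (e in enzymes) {
    m <- gregexpr(e$recognition, sequence, fixed = TRUE)[[1]]
    if (m[1] != -1L) cuts <- c(cuts, as.integer(m) - 1L + e$cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < nchar(sequence)]
  bounds <- c(0L, cuts, nchar(sequence))
  data.frame(
    fragment = substring(sequence, bounds[-length(bounds)] + 1L, bounds[-1]),
    start_offset = bounds[-length(bounds)]
  )
}
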