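#' Reference sequence for an amplicon panel
#'
#' A single named DNA sequence over the strict alphabet ACGT. The panel model
#' is single-reference: a diagnostic panel targets one (concatenated) region
#' per gene set, which keeps the BWT index small.
#'
#' @param name reference (chromosome/contig) name.
#' @param sequence DNA string; coerced to upper case; must be non-empty and
#'   contain only A, C, G, T.
#' @return an object of class `ampliscan_reference` with fields `name`,
#'   `sequence` and `length`.
#' @export
reference <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("reference sequence is empty")
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence contains characters outside ACGT")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence)),
    class = "ampliscan_reference"
  )
}

#' @export
print.ampliscan_reference <- function(x, ...) {
  cat("<reference>", x$name, ":", x$length, "bp\n")
  invisible(x)
}

ref_slice <- function(ref, start, end) {
  # 0-based half-open
  substr(ref$sequence, start + 1L, end)
}

#' Construct an amplicon panel
#'
#' The coordinate backbone of the toolkit: a set of amplicons (PCR products)
#' on one reference, each assigned to exactly one multiplex group, with the
#' primer-derived prefix/suffix delimited so that primer bases can be
#' soft-clipped during mapping and excluded from variant calling. All
#' coordinates are 0-based half-open.
#'
#' @param ref an [reference()] object.
#' @param amplicons data.frame with columns `id`, `gene`, `multiplex`,
#'   `start`, `end`, `fwd_primer_end`, `rev_primer_start` and optionally
#'   `exons_covered` (comma-separated labels).
#' @return an `amplicon_panel` object: list with `reference`, `amplicons`
#'   (data.table) and `multiplexes` (named list of amplicon ids).
#' @export
amplicon_panel <- function(ref, amplicons) {
  stopifnot(inherits(ref, "ampliscan_reference"))
  amplicons <- data.table::as.data.table(amplicons)
  need <- c("id", "gene", "multiplex", "start", "end",
            "fwd_primer_end", "rev_primer_start")
  miss <- setdiff(need, names(amplicons))
  if (length(miss)) stop("panel table lacks columns: ", paste(miss, collapse = ", "))
  if (!"exons_covered" %in% names(amplicons)) amplicons$exons_covered <- ""
  for (col in c("start", "end", "fwd_primer_end", "rev_primer_start")) {
    data.table::set(amplicons, j = col, value = as.integer(amplicons[[col]]))
  }
  if (anyDuplicated(amplicons$id)) {
    stop("duplicated amplicon id: ",
         amplicons$id[duplicated(amplicons$id)][1])
  }
  for (i in seq_len(nrow(amplicons))) {
    a <- amplicons[i]
    if (!(a$start < a$fwd_primer_end && a$fwd_primer_end <= a$rev_primer_start &&
          a$rev_primer_start < a$end)) {
      stop("amplicon ", a$id,
           ": require start < fwd_primer_end <= rev_primer_start < end")
    }
    if (a$start < 0L || a$end > ref$length) {
      stop("amplicon ", a$id, " interval [", a$start, ",", a$end,
           ") outside reference of length ", ref$length)
    }
  }
  mux <- split(amplicons$id, amplicons$multiplex)
  structure(
    list(reference = ref, amplicons = amplicons, multiplexes = mux),
    class = "amplicon_panel"
  )
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("<amplicon_panel>", nrow(x$amplicons), "amplicons in",
      length(x$multiplexes), "multiplexes on", x$reference$name,
      paste0("(", x$reference$length, " bp)\n"))
  invisible(x)
}

#' Load an amplicon panel from BED6+3 and FASTA
#'
#' The panel file is BED-like, tab-separated, with columns
#' `chrom start end id gene multiplex fwd_primer_end rev_primer_start`
#' and an optional ninth `exons_covered` column (comma-separated labels);
#' lines starting with `#` or a `track` line are ignored. Coordinates are
#' BED-style 0-based half-open, which is also the package's internal
#' convention.
#'
#' @param panel_path path to the panel table.
#' @param fasta_path path to a FASTA file holding the reference record named
#'   in the `chrom` column (single reference per panel).
#' @return a validated [amplicon_panel()].
#' @export
load_panel <- function(panel_path, fasta_path) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  lines <- readLines(panel_path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (!length(lines)) stop("panel file ", panel_path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("panel row ", which(nf < 8L)[1], " has fewer than 8 columns")
  }
  tab <- data.table::data.table(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    id = vapply(fields, `[`, "", 4L),
    gene = vapply(fields, `[`, "", 5L),
    multiplex = vapply(fields, `[`, "", 6L),
    fwd_primer_end = as.integer(vapply(fields, `[`, "", 7L)),
    rev_primer_start = as.integer(vapply(fields, `[`, "", 8L)),
    exons_covered = vapply(fields, function(f) if (length(f) >= 9L) f[9L] else "", "")
  )
  chroms <- unique(tab$chrom)
  if (length(chroms) != 1L) {
    stop("panel references multiple chroms (", paste(chroms, collapse = ", "),
         "); the panel model is single-reference")
  }
  hit <- match(chroms, sub("\\s.*$", "", names(fa)))
  if (is.na(hit)) {
    stop("reference record '", chroms, "' not found in ", fasta_path)
  }
  ref <- reference(chroms, as.character(fa[[hit]]))
  tab$chrom <- NULL
  amplicon_panel(ref, tab)
}

#' Write an amplicon panel as BED6+3
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, ...), ...)` restores
#' the panel table up to column order.
#'
#' @param panel an [amplicon_panel()].
#' @param panel_path output path for the BED6+3 table.
#' @param fasta_path optional output path for the reference FASTA.
#' @return `panel_path`, invisibly.
#' @export
write_panel <- function(panel, panel_path, fasta_path = NULL) {
  a <- panel$amplicons
  lines <- paste(panel$reference$name, a$start, a$end, a$id, a$gene,
                 a$multiplex, a$fwd_primer_end, a$rev_primer_start,
                 a$exons_covered, sep = "\t")
  writeLines(lines, panel_path)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(panel$reference$sequence)
    names(seqs) <- panel$reference$name
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(panel_path)
}

#' Exon model for coding-coordinate (HGVS c.) naming
#'
#' Ordered, non-overlapping exon intervals on the panel reference, with the
#' transcript coding coordinate of the first base of each exon derived from
#' cumulative exon widths. All exon bases are treated as coding (a synthetic
#' transcript model; UTR handling is out of scope).
#'
#' @param gene gene symbol.
#' @param exons data.frame with columns `label`, `start`, `end`
#'   (0-based half-open reference intervals, ordered).
#' @return an `exon_model` object.
#' @export
exon_model <- function(gene, exons) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("label", "start", "end") %in% names(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (is.unsorted(exons$start, strictly = TRUE)) {
    stop("exons must be ordered by start")
  }
  if (any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap")
  }
  w <- exons$end - exons$start
  exons$coding_offset <- cumsum(c(0L, w[-length(w)])) + 1L
  structure(list(gene = gene, exons = exons), class = "exon_model")
}

#' Map exons to the amplicons that cover them
#'
#' @param panel an [amplicon_panel()].
#' @param model an [exon_model()].
#' @return data.frame with one row per exon: `label`, `covered` (logical,
#'   TRUE when the union of amplicon inserts contains the whole exon) and
#'   `amplicon_ids` (comma-separated ids of overlapping amplicons). Uncovered
#'   exons are reported, not fatal.
#' @export
exon_intervals <- function(panel, model) {
  a <- panel$amplicons
  out <- lapply(seq_len(nrow(model$exons)), function(i) {
    e <- model$exons[i, ]
    ov <- a$id[a$start < e$end & a$end > e$start]
    # covered means the union of overlapping inserts contains the exon
    covered <- FALSE
    if (length(ov)) {
      sel <- a[a$id %in% ov]
      pos <- sort(unique(unlist(mapply(
        function(s, en) seq.int(s, en - 1L), sel$start, sel$end,
        SIMPLIFY = FALSE))))
      covered <- all(seq.int(e$start, e$end - 1L) %in% pos)
    }
    data.frame(label = e$label, covered = covered,
               amplicon_ids = paste(ov, collapse = ","))
  })
  do.call(rbind, out)
}

#' Check coverage-completeness of a panel against an exon model
#'
#' @inheritParams exon_intervals
#' @return TRUE invisibly; warns listing any uncovered exon.
#' @export
validate_panel_coverage <- function(panel, model) {
  tab <- exon_intervals(panel, model)
  bad <- tab$label[!tab$covered]
  if (length(bad)) {
    warning("exons not fully covered by the panel: ",
            paste(bad, collapse = ", "))
  }
  invisible(length(bad) == 0L)
}

# amplicon containing a 0-based position within its insert (primers excluded
# when insert_only), first match by table order
amplicon_at <- function(panel, pos, insert_only = FALSE) {
  a <- panel$amplicons
  if (insert_only) {
    hit <- which(a$fwd_primer_end <= pos & pos < a$rev_primer_start)
  } else {
    hit <- which(a$start <= pos & pos < a$end)
  }
  if (!length(hit)) return(NA_character_)
  a$id[hit[1]]
}
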