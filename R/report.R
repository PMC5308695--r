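#' Diagnostic performance metrics
#'
#' sensitivity = TP/(TP+FN); false-positive rate = FP/(FP+TP) (the
#' specificity surrogate used when true negatives are unavailable);
#' specificity = TN/(TN+FP); accuracy = (TP+TN)/(TP+TN+FP+FN). Reported as
#' percentages rounded half-up to one decimal; a metric whose denominator
#' is zero is returned as NA with a reason.
#'
#' @param tp,fp,fn,tn non-negative counts (`tn` may be NA when unknown).
#' @return list with `sensitivity`, `fp_rate`, `specificity`, `accuracy`
#'   (percentages) and `undefined` (named reasons for NA metrics).
#' @export
metrics <- function(tp, fp = 0L, fn = 0L, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  pct <- function(x) floor(x * 1000 + 0.5) / 10
  undefined <- character(0)
  sens <- if (tp + fn > 0) pct(tp / (tp + fn)) else {
    undefined["sensitivity"] <- "TP+FN is zero"; NA_real_
  }
  fpr <- if (fp + tp > 0) pct(fp / (fp + tp)) else {
    undefined["fp_rate"] <- "FP+TP is zero"; NA_real_
  }
  spec <- if (!is.na(tn) && tn + fp > 0) pct(tn / (tn + fp)) else {
    undefined["specificity"] <- "TN unavailable or TN+FP zero"; NA_real_
  }
  total <- tp + fp + fn + ifelse(is.na(tn), 0L, tn)
  acc <- if (!is.na(tn) && total > 0) pct((tp + tn) / total) else {
    undefined["accuracy"] <- "TN unavailable or no observations"; NA_real_
  }
  list(sensitivity = sens, fp_rate = fpr, specificity = spec,
       accuracy = acc, undefined = undefined)
}

#' Left-normalise a variant against the reference
#'
#' Trims shared allele prefix/suffix and shifts indels as far left as the
#' reference repeat structure allows (the VCF normal form), so equivalent
#' indel placements compare equal.
#'
#' @param pos 0-based position of the first `ref` base.
#' @param ref,alt allele strings.
#' @param refseq reference sequence string.
#' @return list with normalised `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, refseq) {
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 1 && na >= 1 &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr > 1 && na > 1) {
        ref <- substr(ref, 1, nr - 1); alt <- substr(alt, 1, na - 1)
        changed <- TRUE
      } else if (pos > 0) {
        prev <- substr(refseq, pos, pos)
        ref <- paste0(prev, substr(ref, 1, nr - 1))
        alt <- paste0(prev, substr(alt, 1, na - 1))
        pos <- pos - 1L
        changed <- TRUE
      }
    }
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 2 && na >= 2 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nr); alt <- substr(alt, 2, na)
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

# 3'-most equivalent placement (HGVS convention); expects a normalised
# indel in anchor form (ref or alt of length 1 sharing the first base)
shift3p_indel <- function(pos, ref, alt, refseq) {
  is_del <- nchar(ref) > nchar(alt)
  seg <- if (is_del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  L <- nchar(seg)
  if (L == 0) return(list(pos = pos, ref = ref, alt = alt))
  end_ref <- pos + nchar(ref) # 0-based position just after the ref block
  while (end_ref < nchar(refseq) &&
         substr(refseq, end_ref + 1L, end_ref + 1L) == substr(seg, 1, 1)) {
    seg <- paste0(substr(seg, 2, L), substr(refseq, end_ref + 1L, end_ref + 1L))
    pos <- pos + 1L
    end_ref <- end_ref + 1L
  }
  anchor <- substr(refseq, pos + 1L, pos + 1L)
  if (is_del) list(pos = pos, ref = paste0(anchor, seg), alt = anchor)
  else list(pos = pos, ref = anchor, alt = paste0(anchor, seg))
}

#' Compare called variants with a truth set
#'
#' Variants match on (position, ref, alt) after left-normalisation. True
#' negatives are panel insert positions carrying neither a call nor a truth
#' variant, counted once per position.
#'
#' @param called data.table of candidates (columns `pos`, `ref`, `alt`);
#'   usually the PASS subset of a cascade result.
#' @param truth data.frame of spiked variants (`pos`, `ref`, `alt`).
#' @param panel an [amplicon_panel()].
#' @return list of counts `tp`, `fp`, `fn`, `tn`.
#' @export
compare_to_truth <- function(called, truth, panel) {
  refseq <- panel$reference$sequence
  key <- function(df) {
    if (!nrow(df)) return(character(0))
    pp <- if ("vcf_pos" %in% names(df)) df$vcf_pos else df$pos
    unique(vapply(seq_len(nrow(df)), function(i) {
      z <- normalize_variant(pp[i], df$ref[i], df$alt[i], refseq)
      paste(z$pos, z$ref, z$alt, sep = ":")
    }, ""))
  }
  ck <- key(as.data.frame(called))
  tk <- key(as.data.frame(truth))
  tp <- sum(ck %in% tk)
  fp <- sum(!ck %in% tk)
  fn <- sum(!tk %in% ck)
  a <- panel$amplicons
  insert_pos <- unique(unlist(mapply(
    function(s, e) seq.int(s, e - 1L), a$fwd_primer_end, a$rev_primer_start,
    SIMPLIFY = FALSE)))
  used <- unique(c(
    if (nrow(called)) called$pos,
    if (nrow(truth)) truth$pos))
  tn <- sum(!insert_pos %in% used)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# genomic 0-based position -> coding coordinate string ("181", "476-9",
# "213+11"), or NA outside the model's reach
coding_coord <- function(p0, model) {
  ex <- model$exons
  for (i in seq_len(nrow(ex))) {
    if (p0 >= ex$start[i] && p0 < ex$end[i]) {
      return(as.character(ex$coding_offset[i] + (p0 - ex$start[i])))
    }
  }
  # intronic: nearest exon boundary
  for (i in seq_len(nrow(ex))) {
    nxt_start <- ex$start[i]
    if (p0 < nxt_start) {
      d_next <- nxt_start - p0
      if (i == 1L) return(paste0(ex$coding_offset[1], "-", d_next))
      prev_end <- ex$end[i - 1L]
      d_prev <- p0 - (prev_end - 1L)
      last_c <- ex$coding_offset[i - 1L] + (prev_end - ex$start[i - 1L]) - 1L
      if (d_prev <= d_next) return(paste0(last_c, "+", d_prev))
      return(paste0(ex$coding_offset[i], "-", d_next))
    }
  }
  n <- nrow(ex)
  last_c <- ex$coding_offset[n] + (ex$end[n] - ex$start[n]) - 1L
  paste0(last_c, "+", p0 - (ex$end[n] - 1L))
}

#' HGVS-style coding name of a variant
#'
#' The variant is left-normalised and then 3'-shifted within its repeat
#' context per the HGVS convention before naming, so the name is invariant
#' to the aligner's indel placement. Supports substitution (c.181T>G),
#' deletion (c.843_846delCTCA), duplication (c.5266dupC) and insertion
#' (c.476-9_476-8insT) forms on the panel's transcript model.
#'
#' @param v one-row candidate (`pos`, `ref`, `alt`).
#' @param model an [exon_model()].
#' @param panel an [amplicon_panel()].
#' @return character name; falls back to a genomic `g.` name when the
#'   variant lies outside the exon model's reach.
#' @export
hgvs_name <- function(v, model, panel) {
  refseq <- panel$reference$sequence
  p0 <- if (!is.null(v$vcf_pos)) v$vcf_pos else v$pos
  z <- normalize_variant(p0, v$ref, v$alt, refseq)
  nr <- nchar(z$ref); na <- nchar(z$alt)
  if (nr == 1 && na == 1) {
    cc <- coding_coord(z$pos, model)
    return(paste0("c.", cc, z$ref, ">", z$alt))
  }
  z <- shift3p_indel(z$pos, z$ref, z$alt, refseq)
  nr <- nchar(z$ref); na <- nchar(z$alt)
  if (nr > na) { # deletion of seg after anchor
    seg <- substr(z$ref, 2, nr)
    p1 <- z$pos + 1L # first deleted base, 0-based
    c1 <- coding_coord(p1, model)
    if (nchar(seg) == 1L) return(paste0("c.", c1, "del", seg))
    c2 <- coding_coord(p1 + nchar(seg) - 1L, model)
    return(paste0("c.", c1, "_", c2, "del", seg))
  }
  seg <- substr(z$alt, 2, na)
  L <- nchar(seg)
  # duplication when the inserted segment equals the reference immediately
  # 5' of the insertion point (inclusive of the anchor base)
  dup_start <- z$pos - L + 1L
  if (dup_start >= 0 &&
      substr(refseq, dup_start + 1L, z$pos + 1L) == seg) {
    c1 <- coding_coord(dup_start, model)
    if (L == 1L) return(paste0("c.", c1, "dup", seg))
    c2 <- coding_coord(z$pos, model)
    return(paste0("c.", c1, "_", c2, "dup", seg))
  }
  c1 <- coding_coord(z$pos, model)
  c2 <- coding_coord(z$pos + 1L, model)
  paste0("c.", c1, "_", c2, "ins", seg)
}

#' Molecular classification of a variant
#'
#' Coding SNVs are translated with the standard genetic code and classified
#' synonymous / missense / nonsense; coding indels are frameshift when the
#' length change is not a multiple of three, inframe otherwise. Variants
#' within 2 bases of an exon boundary are splice_region; other non-exonic
#' variants are intronic.
#'
#' @param v one-row candidate (`pos`, `ref`, `alt`).
#' @param model an [exon_model()].
#' @param panel an [amplicon_panel()].
#' @return one of synonymous, missense, nonsense, frameshift,
#'   inframe_indel, splice_region, intronic.
#' @export
classify_molecular <- function(v, model, panel) {
  refseq <- panel$reference$sequence
  p0 <- if (!is.null(v$vcf_pos)) v$vcf_pos else v$pos
  z <- normalize_variant(p0, v$ref, v$alt, refseq)
  ex <- model$exons
  in_exon <- any(z$pos >= ex$start & z$pos < ex$end)
  near_boundary <- any(abs(z$pos - ex$start) <= 2L | abs(z$pos - (ex$end - 1L)) <= 2L)
  if (!in_exon) {
    return(if (near_boundary) "splice_region" else "intronic")
  }
  nr <- nchar(z$ref); na <- nchar(z$alt)
  if (nr != na) {
    return(if ((abs(nr - na)) %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  # SNV (or MNV treated base-wise on its first base)
  cds <- paste0(substring(refseq, ex$start + 1L, ex$end), collapse = "")
  c1 <- suppressWarnings(as.integer(coding_coord(z$pos, model)))
  if (is.na(c1)) return("intronic")
  frame <- (c1 - 1L) %/% 3L
  codon <- substr(cds, frame * 3L + 1L, frame * 3L + 3L)
  if (nchar(codon) < 3L) return("missense")
  within <- (c1 - 1L) %% 3L
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- substr(z$alt, 1, 1)
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[codon]]
  aa_alt <- code[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Write candidates as VCF 4.2
#'
#' Deterministic writer: the body is byte-identical across reruns with the
#' same input. The FILTER column carries the cascade flags; INFO carries
#' VAF, DP, SBdiff, DPp and HPpct.
#'
#' @param candidates data.table from [run_cascade()] (or
#'   [call_candidates()]).
#' @param panel an [amplicon_panel()].
#' @param path output path.
#' @param sample_name sample label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(candidates, panel, path, sample_name = "sample") {
  refname <- panel$reference$name
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=ampliscan"),
    paste0("##contig=<ID=", refname, ",length=", panel$reference$length, ">"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth at site\">",
    "##INFO=<ID=SBdiff,Number=1,Type=Float,Description=\"Absolute strand VAF difference\">",
    "##INFO=<ID=DPp,Number=1,Type=Float,Description=\"Depth test p-value\">",
    "##INFO=<ID=HPpct,Number=1,Type=Float,Description=\"HP-corrected indel frequency\">",
    "##FILTER=<ID=depth_test,Description=\"Start-position distribution differs between wt and mutant reads\">",
    "##FILTER=<ID=insertion_overrun,Description=\"Insertion frequency not above platform error\">",
    "##FILTER=<ID=deletion_displacement,Description=\"Deletion/insertion ratio shift absent\">",
    "##FILTER=<ID=hp_percentage,Description=\"HP-corrected frequency below limit\">",
    "##FILTER=<ID=strand_bias,Description=\"Strand support imbalanced\">",
    paste0("##sample=", sample_name),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(candidates)) {
    get_stat <- function(col, i) {
      if (col %in% names(candidates)) {
        x <- candidates[[col]][i]
        if (is.na(x)) "." else formatC(x, digits = 4, format = "g")
      } else "."
    }
    ord <- order(candidates$pos)
    for (i in ord) {
      v <- candidates[i, ]
      vcf_pos <- (if ("vcf_pos" %in% names(candidates)) v$vcf_pos else v$pos) + 1L
      filt <- if ("filter" %in% names(candidates)) v$filter else "PASS"
      info <- paste0(
        "VAF=", formatC(v$vaf, digits = 4, format = "g"),
        ";DP=", v$depth,
        ";SBdiff=", get_stat("stat_strand_bias", i),
        ";DPp=", get_stat("stat_depth_test", i),
        ";HPpct=", get_stat("stat_hp_percentage", i))
      body <- c(body, paste(refname, vcf_pos, ".", v$ref, v$alt, ".",
                            filt, info, sep = "\t"))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run the full analysis pipeline on one sample
#'
#' simulate (optional) -> map -> pileup -> call -> variant rearrangement ->
#' platform cascade -> evaluate against truth; per-amplicon counts are
#' produced for CNV use. All seeds are recorded in the returned metadata.
#'
#' @param panel an [amplicon_panel()].
#' @param spec a [sample_spec()] (simulated input) or NULL when `reads` is
#'   given.
#' @param reads optional existing read set.
#' @param mode a [calling_mode()].
#' @param platform `"illumina"` or `"iontorrent"`.
#' @param profile [error_profile()] used when simulating.
#' @param hp_db homopolymer database (required for iontorrent cascade).
#' @param exons optional [exon_model()] for annotation.
#' @param aligner_cfg an [aligner_config()].
#' @param filter_cfg a [filter_config()].
#' @param enzymes fragmentation enzymes.
#' @param read_length simulated read length.
#' @param out_dir optional directory for VCF/SAM/audit outputs.
#' @return list with `alignments`, `pileup`, `candidates`, `audit`,
#'   `counts`, `confusion` (+`metrics`) when truth known, `meta`.
#' @export
run_pipeline <- function(panel, spec = NULL, reads = NULL,
                         mode = calling_mode("germline"),
                         platform = c("illumina", "iontorrent"),
                         profile = illumina_profile(), hp_db = NULL,
                         exons = NULL, aligner_cfg = aligner_config(),
                         filter_cfg = filter_config(),
                         enzymes = restriction_enzymes(),
                         read_length = 100L, out_dir = NULL) {
  platform <- match.arg(platform)
  truth <- NULL
  if (is.null(reads)) {
    if (is.null(spec)) stop("either spec or reads must be given")
    mol <- simulate_amplicons(panel, spec)
    reads <- simulate_reads(mol, enzymes, profile, read_length,
                            seed = spec$seed + 1L)
    truth <- spec$variants
  }
  aln <- map_reads(reads, panel, aligner_cfg)
  aln_sorted <- aln[order(aln$ref_start)]
  pile <- build_pileup(aln_sorted, panel)
  cand <- call_candidates(pile, mode, filter_cfg)
  vr <- variant_rearrangement_tool(cand, aln_sorted, panel, mode,
                                   aligner_cfg, filter_cfg)
  cand <- vr$candidates
  casc <- run_cascade(cand, hp_db, filter_cfg, platform)
  counts <- counts_from_alignments(list(sample = aln), panel)
  res <- list(alignments = aln, pileup = pile,
              candidates = casc$candidates, audit = casc$audit,
              counts = counts,
              meta = list(seed = if (!is.null(spec)) spec$seed else NA,
                          mode = mode$name, platform = platform,
                          profile = profile$name,
                          read_length = read_length))
  if (!is.null(truth) && nrow(truth)) {
    passed <- casc$candidates[casc$candidates$filter == "PASS", ]
    cc <- compare_to_truth(passed, truth, panel)
    res$confusion <- cc
    res$metrics <- metrics(cc$tp, cc$fp, cc$fn, cc$tn)
  }
  if (!is.null(exons) && nrow(casc$candidates)) {
    res$candidates$hgvs <- vapply(seq_len(nrow(res$candidates)), function(i) {
      hgvs_name(res$candidates[i, ], exons, panel)
    }, "")
    res$candidates$molecular_class <- vapply(seq_len(nrow(res$candidates)),
                                             function(i) {
      classify_molecular(res$candidates[i, ], exons, panel)
    }, "")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(res$candidates, panel, file.path(out_dir, "variants.vcf"))
    write_sam(aln, panel, file.path(out_dir, "alignments.sam"))
    utils::write.table(res$audit, file.path(out_dir, "audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$meta, file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE, null = "null")
  }
  res
}
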