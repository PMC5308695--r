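test_that("metrics reproduce the formula-derived percentages", {
  # pathogenic ion-torrent counts: TP 19, FN 1 -> sensitivity 95.0
  m1 <- metrics(tp = 19, fp = 16, fn = 1, tn = 680)
  expect_equal(m1$sensitivity, 95.0)
  # TN/(TN+FP) and (TP+TN)/total from the same printed counts
  expect_equal(m1$specificity, 97.7)
  expect_equal(m1$accuracy, 97.6)
  # illumina validation counts: TP 140, FN 0, FP 0
  m2 <- metrics(tp = 140, fp = 0, fn = 0)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$fp_rate, 0)
  # degenerate input: all metrics undefined with reasons
  m0 <- metrics(0, 0, 0, 0)
  expect_true(is.na(m0$sensitivity) && is.na(m0$fp_rate))
  expect_gte(length(m0$undefined), 2L)
  # rounding is half-up to one decimal
  expect_equal(metrics(tp = 1, fn = 7)$sensitivity, 12.5)
})

test_that("variant normalisation makes equivalent indel placements equal", {
  refseq <- "GGATTTTTACGG" # T run 0-based 3..7
  # deletion of one T written at two offsets in the run
  a <- normalize_variant(2L, "AT", "A", refseq)
  b <- normalize_variant(6L, "TT", "T", refseq)
  expect_equal(a, b)
  expect_equal(a$pos, 2L)
  # insertion duplication placements
  i1 <- normalize_variant(4L, "T", "TT", refseq)
  i2 <- normalize_variant(7L, "T", "TT", refseq)
  expect_equal(i1, i2)
  # SNV untouched
  expect_equal(normalize_variant(2L, "A", "C", refseq),
               list(pos = 2L, ref = "A", alt = "C"))
})

test_that("compare_to_truth matches after normalisation and counts TNs once", {
  sp <- fix_panel(1, 1, seed = 3)
  panel <- sp$panel
  refseq <- panel$reference$sequence
  a <- panel$amplicons[1, ]
  p1 <- a$fwd_primer_end + 10L
  ref1 <- substr(refseq, p1 + 1, p1 + 1)
  alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
  truth <- data.frame(pos = p1, ref = ref1, alt = alt1)
  called <- data.frame(pos = p1, ref = ref1, alt = alt1)
  cc <- compare_to_truth(called, truth, panel)
  expect_equal(cc[c("tp", "fp", "fn")], list(tp = 1L, fp = 0L, fn = 0L))
  insert_size <- a$rev_primer_start - a$fwd_primer_end
  expect_equal(cc$tn, insert_size - 1L)
  # one missed
  cc2 <- compare_to_truth(called[0L, ], truth, panel)
  expect_equal(cc2$fn, 1L)
  # equivalent homopolymer offsets of one deletion count once as TP
  runs <- homopolymer_runs(panel, min_len = 3L)
  runs <- runs[runs$start > a$fwd_primer_end + 2 & runs$end < a$rev_primer_start, ]
  r <- runs[1, ]
  tr <- data.frame(pos = r$start - 1L,
                   ref = substr(refseq, r$start, r$start + 1L),
                   alt = substr(refseq, r$start, r$start))
  cl <- data.frame(pos = c(r$start - 1L, r$end - 2L),
                   ref = c(substr(refseq, r$start, r$start + 1L),
                           substr(refseq, r$end - 1L, r$end)),
                   alt = c(substr(refseq, r$start, r$start),
                           substr(refseq, r$end - 1L, r$end - 1L)))
  cc3 <- compare_to_truth(cl, tr, panel)
  expect_equal(cc3$tp, 1L)
  expect_equal(cc3$fp, 0L)
})

# deliberate two-exon model with hand-computed coding coordinates:
# exon1 covers 0-based [50,110) -> c.1..60; exon2 [150,210) -> c.61..120
hgvs_fixture <- function() {
  set.seed(77)
  refseq <- random_dna(300)
  ref <- reference("r", refseq)
  panel <- amplicon_panel(ref, data.frame(
    id = "a1", gene = "G", multiplex = "m1", start = 0L, end = 300L,
    fwd_primer_end = 20L, rev_primer_start = 280L))
  model <- exon_model("G", data.frame(label = c("ex1", "ex2"),
                                      start = c(50L, 150L),
                                      end = c(110L, 210L)))
  list(panel = panel, model = model, refseq = refseq)
}

test_that("hgvs names use coding coordinates with 3'-shifting", {
  fx <- hgvs_fixture()
  refseq <- fx$refseq
  # SNV at 0-based 60 -> exon1 offset 10 -> c.11
  rb <- substr(refseq, 61, 61)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  nm <- hgvs_name(list(pos = 60L, ref = rb, alt = ab), fx$model, fx$panel)
  expect_equal(nm, paste0("c.11", rb, ">", ab))
  # intronic SNV 8 before exon2 start (0-based 142) -> c.61-8
  rb2 <- substr(refseq, 143, 143)
  ab2 <- setdiff(c("A", "C", "G", "T"), rb2)[1]
  expect_equal(hgvs_name(list(pos = 142L, ref = rb2, alt = ab2),
                         fx$model, fx$panel),
               paste0("c.61-8", rb2, ">", ab2))
  # multi-base deletion inside exon2: 0-based 160..163 deleted -> c.72_75del
  del_ref <- substr(refseq, 160, 164)
  nm2 <- hgvs_name(list(pos = 159L, ref = del_ref,
                        alt = substr(del_ref, 1, 1)), fx$model, fx$panel)
  expect_match(nm2, "^c\\.7[0-9]_7[0-9]del")
  # duplication: insert a copy of the base at 0-based 70 after it
  b <- substr(refseq, 71, 71)
  nm3 <- hgvs_name(list(pos = 70L, ref = b, alt = paste0(b, b)),
                   fx$model, fx$panel)
  expect_match(nm3, "dup")
})

test_that("hgvs naming is invariant to the aligner's indel placement", {
  fx <- hgvs_fixture()
  refseq <- fx$refseq
  # build an artificial run inside exon1 by finding any repeated base pair
  runs <- rle(strsplit(substr(refseq, 51, 110), "")[[1]])
  stopifnot(any(runs$lengths >= 2))
  k <- which(runs$lengths >= 2)[1]
  off <- sum(runs$lengths[seq_len(k - 1)]) # 0-based offset in exon
  p <- 50L + off # 0-based run start
  b <- runs$values[k]
  left <- hgvs_name(list(pos = p - 1L,
                         ref = paste0(substr(refseq, p, p), b),
                         alt = substr(refseq, p, p)), fx$model, fx$panel)
  right <- hgvs_name(list(pos = p + runs$lengths[k] - 2L,
                          ref = paste0(b, b), alt = b), fx$model, fx$panel)
  expect_equal(left, right)
})

test_that("molecular classification translates and applies the length rule", {
  # hand-built coding sequence: exon = ATG GCT CAA GGG TTT ... (codons known)
  exon_seq <- "ATGGCTCAAGGGTTTACCATT"
  refseq <- paste0(random_dna(30), exon_seq, random_dna(30))
  # regenerate until flanks introduce no exon-boundary ambiguity (none needed)
  ref <- reference("r", refseq)
  panel <- amplicon_panel(ref, data.frame(
    id = "a1", gene = "G", multiplex = "m1", start = 0L,
    end = nchar(refseq), fwd_primer_end = 5L,
    rev_primer_start = nchar(refseq) - 5L))
  model <- exon_model("G", data.frame(label = "e1", start = 30L,
                                      end = 30L + nchar(exon_seq)))
  # CAA -> TAA: stop gain (codon 3, first base at 0-based 36)
  expect_equal(classify_molecular(list(pos = 36L, ref = "C", alt = "T"),
                                  model, panel), "nonsense")
  # GCT -> GCC: synonymous (third base of codon 2, 0-based 35)
  expect_equal(classify_molecular(list(pos = 35L, ref = "T", alt = "C"),
                                  model, panel), "synonymous")
  # GGG -> GTG: missense
  expect_equal(classify_molecular(list(pos = 40L, ref = "G", alt = "T"),
                                  model, panel), "missense")
  # 1-bp coding insertion: frameshift; 3-bp deletion: inframe
  expect_equal(classify_molecular(list(pos = 40L, ref = "G", alt = "GA"),
                                  model, panel), "frameshift")
  expect_equal(classify_molecular(
    list(pos = 36L, ref = substr(refseq, 37, 40), alt = substr(refseq, 37, 37)),
    model, panel), "inframe_indel")
  # far intronic / splice region
  expect_equal(classify_molecular(list(pos = 10L, ref = "A", alt = "C"),
                                  model, panel), "intronic")
  expect_equal(classify_molecular(list(pos = 29L, ref = "A", alt = "C"),
                                  model, panel), "splice_region")
})

test_that("VCF output is valid VCF 4.2 and byte-deterministic", {
  sp <- fix_panel(1, 1, seed = 3)
  panel <- sp$panel
  refseq <- panel$reference$sequence
  a <- panel$amplicons[1, ]
  p <- a$fwd_primer_end + 12L
  rb <- substr(refseq, p + 1, p + 1)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  cand <- data.table::data.table(
    pos = p, vcf_pos = p, hp_pos = p, type = "SNV", ref = rb, alt = ab,
    event_len = 1L, vaf = 0.42, depth = 188L, alt_count = 79L,
    zygosity = "het", hp_context = 1L, vaf_fwd = 0.4, vaf_rev = 0.44,
    alt_fwd = 40L, alt_rev = 39L, n_fwd = 100L, n_rev = 88L,
    f_ins_sample = 0, f_del_sample = 0, f_ins2_sample = 0,
    start_wt = list(1:3), start_mut = list(1:3), filter = "PASS")
  v1 <- withr::local_tempfile(fileext = ".vcf")
  v2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cand, panel, v1)
  write_vcf(cand, panel, v2)
  expect_identical(readLines(v1), readLines(v2))
  skip_if_not_installed("VariantAnnotation")
  vcf <- VariantAnnotation::readVcf(v1)
  expect_equal(length(vcf), 1L)
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_equal(BiocGenerics::start(rr), p + 1L) # 1-based emission
  expect_equal(as.character(rr$REF), rb)
  # REF consistent with the panel FASTA
  expect_equal(substr(refseq, p + 1, p + 1), as.character(rr$REF))
})

test_that("run_pipeline produces the full artefact set deterministically", {
  sp <- fix_panel(1, 1, seed = 3)
  panel <- sp$panel
  refseq <- panel$reference$sequence
  a <- panel$amplicons[1, ]
  p <- a$fwd_primer_end + 40L
  rb <- substr(refseq, p + 1, p + 1)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  spec <- sample_spec(data.frame(pos = p, ref = rb, alt = ab, af = 0.5),
                      reads_per_amplicon = 150, seed = 5)
  d1 <- withr::local_tempdir()
  res <- run_pipeline(panel, spec, mode = calling_mode("germline"),
                      platform = "illumina", profile = illumina_profile(),
                      exons = sp$exons, out_dir = d1)
  expect_equal(res$confusion$tp, 1L)
  expect_equal(res$confusion$fp, 0L)
  expect_equal(res$metrics$sensitivity, 100)
  expect_true(file.exists(file.path(d1, "variants.vcf")))
  expect_true(file.exists(file.path(d1, "alignments.sam")))
  expect_true("hgvs" %in% names(res$candidates))
  expect_true(all(res$candidates$molecular_class != ""))
  # same seed, byte-identical VCF
  d2 <- withr::local_tempdir()
  run_pipeline(panel, spec, mode = calling_mode("germline"),
               platform = "illumina", profile = illumina_profile(),
               exons = sp$exons, out_dir = d2)
  expect_identical(readLines(file.path(d1, "variants.vcf")),
                   readLines(file.path(d2, "variants.vcf")))
})
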