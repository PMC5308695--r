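# a 60 bp reference with one 5-base C run at 0-based 21..25
eng_ref <- function() {
  reference("r", paste0(
    "ATGCGTACGATTGACCGTAGA", # 0..20
    "CCCCC",                 # 21..25, the homopolymer run
    "TAGGACGTTAGCATGCATGACGGTTACGATCGAT")) # 26..59
}

eng_panel <- function() {
  amplicon_panel(eng_ref(), data.frame(
    id = "a1", gene = "G", multiplex = "m1", start = 0L, end = 60L,
    fwd_primer_end = 2L, rev_primer_start = 58L))
}

test_that("pileup columns follow the stated conventions", {
  panel <- eng_panel()
  refseq <- panel$reference$sequence
  tmpl <- substr(refseq, 11, 40) # 0-based 10..39
  # 10 identical error-free reads
  aln <- fake_aln(rep(10L, 10), rep("30M", 10), rep(tmpl, 10))
  pile <- build_pileup(aln, panel)
  col <- pileup_column(pile, 20L)
  expect_equal(col$depth, 10L)
  expect_equal(unname(col$base_counts[1]), 10L)
  expect_equal(col$ref_base, substr(refseq, 21, 21))
  # 6 ref + 4 alt at one column
  alt_tmpl <- tmpl
  substr(alt_tmpl, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                      substr(tmpl, 11, 11))[1]
  aln2 <- fake_aln(rep(10L, 10), c(rep("30M", 6), rep("10M1X19M", 4)),
                   c(rep(tmpl, 6), rep(alt_tmpl, 4)))
  pile2 <- build_pileup(aln2, panel)
  col2 <- pileup_column(pile2, 20L)
  expect_equal(sort(unname(rowSums(col2$base_counts))), c(4L, 6L))
  # read with a 1-bp deletion spanning a column: in deletion_events and depth
  del_read <- paste0(substr(refseq, 11, 20), substr(refseq, 22, 41))
  aln3 <- fake_aln(c(10L, 10L), c("10M1D20M", "31M"),
                   c(del_read, substr(refseq, 11, 41)))
  pile3 <- build_pileup(aln3, panel)
  col3 <- pileup_column(pile3, 20L)
  expect_equal(unname(col3$deletion_events["1"]), 1L)
  expect_equal(col3$depth, 2L)
  # unsorted input errors
  expect_error(build_pileup(fake_aln(c(20L, 10L), c("30M", "30M"),
                                     c(tmpl, tmpl)), panel), "sorted")
})

test_that("candidates are emitted at the mode thresholds", {
  panel <- eng_panel()
  refseq <- panel$reference$sequence
  mk_pile <- function(n_ref, n_alt, at = 30L) {
    tmpl <- substr(refseq, 11, 50)
    alt_tmpl <- tmpl
    k <- at - 10L
    substr(alt_tmpl, k + 1L, k + 1L) <- setdiff(c("A", "C", "G", "T"),
                                                substr(tmpl, k + 1, k + 1))[1]
    ops_alt <- paste0(k, "M1X", 40L - k - 1L, "M")
    aln <- fake_aln(rep(10L, n_ref + n_alt),
                    c(rep("40M", n_ref), rep(ops_alt, n_alt)),
                    c(rep(tmpl, n_ref), rep(alt_tmpl, n_alt)),
                    strand = rep(c("+", "-"), length.out = n_ref + n_alt))
    build_pileup(aln, panel)
  }
  germ <- calling_mode("germline")
  som <- calling_mode("somatic")
  expect_equal(germ$min_depth, 50L); expect_equal(germ$min_vaf, 0.25)
  expect_equal(som$min_depth, 100L); expect_equal(som$min_vaf, 0.10)
  # depth 200, alt 60 (vaf 0.30): germline het call
  cand <- call_candidates(mk_pile(140, 60), germ)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$vaf, 0.30)
  expect_equal(cand$zygosity, "het")
  # depth 40: below 50x, no call whatever the vaf
  expect_equal(nrow(call_candidates(mk_pile(10, 30), germ)), 0L)
  # depth 150 vaf 0.12: somatic yes, germline no
  p150 <- mk_pile(132, 18)
  expect_equal(nrow(call_candidates(p150, som)), 1L)
  expect_equal(nrow(call_candidates(p150, germ)), 0L)
  # hom annotation at vaf >= 0.75
  expect_equal(call_candidates(mk_pile(20, 180), germ)$zygosity, "hom")
})

test_that("the homopolymer error database averages cohort event fractions", {
  panel <- eng_panel()
  refseq <- panel$reference$sequence
  tmpl <- substr(refseq, 11, 50)
  clean <- function() build_pileup(fake_aln(rep(10L, 50), rep("40M", 50),
                                            rep(tmpl, 50)), panel)
  # zero-error cohort: all fractions zero, nothing high-error
  db0 <- build_hp_database(list(clean(), clean()), panel)
  expect_true(all(db0$f_ins == 0 & db0$f_del == 0))
  expect_false(any(db0$high_error))
  expect_error(build_hp_database(list(clean()), panel), "at least 2")
  # sample with 12% 1-bp insertions at the C-run start (0-based 21..25):
  # pileup anchors the insertion at column 20, reported at run start 21
  ins_read <- paste0(substr(refseq, 11, 21), "C", substr(refseq, 22, 50))
  mk <- function(n_ins, n_tot) {
    build_pileup(fake_aln(rep(10L, n_tot),
                          c(rep("11M1I29M", n_ins), rep("40M", n_tot - n_ins)),
                          c(rep(ins_read, n_ins), rep(tmpl, n_tot - n_ins))),
                 panel)
  }
  db1 <- build_hp_database(list(mk(12, 100), mk(12, 100)), panel)
  row <- db1[db1$pos == 21L, ]
  expect_equal(row$f_ins, 0.12, tolerance = 1e-9)
  expect_true(row$high_error) # 0.12 >= 0.10
  db2 <- build_hp_database(list(mk(5, 100), mk(5, 100)), panel)
  expect_false(db2[db2$pos == 21L, ]$high_error) # 0.05 < 0.10: reliable
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hp_database(db1, f)
  expect_equal(read_hp_database(f)$f_ins, db1$f_ins)
})

test_that("mann_whitney_u matches enumeration and the reference implementation", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0) # no x exceeds any y
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 0.1) # 2/20 arrangements as extreme
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  # oracle property: exact p equals full permutation enumeration for all
  # untied inputs with combined n <= 8
  set.seed(31)
  for (i in 1:25) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    pool <- sample(100, m + n) # untied
    x <- pool[seq_len(m)]; y <- pool[-seq_len(m)]
    ours <- mann_whitney_u(x, y)
    expect_equal(ours$p_value, mwu_perm_oracle(x, y), tolerance = 1e-12)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(ours$U), unname(wt$statistic))
    expect_equal(ours$p_value, wt$p.value, tolerance = 1e-12)
  }
  # tie-corrected normal approximation stays close to wilcox.test's
  set.seed(32)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(1:5, 35, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, wt$p.value, tolerance = 1e-6)
  }
})

test_that("depth test passes degenerate input and flags concentrated mutants", {
  v <- function(wt, mut) list(start_wt = list(wt), start_mut = list(mut))
  # fewer than 3 mutant reads: pass by default
  expect_true(filter_depth_test(v(c(1, 5, 9, 12), c(5, 9)))$pass)
  # all mutants from one off-centre start, wild-type spread over 8: fail
  wt <- rep(seq(0, 70, by = 10), each = 7)
  mut <- rep(60, 50)
  r <- filter_depth_test(v(wt, mut))
  expect_false(r$pass)
  expect_lt(r$p_value, 1e-4)
  # same start distribution: pass with p near uniform
  set.seed(3)
  starts <- seq(0, 60, by = 12)
  r2 <- filter_depth_test(v(sample(starts, 200, TRUE), sample(starts, 60, TRUE)))
  expect_true(r2$pass)
})

test_that("strand bias rules follow the thresholds", {
  v <- function(vf, vr, af, ar, nf, nr) {
    list(vaf_fwd = vf, vaf_rev = vr, alt_fwd = af, alt_rev = ar,
         n_fwd = nf, n_rev = nr)
  }
  expect_true(filter_strand_bias(v(0.50, 0.48, 25, 24, 50, 50))$pass)
  expect_false(filter_strand_bias(v(0.60, 0.10, 30, 5, 50, 50))$pass) # diff > 0.35
  # alt only on the forward strand, 100 informative reverse reads: fail
  expect_false(filter_strand_bias(v(0.4, 0, 20, 0, 50, 100))$pass)
  # one-strand rule needs informative reads on the empty strand
  expect_true(filter_strand_bias(v(0.4, NA, 20, 0, 50, 2))$pass)
})

test_that("insertion overrun, deletion displacement and HP percentage apply their margins", {
  db <- data.table::data.table(
    pos = c(10L, 20L),
    f_ins = c(0.15, 0.02), f_del = c(0.15, 0.01), f_ins2 = c(0.02, 0),
    high_error = c(TRUE, FALSE))
  ins_v <- function(pos, f1, f2) list(hp_pos = pos, pos = pos, type = "insertion",
                                      f_ins_sample = f1, f_ins2_sample = f2,
                                      f_del_sample = 0, vaf = f1)
  # pass: margin 0.30 >= 0.20 and 2-nt insertions elevated
  expect_true(filter_insertion_overrun(ins_v(10L, 0.45, 0.08), db)$pass)
  # fail: margin 0.15 < 0.20
  expect_false(filter_insertion_overrun(ins_v(10L, 0.30, 0.08), db)$pass)
  # fail: 2-nt insertions not elevated
  expect_false(filter_insertion_overrun(ins_v(10L, 0.45, 0.01), db)$pass)
  # low-error position: auto-pass
  expect_true(filter_insertion_overrun(ins_v(20L, 0.40, 0), db)$pass)

  del_v <- function(pos, fd, fi) list(hp_pos = pos, pos = pos, type = "deletion",
                                      f_del_sample = fd, f_ins_sample = fi,
                                      f_ins2_sample = 0, vaf = fd)
  # r_db = 0.5; r_sample = 0.9, insertions down: pass
  expect_true(filter_deletion_displacement(del_v(10L, 0.45, 0.05), db)$pass)
  # shift 0.15 < 0.30: fail
  expect_false(filter_deletion_displacement(del_v(10L, 0.13, 0.07), db)$pass)
  # large shift but insertions up: fail
  expect_false(filter_deletion_displacement(del_v(10L, 0.9, 0.2), db)$pass)
  expect_true(filter_deletion_displacement(del_v(20L, 0.3, 0), db)$pass)

  # HP percentage: corrected = f_event - max(0, f_opp_db - f_opp_sample)
  hp_v <- function(fd, fi) list(hp_pos = 10L, pos = 10L, type = "deletion",
                                f_del_sample = fd, f_ins_sample = fi)
  r <- filter_hp_percentage(hp_v(0.50, 0.15), db) # zero correction
  expect_true(r$pass); expect_equal(r$corrected_vaf, 0.50)
  r2 <- filter_hp_percentage(hp_v(0.30, 0.07), db) # corrected 0.22 < 0.25
  expect_false(r2$pass); expect_equal(r2$corrected_vaf, 0.22)
  r3 <- filter_hp_percentage(hp_v(0.25, 0.15), db) # boundary: >= passes
  expect_true(r3$pass)
})

test_that("the variant rearrangement tool merges split low-frequency indels", {
  panel <- eng_panel()
  refseq <- panel$reference$sequence
  tmpl <- substr(refseq, 31, 58) # 0-based 30..57, away from the C run
  # a 4-bp deletion at 0-based 40..43 split by the aligner into 2+2 with one
  # intervening aligned read base
  read_del <- paste0(substr(refseq, 31, 40), substr(refseq, 45, 58))
  split_ops <- "10M2D1M2D13M"
  n_mut <- 12; n_wt <- 48
  aln <- fake_aln(rep(30L, n_mut + n_wt),
                  c(rep(split_ops, n_mut), rep("28M", n_wt)),
                  c(rep(read_del, n_mut), rep(tmpl, n_wt)),
                  strand = rep(c("+", "-"), length.out = n_mut + n_wt))
  pile <- build_pileup(aln, panel)
  perm <- list(name = "permissive", min_depth = 20L, min_vaf = 0.05,
               indel_detection_limit = 0.25)
  cand <- call_candidates(pile, perm)
  expect_true(any(cand$type == "deletion" & cand$event_len == 2L))
  out <- variant_rearrangement_tool(cand, aln, panel, perm)
  merged <- out$candidates
  expect_true(any(merged$type == "deletion" & merged$event_len >= 4L))
  expect_false(any(merged$event_len == 2L & merged$type == "deletion"))
  # no qualifying candidates: untouched
  out2 <- variant_rearrangement_tool(cand[0L, ], aln, panel, perm)
  expect_identical(out2$candidates, cand[0L, ])
})

test_that("the cascade applies platform rules and monotone survivor counts", {
  # synthetic candidate set with controlled filter outcomes
  db <- data.table::data.table(pos = 5L, f_ins = 0.15, f_del = 0.05,
                               f_ins2 = 0.01, high_error = TRUE)
  base <- data.table::data.table(
    pos = c(5L, 9L, 13L), vcf_pos = c(5L, 9L, 13L), hp_pos = c(5L, 9L, 13L),
    type = c("insertion", "SNV", "SNV"),
    ref = c("A", "C", "G"), alt = c("AT", "T", "A"), event_len = 1L,
    vaf = c(0.3, 0.4, 0.5), depth = 200L, alt_count = c(60L, 80L, 100L),
    zygosity = "het", hp_context = c(4L, 1L, 1L),
    vaf_fwd = c(0.30, 0.40, 0.60), vaf_rev = c(0.31, 0.42, 0.10),
    alt_fwd = c(30L, 40L, 60L), alt_rev = c(30L, 40L, 10L),
    n_fwd = 100L, n_rev = 100L,
    f_ins_sample = c(0.30, 0, 0), f_del_sample = 0, f_ins2_sample = c(0.001, 0, 0),
    start_wt = list(c(1, 8, 15, 22), c(1, 8, 15, 22), c(1, 8, 15, 22)),
    start_mut = list(c(1, 8, 15), c(8, 15, 22), c(1, 15, 22)))
  # illumina: no filters, everything passes
  ill <- run_cascade(base, NULL, filter_config(), "illumina")
  expect_true(all(ill$candidates$filter == "PASS"))
  # iontorrent: the insertion fails overrun (margin 0.15) and the third SNV
  # fails strand bias (diff 0.5)
  ion <- run_cascade(base, db, filter_config(), "iontorrent",
                     pathogenic = c("9:C:T"))
  expect_equal(ion$candidates$filter[1], "insertion_overrun")
  expect_equal(ion$candidates$filter[2], "PASS")
  expect_equal(ion$candidates$filter[3], "strand_bias")
  expect_true(all(diff(ion$audit$total) <= 0)) # monotone
  expect_equal(ion$audit$total[1], 3L)
  expect_equal(ion$audit$total[nrow(ion$audit)], 1L)
  expect_equal(ion$audit$pathogenic[1], 1L)
  expect_equal(ion$audit$pathogenic[nrow(ion$audit)], 1L)
  # empty candidate list
  e <- run_cascade(base[0L, ], db, filter_config(), "iontorrent")
  expect_equal(nrow(e$candidates), 0L)
  expect_true(all(e$audit$total == 0L))
  expect_error(run_cascade(base, NULL, filter_config(), "iontorrent"),
               "database")
})
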