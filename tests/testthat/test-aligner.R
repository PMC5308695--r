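test_that("FM index search agrees with a brute-force scan", {
  idx <- build_index("ACGTACGT")
  expect_equal(fm_search(idx, "ACGT", 0), c(0L, 4L))
  expect_equal(fm_search(idx, "ACGA", 1), c(0L, 4L))
  expect_length(fm_search(idx, "GGGG", 2), 0L)
  # property: random reference, random queries, 0..2 mismatches
  set.seed(7)
  ref <- random_dna(400)
  idx <- build_index(ref)
  for (rep in 1:30) {
    k <- sample(8:20, 1)
    q <- if (runif(1) < 0.7) {
      s <- sample(nchar(ref) - k, 1)
      qq <- substr(ref, s + 1, s + k)
      # inject up to 2 substitutions
      nmm <- sample(0:2, 1)
      if (nmm > 0) {
        at <- sample(k, nmm)
        ch <- strsplit(qq, "")[[1]]
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        qq <- paste(ch, collapse = "")
      }
      qq
    } else random_dna(k)
    for (mm in 0:2) {
      expect_equal(fm_search(idx, q, mm), fm_oracle(ref, q, mm),
                   info = paste("mm", mm, "q", q))
    }
  }
})

test_that("seed keys are taken from both read ends and searched on both strands", {
  set.seed(11)
  ref <- random_dna(600)
  idx <- build_index(ref)
  cfg <- aligner_config()
  read <- substr(ref, 201, 300) # 100 bp from position 200 (0-based)
  hits <- find_seed_hits(read, idx, cfg)
  expect_true(all(c("5p", "3p") %in% hits$key[hits$strand == "+"]))
  expect_true(all(hits$start[hits$strand == "+"] == 200L))
  # 3 substitutions inside the 5' key only: candidate from the 3' key alone
  ch <- strsplit(read, "")[[1]]
  for (at in c(6, 10, 14)) ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
  hits2 <- find_seed_hits(paste(ch, collapse = ""), idx, cfg)
  fwd <- hits2[hits2$strand == "+", ]
  expect_false("5p" %in% fwd$key)
  expect_true("3p" %in% fwd$key)
  # reverse-complemented read: strand '-', same implied start
  rc <- ampliscan:::revcomp(read)
  hits3 <- find_seed_hits(rc, idx, cfg)
  expect_true(all(hits3$strand == "-"))
  expect_true(200L %in% hits3$start)
  # too-short read is reported with a reason
  short <- find_seed_hits("ACGTACGT", idx, cfg)
  expect_identical(attr(short, "reason"), "too_short")
})

test_that("start clustering is single linkage below the distance threshold", {
  cfg <- aligner_config()
  h <- function(starts) data.frame(start = starts, strand = "+", key = "5p")
  expect_equal(cluster_starts(h(c(100, 102, 103)), cfg)$start, 100L)
  expect_equal(sort(cluster_starts(h(c(100, 106)), cfg)$start), c(100L, 106L))
  # chained closure: 100-104-108 joins through the middle
  expect_equal(cluster_starts(h(c(100, 104, 108)), cfg)$start, 100L)
})

test_that("smith_waterman reproduces hand-derived scores and the DP oracle", {
  cfg <- aligner_config()
  r <- smith_waterman("ACGTACGTAC", "ACGTACGTAC", cfg)
  expect_equal(r$score, 100)
  expect_equal(r$ops, "10M")
  expect_equal(smith_waterman("ACGTA", "ACCTA", cfg)$score, 32)
  r3 <- smith_waterman("ACGTACGT", "ACGTTACGT", cfg)
  expect_equal(r3$score, 71)
  expect_true(grepl("D", r3$ops))
  # property: score equals the exhaustive DP oracle (subset of the
  # 1000-case acceptance check)
  set.seed(5)
  for (i in 1:150) {
    read <- random_dna(sample(4:12, 1))
    window <- random_dna(sample(4:12, 1))
    expect_equal(smith_waterman(read, window, cfg)$score,
                 sw_oracle_score(read, window),
                 info = paste(read, window))
  }
})

test_that("rearrangement scores and rewrites follow the long-indel rule", {
  cfg <- aligner_config()
  expect_equal(re_score("10M", cfg), 1000)
  expect_equal(re_score("5M1D5M", cfg), 1010) # short deletion: 10/base
  expect_equal(re_score("5M1I5M", cfg), 1001) # short insertion: 1/base
  expect_equal(re_score("5M11D5M", cfg), 1000 + 1100) # long run scores as matches
  expect_equal(re_score("3S7M", cfg), 700) # clips score 0
  # deletion in a homopolymer is reported at the leftmost placement
  ref <- "TTGCAAAAGCTT"
  read <- "TTGCAAAGCTT" # one A of the run deleted
  sw <- smith_waterman(read, ref, cfg)
  ra <- rearrange_alignment(sw$ops, read, ref, sw$window_offset, cfg)
  tab <- ampliscan:::parse_ops(ra$ops)
  refpos <- ra$ref_start
  for (k in seq_len(nrow(tab))) {
    if (tab$op[k] == "D") break
    if (tab$op[k] %in% c("M", "X")) refpos <- refpos + tab$len[k]
  }
  expect_equal(refpos, 4L) # first A of the run (0-based)
  # an 11-bp deletion beats scattered mismatches under the re-matrix
  expect_gt(re_score("40M11D40M", cfg), re_score("40M11X29M", cfg))
})

test_that("rearrangement conserves the read sequence implied by ops", {
  sp <- fix_panel(2, 1, seed = 3)
  spec <- sample_spec(reads_per_amplicon = 30, seed = 5)
  mol <- simulate_amplicons(sp$panel, spec)
  rs <- simulate_reads(mol, restriction_enzymes(), ion_torrent_profile(),
                       100L, seed = 6)
  aln <- map_reads(rs, sp$panel)
  ok <- aln[aln$mapped, ]
  for (i in seq_len(nrow(ok))) {
    tab <- ampliscan:::parse_ops(ok$ops[i])
    expect_equal(ampliscan:::ops_read_len(tab), nchar(ok$seq[i]))
  }
})

test_that("primer-derived alignment bases are soft-clipped", {
  sp <- fix_panel(1, 1, seed = 3)
  panel <- sp$panel
  a <- panel$amplicons[1, ]
  # fully inside insert: unchanged
  inside <- list(ops = "50M", ref_start = a$fwd_primer_end + 5L)
  expect_identical(soft_clip_primers(inside, panel), inside[c("ops", "ref_start")])
  # alignment starting at the amplicon start: leading bases clipped
  lead <- soft_clip_primers(list(ops = "60M", ref_start = a$start), panel)
  expect_equal(lead$ops, paste0(a$fwd_primer_end - a$start, "S",
                                60 - (a$fwd_primer_end - a$start), "M"))
  expect_equal(lead$ref_start, a$fwd_primer_end)
  # overlap of 7 bases into the reverse primer: trailing 7S
  tr <- soft_clip_primers(list(ops = "50M",
                               ref_start = a$rev_primer_start - 43L), panel)
  expect_equal(tr$ops, "43M7S")
})

test_that("map_reads recovers error-free reads and rejects junk", {
  sp <- fix_panel(2, 1, seed = 3)
  rs <- exact_reads(sp$panel, 200, seed = 4)
  aln <- map_reads(rs, sp$panel)
  expect_true(all(aln$mapped))
  m <- merge(aln, rs, by.x = "read_id", by.y = "id")
  # positions recovered exactly (primer-clipped reads keep a shifted start)
  clipped <- grepl("S", m$ops)
  expect_true(all(m$ref_start[!clipped] == m$true_start[!clipped]))
  expect_gt(mean(!clipped), 0.5)
  # read of random sequence: unmapped
  junk <- data.table::data.table(id = "junk", seq = random_dna(90),
                                 qual = strrep("I", 90))
  expect_false(map_reads(junk, sp$panel)$mapped)
  # malformed record
  bad <- data.table::data.table(id = "bad", seq = "", qual = "")
  expect_error(map_reads(bad, sp$panel), "malformed")
})

test_that("mapped fraction degrades monotonically with extra key errors", {
  sp <- fix_panel(2, 1, seed = 3)
  spec <- sample_spec(reads_per_amplicon = 60, seed = 8)
  mol <- simulate_amplicons(sp$panel, spec)
  rs <- simulate_reads(mol, restriction_enzymes(), ion_torrent_profile(),
                       100L, seed = 9)
  aln <- map_reads(rs, sp$panel)
  set.seed(10)
  worse <- data.table::copy(rs)
  for (i in seq_len(nrow(worse))) {
    ch <- strsplit(worse$seq[i], "")[[1]]
    L <- length(ch)
    keys <- unique(c(5:24, (L - 23):(L - 4)))
    keys <- keys[keys >= 1 & keys <= L]
    at <- sample(keys, min(3L, length(keys)))
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    worse$seq[i] <- paste(ch, collapse = "")
  }
  aln2 <- map_reads(worse, sp$panel)
  expect_gte(mean(aln$mapped), mean(aln2$mapped))
})

test_that("SAM output is valid and readable by the standard tools", {
  skip_if_not_installed("Rsamtools")
  sp <- fix_panel(1, 1, seed = 3)
  rs <- exact_reads(sp$panel, 30, seed = 5)
  aln <- map_reads(rs, sp$panel)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, sp$panel, sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                          overwrite = TRUE, indexDestination = FALSE)
  ga <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(ga$qname), nrow(aln))
  expect_true(all(ga$rname[!is.na(ga$pos)] == "panelref"))
})
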