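#' Sequencing error profile
#'
#' Per-base substitution/insertion/deletion rates with multiplicative
#' escalation of indel rates inside homopolymers. The stated rates are
#' *marginal* (sequence-averaged) rates: during simulation the per-base
#' indel rates are escalation-weighted and renormalised over the concrete
#' molecule set so that the expected genome-wide event rate equals the
#' profile rate. Escalated per-base rates are capped at 0.5.
#'
#' @param name profile name.
#' @param sub_rate,ins_rate,del_rate events per base (fractions in `[0,1)`).
#' @param hp_ins_escalation,hp_del_escalation multiplicative factor applied
#'   per extra base of homopolymer length beyond 2.
#' @param mean_quality mean emitted Phred quality.
#' @param hp_quality_penalty Phred points subtracted per extra homopolymer
#'   base beyond 2 (models the low-quality homopolymer neighbourhoods of ion
#'   semiconductor data).
#' @return an `error_profile` object.
#' @export
error_profile <- function(name, sub_rate, ins_rate, del_rate,
                          hp_ins_escalation = 2, hp_del_escalation = 2,
                          mean_quality = 30, hp_quality_penalty = 0) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0,1)")
  structure(list(name = name, sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, hp_ins_escalation = hp_ins_escalation,
                 hp_del_escalation = hp_del_escalation,
                 mean_quality = mean_quality,
                 hp_quality_penalty = hp_quality_penalty),
            class = "error_profile")
}

#' Built-in platform error profiles
#'
#' Rates per 100 bases: Illumina-like 0.29 substitutions, 0.01 insertions,
#' 0.04 deletions; ion-semiconductor-like 0.23 substitutions, 1.27
#' insertions, 0.67 deletions, with stronger homopolymer escalation and a
#' quality penalty that pushes long-homopolymer neighbourhoods below Q10.
#'
#' @return an [error_profile()].
#' @export
illumina_profile <- function() {
  error_profile("illumina", sub_rate = 0.0029, ins_rate = 0.0001,
                del_rate = 0.0004, hp_ins_escalation = 1.5,
                hp_del_escalation = 1.5, mean_quality = 34,
                hp_quality_penalty = 1)
}

#' @rdname illumina_profile
#' @export
ion_torrent_profile <- function() {
  error_profile("iontorrent", sub_rate = 0.0023, ins_rate = 0.0127,
                del_rate = 0.0067, hp_ins_escalation = 2,
                hp_del_escalation = 2, mean_quality = 24,
                hp_quality_penalty = 4)
}

#' Sample scenario specification
#'
#' Encodes one simulated sample: spiked variants, copy-number events, and
#' the mean sequencing effort.
#'
#' @param variants data.frame with columns `pos` (0-based reference
#'   position), `ref`, `alt` (VCF-style allele strings) and `af` (allele
#'   fraction in (0,1]).
#' @param cnv_events list of `list(amplicon_ids =, copy_number =)` entries;
#'   copy number is out of 2 and must be >= 0.
#' @param reads_per_amplicon mean molecule count per amplicon at copy
#'   number 2 (Poisson).
#' @param seed integer seed; all randomness of the sample flows from it.
#' @return a `sample_spec` object.
#' @export
sample_spec <- function(variants = NULL, cnv_events = list(),
                        reads_per_amplicon = 500, seed = 1L) {
  if (is.null(variants)) {
    variants <- data.frame(pos = integer(), ref = character(),
                           alt = character(), af = numeric())
  }
  variants <- as.data.frame(variants)
  if (nrow(variants)) {
    stopifnot(all(c("pos", "ref", "alt", "af") %in% names(variants)))
    if (any(variants$af <= 0 | variants$af > 1)) {
      stop("allele fractions must be in (0,1]")
    }
  }
  for (ev in cnv_events) {
    if (is.null(ev$amplicon_ids) || is.null(ev$copy_number) ||
        ev$copy_number < 0) {
      stop("each cnv event needs amplicon_ids and copy_number >= 0")
    }
  }
  structure(list(variants = variants, cnv_events = cnv_events,
                 reads_per_amplicon = reads_per_amplicon,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

# homopolymer run length at every position of a sequence
hp_run_lengths <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  rep.int(r$lengths, r$lengths)
}

apply_variants_to_slice <- function(slice, slice_start, variants, ref_seq) {
  # variants: rows with pos/ref/alt; applied right-to-left so earlier
  # coordinates stay valid
  if (!nrow(variants)) return(slice)
  variants <- variants[order(-variants$pos), , drop = FALSE]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    off <- v$pos - slice_start # 0-based offset in slice
    seen <- substr(slice, off + 1L, off + nchar(v$ref))
    if (seen != v$ref) {
      stop("variant ref allele mismatch at position ", v$pos,
           ": reference has '", seen, "', variant says '", v$ref, "'")
    }
    slice <- paste0(substr(slice, 1L, off), v$alt,
                    substr(slice, off + nchar(v$ref) + 1L, nchar(slice)))
  }
  slice
}

#' Simulate amplicon molecules for a sample
#'
#' Models the multiplex-PCR product pool: per amplicon, a Poisson number of
#' molecules with mean `reads_per_amplicon * copy_number / 2`; each molecule
#' is the amplicon's reference slice with each overlapping spiked variant
#' applied independently with probability `af`.
#'
#' @param panel an [amplicon_panel()].
#' @param spec a [sample_spec()].
#' @return data.table with columns `molecule_id`, `amplicon_id`, `ref_start`
#'   (amplicon start) and `seq`.
#' @export
simulate_amplicons <- function(panel, spec) {
  set.seed(spec$seed)
  a <- panel$amplicons
  cn <- stats::setNames(rep(2, nrow(a)), a$id)
  for (ev in spec$cnv_events) {
    unknown <- setdiff(ev$amplicon_ids, a$id)
    if (length(unknown)) stop("cnv event names unknown amplicons: ",
                              paste(unknown, collapse = ", "))
    cn[ev$amplicon_ids] <- ev$copy_number
  }
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    amp <- a[i]
    n <- stats::rpois(1L, spec$reads_per_amplicon * cn[[amp$id]] / 2)
    if (n == 0L) next
    slice <- ref_slice(panel$reference, amp$start, amp$end)
    vv <- spec$variants[spec$variants$pos >= amp$start &
                          spec$variants$pos + nchar(spec$variants$ref) <= amp$end, ,
                        drop = FALSE]
    seqs <- character(n)
    if (nrow(vv)) {
      carry <- matrix(stats::runif(n * nrow(vv)) < rep(vv$af, each = n),
                      nrow = n)
      for (m in seq_len(n)) {
        sel <- vv[carry[m, ], , drop = FALSE]
        seqs[m] <- apply_variants_to_slice(slice, amp$start, sel)
      }
    } else {
      seqs[] <- slice
    }
    out[[i]] <- data.table::data.table(
      amplicon_id = amp$id, ref_start = amp$start, seq = seqs)
  }
  mol <- data.table::rbindlist(out)
  if (!nrow(mol)) {
    return(data.table::data.table(molecule_id = integer(),
                                  amplicon_id = character(),
                                  ref_start = integer(), seq = character()))
  }
  mol[, `:=`(molecule_id = seq_len(.N))]
  data.table::setcolorder(mol, c("molecule_id", "amplicon_id", "ref_start", "seq"))
  mol[]
}

#' Simulate single-end reads from molecules
#'
#' Each molecule is fragmented by restriction digestion; fragments outside
#' the library size-selection window are discarded; each retained fragment
#' yields one read of `min(read_length, fragment length)` taken from a
#' uniformly chosen fragment end/strand. Errors are injected per base at the
#' profile rates, indel rates escalated inside homopolymers (run length 3
#' or more) and renormalised so the marginal rates match the profile.
#' Base qualities are drawn around `mean_quality` and reduced inside
#' homopolymers.
#'
#' @param molecules data.table from [simulate_amplicons()] (columns
#'   `molecule_id`, `amplicon_id`, `ref_start`, `seq`).
#' @param enzymes list of [enzyme()] objects.
#' @param profile an [error_profile()].
#' @param read_length maximum read length (>= 20, the seed-key length).
#' @param seed integer seed.
#' @param size_range retained fragment length window (library size
#'   selection), default `c(50, 300)`.
#' @param digestion `"split"` (default): each molecule is digested with one
#'   enzyme chosen uniformly, modelling a library split over the enzymes so
#'   fragments from different molecules overlap; `"combined"`: all enzymes
#'   cut every molecule.
#' @return a data.table read set with columns `id`, `seq`, `qual`,
#'   `amplicon_id`, `molecule_id`, `strand`, `true_start` (0-based reference
#'   start the read's template was taken from, defined for variant-free
#'   molecules), `mol_offset` and `template_len`.
#' @export
simulate_reads <- function(molecules, enzymes, profile, read_length = 100L,
                           seed = 1L, size_range = c(50L, 300L),
                           digestion = c("split", "combined")) {
  digestion <- match.arg(digestion)
  if (read_length < 20L) stop("read_length must be >= 20 (aligner key length)")
  set.seed(seed)
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  nmol <- nrow(molecules)
  if (!nmol) return(empty_read_set())

  # calibrate injection scales so the expected *observable* (net) event
  # rates over the sequenced bases of this molecule set match the
  # profile's marginal rates
  hp <- lapply(molecules$seq, hp_run_lengths)
  useqs <- unique(molecules$seq)
  ucounts <- as.integer(table(factor(molecules$seq, levels = useqs)))
  uweights <- lapply(useqs, coverage_weights, enzymes = enzymes,
                     read_length = read_length, size_range = size_range,
                     digestion = digestion)
  cal <- calibrate_indel_scales(useqs, ucounts, uweights, profile)
  norm_ins <- cal$s_ins
  norm_del <- cal$s_del

  enzyme_pick <- if (digestion == "split") {
    sample.int(length(enzymes), nmol, replace = TRUE)
  } else rep(1L, nmol)

  recs <- vector("list", nmol)
  for (m in seq_len(nmol)) {
    mseq <- molecules$seq[m]
    mhp <- hp[[m]]
    enz <- if (digestion == "split") enzymes[enzyme_pick[m]] else enzymes
    fr <- digest(mseq, enz)
    keep <- nchar(fr$fragment) >= size_range[1] &
      nchar(fr$fragment) <= size_range[2]
    fr <- fr[keep, , drop = FALSE]
    if (!nrow(fr)) next
    reads <- vector("list", nrow(fr))
    for (k in seq_len(nrow(fr))) {
      flen <- nchar(fr$fragment[k])
      L <- min(read_length, flen)
      from_5p <- stats::runif(1) < 0.5
      if (from_5p) {
        off <- fr$start_offset[k]
        strand <- "+"
      } else {
        off <- fr$start_offset[k] + flen - L
        strand <- "-"
      }
      tmpl <- substr(mseq, off + 1L, off + L)
      thp <- mhp[(off + 1L):(off + L)]
      rr <- inject_errors(tmpl, thp, profile, norm_ins, norm_del)
      seqout <- if (strand == "+") rr$seq else revcomp(rr$seq)
      qualout <- if (strand == "+") rr$qual else paste(rev(strsplit(rr$qual, "")[[1]]), collapse = "")
      reads[[k]] <- data.table::data.table(
        seq = seqout, qual = qualout,
        amplicon_id = molecules$amplicon_id[m],
        molecule_id = molecules$molecule_id[m],
        strand = strand,
        true_start = molecules$ref_start[m] + off,
        mol_offset = off, template_len = L)
    }
    recs[[m]] <- data.table::rbindlist(reads)
  }
  rs <- data.table::rbindlist(recs)
  if (!nrow(rs)) return(empty_read_set())
  rs[, `:=`(id = sprintf("read%06d", seq_len(.N)))]
  data.table::setcolorder(rs, c("id", "seq", "qual", "amplicon_id",
                                "molecule_id", "strand", "true_start",
                                "mol_offset", "template_len"))
  rs[]
}

empty_read_set <- function() {
  data.table::data.table(id = character(), seq = character(),
                         qual = character(), amplicon_id = character(),
                         molecule_id = integer(), strand = character(),
                         true_start = integer(), mol_offset = integer(),
                         template_len = integer())
}

# Expected net (observable) insertion/deletion events in one homopolymer
# run of length r: within a run an insertion and a deletion cancel in the
# emitted read (the run's net length is what a sequencer observes), so the
# observable counts are max(0, I - D) and max(0, D - I) with I ~ Bin(r,
# p_i), D ~ Bin(r, p_d).
net_run_events <- function(r, p_i, p_d) {
  di <- stats::dbinom(0:r, r, p_i)
  dd <- stats::dbinom(0:r, r, p_d)
  e_ins <- 0; e_del <- 0
  for (ii in 0:r) for (dd_ in 0:r) {
    pr <- di[ii + 1] * dd[dd_ + 1]
    if (ii > dd_) e_ins <- e_ins + pr * (ii - dd_)
    if (dd_ > ii) e_del <- e_del + pr * (dd_ - ii)
  }
  c(ins = e_ins, del = e_del)
}

# Expected per-base sequencing weight of one molecule: each retained
# fragment yields one read of min(read_length, len) from a uniformly chosen
# end, so a base is sequenced with probability 0.5 per end-window it falls
# in, averaged over the digestion(s).
coverage_weights <- function(seq, enzymes, read_length, size_range,
                             digestion) {
  n <- nchar(seq)
  digs <- if (digestion == "split") {
    lapply(enzymes, function(e) digest(seq, e))
  } else list(digest(seq, enzymes))
  w <- numeric(n)
  for (fr in digs) {
    flen <- nchar(fr$fragment)
    keep <- flen >= size_range[1] & flen <= size_range[2]
    for (k in which(keep)) {
      L <- min(read_length, flen[k])
      a <- fr$start_offset[k]
      w[(a + 1L):(a + L)] <- w[(a + 1L):(a + L)] + 0.5 / length(digs)
      b <- a + flen[k]
      w[(b - L + 1L):b] <- w[(b - L + 1L):b] + 0.5 / length(digs)
    }
  }
  w
}

# Solve for multiplicative scales on the per-base indel rates such that the
# expected observable events per *sequenced* base over the molecule set
# equal the profile rates (escalation, the 0.5 cap, homopolymer
# cancellation and the non-uniform base sampling of fragment-end reads all
# included). useqs/ucounts/uweights describe the unique molecule sequences,
# their multiplicities and their per-base coverage weights.
calibrate_indel_scales <- function(useqs, ucounts, uweights, profile,
                                   iters = 40L) {
  run_w <- numeric(0) # aggregated coverage weight per run length
  w_nonhp <- 0
  w_total <- 0
  for (u in seq_along(useqs)) {
    ch <- strsplit(useqs[u], "")[[1]]
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- uweights[[u]] * ucounts[u]
    w_total <- w_total + sum(w)
    for (k in seq_along(r$lengths)) {
      len <- r$lengths[k]
      wk <- sum(w[starts[k]:ends[k]])
      if (len >= 3L) {
        key <- as.character(len)
        run_w[key] <- (if (key %in% names(run_w)) run_w[[key]] else 0) +
          wk / len # mean weight x 1 run, scaled back to per-run
      } else {
        w_nonhp <- w_nonhp + wk
      }
    }
  }
  run_len <- as.integer(names(run_w))
  target_i <- profile$ins_rate * w_total
  target_d <- profile$del_rate * w_total
  s_i <- 1; s_d <- 1
  if (target_i <= 0 && target_d <= 0) return(list(s_ins = 1, s_del = 1))
  for (it in seq_len(iters)) {
    obs_i <- w_nonhp * min(0.5, profile$ins_rate * s_i)
    obs_d <- w_nonhp * min(0.5, profile$del_rate * s_d)
    inj_i <- obs_i; inj_d <- obs_d
    for (k in seq_along(run_len)) {
      r <- run_len[k]
      p_i <- min(0.5, profile$ins_rate * s_i * profile$hp_ins_escalation^(r - 2L))
      p_d <- min(0.5, profile$del_rate * s_d * profile$hp_del_escalation^(r - 2L))
      e <- net_run_events(r, p_i, p_d)
      obs_i <- obs_i + run_w[[k]] * e[["ins"]]
      obs_d <- obs_d + run_w[[k]] * e[["del"]]
      inj_i <- inj_i + run_w[[k]] * r * p_i
      inj_d <- inj_d + run_w[[k]] * r * p_d
    }
    # an insertion within ~2 bases of a deletion outside a shared run
    # collapses to one or two substitutions under the flat SW scoring
    # (2 mismatches cost 16 < 18 for I+D), destroying one event of each
    # type: first-order pairwise loss over ~4 neighbour positions
    mean_i <- inj_i / w_total
    mean_d <- inj_d / w_total
    obs_i <- obs_i * (1 - 4 * mean_d)
    obs_d <- obs_d * (1 - 4 * mean_i)
    if (target_i > 0 && obs_i > 0) s_i <- s_i * (target_i / obs_i)^0.8
    if (target_d > 0 && obs_d > 0) s_d <- s_d * (target_d / obs_d)^0.8
  }
  list(s_ins = s_i, s_del = s_d)
}

# per-base error injection on one read template; hp = run length per base
inject_errors <- function(tmpl, hp, profile, norm_ins, norm_del) {
  L <- nchar(tmpl)
  ch <- strsplit(tmpl, "")[[1]]
  e <- pmax(0L, hp - 2L)
  p_ins <- pmin(0.5, profile$ins_rate * profile$hp_ins_escalation^e * norm_ins)
  p_del <- pmin(0.5, profile$del_rate * profile$hp_del_escalation^e * norm_del)
  p_sub <- pmin(0.5, rep(profile$sub_rate, L))
  del <- stats::runif(L) < p_del
  ins <- stats::runif(L) < p_ins
  sub <- stats::runif(L) < p_sub & !del
  if (any(sub)) {
    alt <- vapply(ch[sub], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    ch[sub] <- alt
  }
  ins_base <- character(L)
  if (any(ins)) {
    # homopolymer overcall duplicates the local base; elsewhere random base
    in_hp <- hp >= 3L
    ins_base[ins & in_hp] <- ch[ins & in_hp]
    n_rand <- sum(ins & !in_hp)
    if (n_rand) ins_base[ins & !in_hp] <- sample(c("A", "C", "G", "T"), n_rand, replace = TRUE)
  }
  qual <- stats::rnorm(L, profile$mean_quality, 3) - profile$hp_quality_penalty * e
  qual <- pmin(pmax(round(qual), 2), 41)
  out_n <- (!del) + ins
  keep <- out_n > 0L
  bases <- character(sum(out_n))
  quals <- integer(sum(out_n))
  j <- 1L
  for (i in seq_len(L)) {
    if (!del[i]) {
      bases[j] <- ch[i]; quals[j] <- qual[i]; j <- j + 1L
    }
    if (ins[i]) {
      bases[j] <- ins_base[i]; quals[j] <- qual[i]; j <- j + 1L
    }
  }
  list(seq = paste(bases, collapse = ""),
       qual = phred_to_char(quals))
}

#' Simulate a wild-type cohort for the homopolymer error database
#'
#' Generates `n_samples` independent variant-free samples with the given
#' profile; the per-sample seeds are derived from `seed`.
#'
#' @param panel an [amplicon_panel()].
#' @param profile an [error_profile()].
#' @param n_samples number of samples (default 20, the cohort size the
#'   error database is designed around).
#' @param reads_per_amplicon mean molecules per amplicon.
#' @param read_length read length.
#' @param enzymes fragmentation enzymes.
#' @param seed master seed.
#' @return list of read sets (possibly empty when `n_samples = 0`).
#' @export
simulate_wildtype_cohort <- function(panel, profile, n_samples = 20L,
                                     reads_per_amplicon = 300,
                                     read_length = 100L,
                                     enzymes = restriction_enzymes(),
                                     seed = 1L) {
  if (n_samples == 0L) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L * n_samples)
  lapply(seq_len(n_samples), function(i) {
    spec <- sample_spec(reads_per_amplicon = reads_per_amplicon,
                        seed = seeds[2L * i - 1L])
    mol <- simulate_amplicons(panel, spec)
    simulate_reads(mol, enzymes, profile, read_length, seed = seeds[2L * i])
  })
}

#' Simulate an FFPE-style admixture series
#'
#' Per fraction `f`, molecules are drawn from the mutant sample with
#' probability `f` and from the wild-type sample otherwise, so a
#' heterozygous mutant variant has expected VAF `f/2`.
#'
#' @param panel an [amplicon_panel()].
#' @param mutant_spec,wildtype_spec [sample_spec()]s for the two source
#'   samples (total molecule yield follows `mutant_spec$reads_per_amplicon`).
#' @param fractions mutant fractions, e.g. `c(1/2, 1/4, 1/8, 1/16)`.
#' @param profile an [error_profile()].
#' @param enzymes fragmentation enzymes.
#' @param read_length read length.
#' @param seed master seed.
#' @return named list (one read set per fraction).
#' @export
simulate_admixture <- function(panel, mutant_spec, wildtype_spec,
                               fractions = c(1 / 2, 1 / 4, 1 / 8, 1 / 16),
                               profile = illumina_profile(),
                               enzymes = restriction_enzymes(),
                               read_length = 100L, seed = 1L) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3L * length(fractions)),
                  ncol = 3L)
  out <- vector("list", length(fractions))
  names(out) <- as.character(fractions)
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    ms <- mutant_spec
    ms$reads_per_amplicon <- mutant_spec$reads_per_amplicon * f
    ms$seed <- seeds[i, 1L]
    ws <- wildtype_spec
    ws$reads_per_amplicon <- mutant_spec$reads_per_amplicon * (1 - f)
    ws$seed <- seeds[i, 2L]
    mol_m <- simulate_amplicons(panel, ms)
    mol_w <- simulate_amplicons(panel, ws)
    if (nrow(mol_w)) mol_w[, molecule_id := molecule_id + max(0L, mol_m$molecule_id, na.rm = TRUE)]
    mol <- data.table::rbindlist(list(mol_m, mol_w))
    out[[i]] <- simulate_reads(mol, enzymes, profile, read_length,
                               seed = seeds[i, 3L])
  }
  out
}

#' Read/write read sets as FASTQ (Sanger Phred+33)
#'
#' @param reads a read set data.table (`id`, `seq`, `qual`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Measure realised error rates by realigning reads to their truth molecules
#'
#' Each read is aligned back to the molecule it was simulated from
#' (Smith-Waterman plus the rearrangement pass, as in mapping) and the
#' substitution / insertion / deletion events are counted per 100 read
#' bases. This is the independent readout used to verify that the injected
#' platform error rates are recovered.
#'
#' Rates are estimated over the read interior (`edge_trim` bases excluded
#' from both read ends, numerator and denominator alike): a local aligner
#' cannot resolve indels at read termini, where they are absorbed into soft
#' clips or shifted end alignments, so terminal bases would bias the
#' estimate downward.
#'
#' @param reads read set from [simulate_reads()] (truth columns required).
#' @param molecules the molecule table the reads were simulated from.
#' @param cfg an [aligner_config()].
#' @param edge_trim read-end bases excluded from the estimate.
#' @return list with `per100` (named numeric: sub, ins, del), `events`
#'   (named counts), and `bases` (total interior read bases assessed).
#' @export
measure_error_rates <- function(reads, molecules, cfg = aligner_config(),
                                edge_trim = 8L) {
  stopifnot(all(c("molecule_id", "mol_offset", "template_len") %in% names(reads)))
  mol_seq <- stats::setNames(molecules$seq, molecules$molecule_id)
  n_sub <- 0; n_ins <- 0; n_del <- 0; bases <- 0
  pad <- 12L
  for (i in seq_len(nrow(reads))) {
    mseq <- mol_seq[[as.character(reads$molecule_id[i])]]
    oriented <- if (reads$strand[i] == "+") reads$seq[i] else revcomp(reads$seq[i])
    L <- nchar(oriented)
    if (L <= 2L * edge_trim) next
    lo <- max(0L, reads$mol_offset[i] - pad)
    hi <- min(nchar(mseq), reads$mol_offset[i] + reads$template_len[i] + pad)
    window <- substr(mseq, lo + 1L, hi)
    sw <- smith_waterman(oriented, window, cfg)
    if (sw$score <= 0) next
    ra <- rearrange_alignment(sw$ops, oriented, mseq, lo + sw$window_offset, cfg)
    tab <- parse_ops(ra$ops)
    in_core <- function(rp) rp >= edge_trim & rp < (L - edge_trim)
    readp <- 0L
    for (k in seq_len(nrow(tab))) {
      op <- tab$op[k]; len <- tab$len[k]
      if (op %in% c("M", "X", "I", "S")) {
        rp <- readp + seq_len(len) - 1L
        if (op == "X") n_sub <- n_sub + sum(in_core(rp))
        if (op == "I") n_ins <- n_ins + sum(in_core(rp))
        readp <- readp + len
      } else if (op == "D") {
        if (in_core(readp)) n_del <- n_del + len
      }
    }
    bases <- bases + (L - 2L * edge_trim)
  }
  list(per100 = c(sub = 100 * n_sub / bases, ins = 100 * n_ins / bases,
                  del = 100 * n_del / bases),
       events = c(sub = n_sub, ins = n_ins, del = n_del), bases = bases)
}
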