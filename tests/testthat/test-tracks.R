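# Track extraction, normalization, serialization and QC.

test_that("read strand assignment follows the mismatch majority with ties discarded", {
  ref <- strsplit("ACGTCCGGTACGTCCGGTAC", "")[[1]]
  # all five Cs read as T: top-strand conversion
  read_plus <- gsub("C", "T", paste(ref, collapse = ""))
  expect_identical(assign_read_strand(read_plus, "20M", 0L, ref), "+")
  # no mismatches at all: no information
  expect_identical(assign_read_strand(paste(ref, collapse = ""), "20M", 0L,
                                      ref), "undetermined")
  # aligner tag wins over the pattern
  expect_identical(assign_read_strand(read_plus, "20M", 0L, ref, tag = "-"),
                   "-")
  # exhaustive tie check against a brute-force classifier on small
  # mismatch vectors: convert i Cs to T and j Gs to A, all i, j in 0..3
  cpos <- which(ref == "C")[1:3]
  gpos <- which(ref == "G")[1:3]
  for (i in 0:3) {
    for (j in 0:3) {
      rb <- ref
      if (i > 0) rb[cpos[seq_len(i)]] <- "T"
      if (j > 0) rb[gpos[seq_len(j)]] <- "A"
      want <- if (i > j) "+" else if (j > i) "-" else "undetermined"
      expect_identical(
        assign_read_strand(paste(rb, collapse = ""), "20M", 0L, ref),
        want)
    }
  }
})

test_that("pileup counts converted and unconverted bases and drops the rest", {
  ref <- list(chars = strsplit(strrep("ACGTT", 4), "")[[1]],
              contig = "chrT", length = 20L)
  # 10 plus-strand reads over the C at pos 1; 4 read T, 4 read C, 2 read G
  base_at <- c(rep("T", 4), rep("C", 4), rep("G", 2))
  aln <- data.frame(
    qname = sprintf("r%d", 1:10), flag = 0L, chrom = "chrT", pos = 0L,
    mapq = 60L, cigar = "5M",
    seq = vapply(base_at, function(b) paste0("A", b, "GTT"), character(1)),
    strand = "+", barcode = NA_character_, duplicate = FALSE)
  tr <- extract_conversion_track(aln, ref, min_cov_rate = 1L)
  rec <- tr[tr$pos == 1L & tr$strand == "+", ]
  expect_equal(rec$n_total, 8L)  # the two G reads are not informative
  expect_equal(rec$n_conv, 4L)
})

test_that("extraction equals a brute-force recount of simulated conversion events", {
  fx <- site_sim(theta = 0.5, seed = 11, n_molecules = 80L)
  sim <- simulate_molecules(fx$cfg, fx$ref, 12, keep_truth = TRUE)
  tr <- extract_conversion_track(sim$alignments, fx$ref, min_cov_rate = 1L)
  ev <- sim$truth$events
  recount <- aggregate(converted ~ pos + strand, data = ev,
                       FUN = function(x) c(n = length(x), k = sum(x)))
  recount <- data.frame(pos = recount$pos, strand = recount$strand,
                        n_total = recount$converted[, "n"],
                        n_conv = recount$converted[, "k"])
  recount <- recount[order(recount$pos, recount$strand), ]
  got <- as.data.frame(tr[, c("pos", "strand", "n_total", "n_conv")])
  expect_equal(got$pos, recount$pos)
  expect_equal(got$n_total, as.integer(recount$n_total))
  expect_equal(got$n_conv, as.integer(recount$n_conv))
  # conservation: total informative observations match exactly
  expect_identical(sum(tr$n_total), nrow(ev))
})

test_that("SAM round trip reproduces the in-memory extraction exactly", {
  fx <- site_sim(theta = 0.8, seed = 21, n_molecules = 150L)
  tr_mem <- extract_conversion_track(fx$sim$alignments, fx$ref,
                                     min_cov_rate = 1L)
  sam <- tempfile(fileext = ".sam")
  fa <- tempfile(fileext = ".fa")
  write_sam(fx$sim$alignments, stats::setNames(fx$cfg$length,
                                               fx$cfg$contig), sam)
  write_fasta(fx$ref, fa)
  tr_file <- extract_conversion_track(sam, fa, min_cov_rate = 1L)
  expect_equal(as.data.frame(tr_mem), as.data.frame(tr_file))
})

test_that("duplicate-flagged reads are dropped by default and kept on request", {
  ref <- list(chars = strsplit("AACGT", "")[[1]], contig = "chrT",
              length = 5L)
  aln <- data.frame(qname = c("a", "b"), flag = 0L, chrom = "chrT",
                    pos = 0L, mapq = 60L, cigar = "5M", seq = "AATGT",
                    strand = "+", barcode = NA_character_,
                    duplicate = c(FALSE, TRUE))
  expect_equal(extract_conversion_track(aln, ref,
                                        min_cov_rate = 1L)$n_total, 1L)
  expect_equal(extract_conversion_track(aln, ref, dedup = FALSE,
                                        min_cov_rate = 1L)$n_total, 2L)
})

test_that("overlapping observations from one molecule are counted once", {
  ref <- list(chars = strsplit("AACGT", "")[[1]], contig = "chrT",
              length = 5L)
  # two mates of one fragment covering the same cytosine
  aln <- data.frame(qname = "frag1", flag = 0L, chrom = "chrT", pos = 0L,
                    mapq = 60L, cigar = "5M", seq = "AATGT", strand = "+",
                    barcode = NA_character_, duplicate = FALSE)
  aln <- rbind(aln, aln)
  tr <- extract_conversion_track(aln, ref, min_cov_rate = 1L)
  expect_equal(tr$n_total, 1L)
})

test_that("extraction rejects contigs missing from the reference", {
  ref <- list(chars = strsplit("AACGT", "")[[1]], contig = "chrT",
              length = 5L)
  aln <- data.frame(qname = "a", flag = 0L, chrom = "chrX", pos = 0L,
                    mapq = 60L, cigar = "5M", seq = "AATGT", strand = "+",
                    barcode = NA_character_, duplicate = FALSE)
  expect_error(extract_conversion_track(aln, ref), "chrX")
})

test_that("empty input gives an empty track with undefined global rate", {
  ref <- list(chars = strsplit("AACGT", "")[[1]], contig = "chrT",
              length = 5L)
  aln <- data.frame(qname = character(0), flag = integer(0),
                    chrom = character(0), pos = integer(0),
                    mapq = integer(0), cigar = character(0),
                    seq = character(0), strand = character(0),
                    barcode = character(0), duplicate = logical(0))
  expect_warning(tr <- extract_conversion_track(aln, ref), "empty")
  expect_equal(nrow(tr), 0L)
  expect_true(is.na(attr(tr, "global_rate")))
})

test_that("normalization rescales linearly, clips, and is idempotent at the global rate", {
  tr <- rate_track(c(10L, 20L, 30L), c(0.2, 0.2, 0.9))
  gr <- attr(tr, "global_rate")
  # identity when the target equals the global rate
  same <- normalize_track(tr, gr)
  expect_equal(same$rate, tr$rate)
  # linear scaling: rate 0.2 with target 2x the global rate becomes 0.4-ish
  dbl <- normalize_track(tr, 2 * gr)
  expect_equal(dbl$rate, pmin(tr$rate * 2, 1))
  expect_error(normalize_track(uniform_track(1L, rate = 0), 0.3),
               "global rate")
})

test_that("dose normalization collapses two enzyme-dose simulations onto one profile", {
  mk <- function(p_open, seed) {
    cfg <- sim_config(length = 6000L,
                      enzyme = list(p_open = p_open, p_protected = 0.05),
                      molecules = list(n_molecules = 5000L, frag_len = 150L))
    ref <- simulate_reference(cfg, 400)  # same reference both doses
    tr <- extract_conversion_track(simulate_molecules(cfg, ref, seed,
                                                      naked = TRUE)$alignments,
                                   ref)
    normalize_track(tr, 0.3)
  }
  lo <- mk(0.3, 401)
  hi <- mk(0.6, 402)
  m <- merge(as.data.frame(lo)[, c("pos", "strand", "rate")],
             as.data.frame(hi)[, c("pos", "strand", "rate")],
             by = c("pos", "strand"))
  # windowed profiles agree closely after normalization
  bins <- cut(m$pos, seq(0, 6000, by = 200))
  prof_lo <- tapply(m$rate.x, bins, mean)
  prof_hi <- tapply(m$rate.y, bins, mean)
  expect_lt(max(abs(prof_lo - prof_hi), na.rm = TRUE), 0.02)
})

test_that("track TSV serialization round-trips field-exactly", {
  # small track
  tr <- rate_track(c(5L, 9L, 14L), c(0.1, 0.5, 0.9))
  f <- tempfile(fileext = ".tsv")
  write_track(tr, f)
  back <- read_track(f)
  expect_equal(as.data.frame(tr), as.data.frame(back))
  expect_equal(attr(back, "global_rate"), attr(tr, "global_rate"))
  # empty track
  empty <- conversion_track(data.frame(chrom = character(0),
                                       pos = integer(0),
                                       strand = character(0),
                                       n_conv = integer(0),
                                       n_total = integer(0)))
  write_track(empty, f)
  expect_equal(nrow(read_track(f)), 0L)
  # large random track, property-style
  set.seed(42)
  n <- 10000L
  big <- conversion_track(data.frame(
    chrom = "chrT",
    pos = sort(sample.int(1000000L, n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    n_total = nt <- sample.int(100L, n, replace = TRUE),
    n_conv = vapply(nt, function(x) sample.int(x + 1L, 1L) - 1L,
                    integer(1)),
    context = paste0(sample(c("A", "C", "G", "T"), n, TRUE), "C",
                     sample(c("A", "C", "G", "T"), n, TRUE))))
  write_track(big, f)
  expect_equal(as.data.frame(read_track(f)), as.data.frame(big))
})

test_that("bedGraph export writes width-1 half-open intervals per strand", {
  tr <- conversion_track(data.frame(
    chrom = "chrT", pos = c(3L, 7L), strand = c("+", "-"),
    n_conv = c(1L, 3L), n_total = c(4L, 4L), context = "ACA"),
    min_cov_rate = 1L)
  prefix <- tempfile()
  paths <- write_bedgraph(tr, prefix)
  expect_length(paths, 4L)
  plus <- read.table(paths[1], skip = 1, sep = "\t")
  expect_equal(plus$V2, 3L)
  expect_equal(plus$V3, 4L)
  expect_equal(plus$V4, 0.25)
})

test_that("conversion-rate QC passes inside 25-40% and warns outside", {
  expect_identical(qc_conversion_rate(uniform_track(1:50, 0.30))$status,
                   "pass")
  expect_identical(qc_conversion_rate(uniform_track(1:50, 0.45))$status,
                   "warn")
  expect_identical(qc_conversion_rate(uniform_track(1:50, 0.10))$status,
                   "warn")
  expect_error(qc_conversion_rate(conversion_track(
    data.frame(chrom = character(0), pos = integer(0),
               strand = character(0), n_conv = integer(0),
               n_total = integer(0)))), "empty")
})

test_that("plus and minus strand global rates agree on symmetric naked simulations", {
  cfg <- sim_config(length = 50000L,
                    enzyme = list(p_open = 0.4, p_protected = 0.05),
                    molecules = list(n_molecules = 5000L))
  ref <- simulate_reference(cfg, 51)
  tr <- extract_conversion_track(simulate_molecules(cfg, ref, 52,
                                                    naked = TRUE)$alignments,
                                 ref)
  by_strand <- tapply(seq_len(nrow(tr)), tr$strand, function(i) {
    c(x = sum(tr$n_conv[i]), n = sum(tr$n_total[i]))
  })
  rp <- by_strand[["+"]]; rm <- by_strand[["-"]]
  p_hat <- (rp[["x"]] + rm[["x"]]) / (rp[["n"]] + rm[["n"]])
  se <- sqrt(p_hat * (1 - p_hat) * (1 / rp[["n"]] + 1 / rm[["n"]]))
  expect_lt(abs(rp[["x"]] / rp[["n"]] - rm[["x"]] / rm[["n"]]), 3 * se)
})
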