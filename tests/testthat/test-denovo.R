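# De novo footprint detection: backgrounds, the binomial region strategy,
# the motif-score strategy, annotation and differential binding.

test_that("local background is the ring mean and flags edges", {
  tr <- uniform_track(0:500, rate = 0.4)
  iv <- list(chrom = "chrT", start = 240L, end = 260L)
  bg <- local_background_rate(tr, iv, span = 100L)
  expect_equal(bg$rate, 0.4)
  expect_false(bg$one_sided)
  # interval inside a hot peak: local exceeds the track-wide mean
  rates <- rep(0.3, 501)
  rates[200:300] <- 0.8
  hot <- rate_track(0:500, rates)
  bg_hot <- local_background_rate(hot, iv, span = 50L)
  expect_gt(bg_hot$rate, mean(hot$rate))
  # contig edge: one-sided background
  edge <- local_background_rate(tr, list(chrom = "chrT", start = 10L,
                                         end = 30L), span = 100L)
  expect_true(edge$one_sided)
  expect_error(local_background_rate(tr, iv, span = 10L), "span")
})

test_that("deep depletion is called and a uniform region is not", {
  pos <- 0:600
  rates <- rep(0.5, length(pos))
  rates[300:311] <- 0.02
  tr <- conversion_track(data.frame(
    chrom = "chrT", pos = pos, strand = "+",
    n_conv = as.integer(round(rates * 100)), n_total = 100L,
    context = "ACA"), min_cov_rate = 1L)
  regions <- data.frame(chrom = "chrT", start = 0L, end = 601L)
  calls <- detect_footprint_regions(tr, regions)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$start - 300L), 4L)
  expect_lt(abs(calls$end - 312L), 4L)
  expect_gt(calls$depth_score, 0.4)
  uni <- uniform_track(pos, rate = 0.5)
  expect_equal(nrow(detect_footprint_regions(uni, regions)), 0L)
})

test_that("the binomial test controls the window-level false call rate under the null", {
  n_called <- 0L
  n_windows <- 0L
  for (rep_ in 1:8) {
    cfg <- sim_config(length = 3000L, enzyme = list(p_open = 0.5),
                      molecules = list(n_molecules = 600L,
                                       frag_len = 150L))
    ref <- simulate_reference(cfg, 200 + rep_)
    tr <- extract_conversion_track(
      simulate_molecules(cfg, ref, 300 + rep_, naked = TRUE)$alignments,
      ref)
    calls <- detect_footprint_regions(
      tr, data.frame(chrom = cfg$contig, start = 200L, end = 2800L),
      keep_windows = TRUE)
    w <- attr(calls, "windows")
    n_windows <- n_windows + nrow(w)
    n_called <- n_called + sum(w$q < 0.05)
  }
  expect_gt(n_windows, 10000L)
  mc_err <- sqrt(0.05 * 0.95 / n_windows)
  expect_lte(n_called / n_windows, 0.05 + 2 * mc_err)
})

test_that("planted footprints are recovered with tight boundaries", {
  fx <- footprint_sim(n_ocr = 6L, theta = 0.9, seed = 210,
                      n_molecules = 2000L)
  tr <- extract_conversion_track(fx$sim$alignments, fx$ref)
  calls <- detect_footprint_regions(tr, cbind(chrom = fx$cfg$contig,
                                              fx$ocr[1:2]))
  tru <- fx$truth_intervals
  hit <- vapply(seq_len(nrow(tru)), function(i) {
    ov <- calls$start < tru$end[i] & calls$end > tru$start[i]
    if (!any(ov)) return(c(rec = 0, berr = NA_real_))
    j <- which(ov)[1]
    c(rec = 1, berr = max(abs(calls$start[j] - tru$start[i]),
                          abs(calls$end[j] - tru$end[i])))
  }, numeric(2))
  expect_gte(mean(hit["rec", ]), 0.9)
  expect_lte(mean(hit["berr", ], na.rm = TRUE), 3)
})

test_that("BH correction matches the brute-force oracle exactly", {
  set.seed(220)
  p <- runif(1000)^2
  expect_equal(p.adjust(p, method = "BH"), bh_brute_force(p))
  p_small <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(p.adjust(p_small, method = "BH"), bh_brute_force(p_small))
})

test_that("motif-score strategy separates bound from unbound occurrences", {
  # 12 OCRs with the same planted consensus; half bound, half unbound
  n_ocr <- 12L
  ocr <- data.frame(start = (seq_len(n_ocr) - 1L) * 2000L + 500L,
                    end = (seq_len(n_ocr) - 1L) * 2000L + 1500L)
  cons <- "CCGGTACGGTCC"
  theta <- rep(c(0.9, 0), each = n_ocr / 2L)
  sites <- data.frame(name = sprintf("S%d", seq_len(n_ocr)),
                      consensus = cons,
                      pos = as.integer(ocr$start + 494L), strand = "+",
                      theta = theta, pad = 0L)
  cfg <- sim_config(length = n_ocr * 2000L, ocrs = ocr, tf_sites = sites,
                    molecules = list(n_molecules = 1500L, regions = ocr))
  ref <- simulate_reference(cfg, 230)
  tr <- extract_conversion_track(simulate_molecules(cfg, ref,
                                                    231)$alignments, ref)
  m <- motif_model("CONS", consensus_counts(cons))
  regions <- cbind(chrom = cfg$contig, ocr)
  cand <- scan_motifs(ref, m, regions, pvalue = 1e-4)
  expect_gte(nrow(cand), n_ocr)  # every plant recovered
  set.seed(232)
  scored <- footprint_scan_scores(tr, cand, regions, n_null = 300L)
  scored <- scored[scored$start %in% sites$pos & scored$valid, ]
  lab <- theta[match(scored$start, sites$pos)] > 0
  expect_gte(rank_auc(scored$footprint_score[lab],
                      scored$footprint_score[!lab]), 0.9)
  # bound occurrences reach significance, unbound do not
  expect_true(all(scored$q_value[lab] < 0.05))
  expect_true(mean(scored$q_value[!lab] >= 0.05) >= 0.8)
})

test_that("shuffling the track destroys motif-score significance", {
  fx <- footprint_sim(n_ocr = 6L, theta = 0.9, seed = 240,
                      n_molecules = 1200L)
  tr <- extract_conversion_track(fx$sim$alignments, fx$ref)
  regions <- cbind(chrom = fx$cfg$contig, fx$ocr[, 1:2])
  cand <- data.table::data.table(
    chrom = fx$cfg$contig, start = fx$sites$pos,
    end = fx$sites$pos + nchar(fx$sites$consensus[1]), strand = "+",
    motif_id = "CONS", tf = "CONS", score = 10)
  set.seed(241)
  scored <- footprint_scan_scores(tr, cand, regions, n_null = 300L)
  called <- scored[scored$valid & scored$q_value < 0.05, ]
  expect_gte(nrow(called), 5L)
  # permute rates across positions within the track
  shuf <- data.table::copy(tr)
  set.seed(242)
  perm <- sample.int(nrow(shuf))
  shuf$rate <- shuf$rate[perm]
  set.seed(243)
  reshuffled <- footprint_scan_scores(shuf, cand, regions, n_null = 300L)
  expect_gte(mean(reshuffled$q_value[reshuffled$valid] >= 0.05,
                  na.rm = TRUE), 0.95)
})

test_that("local background mode beats global on heterogeneous openness", {
  # half the OCRs are fully open, half mostly closed: a global background
  # misreads closed-OCR motifs as depleted
  n_ocr <- 16L
  ocr <- data.frame(start = (seq_len(n_ocr) - 1L) * 2000L + 500L,
                    end = (seq_len(n_ocr) - 1L) * 2000L + 1500L,
                    openness = rep(c(1, 0.35), each = n_ocr / 2L))
  cons <- "CCGGTACGGTCC"
  theta <- rep(c(0.9, 0), times = n_ocr / 2L)  # alternate bound/unbound
  sites <- data.frame(name = sprintf("S%d", seq_len(n_ocr)),
                      consensus = cons,
                      pos = as.integer(ocr$start + 494L), strand = "+",
                      theta = theta, pad = 0L)
  cfg <- sim_config(length = n_ocr * 2000L, ocrs = ocr, tf_sites = sites,
                    molecules = list(n_molecules = 1000L, regions = ocr))
  ref <- simulate_reference(cfg, 250)
  tr <- extract_conversion_track(simulate_molecules(cfg, ref,
                                                    251)$alignments, ref)
  regions <- cbind(chrom = cfg$contig, ocr[, 1:2])
  cand <- data.table::data.table(
    chrom = cfg$contig, start = sites$pos,
    end = sites$pos + nchar(cons), strand = "+", motif_id = "CONS",
    tf = "CONS", score = 10)
  auc_for <- function(mode, seed) {
    set.seed(seed)
    sc <- footprint_scan_scores(tr, cand, regions, background = mode,
                                n_null = 200L)
    sc <- sc[sc$valid, ]
    lab <- theta[match(sc$start, sites$pos)] > 0
    rank_auc(sc$footprint_score[lab], sc$footprint_score[!lab])
  }
  expect_gte(auc_for("local", 252), auc_for("global", 253))
})

test_that("footprint annotation labels matches and reports density", {
  fp <- data.frame(chrom = "chrT", start = c(100L, 500L),
                   end = c(115L, 512L))
  motifs <- data.frame(chrom = "chrT", start = 102L, end = 112L,
                       strand = "+", motif_id = "M1", tf = "M1",
                       score = 5)
  ann <- annotate_footprints(fp, motifs,
                             regions = data.frame(chrom = "chrT",
                                                  start = 0L, end = 800L))
  expect_identical(ann$annotated$matched, c(TRUE, FALSE))
  expect_identical(ann$annotated$matched_motifs[1], "M1")
  expect_equal(ann$matched_fraction, 0.5)
  expect_equal(ann$density_per_200bp, 2 / 4)
  # a motif overlapping less than half its length does not match
  ann2 <- annotate_footprints(data.frame(chrom = "chrT", start = 108L,
                                         end = 130L), motifs)
  expect_false(ann2$annotated$matched)
})

test_that("annotation recovers the planted matched fraction on simulation", {
  # 30% of footprints come from motif-free protein blocks
  set.seed(260)
  n <- 200L
  starts <- sort(sample.int(100000L, n)) * 3L
  fp <- data.frame(chrom = "chrT", start = starts, end = starts + 14L)
  has_motif <- runif(n) > 0.3
  motifs <- data.frame(chrom = "chrT", start = fp$start[has_motif] + 2L,
                       end = fp$start[has_motif] + 12L, strand = "+",
                       motif_id = "M1", tf = "M1", score = 5)
  ann <- annotate_footprints(fp, motifs)
  expect_equal(ann$matched_fraction, mean(has_motif), tolerance = 0.02)
})

test_that("differential binding is null on identical inputs and antisymmetric on swap", {
  set.seed(270)
  n <- 300L
  sc <- data.table::data.table(
    chrom = "chrT", start = seq_len(n) * 100L,
    end = seq_len(n) * 100L + 10L, strand = "+",
    motif_id = sample(sprintf("M%d", 1:5), n, replace = TRUE),
    tf = "x", score = 1, footprint_score = rnorm(n, 0.3, 0.05),
    p_value = 0.5, q_value = 0.5, valid = TRUE, reason = "")
  set.seed(271)
  same <- differential_binding(sc, sc, n_perm = 2000L)
  expect_true(all(same$differential_score == 0))
  expect_true(all(same$q_value > 0.9))
  sc_b <- data.table::copy(sc)
  set.seed(272)
  sc_b$footprint_score <- sc$footprint_score + rnorm(n, 0, 0.02)
  set.seed(273)
  ab <- differential_binding(sc, sc_b, n_perm = 2000L)
  set.seed(273)
  ba <- differential_binding(sc_b, sc, n_perm = 2000L)
  ab <- ab[order(ab$cluster), ]
  ba <- ba[order(ba$cluster), ]
  expect_equal(ab$differential_score, -ba$differential_score)
})

test_that("a spiked occupancy loss is the top negative differential hit", {
  set.seed(280)
  n_per <- 80L
  clusters <- sprintf("C%d", 1:8)
  mk <- function(spike) {
    data.table::rbindlist(lapply(clusters, function(cl) {
      mu <- if (cl == "C3" && spike) 0.06 else 0.35
      data.table::data.table(
        chrom = "chrT",
        start = seq_len(n_per) * 1000L + match(cl, clusters),
        end = seq_len(n_per) * 1000L + match(cl, clusters) + 12L,
        strand = "+", motif_id = cl, tf = cl, score = 1,
        footprint_score = rnorm(n_per, mu, 0.05), p_value = 0.5,
        q_value = 0.5, valid = TRUE, reason = "")
    }))
  }
  a <- mk(spike = FALSE)
  b <- mk(spike = TRUE)
  b$footprint_score[b$motif_id != "C3"] <-
    a$footprint_score[a$motif_id != "C3"] + rnorm(7L * n_per, 0, 0.02)
  set.seed(281)
  res <- differential_binding(a, b, n_perm = 5000L)
  neg <- res[order(res$differential_score), ]
  expect_identical(neg$cluster[1], "C3")
  expect_lt(neg$q_value[1], 0.05)
  others <- res[res$cluster != "C3", ]
  expect_gte(mean(others$q_value >= 0.05), 0.95)
})
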