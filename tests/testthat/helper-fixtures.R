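# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except files the tests write themselves.

# track with a uniform conversion rate at every listed position
uniform_track <- function(positions, rate = 0.3, cov = 100L,
                          chrom = "chrT", strand = "+") {
  conversion_track(data.frame(
    chrom = chrom, pos = positions, strand = strand,
    n_conv = as.integer(round(rate * cov)), n_total = cov,
    context = "ACA"), min_cov_rate = 1L)
}

# track with explicit per-position rates
rate_track <- function(positions, rates, cov = 100L, chrom = "chrT",
                       strand = "+", context = "ACA") {
  conversion_track(data.frame(
    chrom = chrom, pos = positions, strand = strand,
    n_conv = as.integer(round(rates * cov)), n_total = cov,
    context = context), min_cov_rate = 1L)
}

# one-OCR, one-TF-site simulation used by several modules; the footprint
# covers the motif exactly (pad 0) so closed-form expectations hold
site_sim <- function(theta, seed, n_molecules = 2000L, p_open = 0.6,
                     p_protected = 0.05, openness = 1) {
  cfg <- sim_config(
    length = 20000L,
    ocrs = data.frame(start = 5000L, end = 7000L, openness = openness),
    tf_sites = data.frame(name = "TF1", consensus = "TGCCACCTGGTGGCA",
                          pos = 5990L, strand = "+", theta = theta,
                          pad = 0L),
    enzyme = list(p_open = p_open, p_protected = p_protected),
    molecules = list(n_molecules = n_molecules,
                     regions = data.frame(start = 5600L, end = 6400L)))
  ref <- simulate_reference(cfg, seed)
  sim <- simulate_molecules(cfg, ref, seed + 1L)
  list(cfg = cfg, ref = ref, sim = sim,
       site = data.frame(chrom = cfg$contig, start = 5990L, end = 6005L,
                         strand = "+", name = "TF1", tf = "TF1"))
}

# multi-OCR simulation with one planted footprint per OCR; the footprint
# is the planted consensus (width 12 by default), protected with
# per-molecule probability theta
footprint_sim <- function(n_ocr, theta, seed, n_molecules = 2000L,
                          consensus = "CCGGTACGGTCC", p_open = 0.6,
                          openness = 1) {
  ocr <- data.frame(start = (seq_len(n_ocr) - 1L) * 2000L + 500L,
                    end = (seq_len(n_ocr) - 1L) * 2000L + 1500L,
                    openness = openness)
  w <- nchar(consensus)
  sites <- data.frame(name = sprintf("FP%d", seq_len(n_ocr)),
                      consensus = consensus,
                      pos = as.integer(ocr$start + 500L - w %/% 2L),
                      strand = "+", theta = theta, pad = 0L)
  cfg <- sim_config(length = n_ocr * 2000L, ocrs = ocr, tf_sites = sites,
                    enzyme = list(p_open = p_open, p_protected = 0.05),
                    molecules = list(n_molecules = n_molecules,
                                     regions = ocr))
  ref <- simulate_reference(cfg, seed)
  sim <- simulate_molecules(cfg, ref, seed + 1L)
  list(cfg = cfg, ref = ref, sim = sim, ocr = ocr, sites = sites,
       truth_intervals = data.frame(chrom = cfg$contig,
                                    start = sites$pos,
                                    end = sites$pos + w))
}

# 4 x L count matrix putting all weight on a consensus sequence
consensus_counts <- function(cons, weight = 10) {
  L <- nchar(cons)
  m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) m[substring(cons, j, j), j] <- weight
  m
}

# rank-based AUC for scores of positives vs negatives
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# brute-force Benjamini-Hochberg used as the oracle against p.adjust
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}
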