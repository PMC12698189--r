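# De novo footprint detection inside open chromatin. Two strategies:
# S1 scores every motif occurrence (FOS against a local background ring)
# and calibrates significance on a positional null drawn from the same
# search regions; S2 slides a window over the track, calls conversion-
# depleted windows by a one-sided binomial test with BH correction, merges
# them into footprint regions and leaves motif scanning to the caller.

#' Local background conversion rate around an interval
#'
#' Mean track rate over `span` bp on each side of `[start, end)`, the
#' interval itself excluded. Global mode callers substitute the search-
#' region-wide mean instead. One-sided backgrounds at contig edges are
#' flagged.
#'
#' @param track A conversion track.
#' @param interval List or single-row `data.frame` with `chrom, start, end`.
#' @param span Background half-width in bp (must exceed the interval width).
#' @return List: `rate` (`NA` when no informative cytosine), `n_c`,
#'   `one_sided`.
#' @export
local_background_rate <- function(track, interval, span = 200L) {
  if (span <= interval$end - interval$start)
    stop_ft("background span must exceed the interval width")
  index <- .track_index(track)
  lf <- .interval_rate(index, interval$chrom,
                       max(interval$start - span, 0L), interval$start)
  rf <- .interval_rate(index, interval$chrom, interval$end,
                       interval$end + span)
  n <- lf[["n"]] + rf[["n"]]
  rate <- if (n > 0) {
    (ifelse(lf[["n"]] > 0, lf[["rate"]] * lf[["n"]], 0) +
       ifelse(rf[["n"]] > 0, rf[["rate"]] * rf[["n"]], 0)) / n
  } else NA_real_
  list(rate = rate, n_c = as.integer(n),
       one_sided = interval$start - span < 0 || lf[["n"]] == 0 ||
         rf[["n"]] == 0)
}

#' Detect footprint regions by binomial depletion test (strategy S2)
#'
#' Slides a `window` bp window (step 1) across each search region. Per
#' window, the summed read counts over its cytosines (`n` total, `x`
#' converted) are tested one-sided against the background rate `p0`
#' (Binomial(n, p0), lower tail); BH correction runs across all windows.
#' Significant windows (q < `alpha`) are merged (gap <= `merge_gap`),
#' trimmed to the span of their individually depleted cytosines, and
#' reported with `depth_score = p0 - x/n`.
#'
#' @param track A conversion track (bias-corrected counts are not altered;
#'   the test uses raw `n_conv`/`n_total`, the background uses the track
#'   `rate`).
#' @param regions Search space `data.frame(chrom, start, end)` (e.g. OCRs).
#' @param window Window width in bp (default 15).
#' @param min_c Minimum informative cytosines per window (default 3).
#' @param background `"local"` (ring of `span` bp, falling back to global
#'   when undefined) or `"global"` (region-wide rate).
#' @param span Local background half-width.
#' @param alpha BH q-value cutoff.
#' @param min_width Minimum footprint width after trimming (default 6).
#' @param merge_gap Maximum gap between significant windows to merge
#'   (default 5).
#' @param trim_alpha Per-cytosine binomial p-value used when trimming a
#'   merged region to its depleted cytosines (default 0.01; footprint
#'   cytosines at realistic coverage are orders of magnitude below this,
#'   while a stricter cut stops chance dips in open flanking cytosines
#'   from stretching the call).
#' @param keep_windows If `TRUE`, attach the per-window test table
#'   (`chrom, wstart, n, x, p0, p, q`) as attribute `"windows"`.
#' @return `data.table(chrom, start, end, width, depth_score, p_value,
#'   q_value, n, x, p0, background_mode)`.
#' @export
detect_footprint_regions <- function(track, regions, window = 15L,
                                     min_c = 3L, background = c("local",
                                                                "global"),
                                     span = 200L, alpha = 0.05,
                                     min_width = 6L, merge_gap = 5L,
                                     trim_alpha = 0.01,
                                     keep_windows = FALSE) {
  background <- match.arg(background)
  regions <- data.table::as.data.table(regions)
  win_list <- list()
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]
    rs <- regions$start[r]; re <- regions$end[r]
    rec <- track[track$chrom == ch & track$pos >= rs & track$pos < re &
                   !is.na(track$rate), ]
    if (!nrow(rec)) {
      warn_ft("region %s:%d-%d has no informative cytosines; skipped",
              ch, rs, re)
      next
    }
    data.table::setorder(rec, pos)
    pos <- rec$pos
    cum_n <- c(0, cumsum(rec$n_total))
    cum_x <- c(0, cumsum(rec$n_conv))
    cum_r <- c(0, cumsum(rec$rate))
    global_p0 <- sum(rec$rate * rec$n_total) / sum(rec$n_total)
    ws <- rs:(re - window)
    if (!length(ws) || ws[1] > re - window) next
    lo <- findInterval(ws - 0.5, pos)
    hi <- findInterval(ws + window - 0.5, pos)
    nc <- hi - lo
    n <- cum_n[hi + 1L] - cum_n[lo + 1L]
    x <- cum_x[hi + 1L] - cum_x[lo + 1L]
    if (background == "local") {
      olo <- findInterval(ws - span - 0.5, pos)
      ohi <- findInterval(ws + window + span - 0.5, pos)
      bg_n <- (ohi - olo) - nc
      bg_sum <- (cum_r[ohi + 1L] - cum_r[olo + 1L]) -
        (cum_r[hi + 1L] - cum_r[lo + 1L])
      p0 <- ifelse(bg_n > 0, bg_sum / bg_n, global_p0)
    } else {
      p0 <- rep(global_p0, length(ws))
    }
    ok <- nc >= min_c & n > 0 & !is.na(p0) & p0 > 0 & p0 < 1
    if (!any(ok)) next
    win_list[[length(win_list) + 1L]] <- data.table::data.table(
      chrom = ch, wstart = ws[ok], n = n[ok], x = x[ok], p0 = p0[ok],
      region = r)
  }
  empty <- data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), width = integer(0),
                                  depth_score = numeric(0),
                                  p_value = numeric(0), q_value = numeric(0),
                                  n = integer(0), x = integer(0),
                                  p0 = numeric(0),
                                  background_mode = character(0))
  finish <- function(out, wins) {
    if (keep_windows) data.table::setattr(out, "windows", wins)
    out
  }
  if (!length(win_list)) return(finish(empty, NULL))
  wins <- data.table::rbindlist(win_list)
  wins$p <- stats::pbinom(wins$x, wins$n, wins$p0)
  wins$q <- stats::p.adjust(wins$p, method = "BH")
  sig <- wins[wins$q < alpha, ]
  if (!nrow(sig)) return(finish(empty, wins))

  calls <- list()
  for (ch in unique(sig$chrom)) {
    sub <- sig[sig$chrom == ch, ]
    merged <- IRanges::reduce(IRanges::IRanges(sub$wstart + 1L,
                                               sub$wstart + window),
                              min.gapwidth = merge_gap + 1L)
    rec <- track[track$chrom == ch & !is.na(track$rate), ]
    data.table::setorder(rec, pos)
    for (i in seq_along(merged)) {
      ms <- IRanges::start(merged)[i] - 1L
      me <- IRanges::end(merged)[i]
      inw <- sub$wstart >= ms & sub$wstart + window <= me
      p0 <- stats::weighted.mean(sub$p0[inw], sub$n[inw])
      cyt <- rec[rec$pos >= ms & rec$pos < me, ]
      if (!nrow(cyt)) next
      cp <- stats::pbinom(cyt$n_conv, cyt$n_total, p0)
      sig_c <- cyt$pos[cp < trim_alpha]
      if (!length(sig_c)) next
      fs <- min(sig_c); fe <- max(sig_c) + 1L
      if (fe - fs < min_width) next
      fc <- cyt[cyt$pos >= fs & cyt$pos < fe, ]
      n <- sum(fc$n_total); x <- sum(fc$n_conv)
      calls[[length(calls) + 1L]] <- data.table::data.table(
        chrom = ch, start = fs, end = fe, width = fe - fs,
        depth_score = p0 - x / n,
        p_value = max(stats::pbinom(x, n, p0), .Machine$double.xmin),
        q_value = min(sub$q[inw]),
        n = n, x = x, p0 = p0, background_mode = background)
    }
  }
  if (!length(calls)) return(finish(empty, wins))
  out <- data.table::rbindlist(calls)
  data.table::setorder(out, chrom, start)
  finish(out[], wins)
}

#' Score candidate motif sites against a positional null (strategy S1)
#'
#' Each candidate site gets a footprint score: the local background ring
#' rate minus the motif-interval rate (i.e. FOS with the background ring as
#' flank). The null distribution is built per motif from random positions
#' of the same length drawn within the same search regions, preserving the
#' rate composition of the searched open chromatin. p-values are rank-based
#' tail probabilities, BH-corrected within each motif.
#'
#' @param track A conversion track.
#' @param candidate_sites Sites from [scan_motifs()].
#' @param regions Search regions the sites came from.
#' @param background `"local"` or `"global"`.
#' @param span Background ring half-width.
#' @param n_null Null draws per motif (default 1000).
#' @param min_null Minimum valid null draws; fewer aborts that motif.
#' @param min_c Minimum informative cytosines on each side.
#' @return `data.table`: candidate sites plus `footprint_score, p_value,
#'   q_value, valid, reason`.
#' @export
footprint_scan_scores <- function(track, candidate_sites, regions,
                                  background = c("local", "global"),
                                  span = 200L, n_null = 1000L,
                                  min_null = 100L, min_c = 2L) {
  background <- match.arg(background)
  sites <- data.table::as.data.table(candidate_sites)
  if (!nrow(sites)) stop_ft("no candidate sites supplied")
  regions <- data.table::as.data.table(regions)
  index <- .track_index(track)
  reg_rate <- {
    tot <- 0; cnt <- 0
    for (r in seq_len(nrow(regions))) {
      v <- .interval_rate(index, regions$chrom[r], regions$start[r],
                          regions$end[r])
      if (v[["n"]] > 0) {
        tot <- tot + v[["rate"]] * v[["n"]]; cnt <- cnt + v[["n"]]
      }
    }
    if (cnt > 0) tot / cnt else NA_real_
  }

  score_one <- function(ch, s, e) {
    m <- .interval_rate(index, ch, s, e)
    if (background == "local") {
      lf <- .interval_rate(index, ch, max(s - span, 0L), s)
      rf <- .interval_rate(index, ch, e, e + span)
      bgn <- lf[["n"]] + rf[["n"]]
      bgr <- if (bgn > 0) {
        (ifelse(lf[["n"]] > 0, lf[["rate"]] * lf[["n"]], 0) +
           ifelse(rf[["n"]] > 0, rf[["rate"]] * rf[["n"]], 0)) / bgn
      } else NA_real_
      if (is.na(bgr)) { bgr <- reg_rate; bgn <- min_c }
    } else {
      bgr <- reg_rate; bgn <- min_c
    }
    c(score = bgr - m[["rate"]], ok = as.numeric(
      m[["n"]] >= min_c && bgn >= min_c && !is.na(bgr) && !is.na(m[["rate"]])))
  }

  out <- data.table::copy(sites)
  out$footprint_score <- NA_real_
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  out$valid <- FALSE
  out$reason <- ""
  widths <- regions$end - regions$start
  for (mid in unique(out$motif_id)) {
    rows <- which(out$motif_id == mid)
    L <- out$end[rows[1]] - out$start[rows[1]]
    obs <- t(vapply(rows, function(i) {
      score_one(out$chrom[i], out$start[i], out$end[i])
    }, numeric(2)))
    out$footprint_score[rows] <- obs[, 1]
    out$valid[rows] <- obs[, 2] > 0
    out$reason[rows] <- ifelse(out$valid[rows], "", "too_few_cytosines")
    # positional null: same-length windows at random positions in regions
    ridx <- sample.int(nrow(regions), n_null, replace = TRUE,
                       prob = pmax(widths - L, 0))
    offs <- floor(stats::runif(n_null) * pmax(widths[ridx] - L, 1))
    null_scores <- vapply(seq_len(n_null), function(j) {
      s <- regions$start[ridx[j]] + offs[j]
      v <- score_one(regions$chrom[ridx[j]], s, s + L)
      if (v[["ok"]] > 0) v[["score"]] else NA_real_
    }, numeric(1))
    null_scores <- null_scores[!is.na(null_scores)]
    if (length(null_scores) < min_null) {
      out$valid[rows] <- FALSE
      out$reason[rows] <- "too_few_valid_null_draws"
      next
    }
    vr <- rows[out$valid[rows]]
    if (length(vr)) {
      p <- vapply(out$footprint_score[vr], function(s) {
        (1 + sum(null_scores >= s)) / (1 + length(null_scores))
      }, numeric(1))
      out$p_value[vr] <- p
      out$q_value[vr] <- stats::p.adjust(p, method = "BH")
    }
  }
  out[]
}

#' Annotate footprints with motif matches and report density
#'
#' A footprint is `matched` when at least one motif site overlaps it by at
#' least `min_frac` of the motif length. Footprint density is reported per
#' 200 bp of searched region, using both the full region length and (when a
#' track is given) only the bp covered by informative cytosines as
#' denominators.
#'
#' @param footprints Calls from [detect_footprint_regions()] (or any
#'   `chrom, start, end` table).
#' @param motif_sites Sites from [scan_motifs()].
#' @param regions Optional searched regions for the density denominator.
#' @param track Optional track for the covered-bp denominator.
#' @param min_frac Minimum overlap as a fraction of motif length.
#' @return List: `annotated` (footprints plus `matched`, `matched_motifs`),
#'   `matched_fraction`, `density_per_200bp`, `density_per_200bp_covered`,
#'   `width_by_class`.
#' @export
annotate_footprints <- function(footprints, motif_sites, regions = NULL,
                                track = NULL, min_frac = 0.5) {
  fp <- data.table::as.data.table(footprints)
  ms <- data.table::as.data.table(motif_sites)
  matched <- rep(FALSE, nrow(fp))
  matched_motifs <- rep("", nrow(fp))
  if (nrow(fp) && nrow(ms)) {
    fgr <- GenomicRanges::GRanges(fp$chrom,
                                  IRanges::IRanges(fp$start + 1L, fp$end))
    mgr <- GenomicRanges::GRanges(ms$chrom,
                                  IRanges::IRanges(ms$start + 1L, ms$end))
    hit <- GenomicRanges::findOverlaps(fgr, mgr)
    if (length(hit)) {
      ow <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(fgr)[S4Vectors::queryHits(hit)],
        IRanges::ranges(mgr)[S4Vectors::subjectHits(hit)]))
      mlen <- ms$end[S4Vectors::subjectHits(hit)] -
        ms$start[S4Vectors::subjectHits(hit)]
      good <- ow >= min_frac * mlen
      if (any(good)) {
        qh <- S4Vectors::queryHits(hit)[good]
        sh <- S4Vectors::subjectHits(hit)[good]
        matched[unique(qh)] <- TRUE
        agg <- tapply(ms$motif_id[sh], qh, function(x) {
          paste(unique(x), collapse = ",")
        })
        matched_motifs[as.integer(names(agg))] <- as.character(agg)
      }
    }
  }
  fp$matched <- matched
  fp$matched_motifs <- matched_motifs
  dens <- dens_cov <- NA_real_
  if (!is.null(regions) && nrow(fp)) {
    regions <- data.table::as.data.table(regions)
    bp <- sum(regions$end - regions$start)
    dens <- nrow(fp) / (bp / 200)
    if (!is.null(track)) {
      cov_bp <- 0
      for (r in seq_len(nrow(regions))) {
        cov_bp <- cov_bp + length(unique(track$pos[
          track$chrom == regions$chrom[r] &
            track$pos >= regions$start[r] & track$pos < regions$end[r]]))
      }
      dens_cov <- if (cov_bp > 0) nrow(fp) / (cov_bp / 200) else NA_real_
    }
  }
  width <- fp$end - fp$start
  list(annotated = fp[],
       matched_fraction = if (nrow(fp)) mean(fp$matched) else NA_real_,
       density_per_200bp = dens,
       density_per_200bp_covered = dens_cov,
       width_by_class = if (nrow(fp)) {
         fp[, list(n = .N, mean_width = mean(end - start),
                   median_width = stats::median(end - start)),
            by = "matched"]
       } else NULL)
}

#' Differential TF binding between two conditions
#'
#' Site footprint scores from the two conditions (same candidate-site
#' universe) are quantile-normalized across conditions; per motif cluster
#' the differential score is the mean normalized score in `b` minus `a`.
#' Significance comes from a size-matched permutation null: repeatedly
#' drawing random site subsets from all clusters and recomputing the mean
#' per-site difference, giving a z-score and two-sided normal p, BH-
#' corrected across clusters.
#'
#' @param scored_a,scored_b Outputs of [footprint_scan_scores()] on the two
#'   conditions (matched row-for-row by site).
#' @param clusters `data.frame(motif_id, cluster)` grouping motifs; motifs
#'   absent from the table form singleton clusters.
#' @param n_perm Permutation draws (default 10000).
#' @param min_sites Clusters below this site count are flagged
#'   `underpowered`.
#' @return `data.table(cluster, n_sites, score_a, score_b,
#'   differential_score, z, p_value, q_value, direction, underpowered)`.
#' @export
differential_binding <- function(scored_a, scored_b, clusters = NULL,
                                 n_perm = 10000L, min_sites = 50L) {
  a <- data.table::as.data.table(scored_a)
  b <- data.table::as.data.table(scored_b)
  key <- c("chrom", "start", "end", "strand", "motif_id")
  m <- merge(a[a$valid == TRUE, c(key, "footprint_score"), with = FALSE],
             b[b$valid == TRUE, c(key, "footprint_score"), with = FALSE],
             by = key, suffixes = c("_a", "_b"))
  if (!nrow(m)) stop_ft("no shared valid sites between conditions")
  qn <- limma::normalizeQuantiles(cbind(m$footprint_score_a,
                                        m$footprint_score_b))
  m$norm_a <- qn[, 1]
  m$norm_b <- qn[, 2]
  m$d <- m$norm_b - m$norm_a
  m$cluster <- m$motif_id
  if (!is.null(clusters)) {
    clusters <- data.table::as.data.table(clusters)
    idx <- match(m$motif_id, clusters$motif_id)
    m$cluster <- ifelse(is.na(idx), m$motif_id, clusters$cluster[idx])
  }
  res <- m[, list(n_sites = .N, score_a = mean(norm_a),
                  score_b = mean(norm_b),
                  differential_score = mean(d)), by = "cluster"]
  d_all <- m$d
  # centre on the median cluster shift rather than the pooled mean:
  # cross-condition quantile normalization redistributes a strong change in
  # one cluster across the others, and the median keeps the bulk of
  # unchanged clusters at z ~ 0
  centre <- stats::median(res$differential_score)
  res$z <- NA_real_
  for (nk in unique(res$n_sites)) {
    draws <- matrix(sample(d_all, n_perm * nk, replace = TRUE), nrow = n_perm)
    mu <- rowMeans(draws)
    rows <- which(res$n_sites == nk)
    sd0 <- stats::sd(mu)
    res$z[rows] <- if (sd0 > 0) {
      (res$differential_score[rows] - centre) / sd0
    } else 0
  }
  res$p_value <- 2 * stats::pnorm(-abs(res$z))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(res$differential_score > 0, "up",
                          ifelse(res$differential_score < 0, "down", "none"))
  res$underpowered <- res$n_sites < min_sites
  data.table::setorder(res, p_value)
  res[]
}

#' Cluster motifs by PFM similarity
#'
#' Pairwise similarity is the best Pearson correlation of flattened,
#' column-aligned PFMs over all ungapped offsets (forward and reverse
#' complement); motifs join one cluster when their similarity reaches
#' `cor_min` (single linkage).
#'
#' @param motifs Named list of `motif_model`s.
#' @param cor_min Similarity threshold (default 0.8).
#' @return `data.table(motif_id, cluster)`.
#' @export
cluster_motifs <- function(motifs, cor_min = 0.8) {
  n <- length(motifs)
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  best_cor <- function(p1, p2) {
    if (ncol(p1) < ncol(p2)) { tmp <- p1; p1 <- p2; p2 <- tmp }
    L1 <- ncol(p1); L2 <- ncol(p2)
    best <- -1
    p2rc <- p2[4:1, L2:1, drop = FALSE]
    for (mat in list(p2, p2rc)) {
      for (off in 0:(L1 - L2)) {
        v1 <- as.vector(p1[, (off + 1):(off + L2)])
        v2 <- as.vector(mat)
        if (stats::sd(v1) > 0 && stats::sd(v2) > 0)
          best <- max(best, stats::cor(v1, v2))
      }
    }
    best
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (best_cor(motifs[[i]]$pfm, motifs[[j]]$pfm) >= cor_min) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  data.table::data.table(motif_id = ids, cluster = ids[root])
}
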