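# Occupancy quantification at known binding sites. The footprint occupancy
# score (FOS) of a site is the mean conversion rate over the two 50 bp
# flanks minus the mean rate over the motif itself; the TF occupancy score
# (TFOS) is the mean FOS over a TF's sites. All rates come from the track's
# `rate` column, i.e. bias-corrected when the track has been corrected.

# sorted per-chromosome index over track records for fast interval means;
# both strands are pooled (records keep their own rate)
.track_index <- function(track) {
  if (inherits(track, "ft_track_index")) return(track)
  idx <- lapply(split(seq_len(nrow(track)), track$chrom), function(rows) {
    pos <- track$pos[rows]
    ord <- order(pos)
    rate <- track$rate[rows][ord]
    keep <- !is.na(rate)
    pos <- pos[ord][keep]
    rate <- rate[keep]
    list(pos = pos, rate = rate, cum = c(0, cumsum(rate)))
  })
  structure(idx, class = "ft_track_index")
}

# mean rate and count of informative cytosines in [start, end) (0-based)
.interval_rate <- function(index, chrom, start, end) {
  ci <- index[[chrom]]
  if (is.null(ci) || !length(ci$pos)) return(c(rate = NA_real_, n = 0))
  lo <- findInterval(start - 0.5, ci$pos)      # records with pos >= start
  hi <- findInterval(end - 0.5, ci$pos)        # records with pos < end
  n <- hi - lo
  if (n <= 0) return(c(rate = NA_real_, n = 0))
  c(rate = (ci$cum[hi + 1L] - ci$cum[lo + 1L]) / n, n = n)
}

# vectorised over parallel start/end vectors on one chromosome
.interval_rate_vec <- function(index, chrom, start, end) {
  ci <- index[[chrom]]
  if (is.null(ci) || !length(ci$pos)) {
    return(list(rate = rep(NA_real_, length(start)),
                n = rep(0L, length(start))))
  }
  lo <- findInterval(start - 0.5, ci$pos)
  hi <- findInterval(end - 0.5, ci$pos)
  n <- hi - lo
  rate <- ifelse(n > 0, (ci$cum[hi + 1L] - ci$cum[lo + 1L]) / pmax(n, 1L),
                 NA_real_)
  list(rate = rate, n = pmax(n, 0L))
}

#' Footprint occupancy scores for a set of binding sites
#'
#' For each site, averages the track rate over the motif interval
#' `[start, end)` and over the two `flank` bp windows on either side, both
#' strands pooled, and scores `fos = flank_rate - motif_rate`. A site is
#' invalid when either side has fewer than `min_c` informative cytosines
#' (AT-rich motifs may have none) — invalid sites carry a `reason`.
#'
#' @param track A conversion track (typically bias-corrected).
#' @param sites `data.frame` with `chrom, start, end` (0-based half-open)
#'   and optional `strand, motif_id, tf, name`.
#' @param flank Flank width in bp on each side (default 50).
#' @param min_c Minimum informative cytosines per side (default 2).
#' @return `data.table` with the site columns plus `motif_rate, flank_rate,
#'   n_motif_c, n_flank_c, fos, valid, reason`.
#' @export
compute_fos <- function(track, sites, flank = 50L, min_c = 2L) {
  stopifnot(min_c >= 1L)
  sites <- data.table::as.data.table(sites)
  if (!nrow(sites)) stop_ft("no sites supplied")
  stopifnot(all(sites$end > sites$start))
  index <- .track_index(track)
  out <- data.table::copy(sites)
  out$motif_rate <- NA_real_
  out$flank_rate <- NA_real_
  out$n_motif_c <- 0L
  out$n_flank_c <- 0L
  for (ch in unique(out$chrom)) {
    rows <- which(out$chrom == ch)
    s <- out$start[rows]; e <- out$end[rows]
    m <- .interval_rate_vec(index, ch, s, e)
    lf <- .interval_rate_vec(index, ch, pmax(s - flank, 0L), s)
    rf <- .interval_rate_vec(index, ch, e, e + flank)
    nfl <- lf$n + rf$n
    fsum <- ifelse(lf$n > 0, lf$rate * lf$n, 0) +
      ifelse(rf$n > 0, rf$rate * rf$n, 0)
    out$motif_rate[rows] <- m$rate
    out$n_motif_c[rows] <- m$n
    out$flank_rate[rows] <- ifelse(nfl > 0, fsum / nfl, NA_real_)
    out$n_flank_c[rows] <- nfl
  }
  out$fos <- out$flank_rate - out$motif_rate
  out$valid <- out$n_motif_c >= min_c & out$n_flank_c >= min_c
  out$reason <- ifelse(out$valid, "",
                       ifelse(out$n_motif_c < min_c,
                              "too_few_motif_cytosines",
                              "too_few_flank_cytosines"))
  out[]
}

#' TF occupancy score from a table of FOS records
#'
#' Averages FOS over valid sites, grouped by the columns in `by` (typically
#' the TF) — giving the mean occupancy of a factor over its binding sites,
#' optionally within one region class.
#'
#' @param fos_records Output of [compute_fos()].
#' @param by Grouping columns present in `fos_records` (default `"tf"` when
#'   present, else a single pooled group).
#' @param region_label Label stored in the output (e.g. `"OCR"`).
#' @param positive_only If `TRUE`, average only sites with `fos > 0`
#'   (an alternative aggregation used when comparing against binding-signal
#'   assays); the output column `aggregation` records the choice.
#' @return `data.table(tf..., region_label, n_sites, n_invalid, tfos,
#'   positive_fraction, flank_access, aggregation)`; zero valid sites yield
#'   an empty table with attribute `exclusion_reasons`.
#' @export
compute_tfos <- function(fos_records, by = NULL, region_label = "all",
                         positive_only = FALSE) {
  fr <- data.table::as.data.table(fos_records)
  if (is.null(by)) by <- intersect("tf", names(fr))
  if (!length(by)) {
    fr$tf <- "all"
    by <- "tf"
  }
  vrec <- fr[fr$valid == TRUE, ]
  if (!nrow(vrec)) {
    reasons <- table(fr$reason)
    out <- data.table::data.table()
    data.table::setattr(out, "exclusion_reasons", reasons)
    warn_ft("no valid FOS records (%s)",
            paste(names(reasons), as.integer(reasons), collapse = ", "))
    return(out)
  }
  use <- if (positive_only) vrec[vrec$fos > 0, ] else vrec
  inv <- fr[, list(n_invalid = sum(!valid)), by = by]
  out <- use[, list(n_sites = .N, tfos = mean(fos),
                    positive_fraction = mean(fos > 0),
                    flank_access = mean(flank_rate)), by = by]
  out <- merge(out, inv, by = by, all.x = TRUE)
  out$region_label <- region_label
  out$aggregation <- if (positive_only) "positive_only" else "all_sites"
  data.table::setorderv(out, by)
  out[]
}

#' Positional conversion-rate matrix around site centres
#'
#' One row per site, columns covering `-half_window .. +half_window` around
#' the motif centre `floor((start+end)/2)`. Minus-strand sites are reversed
#' so the motif 5' end is always on the left. Positions without an
#' informative cytosine are `NA`; `colMeans(.., na.rm = TRUE)` gives the
#' average profile.
#'
#' @param track A conversion track.
#' @param sites Site table as in [compute_fos()].
#' @param half_window Half-width of the window in bp.
#' @return Numeric matrix with an attribute `positions` (relative offsets).
#' @export
profile_matrix <- function(track, sites, half_window = 500L) {
  sites <- data.table::as.data.table(sites)
  # mean rate per exact position, strands pooled
  per_pos <- track[!is.na(track$rate),
                   list(rate = mean(rate)), by = c("chrom", "pos")]
  offsets <- (-half_window):half_window
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offsets))
  for (ch in unique(sites$chrom)) {
    pp <- per_pos[per_pos$chrom == ch, ]
    lookup <- pp$rate
    names(lookup) <- as.character(pp$pos)
    rows <- which(sites$chrom == ch)
    for (i in rows) {
      centre <- (sites$start[i] + sites$end[i]) %/% 2L
      vals <- lookup[as.character(centre + offsets)]
      if (!is.null(sites$strand) && identical(sites$strand[i], "-"))
        vals <- rev(vals)
      mat[i, ] <- vals
    }
  }
  dimnames(mat) <- list(NULL, as.character(offsets))
  attr(mat, "positions") <- offsets
  mat
}

#' Flanking chromatin accessibility of a binding site
#'
#' Mean conversion rate over the two `flank` bp windows beside the motif —
#' the flank side of the FOS, exposed standalone as an accessibility
#' readout. Windows truncated at the contig start are flagged.
#'
#' @inheritParams compute_fos
#' @param site One site (single-row `data.frame` or list with `chrom,
#'   start, end`).
#' @return List: `rate`, `n_c`, `truncated`.
#' @export
flanking_accessibility <- function(track, site, flank = 50L) {
  index <- .track_index(track)
  s <- site$start; e <- site$end
  lf <- .interval_rate(index, site$chrom, max(s - flank, 0L), s)
  rf <- .interval_rate(index, site$chrom, e, e + flank)
  n <- lf[["n"]] + rf[["n"]]
  rate <- if (n > 0) {
    (ifelse(lf[["n"]] > 0, lf[["rate"]] * lf[["n"]], 0) +
       ifelse(rf[["n"]] > 0, rf[["rate"]] * rf[["n"]], 0)) / n
  } else NA_real_
  list(rate = rate, n_c = as.integer(n), truncated = s - flank < 0)
}

#' Relative change of an occupancy score between conditions
#'
#' `(treated - control) / control`, computed per TF after joining two TFOS
#' tables. TFs whose control score is unstable — below `min_score` or backed
#' by fewer than `min_sites` sites — are excluded with a reason, mirroring
#' the filtering of factors with unrobust occupancy before dynamics
#' analysis.
#'
#' @param tfos_treated,tfos_control Outputs of [compute_tfos()].
#' @param score Column to compare (`"tfos"` or `"flank_access"`).
#' @param min_score,min_sites Robustness floor on the control condition.
#' @return `data.table(tf, score_treated, score_control, change_ratio,
#'   excluded, reason)`.
#' @export
change_ratio <- function(tfos_treated, tfos_control, score = "tfos",
                         min_score = 0.02, min_sites = 200L) {
  a <- data.table::as.data.table(tfos_treated)
  b <- data.table::as.data.table(tfos_control)
  key <- intersect(intersect(names(a), names(b)),
                   c("tf", "motif_id", "region_label"))
  m <- merge(a[, c(key, score, "n_sites"), with = FALSE],
             b[, c(key, score, "n_sites"), with = FALSE],
             by = key, suffixes = c("_treated", "_control"))
  st <- m[[paste0(score, "_treated")]]
  sc <- m[[paste0(score, "_control")]]
  nc <- m$n_sites_control
  excluded <- sc < min_score | nc < min_sites
  out <- m[, key, with = FALSE]
  out$score_treated <- st
  out$score_control <- sc
  out$change_ratio <- ifelse(excluded, NA_real_, (st - sc) / sc)
  out$excluded <- excluded
  out$reason <- ifelse(!excluded, "",
                       ifelse(sc < min_score, "control_score_below_floor",
                              "too_few_control_sites"))
  out[]
}

#' Assign binding sites to labelled region classes
#'
#' A site belongs to a label when its motif centre lies inside one of the
#' label's intervals. Overlapping labels are resolved by `priority` (first
#' match wins) for the disjoint assignment; all memberships are also
#' returned in long form. Unassigned sites are labelled `"background"`.
#'
#' @param sites Site table (`chrom, start, end`, 0-based half-open).
#' @param region_sets Named list of interval `data.frame`s
#'   (`chrom, start, end`).
#' @param priority Label order for overlap resolution (default: list order).
#' @return List: `assigned` (sites plus `label`), `memberships`
#'   (`site_idx, label` long table).
#' @export
stratify_sites <- function(sites, region_sets, priority = names(region_sets)) {
  sites <- data.table::as.data.table(sites)
  centre <- (sites$start + sites$end) %/% 2L
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(centre + 1L, width = 1L))
  memberships <- list()
  for (lab in names(region_sets)) {
    rs <- data.table::as.data.table(region_sets[[lab]])
    if (!nrow(rs)) next
    rgr <- GenomicRanges::GRanges(rs$chrom,
                                  IRanges::IRanges(rs$start + 1L, rs$end))
    hit <- GenomicRanges::findOverlaps(sgr, rgr)
    if (length(hit)) {
      memberships[[lab]] <- data.table::data.table(
        site_idx = unique(S4Vectors::queryHits(hit)), label = lab)
    }
  }
  mem <- if (length(memberships)) data.table::rbindlist(memberships) else {
    data.table::data.table(site_idx = integer(0), label = character(0))
  }
  label <- rep("background", nrow(sites))
  for (lab in rev(priority)) {
    idx <- mem$site_idx[mem$label == lab]
    label[idx] <- lab
  }
  assigned <- data.table::copy(sites)
  assigned$label <- label
  list(assigned = assigned[], memberships = mem[order(mem$site_idx), ])
}
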