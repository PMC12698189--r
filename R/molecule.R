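# Single-molecule and single-cell occupancy. Each read covering a motif is
# classified bound/unbound/ambiguous from its own conversion fraction over
# the motif window: a bound TF shields the window, so few of its cytosines
# convert on that molecule. Calls use raw per-read base calls — context
# bias is a rate-level property and cannot be applied to single binary
# observations; requiring several informative cytosines dilutes it instead.

#' Per-read conversion observations at site windows
#'
#' For every (read, site) pair where the read's alignment overlaps the
#' site's assessment window (motif padded by `pad` bp), counts the window
#' cytosines on the read's conversion strand with a determinate base
#' (`n_informative`) and how many of them are converted (`n_converted`).
#' Reads not overlapping a window yield no row.
#'
#' @param alignments Alignment table ([read_alignments()] or simulator
#'   output) or SAM/BAM path.
#' @param reference Reference (as in [extract_conversion_track()]).
#' @param sites Site table with `chrom, start, end` and a unique `name` (or
#'   `motif_id`).
#' @param pad Window padding in bp on each side of the motif (default 2).
#' @param min_mapq Mapping-quality filter.
#' @param require_span If `TRUE` (default), only reads whose alignment
#'   covers the full motif interval are used — a read grazing the window
#'   edge sees mostly flank cytosines and carries no occupancy information.
#' @return `data.table(qname, barcode, site, n_informative, n_converted)`.
#' @export
read_site_observations <- function(alignments, reference, sites, pad = 2L,
                                   min_mapq = 20L, require_span = TRUE) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- data.table::as.data.table(alignments)
  aln <- aln[aln$mapq >= min_mapq, ]
  sites <- data.table::as.data.table(sites)
  if (is.null(sites$name)) sites$name <- sites$motif_id
  refs <- .reference_chars(reference)
  out <- list()
  for (si in seq_len(nrow(sites))) {
    ch <- sites$chrom[si]
    chars <- refs[[ch]]
    if (is.null(chars)) stop_ft("site contig %s not in reference", ch)
    ws <- max(sites$start[si] - pad, 0L)
    we <- min(sites$end[si] + pad, length(chars))
    a <- if (require_span) {
      aln[aln$chrom == ch & aln$pos <= sites$start[si] &
            (aln$pos + nchar(aln$seq)) >= sites$end[si], ]
    } else {
      aln[aln$chrom == ch & aln$pos < we &
            (aln$pos + nchar(aln$seq)) > ws, ]
    }
    if (!nrow(a)) next
    ms <- a$strand
    todo <- which(is.na(ms) | !(ms %in% c("+", "-")))
    for (i in todo) {
      ms[i] <- assign_read_strand(a$seq[i], a$cigar[i], a$pos[i], chars)
    }
    win <- seq_window(chars, ws, we)
    for (s in c("+", "-")) {
      target <- if (s == "+") "C" else "G"
      conv_base <- if (s == "+") "T" else "A"
      cpos <- ws + which(win == target) - 1L
      rows <- which(ms == s)
      if (!length(rows) || !length(cpos)) next
      sub <- a[rows, ]
      width <- nchar(sub$seq)
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(cpos + 1L, width = 1L),
        IRanges::IRanges(sub$pos + 1L, width = width))
      if (!length(hit)) next
      pidx <- S4Vectors::queryHits(hit)
      ridx <- S4Vectors::subjectHits(hit)
      off <- cpos[pidx] - sub$pos[ridx] + 1L
      base <- substring(sub$seq[ridx], off, off)
      inf <- base %in% c(conv_base, target)
      if (!any(inf)) next
      tab <- data.table::data.table(
        qname = sub$qname[ridx[inf]],
        barcode = if (is.null(sub$barcode)) NA_character_
                  else sub$barcode[ridx[inf]],
        converted = base[inf] == conv_base)
      out[[length(out) + 1L]] <- tab[, list(site = sites$name[si],
                                            n_informative = .N,
                                            n_converted = sum(converted)),
                                     by = c("qname", "barcode")]
    }
  }
  if (!length(out)) {
    return(data.table::data.table(qname = character(0),
                                  barcode = character(0),
                                  site = character(0),
                                  n_informative = integer(0),
                                  n_converted = integer(0)))
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("qname", "barcode", "site",
                                 "n_informative", "n_converted"))
  data.table::setorder(res, site, qname)
  res[]
}

#' Fit a two-component binomial mixture to molecule observations
#'
#' EM fit of `x_i ~ w Binom(n_i, p_bound) + (1-w) Binom(n_i, p_unbound)`
#' with `p_bound < p_unbound`, modelling the bound (shielded, rarely
#' converted) and unbound (accessible) molecule populations at one site.
#'
#' @param observations Output of [read_site_observations()] for one site.
#' @param min_c Molecules with fewer informative cytosines are ignored.
#' @param max_iter,tol EM controls.
#' @return List: `p_bound`, `p_unbound`, `weight_bound`, `converged`.
#' @export
fit_binomial_mixture <- function(observations, min_c = 2L, max_iter = 200L,
                                 tol = 1e-8) {
  obs <- data.table::as.data.table(observations)
  obs <- obs[obs$n_informative >= min_c, ]
  if (nrow(obs) < 10) stop_ft("too few molecules to fit a mixture")
  x <- obs$n_converted
  n <- obs$n_informative
  frac <- x / n
  split_at <- mean(frac)
  p1 <- mean(frac[frac <= split_at]); p2 <- mean(frac[frac > split_at])
  if (!is.finite(p2)) p2 <- min(0.99, p1 + 0.3)
  p1 <- min(max(p1, 1e-3), 0.98); p2 <- min(max(p2, p1 + 1e-3), 0.999)
  w <- mean(frac <= split_at)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dbinom(x, n, p1)
    d2 <- (1 - w) * stats::dbinom(x, n, p2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- mean(g)
    p1 <- sum(g * x) / max(sum(g * n), 1e-12)
    p2 <- sum((1 - g) * x) / max(sum((1 - g) * n), 1e-12)
    if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp; w <- 1 - w }
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(p_bound = p1, p_unbound = p2, weight_bound = w,
       converged = converged)
}

#' Classify molecules as bound / unbound / ambiguous
#'
#' With `method = "threshold"` (the default), a molecule whose conversion
#' fraction over the site window is at most `t_bound` is bound (the TF
#' shielded it), at least `t_unbound` unbound, and ambiguous otherwise.
#' With the defaults, a 2-cytosine window yields a determinate call only
#' when unanimous. The fixed thresholds are simple and transparent but bias
#' the bound fraction when one population's conversion rate falls inside
#' the ambiguous band, so for occupancy estimation `method = "likelihood"`
#' classifies each molecule at the binomial likelihood-ratio boundary
#' between the bound and unbound conversion rates (`p_bound`/`p_unbound`,
#' fitted per site by [fit_binomial_mixture()] when not supplied): every
#' molecule with at least `min_c` informative cytosines is determinate.
#'
#' @param observations Output of [read_site_observations()].
#' @param t_bound Upper conversion fraction for a bound call (default 1/3).
#' @param t_unbound Lower fraction for an unbound call (default 2/3).
#' @param min_c Minimum informative cytosines (default 2).
#' @param method `"threshold"` or `"likelihood"`.
#' @param p_bound,p_unbound Conversion rates of the two populations for the
#'   likelihood rule; `NULL` fits them per site.
#' @return The observations with `fraction` and `state` columns; the rule
#'   is recorded in the `params` attribute.
#' @export
classify_molecules <- function(observations, t_bound = 1 / 3,
                               t_unbound = 2 / 3, min_c = 2L,
                               method = c("threshold", "likelihood"),
                               p_bound = NULL, p_unbound = NULL) {
  method <- match.arg(method)
  stopifnot(t_bound < t_unbound)
  calls <- data.table::as.data.table(observations)
  calls$fraction <- ifelse(calls$n_informative > 0,
                           calls$n_converted / calls$n_informative,
                           NA_real_)
  if (method == "threshold") {
    calls$state <- ifelse(
      calls$n_informative < min_c, "ambiguous",
      ifelse(calls$fraction <= t_bound, "bound",
             ifelse(calls$fraction >= t_unbound, "unbound", "ambiguous")))
    params <- list(method = method, t_bound = t_bound,
                   t_unbound = t_unbound, min_c = min_c)
  } else {
    calls$state <- "ambiguous"
    calls$posterior_bound <- NA_real_
    fitted <- list()
    for (s in unique(calls$site)) {
      rows <- which(calls$site == s & calls$n_informative >= min_c)
      if (!length(rows)) next
      if (is.null(p_bound) || is.null(p_unbound)) {
        fit <- fit_binomial_mixture(calls[calls$site == s, ], min_c)
        pb <- fit$p_bound; pu <- fit$p_unbound; w <- fit$weight_bound
      } else {
        pb <- p_bound; pu <- p_unbound; w <- 0.5
      }
      fitted[[s]] <- c(p_bound = pb, p_unbound = pu, weight_bound = w)
      # likelihood-ratio boundary on the conversion fraction
      cut <- (log(1 - pb) - log(1 - pu)) /
        (log(pu / pb) + log((1 - pb) / (1 - pu)))
      calls$state[rows] <- ifelse(calls$fraction[rows] < cut, "bound",
                                  "unbound")
      d1 <- w * stats::dbinom(calls$n_converted[rows],
                              calls$n_informative[rows], pb)
      d2 <- (1 - w) * stats::dbinom(calls$n_converted[rows],
                                    calls$n_informative[rows], pu)
      calls$posterior_bound[rows] <- d1 / pmax(d1 + d2,
                                               .Machine$double.xmin)
    }
    params <- list(method = method, min_c = min_c, rates = fitted)
  }
  data.table::setattr(calls, "params", params)
  calls[]
}

#' Bound fraction of a site with a Wilson confidence interval
#'
#' `bound / (bound + unbound)` over determinate molecule calls; ambiguous
#' calls are excluded from the fraction but counted. For calls carrying
#' mixture posteriors (likelihood classification), the reported fraction is
#' the mean posterior bound probability over determinate molecules, which
#' corrects the hard-assignment bias that arises when few informative
#' cytosines are seen per molecule; the hard counts are still reported.
#'
#' @param calls Output of [classify_molecules()] (one site, or use
#'   `by_site = TRUE` for a per-site table).
#' @param conf Confidence level for the Wilson interval.
#' @param by_site Return one row per `site`.
#' @return List (`fraction, ci_low, ci_high, n_bound, n_unbound,
#'   n_ambiguous`) or a `data.table` of the same per site.
#' @export
site_bound_fraction <- function(calls, conf = 0.95, by_site = FALSE) {
  calls <- data.table::as.data.table(calls)
  one <- function(sub) {
    nb <- sum(sub$state == "bound")
    nu <- sum(sub$state == "unbound")
    na_ <- sum(sub$state == "ambiguous")
    if (nb + nu == 0) {
      return(list(fraction = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, n_bound = nb, n_unbound = nu,
                  n_ambiguous = na_, reason = "no_determinate_calls"))
    }
    frac <- if (!is.null(sub$posterior_bound) &&
                any(!is.na(sub$posterior_bound))) {
      mean(sub$posterior_bound[sub$state != "ambiguous"], na.rm = TRUE)
    } else {
      nb / (nb + nu)
    }
    ci <- wilson_ci(frac * (nb + nu), nb + nu, conf)
    list(fraction = frac, ci_low = ci[1], ci_high = ci[2],
         n_bound = nb, n_unbound = nu, n_ambiguous = na_, reason = "")
  }
  if (by_site) {
    return(calls[, one(.SD), by = "site"])
  }
  one(calls)
}

#' Single-molecule co-occupancy of two sites
#'
#' Joins determinate calls at two sites on the molecule id and tabulates
#' the four joint states over molecules informative at both, with joint-
#' state fractions, a Haldane-corrected odds ratio and a two-sided Fisher
#' exact p-value. Fewer than `min_joint` joint molecules sets a low-power
#' flag.
#'
#' @param calls_a,calls_b Calls from [classify_molecules()] at the two
#'   sites.
#' @param min_joint Low-power threshold (default 20).
#' @return List of class `cooccupancy`: `counts` (named `n_bb, n_bu, n_ub,
#'   n_uu`), `fractions`, `odds_ratio`, `fisher_p`, `n_joint`, `low_power`.
#' @export
cooccupancy <- function(calls_a, calls_b, min_joint = 20L) {
  a <- data.table::as.data.table(calls_a)
  b <- data.table::as.data.table(calls_b)
  a <- a[a$state != "ambiguous", c("qname", "state")]
  b <- b[b$state != "ambiguous", c("qname", "state")]
  j <- merge(a, b, by = "qname", suffixes = c("_a", "_b"))
  n_bb <- sum(j$state_a == "bound" & j$state_b == "bound")
  n_bu <- sum(j$state_a == "bound" & j$state_b == "unbound")
  n_ub <- sum(j$state_a == "unbound" & j$state_b == "bound")
  n_uu <- sum(j$state_a == "unbound" & j$state_b == "unbound")
  n <- n_bb + n_bu + n_ub + n_uu
  counts <- c(n_bb = n_bb, n_bu = n_bu, n_ub = n_ub, n_uu = n_uu)
  or <- ((n_bb + 0.5) * (n_uu + 0.5)) / ((n_bu + 0.5) * (n_ub + 0.5))
  fp <- if (n > 0) {
    stats::fisher.test(matrix(c(n_bb, n_bu, n_ub, n_uu), 2))$p.value
  } else NA_real_
  structure(list(counts = counts,
                 fractions = if (n > 0) counts / n else counts * NA_real_,
                 odds_ratio = or, fisher_p = fp, n_joint = n,
                 low_power = n < min_joint),
            class = "cooccupancy")
}

#' @export
print.cooccupancy <- function(x, ...) {
  cat(sprintf("co-occupancy over %d joint molecules%s\n", x$n_joint,
              if (x$low_power) " [low power]" else ""))
  print(x$counts)
  cat(sprintf("odds ratio %.3f, Fisher p = %.3g\n", x$odds_ratio,
              x$fisher_p))
  invisible(x)
}

#' Per-cell conversion tracks
#'
#' Splits alignments by cell barcode and extracts one track per barcode
#' plus the merged track over all kept reads; merged counts equal the sum
#' of per-cell counts at every cytosine. Reads without a barcode go to an
#' `"unassigned"` bin; a whitelist restricts the per-cell set without
#' affecting `"unassigned"`.
#'
#' @param alignments Alignment table or SAM/BAM path (barcodes in the
#'   `barcode` column / `CB` tag).
#' @param reference Reference.
#' @param whitelist Optional character vector of accepted barcodes.
#' @param ... Passed to [extract_conversion_track()].
#' @return List: `cells` (named list of tracks), `merged` (track over all
#'   reads in `cells`), `unassigned` (track or `NULL`).
#' @export
per_cell_tracks <- function(alignments, reference, whitelist = NULL, ...) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- data.table::as.data.table(alignments)
  no_bc <- is.na(aln$barcode)
  unassigned_aln <- aln[no_bc, ]
  cells_aln <- aln[!no_bc, ]
  if (!is.null(whitelist)) {
    dropped <- cells_aln[!(cells_aln$barcode %in% whitelist), ]
    unassigned_aln <- data.table::rbindlist(list(unassigned_aln, dropped))
    cells_aln <- cells_aln[cells_aln$barcode %in% whitelist, ]
  }
  cells <- lapply(split(cells_aln, cells_aln$barcode), function(sub) {
    extract_conversion_track(sub, reference,
                             sample_id = sub$barcode[1], ...)
  })
  merged <- extract_conversion_track(cells_aln, reference,
                                     sample_id = "merged", ...)
  unassigned <- if (nrow(unassigned_aln)) {
    extract_conversion_track(unassigned_aln, reference,
                             sample_id = "unassigned", ...)
  } else NULL
  list(cells = cells, merged = merged, unassigned = unassigned)
}

#' Smooth a track's rates with a centred moving window
#'
#' Replaces each informative position's rate (strands pooled per position)
#' by the mean rate over informative positions within `window` bp centred
#' on it; positions with no data stay absent rather than becoming zero.
#'
#' @param track A conversion track.
#' @param window Odd window width in bp (default 5).
#' @return `data.table(chrom, pos, rate, rate_smooth)`.
#' @export
smooth_track <- function(track, window = 5L) {
  if (window %% 2L == 0L) stop_ft("smoothing window must be odd")
  half <- (window - 1L) %/% 2L
  per_pos <- track[!is.na(track$rate),
                   list(rate = mean(rate)), by = c("chrom", "pos")]
  data.table::setorder(per_pos, chrom, pos)
  out <- list()
  for (ch in unique(per_pos$chrom)) {
    sub <- per_pos[per_pos$chrom == ch, ]
    cum <- c(0, cumsum(sub$rate))
    lo <- findInterval(sub$pos - half - 0.5, sub$pos)
    hi <- findInterval(sub$pos + half + 0.5 - 1e-9, sub$pos)
    sub$rate_smooth <- (cum[hi + 1L] - cum[lo + 1L]) / (hi - lo)
    out[[ch]] <- sub
  }
  data.table::rbindlist(out)[]
}
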