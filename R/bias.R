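# Sequence-context bias of the deaminase, fitted on a naked-DNA control and
# applied as a multiplicative correction so that footprint signals are not
# confounded by enzyme preference (e.g. the TC-over-GC preference known for
# some double-stranded DNA deaminases).

#' Fit a sequence-context bias model from a naked-DNA track
#'
#' For every length-`k` context with a central C, the expected conversion
#' rate is the pooled `sum(n_conv)/sum(n_total)` over naked-DNA cytosines
#' carrying that context. Contexts absent from the data are marked missing
#' (not zero); contexts with fewer than `min_count` observations are flagged
#' low-confidence and fall back to the genome rate on correction. Strands are
#' pooled unless their genome rates differ by more than `strand_tol`
#' (relative), in which case per-strand tables are kept.
#'
#' @param naked_track Conversion track from protein-free DNA.
#' @param k Context width (odd; default 3, i.e. NCN).
#' @param min_count Low-confidence floor on supporting observations.
#' @param strand_tol Relative strand-rate difference above which the model
#'   stays stranded.
#' @return A `bias_model`: `data.table(context, strand, n_conv, n_total,
#'   expected_rate, low_confidence, missing)` with attributes `k`,
#'   `genome_rate`, `stranded`.
#' @export
fit_bias_model <- function(naked_track, k = 3L, min_count = 200L,
                           strand_tol = 0.10) {
  if (k %% 2L == 0L) stop_ft("context width k must be odd")
  if (!nrow(naked_track)) stop_ft("cannot fit bias model on an empty track")
  track_k <- attr(naked_track, "context_k") %||% nchar(naked_track$context[1])
  if (track_k != k)
    stop_ft("track context width (%d) does not match k = %d", track_k, k)
  genome_rate <- sum(naked_track$n_conv) / sum(naked_track$n_total)

  srates <- naked_track[, list(rate = sum(n_conv) / sum(n_total)),
                        by = "strand"]
  stranded <- nrow(srates) == 2 &&
    abs(diff(srates$rate)) / mean(srates$rate) > strand_tol

  agg_by <- if (stranded) c("context", "strand") else "context"
  tab <- naked_track[, list(n_conv = sum(n_conv), n_total = sum(n_total)),
                     by = agg_by]
  if (!stranded) tab$strand <- "*"
  full <- data.table::CJ(context = all_c_contexts(k),
                         strand = unique(tab$strand))
  tab <- merge(full, tab, by = c("context", "strand"), all.x = TRUE)
  tab$missing <- is.na(tab$n_total)
  tab$n_conv[tab$missing] <- 0L
  tab$n_total[tab$missing] <- 0L
  tab$expected_rate <- ifelse(tab$n_total > 0, tab$n_conv / tab$n_total,
                              NA_real_)
  tab$low_confidence <- tab$n_total < min_count
  data.table::setorder(tab, context, strand)
  data.table::setattr(tab, "k", as.integer(k))
  data.table::setattr(tab, "genome_rate", genome_rate)
  data.table::setattr(tab, "stranded", stranded)
  data.table::setattr(tab, "class",
                      c("bias_model", class(data.table::data.table())))
  tab
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("bias_model: k=%d, genome rate %.4f, %s, %d/%d contexts observed\n",
              attr(x, "k"), attr(x, "genome_rate"),
              if (attr(x, "stranded")) "stranded" else "strand-pooled",
              sum(!x$missing), nrow(x)))
  invisible(x)
}

# expected rate lookup for (context, strand) pairs; low-confidence or
# missing contexts return the genome rate; contexts observed at exactly 0
# return 0 (flagged uncorrectable by the caller)
.expected_rate <- function(model, context, strand) {
  key <- if (attr(model, "stranded")) {
    paste(context, strand)
  } else paste(context, "*")
  mkey <- paste(model$context, model$strand)
  idx <- match(key, mkey)
  exp_rate <- model$expected_rate[idx]
  fallback <- is.na(idx) | model$missing[idx] | model$low_confidence[idx]
  exp_rate[fallback] <- attr(model, "genome_rate")
  exp_rate
}

#' Correct a conversion track for enzyme sequence-context bias
#'
#' Each per-cytosine rate is multiplied by
#' `genome_rate / expected_rate(context)` and clipped to `[0, cap]`. Rates
#' are probabilities, so the correction is a ratio to the genome-wide naked
#' rate rather than a subtraction. Cytosines whose context has an expected
#' rate of exactly zero cannot be corrected and are dropped with a warning;
#' low-confidence and missing contexts fall back to the genome rate (a
#' no-op correction).
#'
#' @param track A conversion track.
#' @param model A `bias_model` from [fit_bias_model()].
#' @param cap Upper clip for corrected rates.
#' @return The track with `rate` replaced by the corrected rate and a
#'   logical column `corrected` set.
#' @export
correct_track <- function(track, model, cap = 1) {
  if (attr(model, "genome_rate") <= 0)
    stop_ft("bias model genome rate must be positive")
  tk <- attr(track, "context_k") %||% nchar(track$context[1])
  if (!is.null(tk) && nrow(track) && tk != attr(model, "k"))
    stop_ft("track context width (%d) does not match model k (%d)",
            tk, attr(model, "k"))
  out <- data.table::copy(track)
  exp_rate <- .expected_rate(model, out$context, out$strand)
  zero <- !is.na(exp_rate) & exp_rate == 0
  if (any(zero)) {
    warn_ft("%d cytosines in contexts with zero expected rate dropped as uncorrectable",
            sum(zero))
    out <- out[!zero, ]
    exp_rate <- exp_rate[!zero]
  }
  out$rate <- pmin(pmax(out$rate * attr(model, "genome_rate") / exp_rate, 0),
                   cap)
  out$corrected <- TRUE
  new_conversion_track(out, attr(track, "sample_id"),
                       attr(track, "global_rate"),
                       attr(track, "context_k") %||% 3L,
                       normalized = isTRUE(attr(track, "normalized")))
}

#' Observed-versus-expected bias report
#'
#' Per-context table of observed rate in `track` against the naked-DNA
#' expectation, sorted by the magnitude of the log ratio so the most biased
#' contexts rank first.
#'
#' @param track A conversion track.
#' @param model A `bias_model`.
#' @return `data.table(context, observed, expected, ratio, log2_ratio, n)`.
#' @export
bias_report <- function(track, model) {
  if (!nrow(track)) {
    return(data.table::data.table(context = character(0),
                                  observed = numeric(0),
                                  expected = numeric(0), ratio = numeric(0),
                                  log2_ratio = numeric(0), n = integer(0)))
  }
  obs <- track[, list(observed = sum(n_conv) / sum(n_total), n = .N),
               by = "context"]
  strand_for <- if (attr(model, "stranded")) "+" else "*"
  obs$expected <- .expected_rate(model, obs$context,
                                 rep(strand_for, nrow(obs)))
  obs$ratio <- obs$observed / obs$expected
  obs$log2_ratio <- log2(obs$ratio)
  obs <- obs[order(-abs(obs$log2_ratio)), ]
  data.table::setcolorder(obs, c("context", "observed", "expected", "ratio",
                                 "log2_ratio", "n"))
  obs[]
}

#' Serialize / read a bias model
#'
#' TSV of `(context, strand, n_conv, n_total, expected_rate)` plus a JSON
#' sidecar `<path>.json` with `k`, `genome_rate`, `stranded`.
#'
#' @param model A `bias_model`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_bias_model <- function(model, path) {
  data.table::fwrite(as.data.frame(model), path, sep = "\t")
  jsonlite::write_json(list(k = attr(model, "k"),
                            genome_rate = attr(model, "genome_rate"),
                            stranded = attr(model, "stranded")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bias_model
#' @export
read_bias_model <- function(path) {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = c("context",
                                                           "strand")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data.table::setattr(tab, "k", as.integer(meta$k))
  data.table::setattr(tab, "genome_rate", meta$genome_rate)
  data.table::setattr(tab, "stranded", isTRUE(meta$stranded))
  data.table::setattr(tab, "class",
                      c("bias_model", class(data.table::data.table())))
  tab
}
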