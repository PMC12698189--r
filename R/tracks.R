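# Per-cytosine conversion tracks. A track is a data.table with one row per
# (chrom, pos, strand) cytosine: pos is the 0-based position of the C on its
# own strand (a '-' record sits at a reference G), n_total counts reads with
# a determinate base (C/T on '+', G/A on '-'), n_conv counts converted reads
# (T on '+', A on '-'), context is the k-mer centred on the C on its strand.

new_conversion_track <- function(dt, sample_id, global_rate, k = 3L,
                                 normalized = FALSE) {
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "global_rate", global_rate)
  data.table::setattr(dt, "context_k", as.integer(k))
  data.table::setattr(dt, "normalized", normalized)
  data.table::setattr(dt, "class",
                      c("conversion_track", class(data.table::data.table())))
  dt
}

#' Construct a conversion track from per-cytosine counts
#'
#' Programmatic constructor validating the track invariants: counts
#' consistent (`0 <= n_conv <= n_total`), contexts centred on C, records
#' unique on (chrom, pos, strand) and sorted by position.
#'
#' @param records `data.frame(chrom, pos, strand, n_conv, n_total)` with
#'   optional `context` (filled with `"NCN"` when absent); `pos` is the
#'   0-based position of the cytosine on its own strand.
#' @param sample_id Label stored on the track.
#' @param min_cov_rate Coverage floor for the global rate.
#' @return A `conversion_track`.
#' @export
conversion_track <- function(records, sample_id = "sample",
                             min_cov_rate = 3L) {
  dt <- data.table::as.data.table(records)
  if (is.null(dt$context)) dt$context <- "NCN"
  stopifnot(all(dt$n_conv >= 0), all(dt$n_conv <= dt$n_total),
            all(dt$strand %in% c("+", "-")))
  k <- nchar(dt$context[1]) %||% 3L
  if (nrow(dt)) {
    centre <- substring(dt$context, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
    if (!all(centre %in% c("C", "N")))
      stop_ft("context must be centred on the cytosine")
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
      stop_ft("records must be unique on (chrom, pos, strand)")
  }
  data.table::setorder(dt, chrom, pos, strand)
  dt$rate <- ifelse(dt$n_total > 0, dt$n_conv / dt$n_total, NA_real_)
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "n_conv",
                                "n_total", "context", "rate"))
  gr <- global_conversion_rate(dt, min_cov_rate)
  new_conversion_track(dt, sample_id, gr, if (nrow(dt)) k else 3L)
}

#' @export
print.conversion_track <- function(x, ...) {
  gr <- attr(x, "global_rate")
  cat(sprintf("conversion_track '%s': %d cytosines, global rate %s%s\n",
              attr(x, "sample_id") %||% "?", nrow(x),
              if (is.null(gr) || is.na(gr)) "undefined"
              else sprintf("%.4f", gr),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  NextMethod()
}

#' Global conversion rate of a track
#'
#' Pooled `sum(n_conv)/sum(n_total)` over cytosines with coverage at least
#' `min_cov` (default 3, suppressing shot noise at barely covered sites).
#'
#' @param track A conversion track.
#' @param min_cov Minimum `n_total` for a cytosine to enter the estimate.
#' @return Fraction in `[0, 1]`, or `NA` if no cytosine qualifies.
#' @export
global_conversion_rate <- function(track, min_cov = 3L) {
  use <- track[track$n_total >= min_cov, ]
  if (!nrow(use)) return(NA_real_)
  sum(use$n_conv) / sum(use$n_total)
}

#' Read alignments from SAM or BAM into a table
#'
#' SAM input is converted with [Rsamtools::asBam()]. The molecule conversion
#' strand tag (default `XG`) and cell barcode tag (default `CB`) are carried
#' through when present.
#'
#' @param path SAM or BAM file.
#' @param strand_tag,barcode_tag Two-letter aligner tag names.
#' @return `data.table` with `qname, flag, chrom, pos` (0-based), `mapq,
#'   cigar, seq, qual, strand` (tag value or `NA`), `barcode, duplicate`.
#' @export
read_alignments <- function(path, strand_tag = "XG", barcode_tag = "CB") {
  if (!file.exists(path)) stop_ft("alignment file not found: %s", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  p <- Rsamtools::ScanBamParam(what = what, tag = c(strand_tag, barcode_tag))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table::data.table(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual))
  tags <- res$tag
  dt$strand <- if (!is.null(tags[[strand_tag]])) {
    as.character(tags[[strand_tag]])
  } else NA_character_
  dt$barcode <- if (!is.null(tags[[barcode_tag]])) {
    as.character(tags[[barcode_tag]])
  } else NA_character_
  dt$duplicate <- bitwAnd(dt$flag, 1024L) > 0L
  dt[!is.na(dt$pos) & bitwAnd(dt$flag, 4L) == 0L, ]
}

# 0-based reference positions consumed by each aligned read base, NA for
# inserted/clipped bases; minimal CIGAR walker (M/=/X/I/D/N/S/H/P)
cigar_ref_positions <- function(cigar, pos0, read_len) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  out <- rep(NA_integer_, read_len)
  qi <- 0L; ri <- pos0
  for (j in seq_along(op)) {
    o <- op[j]; len <- n[j]
    if (o %in% c("M", "=", "X")) {
      out[(qi + 1L):(qi + len)] <- ri:(ri + len - 1L)
      qi <- qi + len; ri <- ri + len
    } else if (o %in% c("I", "S")) {
      qi <- qi + len
    } else if (o %in% c("D", "N")) {
      ri <- ri + len
    } # H and P consume nothing here
  }
  out
}

#' Assign the conversion strand of one read
#'
#' A deaminated molecule reports C-to-T mismatches when its top strand was
#' converted and G-to-A when the bottom strand was. The aligner tag wins when
#' present; otherwise the majority mismatch class decides, with ties and
#' zero-information reads returned as `"undetermined"`.
#'
#' @param seq Read sequence (aligned orientation).
#' @param cigar CIGAR string.
#' @param pos0 0-based leftmost reference position.
#' @param ref_chars Reference as a character vector of bases.
#' @param tag Optional aligner-supplied strand tag (`"+"`/`"-"`).
#' @return `"+"`, `"-"` or `"undetermined"`.
#' @export
assign_read_strand <- function(seq, cigar, pos0, ref_chars, tag = NA) {
  if (!is.na(tag) && tag %in% c("+", "-")) return(tag)
  rb <- strsplit(seq, "")[[1]]
  rp <- cigar_ref_positions(cigar, pos0, length(rb))
  keep <- !is.na(rp)
  if (max(c(rp[keep], -1L)) >= length(ref_chars))
    stop_ft("alignment runs past the reference window")
  ref <- ref_chars[rp[keep] + 1L]
  read <- rb[keep]
  ct <- sum(ref == "C" & read == "T")
  ga <- sum(ref == "G" & read == "A")
  if (ct > ga) "+" else if (ga > ct) "-" else "undetermined"
}

#' Extract a per-cytosine conversion track from alignments
#'
#' Strand-aware pileup: a read assigned to the `+` conversion strand is
#' informative at reference C positions (T = converted, C = unconverted), a
#' `-` read at reference G positions (A = converted, G = unconverted). Bases
#' inconsistent with the conversion model are dropped from `n_total`;
#' observations sharing one `qname` at one cytosine (overlapping mates) are
#' counted once, keeping the higher base quality.
#'
#' @param alignments Alignment table from [read_alignments()] or
#'   [simulate_molecules()], or a SAM/BAM path.
#' @param reference Output of [simulate_reference()], a named
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @param min_mapq,min_baseq Quality filters.
#' @param dedup Drop duplicate-flagged reads (default `TRUE`).
#' @param k Context width (odd).
#' @param sample_id Label stored on the track.
#' @param min_cov_rate Coverage floor for the global rate
#'   (see [global_conversion_rate()]).
#' @return A `conversion_track`.
#' @export
extract_conversion_track <- function(alignments, reference, min_mapq = 20L,
                                     min_baseq = 20L, dedup = TRUE, k = 3L,
                                     sample_id = "sample",
                                     min_cov_rate = 3L) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  aln <- data.table::as.data.table(alignments)
  refs <- .reference_chars(reference)
  if (!nrow(aln)) {
    tr <- new_conversion_track(
      data.table::data.table(chrom = character(0), pos = integer(0),
                             strand = character(0), n_conv = integer(0),
                             n_total = integer(0), context = character(0),
                             rate = numeric(0)),
      sample_id, NA_real_, k)
    warn_ft("empty alignment input: track is empty, global rate undefined")
    return(tr)
  }
  missing_contig <- setdiff(unique(aln$chrom), names(refs))
  if (length(missing_contig))
    stop_ft("contig absent from reference: %s",
            paste(missing_contig, collapse = ", "))
  aln <- aln[aln$mapq >= min_mapq, ]
  if (dedup) aln <- aln[!aln$duplicate, ]
  if (is.null(aln$qual)) aln$qual <- strrep("I", nchar(aln$seq))

  per_chrom <- lapply(names(refs), function(ch) {
    a <- aln[aln$chrom == ch, ]
    if (!nrow(a)) return(NULL)
    chars <- refs[[ch]]
    if (is.null(a$strand)) a$strand <- NA_character_
    ms <- a$strand
    todo <- which(is.na(ms) | !(ms %in% c("+", "-")))
    for (i in todo) {
      ms[i] <- assign_read_strand(a$seq[i], a$cigar[i], a$pos[i], chars)
    }
    a$strand <- ms
    a <- a[a$strand %in% c("+", "-"), ]
    if (!nrow(a)) return(NULL)
    simple <- grepl("^\\d+M$", a$cigar)
    obs <- list()
    for (s in c("+", "-")) {
      target <- if (s == "+") "C" else "G"
      tpos <- which(chars == target) - 1L         # 0-based
      rows <- which(a$strand == s)
      if (!length(rows) || !length(tpos)) next
      sub <- a[rows, ]
      width <- nchar(sub$seq)
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(tpos + 1L, width = 1L),
        IRanges::IRanges(sub$pos + 1L, width = width))
      if (!length(hit)) next
      pidx <- S4Vectors::queryHits(hit)
      ridx <- S4Vectors::subjectHits(hit)
      simple_r <- simple[rows][ridx]
      off <- tpos[pidx] - sub$pos[ridx] + 1L      # 1-based query offset if ungapped
      if (any(!simple_r)) {
        for (u in unique(ridx[!simple_r])) {
          map <- cigar_ref_positions(sub$cigar[u], sub$pos[u],
                                     nchar(sub$seq[u]))
          sel <- which(ridx == u & !simple_r)
          off[sel] <- match(tpos[pidx[sel]], map)
        }
      }
      ok <- !is.na(off) & off >= 1L & off <= width[ridx]
      pidx <- pidx[ok]; ridx <- ridx[ok]; off <- off[ok]
      base <- substring(sub$seq[ridx], off, off)
      bq <- utf8ToInt("!")
      qv <- utf8ToInt(paste(substring(sub$qual[ridx], off, off),
                            collapse = ""))
      qual_ok <- (qv - bq) >= min_baseq
      conv_base <- if (s == "+") "T" else "A"
      unconv_base <- target
      inf <- qual_ok & base %in% c(conv_base, unconv_base)
      if (!any(inf)) next
      obs[[s]] <- data.table::data.table(
        pos = tpos[pidx[inf]], strand = s,
        qname = sub$qname[ridx[inf]],
        converted = base[inf] == conv_base,
        q = qv[inf])
    }
    ob <- data.table::rbindlist(obs)
    if (!nrow(ob)) return(NULL)
    # overlapping mates: one observation per molecule per cytosine,
    # keeping the higher base quality
    data.table::setorder(ob, pos, strand, qname, -q)
    ob <- unique(ob, by = c("pos", "strand", "qname"))
    cnt <- ob[, list(n_conv = sum(converted), n_total = .N),
              by = c("pos", "strand")]
    cnt$chrom <- ch
    cnt$context <- cytosine_context_vec(chars, cnt$pos, cnt$strand, k)
    cnt
  })
  dt <- data.table::rbindlist(per_chrom[!vapply(per_chrom, is.null,
                                                logical(1))])
  if (!nrow(dt)) {
    dt <- data.table::data.table(chrom = character(0), pos = integer(0),
                                 strand = character(0), n_conv = integer(0),
                                 n_total = integer(0), context = character(0))
  }
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "n_conv",
                                "n_total", "context"))
  data.table::setorder(dt, chrom, pos, strand)
  dt$rate <- ifelse(dt$n_total > 0, dt$n_conv / dt$n_total, NA_real_)
  gr <- global_conversion_rate(dt, min_cov_rate)
  new_conversion_track(dt, sample_id, gr, k)
}

.reference_chars <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
  }
  if (is.list(reference) && !is.null(reference$chars)) {
    out <- list(reference$chars)
    names(out) <- reference$contig
    return(out)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- lapply(seq_along(reference),
                  function(i) seq_chars(reference[[i]]))
    names(out) <- names(reference)
    return(out)
  }
  stop_ft("unsupported reference type")
}

#' Normalize a track to a reference conversion rate
#'
#' Scales each per-cytosine rate by `reference_rate / global_rate` and clips
#' to `[0, 1]`, so samples deaminated at different enzyme doses overlay on a
#' common scale. Idempotent when `reference_rate` equals the global rate.
#'
#' @param track A conversion track.
#' @param reference_rate Target global rate.
#' @return The track with `rate` rescaled and `normalized = TRUE`.
#' @export
normalize_track <- function(track, reference_rate) {
  gr <- attr(track, "global_rate")
  if (is.null(gr) || is.na(gr) || gr <= 0)
    stop_ft("cannot normalize: track global rate is zero or undefined")
  out <- data.table::copy(track)
  out$rate <- pmin(pmax(out$rate * reference_rate / gr, 0), 1)
  new_conversion_track(out, attr(track, "sample_id"), gr,
                       attr(track, "context_k") %||% 3L, normalized = TRUE)
}

#' Serialize a track as a cytosine-report TSV
#'
#' Columns `chrom, pos, strand, n_conv, n_total, context`; coordinates are
#' 0-based (stated in the header comment). Round-trips losslessly through
#' [read_track()].
#'
#' @param track A conversion track.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  corrected <- "corrected" %in% names(track)
  hdr <- c("# foottrack cytosine report; pos is 0-based on the cytosine's strand",
           sprintf("# sample_id=%s global_rate=%s context_k=%d corrected=%d",
                   attr(track, "sample_id") %||% "sample",
                   format(attr(track, "global_rate") %||% NA_real_,
                          digits = 17),
                   attr(track, "context_k") %||% 3L,
                   as.integer(corrected)),
           paste(c("chrom", "pos", "strand", "n_conv", "n_total",
                   "context", if (corrected) "rate"), collapse = "\t"))
  body <- if (nrow(track)) {
    if (corrected) {
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s", track$chrom, track$pos,
              track$strand, track$n_conv, track$n_total, track$context,
              format(track$rate, digits = 17, trim = TRUE,
                     scientific = FALSE))
    } else {
      sprintf("%s\t%d\t%s\t%d\t%d\t%s", track$chrom, track$pos,
              track$strand, track$n_conv, track$n_total, track$context)
    }
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cytosine-report TSV written by [write_track()]
#'
#' @param path TSV path.
#' @return A `conversion_track`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# sample_id=", lines, value = TRUE)
  sample_id <- sub(".*sample_id=(\\S+).*", "\\1", meta[1])
  gr <- suppressWarnings(as.numeric(sub(".*global_rate=(\\S+).*", "\\1",
                                        meta[1])))
  k <- as.integer(sub(".*context_k=(\\d+).*", "\\1", meta[1]))
  corrected <- grepl("corrected=1", meta[1])
  body <- lines[!grepl("^#", lines)]
  if (length(body) <= 1L) {
    dt <- data.table::data.table(chrom = character(0), pos = integer(0),
                                 strand = character(0), n_conv = integer(0),
                                 n_total = integer(0), context = character(0))
  } else {
    dt <- data.table::fread(text = body, sep = "\t", header = TRUE,
                            colClasses = list(character = c(1, 3, 6),
                                              integer = c(2, 4, 5)))
    bad <- which(dt$n_conv > dt$n_total | dt$n_total < 0)
    if (length(bad))
      stop_ft("malformed track line %d: n_conv > n_total", bad[1] + 3L)
  }
  if (corrected && nrow(dt)) {
    dt$corrected <- TRUE
  } else {
    dt$rate <- ifelse(dt$n_total > 0, dt$n_conv / dt$n_total, NA_real_)
  }
  new_conversion_track(dt, sample_id, gr, k)
}

#' Export a track as per-strand bedGraph files
#'
#' Writes four files: `<prefix>.<strand>.rate.bedGraph` and
#' `<prefix>.<strand>.cov.bedGraph`, each cytosine as a width-1 0-based
#' half-open interval.
#'
#' @param track A conversion track.
#' @param prefix Output path prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- character(0)
  for (s in c("+", "-")) {
    tag <- if (s == "+") "plus" else "minus"
    sub <- track[track$strand == s, ]
    for (what in c("rate", "cov")) {
      p <- sprintf("%s.%s.%s.bedGraph", prefix, tag, what)
      val <- if (what == "rate") sub$rate else sub$n_total
      writeLines(c(sprintf("track type=bedGraph name=%s_%s_%s",
                           basename(prefix), tag, what),
                   if (nrow(sub)) sprintf("%s\t%d\t%d\t%s", sub$chrom,
                                          sub$pos, sub$pos + 1L,
                                          format(val, trim = TRUE))
                   else character(0)), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Conversion-rate quality control
#'
#' Reports the global conversion rate with a pass/warn flag against the
#' optimal operating range (default 25%-40%: below it footprint contrast is
#' weak, above it occupancy scores degrade), plus per-context rates and
#' strand balance.
#'
#' @param track A conversion track.
#' @param optimal Length-2 numeric, the acceptable global-rate range.
#' @param min_cov Coverage floor for the rate estimates.
#' @return List of class `foottrack_qc`: `global_rate`, `status`
#'   (`"pass"`/`"warn"`), `optimal`, `context_rates`, `strand_rates`.
#' @export
qc_conversion_rate <- function(track, optimal = c(0.25, 0.40), min_cov = 3L) {
  if (!nrow(track)) stop_ft("cannot QC an empty track")
  gr <- global_conversion_rate(track, min_cov)
  use <- track[track$n_total >= min_cov, ]
  ctx <- use[, list(rate = sum(n_conv) / sum(n_total), n = .N),
             by = "context"]
  data.table::setorder(ctx, context)
  str <- use[, list(rate = sum(n_conv) / sum(n_total), n = .N),
             by = "strand"]
  status <- if (!is.na(gr) && gr >= optimal[1] && gr <= optimal[2]) {
    "pass"
  } else "warn"
  structure(list(global_rate = gr, status = status, optimal = optimal,
                 context_rates = ctx, strand_rates = str),
            class = "foottrack_qc")
}

#' @export
print.foottrack_qc <- function(x, ...) {
  cat(sprintf("global conversion rate: %.3f [%s] (optimal %.0f%%-%.0f%%)\n",
              x$global_rate, x$status, 100 * x$optimal[1],
              100 * x$optimal[2]))
  invisible(x)
}
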