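# Motif models and PWM scanning. Motifs are position frequency matrices
# (JASPAR PFM or MEME minimal text); scoring uses log2 odds against a
# background nucleotide distribution, with the score threshold calibrated to
# a p-value by exact dynamic programming over the discretised null score
# distribution (i.i.d. background sequence).

#' Construct a motif model
#'
#' @param motif_id Identifier.
#' @param counts 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param tf Factor or cluster name (default `motif_id`).
#' @param background Named background nucleotide probabilities.
#' @param pseudocount Added per cell (scaled by column sums) before
#'   normalization.
#' @return List of class `motif_model` with `pfm` (column-normalized), `lo`
#'   (log2-odds matrix) and metadata.
#' @export
motif_model <- function(motif_id, counts, tf = motif_id,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                        pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop_ft("motif %s: need a 4-row matrix", motif_id)
  if (ncol(counts) < 4) stop_ft("motif %s: length must be >= 4", motif_id)
  rownames(counts) <- DNA_BASES
  if (pseudocount <= 0 && any(counts == 0))
    stop_ft("motif %s: zero-probability column without pseudocount", motif_id)
  pfm <- sweep(counts + pseudocount / 4,
               2, colSums(counts) + pseudocount, "/")
  lo <- log2(sweep(pfm, 1, background[DNA_BASES], "/"))
  structure(list(motif_id = motif_id, tf = tf, pfm = pfm, lo = lo,
                 background = background, length = ncol(pfm),
                 consensus = paste(DNA_BASES[apply(pfm, 2, which.max)],
                                   collapse = "")),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s (%s), length %d, consensus %s\n",
              x$motif_id, x$tf, x$length, x$consensus))
  invisible(x)
}

#' Read motifs from JASPAR PFM text
#'
#' Accepts the JASPAR 2020+ format: a `>ID NAME` header followed by four
#' lines `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path File path.
#' @param ... Passed to [motif_model()].
#' @return Named list of `motif_model`s.
#' @export
read_jaspar <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_ft("no JASPAR records in %s", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    end <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    motif_id <- hdr[1]
    tf <- if (length(hdr) > 1) hdr[2] else motif_id
    block <- lines[(i + 1):end]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- grep(paste0("^", b, "[ \\t\\[]"), block, value = TRUE)
      if (!length(ln)) stop_ft("JASPAR record %s: missing %s row",
                               motif_id, b)
      as.numeric(strsplit(trimws(gsub("[^0-9.eE+-]", " ",
                                      sub(paste0("^", b), "", ln[1]))),
                          "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    out[[motif_id]] <- motif_model(motif_id, counts, tf = tf, ...)
  }
  out
}

#' Read motifs from MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' the file-level `Background letter frequencies` line, when present, sets
#' the scanning background.
#'
#' @param path File path.
#' @param ... Passed to [motif_model()].
#' @return Named list of `motif_model`s.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg[names(vals)] <- vals
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop_ft("no MEME motifs in %s", path)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]]
    motif_id <- hdr[1]
    tf <- if (length(hdr) > 1) hdr[2] else motif_id
    mat_line <- grep("letter-probability matrix", lines)
    mat_line <- mat_line[mat_line > s][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mat_line]))
    block <- lines[(mat_line + 1):(mat_line + w)]
    probs <- t(vapply(block, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    out[[motif_id]] <- motif_model(motif_id, t(probs), tf = tf,
                                   background = bg, ...)
  }
  out
}

#' Score threshold for a motif p-value
#'
#' Exact null distribution of the log-odds score of a random i.i.d.
#' background sequence, computed by dynamic programming on scores
#' discretised to `1/resolution` bins. Returns the smallest threshold whose
#' tail probability does not exceed `pvalue`, plus the attained tail
#' probability (the threshold is conservative when the score distribution
#' is discrete).
#'
#' @param model A `motif_model`.
#' @param pvalue Target per-position, per-strand p-value.
#' @param resolution Score bins per log2-odds unit.
#' @return List: `threshold` (score), `attained_p`.
#' @export
motif_score_threshold <- function(model, pvalue = 1e-4, resolution = 100L) {
  qi <- round(model$lo * resolution)
  bg <- model$background[DNA_BASES]
  # distribution over integer score sums, built position by position
  vec <- 1
  base_min <- 0L
  for (j in seq_len(ncol(qi))) {
    col <- qi[, j]
    new_min <- base_min + min(col)
    new_max <- base_min + max(col) + (length(vec) - 1L)
    nv <- rep(0, new_max - new_min + 1L)
    for (b in 1:4) {
      sh <- base_min + col[b] - new_min
      nv[(sh + 1L):(sh + length(vec))] <-
        nv[(sh + 1L):(sh + length(vec))] + bg[b] * vec
    }
    vec <- nv
    base_min <- new_min
  }
  scores <- (base_min + seq_along(vec) - 1L) / resolution
  tail_p <- rev(cumsum(rev(vec)))
  ok <- which(tail_p <= pvalue)
  if (!length(ok)) {
    return(list(threshold = scores[length(scores)] + 1 / resolution,
                attained_p = 0))
  }
  i <- ok[1]
  list(threshold = scores[i] - 0.5 / resolution, attained_p = tail_p[i])
}

# log-odds scores of every offset of one sequence (character vector);
# returns numeric vector length(len - L + 1), NA where the window has an
# ambiguous base
.score_sequence <- function(chars, lo) {
  L <- ncol(lo)
  n <- length(chars) - L + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(chars, DNA_BASES)
  sc <- rep(0, n)
  for (j in seq_len(L)) {
    v <- lo[, j][idx[j:(j + n - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Scan motifs over regions of a reference
#'
#' Both strands of every region are scored with the motif's log-odds
#' matrix; positions reaching the p-value-calibrated threshold become
#' binding sites. Overlapping hits of the same motif (either strand) are
#' resolved to the best-scoring one. Nothing outside `regions` is scanned.
#'
#' @param reference Output of [simulate_reference()], a named
#'   `DNAStringSet`, or FASTA path.
#' @param motifs List of `motif_model`s (or a single model).
#' @param regions `data.frame(chrom, start, end)`, 0-based half-open search
#'   space.
#' @param pvalue Motif score p-value threshold (default 1e-4).
#' @param resolution Passed to [motif_score_threshold()].
#' @return `data.table(chrom, start, end, strand, motif_id, tf, score)`
#'   sorted by position, with attribute `attained_p` (named per motif).
#' @export
scan_motifs <- function(reference, motifs, regions, pvalue = 1e-4,
                        resolution = 100L) {
  refs <- .reference_chars(reference)
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  regions <- data.table::as.data.table(regions)
  hits <- list()
  attained <- numeric(0)
  for (m in motifs) {
    thr <- motif_score_threshold(m, pvalue, resolution)
    attained[m$motif_id] <- thr$attained_p
    L <- m$length
    # scores are quantized to the DP grid so the threshold calibration is
    # exact for the scanner, not just for the discretised null
    lo_q <- round(m$lo * resolution) / resolution
    lo_rc <- lo_q[4:1, L:1]                     # reverse complement matrix
    rownames(lo_rc) <- DNA_BASES
    for (r in seq_len(nrow(regions))) {
      ch <- regions$chrom[r]
      chars <- refs[[ch]]
      if (is.null(chars)) stop_ft("region contig %s not in reference", ch)
      win <- seq_window(chars, regions$start[r], regions$end[r])
      if (length(win) < L) next
      s_fwd <- .score_sequence(win, lo_q)
      s_rev <- .score_sequence(win, lo_rc)
      for (str in c("+", "-")) {
        sc <- if (str == "+") s_fwd else s_rev
        keep <- which(!is.na(sc) & sc >= thr$threshold)
        if (!length(keep)) next
        hits[[length(hits) + 1L]] <- data.table::data.table(
          chrom = ch,
          start = regions$start[r] + keep - 1L,
          end = regions$start[r] + keep - 1L + L,
          strand = str, motif_id = m$motif_id, tf = m$tf,
          score = sc[keep])
      }
    }
  }
  if (!length(hits)) {
    out <- data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  motif_id = character(0), tf = character(0),
                                  score = numeric(0))
    data.table::setattr(out, "attained_p", attained)
    return(out)
  }
  dt <- data.table::rbindlist(hits)
  # greedy best-score resolution of overlapping same-motif hits
  resolved <- list()
  for (mid in unique(dt$motif_id)) {
    sub <- dt[dt$motif_id == mid, ]
    data.table::setorder(sub, -score)
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start + 1L, sub$end))
    keep <- rep(TRUE, nrow(sub))
    taken <- GenomicRanges::GRanges()
    for (i in seq_len(nrow(sub))) {
      if (length(taken) &&
          length(GenomicRanges::findOverlaps(gr[i], taken))) {
        keep[i] <- FALSE
      } else {
        taken <- c(taken, gr[i])
      }
    }
    resolved[[mid]] <- sub[keep, ]
  }
  out <- data.table::rbindlist(resolved)
  data.table::setorder(out, chrom, start, motif_id)
  data.table::setattr(out, "attained_p", attained)
  out[]
}
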