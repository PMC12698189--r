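# Generative simulator for deaminase footprinting data. A molecule is a
# genomic fragment deaminated on one strand: cytosines in accessible DNA
# convert with probability p_open * context multiplier (capped at 1),
# cytosines under a nucleosome or a bound TF convert with p_protected.
# Per-molecule TF occupancy is Bernoulli(theta); a closed OCR protects the
# whole region for that molecule unless a bound TF keeps it open.

#' Build a simulation configuration
#'
#' Returns the configuration list consumed by [simulate_reference()] and
#' [simulate_molecules()]. Defaults describe a single 100 kb contig at 50% GC
#' with one deeply covered open chromatin region and no enzyme context bias.
#'
#' @param contig Contig name.
#' @param length Contig length in bp.
#' @param gc GC fraction of the random reference.
#' @param ocrs `data.frame(start, end, openness)`, 0-based half-open open
#'   chromatin regions. `openness` is the fraction of molecules in which the
#'   OCR is accessible (1 = always open); molecules carrying a bound TF inside
#'   the OCR are always accessible.
#' @param tf_sites `data.frame(name, consensus, pos, strand, theta, pad)`:
#'   motif consensus planted at 0-based position `pos`, per-molecule occupancy
#'   probability `theta`, footprint extending `pad` bp beyond the motif.
#' @param nucleosomes List: `enabled`, `width` (147), `repeat_len` (190),
#'   `jitter_sd` (10). Phased arrays tile DNA outside open OCRs, jittered per
#'   molecule.
#' @param enzyme List: `p_open`, `p_protected`, `context_mult` (named vector,
#'   multiplier keyed by the 5' neighbour of the cytosine on its own strand),
#'   `cap`.
#' @param molecules List: `n_molecules` (per region), `frag_len`, `frag_sd`,
#'   `error_rate`, optional `regions` data.frame(start, end) concentrating
#'   fragment centres.
#' @param cells List: `n_cells` (0 = bulk), `molecules_per_cell`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(contig = "chrSim", length = 100000L, gc = 0.5,
                       ocrs = NULL, tf_sites = NULL,
                       nucleosomes = list(), enzyme = list(),
                       molecules = list(), cells = list()) {
  nuc <- utils::modifyList(
    list(enabled = FALSE, width = 147L, repeat_len = 190L, jitter_sd = 10),
    nucleosomes)
  enz <- utils::modifyList(
    list(p_open = 0.6, p_protected = 0.05,
         context_mult = c(A = 1, C = 1, G = 1, T = 1), cap = 1),
    enzyme)
  mol <- utils::modifyList(
    list(n_molecules = 2000L, frag_len = 200L, frag_sd = 20,
         error_rate = 0, regions = NULL),
    molecules)
  cel <- utils::modifyList(list(n_cells = 0L, molecules_per_cell = 100L), cells)
  stopifnot(gc > 0, gc < 1,
            enz$p_open >= 0, enz$p_open <= 1,
            enz$p_protected >= 0, enz$p_protected <= 1)
  if (!is.null(tf_sites)) {
    tf_sites <- as.data.frame(tf_sites)
    if (is.null(tf_sites$strand)) tf_sites$strand <- "+"
    if (is.null(tf_sites$pad)) tf_sites$pad <- 0L
    stopifnot(all(tf_sites$theta >= 0), all(tf_sites$theta <= 1))
  }
  if (!is.null(ocrs)) {
    ocrs <- as.data.frame(ocrs)
    if (is.null(ocrs$openness)) ocrs$openness <- 1
    stopifnot(all(ocrs$end > ocrs$start),
              all(ocrs$openness >= 0), all(ocrs$openness <= 1))
  }
  structure(list(contig = contig, length = as.integer(length), gc = gc,
                 ocrs = ocrs, tf_sites = tf_sites, nucleosomes = nuc,
                 enzyme = enz, molecules = mol, cells = cel),
            class = "sim_config")
}

#' Simulate a reference sequence with planted motif consensi
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seed and config give identical output.
#' @return List with `seq` (a [Biostrings::DNAString]), `chars` (character
#'   vector of bases) and `contig`/`length`.
#' @export
simulate_reference <- function(config, seed) {
  set.seed(seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  chars <- sample(DNA_BASES, config$length, replace = TRUE, prob = p)
  sites <- config$tf_sites
  if (!is.null(sites) && nrow(sites)) {
    iv <- cbind(sites$pos, sites$pos + nchar(sites$consensus))
    if (nrow(sites) > 1) {
      ord <- order(iv[, 1])
      if (any(iv[ord, 1][-1] < iv[ord, 2][-nrow(iv)]))
        stop_ft("planted motif sites overlap")
    }
    for (i in seq_len(nrow(sites))) {
      cons <- toupper(sites$consensus[i])
      if (sites$strand[i] == "-") cons <- revcomp(cons)
      idx <- sites$pos[i] + seq_len(nchar(cons))
      if (any(idx > config$length)) stop_ft("planted site beyond contig end")
      chars[idx] <- strsplit(cons, "")[[1]]
    }
  }
  list(seq = Biostrings::DNAString(paste(chars, collapse = "")),
       chars = chars, contig = config$contig, length = config$length)
}

# union of protection intervals (0-based half-open) for one molecule
# given its bound sites and closed OCRs; nucleosome arrays are added
# outside open OCRs
.molecule_mask <- function(config, bound_sites, closed_ocrs, frag_start,
                           frag_end, nuc_offset) {
  ivs <- list()
  if (!is.null(bound_sites) && nrow(bound_sites)) {
    w <- nchar(bound_sites$consensus)
    ivs[[length(ivs) + 1L]] <- cbind(bound_sites$pos - bound_sites$pad,
                                     bound_sites$pos + w + bound_sites$pad)
  }
  if (!is.null(closed_ocrs) && nrow(closed_ocrs)) {
    ivs[[length(ivs) + 1L]] <- cbind(closed_ocrs$start, closed_ocrs$end)
  }
  nuc <- config$nucleosomes
  if (isTRUE(nuc$enabled)) {
    first <- floor((frag_start - nuc$width - nuc_offset) / nuc$repeat_len)
    starts <- nuc_offset + (first:ceiling((frag_end - nuc_offset) /
                                            nuc$repeat_len)) * nuc$repeat_len
    nivs <- cbind(starts, starts + nuc$width)
    # nucleosome-free open OCRs: clip nucleosomes out of open OCR intervals
    open_ocrs <- config$ocrs
    if (!is.null(closed_ocrs) && !is.null(open_ocrs) && nrow(open_ocrs)) {
      open_ocrs <- open_ocrs[!(open_ocrs$start %in% closed_ocrs$start), ,
                             drop = FALSE]
    }
    if (!is.null(open_ocrs) && nrow(open_ocrs)) {
      keep <- IRanges::IRanges(nivs[, 1] + 1L, nivs[, 2])
      drop <- IRanges::IRanges(open_ocrs$start + 1L, open_ocrs$end)
      res <- IRanges::setdiff(keep, drop)
      nivs <- cbind(IRanges::start(res) - 1L, IRanges::end(res))
    }
    if (nrow(nivs)) ivs[[length(ivs) + 1L]] <- nivs
  }
  if (!length(ivs)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, ivs)
  m <- m[m[, 2] > frag_start & m[, 1] < frag_end, , drop = FALSE]
  if (!nrow(m)) return(matrix(numeric(0), ncol = 2))
  red <- IRanges::reduce(IRanges::IRanges(m[, 1] + 1L, m[, 2]))
  cbind(IRanges::start(red) - 1L, IRanges::end(red))
}

#' Simulate deaminated molecules and their ground truth
#'
#' Draws fragments, per-molecule TF occupancy and OCR accessibility, builds
#' each molecule's protection mask, converts cytosines on the molecule's
#' strand according to the enzyme model, and applies sequencing error.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param seed Integer seed.
#' @param naked If `TRUE`, simulate protein-free DNA: no nucleosomes, no TF
#'   occupancy, no closed OCRs (context bias still applies).
#' @param keep_truth If `TRUE`, record per-molecule conversion events,
#'   protection masks and expected per-cytosine conversion probabilities
#'   (memory-heavy; intended for small runs and oracle tests).
#' @return List with `alignments` (a `data.table` of perfectly aligned reads:
#'   `qname, flag, chrom, pos, mapq, cigar, seq, strand, barcode, duplicate`),
#'   and `truth` (list: `sites`, `occupancy`, and if `keep_truth` also
#'   `events`, `masks`, `expected`).
#' @export
simulate_molecules <- function(config, reference, seed, naked = FALSE,
                               keep_truth = FALSE) {
  set.seed(seed)
  chars <- reference$chars
  L <- reference$length
  mol <- config$molecules
  regions <- mol$regions
  if (is.null(regions)) regions <- data.frame(start = 0L, end = L)
  sites <- config$tf_sites
  if (naked || is.null(sites)) {
    sites <- data.frame(name = character(0), consensus = character(0),
                        pos = integer(0), strand = character(0),
                        theta = numeric(0), pad = integer(0))
  }
  ocrs <- if (naked) NULL else config$ocrs
  enz <- config$enzyme
  nuc <- config$nucleosomes
  if (naked) nuc$enabled <- FALSE
  cfg <- config
  cfg$nucleosomes <- nuc

  n_per <- if (cfg$cells$n_cells > 0) {
    cfg$cells$n_cells * cfg$cells$molecules_per_cell
  } else mol$n_molecules
  barcodes <- if (cfg$cells$n_cells > 0) {
    rep(sprintf("BC%03d", seq_len(cfg$cells$n_cells)),
        each = cfg$cells$molecules_per_cell)
  } else NULL

  aln <- vector("list", nrow(regions) * n_per)
  occ <- vector("list", nrow(regions) * n_per)
  events <- if (keep_truth) vector("list", nrow(regions) * n_per) else NULL
  masks <- if (keep_truth) vector("list", nrow(regions) * n_per) else NULL
  expected <- if (keep_truth) vector("list", nrow(regions) * n_per) else NULL
  k <- 0L
  mult <- enz$context_mult

  for (r in seq_len(nrow(regions))) {
    for (i in seq_len(n_per)) {
      k <- k + 1L
      qname <- sprintf("mol_%d_%d", r, i)
      flen <- max(30L, round(stats::rnorm(1, mol$frag_len, mol$frag_sd)))
      centre <- regions$start[r] +
        floor(stats::runif(1) * (regions$end[r] - regions$start[r]))
      fs <- max(0L, as.integer(centre - flen %/% 2L))
      fe <- min(L, fs + flen)
      fs <- max(0L, fe - flen)
      ms <- if (stats::runif(1) < 0.5) "+" else "-"

      ov <- sites[sites$pos < fe & (sites$pos + nchar(sites$consensus)) > fs, ,
                  drop = FALSE]
      bound <- if (nrow(ov)) stats::runif(nrow(ov)) < ov$theta else logical(0)
      bound_sites <- ov[bound, , drop = FALSE]
      closed <- NULL
      if (!is.null(ocrs) && nrow(ocrs)) {
        oov <- ocrs[ocrs$start < fe & ocrs$end > fs, , drop = FALSE]
        if (nrow(oov)) {
          has_bound <- vapply(seq_len(nrow(oov)), function(j) {
            any(bound_sites$pos >= oov$start[j] & bound_sites$pos < oov$end[j])
          }, logical(1))
          is_closed <- !has_bound & stats::runif(nrow(oov)) >= oov$openness
          closed <- oov[is_closed, , drop = FALSE]
        }
      }
      nuc_off <- if (isTRUE(nuc$enabled)) {
        as.integer(round(stats::rnorm(1, 0, nuc$jitter_sd)))
      } else 0L
      mask <- .molecule_mask(cfg, bound_sites, closed, fs, fe, nuc_off)

      frag <- chars[(fs + 1L):fe]
      if (ms == "+") {
        cpos0 <- fs + which(frag == "C") - 1L
        five <- ifelse(cpos0 > 0L, chars[cpos0], "N")
      } else {
        cpos0 <- fs + which(frag == "G") - 1L
        five <- ifelse(cpos0 + 2L <= L,
                       c(A = "T", C = "G", G = "C", T = "A",
                         N = "N")[chars[cpos0 + 2L]], "N")
      }
      if (length(cpos0)) {
        masked <- rep(FALSE, length(cpos0))
        if (nrow(mask)) {
          for (j in seq_len(nrow(mask)))
            masked <- masked | (cpos0 >= mask[j, 1] & cpos0 < mask[j, 2])
        }
        m5 <- ifelse(five %in% names(mult), mult[five], 1)
        p <- ifelse(masked, enz$p_protected, pmin(enz$p_open * m5, enz$cap))
        conv <- stats::runif(length(cpos0)) < p
      } else {
        p <- numeric(0); conv <- logical(0)
      }
      read <- frag
      if (any(conv)) {
        off <- cpos0[conv] - fs + 1L
        read[off] <- if (ms == "+") "T" else "A"
      }
      if (mol$error_rate > 0) {
        err <- which(stats::runif(length(read)) < mol$error_rate)
        if (length(err)) {
          read[err] <- vapply(read[err], function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
          }, character(1))
        }
      }
      aln[[k]] <- list(qname = qname, flag = 0L, chrom = cfg$contig,
                       pos = fs, mapq = 60L,
                       cigar = sprintf("%dM", fe - fs),
                       seq = paste(read, collapse = ""), strand = ms,
                       barcode = if (is.null(barcodes)) NA_character_
                                 else barcodes[i],
                       duplicate = FALSE)
      if (nrow(ov)) {
        occ[[k]] <- data.table::data.table(qname = qname, site = ov$name,
                                           bound = bound)
      }
      if (keep_truth) {
        events[[k]] <- data.table::data.table(
          qname = qname, pos = cpos0, strand = ms, converted = conv)
        if (nrow(mask)) {
          masks[[k]] <- data.table::data.table(
            qname = qname, start = mask[, 1], end = mask[, 2])
        }
        expected[[k]] <- data.table::data.table(
          qname = qname, pos = cpos0, strand = ms, p_expected = p)
      }
    }
  }
  alignments <- data.table::rbindlist(aln)
  data.table::setorder(alignments, chrom, pos)
  truth <- list(
    sites = sites,
    occupancy = data.table::rbindlist(occ[!vapply(occ, is.null, logical(1))]))
  if (keep_truth) {
    truth$events <- data.table::rbindlist(events)
    truth$masks <- data.table::rbindlist(masks[!vapply(masks, is.null,
                                                       logical(1))])
    truth$expected <- data.table::rbindlist(expected)
  }
  list(alignments = alignments, truth = truth)
}

#' Simulate a multi-condition series sharing one reference and site layout
#'
#' @param config Base [sim_config()].
#' @param schedule Named list: one element per condition, each a list with
#'   optional `theta` (named vector, per-TF occupancy) and `openness`
#'   (scalar or per-OCR vector: fraction of molecules with the OCR
#'   accessible).
#' @param reference Output of [simulate_reference()].
#' @param seed Integer seed; condition i uses `seed + i`.
#' @return Named list of [simulate_molecules()] outputs.
#' @export
simulate_condition_series <- function(config, schedule, reference, seed) {
  out <- vector("list", length(schedule))
  names(out) <- names(schedule)
  for (i in seq_along(schedule)) {
    cfg <- config
    sc <- schedule[[i]]
    if (!is.null(sc$theta)) {
      unknown <- setdiff(names(sc$theta), cfg$tf_sites$name)
      if (length(unknown))
        stop_ft("schedule references unknown TF: %s",
                paste(unknown, collapse = ", "))
      idx <- match(cfg$tf_sites$name, names(sc$theta))
      cfg$tf_sites$theta <- ifelse(is.na(idx), cfg$tf_sites$theta,
                                   sc$theta[idx])
    }
    if (!is.null(sc$openness)) cfg$ocrs$openness <- sc$openness
    out[[i]] <- simulate_molecules(cfg, reference, seed + i)
  }
  out
}

#' Write simulated alignments as a SAM file
#'
#' Reads are emitted coordinate-sorted with MAPQ 60, the molecule conversion
#' strand in tag `XG` and, when present, the cell barcode in tag `CB`.
#'
#' @param alignments Alignment table from [simulate_molecules()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  a <- data.table::as.data.table(alignments)
  data.table::setorder(a, chrom, pos)
  flags <- a$flag + ifelse(a$duplicate, 1024L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXG:Z:%s",
                   a$qname, flags, a$chrom, a$pos + 1L, a$mapq, a$cigar,
                   a$seq, strrep("I", nchar(a$seq)), a$strand)
  has_bc <- !is.na(a$barcode)
  lines[has_bc] <- paste0(lines[has_bc], "\tCB:Z:", a$barcode[has_bc])
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param reference Output of [simulate_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(reference$seq)
  names(seqs) <- reference$contig
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
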