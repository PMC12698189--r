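# Internal helpers shared across modules. Genomic coordinates are 0-based
# half-open everywhere inside the package; conversion to the 1-based
# coordinates of Biostrings/IRanges happens only at the call sites below.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings reverseComplement DNAString
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised reverse complement for plain character vectors
revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a reference sequence into a character vector, cached per call site
seq_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

# reference slice [start, end) in 0-based coordinates
seq_window <- function(chars, start0, end0) {
  start0 <- max(start0, 0L)
  end0 <- min(end0, length(chars))
  if (end0 <= start0) return(character(0))
  chars[(start0 + 1L):end0]
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# context string of width k centred on a cytosine at 0-based position pos0,
# reported on the strand of the cytosine; positions running off the contig
# are padded with 'N'
cytosine_context <- function(chars, pos0, strand, k) {
  half <- (k - 1L) %/% 2L
  idx <- (pos0 - half):(pos0 + half)
  bases <- ifelse(idx >= 0L & idx < length(chars), chars[pmax(idx, 0L) + 1L], "N")
  ctx <- paste(bases, collapse = "")
  if (strand == "-") ctx <- revcomp(ctx) else ctx
}

# vectorised variant: pos0 and strand are vectors
cytosine_context_vec <- function(chars, pos0, strand, k) {
  half <- (k - 1L) %/% 2L
  n <- length(pos0)
  if (n == 0) return(character(0))
  offs <- (-half):half
  mat <- matrix("N", nrow = n, ncol = k)
  for (j in seq_len(k)) {
    idx <- pos0 + offs[j]
    ok <- idx >= 0L & idx < length(chars)
    mat[ok, j] <- chars[idx[ok] + 1L]
  }
  ctx <- apply(mat, 1L, paste, collapse = "")
  neg <- strand == "-"
  if (any(neg)) ctx[neg] <- revcomp_vec(ctx[neg])
  ctx
}

# all length-k contexts with a central C (other positions over ACGT)
all_c_contexts <- function(k) {
  half <- (k - 1L) %/% 2L
  sides <- expand.grid(rep(list(DNA_BASES), k - 1L), stringsAsFactors = FALSE)
  apply(sides, 1L, function(row) {
    paste0(paste(row[seq_len(half)], collapse = ""), "C",
           paste(row[half + seq_len(half)], collapse = ""))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ft <- function(...) stop(sprintf(...), call. = FALSE)
warn_ft <- function(...) warning(sprintf(...), call. = FALSE)
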