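# Independent oracles, deliberately written along different code paths than
# the package implementations they check.

# Exhaustive six-frame ORF scan: every start-codon position is extended to
# its first in-frame stop; candidates sharing a (frame, stop) keep only the
# 5'-most start; starts downstream of the last stop of a frame form partial
# ORFs clipped at the region edge.
oracle_sixframe <- function(region_seq, region_start, region_end, min_aa,
                            start_codons = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(region_seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(region_seq)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") region_seq else rc
    found <- list()  # key: frame|stop-position
    for (i in 0:(n - 3L)) {
      if (!substr(s, i + 1L, i + 3L) %in% start_codons) next
      j <- i
      stop_at <- NA_integer_
      while (j + 3L <= n) {
        if (substr(s, j + 1L, j + 3L) %in% stops) { stop_at <- j; break }
        j <- j + 3L
      }
      if (!is.na(stop_at) && stop_at == i) next  # start cannot be a stop
      key <- paste(i %% 3L, if (is.na(stop_at)) "edge" else stop_at)
      if (is.null(found[[key]]) || i < found[[key]]$i)
        found[[key]] <- list(i = i, stop_at = stop_at)
    }
    for (h in found) {
      if (is.na(h$stop_at)) {
        lo <- h$i
        hi <- h$i + 3L * ((n - h$i) %/% 3L)
        aa_len <- (hi - lo) %/% 3L
        partial <- TRUE
      } else {
        lo <- h$i; hi <- h$stop_at + 3L
        aa_len <- (hi - lo) %/% 3L - 1L
        partial <- FALSE
      }
      if (aa_len < min_aa) next
      gs <- if (strand == "+") region_start + lo else region_end - hi
      ge <- if (strand == "+") region_start + hi else region_end - lo
      out[[length(out) + 1L]] <- data.frame(
        start = gs, end = ge, strand = strand, partial = partial,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), partial = logical()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), ]
}

# Naive direct DFT: scalar trigonometric accumulation, no fft, no complex
# vectorization
oracle_power_at_period <- function(x, period) {
  n <- length(x)
  re <- 0; im <- 0
  for (t in 0:(n - 1L)) {
    ang <- -2 * pi * t / period
    re <- re + x[t + 1L] * cos(ang)
    im <- im + x[t + 1L] * sin(ang)
  }
  (re^2 + im^2) / (n * sum(x^2) + .Machine$double.eps)
}

oracle_period <- function(counts, max_lag) {
  x <- counts - mean(counts)
  lags <- 2:max_lag
  pw <- vapply(lags, function(l) oracle_power_at_period(x, l), numeric(1))
  lags[which.max(pw)]
}
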