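#' Metagene profile of small-RNA fragment termini
#'
#' Aggregates, over all genes, the 5' and 3' termini of sense-strand
#' fragments at signed offsets relative to an anchor codon. Offset 0 is the
#' first base of the anchor codon (the A of ATG for the start anchor);
#' negative offsets lie 5' (upstream in transcript orientation). Minus-strand
#' genes are flipped into transcript orientation, so their profiles
#' superimpose on plus-strand ones. The 3' terminus of a half-open fragment
#' `[s, e)` is position `e - 1`. Contributions are weighted by the
#' collapsed-duplicate fragment count. Genes whose window is truncated by a
#' contig edge contribute only their covered offsets, tracked in
#' `gene_cover`.
#'
#' @param fragments fragment data.frame (chrom, start, end, strand, count)
#' @param genes [gene_models]-like data.frame (gene_id, chrom, start, end,
#'   strand)
#' @param genome_length contig length (edge bookkeeping); may be `Inf`
#' @param window half-width of the offset window, nt
#' @param anchor `"start_codon"` or `"stop_codon"`
#' @return a `termini_profile` list: anchor, window, offsets, counts5,
#'   counts3, n_genes, gene_cover, and per-gene 5'-termini count matrix
#'   `per_gene5`
#' @export
metagene_termini <- function(fragments, genes, genome_length = Inf,
                             window = 40L, anchor = c("start_codon",
                                                      "stop_codon")) {
  anchor <- match.arg(anchor)
  offs <- (-window):window
  n_off <- length(offs)
  counts5 <- setNames(numeric(n_off), offs)
  counts3 <- setNames(numeric(n_off), offs)
  gene_cover <- setNames(numeric(n_off), offs)
  per_gene5 <- matrix(0, nrow(genes), n_off,
                      dimnames = list(genes$gene_id, offs))
  n_genes <- 0L
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    plus <- gn$strand == "+"
    a <- if (anchor == "start_codon") {
      if (plus) gn$start else gn$end - 1L
    } else {
      if (plus) gn$end - 3L else gn$start + 2L
    }
    # offsets covered by the contig for this gene
    if (plus) {
      lo <- max(-window, -a); hi <- min(window, genome_length - 1L - a)
    } else {
      lo <- max(-window, a - genome_length + 1L); hi <- min(window, a)
    }
    if (lo > hi) next
    cov_idx <- which(offs >= lo & offs <= hi)
    gene_cover[cov_idx] <- gene_cover[cov_idx] + 1L
    fr <- fragments[fragments$chrom == gn$chrom &
                      fragments$strand == gn$strand, , drop = FALSE]
    if (nrow(fr) == 0L) next
    p5 <- if (plus) fr$start else fr$end - 1L
    p3 <- if (plus) fr$end - 1L else fr$start
    o5 <- if (plus) p5 - a else a - p5
    o3 <- if (plus) p3 - a else a - p3
    in5 <- o5 >= -window & o5 <= window
    in3 <- o3 >= -window & o3 <= window
    any_in <- FALSE
    if (any(in5)) {
      t5 <- as.numeric(tapply(fr$count[in5], factor(o5[in5], levels = offs),
                              sum))
      t5[is.na(t5)] <- 0
      counts5 <- counts5 + t5
      per_gene5[i, ] <- per_gene5[i, ] + t5
      any_in <- TRUE
    }
    if (any(in3)) {
      t3 <- as.numeric(tapply(fr$count[in3], factor(o3[in3], levels = offs),
                              sum))
      t3[is.na(t3)] <- 0
      counts3 <- counts3 + t3
      any_in <- TRUE
    }
    if (any_in) n_genes <- n_genes + 1L
  }
  structure(list(anchor = anchor, window = window, offsets = offs,
                 counts5 = counts5, counts3 = counts3, n_genes = n_genes,
                 gene_cover = gene_cover, per_gene5 = per_gene5),
            class = "termini_profile")
}

#' @export
print.termini_profile <- function(x, ...) {
  cat(sprintf(
    "termini_profile (%s anchor, +/-%d nt): %d genes, %g 5' and %g 3' termini\n",
    x$anchor, x$window, x$n_genes, sum(x$counts5), sum(x$counts3)))
  invisible(x)
}

#' Export a metagene profile as a TSV table
#' @param profile a `termini_profile`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metagene_tsv <- function(profile, path) {
  write_tsv_table(data.frame(offset = profile$offsets,
                             counts5 = profile$counts5,
                             counts3 = profile$counts3,
                             genes_covering = profile$gene_cover), path)
  invisible(path)
}

#' Detect the Shine-Dalgarno protection window
#'
#' Global call: the contiguous run of offsets within `search` whose pooled
#' 5'-termini counts exceed the flank background (median of offsets outside
#' `search`) by at least `fold`. Per-gene calls use the gene's own in-window
#' termini; because pooled counts are much noisier per gene, a
#' Bonferroni-corrected binomial test of the peak against a uniform
#' distribution over the profile window guards the fold rule. `sd_match`
#' reports an exact-or-one-mismatch motif occurrence within the called
#' window sequence.
#'
#' @param profile a `termini_profile` from [metagene_termini] (start anchor)
#' @param genes the gene table the profile was built from
#' @param genome DNAStringSet (motif matching; `NULL` disables `sd_match`)
#' @param motif Shine-Dalgarno motif (`""` disables matching)
#' @param search offset range searched, default c(-20, 3): the SD sits 4-15
#'   nt upstream, with a small allowance into the start codon
#' @param fold enrichment over flank median required
#' @param min_fragments minimum weighted in-window termini per gene
#' @param alpha per-gene significance level for the peak test
#' @return list with `global` (window_lo, window_hi, background, called) and
#'   `calls` (data.frame: gene_id, window_start, window_end, peak_offset,
#'   score, n_fragments, p_value, sd_match)
#' @export
detect_protection_window <- function(profile, genes, genome = NULL,
                                     motif = "AGGAGG",
                                     search = c(-20L, 3L), fold = 3,
                                     min_fragments = 10L, alpha = 0.05) {
  stopifnot(profile$anchor == "start_codon")
  offs <- profile$offsets
  in_search <- offs >= search[1L] & offs <= search[2L]
  flank <- profile$counts5[!in_search]
  bg <- max(median(flank), 1)
  above <- profile$counts5 >= fold * bg & in_search
  global <- list(window_lo = NA_integer_, window_hi = NA_integer_,
                 background = bg, called = FALSE)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    tot <- vapply(runs, function(j)
      sum(profile$counts5[starts[j]:ends[j]]), numeric(1))
    best <- runs[which.max(tot)]
    global$window_lo <- offs[starts[best]]
    global$window_hi <- offs[ends[best]]
    global$called <- TRUE
  }

  calls <- list()
  n_search <- sum(in_search)
  n_off <- length(offs)
  for (i in seq_len(nrow(genes))) {
    gcounts <- profile$per_gene5[i, ]
    n_in <- sum(gcounts[in_search])
    if (n_in < min_fragments) next
    peak_i <- which(in_search)[which.max(gcounts[in_search])]
    peak <- gcounts[peak_i]
    gflank <- max(median(gcounts[!in_search]), 1)
    score <- peak / gflank
    n_tot <- sum(gcounts)
    p <- min(1, n_search *
               pbinom(peak - 1, n_tot, 1 / n_off, lower.tail = FALSE))
    if (score < fold || p > alpha) next
    # called window: the contiguous enriched run around the peak
    gabove <- gcounts >= fold * gflank & in_search
    r <- rle(gabove)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    j <- which(r$values & starts <= peak_i & ends >= peak_i)
    w_lo <- offs[starts[j[1L]]]; w_hi <- offs[ends[j[1L]]]
    gn <- genes[i, ]
    if (gn$strand == "+") {
      a <- gn$start
      ws <- a + w_lo; we <- a + w_hi + 1L
    } else {
      a <- gn$end - 1L
      ws <- a - w_hi; we <- a - w_lo + 1L
    }
    sd_match <- FALSE
    if (!is.null(genome) && nzchar(motif)) {
      # termini mark the motif's 5' edge: extend the searched sequence
      # transcript-downstream by the motif length
      ci <- match(gn$chrom, names(genome))
      L <- Biostrings::width(genome)[ci]
      ext <- nchar(motif) + 2L
      if (gn$strand == "+") { lo2 <- max(0L, ws - 2L); hi2 <- min(L, we + ext) }
      else { lo2 <- max(0L, ws - ext); hi2 <- min(L, we + 2L) }
      wseq <- as.character(Biostrings::subseq(genome[[ci]], lo2 + 1L, hi2))
      if (gn$strand == "-") wseq <- revcomp_chr(wseq)
      m <- Biostrings::matchPattern(motif, Biostrings::DNAString(wseq),
                                    max.mismatch = 1)
      sd_match <- length(m) > 0L
    }
    calls[[length(calls) + 1L]] <- data.frame(
      gene_id = gn$gene_id, window_start = as.integer(ws),
      window_end = as.integer(we), peak_offset = offs[peak_i],
      score = unname(score), n_fragments = unname(n_in),
      p_value = unname(p), sd_match = sd_match, stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(), window_start = integer(),
               window_end = integer(), peak_offset = integer(),
               score = numeric(), n_fragments = numeric(),
               p_value = numeric(), sd_match = logical())
  rownames(calls) <- NULL
  list(global = global, calls = calls)
}

# direct power of mean-removed counts at the frequency of a candidate
# period; vectorized complex exponential sum
spectral_power_at_period <- function(x, period) {
  n <- length(x)
  t <- seq_len(n) - 1
  z <- sum(x * exp(-2i * pi * t / period))
  Mod(z)^2 / (n * sum(x^2) + .Machine$double.eps)
}

#' Estimate the codon-step periodicity of fragment 5' termini
#'
#' Pools 5'-termini offsets (relative to the start codon, sense strand)
#' within CDS interiors — the first and last `trim` nt of each gene are
#' excluded, isolating the elongation-phase signal from initiation and
#' termination peaks — into a per-offset count vector, and evaluates the
#' discrete spectrum of the mean-removed counts at the frequency of every
#' candidate period 2..`max_lag`. The reported period is the candidate with
#' maximal normalized power; `strength` is that peak's excess over the
#' median across candidates (near 1 for a pure codon-step comb, near 0 for
#' uniform counts).
#'
#' @param fragments fragment data.frame
#' @param genes gene table (gene_id, chrom, start, end, strand)
#' @param max_lag largest candidate period, nt
#' @param trim nt excluded at each CDS end
#' @param min_genes,min_fragments minimum evidence; below `min_fragments`
#'   the period is `NA` with a diagnostic
#' @param strength_threshold `significant` is TRUE when strength exceeds
#'   this
#' @return list(period, strength, significant, n_fragments, n_genes,
#'   power = named vector over candidate periods, counts)
#' @export
estimate_periodicity <- function(fragments, genes, max_lag = 10L,
                                 trim = 9L, min_genes = 5L,
                                 min_fragments = 100L,
                                 strength_threshold = 0.4) {
  max_len <- max(genes$end - genes$start)
  counts <- numeric(max_len)
  cover <- numeric(max_len)   # genes whose interior spans each offset
  n_frag <- 0; genes_hit <- 0L
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    glen <- gn$end - gn$start
    if (glen - trim - 1L >= trim)
      cover[(trim + 1L):(glen - trim)] <- cover[(trim + 1L):(glen - trim)] + 1
    fr <- fragments[fragments$chrom == gn$chrom &
                      fragments$strand == gn$strand, , drop = FALSE]
    if (nrow(fr) == 0L) next
    p5 <- if (gn$strand == "+") fr$start else fr$end - 1L
    o <- if (gn$strand == "+") p5 - gn$start else gn$end - 1L - p5
    keep <- o >= trim & o <= glen - trim - 1L
    if (!any(keep)) next
    genes_hit <- genes_hit + 1L
    tb <- tapply(fr$count[keep], o[keep], sum)
    idx <- as.integer(names(tb)) + 1L
    counts[idx] <- counts[idx] + tb
    n_frag <- n_frag + sum(fr$count[keep])
  }
  if (genes_hit < min_genes || n_frag < min_fragments) {
    return(list(period = NA_integer_, strength = NA_real_,
                significant = FALSE, n_fragments = n_frag,
                n_genes = genes_hit, power = NULL, counts = counts,
                diagnostic = sprintf(
                  "insufficient evidence: %d genes, %g interior termini",
                  genes_hit, n_frag)))
  }
  # per-gene-coverage normalization removes the envelope induced by the
  # gene-length distribution; sparsely covered tail offsets are dropped
  usable <- which(cover >= min(3, max(cover)))
  rate <- counts[usable] / cover[usable]
  res <- periodicity_from_counts(rate, max_lag = max_lag,
                                 strength_threshold = strength_threshold,
                                 n_fragments = n_frag, n_genes = genes_hit)
  res$counts <- counts
  res
}

#' Periodicity of a per-offset count vector
#'
#' The estimator behind [estimate_periodicity], exposed for count vectors
#' built elsewhere.
#'
#' @param counts per-offset non-negative counts
#' @param max_lag largest candidate period
#' @param strength_threshold significance cut on the strength
#' @param n_fragments,n_genes bookkeeping copied into the result
#' @return see [estimate_periodicity]
#' @export
periodicity_from_counts <- function(counts, max_lag = 10L,
                                    strength_threshold = 0.4,
                                    n_fragments = sum(counts),
                                    n_genes = NA_integer_) {
  stopifnot(max_lag >= 2L, length(counts) > max_lag)
  x <- counts - mean(counts)
  lags <- 2:max_lag
  pw <- vapply(lags, function(l) spectral_power_at_period(x, l), numeric(1))
  names(pw) <- lags
  q <- pw / max(sum(pw), .Machine$double.eps)
  period <- lags[which.max(pw)]
  strength <- unname(q[as.character(period)] - median(q))
  list(period = period, strength = strength,
       significant = strength > strength_threshold,
       n_fragments = n_fragments, n_genes = n_genes, power = pw,
       counts = counts)
}

#' Call ribosome binding sites per gene
#'
#' Builds the start-anchored termini profile, runs the per-gene protection
#' test, and returns calls plus a misses report. Novel ORFs recovered by
#' proteogenomics are eligible anchors: pass them concatenated with the
#' annotated genes.
#'
#' @param genes gene table (annotated CDS and/or novel ORFs; needs gene_id,
#'   chrom, start, end, strand)
#' @param fragments fragment data.frame
#' @param genome DNAStringSet
#' @param window metagene half-window, nt
#' @param motif SD motif for `sd_match`
#' @param fold,min_fragments,alpha protection-test parameters (see
#'   [detect_protection_window])
#' @return list(calls, misses, profile, global)
#' @export
call_rbs <- function(genes, fragments, genome, window = 40L,
                     motif = "AGGAGG", fold = 3, min_fragments = 10L,
                     alpha = 0.05) {
  L <- Biostrings::width(genome)[1L]
  profile <- metagene_termini(fragments, genes, genome_length = L,
                              window = window, anchor = "start_codon")
  det <- detect_protection_window(profile, genes, genome, motif = motif,
                                  fold = fold,
                                  min_fragments = min_fragments,
                                  alpha = alpha)
  misses <- setdiff(genes$gene_id, det$calls$gene_id)
  list(calls = det$calls, misses = misses, profile = profile,
       global = det$global)
}

#' Write RBS calls as GFF3
#' @param calls calls data.frame from [call_rbs]
#' @param genes the gene table used for calling (strand lookup)
#' @param chrom chromosome name
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rbs_gff3 <- function(calls, genes, chrom, path) {
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- genes$strand[match(calls$gene_id, genes$gene_id)]
  models <- gene_models(
    gene_id = paste0("rbs_", calls$gene_id), chrom = chrom,
    start = calls$window_start, end = calls$window_end, strand = strand,
    kind = "RBS",
    attributes = lapply(seq_len(nrow(calls)), function(i)
      c(gene = calls$gene_id[i],
        peak_offset = as.character(calls$peak_offset[i]),
        score = sprintf("%.3f", calls$score[i]),
        sd_match = tolower(as.character(calls$sd_match[i])))))
  write_gff3(models, path)
  invisible(path)
}

#' Plot a metagene termini profile
#' @param profile a `termini_profile`
#' @return a ggplot object
#' @export
plot_metagene <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- rbind(
    data.frame(offset = profile$offsets, count = profile$counts5,
               terminus = "5'"),
    data.frame(offset = profile$offsets, count = profile$counts3,
               terminus = "3'"))
  ggplot2::ggplot(df, ggplot2::aes(offset, count, fill = terminus)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c("5'" = "firebrick",
                                          "3'" = "steelblue")) +
    ggplot2::labs(x = sprintf("offset from %s (nt)", profile$anchor),
                  y = "weighted termini") +
    ggplot2::theme_minimal()
}
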