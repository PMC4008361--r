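#' Normalize coverage tracks within and between libraries
#'
#' Within-library: counts-per-million scaling (tracks sharing a
#' `library_id` — typically the two strands of one time point — are scaled
#' by their joint total). Between-library: a median-of-ratios factor
#' computed over annotated-gene mean coverages (the DESeq-style size
#' factor), applied when an annotation and at least two libraries are
#' available.
#'
#' @param tracks list of [coverage_track] objects
#' @param annotation optional [gene_models] used for between-library factors
#' @return the normalized track list, with a `size_factors` attribute
#' @export
normalize_tracks <- function(tracks, annotation = NULL) {
  stopifnot(length(tracks) > 0L)
  libs <- vapply(tracks, `[[`, character(1), "library_id")
  totals <- tapply(vapply(tracks, function(t) sum(t$values), numeric(1)),
                   libs, sum)
  if (any(totals == 0))
    stop("empty library: ", paste(names(totals)[totals == 0], collapse = ", "))
  out <- lapply(tracks, function(t) {
    t$values <- t$values * 1e6 / totals[[t$library_id]]
    t
  })
  sf <- setNames(rep(1, length(totals)), names(totals))
  if (!is.null(annotation) && length(unique(libs)) >= 2L) {
    genes <- annotation[annotation$kind == "CDS", , drop = FALSE]
    if (nrow(genes) >= 2L) {
      mat <- vapply(unique(libs), function(lb) {
        tr <- out[libs == lb]
        vapply(seq_len(nrow(genes)), function(i) {
          gn <- genes[i, ]
          v <- 0
          for (t in tr)
            if (t$strand %in% c(gn$strand, "both"))
              v <- v + mean(t$values[(gn$start + 1L):gn$end])
          v
        }, numeric(1))
      }, numeric(nrow(genes)))
      pos <- rowSums(mat > 0) == ncol(mat)
      if (sum(pos) >= 2L) {
        lg <- log(mat[pos, , drop = FALSE])
        geo <- rowMeans(lg)
        sfv <- apply(lg, 2L, function(col) exp(median(col - geo)))
        sf[colnames(mat)] <- sfv
        out <- lapply(out, function(t) {
          t$values <- t$values / sf[[t$library_id]]
          t
        })
      }
    }
  }
  attr(out, "size_factors") <- sf
  out
}

# per-track genomic background: median coverage over positions free of
# annotated features (floor avoids zero thresholds on sparse libraries)
track_backgrounds <- function(tracks, annotation = NULL, floor = 1e-3) {
  vapply(tracks, function(t) {
    v <- t$values
    if (!is.null(annotation) && nrow(annotation) > 0L) {
      mask <- rep(TRUE, length(v))
      ann <- annotation[annotation$start < length(v), , drop = FALSE]
      for (i in seq_len(nrow(ann)))
        mask[(ann$start[i] + 1L):min(ann$end[i], length(v))] <- FALSE
      v <- v[mask]
    }
    max(median(v), floor)
  }, numeric(1))
}

#' Detect transcribed intergenic regions
#'
#' Within each intergenic region, maximal runs of at least `min_run` bases
#' whose coverage reaches `k` times the genomic background (median coverage
#' of annotation-free positions, per track) in at least one time point are
#' reported; runs separated by gaps of at most `merge_gap` nt are merged.
#'
#' @param tracks normalized [coverage_track] list (strand-specific)
#' @param intergenic data.frame from [extract_intergenic]
#' @param annotation [gene_models] used for background estimation
#' @param k fold-over-background threshold
#' @param min_run minimum run length, nt
#' @param merge_gap maximum gap merged, nt
#' @return data.frame: chrom, start, end, strand, max_expr, dynamic,
#'   per-time-point region means in `attr(, "tp_means")` (one row per
#'   region, one column per library)
#' @export
detect_transcribed_regions <- function(tracks, intergenic, annotation,
                                       k = 5, min_run = 50L,
                                       merge_gap = 20L) {
  bg <- track_backgrounds(tracks, annotation)
  strands <- vapply(tracks, `[[`, character(1), "strand")
  libs <- vapply(tracks, `[[`, character(1), "library_id")
  out <- list(); tpm <- list()
  for (strand in intersect(c("+", "-", "both"), unique(strands))) {
    tsel <- which(strands == strand)
    for (ri in seq_len(nrow(intergenic))) {
      rg <- intergenic[ri, ]
      span <- (rg$start + 1L):rg$end
      above <- rep(FALSE, length(span))
      for (ti in tsel)
        above <- above | tracks[[ti]]$values[span] >= k * bg[ti]
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      if (length(runs) == 0L) next
      ir <- IRanges::reduce(IRanges::IRanges(starts[runs], ends[runs]),
                            min.gapwidth = merge_gap + 1L)
      ir <- ir[IRanges::width(ir) >= min_run]
      for (j in seq_along(ir)) {
        gs <- rg$start + IRanges::start(ir)[j] - 1L
        ge <- rg$start + IRanges::end(ir)[j]
        means <- vapply(tsel, function(ti)
          mean(tracks[[ti]]$values[(gs + 1L):ge]), numeric(1))
        names(means) <- libs[tsel]
        cv <- if (mean(means) > 0) sd(means) / mean(means) else 0
        out[[length(out) + 1L]] <- data.frame(
          chrom = rg$chrom, start = gs, end = ge,
          strand = if (strand == "both") "+" else strand,
          max_expr = max(means), dynamic = cv > 0.5,
          stringsAsFactors = FALSE)
        tpm[[length(tpm) + 1L]] <- means
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      max_expr = numeric(), dynamic = logical())
    attr(res, "tp_means") <- matrix(numeric(0), 0, 0)
    return(res)
  }
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$start, res$strand)
  res <- res[o, ]
  rownames(res) <- NULL
  attr(res, "tp_means") <- do.call(rbind, tpm)[o, , drop = FALSE]
  res
}

#' Is an interval transcribed?
#'
#' TRUE iff the mean normalized coverage over the interval reaches `k`
#' times the genomic background in at least one time point on the matching
#' strand.
#'
#' @param orf one-row data.frame with chrom, start, end, strand
#' @param tracks normalized [coverage_track] list
#' @param annotation [gene_models] for background estimation
#' @param k fold-over-background threshold
#' @param background optional precomputed [track_backgrounds] result
#' @return list(transcribed, mean_expr) — mean_expr is the maximum
#'   per-time-point mean
#' @export
is_transcribed <- function(orf, tracks, annotation = NULL, k = 5,
                           background = NULL) {
  stopifnot(nrow(orf) == 1L)
  if (orf$end <= orf$start) stop("empty interval")
  bg <- background %||% track_backgrounds(tracks, annotation)
  strands <- vapply(tracks, `[[`, character(1), "strand")
  tsel <- which(strands %in% c(orf$strand, "both"))
  if (length(tsel) == 0L) stop("no track matches strand ", orf$strand)
  span <- (orf$start + 1L):orf$end
  means <- vapply(tsel, function(ti) mean(tracks[[ti]]$values[span]),
                  numeric(1))
  hits <- means >= k * bg[tsel]
  list(transcribed = any(hits), mean_expr = max(means))
}

#' Size and expression cumulative-distribution tables per gene class
#'
#' Builds the long-format empirical-CDF tables comparing novel and annotated
#' genes by protein length (aa) and maximal expression.
#'
#' @param novel data.frame of novel ORFs (needs start/end and optionally
#'   mean_expr)
#' @param annotated [gene_models] of annotated CDS
#' @param tracks optional normalized tracks used to compute per-gene
#'   max expression
#' @param annotation annotation for background estimation (defaults to
#'   `annotated`)
#' @return data.frame: class, metric (`length_aa` or `max_expr`), value,
#'   cumfrac — within each class/metric, sorted values with their ECDF
#' @export
cumulative_summaries <- function(novel, annotated, tracks = NULL,
                                 annotation = annotated) {
  gene_len_aa <- function(df)
    pmax(0L, (df$end - df$start) %/% 3L - 1L)
  classes <- list(novel = novel, annotated = annotated)
  rows <- list()
  for (cl in names(classes)) {
    df <- classes[[cl]]
    if (is.null(df) || nrow(df) == 0L) next
    vals <- sort(gene_len_aa(df))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, metric = "length_aa", value = vals,
      cumfrac = seq_along(vals) / length(vals), stringsAsFactors = FALSE)
    if (!is.null(tracks)) {
      me <- vapply(seq_len(nrow(df)), function(i)
        is_transcribed(df[i, ], tracks, annotation)$mean_expr, numeric(1))
      me <- sort(me)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, metric = "max_expr", value = me,
        cumfrac = seq_along(me) / length(me), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(class = character(), metric = character(),
                      value = numeric(), cumfrac = numeric()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Plot cumulative size/expression distributions
#'
#' @param summaries output of [cumulative_summaries]
#' @return a ggplot object
#' @export
plot_cumulative <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = value, y = cumfrac, colour = class)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cumulative frequency") +
    ggplot2::theme_minimal()
}
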