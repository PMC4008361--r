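#' Extract intergenic regions
#'
#' Complement of the annotated features (any kind), clipped to the genome,
#' with flanking gene bookkeeping. Regions shorter than `min_len` are
#' dropped.
#'
#' @param annotation a [gene_models] data.frame
#' @param genome DNAStringSet (for chromosome lengths)
#' @param min_len minimum region length, nt
#' @return data.frame with chrom, start, end (0-based half-open),
#'   flank_upstream, flank_downstream (gene ids or NA at contig ends)
#' @export
extract_intergenic <- function(annotation, genome, min_len = 1L) {
  stopifnot(nrow(annotation) > 0L)
  out <- list()
  for (chrom in names(genome)) {
    L <- Biostrings::width(genome)[match(chrom, names(genome))]
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ann) == 0L) {
      out[[chrom]] <- data.frame(chrom = chrom, start = 0L, end = L,
                                 flank_upstream = NA_character_,
                                 flank_downstream = NA_character_)
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(ann$start + 1L, ann$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (length(gaps) == 0L) next
    gs <- IRanges::start(gaps) - 1L
    ge <- IRanges::end(gaps)
    ann_sorted <- ann[order(ann$start), , drop = FALSE]
    up <- vapply(gs, function(p) {
      i <- which(ann_sorted$end <= p)
      if (length(i)) ann_sorted$gene_id[max(i)] else NA_character_
    }, character(1))
    down <- vapply(ge, function(p) {
      i <- which(ann_sorted$start >= p)
      if (length(i)) ann_sorted$gene_id[min(i)] else NA_character_
    }, character(1))
    out[[chrom]] <- data.frame(chrom = chrom, start = gs, end = ge,
                               flank_upstream = up, flank_downstream = down,
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), flank_upstream = character(),
                      flank_downstream = character()))
  res <- do.call(rbind, out)
  res <- res[res$end - res$start >= min_len, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_orf_frame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(),
             start_codon = character(), protein = character(),
             partial = logical(), evidence = character(),
             classification = character(), stringsAsFactors = FALSE)
}

# genome-relative frame of an ORF: frame of its first transcribed base
genome_frame <- function(start, end, strand, genome_length) {
  ifelse(strand == "+", start %% 3L, (genome_length - end) %% 3L)
}

# scan one oriented sequence for stop-to-stop ORFs; local 0-based coords
scan_frames_local <- function(seq, min_aa, start_codons) {
  n <- nchar(seq)
  hits <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 2L) next
    idx <- f + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, idx + 1L, idx + 3L)
    stop_i <- which(codons %in% STOP_CODONS)
    seg_begin <- c(1L, stop_i + 1L)
    seg_stop <- c(stop_i, NA_integer_)  # NA: runs off the region edge
    for (sgi in seq_along(seg_begin)) {
      b <- seg_begin[sgi]; st <- seg_stop[sgi]
      last <- if (is.na(st)) n_cod else st - 1L
      if (b > last) next
      cand <- which(codons[b:last] %in% start_codons)
      if (length(cand) == 0L) next
      first_start <- b + cand[1L] - 1L
      partial <- is.na(st)
      aa_len <- last - first_start + 1L  # sense codons incl. start
      if (aa_len < min_aa) next
      lo <- idx[first_start]
      hi <- if (partial) idx[last] + 3L else idx[st] + 3L
      alt <- cand[-1L]
      hits[[length(hits) + 1L]] <- list(
        frame = f, lo = lo, hi = hi, partial = partial,
        start_codon = codons[first_start],
        alt_starts = if (length(alt)) idx[b + alt - 1L] else integer(0))
    }
  }
  hits
}

#' Six-frame ORF scan of a region
#'
#' For each of the six frames, every maximal stop-to-stop interval is
#' scanned for its 5'-most allowed start codon; the ORF runs from that start
#' through the terminal stop codon (included). Stop-free frame ends are
#' reported as `partial` ORFs clipped at the region edge. Downstream
#' alternative starts are kept in the `alt_starts` attribute column.
#'
#' @param region one-row data.frame (or list) with chrom, start, end
#' @param genome DNAStringSet
#' @param min_aa minimum protein length in amino acids (start codon
#'   included, stop excluded)
#' @param start_codons allowed start codons
#' @return data.frame of candidate ORFs: chrom, start, end, strand, frame,
#'   start_codon, protein, partial, evidence, classification, alt_starts
#' @export
six_frame_orfs <- function(region, genome, min_aa = 30L,
                           start_codons = START_CODONS) {
  chrom <- region$chrom[1L]
  rs <- region$start[1L]; re <- region$end[1L]
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  stopifnot(rs >= 0L, re <= L, rs < re)
  rseq <- as.character(Biostrings::subseq(genome[[match(chrom,
                                                        names(genome))]],
                                          rs + 1L, re))
  if (!grepl("[ACGT]", rseq)) return(empty_orf_frame())
  out <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") rseq else revcomp_chr(rseq)
    for (h in scan_frames_local(sseq, min_aa, start_codons)) {
      if (strand == "+") {
        gs <- rs + h$lo; ge <- rs + h$hi
        alt <- rs + h$alt_starts
      } else {
        gs <- re - h$hi; ge <- re - h$lo
        alt <- re - h$alt_starts  # 3' coordinate of each alternative start
      }
      sense <- if (strand == "+")
        as.character(Biostrings::subseq(
          genome[[match(chrom, names(genome))]], gs + 1L, ge))
      else revcomp_chr(as.character(Biostrings::subseq(
        genome[[match(chrom, names(genome))]], gs + 1L, ge)))
      prot <- if (h$partial) {
        aa <- translate_dna(sense)
        substr(aa, 1L, 1L) <- "M"; aa
      } else translate_orf(sense)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = gs, end = ge, strand = strand,
        frame = genome_frame(gs, ge, strand, L),
        start_codon = h$start_codon, protein = prot, partial = h$partial,
        evidence = "sixframe", classification = NA_character_,
        alt_starts = paste(alt, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_orf_frame())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Six-frame ORF discovery over all intergenic regions
#'
#' @param annotation a [gene_models] data.frame
#' @param genome DNAStringSet
#' @param min_region_len minimum intergenic region length scanned
#' @inheritParams six_frame_orfs
#' @return data.frame of candidate ORFs (see [six_frame_orfs])
#' @export
discover_orfs <- function(annotation, genome, min_aa = 30L,
                          min_region_len = 60L,
                          start_codons = START_CODONS) {
  regions <- extract_intergenic(annotation, genome, min_len = min_region_len)
  res <- lapply(seq_len(nrow(regions)), function(i)
    six_frame_orfs(regions[i, ], genome, min_aa, start_codons))
  out <- do.call(rbind, c(list(empty_orf_frame()), res))
  rownames(out) <- NULL
  out
}

#' Write candidate ORF proteins as FASTA (the peptide search space)
#' @param orfs data.frame from [six_frame_orfs]/[discover_orfs]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orf_proteins <- function(orfs, path) {
  ids <- sprintf("%s_%d_%d_%s", orfs$chrom, orfs$start, orfs$end,
                 orfs$strand)
  aa <- Biostrings::AAStringSet(setNames(orfs$protein, ids))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
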