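#' Map peptides onto the six-frame translation of a genome
#'
#' Reports every exact amino-acid-level occurrence of each peptide in any of
#' the six translated frames, with genome coordinates (nt span = 3 x peptide
#' length). Isoleucine and leucine are treated as equivalent by default,
#' since mass spectrometry cannot distinguish them. Peptides containing
#' ambiguity codes (B/Z/X) are skipped with a warning.
#'
#' @param peptides data.frame with columns peptide, confidence, sample (or a
#'   character vector of peptide sequences)
#' @param genome DNAStringSet
#' @param collapse_il treat I and L as the same residue
#' @return data.frame with one row per placement: peptide, confidence,
#'   sample, chrom, start, end, strand, frame, n_placements, unique.
#'   Peptides with no placement contribute no rows; the full set of mapped
#'   peptide sequences is in `attr(, "searched")`.
#' @export
map_peptides <- function(peptides, genome, collapse_il = TRUE) {
  if (is.character(peptides))
    peptides <- data.frame(peptide = peptides, confidence = NA_real_,
                           sample = NA_character_, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "confidence", "sample") %in% names(peptides)))
  bad <- grepl("[BZX]", peptides$peptide)
  if (any(bad)) {
    warning(sum(bad), " peptide(s) with ambiguous residues (B/Z/X) skipped")
    peptides <- peptides[!bad, , drop = FALSE]
  }
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides$peptide)))
    stop("peptides must be amino-acid strings over the 20-letter alphabet")

  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    gchr <- as.character(genome[[ci]])
    L <- nchar(gchr)
    frames <- six_frame_proteins(gchr, collapse_il = collapse_il)
    uniq <- unique(peptides$peptide)
    for (pep in uniq) {
      key <- if (collapse_il) gsub("I", "L", pep, fixed = TRUE) else pep
      plen <- nchar(pep)
      for (fn in names(frames)) {
        strand <- substr(fn, 1L, 1L)
        f <- as.integer(substr(fn, 2L, 2L))
        m <- gregexpr(key, frames[[fn]], fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        for (aapos in as.integer(m)) {
          nt0 <- f + 3L * (aapos - 1L)
          if (strand == "+") { gs <- nt0; ge <- nt0 + 3L * plen }
          else { ge <- L - nt0; gs <- ge - 3L * plen }
          out[[length(out) + 1L]] <- data.frame(
            peptide = pep, chrom = chrom, start = gs, end = ge,
            strand = strand, frame = f, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(peptide = character(), confidence = numeric(),
                      sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      n_placements = integer(), unique = logical())
    attr(res, "searched") <- unique(peptides$peptide)
    return(res)
  }
  pl <- do.call(rbind, out)
  np <- table(pl$peptide)
  pl$n_placements <- as.integer(np[pl$peptide])
  pl$unique <- pl$n_placements == 1L
  # re-attach identification metadata (a peptide may appear in several
  # samples; replicate placements per identification row)
  res <- merge(peptides, pl, by = "peptide")
  res <- res[order(res$peptide, res$start), ]
  rownames(res) <- NULL
  attr(res, "searched") <- unique(peptides$peptide)
  res
}

sense_codon <- function(gchr, pos, strand, L) {
  # codon whose first transcribed base sits at transcript position `pos`
  if (strand == "+") substr(gchr, pos + 1L, pos + 3L)
  else revcomp_chr(substr(gchr, L - pos - 2L, L - pos))
}

#' Expand a uniquely-placed peptide in frame into a candidate ORF
#'
#' Walks downstream from the placement to the first in-frame stop codon
#' (included in the ORF interval) and upstream to the 5'-most allowed start
#' codon not separated from the peptide by an in-frame stop. If the upstream
#' scan exhausts `max_extension` (or the contig) without meeting a stop and
#' finds no start, or meets a stop with no start codon in between, the ORF
#' is flagged `partial` — the frameshift-suspect situation where no
#' compatible start exists upstream of the peptide.
#'
#' @param hit one placement row from [map_peptides] (must be unique)
#' @param genome DNAStringSet
#' @param start_codons allowed start codons
#' @param max_extension upstream search bound, nt
#' @return one-row candidate ORF data.frame (see [six_frame_orfs])
#' @export
expand_to_orf <- function(hit, genome, start_codons = START_CODONS,
                          max_extension = 3000L) {
  stopifnot(nrow(hit) == 1L)
  if (!isTRUE(hit$unique))
    stop("only uniquely-placed peptides seed ORF expansion")
  ci <- match(hit$chrom, names(genome))
  gchr <- as.character(genome[[ci]])
  L <- nchar(gchr)
  # transcript coordinates: position of the first transcribed base
  t5 <- if (hit$strand == "+") hit$start else L - hit$end
  t3 <- if (hit$strand == "+") hit$end else L - hit$start  # one past last

  # downstream: first in-frame stop, included
  pos <- t3
  orf_t3 <- NA_integer_
  while (pos + 3L <= L) {
    if (sense_codon(gchr, pos, hit$strand, L) %in% STOP_CODONS) {
      orf_t3 <- pos + 3L; break
    }
    pos <- pos + 3L
  }
  partial3 <- is.na(orf_t3)
  if (partial3) orf_t3 <- t3 + 3L * ((L - t3) %/% 3L)

  # upstream: 5'-most start before the first in-frame stop
  pos <- t5 - 3L
  best_start <- NA_integer_
  start_cod <- NA_character_
  met_stop <- FALSE
  while (pos >= 0L && t5 - pos <= max_extension) {
    cod <- sense_codon(gchr, pos, hit$strand, L)
    if (cod %in% STOP_CODONS) { met_stop <- TRUE; break }
    if (cod %in% start_codons) { best_start <- pos; start_cod <- cod }
    pos <- pos - 3L
  }
  partial5 <- is.na(best_start)
  orf_t5 <- if (partial5) t5 else best_start
  partial <- partial5 || partial3

  gs <- if (hit$strand == "+") orf_t5 else L - orf_t3
  ge <- if (hit$strand == "+") orf_t3 else L - orf_t5
  sense <- if (hit$strand == "+") substr(gchr, gs + 1L, ge)
           else revcomp_chr(substr(gchr, gs + 1L, ge))
  prot <- if (partial) {
    aa <- translate_dna(sense)
    if (!partial5) substr(aa, 1L, 1L) <- "M"
    sub("\\*$", "", aa)
  } else translate_orf(sense)
  data.frame(chrom = hit$chrom, start = gs, end = ge, strand = hit$strand,
             frame = genome_frame(gs, ge, hit$strand, L),
             start_codon = start_cod, protein = prot, partial = partial,
             evidence = "peptide", classification = NA_character_,
             alt_starts = "", met_upstream_stop = met_stop,
             stringsAsFactors = FALSE)
}

#' Classify a candidate ORF against the existing annotation
#'
#' * `novel` — no same-strand overlap with any annotated feature;
#' * `confirms_hypothetical` — same-strand same-frame overlap with a gene
#'   annotated as hypothetical;
#' * `extension` — same-strand same-frame overlap with a non-hypothetical
#'   annotated gene;
#' * `frameshift_flag` — same-strand overlap at a near-frame offset (1-2 nt
#'   within the codon cycle), or a `partial` expansion adjacent to (within
#'   `adjacency` nt of) an annotated gene.
#'
#' @param orf one-row candidate ORF data.frame
#' @param annotation a [gene_models] data.frame
#' @param genome DNAStringSet
#' @param adjacency nt distance treated as "adjacent" for partial ORFs
#' @return classification string
#' @export
classify_orf <- function(orf, annotation, genome, adjacency = 3L) {
  stopifnot(nrow(orf) == 1L)
  L <- Biostrings::width(genome)[match(orf$chrom, names(genome))]
  ann <- annotation[annotation$chrom == orf$chrom &
                      annotation$strand == orf$strand &
                      annotation$kind %in% c("CDS", "novel_ORF"), ,
                    drop = FALSE]
  if (nrow(ann) == 0L) return("novel")
  ov <- ann$start < orf$end & ann$end > orf$start
  if (!any(ov)) {
    if (isTRUE(orf$partial)) {
      near <- ann$start < orf$end + adjacency & ann$end > orf$start - adjacency
      if (any(near)) return("frameshift_flag")
    }
    return("novel")
  }
  hit <- ann[ov, , drop = FALSE]
  af <- genome_frame(hit$start, hit$end, hit$strand, L)
  same <- af == orf$frame
  if (any(same)) {
    prods <- vapply(hit$attributes[same], function(a)
      tolower(a[["product"]] %||% ""), character(1))
    if (any(grepl("hypothetical", prods))) return("confirms_hypothetical")
    return("extension")
  }
  "frameshift_flag"
}

#' Seed, expand and classify protein calls from a peptide table
#'
#' Runs [map_peptides], expands each uniquely-placed peptide with
#' [expand_to_orf], de-duplicates the resulting ORFs, attaches every
#' placement (unique or not) falling in-frame inside each ORF as supporting
#' evidence, and classifies each ORF with [classify_orf].
#'
#' @param peptides peptide identification table (peptide, confidence,
#'   sample)
#' @param genome DNAStringSet
#' @param annotation a [gene_models] data.frame
#' @param min_conf confidence (percent) for a peptide to count as confident
#' @param collapse_il treat I/L as equivalent when matching
#' @param max_extension upstream expansion bound, nt
#' @return data.frame of protein calls: ORF columns plus n_peptides,
#'   n_conf_peptides, peptide_ids (list column of supporting placement
#'   rows)
#' @export
proteogenomic_calls <- function(peptides, genome, annotation,
                                min_conf = 95, collapse_il = TRUE,
                                max_extension = 3000L) {
  hits <- map_peptides(peptides, genome, collapse_il = collapse_il)
  if (nrow(hits) == 0L) {
    out <- empty_orf_frame()
    out$n_peptides <- integer(0); out$n_conf_peptides <- integer(0)
    out$met_upstream_stop <- logical(0)
    out$peptides <- I(list())
    return(out)
  }
  seeds <- hits[hits$unique, , drop = FALSE]
  seeds <- seeds[!duplicated(seeds[c("peptide", "chrom", "start", "strand")]),
                 , drop = FALSE]
  orfs <- lapply(seq_len(nrow(seeds)), function(i)
    expand_to_orf(seeds[i, ], genome, max_extension = max_extension))
  orfs <- do.call(rbind, orfs)
  key <- sprintf("%s:%d-%d:%s", orfs$chrom, orfs$start, orfs$end,
                 orfs$strand)
  orfs <- orfs[!duplicated(key), , drop = FALSE]
  rownames(orfs) <- NULL

  sup <- lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    inside <- hits$chrom == o$chrom & hits$strand == o$strand &
      hits$start >= o$start & hits$end <= o$end & hits$frame == o$frame
    hits[inside, , drop = FALSE]
  })
  orfs$n_peptides <- vapply(sup, function(s)
    length(unique(s$peptide)), integer(1))
  orfs$n_conf_peptides <- vapply(sup, function(s)
    length(unique(s$peptide[s$confidence >= min_conf])), integer(1))
  orfs$classification <- vapply(seq_len(nrow(orfs)), function(i)
    classify_orf(orfs[i, ], annotation, genome), character(1))
  orfs$peptides <- I(sup)
  orfs
}

#' Apply the protein acceptance rules
#'
#' A call is `accepted` with at least two confident (>= `min_conf` percent)
#' independent peptides — independent meaning distinct peptide sequences.
#' Single-confident-peptide calls are set to `needs_rna_validation` and
#' accepted only if their ORF is transcribed in at least one time point
#' (coverage at `k` times the intergenic background); everything else is
#' `rejected`.
#'
#' @param calls data.frame from [proteogenomic_calls]
#' @param tracks normalized coverage tracks (needed only when single-peptide
#'   calls are present); `NULL` rejects such calls
#' @param annotation a [gene_models] data.frame (background estimation)
#' @param min_conf confident-peptide threshold, percent
#' @param min_peptides peptides required for direct acceptance
#' @param k transcription threshold, fold over background
#' @return `calls` with added columns status, rna_validated, mean_expr
#' @export
filter_proteins <- function(calls, tracks = NULL, annotation = NULL,
                            min_conf = 95, min_peptides = 2L, k = 5) {
  if (nrow(calls) == 0L) {
    calls$status <- character(0); calls$rna_validated <- logical(0)
    calls$mean_expr <- numeric(0)
    return(calls)
  }
  if ("peptides" %in% names(calls))
    calls$n_conf_peptides <- vapply(calls$peptides, function(s)
      length(unique(s$peptide[s$confidence >= min_conf])), integer(1))
  status <- character(nrow(calls))
  rna <- logical(nrow(calls))
  expr <- rep(NA_real_, nrow(calls))
  bg <- if (!is.null(tracks)) track_backgrounds(tracks, annotation) else NULL
  for (i in seq_len(nrow(calls))) {
    nc <- calls$n_conf_peptides[i]
    if (nc >= min_peptides) {
      status[i] <- "accepted"
    } else if (nc == 1L) {
      status[i] <- "needs_rna_validation"
      if (!is.null(tracks)) {
        v <- is_transcribed(calls[i, ], tracks, annotation, k = k,
                            background = bg)
        rna[i] <- v$transcribed
        expr[i] <- v$mean_expr
        status[i] <- if (v$transcribed) "accepted" else "rejected"
      }
    } else {
      status[i] <- "rejected"
    }
  }
  calls$status <- status
  calls$rna_validated <- rna
  calls$mean_expr <- expr
  calls
}
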