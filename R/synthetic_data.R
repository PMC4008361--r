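#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics dataset: a toy high-G+C genome
#' with annotated and hidden (un-annotated) protein-coding genes, a
#' Shine-Dalgarno motif upstream of every start codon, one frameshift
#' mis-annotation, strand-specific coverage tracks over several fermentation
#' time points, ribosome-protected small-RNA fragments with codon-step
#' structure, and a peptide identification table with decoys.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs
#' @param genome_length genome length, nt
#' @param gc_content target G+C fraction (the organism class emulated here
#'   runs around 0.72)
#' @param chrom chromosome name
#' @param n_annotated_genes,n_hidden_genes numbers of annotated and hidden
#'   genes planted
#' @param annotated_len_codons,hidden_len_codons length ranges (codons,
#'   including start, excluding stop); hidden genes are drawn shorter, as
#'   genes missed by ab initio annotation tend to be
#' @param sd_motif Shine-Dalgarno motif planted upstream of each start
#' @param sd_spacer nt between the motif 3' end and the first base of the
#'   start codon
#' @param frameshift_genes number of annotated genes whose emitted model is
#'   frame-shifted relative to the true gene (0 or 1)
#' @param frameshift_offset nt offset of the mis-annotated model
#' @param n_noncoding_transcribed number of transcribed non-coding
#'   intergenic segments planted
#' @param noncoding_len_range length range (nt) of those segments
#' @param coverage_depth mean per-base coverage of an expression-1 feature
#' @param background_depth mean per-base background coverage
#' @param n_time_points number of coverage time points
#' @param fragment_protection_strength `s >= 0`; controls both the size of
#'   the SD-protected fragment population and the in-phase weight of
#'   CDS-interior 5' termini (`s = 0` gives uniform termini, no protection)
#' @param fragment_depth expected fragments per unit expression per gene
#' @param fragment_background expected genome-wide background fragments
#' @param fragment_len_range fragment size-selection window, nt
#' @param peptide_confidence_model list with `true_range` and `decoy_range`
#'   (percent confidence ranges for genuine and decoy peptides)
#' @param n_decoy_peptides decoy peptides emitted
#' @param n_annotated_with_peptides annotated genes that also receive
#'   peptides
#' @param min_gap minimum intergenic gap, nt
#' @param n_reactions_unique orphan reactions with a uniquely matching
#'   planted gene (the synthetic fixture adds three special cases: a
#'   two-domain multiplicity reaction, a synteny tie-break reaction and an
#'   unassignable reaction)
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 100000L,
                              gc_content = 0.72,
                              chrom = "synchr1",
                              n_annotated_genes = 60L,
                              n_hidden_genes = 12L,
                              annotated_len_codons = c(100L, 400L),
                              hidden_len_codons = c(40L, 100L),
                              sd_motif = "AGGAGG",
                              sd_spacer = 7L,
                              frameshift_genes = 1L,
                              frameshift_offset = 2L,
                              n_noncoding_transcribed = 8L,
                              noncoding_len_range = c(150L, 400L),
                              coverage_depth = 50,
                              background_depth = 1,
                              n_time_points = 6L,
                              fragment_protection_strength = 8,
                              fragment_depth = 60,
                              fragment_background = 2000,
                              fragment_len_range = c(15L, 50L),
                              peptide_confidence_model =
                                list(true_range = c(95, 100),
                                     decoy_range = c(50, 94.9)),
                              n_decoy_peptides = 20L,
                              n_annotated_with_peptides = 15L,
                              min_gap = 150L,
                              n_reactions_unique = 8L) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$sd_spacer >= 4, cfg$sd_spacer + nchar(cfg$sd_motif) <= 15,
            cfg$frameshift_genes %in% c(0L, 1L),
            cfg$n_time_points >= 1L,
            cfg$fragment_protection_strength >= 0,
            cfg$min_gap >= 30L)
  class(cfg) <- "simulation_config"
  cfg
}

# codon sampler excluding stops, with a mild GC-rich wobble preference
codon_weights <- function(gc) {
  b <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  grid <- expand.grid(b1 = names(b), b2 = names(b), b3 = names(b),
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  w <- b[grid$b1] * b[grid$b2] * b[grid$b3] *
    ifelse(grid$b3 %in% c("G", "C"), 1.5, 1)
  keep <- !codons %in% STOP_CODONS
  setNames(w[keep] / sum(w[keep]), codons[keep])
}

sample_cds <- function(n_codons, cw) {
  start <- sample(START_CODONS, 1L, prob = c(0.6, 0.3, 0.1))
  stopc <- sample(STOP_CODONS, 1L, prob = c(0.15, 0.25, 0.6))
  body <- sample(names(cw), n_codons - 1L, replace = TRUE, prob = cw)
  paste0(start, paste(body, collapse = ""), stopc)
}

profile_shapes <- function(n_tp) {
  g <- exp(seq(log(0.25), log(2.5), length.out = n_tp))
  mid <- ceiling(n_tp / 2)
  pulse <- 0.3 + 2.2 * exp(-((seq_len(n_tp) - mid)^2) / 2)
  list(flat = rep(1, n_tp), up = g, down = rev(g), pulse = pulse)
}

#' Simulate a high-G+C genome with planted ground truth
#'
#' Draws intergenic background at the target G+C, plants non-overlapping
#' annotated genes, hidden genes and non-coding transcribed segments, places
#' the SD motif `sd_spacer` nt upstream of every start codon, caps each gene
#' with an in-frame upstream stop codon (so upstream ORF extension terminates
#' at the planted start), and — for the frameshift gene — emits an annotation
#' record derived from a frame-shifted copy of the true gene while the
#' genome keeps the true sequence.
#'
#' @param config a [simulation_config]
#' @return list with elements `genome` (DNAStringSet), `truth` (ground-truth
#'   list) and `annotation` ([gene_models] as emitted to GFF3: hidden genes
#'   absent, the frameshift gene mis-annotated)
#' @export
simulate_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  cw <- codon_weights(config$gc_content)
  base_p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
              G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  g <- sample(names(base_p), L, replace = TRUE, prob = base_p)

  n_ann <- config$n_annotated_genes
  n_hid <- config$n_hidden_genes
  n_nc <- config$n_noncoding_transcribed
  feats <- data.frame(
    type = c(rep("annotated", n_ann), rep("hidden", n_hid),
             rep("noncoding", n_nc)),
    stringsAsFactors = FALSE)
  feats <- feats[sample(nrow(feats)), , drop = FALSE]
  codons <- integer(nrow(feats))
  lens <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    if (feats$type[i] == "noncoding") {
      lens[i] <- sample(config$noncoding_len_range[1]:
                          config$noncoding_len_range[2], 1L)
    } else {
      rng <- if (feats$type[i] == "hidden") config$hidden_len_codons
             else config$annotated_len_codons
      codons[i] <- sample(rng[1]:rng[2], 1L)
      lens[i] <- 3L * (codons[i] + 1L)  # + stop codon
    }
  }
  nf <- nrow(feats)
  slack <- L - sum(lens) - (nf + 1L) * config$min_gap
  if (slack < 0L)
    stop("cannot place ", nf, " features in a ", L,
         " nt genome without overlap; increase genome_length")
  extra <- as.vector(rmultinom(1L, slack, rep(1 / (nf + 1L), nf + 1L)))
  gaps <- config$min_gap + extra
  starts <- cumsum(c(gaps[1L], lens[-nf] + gaps[-c(1L, nf + 1L)]))
  ends <- starts + lens
  feats$start <- as.integer(starts)
  feats$end <- as.integer(ends)
  feats$strand <- sample(c("+", "-"), nf, replace = TRUE)
  feats$codons <- codons

  sd_m <- config$sd_motif
  sd_len <- nchar(sd_m)
  spacer <- config$sd_spacer
  is_gene <- feats$type != "noncoding"

  fs_row <- 0L
  if (config$frameshift_genes > 0L) {
    cand <- which(feats$type == "annotated" & feats$strand == "+")
    fs_row <- cand[sample(length(cand), 1L)]
  }

  genes <- list(); rbs <- list()
  gi <- 0L; hi <- 0L
  for (i in seq_len(nf)) {
    if (!is_gene[i]) next
    s <- feats$start[i]; e <- feats$end[i]; strand <- feats$strand[i]
    cds <- sample_cds(feats$codons[i], cw)
    if (strand == "+") {
      g[(s + 1L):e] <- strsplit(cds, "")[[1L]]
      sd_s <- s - spacer - sd_len
      g[(sd_s + 1L):(sd_s + sd_len)] <- strsplit(sd_m, "")[[1L]]
      g[(s - 18L + 1L):(s - 15L)] <- c("T", "G", "A")  # upstream in-frame stop
      # keep the two free in-frame codons of the gap start-codon-free
      for (u in c(s - 6L, s - 3L)) {
        while (paste(g[(u + 1L):(u + 3L)], collapse = "") %in% START_CODONS)
          g[(u + 1L):(u + 3L)] <- sample(names(base_p), 3L, TRUE, base_p)
      }
    } else {
      g[(s + 1L):e] <- strsplit(revcomp_chr(cds), "")[[1L]]
      sd_s <- e + spacer
      g[(sd_s + 1L):(sd_s + sd_len)] <- strsplit(revcomp_chr(sd_m), "")[[1L]]
      g[(e + 15L + 1L):(e + 18L)] <- c("T", "C", "A")  # revcomp of TGA
      for (u in c(e + 3L, e)) {  # transcript offsets -6, -3
        while (revcomp_chr(paste(g[(u + 1L):(u + 3L)], collapse = "")) %in%
                 START_CODONS)
          g[(u + 1L):(u + 3L)] <- sample(names(base_p), 3L, TRUE, base_p)
      }
    }
    hidden <- feats$type[i] == "hidden"
    if (hidden) { hi <- hi + 1L; id <- sprintf("hid_%03d", hi) }
    else { gi <- gi + 1L; id <- sprintf("ann_%03d", gi) }
    if (i == fs_row) fs_id <- id
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = id, chrom = config$chrom, start = s, end = e,
      strand = strand, hidden = hidden, cds = cds,
      stringsAsFactors = FALSE)
    rbs[[length(rbs) + 1L]] <- data.frame(
      gene_id = id, sd_start = as.integer(sd_s),
      sd_end = as.integer(sd_s + sd_len), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes$protein <- translate_orf(genes$cds)
  rbs <- do.call(rbind, rbs)
  genome_chr <- paste(g, collapse = "")

  # annotation product names; a quarter of annotated genes "hypothetical"
  genes$product <- ifelse(genes$hidden, NA_character_, "annotated protein")
  ann_ids <- genes$gene_id[!genes$hidden]
  hyp <- sample(ann_ids, max(1L, round(0.25 * length(ann_ids))))
  genes$product[genes$gene_id %in% hyp] <- "hypothetical protein"

  # frameshift mis-annotation: emitted model shifted by frameshift_offset,
  # ending at the first stop codon of the shifted frame
  frameshift <- data.frame(gene_id = character(), true_start = integer(),
                           true_end = integer(), ann_start = integer(),
                           ann_end = integer(), strand = character(),
                           offset = integer())
  if (fs_row > 0L) {
    tg <- genes[genes$gene_id == fs_id, ]
    a_s <- tg$start + config$frameshift_offset
    pos <- a_s
    a_e <- NA_integer_
    while (pos + 3L <= L && pos < tg$end + 3000L) {
      if (substr(genome_chr, pos + 1L, pos + 3L) %in% STOP_CODONS) {
        a_e <- pos + 3L; break
      }
      pos <- pos + 3L
    }
    if (is.na(a_e)) a_e <- a_s + 3L * ((tg$end - a_s) %/% 3L)
    frameshift <- data.frame(gene_id = fs_id, true_start = tg$start,
                             true_end = tg$end, ann_start = as.integer(a_s),
                             ann_end = as.integer(a_e), strand = tg$strand,
                             offset = config$frameshift_offset)
  }

  nc <- feats[feats$type == "noncoding", , drop = FALSE]
  transcribed_segments <- data.frame(
    seg_id = sprintf("nc_%03d", seq_len(nrow(nc))), chrom = config$chrom,
    start = nc$start, end = nc$end, strand = nc$strand,
    stringsAsFactors = FALSE)

  # expression ground truth shared by the coverage and fragment simulators
  shapes <- profile_shapes(config$n_time_points)
  feat_ids <- c(genes$gene_id, transcribed_segments$seg_id)
  profs <- sample(names(shapes), length(feat_ids), replace = TRUE,
                  prob = c(0.4, 0.2, 0.2, 0.2))
  hid_ids <- genes$gene_id[genes$hidden]
  if (length(hid_ids) > 0L) profs[feat_ids == hid_ids[1L]] <- "down"
  expression <- data.frame(
    feature_id = feat_ids,
    base_expr = pmax(0.5, rlnorm(length(feat_ids), log(2), 0.6)),
    profile = profs, stringsAsFactors = FALSE)
  mult <- do.call(rbind, shapes)[expression$profile, , drop = FALSE]
  rownames(mult) <- feat_ids

  truth <- structure(list(
    genes = genes, rbs = rbs, frameshift = frameshift,
    transcribed_segments = transcribed_segments,
    expression = expression, multipliers = mult,
    config = config), class = "sim_truth")

  annotation <- emit_annotation(truth)
  genome <- Biostrings::DNAStringSet(setNames(genome_chr, config$chrom))
  list(genome = genome, truth = truth, annotation = annotation)
}

# the annotation as a downstream user would receive it: hidden genes
# missing, the frameshift gene mis-modelled
emit_annotation <- function(truth) {
  ann <- truth$genes[!truth$genes$hidden, , drop = FALSE]
  attrs <- lapply(ann$product, function(p) c(product = p))
  models <- gene_models(ann$gene_id, ann$chrom, ann$start, ann$end,
                        ann$strand, kind = "CDS", attributes = attrs)
  if (nrow(truth$frameshift) > 0L) {
    fs <- truth$frameshift
    i <- match(fs$gene_id, models$gene_id)
    models$start[i] <- fs$ann_start
    models$end[i] <- fs$ann_end
    models$attributes[[i]] <- c(models$attributes[[i]],
                                note = "ab-initio model")
  }
  models
}

#' Simulate strand-specific coverage tracks
#'
#' One track per time point per strand. Expressed features (all genes at
#' their true coordinates, plus the planted non-coding transcribed segments)
#' contribute `coverage_depth * base_expr * time-point multiplier` to the
#' per-base Poisson rate on their strand, on top of a flat
#' `background_depth`.
#'
#' @param genome DNAStringSet from [simulate_genome]
#' @param truth ground truth from the same call
#' @param config the same [simulation_config]
#' @return list of [coverage_track] objects, names `tp<t>_<strand>`
#' @export
simulate_coverage <- function(genome, truth, config = truth$config) {
  set.seed(config$seed + 1L)
  L <- Biostrings::width(genome)[1L]
  feats <- rbind(
    data.frame(id = truth$genes$gene_id, start = truth$genes$start,
               end = truth$genes$end, strand = truth$genes$strand),
    data.frame(id = truth$transcribed_segments$seg_id,
               start = truth$transcribed_segments$start,
               end = truth$transcribed_segments$end,
               strand = truth$transcribed_segments$strand))
  expr <- setNames(truth$expression$base_expr, truth$expression$feature_id)
  tracks <- list()
  for (t in seq_len(config$n_time_points)) {
    for (strand in c("+", "-")) {
      lam <- rep(config$background_depth, L)
      sel <- feats[feats$strand == strand, , drop = FALSE]
      for (j in seq_len(nrow(sel))) {
        f <- sel[j, ]
        lam[(f$start + 1L):f$end] <- lam[(f$start + 1L):f$end] +
          config$coverage_depth * expr[[f$id]] * truth$multipliers[f$id, t]
      }
      vals <- if (all(lam == 0)) numeric(L) else rpois(L, lam)
      nm <- sprintf("tp%d_%s", t, strand)
      tracks[[nm]] <- coverage_track(vals, library_id = sprintf("tp%d", t),
                                     time_point = sprintf("tp%d", t),
                                     strand = strand)
    }
  }
  tracks
}

# in-phase weight of CDS-interior 5' termini under the ribosome-step model
phase_weight <- function(strength) 1 / 3 + (2 / 3) * strength / (strength + 4)
protected_fraction <- function(strength) 0.5 * strength / (strength + 4)

#' Simulate ribosome-protected small-RNA fragments
#'
#' Three populations per expressed gene: (a) SD-protected fragments whose 5'
#' termini pile at the planted SD window start (with +/-2 nt jitter), (b)
#' CDS-interior fragments whose 5' termini prefer in-phase codon positions
#' with multinomial weight `w` on phase 0 and `(1-w)/2` on the other two
#' phases, and (c) a uniform genome-wide degradation background. Fragment
#' lengths are uniform over the size-selection window. Duplicates are
#' collapsed into counts.
#'
#' @inheritParams simulate_coverage
#' @return data.frame with chrom, start, end, strand, count (0-based
#'   half-open)
#' @export
simulate_fragments <- function(genome, truth, config = truth$config) {
  set.seed(config$seed + 2L)
  L <- Biostrings::width(genome)[1L]
  s <- config$fragment_protection_strength
  w <- phase_weight(s)
  p_prot <- protected_fraction(s)
  lmin <- config$fragment_len_range[1]; lmax <- config$fragment_len_range[2]
  sd_len <- nchar(config$sd_motif)
  expr <- setNames(truth$expression$base_expr, truth$expression$feature_id)
  jitter_p <- c(0.05, 0.15, 0.6, 0.15, 0.05)

  p5 <- integer(0); len <- integer(0); strand <- character(0)
  for (j in seq_len(nrow(truth$genes))) {
    gn <- truth$genes[j, ]
    n <- rpois(1L, config$fragment_depth * expr[[gn$gene_id]])
    if (n == 0L) next
    n_prot <- rbinom(1L, n, p_prot)
    n_int <- n - n_prot
    offs <- integer(0)
    if (n_prot > 0L) {
      sd_off <- -(config$sd_spacer + sd_len)
      offs <- c(offs, sd_off + sample(-2L:2L, n_prot, TRUE, jitter_p))
    }
    if (n_int > 0L) {
      glen <- gn$end - gn$start
      cod <- sample(3L:(glen %/% 3L - 4L), n_int, replace = TRUE)
      phase <- sample(0L:2L, n_int, TRUE, c(w, (1 - w) / 2, (1 - w) / 2))
      offs <- c(offs, 3L * cod + phase)
    }
    gpos <- if (gn$strand == "+") gn$start + offs else gn$end - 1L - offs
    p5 <- c(p5, gpos)
    len <- c(len, sample(lmin:lmax, length(offs), replace = TRUE))
    strand <- c(strand, rep(gn$strand, length(offs)))
  }
  n_bg <- rpois(1L, config$fragment_background)
  if (n_bg > 0L) {
    p5 <- c(p5, sample.int(L, n_bg) - 1L)
    len <- c(len, sample(lmin:lmax, n_bg, replace = TRUE))
    strand <- c(strand, sample(c("+", "-"), n_bg, replace = TRUE))
  }
  start <- ifelse(strand == "+", p5, p5 - len + 1L)
  end <- start + len
  keep <- start >= 0L & end <= L
  df <- data.frame(chrom = config$chrom, start = start[keep],
                   end = end[keep], strand = strand[keep],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[c("chrom", "start", "end", "strand")], sum)
  agg <- agg[order(agg$start, agg$end, agg$strand), ]
  rownames(agg) <- NULL
  agg[, c("chrom", "start", "end", "strand", "count")]
}

# six-frame protein strings of a genome, I/L-collapsed on request
six_frame_proteins <- function(genome_chr, collapse_il = TRUE) {
  L <- nchar(genome_chr)
  rc <- revcomp_chr(genome_chr)
  res <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") genome_chr else rc
    for (f in 0:2) {
      n_aa <- (L - f) %/% 3L
      if (n_aa < 1L) next
      aa <- translate_dna(substr(seqs, f + 1L, f + 3L * n_aa))
      if (collapse_il) aa <- gsub("I", "L", aa, fixed = TRUE)
      res[[paste0(strand, f)]] <- aa
    }
  }
  res
}

count_genome_occurrences <- function(pep, frames) {
  pep <- gsub("I", "L", pep, fixed = TRUE)
  sum(vapply(frames, function(fr) {
    m <- gregexpr(pep, fr, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1)))
}

# tryptic-style windows: substrings ending at K/R, 7-30 aa, never touching
# the initiator residue
tryptic_windows <- function(protein, min_len = 7L, max_len = 30L) {
  aa <- strsplit(protein, "")[[1L]]
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts >= min_len + 1L]
  out <- list()
  for (e in cuts) {
    starts <- max(2L, e - max_len + 1L):(e - min_len + 1L)
    for (st in starts) out[[length(out) + 1L]] <- c(st, e)
  }
  out
}

#' Simulate the peptide identification table
#'
#' Every hidden gene receives 1-4 tryptic-style peptides from its true
#' translation (one designated hidden gene gets exactly one, to exercise the
#' single-peptide RNA-validation path); a subset of annotated genes receives
#' peptides; the frameshift gene receives peptides translated from the true
#' (un-shifted) frame; decoys are shuffled true peptides re-checked to have
#' no in-frame genome match. Confidences are drawn from the configured
#' true/decoy ranges.
#'
#' @inheritParams simulate_coverage
#' @return data.frame with columns peptide, confidence, sample, source_gene
#'   (NA for decoys), is_decoy
#' @export
simulate_peptides <- function(genome, truth, config = truth$config) {
  set.seed(config$seed + 3L)
  genome_chr <- as.character(genome[[1L]])
  frames <- six_frame_proteins(genome_chr)
  tps <- sprintf("tp%d", seq_len(config$n_time_points))
  cm <- config$peptide_confidence_model

  pick_peptides <- function(gene, k, avoid_in = NULL) {
    wins <- tryptic_windows(gene$protein)
    if (length(wins) == 0L) return(character(0))
    wins <- wins[sample(length(wins))]
    out <- character(0)
    for (wdw in wins) {
      pep <- substr(gene$protein, wdw[1L], wdw[2L])
      if (pep %in% out) next
      if (count_genome_occurrences(pep, frames) != 1L) next
      if (!is.null(avoid_in) &&
          grepl(gsub("I", "L", pep, fixed = TRUE),
                gsub("I", "L", avoid_in, fixed = TRUE), fixed = TRUE)) next
      out <- c(out, pep)
      if (length(out) == k) break
    }
    out
  }

  rows <- list()
  add <- function(pep, gene_id, decoy) {
    rng <- if (decoy) cm$decoy_range else cm$true_range
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide = pep, confidence = runif(1L, rng[1L], rng[2L]),
      sample = sample(tps, 1L),
      source_gene = if (decoy) NA_character_ else gene_id,
      is_decoy = decoy, stringsAsFactors = FALSE)
  }

  hid <- truth$genes[truth$genes$hidden, , drop = FALSE]
  single_id <- if (nrow(hid) > 0L) hid$gene_id[1L] else NA_character_
  for (j in seq_len(nrow(hid))) {
    gn <- hid[j, ]
    k <- if (gn$gene_id == single_id) 1L else sample(2:4, 1L)
    for (pep in pick_peptides(gn, k)) add(pep, gn$gene_id, FALSE)
  }

  ann <- truth$genes[!truth$genes$hidden, , drop = FALSE]
  fs_id <- if (nrow(truth$frameshift) > 0L) truth$frameshift$gene_id else NULL
  with_pep <- sample(setdiff(ann$gene_id, fs_id),
                     min(config$n_annotated_with_peptides,
                         nrow(ann) - length(fs_id)))
  for (id in with_pep) {
    gn <- ann[ann$gene_id == id, ]
    for (pep in pick_peptides(gn, sample(2:4, 1L))) add(pep, id, FALSE)
  }
  if (!is.null(fs_id)) {
    gn <- ann[ann$gene_id == fs_id, ]
    fs <- truth$frameshift
    ann_prot <- tryCatch({
      n <- fs$ann_end - fs$ann_start
      if (n >= 6L) translate_orf(substr(as.character(genome[[1L]]),
                                        fs$ann_start + 1L, fs$ann_end))
      else ""
    }, error = function(e) "")
    for (pep in pick_peptides(gn, 2L, avoid_in = ann_prot))
      add(pep, fs_id, FALSE)
  }

  true_peps <- unique(vapply(rows, function(r) r$peptide, character(1)))
  n_dec <- config$n_decoy_peptides
  made <- 0L; guard <- 0L
  while (made < n_dec && guard < 50L * n_dec) {
    guard <- guard + 1L
    src <- sample(true_peps, 1L)
    dec <- paste(sample(strsplit(src, "")[[1L]]), collapse = "")
    if (dec %in% true_peps) next
    if (count_genome_occurrences(dec, frames) > 0L) next
    add(dec, NA_character_, TRUE)
    made <- made + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the orphan-reaction fixture
#'
#' Builds the domain, reaction and ortholog-neighbourhood tables with planted
#' gene-reaction truth: `n_reactions_unique` reactions with one uniquely
#' matching gene, one reaction requiring a domain in duplicate (only one
#' gene carries two copies), one reaction whose two domain-tied candidates
#' are separated by synteny, and one essential reaction with no matching
#' gene at all.
#'
#' @inheritParams simulate_coverage
#' @return list with data.frames `domains`, `reactions` (required_domains is
#'   a comma-joined multiset), `orthologs`, and `assignments` (the planted
#'   truth)
#' @export
simulate_gsmr_tables <- function(genome, truth, config = truth$config) {
  set.seed(config$seed + 4L)
  ann <- truth$genes[!truth$genes$hidden, , drop = FALSE]
  ann <- ann[order(ann$start), ]
  ids <- ann$gene_id
  n <- length(ids)
  stopifnot(n >= config$n_reactions_unique + 8L)

  dom_rows <- list()
  add_dom <- function(gene, dom, ev) {
    dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
      gene_id = gene, domain_id = dom, evalue = ev,
      aa_start = sample(1:50, 1L), aa_end = sample(60:120, 1L),
      stringsAsFactors = FALSE)
  }
  rxn_rows <- list(); truth_rows <- list()
  add_rxn <- function(rid, doms, essential, true_gene, verdict) {
    rxn_rows[[length(rxn_rows) + 1L]] <<- data.frame(
      reaction_id = rid, required_domains = paste(doms, collapse = ","),
      essential = essential, stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      reaction_id = rid, true_gene = true_gene, verdict = verdict,
      stringsAsFactors = FALSE)
  }

  pool <- sample(ids)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }

  # uniquely-signalled reactions
  for (r in seq_len(config$n_reactions_unique)) {
    dom <- sprintf("DOM%03d", r)
    tg <- take(1L)
    add_dom(tg, dom, 10^runif(1L, -12, -5))
    # same domain on an unused gene but above the E-value cut-off
    add_dom(sample(pool, 1L), dom, 10^runif(1L, -2.5, -1))
    add_rxn(sprintf("rxn_unique_%02d", r), dom, FALSE, tg,
            "single_candidate")
  }
  # duplicate-domain multiplicity (cardiolipin-synthase-like logic)
  tg <- take(1L); other <- take(1L)
  add_dom(tg, "PLDc", 1e-6); add_dom(tg, "PLDc", 1e-5)
  add_dom(other, "PLDc", 1e-7)
  add_rxn("rxn_dup_domain", c("PLDc", "PLDc"), FALSE, tg, "single_candidate")
  # synteny tie-break: two genes with the full domain pair
  tg <- take(1L); rival <- take(1L)
  for (gid in c(tg, rival)) { add_dom(gid, "ECH", 1e-8); add_dom(gid, "ECH_C", 1e-8) }
  add_rxn("rxn_synteny_tie", c("ECH", "ECH_C"), FALSE, tg,
          "multiple_candidates")
  # multi-domain ambiguity
  g1 <- take(1L); g2 <- take(1L)
  add_dom(g1, "PEMT", 1e-9); add_dom(g1, "MFS_1", 1e-9)
  add_dom(g2, "PEMT", 1e-8); add_dom(g2, "PhaG_MnhG_YufB", 1e-6)
  add_rxn("rxn_multidomain", "PEMT", FALSE, NA_character_,
          "ambiguous_multidomain")
  # essential reaction with no candidate (thymidine-kinase-like outcome)
  add_rxn("rxn_orphan", "dUTP_kin", TRUE, NA_character_, "unassigned")
  # background noise domains, only on genes not planted as candidates
  for (gid in sample(pool, min(20L, length(pool)))) {
    add_dom(gid, sprintf("NOISE%02d", sample(1:30, 1L)), 10^runif(1L, -6, -1))
  }

  domains <- do.call(rbind, dom_rows)
  reactions <- do.call(rbind, rxn_rows)
  assignments <- do.call(rbind, truth_rows)

  # ortholog/neighbourhood tables: our genome plus two references that keep
  # the neighbourhood of every true candidate; the synteny-tie rival gets a
  # scrambled context
  og <- setNames(sprintf("OG%04d", seq_len(n)), ids)
  self <- data.frame(genome = "self", gene = ids, ortho_group = og[ids],
                     position_index = seq_len(n), stringsAsFactors = FALSE)
  refs <- list()
  rival_og <- og[[rival]]
  for (rg in c("refA", "refB")) {
    keep <- sort(sample(seq_len(n), round(0.8 * n)))
    grp <- og[ids[keep]]
    if (rg == "refA") grp <- grp[sample(length(grp))]  # order-scrambled ref
    if (rival_og %in% grp && rg == "refB") {
      # move the rival far from its native neighbours
      i <- which(grp == rival_og)
      grp <- c(grp[-i][1:5], grp[i], grp[-i][-(1:5)])
    }
    refs[[rg]] <- data.frame(genome = rg,
                             gene = paste0(rg, "_", seq_along(grp)),
                             ortho_group = unname(grp),
                             position_index = seq_along(grp),
                             stringsAsFactors = FALSE)
  }
  orthologs <- rbind(self, refs$refA, refs$refB)
  rownames(orthologs) <- NULL
  list(domains = domains, reactions = reactions, orthologs = orthologs,
       assignments = assignments)
}

#' Simulate the complete multi-omics dataset
#'
#' Runs all simulators in sequence under the configured seed.
#'
#' @param config a [simulation_config]
#' @return list with genome, truth, annotation, coverage, fragments,
#'   peptides, gsmr
#' @export
simulate_dataset <- function(config = simulation_config()) {
  gsim <- simulate_genome(config)
  list(genome = gsim$genome, truth = gsim$truth,
       annotation = gsim$annotation,
       coverage = simulate_coverage(gsim$genome, gsim$truth, config),
       fragments = simulate_fragments(gsim$genome, gsim$truth, config),
       peptides = simulate_peptides(gsim$genome, gsim$truth, config),
       gsmr = simulate_gsmr_tables(gsim$genome, gsim$truth, config))
}

#' Write a simulated dataset to disk
#'
#' Emits genome.fasta, annotated.gff3, truth.json,
#' coverage_tp<t>.<strand>.bedgraph, fragments.bed, peptides.tsv,
#' domains.tsv, reactions.tsv, orthologs.tsv.
#'
#' @param sim result of [simulate_dataset]
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$genome, p("genome.fasta"))
  write_gff3(sim$annotation, p("annotated.gff3"))
  for (nm in names(sim$coverage)) {
    tr <- sim$coverage[[nm]]
    strand_tag <- if (tr$strand == "+") "plus" else "minus"
    write_bedgraph(tr, names(sim$genome)[1L],
                   p(sprintf("coverage_%s.%s.bedgraph", tr$time_point,
                             strand_tag)))
  }
  write_bed(sim$fragments, p("fragments.bed"))
  write_tsv_table(sim$peptides[, c("peptide", "confidence", "sample")],
                  p("peptides.tsv"))
  write_tsv_table(sim$gsmr$domains, p("domains.tsv"))
  write_tsv_table(sim$gsmr$reactions, p("reactions.tsv"))
  write_tsv_table(sim$gsmr$orthologs, p("orthologs.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(genes = tr$genes, rbs = tr$rbs, frameshift = tr$frameshift,
         transcribed_segments = tr$transcribed_segments,
         expression = tr$expression),
    p("truth.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
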