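test_that("planted peptides map uniquely to their source gene; decoys nowhere", {
  sim <- shared_sim()
  hits <- map_peptides(sim$peptides[, c("peptide", "confidence", "sample")],
                       sim$genome)
  tp <- sim$peptides[!sim$peptides$is_decoy, ]
  for (i in seq_len(nrow(tp))) {
    h <- hits[hits$peptide == tp$peptide[i], ]
    expect_true(all(h$unique))
    gn <- sim$truth$genes[sim$truth$genes$gene_id == tp$source_gene[i], ]
    expect_true(all(h$start >= gn$start & h$end <= gn$end &
                      h$strand == gn$strand))
  }
  expect_false(any(sim$peptides$peptide[sim$peptides$is_decoy] %in%
                     hits$peptide))
})

test_that("every placement re-translates exactly to its peptide", {
  sim <- shared_sim()
  hits <- map_peptides(sim$peptides[, c("peptide", "confidence", "sample")],
                       sim$genome)
  g <- sim$genome[[1L]]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    s <- as.character(Biostrings::subseq(g, h$start + 1L, h$end))
    if (h$strand == "-") s <- annotforge:::revcomp_chr(s)
    aa <- annotforge:::translate_dna(s)
    expect_identical(gsub("I", "L", aa), gsub("I", "L", h$peptide))
  }
})

test_that("repeated peptides are non-unique with all placements listed", {
  # one gene duplicated verbatim in two places
  unit <- "ATGGACGAGTTCGGCCACATCAAGCTGATGAACCCGCAGCGCTGA"
  pad1 <- paste(rep("C", 30), collapse = "")
  g <- tiny_genome(c(chr = paste0(pad1, unit, pad1, unit, pad1)))
  pep <- "MDEFGHIKLMNPQR"  # aa 1-14 of the unit's translation
  hits <- map_peptides(pep, g)
  expect_equal(nrow(hits), 2L)
  expect_true(all(!hits$unique))
  expect_equal(hits$n_placements, c(2L, 2L))
  expect_error(expand_to_orf(hits[1, ], g), "uniquely")
})

test_that("ambiguous residues are skipped, invalid alphabets rejected", {
  g <- tiny_genome(c(chr = "ATGAAATAA"))
  expect_warning(h <- map_peptides(c("MKX", "MK"), g), "skipped")
  expect_error(map_peptides("MK1", g), "alphabet")
})

test_that("in-frame expansion of a mid-gene peptide recovers the planted gene", {
  sim <- shared_sim()
  hid <- sim$truth$genes[sim$truth$genes$hidden, ]
  tp <- sim$peptides[!sim$peptides$is_decoy &
                       sim$peptides$source_gene %in% hid$gene_id, ]
  hits <- map_peptides(tp[, c("peptide", "confidence", "sample")],
                       sim$genome)
  for (pep in unique(tp$peptide)) {
    h <- hits[hits$peptide == pep, ][1, ]
    orf <- expand_to_orf(h, sim$genome)
    gn <- hid[hid$gene_id == tp$source_gene[tp$peptide == pep][1L], ]
    expect_equal(orf$start, gn$start)
    expect_equal(orf$end, gn$end)
    expect_equal(orf$strand, gn$strand)
    expect_false(orf$partial)
    expect_identical(orf$protein, gn$protein)
  }
})

test_that("a frame with no upstream start before a stop gives a partial ORF", {
  # TAA stop immediately upstream of the peptide codons, no start between
  g <- tiny_genome(c(chr = paste0("CCCTAA", "GACGAGTTCGGCCAC", "TGA", "CCC")))
  hits <- map_peptides("DEFGH", g)
  expect_equal(nrow(hits), 1L)
  orf <- expand_to_orf(hits[1, ], g)
  expect_true(orf$partial)
  expect_true(orf$met_upstream_stop)
  expect_equal(orf$start, 6L)   # clipped at the peptide itself
  expect_equal(orf$end, 24L)    # through the downstream stop
})

test_that("classification separates novel, hypothetical, extension and frameshift", {
  sim <- shared_sim()
  calls <- proteogenomic_calls(
    sim$peptides[, c("peptide", "confidence", "sample")],
    sim$genome, sim$annotation)
  hid <- sim$truth$genes[sim$truth$genes$hidden, ]
  for (i in seq_len(nrow(hid))) {
    m <- calls[calls$start == hid$start[i] & calls$end == hid$end[i], ]
    expect_equal(nrow(m), 1L)
    expect_equal(m$classification, "novel")
  }
  # annotated genes with peptides and a hypothetical product are confirmed
  hyp_ids <- sim$annotation$gene_id[vapply(sim$annotation$attributes,
    function(a) identical(unname(a["product"]), "hypothetical protein"),
    logical(1))]
  srcs <- unique(sim$peptides$source_gene[!sim$peptides$is_decoy])
  hyp_with <- setdiff(intersect(hyp_ids, srcs),
                      sim$truth$frameshift$gene_id)
  ann_with <- setdiff(intersect(sim$annotation$gene_id, srcs),
                      c(hyp_ids, sim$truth$frameshift$gene_id))
  for (gid in hyp_with) {
    gn <- sim$truth$genes[sim$truth$genes$gene_id == gid, ]
    m <- calls[calls$start == gn$start & calls$end == gn$end, ]
    expect_equal(m$classification, "confirms_hypothetical")
  }
  for (gid in ann_with) {
    gn <- sim$truth$genes[sim$truth$genes$gene_id == gid, ]
    m <- calls[calls$start == gn$start & calls$end == gn$end, ]
    expect_equal(m$classification, "extension")
  }
  # the planted frameshift gene
  fs <- sim$truth$frameshift
  m <- calls[calls$start == fs$true_start & calls$end == fs$true_end, ]
  expect_equal(m$classification, "frameshift_flag")
})

test_that("acceptance rules follow the two-peptide / RNA-validation logic", {
  mk_call <- function(confs, classification = "novel") {
    peps <- data.frame(peptide = sprintf("PEPTIDE%dK", seq_along(confs)),
                       confidence = confs)
    df <- data.frame(chrom = "chr", start = 30L, end = 60L, strand = "+",
                     frame = 0L, start_codon = "ATG", protein = "M",
                     partial = FALSE, evidence = "peptide",
                     classification = classification,
                     n_peptides = length(confs),
                     n_conf_peptides = sum(confs >= 95))
    df$peptides <- I(list(peps))
    df
  }
  ann <- gene_models("g1", "chr", 90L, 120L, "+", kind = "CDS")
  hot <- coverage_track(c(rep(1, 30), rep(50, 30), rep(1, 60)),
                        "tp1", "tp1", "+")
  cold <- coverage_track(rep(1, 120), "tp2", "tp2", "+")

  # two confident peptides: accepted outright
  r <- filter_proteins(mk_call(c(96, 96)), list(cold), ann)
  expect_equal(r$status, "accepted")
  expect_false(r$rna_validated)
  # one confident peptide + transcription: accepted via RNA validation
  r <- filter_proteins(mk_call(99), list(hot, cold), ann)
  expect_equal(r$status, "accepted")
  expect_true(r$rna_validated)
  # one confident peptide, no transcription: rejected
  r <- filter_proteins(mk_call(99), list(cold), ann)
  expect_equal(r$status, "rejected")
  # one confident peptide, no transcription evidence available
  r <- filter_proteins(mk_call(99), NULL, ann)
  expect_equal(r$status, "needs_rna_validation")
  # peptides below the confidence cut do not count
  r <- filter_proteins(mk_call(c(94, 93)), list(hot), ann)
  expect_equal(r$status, "rejected")
  # mixed: one at 96, one at 94 behaves as a single-peptide call
  r <- filter_proteins(mk_call(c(96, 94)), list(hot, cold), ann)
  expect_equal(r$status, "accepted")
  expect_true(r$rna_validated)
})

test_that("lowering the confidence threshold never shrinks the accepted set", {
  sim <- shared_sim()
  calls <- proteogenomic_calls(
    sim$peptides[, c("peptide", "confidence", "sample")],
    sim$genome, sim$annotation)
  tracks <- normalize_tracks(sim$coverage, sim$annotation)
  prev <- character(0)
  for (thr in c(99, 97, 95, 90, 80)) {
    f <- filter_proteins(calls, tracks, sim$annotation, min_conf = thr)
    acc <- sprintf("%d:%d", f$start, f$end)[f$status == "accepted"]
    expect_true(all(prev %in% acc))
    prev <- acc
  }
})
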