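test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 11L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$truth$expression, b$truth$expression)
})

test_that("the genome hits the configured G+C within binomial tolerance", {
  gs <- simulate_genome(simulation_config(seed = 3L))
  gc <- sum(Biostrings::letterFrequency(gs$genome[[1L]], c("G", "C")))
  expect_lt(abs(gc / Biostrings::width(gs$genome)[1L] - 0.72), 0.02)
})

test_that("planted genes are well-formed ORFs with SD motifs in place", {
  sim <- shared_sim()
  g <- sim$genome[[1L]]
  for (i in seq_len(nrow(sim$truth$genes))) {
    gn <- sim$truth$genes[i, ]
    s <- as.character(Biostrings::subseq(g, gn$start + 1L, gn$end))
    if (gn$strand == "-") s <- annotforge:::revcomp_chr(s)
    expect_identical(s, gn$cds)
    expect_true(substr(s, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_false(grepl("*", gn$protein, fixed = TRUE))
  }
  for (i in seq_len(nrow(sim$truth$rbs))) {
    r <- sim$truth$rbs[i, ]
    gn <- sim$truth$genes[sim$truth$genes$gene_id == r$gene_id, ]
    sd <- as.character(Biostrings::subseq(g, r$sd_start + 1L, r$sd_end))
    if (gn$strand == "-") sd <- annotforge:::revcomp_chr(sd)
    expect_identical(sd, "AGGAGG")
    # SD window 4-15 nt upstream of the start (transcript orientation)
    d <- if (gn$strand == "+") gn$start - r$sd_end else r$sd_start - gn$end
    expect_gte(d, 4L); expect_lte(d, 15L)
  }
})

test_that("hidden genes are absent from the emitted annotation, present in truth", {
  sim <- shared_sim()
  hid <- sim$truth$genes$gene_id[sim$truth$genes$hidden]
  expect_gt(length(hid), 0L)
  expect_false(any(hid %in% sim$annotation$gene_id))
  none <- simulate_genome(small_cfg(seed = 2L, n_hidden_genes = 0L))
  expect_equal(sum(none$truth$genes$hidden), 0L)
})

test_that("the frameshift record is offset from the true gene in its frame", {
  sim <- shared_sim()
  fs <- sim$truth$frameshift
  expect_equal(nrow(fs), 1L)
  ann <- sim$annotation[sim$annotation$gene_id == fs$gene_id, ]
  expect_equal(ann$start - fs$true_start, fs$offset)
  expect_equal((ann$end - ann$start) %% 3L, 0L)
  # the mis-annotated model really is in a shifted frame
  expect_false((ann$start %% 3L) == (fs$true_start %% 3L))
})

test_that("impossible placements fail with advice to enlarge the genome", {
  expect_error(simulate_genome(simulation_config(seed = 1L,
                                                 genome_length = 5000L)),
               "increase genome_length")
})

test_that("coverage follows the planted expression program", {
  sim <- shared_sim()
  cfg <- sim$truth$config
  hid <- sim$truth$genes[sim$truth$genes$hidden, ][1, ]
  e <- sim$truth$expression
  base <- e$base_expr[e$feature_id == hid$gene_id]
  mult <- sim$truth$multipliers[hid$gene_id, ]
  means <- interval_tp_means(sim$coverage, hid$start, hid$end, hid$strand)
  # planted expression at the best time point is far above background
  expect_gt(max(means), 10 * cfg$background_depth)
  expect_gt(cor(means, cfg$coverage_depth * base * mult), 0.99)
  # the designated switch-down hidden gene decreases monotonically
  expect_equal(e$profile[e$feature_id == hid$gene_id], "down")
  expect_true(all(diff(means) < 0))
})

test_that("coverage totals match planted expression within Poisson error", {
  sim <- shared_sim()
  cfg <- sim$truth$config
  gn <- sim$truth$genes[!sim$truth$genes$hidden, ][1, ]
  e <- sim$truth$expression
  lam <- cfg$background_depth + cfg$coverage_depth *
    e$base_expr[e$feature_id == gn$gene_id] *
    sim$truth$multipliers[gn$gene_id, 1L]
  tr <- sim$coverage[[paste0("tp1_", gn$strand)]]
  tot <- sum(tr$values[(gn$start + 1L):gn$end])
  expected <- lam * (gn$end - gn$start)
  expect_lt(abs(tot - expected), 6 * sqrt(expected))
})

test_that("zero-depth configuration yields all-zero tracks", {
  cfg <- small_cfg(seed = 5L, coverage_depth = 0, background_depth = 0)
  gs <- simulate_genome(cfg)
  cov <- simulate_coverage(gs$genome, gs$truth, cfg)
  expect_true(all(vapply(cov, function(t) all(t$values == 0), logical(1))))
})

test_that("fragments obey the size selection and gene strand", {
  cfg <- small_cfg(seed = 9L, fragment_background = 0)
  gs <- simulate_genome(cfg)
  fr <- simulate_fragments(gs$genome, gs$truth, cfg)
  len <- fr$end - fr$start
  expect_true(all(len >= 15L & len <= 50L))
  minus <- gs$truth$genes[gs$truth$genes$strand == "-", ]
  for (i in seq_len(min(5L, nrow(minus)))) {
    gn <- minus[i, ]
    near <- fr$start >= gn$start - 60L & fr$end <= gn$end + 60L
    expect_true(all(fr$strand[near] == "-"))
  }
})

test_that("a no-protection control has uniform 5'-termini phases", {
  cfg <- small_cfg(seed = 13L, fragment_protection_strength = 0,
                   fragment_background = 0)
  gs <- simulate_genome(cfg)
  fr <- simulate_fragments(gs$genome, gs$truth, cfg)
  phases <- integer(0)
  for (i in seq_len(nrow(gs$truth$genes))) {
    gn <- gs$truth$genes[i, ]
    p5 <- if (gn$strand == "+") fr$start else fr$end - 1L
    o <- if (gn$strand == "+") p5 - gn$start else gn$end - 1L - p5
    keep <- fr$strand == gn$strand & o >= 9L & o <= gn$end - gn$start - 10L
    phases <- c(phases, rep(o[keep] %% 3L, fr$count[keep]))
  }
  expect_gt(length(phases), 1000L)
  p <- chisq.test(table(factor(phases, levels = 0:2)))$p.value
  expect_gt(p, 0.01)
})

test_that("true peptides are in-genome, decoys are not", {
  sim <- shared_sim()
  frames <- annotforge:::six_frame_proteins(as.character(sim$genome[[1L]]))
  true_p <- sim$peptides[!sim$peptides$is_decoy, ]
  for (pep in unique(true_p$peptide))
    expect_equal(annotforge:::count_genome_occurrences(pep, frames), 1L)
  decoys <- sim$peptides[sim$peptides$is_decoy, ]
  expect_equal(nrow(decoys), sim$truth$config$n_decoy_peptides)
  for (pep in decoys$peptide)
    expect_equal(annotforge:::count_genome_occurrences(pep, frames), 0L)
})

test_that("peptides are tryptic-style and respect the planted design", {
  sim <- shared_sim()
  tp <- sim$peptides[!sim$peptides$is_decoy, ]
  expect_true(all(grepl("[KR]$", tp$peptide)))
  expect_true(all(nchar(tp$peptide) >= 7L & nchar(tp$peptide) <= 30L))
  expect_true(all(tp$confidence >= 95))
  expect_true(all(sim$peptides$confidence[sim$peptides$is_decoy] < 95))
  # every hidden gene got 1-4 peptides; the designated one exactly 1
  hid <- sim$truth$genes$gene_id[sim$truth$genes$hidden]
  counts <- table(tp$source_gene)[hid]
  expect_true(all(counts >= 1L & counts <= 4L))
  expect_equal(unname(counts[hid[1L]]), 1L)
})

test_that("the frameshift gene's peptides avoid the mis-annotated translation", {
  sim <- shared_sim()
  fs <- sim$truth$frameshift
  ann <- sim$annotation[sim$annotation$gene_id == fs$gene_id, ]
  ann_prot <- annotforge:::translate_orf(
    as.character(Biostrings::subseq(sim$genome[[1L]], ann$start + 1L,
                                    ann$end)))
  peps <- sim$peptides$peptide[sim$peptides$source_gene %in% fs$gene_id]
  expect_gt(length(peps), 0L)
  for (pep in peps)
    expect_false(grepl(pep, ann_prot, fixed = TRUE))
})
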