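test_that("termini offsets follow the metagene definition on both strands", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr",
                      start = c(100L, 300L), end = c(200L, 400L),
                      strand = c("+", "-"))
  # transcript geometry [start-15, start+5) on each gene
  frags <- data.frame(chrom = "chr",
                      start = c(100L - 15L, 400L - 5L),
                      end = c(100L + 5L, 400L + 15L),
                      strand = c("+", "-"), count = c(1L, 1L))
  prof <- metagene_termini(frags, genes, genome_length = 1000L,
                           window = 40L)
  expect_equal(unname(prof$counts5[as.character(-15)]), 2)
  expect_equal(unname(prof$counts3[as.character(4)]), 2)
  expect_equal(sum(prof$counts5), 2)
  expect_equal(sum(prof$counts3), 2)
  expect_equal(prof$n_genes, 2L)
  # per-gene bookkeeping matches the pooled profile
  expect_equal(colSums(prof$per_gene5), unname(prof$counts5),
               ignore_attr = TRUE)
})

test_that("termini counts conserve the weighted in-window fragment totals", {
  sim <- shared_sim()
  genes <- sim$truth$genes
  prof <- metagene_termini(sim$fragments, genes,
                           Biostrings::width(sim$genome)[1L], window = 30L)
  total <- 0
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    a <- if (gn$strand == "+") gn$start else gn$end - 1L
    fr <- sim$fragments[sim$fragments$strand == gn$strand, ]
    p5 <- if (gn$strand == "+") fr$start else fr$end - 1L
    o <- if (gn$strand == "+") p5 - a else a - p5
    total <- total + sum(fr$count[o >= -30L & o <= 30L])
  }
  expect_equal(sum(prof$counts5), total)
})

test_that("profiles are invariant under genome reverse-complement", {
  sim <- shared_sim()
  L <- Biostrings::width(sim$genome)[1L]
  genes <- sim$truth$genes
  flip_genes <- transform(genes, start = L - end, end = L - start,
                          strand = ifelse(strand == "+", "-", "+"))
  flip_frags <- transform(sim$fragments, start = L - end, end = L - start,
                          strand = ifelse(strand == "+", "-", "+"))
  a <- metagene_termini(sim$fragments, genes, L, window = 25L)
  b <- metagene_termini(flip_frags, flip_genes, L, window = 25L)
  expect_equal(a$counts5, b$counts5)
  expect_equal(a$counts3, b$counts3)
  expect_equal(a$n_genes, b$n_genes)
})

test_that("the metagene 5' peak sits at the planted SD geometry", {
  sim <- shared_sim()
  prof <- metagene_termini(sim$fragments, sim$truth$genes,
                           Biostrings::width(sim$genome)[1L])
  up <- prof$offsets < 0
  peak <- prof$offsets[up][which.max(prof$counts5[up])]
  expect_equal(peak, -(7L + 6L))  # -(sd_spacer + |AGGAGG|)
})

test_that("the global protection window covers the planted SD interval", {
  sim <- shared_sim()
  rb <- call_rbs(sim$truth$genes, sim$fragments, sim$genome)
  expect_true(rb$global$called)
  # the protected 5' termini pile at the SD 5' edge: the called window must
  # contain the planted anchor -(sd_spacer + |AGGAGG|)
  expect_lte(rb$global$window_lo, -13L)
  expect_gte(rb$global$window_hi, -13L)
  # most per-gene peaks within 2 nt of the planted SD start
  expect_gt(mean(abs(rb$calls$peak_offset + 13L) <= 2L), 0.8)
  expect_true(all(rb$calls$score >= 3))
  # called windows carry the motif
  expect_gt(mean(rb$calls$sd_match), 0.9)
})

test_that("no-protection controls yield almost no calls and no global window", {
  cfg <- small_cfg(seed = 21L, fragment_protection_strength = 0)
  gs <- simulate_genome(cfg)
  fr <- simulate_fragments(gs$genome, gs$truth, cfg)
  rb <- call_rbs(gs$truth$genes, fr, gs$genome)
  expect_false(rb$global$called)
  expect_lte(nrow(rb$calls) / nrow(gs$truth$genes), 0.05)
})

test_that("unexpressed anchors receive no call; motif-free calling still works", {
  sim <- shared_sim()
  genes <- rbind(sim$truth$genes[, c("gene_id", "chrom", "start", "end",
                                     "strand")],
                 data.frame(gene_id = "ghost", chrom = names(sim$genome)[1L],
                            start = 21L, end = 51L, strand = "+"))
  rb <- call_rbs(genes, sim$fragments[0, ], sim$genome)
  expect_equal(nrow(rb$calls), 0L)
  expect_true("ghost" %in% rb$misses)
  prof <- metagene_termini(sim$fragments, sim$truth$genes,
                           Biostrings::width(sim$genome)[1L])
  with_m <- detect_protection_window(prof, sim$truth$genes, sim$genome,
                                     motif = "AGGAGG")
  no_m <- detect_protection_window(prof, sim$truth$genes, sim$genome,
                                   motif = "")
  expect_equal(no_m$calls$peak_offset, with_m$calls$peak_offset)
  expect_true(all(!no_m$calls$sd_match))
})

test_that("a pure codon comb gives period 3 at near-maximal strength", {
  counts <- rep(c(9, 1, 1), 40)
  r <- periodicity_from_counts(counts)
  expect_equal(r$period, 3L)
  expect_gt(r$strength, 0.8)
  expect_true(r$significant)
  u <- periodicity_from_counts(rep(5, 120))
  expect_false(u$significant)
})

test_that("the spectral estimator agrees with a naive DFT oracle", {
  set.seed(314)
  for (rep in 1:100) {
    n <- sample(60:200, 1L)
    counts <- rpois(n, 4)
    if (rep %% 2 == 0) {  # half the cases carry a planted period
      p <- sample(2:10, 1L)
      counts <- counts + 6 * (seq_len(n) %% p == 0)
    }
    got <- periodicity_from_counts(counts, max_lag = 10L)
    expect_equal(got$period, oracle_period(counts, 10L))
  }
})

test_that("default synthetic fragments show the 3-nt ribosome step", {
  sim <- shared_sim()
  r <- estimate_periodicity(sim$fragments, sim$truth$genes)
  expect_equal(r$period, 3L)
  expect_true(r$significant)
  few <- estimate_periodicity(sim$fragments[0, ], sim$truth$genes)
  expect_true(is.na(few$period))
  expect_match(few$diagnostic, "insufficient")
})
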