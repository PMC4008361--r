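test_that("normalization equalizes library scale and is idempotent on equals", {
  v <- c(rep(0, 10), rep(10, 20), rep(2, 10))
  t1 <- coverage_track(v, "lib1", "tp1", "+")
  t2 <- coverage_track(v, "lib2", "tp2", "+")
  n <- normalize_tracks(list(t1, t2))
  expect_equal(n[[1L]]$values, n[[2L]]$values)

  t2b <- coverage_track(2 * v, "lib2", "tp2", "+")
  n <- normalize_tracks(list(t1, t2b))
  expect_equal(n[[1L]]$values, n[[2L]]$values)

  t0 <- coverage_track(rep(0, 40), "lib3", "tp3", "+")
  expect_error(normalize_tracks(list(t1, t0)), "empty library")
})

test_that("normalization preserves within-library rank order of region means", {
  sim <- shared_sim()
  n <- normalize_tracks(sim$coverage, sim$annotation)
  regs <- sim$truth$genes[1:10, ]
  for (ti in c(1L, 5L)) {
    raw <- vapply(seq_len(nrow(regs)), function(i)
      mean(sim$coverage[[ti]]$values[(regs$start[i] + 1L):regs$end[i]]),
      numeric(1))
    nor <- vapply(seq_len(nrow(regs)), function(i)
      mean(n[[ti]]$values[(regs$start[i] + 1L):regs$end[i]]), numeric(1))
    expect_equal(order(raw), order(nor))
  }
})

test_that("planted transcribed segments are recovered with high overlap", {
  sim <- shared_sim()
  n <- normalize_tracks(sim$coverage, sim$annotation)
  intergenic <- extract_intergenic(sim$annotation, sim$genome)
  det <- detect_transcribed_regions(n, intergenic, sim$annotation)
  ts <- sim$truth$transcribed_segments
  jac <- vapply(seq_len(nrow(ts)), function(i) {
    s <- ts[i, ]
    cand <- det[det$strand == s$strand, ]
    if (nrow(cand) == 0L) return(0)
    inter <- pmax(0, pmin(cand$end, s$end) - pmax(cand$start, s$start))
    max(inter / ((cand$end - cand$start) + (s$end - s$start) - inter))
  }, numeric(1))
  expect_true(all(jac >= 0.8))
  # detections never overlap annotated features
  for (i in seq_len(nrow(det))) {
    expect_false(any(sim$annotation$start < det$end[i] &
                       sim$annotation$end > det$start[i] &
                       sim$annotation$chrom == det$chrom[i]))
  }
})

test_that("detection count is monotone non-increasing in the threshold", {
  sim <- shared_sim()
  n <- normalize_tracks(sim$coverage, sim$annotation)
  intergenic <- extract_intergenic(sim$annotation, sim$genome)
  counts <- vapply(c(2, 5, 10, 50, 500),
                   function(k) nrow(detect_transcribed_regions(
                     n, intergenic, sim$annotation, k = k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-coverage regions are not reported", {
  g <- tiny_genome(c(chr = paste(rep("ACGT", 100), collapse = "")))
  ann <- gene_models("g1", "chr", 0L, 90L, "+", kind = "CDS")
  tr <- coverage_track(c(rep(5, 90), rep(0, 310)), "tp1", "tp1", "+")
  det <- detect_transcribed_regions(list(tr),
                                    extract_intergenic(ann, g), ann)
  expect_equal(nrow(det), 0L)
})

test_that("is_transcribed separates expressed genes from cold intervals", {
  sim <- shared_sim()
  n <- normalize_tracks(sim$coverage, sim$annotation)
  hid <- sim$truth$genes[sim$truth$genes$hidden, ][1, ]
  v <- is_transcribed(hid, n, sim$annotation)
  expect_true(v$transcribed)
  expect_gt(v$mean_expr, 0)
  # a bare intergenic interval with no planted feature (features are
  # non-overlapping, so gaps come straight from the sorted table)
  feats <- rbind(sim$truth$genes[, c("start", "end")],
                 sim$truth$transcribed_segments[, c("start", "end")])
  feats <- feats[order(feats$start), ]
  gaps_start <- c(0L, feats$end)
  gaps_end <- c(feats$start, Biostrings::width(sim$genome)[1L])
  gi <- which(gaps_end - gaps_start >= 200L)[1L]
  mid <- (gaps_start[gi] + gaps_end[gi]) %/% 2L
  cold <- data.frame(chrom = names(sim$genome)[1L], start = mid - 50L,
                     end = mid + 50L, strand = "+")
  expect_false(is_transcribed(cold, n, sim$annotation)$transcribed)
  expect_error(is_transcribed(transform(cold, end = start), n,
                              sim$annotation), "empty interval")
})

test_that("cumulative tables are proper ECDFs and novel genes skew short", {
  sim <- shared_sim()
  novel <- sim$truth$genes[sim$truth$genes$hidden, ]
  annotated <- sim$annotation[sim$annotation$kind == "CDS", ]
  cs <- cumulative_summaries(novel, annotated)
  for (cl in unique(cs$class)) {
    sub <- cs[cs$class == cl & cs$metric == "length_aa", ]
    expect_true(all(diff(sub$cumfrac) >= 0))
    expect_equal(sub$cumfrac[nrow(sub)], 1)
  }
  nl <- cs$value[cs$class == "novel" & cs$metric == "length_aa"]
  al <- cs$value[cs$class == "annotated" & cs$metric == "length_aa"]
  p <- suppressWarnings(wilcox.test(nl, al, alternative = "less")$p.value)
  expect_lt(p, 0.01)
  empty <- cumulative_summaries(novel[0, ], annotated[0, ])
  expect_equal(nrow(empty), 0L)
})
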