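# scaled-down simulation used by unit tests (acceptance tests run the
# default configuration)
small_cfg <- function(seed = 1L, ...) {
  base <- list(seed = seed, genome_length = 40000L,
               n_annotated_genes = 24L, n_hidden_genes = 6L,
               n_noncoding_transcribed = 4L,
               n_annotated_with_peptides = 8L,
               fragment_background = 800)
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

# one small simulated dataset shared across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_cfg(seed = 7L))
    cache
  }
})

tiny_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

# per-time-point mean coverage of an interval, one value per library
interval_tp_means <- function(tracks, start, end, strand) {
  sel <- Filter(function(t) t$strand == strand, tracks)
  vapply(sel, function(t) mean(t$values[(start + 1L):end]), numeric(1))
}
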