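# Shared fixtures, built in code. The small pair is used by many module
# tests; it is generated once per test run and memoised here.

fixture_env <- new.env(parent = emptyenv())

small_grammar <- function(seed = 7L) {
  grammar_spec(seed = seed)
}

# small two-species pair with tracks (1 chromosome x 128 kb per genome)
small_pair <- function() {
  if (is.null(fixture_env$pair)) {
    pair <- generate_species_pair(small_grammar(), n_chrom = 1,
                                  chrom_len = 2^17, shared_fraction = 0.5,
                                  block_len = 2^15, seq_len = 4096)
    fixture_env$pair <- simulate_signal_tracks(pair)
  }
  fixture_env$pair
}

# a tiny network everybody can afford to forward through
tiny_config <- function(heads = c(A = 3, B = 2), seq_len = 1024,
                        dropout = 0) {
  model_config(seq_len = seq_len, tower_blocks = 3, init_filters = 6,
               filter_growth = 1.26, first_kernel = 15, tower_kernel = 5,
               dilated_blocks = 2, dilated_filters = 4,
               residual_filters = round(6 * 1.26^2),
               final_filters = 10, heads = heads,
               residual_dropout = dropout, final_dropout = dropout)
}

tiny_model <- function(seed = 2L, ...) build_model(tiny_config(...), seed)

random_seq <- function(n, seed = 1) {
  with_seed <- get("with_seed", asNamespace("crossreg"))
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

# random training examples for a tiny model (constant-free targets)
random_examples <- function(n, config, genome_id = "A", seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- encode_sequence(random_seq(config$seq_len, seed + i))
    y <- matrix(rexp(config$n_bins * config$heads[[genome_id]]),
                config$n_bins)
    structure(list(x = x, y = y, genome_id = genome_id, chrom = "chr1",
                   start = 0L, end = config$seq_len, split = "train"),
              class = "training_example")
  })
}
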