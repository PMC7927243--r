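# Shared fixtures: small simulation configs and random codon weight tables.

small_cfg <- function(seed = 101, ...) {
  defaults <- list(seed = seed, n_variants = 30, cells_total = 30000,
                   reads_per_bin = 3000, n_replicates = 2, error_rate = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# random weight table over n codons, weights in (0, 1] with at least one 1
random_weights <- function(n = 8, seed = 1) {
  withr::with_seed(seed, {
    codons <- sample(sense_codons(), n)
    w <- runif(n, 0.05, 1)
    w[sample(n, 1)] <- 1
    setNames(w, codons)
  })
}

random_seq_from <- function(weights, length = 8, seed = 1) {
  withr::with_seed(seed,
    paste(sample(names(weights), length, replace = TRUE), collapse = ""))
}
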