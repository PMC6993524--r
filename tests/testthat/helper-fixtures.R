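# Shared fixtures: all test data is generated in code.

default_params <- gradient_params()

# Random A/C/G/T scaffold with exact composition control via sampling.
random_scaffold <- function(len, gc = 0.5, seed = NULL, name = "chr") {
  if (!is.null(seed)) set.seed(seed)
  s <- sample(c("G", "C", "A", "T"), len, replace = TRUE,
              prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  out <- Biostrings::DNAStringSet(paste0(s, collapse = ""))
  names(out) <- name
  out
}

# A small labeled/unlabeled two-reference setup used by several tests.
two_ref_setup <- function(seed = 42, len = 30000) {
  refs <- c(random_scaffold(len, 0.40, seed, "low_chr"),
            random_scaffold(len, 0.60, seed + 1, "high_chr"))
  frags <- rbind(
    fragment_reference(refs["low_chr"], fragment_size_model("normal", 6000, 1000,
                       min_bp = 2000, max_bp = 12000),
                       coverage = 2, reference_id = "low", seed = seed),
    fragment_reference(refs["high_chr"], fragment_size_model("normal", 6000, 1000,
                       min_bp = 2000, max_bp = 12000),
                       coverage = 2, reference_id = "high", seed = seed + 1)
  )
  comm <- community_profile("s1", c("low", "high"), c(0.5, 0.5))
  inc <- incorporator_table("s1", "low", "13C", 100, 0)
  list(refs = refs, frags = frags, comm = comm, inc = inc)
}
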