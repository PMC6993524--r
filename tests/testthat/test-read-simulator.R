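test_that("multinomial allocation matches abundance proportions", {
  expect_equal(allocate_reads(c(0, 2.5, 0), 100, seed = 1),
               c(0L, 100L, 0L))
  expect_equal(allocate_reads(c(1, 1), 0), c(0L, 0L))
  set.seed(2)
  counts <- allocate_reads(c(3, 1), 1e5, seed = 3)
  expect_equal(sum(counts), 1e5)
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(counts[1] / 1e5 - 0.75), 3 * se)
  expect_error(allocate_reads(c(0, 0), 10), "all read abundances are zero")
})

test_that("generated pairs respect fragment bounds, insert model and lengths", {
  frag <- data.frame(reference_id = "r", scaffold_id = "c",
                     start = 1000L, end = 21000L)
  set.seed(4)
  p <- generate_pairs(frag, 1e4, read_length = 151,
                      insert_mean = 1000, insert_sd = 5)
  expect_equal(nrow(p), 1e4)
  expect_true(all(p$fwd_start >= 1000L & p$rev_end <= 21000L))
  expect_true(all(p$fwd_end - p$fwd_start == 151L))
  expect_true(all(p$rev_end - p$rev_start == 151L))
  expect_true(all(p$insert_size == p$rev_end - p$fwd_start))
  expect_true(all(p$insert_size >= 151L))
  expect_lt(abs(mean(p$insert_size) - 1000), 2 * 5 / sqrt(1e4) + 0.5)
  # fair mate-orientation coin
  expect_lt(abs(mean(p$flip) - 0.5), 3 * 0.5 / sqrt(1e4))
  expect_error(generate_pairs(data.frame(reference_id = "r", scaffold_id = "c",
                                         start = 0L, end = 100L), 1, 151),
               "shorter than read_length")
})

test_that("degenerate insert makes mates exact reverse complements", {
  ref <- random_scaffold(5000, 0.5, seed = 5, name = "c")
  frag <- data.frame(reference_id = "r", scaffold_id = "c",
                     start = 0L, end = 5000L)
  set.seed(6)
  p <- generate_pairs(frag, 50, read_length = 100,
                      insert_mean = 100, insert_sd = 0)
  p <- cbind(pair_id = sprintf("pair%d", seq_len(nrow(p))), p)
  seqs <- pair_sequences(p, ref)
  expect_equal(as.character(seqs$R2),
               as.character(Biostrings::reverseComplement(seqs$R1)),
               ignore_attr = TRUE)
})

test_that("window libraries are seed-reproducible and order-independent", {
  s <- two_ref_setup()
  fb <- fragment_bd(s$frags, s$comm, s$inc, params = default_params, seed = 1)
  ab <- fragment_window_abundance(fb, bd_window(1.70, 1.78),
                                  default_params, 0.001)
  a <- simulate_window_library(ab, 2000, seed = 99, window = "w")
  b <- simulate_window_library(ab, 2000, seed = 99, window = "w")
  expect_identical(a, b)
  # per-fragment RNG streams: reversing fragment order yields the same reads
  rev_ab <- ab[rev(seq_len(nrow(ab))), ]
  c_ <- simulate_window_library(rev_ab, 2000, seed = 99, window = "w")
  key <- function(p) sort(paste(p$scaffold_id, p$fwd_start, p$rev_end, p$flip))
  expect_identical(key(a), key(c_))
})

test_that("library files round-trip: order, ids, provenance and mate pairing", {
  s <- two_ref_setup()
  fb <- fragment_bd(s$frags, s$comm, s$inc, params = default_params, seed = 1)
  ab <- fragment_window_abundance(fb, bd_window(1.70, 1.78),
                                  default_params, 0.001)
  pairs <- simulate_window_library(ab, 500, seed = 7, window = "w1")
  r1 <- tempfile(fileext = ".fasta"); r2 <- tempfile(fileext = ".fasta")
  write_library(pairs, s$refs, r1, r2)
  R1 <- Biostrings::readDNAStringSet(r1)
  R2 <- Biostrings::readDNAStringSet(r2)
  expect_length(R1, 500); expect_length(R2, 500)
  h1 <- parse_read_header(names(R1)); h2 <- parse_read_header(names(R2))
  expect_identical(h1$pair_id, h2$pair_id)
  expect_equal(h1$mate, rep(1L, 500)); expect_equal(h2$mate, rep(2L, 500))
  # byte-for-byte re-extraction from header coordinates
  for (set in list(list(R1, h1), list(R2, h2))) {
    reads <- set[[1]]; h <- set[[2]]
    ext <- Biostrings::subseq(s$refs[match(h$scaffold_id, names(s$refs))],
                              h$start + 1L, h$end)
    rc <- h$strand == "-"
    ext[rc] <- Biostrings::reverseComplement(ext[rc])
    expect_equal(as.character(ext), as.character(reads), ignore_attr = TRUE)
  }
  # exactly one mate of each pair is the forward read
  expect_true(all(xor(h1$strand == "+", h2$strand == "+")))
})

test_that("shotgun read shares follow length-weighted reference abundance", {
  refs <- c(random_scaffold(40000, 0.5, seed = 8, name = "a_chr"),
            random_scaffold(20000, 0.5, seed = 9, name = "b_chr"))
  model <- fragment_size_model("uniform", min_bp = 4000, max_bp = 4000)
  frags <- rbind(
    fragment_reference(refs["a_chr"], model, 1, reference_id = "a", seed = 1),
    fragment_reference(refs["b_chr"], model, 1, reference_id = "b", seed = 2))
  comm <- community_profile("s1", c("a", "b"), c(0.9, 0.1))
  fb <- fragment_bd(frags, comm, params = default_params, seed = 3)
  ab <- shotgun_abundance(fb)
  pairs <- simulate_window_library(ab, 1e4, read_length = 150,
                                   insert_mean = 600, insert_sd = 50,
                                   seed = 10, window = "shotgun")
  share_a <- mean(pairs$reference_id == "a")
  # closed-form expectation: alpha * total fragment length per reference
  w <- c(0.9 * 40000, 0.1 * 20000)
  exp_a <- w[1] / sum(w)
  se <- sqrt(exp_a * (1 - exp_a) / 1e4)
  expect_lt(abs(share_a - exp_a), 3 * se)
})
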