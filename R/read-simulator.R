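# 32-bit FNV-1a hash of a string, folded into a positive R integer.
# Used to derive independent per-fragment RNG streams from the master
# seed, so that parallel execution order cannot affect the output.
.hash32 <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

.derive_seed <- function(master, key) {
  as.integer((as.numeric(master) * 69069 + .hash32(key)) %% 2147483647L)
}

#' Allocate read pairs to fragments
#'
#' A single multinomial draw of `total_pairs` over the fragments with
#' probabilities proportional to their read abundances.
#'
#' @param alpha_r Read abundances (from [read_abundance()]), one per
#'   fragment; at least one must be positive.
#' @param total_pairs Number of read pairs in the library (>= 0).
#' @param seed Optional integer seed.
#' @return Integer vector of pair counts summing to `total_pairs`.
#' @export
allocate_reads <- function(alpha_r, total_pairs, seed = NULL) {
  stopifnot(is.numeric(alpha_r), total_pairs >= 0)
  if (any(alpha_r < 0)) stop("allocate_reads: negative read abundance")
  if (total_pairs == 0) return(integer(length(alpha_r)))
  tot <- sum(alpha_r)
  if (tot <= 0)
    stop("allocate_reads: all read abundances are zero; ",
         "the window recovers no fragments")
  if (!is.null(seed)) set.seed(as.integer(seed))
  as.integer(stats::rmultinom(1, size = total_pairs, prob = alpha_r / tot))
}

#' Generate paired-end reads from one fragment
#'
#' For each pair, an insert (total template length, forward start to
#' reverse end) is drawn from `Normal(insert_mean, insert_sd)`, rounded
#' and clamped to `[read_length, fragment length]`; the template start is
#' uniform over the admissible positions inside the fragment; and a fair
#' coin decides which physical end is written as mate 1. Coordinates are
#' propagated to the source scaffold, so re-extracting them reproduces the
#' read sequences exactly.
#'
#' @param fragment One-row fragment data.frame (needs `reference_id`,
#'   `scaffold_id`, `start`, `end`).
#' @param n Number of pairs to generate.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert-size model (bp).
#' @param window Window label recorded in the pairs.
#' @return A data.frame with one row per pair: scaffold coordinates of the
#'   forward and reverse reads (0-based half-open), `insert_size`, and
#'   `flip` (TRUE when the reverse read is written as mate 1).
#' @export
generate_pairs <- function(fragment, n, read_length = 151,
                           insert_mean = 1000, insert_sd = 5,
                           window = NA_character_) {
  stopifnot(nrow(fragment) == 1L, n >= 0)
  flen <- fragment$end - fragment$start
  if (flen < read_length)
    stop("generate_pairs: fragment shorter than read_length; ",
         "exclude it upstream")
  if (n == 0L) return(NULL)
  ins <- as.integer(round(stats::rnorm(n, insert_mean, insert_sd)))
  ins <- pmin(pmax(ins, read_length), flen)
  tmpl_start <- fragment$start +
    floor(stats::runif(n, 0, flen - ins + 1))
  fwd_start <- as.integer(tmpl_start)
  fwd_end <- fwd_start + as.integer(read_length)
  rev_end <- as.integer(tmpl_start + ins)
  rev_start <- rev_end - as.integer(read_length)
  data.frame(
    reference_id = fragment$reference_id,
    scaffold_id = fragment$scaffold_id,
    fwd_start = fwd_start, fwd_end = fwd_end,
    rev_start = rev_start, rev_end = rev_end,
    insert_size = ins,
    flip = stats::runif(n) < 0.5,
    window = window,
    stringsAsFactors = FALSE
  )
}

#' Simulate a read library for one BD window
#'
#' Drives the per-window read generation: fragments shorter than the read
#' length are excluded from the abundance normalization (with a message),
#' pairs are allocated multinomially by read abundance, and each
#' fragment's pairs are drawn from an RNG stream derived from the master
#' seed and the fragment's coordinates, making the result independent of
#' fragment processing order.
#'
#' @param abund Fragment table with `alpha_f` (from
#'   [fragment_window_abundance()] or [shotgun_abundance()]).
#' @param total_pairs Library size in read pairs.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert-size model (bp).
#' @param seed Master integer seed (mandatory: libraries are always
#'   reproducible).
#' @param window Window label recorded on every pair.
#' @return A pairs data.frame (see [generate_pairs()]) with `pair_id`
#'   prepended.
#' @export
simulate_window_library <- function(abund, total_pairs, read_length = 151,
                                    insert_mean = 1000, insert_sd = 5,
                                    seed, window = NA_character_) {
  stopifnot(!missing(seed))
  ok <- abund$length >= read_length
  if (!all(ok)) {
    message("simulate_window_library: excluding ", sum(!ok),
            " fragment(s) shorter than the read length")
    abund <- abund[ok, , drop = FALSE]
  }
  if (nrow(abund) == 0L)
    stop("simulate_window_library: no fragment is as long as a read")
  # canonical fragment order: the multinomial allocation and the emitted
  # library are then independent of the caller's row order
  abund <- abund[order(abund$reference_id, abund$scaffold_id,
                       abund$start, abund$end), , drop = FALSE]
  alpha_r <- read_abundance(abund$alpha_f, abund$length, read_length)
  counts <- allocate_reads(alpha_r, total_pairs,
                           seed = .derive_seed(seed, paste0("alloc|", window)))
  keep <- which(counts > 0L)
  res <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    key <- paste(abund$reference_id[i], abund$scaffold_id[i],
                 abund$start[i], abund$end[i], window, sep = "|")
    set.seed(.derive_seed(seed, key))
    res[[j]] <- generate_pairs(abund[i, , drop = FALSE], counts[i],
                               read_length, insert_mean, insert_sd,
                               window = window)
  }
  pairs <- do.call(rbind, res)
  if (is.null(pairs))
    stop("allocate_reads: all read abundances are zero; ",
         "the window recovers no fragments")
  pairs <- cbind(pair_id = sprintf("pair%d", seq_len(nrow(pairs))), pairs,
                 stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs
}

# Header grammar: pair{n}|{reference}|{scaffold}:{start}-{end}({strand})|{window}
# with 1-based inclusive coordinates of the mate's own bases and strand
# "+" (as-is) or "-" (reverse complement), plus /1 /2 mate suffixes.
.mate_header <- function(pairs, mate) {
  fwd_as_1 <- !pairs$flip
  take_fwd <- if (mate == 1L) fwd_as_1 else !fwd_as_1
  start <- ifelse(take_fwd, pairs$fwd_start, pairs$rev_start)
  end <- ifelse(take_fwd, pairs$fwd_end, pairs$rev_end)
  strand <- ifelse(take_fwd, "+", "-")
  sprintf("%s|%s|%s:%d-%d(%s)|%s/%d",
          pairs$pair_id, pairs$reference_id, pairs$scaffold_id,
          start + 1L, end, strand,
          ifelse(is.na(pairs$window), "NA", pairs$window), mate)
}

#' Materialize read-pair sequences from the references
#'
#' @param pairs Pairs data.frame from [simulate_window_library()].
#' @param references `DNAStringSet` holding all scaffolds (unique names
#'   matching `scaffold_id`).
#' @return A list with named `DNAStringSet`s `R1` and `R2`; reverse-strand
#'   mates are reverse complemented.
#' @export
pair_sequences <- function(pairs, references) {
  nm <- sub("\\s.*$", "", names(references))
  names(references) <- nm
  get_mate <- function(mate) {
    fwd_as_1 <- !pairs$flip
    take_fwd <- if (mate == 1L) fwd_as_1 else !fwd_as_1
    start <- ifelse(take_fwd, pairs$fwd_start, pairs$rev_start)
    end <- ifelse(take_fwd, pairs$fwd_end, pairs$rev_end)
    idx <- match(pairs$scaffold_id, nm)
    if (anyNA(idx))
      stop("pair_sequences: scaffold(s) missing from references: ",
           paste(unique(pairs$scaffold_id[is.na(idx)]), collapse = ", "))
    seqs <- Biostrings::subseq(references[idx], start = start + 1L, end = end)
    rc <- !take_fwd
    if (any(rc)) seqs[rc] <- Biostrings::reverseComplement(seqs[rc])
    names(seqs) <- .mate_header(pairs, mate)
    seqs
  }
  list(R1 = get_mate(1L), R2 = get_mate(2L))
}

#' Write a paired read library
#'
#' Serializes mates to two multi-FASTA (or FASTQ) files in identical
#' order with identifiers differing only in the mate suffix. FASTQ output
#' applies a sequencing [error_profile()] (substitutions only, never
#' indels) before writing.
#'
#' @param pairs Pairs data.frame from [simulate_window_library()].
#' @param references `DNAStringSet` of all scaffolds.
#' @param r1_path,r2_path Output paths.
#' @param format `"fasta"` or `"fastq"`.
#' @param profile An [error_profile()]; required for FASTQ output.
#' @param seed Integer seed for the error draws (FASTQ only).
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_library <- function(pairs, references, r1_path, r2_path,
                          format = c("fasta", "fastq"), profile = NULL,
                          seed = NULL) {
  format <- match.arg(format)
  seqs <- pair_sequences(pairs, references)
  if (format == "fasta") {
    Biostrings::writeXStringSet(seqs$R1, r1_path)
    Biostrings::writeXStringSet(seqs$R2, r2_path)
  } else {
    if (is.null(profile))
      stop("write_library: FASTQ output needs an error_profile")
    if (!is.null(seed)) set.seed(as.integer(seed))
    fq1 <- apply_errors(seqs$R1, profile)
    fq2 <- apply_errors(seqs$R2, profile)
    .write_fastq(fq1$reads, fq1$qualities, r1_path)
    .write_fastq(fq2$reads, fq2$qualities, r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Parse a read header back into provenance fields
#'
#' Inverse of the library header grammar; used for round-trip checks.
#'
#' @param headers Character vector of read names.
#' @return data.frame with `pair_id`, `reference_id`, `scaffold_id`,
#'   `start` (0-based), `end` (exclusive), `strand`, `window`, `mate`.
#' @export
parse_read_header <- function(headers) {
  m <- regmatches(headers,
    regexec("^(\\S+)\\|([^|]+)\\|([^|:]+):(\\d+)-(\\d+)\\(([+-])\\)\\|([^/]+)/([12])$",
            headers))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("parse_read_header: malformed header(s): ",
         paste(utils::head(headers[bad], 3), collapse = "; "))
  f <- function(i) vapply(m, `[[`, "", i + 1L)
  data.frame(pair_id = f(1), reference_id = f(2), scaffold_id = f(3),
             start = as.integer(f(4)) - 1L, end = as.integer(f(5)),
             strand = f(6), window = f(7), mate = as.integer(f(8)),
             stringsAsFactors = FALSE)
}
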