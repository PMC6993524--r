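#' Parametric per-cycle sequencing error profile
#'
#' Describes, for each sequencing cycle, the substitution probability and
#' the mean/SD of the Phred quality score. Platform presets are simple
#' parametric shapes (flat, linear ramp, logistic tail degradation) that
#' approximate short-read platform behaviour without external model files:
#' \describe{
#'   \item{flat}{constant error rate across cycles.}
#'   \item{miseq-like}{linear ramp from ~0.1% to ~1% over the read.}
#'   \item{hiseq-like}{low flat core with a logistic rise toward the 3'
#'     end (to ~0.6%).}
#'   \item{novaseq-like}{very low flat core with a mild logistic tail
#'     (to ~0.3%); the default.}
#' }
#' Quality means follow the error curve via the Phred transform of the
#' per-cycle error rate, clamped to \[2, 41\].
#'
#' @param read_length Read length (number of cycles).
#' @param platform Preset name (see above).
#' @param error_rate Base error rate for the `flat` preset (default 0.001).
#' @param quality_sd Per-cycle SD of the drawn quality scores (default 3).
#' @return An object of class `error_profile` with vectors `error_prob`,
#'   `quality_mean` (length `read_length`) and scalar `quality_sd`.
#' @examples
#' pr <- error_profile(151, "novaseq-like")
#' range(pr$error_prob)
#' @export
error_profile <- function(read_length,
                          platform = c("novaseq-like", "miseq-like",
                                       "hiseq-like", "flat"),
                          error_rate = 0.001, quality_sd = 3) {
  platform <- match.arg(platform)
  stopifnot(read_length >= 1)
  cyc <- seq_len(read_length)
  logistic_tail <- function(base, top, mid_frac, steep) {
    base + (top - base) / (1 + exp(-steep * (cyc - mid_frac * read_length)))
  }
  p <- switch(platform,
    "flat" = rep(error_rate, read_length),
    "miseq-like" = 0.001 + (0.01 - 0.001) * (cyc - 1) / max(read_length - 1, 1),
    "hiseq-like" = logistic_tail(0.001, 0.006, 0.8, 10 / read_length),
    "novaseq-like" = logistic_tail(0.0005, 0.003, 0.85, 12 / read_length)
  )
  if (any(p < 0 | p > 1)) stop("error_profile: probabilities outside [0, 1]")
  qmean <- pmin(pmax(round(-10 * log10(pmax(p, 1e-5))), 2), 41)
  structure(list(error_prob = p, quality_mean = qmean,
                 quality_sd = quality_sd, platform = platform,
                 read_length = as.integer(read_length)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("Error profile '%s': %d cycles, error %.4g-%.4g, Q %d-%d\n",
              x$platform, x$read_length, min(x$error_prob), max(x$error_prob),
              min(x$quality_mean), max(x$quality_mean)))
  invisible(x)
}

#' Apply substitution errors and quality scores to reads
#'
#' Each base is independently substituted with its cycle's probability to
#' a uniformly chosen different base; ambiguous bases (N) are left
#' untouched. Read lengths never change: the model introduces no gaps.
#' Qualities are drawn per cycle from `Normal(quality_mean, quality_sd)`,
#' rounded and clamped to \[2, 41\], and encoded Phred+33.
#'
#' @param reads A `DNAStringSet` of equal-width reads matching the profile
#'   length (or a character vector).
#' @param profile An [error_profile()].
#' @return A list with `reads` (mutated `DNAStringSet`, same names and
#'   widths) and `qualities` (character vector of Phred+33 strings).
#' @export
apply_errors <- function(reads, profile) {
  stopifnot(inherits(profile, "error_profile"))
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  w <- Biostrings::width(reads)
  if (length(unique(w)) > 1L || (length(w) && w[1] != profile$read_length))
    stop("apply_errors: read length (", paste(unique(w), collapse = ","),
         ") does not match profile length (", profile$read_length, ")")
  n <- length(reads)
  L <- profile$read_length
  if (n == 0L) return(list(reads = reads, qualities = character(0)))

  m <- as.matrix(reads)  # n x L character matrix
  perr <- matrix(profile$error_prob, nrow = n, ncol = L, byrow = TRUE)
  hit <- matrix(stats::runif(n * L), n, L) < perr
  subst_ok <- m %in% c("A", "C", "G", "T")
  dim(subst_ok) <- dim(m)
  hit <- hit & subst_ok
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(m[hit], bases)
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  out <- Biostrings::DNAStringSet(do.call(paste0, asplit(m, 2L)))
  names(out) <- names(reads)

  q <- matrix(stats::rnorm(n * L,
                           mean = rep(profile$quality_mean, each = n),
                           sd = profile$quality_sd), n, L)
  q <- pmin(pmax(round(q), 2), 41)
  quals <- vapply(seq_len(n),
                  function(i) rawToChar(as.raw(q[i, ] + 33L)), "")
  list(reads = out, qualities = quals)
}

# Plain-text FASTQ writer (Phred+33).
.write_fastq <- function(reads, qualities, path) {
  stopifnot(length(reads) == length(qualities))
  con <- file(path, "w")
  on.exit(close(con))
  rec <- rbind(paste0("@", names(reads)), as.character(reads),
               "+", qualities)
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Convert an error-free FASTA library to FASTQ
#'
#' Reads a multi-FASTA read file, applies an [error_profile()] and writes
#' FASTQ in the same record order with the same identifiers. Sequence
#' lengths are preserved exactly (substitutions only, no gaps).
#'
#' @param fasta_path Input FASTA path.
#' @param fastq_path Output FASTQ path.
#' @param profile An [error_profile()]; defaults to a `novaseq-like`
#'   profile of the observed read length.
#' @param seed Optional integer seed.
#' @return Invisibly, `fastq_path`.
#' @export
fasta_to_fastq <- function(fasta_path, fastq_path, profile = NULL,
                           seed = NULL) {
  reads <- Biostrings::readDNAStringSet(fasta_path)
  if (is.null(profile))
    profile <- error_profile(Biostrings::width(reads)[1])
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- apply_errors(reads, profile)
  .write_fastq(res$reads, res$qualities, fastq_path)
  invisible(fastq_path)
}
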