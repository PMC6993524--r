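#' Build or validate a community profile
#'
#' A community profile holds per-sample relative abundances of references.
#' Abundances must be non-negative and sum to 1 per sample; totals off by
#' at most 1e-3 are renormalized with a message, larger deviations are an
#' error.
#'
#' @param sample_id Sample identifier(s), recycled against `reference_id`.
#' @param reference_id Reference identifiers.
#' @param abundance Relative abundances (fractions).
#' @return A data.frame of class `community_profile` with columns
#'   `sample_id`, `reference_id`, `abundance`.
#' @export
community_profile <- function(sample_id, reference_id, abundance) {
  df <- data.frame(sample_id = as.character(sample_id),
                   reference_id = as.character(reference_id),
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$abundance)) || any(df$abundance < 0))
    stop("community_profile: abundances must be finite and >= 0")
  if (anyDuplicated(df[, c("sample_id", "reference_id")]))
    stop("community_profile: duplicate (sample, reference) rows")
  for (s in unique(df$sample_id)) {
    i <- df$sample_id == s
    tot <- sum(df$abundance[i])
    if (abs(tot - 1) > 1e-3)
      stop("community_profile: abundances of sample '", s, "' sum to ",
           signif(tot, 6), ", not 1")
    if (abs(tot - 1) > 1e-6) {
      message("community_profile: renormalizing sample '", s,
              "' (total ", signif(tot, 8), ")")
      df$abundance[i] <- df$abundance[i] / tot
    }
  }
  df <- df[order(df$sample_id, df$reference_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("community_profile", "data.frame")
  df
}

#' Read or write a community table (long-format TSV)
#'
#' Columns: `sample_id`, `reference_id`, `abundance`.
#'
#' @param path TSV path.
#' @return A `community_profile`.
#' @export
read_community <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "reference_id", "abundance")
  if (!all(need %in% names(df)))
    stop("read_community: ", path, " must have columns ",
         paste(need, collapse = ", "))
  community_profile(df$sample_id, df$reference_id, df$abundance)
}

#' @rdname read_community
#' @param profile A `community_profile`.
#' @export
write_community <- function(profile, path) {
  utils::write.table(profile[, c("sample_id", "reference_id", "abundance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build or validate an incorporator table
#'
#' Lists, per sample and reference, the isotope and the mean/SD of atom
#' percent excess for isotopically labeled ("incorporator") references.
#' References absent from the table are unlabeled (atom excess identically
#' zero).
#'
#' @param sample_id,reference_id Identifiers.
#' @param isotope `"13C"` or `"15N"` per row.
#' @param mean_excess Mean atom percent excess in \[0, 100\].
#' @param sd_excess SD of atom percent excess (>= 0).
#' @return A data.frame of class `incorporator_table`.
#' @export
incorporator_table <- function(sample_id = character(0),
                               reference_id = character(0),
                               isotope = character(0),
                               mean_excess = numeric(0),
                               sd_excess = numeric(0)) {
  df <- data.frame(sample_id = as.character(sample_id),
                   reference_id = as.character(reference_id),
                   isotope = as.character(isotope),
                   mean_excess = as.numeric(mean_excess),
                   sd_excess = as.numeric(sd_excess),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    isotope_delta(df$isotope)  # validates
    if (any(df$mean_excess < 0 | df$mean_excess > 100))
      stop("incorporator_table: mean_excess must lie in [0, 100] percent")
    if (any(df$sd_excess < 0))
      stop("incorporator_table: sd_excess must be >= 0")
    if (anyDuplicated(df[, c("sample_id", "reference_id")]))
      stop("incorporator_table: duplicate (sample, reference) rows")
  }
  class(df) <- c("incorporator_table", "data.frame")
  df
}

#' @rdname incorporator_table
#' @param path TSV path with columns `sample_id`, `reference_id`,
#'   `isotope`, `mean_excess`, `sd_excess` (percent units).
#' @export
read_incorporators <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "reference_id", "isotope", "mean_excess", "sd_excess")
  if (!all(need %in% names(df)))
    stop("read_incorporators: ", path, " must have columns ",
         paste(need, collapse = ", "))
  incorporator_table(df$sample_id, df$reference_id, df$isotope,
                     df$mean_excess, df$sd_excess)
}

#' Draw per-fragment atom fraction excess
#'
#' For an incorporator, each fragment receives an independent draw from
#' `Normal(mean_excess, sd_excess)` (percent units), clamped to
#' \[0, 100\] and divided by 100. Non-incorporators get exactly 0.
#'
#' @param table An [incorporator_table()].
#' @param sample_id,reference_id Which (sample, reference) the fragments
#'   belong to.
#' @param n Number of fragments (draws).
#' @return Numeric vector of atom fraction excess in \[0, 1\].
#' @export
sample_atom_excess <- function(table, sample_id, reference_id, n = 1L) {
  stopifnot(inherits(table, "incorporator_table"))
  i <- which(table$sample_id == sample_id &
               table$reference_id == reference_id)
  if (length(i) == 0L) return(rep(0, n))
  m <- table$mean_excess[i]; s <- table$sd_excess[i]
  draw <- if (s == 0) rep(m, n) else stats::rnorm(n, m, s)
  pmin(pmax(draw, 0), 100) / 100
}

#' Generate a lognormal rank-abundance community
#'
#' Draws reference abundances from a lognormal distribution, sorts them
#' into a rank-abundance curve, normalizes to sum 1, and then swaps a
#' random `ceiling(permute_frac * n)` of rank positions pairwise to add
#' realistic between-replicate variation.
#'
#' @param n_refs Number of references (>= 1).
#' @param mean_abund Mean relative abundance in percent (lognormal scale
#'   parameter `exp(meanlog)`); default 2.0.
#' @param sd Standard deviation of the log abundances; default 0.8.
#' @param permute_frac Fraction of rank positions to permute; default 0.1.
#' @param reference_ids Optional reference names (default `ref001`, ...).
#' @param sample_id Sample name for the resulting profile.
#' @param seed Optional integer seed.
#' @return A `community_profile` for one sample, ordered by reference id.
#' @examples
#' cp <- generate_community(10, seed = 1)
#' sum(cp$abundance)
#' @export
generate_community <- function(n_refs, mean_abund = 2.0, sd = 0.8,
                               permute_frac = 0.1, reference_ids = NULL,
                               sample_id = "sample1", seed = NULL) {
  stopifnot(n_refs >= 1)
  if (!is.finite(sd) || sd <= 0)
    stop("generate_community: sd must be > 0")
  if (!is.finite(mean_abund) || mean_abund <= 0)
    stop("generate_community: mean_abund must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(reference_ids))
    reference_ids <- sprintf("ref%03d", seq_len(n_refs))
  stopifnot(length(reference_ids) == n_refs)
  ab <- stats::rlnorm(n_refs, meanlog = log(mean_abund), sdlog = sd)
  ab <- sort(ab, decreasing = TRUE)
  ab <- ab / sum(ab)
  if (permute_frac > 0 && n_refs >= 2) {
    k <- min(ceiling(permute_frac * n_refs), n_refs)
    if (k %% 2 == 1L) k <- k + 1L
    k <- min(k, 2L * floor(n_refs / 2))
    idx <- sample.int(n_refs, k)
    half <- k %/% 2L
    tmp <- ab[idx[seq_len(half)]]
    ab[idx[seq_len(half)]] <- ab[idx[half + seq_len(half)]]
    ab[idx[half + seq_len(half)]] <- tmp
  }
  community_profile(sample_id, reference_ids, ab)
}

#' Generate a gradient fraction set
#'
#' Partitions `[rho_min, rho_max]` into contiguous fractions whose widths
#' are drawn from a truncated normal model, mimicking empirical fraction
#' tables; the last fraction is truncated at `rho_max`.
#'
#' @param rho_min,rho_max Gradient BD bounds (g/ml).
#' @param mean_size,sd_size Mean and SD of fraction width (g/ml); defaults
#'   0.004 and 0.0003.
#' @param min_size Lower truncation of the width draw (g/ml); default
#'   0.002.
#' @param seed Optional integer seed.
#' @return A [fraction_set()].
#' @examples
#' fs <- generate_fractions(1.675, 1.771, sd_size = 0, seed = 1)
#' length(fs)  # 24 fractions of width 0.004
#' @export
generate_fractions <- function(rho_min, rho_max, mean_size = 0.004,
                               sd_size = 0.0003, min_size = 0.002,
                               seed = NULL) {
  if (!(rho_min < rho_max))
    stop("generate_fractions: rho_min must be < rho_max")
  if (!is.finite(mean_size) || mean_size <= 0 || min_size <= 0 ||
      sd_size < 0)
    stop("generate_fractions: size model must admit only positive sizes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- rho_min
  repeat {
    w <- if (sd_size == 0) mean_size else {
      d <- stats::rnorm(1, mean_size, sd_size)
      while (d < min_size) d <- stats::rnorm(1, mean_size, sd_size)
      d
    }
    nxt <- b[length(b)] + w
    if (nxt >= rho_max - 1e-12) { b <- c(b, rho_max); break }
    b <- c(b, nxt)
  }
  fraction_set(b)
}
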