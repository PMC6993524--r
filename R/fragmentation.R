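#' Fragment-size distribution model
#'
#' Describes the length distribution of extraction fragments produced by
#' in-silico shearing. Supported families: `uniform` (on
#' `[min_bp, max_bp]`), `normal`, `truncated-normal` and `skew-normal`
#' (location/scale/shape parameterization). All draws are rounded to whole
#' base pairs and bounded by `[min_bp, max_bp]`.
#'
#' @param family One of `"uniform"`, `"normal"`, `"truncated-normal"`,
#'   `"skew-normal"`.
#' @param location Location parameter in bp (mean for normal families; for
#'   `uniform`, ignored in favour of the bounds).
#' @param scale Scale parameter in bp (> 0 unless the family is uniform).
#' @param skew Shape parameter (skew-normal only).
#' @param min_bp,max_bp Hard truncation bounds in bp (`min_bp >= 1`).
#' @return An object of class `fragment_size_model`.
#' @examples
#' fragment_size_model("normal", 9000, 2500)
#' fragment_size_model("uniform", min_bp = 5000, max_bp = 5000)
#' @export
fragment_size_model <- function(family = c("normal", "uniform",
                                           "truncated-normal", "skew-normal"),
                                location = 9000, scale = 2500, skew = 0,
                                min_bp = 500, max_bp = 100000) {
  family <- match.arg(family)
  stopifnot(is.numeric(min_bp), is.numeric(max_bp))
  min_bp <- as.integer(round(min_bp)); max_bp <- as.integer(round(max_bp))
  if (min_bp < 1L || max_bp < min_bp)
    stop("fragment_size_model: need 1 <= min_bp <= max_bp")
  if (family != "uniform" && (!is.finite(scale) || scale <= 0))
    stop("fragment_size_model: scale must be > 0")
  structure(list(family = family, location = location, scale = scale,
                 skew = skew, min_bp = min_bp, max_bp = max_bp),
            class = "fragment_size_model")
}

# Standard skew-normal draw via the conditioning representation:
# Z = delta |Z0| + sqrt(1 - delta^2) Z1, delta = skew / sqrt(1 + skew^2).
.rskewnorm <- function(n, location, scale, skew) {
  delta <- skew / sqrt(1 + skew^2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  location + scale * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' Draw fragment lengths from a size model
#'
#' Truncation for the normal-family models is by rejection with a resample
#' cap of 1000 rounds, after which remaining draws are clamped to the
#' bounds (with a warning).
#'
#' @param n Number of lengths to draw.
#' @param model A [fragment_size_model()].
#' @return Integer vector of lengths in `[min_bp, max_bp]`.
#' @export
sample_fragment_lengths <- function(n, model) {
  stopifnot(inherits(model, "fragment_size_model"), n >= 0)
  if (n == 0L) return(integer(0))
  draw <- switch(model$family,
    "uniform" = stats::runif(n, model$min_bp, model$max_bp + 1),
    "normal" = stats::rnorm(n, model$location, model$scale),
    "truncated-normal" = stats::rnorm(n, model$location, model$scale),
    "skew-normal" = .rskewnorm(n, model$location, model$scale, model$skew)
  )
  len <- as.integer(pmin(pmax(floor(draw), model$min_bp), model$max_bp))
  if (model$family %in% c("truncated-normal", "skew-normal")) {
    # rejection-resample anything that needed clamping
    bad <- which(draw < model$min_bp | draw >= model$max_bp + 1)
    rounds <- 0L
    while (length(bad) && rounds < 1000L) {
      redraw <- switch(model$family,
        "truncated-normal" = stats::rnorm(length(bad), model$location, model$scale),
        "skew-normal" = .rskewnorm(length(bad), model$location, model$scale, model$skew)
      )
      ok <- redraw >= model$min_bp & redraw < model$max_bp + 1
      len[bad[ok]] <- as.integer(floor(redraw[ok]))
      bad <- bad[!ok]
      rounds <- rounds + 1L
    }
    if (length(bad))
      warning("sample_fragment_lengths: ", length(bad),
              " draws clamped to bounds after 1000 rejection rounds")
  }
  len
}

#' @export
print.fragment_size_model <- function(x, ...) {
  cat(sprintf("Fragment size model: %s(location = %g, scale = %g%s), bounds [%d, %d] bp\n",
              x$family, x$location, x$scale,
              if (x$family == "skew-normal") paste0(", skew = ", x$skew) else "",
              x$min_bp, x$max_bp))
  invisible(x)
}

#' G+C content of a sequence window
#'
#' Counts G and C (either case) over the unambiguous bases of the window;
#' ambiguous IUPAC codes (N etc.) are excluded from the denominator.
#'
#' @param x A `DNAStringSet`, `DNAString`, or character vector of sequences.
#' @return Numeric vector of G+C fractions.
#' @examples
#' gc_content(c("ATGC", "AAAA", "ATGN"))
#' @export
gc_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  counts <- Biostrings::letterFrequency(x, letters = c("G", "C", "A", "T"))
  unamb <- rowSums(counts)
  if (any(Biostrings::width(x) == 0L))
    stop("gc_content: empty window")
  if (any(unamb == 0L))
    stop("gc_content: window contains no unambiguous bases")
  unname((counts[, "G"] + counts[, "C"]) / unamb)
}

#' Shear a reference into extraction fragments
#'
#' Simulates DNA fragmentation during extraction: each scaffold is tiled
#' left-to-right with lengths drawn from the size model, and tiling passes
#' repeat until the summed fragment length reaches `coverage` times the
#' reference length (the pass in progress stops after the fragment that
#' crosses the target). A trailing remainder shorter than `min_bp` is
#' merged into the preceding fragment, so every pass covers each scaffold
#' exactly. Fragments never span scaffold boundaries. Scaffolds shorter
#' than `min_bp` become single whole-scaffold fragments (with a warning).
#' Fragments that are more than 50% ambiguous bases are dropped (with a
#' warning).
#'
#' @param reference A `DNAStringSet` (scaffolds of one reference) or the
#'   path to a FASTA/multi-FASTA file.
#' @param size_model A [fragment_size_model()].
#' @param coverage Target fold fragment coverage (> 0).
#' @param reference_id Identifier recorded for the reference; defaults to
#'   the file base name or `"reference"`.
#' @param seed Optional integer seed for reproducible shearing.
#' @return A data.frame of fragments with columns `reference_id`,
#'   `scaffold_id`, `start` (0-based inclusive), `end` (0-based
#'   exclusive), `length`, `gc`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr = paste(rep("ACGT", 2500), collapse = "")))
#' fr <- fragment_reference(ref, fragment_size_model("uniform", min_bp = 1000,
#'                                                   max_bp = 1000), coverage = 1)
#' nrow(fr)
#' @export
fragment_reference <- function(reference, size_model, coverage = 1,
                               reference_id = NULL, seed = NULL) {
  stopifnot(inherits(size_model, "fragment_size_model"), coverage > 0)
  if (is.character(reference)) {
    if (is.null(reference_id))
      reference_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (is.null(reference_id)) reference_id <- "reference"
  if (!inherits(reference, "DNAStringSet"))
    stop("fragment_reference: reference must be a DNAStringSet or FASTA path")
  if (length(reference) == 0L || sum(Biostrings::width(reference)) == 0L)
    stop("fragment_reference: empty reference '", reference_id, "'")
  if (!is.null(seed)) set.seed(as.integer(seed))

  scaff_names <- names(reference)
  if (is.null(scaff_names)) scaff_names <- paste0("scaffold", seq_along(reference))
  scaff_names <- sub("\\s.*$", "", scaff_names)
  widths <- Biostrings::width(reference)
  total_len <- sum(widths)
  target <- coverage * total_len

  starts <- integer(0); ends <- integer(0); scaffs <- character(0)
  emitted <- 0
  short <- widths < size_model$min_bp
  if (any(short))
    warning("fragment_reference: ", sum(short), " scaffold(s) shorter than min_bp; ",
            "kept as single whole-scaffold fragments")
  repeat {
    for (i in seq_along(reference)) {
      L <- widths[i]
      if (short[i]) {
        starts <- c(starts, 0L); ends <- c(ends, L)
        scaffs <- c(scaffs, scaff_names[i])
        emitted <- emitted + L
        next
      }
      pos <- 0L
      # draw a generous batch of lengths for this scaffold pass
      lens <- sample_fragment_lengths(max(8L, ceiling(L / size_model$min_bp)),
                                      size_model)
      k <- 1L
      while (pos < L) {
        if (k > length(lens)) {
          lens <- c(lens, sample_fragment_lengths(length(lens), size_model))
        }
        fl <- lens[k]; k <- k + 1L
        end <- min(pos + fl, L)
        if (L - end < size_model$min_bp) end <- L  # merge trailing remainder
        starts <- c(starts, pos); ends <- c(ends, end)
        scaffs <- c(scaffs, scaff_names[i])
        emitted <- emitted + (end - pos)
        pos <- end
        if (emitted >= target) break
      }
      if (emitted >= target) break
    }
    if (emitted >= target) break
  }

  frags <- data.frame(reference_id = reference_id, scaffold_id = scaffs,
                      start = as.integer(starts), end = as.integer(ends),
                      stringsAsFactors = FALSE)
  frags$length <- frags$end - frags$start
  seqs <- extract_fragment_seqs(reference, frags)
  counts <- Biostrings::letterFrequency(seqs, letters = c("G", "C", "A", "T"))
  unamb <- rowSums(counts)
  amb_frac <- 1 - unamb / frags$length
  drop <- amb_frac > 0.5
  if (any(drop)) {
    warning("fragment_reference: dropped ", sum(drop),
            " fragment(s) that are >50% ambiguous bases")
    frags <- frags[!drop, , drop = FALSE]
    counts <- counts[!drop, , drop = FALSE]
    unamb <- unamb[!drop]
  }
  frags$gc <- (counts[, "G"] + counts[, "C"]) / unamb
  rownames(frags) <- NULL
  frags
}

#' Extract fragment sequences from their reference
#'
#' @param reference `DNAStringSet` of scaffolds (names must match
#'   `fragments$scaffold_id`).
#' @param fragments Fragment data.frame with `scaffold_id`, `start`, `end`
#'   (0-based half-open).
#' @return `DNAStringSet` of fragment sequences.
#' @export
extract_fragment_seqs <- function(reference, fragments) {
  nm <- names(reference)
  if (is.null(nm)) nm <- paste0("scaffold", seq_along(reference))
  nm <- sub("\\s.*$", "", nm)
  idx <- match(fragments$scaffold_id, nm)
  if (anyNA(idx))
    stop("extract_fragment_seqs: unknown scaffold id(s): ",
         paste(unique(fragments$scaffold_id[is.na(idx)]), collapse = ", "))
  Biostrings::subseq(reference[idx],
                     start = fragments$start + 1L, end = fragments$end)
}

#' Write a fragment table to TSV
#'
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
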