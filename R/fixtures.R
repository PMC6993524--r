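#' Generate a synthetic genome with controlled G+C
#'
#' Draws a random A/C/G/T sequence whose blockwise G+C follows a
#' piecewise-constant drift model around the target: each block of
#' `block_bp` bases gets its own G+C target, jittered around `gc` with SD
#' `drift`, emulating the intra-genomic G+C heterogeneity of real
#' genomes. With `drift = 0` the whole genome is a single composition.
#'
#' @param length_bp Genome length (>= 1000).
#' @param gc Target G+C fraction in (0, 1).
#' @param drift SD of the per-block G+C jitter (default 0.02).
#' @param block_bp Block length in bp (default 10000).
#' @param name Scaffold name.
#' @param seed Optional integer seed.
#' @return A named `DNAStringSet` of length 1.
#' @examples
#' g <- make_genome(50000, 0.5, seed = 1)
#' gc_content(g)
#' @export
make_genome <- function(length_bp, gc = 0.5, drift = 0.02,
                        block_bp = 10000, name = "synthetic", seed = NULL) {
  stopifnot(length_bp >= 1000, block_bp >= 1)
  if (!is.finite(gc) || gc <= 0 || gc >= 1)
    stop("make_genome: target gc must lie strictly inside (0, 1)")
  if (drift < 0) stop("make_genome: drift must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_blocks <- ceiling(length_bp / block_bp)
  block_gc <- pmin(pmax(stats::rnorm(n_blocks, gc, drift), 0.05), 0.95)
  sizes <- rep(block_bp, n_blocks)
  sizes[n_blocks] <- length_bp - block_bp * (n_blocks - 1L)
  p_gc <- rep(block_gc, sizes)
  is_gc <- stats::runif(length_bp) < p_gc
  strong <- sample(c("G", "C"), length_bp, replace = TRUE)
  weak <- sample(c("A", "T"), length_bp, replace = TRUE)
  seq <- ifelse(is_gc, strong, weak)
  out <- Biostrings::DNAStringSet(paste0(seq, collapse = ""))
  names(out) <- name
  out
}

#' Per-fraction genomic DNA quantity across a gradient
#'
#' The gradient-profile summary used to sanity-check simulated
#' distributions against banding expectations: within each fraction, each
#' fragment's recovered abundance is multiplied by its length and summed,
#' then the per-fraction totals are normalized to the fraction with the
#' greatest quantity.
#'
#' @param fragments Fragment table from [fragment_bd()] (columns `alpha`,
#'   `rho`, `sigma`, `length`).
#' @param fractions A [fraction_set()].
#' @param params A [gradient_params()] object.
#' @param p_dbl Proportion of DNA in the DBL (default 0.001).
#' @return A data.frame with one row per fraction: `fraction`, `rho_min`,
#'   `rho_max`, `bd_mid`, `quantity` (summed abundance x length, bp
#'   units) and `normalized` (max exactly 1). If every fraction is empty
#'   the normalized column is all zero (with a warning), not an error.
#' @export
gradient_profile <- function(fragments, fractions,
                             params = gradient_params(), p_dbl = 0.001) {
  stopifnot(inherits(fractions, "fraction_set"))
  rows <- lapply(fractions, function(w) {
    ab <- fragment_window_abundance(fragments, w, params, p_dbl)
    data.frame(fraction = w$label, rho_min = w$rho_min, rho_max = w$rho_max,
               bd_mid = (w$rho_min + w$rho_max) / 2,
               quantity = sum(ab$alpha_f * ab$length),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  mx <- max(prof$quantity)
  if (mx <= 0) {
    warning("gradient_profile: no DNA recovered in any fraction")
    prof$normalized <- 0
  } else {
    prof$normalized <- prof$quantity / mx
  }
  prof
}

#' Write a gradient profile to TSV
#'
#' @param profile Output of [gradient_profile()].
#' @param path TSV path.
#' @export
write_gradient_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a ready-to-run synthetic fixture set
#'
#' Writes synthetic reference genomes (FASTA, one file per reference),
#' a community table, an incorporator table and a minimal configuration
#' file into a directory, so a full simulation can run without any
#' external data.
#'
#' @param dir Output directory (created if needed).
#' @param n_refs Number of references.
#' @param genome_bp Genome length per reference.
#' @param gc_targets G+C targets, recycled across references.
#' @param labeled Indices of references made 13C incorporators.
#' @param mean_excess,sd_excess Atom percent excess distribution of the
#'   incorporators (defaults 90 and 5).
#' @param seed Integer seed.
#' @return Invisibly, a list with the paths written (`references`,
#'   `community`, `incorporators`, `config`) plus the in-memory objects.
#' @export
make_fixture_set <- function(dir, n_refs = 5, genome_bp = 50000,
                             gc_targets = c(0.4, 0.45, 0.5, 0.55, 0.6),
                             labeled = 1L, mean_excess = 90, sd_excess = 5,
                             seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_dir <- file.path(dir, "references")
  dir.create(ref_dir, showWarnings = FALSE)
  ids <- sprintf("ref%03d", seq_len(n_refs))
  gcs <- rep_len(gc_targets, n_refs)
  refs <- Biostrings::DNAStringSet()
  paths <- character(n_refs)
  for (i in seq_len(n_refs)) {
    g <- make_genome(genome_bp, gcs[i], name = paste0(ids[i], "_chr"),
                     seed = seed + i)
    paths[i] <- file.path(ref_dir, paste0(ids[i], ".fasta"))
    Biostrings::writeXStringSet(g, paths[i])
    refs <- c(refs, g)
  }
  comm <- generate_community(n_refs, reference_ids = ids, seed = seed)
  inc <- incorporator_table(
    sample_id = rep("sample1", length(labeled)),
    reference_id = ids[labeled], isotope = rep("13C", length(labeled)),
    mean_excess = rep(mean_excess, length(labeled)),
    sd_excess = rep(sd_excess, length(labeled))
  )
  comm_path <- file.path(dir, "community.tsv")
  inc_path <- file.path(dir, "incorporators.tsv")
  write_community(comm, comm_path)
  utils::write.table(inc, inc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(
    mode = "window",
    reference_dir = ref_dir,
    community_table = comm_path,
    incorporator_table = inc_path,
    output_dir = file.path(dir, "output"),
    window = list(rho_min = 1.72, rho_max = 1.77),
    fragment = list(family = "normal", location = 9000, scale = 2500,
                    min_bp = 500, max_bp = 20000, coverage = 2),
    p_dbl = 0.001,
    read_length = 151,
    insert = list(mean = 1000, sd = 5),
    total_pairs = 10000,
    seed = seed,
    output_format = "fasta"
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(references = paths, community = comm_path,
                 incorporators = inc_path, config = cfg_path,
                 ref_seqs = refs, community_profile = comm,
                 incorporator_tbl = inc))
}
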