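#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration describing a full simulation run: input
#' paths, simulation mode, gradient physics, fragmentation, sequencing
#' parameters and the mandatory seed. All validation problems are
#' collected and reported together. Unit conversions are applied at load
#' time: a gradient `tube_angle_degrees` key is converted to radians, and
#' incorporator tables remain in percent units (they are converted to
#' fractions when atom excess is drawn).
#'
#' @param path YAML file path.
#' @return A validated list of class `sip_config` with defaults filled in.
#' @section Keys:
#' \describe{
#'   \item{mode}{`"window"`, `"fractions"` or `"shotgun"`.}
#'   \item{reference_dir}{directory of FASTA files, one per reference.}
#'   \item{community_table}{long-format TSV (sample_id, reference_id,
#'     abundance).}
#'   \item{incorporator_table}{optional TSV of labeled references.}
#'   \item{window}{`rho_min`/`rho_max` (required for mode = window).}
#'   \item{fractions}{`rho_min`, `rho_max` and optional width model
#'     (`mean_size`, `sd_size`, `min_size`) for mode = fractions.}
#'   \item{gradient}{overrides for [gradient_params()] fields; accepts
#'     `tube_angle_degrees`.}
#'   \item{fragment}{[fragment_size_model()] fields plus `coverage`.}
#'   \item{p_dbl, read_length, insert (mean, sd), total_pairs, seed,
#'     threads, output_format, platform}{sequencing and run controls.}
#' }
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  need <- function(key) {
    if (is.null(raw[[key]])) problems <<- c(problems, paste0("missing key: ", key))
  }
  need("mode"); need("reference_dir"); need("community_table")
  need("output_dir"); need("seed")
  mode <- raw$mode
  if (!is.null(mode) && !mode %in% c("window", "fractions", "shotgun"))
    problems <- c(problems, paste0("unknown mode: ", mode))
  if (identical(mode, "window")) {
    if (is.null(raw$window$rho_min))
      problems <- c(problems, "mode=window requires window: rho_min")
    if (is.null(raw$window$rho_max))
      problems <- c(problems, "mode=window requires window: rho_max")
  }
  if (identical(mode, "fractions")) {
    if (is.null(raw$fractions$rho_min) || is.null(raw$fractions$rho_max))
      problems <- c(problems,
                    "mode=fractions requires fractions: rho_min and rho_max")
  }
  for (p in c("reference_dir", "community_table", "incorporator_table")) {
    if (!is.null(raw[[p]]) && !file.exists(raw[[p]]))
      problems <- c(problems, paste0(p, " does not exist: ", raw[[p]]))
  }
  if (length(problems))
    stop("load_config: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))

  g <- raw$gradient
  if (!is.null(g$tube_angle_degrees)) {
    g$tube_angle <- g$tube_angle_degrees * pi / 180
    g$tube_angle_degrees <- NULL
  }
  gp_args <- if (is.null(g)) list()
             else g[intersect(names(g), names(formals(gradient_params)))]
  params <- do.call(gradient_params, gp_args)

  fr <- raw$fragment
  size_model <- fragment_size_model(
    family = fr$family %||% "normal",
    location = fr$location %||% 9000,
    scale = fr$scale %||% 2500,
    skew = fr$skew %||% 0,
    min_bp = fr$min_bp %||% 500,
    max_bp = fr$max_bp %||% 100000
  )

  cfg <- list(
    mode = mode,
    reference_dir = raw$reference_dir,
    community_table = raw$community_table,
    incorporator_table = raw$incorporator_table,
    output_dir = raw$output_dir,
    window = raw$window,
    fractions = raw$fractions,
    params = params,
    size_model = size_model,
    coverage = fr$coverage %||% 1,
    p_dbl = raw$p_dbl %||% 0.001,
    read_length = as.integer(raw$read_length %||% 151L),
    insert_mean = raw$insert$mean %||% 1000,
    insert_sd = raw$insert$sd %||% 5,
    total_pairs = as.integer(raw$total_pairs %||% 10000L),
    seed = as.integer(raw$seed),
    threads = as.integer(raw$threads %||% 1L),
    output_format = raw$output_format %||% "fasta",
    platform = raw$platform %||% "novaseq-like"
  )
  if (!cfg$output_format %in% c("fasta", "fastq"))
    stop("load_config: output_format must be fasta or fastq")
  class(cfg) <- "sip_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read all references: one FASTA per reference, reference_id = file base
# name; returns list(refs = named list of DNAStringSet, all = combined
# DNAStringSet with unique scaffold names).
.load_references <- function(reference_dir) {
  files <- list.files(reference_dir, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files))
    stop("no FASTA files found in ", reference_dir)
  refs <- list()
  for (f in files) {
    id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(f))
    s <- Biostrings::readDNAStringSet(f)
    names(s) <- sub("\\s.*$", "", names(s))
    refs[[id]] <- s
  }
  all <- do.call(c, unname(refs))
  if (anyDuplicated(names(all)))
    stop("scaffold names collide across references: ",
         paste(unique(names(all)[duplicated(names(all))]), collapse = ", "))
  list(refs = refs, all = all)
}

#' Run a full simulation from a configuration
#'
#' Orchestrates fragmentation, the gradient abundance model, read
#' generation and serialization for every sample of the community table
#' (and every fraction in fractions mode), then writes a JSON manifest of
#' resolved parameters, output files, MD5 checksums and read counts.
#' Fragments are generated once per reference and reused across samples
#' and fractions. With `threads > 1`, windows/samples are simulated in
#' parallel; per-fragment RNG streams are derived from the master seed so
#' the output is identical for any worker count.
#'
#' @param config A `sip_config` from [load_config()], or a path to one.
#' @return Invisibly, the manifest list (also written to
#'   `output_dir/manifest.json`).
#' @export
run_simulation <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "sip_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  loaded <- .load_references(config$reference_dir)
  community <- read_community(config$community_table)
  incorp <- if (is.null(config$incorporator_table)) incorporator_table()
            else read_incorporators(config$incorporator_table)

  # one fragment set, reused everywhere
  frag_list <- lapply(names(loaded$refs), function(id) {
    fragment_reference(loaded$refs[[id]], config$size_model,
                       coverage = config$coverage, reference_id = id,
                       seed = .derive_seed(config$seed, paste0("frag|", id)))
  })
  fragments <- do.call(rbind, frag_list)

  windows <- switch(config$mode,
    "window" = list(bd_window(config$window$rho_min, config$window$rho_max,
                              label = "window")),
    "fractions" = {
      fs <- generate_fractions(
        config$fractions$rho_min, config$fractions$rho_max,
        mean_size = config$fractions$mean_size %||% 0.004,
        sd_size = config$fractions$sd_size %||% 0.0003,
        min_size = config$fractions$min_size %||% 0.002,
        seed = .derive_seed(config$seed, "fractions"))
      unclass(fs)
    },
    "shotgun" = list(NULL)
  )

  samples <- unique(community$sample_id)
  jobs <- expand.grid(sample = samples, win = seq_along(windows),
                      stringsAsFactors = FALSE)
  run_job <- function(k) {
    s <- jobs$sample[k]; w <- windows[[jobs$win[k]]]
    fb <- fragment_bd(fragments, community, incorp, sample_id = s,
                      params = config$params,
                      seed = .derive_seed(config$seed, paste0("bd|", s)))
    if (is.null(w)) {
      ab <- shotgun_abundance(fb)
      wlab <- "shotgun"
    } else {
      ab <- fragment_window_abundance(fb, w, config$params, config$p_dbl)
      wlab <- w$label
    }
    tag <- paste0(s, "_", wlab)
    pairs <- simulate_window_library(
      ab, config$total_pairs, config$read_length,
      config$insert_mean, config$insert_sd,
      seed = .derive_seed(config$seed, paste0("reads|", tag)),
      window = wlab)
    ext <- if (config$output_format == "fasta") "fasta" else "fastq"
    r1 <- file.path(config$output_dir, paste0(tag, "_R1.", ext))
    r2 <- file.path(config$output_dir, paste0(tag, "_R2.", ext))
    profile <- if (config$output_format == "fastq")
      error_profile(config$read_length, config$platform) else NULL
    write_library(pairs, loaded$all, r1, r2,
                  format = config$output_format, profile = profile,
                  seed = .derive_seed(config$seed, paste0("errors|", tag)))
    list(sample = s, window = wlab, n_pairs = nrow(pairs),
         out_of_gradient = attr(ab, "out_of_gradient") %||% 0L,
         files = c(r1, r2), md5 = unname(tools::md5sum(c(r1, r2))))
  }
  results <- if (config$threads > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), run_job,
                       mc.cores = config$threads, mc.preschedule = FALSE)
  } else {
    lapply(seq_len(nrow(jobs)), run_job)
  }
  err <- vapply(results, inherits, TRUE, "try-error")
  if (any(err)) stop("run_simulation: a job failed: ", results[[which(err)[1]]])

  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    total_pairs = config$total_pairs,
    read_length = config$read_length,
    p_dbl = config$p_dbl,
    references = names(loaded$refs),
    n_fragments = nrow(fragments),
    libraries = lapply(results, function(r)
      list(sample = r$sample, window = r$window, n_pairs = r$n_pairs,
           out_of_gradient = r$out_of_gradient,
           files = as.list(r$files), md5 = as.list(r$md5)))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
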