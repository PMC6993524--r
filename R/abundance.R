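#' Assign buoyant-density statistics to fragments
#'
#' Joins fragments to their sample's community abundances and incorporator
#' assignments, draws a per-fragment atom fraction excess, and computes the
#' theoretical BD (from G+C), the isotope-adjusted BD, and the diffusion
#' SD of each fragment.
#'
#' @param fragments Fragment data.frame from [fragment_reference()] (may
#'   hold several references).
#' @param community A [community_profile()] (one sample).
#' @param incorporators An [incorporator_table()]; may be empty.
#' @param sample_id Sample to simulate; defaults to the single sample in
#'   `community`.
#' @param params A [gradient_params()] object.
#' @param seed Optional integer seed for the atom-excess draws.
#' @return The fragment data.frame with added columns `alpha`,
#'   `atom_excess` (fraction), `isotope`, `rho_t`, `rho`, `sigma`.
#' @export
fragment_bd <- function(fragments, community, incorporators = incorporator_table(),
                        sample_id = NULL, params = gradient_params(),
                        seed = NULL) {
  stopifnot(inherits(community, "community_profile"),
            inherits(incorporators, "incorporator_table"))
  if (is.null(sample_id)) {
    sample_id <- unique(community$sample_id)
    if (length(sample_id) != 1L)
      stop("fragment_bd: community holds several samples; pass sample_id")
  }
  comm <- community[community$sample_id == sample_id, , drop = FALSE]
  idx <- match(fragments$reference_id, comm$reference_id)
  if (anyNA(idx))
    stop("fragment_bd: reference(s) missing from community table: ",
         paste(unique(fragments$reference_id[is.na(idx)]), collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- fragments
  out$alpha <- comm$abundance[idx]
  out$atom_excess <- 0
  out$isotope <- NA_character_
  inc <- incorporators[incorporators$sample_id == sample_id, , drop = FALSE]
  for (r in unique(out$reference_id)) {
    j <- which(out$reference_id == r)
    k <- which(inc$reference_id == r)
    if (length(k)) {
      out$atom_excess[j] <- sample_atom_excess(incorporators, sample_id, r,
                                               n = length(j))
      out$isotope[j] <- inc$isotope[k]
    }
  }
  out$rho_t <- theoretical_bd(out$gc)
  delta <- rep(0, nrow(out))
  lab <- !is.na(out$isotope)
  if (any(lab)) delta[lab] <- isotope_delta(out$isotope[lab])
  out$rho <- out$rho_t + out$atom_excess * delta
  out$sigma <- diffusion_sigma(out$rho, out$length, params)
  out
}

#' Proportion of a fragment's lumen population inside a BD window
#'
#' The lumen population of a fragment is normally distributed in BD with
#' mean `rho` and SD `sigma`; the recovered proportion is the normal CDF
#' mass between the window bounds.
#'
#' @param rho Fragment BD (g/ml, vectorized).
#' @param sigma Diffusion SD (g/ml, > 0, vectorized).
#' @param window A [bd_window()].
#' @return Proportion in \[0, 1\].
#' @examples
#' lumen_recovery(1.71, 0.005, bd_window(1.70, 1.72))
#' @export
lumen_recovery <- function(rho, sigma, window) {
  stopifnot(inherits(window, "bd_window"))
  if (any(sigma <= 0)) stop("lumen_recovery: sigma must be > 0")
  stats::pnorm((window$rho_max - rho) / sigma) -
    stats::pnorm((window$rho_min - rho) / sigma)
}

#' Lumen abundance of a fragment in a window
#'
#' `alpha_L = alpha (1 - p_dbl) * p_LR`: the share of the fragment not
#' trapped in the diffusive boundary layer, times the lumen proportion
#' recovered in the window.
#'
#' @param alpha Fragment (reference) relative abundance.
#' @param p_dbl Proportion of DNA in the diffusive boundary layer
#'   (`0 <= p_dbl < 1`).
#' @param p_lr Lumen proportion recovered, from [lumen_recovery()].
#' @return Lumen abundance.
#' @export
lumen_abundance <- function(alpha, p_dbl, p_lr) {
  if (any(p_dbl < 0 | p_dbl >= 1))
    stop("lumen_abundance: p_dbl must lie in [0, 1)")
  alpha * (1 - p_dbl) * p_lr
}

#' Diffusive-boundary-layer abundance of a fragment in a window
#'
#' The DBL mass of a fragment is spread uniformly over its DBL BD range;
#' the window recovers the fraction of that range it covers, times
#' `alpha * p_dbl`. By default the window is first intersected with the
#' DBL range, so a window wider than the DBL range recovers at most the
#' whole DBL mass; `clip = FALSE` gives the literal (unclipped) width
#' ratio for parity runs.
#'
#' @param alpha Fragment relative abundance.
#' @param p_dbl Proportion of DNA in the DBL.
#' @param window A [bd_window()].
#' @param dbl A `dbl_range` from [dbl_position_range()], or a list with
#'   `rho_dbl_min`, `rho_dbl_max`.
#' @param clip Intersect the window with the DBL range first (default
#'   TRUE).
#' @return DBL abundance (0 if the window and DBL range are disjoint).
#' @export
dbl_abundance <- function(alpha, p_dbl, window, dbl, clip = TRUE) {
  stopifnot(inherits(window, "bd_window"))
  lo <- dbl$rho_dbl_min; hi <- dbl$rho_dbl_max
  if (!(lo < hi)) stop("dbl_abundance: invalid DBL range")
  width <- if (clip) {
    pmax(0, pmin(window$rho_max, hi) - pmax(window$rho_min, lo))
  } else {
    window$rho_max - window$rho_min
  }
  width / (hi - lo) * alpha * p_dbl
}

# Vectorized DBL BD ranges for a vector of equilibrium radii.
# Returns a list(rho_dbl_min, rho_dbl_max); NA where x is NA.
.dbl_bd_range_vec <- function(x, params) {
  rt <- params$tube_radius; th <- params$tube_angle; rmax <- params$r_max
  cross <- .dbl_crossovers(params)
  u <- pmin(pmax((x - rmax + rt) / rt, -1), 1)
  s_min <- ifelse(x <= cross["lower"],
                  rt + (rmax - rt * cos(th) - rt - x) / sin(th),
                  rt - rt * cos(th - asin(u)))
  s_max <- ifelse(x <= cross["upper"],
                  rt + (rmax + rt * cos(th) - rt - x) / sin(th),
                  rt - rt * cos(th - pi + asin(u)))
  bd_hi <- tube_position_to_bd(s_min, params)
  bd_lo <- tube_position_to_bd(s_max, params)
  list(rho_dbl_min = pmin(bd_lo, bd_hi), rho_dbl_max = pmax(bd_lo, bd_hi))
}

#' Recovered abundance of fragments in a BD window
#'
#' Composes the full gradient model for each fragment: lumen recovery via
#' the normal CDF, DBL contamination via tube geometry, and their sum.
#' Fragments whose equilibrium position falls outside the tube's radial
#' extent contribute no DBL mass (their count is reported in the
#' `out_of_gradient` attribute); their lumen term is still computed.
#'
#' @param fragments Fragment data.frame from [fragment_bd()] (columns
#'   `alpha`, `rho`, `sigma` required).
#' @param window A [bd_window()].
#' @param params A [gradient_params()] object.
#' @param p_dbl Proportion of DNA in the DBL (scalar, default 0.001).
#' @param clip_dbl Clip the DBL window overlap (see [dbl_abundance()]).
#' @return The fragment data.frame with added columns `window`, `p_LR`,
#'   `alpha_L`, `alpha_DBL`, `alpha_f` (= `alpha_L + alpha_DBL`).
#' @export
fragment_window_abundance <- function(fragments, window,
                                      params = gradient_params(),
                                      p_dbl = 0.001, clip_dbl = TRUE) {
  stopifnot(inherits(window, "bd_window"))
  need <- c("alpha", "rho", "sigma")
  if (!all(need %in% names(fragments)))
    stop("fragment_window_abundance: fragments lack BD columns ",
         "(run fragment_bd() first)")
  out <- fragments
  out$window <- if (is.na(window$label))
    sprintf("[%.4f,%.4f]", window$rho_min, window$rho_max) else window$label

  out$p_LR <- lumen_recovery(out$rho, out$sigma, window)
  out$alpha_L <- lumen_abundance(out$alpha, p_dbl, out$p_LR)

  rad <- 2 * params$beta * (out$rho - params$avg_density) /
    params$angular_velocity^2 + params$isoconcentration^2
  x <- ifelse(rad >= 0, sqrt(pmax(rad, 0)), NA_real_)
  in_tube <- !is.na(x) & x >= params$r_min & x <= params$r_max
  n_out <- sum(!in_tube)
  out$alpha_DBL <- 0
  if (any(in_tube) && p_dbl > 0) {
    rng <- .dbl_bd_range_vec(x[in_tube], params)
    wmax <- window$rho_max; wmin <- window$rho_min
    width <- if (clip_dbl) {
      pmax(0, pmin(wmax, rng$rho_dbl_max) - pmax(wmin, rng$rho_dbl_min))
    } else {
      rep(wmax - wmin, sum(in_tube))
    }
    out$alpha_DBL[in_tube] <- width / (rng$rho_dbl_max - rng$rho_dbl_min) *
      out$alpha[in_tube] * p_dbl
  }
  out$alpha_f <- out$alpha_L + out$alpha_DBL
  attr(out, "out_of_gradient") <- n_out
  out
}

#' Read-level abundance of a fragment
#'
#' `alpha_r = alpha_f * l_f / (2 l_r)`: the number of read pairs a
#' fragment can yield scales with its length in read units.
#'
#' @param alpha_f Fragment abundance in the window.
#' @param fragment_length Fragment length in bp.
#' @param read_length Read length in bp (>= 1).
#' @return Read abundance (same length as inputs).
#' @examples
#' read_abundance(1, 3000, 150)  # 10
#' @export
read_abundance <- function(alpha_f, fragment_length, read_length) {
  if (any(read_length < 1)) stop("read_abundance: read_length must be >= 1")
  if (any(fragment_length < read_length))
    stop("read_abundance: fragment shorter than read length; ",
         "exclude such fragments upstream")
  alpha_f * fragment_length / (2 * read_length)
}

#' Shotgun-control fragment abundance
#'
#' In the conventional shotgun simulation no gradient fractionation is
#' applied: each fragment's abundance equals its parent reference
#' abundance exactly.
#'
#' @param fragments Fragment data.frame with an `alpha` column (from
#'   [fragment_bd()]), or a numeric vector of alphas.
#' @return The input with `alpha_f = alpha` (data.frame) or the vector
#'   itself.
#' @export
shotgun_abundance <- function(fragments) {
  if (is.numeric(fragments)) return(fragments)
  if (!"alpha" %in% names(fragments))
    stop("shotgun_abundance: fragments lack an 'alpha' column")
  fragments$alpha_f <- fragments$alpha
  fragments
}

#' Write a per-window fragment abundance table
#'
#' @param abund Output of [fragment_window_abundance()] (possibly several
#'   windows row-bound).
#' @param path TSV output path.
#' @export
write_abundance_table <- function(abund, path) {
  cols <- intersect(c("reference_id", "scaffold_id", "start", "end",
                      "length", "window", "alpha_L", "alpha_DBL", "alpha_f"),
                    names(abund))
  utils::write.table(abund[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
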