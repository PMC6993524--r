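#' Theoretical buoyant density of DNA from its G+C content
#'
#' The equilibrium buoyant density of unlabeled DNA in a CsCl gradient is a
#' linear function of the molar G+C fraction: `rho_t = 0.098 (G+C) + 1.66`.
#'
#' @param gc G+C content as a fraction in \[0, 1\] (vectorized).
#' @return Buoyant density in g/ml.
#' @examples
#' theoretical_bd(c(0, 0.5, 1))
#' @export
theoretical_bd <- function(gc) {
  stopifnot(is.numeric(gc))
  if (any(!is.finite(gc)) || any(gc < 0 | gc > 1))
    stop("theoretical_bd: gc must lie in [0, 1]")
  0.098 * gc + 1.66
}

#' Maximal buoyant-density shift at full isotope labeling
#'
#' @param isotope `"13C"` or `"15N"`.
#' @return The BD increase delta (g/ml) at 100% atom excess: 0.036 for 13C,
#'   0.016 for 15N.
#' @export
isotope_delta <- function(isotope) {
  deltas <- c("13C" = 0.036, "15N" = 0.016)
  isotope <- as.character(isotope)
  if (any(!isotope %in% names(deltas)))
    stop("isotope_delta: unknown isotope '",
         paste(setdiff(isotope, names(deltas)), collapse = ", "),
         "' (supported: 13C, 15N)")
  unname(deltas[isotope])
}

#' Isotope-adjusted buoyant density
#'
#' Shifts the theoretical BD of a fragment by `A * delta`, where `A` is the
#' atom fraction excess of the heavy isotope and `delta` the full-label
#' shift for that isotope.
#'
#' @param rho_t Theoretical (unlabeled) BD in g/ml (vectorized).
#' @param atom_excess Atom excess as a fraction in \[0, 1\] (vectorized).
#' @param isotope `"13C"` or `"15N"`.
#' @return Adjusted BD in g/ml.
#' @examples
#' labeled_bd(1.709, 1, "13C")   # 1.745
#' labeled_bd(1.709, 0, "13C")   # unchanged
#' @export
labeled_bd <- function(rho_t, atom_excess, isotope = "13C") {
  stopifnot(is.numeric(rho_t), is.numeric(atom_excess))
  if (any(!is.finite(atom_excess)) || any(atom_excess < 0 | atom_excess > 1))
    stop("labeled_bd: atom_excess must lie in [0, 1]")
  rho_t + atom_excess * isotope_delta(isotope)
}

#' Diffusion standard deviation of a fragment's buoyant density
#'
#' At sedimentation-diffusion equilibrium a fragment's BD is normally
#' distributed in the tube lumen with standard deviation
#' `sigma = sqrt(rho R T / (beta^2 G M_c l))`, decreasing with fragment
#' length `l` as `1/sqrt(l)`.
#'
#' @param rho Fragment BD in g/ml (vectorized).
#' @param length_bp Fragment length in base pairs (vectorized, >= 1).
#' @param params A [gradient_params()] object.
#' @return Standard deviation of BD in g/ml.
#' @examples
#' gp <- gradient_params()
#' diffusion_sigma(1.709, 1e4, gp)
#' @export
diffusion_sigma <- function(rho, length_bp, params = gradient_params()) {
  stopifnot(inherits(params, "gradient_params"),
            is.numeric(rho), is.numeric(length_bp))
  if (any(!is.finite(length_bp)) || any(length_bp < 1))
    stop("diffusion_sigma: length_bp must be >= 1")
  if (any(rho <= 0)) stop("diffusion_sigma: rho must be > 0")
  sqrt(rho * params$gas_constant * params$temperature /
         (params$beta^2 * params$buoyancy_factor * params$base_pair_mass *
            length_bp))
}

#' Isoconcentration point of a fixed-angle gradient
#'
#' The rotor radius at which the gradient density equals the average loading
#' density: `I = sqrt((r_min^2 + r_min r_max + r_max^2) / 3)`.
#'
#' @param r_min,r_max Distances (cm) from the axis of rotation to the top
#'   and bottom of the tube; `0 < r_min <= r_max`.
#' @return The isoconcentration point in cm, always within
#'   `[r_min, r_max]`.
#' @examples
#' isoconcentration_point(2.6176, 4.8518)
#' @export
isoconcentration_point <- function(r_min, r_max) {
  stopifnot(is.numeric(r_min), is.numeric(r_max))
  if (any(r_min <= 0) || any(r_max <= 0))
    stop("isoconcentration_point: radii must be > 0")
  if (any(r_min > r_max))
    stop("isoconcentration_point: r_min must be <= r_max")
  sqrt((r_min^2 + r_min * r_max + r_max^2) / 3)
}

#' Equilibrium radial position of a fragment in the spinning gradient
#'
#' Distance from the axis of rotation at which a fragment of buoyant
#' density `rho` bands: `x = sqrt(2 beta (rho - D) / omega^2 + I^2)`.
#' Densities so far below the average gradient density that the radicand is
#' negative would float off the gradient and raise an error.
#'
#' @param rho Fragment BD in g/ml (vectorized).
#' @param params A [gradient_params()] object.
#' @return Radial position in cm, strictly increasing in `rho`.
#' @examples
#' gp <- gradient_params()
#' equilibrium_position(gp$avg_density, gp)  # = I
#' @export
equilibrium_position <- function(rho, params = gradient_params()) {
  stopifnot(inherits(params, "gradient_params"), is.numeric(rho))
  rad <- 2 * params$beta * (rho - params$avg_density) /
    params$angular_velocity^2 + params$isoconcentration^2
  if (any(rad < 0))
    stop("equilibrium_position: density out of gradient (rho = ",
         paste(signif(rho[rad < 0], 6), collapse = ", "),
         " g/ml floats off the low end)")
  sqrt(rad)
}

#' Buoyant density at a radial position of the model gradient
#'
#' The analytic model gradient: the closed-form inverse of
#' [equilibrium_position()], `rho = D + omega^2 (x^2 - I^2) / (2 beta)`.
#'
#' @param x Radial position in cm (vectorized), within the tube extent.
#' @param params A [gradient_params()] object.
#' @param check Validate that `x` lies within the physical tube extent
#'   (default TRUE). Internal callers that pre-clamp may disable it.
#' @return BD in g/ml, strictly increasing in `x`.
#' @examples
#' gp <- gradient_params()
#' position_to_bd(gp$isoconcentration, gp)  # = D
#' @export
position_to_bd <- function(x, params = gradient_params(), check = TRUE) {
  stopifnot(inherits(params, "gradient_params"), is.numeric(x))
  if (check && (any(x < 0) || any(x > params$r_max)))
    stop("position_to_bd: position outside the tube extent [0, r_max = ",
         params$r_max, "] cm")
  params$avg_density + params$angular_velocity^2 *
    (x^2 - params$isoconcentration^2) / (2 * params$beta)
}

#' Tabulated model gradient (parity variant)
#'
#' A lookup-table version of the model gradient for cross-checking the
#' analytic mapping: BD is tabulated on a regular grid of radial positions
#' and inverted by linear interpolation.
#'
#' @param params A [gradient_params()] object.
#' @param step Table step size in cm.
#' @return A data.frame with columns `position` (cm) and `bd` (g/ml).
#' @export
model_gradient_table <- function(params = gradient_params(), step = 1e-3) {
  stopifnot(step > 0)
  pos <- unique(c(seq(params$r_min, params$r_max, by = step), params$r_max))
  data.frame(position = pos, bd = position_to_bd(pos, params))
}

# Crossover radii between the cylindrical wall section and the rounded
# bottom cap, one per DBL bound (derived from formula continuity at the
# cap junction).
.dbl_crossovers <- function(params) {
  ct <- cos(params$tube_angle)
  c(lower = params$r_max - params$tube_radius * (1 + ct),
    upper = params$r_max - params$tube_radius * (1 - ct))
}

#' Tube-wall position range contaminated by a fragment's DBL
#'
#' During deceleration a thin diffusive boundary layer (DBL) of
#' unequilibrated DNA clings to the tube wall. A fragment banding at radial
#' position `x` touches the wall over a range of positions along the tube
#' (measured from the tube bottom), computed with the cylindrical-section
#' or rounded-bottom formula depending on where the iso-density surface
#' meets the wall. The positions are then mapped back to buoyant densities
#' through the tube-midline model gradient, giving the BD interval this
#' fragment's DBL contaminates after reorientation.
#'
#' @param x Equilibrium radial position (cm) of the fragment, from
#'   [equilibrium_position()].
#' @param params A [gradient_params()] object.
#' @return A list of class `dbl_range` with elements `x_min`, `x_max`
#'   (tube positions, cm, `x_min < x_max`) and `rho_dbl_min`,
#'   `rho_dbl_max` (g/ml), clamped to the gradient's physical BD extent.
#' @examples
#' gp <- gradient_params()
#' dbl_position_range(equilibrium_position(1.72, gp), gp)
#' @export
dbl_position_range <- function(x, params = gradient_params()) {
  stopifnot(inherits(params, "gradient_params"),
            is.numeric(x), length(x) == 1L)
  if (!is.finite(x) || x < params$r_min || x > params$r_max)
    stop("dbl_position_range: x = ", signif(x, 6),
         " cm outside the tube radial extent [r_min = ", params$r_min,
         ", r_max = ", params$r_max, "]")
  rt <- params$tube_radius
  th <- params$tube_angle
  rmax <- params$r_max
  cross <- .dbl_crossovers(params)

  # position of the lower (denser) end of the wall band
  x_min <- if (x <= cross["lower"]) {
    rt + (rmax - rt * cos(th) - rt - x) / sin(th)          # cylindrical wall
  } else {
    u <- (x - rmax + rt) / rt
    rt - rt * cos(th - asin(u))                            # rounded bottom
  }
  # position of the upper (lighter) end of the wall band
  x_max <- if (x <= cross["upper"]) {
    rt + (rmax + rt * cos(th) - rt - x) / sin(th)
  } else {
    u <- (x - rmax + rt) / rt
    rt - rt * cos(th - pi + asin(u))
  }
  x_min <- unname(x_min); x_max <- unname(x_max)
  if (!(x_min < x_max))
    stop("dbl_position_range: degenerate DBL interval at x = ", x)

  bd <- sort(tube_position_to_bd(c(x_min, x_max), params))
  structure(list(x_min = x_min, x_max = x_max,
                 rho_dbl_min = bd[1], rho_dbl_max = bd[2]),
            class = "dbl_range")
}

#' Buoyant density of the model gradient at a tube-wall position
#'
#' Maps a position along the tube (cm from the tube bottom) to the BD of
#' the gradient there, by projecting onto the tube midline radius
#' `r(s) = (r_max - r_t) + (r_t - s) sin(theta)` and applying the analytic
#' model gradient. Radii are clamped to the tube extent, so positions above
#' the tube top return the BD at `r_min`.
#'
#' @param s Position along the tube from the bottom (cm, vectorized).
#' @param params A [gradient_params()] object.
#' @return BD in g/ml, non-increasing in `s`.
#' @export
tube_position_to_bd <- function(s, params = gradient_params()) {
  stopifnot(is.numeric(s))
  r <- (params$r_max - params$tube_radius) +
    (params$tube_radius - s) * sin(params$tube_angle)
  r <- pmin(pmax(r, params$r_min), params$r_max)
  position_to_bd(r, params, check = FALSE)
}
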