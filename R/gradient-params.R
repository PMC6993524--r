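#' Physical and geometric parameters of an isopycnic CsCl gradient
#'
#' Bundles the centrifugation conditions, rotor/tube geometry and the
#' physical constants of aqueous CsCl used throughout the buoyant-density
#' (BD) model. Defaults describe a typical fixed-angle ultracentrifugation
#' setup (TLA-110-class rotor at 55,000 rpm) and the standard literature
#' constants for CsCl.
#'
#' @param temperature Centrifugation temperature in kelvin.
#' @param avg_density Average density of the gradient solution `D` (g/ml).
#' @param angular_velocity Angular velocity of centrifugation (rad/s).
#' @param r_min,r_max Minimum/maximum distance from the axis of rotation to
#'   the tube (cm). `r_max` is the radius of the deepest point of the tube.
#' @param tube_radius Radius of the ultracentrifuge tube (cm).
#' @param tube_angle Angle of the tube relative to the axis of rotation
#'   (radians, in (0, pi/2]).
#' @param beta Proportionality constant of aqueous CsCl.
#' @param buoyancy_factor Buoyancy factor `G`.
#' @param base_pair_mass Mean molar weight of a nucleotide base pair in CsCl
#'   solution (g/mol).
#' @param gas_constant Universal gas constant `R`. The default is the value
#'   conventionally quoted in J/(mol K); see the methods vignette for the
#'   unit-system caveat affecting the absolute scale of the diffusion term.
#'
#' @return An object of class `gradient_params` (a validated list).
#' @examples
#' gp <- gradient_params()
#' gp$avg_density
#' @export
gradient_params <- function(temperature = 293.15,
                            avg_density = 1.70,
                            angular_velocity = 2 * pi * 55000 / 60,
                            r_min = 2.6176,
                            r_max = 4.8518,
                            tube_radius = 0.65,
                            tube_angle = 0.4992,
                            beta = 1.14e9,
                            buoyancy_factor = 7.87e-10,
                            base_pair_mass = 882,
                            gas_constant = 8.314) {
  p <- list(
    temperature = temperature, avg_density = avg_density,
    angular_velocity = angular_velocity,
    r_min = r_min, r_max = r_max,
    tube_radius = tube_radius, tube_angle = tube_angle,
    beta = beta, buoyancy_factor = buoyancy_factor,
    base_pair_mass = base_pair_mass, gas_constant = gas_constant
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("gradient_params: '", nm, "' must be a single finite number")
  }
  if (!(p$r_min > 0 && p$r_min < p$r_max))
    stop("gradient_params: need 0 < r_min < r_max")
  if (p$tube_radius <= 0)
    stop("gradient_params: tube_radius must be > 0")
  if (!(p$tube_angle > 0 && p$tube_angle <= pi / 2))
    stop("gradient_params: tube_angle must lie in (0, pi/2] radians")
  if (p$temperature <= 0 || p$angular_velocity <= 0)
    stop("gradient_params: temperature and angular_velocity must be > 0")
  if (p$avg_density <= 1)
    stop("gradient_params: avg_density must be > 1 g/ml")
  if (p$beta <= 0 || p$buoyancy_factor <= 0 || p$base_pair_mass <= 0 ||
      p$gas_constant <= 0)
    stop("gradient_params: physical constants must be > 0")
  p$isoconcentration <- isoconcentration_point(p$r_min, p$r_max)
  class(p) <- "gradient_params"
  p
}

#' @export
print.gradient_params <- function(x, ...) {
  cat("Isopycnic gradient parameters\n")
  cat(sprintf("  T = %.2f K, D = %.4f g/ml, omega = %.1f rad/s\n",
              x$temperature, x$avg_density, x$angular_velocity))
  cat(sprintf("  tube: r_min = %.4f cm, r_max = %.4f cm, r_t = %.3f cm, theta = %.4f rad\n",
              x$r_min, x$r_max, x$tube_radius, x$tube_angle))
  cat(sprintf("  constants: beta = %.3g, G = %.3g, M_c = %g, R = %g\n",
              x$beta, x$buoyancy_factor, x$base_pair_mass, x$gas_constant))
  cat(sprintf("  isoconcentration point I = %.4f cm\n", x$isoconcentration))
  invisible(x)
}

#' A sequenced buoyant-density window
#'
#' @param rho_min,rho_max Window bounds in g/ml (`rho_min < rho_max`).
#'   Infinite bounds are allowed (useful for whole-gradient checks).
#' @param label Optional fraction identifier.
#' @return An object of class `bd_window`.
#' @examples
#' bd_window(1.72, 1.77)
#' @export
bd_window <- function(rho_min, rho_max, label = NULL) {
  stopifnot(is.numeric(rho_min), is.numeric(rho_max),
            length(rho_min) == 1L, length(rho_max) == 1L)
  if (!(rho_min < rho_max))
    stop("bd_window: rho_min must be < rho_max (got ",
         rho_min, " >= ", rho_max, ")")
  structure(list(rho_min = rho_min, rho_max = rho_max,
                 label = if (is.null(label)) NA_character_ else as.character(label)),
            class = "bd_window")
}

#' @export
print.bd_window <- function(x, ...) {
  cat(sprintf("BD window [%.4f, %.4f] g/ml%s\n", x$rho_min, x$rho_max,
              if (is.na(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

#' An ordered, contiguous set of gradient fractions
#'
#' @param boundaries Increasing numeric vector of BD boundaries (g/ml);
#'   fraction i spans `[boundaries[i], boundaries[i+1])`.
#' @param labels Optional fraction labels (length `length(boundaries) - 1`).
#' @return An object of class `fraction_set`: a list of [bd_window()]s.
#' @examples
#' fs <- fraction_set(seq(1.675, 1.771, by = 0.004))
#' length(fs)
#' @export
fraction_set <- function(boundaries, labels = NULL) {
  stopifnot(is.numeric(boundaries), length(boundaries) >= 2L)
  if (any(diff(boundaries) <= 0))
    stop("fraction_set: boundaries must be strictly increasing")
  n <- length(boundaries) - 1L
  if (is.null(labels)) labels <- sprintf("F%02d", seq_len(n))
  if (length(labels) != n)
    stop("fraction_set: need one label per fraction")
  ws <- lapply(seq_len(n), function(i)
    bd_window(boundaries[i], boundaries[i + 1L], labels[i]))
  structure(ws, boundaries = boundaries, class = "fraction_set")
}

#' @export
print.fraction_set <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("Fraction set: %d contiguous windows spanning [%.4f, %.4f] g/ml\n",
              length(x), min(b), max(b)))
  invisible(x)
}
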