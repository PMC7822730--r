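## Schulz polydispersity and dilute-solution scattering theory.
##
## The Schulz (gamma-type) size distribution is parameterised by the
## number-average radius <R> and the normalized standard deviation
## sigma* = sd(R)/<R>.  With c = 1/sigma*^2 and b = <R>/c the density is
##   P(R) = (R/b)^(c-1) exp(-R/b) / (b Gamma(c)).
## All scattering-weighted sizes below follow from its closed-form moments.

#' Schulz size distribution
#'
#' Construct a Schulz (gamma) radius distribution, the polydispersity model
#' used throughout the package.
#'
#' @param mean_radius Number-average radius \code{<R>} (nm), > 0.
#' @param sigma_star Normalized standard deviation \code{sd(R)/<R>},
#'   in \code{[0, 1)}. \code{0} denotes the monodisperse limit.
#' @return An object of class \code{"schulz_dist"}.
#' @examples
#' d <- schulz_dist(2.51, 0.475)
#' schulz_moment(d, 1)  # the mean radius
#' @export
schulz_dist <- function(mean_radius, sigma_star) {
  stopifnot(is.numeric(mean_radius), length(mean_radius) == 1L,
            is.numeric(sigma_star), length(sigma_star) == 1L)
  if (mean_radius <= 0) stop("mean_radius must be > 0")
  if (sigma_star < 0 || sigma_star >= 1) stop("sigma_star must be in [0, 1)")
  structure(list(mean_radius = mean_radius, sigma_star = sigma_star),
            class = "schulz_dist")
}

#' @export
print.schulz_dist <- function(x, ...) {
  cat(sprintf("Schulz distribution: <R> = %g, sigma* = %g\n",
              x$mean_radius, x$sigma_star))
  invisible(x)
}

# Below this sigma* the gamma density over/underflows are avoidable but the
# distribution is indistinguishable from a delta; switch to the monodisperse
# branch.
.SIGMA_STAR_MONO <- 0.02

#' Schulz probability density
#'
#' Density of the Schulz radius distribution, evaluated in log-space so that
#' large shape parameters (small \code{sigma_star}) do not overflow
#' \code{Gamma(c)}.
#'
#' @param dist A [schulz_dist()].
#' @param r Radii at which to evaluate (same units as \code{mean_radius}).
#' @return Density values.
#' @export
schulz_density <- function(dist, r) {
  stopifnot(inherits(dist, "schulz_dist"))
  if (dist$sigma_star < .SIGMA_STAR_MONO) {
    stop("density undefined in the monodisperse limit; use moments instead")
  }
  cc <- 1 / dist$sigma_star^2
  b <- dist$mean_radius / cc
  stats::dgamma(r, shape = cc, scale = b)
}

#' Moments of the Schulz distribution
#'
#' Closed-form n-th raw moment
#' \code{<R^n> = <R>^n sigma*^(2n) Gamma(n + 1/sigma*^2) / Gamma(1/sigma*^2)}.
#'
#' @param dist A [schulz_dist()].
#' @param n Non-negative integer order, \code{n <= 12} (higher moments of a
#'   broad distribution are numerically explosive and never needed here).
#' @return \code{<R^n>} in \code{mean_radius} units to the n-th power.
#' @export
schulz_moment <- function(dist, n) {
  stopifnot(inherits(dist, "schulz_dist"))
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer")
  if (n > 12) stop("n must be <= 12")
  if (dist$sigma_star == 0) return(dist$mean_radius^n)
  cc <- 1 / dist$sigma_star^2
  # log-space ratio Gamma(n+c)/Gamma(c) for stability at large c
  dist$mean_radius^n * dist$sigma_star^(2 * n) *
    exp(lgamma(n + cc) - lgamma(cc))
}

#' Intensity-averaged hydrodynamic radius
#'
#' The z-average \code{Rh = <R^6>/<R^5>} measured by dynamic light
#' scattering in a polydisperse ensemble; reduces to
#' \code{<R> sigma*^2 (5 + 1/sigma*^2)}.
#'
#' @param dist A [schulz_dist()].
#' @return Radius in \code{mean_radius} units.
#' @export
intensity_avg_rh <- function(dist) {
  stopifnot(inherits(dist, "schulz_dist"))
  s <- dist$sigma_star
  if (s == 0) return(dist$mean_radius)
  dist$mean_radius * s^2 * (5 + 1 / s^2)
}

.rg_shape_factor <- function(sigma_star) {
  # intensity-averaged Rg / <R>:  sigma*^2 sqrt(3 (7+1/s^2)(6+1/s^2) / 5)
  s <- sigma_star
  if (s == 0) return(sqrt(3 / 5))
  s^2 * sqrt(3 * (7 + 1 / s^2) * (6 + 1 / s^2) / 5)
}

#' Intensity-averaged radius of gyration
#'
#' \code{Rg = sqrt(3 <R^8> / (5 <R^6>))} for solid spheres with Schulz radii,
#' the quantity a Guinier analysis of the polydisperse form factor reports.
#'
#' @param dist A [schulz_dist()].
#' @return Radius in \code{mean_radius} units.
#' @export
intensity_avg_rg <- function(dist) {
  stopifnot(inherits(dist, "schulz_dist"))
  dist$mean_radius * .rg_shape_factor(dist$sigma_star)
}

#' Number-average radius from an Rg constraint
#'
#' Inverts [intensity_avg_rg()] (linear in \code{<R>}) so that a fitted
#' distribution can be tied to an experimentally observed radius of gyration.
#'
#' @param sigma_star Normalized standard deviation in \code{[0, 1)}.
#' @param rg_target Target intensity-averaged radius of gyration (> 0).
#' @return The number-average radius \code{<R>} with that Rg.
#' @export
mean_radius_from_rg <- function(sigma_star, rg_target) {
  if (sigma_star < 0 || sigma_star >= 1) stop("sigma_star must be in [0, 1)")
  if (rg_target <= 0) stop("rg_target must be > 0")
  rg_target / .rg_shape_factor(sigma_star)
}

#' Ellipsoid of revolution shape model
#'
#' @param aspect_ratio Polar over equatorial semi-axis \code{p} (> 0);
#'   \code{p > 1} prolate, \code{p < 1} oblate, \code{p = 1} sphere.
#' @param equatorial_semiaxis Equatorial semi-axis \code{b} (nm).
#' @return An object of class \code{"shape_model"}.
#' @export
shape_model <- function(aspect_ratio, equatorial_semiaxis = 1) {
  if (aspect_ratio <= 0) stop("aspect_ratio must be > 0")
  if (equatorial_semiaxis <= 0) stop("equatorial_semiaxis must be > 0")
  structure(list(aspect_ratio = aspect_ratio,
                 equatorial_semiaxis = equatorial_semiaxis),
            class = "shape_model")
}

#' Hydrodynamic radius of an ellipsoid of revolution
#'
#' Stick-boundary Perrin friction result. Prolate (\code{p > 1}):
#' \code{b sqrt(p^2-1)/ln(p + sqrt(p^2-1))}; oblate (\code{p < 1}):
#' \code{b sqrt(1-p^2)/atan(sqrt(1-p^2)/p)}. Both branches are continuous at
#' the sphere limit, which is evaluated by series for \code{|p-1| < 1e-4}.
#'
#' @param shape A [shape_model()].
#' @return Hydrodynamic radius in the units of \code{equatorial_semiaxis}.
#' @export
ellipsoid_hydro_radius <- function(shape) {
  stopifnot(inherits(shape, "shape_model"))
  p <- shape$aspect_ratio
  b <- shape$equatorial_semiaxis
  if (abs(p - 1) < 1e-4) {
    # Rh/b = 1 + (p-1)/3 - ... ; first order suffices at this tolerance
    return(b * (1 + (p - 1) / 3))
  }
  if (p > 1) {
    xi <- sqrt(p^2 - 1)
    b * xi / log(p + xi)
  } else {
    xi <- sqrt(1 - p^2)
    b * xi / atan(xi / p)
  }
}

#' Radius of gyration of a solid ellipsoid of revolution
#'
#' \code{Rg = b sqrt((2 + p^2) / 5)}.
#'
#' @param shape A [shape_model()].
#' @return Radius of gyration in the units of \code{equatorial_semiaxis}.
#' @export
ellipsoid_gyration_radius <- function(shape) {
  stopifnot(inherits(shape, "shape_model"))
  shape$equatorial_semiaxis * sqrt((2 + shape$aspect_ratio^2) / 5)
}

#' Rh/Rg map for polydisperse ellipsoids
#'
#' Ratio of the intensity-averaged hydrodynamic radius to the
#' intensity-averaged radius of gyration for an ellipsoid of revolution whose
#' semi-axes carry a common Schulz scale polydispersity (fixed aspect ratio).
#' The shape factors and the polydispersity averages factorize, so the ratio
#' is the product of the monodisperse shape ratio and the polydisperse sphere
#' ratio. Its maximum over shapes and polydispersities is the monodisperse
#' sphere value \code{sqrt(5/3) ~ 1.29}: both nonsphericity and
#' polydispersity lower it.
#'
#' @param p Aspect ratio (> 0).
#' @param sigma_star Normalized standard deviation of the common size scale.
#' @return Dimensionless ratio Rh/Rg.
#' @export
rh_rg_ratio_map <- function(p, sigma_star) {
  shp <- shape_model(p, 1)
  fh <- ellipsoid_hydro_radius(shp)
  fg <- ellipsoid_gyration_radius(shp)
  s <- sigma_star
  if (s == 0) {
    poly <- 1 / sqrt(3 / 5)
  } else {
    poly <- (s^2 * (5 + 1 / s^2)) / .rg_shape_factor(s)
  }
  (fh / fg) * poly * sqrt(3 / 5)
}

#' Polydisperse sphere form-factor model
#'
#' @param distribution A [schulz_dist()] of sphere radii.
#' @param scale Positive intensity prefactor.
#' @param background Non-negative constant background intensity.
#' @return An object of class \code{"form_factor_model"}.
#' @export
form_factor_model <- function(distribution, scale = 1, background = 0) {
  stopifnot(inherits(distribution, "schulz_dist"))
  if (scale <= 0) stop("scale must be > 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(distribution = distribution, scale = scale,
                 background = background),
            class = "form_factor_model")
}

# Normalized sphere scattering amplitude 3 (sin x - x cos x)/x^3, with the
# small-x series to avoid cancellation.
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  out[small] <- 1 - x[small]^2 / 10
  xs <- x[!small]
  out[!small] <- 3 * (sin(xs) - xs * cos(xs)) / xs^3
  out
}

# Fixed 256-node Gauss-Legendre rule on [0, 10 <R>]: deterministic,
# reproducible quadrature of the Schulz density (tail mass beyond 10 <R> is
# negligible for sigma* <= 0.6).
.schulz_quadrature <- function(dist, n_nodes = 256L) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 10 * dist$mean_radius)
  if (dist$sigma_star < .SIGMA_STAR_MONO) {
    # monodisperse: single node at <R>
    return(list(r = dist$mean_radius, w = 1))
  }
  w <- gl$w * schulz_density(dist, gl$x)
  list(r = gl$x, w = w / sum(w))
}

#' Polydisperse sphere form-factor intensity
#'
#' Dilute-solution scattering intensity of Schulz-distributed solid spheres,
#' \code{I0(q) = scale * int P(R) V(R)^2 A(qR)^2 dR + background} with
#' \code{A} the normalized sphere amplitude. Quadrature uses a fixed 256-node
#' rule on \code{[0, 10 <R>]}.
#'
#' @param model A [form_factor_model()].
#' @param q_grid Positive scattering vectors (inverse \code{mean_radius}
#'   units).
#' @return Intensity at each \code{q}.
#' @export
polydisperse_form_intensity <- function(model, q_grid) {
  stopifnot(inherits(model, "form_factor_model"))
  if (length(q_grid) == 0) stop("empty q grid")
  if (any(q_grid <= 0)) stop("q_grid must be positive")
  quad <- .schulz_quadrature(model$distribution)
  v2 <- ((4 * pi / 3) * quad$r^3)^2
  vapply(q_grid, function(q) {
    model$scale * sum(quad$w * v2 * sphere_amplitude(q * quad$r)^2) +
      model$background
  }, numeric(1))
}
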