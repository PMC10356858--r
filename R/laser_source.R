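#' Laser operating point
#'
#' One treatment condition: laser power, Gaussian spot radius, irradiation
#' time and ambient temperature.
#'
#' @param power Laser power (W); zero is allowed for null-pulse checks.
#' @param spot_radius Gaussian spot radius, the standard deviation of the
#'   radial beam profile (mm).
#' @param duration Irradiation time (s).
#' @param ambient Ambient air temperature (degrees C).
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(power, spot_radius, duration, ambient) {
  if (power < 0 || spot_radius <= 0 || duration <= 0) {
    stop("power must be non-negative; spot_radius and duration positive",
         call. = FALSE)
  }
  structure(list(power = power, spot_radius = spot_radius,
                 duration = duration, ambient = ambient),
            class = "operating_point")
}

#' Surface heat-exchange environment
#'
#' The skin surface exchanges heat with the surrounding air through a Robin
#' (convective) boundary condition `-k dT/dz = h_conv (T - ambient)`. The
#' ambient temperature usually comes from the operating point; `h_conv`
#' lumps free convection and radiation.
#'
#' @param h_conv Surface heat-transfer coefficient (W m^-2 K^-1).
#' @param ambient Ambient temperature (degrees C); `NA` means take it from
#'   the operating point at simulation time.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(h_conv = 10, ambient = NA_real_) {
  if (h_conv < 0) stop("h_conv must be non-negative", call. = FALSE)
  structure(list(h_conv = h_conv, ambient = ambient),
            class = "environment_spec")
}

#' Volumetric laser heat source
#'
#' Evaluates the Gaussian Beer-Lambert source on the solver grid: a radial
#' Gaussian of standard deviation equal to the spot radius, attenuated
#' axially by the cumulative optical depth across the layers. Two radial
#' normalizations are available: `"cylindrical"` (default) divides by
#' `2 pi sigma^2`, so that the power deposited in an infinitely deep domain
#' equals `power * (1 - exp(-total optical depth))`; `"literal"` divides by
#' `sigma * sqrt(2 pi)` (a one-dimensional Gaussian normalization, retained
#' for comparison; it is not power-consistent in cylindrical geometry and
#' under-heats by about three orders of magnitude at these parameters).
#'
#' Deposition is integrated exactly over each control volume (closed-form
#' Gaussian annulus fractions times Beer-Lambert cell absorption), so the
#' discrete energy input does not depend on grid resolution.
#'
#' @param model A [skin_model()].
#' @param op An [operating_point()].
#' @param grid A [build_grid()] result for `model`.
#' @param normalization `"cylindrical"` or `"literal"`.
#' @param attenuation `"absorption"` (Beer-Lambert with `mu_a` only, the
#'   default) or `"effective"` (attenuate with `mu_a + mu_s`; the absorbed
#'   fraction per cell is then scaled by `mu_a / (mu_a + mu_s)`).
#' @return An object of class `source_field`: `q` (node values, W m^-3),
#'   `q_cv` (watts deposited per control volume, `nr x nz`), and
#'   `deposited` (total watts in the domain).
#' @export
laser_source <- function(model, op, grid,
                         normalization = c("cylindrical", "literal"),
                         attenuation = c("absorption", "effective")) {
  stopifnot(inherits(model, "skin_model"), inherits(op, "operating_point"),
            inherits(grid, "bioheat_grid"))
  normalization <- match.arg(normalization)
  attenuation <- match.arg(attenuation)
  check_grid_model(grid, model)

  sigma <- op$spot_radius * 1e-3
  props <- layer_properties_si(model)
  mu_seg <- if (attenuation == "absorption") {
    props$mu_a[grid$seg_layer]
  } else {
    props$mu_a[grid$seg_layer] + props$mu_s[grid$seg_layer]
  }
  frac_seg <- if (attenuation == "absorption") {
    rep(1, length(grid$seg_layer))
  } else {
    props$mu_a[grid$seg_layer] / pmax(mu_seg, .Machine$double.eps)
  }

  z <- grid$z; r <- grid$r; zf <- grid$zf; rf <- grid$rf
  nz <- length(z); nr <- length(r)
  tau_node <- c(0, cumsum(mu_seg * diff(z)))   # optical depth, piecewise linear
  tau_at <- function(zz) stats::approx(z, tau_node, zz, rule = 2)$y

  # radial weights: annulus-integrated Gaussian fractions, scaled per mode
  frac_r <- exp(-rf[-(nr + 1)]^2 / (2 * sigma^2)) -
    exp(-rf[-1]^2 / (2 * sigma^2))
  scale_r <- if (normalization == "cylindrical") 1 else sigma * sqrt(2 * pi)
  # axial weights: fraction of beam power absorbed within each control volume
  frac_z <- frac_seg[pmin(seq_len(nz), nz - 1)] *
    (exp(-tau_at(zf[-(nz + 1)])) - exp(-tau_at(zf[-1])))
  q_cv <- op$power * scale_r * outer(frac_r, frac_z)

  # node values for display / point-wise use
  mu_node <- c(mu_seg, mu_seg[nz - 1])
  frac_node <- c(frac_seg, frac_seg[nz - 1])
  norm_r <- if (normalization == "cylindrical") {
    1 / (2 * pi * sigma^2)
  } else {
    1 / (sigma * sqrt(2 * pi))
  }
  q <- op$power * norm_r *
    outer(exp(-r^2 / (2 * sigma^2)), frac_node * mu_node * exp(-tau_node))

  structure(
    list(q = q, q_cv = q_cv, deposited = sum(q_cv),
         normalization = normalization, attenuation = attenuation,
         total_optical_depth = tau_node[nz]),
    class = "source_field"
  )
}

#' Source field from node values
#'
#' Wraps an arbitrary volumetric heat deposition (W m^-3 at the grid nodes)
#' as a `source_field` so it can be passed to [simulate_treatment()] in
#' place of the laser source (e.g. a depth-only test source). Cell watts are
#' obtained by midpoint quadrature over each control volume.
#'
#' @param grid A `bioheat_grid`.
#' @param q Matrix `length(r) x length(z)` of W m^-3, or a function
#'   `f(r, z)` evaluated on the node tensor grid.
#' @return A `source_field`.
#' @export
as_source_field <- function(grid, q) {
  stopifnot(inherits(grid, "bioheat_grid"))
  nr <- length(grid$r); nz <- length(grid$z)
  if (is.function(q)) q <- outer(grid$r, grid$z, q)
  stopifnot(is.matrix(q), nrow(q) == nr, ncol(q) == nz, all(is.finite(q)))
  vol <- outer(grid$area_r, grid$dz_cv)
  q_cv <- q * vol
  structure(list(q = q, q_cv = q_cv, deposited = sum(q_cv),
                 normalization = "custom", attenuation = "custom",
                 total_optical_depth = NA_real_),
            class = "source_field")
}

check_grid_model <- function(grid, model) {
  if (!isTRUE(all.equal(grid$boundaries, model$boundaries * 1e-6))) {
    stop("grid was built for a different skin model", call. = FALSE)
  }
  invisible(TRUE)
}
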