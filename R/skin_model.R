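#' Tissue layer
#'
#' One layer of the layered skin model, carrying both thermal and optical
#' properties. Thermal properties enter the Pennes bioheat equation; optical
#' properties drive the Beer-Lambert attenuation of the laser source.
#'
#' @param name Layer name.
#' @param thickness Layer thickness in micrometres.
#' @param rho Density (kg m^-3).
#' @param cp Specific heat capacity (J kg^-1 K^-1).
#' @param k Thermal conductivity (W m^-1 K^-1).
#' @param mu_a Absorption coefficient (cm^-1).
#' @param mu_s Scattering coefficient (cm^-1). Carried in the model; only used
#'   by the optional effective-attenuation source mode.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, rho, cp, k, mu_a, mu_s = 0) {
  stopifnot(is.character(name), length(name) == 1)
  for (v in c(thickness = thickness, rho = rho, cp = cp, k = k)) {
    if (!is.finite(v) || v <= 0) {
      stop("thickness, rho, cp and k must be positive and finite", call. = FALSE)
    }
  }
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be non-negative", call. = FALSE)
  structure(
    list(name = name, thickness = thickness, rho = rho, cp = cp, k = k,
         mu_a = mu_a, mu_s = mu_s),
    class = "tissue_layer"
  )
}

#' Blood perfusion and metabolic parameters
#'
#' Parameters of the perfusion sink `omega_b * c_b * (t_b - T)` and the
#' metabolic source `q_m` in the Pennes equation. For sub-second laser pulses
#' both terms are negligible, so the defaults are zero perfusion and zero
#' metabolic heating; the blood specific heat defaults to the blood-layer
#' value of the skin model.
#'
#' @param omega_b Blood perfusion rate (kg m^-3 s^-1, volumetric convention).
#' @param c_b Blood specific heat (J kg^-1 K^-1).
#' @param t_b Arterial blood temperature (degrees C).
#' @param q_m Metabolic heat production rate (W m^-3).
#' @return An object of class `perfusion_params`.
#' @export
perfusion_params <- function(omega_b = 0, c_b = 3670, t_b = 37, q_m = 0) {
  if (c_b <= 0) stop("c_b must be positive", call. = FALSE)
  if (omega_b < 0 || q_m < 0) {
    stop("omega_b and q_m must be non-negative", call. = FALSE)
  }
  structure(list(omega_b = omega_b, c_b = c_b, t_b = t_b, q_m = q_m),
            class = "perfusion_params")
}

#' Layered skin model
#'
#' An ordered stack of [tissue_layer()]s, surface downward, with perfusion
#' parameters and the core (deep-tissue) temperature that anchors the lower
#' boundary condition.
#'
#' @param layers List of [tissue_layer()] objects, ordered from the surface.
#' @param perfusion A [perfusion_params()] object.
#' @param core_temperature Deep-tissue temperature (degrees C).
#' @return An object of class `skin_model` with derived fields
#'   `total_depth` (um) and `boundaries` (um, length `n_layers + 1`).
#' @export
skin_model <- function(layers, perfusion = perfusion_params(),
                       core_temperature = 37) {
  if (length(layers) == 0) stop("at least one layer is required", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "tissue_layer")
  if (!all(ok)) stop("all layers must be tissue_layer objects", call. = FALSE)
  stopifnot(inherits(perfusion, "perfusion_params"))
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  boundaries <- c(0, cumsum(th))
  structure(
    list(layers = layers, perfusion = perfusion,
         core_temperature = core_temperature,
         total_depth = sum(th), boundaries = boundaries),
    class = "skin_model"
  )
}

#' Default five-layer skin model
#'
#' The layered model of human skin used throughout the package: stratum
#' corneum (10 um), epidermis (80 um), upper dermis (260 um), blood layer
#' (150 um) and subdermal lower dermis (1500 um), total depth 2000 um. The
#' stratum corneum carries epidermis properties (no separate measurement is
#' available for such a thin keratin film), the dermis optical properties are
#' shared by the upper and lower dermis, and the blood layer uses whole-blood
#' optics.
#'
#' @param perfusion A [perfusion_params()] object.
#' @param core_temperature Deep-tissue temperature (degrees C).
#' @return A `skin_model`.
#' @examples
#' m <- default_skin_model()
#' m$total_depth  # 2000 um
#' @export
default_skin_model <- function(perfusion = perfusion_params(),
                               core_temperature = 37) {
  skin_model(
    layers = list(
      tissue_layer("stratum_corneum", 10, 1210, 2250, 0.197, 2.7, 450),
      tissue_layer("epidermis", 80, 1210, 2250, 0.197, 2.7, 450),
      tissue_layer("upper_dermis", 260, 1090, 3350, 0.422, 0.7, 180),
      tissue_layer("blood", 150, 1060, 3670, 0.486, 0.5, 44.9),
      tissue_layer("lower_dermis", 1500, 1090, 3350, 0.422, 0.7, 180)
    ),
    perfusion = perfusion,
    core_temperature = core_temperature
  )
}

#' Layer lookup by depth
#'
#' Returns the layer whose half-open depth interval `[top, bottom)` contains
#' `z`; the total depth maps to the deepest layer. Depth is measured from the
#' skin surface, increasing downward.
#'
#' @param model A `skin_model`.
#' @param z Depth in micrometres, `0 <= z <= total_depth`.
#' @return The `tissue_layer` containing depth `z`.
#' @export
layer_at_depth <- function(model, z) {
  stopifnot(inherits(model, "skin_model"), length(z) == 1)
  if (!is.finite(z) || z < 0 || z > model$total_depth) {
    stop("depth z must lie in [0, ", model$total_depth, "] um", call. = FALSE)
  }
  model$layers[[layer_index_at_depth(model, z)]]
}

# vectorized index lookup; half-open [top, bottom), z = total -> last layer
layer_index_at_depth <- function(model, z) {
  pmin(findInterval(z, model$boundaries, rightmost.closed = TRUE),
       length(model$layers))
}

# per-layer properties in SI units (m, m^-1)
layer_properties_si <- function(model) {
  lay <- model$layers
  data.frame(
    name = vapply(lay, `[[`, character(1), "name"),
    thickness = vapply(lay, `[[`, numeric(1), "thickness") * 1e-6,
    rho = vapply(lay, `[[`, numeric(1), "rho"),
    cp = vapply(lay, `[[`, numeric(1), "cp"),
    k = vapply(lay, `[[`, numeric(1), "k"),
    mu_a = vapply(lay, `[[`, numeric(1), "mu_a") * 100,
    mu_s = vapply(lay, `[[`, numeric(1), "mu_s") * 100,
    stringsAsFactors = FALSE
  )
}

#' @export
print.skin_model <- function(x, ...) {
  cat("Layered skin model:", length(x$layers), "layers,",
      x$total_depth, "um total depth\n")
  p <- layer_properties_si(x)
  df <- data.frame(
    layer = p$name,
    thickness_um = p$thickness * 1e6,
    rho = p$rho, cp = p$cp, k = p$k,
    mu_a_cm = p$mu_a / 100, mu_s_cm = p$mu_s / 100
  )
  print(df, row.names = FALSE)
  pf <- x$perfusion
  cat(sprintf("perfusion: omega_b = %g kg m-3 s-1, c_b = %g, T_b = %g C, q_m = %g W m-3\n",
              pf$omega_b, pf$c_b, pf$t_b, pf$q_m))
  cat("core temperature:", x$core_temperature, "C\n")
  invisible(x)
}

#' Write a skin model to a YAML or JSON configuration file
#'
#' @param model A `skin_model`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_skin_model <- function(model, path) {
  stopifnot(inherits(model, "skin_model"))
  obj <- list(
    core_temperature = model$core_temperature,
    perfusion = unclass(model$perfusion),
    layers = lapply(model$layers, unclass)
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a skin model from a YAML or JSON configuration file
#'
#' @param path Path written by [write_skin_model()] (or hand-edited in the
#'   same layout: a `layers` list plus `perfusion` and `core_temperature`).
#' @return A `skin_model`.
#' @export
read_skin_model <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  n_layers <- if (is.data.frame(obj$layers)) nrow(obj$layers)
              else length(obj$layers)
  layers <- lapply(seq_len(n_layers), function(i) {
    li <- if (is.data.frame(obj$layers)) as.list(obj$layers[i, ]) else obj$layers[[i]]
    tissue_layer(li$name, li$thickness, li$rho, li$cp, li$k, li$mu_a, li$mu_s)
  })
  pf <- as.list(obj$perfusion)
  skin_model(layers,
             perfusion = perfusion_params(pf$omega_b, pf$c_b, pf$t_b, pf$q_m),
             core_temperature = obj$core_temperature)
}
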