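#' Grid resolution settings
#'
#' Controls the graded structured (r, z) grid used by the axisymmetric
#' bioheat solver. Depth spacing is uniform and fine (`dz_fine`) down to
#' `fine_depth` so that the thin stratum corneum and the 20 um indicator
#' depth are resolved exactly, then grows geometrically within each tissue
#' layer up to `dz_max`. The radial grid is uniform over the beam
#' (`spot_radius / nr_spot`) out to 2.5 spot radii, then grows geometrically
#' to the lateral extent.
#'
#' @param dz_fine Uniform near-surface depth spacing (m).
#' @param fine_depth Depth down to which `dz_fine` is used (m).
#' @param z_growth Geometric growth factor of depth spacing below
#'   `fine_depth`.
#' @param dz_max Maximum depth spacing (m).
#' @param nr_spot Number of radial cells per spot radius inside the beam.
#' @param r_growth Geometric growth factor of radial spacing beyond the beam.
#' @param dr_max Maximum radial spacing (m).
#' @param r_extent Lateral extent of the domain (m); `NULL` means
#'   `max(5 * spot_radius, 10 mm)`, far enough that the zero-flux lateral
#'   boundary is invisible to the indicators.
#' @param refine Refinement factor; 2 halves every spacing (used for grid
#'   convergence checks).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dz_fine = 2e-6, fine_depth = 4e-5, z_growth = 1.2,
                      dz_max = 1e-4, nr_spot = 12, r_growth = 1.25,
                      dr_max = 1.5e-3, r_extent = NULL, refine = 1) {
  stopifnot(dz_fine > 0, fine_depth >= 2e-5, z_growth > 1, dz_max >= dz_fine,
            nr_spot >= 2, r_growth > 1, refine >= 1)
  structure(list(dz_fine = dz_fine, fine_depth = fine_depth,
                 z_growth = z_growth, dz_max = dz_max, nr_spot = nr_spot,
                 r_growth = r_growth, dr_max = dr_max, r_extent = r_extent,
                 refine = refine),
            class = "grid_spec")
}

#' Coarse grid settings for quick runs and fixtures
#'
#' @return A `grid_spec` with roughly half the resolution of the default in
#'   each direction. Intended for smoke tests and pipeline dry runs; the
#'   default spec should be used for reported numbers.
#' @export
coarse_grid_spec <- function() {
  grid_spec(dz_fine = 4e-6, fine_depth = 4e-5, z_growth = 1.35, dz_max = 2e-4,
            nr_spot = 6, r_growth = 1.4, dr_max = 2.5e-3)
}

# geometric spacing sequence from a to b, start spacing ~h0 growing by
# `growth` up to hmax, rescaled so the last node lands exactly on b
graded_seq <- function(a, b, h0, growth, hmax) {
  len <- b - a
  if (len <= h0) return(b)
  hs <- h0
  while (sum(hs) < len) hs <- c(hs, min(hmax, hs[length(hs)] * growth))
  hs <- hs * len / sum(hs)
  a + cumsum(hs)
}

#' Build the axisymmetric solver grid
#'
#' Constructs a graded structured grid for [simulate_treatment()]. Every
#' layer boundary coincides with a depth node, the 20 um indicator depth is
#' a node, and control-volume geometry (annulus areas, cell heights,
#' per-segment conductivities, cell heat capacities) is precomputed.
#'
#' @param model A [skin_model()].
#' @param spot_radius Spot radius (mm) the radial grading should resolve;
#'   use the largest spot radius of a planned sweep.
#' @param spec A [grid_spec()].
#' @return An object of class `bioheat_grid` with fields `r`, `z` (node
#'   coordinates, m), face coordinates, control-volume areas and heights,
#'   per-cell material arrays and the 20 um probe index.
#' @export
build_grid <- function(model, spot_radius = 2, spec = grid_spec()) {
  stopifnot(inherits(model, "skin_model"), inherits(spec, "grid_spec"))
  if (spot_radius <= 0) stop("spot_radius must be positive", call. = FALSE)
  f <- spec$refine
  sigma <- spot_radius * 1e-3
  props <- layer_properties_si(model)
  bounds <- model$boundaries * 1e-6          # m
  depth <- model$total_depth * 1e-6
  probe <- 2e-5

  # depth nodes: fine uniform region, then per-layer geometric grading
  dzf <- spec$dz_fine / f
  fd <- min(spec$fine_depth, depth)
  z <- seq(0, fd, by = dzf)
  anchors <- sort(unique(c(fd, bounds[bounds > fd], depth)))
  if (length(anchors) > 1) {
    for (s in seq_len(length(anchors) - 1)) {
      a <- anchors[s]; b <- anchors[s + 1]
      h0 <- min(max(dzf, (b - a) / 40), 2e-5) / f
      z <- c(z, graded_seq(a, b, h0, spec$z_growth, spec$dz_max / f))
    }
  }
  z <- sort(unique(round(c(z, bounds[bounds <= fd], probe), 12)))
  if (any(abs(z - probe) < 1e-12) == FALSE) {
    stop("internal error: probe depth not on the grid", call. = FALSE)
  }
  nz <- length(z)

  # every layer must be resolved by at least one interior node or both faces
  for (l in seq_len(nrow(props))) {
    n_in <- sum(z >= bounds[l] - 1e-12 & z <= bounds[l + 1] + 1e-12)
    if (n_in < 3) {
      stop("layer '", props$name[l], "' is thinner than the grid can resolve; ",
           "reduce dz_fine or dz_max", call. = FALSE)
    }
  }

  # radial nodes: uniform across the beam, graded to the lateral extent
  extent <- if (is.null(spec$r_extent)) max(5 * sigma, 1e-2) else spec$r_extent
  dr0 <- sigma / (spec$nr_spot * f)
  r <- seq(0, min(2.5 * sigma, extent), by = dr0)
  if (max(r) < extent) {
    r <- c(r, graded_seq(max(r), extent, sigma / (8 * f), spec$r_growth,
                         spec$dr_max / f))
  }
  r <- sort(unique(round(r, 12)))
  nr <- length(r)

  # control-volume geometry
  rf <- c(0, (r[-1] + r[-nr]) / 2, r[nr])
  zf <- c(0, (z[-1] + z[-nz]) / 2, z[nz])
  area_r <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2)  # annulus area per radial node
  dz_cv <- zf[-1] - zf[-(nz + 1)]              # control-volume height per z node

  # material arrays: z segments between nodes lie inside a single layer
  zm <- (z[-1] + z[-nz]) / 2
  seg_layer <- layer_index_at_depth(model, pmin(zm * 1e6, model$total_depth))
  k_seg <- props$k[seg_layer]
  rc_seg <- props$rho[seg_layer] * props$cp[seg_layer]
  # node-centred values, weighted over the two half segments of each cv
  w_lo <- c(0, z[-1] - zf[2:nz])               # upper half-cell height
  w_hi <- c(zf[2:nz] - z[-nz], 0)              # lower half-cell height
  rc_lo <- c(0, rc_seg); rc_hi <- c(rc_seg, 0)
  k_lo <- c(0, k_seg); k_hi <- c(k_seg, 0)
  rhocp_node <- (w_lo * rc_lo + w_hi * rc_hi) / (w_lo + w_hi)
  k_node <- (w_lo * k_lo + w_hi * k_hi) / (w_lo + w_hi)

  structure(
    list(r = r, z = z, rf = rf, zf = zf, area_r = area_r, dz_cv = dz_cv,
         seg_layer = seg_layer, k_seg = k_seg, rhocp_node = rhocp_node,
         k_node = k_node, probe_index = which(abs(z - probe) < 1e-12)[1],
         boundaries = bounds, spec = spec, spot_radius = spot_radius),
    class = "bioheat_grid"
  )
}

#' @export
print.bioheat_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric bioheat grid: %d radial x %d depth nodes\n",
              length(x$r), length(x$z)))
  cat(sprintf("  r: [0, %.3g] mm, dr in [%.3g, %.3g] um\n",
              max(x$r) * 1e3, min(diff(x$r)) * 1e6, max(diff(x$r)) * 1e6))
  cat(sprintf("  z: [0, %.3g] um, dz in [%.3g, %.3g] um\n",
              max(x$z) * 1e6, min(diff(x$z)) * 1e6, max(diff(x$z)) * 1e6))
  invisible(x)
}
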