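#' Optical properties of a turbid medium
#'
#' Bundles the four quantities that drive photon transport in tissue: the
#' absorption coefficient `mu_a` (1/cm), the reduced scattering coefficient
#' `mu_s_prime` (1/cm), the scattering anisotropy `g` (mean cosine of the
#' scattering angle) and the refractive index `n`. The full scattering
#' coefficient `mu_s = mu_s_prime / (1 - g)` is derived and stored alongside.
#'
#' Defaults are the murine-tumor values used throughout the package:
#' `mu_a = 0.69` /cm and `mu_s_prime = 11` /cm at 690 nm with `n = 1.4`.
#' Only the reduced scattering coefficient is usually measured; `g = 0.9` is
#' the conventional soft-tissue anisotropy, and results depend on `g` only
#' through `mu_s_prime` once the medium is diffusive (similarity relation).
#'
#' @param mu_a Absorption coefficient, 1/cm. Non-negative.
#' @param mu_s_prime Reduced scattering coefficient, 1/cm. Positive.
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return A one-row tibble of class `optical_properties` with columns
#'   `mu_a`, `mu_s_prime`, `g`, `n` and the derived `mu_s`.
#' @examples
#' optical_properties()
#' optical_properties(mu_a = 0.2, mu_s_prime = 15)
#' @export
optical_properties <- function(mu_a = 0.69, mu_s_prime = 11, g = 0.9,
                               n = 1.4) {
  if (any(mu_a < 0)) abort("`mu_a` must be >= 0")
  if (any(mu_s_prime <= 0)) abort("`mu_s_prime` must be > 0")
  if (any(abs(g) >= 1)) abort("`g` must satisfy |g| < 1")
  if (any(n < 1)) abort("`n` must be >= 1")
  out <- tibble::tibble(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g, n = n,
                        mu_s = mu_s_prime / (1 - g))
  class(out) <- c("optical_properties", class(out))
  out
}

#' Cubic voxel grid for transport and dose maps
#'
#' The target volume is an `nx` x `ny` x `nz` block of identical cubic
#' voxels of edge `voxel_cm`. Voxel `(i, j, k)` (1-based in R) spans the
#' half-open cube `[(i-1) h, i h) x ...`; the illuminated surface is the
#' `z = 0` face and `z` increases with depth; the beam axis passes through
#' the lateral centre of the grid.
#'
#' @param nx,ny,nz Voxel counts along x, y and z (depth).
#' @param voxel_cm Voxel edge length in cm (e.g. 0.05 for 0.5-mm voxels).
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(100, voxel_cm = 0.05)
#' @export
voxel_grid <- function(nx = 100, ny = nx, nz = nx, voxel_cm = 0.05) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 1)) abort("grid dimensions must be positive")
  if (voxel_cm <= 0) abort("`voxel_cm` must be > 0")
  structure(list(nx = nx, ny = ny, nz = nz, voxel_cm = voxel_cm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of (%.3g mm)^3, %g x %g x %g cm\n",
              x$nx, x$ny, x$nz, x$voxel_cm * 10,
              x$nx * x$voxel_cm, x$ny * x$voxel_cm, x$nz * x$voxel_cm))
  invisible(x)
}

#' Collimated disc source
#'
#' Uniform collimated beam in air, normal to the illuminated (`z = 0`)
#' face, centred on the grid axis. The optical power follows from the
#' in-air fluence rate times the disc area.
#'
#' @param fluence_rate Incident in-air fluence rate, mW/cm^2.
#' @param diameter_cm Beam diameter, cm (default 1.0 = the 10-mm disc).
#' @return An object of class `disc_source` with fields `fluence_rate`,
#'   `diameter_cm`, `area_cm2` and `power_W`.
#' @examples
#' disc_source(50)$power_W  # 0.03927 W for the 10-mm disc
#' @export
disc_source <- function(fluence_rate, diameter_cm = 1.0) {
  if (fluence_rate < 0) abort("`fluence_rate` must be >= 0")
  if (diameter_cm <= 0) abort("`diameter_cm` must be > 0")
  area <- pi * (diameter_cm / 2)^2
  structure(list(fluence_rate = fluence_rate, diameter_cm = diameter_cm,
                 area_cm2 = area, power_W = fluence_rate * area / 1000),
            class = "disc_source")
}

#' @export
print.disc_source <- function(x, ...) {
  cat(sprintf("<disc_source> %g mW/cm2 over a %g-mm disc (%.4f cm2, %.4g W)\n",
              x$fluence_rate, x$diameter_cm * 10, x$area_cm2, x$power_W))
  invisible(x)
}

#' Voxelized optical phantom
#'
#' Assigns one `optical_properties` record to every voxel of a grid:
#' a homogeneous background optionally overridden by simple regions.
#' Supported region shapes:
#'
#' * `phantom_layer(z_from_cm, z_to_cm, props)` - a slab of full lateral
#'   extent between two depths (half-open `[z_from, z_to)`).
#' * `phantom_sphere(center_cm, radius_cm, props)` - all voxels whose centre
#'   lies inside the sphere.
#'
#' Regions are painted in order, so later regions take priority where they
#' overlap. Region bounds must lie inside the grid.
#'
#' @param grid A [voxel_grid()].
#' @param background `optical_properties` for unassigned voxels.
#' @param regions List of region specs built with [phantom_layer()] /
#'   [phantom_sphere()].
#' @return An object of class `phantom`: the grid, a per-voxel property
#'   index array and the property table.
#' @examples
#' ph <- make_phantom(voxel_grid(20, voxel_cm = 0.05))
#' ph2 <- make_phantom(voxel_grid(20, voxel_cm = 0.05),
#'   regions = list(phantom_layer(0, 0.2, optical_properties(mu_a = 1.38))))
#' @export
make_phantom <- function(grid, background = optical_properties(),
                         regions = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  props <- as.data.frame(background)[, c("mu_a", "mu_s_prime", "g", "n",
                                         "mu_s")]
  idx <- array(1L, dim = c(grid$nx, grid$ny, grid$nz))
  h <- grid$voxel_cm
  if (length(regions)) {
    # voxel-centre coordinates
    cx <- (seq_len(grid$nx) - 0.5) * h
    cy <- (seq_len(grid$ny) - 0.5) * h
    cz <- (seq_len(grid$nz) - 0.5) * h
    for (rg in regions) {
      if (!inherits(rg, "phantom_region")) abort(
        "regions must be built with phantom_layer() or phantom_sphere()")
      props <- rbind(props, as.data.frame(rg$props)[, names(props)])
      pid <- nrow(props)
      if (rg$shape == "layer") {
        if (rg$z_from < 0 || rg$z_to > grid$nz * h)
          abort("layer bounds lie outside the grid")
        sel <- cz >= rg$z_from & cz < rg$z_to
        idx[, , sel] <- pid
      } else {
        if (any(rg$center < 0) ||
            any(rg$center > c(grid$nx, grid$ny, grid$nz) * h))
          abort("sphere centre lies outside the grid")
        r2 <- rg$radius^2
        for (i in seq_len(grid$nx)) {
          d2 <- (cx[i] - rg$center[1])^2 +
            outer((cy - rg$center[2])^2, (cz - rg$center[3])^2, "+")
          idx[i, , ][d2 <= r2] <- pid
        }
      }
    }
  }
  structure(list(grid = grid, property_index = idx,
                 properties = tibble::as_tibble(props)),
            class = "phantom")
}

#' @rdname make_phantom
#' @param z_from_cm,z_to_cm Depth bounds of a layer, cm.
#' @param props `optical_properties` of the region.
#' @export
phantom_layer <- function(z_from_cm, z_to_cm, props) {
  stopifnot(z_to_cm > z_from_cm)
  structure(list(shape = "layer", z_from = z_from_cm, z_to = z_to_cm,
                 props = props), class = "phantom_region")
}

#' @rdname make_phantom
#' @param center_cm Sphere centre, numeric length 3 (x, y, z) in cm.
#' @param radius_cm Sphere radius, cm.
#' @export
phantom_sphere <- function(center_cm, radius_cm, props) {
  stopifnot(length(center_cm) == 3, radius_cm > 0)
  structure(list(shape = "sphere", center = as.numeric(center_cm),
                 radius = radius_cm, props = props),
            class = "phantom_region")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d grid, %d property region(s)\n",
              x$grid$nx, x$grid$ny, x$grid$nz, nrow(x$properties)))
  print(x$properties)
  invisible(x)
}
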