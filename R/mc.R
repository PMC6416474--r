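#' Sample a photon free path
#'
#' Free propagation lengths between scattering events are exponentially
#' distributed with mean `1 / mu_s`; the inverse-CDF transform of a uniform
#' deviate `u` on (0, 1] gives `-log(u) / mu_s`.
#'
#' @param u Uniform deviates on (0, 1].
#' @param mu_s Scattering coefficient, 1/cm (> 0).
#' @return Path lengths in cm.
#' @examples
#' sample_free_path(exp(-1), mu_s = 110)  # one mean free path, 1/110 cm
#' @export
sample_free_path <- function(u, mu_s) {
  if (any(mu_s <= 0)) abort("`mu_s` must be > 0")
  if (any(u <= 0 | u > 1)) abort("`u` must lie in (0, 1]")
  -log(u) / mu_s
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel intensity reflectances for a
#' ray crossing an `n1 -> n2` interface at incidence cosine `cos_theta_i`.
#' Beyond the critical angle (when `n1 > n2`) the reflectance is 1.
#'
#' @param n1,n2 Refractive indices on the incident and transmitted side.
#' @param cos_theta_i Cosine of the angle of incidence, in \[0, 1\].
#' @return Reflectance in \[0, 1\], vectorized over the longest argument.
#' @examples
#' fresnel_unpolarized(1, 1.4, 1)        # normal incidence, (0.4/2.4)^2
#' fresnel_unpolarized(1.4, 1, cos(80 * pi / 180))  # total internal reflection
#' @export
fresnel_unpolarized <- function(n1, n2, cos_theta_i) {
  if (any(n1 < 1) || any(n2 < 1)) abort("refractive indices must be >= 1")
  if (any(cos_theta_i < 0 | cos_theta_i > 1))
    abort("`cos_theta_i` must lie in [0, 1]")
  as.numeric(cpp_fresnel_unpolarized(n1, n2, cos_theta_i))
}

#' Sample the Henyey-Greenstein phase function
#'
#' Draws scattering deflection cosines from the Henyey-Greenstein
#' distribution with anisotropy `g` by inverse-CDF sampling of uniform
#' deviates; `g = 0` reduces to isotropic scattering (`2 u - 1`). The
#' azimuthal angle (not returned) is uniform on \[0, 2 pi).
#'
#' @param g Anisotropy factor, |g| < 1.
#' @param u Uniform deviates on \[0, 1).
#' @return Deflection cosines in \[-1, 1\].
#' @examples
#' hg_sample(0, 0.75)    # isotropic: 0.5
#' mean(hg_sample(0.9, runif(1e5)))  # ~ 0.9: the mean cosine equals g
#' @export
hg_sample <- function(g, u) {
  if (abs(g) >= 1) abort("`g` must satisfy |g| < 1")
  if (any(u < 0 | u >= 1)) abort("`u` must lie in [0, 1)")
  as.numeric(cpp_hg_sample(g, u))
}

#' Run a voxel Monte Carlo fluence-rate simulation
#'
#' Launches `n_photons` photon packets from a collimated disc source in air
#' onto the `z = 0` face of the phantom and estimates the steady-state light
#' fluence rate in every voxel. Each packet starts with weight 1, loses the
#' specular Fresnel fraction at the air-tissue interface, then performs a
#' random walk: free paths drawn from the local scattering coefficient
#' (carried as dimensionless optical depth so a path crossing into a voxel
#' with different `mu_s` is rescaled), continuous absorption weighting
#' `exp(-mu_a l)` deposited in every traversed voxel, Henyey-Greenstein
#' redirection at scattering sites, and unpolarized Fresnel reflection
#' against air at all six exterior faces. Weight escaping through the
#' illuminated face is tallied as diffuse reflectance, weight escaping
#' elsewhere as transmittance.
#'
#' Packets falling below `weight_threshold` undergo Russian roulette by
#' default (survival probability 1/10, survivor weight x 10), which keeps
#' the deposition estimator unbiased; `roulette = FALSE` truncates instead.
#'
#' The per-voxel fluence rate uses the absorbed-weight estimator
#' `phi = A P / (mu_a V n_photons)` (mW/cm^2, with the source power P in
#' mW and voxel volume V in cm^3); voxels with `mu_a = 0` use the
#' track-length estimator `phi = sum(w l) P / (V n_photons)`, which is the
#' same quantity without the absorption intermediate.
#'
#' Randomness comes from a counter-based generator keyed on
#' `(seed, photon index)`, so a run is reproducible and independent of
#' execution order.
#'
#' @param phantom A [make_phantom()] object (or a [voxel_grid()], in which
#'   case default homogeneous optics are used).
#' @param source A [disc_source()].
#' @param n_photons Number of photon packets.
#' @param seed Integer seed for the photon streams.
#' @param weight_threshold Weight below which termination is considered.
#' @param roulette Use Russian roulette (`TRUE`, default) or truncation.
#' @return An object of class `fluence_map`: `values` (3-D array of
#'   fluence rate, mW/cm^2), `grid`, `source`, `n_photons`, `seed` and
#'   `energy_balance` (named fractions `specular`, `diffuse_reflected`,
#'   `transmitted`, `absorbed`, summing to 1).
#' @examples
#' ph <- make_phantom(voxel_grid(40, voxel_cm = 0.05))
#' fl <- run_mc(ph, disc_source(50), n_photons = 5000, seed = 1)
#' glance(fl)
#' @export
run_mc <- function(phantom, source, n_photons = 2e6, seed = 1,
                   weight_threshold = 1e-4, roulette = TRUE) {
  if (inherits(phantom, "voxel_grid")) phantom <- make_phantom(phantom)
  stopifnot(inherits(phantom, "phantom"), inherits(source, "disc_source"))
  if (n_photons < 1) abort("`n_photons` must be >= 1")
  if (weight_threshold <= 0 || weight_threshold >= 1)
    abort("`weight_threshold` must lie in (0, 1)")
  g <- phantom$grid
  if (n_photons < 1e4)
    warn("fewer than 1e4 photons: fluence estimates will be very noisy")
  props <- as.matrix(phantom$properties[, c("mu_a", "mu_s", "g", "n")])
  res <- cpp_run_mc(c(g$nx, g$ny, g$nz), g$voxel_cm,
                    as.integer(phantom$property_index) - 1L, props,
                    source$diameter_cm / 2, n_photons, seed,
                    weight_threshold, roulette)
  A <- array(res$absorbed, dim = c(g$nx, g$ny, g$nz))
  V <- g$voxel_cm^3
  P_mW <- source$power_W * 1000
  mu_a_vox <- array(props[as.integer(phantom$property_index), "mu_a"],
                    dim = dim(A))
  phi <- array(0, dim = dim(A))
  pos <- mu_a_vox > 0
  phi[pos] <- A[pos] * P_mW / (mu_a_vox[pos] * V * n_photons)
  phi[!pos] <- A[!pos] * P_mW / (V * n_photons)   # track-length estimator
  balance <- c(
    specular = res$specular,
    diffuse_reflected = res$diffuse,
    transmitted = res$transmitted,
    # roulette bookkeeping closes the ledger exactly: killed weight counts
    # as absorbed, injected survivor weight is subtracted back out
    absorbed = res$absorbed_deposited + res$roulette_killed -
      res$roulette_injected)
  structure(list(values = phi, grid = g, source = source,
                 phantom = phantom, n_photons = n_photons, seed = seed,
                 weight_threshold = weight_threshold, roulette = roulette,
                 energy_balance = balance),
            class = "fluence_map")
}

#' Rescale a fluence map to a different incident fluence rate
#'
#' Photon transport is linear in source power: the fluence rate per unit
#' incident power is a property of the geometry and optics alone. This
#' rescales an existing Monte Carlo result exactly to a new incident in-air
#' fluence rate, avoiding a second simulation when only the lamp setting
#' changes.
#'
#' @param map A `fluence_map`.
#' @param fluence_rate New incident in-air fluence rate, mW/cm^2.
#' @return A `fluence_map` with rescaled values and source.
#' @export
scale_source <- function(map, fluence_rate) {
  stopifnot(inherits(map, "fluence_map"))
  old <- map$source$fluence_rate
  if (old <= 0) abort("cannot rescale a zero-power source")
  map$values <- map$values * (fluence_rate / old)
  map$source <- disc_source(fluence_rate, map$source$diameter_cm)
  map
}

#' Diffuse reflectance of a simulated medium
#'
#' Fraction of launched photon weight that escaped back through the
#' illuminated (`z = 0`) face after subsurface scattering; the specular
#' component is excluded.
#'
#' @param map A `fluence_map` from [run_mc()].
#' @return Diffuse reflectance Rd (dimensionless).
#' @export
diffuse_reflectance <- function(map) {
  stopifnot(inherits(map, "fluence_map"))
  unname(map$energy_balance["diffuse_reflected"])
}

# central lateral indices: the 2 x 2 (even count) or single (odd) voxel
# column(s) straddling the beam axis
center_indices <- function(n) {
  if (n %% 2 == 0) c(n %/% 2, n %/% 2 + 1) else (n + 1) %/% 2
}

#' Centre-axis depth profile of a fluence map
#'
#' Extracts the axial voxel column at the beam centre (averaging the
#' 2 x 2 central columns when the lateral voxel count is even, since the
#' beam axis then passes through a voxel corner) and reports depth at voxel
#' centres together with the ratio of in-tissue fluence rate to the
#' incident in-air fluence rate.
#'
#' @param map A `fluence_map`.
#' @return A tibble with columns `depth_cm`, `phi` (mW/cm^2) and `ratio`.
#' @export
centerline_profile <- function(map) {
  stopifnot(inherits(map, "fluence_map"))
  g <- map$grid
  ci <- center_indices(g$nx)
  cj <- center_indices(g$ny)
  phi <- apply(map$values[ci, cj, , drop = FALSE], 3, mean)
  tibble::tibble(
    depth_cm = (seq_len(g$nz) - 0.5) * g$voxel_cm,
    phi = phi,
    ratio = if (map$source$fluence_rate > 0)
      phi / map$source$fluence_rate else NA_real_)
}

#' Trace a single photon packet
#'
#' Replays photon `photon_id` of the stream keyed by `seed` through the
#' phantom and returns its per-voxel deposition record. Mainly a
#' reproducibility and debugging aid: the same `(seed, photon_id)` always
#' yields the identical trajectory.
#'
#' @inheritParams run_mc
#' @param photon_id Index of the photon within the stream (0-based).
#' @return A tibble with one row per traversed voxel sub-path: voxel
#'   indices `i`, `j`, `k` (1-based) and the `deposit`ed weight; the exit
#'   record is in attributes `specular`, `diffuse`, `transmitted`.
#' @export
trace_photon <- function(phantom, source, seed = 1, photon_id = 0,
                         weight_threshold = 1e-4, roulette = TRUE) {
  if (inherits(phantom, "voxel_grid")) phantom <- make_phantom(phantom)
  g <- phantom$grid
  props <- as.matrix(phantom$properties[, c("mu_a", "mu_s", "g", "n")])
  res <- cpp_trace_photon(c(g$nx, g$ny, g$nz), g$voxel_cm,
                          as.integer(phantom$property_index) - 1L, props,
                          source$diameter_cm / 2, seed, photon_id,
                          weight_threshold, roulette)
  v0 <- res$voxel - 1L
  out <- tibble::tibble(
    i = v0 %% g$nx + 1L,
    j = (v0 %/% g$nx) %% g$ny + 1L,
    k = v0 %/% (g$nx * g$ny) + 1L,
    deposit = res$deposit)
  attr(out, "specular") <- res$specular
  attr(out, "diffuse") <- res$diffuse
  attr(out, "transmitted") <- res$transmitted
  out
}

#' @export
print.fluence_map <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<fluence_map> %d x %d x %d @ %.3g mm | %s photons | peak %.4g mW/cm2\n",
    g$nx, g$ny, g$nz, g$voxel_cm * 10,
    format(x$n_photons, big.mark = ","), max(x$values)))
  eb <- x$energy_balance
  cat(sprintf("  energy balance: specular %.4f, diffuse %.4f, transmitted %.4f, absorbed %.4f\n",
              eb["specular"], eb["diffuse_reflected"], eb["transmitted"],
              eb["absorbed"]))
  invisible(x)
}

#' @rdname run_mc
#' @param x A `fluence_map`.
#' @param ... Unused.
#' @export
glance.fluence_map <- function(x, ...) {
  eb <- x$energy_balance
  tibble::tibble(
    n_photons = x$n_photons, seed = x$seed,
    peak_phi = max(x$values),
    peak_ratio = if (x$source$fluence_rate > 0)
      max(x$values) / x$source$fluence_rate else NA_real_,
    specular = unname(eb["specular"]),
    diffuse_reflectance = unname(eb["diffuse_reflected"]),
    transmitted = unname(eb["transmitted"]),
    absorbed = unname(eb["absorbed"]))
}

#' @rdname run_mc
#' @export
tidy.fluence_map <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    i = rep(seq_len(g$nx), times = g$ny * g$nz),
    j = rep(rep(seq_len(g$ny), each = g$nx), times = g$nz),
    k = rep(seq_len(g$nz), each = g$nx * g$ny),
    depth_cm = (rep(seq_len(g$nz), each = g$nx * g$ny) - 0.5) * g$voxel_cm,
    phi = as.numeric(x$values))
}

#' @rdname run_mc
#' @param object A `fluence_map`.
#' @export
autoplot.fluence_map <- function(object, ...) {
  g <- object$grid
  ci <- center_indices(g$nx)[1]
  slice <- object$values[ci, , ]
  df <- tibble::tibble(
    y_cm = rep((seq_len(g$ny) - 0.5) * g$voxel_cm, times = g$nz),
    z_cm = rep((seq_len(g$nz) - 0.5) * g$voxel_cm, each = g$ny),
    phi = as.numeric(slice))
  ggplot2::ggplot(df, ggplot2::aes(.data$y_cm, .data$z_cm,
                                   fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "phi (mW/cm2)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (cm)", y = "depth z (cm)",
                  title = "Fluence rate, central YZ slice")
}
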