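#' Photokinetic parameters of a photosensitizer
#'
#' Constants of the macroscopic type II PDT rate equations. The defaults
#' are the published benzoporphyrin derivative (BPD, Visudyne) values:
#' `g = 1.7` uM/s (maximum oxygen supply rate), `delta = 33` uM
#' (low-concentration correction), `beta = 11.9` uM (oxygen quenching
#' threshold), `sigma = 1.8e-5` 1/uM (specific photobleaching ratio) and
#' `xi = 0.055` cm^2 mW^-1 s^-1 (oxygen consumption / excitation rate
#' proportionality). `O2_initial = 40` uM is the assumed initial
#' ground-state oxygen concentration.
#'
#' @param g Oxygen supply rate, uM/s.
#' @param delta Low-concentration correction, uM.
#' @param beta Oxygen quenching threshold, uM.
#' @param sigma Specific photobleaching ratio, 1/uM.
#' @param xi Excitation rate proportionality, cm^2 mW^-1 s^-1.
#' @param O2_initial Initial ground-state oxygen concentration, uM.
#' @return A list of class `pk_params`.
#' @examples
#' pk_params()
#' @export
pk_params <- function(g = 1.7, delta = 33, beta = 11.9, sigma = 1.8e-5,
                      xi = 0.055, O2_initial = 40) {
  vals <- list(g = g, delta = delta, beta = beta, sigma = sigma, xi = xi,
               O2_initial = O2_initial)
  if (any(unlist(vals) <= 0)) abort("all photokinetic parameters must be > 0")
  structure(vals, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> g=%g uM/s, delta=%g uM, beta=%g uM, sigma=%g /uM, xi=%g cm2/mW/s, O2(0)=%g uM\n",
    x$g, x$delta, x$beta, x$sigma, x$xi, x$O2_initial))
  invisible(x)
}

#' Right-hand side of the photokinetic rate equations
#'
#' Instantaneous rates of change of the photokinetic state under fluence
#' rate `phi`:
#' \deqn{d[S_0]/dt = -\xi\sigma\phi([S_0]+\delta)\frac{[O_2]}{[O_2]+\beta}[S_0]}
#' \deqn{d[O_2]/dt = -\xi\phi[S_0]\frac{[O_2]}{[O_2]+\beta} + g(1-[O_2]/[O_2]_0)}
#' \deqn{d[O_2]_{rx}/dt = \xi\phi[S_0]\frac{[O_2]}{[O_2]+\beta}}
#'
#' @param state Named numeric: `S0`, `O2`, `O2rx` (uM), all >= 0.
#' @param phi Fluence rate, mW/cm^2 (>= 0).
#' @param params A [pk_params()] object.
#' @return Named numeric vector of derivatives (uM/s).
#' @examples
#' pk_rhs(c(S0 = 0.53, O2 = 40, O2rx = 0), phi = 168, pk_params())
#' @export
pk_rhs <- function(state, phi, params = pk_params()) {
  stopifnot(inherits(params, "pk_params"))
  s <- as.list(state)
  if (any(unlist(s[c("S0", "O2", "O2rx")]) < 0) || phi < 0)
    abort("state components and `phi` must be non-negative")
  frac <- s$O2 / (s$O2 + params$beta)
  rx <- params$xi * phi * s$S0 * frac
  c(S0 = -params$xi * params$sigma * phi * (s$S0 + params$delta) * frac * s$S0,
    O2 = -rx + params$g * (1 - s$O2 / params$O2_initial),
    O2rx = rx)
}

#' Integrate the photokinetic equations for one voxel
#'
#' Solves the initial-value problem for `(S0, O2, O2rx)` under a
#' time-constant fluence rate with an embedded Dormand-Prince RK5(4) pair.
#' Any trial step whose solution would cross zero is rejected and halved,
#' so all components remain non-negative at every accepted step;
#' magnitudes below 1e-12 uM are clamped to zero. The fluence rate is held
#' constant over the treatment because a single transport solution is
#' applied to the whole session (optical properties are assumed unaffected
#' by photobleaching).
#'
#' @param phi Fluence rate at the voxel, mW/cm^2.
#' @param S0_init Initial photosensitizer concentration, uM.
#' @param params A [pk_params()].
#' @param T_s Treatment time, s.
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param h0 Initial step size, s.
#' @param trajectory If `TRUE`, record the state at every accepted step.
#' @return A list of class `pk_state` with final `S0`, `O2`, `O2rx` (uM)
#'   and, when requested, a `trajectory` tibble (`time_s`, `S0`, `O2`,
#'   `O2rx`).
#' @examples
#' st <- integrate_pk(phi = 168, S0_init = 0.53, T_s = 600)
#' st$O2rx  # reacted singlet oxygen after 600 s, uM
#' @export
integrate_pk <- function(phi, S0_init, params = pk_params(), T_s,
                         rtol = 1e-6, atol = 1e-9, h0 = 1e-3,
                         trajectory = FALSE) {
  stopifnot(inherits(params, "pk_params"))
  if (T_s < 0) abort("`T_s` must be >= 0")
  if (S0_init < 0 || phi < 0) abort("`S0_init` and `phi` must be >= 0")
  res <- cpp_integrate_pk(phi, S0_init, unclass(params), T_s, rtol, atol,
                          h0, trajectory)
  if (res$status != 0)
    abort("photokinetic integration failed: step size underflow")
  out <- list(S0 = res$S0, O2 = res$O2, O2rx = res$O2rx, phi = phi,
              S0_init = S0_init, T_s = T_s, params = params)
  if (trajectory) {
    out$trajectory <- tibble::tibble(
      time_s = res$times, S0 = res$states[, 1], O2 = res$states[, 2],
      O2rx = res$states[, 3])
  }
  structure(out, class = "pk_state")
}

#' @export
print.pk_state <- function(x, ...) {
  cat(sprintf(
    "<pk_state> t=%g s @ phi=%g mW/cm2: S0 %.4g uM, O2 %.4g uM, O2rx %.4g uM\n",
    x$T_s, x$phi, x$S0, x$O2, x$O2rx))
  invisible(x)
}

#' @rdname integrate_pk
#' @param x,object A `pk_state`.
#' @param ... Unused.
#' @export
tidy.pk_state <- function(x, ...) {
  if (is.null(x$trajectory))
    abort("no trajectory recorded; rerun integrate_pk(trajectory = TRUE)")
  tidyr::pivot_longer(x$trajectory, c("S0", "O2", "O2rx"),
                      names_to = "species", values_to = "conc_uM")
}

#' @rdname integrate_pk
#' @export
autoplot.pk_state <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$time_s, .data$conc_uM,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (uM)")
}

#' Reacted singlet oxygen dose map
#'
#' Integrates the photokinetic equations independently in every voxel of a
#' fluence map (each voxel sees its own time-constant fluence rate) and
#' returns the cumulative reacted singlet oxygen concentration after the
#' treatment time. Voxels with zero fluence contribute zero dose. Because
#' voxels are independent, any execution order gives identical results.
#'
#' For large treatments where only the beam-axis dose is needed,
#' `voxels = "center"` restricts the integration to the central axial
#' column(s), which is all that [dose_at_depth()] and
#' [dose_depth_profile()] consume.
#'
#' @param fluence A `fluence_map` from [run_mc()].
#' @param S0_init Initial photosensitizer concentration, uM: a scalar
#'   (uniform) or an array matching the grid.
#' @param params A [pk_params()].
#' @param T_s Treatment time, s.
#' @param rtol,atol,h0 Solver controls, as in [integrate_pk()].
#' @param voxels `"all"` (default) for the full map or `"center"` for the
#'   beam-axis column only.
#' @return An object of class `dose_map`: `values` is a 3-D array of
#'   reacted singlet oxygen in mM (`NA` outside the integrated region when
#'   `voxels = "center"`), plus the grid, parameters and treatment time.
#' @examples
#' ph <- make_phantom(voxel_grid(30, voxel_cm = 0.05))
#' fl <- run_mc(ph, disc_source(50), n_photons = 2e4, seed = 7)
#' dm <- dose_map(fl, S0_init = 0.53, T_s = 600, voxels = "center")
#' dose_at_depth(dm, 0.3)
#' @export
dose_map <- function(fluence, S0_init, params = pk_params(), T_s,
                     rtol = 1e-6, atol = 1e-9, h0 = 1e-3,
                     voxels = c("all", "center")) {
  stopifnot(inherits(fluence, "fluence_map"))
  voxels <- match.arg(voxels)
  if (T_s < 0) abort("`T_s` must be >= 0")
  g <- fluence$grid
  dims <- c(g$nx, g$ny, g$nz)
  uniform_s0 <- length(S0_init) == 1
  if (!uniform_s0 && !identical(dim(S0_init), dims))
    abort("per-voxel `S0_init` must match the grid dimensions")
  if (any(S0_init < 0)) abort("`S0_init` must be >= 0")
  if (voxels == "all") {
    dose_uM <- cpp_dose_vec(as.numeric(fluence$values),
                            as.numeric(S0_init), unclass(params), T_s,
                            rtol, atol, h0)
    values <- array(dose_uM / 1000, dim = dims)
  } else {
    ci <- center_indices(g$nx)
    cj <- center_indices(g$ny)
    values <- array(NA_real_, dim = dims)
    phi_col <- fluence$values[ci, cj, , drop = FALSE]
    s0_col <- if (uniform_s0) S0_init else
      as.numeric(S0_init[ci, cj, , drop = FALSE])
    dose_uM <- cpp_dose_vec(as.numeric(phi_col), s0_col, unclass(params),
                            T_s, rtol, atol, h0)
    values[ci, cj, ] <- dose_uM / 1000
  }
  structure(list(values = values, grid = g, treatment_time_s = T_s,
                 params = params, S0_init = S0_init,
                 source = fluence$source, voxels = voxels),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<dose_map> %d x %d x %d @ %.3g mm | T = %g s | max [1O2]rx %.4g mM\n",
    g$nx, g$ny, g$nz, g$voxel_cm * 10, x$treatment_time_s,
    max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Singlet oxygen dose at a given depth on the beam axis
#'
#' The dose "at depth d" is defined on voxel-layer interfaces: the mean of
#' the two beam-axis voxel values adjacent to the depth plane (for 3 mm:
#' layers 3 and 4 of a 1-mm grid, 6 and 7 of a 0.5-mm grid, 12 and 13 of a
#' 0.25-mm grid). Lateral "beam axis" values average the 2 x 2 central
#' columns when the lateral voxel count is even.
#'
#' @param map A `dose_map`.
#' @param depth_cm Depth of the interface, cm; must coincide with a voxel
#'   boundary strictly inside the grid.
#' @return Dose in mM.
#' @export
dose_at_depth <- function(map, depth_cm = 0.3) {
  stopifnot(inherits(map, "dose_map"))
  g <- map$grid
  h <- g$voxel_cm
  layer <- depth_cm / h
  if (depth_cm <= 0 || depth_cm >= g$nz * h)
    abort("`depth_cm` lies outside the grid")
  if (abs(layer - round(layer)) > 1e-9)
    abort("`depth_cm` must fall on a voxel-layer interface")
  layer <- as.integer(round(layer))
  ci <- center_indices(g$nx)
  cj <- center_indices(g$ny)
  mean(map$values[ci, cj, c(layer, layer + 1L)])
}

#' Centre-axis dose-depth profile
#'
#' @param map A `dose_map`.
#' @return A tibble with `depth_cm` (voxel centres) and `dose_mM`.
#' @export
dose_depth_profile <- function(map) {
  stopifnot(inherits(map, "dose_map"))
  g <- map$grid
  ci <- center_indices(g$nx)
  cj <- center_indices(g$ny)
  tibble::tibble(
    depth_cm = (seq_len(g$nz) - 0.5) * g$voxel_cm,
    dose_mM = apply(map$values[ci, cj, , drop = FALSE], 3, mean))
}

#' @rdname dose_map
#' @param x,object A `dose_map`.
#' @param ... Unused.
#' @export
glance.dose_map <- function(x, ...) {
  tibble::tibble(
    treatment_time_s = x$treatment_time_s,
    max_dose_mM = max(x$values, na.rm = TRUE),
    dose_3mm_mM = tryCatch(dose_at_depth(x, 0.3), error = function(e) NA_real_))
}

#' @rdname dose_map
#' @export
autoplot.dose_map <- function(object, ...) {
  prof <- dose_depth_profile(object)
  ggplot2::ggplot(prof, ggplot2::aes(.data$depth_cm, .data$dose_mM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (cm)", y = "[1O2]rx (mM)",
                  title = "Singlet oxygen dose on the beam axis")
}

#' Fixed-step classical RK4 reference integration
#'
#' Brute-force reference solver for the photokinetic equations: classical
#' fourth-order Runge-Kutta with a constant step. Orders of magnitude
#' slower than [integrate_pk()]; used to validate the adaptive solver.
#'
#' @inheritParams integrate_pk
#' @param dt Fixed step size, s.
#' @return Named numeric: final `S0`, `O2`, `O2rx` (uM).
#' @export
integrate_pk_rk4 <- function(phi, S0_init, params = pk_params(), T_s,
                             dt = 1e-3) {
  p <- params
  deriv <- function(y) {
    frac <- y[2] / (y[2] + p$beta)
    rx <- p$xi * phi * y[1] * frac
    c(-p$xi * p$sigma * phi * (y[1] + p$delta) * frac * y[1],
      -rx + p$g * (1 - y[2] / p$O2_initial),
      rx)
  }
  y <- c(S0_init, p$O2_initial, 0)
  n <- ceiling(T_s / dt)
  dt <- T_s / n
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c(S0 = y[1], O2 = y[2], O2rx = y[3])
}
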