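#' Parameters of the 1-D analytic fluence-ratio model
#'
#' The centre-beam depth profile of the fluence-rate ratio phi/phi_air in a
#' broad-beam geometry is well approximated by a buildup term times a
#' two-exponential decay,
#' \deqn{\phi/\phi_{air}(d) = (1 - b e^{-\lambda_1 d})
#'       (C_2 e^{-\lambda_2 d} + C_3 e^{-\lambda_3 d}),}
#' whose six coefficients are functions of the optical properties, the
#' effective attenuation coefficient and the diffuse reflectance Rd.
#'
#' @param lambda1,lambda2,lambda3 Attenuation constants, 1/cm (> 0).
#' @param b,C2,C3 Dimensionless amplitudes.
#' @param Rd Diffuse reflectance anchor (optional, informational).
#' @param mu_eff Effective attenuation coefficient, 1/cm (optional).
#' @return One-row tibble of class `eq5_params`.
#' @export
eq5_params <- function(lambda1, lambda2, lambda3, b, C2, C3, Rd = NA_real_,
                       mu_eff = NA_real_) {
  if (any(c(lambda1, lambda2, lambda3) <= 0))
    abort("attenuation constants must be > 0")
  if (!is.na(Rd) && (Rd < 0 || Rd >= 1)) abort("`Rd` must lie in [0, 1)")
  out <- tibble::tibble(lambda1 = lambda1, lambda2 = lambda2,
                        lambda3 = lambda3, b = b, C2 = C2, C3 = C3,
                        Rd = Rd, mu_eff = mu_eff)
  class(out) <- c("eq5_params", class(out))
  out
}

#' Evaluate the analytic fluence-ratio model
#'
#' @param d Depths, cm (>= 0).
#' @param params An [eq5_params()] row.
#' @return phi/phi_air at each depth.
#' @examples
#' p <- eq5_params(8, 5, 1, b = 0.6, C2 = 4, C3 = 0.3)
#' eq5_ratio(c(0, 0.1, 1), p)
#' @export
eq5_ratio <- function(d, params) {
  stopifnot(inherits(params, "eq5_params"))
  if (any(d < 0)) abort("`d` must be >= 0")
  (1 - params$b * exp(-params$lambda1 * d)) *
    (params$C2 * exp(-params$lambda2 * d) + params$C3 * exp(-params$lambda3 * d))
}

#' Fit the analytic model to a Monte Carlo centreline profile
#'
#' Levenberg-Marquardt least-squares fit of the six-parameter
#' buildup-times-two-exponential model to a `(depth, ratio)` profile.
#' Residuals are weighted by `1/ratio` by default ("relative" weighting):
#' Monte Carlo profile noise is approximately multiplicative, and relative
#' weighting is what identifies the near-surface buildup constant.
#' Six-term exponential mixtures are ill-conditioned, so the fit is
#' multi-started from several data-driven initializations (tail log-slope
#' for the decay constants, surface values for the amplitudes) and the
#' lowest-residual convergent fit is returned.
#'
#' @param profile Data frame with columns `depth_cm` and `ratio` (e.g.
#'   from [centerline_profile()]); at least 12 points spanning several
#'   attenuation lengths.
#' @param n_starts Number of random restarts around the base start.
#' @param seed Seed for the restart jitter.
#' @param weighting `"relative"` (default, residuals scaled by the
#'   observed ratio) or `"absolute"`.
#' @return Object of class `eq5_fit`: `params` ([eq5_params()] row),
#'   unweighted `rms` residual, `profile`, and the underlying
#'   [minpack.lm::nls.lm()] object.
#' @examples
#' p <- eq5_params(8, 5, 1, b = 0.6, C2 = 4, C3 = 0.3)
#' prof <- tibble::tibble(depth_cm = seq(0.02, 2, by = 0.04),
#'                        ratio = eq5_ratio(depth_cm, p))
#' fit <- fit_eq5(prof)
#' glance(fit)
#' @export
fit_eq5 <- function(profile, n_starts = 3, seed = 1,
                    weighting = c("relative", "absolute")) {
  profile <- tibble::as_tibble(profile)
  weighting <- match.arg(weighting)
  if (!all(c("depth_cm", "ratio") %in% names(profile)))
    abort("`profile` needs columns `depth_cm` and `ratio`")
  profile <- dplyr::filter(profile, is.finite(.data$ratio))
  if (nrow(profile) < 12) abort("need at least 12 profile points")

  d <- profile$depth_cm
  y <- profile$ratio
  w <- if (weighting == "relative") 1 / pmax(abs(y), 1e-6) else rep(1, length(y))
  predict_eq5 <- function(p) {
    (1 - p[["b"]] * exp(-p[["l1"]] * d)) *
      (p[["c2"]] * exp(-p[["l2"]] * d) + p[["c3"]] * exp(-p[["l3"]] * d))
  }

  # data-driven starting values: deep tail log-slope ~ the slow decay
  tail_n <- max(5L, nrow(profile) %/% 3L)
  tl <- utils::tail(dplyr::filter(profile, .data$ratio > 0), tail_n)
  slope <- -coef(lm(log(ratio) ~ depth_cm, data = tl))[["depth_cm"]]
  if (!is.finite(slope) || slope <= 0) slope <- 1
  peak <- max(y)
  base <- c(l1 = 4 * slope, l2 = 2 * slope, l3 = slope,
            b = 0.3, c2 = peak, c3 = 0.3 * peak)

  jitter_rng <- withr_seed_runif(seed, n_starts * 6)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fac <- exp(0.5 * (jitter_rng[(s - 1) * 6 + 1:6] - 0.5))
    start <- base * if (s == 1) 1 else fac
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = function(p) w * (y - predict_eq5(p)),
        lower = c(1e-3, 1e-3, 1e-3, -5, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      obj <- sum(fit$fvec^2)
      if (is.null(best) || obj < best$obj) best <- list(fit = fit, obj = obj)
    }
  }
  if (is.null(best))
    abort("analytic-model fit failed to converge from any start")
  cf <- best$fit$par
  # order the two decay terms so lambda2 >= lambda3 (fast term first)
  if (cf[["l2"]] < cf[["l3"]]) {
    cf[c("l2", "l3")] <- cf[c("l3", "l2")]
    cf[c("c2", "c3")] <- cf[c("c3", "c2")]
  }
  structure(list(
    params = eq5_params(cf[["l1"]], cf[["l2"]], cf[["l3"]], cf[["b"]],
                        cf[["c2"]], cf[["c3"]]),
    rms = sqrt(mean((y - predict_eq5(best$fit$par))^2)),
    profile = profile, fit = best$fit),
    class = "eq5_fit")
}

# deterministic uniform deviates without touching the global RNG stream
withr_seed_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

#' @export
print.eq5_fit <- function(x, ...) {
  cat("<eq5_fit>\n")
  print(x$params)
  cat(sprintf("  RMS residual: %.4g (%.2f%% of peak ratio)\n", x$rms,
              100 * x$rms / max(x$profile$ratio)))
  invisible(x)
}

#' @rdname fit_eq5
#' @param x,object An `eq5_fit`.
#' @param ... Unused.
#' @export
tidy.eq5_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda1", "lambda2", "lambda3", "b", "C2", "C3"),
    estimate = as.numeric(x$params[1, c("lambda1", "lambda2", "lambda3",
                                        "b", "C2", "C3")]))
}

#' @rdname fit_eq5
#' @export
glance.eq5_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, rms_frac_of_peak = x$rms / max(x$profile$ratio),
                 n = nrow(x$profile))
}

#' @rdname fit_eq5
#' @export
augment.eq5_fit <- function(x, ...) {
  dplyr::mutate(x$profile,
                fitted = eq5_ratio(.data$depth_cm, x$params),
                resid = .data$ratio - .data$fitted)
}

#' @rdname fit_eq5
#' @export
autoplot.eq5_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$depth_cm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ratio), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "depth (cm)", y = "phi / phi_air",
                  title = "Analytic fit to the MC centreline profile")
}
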