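#' Ellipsoidal tumor volume from two caliper diameters
#'
#' `V = pi a^2 b / 6`, with `a` the width-axis and `b` the length-axis
#' diameter.
#'
#' @param a,b Diameters, mm (>= 0).
#' @return Volume, mm^3.
#' @examples
#' tumor_volume(3, 5)
#' @export
tumor_volume <- function(a, b) {
  if (any(a < 0) || any(b < 0)) abort("diameters must be >= 0")
  pi * a^2 * b / 6
}

#' Fit an exponential tumor regrowth rate
#'
#' Tumor volumes over the 14-day follow-up are modelled as
#' `V(t) = V0 exp(k t)`; `k` is estimated by the least-squares slope of
#' `log(V)` against day. Zero (or negative) volumes - regression below the
#' measurement floor in cured animals - cannot enter a log fit and are
#' dropped; if fewer than 3 positive-volume points remain the tumor is
#' treated as cured and `k = 0` is reported.
#'
#' @param measurements Data frame with a `day` column and either
#'   `volume_mm3` or the caliper diameters `a_mm` and `b_mm` (converted
#'   via [tumor_volume()]).
#' @return Object of class `regrowth_fit`: `k` (clamped at 0), `k_raw`
#'   (the unclamped slope), `n_used`, and the `lm` fit (NULL when cured).
#' @examples
#' m <- tibble::tibble(day = 0:14, volume_mm3 = 20 * exp(0.4 * (0:14)))
#' fit_regrowth(m)$k  # 0.4
#' @export
fit_regrowth <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  if (!"volume_mm3" %in% names(m)) {
    if (!all(c("a_mm", "b_mm") %in% names(m)))
      abort("need `volume_mm3` or both `a_mm` and `b_mm`")
    m$volume_mm3 <- tumor_volume(m$a_mm, m$b_mm)
  }
  if (!"day" %in% names(m)) abort("need a `day` column")
  if (nrow(m) < 3) abort("need at least 3 time points")
  pos <- dplyr::filter(m, .data$volume_mm3 > 0)
  if (nrow(pos) < 3) {
    return(structure(list(k = 0, k_raw = NA_real_, n_used = nrow(pos),
                          fit = NULL, cured = TRUE),
                     class = "regrowth_fit"))
  }
  fit <- lm(log(volume_mm3) ~ day, data = pos)
  k_raw <- unname(coef(fit)[["day"]])
  structure(list(k = max(k_raw, 0), k_raw = k_raw, n_used = nrow(pos),
                 fit = fit, cured = FALSE),
            class = "regrowth_fit")
}

#' @export
print.regrowth_fit <- function(x, ...) {
  cat(sprintf("<regrowth_fit> k = %.4g /day (raw %.4g, %d points%s)\n",
              x$k, x$k_raw, x$n_used, if (x$cured) ", cured" else ""))
  invisible(x)
}

#' @rdname fit_regrowth
#' @param x A `regrowth_fit`.
#' @param ... Unused.
#' @export
glance.regrowth_fit <- function(x, ...) {
  tibble::tibble(k = x$k, k_raw = x$k_raw, n_used = x$n_used,
                 cured = x$cured)
}

#' Cure index from regrowth rates
#'
#' `CI = 1 - k / k_ctr`: 1 means no regrowth over the follow-up window
#' (cure), 0 means regrowth at the untreated-control rate.
#'
#' @param k Treated-group regrowth rate, 1/days (>= 0).
#' @param k_ctr Control-group regrowth rate, 1/days (> 0).
#' @return Cure index (dimensionless), vectorized over `k`.
#' @examples
#' cure_index(0.40, 0.41)
#' @export
cure_index <- function(k, k_ctr) {
  if (any(k_ctr <= 0)) abort("`k_ctr` must be > 0")
  if (any(k < 0)) abort("`k` must be >= 0")
  1 - k / k_ctr
}

#' Logistic dose-response parameters
#'
#' Three-parameter logistic `CI(D) = A / (1 + B exp(-c D))` linking cure
#' index to singlet oxygen dose at 3 mm. Defaults are the published
#' BPD/mouse fit: plateau `A = 1.08`, scale `B = 3490`, rate
#' `c = 8.301` per mM.
#'
#' @param A Plateau (> 0).
#' @param B Scale (> 0).
#' @param c Rate per mM of dose (> 0).
#' @return One-row tibble of class `dose_response_params`.
#' @export
dose_response_params <- function(A = 1.08, B = 3490, c = 8.301) {
  if (any(c(A, B, c) <= 0)) abort("A, B and c must all be > 0")
  out <- tibble::tibble(A = A, B = B, c = c)
  class(out) <- c("dose_response_params", class(out))
  out
}

#' Predicted cure index from singlet oxygen dose
#'
#' @param dose Reacted singlet oxygen dose at 3 mm, mM (>= 0).
#' @param params A [dose_response_params()] row.
#' @return Predicted cure index, vectorized.
#' @examples
#' logistic_ci(1.3)  # above 1: the ~1.3 mM cure threshold
#' @export
logistic_ci <- function(dose, params = dose_response_params()) {
  stopifnot(inherits(params, "dose_response_params"))
  if (any(dose < 0)) abort("`dose` must be >= 0")
  params$A / (1 + params$B * exp(-params$c * dose))
}

#' Fit the logistic dose-response to observed (dose, CI) records
#'
#' Unweighted least-squares fit of the three-parameter logistic to group
#' records of any dose metric against cure index, via multi-started
#' Levenberg-Marquardt. Comparing the residual of a fit against reacted
#' singlet oxygen with that against incident in-air fluence quantifies
#' which metric better predicts outcome.
#'
#' @param records Data frame with columns `dose` (any dose metric) and
#'   `ci`; at least 6 records.
#' @param n_starts Random restarts around data-driven starting values.
#' @param seed Seed for restart jitter.
#' @return Object of class `logistic_fit`: `params`
#'   ([dose_response_params()] row), `rms`, `records`, `fit`.
#' @examples
#' d <- bpd_mouse_groups()
#' f <- correlate_outcomes(data.frame(dose = d$dose_0.50mm_mM, ci = d$ci))
#' glance(f)
#' @export
correlate_outcomes <- function(records, n_starts = 5, seed = 1) {
  r <- tibble::as_tibble(records)
  if (!all(c("dose", "ci") %in% names(r)))
    abort("`records` needs columns `dose` and `ci`")
  r <- dplyr::filter(r, is.finite(.data$dose), is.finite(.data$ci))
  if (nrow(r) < 6) abort("need at least 6 records")
  # starting values: plateau near max CI, rate from the dose scale
  sc <- stats::median(r$dose)
  base <- c(A = max(r$ci) * 1.05 + 1e-3, B = 100, c = 4 / sc)
  model <- ci ~ A / (1 + B * exp(-c * dose))
  jit <- withr_seed_runif(seed, n_starts * 3)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fac <- exp(2 * (jit[(s - 1) * 3 + 1:3] - 0.5))
    start <- as.list(base * if (s == 1) 1 else fac)
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = r, start = start,
                        lower = c(1e-6, 1e-6, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rms <- sqrt(mean(resid(fit)^2))
      if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
    }
  }
  if (is.null(best)) abort("logistic dose-response fit failed to converge")
  cf <- coef(best$fit)
  structure(list(params = dose_response_params(cf[["A"]], cf[["B"]],
                                               cf[["c"]]),
                 rms = best$rms, records = r, fit = best$fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> CI = %.4g / (1 + %.4g exp(-%.4g D)), RMS %.4g\n",
              x$params$A, x$params$B, x$params$c, x$rms))
  invisible(x)
}

#' @rdname correlate_outcomes
#' @param x,object A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "c"),
                 estimate = c(x$params$A, x$params$B, x$params$c))
}

#' @rdname correlate_outcomes
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, n = nrow(x$records))
}

#' @rdname correlate_outcomes
#' @export
augment.logistic_fit <- function(x, ...) {
  dplyr::mutate(x$records,
                fitted = logistic_ci(.data$dose, x$params),
                resid = .data$ci - .data$fitted)
}

#' @rdname correlate_outcomes
#' @export
autoplot.logistic_fit <- function(object, ...) {
  r <- object$records
  grid <- tibble::tibble(dose = seq(0, max(r$dose) * 1.1, length.out = 200))
  grid$ci <- logistic_ci(grid$dose, object$params)
  ggplot2::ggplot(r, ggplot2::aes(.data$dose, .data$ci)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red3") +
    ggplot2::labs(x = "dose metric", y = "cure index")
}

#' Simulate noisy tumor regrowth measurements
#'
#' Generates daily caliper measurements for a tumor regrowing at rate `k`
#' with multiplicative lognormal measurement noise, the synthetic analogue
#' of the 14-day follow-up. Diameters are back-computed assuming a
#' spherical tumor (`a = b`), so `tumor_volume()` recovers the intended
#' noisy volume.
#'
#' @param k True regrowth rate, 1/days.
#' @param v0 Initial volume, mm^3.
#' @param days Measurement days.
#' @param cv Lognormal coefficient of variation of the volume noise.
#' @param seed Seed.
#' @return Tibble with `day`, `a_mm`, `b_mm`, `volume_mm3`.
#' @export
simulate_regrowth <- function(k, v0 = 30, days = 0:14, cv = 0.1, seed = 1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  v <- v0 * exp(k * days) * exp(rnorm(length(days), -sdlog^2 / 2, sdlog))
  d <- (6 * v / pi)^(1 / 3)
  tibble::tibble(day = days, a_mm = d, b_mm = d, volume_mm3 = v)
}

#' Treated-group summaries of the BPD mouse study
#'
#' The 15 treatment groups of the BPD-mediated PDT mouse study (group 15
#' is the untreated control): illumination settings, pre-treatment BPD
#' concentration, the reference singlet oxygen dose at 3 mm from the
#' original study and from the voxel simulations at three grid
#' resolutions, the fitted regrowth rate and the cure index. These printed
#' values serve as pipeline inputs (columns 1-5) and as reference outputs
#' for cross-implementation comparison (columns 7-12).
#'
#' @return A tibble with one row per group.
#' @examples
#' bpd_mouse_groups()
#' @export
bpd_mouse_groups <- function() {
  tibble::tribble(
    ~group, ~fluence_rate_mW_cm2, ~time_s, ~fluence_J_cm2, ~bpd_uM,
    ~power_W, ~study_dose_mM, ~dose_1.00mm_mM, ~dose_0.50mm_mM,
    ~dose_0.25mm_mM, ~k_per_day, ~ci,
    1L,  50, 600,  30,  0.53, 0.0393, 0.39, 0.4067, 0.4057, 0.4054, 0.40, 0.0377,
    2L,  75, 400,  30,  0.72, 0.0589, 0.45, 0.4607, 0.4633, 0.4638, 0.38, 0.0556,
    3L, 150, 200,  30,  0.56, 0.1178, 0.29, 0.2913, 0.2936, 0.2941, 0.40, 0.0237,
    4L,  50, 1400, 70,  0.73, 0.0393, 0.90, 0.9147, 0.9200, 0.9213, 0.28, 0.3151,
    5L,  75, 1333, 100, 0.41, 0.0589, 0.60, 0.5977, 0.6032, 0.6044, 0.37, 0.1037,
    6L,  50, 2700, 135, 0.50, 0.0393, 0.78, 0.7839, 0.7910, 0.7928, 0.34, 0.1646,
    7L,  75, 1800, 135, 0.53, 0.0589, 0.82, 0.8246, 0.8319, 0.8337, 0.32, 0.2139,
    8L, 150, 900,  135, 0.58, 0.1178, 0.85, 0.8626, 0.8684, 0.8698, 0.28, 0.3240,
    9L,  75, 2000, 150, 0.84, 0.0589, 1.30, 1.3094, 1.3196, 1.3222, 0.00, 1.0000,
    10L, 100, 1500, 150, 0.66, 0.0785, 1.03, 1.0292, 1.0373, 1.0393, 0.11, 0.7432,
    11L,  75, 3333, 250, 0.58, 0.0589, 0.96, 0.9600, 0.9630, 0.9637, 0.25, 0.3878,
    12L, 150, 1667, 250, 0.77, 0.1178, 1.26, 1.2599, 1.2651, 1.2664, 0.00, 1.0000,
    13L, 150, 2000, 300, 0.77, 0.1178, 1.27, 1.2728, 1.2758, 1.2766, 0.00, 1.0000,
    14L, 150, 2333, 350, 0.81, 0.1178, 1.35, 1.3432, 1.3450, 1.3454, 0.00, 1.0000,
    15L,   0,    0,   0,    NA,     NA,   NA,     NA,     NA,     NA, 0.41, 0.0000)
}
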