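test_that("ellipsoidal tumor volume formula", {
  expect_equal(tumor_volume(3, 5), pi * 9 * 5 / 6)
  expect_equal(tumor_volume(2, 2), pi * 8 / 6)  # sphere: pi d^3 / 6
  expect_equal(tumor_volume(0, 5), 0)
  expect_error(tumor_volume(-1, 2), ">= 0")
})

test_that("regrowth fitting is exact on noiseless exponentials", {
  m <- tibble::tibble(day = 0:14, volume_mm3 = 20 * exp(0.4 * (0:14)))
  fit <- fit_regrowth(m)
  expect_equal(fit$k, 0.4, tolerance = 1e-10)
  # caliper input route: a = b gives the same volumes back
  d <- (6 * m$volume_mm3 / pi)^(1 / 3)
  fit2 <- fit_regrowth(tibble::tibble(day = 0:14, a_mm = d, b_mm = d))
  expect_equal(fit2$k, 0.4, tolerance = 1e-8)
  # constant volume: no regrowth
  expect_equal(fit_regrowth(tibble::tibble(day = 0:14,
                                           volume_mm3 = 25))$k, 0)
  expect_error(fit_regrowth(tibble::tibble(day = 0:1, volume_mm3 = c(1, 2))),
               "3 time points")
})

test_that("regrowth estimator is unbiased at the observed noise level", {
  ks <- vapply(1:200, function(i) {
    fit_regrowth(simulate_regrowth(0.28, cv = 0.1, seed = 1000 + i))$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.28), 0.02)
})

test_that("cured tumors (vanishing volumes) report k = 0", {
  m <- tibble::tibble(day = 0:6, volume_mm3 = c(20, 10, 3, 0, 0, 0, 0))
  fit <- fit_regrowth(m)
  expect_equal(fit$n_used, 3)  # zero volumes dropped, 3 positives remain
  m2 <- tibble::tibble(day = 0:6, volume_mm3 = c(20, 5, 0, 0, 0, 0, 0))
  fit2 <- fit_regrowth(m2)
  expect_true(fit2$cured)
  expect_equal(fit2$k, 0)
})

test_that("cure index follows 1 - k/k_ctr and its monotonicity", {
  expect_equal(cure_index(0, 0.41), 1)
  expect_equal(cure_index(0.41, 0.41), 0)
  expect_equal(cure_index(0.40, 0.41), 1 - 0.40 / 0.41)  # 0.02439
  ks <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(cure_index(ks, 0.41)) < 0))
  expect_error(cure_index(0.1, 0), "k_ctr")
  expect_error(cure_index(-0.1, 0.41), "k")
})

test_that("logistic dose-response has the published shape", {
  expect_equal(logistic_ci(100), 1.08)                 # plateau
  expect_equal(logistic_ci(0), 1.08 / 3491)
  expect_gte(logistic_ci(1.3), 1.0)  # ~1.3 mM is the cure threshold
  doses <- seq(0, 2, by = 0.1)
  expect_true(all(diff(logistic_ci(doses)) > 0))
  expect_error(logistic_ci(-1), "dose")
})

test_that("logistic fitting recovers noiseless parameters to 1e-6", {
  truth <- dose_response_params(1.05, 2000, 7.5)
  doses <- bpd_mouse_groups()$dose_0.50mm_mM[1:14]
  rec <- tibble::tibble(dose = doses, ci = logistic_ci(doses, truth))
  fit <- correlate_outcomes(rec)
  expect_rel(fit$params$A, 1.05, 1e-6)
  expect_rel(fit$params$B, 2000, 1e-5)
  expect_rel(fit$params$c, 7.5, 1e-6)
})

test_that("singlet oxygen dose predicts outcome better than light dose", {
  tab <- bpd_mouse_groups()
  treated <- tab[tab$group <= 14, ]
  fit_dose <- correlate_outcomes(
    data.frame(dose = treated$dose_0.50mm_mM, ci = treated$ci))
  fit_fluence <- correlate_outcomes(
    data.frame(dose = treated$fluence_J_cm2, ci = treated$ci))
  expect_lt(glance(fit_dose)$rms, glance(fit_fluence)$rms)
  # fitted parameters in the neighbourhood of the published curve
  expect_gt(fit_dose$params$A, 0.9)
  expect_lt(fit_dose$params$A, 1.3)
  expect_gt(fit_dose$params$c, 5)
  expect_lt(fit_dose$params$c, 13)
  expect_gt(log10(fit_dose$params$B), 2.5)
  expect_lt(log10(fit_dose$params$B), 4.5)
  # rank correlation: dose orders outcomes better than incident fluence
  rho_dose <- cor(treated$dose_0.50mm_mM, treated$ci, method = "spearman")
  rho_flu <- cor(treated$fluence_J_cm2, treated$ci, method = "spearman")
  expect_gt(rho_dose, rho_flu)
})
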