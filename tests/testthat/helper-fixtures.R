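# Shared Monte Carlo fixtures, computed once per test run and memoized.
# The reference configuration is the murine-tumor phantom: mu_a = 0.69 /cm,
# mu_s' = 11 /cm, g = 0.9, n = 1.4, 10-mm disc beam, 100^3 grid.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# seeds are fixed per fixture so every test run sees the same realization
fx_seed <- c(`50` = 101, `75` = 102, `100` = 103, `150` = 104)

# full-resolution reference run at a given incident fluence rate (mW/cm2)
fx_mc <- function(rate, n_photons = 2e6) {
  fixture(sprintf("mc_%g", rate), function() {
    ph <- make_phantom(voxel_grid(100, voxel_cm = 0.05))
    run_mc(ph, disc_source(rate), n_photons = n_photons,
           seed = fx_seed[[as.character(rate)]])
  })
}

# 0.25-mm resolution run for grid-convergence checks
fx_mc_quarter <- function(n_photons = 2e6) {
  fixture("mc_quarter", function() {
    ph <- make_phantom(voxel_grid(100, voxel_cm = 0.025))
    run_mc(ph, disc_source(50), n_photons = n_photons, seed = 201)
  })
}

# full-map group-1 dose (50 mW/cm2, 600 s, BPD 0.53 uM)
fx_dose1 <- function() {
  fixture("dose1", function() {
    dose_map(fx_mc(50), S0_init = 0.53, T_s = 600, voxels = "all")
  })
}

# brute-force RK4 reference solution (dt = 1 ms) for the group-1 peak voxel
fx_rk4_ref <- function() {
  fixture("rk4_ref", function() {
    integrate_pk_rk4(168, 0.53, T_s = 600, dt = 1e-3)
  })
}

# small fast map for unit tests that only need a plausible fluence field
fx_mc_small <- function() {
  fixture("mc_small", function() {
    ph <- make_phantom(voxel_grid(30, voxel_cm = 0.05))
    run_mc(ph, disc_source(50), n_photons = 3e4, seed = 11)
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
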