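#' Treatment session description
#'
#' Collects everything one simulated PDT session needs: illumination
#' (incident in-air fluence rate on the 10-mm disc and treatment time),
#' pre-treatment photosensitizer concentration, grid resolution, optical
#' properties and photokinetic parameters. Defaults reproduce the standard
#' murine-tumor configuration (mu_a = 0.69 /cm, mu_s' = 11 /cm, n = 1.4,
#' 40 uM initial oxygen, BPD photokinetics).
#'
#' @param fluence_rate Incident in-air fluence rate, mW/cm^2.
#' @param time_s Treatment time, s.
#' @param bpd_uM Pre-treatment photosensitizer concentration, uM.
#' @param fluence_J_cm2 Optional incident fluence; checked against
#'   `fluence_rate * time_s / 1000` (warning if > 1% off).
#' @param group_id Optional label.
#' @param voxel_mm Voxel edge, mm (grid is 100^3 by default).
#' @param n_voxels Voxels per axis.
#' @param optics [optical_properties()] row.
#' @param pk [pk_params()].
#' @param beam_diameter_cm Source disc diameter, cm.
#' @param n_photons,seed,weight_threshold,roulette Monte Carlo settings.
#' @param rtol,atol Photokinetic solver tolerances.
#' @return A list of class `treatment_session`.
#' @examples
#' treatment_session(fluence_rate = 50, time_s = 600, bpd_uM = 0.53)
#' @export
treatment_session <- function(fluence_rate, time_s, bpd_uM,
                              fluence_J_cm2 = NULL, group_id = NA,
                              voxel_mm = 0.5, n_voxels = 100,
                              optics = optical_properties(),
                              pk = pk_params(), beam_diameter_cm = 1.0,
                              n_photons = 2e6, seed = 1,
                              weight_threshold = 1e-4, roulette = TRUE,
                              rtol = 1e-6, atol = 1e-9) {
  if (is.null(fluence_rate)) abort("missing field: `fluence_rate` (mW/cm2)")
  if (is.null(time_s)) abort("missing field: `time_s` (treatment time, s)")
  if (is.null(bpd_uM))
    abort("missing field: `bpd_uM` (photosensitizer concentration, uM)")
  if (fluence_rate < 0 || time_s < 0 || bpd_uM < 0)
    abort("fluence rate, time and photosensitizer concentration must be >= 0")
  expected <- fluence_rate * time_s / 1000
  if (!is.null(fluence_J_cm2) && expected > 0 &&
      abs(fluence_J_cm2 - expected) / expected > 0.01) {
    warn(sprintf(
      "incident fluence %g J/cm2 differs from rate x time = %g J/cm2 by > 1%%",
      fluence_J_cm2, expected))
  }
  structure(list(
    group_id = group_id, fluence_rate = fluence_rate, time_s = time_s,
    fluence_J_cm2 = if (is.null(fluence_J_cm2)) expected else fluence_J_cm2,
    bpd_uM = bpd_uM,
    grid = voxel_grid(n_voxels, voxel_cm = voxel_mm / 10),
    optics = optics, pk = pk,
    source = disc_source(fluence_rate, beam_diameter_cm),
    mc = list(n_photons = n_photons, seed = seed,
              weight_threshold = weight_threshold, roulette = roulette),
    solver = list(rtol = rtol, atol = atol)),
    class = "treatment_session")
}

#' @export
print.treatment_session <- function(x, ...) {
  cat(sprintf(
    "<treatment_session>%s %g mW/cm2 x %g s (%g J/cm2), BPD %g uM, %.3g-mm voxels\n",
    if (is.na(x$group_id)) "" else paste0(" [group ", x$group_id, "]"),
    x$fluence_rate, x$time_s, x$fluence_J_cm2, x$bpd_uM,
    x$grid$voxel_cm * 10))
  invisible(x)
}

#' Session for one of the reference mouse treatment groups
#'
#' Builds the [treatment_session()] matching a row of
#' [bpd_mouse_groups()].
#'
#' @param group Group number (1-15).
#' @param voxel_mm Grid resolution, mm.
#' @param ... Passed to [treatment_session()].
#' @export
group_session <- function(group, voxel_mm = 0.5, ...) {
  tab <- bpd_mouse_groups()
  row <- tab[tab$group == group, ]
  if (nrow(row) != 1) abort(sprintf("unknown group %s", group))
  treatment_session(
    fluence_rate = row$fluence_rate_mW_cm2, time_s = row$time_s,
    bpd_uM = if (is.na(row$bpd_uM)) 0 else row$bpd_uM,
    fluence_J_cm2 = row$fluence_J_cm2, group_id = row$group,
    voxel_mm = voxel_mm, ...)
}

#' Load a treatment session from a YAML or JSON config file
#'
#' Reads a session config and fills every omitted field with the standard
#' defaults (murine-tumor optics, BPD photokinetics, 40 uM oxygen, 10-mm
#' disc, 100^3 grid of 0.5-mm voxels). Both a structured layout
#' (`source:`, `grid:`, `optics:`, `pk:`, `mc:` blocks) and a flat
#' shorthand (`fluence_rate`, `time`, `BPD` at top level) are accepted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [treatment_session()].
#' @export
load_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config did not parse to a mapping")

  # exact-name accessor: `$` on lists partial-matches, which would let
  # `fluence` pick up `fluence_rate`
  gx <- function(l, nm) if (is.list(l) && nm %in% names(l)) l[[nm]] else NULL
  pick <- function(...) {
    for (v in list(...)) if (!is.null(v)) return(v)
    NULL
  }
  num <- function(x, field) {
    if (is.null(x)) return(NULL)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) abort(sprintf("field `%s` is not numeric", field))
    x
  }
  src <- gx(cfg, "source"); grd <- gx(cfg, "grid")
  pkc <- gx(cfg, "pk"); mcc <- gx(cfg, "mc")
  op <- gx(cfg, "optics"); pkp <- gx(pkc, "params")
  fluence_rate <- num(pick(gx(src, "fluence_rate"), gx(cfg, "fluence_rate")),
                      "source.fluence_rate")
  time_s <- num(pick(gx(pkc, "time_s"), gx(cfg, "time_s"), gx(cfg, "time")),
                "pk.time_s")
  bpd <- num(pick(gx(pkc, "S0_init_uM"), gx(cfg, "BPD"), gx(cfg, "bpd_uM")),
             "pk.S0_init_uM")
  if (is.null(fluence_rate)) abort("missing field: `source.fluence_rate`")
  if (is.null(time_s)) abort("missing field: `pk.time_s` (or `time`)")
  if (is.null(bpd)) abort("missing field: `pk.S0_init_uM` (or `BPD`)")

  optics <- optical_properties(
    mu_a = pick(num(gx(op, "mu_a"), "optics.mu_a"), 0.69),
    mu_s_prime = pick(num(gx(op, "mu_s_prime"), "optics.mu_s_prime"), 11),
    g = pick(num(gx(op, "g"), "optics.g"), 0.9),
    n = pick(num(gx(op, "n"), "optics.n"), 1.4))
  pk <- pk_params(
    g = pick(num(gx(pkp, "g"), "pk.params.g"), 1.7),
    delta = pick(num(gx(pkp, "delta"), "pk.params.delta"), 33),
    beta = pick(num(gx(pkp, "beta"), "pk.params.beta"), 11.9),
    sigma = pick(num(gx(pkp, "sigma"), "pk.params.sigma"), 1.8e-5),
    xi = pick(num(gx(pkp, "xi"), "pk.params.xi"), 0.055),
    O2_initial = pick(num(pick(gx(pkc, "O2_init_uM"),
                               gx(pkp, "O2_initial")), "pk.O2_init_uM"), 40))
  treatment_session(
    fluence_rate = fluence_rate, time_s = time_s, bpd_uM = bpd,
    fluence_J_cm2 = num(pick(gx(cfg, "fluence"), gx(cfg, "fluence_J_cm2")),
                        "fluence"),
    group_id = pick(gx(cfg, "group"), NA),
    voxel_mm = pick(num(gx(grd, "voxel_mm"), "grid.voxel_mm"), 0.5),
    n_voxels = pick(num(gx(grd, "n"), "grid.n"), 100),
    optics = optics, pk = pk,
    beam_diameter_cm = pick(num(gx(src, "diameter_mm"),
                                "source.diameter_mm"), 10) / 10,
    n_photons = pick(num(gx(mcc, "n_photons"), "mc.n_photons"), 2e6),
    seed = pick(num(gx(mcc, "seed"), "mc.seed"), 1),
    weight_threshold = pick(num(gx(mcc, "weight_threshold"),
                                "mc.weight_threshold"), 1e-4),
    roulette = pick(gx(mcc, "roulette"), TRUE),
    rtol = pick(num(gx(pkc, "rtol"), "pk.rtol"), 1e-6),
    atol = pick(num(gx(pkc, "atol"), "pk.atol"), 1e-9))
}

#' Run the full light-transport + photokinetics pipeline
#'
#' Chains [run_mc()] (or reuses a supplied fluence map), [dose_map()] and
#' [dose_at_depth()] for one session and collects a report. Sessions with
#' zero source power, zero photosensitizer or zero treatment time skip the
#' transport step and report an all-zero dose map. Re-running with the
#' same seed reproduces identical values.
#'
#' @param session A [treatment_session()].
#' @param n_photons,seed Optional overrides of the session MC settings.
#' @param full_map Integrate the photokinetics in every voxel (`TRUE`) or
#'   only along the beam-axis column (`FALSE`, much faster; the depth dose
#'   and profile are unaffected).
#' @param fluence Optional precomputed `fluence_map` for this geometry
#'   (e.g. from [scale_source()]); skips the MC stage.
#' @param out_dir If non-NULL, write `fluence.nrrd`, `dose.nrrd` (and
#'   `.nii.gz` copies), `profile.csv` and `report.json` there.
#' @return Object of class `pdt_report` with the fluence map, dose map,
#'   `dose_3mm_mM`, `max_dose_mM` (full maps only), energy balance and
#'   stage runtimes.
#' @examples
#' s <- treatment_session(50, 600, 0.53, n_voxels = 30, n_photons = 2e4)
#' rep <- run_pipeline(s)
#' rep$dose_3mm_mM
#' @export
run_pipeline <- function(session, n_photons = NULL, seed = NULL,
                         full_map = FALSE, fluence = NULL, out_dir = NULL) {
  stopifnot(inherits(session, "treatment_session"))
  n_photons <- n_photons %||% session$mc$n_photons
  seed <- seed %||% session$mc$seed
  timings <- c(mc = NA_real_, pk = NA_real_)
  dark <- session$fluence_rate <= 0 || session$time_s <= 0 ||
    session$bpd_uM <= 0
  g <- session$grid

  if (is.null(fluence)) {
    if (session$fluence_rate > 0) {
      ph <- make_phantom(g, background = session$optics)
      t0 <- proc.time()[["elapsed"]]
      fluence <- run_mc(ph, session$source, n_photons = n_photons,
                        seed = seed,
                        weight_threshold = session$mc$weight_threshold,
                        roulette = session$mc$roulette)
      timings["mc"] <- proc.time()[["elapsed"]] - t0
    } else {
      fluence <- structure(list(
        values = array(0, dim = c(g$nx, g$ny, g$nz)), grid = g,
        source = session$source, n_photons = 0, seed = seed,
        weight_threshold = session$mc$weight_threshold,
        roulette = session$mc$roulette,
        energy_balance = c(specular = 0, diffuse_reflected = 0,
                           transmitted = 0, absorbed = 0)),
        class = "fluence_map")
    }
  }
  t0 <- proc.time()[["elapsed"]]
  dm <- dose_map(fluence, S0_init = if (dark) 0 else session$bpd_uM,
                 params = session$pk, T_s = session$time_s,
                 rtol = session$solver$rtol, atol = session$solver$atol,
                 voxels = if (full_map) "all" else "center")
  timings["pk"] <- proc.time()[["elapsed"]] - t0

  report <- structure(list(
    session = session, fluence = fluence, dose = dm,
    dose_3mm_mM = dose_at_depth(dm, 0.3),
    max_dose_mM = if (full_map) max(dm$values) else NA_real_,
    peak_phi = max(fluence$values),
    energy_balance = fluence$energy_balance,
    n_photons = fluence$n_photons, seed = seed, timings = timings),
    class = "pdt_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pdt_report <- function(x, ...) {
  print(x$session)
  cat(sprintf("  peak fluence rate: %.4g mW/cm2 (ratio %.3f)\n", x$peak_phi,
              x$peak_phi / max(x$session$fluence_rate, 1e-300)))
  cat(sprintf("  [1O2]rx at 3 mm: %.4f mM%s\n", x$dose_3mm_mM,
              if (is.na(x$max_dose_mM)) "" else
                sprintf(" | map max %.4f mM", x$max_dose_mM)))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pdt_report`.
#' @param ... Unused.
#' @export
glance.pdt_report <- function(x, ...) {
  tibble::tibble(
    group = x$session$group_id,
    fluence_rate_mW_cm2 = x$session$fluence_rate,
    time_s = x$session$time_s, bpd_uM = x$session$bpd_uM,
    n_photons = x$n_photons, seed = x$seed,
    peak_phi_mW_cm2 = x$peak_phi,
    dose_3mm_mM = x$dose_3mm_mM, max_dose_mM = x$max_dose_mM,
    diffuse_reflectance = unname(x$energy_balance["diffuse_reflected"]))
}

#' Batch pipeline over a table of treatment groups
#'
#' Runs the pipeline for every requested group of a Table-of-groups tibble
#' (default: the reference mouse groups). Because transport is linear in
#' source power, one Monte Carlo run is performed per distinct incident
#' fluence rate and shared across the groups that use it; photokinetics
#' are then integrated per group along the beam axis.
#'
#' @param groups Which group numbers to run.
#' @param voxel_mm Grid resolution, mm.
#' @param n_photons Photons per distinct-rate MC run.
#' @param seed Base seed; each distinct rate r uses `seed + rank(r) - 1`.
#' @param table Group table, defaults to [bpd_mouse_groups()].
#' @return A tibble: group settings, simulated `dose_3mm_mM` and the
#'   reference dose column for the chosen resolution (when available).
#' @export
run_batch <- function(groups = 1:14, voxel_mm = 0.5, n_photons = 2e6,
                      seed = 1, table = bpd_mouse_groups()) {
  tab <- dplyr::filter(table, .data$group %in% groups)
  if (nrow(tab) == 0) abort("no matching groups")
  rates <- sort(unique(tab$fluence_rate_mW_cm2[tab$fluence_rate_mW_cm2 > 0]))
  maps <- list()
  for (i in seq_along(rates)) {
    s <- treatment_session(rates[i], 1, 1, voxel_mm = voxel_mm)
    ph <- make_phantom(s$grid, background = s$optics)
    maps[[as.character(rates[i])]] <-
      run_mc(ph, s$source, n_photons = n_photons, seed = seed + i - 1)
  }
  purrr::map_dfr(seq_len(nrow(tab)), function(r) {
    row <- tab[r, ]
    sess <- group_session(row$group, voxel_mm = voxel_mm)
    fl <- if (row$fluence_rate_mW_cm2 > 0)
      maps[[as.character(row$fluence_rate_mW_cm2)]] else NULL
    rep <- run_pipeline(sess, fluence = fl, full_map = FALSE)
    ref_col <- sprintf("dose_%.2fmm_mM", voxel_mm)
    tibble::tibble(
      group = row$group,
      fluence_rate_mW_cm2 = row$fluence_rate_mW_cm2,
      time_s = row$time_s, bpd_uM = row$bpd_uM,
      dose_3mm_mM = rep$dose_3mm_mM,
      reference_dose_mM = if (ref_col %in% names(row))
        row[[ref_col]] else NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Volumetric and report I/O
# ---------------------------------------------------------------------------

#' Write / read a 3-D volume as NRRD
#'
#' Minimal single-file NRRD (raw little-endian doubles with voxel spacing
#' in the header), enough for exchange with standard volume viewers.
#'
#' @param volume 3-D numeric array.
#' @param path Output path (`.nrrd`).
#' @param voxel_cm Voxel edge, cm (stored in mm in the header).
#' @export
write_nrrd <- function(volume, path, voxel_cm) {
  stopifnot(length(dim(volume)) == 3)
  sp <- voxel_cm * 10
  hdr <- c("NRRD0004", "type: double", "dimension: 3",
           sprintf("sizes: %d %d %d", dim(volume)[1], dim(volume)[2],
                   dim(volume)[3]),
           "space: left-posterior-superior",
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)", sp, sp, sp),
           "space units: \"mm\" \"mm\" \"mm\"",
           "endian: little", "encoding: raw", "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_nrrd
#' @return `read_nrrd()`: a list with `values` (3-D array) and `voxel_cm`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  sizes <- as.integer(strsplit(sub("^sizes: *", "", grep("^sizes:", hdr,
                                                         value = TRUE)),
                               " ")[[1]])
  sd_line <- grep("^space directions:", hdr, value = TRUE)
  sp <- if (length(sd_line))
    as.numeric(sub("^\\(([^,]+),.*", "\\1",
                   sub("^space directions: *", "", sd_line))) else NA_real_
  vals <- readBin(con, "numeric", n = prod(sizes), size = 8,
                  endian = "little")
  list(values = array(vals, dim = sizes), voxel_cm = sp / 10)
}

#' Write a 3-D volume as NIfTI
#'
#' @inheritParams write_nrrd
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(volume, path, voxel_cm) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_cm * 10, 3)  # mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Write the standard output set for one pipeline run
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$dose$grid$voxel_cm
  write_nrrd(report$fluence$values, file.path(out_dir, "fluence.nrrd"), h)
  if (report$dose$voxels == "all")
    write_nrrd(report$dose$values, file.path(out_dir, "dose.nrrd"), h)
  prof <- centerline_profile(report$fluence)
  prof$dose_mM <- dose_depth_profile(report$dose)$dose_mM
  write.csv(prof, file.path(out_dir, "profile.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(group = report$session$group_id,
         fluence_rate_mW_cm2 = report$session$fluence_rate,
         time_s = report$session$time_s,
         bpd_uM = report$session$bpd_uM,
         n_photons = report$n_photons, seed = report$seed,
         dose_3mm_mM = report$dose_3mm_mM,
         max_dose_mM = report$max_dose_mM,
         peak_phi_mW_cm2 = report$peak_phi,
         energy_balance = as.list(report$energy_balance),
         timings_s = as.list(report$timings)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
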