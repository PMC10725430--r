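# Synthetic two-group cohorts: per-cell generator parameters are drawn
# lognormally around group means scaled by configurable effect factors, the
# raw inputs (spectra, trees, soma-plane images, sweeps) are generated, and
# the full analysis pipeline recovers the per-cell metrics into a tidy table.

#' Specify a synthetic two-group cohort
#'
#' Effect factors multiply the "older" group's generating parameter relative
#' to "younger". Defaults emulate the qualitative aging effects the pipeline
#' is designed to detect (shorter branches, lower leaflet VF, fewer reduced
#' cytochromes, higher input resistance), but every factor is configurable
#' and `1` everywhere gives an exact null.
#'
#' @param n_per_group Cells per group (>= 3).
#' @param branch_length_factor,vf_factor,cytc_factor,ri_factor Multiplicative
#'   "older" group effects on mean segment length (and radial extent),
#'   leaflet fog, the 750 cm^-1 cytochrome amplitude, and membrane
#'   resistance.
#' @param noise_cv Coefficient of variation of the lognormal cell-level
#'   spread (default 0.15).
#' @param cells_per_patient Cells per synthetic patient id (default 3).
#' @param seed Integer seed; the same spec always generates identical
#'   outputs.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15, branch_length_factor = 0.75,
                        vf_factor = 0.6, cytc_factor = 0.7, ri_factor = 1.5,
                        noise_cv = 0.15, cells_per_patient = 3, seed = 1) {
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  factors <- c(branch_length_factor, vf_factor, cytc_factor, ri_factor)
  if (any(factors <= 0)) stop("effect factors must be > 0")
  structure(list(n_per_group = n_per_group,
                 branch_length_factor = branch_length_factor,
                 vf_factor = vf_factor, cytc_factor = cytc_factor,
                 ri_factor = ri_factor, noise_cv = noise_cv,
                 cells_per_patient = cells_per_patient, seed = seed),
            class = "cohort_spec")
}

# Lognormal multiplier with unit median and coefficient of variation cv.
.lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Generate a synthetic cohort and recover its metrics with the pipeline
#'
#' For every cell, cell-level generating parameters are drawn (lognormal
#' around the group mean, "older" means scaled by the spec's effect factors),
#' the raw inputs are generated with [gen_raman()], [gen_astrocyte()],
#' [gen_vf_image()] and [gen_passive_sweep()], and the analysis operations
#' ([metrics_532()], [sholl_3d()] + [branch_metrics()],
#' [domain_area_from_endpoints()], [leaflet_vf()], [input_resistance()])
#' recover the per-cell metrics.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory: when given, raw inputs (spectra CSVs,
#'   SWC files, sweep CSVs), a manifest and the ground truth are written
#'   there.
#' @return A list of class `cohort`: `table` (per-cell metric data frame
#'   with `patient_id`, `cell_id`, `group`), `ground_truth` (per-cell
#'   generating parameters) and `spec`.
#' @export
gen_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("younger", "older")
  n <- spec$n_per_group
  cv <- spec$noise_cv
  set.seed(derive_seed(spec$seed, 0))
  # cell-level parameter draws for both groups at once
  draw <- function(base, factor_older) {
    c(base * .lnorm_mult(n, cv), base * factor_older * .lnorm_mult(n, cv))
  }
  par_seg <- draw(8, spec$branch_length_factor)      # mean segment length um
  par_fog <- pmin(draw(7, spec$vf_factor), 95)       # fog VF %
  par_a750 <- draw(1.5, spec$cytc_factor)            # cyt c peak amplitude
  par_a1126 <- draw(1.0, spec$cytc_factor)           # cyt b peak amplitude
  par_a1440 <- draw(4.0, 1)                          # lipid peak
  par_a1660 <- draw(3.0, 1)                          # protein peak
  par_r <- draw(80, spec$ri_factor)                  # membrane R, MOhm

  rows <- list(); gt <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list()
  }
  for (i in seq_len(2 * n)) {
    g <- groups[(i - 1) %/% n + 1]
    cell <- sprintf("%s_%02d", g, (i - 1) %% n + 1)
    patient <- sprintf("%s_P%d", g, ((i - 1) %% n) %/% spec$cells_per_patient + 1)

    sp <- gen_raman(
      peaks = data.frame(
        center = c(750, 1126, 1440, 1550, 1660),
        amplitude = c(par_a750[i], par_a1126[i], par_a1440[i],
                      0.6 * par_a750[i], par_a1660[i]),
        width = c(8, 8, 10, 12, 9)),
      baseline_coeffs = c(10, -3, 2, 1.5), noise_sd = 0.02,
      seed = derive_seed(spec$seed, 10 * i + 1), cell_id = cell,
      cell_class = "astrocyte")
    rm532 <- metrics_532(sp)

    ast <- gen_astrocyte(
      n_primary = 5, branching_prob = 0.25,
      mean_segment_um = par_seg[i],
      max_radius_um = 40 * par_seg[i] / 8,
      seed = derive_seed(spec$seed, 10 * i + 2), rasterize = FALSE)
    bm <- branch_metrics(ast$tracing, sholl_3d(ast$tracing))
    dom <- domain_area_from_endpoints(ast$tracing)

    vf_img <- gen_vf_image(fog_vf = par_fog[i], soma_radius_um = 4,
                           n_rings = 3, ring_amp = 40, radius_um = 50,
                           lateral_res = 0.5, noise_sd = 0.5,
                           seed = derive_seed(spec$seed, 10 * i + 3))
    ctr <- attr(vf_img, "ground_truth")$center_px
    vf <- leaflet_vf(vf_img, soma_center = ctr, soma_z = 1)

    sw <- gen_passive_sweep(R_mohm = par_r[i], C_pf = 20, step = 5,
                            mode = "vclamp", noise_sd = 5,
                            seed = derive_seed(spec$seed, 10 * i + 4))
    ri <- input_resistance(sw, step_mv = 5)

    rows[[i]] <- data.frame(
      patient_id = patient, cell_id = cell, group = g,
      red_cyt_cb_per_protein = rm532$red_cyt_cb_per_protein,
      protein_to_lipid = rm532$protein_to_lipid,
      c_to_b = rm532$c_to_b,
      mean_branch_length = bm$mean_branch_length,
      max_intersections = bm$max_intersections,
      domain_area = dom,
      characteristic_vf = vf$characteristic_vf,
      ri_mohm = ri,
      stringsAsFactors = FALSE)
    gt[[cell]] <- list(group = g, mean_segment_um = par_seg[i],
                       fog_vf = par_fog[i], a750 = par_a750[i],
                       a1126 = par_a1126[i], a1440 = par_a1440[i],
                       a1660 = par_a1660[i], R_mohm = par_r[i],
                       branch_lengths = ast$ground_truth$branch_lengths)
    if (!is.null(out_dir)) {
      spec_file <- sprintf("%s_spectrum.csv", cell)
      utils::write.csv(data.frame(shift_cm1 = sp$shifts,
                                  intensity = sp$intensities),
                       file.path(out_dir, spec_file), row.names = FALSE)
      swc_file <- sprintf("%s.swc", cell)
      write_swc(ast$tracing, file.path(out_dir, swc_file))
      sweep_file <- sprintf("%s_sweep.csv", cell)
      utils::write.csv(data.frame(t_ms = sw$time, primary = sw$primary,
                                  command = sw$command),
                       file.path(out_dir, sweep_file), row.names = FALSE)
      manifest[[i]] <- data.frame(cell_id = cell, patient_id = patient,
                                  group = g, spectrum = spec_file,
                                  swc = swc_file, sweep = sweep_file,
                                  stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(do.call(rbind, manifest),
                     file.path(out_dir, "cohort_manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(table = tab, ground_truth = gt, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells per group, seed %d\n",
              x$spec$n_per_group, x$spec$seed))
  invisible(x)
}
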