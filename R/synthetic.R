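# Synthetic-data generators: every pipeline input modality with known ground
# truth. All generators are seed-deterministic; a study-level seed is expanded
# into per-cell sub-seeds by a fixed counter scheme (see derive_seed).

#' Derive a reproducible sub-seed from a global seed and counter
#'
#' `sub = (seed * 48271 + counter * 16807) mod (2^31 - 1)`, kept within the
#' 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param counter Non-negative integer counter.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(counter) * 16807) %% m)
}

#' Generate a synthetic Raman spectrum
#'
#' Spectrum = polynomial baseline + sum of Gaussian peaks + i.i.d. Gaussian
#' noise, on a 1 cm^-1 grid over 600-1800 cm^-1. The baseline polynomial is
#' evaluated in the scaled coordinate `u = (shift - 1200) / 600` (so `u` spans
#' -1..1) for numerical stability.
#'
#' @param peaks Data frame or list of `(center, amplitude, width)` rows;
#'   width is the Gaussian SD in cm^-1.
#' @param baseline_coeffs Polynomial coefficients in `u`, lowest order first.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @param laser_nm Laser line recorded in the spectrum metadata.
#' @param cell_id,cell_class Metadata.
#' @return A [raman_spectrum()] with attribute `ground_truth` (peaks,
#'   baseline coefficients, noise level).
#' @export
gen_raman <- function(peaks, baseline_coeffs = c(0), noise_sd = 0, seed = 1,
                      laser_nm = 532, cell_id = NA_character_,
                      cell_class = NA_character_) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0) {
    names(peaks)[1:3] <- c("center", "amplitude", "width")
    if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  }
  shifts <- 600:1800
  u <- (shifts - 1200) / 600
  base <- rep(0, length(u))
  for (k in seq_along(baseline_coeffs))
    base <- base + baseline_coeffs[k] * u^(k - 1)
  sig <- base
  for (i in seq_len(nrow(peaks)))
    sig <- sig + peaks$amplitude[i] *
      exp(-(shifts - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
  }
  sp <- raman_spectrum(shifts, sig, laser_nm = laser_nm,
                       cell_id = cell_id, cell_class = cell_class)
  attr(sp, "ground_truth") <- list(peaks = peaks,
                                   baseline_coeffs = baseline_coeffs,
                                   noise_sd = noise_sd)
  sp
}

# Random unit vector with the z-component damped by z_flatten (protoplasmic
# astrocytes are flattened in z).
.rand_dir <- function(z_flatten) {
  v <- stats::rnorm(3)
  v[3] <- v[3] * z_flatten
  v / sqrt(sum(v^2))
}

#' Generate a stochastic astrocyte: tracing, ground truth and optional stack
#'
#' Grows a 3D tree from the soma: `n_primary` primary branches leave the root
#' in random directions; each segment has exponential length, a direction
#' that random-walks with an outward bias, and branches with probability
#' `branching_prob`; growth stops at `max_radius_um`. The tree is optionally
#' rasterized into an image stack: soma sphere and branches at intensity 100,
#' a uniform leaflet "fog" at `fog_vf` (percent of soma intensity) elsewhere,
#' plus Gaussian noise.
#'
#' @param n_primary Number of primary branches (>= 1).
#' @param branching_prob Per-segment branching probability in `[0, 1]`.
#' @param mean_segment_um Mean segment length (um).
#' @param max_radius_um Maximal radial extent (um).
#' @param fog_vf Leaflet fog intensity as percent of soma intensity (0-100).
#' @param soma_radius_um Soma radius (um).
#' @param seed Integer seed.
#' @param rasterize Also build the image stack (default TRUE).
#' @param lateral_res Isotropic voxel size of the rasterized stack (um).
#' @param z_flatten Damping of growth in z (default 0.4).
#' @param noise_sd Stack noise SD (intensity units; soma = 100).
#' @param max_nodes Safety cap on tree size.
#' @return List with `tracing`, `stack` (or NULL), and `ground_truth`
#'   (parameters, per-branch lengths, tip coordinates, totals).
#' @export
gen_astrocyte <- function(n_primary = 6, branching_prob = 0.25,
                          mean_segment_um = 8, max_radius_um = 40,
                          fog_vf = 7, soma_radius_um = 4, seed = 1,
                          rasterize = TRUE, lateral_res = 0.4,
                          z_flatten = 0.4, noise_sd = 1, max_nodes = 2000) {
  if (n_primary < 1) stop("n_primary must be >= 1")
  if (fog_vf < 0 || fog_vf > 100) stop("fog_vf must be in [0, 100]")
  stopifnot(mean_segment_um > 0, max_radius_um > 0, soma_radius_um > 0)
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = soma_radius_um, parent = -1L)
  # active tips: node index + current direction
  tips <- lapply(seq_len(n_primary), function(i)
    list(node = 1L, dir = .rand_dir(z_flatten)))
  while (length(tips) > 0 && nrow(nodes) < max_nodes) {
    tip <- tips[[1]]; tips <- tips[-1]
    pos <- as.numeric(nodes[tip$node, c("x", "y", "z")])
    len <- min(max(stats::rexp(1, 1 / mean_segment_um), 1), 3 * mean_segment_um)
    outward <- if (sum(pos^2) > 0) pos / sqrt(sum(pos^2)) else tip$dir
    d <- tip$dir + 0.5 * .rand_dir(z_flatten) + 0.3 * outward
    d[3] <- d[3] * z_flatten
    d <- d / sqrt(sum(d^2))
    new_pos <- pos + len * d
    r_new <- sqrt(sum(new_pos^2))
    terminated <- FALSE
    if (r_new > max_radius_um) {
      new_pos <- pos + (len * (max_radius_um - sqrt(sum(pos^2))) /
                          (r_new - sqrt(sum(pos^2)))) * d
      terminated <- TRUE
    }
    nid <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(id = nid, type = 3L,
                                     x = new_pos[1], y = new_pos[2],
                                     z = new_pos[3], radius = 0.5,
                                     parent = nodes$id[tip$node]))
    if (!terminated) {
      if (stats::runif(1) < branching_prob) {
        tips <- c(tips, list(list(node = nid, dir = d + 0.4 * .rand_dir(z_flatten)),
                             list(node = nid, dir = d + 0.4 * .rand_dir(z_flatten))))
        tips[[length(tips) - 1]]$dir <- tips[[length(tips) - 1]]$dir /
          sqrt(sum(tips[[length(tips) - 1]]$dir^2))
        tips[[length(tips)]]$dir <- tips[[length(tips)]]$dir /
          sqrt(sum(tips[[length(tips)]]$dir^2))
      } else {
        tips <- c(tips, list(list(node = nid, dir = d)))
      }
    }
  }
  trc <- tracing(nodes)
  paths <- branch_paths(trc)
  kids <- children_of(trc)
  tip_idx <- which(vapply(kids, length, 1L) == 0 & seq_len(nrow(nodes)) != trc$root)
  gt <- list(n_primary = n_primary, branching_prob = branching_prob,
             mean_segment_um = mean_segment_um, max_radius_um = max_radius_um,
             fog_vf = fog_vf, soma_radius_um = soma_radius_um,
             branch_lengths = vapply(paths, `[[`, numeric(1), "length"),
             tip_xy = as.matrix(nodes[tip_idx, c("x", "y")]),
             n_tips = length(tip_idx), seed = seed)
  stack <- NULL
  if (rasterize) {
    stack <- rasterize_tracing(trc, soma_radius_um = soma_radius_um,
                               fog_vf = fog_vf, lateral_res = lateral_res,
                               max_radius_um = max_radius_um,
                               z_extent_um = max_radius_um * z_flatten +
                                 soma_radius_um + 2,
                               noise_sd = noise_sd)
  }
  list(tracing = trc, stack = stack, ground_truth = gt)
}

#' Rasterize a tracing into an image stack
#'
#' Branches and the soma sphere are painted at intensity 100 over a uniform
#' fog of `fog_vf` (percent of soma); Gaussian noise is added by the caller's
#' RNG state.
#'
#' @param trc A [tracing()] centered on the soma at the origin.
#' @param soma_radius_um,fog_vf,lateral_res,max_radius_um,z_extent_um,noise_sd
#'   Geometry and intensity parameters.
#' @param branch_radius_um Radius of the painted branch tube (um).
#' @return An [image_stack()].
#' @export
rasterize_tracing <- function(trc, soma_radius_um = 4, fog_vf = 7,
                              lateral_res = 0.4, max_radius_um = 40,
                              z_extent_um = NULL, noise_sd = 0,
                              branch_radius_um = 0.5) {
  res <- lateral_res
  L <- max_radius_um + 2
  if (is.null(z_extent_um)) z_extent_um <- L
  nxy <- 2L * ceiling(L / res) + 1L
  nz <- 2L * ceiling(z_extent_um / res) + 1L
  vox <- array(fog_vf, dim = c(nz, nxy, nxy))
  to_idx <- function(um, n) pmin(pmax(round(um / res) + (n + 1L) %/% 2L, 1L), n)
  # soma sphere
  zi <- seq_len(nz); yi <- seq_len(nxy); xi <- seq_len(nxy)
  zu <- (zi - (nz + 1L) %/% 2L) * res
  yu <- (yi - (nxy + 1L) %/% 2L) * res
  xu <- (xi - (nxy + 1L) %/% 2L) * res
  keep_z <- which(abs(zu) <= soma_radius_um)
  for (z in keep_z) {
    rr <- sqrt(outer(yu^2, xu^2, "+") + zu[z]^2)
    vox[z, , ][rr <= soma_radius_um] <- 100
  }
  # branches, painted as tubes of branch_radius_um (dye-filled processes are
  # at least diffraction-limited in width)
  rb <- max(0L, floor(branch_radius_um / res + 1e-9))
  offs <- expand.grid(dz = -rb:rb, dy = -rb:rb, dx = -rb:rb)
  offs <- offs[sqrt(offs$dz^2 + offs$dy^2 + offs$dx^2) * res <=
                 branch_radius_um + 1e-9, , drop = FALSE]
  seg <- tracing_segments(trc)
  for (i in seq_along(seg$child)) {
    p <- seg$from[i, ]; q <- seg$to[i, ]
    len <- sqrt(sum((q - p)^2))
    ns <- max(2L, ceiling(len / (res / 2)))
    tt <- seq(0, 1, length.out = ns)
    xs <- p[1] + tt * (q[1] - p[1])
    ys <- p[2] + tt * (q[2] - p[2])
    zs <- p[3] + tt * (q[3] - p[3])
    for (k in seq_len(nrow(offs))) {
      vox[cbind(to_idx(zs + offs$dz[k] * res, nz),
                to_idx(ys + offs$dy[k] * res, nxy),
                to_idx(xs + offs$dx[k] * res, nxy))] <- 100
    }
  }
  if (noise_sd > 0) {
    vox <- vox + stats::rnorm(length(vox), sd = noise_sd)
    vox[vox < 0] <- 0
  }
  image_stack(vox, lateral_res = res, z_step = res)
}

#' Generate a soma-plane fluorescence image for VF estimation
#'
#' A single-plane stack: soma disc at intensity 100, uniform leaflet fog at
#' `fog_vf` percent, and optional annular "branch crossings" (rings of given
#' width and amplitude at random radii) that the VF excision step must
#' discard; plus Gaussian noise.
#'
#' @param fog_vf Fog intensity, percent of soma (ground truth VF).
#' @param soma_radius_um Soma radius (um).
#' @param n_rings Number of branch-crossing rings.
#' @param ring_amp Ring amplitude in percent of soma intensity.
#' @param ring_width_um Radial ring width (um).
#' @param radius_um Image half-size (um); must exceed the soma radius plus
#'   the VF measurement band.
#' @param lateral_res Pixel size (um).
#' @param noise_sd Noise SD (percent of soma).
#' @param seed Integer seed.
#' @return An [image_stack()] with one plane and attribute `ground_truth`.
#' @export
gen_vf_image <- function(fog_vf = 7, soma_radius_um = 4, n_rings = 3,
                         ring_amp = 40, ring_width_um = 1, radius_um = 50,
                         lateral_res = 0.5, noise_sd = 0.5, seed = 1) {
  if (fog_vf < 0 || fog_vf > 100) stop("fog_vf must be in [0, 100]")
  set.seed(seed)
  n <- 2L * ceiling(radius_um / lateral_res) + 1L
  cu <- ((seq_len(n)) - (n + 1L) %/% 2L) * lateral_res
  rr <- sqrt(outer(cu^2, cu^2, "+"))
  img <- matrix(fog_vf, n, n)
  img[rr <= soma_radius_um] <- 100
  # branch crossings at distinct radii (>= 4 um apart, as crossings of
  # separate resolvable branches)
  ring_radii <- numeric(0)
  tries <- 0
  while (length(ring_radii) < n_rings && tries < 200) {
    cand <- stats::runif(1, soma_radius_um + 5, radius_um - 6)
    if (!length(ring_radii) || min(abs(ring_radii - cand)) >= 4)
      ring_radii <- c(ring_radii, cand)
    tries <- tries + 1
  }
  for (r0 in ring_radii)
    img[abs(rr - r0) <= ring_width_um / 2 & rr > soma_radius_um] <-
      fog_vf + ring_amp
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = noise_sd)
    img[img < 0] <- 0
  }
  st <- image_stack(array(img, dim = c(1L, n, n)),
                    lateral_res = lateral_res, z_step = lateral_res)
  attr(st, "ground_truth") <- list(fog_vf = fog_vf,
                                   soma_radius_um = soma_radius_um,
                                   ring_radii = ring_radii,
                                   center_px = c((n + 1L) %/% 2L, (n + 1L) %/% 2L))
  st
}

#' Generate a passive RC membrane step response
#'
#' Single-compartment response with time constant `tau = R * C`: in voltage
#' clamp the current relaxes toward `V / R` (with a capacitive transient); in
#' current clamp the voltage charges toward `I * R`.
#'
#' @param R_mohm Membrane resistance (MOhm).
#' @param C_pf Membrane capacitance (pF).
#' @param step Step amplitude: mV in vclamp, pA in cclamp.
#' @param mode `"vclamp"` or `"cclamp"`.
#' @param noise_sd Gaussian noise SD (pA or mV).
#' @param seed Integer seed.
#' @param dt Sample interval (ms).
#' @param t_on,t_off,t_total Step timing (ms).
#' @param v_rest Resting potential for cclamp (mV).
#' @return A [sweep_record()] with attribute `ground_truth`.
#' @export
gen_passive_sweep <- function(R_mohm, C_pf, step = 5,
                              mode = c("vclamp", "cclamp"),
                              noise_sd = 0, seed = 1, dt = 0.1,
                              t_on = 100, t_off = 600, t_total = 800,
                              v_rest = -70) {
  mode <- match.arg(mode)
  if (R_mohm <= 0 || C_pf <= 0) stop("R and C must be > 0")
  tau <- R_mohm * C_pf / 1000       # ms
  time <- seq(0, t_total, by = dt)
  instep <- time >= t_on & time < t_off
  after <- time >= t_off
  ts <- time - t_on
  ta <- time - t_off
  if (mode == "vclamp") {
    i_ss <- 1000 * step / R_mohm    # pA
    x <- numeric(length(time))
    x[instep] <- i_ss + 4 * i_ss * exp(-ts[instep] / tau)
    x[after] <- -4 * i_ss * exp(-ta[after] / tau)
    cmd <- ifelse(instep, step, 0)
  } else {
    dv <- step * R_mohm / 1000      # mV
    x <- rep(v_rest, length(time))
    x[instep] <- v_rest + dv * (1 - exp(-ts[instep] / tau))
    x[after] <- v_rest + dv * exp(-ta[after] / tau)
    cmd <- ifelse(instep, step, 0)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  }
  sw <- sweep_record(time, x, command = cmd, mode = mode,
                     step_window = c(t_on, t_off))
  attr(sw, "ground_truth") <- list(R_mohm = R_mohm, C_pf = C_pf,
                                   tau_ms = tau, step = step)
  sw
}

#' Generate a current-clamp sweep with a stereotyped AP train
#'
#' The step depolarizes the cell (with a 10 ms onset ramp, slow enough not to
#' trigger the dV/dt spike criterion) to a plateau; triangular AP templates
#' (linear rise and fall between threshold and peak) are placed at
#' inter-spike intervals interpolating from `first_isi_ms` to `last_isi_ms`.
#' An afterhyperpolarization follows the step. Ground-truth adaptation is
#' `last_isi_ms / first_isi_ms`; the analytic half-width is
#' `(rise_ms + fall_ms) / 2`.
#'
#' @param n_spikes Number of APs (>= 0).
#' @param first_isi_ms,last_isi_ms First and last inter-spike intervals (ms).
#' @param threshold_mv Voltage at spike onset (also the plateau when spiking).
#' @param peak_mv Spike peak voltage (overshoot when > 0).
#' @param rise_ms,fall_ms Template rise and fall times (ms).
#' @param plateau_mv Plateau for non-spiking sweeps; default
#'   `threshold_mv` when spiking, `v_rest + 5` otherwise.
#' @param step_pa Step amplitude recorded in the command trace (pA).
#' @param ahp_mv AHP depth below baseline after the step (mV).
#' @param v_rest Resting potential (mV).
#' @param dt Sample interval (ms).
#' @param t_on,t_off,t_total Step timing (ms).
#' @param seed Integer seed (unused unless noise is added; kept for API
#'   symmetry).
#' @param noise_sd Gaussian noise SD (mV).
#' @return A cclamp [sweep_record()] with attribute `ground_truth`.
#' @export
gen_ap_train <- function(n_spikes, first_isi_ms = 10, last_isi_ms = 20,
                         threshold_mv = -40, peak_mv = 20,
                         rise_ms = 1, fall_ms = 2, plateau_mv = NULL,
                         step_pa = 440, ahp_mv = 5, v_rest = -70,
                         dt = 0.05, t_on = 100, t_off = 600, t_total = 800,
                         seed = 1, noise_sd = 0) {
  if (n_spikes < 0) stop("n_spikes must be >= 0")
  if (first_isi_ms <= 0 || last_isi_ms <= 0) stop("ISIs must be > 0")
  if (n_spikes >= 2 && min(first_isi_ms, last_isi_ms) <= rise_ms + fall_ms)
    stop("overlapping templates: ISI shorter than the AP template")
  if (is.null(plateau_mv))
    plateau_mv <- if (n_spikes > 0) threshold_mv else v_rest + 5
  time <- seq(0, t_total, by = dt)
  v <- rep(v_rest, length(time))
  ramp_ms <- 10
  ramp <- time >= t_on & time < t_on + ramp_ms
  v[ramp] <- v_rest + (plateau_mv - v_rest) * (time[ramp] - t_on) / ramp_ms
  plateau <- time >= t_on + ramp_ms & time < t_off
  v[plateau] <- plateau_mv
  after <- time >= t_off
  v[after] <- v_rest - ahp_mv * exp(-(time[after] - t_off) / 50)
  peak_times <- numeric(0)
  if (n_spikes > 0) {
    isis <- if (n_spikes >= 2)
      seq(first_isi_ms, last_isi_ms, length.out = n_spikes - 1) else numeric(0)
    peak_times <- t_on + ramp_ms + 10 + rise_ms + cumsum(c(0, isis))
    if (max(peak_times) + fall_ms >= t_off)
      stop("overlapping templates: train does not fit in the step")
    for (pt in peak_times) {
      rise_sel <- time >= pt - rise_ms & time <= pt
      fall_sel <- time > pt & time <= pt + fall_ms
      v[rise_sel] <- threshold_mv +
        (peak_mv - threshold_mv) * (time[rise_sel] - (pt - rise_ms)) / rise_ms
      v[fall_sel] <- peak_mv -
        (peak_mv - threshold_mv) * (time[fall_sel] - pt) / fall_ms
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  cmd <- ifelse(time >= t_on & time < t_off, step_pa, 0)
  sw <- sweep_record(time, v, command = cmd, mode = "cclamp",
                     step_window = c(t_on, t_off))
  attr(sw, "ground_truth") <- list(
    n_spikes = n_spikes, peak_times = peak_times,
    adaptation = if (n_spikes >= 3) last_isi_ms / first_isi_ms else NA_real_,
    overshoot = peak_mv, threshold_mv = threshold_mv,
    half_width = (rise_ms + fall_ms) / 2, ahp_mv = ahp_mv, step_pa = step_pa)
  sw
}

#' Generate a spontaneous IPSC trace
#'
#' Homogeneous Poisson event times; each event is an instantaneous-rise,
#' single-exponential-decay inward (negative) deflection; plus Gaussian
#' noise.
#'
#' @param rate_hz Event rate (>= 0).
#' @param amp_pa Event amplitude (pA, magnitude).
#' @param tau_ms Decay time constant (> 0).
#' @param duration_s Trace duration (> 0).
#' @param noise_sd Noise SD (pA).
#' @param seed Integer seed.
#' @param dt Sample interval (ms).
#' @return A vclamp [sweep_record()] with attribute `ground_truth`
#'   (event times, amplitude, tau, rate).
#' @export
gen_sipsc_trace <- function(rate_hz, amp_pa = 50, tau_ms = 10,
                            duration_s = 60, noise_sd = 0, seed = 1,
                            dt = 0.2) {
  if (rate_hz < 0) stop("rate must be >= 0")
  if (tau_ms <= 0) stop("tau must be > 0")
  if (duration_s <= 0) stop("duration must be > 0")
  set.seed(seed)
  n_ev <- stats::rpois(1, rate_hz * duration_s)
  times <- sort(stats::runif(n_ev, 0, duration_s * 1000))
  t <- seq(0, duration_s * 1000, by = dt)
  x <- numeric(length(t))
  span <- ceiling(8 * tau_ms / dt)
  for (te in times) {
    i0 <- floor(te / dt) + 1L
    idx <- i0:min(length(t), i0 + span)
    x[idx] <- x[idx] - amp_pa * exp(-(t[idx] - te) / tau_ms)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  sw <- sweep_record(t, x, mode = "vclamp")
  attr(sw, "ground_truth") <- list(event_times_ms = times, amp_pa = amp_pa,
                                   tau_ms = tau_ms, rate_hz = rate_hz,
                                   n_events = n_ev)
  sw
}
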