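# Patch-clamp feature extraction: input resistance and IV curves from
# voltage-clamp step families, action-potential train features from
# current-clamp step families, and spontaneous IPSC detection with
# single-exponential decay fits.

#' Construct a recording sweep
#'
#' @param time Uniform time grid in milliseconds.
#' @param primary Recorded signal: pA in voltage clamp, mV in current clamp.
#' @param command Stimulus waveform (mV steps in vclamp, pA steps in cclamp).
#' @param mode `"vclamp"` or `"cclamp"`.
#' @param step_window `(t_on, t_off)` of the stimulus step in ms.
#' @return An object of class `sweep`.
#' @export
sweep_record <- function(time, primary, command = NULL,
                         mode = c("vclamp", "cclamp"),
                         step_window = NULL) {
  mode <- match.arg(mode)
  time <- as.numeric(time)
  dt <- diff(time)
  if (length(time) < 2 || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("time must be a uniform grid")
  if (length(primary) != length(time))
    stop("primary must match time")
  if (!is.null(command) && length(command) != length(time))
    stop("command must match time")
  if (!is.null(step_window)) {
    if (step_window[1] >= step_window[2] ||
        step_window[1] < time[1] || step_window[2] > time[length(time)])
      stop("step_window must satisfy t_on < t_off within the record")
  }
  structure(list(time = time, primary = as.numeric(primary),
                 command = command, mode = mode, step_window = step_window,
                 dt = dt[1]),
            class = "sweep")
}

# Mean of primary over baseline (before t_on) and steady state (last `frac`
# of the step).
.step_levels <- function(sw, frac = 0.2) {
  t_on <- sw$step_window[1]; t_off <- sw$step_window[2]
  pre <- sw$time < t_on
  ss <- sw$time >= t_off - frac * (t_off - t_on) & sw$time < t_off
  if (!any(pre) || !any(ss)) stop("step window leaves no baseline or plateau")
  list(baseline = mean(sw$primary[pre]),
       steady = mean(sw$primary[ss]),
       baseline_sd = stats::sd(sw$primary[pre]),
       n_ss = sum(ss))
}

#' Input resistance from a voltage-clamp test step
#'
#' `R_i = step / dI_ss` where `dI_ss` is the mean current over the last 20
#' percent of the step minus the mean baseline current before the step.
#' With mV and pA the ratio is in GOhm, reported in MOhm.
#'
#' @param sw A vclamp [sweep_record()].
#' @param step_mv Command step amplitude in mV (default 5).
#' @param ss_frac Fraction of the step treated as steady state (default 0.2).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sw, step_mv = 5, ss_frac = 0.2) {
  stopifnot(inherits(sw, "sweep"))
  if (sw$mode != "vclamp") stop("input_resistance requires a vclamp sweep")
  lv <- .step_levels(sw, ss_frac)
  d_i <- lv$steady - lv$baseline
  floor_pa <- 3 * lv$baseline_sd / sqrt(lv$n_ss)
  if (!is.finite(d_i) || d_i == 0 || abs(d_i) < floor_pa)
    stop("unresolvable resistance: steady-state current change below noise floor")
  1000 * step_mv / d_i
}

#' Current-voltage relationship from a voltage-step family
#'
#' One sweep per step voltage; the steady current is the last-20-percent mean
#' minus baseline. The slope conductance is the least-squares slope of I
#' against V (pA/mV = nS) and the passive input resistance its reciprocal.
#'
#' @param sweeps List of vclamp [sweep_record()]s.
#' @param step_voltages Step amplitudes in mV; default read from each sweep's
#'   command waveform.
#' @return An object of class `iv_curve` with `step_voltages`,
#'   `steady_currents`, `slope_conductance` (nS) and `r_input` (MOhm).
#' @export
iv_curve <- function(sweeps, step_voltages = NULL) {
  if (length(sweeps) < 2) stop("insufficient data: need at least 2 voltage steps")
  if (is.null(step_voltages)) {
    step_voltages <- vapply(sweeps, function(sw) {
      if (is.null(sw$command)) stop("step_voltages required when sweeps lack command")
      t_on <- sw$step_window[1]; t_off <- sw$step_window[2]
      instep <- sw$time >= t_on & sw$time <= t_off
      mean(sw$command[instep]) - mean(sw$command[sw$time < t_on])
    }, numeric(1))
  }
  currents <- vapply(sweeps, function(sw) {
    lv <- .step_levels(sw)
    lv$steady - lv$baseline
  }, numeric(1))
  o <- order(step_voltages)
  step_voltages <- step_voltages[o]; currents <- currents[o]
  slope <- stats::coef(stats::lm(currents ~ step_voltages))[[2]]
  structure(list(step_voltages = step_voltages, steady_currents = currents,
                 slope_conductance = slope,
                 r_input = 1000 / slope),
            class = "iv_curve")
}

#' Detect action potentials by dV/dt threshold crossing
#'
#' Spike onsets are upward crossings of `threshold_slope` by dV/dt with a
#' refractory gap of at least 1 ms between onsets; the spike peak is the
#' local voltage maximum after the onset.
#'
#' @param sw A cclamp [sweep_record()].
#' @param threshold_slope Onset criterion in mV/ms (default 10).
#' @param refractory_ms Minimum onset separation (default 1).
#' @param peak_search_ms Window after onset searched for the peak (default 5).
#' @return Data frame with one row per spike: `onset_idx`, `peak_idx`,
#'   `onset_t`, `peak_t`, `threshold_v`, `peak_v`. Zero rows when no spikes.
#' @export
detect_spikes <- function(sw, threshold_slope = 10, refractory_ms = 1,
                          peak_search_ms = 5) {
  stopifnot(inherits(sw, "sweep"))
  if (sw$mode != "cclamp") stop("detect_spikes requires a cclamp sweep")
  v <- sw$primary
  dvdt <- c(NA, diff(v) / sw$dt)
  up <- which(dvdt >= threshold_slope & c(NA, dvdt[-length(dvdt)]) < threshold_slope)
  up <- up[!is.na(up)]
  up <- pmax(up - 1L, 1L)   # onset = last sample before the slope crossing
  onsets <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (sw$time[i] - last_t >= refractory_ms) {
      onsets <- c(onsets, i)
      last_t <- sw$time[i]
    }
  }
  if (length(onsets) == 0)
    return(data.frame(onset_idx = integer(0), peak_idx = integer(0),
                      onset_t = numeric(0), peak_t = numeric(0),
                      threshold_v = numeric(0), peak_v = numeric(0)))
  n <- length(v)
  peaks <- vapply(seq_along(onsets), function(k) {
    i <- onsets[k]
    lim <- min(n, i + round(peak_search_ms / sw$dt),
               if (k < length(onsets)) onsets[k + 1] - 1L else n)
    i - 1L + which.max(v[i:lim])
  }, integer(1))
  data.frame(onset_idx = onsets, peak_idx = peaks,
             onset_t = sw$time[onsets], peak_t = sw$time[peaks],
             threshold_v = v[onsets], peak_v = v[peaks])
}

# Half-width of one spike: duration at the voltage halfway between the dV/dt
# threshold crossing and the peak, with linear interpolation between samples.
.spike_half_width <- function(sw, onset_idx, peak_idx) {
  v <- sw$primary; t <- sw$time
  half <- (v[onset_idx] + v[peak_idx]) / 2
  i <- peak_idx
  while (i > onset_idx && v[i - 1] >= half) i <- i - 1
  t_up <- if (i == onset_idx || v[i] == half) t[i] else
    t[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) * sw$dt
  j <- peak_idx
  n <- length(v)
  while (j < n && v[j + 1] > half) j <- j + 1
  if (j == n) return(NA_real_)
  t_dn <- t[j] + (v[j] - half) / (v[j] - v[j + 1]) * sw$dt
  t_dn - t_up
}

#' Action-potential train features from a current-step family
#'
#' Applies the study conventions:
#' * `max_frequency`: spike count in the largest step divided by step
#'   duration (Hz).
#' * `rheobase`: amplitude of the step immediately preceding the first step
#'   that evokes a spike (the conventional first-spiking amplitude is also
#'   returned as `rheobase_first_spiking`).
#' * `ahp`: pre-step baseline minus the post-step voltage trough (mV,
#'   positive for hyperpolarization), measured on the largest step.
#' * `adaptation`: instantaneous frequency of the first AP pair divided by
#'   that of the last pair in the largest step (equivalently last ISI over
#'   first ISI); needs at least 3 spikes.
#' * `overshoot`: mean spike peak voltage above 0 mV over spikes of the first
#'   spiking sweep.
#' * `half_width`: spike duration at the voltage halfway between the dV/dt
#'   threshold crossing and the peak, averaged over spikes of the first
#'   spiking sweep (ms).
#'
#' Features that need spikes are `NA` when no step evokes any.
#'
#' @param sweeps List of cclamp [sweep_record()]s, one per step amplitude.
#' @param step_amplitudes Increasing current-step amplitudes in pA.
#' @param threshold_slope dV/dt spike criterion in mV/ms.
#' @param ahp_window_ms Post-step window searched for the AHP trough.
#' @return A list of class `ap_features`.
#' @export
ap_features <- function(sweeps, step_amplitudes, threshold_slope = 10,
                        ahp_window_ms = 200) {
  stopifnot(length(sweeps) == length(step_amplitudes))
  if (is.unsorted(step_amplitudes, strictly = TRUE))
    stop("step_amplitudes must be strictly increasing")
  spikes <- lapply(sweeps, function(sw) {
    sp <- detect_spikes(sw, threshold_slope)
    sp[sp$onset_t >= sw$step_window[1] & sp$onset_t <= sw$step_window[2], ]
  })
  counts <- vapply(spikes, nrow, integer(1))
  top <- length(sweeps)
  sw_top <- sweeps[[top]]
  dur_s <- diff(sw_top$step_window) / 1000
  max_frequency <- counts[top] / dur_s
  first_spiking <- if (any(counts > 0)) which(counts > 0)[1] else NA_integer_

  rheobase <- rheobase_first <- NA_real_
  overshoot <- half_width <- adaptation <- NA_real_
  if (!is.na(first_spiking)) {
    rheobase_first <- step_amplitudes[first_spiking]
    rheobase <- if (first_spiking > 1) step_amplitudes[first_spiking - 1] else NA_real_
    sp1 <- spikes[[first_spiking]]
    sw1 <- sweeps[[first_spiking]]
    overshoot <- mean(sp1$peak_v)
    hw <- vapply(seq_len(nrow(sp1)), function(k)
      .spike_half_width(sw1, sp1$onset_idx[k], sp1$peak_idx[k]), numeric(1))
    half_width <- mean(hw, na.rm = TRUE)
    if (counts[top] >= 3) {
      tt <- spikes[[top]]$peak_t
      isi_first <- tt[2] - tt[1]
      isi_last <- tt[length(tt)] - tt[length(tt) - 1]
      adaptation <- isi_last / isi_first
    }
  }
  pre <- sw_top$time < sw_top$step_window[1]
  post <- sw_top$time > sw_top$step_window[2] &
    sw_top$time <= sw_top$step_window[2] + ahp_window_ms
  ahp <- if (any(post)) mean(sw_top$primary[pre]) - min(sw_top$primary[post])
         else NA_real_
  structure(
    list(max_frequency = max_frequency, rheobase = rheobase,
         rheobase_first_spiking = rheobase_first, ahp = ahp,
         adaptation = adaptation, overshoot = overshoot,
         half_width = half_width, spike_counts = counts),
    class = "ap_features"
  )
}

# Single-exponential decay fit A * exp(-s / tau) by 1-D least squares over
# tau with the amplitude profiled out.
fit_exp_decay <- function(s, d, tau_range) {
  sse <- function(tau) {
    w <- exp(-s / tau)
    a <- sum(d * w) / sum(w * w)
    sum((d - a * w)^2)
  }
  tau <- stats::optimize(sse, tau_range)$minimum
  w <- exp(-s / tau)
  list(tau = tau, amplitude = sum(d * w) / sum(w * w))
}

#' Detect spontaneous IPSCs in a voltage-clamp trace
#'
#' Events are deflections of the recorded current exceeding `amp_threshold`
#' relative to a running-median local baseline, with a rise faster than the
#' decay. Event amplitude is the peak deviation from baseline; the decay time
#' constant is a single-exponential least-squares fit over `tau_fit_window`
#' after the peak.
#'
#' @param sw A vclamp [sweep_record()] at fixed holding potential.
#' @param amp_threshold Detection threshold in pA (default 10).
#' @param tau_fit_window Fit window after the peak in ms (default 50).
#' @param polarity `-1` for inward (downward) events, `+1` for outward.
#' @param baseline_window_ms Running-median window (default 200).
#' @param max_rise_ms Maximum threshold-to-peak rise time (default 5).
#' @param min_above_ms Minimum time the deviation must stay above
#'   `amp_threshold` (default 1 ms), rejecting narrow noise spikes.
#' @return An object of class `event_list`: data frame with `onset_t`,
#'   `peak_t`, `amplitude` (pA, positive) and `decay_tau` (ms), plus
#'   attribute `duration_s`.
#' @export
detect_sipscs <- function(sw, amp_threshold = 10, tau_fit_window = 50,
                          polarity = -1, baseline_window_ms = 200,
                          max_rise_ms = 5, min_above_ms = 1) {
  stopifnot(inherits(sw, "sweep"))
  if (sw$mode != "vclamp") stop("detect_sipscs requires a vclamp sweep")
  x <- sw$primary
  k <- 2L * floor(baseline_window_ms / sw$dt / 2) + 1L
  k <- min(k, if (length(x) %% 2 == 1) length(x) else length(x) - 1L)
  base <- stats::runmed(x, k, endrule = "median")
  dev <- polarity * (x - base)
  # hysteresis run closure: an event opens above amp_threshold and closes
  # when the deviation falls below half of it, so tail noise does not split
  # one event into several
  r <- rle(dev > amp_threshold / 2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    if (sum(dev[a:b] > amp_threshold) < max(1L, round(min_above_ms / sw$dt)))
      next
    pk <- a - 1L + which.max(dev[a:b])
    rise <- (pk - a) * sw$dt
    if (rise > max_rise_ms) next
    lim <- min(length(x), pk + round(tau_fit_window / sw$dt))
    seg <- dev[pk:lim]
    # truncate at the rebound of an overlapping next event
    rebound <- which(seg > cummin(seg) + 0.25 * seg[1])
    if (length(rebound) && rebound[1] > 3) seg <- seg[seq_len(rebound[1] - 1)]
    fit <- fit_exp_decay((seq_along(seg) - 1) * sw$dt, seg,
                         c(sw$dt / 2, 4 * tau_fit_window))
    if (fit$tau <= rise) next          # decay must outlast the rise
    rows[[length(rows) + 1L]] <- data.frame(
      onset_t = sw$time[a], peak_t = sw$time[pk],
      amplitude = dev[pk], decay_tau = fit$tau)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_t = numeric(0), peak_t = numeric(0),
               amplitude = numeric(0), decay_tau = numeric(0))
  attr(out, "duration_s") <- diff(range(sw$time)) / 1000
  class(out) <- c("event_list", class(out))
  out
}

#' Summary statistics of detected synaptic events
#'
#' With several sweeps, amplitude and decay are averaged within each sweep
#' first and then across sweeps; frequency is the mean of per-sweep
#' count-over-duration rates.
#'
#' @param events An `event_list` or a list of them.
#' @param duration Recording duration per sweep in seconds; default taken
#'   from the `duration_s` attribute.
#' @return List with `frequency` (Hz), `mean_amplitude` (pA), `mean_decay`
#'   (ms) and `n_events`. Amplitude/decay are `NA` when no events.
#' @export
event_stats <- function(events, duration = NULL) {
  if (inherits(events, "event_list")) events <- list(events)
  if (is.null(duration))
    duration <- vapply(events, function(e) attr(e, "duration_s"), numeric(1))
  duration <- rep_len(duration, length(events))
  if (any(duration <= 0)) stop("duration must be > 0")
  freqs <- mapply(function(e, d) nrow(e) / d, events, duration)
  amps <- vapply(events, function(e)
    if (nrow(e)) mean(e$amplitude) else NA_real_, numeric(1))
  decs <- vapply(events, function(e)
    if (nrow(e)) mean(e$decay_tau) else NA_real_, numeric(1))
  n <- sum(vapply(events, nrow, integer(1)))
  list(frequency = mean(freqs),
       mean_amplitude = if (all(is.na(amps))) NA_real_ else mean(amps, na.rm = TRUE),
       mean_decay = if (all(is.na(decs))) NA_real_ else mean(decs, na.rm = TRUE),
       n_events = n)
}

#' Read a long-format sweep CSV
#'
#' Columns `t_ms`, `primary` and optionally `command`; metadata supplied as
#' arguments.
#'
#' @param path CSV path.
#' @inheritParams sweep_record
#' @return A [sweep_record()].
#' @export
read_sweep <- function(path, mode = c("vclamp", "cclamp"), step_window = NULL) {
  d <- utils::read.csv(path)
  sweep_record(d$t_ms, d$primary,
               command = if ("command" %in% names(d)) d$command else NULL,
               mode = mode, step_window = step_window)
}
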