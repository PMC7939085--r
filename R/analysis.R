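# Quantitative readouts: response amplitudes, step-criterion spike
# thresholds, attenuation profiles, axial currents, source/sink ratios,
# PSTHs and burst-pause statistics.

#' Dendritic response amplitude of a trace
#'
#' Maximum voltage in the response window minus the baseline, where the
#' baseline is the median over the pre-stimulus window (median rather than
#' mean so a backpropagated somatic spike inside the baseline window does
#' not bias it).
#'
#' @param t time base, ms
#' @param v voltage trace, mV
#' @param stimulus_time ms
#' @param baseline_window ms before the stimulus (default 50)
#' @param response_window ms after the stimulus (default 20)
#' @return amplitude, mV
#' @export
response_amplitude <- function(t, v, stimulus_time, baseline_window = 50,
                               response_window = 20) {
  base_idx <- t >= stimulus_time - baseline_window & t < stimulus_time
  resp_idx <- t >= stimulus_time & t <= stimulus_time + response_window
  if (!any(base_idx) || !any(resp_idx)) stop("empty analysis window")
  max(v[resp_idx]) - median(v[base_idx])
}

#' Detect the dendritic spike threshold from an input-output curve
#'
#' Implements the step criterion: fit a line to the per-n mean amplitudes of
#' the sub-threshold segment and report the smallest `n` at which at least
#' `frac` of trials exceed the linear prediction by `jump_mV`. The
#' sub-threshold fit uses the n values below the candidate step (at least
#' the two smallest).
#'
#' @param curve data.frame with columns `n` and `amplitude` (one row per
#'   trial)
#' @param jump_mV step size above the linear extrapolation (default 10)
#' @param frac fraction of trials that must jump (default 0.5)
#' @return list with `threshold` (synapse count or `NA`), and per-n
#'   `spike_fraction`
#' @export
detect_dendritic_spike_threshold <- function(curve, jump_mV = 10, frac = 0.5) {
  ns <- sort(unique(curve$n))
  if (length(ns) < 2) stop("need >= 2 synapse counts")
  spike_frac <- setNames(numeric(length(ns)), ns)
  threshold <- NA_integer_
  # the two smallest counts anchor the sub-threshold fit; each further count
  # joins the fit only while it has not jumped, so the extrapolation always
  # reflects the linear (no-spike) segment
  mean_amp <- vapply(ns, function(k) {
    a <- curve$amplitude[curve$n == k]
    if (any(a > stats::quantile(a, 0.5) + jump_mV)) median(a) else mean(a)
  }, numeric(1))
  sub <- ns[1:2]
  for (i in seq_along(ns)) {
    if (i <= 2) {
      spike_frac[i] <- 0
      next
    }
    fit_x <- sub
    fit_y <- mean_amp[match(sub, ns)]
    fit <- lm(fit_y ~ fit_x)
    pred <- unname(coef(fit)[1] + coef(fit)[2] * ns[i])
    amps <- curve$amplitude[curve$n == ns[i]]
    spike_frac[i] <- mean(amps > pred + jump_mV)
    if (is.na(threshold) && spike_frac[i] >= frac) threshold <- ns[i]
    if (spike_frac[i] < frac) sub <- c(sub, ns[i])
  }
  list(threshold = threshold, spike_fraction = spike_frac)
}

#' Somatopetal attenuation profile of a dendritic spike
#'
#' Given response peaks at sites of increasing path distance from the
#' initiation site, interpolates peak-vs-distance and reports the percent
#' decay over a given propagation distance.
#'
#' @param distances path distances from the initiation site, um (ascending)
#' @param peaks response peak amplitudes at those sites, mV
#' @param over propagation distance for the summary decay, um (default 50)
#' @return list with `profile` (data.frame distance/peak/percent_of_origin)
#'   and `decay_percent` over `over` um
#' @export
attenuation_profile <- function(distances, peaks, over = 50) {
  if (length(distances) < 2) stop("need >= 2 sites")
  if (is.unsorted(distances, strictly = TRUE)) stop("distances must be ascending")
  pct <- 100 * peaks / peaks[1]
  p_at <- approx(distances, pct, xout = distances[1] + over, rule = 2)$y
  list(profile = data.frame(distance = distances, peak = peaks,
                            percent_of_origin = pct),
       decay_percent = 100 - p_at)
}

#' Axial current between two recorded sites
#'
#' Ohm's law on the voltage difference: `I = (V_a - V_b) / r_a` in nA
#' (mV/MOhm), positive flowing a to b.
#'
#' @param t shared time base, ms
#' @param v_a,v_b voltage traces, mV
#' @param r_a axial resistance between the sites, MOhm
#' @return list with `t`, `i_ax` (nA) and `peak` (max |i_ax|)
#' @export
axial_current <- function(t, v_a, v_b, r_a) {
  if (length(v_a) != length(v_b) || length(v_a) != length(t))
    stop("traces must share a time base")
  if (r_a <= 0) stop("r_a must be positive")
  i <- (v_a - v_b) / r_a
  list(t = t, i_ax = i, peak = max(abs(i)))
}

#' Source/sink ratio of a branch
#'
#' Branch membrane area (the "source", measuring available Ca channels)
#' divided by the peak axial current drained into the rest of the tree (the
#' "sink"), um2/nA. Larger ratios predict higher branch excitability.
#'
#' @param area branch membrane area, um2
#' @param peak_iax peak |axial current|, nA
#' @return ratio, um2/nA
#' @export
source_sink_ratio <- function(area, peak_iax) {
  if (any(peak_iax <= 0)) stop("peak axial current must be positive")
  area / peak_iax
}

#' Detect somatic spikes in a voltage trace
#'
#' Upward crossings of the threshold with a refractory lockout; spike time
#' is the crossing sample. (The solver detects spikes online with the same
#' rule at full dt resolution; this trace-based detector exists for
#' cross-checking and for analysing exported traces.)
#'
#' @param t time base, ms
#' @param v voltage trace, mV
#' @param thresh threshold, mV (default -20)
#' @param refractory lockout, ms (default 1)
#' @return spike times, ms
#' @export
detect_somatic_spikes <- function(t, v, thresh = -20, refractory = 1) {
  up <- which(v[-1] >= thresh & v[-length(v)] < thresh) + 1L
  times <- t[up]
  if (!length(times)) return(numeric())
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce lockout sequentially
  out <- times[1]
  for (x in times[-1]) if (x - out[length(out)] >= refractory) out <- c(out, x)
  out
}

#' Peristimulus time histogram
#'
#' @param spike_trials list of spike-time vectors (ms), one per trial,
#'   already aligned to the stimulus (stimulus at `stimulus_time`)
#' @param bin bin width, ms (default 2)
#' @param window `c(lo, hi)` ms around which to histogram
#' @param stimulus_time ms
#' @return list of class `pc_psth`: `edges`, `mid`, `rate` (Hz), `trials`,
#'   `bin`, `stimulus_time`
#' @export
compute_psth <- function(spike_trials, bin = 2, window = c(-200, 150),
                         stimulus_time = 0) {
  if (bin <= 0) stop("bin width must be positive")
  if (!length(spike_trials)) stop("need >= 1 trial")
  edges <- seq(window[1], window[2], by = bin)
  all_rel <- unlist(spike_trials, use.names = FALSE) - stimulus_time
  all_rel <- all_rel[all_rel >= window[1] & all_rel < window[2]]
  counts <- if (length(all_rel)) {
    hist(all_rel, breaks = edges, plot = FALSE, right = FALSE)$counts
  } else rep(0L, length(edges) - 1)
  structure(list(edges = edges, mid = edges[-length(edges)] + bin / 2,
                 rate = counts / (length(spike_trials) * bin * 1e-3),
                 trials = length(spike_trials), bin = bin,
                 stimulus_time = stimulus_time),
            class = "pc_psth")
}

#' Burst-pause statistics from a PSTH
#'
#' Baseline = mean rate over `[-200, 0)` ms; `max_rate` = maximum bin in
#' `(0, 30]` ms after the stimulus; `pause_duration` = total length of the
#' first contiguous run of bins, starting after the burst peak, whose rate
#' falls below `pause_frac * baseline` (0 if none).
#'
#' @param psth `pc_psth`
#' @param pause_frac pause criterion as a fraction of baseline (default 0.2)
#' @param burst_window ms after stimulus searched for the burst (default 30)
#' @return list with `baseline_rate`, `max_rate` (Hz), `pause_duration` (ms)
#' @export
burst_pause_stats <- function(psth, pause_frac = 0.2, burst_window = 30) {
  mid <- psth$mid
  pre <- mid >= -200 & mid < 0
  if (!any(pre)) stop("PSTH lacks a pre-stimulus window")
  baseline <- mean(psth$rate[pre])
  burst <- mid > 0 & mid <= burst_window
  max_rate <- if (any(burst)) max(psth$rate[burst]) else baseline
  peak_bin <- which(burst)[which.max(psth$rate[burst])]
  post <- which(seq_along(mid) > peak_bin)
  low <- psth$rate[post] < pause_frac * baseline
  pause <- 0
  if (any(low)) {
    first_low <- which(low)[1]
    run_end <- first_low
    while (run_end < length(low) && low[run_end + 1]) run_end <- run_end + 1
    pause <- (run_end - first_low + 1) * psth$bin
  }
  list(baseline_rate = baseline, max_rate = max_rate, pause_duration = pause)
}

#' @importFrom graphics hist
#' @importFrom stats approx
NULL
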