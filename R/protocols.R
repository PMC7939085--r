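# Protocol runners: each composes morphology, mechanisms, synthetic inputs
# and the solver into one of the model's standard experiments and returns a
# structured result for the analysis module.

#' Full model configuration
#'
#' @return nested list: `morphology`, `channels`, `densities`, `capool`,
#'   `sim` (solver and trial timing parameters)
#' @export
pc_config <- function() {
  list(morphology = morphology_config(),
       channels = default_channels(),
       densities = default_densities(),
       capool = default_capools(),
       sim = list(dt = 0.025, dt_out = 0.1, settle = 1500, jitter_max = 25,
                  stim_time = 60, baseline = 50, response = 20))
}

#' Assemble the reduced Purkinje-cell model
#'
#' Builds the section tree, discretizes it, and attaches the mechanism set.
#'
#' @param config list from [pc_config()]
#' @return list of class `pc_model`: `graph`, `mech`, `config`, `hash`
#' @export
pc_model <- function(config = pc_config()) {
  sections <- build_reduced_pc(config$morphology)
  graph <- discretize(sections,
                      rule = list(max_len = config$morphology$discretization$max_len),
                      passive = config$morphology$passive)
  mech <- mechanism_set(graph, config$channels, config$densities,
                        config$capool)
  structure(list(graph = graph, mech = mech, config = config,
                 hash = config_hash(config)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model (%d compartments, hash %s)\n", x$graph$n,
              substr(x$hash, 1, 8)))
  invisible(x)
}

# Standard recording sites for a branch: tip (initiation site), distal and
# proximal main dendrite, soma.
branch_sites <- function(graph, branch_id) {
  key <- as.character(branch_id)
  members <- graph$branch_index[[key]]
  tip <- members[which.max(graph$comps$dist_soma[members])]
  conn <- graph$connection_segment[[key]]
  distal_main <- graph$comps$parent[conn]
  limb <- graph$comps$limb_id[distal_main]
  limb_comps <- graph$comps$id[!is.na(graph$comps$limb_id) &
                                graph$comps$limb_id == limb &
                                graph$comps$region == "main"]
  proximal_main <- limb_comps[which.min(graph$comps$dist_soma[limb_comps])]
  c(tip = tip, distal_main = distal_main, proximal_main = proximal_main,
    soma = graph$soma)
}

holding_program <- function(model, hold_nA) {
  prog <- stimulus_program()
  if (hold_nA != 0)
    prog <- inject_current(prog, model$graph$soma, hold_nA)
  prog
}

# Settled-state cache: settling to the tonic regime is deterministic per
# (mechanism set, holding current), so protocols share it across trials.
.settle_cache <- new.env(parent = emptyenv())

settled_state <- function(model, hold_nA = 0, mech = model$mech) {
  key <- config_hash(list(model$hash, hold_nA, mech$gdens))
  if (!is.null(.settle_cache[[key]])) return(.settle_cache[[key]])
  st <- settle_state(model$graph, mech, holding_program(model, hold_nA),
                     duration = model$config$sim$settle,
                     dt = model$config$sim$dt)
  .settle_cache[[key]] <- st
  st
}

# Advance a settled state by the per-trial jitter extension (0-25 ms,
# rounded to the solver grid) to de-phase the tonic cycle across trials.
jitter_state <- function(model, state, hold_nA, seed, mech = model$mech) {
  jmax <- model$config$sim$jitter_max
  dt <- model$config$sim$dt
  j <- with_seed(seed, runif(1, 0, jmax))
  j <- max(dt, round(j / dt) * dt)
  rec <- run_simulation(model$graph, mech, holding_program(model, hold_nA),
                        recorder_spec(v = model$graph$soma), tstop = j,
                        dt = dt, dt_out = j, init = state)
  rec$state
}

# One synchronous-activation trial; returns the recording.
clustered_trial <- function(model, branch_id, n_syn, seed, hold_nA = 0,
                            mech = model$mech, ffi = NULL, partner = NULL,
                            recorders = NULL, state = NULL,
                            background = NULL, tstop = NULL) {
  sim <- model$config$sim
  if (is.null(state)) state <- settled_state(model, hold_nA, mech)
  state <- jitter_state(model, state, hold_nA, sub_seed(seed, 7L), mech)
  prog <- holding_program(model, hold_nA)
  if (n_syn > 0) {
    plan <- place_clustered_synapses(model$graph, branch_id, n_syn,
                                     sub_seed(seed, 1L))
    prog <- add_synapses(prog, clustered_synapse_table(plan, sim$stim_time))
  }
  if (!is.null(partner) && partner$n > 0) {
    plan2 <- place_clustered_synapses(model$graph, partner$branch_id,
                                      partner$n, sub_seed(seed, 2L))
    prog <- add_synapses(prog, clustered_synapse_table(plan2, sim$stim_time))
  }
  if (!is.null(ffi) && ffi$n_stellate > 0) {
    prog <- add_synapses(prog, schedule_ffi(model$graph, branch_id,
                                            sim$stim_time, ffi$n_stellate,
                                            ffi$delay, sub_seed(seed, 3L)))
  }
  if (!is.null(background)) prog <- add_synapses(prog, background)
  if (is.null(recorders))
    recorders <- recorder_spec(v = branch_sites(model$graph, branch_id))
  if (is.null(tstop)) tstop <- sim$stim_time + sim$response + 10
  run_simulation(model$graph, mech, prog, recorders, tstop = tstop,
                 dt = sim$dt, dt_out = sim$dt_out, init = state)
}

#' Input-output curve of a branch
#'
#' For each synapse count and trial, a fresh random clustered placement is
#' activated synchronously once; tip and distal-main response amplitudes are
#' extracted. Optional feed-forward inhibition (`ffi = list(n_stellate,
#' delay)`) and a co-activated partner branch (`partner = list(branch_id,
#' n)`; `n = NA` matches the stimulated count) ride on every trial.
#'
#' @param model `pc_model`
#' @param branch_id stimulated branch
#' @param n_range synapse counts (default 5-70 step 5)
#' @param trials placements per count (default 10)
#' @param hold_nA somatic holding current
#' @param seed integer seed; trial seeds derive from it, independent of the
#'   order conditions are run in
#' @param ffi optional inhibition, `list(n_stellate, delay)` (ms, negative =
#'   preceding)
#' @param partner optional co-activation, `list(branch_id, n)`
#' @param mech optional mechanism override (density scaling experiments)
#' @return list of class `pc_io_curve`: `curve` (n, trial, amplitude,
#'   amplitude_main), `threshold`, `spike_fraction`, parameters and seeds
#' @export
run_io_curve <- function(model, branch_id, n_range = seq(5, 70, by = 5),
                         trials = 10, hold_nA = 0, seed = 1, ffi = NULL,
                         partner = NULL, mech = model$mech) {
  sim <- model$config$sim
  rows <- list()
  for (n in n_range) {
    for (tr in seq_len(trials)) {
      s <- sub_seed(seed, n, tr)
      p <- partner
      if (!is.null(p) && is.na(p$n)) p$n <- n
      rec <- clustered_trial(model, branch_id, n, s, hold_nA, mech,
                             ffi = ffi, partner = p)
      amp <- response_amplitude(rec$t, rec$v[, "tip"], sim$stim_time,
                                sim$baseline, sim$response)
      ampm <- response_amplitude(rec$t, rec$v[, "distal_main"], sim$stim_time,
                                 sim$baseline, sim$response)
      rows[[length(rows) + 1L]] <- data.frame(n = n, trial = tr,
                                              amplitude = amp,
                                              amplitude_main = ampm,
                                              seed = s)
    }
  }
  curve <- do.call(rbind, rows)
  det <- detect_dendritic_spike_threshold(curve)
  structure(list(curve = curve, threshold = det$threshold,
                 spike_fraction = det$spike_fraction,
                 branch_id = branch_id, n_range = n_range, trials = trials,
                 hold_nA = hold_nA, ffi = ffi, partner = partner,
                 seed = seed, hash = model$hash),
            class = "pc_io_curve")
}

#' @export
print.pc_io_curve <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "none" else paste(x$threshold, "synapses")
  cat(sprintf("pc_io_curve: branch %d, hold %.2f nA, threshold %s\n",
              x$branch_id, x$hold_nA, thr))
  invisible(x)
}

#' PF burst-train protocol
#'
#' A train of `n_stim` stimuli at `freq` Hz; at each stimulus a fresh random
#' placement of `syn_per_stim` PF synapses in the branch is activated
#' synchronously. Returns dendritic-tip and somatic traces plus a simple
#' dendritic-spike flag (tip depolarising beyond -30 mV).
#'
#' @param model `pc_model`
#' @param branch_id stimulated branch
#' @param n_stim stimuli in the train (default 10)
#' @param freq train rate, Hz (default 200)
#' @param syn_per_stim synapses per stimulus (default 10)
#' @param hold_nA somatic holding current
#' @param seed integer seed
#' @return list of class `pc_burst`: `recording`, `stim_times`,
#'   `dendritic_spike` (logical), `tip_max`
#' @export
run_burst_protocol <- function(model, branch_id, n_stim = 10, freq = 200,
                               syn_per_stim = 10, hold_nA = 0, seed = 1) {
  sim <- model$config$sim
  state <- settled_state(model, hold_nA)
  state <- jitter_state(model, state, hold_nA, sub_seed(seed, 7L))
  prog <- holding_program(model, hold_nA)
  stim_times <- sim$stim_time + (seq_len(n_stim) - 1) * 1000 / freq
  for (k in seq_len(max(n_stim, 0))) {
    plan <- place_clustered_synapses(model$graph, branch_id, syn_per_stim,
                                     sub_seed(seed, 10L + k))
    prog <- add_synapses(prog, clustered_synapse_table(plan, stim_times[k]))
  }
  sites <- branch_sites(model$graph, branch_id)
  tstop <- sim$stim_time + n_stim * 1000 / freq + 30
  if (n_stim == 0) tstop <- sim$stim_time + 30
  rec <- run_simulation(model$graph, model$mech, prog,
                        recorder_spec(v = sites), tstop = tstop,
                        dt = sim$dt, dt_out = sim$dt_out, init = state)
  tip_max <- max(rec$v[rec$t >= sim$stim_time, "tip"])
  structure(list(recording = rec, stim_times = stim_times[seq_len(n_stim)],
                 dendritic_spike = tip_max > -30, tip_max = tip_max,
                 branch_id = branch_id, hold_nA = hold_nA, seed = seed),
            class = "pc_burst")
}

#' Record a dendritic spike waveform for the sink assay
#'
#' Triggers a reliably supra-threshold volley on the canonical branch and
#' records the membrane potential at the distal main dendrite (the
#' attachment site), returning it as a clamp waveform.
#'
#' @param model `pc_model`
#' @param branch_id source branch (default 8)
#' @param n_syn synapse count (default 50)
#' @param seed integer seed
#' @return list `t`, `v` usable with [waveform_clamp()]
#' @export
record_spike_waveform <- function(model, branch_id = 8, n_syn = 50, seed = 1) {
  sim <- model$config$sim
  rec <- clustered_trial(model, branch_id, n_syn, sub_seed(seed, 4L), 0)
  list(t = rec$t, v = rec$v[, "distal_main"])
}

#' Sink assay: clamp each connection segment with a spike waveform
#'
#' For each branch separately, the unique compartment connecting it to the
#' main dendrite is ideally clamped to the supplied spike waveform while the
#' rest of the tree evolves freely; the peak axial current flowing from the
#' connection segment into the parent main dendrite measures the branch's
#' current sink. The ratio branch area / peak sink current is the
#' source/sink excitability measure.
#'
#' @param model `pc_model`
#' @param waveform list `t`, `v` from [record_spike_waveform()]
#' @param branch_ids branches to assay (default all 22)
#' @return data.frame of class `pc_sink_assay`: `branch_id`, `peak_iax_nA`,
#'   `area_um2`, `ratio`
#' @export
run_sink_assay <- function(model, waveform, branch_ids = 1:22) {
  if (is.null(waveform)) stop("a recorded spike waveform is required")
  graph <- model$graph
  state <- settled_state(model, 0)
  rows <- lapply(branch_ids, function(b) {
    conn <- graph$connection_segment[[as.character(b)]]
    par <- graph$comps$parent[conn]
    rec <- waveform_clamp(graph, model$mech, conn, waveform,
                          recorder_spec(v = graph$soma,
                                        iax = data.frame(a = conn, b = par)),
                          tstop = max(waveform$t), init = state,
                          dt = model$config$sim$dt)
    area <- sum(graph$comps$area[graph$branch_index[[as.character(b)]]])
    peak <- max(abs(rec$iax[, 1]))
    data.frame(branch_id = b, peak_iax_nA = peak, area_um2 = area,
               ratio = source_sink_ratio(area, peak))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pc_sink_assay", "data.frame")
  out
}

#' Two-branch co-activation protocol
#'
#' The same number of PF synapses is activated simultaneously in two
#' branches; the threshold of the primary branch is extracted with and
#' without the partner.
#'
#' @param model `pc_model`
#' @param branch_a primary branch
#' @param branch_b partner branch (distinct)
#' @param n_range,trials,seed as in [run_io_curve()]
#' @return list with `solo` and `paired` io-curves and their thresholds
#' @export
run_coactivation <- function(model, branch_a, branch_b,
                             n_range = seq(5, 70, by = 5), trials = 10,
                             seed = 1) {
  if (branch_a == branch_b) stop("co-activation needs two distinct branches")
  solo <- run_io_curve(model, branch_a, n_range, trials, seed = seed)
  paired <- run_io_curve(model, branch_a, n_range, trials, seed = seed,
                         partner = list(branch_id = branch_b, n = NA))
  list(solo = solo, paired = paired,
       threshold_solo = solo$threshold, threshold_paired = paired$threshold,
       branch_a = branch_a, branch_b = branch_b)
}

#' Branch channel-density scaling protocol
#'
#' Scales all active channel densities of one branch by each factor and
#' reruns the io-curve with the same seeds. At the largest factor a
#' localization map is recorded during a supra-threshold volley: peak
#' depolarisation inside the scaled branch versus in every other branch.
#'
#' @param model `pc_model`
#' @param branch_id scaled branch
#' @param factors density multipliers (default 1:4)
#' @param n_range,trials,seed as in [run_io_curve()]
#' @return list of class `pc_density_scaling`: per-factor io-curves and
#'   thresholds, plus `localization` (data.frame branch_id, peak_mV) at the
#'   largest factor
#' @export
run_density_scaling <- function(model, branch_id, factors = 1:4,
                                n_range = seq(5, 70, by = 5), trials = 10,
                                seed = 1) {
  graph <- model$graph
  io <- list()
  for (f in factors) {
    mech_f <- mechanism_scaling(model$mech, graph, branch_id, f)
    io[[as.character(f)]] <- run_io_curve(model, branch_id, n_range, trials,
                                          seed = seed, mech = mech_f)
  }
  fmax <- max(factors)
  mech_f <- mechanism_scaling(model$mech, graph, branch_id, fmax)
  # localization: supra-threshold volley, record every branch tip
  thr <- io[[as.character(fmax)]]$threshold
  n_loc <- if (is.na(thr)) max(n_range) else min(max(n_range), thr + 10)
  tips <- vapply(as.character(1:22), function(b) {
    members <- graph$branch_index[[b]]
    members[which.max(graph$comps$dist_soma[members])]
  }, numeric(1))
  rec <- clustered_trial(model, branch_id, n_loc, sub_seed(seed, 5L), 0,
                         mech = mech_f,
                         recorders = recorder_spec(v = tips))
  sim <- model$config$sim
  peaks <- vapply(seq_along(tips), function(j)
    response_amplitude(rec$t, rec$v[, j], sim$stim_time, sim$baseline,
                       sim$response), numeric(1))
  structure(list(io = io,
                 thresholds = vapply(io, function(x)
                   as.numeric(x$threshold %||% NA), numeric(1)),
                 localization = data.frame(branch_id = 1:22, peak_mV = peaks,
                                           n_syn = n_loc),
                 branch_id = branch_id, factors = factors, seed = seed),
            class = "pc_density_scaling")
}

#' Inhibition sweep protocol
#'
#' Thresholds on a grid of stellate-cell counts and inhibition delays, with
#' both PF and stellate synapses placed within the stimulated branch.
#' Optionally reproduces the resting IPSP measurement (soma held near
#' -71.8 mV by a -0.4 nA holding current) for the linearity check.
#'
#' @param model `pc_model`
#' @param branch_id stimulated branch
#' @param n_stellate_range stellate-cell counts
#' @param delays inhibition timing relative to PF, ms
#' @param n_range,trials,seed as in [run_io_curve()]
#' @return list of class `pc_inhibition_sweep`: `grid` (data.frame
#'   n_stellate, delay, threshold) and the per-cell io-curves
#' @export
run_inhibition_sweep <- function(model, branch_id,
                                 n_stellate_range = c(2, 8, 13),
                                 delays = 1.4, n_range = seq(5, 70, by = 5),
                                 trials = 10, seed = 1) {
  rows <- list()
  ios <- list()
  for (ns in n_stellate_range) {
    for (d in delays) {
      io <- run_io_curve(model, branch_id, n_range, trials, seed = seed,
                         ffi = list(n_stellate = ns, delay = d))
      key <- sprintf("s%02d_d%+.1f", ns, d)
      ios[[key]] <- io
      rows[[key]] <- data.frame(n_stellate = ns, delay = d,
                                threshold = as.numeric(io$threshold %||% NA))
    }
  }
  structure(list(grid = do.call(rbind, rows), io = ios,
                 branch_id = branch_id, seed = seed),
            class = "pc_inhibition_sweep")
}

#' Dendritic-tip IPSP amplitude versus inhibition strength
#'
#' The model is silenced by a somatic holding current that brings the soma
#' near -71.8 mV (-1.1 nA in this reduced cell); each stellate-cell count is
#' activated once and the tip-hyperpolarisation amplitude recorded.
#'
#' @param model `pc_model`
#' @param branch_id branch carrying the inhibitory synapses
#' @param n_stellate_range cell counts (default 2-13)
#' @param seed integer seed
#' @param hold somatic holding current, nA
#' @return data.frame `n_stellate`, `ipsp_mV` (positive amplitudes)
#' @export
run_ipsp_curve <- function(model, branch_id = 8, n_stellate_range = 2:13,
                           seed = 1, hold = -1.1) {
  sim <- model$config$sim
  state <- settled_state(model, hold)
  sites <- branch_sites(model$graph, branch_id)
  rows <- lapply(n_stellate_range, function(ns) {
    prog <- holding_program(model, hold)
    # one seed across counts: cell placements are nested, so the curve
    # reflects recruitment of a fixed stellate population
    prog <- add_synapses(prog, schedule_ffi(model$graph, branch_id,
                                            sim$stim_time, ns, 0,
                                            sub_seed(seed, 17L)))
    rec <- run_simulation(model$graph, model$mech, prog,
                          recorder_spec(v = sites),
                          tstop = sim$stim_time + 60, dt = sim$dt,
                          dt_out = sim$dt_out, init = state)
    base_idx <- rec$t >= sim$stim_time - sim$baseline & rec$t < sim$stim_time
    resp_idx <- rec$t >= sim$stim_time & rec$t <= sim$stim_time + 40
    ipsp <- median(rec$v[base_idx, "tip"]) - min(rec$v[resp_idx, "tip"])
    data.frame(n_stellate = ns, ipsp_mV = ipsp)
  })
  do.call(rbind, rows)
}

#' PSTH protocol: trial-averaged somatic spiking around a PF volley
#'
#' Per trial: fresh placement seed, settle-jitter, optional fresh background
#' bombardment; somatic spike times are collected and the PSTH plus
#' burst-pause statistics computed. With two branches the same synapse count
#' is placed in each.
#'
#' @param model `pc_model`
#' @param branch_ids one or two branches
#' @param n_syn synapses per branch
#' @param trials number of trials (reference grid 500; default 100, the
#'   scaled-down grid this package evaluates routinely)
#' @param background logical, in-vivo-like bombardment on/off
#' @param seed integer seed
#' @param window PSTH window around the volley, ms
#' @return list of class `pc_psth_result`: `psth`, `stats`
#'   ([burst_pause_stats()]), `spike_trials`, parameters
#' @export
run_psth_condition <- function(model, branch_ids, n_syn, trials = 100,
                               background = FALSE, seed = 1,
                               window = c(-200, 150)) {
  stopifnot(trials >= 1, length(branch_ids) %in% 1:2)
  sim <- model$config$sim
  pre <- -window[1]
  post <- window[2]
  state0 <- settled_state(model, 0)
  ens <- background_ensemble()
  spike_trials <- vector("list", trials)
  for (tr in seq_len(trials)) {
    s <- sub_seed(seed, 31L, tr)
    state <- jitter_state(model, state0, 0, sub_seed(s, 7L))
    prog <- stimulus_program()
    t_stim <- pre + 20   # 20 ms guard so conductances settle before window
    for (j in seq_along(branch_ids)) {
      plan <- place_clustered_synapses(model$graph, branch_ids[j], n_syn,
                                       sub_seed(s, j))
      prog <- add_synapses(prog, clustered_synapse_table(plan, t_stim))
    }
    if (background) {
      bg <- generate_background_trains(model$graph, ens,
                                       duration = t_stim + post,
                                       seed = sub_seed(s, 5L))
      prog <- add_synapses(prog, bg)
    }
    rec <- run_simulation(model$graph, model$mech, prog,
                          recorder_spec(v = model$graph$soma),
                          tstop = t_stim + post, dt = sim$dt,
                          dt_out = sim$dt_out, init = state)
    spike_trials[[tr]] <- rec$spikes - t_stim
  }
  psth <- compute_psth(spike_trials, bin = 2, window = window,
                       stimulus_time = 0)
  structure(list(psth = psth, stats = burst_pause_stats(psth),
                 spike_trials = spike_trials, branch_ids = branch_ids,
                 n_syn = n_syn, trials = trials, background = background,
                 seed = seed),
            class = "pc_psth_result")
}

#' @export
print.pc_psth_result <- function(x, ...) {
  cat(sprintf(
    "pc_psth_result: branch %s, %d synapses, %d trials | max %.0f Hz, pause %.0f ms\n",
    paste(x$branch_ids, collapse = "&"), x$n_syn, x$trials,
    x$stats$max_rate, x$stats$pause_duration))
  invisible(x)
}
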