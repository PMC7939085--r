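# R-side driver for the compiled cable solver: stimulus programs,
# recorders, initialisation/settle handling, and the ideal waveform clamp.

#' Create an empty stimulus program
#'
#' A stimulus program collects synapses (with their event trains), constant
#' current injections, and at most one ideal voltage clamp.
#'
#' @return list of class `stimulus_program`
#' @export
stimulus_program <- function() {
  structure(list(synapses = empty_synapse_table(),
                 injections = data.frame(comp = integer(), amp = numeric(),
                                         t0 = numeric(), t1 = numeric()),
                 vclamp = NULL),
            class = "stimulus_program")
}

#' Append a constant current injection
#'
#' Overlapping injections at one compartment sum.
#'
#' @param program `stimulus_program`
#' @param comp compartment id
#' @param amp amplitude, nA (positive depolarising)
#' @param window `c(start, stop)` ms; defaults to the whole run
#' @return updated program
#' @export
inject_current <- function(program, comp, amp, window = c(0, Inf)) {
  program$injections <- rbind(program$injections,
                              data.frame(comp = comp, amp = amp,
                                         t0 = window[1], t1 = window[2]))
  program
}

#' Attach synapses to a stimulus program
#'
#' @param program `stimulus_program`
#' @param table synapse table ([clustered_synapse_table()],
#'   [schedule_ffi()], [generate_background_trains()], ...)
#' @return updated program
#' @export
add_synapses <- function(program, table) {
  program$synapses <- bind_synapses(program$synapses, table)
  program
}

#' Attach an ideal voltage clamp
#'
#' @param program `stimulus_program`
#' @param comp compartment id
#' @param t,v waveform samples (strictly increasing `t`); a constant clamp is
#'   `t = c(0, tstop)`, `v = rep(level, 2)`
#' @return updated program
#' @export
add_voltage_clamp <- function(program, comp, t, v) {
  if (length(t) != length(v)) stop("waveform t and v lengths differ")
  if (any(diff(t) <= 0)) stop("waveform samples must be strictly increasing in t")
  program$vclamp <- list(comp = comp, t = t, v = v)
  program
}

#' Recorder specification
#'
#' @param v compartment ids whose membrane potential to record (named vector
#'   names the traces)
#' @param ca compartment ids for submembrane `[Ca]`
#' @param iax data.frame `a`, `b` of adjacent compartment pairs for axial
#'   current (positive a -> b)
#' @param ichan data.frame `comp`, `channel` for channel currents
#' @return list of class `recorder_spec`
#' @export
recorder_spec <- function(v = integer(), ca = integer(), iax = NULL,
                          ichan = NULL) {
  structure(list(v = v, ca = ca, iax = iax, ichan = ichan),
            class = "recorder_spec")
}

syn_for_cpp <- function(tab) {
  if (nrow(tab) == 0) {
    return(list(comp = integer(), tau_rise = numeric(), tau_decay = numeric(),
                gpeak = numeric(), erev = numeric(), events = numeric(),
                ev_offset = 0L))
  }
  ev <- tab$events
  lens <- vapply(ev, length, integer(1))
  list(comp = as.integer(tab$comp) - 1L,
       tau_rise = tab$tau_rise, tau_decay = tab$tau_decay,
       gpeak = tab$g_peak, erev = tab$e_rev,
       events = as.numeric(unlist(ev, use.names = FALSE)),
       ev_offset = c(0L, cumsum(lens)))
}

#' Initial solver state at a uniform voltage
#'
#' Gates at their steady state for `v`, `[Ca]` at rest.
#'
#' @param graph `pc_graph`
#' @param mech `mechanism_set`
#' @param v initial membrane potential, mV
#' @return state list (`v`, `gates`, `ca`)
#' @export
initial_state <- function(graph, mech, v = -65) {
  list(v = rep(v, graph$n),
       gates = .cpp_gate_init(channels_for_cpp(mech$channels), graph$n, v),
       ca = rep(mech$capool_vec$rest, graph$n))
}

#' Run a simulation
#'
#' Integrates the branched cable equation with the attached mechanisms and
#' stimulus program. Deterministic: the solver consumes pre-generated event
#' trains, so identical inputs give bitwise-identical recordings.
#'
#' @param graph `pc_graph`
#' @param mech `mechanism_set`
#' @param stimulus `stimulus_program`
#' @param recorders `recorder_spec`
#' @param tstop duration, ms
#' @param dt solver step, ms (default 0.025)
#' @param dt_out trace sampling step, ms (integer multiple of `dt`)
#' @param init state list from a previous run (`$state`) or
#'   [initial_state()]; default rests at -65 mV
#' @param spike_thresh somatic spike detection threshold, mV
#' @return object of class `pc_recording`: `t`, matrices `v`, `ca`, `iax`,
#'   `ichan`, `i_clamp`, somatic `spikes` (ms), and `state` (final state for
#'   chaining)
#' @export
run_simulation <- function(graph, mech, stimulus = stimulus_program(),
                           recorders = recorder_spec(v = graph$soma),
                           tstop, dt = 0.025, dt_out = 0.1, init = NULL,
                           spike_thresh = -20) {
  stopifnot(tstop > 0, dt > 0)
  if (abs(dt_out / dt - round(dt_out / dt)) > 1e-9)
    stop("dt_out must be an integer multiple of dt")
  if (is.null(init)) init <- initial_state(graph, mech)
  cg <- graph$comps
  morph <- list(parent = as.integer(cg$parent) - 1L,
                ra = ifelse(is.na(cg$ra), 1, cg$ra),
                area = cg$area, cm = cg$cm)
  iax <- recorders$iax
  if (is.null(iax)) iax <- data.frame(a = integer(), b = integer())
  r_pair <- mapply(function(a, b) {
    if (cg$parent[a] == b) cg$ra[a]
    else if (cg$parent[b] == a) cg$ra[b]
    else stop("iax recorder pair must be adjacent compartments")
  }, iax$a, iax$b)
  ichan <- recorders$ichan
  if (is.null(ichan)) ichan <- data.frame(comp = integer(), channel = character())
  chan_idx <- match(ichan$channel, names(mech$channels)) - 1L
  if (nrow(ichan) && anyNA(chan_idx)) stop("unknown channel in ichan recorder")

  vclamp <- stimulus$vclamp
  if (!is.null(vclamp)) {
    if (min(vclamp$t) > 0 || max(vclamp$t) < tstop)
      stop("clamp waveform must cover [0, tstop]")
    vclamp <- list(comp = as.integer(vclamp$comp) - 1L, t = vclamp$t,
                   v = vclamp$v)
  }

  res <- .cpp_simulate(
    morph, channels_for_cpp(mech$channels), mech$gdens,
    mech$capool_vec,
    syn_for_cpp(stimulus$synapses),
    list(comp = as.integer(stimulus$injections$comp) - 1L,
         amp = stimulus$injections$amp,
         t0 = stimulus$injections$t0,
         t1 = pmin(stimulus$injections$t1, tstop + 1)),
    vclamp,
    list(v = as.integer(recorders$v) - 1L,
         ca = as.integer(recorders$ca) - 1L,
         iax = list(a = as.integer(iax$a) - 1L, b = as.integer(iax$b) - 1L,
                    r = as.numeric(r_pair)),
         ichan = list(comp = as.integer(ichan$comp) - 1L,
                      chan = as.integer(chan_idx))),
    tstop, dt, dt_out, init, as.integer(graph$soma) - 1L, spike_thresh, 1.0)
  colnames(res$v) <- names(recorders$v) %||% as.character(recorders$v)
  res$dt_out <- dt_out
  res$tstop <- tstop
  class(res) <- "pc_recording"
  res
}

#' @export
print.pc_recording <- function(x, ...) {
  cat(sprintf("pc_recording: %.1f ms, %d traces, %d somatic spikes\n",
              x$tstop, ncol(x$v), length(x$spikes)))
  invisible(x)
}

#' Settle the model to its ongoing regime
#'
#' Runs the model (with any holding current active) for `duration` ms and
#' returns the final state, which protocols reuse as the initial state of
#' every trial. A brief depolarising kick (0.3 nA for the first 100 ms)
#' initialises the cell onto its tonic firing limit cycle rather than the
#' coexisting silent state; the remaining settle time washes the kick out.
#' A per-trial settle extension of 0-25 ms (drawn by the protocol)
#' de-phases the tonic cycle across trials.
#'
#' @param graph,mech model
#' @param stimulus holding-current program active during settling
#' @param duration ms (default 2000)
#' @param dt solver step
#' @param kick initialisation kick, nA over the first 100 ms (0 disables)
#' @return state list
#' @export
settle_state <- function(graph, mech, stimulus = stimulus_program(),
                         duration = 2000, dt = 0.025, kick = 0.3) {
  if (kick != 0)
    stimulus <- inject_current(stimulus, graph$soma, kick, c(0, 100))
  rec <- run_simulation(graph, mech, stimulus,
                        recorder_spec(v = graph$soma), tstop = duration,
                        dt = dt, dt_out = 10 * dt)
  rec$state
}

#' Ideal waveform clamp of one compartment
#'
#' Clamps `comp` to the sampled waveform; the rest of the tree evolves
#' freely. Records the clamp current and (via `recorders`) any axial
#' currents of interest.
#'
#' @param graph,mech model
#' @param comp compartment to clamp
#' @param waveform list with `t`, `v` covering `[0, tstop]`
#' @param recorders `recorder_spec`
#' @param tstop ms
#' @param init optional initial state
#' @param dt solver step
#' @return `pc_recording` with `i_clamp` trace (nA, positive = outward
#'   current supplied by the clamp)
#' @export
waveform_clamp <- function(graph, mech, comp, waveform,
                           recorders = recorder_spec(v = graph$soma),
                           tstop, init = NULL, dt = 0.025) {
  prog <- add_voltage_clamp(stimulus_program(), comp, waveform$t, waveform$v)
  run_simulation(graph, mech, prog, recorders, tstop = tstop, dt = dt,
                 init = init)
}
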