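# Synthetic synaptic input: bi-exponential conductance synapses, clustered
# parallel-fiber placement, stellate feed-forward inhibition, and in-vivo
# like Poisson background bombardment.

#' Synapse kinetic specifications
#'
#' Defaults: parallel-fiber AMPA synapses rise/decay 0.3/3 ms, peak 0.5 nS,
#' reversal 0 mV; stellate and basket GABA synapses rise/decay 1/8 ms,
#' reversal -85 mV, with each presynaptic cell contributing 1 nS of total
#' peak conductance split over its synapses (16 per stellate cell, so
#' 0.0625 nS per synapse).
#'
#' @param kind one of `"PF_AMPA"`, `"stellate_GABA"`, `"basket_GABA"`
#' @param tau_rise,tau_decay,g_peak,e_rev optional overrides
#' @return list of class `synapse_spec`
#' @export
synapse_spec <- function(kind = c("PF_AMPA", "stellate_GABA", "basket_GABA"),
                         tau_rise = NULL, tau_decay = NULL, g_peak = NULL,
                         e_rev = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    PF_AMPA = list(tau_rise = 0.3, tau_decay = 3, g_peak = 0.5, e_rev = 0),
    stellate_GABA = list(tau_rise = 1, tau_decay = 8, g_peak = 1 / 16,
                         e_rev = -85),
    basket_GABA = list(tau_rise = 1, tau_decay = 8, g_peak = 1 / 40,
                       e_rev = -85))
  s <- list(kind = kind,
            tau_rise = tau_rise %||% def$tau_rise,
            tau_decay = tau_decay %||% def$tau_decay,
            g_peak = g_peak %||% def$g_peak,
            e_rev = e_rev %||% def$e_rev)
  if (s$tau_rise <= 0 || s$tau_decay <= s$tau_rise)
    stop("need 0 < tau_rise < tau_decay")
  if (s$g_peak <= 0) stop("g_peak must be positive")
  structure(s, class = "synapse_spec")
}

#' Bi-exponential synaptic conductance waveform
#'
#' `g(t) = g_peak * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` for t >= 0,
#' 0 before the activation, with `N` normalising the peak to `g_peak`.
#' Multiple activations superpose linearly.
#'
#' @param t time since activation, ms (vectorised)
#' @param spec [synapse_spec()]
#' @return conductance, nS
#' @export
biexp_conductance <- function(t, spec) {
  tr <- spec$tau_rise; td <- spec$tau_decay
  tp <- tr * td / (td - tr) * log(td / tr)
  norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
  ifelse(t < 0, 0, spec$g_peak * norm * (exp(-t / td) - exp(-t / tr)))
}

#' Place clustered PF synapses within one branch
#'
#' Draws `n` compartments from the branch, with replacement, weighted by
#' compartment membrane area (so synapse density is uniform per unit
#' membrane), reproducibly for a given seed.
#'
#' @param graph `pc_graph`
#' @param branch_id branch 1-22
#' @param n number of synapses
#' @param seed integer seed
#' @return data.frame of class `placement_plan` with `synapse`, `comp`
#' @export
place_clustered_synapses <- function(graph, branch_id, n, seed) {
  key <- as.character(branch_id)
  if (!key %in% names(graph$branch_index)) stop("unknown branch ", branch_id)
  if (n < 1) stop("need n >= 1")
  members <- graph$branch_index[[key]]
  w <- graph$comps$area[members]
  comp <- with_seed(seed, sample(members, n, replace = TRUE, prob = w))
  out <- data.frame(synapse = seq_len(n), comp = comp,
                    branch_id = branch_id, seed = seed)
  class(out) <- c("placement_plan", "data.frame")
  out
}

#' Background synaptic ensemble description
#'
#' In-vivo-like bombardment: 2000 PF synapses firing independently at
#' 0.135 Hz spread area-weighted over all spiny compartments; 9 stellate
#' cells x 16 synapses at 14.4 Hz per cell on spiny dendrites; 4 basket
#' cells x 40 synapses at 14.4 Hz per cell split over soma and AIS. All 16
#' synapses of one stellate cell share that cell's spike train (likewise for
#' basket cells).
#'
#' @param n_pf,pf_rate PF pool size and rate (Hz)
#' @param n_stellate_cells,stellate_syn_per_cell,stellate_rate stellate pool
#' @param n_basket_cells,basket_syn_per_cell,basket_rate basket pool
#' @return list of class `background_ensemble`
#' @export
background_ensemble <- function(n_pf = 2000, pf_rate = 0.135,
                                n_stellate_cells = 9,
                                stellate_syn_per_cell = 16,
                                stellate_rate = 14.4,
                                n_basket_cells = 4, basket_syn_per_cell = 40,
                                basket_rate = 14.4) {
  structure(list(n_pf = n_pf, pf_rate = pf_rate,
                 n_stellate_cells = n_stellate_cells,
                 stellate_syn_per_cell = stellate_syn_per_cell,
                 stellate_rate = stellate_rate,
                 n_basket_cells = n_basket_cells,
                 basket_syn_per_cell = basket_syn_per_cell,
                 basket_rate = basket_rate),
            class = "background_ensemble")
}

poisson_train <- function(rate_hz, duration_ms) {
  if (rate_hz <= 0) return(numeric())
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}

#' Generate background event trains and placements
#'
#' @param graph `pc_graph`
#' @param ensemble [background_ensemble()]
#' @param duration ms
#' @param seed integer seed
#' @return data.frame with one row per synapse (`comp`, `kind`, `cell`,
#'   `tau_rise`, `tau_decay`, `g_peak`, `e_rev`) and a list-column `events`
#' @export
generate_background_trains <- function(graph, ensemble, duration, seed) {
  cg <- graph$comps
  spiny <- cg$id[cg$region == "spiny"]
  somatic <- cg$id[cg$region %in% c("soma", "AIS")]
  pf <- synapse_spec("PF_AMPA")
  st <- synapse_spec("stellate_GABA")
  bk <- synapse_spec("basket_GABA")
  with_seed(seed, {
    rows <- list()
    # PF pool: independent trains
    pf_comp <- sample(spiny, ensemble$n_pf, replace = TRUE,
                      prob = cg$area[spiny])
    pf_ev <- lapply(seq_len(ensemble$n_pf), function(i)
      poisson_train(ensemble$pf_rate, duration))
    rows$pf <- data.frame(comp = pf_comp, kind = "PF_AMPA",
                          cell = NA_integer_, tau_rise = pf$tau_rise,
                          tau_decay = pf$tau_decay, g_peak = pf$g_peak,
                          e_rev = pf$e_rev)
    rows$pf$events <- pf_ev
    # stellate cells: one shared train per cell
    st_list <- lapply(seq_len(ensemble$n_stellate_cells), function(cell) {
      train <- poisson_train(ensemble$stellate_rate, duration)
      comp <- sample(spiny, ensemble$stellate_syn_per_cell, replace = TRUE,
                     prob = cg$area[spiny])
      d <- data.frame(comp = comp, kind = "stellate_GABA", cell = cell,
                      tau_rise = st$tau_rise, tau_decay = st$tau_decay,
                      g_peak = st$g_peak, e_rev = st$e_rev)
      d$events <- rep(list(train), nrow(d))
      d
    })
    # basket cells: shared train, soma + AIS
    bk_list <- lapply(seq_len(ensemble$n_basket_cells), function(cell) {
      train <- poisson_train(ensemble$basket_rate, duration)
      comp <- sample(somatic, ensemble$basket_syn_per_cell, replace = TRUE,
                     prob = cg$area[somatic])
      d <- data.frame(comp = comp, kind = "basket_GABA", cell = cell,
                      tau_rise = bk$tau_rise, tau_decay = bk$tau_decay,
                      g_peak = bk$g_peak, e_rev = bk$e_rev)
      d$events <- rep(list(train), nrow(d))
      d
    })
    out <- do.call(rbind, c(rows, st_list, bk_list))
    rownames(out) <- NULL
    out
  })
}

#' Schedule feed-forward stellate inhibition on a branch
#'
#' Each of `n_stellate` cells fires once at `pf_time + delay`; its 16
#' synapses are placed area-weighted within the stimulated branch, each
#' carrying 1/16 of the cell's 1 nS peak conductance.
#'
#' @param graph `pc_graph`
#' @param branch_id target branch
#' @param pf_time PF volley time, ms
#' @param n_stellate number of stellate cells, 0-13
#' @param delay inhibition delay relative to PF, ms (negative = preceding)
#' @param seed integer seed for placement
#' @param max_cells configured maximum (~10 stellate cells converge on one
#'   Purkinje cell; up to 13 explored)
#' @return synapse table as in [generate_background_trains()]
#' @export
schedule_ffi <- function(graph, branch_id, pf_time, n_stellate, delay,
                         seed, max_cells = 13) {
  if (n_stellate > max_cells) stop("n_stellate exceeds configured maximum")
  if (n_stellate < 0) stop("n_stellate must be >= 0")
  if (n_stellate == 0) return(empty_synapse_table())
  st <- synapse_spec("stellate_GABA")
  key <- as.character(branch_id)
  if (!key %in% names(graph$branch_index)) stop("unknown branch ", branch_id)
  members <- graph$branch_index[[key]]
  w <- graph$comps$area[members]
  with_seed(seed, {
    cells <- lapply(seq_len(n_stellate), function(cell) {
      comp <- sample(members, 16, replace = TRUE, prob = w)
      d <- data.frame(comp = comp, kind = "stellate_GABA", cell = cell,
                      tau_rise = st$tau_rise, tau_decay = st$tau_decay,
                      g_peak = st$g_peak, e_rev = st$e_rev)
      d$events <- rep(list(pf_time + delay), nrow(d))
      d
    })
    out <- do.call(rbind, cells)
    rownames(out) <- NULL
    out
  })
}

#' Synapse table for a synchronously activated clustered placement
#'
#' @param plan [place_clustered_synapses()] placement
#' @param time activation time(s), ms
#' @param spec synapse kinetics, default PF AMPA
#' @return synapse table as in [generate_background_trains()]
#' @export
clustered_synapse_table <- function(plan, time, spec = synapse_spec("PF_AMPA")) {
  d <- data.frame(comp = plan$comp, kind = spec$kind, cell = NA_integer_,
                  tau_rise = spec$tau_rise, tau_decay = spec$tau_decay,
                  g_peak = spec$g_peak, e_rev = spec$e_rev)
  d$events <- rep(list(sort(time)), nrow(d))
  d
}

empty_synapse_table <- function() {
  d <- data.frame(comp = integer(), kind = character(), cell = integer(),
                  tau_rise = numeric(), tau_decay = numeric(),
                  g_peak = numeric(), e_rev = numeric())
  d$events <- list()
  d
}

#' Combine synapse tables
#'
#' @param ... synapse tables
#' @return a single synapse table
#' @export
bind_synapses <- function(...) {
  tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(tabs)) return(empty_synapse_table())
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
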