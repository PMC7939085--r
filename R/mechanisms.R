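# Membrane mechanisms: Hodgkin-Huxley style gated currents, leak, and the
# submembrane Ca pool.
#
# All gates use Boltzmann steady states x_inf(V) = 1/(1 + exp(-(V-Vhalf)/k))
# (k < 0 for inactivation) and a bell-shaped voltage-dependent time constant
# tau(V) = base + amp * exp(-((V-center)/width)^2), clamped at tau_min =
# 0.05 ms for stiffness control. Ca-dependent channels (BK, SK) multiply a
# Hill function of the local submembrane [Ca]. The CaP current uses a fixed
# high driving-force reversal (+130 mV) instead of GHK flux.
#
# Sign convention: outward membrane current positive.

TAU_MIN <- 0.05

#' Construct a gating variable
#'
#' @param name gate label
#' @param kind `"activation"` (k > 0) or `"inactivation"` (k < 0)
#' @param vhalf half-activation voltage, mV
#' @param k slope, mV (sign must match `kind`)
#' @param power integer exponent in the channel open probability
#' @param tau_base,tau_amp,tau_center,tau_width parameters of the
#'   bell-shaped time constant, ms / ms / mV / mV
#' @return list of class `gating_variable`
#' @export
gating_variable <- function(name, kind = c("activation", "inactivation"),
                            vhalf, k, power = 1L,
                            tau_base = 0.2, tau_amp = 0, tau_center = -50,
                            tau_width = 20) {
  kind <- match.arg(kind)
  if (kind == "activation" && k <= 0) stop("activation gate needs k > 0")
  if (kind == "inactivation" && k >= 0) stop("inactivation gate needs k < 0")
  structure(list(name = name, kind = kind, vhalf = vhalf, k = k,
                 power = as.integer(power), tau_base = tau_base,
                 tau_amp = tau_amp, tau_center = tau_center,
                 tau_width = tau_width),
            class = "gating_variable")
}

#' Steady state and time constant of a gate
#'
#' @param gate a [gating_variable()]
#' @param v membrane potential, mV (vectorised)
#' @return list with `xinf` and `tau` (ms, clamped at 0.05)
#' @export
gate_steady_state_tau <- function(gate, v) {
  xinf <- 1 / (1 + exp(-(v - gate$vhalf) / gate$k))
  tau <- gate$tau_base +
    gate$tau_amp * exp(-((v - gate$tau_center) / gate$tau_width)^2)
  list(xinf = xinf, tau = pmax(tau, TAU_MIN))
}

#' Construct a channel specification
#'
#' @param name channel name
#' @param erev reversal potential, mV
#' @param gates list of [gating_variable()] (may be empty, e.g. leak, SK)
#' @param ca_dep `"none"` or `"hill"` ([Ca] half-activation)
#' @param ca50 half-activation [Ca], uM (Hill channels)
#' @param hill Hill coefficient
#' @param is_ca whether the current carries Ca into the submembrane pool
#' @return list of class `channel_spec`
#' @export
channel_spec <- function(name, erev, gates = list(),
                         ca_dep = c("none", "hill"), ca50 = 1, hill = 2,
                         is_ca = FALSE) {
  ca_dep <- match.arg(ca_dep)
  structure(list(name = name, erev = erev, gates = gates, ca_dep = ca_dep,
                 ca50 = ca50, hill = hill, is_ca = is_ca),
            class = "channel_spec")
}

#' Membrane current density of a channel
#'
#' `I = gbar * prod(x_i^p_i) * f(Ca) * (V - E)` in mA/cm2, positive outward.
#'
#' @param spec [channel_spec()]
#' @param v membrane potential, mV
#' @param gates numeric vector of gate states in `[0, 1]`, one per gate
#' @param ca submembrane [Ca], uM
#' @param gbar conductance density, S/cm2
#' @return current density mA/cm2
#' @export
channel_current <- function(spec, v, gates = numeric(), ca = 0.045, gbar) {
  if (length(gates) != length(spec$gates))
    stop("need one gate state per gate of ", spec$name)
  if (length(gates) && (any(gates < 0) | any(gates > 1)))
    stop("gate states must lie in [0, 1]")
  p <- 1
  for (i in seq_along(gates)) p <- p * gates[i]^spec$gates[[i]]$power
  f <- if (spec$ca_dep == "hill") ca^spec$hill / (ca^spec$hill + spec$ca50^spec$hill) else 1
  gbar * p * f * (v - spec$erev)
}

#' Submembrane calcium pool parameters
#'
#' A single-shell pool: `d[Ca]/dt = -beta * I_Ca - ([Ca] - rest)/tau` with
#' `beta = 51.82 / depth` uM cm2/(mA ms) from the shell volume and Faraday
#' constant (inward current is negative, so inflow raises [Ca]).
#'
#' @param depth shell depth, um
#' @param tau decay time constant, ms
#' @param rest resting [Ca], uM
#' @return list of class `calcium_pool`
#' @export
calcium_pool <- function(depth = 0.1, tau = 1.5, rest = 0.045) {
  structure(list(depth = depth, tau = tau, rest = rest,
                 beta = 51.82 / depth), class = "calcium_pool")
}

#' Advance a calcium pool one time step
#'
#' Analytic exponential update with the Ca current frozen over the step;
#' identical to the scheme used inside the solver.
#'
#' @param pool [calcium_pool()]
#' @param ca current [Ca], uM
#' @param i_ca Ca current density, mA/cm2 (inward negative)
#' @param dt step, ms
#' @return new [Ca], uM (never negative)
#' @export
calcium_update <- function(pool, ca, i_ca, dt) {
  ca_inf <- max(0, pool$rest - pool$beta * pool$tau * i_ca)
  ca_inf + (ca - ca_inf) * exp(-dt / pool$tau)
}

#' Canonical channel kinetics
#'
#' The channel library of the reduced model: fast Na and delayed-rectifier K
#' on soma/AIS for tonic spiking, high-threshold P-type Ca plus Kv3, Kv4,
#' two BK components (iberiotoxin-sensitive and -insensitive), and SK on the
#' dendrites, and ohmic leak everywhere. Kinetic parameters are standard
#' Boltzmann/bell-tau forms chosen for this reduced model and fixed here;
#' only densities are touched by calibration.
#'
#' @return named list of [channel_spec()]
#' @export
default_channels <- function() {
  list(
    NaF = channel_spec("NaF", erev = 60, gates = list(
      gating_variable("m", "activation", vhalf = -48, k = 4, power = 3L,
                      tau_base = 0.05, tau_amp = 0),
      gating_variable("h", "inactivation", vhalf = -60, k = -3.5, power = 1L,
                      tau_base = 0.15, tau_amp = 4, tau_center = -60,
                      tau_width = 20))),
    KdR = channel_spec("KdR", erev = -88, gates = list(
      gating_variable("n", "activation", vhalf = -35, k = 7, power = 4L,
                      tau_base = 0.2, tau_amp = 1.5, tau_center = -50,
                      tau_width = 30))),
    CaP = channel_spec("CaP", erev = 130, is_ca = TRUE, gates = list(
      gating_variable("m", "activation", vhalf = -27, k = 4, power = 2L,
                      tau_base = 0.2, tau_amp = 0.6, tau_center = -30,
                      tau_width = 25),
      gating_variable("h", "inactivation", vhalf = -33, k = -5, power = 1L,
                      tau_base = 12, tau_amp = 0))),
    Kv3 = channel_spec("Kv3", erev = -88, gates = list(
      gating_variable("n", "activation", vhalf = -12, k = 8, power = 2L,
                      tau_base = 0.3, tau_amp = 1.0, tau_center = -30,
                      tau_width = 30))),
    Kv4 = channel_spec("Kv4", erev = -88, gates = list(
      gating_variable("a", "activation", vhalf = -45, k = 8, power = 2L,
                      tau_base = 0.25, tau_amp = 1.0, tau_center = -55,
                      tau_width = 30),
      gating_variable("b", "inactivation", vhalf = -63, k = -4, power = 1L,
                      tau_base = 15, tau_amp = 40, tau_center = -65,
                      tau_width = 25))),
    BK_is = channel_spec("BK_is", erev = -88, ca_dep = "hill", ca50 = 2,
                         hill = 2, gates = list(
      gating_variable("m", "activation", vhalf = -10, k = 9, power = 1L,
                      tau_base = 0.2, tau_amp = 0.5, tau_center = -20,
                      tau_width = 30))),
    BK_ii = channel_spec("BK_ii", erev = -88, ca_dep = "hill", ca50 = 1,
                         hill = 2, gates = list(
      gating_variable("m", "activation", vhalf = -22, k = 10, power = 1L,
                      tau_base = 1.5, tau_amp = 2, tau_center = -30,
                      tau_width = 30))),
    SK = channel_spec("SK", erev = -88, ca_dep = "hill", ca50 = 0.8,
                      hill = 4, gates = list()),
    leak_soma = channel_spec("leak_soma", erev = -45, gates = list()),
    leak_dend = channel_spec("leak_dend", erev = -60, gates = list())
  )
}

#' Canonical conductance densities per region
#'
#' S/cm2 per region and channel. The dendritic K-current balance encodes the
#' model's baseline ratios: Kv3 at 67% of its internal reference and the
#' iberiotoxin-sensitive BK at 200% of its reference, next to a distinct
#' iberiotoxin-insensitive BK component. Main dendrites carry the spiny
#' channel set at reduced CaP density. Values are the calibrated defaults of
#' the package.
#'
#' @return named list region -> named numeric vector of densities
#' @export
default_densities <- function() {
  list(
    soma = c(NaF = 0.5, KdR = 0.25, CaP = 5e-5, Kv4 = 3e-2, SK = 9e-3,
             leak_soma = 2.9e-3),
    AIS  = c(NaF = 0.45, KdR = 0.09, leak_dend = 6e-5),
    main = c(CaP = 4e-5, Kv3 = 0.004, Kv4 = 0.002, BK_is = 8e-4,
             BK_ii = 4e-4, SK = 1e-4, leak_dend = 6e-5),
    spiny = c(CaP = 1.6e-2, Kv3 = 1e-2, Kv4 = 6e-3, BK_is = 1.5e-2,
              BK_ii = 1.2e-3, SK = 1e-4, leak_dend = 6e-5),
    # branch stems (connection segments) carry the spiny channel set
    stem = c(CaP = 1.6e-2, Kv3 = 1e-2, Kv4 = 6e-3, BK_is = 1.5e-2,
             BK_ii = 1.2e-3, SK = 1e-4, leak_dend = 6e-5)
  )
}

#' Assemble a mechanism set on a compartment graph
#'
#' Expands per-region densities into the per-compartment density matrix the
#' solver consumes and attaches the channel library and Ca-pool constants.
#'
#' @param graph `pc_graph`
#' @param channels channel library, see [default_channels()]
#' @param densities per-region densities, see [default_densities()]
#' @param capool a single [calcium_pool()] used everywhere, or a named list
#'   of pools per region (see [default_capools()]); pool kinetics differ
#'   between the fast somatic shell and the slower spiny-dendrite shell
#' @return object of class `mechanism_set`
#' @export
mechanism_set <- function(graph, channels = default_channels(),
                          densities = default_densities(),
                          capool = default_capools()) {
  cn <- names(channels)
  gd <- matrix(0, nrow = graph$n, ncol = length(cn),
               dimnames = list(NULL, cn))
  for (reg in names(densities)) {
    rows <- which(graph$comps$region == reg)
    dv <- densities[[reg]]
    if (!all(names(dv) %in% cn))
      stop("unknown channel in densities: ",
           paste(setdiff(names(dv), cn), collapse = ", "))
    for (ch in names(dv)) gd[rows, ch] <- dv[[ch]]
  }
  if (inherits(capool, "calcium_pool")) {
    regs <- unique(graph$comps$region)
    capool <- setNames(rep(list(capool), length(regs)), regs)
  }
  rest <- unique(vapply(capool, `[[`, numeric(1), "rest"))
  if (length(rest) != 1) stop("all Ca pools must share one resting [Ca]")
  tau_vec <- beta_vec <- numeric(graph$n)
  for (reg in unique(graph$comps$region)) {
    pool <- capool[[reg]]
    if (is.null(pool)) stop("no Ca pool for region ", reg)
    rows <- which(graph$comps$region == reg)
    tau_vec[rows] <- pool$tau
    beta_vec[rows] <- pool$beta
  }
  structure(list(channels = channels, gdens = gd, densities = densities,
                 capool = capool,
                 capool_vec = list(tau = tau_vec, beta = beta_vec,
                                   rest = rest)),
            class = "mechanism_set")
}

#' Default region-resolved calcium pools
#'
#' A fast shell under the soma/AIS membrane (tau 2 ms: Ca there tracks the
#' spike) and a slower shell in the dendrites (tau 60 ms: the Ca tail after
#' a dendritic spike keeps SK/BK active and carries the post-burst pause).
#'
#' @return named list of [calcium_pool()] per region
#' @export
default_capools <- function() {
  fast <- calcium_pool(depth = 0.1, tau = 15)
  slow <- calcium_pool(depth = 0.4, tau = 60)
  list(soma = fast, AIS = fast, main = slow, spiny = slow, stem = slow)
}

#' Scale channel densities on one branch
#'
#' Multiplies conductance densities by `factor` on the compartments of the
#' target branch only; composition of scalings is multiplicative. With
#' `channel = NULL` all channels on the branch are scaled (leak excluded, so
#' "density scaling" means the active conductances).
#'
#' @param mech `mechanism_set`
#' @param graph `pc_graph`
#' @param branch_id branch 1-22
#' @param factor non-negative multiplier
#' @param channel optional single channel name to restrict the scaling
#' @return a new `mechanism_set`
#' @export
mechanism_scaling <- function(mech, graph, branch_id, factor, channel = NULL) {
  if (factor < 0) stop("factor must be >= 0")
  key <- as.character(branch_id)
  if (!key %in% names(graph$branch_index)) stop("unknown branch ", branch_id)
  rows <- graph$branch_index[[key]]
  cols <- if (is.null(channel)) {
    setdiff(colnames(mech$gdens), c("leak_soma", "leak_dend"))
  } else {
    if (!channel %in% colnames(mech$gdens)) stop("unknown channel ", channel)
    channel
  }
  mech$gdens[rows, cols] <- mech$gdens[rows, cols] * factor
  mech
}

# Flatten the channel library into the list form the C++ core expects.
channels_for_cpp <- function(channels) {
  lapply(channels, function(ch) {
    list(name = ch$name, erev = ch$erev, is_ca = isTRUE(ch$is_ca),
         ca_dep = if (ch$ca_dep == "hill") 1L else 0L,
         ca50 = ch$ca50, hill = ch$hill,
         gates = lapply(ch$gates, function(g)
           list(vhalf = g$vhalf, k = g$k, power = g$power,
                tau_base = g$tau_base, tau_amp = g$tau_amp,
                tau_center = g$tau_center, tau_width = g$tau_width)))
  })
}
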