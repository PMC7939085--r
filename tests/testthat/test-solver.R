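test_that("passive RC response matches the closed form at one time constant", {
  g <- toy_chain(1, len = 20, diam = 20, cm = 1)
  mech <- toy_leak_mech(g, g_leak = 1e-4, e_leak = -65)
  area_cm2 <- g$comps$area * 1e-8
  R <- 1 / (1e-4 * area_cm2) * 1e-6              # MOhm
  tau <- 1 * 1e-3 / 1e-4                         # ms (Cm/g)
  I <- 0.05                                      # nA
  prog <- inject_current(stimulus_program(), 1, I, c(0, Inf))
  rec <- run_simulation(g, mech, prog, recorder_spec(v = 1), tstop = tau,
                        init = initial_state(g, mech, -65), dt = 0.025,
                        dt_out = 0.025)
  v_end <- unname(rec$v[nrow(rec$v), 1]) + 65
  expect_equal(v_end, unname(I * R * (1 - exp(-1))), tolerance = 5e-3)
})

test_that("two-compartment steady state matches the resistor network", {
  g <- toy_chain(2, len = 30, diam = 2)
  mech <- toy_leak_mech(g, g_leak = 2e-4, e_leak = -65)
  gm <- 2e-4 * g$comps$area[1] * 1e-8 * 1e6      # uS per compartment
  k <- 1 / g$comps$ra[2]                         # uS coupling
  I <- 0.02
  # solve [gm+k, -k; -k, gm+k] (V-E) = [0, I]
  A <- matrix(c(gm + k, -k, -k, gm + k), 2, 2)
  dv <- solve(A, c(0, I))
  prog <- inject_current(stimulus_program(), 2, I, c(0, Inf))
  rec <- run_simulation(g, mech, prog, recorder_spec(v = c(a = 1, b = 2)),
                        tstop = 200, init = initial_state(g, mech, -65))
  expect_equal(unname(rec$v[nrow(rec$v), ]) + 65, dv, tolerance = 1e-3)
})

test_that("a resting passive tree stays at rest to machine-level drift", {
  g <- toy_chain(5, len = 30, diam = 1.5)
  mech <- toy_leak_mech(g, e_leak = -65)
  rec <- run_simulation(g, mech, stimulus_program(),
                        recorder_spec(v = seq_len(5)), tstop = 100,
                        init = initial_state(g, mech, -65))
  expect_lt(max(abs(rec$v + 65)), 1e-3)          # < 1 uV per 100 ms
})

test_that("gate relaxation under voltage clamp matches the analytic form", {
  g <- toy_chain(1)
  ch <- list(
    Kv4 = default_channels()$Kv4,
    leak_soma = channel_spec("leak_soma", erev = -65))
  mech <- mechanism_set(g, ch, list(soma = c(Kv4 = 1e-3, leak_soma = 1e-4)),
                        calcium_pool())
  v0 <- -80; vc <- -40; tstop <- 6
  init <- initial_state(g, mech, vc)
  init$gates <- .cpp_gate_init(pfspike:::channels_for_cpp(ch), 1, v0)
  init$v <- rep(vc, 1)
  prog <- add_voltage_clamp(stimulus_program(), 1, c(0, tstop), c(vc, vc))
  rec <- run_simulation(g, mech, prog, recorder_spec(v = 1), tstop = tstop,
                        init = init)
  for (j in 1:2) {
    gt <- ch$Kv4$gates[[j]]
    ss <- gate_steady_state_tau(gt, vc)
    x0 <- gate_steady_state_tau(gt, v0)$xinf
    expected <- ss$xinf + (x0 - ss$xinf) * exp(-tstop / ss$tau)
    expect_equal(rec$state$gates[1, j], expected, tolerance = 1e-3)
  }
})

test_that("solver matches an adaptive-ODE reference on a 3-compartment active model", {
  skip_if_not_installed("deSolve")
  g <- toy_chain(3, len = 30, diam = 2, cm = 1)
  ch <- list(
    CaP = default_channels()$CaP,
    Kv3 = default_channels()$Kv3,
    leak_soma = channel_spec("leak_soma", erev = -65))
  dens <- c(CaP = 3e-4, Kv3 = 5e-4, leak_soma = 1e-4)
  mech <- mechanism_set(g, ch, list(soma = dens), calcium_pool(tau = 10))
  I <- 0.06; t_on <- 5; t_off <- 45; tstop <- 100
  prog <- inject_current(stimulus_program(), 3, I, c(t_on, t_off))
  rec <- run_simulation(g, mech, prog, recorder_spec(v = 1:3), tstop = tstop,
                        init = initial_state(g, mech, -65), dt = 0.025,
                        dt_out = 0.1)

  # independent reference: full ODE system integrated by deSolve::lsoda
  area_cm2 <- g$comps$area[1] * 1e-8
  cap_nF <- 1 * g$comps$area[1] * 1e-5
  kax <- 1 / g$comps$ra[2]
  pool <- calcium_pool(tau = 10)
  gates <- list(CaP = ch$CaP$gates, Kv3 = ch$Kv3$gates)
  rhs <- function(t, y, parms) {
    v <- y[1:3]; m <- y[4:6]; h <- y[7:9]; n <- y[10:12]; ca <- y[13:15]
    ich <- function(i) {
      i_cap <- dens["CaP"] * m[i]^2 * h[i] * (v[i] - 130)
      i_kv3 <- dens["Kv3"] * n[i]^2 * (v[i] - (-88))
      i_leak <- dens["leak_soma"] * (v[i] + 65)
      c(total = unname((i_cap + i_kv3 + i_leak) * area_cm2 * 1e6),
        ca = unname(i_cap))
    }
    dv <- numeric(3); dca <- numeric(3)
    iax <- c(kax * (v[2] - v[1]), kax * (v[1] - v[2]) + kax * (v[3] - v[2]),
             kax * (v[2] - v[3]))
    for (i in 1:3) {
      cur <- ich(i)
      inj <- if (i == 3 && t >= t_on && t < t_off) I else 0
      dv[i] <- (-cur[["total"]] + iax[i] + inj) / cap_nF
      dca[i] <- -pool$beta * cur[["ca"]] - (ca[i] - pool$rest) / pool$tau
    }
    gdot <- function(gt, x, i) {
      ss <- gate_steady_state_tau(gt, v[i])
      (ss$xinf - x) / ss$tau
    }
    dm <- sapply(1:3, function(i) gdot(gates$CaP[[1]], m[i], i))
    dh <- sapply(1:3, function(i) gdot(gates$CaP[[2]], h[i], i))
    dn <- sapply(1:3, function(i) gdot(gates$Kv3[[1]], n[i], i))
    list(c(dv, dm, dh, dn, dca))
  }
  y0 <- c(rep(-65, 3),
          rep(gate_steady_state_tau(gates$CaP[[1]], -65)$xinf, 3),
          rep(gate_steady_state_tau(gates$CaP[[2]], -65)$xinf, 3),
          rep(gate_steady_state_tau(gates$Kv3[[1]], -65)$xinf, 3),
          rep(pool$rest, 3))
  ref <- deSolve::lsoda(y0, seq(0, tstop, 0.1), rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  rms <- sqrt(mean((rec$v - ref[, 2:4])^2))
  expect_lt(rms, 0.5)
})

test_that("Kirchhoff balance holds at a steady junction", {
  g <- canonical_model()$graph
  ch <- list(leak_soma = channel_spec("leak_soma", erev = -65))
  dens <- list(soma = c(leak_soma = 1e-4), AIS = c(leak_soma = 1e-4),
               main = c(leak_soma = 1e-4), spiny = c(leak_soma = 1e-4))
  mech <- mechanism_set(g, ch, dens, calcium_pool())
  prog <- inject_current(stimulus_program(), g$soma, 0.1, c(0, Inf))
  rec <- run_simulation(g, mech, prog, recorder_spec(v = g$soma),
                        tstop = 400, init = initial_state(g, mech, -65))
  v <- rec$state$v
  # at the soma junction: sum of axial inflow + injection = membrane current
  children <- which(g$comps$parent == g$soma)
  axial_in <- sum((v[children] - v[g$soma]) / g$comps$ra[children])
  i_mem <- 1e-4 * g$comps$area[g$soma] * 1e-2 * (v[g$soma] + 65)
  expect_lt(abs(axial_in + 0.1 - i_mem), 1e-6)
})

test_that("identical seeds reproduce recordings bitwise", {
  m <- canonical_model()
  run_once <- function() {
    plan <- place_clustered_synapses(m$graph, 8, 20, seed = 11)
    prog <- add_synapses(stimulus_program(), clustered_synapse_table(plan, 30))
    run_simulation(m$graph, m$mech, prog,
                   recorder_spec(v = pfspike:::branch_sites(m$graph, 8)),
                   tstop = 60, init = initial_state(m$graph, m$mech, -65))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$v, b$v)
  expect_identical(a$spikes, b$spikes)
})

test_that("waveform clamp tracks the target and reports sensible currents", {
  g <- toy_chain(4, len = 30, diam = 1.5)
  mech <- toy_leak_mech(g, e_leak = -65)
  # constant clamp at rest: clamp current settles below 1 pA
  rec <- waveform_clamp(g, mech, 2, list(t = c(0, 50), v = c(-65, -65)),
                        recorder_spec(v = 2), tstop = 50,
                        init = initial_state(g, mech, -65))
  expect_lt(abs(rec$i_clamp[length(rec$i_clamp)]), 1e-3)
  expect_equal(max(abs(rec$v[, 1] + 65)), 0, tolerance = 1e-9)
  # step waveform on a slow thin cable: neighbour axial current right after
  # the step equals dV/r (the neighbour has barely charged yet)
  gs <- toy_chain(4, len = 100, diam = 0.3)
  mechs <- toy_leak_mech(gs, e_leak = -65)
  wf <- list(t = c(0, 10, 10.025, 50), v = c(-65, -65, -55, -55))
  rec2 <- waveform_clamp(gs, mechs, 2, wf,
                         recorder_spec(v = 3,
                                       iax = data.frame(a = 2, b = 3)),
                         tstop = 50, init = initial_state(gs, mechs, -65))
  idx <- which(rec2$t > 10.05)[1]
  expect_equal(rec2$iax[idx, 1], 10 / gs$comps$ra[3], tolerance = 0.05)
  # passive linearity: doubling axial resistivity halves the peak current
  g2 <- toy_chain(4, len = 100, diam = 0.3, ra = 240)
  mech2 <- toy_leak_mech(g2, e_leak = -65)
  rec3 <- waveform_clamp(g2, mech2, 2, wf,
                         recorder_spec(v = 3,
                                       iax = data.frame(a = 2, b = 3)),
                         tstop = 50, init = initial_state(g2, mech2, -65))
  expect_equal(max(rec2$iax[, 1]) / max(rec3$iax[, 1]), 2, tolerance = 0.1)
})

test_that("overlapping current injections superpose", {
  g <- toy_chain(1)
  mech <- toy_leak_mech(g)
  p1 <- inject_current(stimulus_program(), 1, 0.01, c(0, 100))
  p1 <- inject_current(p1, 1, 0.01, c(50, 150))
  p2 <- inject_current(stimulus_program(), 1, 0.02, c(50, 100))
  p2 <- inject_current(p2, 1, 0.01, c(0, 50))
  p2 <- inject_current(p2, 1, 0.01, c(100, 150))
  r1 <- run_simulation(g, mech, p1, recorder_spec(v = 1), tstop = 150,
                       init = initial_state(g, mech, -65))
  r2 <- run_simulation(g, mech, p2, recorder_spec(v = 1), tstop = 150,
                       init = initial_state(g, mech, -65))
  expect_equal(r1$v, r2$v, tolerance = 1e-12)
  # zero-amplitude injection is a no-op
  p3 <- inject_current(stimulus_program(), 1, 0, c(0, 100))
  r3 <- run_simulation(g, mech, p3, recorder_spec(v = 1), tstop = 150,
                       init = initial_state(g, mech, -65))
  r0 <- run_simulation(g, mech, stimulus_program(), recorder_spec(v = 1),
                       tstop = 150, init = initial_state(g, mech, -65))
  expect_identical(r3$v, r0$v)
})

test_that("halving dt preserves the firing pattern", {
  # near its tonic limit cycle the pacemaker is phase-sensitive, so late
  # spike times decorrelate under any perturbation; convergence is checked
  # on the first spikes and on the rate over the full window
  m <- canonical_model()
  st <- pfspike:::settled_state(m, 0)
  r1 <- run_simulation(m$graph, m$mech, stimulus_program(),
                       recorder_spec(v = m$graph$soma), tstop = 500,
                       dt = 0.05, dt_out = 0.1, init = st)
  r2 <- run_simulation(m$graph, m$mech, stimulus_program(),
                       recorder_spec(v = m$graph$soma), tstop = 500,
                       dt = 0.025, dt_out = 0.1, init = st)
  expect_gt(length(r2$spikes), 5)
  expect_lte(abs(length(r1$spikes) - length(r2$spikes)), 3)
  expect_lt(abs(r1$spikes[1] - r2$spikes[1]), 0.5)
})
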