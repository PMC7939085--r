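test_that("response amplitude is baseline-robust", {
  t <- seq(0, 100, 0.1)
  v <- rep(-65, length(t))
  expect_equal(response_amplitude(t, v, 60), 0)
  # constructed EPSP of 8 mV
  v2 <- v + 8 * exp(-pmax(t - 60, 0) / 5) * (t >= 60) * (1 - exp(-pmax(t - 60, 0) / 0.5))
  amp <- response_amplitude(t, v2, 60)
  expect_equal(amp, 8 * max(exp(-(t - 60) / 5) * (1 - exp(-(t - 60) / 0.5)),
                            na.rm = TRUE)[1], tolerance = 0.05)
  # a backpropagated spike inside the baseline window barely moves the result
  v3 <- v2
  v3[t > 20 & t < 21] <- 10
  expect_lt(abs(response_amplitude(t, v3, 60) - amp), 0.5)
  expect_error(response_amplitude(t, v, 200), "window")
})

test_that("step detection follows the jump-over-linear-fit rule", {
  mk <- function(ns, amps_per_n) {
    do.call(rbind, lapply(seq_along(ns), function(i)
      data.frame(n = ns[i], amplitude = amps_per_n[[i]])))
  }
  ns <- seq(5, 50, 5)
  # perfectly linear curve: no threshold
  lin <- mk(ns, lapply(ns, function(n) rep(0.4 * n, 5)))
  expect_true(is.na(detect_dendritic_spike_threshold(lin)$threshold))
  # clean step at 35 in all trials
  stepc <- mk(ns, lapply(ns, function(n)
    rep(0.4 * n + if (n >= 35) 25 else 0, 5)))
  expect_equal(detect_dendritic_spike_threshold(stepc)$threshold, 35)
  # 5/10 jumped at 35, 10/10 at 40: threshold depends on frac
  mixed <- mk(ns, lapply(ns, function(n) {
    base <- rep(0.4 * n, 10)
    if (n == 35) base[1:5] <- base[1:5] + 25
    if (n >= 40) base <- base + 25
    base
  }))
  expect_equal(detect_dendritic_spike_threshold(mixed, frac = 0.5)$threshold, 35)
  expect_equal(detect_dendritic_spike_threshold(mixed, frac = 0.8)$threshold, 40)
})

test_that("attenuation profile interpolates percent decay", {
  expect_equal(attenuation_profile(c(0, 25, 50, 100),
                                   c(40, 40, 40, 40))$decay_percent, 0)
  d <- seq(0, 120, 10)
  pk <- 50 * exp(-d / 60)
  prof <- attenuation_profile(d, pk)
  expect_equal(prof$decay_percent, 100 * (1 - exp(-50 / 60)), tolerance = 0.2)
  expect_error(attenuation_profile(c(0, 0, 10), c(1, 1, 1)), "ascending")
  # invariance to uniform time shifts is inherited from peak-based inputs:
  # peaks do not change if traces are shifted, so the profile cannot either
})

test_that("axial current is Ohmic and antisymmetric", {
  t <- seq(0, 10, 0.1)
  va <- rep(-50, length(t)); vb <- rep(-60, length(t))
  r <- axial_current(t, va, vb, 5)
  expect_true(all(r$i_ax == 2))                  # 10 mV / 5 MOhm
  expect_equal(axial_current(t, vb, va, 5)$i_ax, -r$i_ax)
  expect_true(all(axial_current(t, va, va, 5)$i_ax == 0))
  expect_error(axial_current(t, va, vb[-1], 5), "time base")
  expect_error(axial_current(t, va, vb, 0), "positive")
})

test_that("source/sink ratio is a homogeneous quotient", {
  expect_equal(source_sink_ratio(100, 1), 100)
  expect_equal(source_sink_ratio(200, 1), 2 * source_sink_ratio(100, 1))
  expect_error(source_sink_ratio(100, 0), "positive")
})

test_that("somatic spike detection agrees with the online detector", {
  # constructed three-spike trace
  t <- seq(0, 100, 0.1)
  v <- rep(-60, length(t))
  for (t0 in c(20, 50, 80)) v[t >= t0 & t < t0 + 1] <- 10
  sp <- detect_somatic_spikes(t, v)
  expect_length(sp, 3)
  expect_equal(sp, c(20, 50, 80), tolerance = 0.2)
  expect_length(detect_somatic_spikes(t, rep(-60, length(t))), 0)
  # cross-check the two code paths on a tonic run
  m <- canonical_model()
  st <- pfspike:::settled_state(m, 0)
  rec <- run_simulation(m$graph, m$mech, stimulus_program(),
                        recorder_spec(v = c(soma = m$graph$soma)),
                        tstop = 1000, init = st)
  off <- detect_somatic_spikes(rec$t, rec$v[, "soma"])
  expect_lt(abs(length(off) - length(rec$spikes)), 2)
})

test_that("PSTH computation conserves spike mass and scales to Hz", {
  # 10 spikes in one 2-ms bin over 100 trials -> 50 Hz
  trials <- c(replicate(10, 5, simplify = FALSE),
              replicate(90, numeric(), simplify = FALSE))
  psth <- compute_psth(trials, bin = 2, window = c(-10, 10))
  expect_equal(max(psth$rate), 10 / (100 * 0.002))
  expect_equal(sum(psth$rate) * 0.002 * 100, 10)   # mass conservation
  expect_true(all(compute_psth(replicate(5, numeric(), simplify = FALSE),
                               window = c(-10, 10))$rate == 0))
  expect_error(compute_psth(trials, bin = 0), "positive")
  # Poisson trains with no stimulus: mean rate ~ lambda
  set.seed(9)
  lam <- 80
  tr <- replicate(200, sort(runif(rpois(1, lam * 0.4), -200, 200)),
                  simplify = FALSE)
  p2 <- compute_psth(tr, bin = 2, window = c(-200, 200))
  se <- sqrt(lam / (200 * 0.002 * 200))
  expect_lt(abs(mean(p2$rate) - lam), 3 * se)
})

test_that("burst-pause statistics implement the declared rules", {
  mk_psth <- function(rate, bin = 2, window = c(-200, 150)) {
    edges <- seq(window[1], window[2], bin)
    structure(list(edges = edges, mid = edges[-length(edges)] + bin / 2,
                   rate = rate, trials = 100, bin = bin, stimulus_time = 0),
              class = "pc_psth")
  }
  nbin <- length(seq(-200, 150, 2)) - 1
  flat <- mk_psth(rep(40, nbin))
  s <- burst_pause_stats(flat)
  expect_equal(s$baseline_rate, 40)
  expect_equal(s$max_rate, 40)
  expect_equal(s$pause_duration, 0)
  # burst at +4 ms, zeros from +10 to +70
  r <- rep(40, nbin)
  mids <- flat$mid
  r[mids > 2 & mids < 6] <- 300
  r[mids >= 10 & mids <= 70] <- 0
  s2 <- burst_pause_stats(mk_psth(r))
  expect_equal(s2$max_rate, 300)
  expect_equal(s2$pause_duration, 60, tolerance = 4)
  # raising the pause criterion never shortens the measured pause on
  # burst-then-dip-then-recover shapes
  set.seed(4)
  for (k in 1:20) {
    r3 <- rep(40, nbin) + rnorm(nbin, 0, 2)
    r3[mids > 0 & mids <= 4] <- 250
    dip_len <- sample(5:40, 1)
    r3[mids > 6 & mids <= 6 + 2 * dip_len] <- runif(1, 0, 6)
    p02 <- burst_pause_stats(mk_psth(r3), pause_frac = 0.2)$pause_duration
    p05 <- burst_pause_stats(mk_psth(r3), pause_frac = 0.5)$pause_duration
    expect_gte(p05, p02)
  }
  expect_error(burst_pause_stats(mk_psth(rep(1, 10), window = c(10, 30))),
               "pre-stimulus")
})
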