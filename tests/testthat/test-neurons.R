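# Neuron models: rate functions, single-step oracles, firing behaviour,
# spike detection, and the RK4 accuracy reference.

test_that("gate rate constants match direct substitution and analytic limits", {
  r0 <- hh_rates(0)
  expect_equal(r0$ah, 0.07)
  expect_equal(r0$bm, 4)
  expect_equal(r0$bn, 0.125)
  expect_equal(r0$am, 2.5 / (exp(2.5) - 1))

  # removable singularities: compare with the raw formula evaluated nearby
  raw_am <- function(v) (2.5 - 0.1 * v) / (exp(2.5 - 0.1 * v) - 1)
  raw_an <- function(v) (0.1 - 0.01 * v) / (exp(1 - 0.1 * v) - 1)
  expect_equal(hh_rates(25)$am, 1)
  expect_equal(hh_rates(25)$am, raw_am(25 + 1e-6), tolerance = 1e-6)
  expect_equal(hh_rates(25)$am, raw_am(25 - 1e-6), tolerance = 1e-6)
  expect_equal(hh_rates(10)$an, 0.1)
  expect_equal(hh_rates(10)$an, raw_an(10 + 1e-6), tolerance = 1e-6)
  expect_equal(hh_rates(10)$an, raw_an(10 - 1e-6), tolerance = 1e-6)
})

test_that("the HH membrane rests stably and obeys single-step arithmetic", {
  p <- hh_params()
  # steady-state gates at rest: no drift beyond 0.5 mV over 100 ms
  tr <- simulate_hh(p, stimulus = 0, t_end = 100, dt = 0.01)
  expect_lt(max(abs(tr$V - p$Vrest)), 0.5)

  # all conductance pathways gated shut and no current: V unchanged
  s <- list(V = -55, m = 0, n = 0, h = 0)
  p0 <- hh_params(gL = 0)
  expect_equal(hh_step(s, p0, IExt = 0, dt = 0.01)$V, -55)

  # one Euler step against an independently evaluated formula
  s1 <- list(V = -60, m = 0.1, n = 0.4, h = 0.5)
  nxt <- hh_step(s1, p, IExt = 7, dt = 0.02)
  expected_V <- -60 + 0.02 * (7 - p$gNaMax * 0.1^3 * 0.5 * (-60 - p$ENa) -
                                p$gKMax * 0.4^4 * (-60 - p$EK) -
                                p$gL * (-60 - p$EL)) / p$Cm
  expect_equal(nxt$V, expected_V, tolerance = 1e-12)
  vs <- -60 - p$Vrest
  am <- (2.5 - 0.1 * vs) / (exp(2.5 - 0.1 * vs) - 1)
  expect_equal(nxt$m, 0.1 + 0.02 * (am * 0.9 - 4 * exp(-vs / 18) * 0.1),
               tolerance = 1e-9)
})

test_that("gates stay within [0, 1] across stimuli", {
  for (amp in c(0, 3, 10, 50)) {
    tr <- simulate_hh(stimulus = amp, t_end = 50, dt = 0.01)
    expect_true(all(tr$m >= 0 & tr$m <= 1))
    expect_true(all(tr$n >= 0 & tr$n <= 1))
    expect_true(all(tr$h >= 0 & tr$h <= 1))
  }
})

test_that("HH firing rate is non-decreasing in the injected current", {
  amps <- c(3, 7, 9, 12, 15)
  counts <- vapply(amps, function(a) {
    length(detect_spikes(simulate_hh(stimulus = a, t_end = 200, dt = 0.01))$times)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])
})

test_that("Izhikevich steps match hand-evaluated updates and reset semantics", {
  p <- izh_params(a = 0.02, b = 0.2, c = -65, d = 8)
  nxt <- izh_step(list(V = -70, u = -14), p, I = 10, dt = 1)
  expect_equal(nxt$V, -60)
  expect_equal(nxt$u, -14)
  expect_false(nxt$spike)

  # reset path: previous V at 35 >= 30
  r <- izh_step(list(V = 35, u = -10), p, I = 0, dt = 1)
  expect_equal(r$V, -65)
  expect_equal(r$u, -2)
  expect_true(r$spike)

  # subthreshold quiescence from rest
  tr <- simulate_izh(p, stimulus = 0, t_end = 1000, dt = 0.1)
  expect_length(detect_spikes(tr)$times, 0L)
  expect_lte(izh_residuals(tr, p), 1e-9)
})

test_that("Izhikevich presets produce regular spiking and chattering", {
  rs <- simulate_izh(izh_params(preset = "regular_spiking"), stimulus = 10,
                     t_end = 1000, dt = 0.1)
  ii <- isi(detect_spikes(rs))
  expect_gt(length(ii), 5)
  # periodic after the first spike: tiny coefficient of variation
  expect_lt(sd(ii[-1]) / mean(ii[-1]), 0.05)

  ch <- simulate_izh(izh_params(preset = "chattering"), stimulus = 10,
                     t_end = 1000, dt = 0.1)
  ic <- isi(detect_spikes(ch))
  # grouped spikes: clearly bimodal interval histogram
  short <- ic[ic < 10]; long <- ic[ic >= 10]
  expect_gt(length(short), 5)
  expect_gt(length(long), 5)
  expect_gt(min(long) / max(short), 3)
})

test_that("AdEx steps rest at the fixed point and reset on the cutoff", {
  p <- adex_params(preset = "tonic")
  # near rest the exponential term is negligible
  s <- list(V = p$EL, w = 0)
  nxt <- adex_step(s, p, Iin = 0, dt = 0.1)
  expect_lt(abs(nxt$V - p$EL), 1e-3 * 0.1)

  r <- adex_step(list(V = 5, w = 100), adex_params(preset = "tonic", b = 50),
                 Iin = 0, dt = 0.1)
  expect_equal(r$V, -58)
  expect_equal(r$w, 150)
  expect_true(r$spike)

  # one Euler step against an independently evaluated formula
  s2 <- list(V = -55, w = 30)
  n2 <- adex_step(s2, p, Iin = 120, dt = 0.1)
  expV <- -55 + 0.1 * (-p$gL * (-55 - p$EL) +
                         p$gL * p$DeltaT * exp((-55 - p$Vt) / p$DeltaT) -
                         30 + 120) / p$C
  expW <- 30 + 0.1 * (p$a * (-55 - p$EL) - 30) / p$tau_w
  expect_equal(n2$V, expV, tolerance = 1e-12)
  expect_equal(n2$w, expW, tolerance = 1e-12)
})

test_that("AdEx adaptation lengthens interspike intervals when b > 0", {
  tr <- simulate_adex(adex_params(preset = "adapting"), stimulus = 400,
                      t_end = 500, dt = 0.1)
  ii <- isi(detect_spikes(tr))
  expect_gt(length(ii), 3)
  expect_true(all(diff(ii) >= -1e-9))
  expect_lte(adex_residuals(tr, adex_params(preset = "adapting")), 1e-9)
})

test_that("spike detection handles flat traces, crossings and reset events", {
  flat <- data.frame(time = seq(0, 10, 0.1), V = -70)
  expect_length(detect_spikes(flat)$times, 0L)

  # constructed trace crossing -20 upward exactly twice
  V <- c(-70, -30, 10, -40, -70, -10, 20, -60)
  tr <- data.frame(time = seq_along(V) - 1, V = V)
  s <- detect_spikes(tr, threshold = -20)
  expect_equal(s$times, c(2, 5))

  # reset-event identity for a spiking run
  run <- simulate_izh(izh_params(preset = "regular_spiking"), stimulus = 10,
                      t_end = 300, dt = 0.1)
  expect_length(detect_spikes(run)$times, length(attr(run, "spike_ticks")))
  expect_equal(detect_spikes(attr(run, "spike_ticks"), dt = 0.1)$times,
               detect_spikes(run)$times)
})

test_that("the RK4 reference is accurate and brackets the Euler traces", {
  tr <- integrate_reference("decay", t_end = 1, dt = 0.01, init = list(V = 1))
  expect_equal(tr$V[nrow(tr)], exp(-1), tolerance = 1e-8)

  # zero stimulus from rest: both integrators agree to well under 0.5 mV
  e <- simulate_hh(stimulus = 0, t_end = 50, dt = 0.01)
  r <- integrate_reference("hh", stimulus = 0, t_end = 50, dt = 0.01)
  expect_lt(max(abs(e$V - r$V)), 0.5)

  # sup-norm discrepancy shrinks as dt halves (first-order Euler)
  sup <- vapply(c(0.04, 0.02, 0.01), function(dt) {
    eu <- simulate_hh(stimulus = 6, t_end = 25, dt = dt)
    rk <- integrate_reference("hh", stimulus = 6, t_end = 25, dt = dt)
    max(abs(eu$V - rk$V))
  }, 0)
  expect_true(all(diff(sup) < 0))
})

test_that("simulation traces satisfy their difference equations exactly", {
  hh <- simulate_hh(stimulus = 8, t_end = 40, dt = 0.01)
  expect_lte(hh_residuals(hh), 1e-9)
  iz <- simulate_izh(izh_params(preset = "chattering"), stimulus = 10,
                     t_end = 200, dt = 0.1)
  expect_lte(izh_residuals(iz, izh_params(preset = "chattering")), 1e-9)
  ad <- simulate_adex(adex_params(preset = "tonic"), stimulus = 300,
                      t_end = 200, dt = 0.1)
  expect_lte(adex_residuals(ad, adex_params(preset = "tonic")), 1e-9)
})
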