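# Circuit component library: Ohm/Ampere laws, Kirchhoff composition,
# convergence of the backward-difference capacitor discretization.

test_that("component constructors validate parameters", {
  st <- cob_store(time_grid(2, dt = 0.1))
  expect_error(make_resistor(st, -1), class = "tcob_parameter_error")
  expect_error(make_capacitor(st, 0), class = "tcob_parameter_error")
  expect_error(series_comp(st, list()), class = "tcob_parameter_error")
  expect_error(parallel_comp(st, list()), class = "tcob_parameter_error")
})

test_that("a sinusoidal source vanishes where freq * t = pi", {
  dt <- 0.1
  k <- 100L  # freq * k * dt = pi
  st <- cob_store(time_grid(k, dt = dt))
  make_source(st, amplitude = 2, freq = pi / (k * dt))
  tr <- run_cob(st)
  expect_equal(tr[[2]][k], 0, tolerance = 1e-12)
  expect_equal(tr[[2]][k / 2], 2, tolerance = 1e-12)  # quarter period: peak
})

test_that("two equal resistors in parallel draw twice the single-branch current", {
  st <- cob_store(time_grid(3, dt = 0.1))
  r1 <- make_resistor(st, 4); r2 <- make_resistor(st, 4)
  par <- parallel_comp(st, list(r1, r2))
  bind_series(st, par, "V", 1:3, 8)
  tr <- run_cob(st)
  expect_equal(tr[[paste0(par$id, ".I")]], rep(2 * 8 / 4, 3), tolerance = 1e-9)
})

test_that("a single-component parallel group passes V and I through unchanged", {
  st <- cob_store(time_grid(3, dt = 0.1))
  r <- make_resistor(st, 5)
  par <- parallel_comp(st, list(r))
  bind_series(st, par, "V", 1:3, 10)
  tr <- run_cob(st)
  expect_equal(tr[[paste0(r$id, ".V")]], rep(10, 3))
  expect_equal(tr[[paste0(par$id, ".I")]], tr[[paste0(r$id, ".I")]])
})

test_that("Kirchhoff residuals vanish throughout a driven sample circuit", {
  st <- cob_store(time_grid(60, dt = 0.05))
  ckt <- sample_circuit(st)
  tr <- run_cob(st)
  expect_lte(attr(store_residuals(st), "max"), 1e-9)
  col <- function(inst, a) tr[[paste0(inst$id, ".", a)]]
  # explicit audit: branch currents sum to the loop current (zero)
  isum <- col(ckt$source, "I") + col(ckt$rc, "I") + col(ckt$r2, "I")
  expect_lt(max(abs(isum)), 1e-9)
  vdiff <- col(ckt$r1, "V") + col(ckt$cap, "V") - col(ckt$rc, "V")
  expect_lt(max(abs(vdiff)), 1e-9)
})

test_that("series RC steady-state current amplitude matches the impedance formula", {
  # |I| = A / sqrt(R^2 + 1/(w Cap)^2); first-order discretization, small dt
  A <- 1; w <- 1; R <- 1; Cap <- 1; dt <- 0.02
  ncycles <- 3
  ticks <- as.integer(round(ncycles * 2 * pi / w / dt))
  st <- cob_store(time_grid(ticks, dt = dt))
  src <- make_source(st, A, w)
  rc <- series_comp(st, list(make_resistor(st, R), make_capacitor(st, Cap)))
  parallel_comp(st, list(src, rc), closed = TRUE)
  tr <- run_cob(st)
  Iser <- tr[[paste0(rc$id, ".I")]]
  last <- tr$time > (ncycles - 1) * 2 * pi / w
  amp <- (max(Iser[last]) - min(Iser[last])) / 2
  expect_equal(amp, A / sqrt(R^2 + 1 / (w * Cap)^2), tolerance = 0.02)
})

test_that("the RC step response converges at first order as dt halves", {
  # closed loop: DC source + R + C; V_C(t) = A (1 - exp(-t / (R Cap)))
  err_at <- function(dt) {
    A <- 1; R <- 1; Cap <- 1
    t_final <- 1
    ticks <- as.integer(round(t_final / dt))
    st <- cob_store(time_grid(ticks, dt = dt))
    src <- make_dc_source(st, A)
    cp <- make_capacitor(st, Cap)
    rc <- series_comp(st, list(make_resistor(st, R), cp))
    parallel_comp(st, list(src, rc), closed = TRUE)
    tr <- run_cob(st)
    vc <- tr[[paste0(cp$id, ".V")]]
    exact <- A * (1 - exp(-tr$time / (R * Cap)))
    max(abs(vc - exact))
  }
  e1 <- err_at(0.1)
  e2 <- err_at(0.05)
  expect_lt(e2, e1)
  expect_equal(e2 / e1, 0.5, tolerance = 0.25)  # first-order halving
})

test_that("circuits build from nested JSON configuration", {
  cfg <- list(type = "parallel", children = list(
    list(type = "source", amplitude = 1, freq = 1),
    list(type = "series", children = list(
      list(type = "resistor", R = 1),
      list(type = "capacitor", Cap = 1)))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  st <- cob_store(time_grid(20, dt = 0.05))
  top <- circuit_from_config(st, read_config(path))
  tr <- run_cob(st)
  expect_lte(attr(store_residuals(st), "max"), 1e-9)
  expect_equal(tr[[paste0(top$id, ".I")]], rep(0, 20))  # closed loop
})
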