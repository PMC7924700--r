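# Core engine semantics: class definition, instantiation, series variables,
# per-tick solving, conditional constraints, and solver properties.

component_cls <- function() define_class("component",
  attributes = c(V = "series", I = "series"), env = baseenv())

test_that("class definition merges inheritance and rejects bad definitions", {
  comp <- component_cls()
  res <- define_class("resistor", parent = comp,
                      attributes = c(R = "scalar"),
                      constraints = list(con(V == I * R)), env = baseenv())
  expect_length(res$attributes, 3L)
  expect_length(res$constraints, 1L)

  # zero constraints: instances are pure data
  plain <- define_class("plain", attributes = c(x = "series"), env = baseenv())
  expect_length(plain$constraints, 0L)

  # redeclaring a parent attribute
  expect_error(define_class("bad", parent = comp, attributes = c(V = "series")),
               class = "tcob_definition_error")
  # unknown symbol in a constraint names the symbol
  err <- expect_error(
    define_class("bad2", attributes = c(x = "series"),
                 constraints = list(con(x == y + 1))),
    class = "tcob_definition_error")
  expect_match(conditionMessage(err), "'y'")
})

test_that("instantiation binds arguments, expands quantifiers, checks arity", {
  st <- cob_store(time_grid(3, dt = 0.1))
  r <- make_resistor(st, R = 5)
  bind_series(st, r, "I", 1:3, 2)
  tr <- run_cob(st)
  expect_equal(tr$resistor1.V, rep(10, 3))

  # quantified constraints expand per component
  st2 <- cob_store(time_grid(2, dt = 0.1))
  r1 <- make_resistor(st2, 1); r2 <- make_resistor(st2, 1)
  par <- parallel_comp(st2, list(r1, r2))
  # forall -> 2 voltage equalities, sum -> 1 current constraint
  kinds <- vapply(par$constraints, `[[`, "", "label")
  expect_length(par$constraints, 3L)

  # constructor arity and creational inconsistency
  cls <- define_class("withctor", attributes = c(x = "scalar"),
                      constructor = list(params = "x0",
                                         constraints = list(con(x == x0))),
                      env = baseenv())
  st3 <- cob_store(time_grid(2, dt = 1))
  inst <- instantiate(cls, st3, args = list(x0 = 7))
  expect_equal(inst$attrs$x$value, 7)
  expect_error(instantiate(cls, st3, args = list()),
               class = "tcob_definition_error")

  bad <- define_class("impossible",
                      constructor = list(constraints = list(con(1 == 2))),
                      env = baseenv())
  expect_error(instantiate(bad, st3), class = "tcob_inconsistency_error")
})

test_that("series references resolve past values and flag unknown futures", {
  st <- cob_store(time_grid(5, dt = 1))
  cls <- define_class("s", attributes = c(v = "series"), env = baseenv())
  inst <- instantiate(cls, st, init = list(v = c("1" = 5)))
  expect_equal(resolve_series(inst, "v", -1, 2), 5)
  expect_error(resolve_series(inst, "v", -1, 1),
               class = "tcob_underdetermined_error")
  unk <- resolve_series(inst, "v", 0, 2)
  expect_s3_class(unk, "tcob_unknown")
  expect_equal(unk$tick, 2L)
  expect_error(resolve_series(inst, "v", 2, 1), class = "tcob_definition_error")
})

test_that("the on-off controller alternates via next-tick conditional constraints", {
  st <- cob_store(time_grid(3, dt = 1))
  instantiate(controller_class(), st, init = list(C = c("1" = "on")))
  tr <- run_cob(st)
  expect_equal(tr[[2]], c("on", "off", "on"))

  # period-2 over a longer horizon
  st2 <- cob_store(time_grid(20, dt = 1))
  instantiate(controller_class(), st2, init = list(C = c("1" = "on")))
  tr2 <- run_cob(st2)
  expect_equal(tr2[[2]], rep(c("on", "off"), 10))
})

test_that("a capacitor difference equation integrates to the closed form", {
  # I = Cap dV/dt with constant I: V(k) = V(1) + (k-1) dt I / Cap
  st <- cob_store(time_grid(10, dt = 0.5))
  cp <- make_capacitor(st, Cap = 2, V0 = 0)
  bind_series(st, cp, "I", 1:10, 3)
  tr <- run_cob(st)
  k <- 1:10
  expect_equal(tr$capacitor1.V, 0 + (k - 1) * 0.5 * 3 / 2, tolerance = 1e-12)
})

test_that("inconsistent and underdetermined systems fail loudly", {
  st <- cob_store(time_grid(2, dt = 1))
  cls <- define_class("contradiction", attributes = c(x = "series"),
                      constraints = list(con(0 == 1)), env = baseenv())
  instantiate(cls, st)
  expect_error(step_store(st, 1), class = "tcob_inconsistency_error")

  st2 <- cob_store(time_grid(2, dt = 1))
  cls2 <- define_class("open", attributes = c(x = "series", y = "series"),
                       constraints = list(con(x == y)), env = baseenv())
  instantiate(cls2, st2)
  err <- expect_error(step_store(st2, 1), class = "tcob_underdetermined_error")
  expect_match(conditionMessage(err), "open1")
})

test_that("solve_system is non-directional and handles simultaneous systems", {
  expect_equal(solve_system(list(quote(V == I * R)),
                            knowns = list(V = 10, R = 5))$I, 2)
  expect_equal(solve_system(list(quote(V == I * R)),
                            knowns = list(I = 2, V = 10))$R, 5)
  s <- solve_system(list(x + y ~ 3, x - y ~ 1))
  expect_equal(s$x, 2)
  expect_equal(s$y, 1)
  # round trip V -> I -> V recovers the original value
  I <- solve_system(list(quote(V == I * R)), knowns = list(V = 10, R = 5))$I
  V <- solve_system(list(quote(V == I * R)), knowns = list(I = I, R = 5))$V
  expect_equal(V, 10, tolerance = 1e-12)
})

test_that("traces are independent of constraint declaration order", {
  build <- function(perm) {
    cons <- list(con(x == 2 * y),
                 con(y + z == Time),
                 con(z == 1))[perm]
    cls <- define_class("abc",
                        attributes = c(x = "series", y = "series", z = "series"),
                        constraints = cons, env = baseenv())
    st <- cob_store(time_grid(6, dt = 0.5))
    instantiate(cls, st, id = "a")
    run_cob(st)
  }
  ref <- build(1:3)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    alt <- build(perm)
    expect_lt(max(abs(as.matrix(ref[-1]) - as.matrix(alt[-1]))), 1e-12)
  }
})

test_that("solved series values are immutable across later steps", {
  st <- cob_store(time_grid(6, dt = 1))
  instantiate(controller_class(), st, init = list(C = c("1" = "on")))
  snapshots <- list()
  for (k in 1:6) {
    step_store(st, k)
    snapshots[[k]] <- trace_table(st)[[2]][1:k]
  }
  final <- snapshots[[6]]
  for (k in 1:5) expect_identical(snapshots[[k]], final[1:k])
  # rebinding a solved tick to a different value is an inconsistency
  expect_error(bind_series(st, st$instances[[1]], "C", 1, "off"),
               class = "tcob_inconsistency_error")
})

test_that("a zero-constraint store runs and returns initializers only", {
  st <- cob_store(time_grid(10, dt = 1))
  cls <- define_class("data", attributes = c(x = "series"), env = baseenv())
  instantiate(cls, st, init = list(x = c("1" = 4)))
  tr <- run_cob(st)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr[[2]], c(4, rep(NA_real_, 9)))
})

test_that("engine-hosted neuron classes reproduce the direct simulators", {
  # Hodgkin-Huxley, 2 ms at dt = 0.01
  st <- cob_store(time_grid(200, dt = 0.01))
  nrn <- hh_cob(st)
  bind_series(st, nrn, "IExt", 1:200, 10)
  tr <- run_cob(st)
  d <- simulate_hh(stimulus = 10, t_end = 1.99, dt = 0.01)
  expect_equal(tr$hh.V, d$V, tolerance = 1e-12)
  expect_equal(tr$hh.m, d$m, tolerance = 1e-12)
  expect_lte(attr(store_residuals(st), "max"), 1e-9)

  # Izhikevich with resets (conditional-constraint path), 30 ms at dt = 0.1
  st2 <- cob_store(time_grid(300, dt = 0.1))
  izh <- izh_cob(st2, izh_params(preset = "regular_spiking"))
  bind_series(st2, izh, "I", 1:300, 10)
  tr2 <- run_cob(st2)
  d2 <- simulate_izh(izh_params(preset = "regular_spiking"), stimulus = 10,
                     t_end = 29.9, dt = 0.1)
  expect_equal(tr2$izh.V, d2$V, tolerance = 1e-12)

  # AdEx, 30 ms at dt = 0.1
  st3 <- cob_store(time_grid(300, dt = 0.1))
  ade <- adex_cob(st3, adex_params(preset = "tonic"))
  bind_series(st3, ade, "I", 1:300, 300)
  tr3 <- run_cob(st3)
  d3 <- simulate_adex(adex_params(preset = "tonic"), stimulus = 300,
                      t_end = 29.9, dt = 0.1)
  expect_equal(tr3$adex.V, d3$V, tolerance = 1e-12)
})
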