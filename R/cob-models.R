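# Neuron models expressed as constrained-object classes on the engine.
# These are the declarative forms of the same difference equations the
# direct simulators step: membrane state variables are series attributes,
# the update relations are (conditional) constraints referencing previous
# values, and the after-spike resets of the voltage-reset models are the
# conditional-constraint path.  The direct simulators are the fast route;
# the engine classes exist to show, and test, that both routes coincide.

hh_am <- function(v) expc(2.5 - 0.1 * v)
hh_bm <- function(v) 4 * exp(-v / 18)
hh_an <- function(v) 0.1 * expc(1 - 0.1 * v)
hh_bn <- function(v) 0.125 * exp(-v / 80)
hh_ah <- function(v) 0.07 * exp(-v / 20)
hh_bh <- function(v) 1 / (exp(3 - 0.1 * v) + 1)
clip01 <- function(x) min(1, max(0, x))

#' Neuron models as constrained-object classes
#'
#' `hh_cob()`, `izh_cob()` and `adex_cob()` instantiate the
#' Hodgkin-Huxley, Izhikevich and AdEx models as classes in a constraint
#' store: parameters are scalar attributes, state variables are series, and
#' each difference equation is a constraint on the current value in terms
#' of previous ones.  The reset models use conditional constraints (when
#' the previous voltage reached the cutoff, the current value is pinned to
#' the reset potential).  Bind the stimulus into the `IExt`/`I` series with
#' [bind_series()] and run with [run_cob()]; the trace coincides with the
#' direct simulators ([simulate_hh()] and friends) on the same grid.
#'
#' @param store a [cob_store()]; its grid supplies `dt` and the horizon.
#' @param params the matching parameter set.
#' @param id instance id.
#' @return the `tcob_instance`.
#' @examples
#' st <- cob_store(time_grid(200, dt = 0.01))
#' nrn <- hh_cob(st)
#' bind_series(st, nrn, "IExt", 1:200, 10)
#' tr <- run_cob(st)
#' @export
hh_cob <- function(store, params = hh_params(), id = "hh") {
  cls <- define_class("hh_neuron",
    attributes = c(Cm = "scalar", gNaMax = "scalar", gKMax = "scalar",
                   gL = "scalar", ENa = "scalar", EK = "scalar",
                   EL = "scalar", Vrest = "scalar",
                   V = "series", m = "series", n = "series", h = "series",
                   IExt = "series"),
    constraints = list(
      con_if(Time > 1,
             V == prev(V) + dt * (prev(IExt) -
               gNaMax * prev(m)^3 * prev(h) * (prev(V) - ENa) -
               gKMax * prev(n)^4 * (prev(V) - EK) -
               gL * (prev(V) - EL)) / Cm),
      con_if(Time > 1,
             m == clip01(prev(m) + dt * (hh_am(prev(V) - Vrest) * (1 - prev(m)) -
                                           hh_bm(prev(V) - Vrest) * prev(m)))),
      con_if(Time > 1,
             n == clip01(prev(n) + dt * (hh_an(prev(V) - Vrest) * (1 - prev(n)) -
                                           hh_bn(prev(V) - Vrest) * prev(n)))),
      con_if(Time > 1,
             h == clip01(prev(h) + dt * (hh_ah(prev(V) - Vrest) * (1 - prev(h)) -
                                           hh_bh(prev(V) - Vrest) * prev(h))))),
    env = environment())
  s0 <- hh_init(params)
  instantiate(cls, store, id = id,
              args = unclass(params)[c("Cm", "gNaMax", "gKMax", "gL", "ENa", "EK", "EL",
                              "Vrest")],
              init = list(V = c("1" = s0$V), m = c("1" = s0$m),
                          n = c("1" = s0$n), h = c("1" = s0$h)))
}

#' @rdname hh_cob
#' @param V0 initial voltage (mV).
#' @export
izh_cob <- function(store, params = izh_params(), id = "izh", V0 = -70) {
  cls <- define_class("izh_neuron",
    attributes = c(a = "scalar", b = "scalar", cr = "scalar", d = "scalar",
                   Vpeak = "scalar", V = "series", u = "series", I = "series"),
    constraints = list(
      con_if(Time > 1 && prev(V) >= Vpeak, V == cr),
      con_if(Time > 1 && prev(V) >= Vpeak, u == prev(u) + d),
      con_if(Time > 1 && prev(V) < Vpeak,
             V == min(Vpeak, prev(V) + dt * (0.04 * prev(V)^2 + 5 * prev(V) +
                                               140 - prev(u) + prev(I)))),
      con_if(Time > 1 && prev(V) < Vpeak,
             u == prev(u) + dt * a * (b * prev(V) - prev(u)))),
    env = environment())
  instantiate(cls, store, id = id,
              args = list(a = params$a, b = params$b, cr = params$c,
                          d = params$d, Vpeak = params$Vpeak),
              init = list(V = c("1" = V0), u = c("1" = params$b * V0)))
}

#' @rdname hh_cob
#' @param w0 initial adaptation current (pA).
#' @export
adex_cob <- function(store, params = adex_params(), id = "adex",
                     V0 = NULL, w0 = 0) {
  cls <- define_class("adex_neuron",
    attributes = c(C = "scalar", gL = "scalar", EL = "scalar",
                   DeltaT = "scalar", Vt = "scalar", Vr = "scalar",
                   tau_w = "scalar", a = "scalar", b = "scalar",
                   Vcut = "scalar", V = "series", w = "series", I = "series"),
    constraints = list(
      con_if(Time > 1 && prev(V) > Vcut, V == Vr),
      con_if(Time > 1 && prev(V) > Vcut, w == prev(w) + b),
      con_if(Time > 1 && prev(V) <= Vcut,
             V == min(30, prev(V) + dt * (-gL * (prev(V) - EL) +
               gL * DeltaT * exp(min((prev(V) - Vt) / DeltaT, 20)) -
               prev(w) + prev(I)) / C)),
      con_if(Time > 1 && prev(V) <= Vcut,
             w == prev(w) + dt * (a * (prev(V) - EL) - prev(w)) / tau_w)),
    env = environment())
  instantiate(cls, store, id = id,
              args = unclass(params)[c("C", "gL", "EL", "DeltaT", "Vt", "Vr", "tau_w",
                              "a", "b", "Vcut")],
              init = list(V = c("1" = V0 %||% params$EL), w = c("1" = w0)))
}
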