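# Hodgkin-Huxley membrane model, integrated as difference equations
# (forward Euler), the same time-stepped regime the constraint engine uses.

#' Hodgkin-Huxley parameters
#'
#' Classic squid-axon parameter set, with the integrated membrane voltage on
#' an absolute scale resting at `Vrest` (-70 mV by default) and the reversal
#' potentials placed at their classic offsets from rest.  The gate rate
#' functions are evaluated at `V - Vrest` (the classic convention with rest
#' at 0 mV).
#'
#' @param Cm membrane capacitance (uF/cm^2).
#' @param gNaMax,gKMax,gL maximal sodium, potassium and leak conductances
#'   (mS/cm^2), non-negative.
#' @param Vrest resting potential (mV).
#' @param ENa,EK,EL reversal potentials (mV).
#' @return a list of class `hh_params`.
#' @export
hh_params <- function(Cm = 1, gNaMax = 120, gKMax = 36, gL = 0.3,
                      Vrest = -70, ENa = Vrest + 115, EK = Vrest - 12,
                      EL = Vrest + 10.6) {
  if (Cm <= 0) tcob_abort("tcob_parameter_error", "Cm must be positive")
  if (gNaMax < 0 || gKMax < 0 || gL < 0)
    tcob_abort("tcob_parameter_error", "conductances must be non-negative")
  structure(list(Cm = Cm, gNaMax = gNaMax, gKMax = gKMax, gL = gL,
                 Vrest = Vrest, ENa = ENa, EK = EK, EL = EL),
            class = "hh_params")
}

# x / (e^x - 1) with its removable singularity at x = 0
expc <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2 + x^2 / 12, x / expm1(x))

#' Hodgkin-Huxley gate rate constants
#'
#' The empirical opening (`alpha`) and closing (`beta`) rates of the m, n
#' and h gates as functions of the membrane voltage relative to rest
#' (`v_shift`, mV).  The removable singularities of `alpha_m` (at
#' `v_shift = 25`) and `alpha_n` (at `v_shift = 10`) return their analytic
#' limits, so the function is total.  Vectorized over `v_shift`.
#'
#' @param v_shift membrane voltage relative to rest (mV).
#' @return a list with components `am`, `bm`, `an`, `bn`, `ah`, `bh`.
#' @examples
#' hh_rates(0)   # ah = 0.07, bm = 4, bn = 0.125
#' hh_rates(25)$am  # 1, the limit of x / (e^x - 1)
#' @export
hh_rates <- function(v_shift) {
  v <- v_shift
  list(am = expc(2.5 - 0.1 * v),
       bm = 4 * exp(-v / 18),
       an = 0.1 * expc(1 - 0.1 * v),
       bn = 0.125 * exp(-v / 80),
       ah = 0.07 * exp(-v / 20),
       bh = 1 / (exp(3 - 0.1 * v) + 1))
}

#' @rdname hh_rates
#' @return `hh_steady_gates` returns the steady-state opening probabilities
#'   `m`, `n`, `h` (`x_inf = alpha / (alpha + beta)`) at `v_shift`.
#' @export
hh_steady_gates <- function(v_shift = 0) {
  r <- hh_rates(v_shift)
  list(m = r$am / (r$am + r$bm),
       n = r$an / (r$an + r$bn),
       h = r$ah / (r$ah + r$bh))
}

#' @rdname hh_step
#' @export
hh_init <- function(params = hh_params()) {
  g <- hh_steady_gates(0)
  list(V = params$Vrest, m = g$m, n = g$n, h = g$h)
}

#' One forward-Euler step of the Hodgkin-Huxley difference equations
#'
#' Advances the state by `dt` ms: the membrane equation
#' `Cm dV/dt = IExt - gNaMax m^3 h (V - ENa) - gKMax n^4 (V - EK) - gL (V - EL)`
#' and the three gate equations `dx/dt = alpha (1 - x) - beta x`, with the
#' rates evaluated at `V - Vrest` and the gates clipped to `[0, 1]`.
#'
#' @param state list with `V`, `m`, `n`, `h` (see [hh_init()]).
#' @param params an [hh_params()] set.
#' @param IExt injected current over this step (model current units).
#' @param dt time step (ms).
#' @return the next state, a list with `V`, `m`, `n`, `h`.
#' @export
hh_step <- function(state, params, IExt, dt) {
  V <- state$V; m <- state$m; n <- state$n; h <- state$h
  p <- params
  INa <- p$gNaMax * m^3 * h * (V - p$ENa)
  IK <- p$gKMax * n^4 * (V - p$EK)
  IL <- p$gL * (V - p$EL)
  Vn <- V + dt * (IExt - INa - IK - IL) / p$Cm
  r <- hh_rates(V - p$Vrest)
  mn <- min(1, max(0, m + dt * (r$am * (1 - m) - r$bm * m)))
  nn <- min(1, max(0, n + dt * (r$an * (1 - n) - r$bn * n)))
  hn <- min(1, max(0, h + dt * (r$ah * (1 - h) - r$bh * h)))
  if (!is.finite(Vn))
    tcob_abort("tcob_numeric_error", "membrane voltage diverged")
  list(V = Vn, m = mn, n = nn, h = hn)
}

#' Simulate a Hodgkin-Huxley neuron
#'
#' Forward-Euler integration of the difference equations from rest
#' (voltage `Vrest`, gates at their steady state) under a stimulus current.
#'
#' @param params an [hh_params()] set.
#' @param stimulus injected current: a single number (constant), a numeric
#'   vector sampled on the grid, or a function of time (ms).
#' @param t_end duration (ms).
#' @param dt time step (ms), 0.01 by default.
#' @param init optional initial state (defaults to [hh_init()]).
#' @return a `data.frame` with columns `time`, `V`, `m`, `n`, `h`, `IExt`;
#'   the first row is the initial state at `time = 0`.
#' @examples
#' tr <- simulate_hh(stimulus = 10, t_end = 20)
#' max(tr$V)  # action-potential peak, around +40 mV
#' @export
simulate_hh <- function(params = hh_params(), stimulus = 0, t_end = 100,
                        dt = 0.01, init = NULL) {
  n <- as.integer(round(t_end / dt)) + 1L
  I <- stim_values(stimulus, dt, n)
  s0 <- init %||% hh_init(params)
  V <- m <- nn <- h <- numeric(n)
  V[1] <- s0$V; m[1] <- s0$m; nn[1] <- s0$n; h[1] <- s0$h
  p <- params
  Cm <- p$Cm; gNa <- p$gNaMax; gK <- p$gKMax; gL <- p$gL
  ENa <- p$ENa; EK <- p$EK; EL <- p$EL; Vr <- p$Vrest
  for (k in 2:n) {
    Vp <- V[k - 1L]; mp <- m[k - 1L]; np <- nn[k - 1L]; hp <- h[k - 1L]
    V[k] <- Vp + dt * (I[k - 1L] - gNa * mp^3 * hp * (Vp - ENa) -
                         gK * np^4 * (Vp - EK) - gL * (Vp - EL)) / Cm
    vs <- Vp - Vr
    am <- expc(2.5 - 0.1 * vs); bm <- 4 * exp(-vs / 18)
    an <- 0.1 * expc(1 - 0.1 * vs); bn <- 0.125 * exp(-vs / 80)
    ah <- 0.07 * exp(-vs / 20); bh <- 1 / (exp(3 - 0.1 * vs) + 1)
    m[k] <- min(1, max(0, mp + dt * (am * (1 - mp) - bm * mp)))
    nn[k] <- min(1, max(0, np + dt * (an * (1 - np) - bn * np)))
    h[k] <- min(1, max(0, hp + dt * (ah * (1 - hp) - bh * hp)))
  }
  if (!all(is.finite(V)))
    tcob_abort("tcob_numeric_error",
               sprintf("membrane voltage diverged at tick %d",
                       which(!is.finite(V))[1]))
  data.frame(time = (seq_len(n) - 1L) * dt, V = V, m = m, n = nn, h = h,
             IExt = I)
}

#' Residual sweep over a simulated neuron trace
#'
#' Recomputes every difference-equation residual of a stored trace: the
#' statement that each row follows from the previous one through the model's
#' update relations.  This is the trace-level analogue of
#' [store_residuals()] for the direct simulators.
#'
#' @param trace a trace returned by [simulate_hh()], [simulate_izh()] or
#'   [simulate_adex()].
#' @param params the parameter set used for the simulation.
#' @param dt the time step used (ms); inferred from the trace if omitted.
#' @return the maximum absolute residual over all rows and relations.
#' @export
hh_residuals <- function(trace, params = hh_params(), dt = NULL) {
  dt <- dt %||% (trace$time[2] - trace$time[1])
  p <- params
  n <- nrow(trace)
  V <- trace$V; m <- trace$m; nn <- trace$n; h <- trace$h; I <- trace$IExt
  i <- seq_len(n - 1L)
  rV <- V[i + 1L] - (V[i] + dt * (I[i] - p$gNaMax * m[i]^3 * h[i] * (V[i] - p$ENa) -
                                    p$gKMax * nn[i]^4 * (V[i] - p$EK) -
                                    p$gL * (V[i] - p$EL)) / p$Cm)
  vs <- V[i] - p$Vrest
  r <- hh_rates(vs)
  rm <- m[i + 1L] - pmin(1, pmax(0, m[i] + dt * (r$am * (1 - m[i]) - r$bm * m[i])))
  rn <- nn[i + 1L] - pmin(1, pmax(0, nn[i] + dt * (r$an * (1 - nn[i]) - r$bn * nn[i])))
  rh <- h[i + 1L] - pmin(1, pmax(0, h[i] + dt * (r$ah * (1 - h[i]) - r$bh * h[i])))
  max(abs(c(rV, rm, rn, rh)))
}

# stimulus -> per-tick numeric vector (tick k is time (k-1)*dt)
stim_values <- function(stimulus, dt, n) {
  tt <- (seq_len(n) - 1L) * dt
  if (is.function(stimulus)) return(vapply(tt, stimulus, 0))
  if (is.numeric(stimulus) && length(stimulus) == 1L) return(rep(stimulus, n))
  if (is.numeric(stimulus)) {
    if (length(stimulus) < n)
      tcob_abort("tcob_parameter_error",
                 sprintf("stimulus vector has %d values but the grid has %d ticks",
                         length(stimulus), n))
    return(stimulus[seq_len(n)])
  }
  tcob_abort("tcob_parameter_error",
             "stimulus must be a number, a numeric vector or a function of time")
}

#' Smallest step current giving sustained repetitive firing
#'
#' Scans step-current amplitudes in increasing order and reports the first
#' one for which the neuron fires at least `min_spikes` spikes within
#' `t_end` ms (the repetitive-firing onset, a discrete rheobase estimate).
#'
#' @param amplitudes currents to scan, in increasing order.
#' @param params an [hh_params()] set.
#' @param t_end,dt simulation horizon and step (ms).
#' @param min_spikes spikes required to call the firing sustained.
#' @param threshold spike-detection threshold (mV).
#' @return the smallest amplitude that fires, or `NA` if none does; the
#'   per-amplitude spike counts are attached as attribute `counts`.
#' @export
hh_firing_onset <- function(amplitudes = 1:10, params = hh_params(),
                            t_end = 500, dt = 0.01, min_spikes = 3,
                            threshold = -20) {
  counts <- integer(length(amplitudes))
  onset <- NA_real_
  for (i in seq_along(amplitudes)) {
    tr <- simulate_hh(params, stimulus = amplitudes[i], t_end = t_end, dt = dt)
    counts[i] <- length(detect_spikes(tr, threshold = threshold)$times)
    if (is.na(onset) && counts[i] >= min_spikes) {
      onset <- amplitudes[i]
      break
    }
  }
  structure(onset, counts = setNames(counts[seq_len(i)],
                                     amplitudes[seq_len(i)]))
}
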