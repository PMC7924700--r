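#' Spike trains
#'
#' An ordered list of spike times (ms) with an optional source identifier.
#'
#' @param times strictly increasing numeric vector of spike times (ms).
#' @param source cell identifier.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(), source = NA_character_) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    tcob_abort("tcob_parameter_error", "spike times must be strictly increasing")
  structure(list(times = times, source = source), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spike(s)\n",
              x$source %||% "?", length(x$times)))
  if (length(x$times)) cat(" ", paste(signif(x$times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Extract spikes from a voltage trace or reset events
#'
#' For the reset models a spike is a reset event: pass the trace returned
#' by [simulate_izh()]/[simulate_adex()] (its `spike_ticks` attribute is
#' used) or an integer vector of reset ticks together with `dt`.  For
#' continuous traces (Hodgkin-Huxley) spikes are upward crossings of
#' `threshold` (default -20 mV), one spike per crossing.  An empty or flat
#' trace yields an empty train.
#'
#' @param x a trace `data.frame` with columns `time` and `V`, or an integer
#'   vector of reset ticks.
#' @param threshold crossing threshold (mV) for continuous traces.
#' @param dt tick duration (ms), required when `x` is a tick vector; tick
#'   `k` maps to time `(k - 1) * dt`.
#' @param source cell identifier carried on the result.
#' @return a [spike_train()].
#' @export
detect_spikes <- function(x, threshold = -20, dt = NULL, source = NA_character_) {
  if (is.data.frame(x)) {
    ticks <- attr(x, "spike_ticks")
    if (!is.null(ticks))
      return(spike_train(x$time[ticks], source))
    V <- x$V
    n <- length(V)
    if (n < 2L) return(spike_train(numeric(), source))
    idx <- which(V[-n] < threshold & V[-1L] >= threshold) + 1L
    return(spike_train(x$time[idx], source))
  }
  if (is.numeric(x)) {
    if (is.null(dt))
      tcob_abort("tcob_parameter_error", "dt is required for a tick vector")
    return(spike_train((as.integer(x) - 1L) * dt, source))
  }
  tcob_abort("tcob_parameter_error", "x must be a trace data.frame or a tick vector")
}

#' Interspike intervals of a spike train
#' @param train a [spike_train()].
#' @return numeric vector of interspike intervals (ms).
#' @export
isi <- function(train) diff(train$times)

#' Reference Runge-Kutta integration
#'
#' Classic fourth-order Runge-Kutta over the same model right-hand sides as
#' the forward-Euler difference equations, with after-spike resets applied
#' between steps for the reset models.  Intended as an independent accuracy
#' reference for the Euler traces, not as the simulation path.
#'
#' @param model one of `"hh"`, `"izh"`, `"adex"`, or `"decay"` (the linear
#'   test equation `dV/dt = -V`).
#' @param params the matching parameter set ([hh_params()], [izh_params()],
#'   [adex_params()]; ignored for `"decay"`).
#' @param stimulus as in [simulate_hh()].
#' @param t_end,dt horizon and step (ms).
#' @param init optional initial state; model-specific defaults otherwise.
#' @return a trace `data.frame` with `time`, `V` and the model's remaining
#'   state variables; reset models carry a `spike_ticks` attribute.
#' @examples
#' tr <- integrate_reference("decay", t_end = 1, dt = 0.01, init = list(V = 1))
#' abs(tr$V[nrow(tr)] - exp(-1)) < 1e-8
#' @export
integrate_reference <- function(model, params = NULL, stimulus = 0,
                                t_end = 100, dt = 0.01, init = NULL) {
  n <- as.integer(round(t_end / dt)) + 1L
  I <- stim_values(stimulus, dt, n)
  model <- match.arg(model, c("hh", "izh", "adex", "decay"))
  if (model == "hh") {
    p <- params %||% hh_params()
    s0 <- init %||% hh_init(p)
    deriv <- function(s, Iv) {
      r <- hh_rates(s[1] - p$Vrest)
      c(
        (Iv - p$gNaMax * s[2]^3 * s[4] * (s[1] - p$ENa) -
           p$gKMax * s[3]^4 * (s[1] - p$EK) - p$gL * (s[1] - p$EL)) / p$Cm,
        r$am * (1 - s[2]) - r$bm * s[2],
        r$an * (1 - s[3]) - r$bn * s[3],
        r$ah * (1 - s[4]) - r$bh * s[4])
    }
    out <- rk4_loop(c(s0$V, s0$m, s0$n, s0$h), deriv, I, dt, n)
    return(data.frame(time = (seq_len(n) - 1L) * dt, V = out[, 1],
                      m = out[, 2], n = out[, 3], h = out[, 4]))
  }
  if (model == "decay") {
    s0 <- init %||% list(V = 1)
    out <- rk4_loop(s0$V, function(s, Iv) -s, I, dt, n)
    return(data.frame(time = (seq_len(n) - 1L) * dt, V = out[, 1]))
  }
  if (model == "izh") {
    p <- params %||% izh_params()
    s0 <- init %||% list(V = -70, u = p$b * -70)
    deriv <- function(s, Iv) c(0.04 * s[1]^2 + 5 * s[1] + 140 - s[2] + Iv,
                               p$a * (p$b * s[1] - s[2]))
    reset <- function(s) if (s[1] >= p$Vpeak) c(p$c, s[2] + p$d) else NULL
    out <- rk4_loop(c(s0$V, s0$u), deriv, I, dt, n, reset)
    tr <- data.frame(time = (seq_len(n) - 1L) * dt, V = out[, 1], u = out[, 2])
    attr(tr, "spike_ticks") <- attr(out, "spike_ticks")
    return(tr)
  }
  p <- params %||% adex_params()
  s0 <- init %||% list(V = p$EL, w = 0)
  deriv <- function(s, Iv) {
    expterm <- p$gL * p$DeltaT * exp(min((s[1] - p$Vt) / p$DeltaT, 20))
    c((-p$gL * (s[1] - p$EL) + expterm - s[2] + Iv) / p$C,
      (p$a * (s[1] - p$EL) - s[2]) / p$tau_w)
  }
  reset <- function(s) if (s[1] > p$Vcut) c(p$Vr, s[2] + p$b) else NULL
  out <- rk4_loop(c(s0$V, s0$w), deriv, I, dt, n, reset)
  tr <- data.frame(time = (seq_len(n) - 1L) * dt, V = out[, 1], w = out[, 2])
  attr(tr, "spike_ticks") <- attr(out, "spike_ticks")
  tr
}

rk4_loop <- function(s0, deriv, I, dt, n, reset = NULL) {
  m <- length(s0)
  out <- matrix(0, n, m)
  out[1, ] <- s0
  s <- s0
  spikes <- integer()
  for (k in 2:n) {
    if (!is.null(reset)) {
      rs <- reset(s)
      if (!is.null(rs)) {
        s <- rs
        out[k, ] <- s
        spikes[[length(spikes) + 1L]] <- k
        next
      }
    }
    Iv <- I[k - 1L]
    k1 <- deriv(s, Iv)
    k2 <- deriv(s + dt / 2 * k1, Iv)
    k3 <- deriv(s + dt / 2 * k2, Iv)
    k4 <- deriv(s + dt * k3, Iv)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(s)))
      tcob_abort("tcob_numeric_error",
                 sprintf("reference integration diverged at tick %d", k))
    out[k, ] <- s
  }
  attr(out, "spike_ticks") <- spikes
  out
}
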