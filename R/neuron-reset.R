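# Voltage-reset neuron models (Izhikevich and adaptive exponential
# integrate-and-fire).  The discontinuous after-spike reset is the
# conditional-constraint path: when the previous-tick voltage is at or above
# the cutoff, the new value is pinned to the reset potential instead of
# following the difference equation.

#' Izhikevich model parameters
#'
#' @param a recovery time scale (1/ms).
#' @param b recovery sensitivity.
#' @param c after-spike reset value of `V` (mV).
#' @param d after-spike increment of the recovery variable `u`.
#' @param Vpeak upswing cutoff (mV); must exceed `c`.
#' @param preset instead of individual values, one of `"regular_spiking"`
#'   (cortical regular spiking) or `"chattering"` (bursts of closely spaced
#'   spikes).
#' @return a list of class `izh_params`.
#' @export
izh_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, Vpeak = 30,
                       preset = NULL) {
  if (!is.null(preset)) {
    ps <- switch(preset,
      regular_spiking = list(a = 0.02, b = 0.2, c = -65, d = 8),
      chattering = list(a = 0.02, b = 0.2, c = -50, d = 2),
      tcob_abort("tcob_parameter_error",
                 sprintf("unknown Izhikevich preset '%s'", preset)))
    # explicitly supplied arguments override the preset
    supplied <- names(match.call())[-1]
    for (nm in setdiff(names(ps), supplied)) assign(nm, ps[[nm]])
  }
  if (Vpeak <= c)
    tcob_abort("tcob_parameter_error", "Vpeak must exceed the reset value c")
  structure(list(a = a, b = b, c = c, d = d, Vpeak = Vpeak),
            class = "izh_params")
}

#' One step of the Izhikevich difference equations
#'
#' If the previous voltage is at or above `Vpeak` the after-spike reset is
#' applied (`V <- c`, `u <- u + d`, a spike is recorded); otherwise a
#' forward-Euler step of `dV/dt = 0.04 V^2 + 5 V + 140 - u + I` and
#' `du/dt = a (b V - u)`.
#'
#' @param state list with `V` (mV) and recovery variable `u`.
#' @param params an [izh_params()] set.
#' @param I injected current.
#' @param dt time step (ms).
#' @return list with `V`, `u` and logical `spike`.
#' @export
izh_step <- function(state, params, I, dt) {
  V <- state$V; u <- state$u; p <- params
  if (V >= p$Vpeak)
    return(list(V = p$c, u = u + p$d, spike = TRUE))
  Vn <- V + dt * (0.04 * V^2 + 5 * V + 140 - u + I)
  un <- u + dt * p$a * (p$b * V - u)
  if (!is.finite(Vn))
    tcob_abort("tcob_numeric_error", "membrane voltage diverged")
  list(V = Vn, u = un, spike = FALSE)
}

#' Simulate an Izhikevich neuron
#'
#' The traced voltage is clamped at `Vpeak` on spike ticks (the finite
#' maximum upswing recorded for display); the reset fires on the following
#' tick.  Spike times are the reset ticks.
#'
#' @inheritParams simulate_hh
#' @param params an [izh_params()] set.
#' @param V0 initial voltage (mV); `u` starts at `b * V0`.
#' @return a `data.frame` with columns `time`, `V`, `u`, `I` and attribute
#'   `spike_ticks` (integer row indices of the resets).
#' @export
simulate_izh <- function(params = izh_params(), stimulus = 0, t_end = 200,
                         dt = 0.1, V0 = -70) {
  n <- as.integer(round(t_end / dt)) + 1L
  I <- stim_values(stimulus, dt, n)
  p <- params
  V <- u <- numeric(n)
  V[1] <- V0; u[1] <- p$b * V0
  resets <- integer()
  for (k in 2:n) {
    Vp <- V[k - 1L]; up <- u[k - 1L]
    if (Vp >= p$Vpeak) {
      V[k] <- p$c
      u[k] <- up + p$d
      resets[[length(resets) + 1L]] <- k
    } else {
      V[k] <- min(p$Vpeak, Vp + dt * (0.04 * Vp^2 + 5 * Vp + 140 - up + I[k - 1L]))
      u[k] <- up + dt * p$a * (p$b * Vp - up)
    }
  }
  out <- data.frame(time = (seq_len(n) - 1L) * dt, V = V, u = u, I = I)
  attr(out, "spike_ticks") <- resets
  out
}

#' @rdname hh_residuals
#' @export
izh_residuals <- function(trace, params = izh_params(), dt = NULL) {
  dt <- dt %||% (trace$time[2] - trace$time[1])
  p <- params
  n <- nrow(trace)
  V <- trace$V; u <- trace$u; I <- trace$I
  i <- seq_len(n - 1L)
  reset <- V[i] >= p$Vpeak
  rV <- ifelse(reset, V[i + 1L] - p$c,
               V[i + 1L] - pmin(p$Vpeak, V[i] + dt * (0.04 * V[i]^2 + 5 * V[i] +
                                                        140 - u[i] + I[i])))
  ru <- ifelse(reset, u[i + 1L] - (u[i] + p$d),
               u[i + 1L] - (u[i] + dt * p$a * (p$b * V[i] - u[i])))
  max(abs(c(rV, ru)))
}

#' Adaptive exponential integrate-and-fire parameters
#'
#' @param C membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL resting potential (mV).
#' @param DeltaT slope factor (mV), positive.
#' @param Vt threshold potential (mV).
#' @param Vr reset potential (mV).
#' @param tau_w adaptation time constant (ms), positive.
#' @param a subthreshold adaptation (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param Vcut spike cutoff (mV): the neuron is reset on the tick after `V`
#'   exceeds this value (0 mV).
#' @param preset instead of individual values, one of `"tonic"` (tonic
#'   spiking with sharp reset), `"adapting"` (spike-frequency adaptation),
#'   or a cerebellar cell preset `"granule"`, `"golgi"`, `"purkinje"`.
#'   Cell presets are configuration, chosen to give plausible desk-scale
#'   behaviour, not fits to recordings.
#' @return a list of class `adex_params`.
#' @export
adex_params <- function(C = 200, gL = 10, EL = -70, DeltaT = 2, Vt = -50,
                        Vr = -58, tau_w = 30, a = 2, b = 0, Vcut = 0,
                        preset = NULL) {
  if (!is.null(preset)) {
    ps <- switch(preset,
      tonic    = list(C = 200, gL = 10, EL = -70, Vt = -50, Vr = -58,
                      tau_w = 30, a = 2, b = 0),
      adapting = list(C = 200, gL = 12, EL = -70, Vt = -50, Vr = -58,
                      tau_w = 300, a = 2, b = 60),
      granule  = list(C = 3.1, gL = 0.43, EL = -70, Vt = -55, Vr = -63,
                      tau_w = 23, a = 0.3, b = 0.2),
      golgi    = list(C = 76, gL = 3.6, EL = -70, Vt = -55, Vr = -62,
                      tau_w = 21, a = 1, b = 10),
      purkinje = list(C = 107, gL = 4.3, EL = -70, Vt = -52, Vr = -60,
                      tau_w = 100, a = 2, b = 20),
      tcob_abort("tcob_parameter_error",
                 sprintf("unknown AdEx preset '%s'", preset)))
    # explicitly supplied arguments override the preset
    supplied <- names(match.call())[-1]
    for (nm in setdiff(names(ps), supplied)) assign(nm, ps[[nm]])
  }
  if (DeltaT <= 0) tcob_abort("tcob_parameter_error", "DeltaT must be positive")
  if (tau_w <= 0) tcob_abort("tcob_parameter_error", "tau_w must be positive")
  structure(list(C = C, gL = gL, EL = EL, DeltaT = DeltaT, Vt = Vt, Vr = Vr,
                 tau_w = tau_w, a = a, b = b, Vcut = Vcut),
            class = "adex_params")
}

#' One step of the AdEx difference equations
#'
#' If the previous voltage exceeds the cutoff (`Vcut`, 0 mV) the after-spike
#' reset is applied (`V <- Vr`, `w <- w + b`, a spike is recorded);
#' otherwise a forward-Euler step of
#' `C dV/dt = -gL (V - EL) + gL DeltaT exp((V - Vt)/DeltaT) - w + Iin` and
#' `tau_w dw/dt = a (V - EL) - w`.  `Iin` enters positively: a positive
#' drive depolarizes.  The exponential argument is capped at 20 to avoid
#' overflow on the tick before the reset.
#'
#' @param state list with `V` (mV) and adaptation current `w` (pA).
#' @param params an [adex_params()] set.
#' @param Iin input current (pA), depolarizing when positive.
#' @param dt time step (ms).
#' @return list with `V`, `w` and logical `spike`.
#' @export
adex_step <- function(state, params, Iin, dt) {
  V <- state$V; w <- state$w; p <- params
  if (V > p$Vcut)
    return(list(V = p$Vr, w = w + p$b, spike = TRUE))
  expterm <- p$gL * p$DeltaT * exp(min((V - p$Vt) / p$DeltaT, 20))
  Vn <- V + dt * (-p$gL * (V - p$EL) + expterm - w + Iin) / p$C
  wn <- w + dt * (p$a * (V - p$EL) - w) / p$tau_w
  if (!is.finite(Vn))
    tcob_abort("tcob_numeric_error", "membrane voltage diverged")
  list(V = Vn, w = wn, spike = FALSE)
}

#' Simulate an AdEx neuron
#'
#' The traced voltage is clamped at +30 mV on the spike upswing (a finite
#' recorded peak, as for the Izhikevich trace); since +30 exceeds the 0 mV
#' cutoff the reset fires on the following tick regardless.  Spike times
#' are the reset ticks.
#'
#' @inheritParams simulate_hh
#' @param params an [adex_params()] set.
#' @param V0 initial voltage (mV).
#' @param w0 initial adaptation current (pA).
#' @return a `data.frame` with columns `time`, `V`, `w`, `I` and attribute
#'   `spike_ticks`.
#' @export
simulate_adex <- function(params = adex_params(), stimulus = 0, t_end = 200,
                          dt = 0.1, V0 = -70, w0 = 0) {
  n <- as.integer(round(t_end / dt)) + 1L
  I <- stim_values(stimulus, dt, n)
  p <- params
  V <- w <- numeric(n)
  V[1] <- V0; w[1] <- w0
  resets <- integer()
  peak <- 30
  for (k in 2:n) {
    Vp <- V[k - 1L]; wp <- w[k - 1L]
    if (Vp > p$Vcut) {
      V[k] <- p$Vr
      w[k] <- wp + p$b
      resets[[length(resets) + 1L]] <- k
    } else {
      expterm <- p$gL * p$DeltaT * exp(min((Vp - p$Vt) / p$DeltaT, 20))
      V[k] <- min(peak, Vp + dt * (-p$gL * (Vp - p$EL) + expterm - wp + I[k - 1L]) / p$C)
      w[k] <- wp + dt * (p$a * (Vp - p$EL) - wp) / p$tau_w
    }
  }
  out <- data.frame(time = (seq_len(n) - 1L) * dt, V = V, w = w, I = I)
  attr(out, "spike_ticks") <- resets
  out
}

#' @rdname hh_residuals
#' @export
adex_residuals <- function(trace, params = adex_params(), dt = NULL) {
  dt <- dt %||% (trace$time[2] - trace$time[1])
  p <- params
  n <- nrow(trace)
  V <- trace$V; w <- trace$w; I <- trace$I
  i <- seq_len(n - 1L)
  reset <- V[i] > p$Vcut
  expterm <- p$gL * p$DeltaT * exp(pmin((V[i] - p$Vt) / p$DeltaT, 20))
  rV <- ifelse(reset, V[i + 1L] - p$Vr,
               V[i + 1L] - pmin(30, V[i] + dt * (-p$gL * (V[i] - p$EL) + expterm -
                                                   w[i] + I[i]) / p$C))
  rw <- ifelse(reset, w[i + 1L] - (w[i] + p$b),
               w[i + 1L] - (w[i] + dt * (p$a * (V[i] - p$EL) - w[i]) / p$tau_w))
  max(abs(c(rV, rw)))
}
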