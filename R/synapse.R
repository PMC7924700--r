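# Conductance-based synapses.  The synaptic current is
# I_syn(t) = g_syn(t) (V - E_syn), with the conductance time course g(t)
# given by one of three stereotyped kernels: single exponential
# (instantaneous rise, exponential decay), alpha (finite rise, peak gmax at
# t0 + tau), or double exponential (independent rise and decay constants,
# normalized so the peak equals gmax at t_peak).  All kernels are causal:
# identically zero before the presynaptic spike time t0.

#' Synapse parameters
#'
#' @param gmax maximal conductance (nS), non-negative.
#' @param tau time constant (ms) for the single-exponential and alpha
#'   kernels, positive.
#' @param tau_rise,tau_decay rise and decay constants (ms) for the
#'   double-exponential kernel; requires `tau_decay > tau_rise > 0`.
#' @param Esyn synaptic reversal potential (mV).
#' @param t0 most recent presynaptic spike time (ms).
#' @return a list of class `syn_params`.
#' @export
syn_params <- function(gmax = 1, tau = 3, tau_rise = 1, tau_decay = 3,
                       Esyn = 0, t0 = 0) {
  if (gmax < 0) tcob_abort("tcob_parameter_error", "gmax must be non-negative")
  structure(list(gmax = gmax, tau = tau, tau_rise = tau_rise,
                 tau_decay = tau_decay, Esyn = Esyn, t0 = t0),
            class = "syn_params")
}

#' Synaptic conductance kernels
#'
#' `g_single_exp` rises instantaneously to `gmax` at `t0` and decays as
#' `gmax exp(-(t - t0)/tau)`.  `g_alpha` is
#' `gmax ((t - t0)/tau) exp(1 - (t - t0)/tau)`, zero at onset and peaking at
#' `gmax` at `t0 + tau`.  `g_double_exp` is the normalized difference of
#' exponentials
#' `gmax f_norm (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise))`,
#' peaking at `gmax` at `t_peak` (see [double_exp_derived()]).  All are zero
#' for `t < t0` and vectorized over `t`.
#'
#' @param t time (ms); may be a vector.
#' @param p a [syn_params()] set.
#' @return conductance (nS).
#' @examples
#' p <- syn_params(gmax = 2, tau = 3)
#' g_single_exp(p$t0, p)            # 2
#' g_alpha(p$t0 + p$tau, p)         # 2, the kernel's peak
#' @export
g_single_exp <- function(t, p) {
  if (p$tau <= 0) tcob_abort("tcob_parameter_error", "tau must be positive")
  s <- t - p$t0
  ifelse(s < 0, 0, p$gmax * exp(-s / p$tau))
}

#' @rdname g_single_exp
#' @export
g_alpha <- function(t, p) {
  if (p$tau <= 0) tcob_abort("tcob_parameter_error", "tau must be positive")
  s <- (t - p$t0) / p$tau
  ifelse(s < 0, 0, p$gmax * s * exp(1 - s))
}

#' Double-exponential kernel derived quantities
#'
#' The time of peak conductance
#' `t_peak = t0 + (tau_decay tau_rise / (tau_decay - tau_rise)) ln(tau_decay / tau_rise)`
#' and the normalization `f_norm` chosen so that the kernel equals `gmax`
#' exactly at `t_peak`.
#'
#' @param p a [syn_params()] set with `tau_decay > tau_rise > 0`.
#' @return list with `t_peak` (ms) and `f_norm` (dimensionless).
#' @examples
#' d <- double_exp_derived(syn_params(tau_rise = 1, tau_decay = 3))
#' d$t_peak  # 1.5 * log(3) ~ 1.648 ms
#' @export
double_exp_derived <- function(p) {
  if (!(p$tau_decay > p$tau_rise && p$tau_rise > 0))
    tcob_abort("tcob_parameter_error", "need tau_decay > tau_rise > 0")
  tp <- p$t0 + p$tau_decay * p$tau_rise / (p$tau_decay - p$tau_rise) *
    log(p$tau_decay / p$tau_rise)
  s <- tp - p$t0
  fn <- 1 / (exp(-s / p$tau_decay) - exp(-s / p$tau_rise))
  list(t_peak = tp, f_norm = fn)
}

#' @rdname g_single_exp
#' @export
g_double_exp <- function(t, p) {
  d <- double_exp_derived(p)
  s <- t - p$t0
  ifelse(s < 0, 0,
         p$gmax * d$f_norm * (exp(-s / p$tau_decay) - exp(-s / p$tau_rise)))
}

#' Synaptic current
#'
#' `I_syn = g (V - Esyn)` in the ionic convention: the current is negative
#' (inward, depolarizing) when the membrane sits below an excitatory
#' reversal potential.
#'
#' @param g conductance (nS).
#' @param V membrane voltage (mV).
#' @param Esyn reversal potential (mV).
#' @return current (nS x mV = pA).
#' @export
syn_current <- function(g, V, Esyn) g * (V - Esyn)

#' Receptor kinetics presets
#'
#' Double-exponential parameter sets for the four canonical receptor
#' channels: AMPA (fast excitatory), NMDA (slow excitatory), GABAA (fast
#' inhibitory) and GABAB (slow inhibitory).  Excitatory reversal potentials
#' are 0 mV; inhibitory ones sit below the resting potential.  Time
#' constants honour the ordering AMPA fastest, then GABAA, then NMDA and
#' GABAB slowest; the numeric values are configurable defaults, not fitted
#' constants.  No NMDA magnesium-block voltage dependence is applied.
#'
#' @param name one of `"AMPA"`, `"NMDA"`, `"GABAA"`, `"GABAB"`.
#' @param gmax maximal conductance (nS); overrides the preset default.
#' @param ... further overrides passed to [syn_params()] fields
#'   (`tau_rise`, `tau_decay`, `Esyn`, `t0`).
#' @return a [syn_params()] set.
#' @examples
#' receptor_preset("AMPA")$tau_decay   # 2 ms
#' receptor_preset("GABAB")$tau_decay  # 150 ms
#' @export
receptor_preset <- function(name, gmax = NULL, ...) {
  base <- switch(name,
    AMPA  = list(gmax = 0.5, tau_rise = 0.5, tau_decay = 2, Esyn = 0),
    NMDA  = list(gmax = 0.2, tau_rise = 2, tau_decay = 100, Esyn = 0),
    GABAA = list(gmax = 0.5, tau_rise = 0.5, tau_decay = 5, Esyn = -75),
    GABAB = list(gmax = 0.1, tau_rise = 30, tau_decay = 150, Esyn = -80),
    tcob_abort("tcob_parameter_error",
               sprintf("unknown receptor '%s'", name)))
  over <- list(...)
  if (!is.null(gmax)) base$gmax <- gmax
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  p <- do.call(syn_params, base)
  p$receptor <- name
  p
}

#' Conductance response to a presynaptic spike train
#'
#' Kernels sum linearly over the spike history: the conductance at time `t`
#' is the sum of one kernel per presynaptic spike.
#'
#' @param t time (ms); may be a vector.
#' @param p a [syn_params()] set.
#' @param spikes numeric vector of presynaptic spike times (ms); if `NULL`,
#'   the single spike at `p$t0` is used.
#' @param kernel which kernel to use.
#' @return conductance (nS), vectorized over `t`.
#' @export
g_train <- function(t, p, spikes = NULL,
                    kernel = c("double_exp", "alpha", "single_exp")) {
  kernel <- match.arg(kernel)
  kf <- switch(kernel, double_exp = g_double_exp, alpha = g_alpha,
               single_exp = g_single_exp)
  spikes <- spikes %||% p$t0
  if (!length(spikes)) return(rep(0, length(t)))
  out <- rep(0, length(t))
  for (s in spikes) {
    ps <- p; ps$t0 <- s
    out <- out + kf(t, ps)
  }
  out
}

#' Conductance time course as a table
#'
#' @param p a [syn_params()] set.
#' @param t_end,dt horizon and sampling step (ms).
#' @param spikes presynaptic spike times (ms).
#' @param kernel which kernel to use.
#' @return a `data.frame` with columns `time` and `g`, suitable for
#'   [write_trace()].
#' @export
conductance_trace <- function(p, t_end = 100, dt = 0.1, spikes = NULL,
                              kernel = c("double_exp", "alpha", "single_exp")) {
  tt <- seq(0, t_end, by = dt)
  data.frame(time = tt, g = g_train(tt, p, spikes, kernel))
}
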