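#' Stimulus specification
#'
#' A declarative description of an input: a step current, a single spike, a
#' spike burst (five spikes by default, the in-vivo-like mossy input; one
#' spike is the in-vitro-like mode), a sinusoid, or a spike file.
#'
#' @param kind one of `"step_current"`, `"single_spike"`, `"burst"`,
#'   `"sinusoid"`, `"spike_file"`.
#' @param amplitude current (pA) or voltage (V) amplitude.
#' @param onset,offset stimulus window (ms); `onset < offset`.
#' @param n_spikes spikes per burst (>= 1); forced to 1 for
#'   `"single_spike"`.
#' @param isi inter-spike interval within a burst (ms), positive.
#' @param freq angular frequency (rad/ms) for sinusoids.
#' @param seed optional RNG seed carried with the spec.
#' @param path spike file path for `"spike_file"`.
#' @return a list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("step_current", "single_spike", "burst",
                                   "sinusoid", "spike_file"),
                          amplitude = 10, onset = 0, offset = Inf,
                          n_spikes = 5, isi = 10, freq = 1, seed = NULL,
                          path = NULL) {
  kind <- match.arg(kind)
  if (onset >= offset)
    tcob_abort("tcob_parameter_error", "onset must be earlier than offset")
  if (kind == "single_spike") n_spikes <- 1L
  if (n_spikes < 1)
    tcob_abort("tcob_parameter_error", "n_spikes must be >= 1")
  if (isi <= 0)
    tcob_abort("tcob_parameter_error", "isi must be positive")
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 offset = offset, n_spikes = as.integer(n_spikes), isi = isi,
                 freq = freq, seed = seed, path = path),
            class = "stimulus_spec")
}

#' Step-current series on a grid
#'
#' `amplitude` on `[onset, offset)`, zero elsewhere, sampled at
#' `t = (k - 1) dt` for ticks `k = 1..n`.
#'
#' @param spec a [stimulus_spec()] (kind `"step_current"`).
#' @param dt,t_end grid step and horizon (ms).
#' @return numeric vector with one value per tick.
#' @export
gen_step_current <- function(spec, dt, t_end) {
  n <- as.integer(round(t_end / dt)) + 1L
  tt <- (seq_len(n) - 1L) * dt
  spec$amplitude * (tt >= spec$onset & tt < spec$offset)
}

#' Spike-burst times
#'
#' `n_spikes` spike times starting at `onset`, spaced `isi` ms apart
#' (defaults: five spikes, 10 ms apart - the in-vivo-like burst; a
#' `single_spike` spec yields the one in-vitro-like spike at onset).
#' Spikes beyond `t_end` are dropped with a warning.
#'
#' @param spec a [stimulus_spec()].
#' @param t_end horizon (ms), `Inf` for no truncation.
#' @return a [spike_train()].
#' @export
gen_burst <- function(spec, t_end = Inf) {
  times <- spec$onset + (seq_len(spec$n_spikes) - 1L) * spec$isi
  if (any(times > t_end)) {
    warning(sprintf("burst truncated: %d of %d spikes fall after %g ms",
                    sum(times > t_end), length(times), t_end))
    times <- times[times <= t_end]
  }
  spike_train(times, source = "stimulus")
}

#' Sinusoidal series on a grid
#'
#' @param spec a [stimulus_spec()] (kind `"sinusoid"`).
#' @inheritParams gen_step_current
#' @return numeric vector `amplitude * sin(freq * t)` per tick.
#' @export
gen_sinusoid <- function(spec, dt, t_end) {
  n <- as.integer(round(t_end / dt)) + 1L
  tt <- (seq_len(n) - 1L) * dt
  spec$amplitude * sin(spec$freq * tt)
}

#' Resolve a stimulus spec into mossy/current input
#'
#' @param spec a [stimulus_spec()].
#' @param dt,t_end grid (ms).
#' @return for spike kinds, a [spike_train()]; otherwise a per-tick numeric
#'   vector.
#' @export
gen_stimulus <- function(spec, dt, t_end) {
  switch(spec$kind,
    step_current = gen_step_current(spec, dt, t_end),
    sinusoid = gen_sinusoid(spec, dt, t_end),
    burst = ,
    single_spike = gen_burst(spec, t_end),
    spike_file = read_spikes(spec$path))
}
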