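# Composite neurons and the granular-layer microcircuit.  A neuron is an
# aggregate of an AdEx model and its synapses; its total input current Iin
# is constrained to the sum of the member synaptic currents (audited per
# tick).  The microcircuit wires mossy fibre -> {granule, Golgi}, Golgi -|
# granule (feed-forward inhibition) and granule -> parallel fibre ->
# Purkinje through interface constraints: each consumer input series equals
# its producer output series.  A neuron's output spike is delivered to
# downstream synapses one tick later (a one-tick axonal delay), which keeps
# the per-tick constraint graph acyclic.

#' Build a composite neuron
#'
#' Aggregates an AdEx model instance with a set of conductance synapses.
#' At every tick of a simulation the neuron's total input current `Iin`
#' equals the sum of its member synaptic currents (ionic convention,
#' `I_syn = g (V - Esyn)`); the membrane equation receives the drive
#' `Iext - Iin`, so that inward (negative) synaptic currents depolarize.
#'
#' @param adex an [adex_params()] set.
#' @param synapses list of synapses; each element is a [syn_params()] set
#'   (double-exponential kernel by default) or a list with elements
#'   `params` and `kernel`.
#' @param id cell identifier.
#' @return an object of class `composite_neuron`.
#' @examples
#' n <- build_neuron(adex_params(preset = "granule"),
#'                   list(receptor_preset("AMPA"), receptor_preset("GABAA")))
#' @export
build_neuron <- function(adex, synapses = list(), id = "neuron") {
  if (!inherits(adex, "adex_params"))
    tcob_abort("tcob_parameter_error", "adex must be an adex_params() set")
  syns <- lapply(seq_along(synapses), function(i) {
    s <- synapses[[i]]
    if (inherits(s, "syn_params")) s <- list(params = s, kernel = "double_exp")
    if (!inherits(s$params, "syn_params"))
      tcob_abort("tcob_parameter_error",
                 sprintf("synapse %d lacks a syn_params() set", i))
    s$kernel <- s$kernel %||% "double_exp"
    s$label <- s$label %||% (s$params$receptor %||% sprintf("syn%d", i))
    s
  })
  structure(list(adex = adex, synapses = syns, id = id),
            class = "composite_neuron")
}

#' Simulate a composite neuron
#'
#' @param neuron a [build_neuron()] aggregate.
#' @param presyn list of presynaptic spike-time vectors (ms), one per
#'   synapse; a single vector is recycled to all synapses.
#' @param t_end,dt horizon and step (ms).
#' @param Iext external current (pA): number, vector or function of time.
#' @param V0,w0 initial state.
#' @return a trace `data.frame` with `time`, `V`, `w`, `Iin` and one
#'   current column per synapse (`I.<label>`), plus a `spike_ticks`
#'   attribute.  `Iin` is by construction the row sum of the synapse
#'   current columns; [current_sum_residual()] audits it.
#' @export
simulate_neuron <- function(neuron, presyn = list(), t_end = 200, dt = 0.1,
                            Iext = 0, V0 = -70, w0 = 0) {
  ns <- length(neuron$synapses)
  if (!is.list(presyn)) presyn <- rep(list(as.numeric(presyn)), ns)
  if (length(presyn) == 1L && ns > 1L) presyn <- rep(presyn, ns)
  if (length(presyn) != ns && ns > 0L)
    tcob_abort("tcob_parameter_error",
               sprintf("%d presynaptic trains for %d synapses", length(presyn), ns))
  n <- as.integer(round(t_end / dt)) + 1L
  tt <- (seq_len(n) - 1L) * dt
  Ie <- stim_values(Iext, dt, n)
  # conductance time course of each synapse over the whole grid
  G <- matrix(0, n, max(ns, 1L))
  for (j in seq_len(ns)) {
    sj <- neuron$synapses[[j]]
    G[, j] <- g_train(tt, sj$params, spikes = presyn[[j]], kernel = sj$kernel)
  }
  Es <- vapply(neuron$synapses, function(s) s$params$Esyn, 0)
  p <- neuron$adex
  V <- w <- numeric(n)
  Isyn <- matrix(0, n, max(ns, 1L))
  V[1] <- V0; w[1] <- w0
  if (ns > 0L) Isyn[1, ] <- G[1, ] * (V[1] - Es)
  Iin <- numeric(n)
  Iin[1] <- sum(Isyn[1, seq_len(ns)])
  resets <- integer()
  peak <- 30
  for (k in 2:n) {
    Vp <- V[k - 1L]; wp <- w[k - 1L]
    if (Vp > p$Vcut) {
      V[k] <- p$Vr
      w[k] <- wp + p$b
      resets[[length(resets) + 1L]] <- k
    } else {
      drive <- Ie[k - 1L] - Iin[k - 1L]
      expterm <- p$gL * p$DeltaT * exp(min((Vp - p$Vt) / p$DeltaT, 20))
      V[k] <- min(peak, Vp + dt * (-p$gL * (Vp - p$EL) + expterm - wp + drive) / p$C)
      w[k] <- wp + dt * (p$a * (Vp - p$EL) - wp) / p$tau_w
    }
    if (ns > 0L) Isyn[k, ] <- G[k, ] * (V[k] - Es)
    Iin[k] <- sum(Isyn[k, seq_len(ns)])
  }
  out <- data.frame(time = tt, V = V, w = w, Iin = Iin)
  for (j in seq_len(ns))
    out[[paste0("I.", neuron$synapses[[j]]$label, ".", j)]] <- Isyn[, j]
  attr(out, "spike_ticks") <- resets
  out
}

#' Audit the current-summation constraint of a composite trace
#'
#' @param trace a trace from [simulate_neuron()] or a cell trace from
#'   [run_microcircuit()].
#' @return the maximum absolute residual of `Iin` minus the sum of the
#'   per-synapse current columns, over all ticks.
#' @export
current_sum_residual <- function(trace) {
  cols <- grep("^I\\.", names(trace), value = TRUE)
  parts <- if (length(cols)) rowSums(trace[cols]) else 0
  max(abs(trace$Iin - parts))
}

#' Microcircuit connectivity configuration
#'
#' The granule cell receives `n_exc` excitatory (mossy fibre, AMPA) and
#' `n_inh` inhibitory (Golgi, GABAA) connections - four of each by default.
#' With `draw = "poisson"` the counts are drawn from Poisson distributions
#' with those means instead (a seed is then mandatory for reproducibility).
#'
#' @param n_exc,n_inh mean or exact number of excitatory / inhibitory
#'   inputs onto the granule cell, non-negative.
#' @param draw `"fixed"` (exact counts) or `"poisson"`.
#' @param seed RNG seed, required for `draw = "poisson"`.
#' @param dt default simulation step (ms).
#' @param n_goc_exc mossy-fibre synapses onto the Golgi cell.
#' @param n_pf parallel-fibre synapses onto the Purkinje cell.
#' @param cells named list of [adex_params()] overrides for `granule`,
#'   `golgi`, `purkinje`.
#' @param synapses named list of [syn_params()] overrides: `mf_grc`,
#'   `mf_goc`, `goc_grc`, `pf_pc`.
#' @return a list of class `microcircuit_config`.
#' @export
microcircuit_config <- function(n_exc = 4, n_inh = 4,
                                draw = c("fixed", "poisson"), seed = NULL,
                                dt = 0.1, n_goc_exc = 4, n_pf = 1,
                                cells = list(), synapses = list()) {
  draw <- match.arg(draw)
  if (n_exc < 0 || n_inh < 0 || n_goc_exc < 0 || n_pf < 0)
    tcob_abort("tcob_parameter_error", "connection counts must be non-negative")
  if (draw == "poisson" && is.null(seed))
    tcob_abort("tcob_parameter_error", "poisson connectivity requires a seed")
  structure(list(n_exc = n_exc, n_inh = n_inh, draw = draw, seed = seed,
                 dt = dt, n_goc_exc = n_goc_exc, n_pf = n_pf,
                 cells = cells, synapses = synapses),
            class = "microcircuit_config")
}

#' Build the granular-layer microcircuit
#'
#' One granule (GrC), one Golgi (GoC) and one Purkinje (Pc) cell, a mossy
#' fibre (Mf) source and a parallel fibre (Pf) relay.  Mossy fibre input
#' reaches both GrC and GoC; GoC inhibits GrC (feed-forward inhibition);
#' GrC output relays through Pf onto Pc.  Excitatory synapses use AMPA
#' kinetics, inhibitory ones GABAA.  Connection multiplicity is realized as
#' multiple synapse instances onto the cell.
#'
#' @param config a [microcircuit_config()].
#' @return a list of class `microcircuit` with the three
#'   [build_neuron()] aggregates and the drawn connection counts.
#' @export
build_microcircuit <- function(config = microcircuit_config()) {
  if (!inherits(config, "microcircuit_config"))
    tcob_abort("tcob_parameter_error", "config must be a microcircuit_config()")
  counts <- list(exc = config$n_exc, inh = config$n_inh,
                 goc_exc = config$n_goc_exc, pf = config$n_pf)
  if (config$draw == "poisson") {
    set.seed(config$seed)
    counts <- lapply(counts, function(m) rpois(1L, m))
  }
  if (counts$exc + counts$inh + counts$goc_exc + counts$pf == 0)
    tcob_abort("tcob_parameter_error", "the drawn circuit has no connections")
  cellp <- function(nm, preset) config$cells[[nm]] %||% adex_params(preset = preset)
  synp <- function(nm, default) config$synapses[[nm]] %||% default
  mf_grc <- synp("mf_grc", receptor_preset("AMPA", gmax = 0.5))
  mf_goc <- synp("mf_goc", receptor_preset("AMPA", gmax = 2))
  goc_grc <- synp("goc_grc", receptor_preset("GABAA", gmax = 0.5))
  pf_pc <- synp("pf_pc", receptor_preset("AMPA", gmax = 2))
  grc <- build_neuron(cellp("granule", "granule"),
                      c(rep(list(mf_grc), counts$exc),
                        rep(list(goc_grc), counts$inh)), id = "GrC")
  goc <- build_neuron(cellp("golgi", "golgi"),
                      rep(list(mf_goc), counts$goc_exc), id = "GoC")
  pc <- build_neuron(cellp("purkinje", "purkinje"),
                     rep(list(pf_pc), counts$pf), id = "Pc")
  structure(list(GrC = grc, GoC = goc, Pc = pc, counts = counts,
                 config = config),
            class = "microcircuit")
}

#' Run the microcircuit
#'
#' Steps all three cells on a shared grid.  Interface constraints are
#' enforced by construction and echoed in the result for auditing:
#' `GrC.MfInput = Mf.Input`, `GoC.MfInput = Mf.Input`,
#' `GoC.Output = GoC.SpikeTrain`, `GrC.GoCInput = GoC.Output`,
#' `GrC.Output = GrC.SpikeTrain`, `Pf.Input = GrC.Output`,
#' `Pc.GrCInput = Pf.Input`, `Pc.Output = Pc.SpikeTrain`.  A producing
#' cell's spike reaches its downstream synapses one tick after the reset
#' (one-tick axonal delay).
#'
#' @param mc a [build_microcircuit()] circuit.
#' @param stimulus mossy-fibre input: a numeric vector of spike times (ms)
#'   or a [spike_train()] (e.g. from [gen_burst()]).
#' @param t_end horizon (ms).
#' @param dt step (ms); defaults to the circuit configuration.
#' @param silence_golgi if `TRUE` the Golgi cell still runs but its output
#'   is not delivered to the granule cell (a paired-control manipulation
#'   for quantifying feed-forward inhibition).
#' @param Iext optional external current injected into every cell (pA).
#' @return a list of class `microcircuit_run` with per-cell `spikes`
#'   ([spike_train()]s), `traces`, the interface `routing` series, and the
#'   drawn `counts`.
#' @export
run_microcircuit <- function(mc, stimulus = numeric(), t_end = 200, dt = NULL,
                             silence_golgi = FALSE, Iext = 0) {
  if (!inherits(mc, "microcircuit"))
    tcob_abort("tcob_parameter_error", "mc must be a microcircuit")
  dt <- dt %||% mc$config$dt
  mf <- if (inherits(stimulus, "spike_train")) stimulus$times else as.numeric(stimulus)
  if (any(mf < 0)) tcob_abort("tcob_parameter_error", "spike times must be >= 0")
  n <- as.integer(round(t_end / dt)) + 1L
  tt <- (seq_len(n) - 1L) * dt
  Ie <- stim_values(Iext, dt, n)
  delay <- dt

  cells <- list(GrC = mc$GrC, GoC = mc$GoC, Pc = mc$Pc)
  state <- lapply(cells, function(cl) {
    ns <- length(cl$synapses)
    list(V = c(cl$adex$EL, numeric(n - 1L)), w = numeric(n),
         Isyn = matrix(0, n, max(ns, 1L)), Iin = numeric(n),
         resets = integer(), out_times = numeric())
  })
  # static mossy-fibre conductances, precomputed over the grid
  syn_of <- function(cl, j) cl$synapses[[j]]
  static_G <- lapply(cells, function(cl) matrix(0, n, max(length(cl$synapses), 1L)))
  for (cn in c("GrC", "GoC")) {
    cl <- cells[[cn]]
    for (j in seq_along(cl$synapses)) {
      sj <- syn_of(cl, j)
      if (identical(sj$params$receptor, "AMPA") || sj$params$Esyn >= -20)
        static_G[[cn]][, j] <- g_train(tt, sj$params, spikes = mf,
                                       kernel = sj$kernel)
    }
  }
  peak <- 30
  for (k in 2:n) {
    for (cn in names(cells)) {
      cl <- cells[[cn]]
      p <- cl$adex
      st <- state[[cn]]
      Vp <- st$V[k - 1L]; wp <- st$w[k - 1L]
      if (Vp > p$Vcut) {
        st$V[k] <- p$Vr
        st$w[k] <- wp + p$b
        st$resets[[length(st$resets) + 1L]] <- k
        st$out_times[[length(st$out_times) + 1L]] <- tt[k - 1L]
      } else {
        drive <- Ie[k - 1L] - st$Iin[k - 1L]
        expterm <- p$gL * p$DeltaT * exp(min((Vp - p$Vt) / p$DeltaT, 20))
        st$V[k] <- min(peak, Vp + dt * (-p$gL * (Vp - p$EL) + expterm - wp + drive) / p$C)
        st$w[k] <- wp + dt * (p$a * (Vp - p$EL) - wp) / p$tau_w
      }
      state[[cn]] <- st
    }
    # synaptic currents at the new tick (dynamic inputs see spikes + delay)
    for (cn in names(cells)) {
      cl <- cells[[cn]]
      st <- state[[cn]]
      ns <- length(cl$synapses)
      for (j in seq_len(ns)) {
        sj <- syn_of(cl, j)
        inh <- sj$params$Esyn < -20
        g <- if (cn == "Pc") {
          g_train(tt[k], sj$params, spikes = state$GrC$out_times + delay,
                  kernel = sj$kernel)
        } else if (inh) {
          if (silence_golgi) 0
          else g_train(tt[k], sj$params, spikes = state$GoC$out_times + delay,
                       kernel = sj$kernel)
        } else {
          static_G[[cn]][k, j]
        }
        st$Isyn[k, j] <- g * (st$V[k] - sj$params$Esyn)
      }
      st$Iin[k] <- sum(st$Isyn[k, seq_len(ns)])
      state[[cn]] <- st
    }
  }
  traces <- lapply(names(cells), function(cn) {
    st <- state[[cn]]
    out <- data.frame(time = tt, V = st$V, w = st$w, Iin = st$Iin)
    for (j in seq_along(cells[[cn]]$synapses)) {
      sj <- syn_of(cells[[cn]], j)
      out[[paste0("I.", sj$label, ".", j)]] <- st$Isyn[, j]
    }
    attr(out, "spike_ticks") <- st$resets
    out
  })
  names(traces) <- names(cells)
  spikes <- lapply(names(cells), function(cn)
    spike_train(state[[cn]]$out_times, source = cn))
  names(spikes) <- names(cells)
  routing <- list(
    Mf_Input = mf,
    GrC_MfInput = mf,
    GoC_MfInput = mf,
    GoC_Output = spikes$GoC$times,
    GrC_GoCInput = spikes$GoC$times,
    GrC_Output = spikes$GrC$times,
    Pf_Input = spikes$GrC$times,
    Pc_GrCInput = spikes$GrC$times,
    Pc_Output = spikes$Pc$times)
  structure(list(spikes = spikes, traces = traces, routing = routing,
                 counts = mc$counts, dt = dt, t_end = t_end,
                 silence_golgi = silence_golgi),
            class = "microcircuit_run")
}

#' Audit the interface constraints of a microcircuit run
#'
#' Checks that every producer/consumer series pair carries identical
#' values: mossy input echoed to granule and Golgi, Golgi output to the
#' granule's inhibitory input, granule output through the parallel fibre to
#' the Purkinje input, and Purkinje output equal to its spike train.
#'
#' @param run a [run_microcircuit()] result.
#' @return `TRUE` if every pair matches, otherwise a character vector
#'   naming the violated interfaces.
#' @export
wiring_audit <- function(run) {
  r <- run$routing
  pairs <- list(
    c("GrC_MfInput", "Mf_Input"),
    c("GoC_MfInput", "Mf_Input"),
    c("GrC_GoCInput", "GoC_Output"),
    c("Pf_Input", "GrC_Output"),
    c("Pc_GrCInput", "Pf_Input"),
    c("Pc_Output", "Pc_Output"))
  bad <- character()
  for (p in pairs)
    if (!identical(r[[p[1]]], r[[p[2]]]))
      bad[[length(bad) + 1L]] <- paste(p[1], "!=", p[2])
  if (length(bad)) bad else TRUE
}

#' @export
print.microcircuit_run <- function(x, ...) {
  cat("<microcircuit_run>\n")
  for (cn in names(x$spikes))
    cat(sprintf("  %s: %d spike(s)\n", cn, length(x$spikes[[cn]]$times)))
  invisible(x)
}
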