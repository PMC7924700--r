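# AC-circuit component library: the engine's canonical validation example.
# A resistor carries Ohm's law V = I*R; a capacitor carries Ampere's law
# I = Cap * dV/dt with the derivative discretized backward,
# (V(k) - V(k-1)) / dt; a source imposes V = amp * sin(freq * Time * dt).
# series_comp and parallel_comp compose components through quantified
# Kirchhoff constraints.

circuit_classes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    component <- define_class("component",
      attributes = c(V = "series", I = "series"),
      env = baseenv())
    resistor <- define_class("resistor", parent = component,
      attributes = c(R = "scalar"),
      constraints = list(con(V == I * R)),
      env = baseenv())
    capacitor <- define_class("capacitor", parent = component,
      attributes = c(Cap = "scalar"),
      constraints = list(con_if(Time > 1, I == Cap * (V - prev(V)) / dt)),
      env = baseenv())
    source <- define_class("source", parent = component,
      attributes = c(amp = "scalar", freq = "scalar"),
      constraints = list(con(V == amp * sin(freq * Time * dt))),
      env = baseenv())
    dc_source <- define_class("dc_source", parent = component,
      attributes = c(amp = "scalar"),
      constraints = list(con(V == amp)),
      env = baseenv())
    series_comp <- define_class("series_comp", parent = component,
      attributes = c(comps = "components"),
      constraints = list(con_forall("comps", it.I == I),
                         con_sum("comps", it.V, V)),
      env = baseenv())
    parallel_comp <- define_class("parallel_comp", parent = component,
      attributes = c(comps = "components"),
      constraints = list(con_forall("comps", it.V == V),
                         con_sum("comps", it.I, I)),
      env = baseenv())
    # a closed loop: the composite's terminals are shorted, so the branch
    # currents must sum to zero (Kirchhoff's current law at the junction)
    closed_circuit <- define_class("closed_circuit", parent = component,
      attributes = c(comps = "components"),
      constraints = list(con_forall("comps", it.V == V),
                         con_sum("comps", it.I, I),
                         con(I == 0)),
      env = baseenv())
    cache <<- list(component = component, resistor = resistor,
                   capacitor = capacitor, source = source,
                   dc_source = dc_source, series_comp = series_comp,
                   parallel_comp = parallel_comp,
                   closed_circuit = closed_circuit)
    cache
  }
})

#' Circuit components as constrained objects
#'
#' Constructors for the AC-circuit component library: resistor (`V = I R`),
#' capacitor (`I = Cap dV/dt`, backward difference), sinusoidal voltage
#' source (`V = amp sin(freq * Time * dt)`), DC source, and series/parallel
#' composition via quantified Kirchhoff constraints (in a parallel group all
#' component voltages equal the group voltage and the component currents sum
#' to the group current; dually for a series group).
#'
#' @param store a [cob_store()].
#' @param R resistance (ohm), positive.
#' @param Cap capacitance, positive.
#' @param V0 initial capacitor voltage at tick 1 (volt).
#' @param amplitude source amplitude (volt).
#' @param freq angular frequency (rad/ms).
#' @param components list of already-instantiated components (at least one).
#' @param closed for [parallel_comp()]: if `TRUE` the group is a closed
#'   loop and its total current is constrained to zero.
#' @return a `tcob_instance`.
#' @examples
#' st <- cob_store(time_grid(5, dt = 0.1))
#' r <- make_resistor(st, R = 5)
#' bind_series(st, r, "I", 1:5, 2)
#' run_cob(st)  # V solves to 10 at every tick
#' @export
make_resistor <- function(store, R) {
  if (!is.numeric(R) || R <= 0)
    tcob_abort("tcob_parameter_error", "R must be positive")
  instantiate(circuit_classes()$resistor, store, args = list(R = R))
}

#' @rdname make_resistor
#' @export
make_capacitor <- function(store, Cap, V0 = 0) {
  if (!is.numeric(Cap) || Cap <= 0)
    tcob_abort("tcob_parameter_error", "Cap must be positive")
  instantiate(circuit_classes()$capacitor, store, args = list(Cap = Cap),
              init = list(V = c("1" = V0)))
}

#' @rdname make_resistor
#' @export
make_source <- function(store, amplitude, freq) {
  instantiate(circuit_classes()$source, store,
              args = list(amp = amplitude, freq = freq))
}

#' @rdname make_resistor
#' @export
make_dc_source <- function(store, amplitude) {
  instantiate(circuit_classes()$dc_source, store, args = list(amp = amplitude))
}

#' @rdname make_resistor
#' @export
series_comp <- function(store, components) {
  if (!length(components))
    tcob_abort("tcob_parameter_error", "a series group needs at least one component")
  instantiate(circuit_classes()$series_comp, store, args = list(comps = components))
}

#' @rdname make_resistor
#' @export
parallel_comp <- function(store, components, closed = FALSE) {
  if (!length(components))
    tcob_abort("tcob_parameter_error", "a parallel group needs at least one component")
  cls <- if (closed) circuit_classes()$closed_circuit else circuit_classes()$parallel_comp
  instantiate(cls, store, args = list(comps = components))
}

#' Build the sample AC circuit
#'
#' A closed loop holding a sinusoidal source in parallel with a resistor and
#' with a resistor-capacitor series branch.  Parameters default to unit
#' values; they are configuration, not measurements.
#'
#' @param store a [cob_store()].
#' @param R1 series-branch resistance (ohm).
#' @param Cap series-branch capacitance.
#' @param R2 parallel resistor (ohm).
#' @param amplitude,freq source amplitude (volt) and angular frequency (rad/ms).
#' @return list of the instances (`source`, `r1`, `cap`, `rc`, `r2`, `loop`).
#' @export
sample_circuit <- function(store, R1 = 1, Cap = 1, R2 = 1,
                           amplitude = 1, freq = 1) {
  src <- make_source(store, amplitude, freq)
  r1 <- make_resistor(store, R1)
  cap <- make_capacitor(store, Cap)
  rc <- series_comp(store, list(r1, cap))
  r2 <- make_resistor(store, R2)
  loop <- parallel_comp(store, list(src, rc, r2), closed = TRUE)
  list(source = src, r1 = r1, cap = cap, rc = rc, r2 = r2, loop = loop)
}

#' Build a circuit from a nested configuration
#'
#' The topology is a nested list: leaves are
#' `list(type = "resistor", R = ...)`, `list(type = "capacitor", Cap = ...,
#' V0 = ...)`, `list(type = "source", amplitude = ..., freq = ...)` or
#' `list(type = "dc_source", amplitude = ...)`; interior nodes are
#' `list(type = "series"/"parallel", children = list(...))`.  The top-level
#' group is built as a closed loop when it is a parallel group.
#'
#' @param store a [cob_store()].
#' @param topology nested list as above (e.g. parsed from JSON or YAML with
#'   [read_config()]).
#' @return the top-level `tcob_instance`.
#' @export
circuit_from_config <- function(store, topology) {
  build <- function(node, top = FALSE) {
    type <- node$type %||% tcob_abort("tcob_parameter_error", "topology node lacks a type")
    switch(type,
      resistor = make_resistor(store, node$R),
      capacitor = make_capacitor(store, node$Cap, node$V0 %||% 0),
      source = make_source(store, node$amplitude, node$freq),
      dc_source = make_dc_source(store, node$amplitude),
      series = series_comp(store, lapply(node$children, build)),
      parallel = parallel_comp(store, lapply(node$children, build),
                               closed = isTRUE(top)),
      tcob_abort("tcob_parameter_error",
                 sprintf("unknown circuit component type '%s'", type)))
  }
  build(topology, top = TRUE)
}
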