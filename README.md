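# tcob — temporal constrained objects for neuronal and circuit dynamics

`tcob` is a time-stepped **declarative** simulation framework for
computational neuroscientists and anyone modelling dynamical systems as
difference equations.  Instead of writing an update loop, you declare
*constrained-object classes*: attributes (some of them **series
variables**, time-indexed sequences with `prev(v)` / `nxt(v)` reference
semantics) plus the constraints that relate them — simple equations,
conditional `guard -> consequent` rules, and `forall`/`sum` quantifiers
over component arrays.  A per-tick solver maintains every constraint by
local propagation, linear solving and damped iteration, with residuals
bounded by `1e-9` and solved values immutable.

On top of the engine the package ships:

* an **AC-circuit library** (Ohm's law `V = IR`, the capacitor law
  `I = C dV/dt` as a backward difference, Kirchhoff composition) — the
  engine's canonical validation example;
* three neuron models, each as a fast stepper *and* as a constrained-object
  class: **Hodgkin–Huxley** (`C_m dV/dt = I - g_Na m^3 h (V-E_Na) -
  g_K n^4 (V-E_K) - g_L (V-E_L)` with the classic empirical gate rates),
  **Izhikevich** (`dV/dt = 0.04V^2 + 5V + 140 - u + I`, reset
  `V <- c, u <- u + d`), and **AdEx** (exponential spike initiation with an
  adaptation current, reset `V <- V_r, w <- w + b`);
* **conductance synapses** `I_syn = g(t)(V - E_syn)` with
  single-exponential, alpha and normalized double-exponential kernels and
  AMPA / NMDA / GABAA / GABAB presets;
* a **cerebellar granular-layer microcircuit** (mossy fibre → granule &
  Golgi; Golgi ⊣ granule feed-forward inhibition; granule → parallel fibre
  → Purkinje) wired through audited interface constraints;
* stimulus generators (steps, bursts, sinusoids), CSV/spike-file I/O,
  JSON/YAML configs, and a `tcob_cli()` command-line front end.

## A worked example

Declarative first — Ohm's law is non-directional, and the on–off controller
shows conditional constraints posting next-tick values:

```r
library(tcob)

solve_system(list(quote(V == I * R)), knowns = list(V = 10, R = 5))
#> $I
#> [1] 2

st <- cob_store(time_grid(5, dt = 1))
instantiate(controller_class(), st, init = list(C = c("1" = "on")))
run_cob(st)[[2]]
#> [1] "on"  "off" "on"  "off" "on"
```

A Hodgkin–Huxley neuron under a 10-unit step current, from rest at −70 mV:

```r
tr <- simulate_hh(stimulus = 10, t_end = 100, dt = 0.01)
max(tr$V)                      # action-potential peak (mV)
#> [1] 35.54341
sp <- detect_spikes(tr)        # upward crossings of -20 mV
length(sp$times)               # 7 spikes in 100 ms -> 70 Hz
#> [1] 7
head(sp$times, 3)
#> [1]  1.86 16.77 31.41
```

The peak sits around +40 mV and the cell fires repetitively — increase the
current and the rate increases.  The same model runs on the constraint
engine (`hh_cob()`), and the two traces agree to machine precision.

The microcircuit under an in-vivo-like burst (5 mossy spikes, 10 ms apart):

```r
mc  <- build_microcircuit()    # 4 excitatory + 4 inhibitory granule inputs
run <- run_microcircuit(mc, gen_burst(stimulus_spec("burst", onset = 20), 200),
                        t_end = 200)
run
#> <microcircuit_run>
#>   GrC: 15 spike(s)
#>   GoC: 4 spike(s)
#>   Pc: 1 spike(s)
wiring_audit(run)              # interface constraints carry identical series
#> [1] TRUE
```

Silence the Golgi cell (`silence_golgi = TRUE`) and the granule spike count
rises — feed-forward inhibition at work.

From a shell:

```sh
Rscript inst/cli/tcob.R simulate --model hh --i 6 --tstop 500 --out hh.csv
Rscript inst/cli/tcob.R sweep --model hh --i-range 1:10:1
Rscript inst/cli/tcob.R validate
```

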