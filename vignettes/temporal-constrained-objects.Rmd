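---
title: "Temporal constrained objects: the model, the solver, and the neuronal dynamics built on them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal constrained objects: the model, the solver, and the neuronal dynamics built on them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcob)
```

## The paradigm

A *constrained object* is an object whose attribute values are determined by
declarative relations rather than imperative assignment: a class bundles
typed attributes with constraints, and a solver — not the modeller's control
flow — keeps every constraint satisfied.  A *temporal* constrained object
extends this with **series variables**: attributes that take an unbounded
sequence of values over a discrete tick counter `Time` (starting at 1,
incremented by one per step; model time in milliseconds is `Time * dt`).
Within a constraint, `prev(v)` refers to the previous value of series `v`
and `nxt(v)` to its next value, so ordinary differential equations enter the
framework as difference equations: a relation between a value, its
predecessor, and `dt`.

Constraints come in four forms: simple equations; conditional constraints
(`guard -> consequent`), which enforce the consequent — possibly on the next
tick's value — wherever the guard holds; and the two quantified forms,
`forall` and `sum`, which expand over an array of aggregated components at
instantiation time (static expansion; creating objects mid-run is out of
scope).  The canonical quantified example is Kirchhoff's laws: in a parallel
group every component voltage equals the group voltage and the component
currents sum to the group current.

## The per-step solver

`step_store()` instantiates every constraint at tick `k`, substituting
already-solved past values, and solves what remains:

1. **Local propagation.**  Equations with a single unknown are solved first,
   repeatedly, to a fixpoint.  A one-unknown equation is solved by direct
   assignment when one side is the bare unknown (this also carries
   non-numeric series such as the on/off controller state); otherwise by
   numeric linear extraction (two residual evaluations determine slope and
   intercept; a third checks linearity), falling back to a damped
   one-dimensional iteration for nonlinear cases.
2. **Guard re-evaluation.**  Conditional guards are evaluated on determined
   values only.  If a guard's operand is still unknown, propagation
   continues first and the guard is retried — a two-phase step.  `&&` and
   `||` short-circuit structurally, so `Time > 1 && prev(V) > 0` is safe at
   the first tick even though `prev(V)` does not exist there.  A guard that
   remains undetermined at the end of the step is an error: the store fails
   loudly rather than guessing.
3. **Simultaneous subsystems.**  Remaining equations are grouped into
   connected components.  A subsystem that probes as linear (constant
   finite-difference Jacobian) is solved as a linear system by QR; rank
   deficiency raises an underdetermined error and residual failure an
   inconsistency — never a silently chosen solution.  Nonlinear subsystems
   use damped Newton-type iteration with damping factor 0.5, at most 100
   iterations, tolerance `1e-9`.

Numerical choices: the store tolerance defaults to `1e-9`; every
instantiated constraint must have `|lhs - rhs|` at or below it after the
step (`store_residuals()` re-derives this from the stored values, the
machine-checkable audit).  Solved values are immutable — re-binding a solved
tick is an inconsistency error, which is what makes the after-spike "reset"
below a declarative statement about a *new* point in time rather than a
mutation.  Constraints at tick `k` may bind values at `k` and `k + 1` only;
deeper future references are rejected, because none of the models here need
them and a bounded look-ahead keeps the step semantics simple.  Declaring
constraints in a different order changes nothing observable: propagation
solves each equation exactly, and the linear path is order-insensitive to
rounding (the test suite asserts agreement within `1e-12`).

## The circuit library

The AC-circuit components are the engine's validation example because every
law is a one-line constraint: `V == I * R` for the resistor,
`I == Cap * (V - prev(V)) / dt` for the capacitor (the derivative
discretized as a backward difference — the change in voltage over one unit
of time), `V == amp * sin(freq * Time * dt)` for the source (sine phase
convention, zero initial capacitor voltage unless configured).  Composition
is by quantified constraints, and a `closed` parallel group adds `I == 0`:
the branch currents of a closed loop must cancel, which is what determines
the source current.  Because the capacitor constraint couples the unknowns
at each tick, a driven RC loop exercises the simultaneous linear path every
step.  The discretization is first order: the step-response error against
the analytic exponential halves when `dt` halves, and the steady-state
current amplitude of a series RC loop matches `A / sqrt(R^2 + 1/(w Cap)^2)`
within 2% at small `dt` (both are tests).

## Neuron models

Three models cover the two formulations: continuous voltage dynamics
(Hodgkin–Huxley) and piecewise dynamics with voltage reset (Izhikevich,
AdEx).  Each exists twice — as a fast direct stepper
(`simulate_hh()` and friends) and as a constrained-object class on the
engine (`hh_cob()`, `izh_cob()`, `adex_cob()`).  Both routes step the same
difference equations and the suite asserts their traces coincide to
`1e-12`; the direct route exists purely because a generic constraint store
is the wrong tool for a 50 000-tick production run, while the engine route
is the point of the package.

**Hodgkin–Huxley.**  Forward-Euler update of
`Cm dV/dt = IExt - gNaMax m^3 h (V - ENa) - gKMax n^4 (V - EK) - gL (V - EL)`
with the three gate equations `dx/dt = alpha(1-x) - beta x`, gates clipped
to [0, 1].  The rate functions are the classic empirical forms with
removable singularities handled analytically (`x / (e^x - 1) -> 1`).  The
integrated voltage is absolute with rest at −70 mV while the rates are
evaluated at `V - Vrest` — the classic convention with rest at 0.  The
parameter values are the classic squid-axon set (`Cm = 1`, `gNaMax = 120`,
`gKMax = 36`, `gL = 0.3` with reversal potentials at their classic offsets
from rest); units are taken at face value (current units, mV, ms) without
dimensional reconciliation.  Default `dt` is 0.01 ms.

A point worth being explicit about: under a step-current protocol this
parameter set fires a *single* spike from roughly 3 current units, but
sustained repetitive firing (a stable limit cycle) only appears just above
6 — at exactly 6.0 the model fires twice and settles into a damped
subthreshold oscillation, which the independent RK4 reference reproduces,
so it is a property of the dynamics and not of the Euler step.  An integer
amplitude scan with a "3 or more spikes in 500 ms" criterion therefore
reports 7 as the smallest repetitively firing amplitude.  The scan, the
criterion and the parameter set are all fixed by design; the measured onset
is reported as measured.

**Izhikevich.**  `dV/dt = 0.04 V^2 + 5V + 140 - u + I`,
`du/dt = a (bV - u)`, with the after-spike reset `V <- c`, `u <- u + d`
applied when the *previous* voltage reached the 30 mV cutoff — on the
engine this is a pair of conditional constraints gated on `prev(V)`, the
discontinuity entering as a declaratively specified new value.  The reset
is triggered by the membrane voltage (the recovery variable has no
plausible 30 mV threshold and the reset would otherwise never fire from
rest).  The traced voltage is clamped at the cutoff on the spike tick, so
plots show a finite stereotyped upswing.  Presets: `regular_spiking`
(c = −65, d = 8; periodic firing, interspike CV well under 0.05) and
`chattering` (c = −50, d = 2; grouped spikes with a clearly bimodal
interval histogram).  Default `dt` 0.1 ms.

**AdEx.**  `C dV/dt = -gL (V - EL) + gL DeltaT exp((V - Vt)/DeltaT) - w + Iin`,
`tau_w dw/dt = a (V - EL) - w`, reset `V <- Vr`, `w <- w + b` when the
previous voltage exceeded 0 mV.  The signs follow the standard formulation
with a positive `Iin` depolarizing.  The exponential argument is capped at
20 — the cap only ever binds on the tick before a reset, so it bounds the
recorded upswing without affecting subthreshold dynamics (the term is below
`e^-10` whenever `V <= Vt - 10 DeltaT`).  Presets `tonic` and `adapting`
are the standard textbook firing-pattern sets (200 pF, 10–12 nS); with
`b > 0` successive interspike intervals are non-decreasing under constant
current, the adaptation signature.  The cerebellar presets (`granule`,
small and high-impedance at 3.1 pF / 0.43 nS; `golgi`; `purkinje`) are
plausible desk-scale configurations with rest pinned at −70 mV, not fits
to recordings — the source literature for such cells reports parameters we
do not reproduce here, so these presets are configuration, never
reproduction targets.

Spike extraction: for the reset models a spike *is* a reset event; for
continuous traces it is an upward crossing of −20 mV, one spike per
crossing.  `integrate_reference()` supplies an independent classic RK4
integration of the same right-hand sides (resets applied between steps)
used only as an accuracy oracle: the Euler-vs-RK4 sup-norm voltage
discrepancy shrinks monotonically as `dt` is halved (0.04, 0.02, 0.01 ms).

## Synapses

Conductance-based: `I_syn = g(t) (V - Esyn)` in the ionic convention
(inward currents negative).  Three kernels, all causal (identically zero
before the spike) and all normalized so their peak equals `gmax`: single
exponential (peak at onset), alpha (`(s/tau) e^{1 - s/tau}`, peak at
`t0 + tau` — the printed form of the exponent only makes the peak equal
`gmax` there under this standard reading, which the tests enforce), and the
double exponential with
`t_peak = t0 + (tau_d tau_r / (tau_d - tau_r)) ln(tau_d / tau_r)` and a
normalization constant defined as the *difference* of the two exponentials
at the peak — the sign that makes `g(t_peak) = gmax` an identity (asserted
to `1e-9`).  As `tau_rise -> tau_decay` the double exponential converges to
the alpha shape (relative L2 distance under 1% at ratio 1.001).  Kernels
sum linearly over the presynaptic spike history.  Receptor presets order
the kinetics AMPA (0.5/2 ms) < GABAA (0.5/5) < NMDA (2/100) <= GABAB
(30/150), excitatory reversal at 0 mV, inhibitory below rest; no NMDA
magnesium block is modelled (none is defined for these models; the hook is
simply absent rather than half-specified).

## The microcircuit

One granule, one Golgi and one Purkinje cell — connection multiplicity is
realized as multiple synapse instances onto a cell rather than cell arrays,
matching the single-cell-per-population wiring diagram the circuit
represents.  The granule cell receives exactly 4 excitatory (mossy fibre,
AMPA) and 4 inhibitory (Golgi, GABAA) synapses by default; "about four" can
instead be drawn Poisson(4) with a mandatory seed.  Golgi inhibition uses
GABAA by default (the fast inhibitory receptor; configurable), and one
granule cell feeds the Purkinje cell through the parallel-fibre relay —
both choices are open in the circuit's description and are configuration
here.  The interface constraints are identities between producer and
consumer series (`GrC.MfInput = Mf.Input`, `GrC.GoCInput = GoC.Output`,
`Pf.Input = GrC.Output`, `Pc.GrCInput = Pf.Input`,
`Pc.Output = Pc.SpikeTrain`), echoed in the run result and audited by
`wiring_audit()`.  A spiking cell's output reaches its downstream synapses
one tick after the reset — a one-tick axonal delay, chosen because a
zero-delay loop would create within-tick cyclic constraints between cells;
the composite current-summation constraint (`Iin` equals the sum of the
member synaptic currents) is audited to `1e-9` at every tick.  Note the
sign bookkeeping: `Iin` is recorded in the ionic convention, and the
membrane equation receives `Iext - Iin`, so an inward synaptic current
depolarizes — with `+ Iin` as the drive an excitatory synapse would
hyperpolarize, contradicting both the physiology and the circuit's
feed-forward logic.

## Stimuli, files, interfaces

Inputs are generated, not loaded: step currents (`amplitude` on
`[onset, offset)`), sinusoids, and spike bursts — five spikes by default,
the in-vivo-like mossy pattern; a single spike is the in-vitro-like mode.
Burst spacing defaults to 10 ms (only the count is prescribed by the
protocol; the spacing is a configuration default).  Traces serialize to
CSV with time printed to six decimals; spike trains to plain text, one
millisecond value per line (no neuro-specific container format is imposed);
configurations are JSON or YAML; every CLI run writes a manifest echoing
the resolved parameters and seed, and identical configuration plus seed
yields byte-identical outputs.

## What the synthetic inputs do and do not show

The generators emulate idealized protocols: noiseless current steps with
instantaneous edges, perfectly regular bursts, exact connection counts.
Real recordings have synaptic jitter, trial-to-trial variability,
heterogeneous synaptic weights and many cells per population.  Passing
tests therefore demonstrate that the declarative formulation and solver
reproduce the *deterministic* dynamics of these models under clean
protocols — firing-pattern classes, kernel identities, circuit-level
inhibition — not that the presets quantitatively match any recorded cell.

## Problem sizes

The suite runs desk-scale: engine traces of a few hundred ticks
(equivalence checks between the engine and direct routes), circuit loops of
up to ~950 ticks at `dt = 0.02` ms for the impedance check, single-neuron
runs of 200–1000 ms, the current scan at `dt = 0.01` ms over 500 ms per
amplitude, and 120–200 ms microcircuit runs.  These sizes were chosen so
the full suite completes in well under a minute while every property is
exercised at the `dt` values the convergence statements refer to.

## Known limitations

No general CLP solver, no backtracking, no constraint entailment beyond the
forms above; underdetermined stores fail rather than enumerate solutions.
No multi-compartment morphology, channel Markov schemes, temperature
scaling, plasticity, or population-scale networks.  Non-series-parallel
circuit topologies are not expressible in the composition classes.  The
engine favours transparency over speed; long simulations belong on the
direct steppers, whose equivalence with the engine is what the tests
establish.
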