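---
title: "Methods: dynamically partitionable autoassociative networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamically partitionable autoassociative networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpaan)
```

This vignette documents the model the package implements, the main
design decisions, and the limitations of the approach. It is a methods
note, not a tutorial; see the README for a worked example.

## The model

A **dynamically partitionable autoassociative network** is a Hopfield
attractor network of `N` threshold neurons divided into `K` partitions
("slots") of sizes `N_1, …, N_K`, together with a `K × K` binary gate
matrix that can mask whole between-partition synapse blocks at run time.
The stored weights never change after training; all run-time flexibility
comes from gating.

**Activations.** Units take values in `{-1, +1}`, plus `0` for a blank
(undriven) unit. A blank unit contributes nothing to any net input or
energy term, and a unit with exactly zero net input keeps its previous
value — so a fully blank slot stays blank under closed gates. The
three-valued alphabet is a modelling convenience: it lets "slot is
empty" be a genuine network state rather than a bookkeeping flag, which
both the transfer operation (blank the target first) and the
declarative-memory cycle (blank the retrieval slot before cueing)
depend on.

**Vocabulary.** A vocabulary of `L` symbols is a set of random global
patterns over all `N` units, each entry `+1` with probability equal to
the coding level (default 0.5, i.e. dense unbiased patterns) and `-1`
otherwise. The restriction of pattern `l` to slot `k` is the *piece*
slot `k` holds when representing symbol `l`. Crucially the same symbol
has a *different* piece in every slot: slots are bound registers, and
equality is detected energetically, not by pattern identity.

**Learning.** One-shot outer-product (Hebbian) training:
`W = (1/N) Σ_l ξ^l (ξ^l)ᵀ` with a zeroed diagonal. `W` is symmetric, so
the asynchronous dynamics admit the Hopfield energy
`E = -(1/2) Σ_{i≠j} w_ij x_i x_j` as a Lyapunov function (the test
suite verifies monotone descent on random trajectories).

**Dynamics.** `x_i ← sign(Σ_j g_ij w_ij x_j)` where `g` masks gated-off
blocks; synchronous sweeps are the default (fast, and adequate because
the states of interest start at or near stored attractors), asynchronous
single-unit updates are available where the Lyapunov property matters.
Slots can be *clamped* (frozen) for the duration of a settle.

## Equality detection

The cross energy between slots `k` and `k'`,
`E_kk' = -2 x_kᵀ W[k,k'] x_{k'}`, is strongly negative when the two
slots hold pieces of the *same* stored pattern and near zero otherwise,
because the between-block weights encode exactly the piece-to-piece
correlations of the training set. One binary neuron per unordered slot
pair (`K(K-1)/2` in total) thresholds this quantity.

Thresholds are calibrated per pair by sweeping the whole vocabulary:
compute the matched population (both slots hold the same symbol, `L`
values) and the mismatched population (`L(L-1)` values) and place the
threshold at the midpoint of the **gap** — `(max matched +
min mismatched)/2`. An earlier draft used the midpoint of the population
*means*; that fails on skewed energy distributions (a mismatched value
can sit below the midpoint of means even with a comfortable separating
margin), whereas the gap midpoint is exact on every vocabulary state
whenever the populations separate at all. Calibration raises an error
if they overlap. Blank slots have zero cross energy and therefore never
compare equal to anything.

## Transfer

To copy the symbol in slot `k` into slot `k'`: blank the target, clamp
the source, open the `k → k'` gate and the target's recurrent gates,
and settle (default budget 40 sweeps). The opened block projects the
source piece's correlations into the target, and attractor completion
snaps the target onto its own piece of the same symbol. The gate matrix
passed in is not modified; transfer works on a copy.

## Vocabulary screening

At the loads the packaged models use (11 symbols on 100-neuron slots,
load `α ≈ 0.11`), a plain Hopfield network retains stored patterns with
a small per-unit flip probability (~10⁻³). That is usually harmless
globally, but the architecture's premise is stronger: *every* slot, cut
off from the rest, must retain *every* symbol piece as a fixed point,
since isolated-slot stability is what holds registers constant while
other slots settle. An unconditioned random vocabulary occasionally
violates this through crosstalk (observed in practice: a single symbol
detector dropping below threshold because its piece drifted under
isolated settling).

`build_vocabulary()` therefore screens draws: patterns are accepted
sequentially, and a draw is rejected if adding it would leave any piece
unstable on its isolated partition (or any full pattern unstable
globally). If an accepted prefix proves unextendable within the retry
budget, the whole prefix is discarded and generation restarts on the
same random stream, so results remain deterministic per seed. The screen
conditions the random *draw*; the learning rule and dynamics are
untouched. Over-capacity requests still fail with an informative error,
and `ensure_stable = FALSE` recovers unconditioned patterns.

## Symbolic control

* **Symbol detectors** are perceptrons: one unit per (slot, symbol)
  pair, firing when the normalized overlap of the slot contents with the
  symbol's piece exceeds a threshold (default 0.9).
* **Production rules** are linear thresholded neurons over equality and
  detector bits with integer weights; a `-1` weight is a veto synapse.
  Conflict resolution picks the satisfied rule with the highest net
  input, ties broken by definition order. Rule actions set slots,
  transfer between slots, and request a declarative-memory retrieval
  (with an explicit list of slots to blank first).
* **Declarative memory** stores chunks as concatenations of vocabulary
  pieces over designated slots; retrieval scores each chunk by the mean
  per-slot normalized overlap over the non-blank cue slots and writes
  the winner into the blank slots only (ties by storage order).

## The match–execute runtime and the Count Model

`run_model()` iterates cycles of: settle (default 10 sweeps, gates
closed) → read equality/detector bits → evaluate productions → execute
the winner's actions (transfers: 40-sweep budget) → if a retrieval was
requested, blank the listed slots, settle 5 sweeps, retrieve, settle 5
more. The packaged Count Model uses 7 slots × 100 neurons (goal buffer
IsA/start/end/count; declarative buffer IsA/first/second), 11 symbols,
7 count-order facts, and three rules (`start`, `increment` with a veto
from the count-equals-end equality neuron, `stop` which halts). Counting
from start to end takes `end - start` increment firings and
`end - start + 2` cycles, which the test suite verifies for all 28
start/end pairs over multiple vocabulary seeds.

One deliberate design choice: the retrieval action names the slots to
blank explicitly rather than blanking "currently empty" slots, because
on increment cycles the retrieval slot still holds the previous cycle's
answer and must be cleared for the new cue to drive completion.

## What is simulated, and limitations

Everything in the package is self-generated: vocabularies are seeded
random draws, and all reported behaviour is computed by the simulator —
there is no empirical data. Problem sizes exercised are slots of 60–100
neurons and vocabularies of up to 11 symbols (total networks up to 700
units), where every claim in the README is reproduced by the test suite
or by `scripts/acceptance.R`.

Limitations worth keeping in mind:

* Capacity is the classic Hopfield bound; the stability screen makes
  moderate loads exact but cannot rescue genuinely over-capacity
  vocabularies, and screening cost grows as acceptance probability
  falls.
* Gating, clamping, detectors, productions, and the cycle schedule are
  algorithmic scaffolding, not neural dynamics; the package models the
  attractor substrate neurally and the control structure symbolically.
* Synchronous settling has no Lyapunov guarantee (two-cycles are
  possible in principle); the runtime relies on starting at or near
  stored attractors. The asynchronous mode is provided where the energy
  argument is needed.
* Equality calibration assumes the run-time slot contents are vocabulary
  pieces (possibly noisy); arbitrary non-vocabulary states carry no
  calibrated guarantee.
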