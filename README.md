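# dpaan

Simulation of **dynamically partitionable autoassociative networks**
(DPAANs): Hopfield attractor networks divided into slot-like partitions
whose between-partition synapse blocks can be gated on and off at run
time. Gating turns a single attractor network into a bank of symbolic
registers that can copy, compare, and hold discrete symbols with purely
neural machinery — the substrate the package then uses to run
production-rule cognitive models, up to a full neural implementation of
the ACT-R Count Model. The intended audience is computational
neuroscientists and cognitive modellers interested in how symbolic
variable binding can be grounded in attractor dynamics.

## The model

A network of `N` bipolar neurons (activations in `{-1, +1}`, plus `0`
for a blank, undriven unit) is divided into `K` partitions ("slots") of
sizes `N_1 … N_K`. A vocabulary of `L` symbols is a set of random global
patterns `ξ¹ … ξᴸ` over all `N` units; the restriction of pattern `l` to
slot `k` is the *piece* that slot holds when it represents symbol `l`.
Weights are trained once by the outer-product (Hebbian) rule

    w_ij = (1/N) Σ_l ξ_i^l ξ_j^l ,   w_ii = 0 ,

and never change afterwards. A `K × K` binary gate matrix masks whole
between-slot synapse blocks at run time without touching the stored
weights; the dynamics are threshold updates `x_i ← sign(Σ_j g·w_ij x_j)`
(zero net input keeps the previous value, so blank slots stay blank),
either synchronous or asynchronous. With symmetric weights the
asynchronous dynamics descend the Hopfield energy

    E = -(1/2) Σ_{i≠j} w_ij x_i x_j .

Three constructions ride on this substrate:

* **Equality detection.** The cross energy
  `E_kk' = -2 x_k' W[k,k'] x_{k'}` between two slots is low precisely
  when they hold pieces of the same stored pattern. One thresholded
  neuron per slot pair reads this out; thresholds are calibrated from
  the vocabulary (midpoint of the gap between matched and mismatched
  energy populations).
* **Transfer.** To copy slot `k` into slot `k'`: blank the target, clamp
  the source, open the `k → k'` gate plus the target's internal gates,
  and let attractor completion fill in the target's piece of the same
  symbol.
* **Control.** Perceptron symbol detectors and production rules (linear
  thresholded neurons over equality and detector bits, with `-1` veto
  synapses) select actions; a declarative-memory module completes
  partially cued chunks. A match–execute cycle loop runs ACT-R-style
  models.

## Worked example

```r
library(dpaan)

net <- dpaan(rep(100, 5), c("red", "blue", "square", "circle"), seed = 1)
summary(net)
#> Dynamically partitionable autoassociative network
#>   slots:         K = 5 (100, 100, 100, 100, 100)
#>   neurons:       N = 500
#>   vocabulary:    L = 4 (red, blue, square, circle)
#>   coding level:  0.50
#>   stable attractors: 4 of 4 vocabulary patterns
#>   equality margin:   21.968 (worst slot pair)

# a red circle and a red square, slot 5 (vocalization) blank
st <- new_state(net)
st <- set_slot(st, 1, "red", net)
st <- set_slot(st, 2, "circle", net)
st <- set_slot(st, 3, "red", net)

equality_readout(net, st)
#> eq_1_2 eq_1_3 eq_1_4 eq_1_5 eq_2_3 eq_2_4 eq_2_5 eq_3_4 eq_3_5 eq_4_5
#>      0      1      0      0      0      0      0      0      0      0

tr <- transfer(net, st, from = 1, to = 5)
predict(net, tr$state)
#>       X1       X2       X3       X4       X5
#>    "red" "circle"    "red"       NA    "red"
```

Only the (1,3) equality neuron fires — the two objects share a colour —
and the gated transfer copies `"red"` into the empty slot 5.

The full Count Model (7 slots × 100 neurons, 11 symbols, 7 declarative
count-order facts, 3 production rules):

```r
run_count_demo("two", "seven", seed = 1)
#> Model run: 7 cycle(s), halted by a stop production
#>   fired: start, increment, increment, increment, increment, increment, stop
#>   raster: 56 timesteps x 700 neurons
```

The count slot traverses `two three four five six seven`: one `start`
cycle, `end - start = 5` increments, one `stop`. Two further demos are
packaged: `run_binding_demo()` (the scene above, run as raw attractor
dynamics) and `run_jealousy_demo()` (a syntax-sensitive rule with a veto
synapse that fires on "John loves Mary, Mary loves Sam" but not on the
mutual-love scene). A command-line front end for all three is installed
at `system.file("cli", "dpaan_demo.R", package = "dpaan")`.

## Reproduction

`scripts/acceptance.R` rebuilds the Count Model network from scratch
against the installed package and counts how many of its 11 vocabulary
patterns are stable fixed points of the full ungated dynamics:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
# t4 = 11 stable patterns of 11 symbols (N = 700)
```

writing `{"t4": {"value": 11, "n": 700}}`. The seed controls vocabulary
generation; the generator screens draws so that every symbol is retained
(see the methods vignette, `vignettes/dpaan-methods.Rmd`, for why and
for the model's assumptions and limitations).
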