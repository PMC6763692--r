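# neurocable

A desk-scale simulator for networks of morphologically detailed neurons,
written for computational neuroscientists and simulator engineers who want
the *compute core* of a compartmental network engine — cable-equation
integration on neuron trees, event-driven synaptic communication, and
reproducible state serialization — in a form small enough to read, test,
and modify.

## What it computes

Each neuron is a rooted tree of unbranched cables discretized into
compartments. The membrane potential obeys the cable equation

```
(d / 4·Ra) ∂²v/∂x² = cm ∂v/∂t + I_pas + I_ion + I_syn
```

integrated with implicit (backward) Euler at a fixed step (default
Δt = 0.025 ms). Each step performs, in order: event-driven spike delivery,
matrix assembly with linearized mechanism currents, direct Gaussian
elimination on the tree (Hines solve — parent-before-child ordering makes
the arithmetic cost identical to an unbranched cable of equal size), state
update, and threshold detection. Cells interact only through delayed spike
events, synchronized by a global exchange every minimum-delay interval.

Around that core the package provides:

- **Mechanisms in Structure-of-Arrays pools** — passive leak,
  Hodgkin–Huxley channels, exponential synapses, current clamps, gap
  junctions, stochastic stimulus sources; user types via
  `register_mechanism()`.
- **Node permutations** (`interleaved_order()`, `constant_depth_order()`)
  and a `parent_contiguity()` locality metric modelling warp-coalesced
  parent access, with simulation invariance under any valid permutation.
- **Deterministic archives** — on-disk models (`write_model()` /
  `read_model()`, integer-offset references with semantic tags) and
  checkpoint–restart (`save_checkpoint()` / `restore_checkpoint()`) that
  collapses undelivered deliveries back into single source events.
- **Counter-based RNG** (`counter_rng()`, Threefry-style) so every stream
  is a pure function of (seed, gid, purpose) — runs are bit-reproducible
  and independent of cell-group partitioning.
- A **ring-network benchmark generator** (`ring_network()`) with
  seed-deterministic random dendritic branching.

## Worked example

A 16-cell ring: each soma carries HH channels and an exponential synapse;
cell k excites cell k+1 (weight 0.05 µS, delay 1 ms); one stimulus event
enters cell 0 at t = 2 ms.

```r
library(neurocable)
m  <- ring_network(n_types = 1, cells_per_type = 16, seed = 7)
st <- init_state(m, dt = 0.025)
raster <- run(st, 50)
head(raster, 5)
#> # A tibble: 5 × 2
#>    time   gid
#>   <dbl> <int>
#> 1  2.33     0
#> 2  3.65     1
#> 3  4.98     2
#> 4  6.3      3
#> 5  7.63     4
nrow(raster); length(unique(raster$gid)); st$op_count
#> [1] 36
#> [1] 16
#> [1] 672000
```

Cell 0 fires 0.33 ms after its synaptic event; the wave then advances one
cell per ~1.33 ms (1 ms axonal delay + integration latency) and circulates:
36 spikes across all 16 cells in 50 ms. The operation counter confirms the
solver's branching-independent cost: 80 nodes × 2000 steps, 5 multiplies/
divides per non-root node plus 1 per root — (5·64 + 16) × 2000 = 672,000
for the 16 five-node cells.

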