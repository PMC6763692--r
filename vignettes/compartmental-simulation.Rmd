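---
title: "Compartmental network simulation: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental network simulation: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocable)
```

## The model

neurocable simulates networks of morphologically detailed neurons. Each cell
is a rooted tree of unbranched cables ("sections"), discretized into
compartments (nodes) that each carry one membrane-potential unknown. The
membrane potential $v$ on a cable of diameter $d$, axial resistivity $R_a$
and specific capacitance $c_m$ obeys the cable equation

$$\frac{d}{4 R_a}\frac{\partial^2 v}{\partial x^2}
  = c_m \frac{\partial v}{\partial t} + I_{\mathrm{pas}} + I_{\mathrm{ion}} + I_{\mathrm{syn}},$$

where the right-hand currents are the passive leak, voltage-gated channel
currents, and synaptic currents. Spatial discretization turns this into a
stiff tree-structured ODE system coupled between cells only by discrete
spike events, which is what makes the hybrid clock--event algorithm work:
within a fixed time step membranes are integrated implicitly, while spikes
travel between cells as timestamped events with axonal delays.

Every step executes, in order: (1) delivery of synaptic events due in
$(t, t+\Delta t]$, (2) assembly of the linear system including the
linearized mechanism currents, (3) direct Gaussian elimination on the tree,
(4) state-variable update, (5) threshold detection. Sources and targets are
synchronized by a global spike exchange once per *minimum delay* interval
(the smallest NetCon delay): no delivery can come due sooner than one
minimum delay after its source spike, so exchanging more often cannot
change any result (a property the tests assert).

## Units

All quantities use a single consistent system chosen so that no per-step
conversion factors appear: voltage mV, time ms, conductance µS, current nA,
capacitance nF. Geometry is specified in the field's customary units (µm,
Ω·cm, µF/cm²) and converted once at discretization: node area
$\pi d \,\Delta x$ (µm²), node capacitance $c_m \cdot \mathrm{area} \cdot 10^{-5}$ (nF),
axial conductance $10^2 \pi d^2 / (4 R_a \Delta x)$ (µS). Density-mechanism
currents (mA/cm²) and conductances (S/cm²) convert to absolute nA and µS
through the instance's node area with the shared factor
$\mathrm{area} \cdot 10^{-2}$.

## Numerics

**Integration.** Implicit (backward) Euler with a fixed step, default
$\Delta t = 0.025$ ms. Backward Euler is the simplest A-stable choice for
the stiff discretized cable and keeps checkpoint state minimal (voltages and
mechanism states only). Channel and synapse states advance *after* the
voltage solve using end-of-step voltages, rather than NEURON's staggered
half-step scheme; this trades second-order accuracy in time for a simpler,
fully restartable update and is a documented numerical difference from that
simulator family.

**Tree solver.** The membrane matrix is symmetric with one off-diagonal per
node (toward its parent). Because nodes are ordered parent-before-child, a
single reverse sweep eliminates every node onto its parent and a forward
sweep back-substitutes — Gaussian elimination with minimum-degree ordering
specialized to trees. The multiply/divide count is $5(n - r) + r$ for $n$
nodes and $r$ roots, independent of branching; the solver tallies it at run
time and the tests check both the dense-solve oracle (1e-10 relative) and
the count identity across random topologies.

**Gating updates.** Hodgkin-Huxley gates use the exponential (exact-relaxation)
update $x \leftarrow x_\infty + (x - x_\infty) e^{-\Delta t(\alpha+\beta)}$,
which keeps $x \in [0,1]$ for any step size. The classic squid-axon rate
functions are built in (defaults $\bar g_{Na} = 0.12$, $\bar g_K = 0.036$,
$g_L = 3\cdot10^{-4}$ S/cm²; $e_{Na} = 50$, $e_K = -77$, $e_L = -54.3$ mV);
the removable singularities of $\alpha_m$ (at $-40$ mV) and $\alpha_n$ (at
$-55$ mV) switch to a two-term Taylor expansion when the scaled argument is
within $10^{-6}$, giving the exact limits.

**Initialization.** $v = -65$ mV everywhere by default; gating states start
at their steady state at the initial voltage. Spike times are the
end-of-step time of the crossing step (no interpolation), matching the
fixed-step event quantization; a watcher rearms only after its voltage
falls back below threshold, and the crossing rule is $v \ge \theta$.

**Gap junctions.** Electrical coupling is explicit in the peer: the current
is $g_{gap}(v_{\mathrm{self}} - v_{\mathrm{peer}}^{\mathrm{prev}})$ with the peer
voltage snapshotted at the end of the previous step, and only the self
conductance enters the matrix. This keeps the matrix a forest of
independent trees (cells never couple through the solve) at the cost of
explicit-coupling accuracy, adequate under the fixed small step; the tests
compare the two-cell relaxation against the closed-form ODE solution.

**Event ordering.** Deliveries are popped in the total order (time,
source gid, netcon id); ties are otherwise unspecified in event-driven
simulators, and fixing them makes every run bit-reproducible. Due-time
comparisons carry a $10^{-9}$ ms tolerance to absorb floating accumulation
of $t$ (internally $t$ is always `step_index * dt`). Delays are not
quantized to the step.

## Structure-of-Arrays pools and node orderings

All instances of one mechanism type within one cell group live in a single
pool holding one contiguous vector per parameter and per state, plus an
ascending node-index map — never an array of per-instance structs. Kernels
are pure vectorized functions over the instance axis.

Two node permutations reorganize memory the way SIMD hardware prefers.
*Interleaved* puts node $j$ of each of $N$ identical cells at
`offset + j*N + c`, so corresponding compartments are adjacent and the
parents of one 32-wide group are exactly the previous group. *Constant
depth* makes all nodes of equal tree depth adjacent (corresponding nodes of
identical cells side by side), and within one cell and depth keeps children
of the same branch node maximally separated by ordering a depth row
child-position-major. A note on the tie-break: depth rows are ordered by
(sibling-separating rank, type, cell) — rank-major rather than cell-major —
because that is what makes corresponding nodes of identical cells adjacent.
Since desk hardware cannot reproduce GPU warp timings, the measurable
stand-in is `parent_contiguity()`: the fraction of consecutive
`warp_size`-node groups whose parents form a consecutive ascending run
(trailing partial groups are ignored). It is 1.0 for interleaved layouts
with ≥ 32 identical cells per type, non-decreasing in cells-per-type, and
the constant-depth layout dominates interleaving when every cell is unique.

Any valid permutation leaves the simulation unchanged up to elimination-
order roundoff: rasters are identical and voltage traces agree to
$10^{-6}$ mV on the test networks, which the acceptance checks assert.

## Random streams

All randomness flows through a counter-based generator (Threefry-2x64-20:
five 4-round add-xor-rotate blocks with a key injection after each block;
constants frozen by golden tests). A draw is a pure function of a 128-bit key and a
64-bit counter, so streams are keyed per (seed, gid, purpose) and results
are independent of cell-group partitioning, evaluation order, and
checkpoint boundaries. Checkpoints store stream *counters*, not generator
state blobs, so restores are portable.

## The synthetic ring benchmark

The generator builds `n_types * cells_per_type` cells. Each type draws a
random dendritic branching pattern from its stream: `n_dend` passive
dendrites attach uniformly at random to an already-placed section, with
section depth capped (default 3). Every cell has
`soma_nseg + n_dend * nseg_per_dend` nodes regardless of branching; the
published large configuration (3-node soma + 40 two-node dendrites = 83
nodes, 131,072 cells, 10,878,976 nodes) is reproduced as a count-only
check. Somata carry HH channels, dendrites a passive leak
($g = 10^{-3}$ S/cm², $e = -65$ mV), and each soma hosts an exponential
synapse ($\tau = 2$ ms, $e = 0$ mV). Rings of `ring_size` consecutive cells
are wired cell $k \to k+1$ with weight 0.05 µS and delay 1 ms — strong
enough that one presynaptic spike reliably fires the next soma, so a single
stimulus event per ring (one-spike stimulus source at $t = 1$ ms) launches
a self-sustained wave whose order and latency the tests check.

What this emulates is the *communication and memory structure* of large
network models: branching diversity, event fan-out, delay-bounded exchange.
What it does not emulate: biological channel diversity, conductance-scale
heterogeneity, plasticity, or realistic connectivity statistics — so
passing tests demonstrate the correctness of the numerics and event
machinery, not biological validity of any particular network.

Test and acceptance problem sizes are deliberately desk-scale (64-cell
rings over 100 ms, trees up to 200 nodes, $10^5$-draw RNG samples); every
property they check is size-independent, and the one published
large-network figure is verified as pure bookkeeping.

## Archives and checkpoint-restart

A model archive is a directory: a JSON manifest plus flat little-endian
binary datasets written per cell group, so a writer can instantiate and
flush one group at a time with bounded peak memory. No absolute addresses
are stored; every cross-reference is an integer offset labelled with a
semantic tag (`voltage_offset`, `area_offset`, `point_process_index`,
`netcon_target`, `presyn_index`, `peer_voltage_offset`), and unknown tags
are fatal on read. Output bytes are a pure function of the model, enabling
content-hash regression tests.

A checkpoint stores voltages, mechanism states, watcher arming, stream
counters, and pending events. Per-netcon delivery events are *collapsed*:
each source spike with undelivered fan-out is stored once as
`(gid, spike_time)`, and restore re-runs the fan-out, dropping deliveries
due at or before the checkpoint time (events exactly at the boundary count
as delivered, avoiding double delivery). Continuing a restored run
reproduces the uninterrupted raster bit-identically; supplying a different
stimulus seed at restore diverges only after the restore time.

## Worked example

```{r example, eval = FALSE}
m <- ring_network(n_types = 1, cells_per_type = 16, seed = 7)
st <- init_state(m, dt = 0.025)
raster <- run(st, 50)
head(raster, 3)
#> # A tibble: 3 x 2
#>    time   gid
#>   <dbl> <int>
#> 1  2.33     0
#> 2  3.65     1
#> 3  4.98     2
```

The stimulus event arrives at cell 0's synapse at $t = 2$ ms (1 ms start +
1 ms delay); the soma fires 0.325 ms later, and the wave advances one cell
per ~1.33 ms (1 ms synaptic delay + integration latency) around the ring.

## Known limitations

- First-order time accuracy (no staggered half-step, no variable step);
  results converge to the staggered scheme's as $\Delta t \to 0$ but differ
  at finite step.
- Mechanism kernels are interpreted R over SoA vectors; the solver and RNG
  are compiled. Desk-scale networks (~10^2 cells) run in seconds; this is a
  correctness-first engine, not an HPC engine.
- Single process. Cell groups are logical ranks that make partition
  invariance a *testable contract* rather than a parallelization.
- Density mechanisms cannot receive events; artificial cells have no
  membrane. Both restrictions are enforced at registration.
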