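---
title: "Stochastic gating of RyR2 clusters: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic gating of RyR2 clusters: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryrcluster)
```

## The model

Cardiac ryanodine receptors (RyR2) release Ca from the sarcoplasmic
reticulum and sit in clusters of tens to hundreds of channels at dyadic
junctions. `ryrcluster` models such a cluster as a lattice of coupled
tetramers and measures the waiting time to a spontaneous Ca spark — the
first passage of the open-channel count past a threshold, starting from
a fully closed cluster.

Each channel has four identical subunits on a ring, each either closed
($s_i = -1$) or open ($s_i = +1$). A closed subunit opens at rate
$k_f\,\gamma_i$ with $k_f = k_{fo}\,\mathrm{Ca}$, and an open subunit
closes at rate $k_b/\gamma_i$, with the cooperativity factor

$$\gamma_i \;=\; \exp\!\Big[\delta\,(s_{i-1}+s_{i+1}) \;+\;
  \textstyle\sum_b \sigma_b\, s_b\Big],$$

where the first term couples the subunit to its two ring neighbours with
dimensionless mismatch penalty $\delta$, and the sum runs over the
subunit's physical contacts with subunits $s_b$ of adjacent channels,
each with strength $\sigma_b$. Conformational mismatch with neighbours
is penalized; agreement is rewarded. Because opening is scaled by
$\gamma_i$ and closing by $\gamma_i^{-1}$, every flip satisfies
$k_+/k_- = (k_{fo}\mathrm{Ca}/k_b)\,\gamma_i^2$ and the chain is
reversible at fixed Ca, with a Boltzmann stationary law (verified
exactly in the test suite via `stationary_distribution()`).

A note on the coupling exponent: with a flat typesetting of the cluster
coupling factor it is ambiguous whether $\sigma$ is itself multiplied by
$\delta$. We treat $\sigma_b$ as a bare dimensionless energy, entering
the exponent on the same footing as $\delta$. Under this reading the
package reproduces the reference order-of-magnitude waiting times that
define this model's behaviour (a 10×10 oblique cluster at
$c_o = 5\,\mu M$, $\sigma = 1$ waits $\sim 10^5$ ms; the
$\sigma: 0 \to 0.5$ effect at $c_o = 5\,\mu M$ spans almost four
decades), whereas the alternative reading (an effective scale
$\delta\sigma$) compresses those effects by more than a decade. The
choice is therefore fixed by the model's own quantitative behaviour, and
the acceptance suite pins it.

A channel *conducts* when at least 3 of its 4 subunits are open (a
majority rule; the threshold is exposed as
`open_rule_min_subunits` but defaults to 3). Ca feedback uses the
rapid-diffusion approximation: Ca diffuses 600–1000 nm over a ~1 ms
open time (`diffusion_length()`), farther than any cluster, so the
dyadic pool is well mixed and

$$\mathrm{Ca} = c_o + g\,n_o,$$

with $n_o$ the conducting-channel count, $g$ the per-channel Ca
increment, and $c_o$ the background concentration. This closes the
calcium-induced-calcium-release loop: each opening raises Ca, which
accelerates further openings — hence the explosive, regenerative
activation once a fluctuation crosses the threshold.

### Parameters and units

Time is in ms, concentration in $\mu$M, rates in ms$^{-1}$, everywhere.
Defaults of `ryr_params()`:

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | intra-channel mismatch penalty (dimensionless) |
| `sigma` | 1 | inter-channel coupling strength (dimensionless) |
| `kfo` | 0.005 | Ca binding rate constant, $\mu$M$^{-1}$ms$^{-1}$ |
| `kb` | 0.3 | subunit closing rate, ms$^{-1}$ (~3 ms open time) |
| `g` | 25 | dyadic Ca per open channel, $\mu$M |
| `co` | 0.1 | diastolic background Ca, $\mu$M |
| `nc` | 5 | spark threshold on the open-channel count |

`kfo` keeps isolated channels almost surely closed at diastolic Ca
(~0.1 $\mu$M); `g = 25` places 1–3 open channels in the 25–75 $\mu$M
window needed to sustain regenerative release; `nc = 5` exceeds the
baseline fluctuation size, and any threshold above the fluctuations
yields the same waiting time because crossing is regenerative (the test
suite checks that the cluster fills within 10 ms of crossing).

## Cluster architectures

Channels are 30 nm squares on a grid; subunits 1–4 occupy the corners
NW, NE, SE, SW in ring order. Two idealized contact geometries are
built-in:

* `build_adjoining()` — side-by-side rows and columns; each adjacent
  pair shares **two** subunit bonds (right: a2–b1, a3–b4; up: a1–b4,
  a2–b3), so interior subunits carry 2 bonds and an $L\times L$ lattice
  has $4L(L-1)$ bonds.
* `build_oblique()` — staggered checkerboard contacts; **one** bond per
  adjacent pair, always of type 1–3 or 2–4 (right: a2–b4; up: a1–b3),
  so interior subunits carry 1 bond and an $L\times L$ lattice has
  $2L(L-1)$ bonds.

The specific corner-to-corner direction map is a recorded convention
(the physical constraint is only the ring adjacency, the bond counts
and the 1–3/2–4 typing); any consistent convention produces the same
dynamics.

Heterogeneity enters two ways:

* `dilute_bonds(g, p)` retains each inter-channel bond independently
  with probability $p$ — a model of progressive loss of structural
  integrity. Intra-channel ring coupling is never diluted, and
  disconnected channels still share the dyadic Ca pool (they remain in
  the same microdomain).
* `grow_preferential(n, nx, ny, alpha)` places channels sequentially,
  choosing an empty site with weight $(1+n_e)^\alpha$ where $n_e$
  counts occupied von Neumann neighbours, then bonds adjacent pairs
  with the oblique pattern. The weight is read as $(1+n_e)^\alpha$
  because that is the only reading for which $\alpha = 0$ is exactly
  uniform placement; the first channel is uniform over all sites.

## Exact stochastic simulation

`simulate_waiting_time()` runs the Gillespie algorithm with no
approximation: waiting times are exponential in the total propensity,
and the flipping subunit is chosen proportionally to its rate. The C++
engine keeps per-channel partial sums of opening weights
$e^{e_u}$ (closed subunits) and closing rates $k_b e^{-e_u}$ (open
subunits); a flip updates only the flipped subunit, its two ring
neighbours and its bond partners, and a change of $n_o$ only rescales
the global factor $k_{fo}\mathrm{Ca}$ shared by all opening
propensities. Sums are rebuilt from scratch every $2^{20}$ events to
bound floating-point drift (every $2^{12}$ events under `audit = TRUE`,
which additionally verifies the incremental sums at $10^{-9}$ relative
tolerance). On one core this sustains millions of events per second,
which is what the $\sim 10^6$ ms waiting-time regimes require.

Runs start all-closed and stop at the first time $n_o \ge n_c$
(threshold semantics: *reaches*, which for any supra-fluctuation
threshold is indistinguishable from *exceeds*), or at the censoring
horizon `t_max` (default $10^7$ ms); censored runs are flagged and any
ensemble containing one reports its mean as a lower bound rather than
silently averaging.

`run_ensemble()` pre-draws one seed per run from the master seed, so
ensembles are bit-reproducible and order-independent; when given a
generator function instead of a fixed geometry it samples a fresh
morphology (dilution mask, grown cluster) per run. The summary follows
the subset convention: the mean over all runs, with an error bar equal
to the standard deviation of 5 disjoint subset means (10 runs each at
the full 50-run protocol).

## The exact oracle

For clusters of up to 4 channels ($\le 2^{16}$ states),
`exact_mfpt()` enumerates every subunit configuration, builds the full
generator — including the state-dependent Ca, which is a deterministic
function of the configuration — and solves the sparse linear system for
the mean absorption time into $\{n_o \ge n_c\}$.
`stationary_distribution()` solves global balance at fixed Ca
($g = 0$). Systems up to 4096 states go through a direct sparse LU; the
4-channel state space (65,536 states), where LU fill-in on the
hypercube-structured graph is prohibitive, uses a Jacobi-scaled
BiCGSTAB iteration (residual tolerance $10^{-12}$, a few dozen
matrix-vector products in practice). The oracle recomputes rates from the formulas independently
of both the R rate functions and the C++ engine; the test suite then
closes the triangle: oracle vs an independent dense construction
(plain-loop generator, and a Kronecker-sum product chain for
independent channels) at $10^{-8}$, engine vs oracle at 3 standard
errors across a grid of sizes, couplings, Ca levels and thresholds.

## Experiment drivers

`sweep_co()`, `sweep_sigma()`, `sweep_dilution()` and `sweep_alpha()`
reproduce the four standard protocols: waiting time vs background Ca
(5–120 $\mu$M, $\sigma \in \{0, 0.5, 1\}$, sizes 5×5–20×20), vs
coupling strength (at rest, $c_o = 5\,\mu$M, and at high Ca,
100 $\mu$M), vs bond retention ($\sigma = 1$, $c_o = 2\,\mu$M, fresh
mask per run) and vs clustering exponent (50 channels on 20×20,
$c_o = 2.5\,\mu$M, fresh morphology per run). Results carry per-run
tables and a provenance record (spec, seeds, package version) that
`replay_sweep()` turns back into the identical tables; `write_results()`
/ `load_results()` persist them as CSV + JSON.

## Numerical and testing choices

* **Problem sizes.** The automated checks run the published protocols at
  reduced replicate counts (10–50 runs per point, 5×5 lattices for
  monotonicity properties) — enough to resolve order-of-magnitude
  claims at the half-decade tolerance appropriate for quantities quoted
  as $\sim 10^x$ ms, while keeping the default suite in the minutes
  range. The full 50-run, 10×10/20×20 protocols are one argument change
  away.
* **Degenerate inputs.** 1×1 lattices have no bonds ($\sigma$ is then
  irrelevant, tested bit-exactly); unreachable thresholds censor
  (simulation) or return `Inf` (oracle); `p` outside $[0,1]$, non-finite
  parameters and malformed geometry/parameter files are rejected, with
  unknown JSON keys an error rather than silently ignored.
* **What the generators do and do not emulate.** Dilution and
  preferential growth produce the *statistical* features the mechanism
  depends on — reduced bond counts, fragmented components, compact vs
  dispersed morphologies — on an idealized square lattice with a single
  pure contact geometry. Real clusters mix adjoining and oblique
  contacts, are not axis-aligned, and are remodelled by accessory
  proteins; channel inactivation, SR depletion and Ca clearance are
  likewise outside scope (they shape spark termination, not the
  initiation times modelled here). Passing tests therefore certify the
  coupled-gating mechanism and its exponential structural sensitivity,
  not a quantitative fit to any particular cell.
* **Known limitations.** Waiting-time distributions in the strongly
  coupled regime are heavy-tailed, so small-ensemble means carry
  sampling error of order their own magnitude — the reason
  order-of-magnitude tolerances are used. The oracle is capped at 4
  channels by state-space growth. At extreme coupling
  ($\sigma \gtrsim 1.5$ on large adjoining lattices) waiting times
  exceed the $10^7$ ms horizon and results are reported as censored
  lower bounds.
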