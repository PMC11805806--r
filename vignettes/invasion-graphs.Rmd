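---
title: "Invasion graphs and heteroclinic cycles in Lotka-Volterra systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion graphs and heteroclinic cycles in Lotka-Volterra systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcycles)
```

## The model

`lvcycles` analyses the generalized Lotka-Volterra system

$$\dot u_i = u_i \Big( b_i + \sum_{j=1}^N a_{ij} u_j \Big), \qquad i = 1, \dots, N,$$

on the nonnegative cone, where $b$ collects the intrinsic growth rates and
$A = (a_{ij})$ the per-capita interaction rates. The package's scope is the
class of **Volterra-Lyapunov (VL) stable** matrices: those for which some
positive diagonal $H$ makes $HA + A^T H$ negative definite. VL stability is
the strongest classical notion of diagonal stability for this model; it
guarantees a global attractor and a unique globally asymptotically stable
stationary solution (the GASS), not only for the full system but for every
subcommunity.

Three layers of structure are computed on top of the model:

1. **Communities and equilibria.** A set $I \subseteq \{1,\dots,N\}$ is an
   *admissible community* when the linear system $-A(I)\,u = b(I)$ (principal
   submatrix and subvector on $I$) has a strictly positive solution; embedded
   with zeros it is the unique equilibrium supported exactly on $I$.
2. **Invasion rates and the invasion graph.** The invasion rate
   $r_i(I) = b_i + \sum_{j \in I} a_{ij} u^I_j$ is the per-capita growth of
   species $i$ introduced at vanishing density into $u^I$ (with
   $r_i(\emptyset) = b_i$). The invasion graph (IG) places an edge
   $I \to J$ when every member of $J \setminus I$ can invade $I$ and every
   member of $I \setminus J$ dies out at $J$. For VL stable $A$ the IG is a
   subgraph of the connection graph of actual heteroclinic orbits, and the
   two coincide when all equilibria are hyperbolic (all absent-species rates
   nonzero); an acyclic IG then certifies a gradient attractor whose whole
   structure the graph recovers.
3. **Cycles.** A cycle in the IG of a hyperbolic VL stable system corresponds
   to a heteroclinic cycle of the dynamics -- the object this package is
   built to find, exhibit and exclude.

## Certifying VL stability

Deciding VL stability exactly is not attempted (and no exported routine
pretends to). Instead two complementary numerical devices are provided.

**The constructive direction.** $A$ is VL stable iff $A = H(S + J)$ with $H$
positive diagonal, $S$ symmetric stable and $J$ antisymmetric, with the
certificate identity $H^{-1}A + A^T H^{-1} = 2S$. `random_vl_stable()` runs
this construction on random ingredients, which yields arbitrarily many
matrices whose VL stability is known *a priori* -- the ground truth used to
benchmark the detector. The ingredient distributions are genuinely open
choices; the package uses $H_{ii} \sim U(0.1, 1.1)$, Gaussian $K$ and $F$
(with $J = K - K^T$, $S = F + F^T - \alpha I$), and
$\alpha = \max(0, \lambda_{\max}(F + F^T)) + 0.5$, the margin guaranteeing a
strictly stable $S$. All scales are arguments; one integer seed makes a draw
bit-reproducible.

**The detection direction.** For a given $A$, `detect_vl()` minimizes
$\mathcal{O}(h) = \lambda_{\max}(HA + A^T H)$ over the open box
$h \in (0,1)^N$ (positive homogeneity of $\mathcal{O}$ makes the restriction
to the unit box harmless) from up to `n_initial` random starts, stopping as
soon as any iterate drops below a negative threshold (default $-10^{-10}$).
The verdict is asymmetric by design: `vl_stable` always carries a multiplier
$h$ whose recomputed objective is negative -- a certificate checkable by
`verify_certificate()` independently of the optimizer -- while failure to
find one is only ever reported as `inconclusive`, never as "unstable". The
objective is nonsmooth at eigenvalue crossings, so no part of the contract
relies on the optimizer converging: L-BFGS-B with the analytic
(sub)gradient $2 v_i (Av)_i$ (top unit eigenvector $v$) is used because it is
fast in practice, and any failure mode it has can only cost recall, never
precision. `detect_vl_dense()` replaces the random starts with a fixed
enumeration of the dyadic rationals in $(0,1)^N$ (by denominator level, then
lexicographically); it halts on every VL stable input given enough
iterations, which makes VL stability partially decidable, and the iteration
cap makes the procedure practical.

## Enumeration, the invasion graph, and its cycles

`enumerate_admissible()` sweeps all $2^N$ subsets (bitmask enumeration,
capped at $N \le 20$ by default), solving each community's linear system
directly. Numerical policy:

* admissibility demands $u_i > 10^{-9}$ (absolute); near-zero candidates are
  boundary cases and are rejected with reason `"negative"`;
* a reciprocal condition number below $10^{-12}$ marks the community
  `"singular"` and excludes it without aborting the sweep (VL stability
  actually rules this out, but the enumerator does not assume its input is
  VL stable);
* every catalogued equilibrium is checked in the tests to satisfy its linear
  system to $10^{-8}$ in the max norm.

`build_ig()` applies the edge rule with strict inequalities at tolerance
$10^{-9}$: a rate within tolerance of zero licenses nothing. This is
deliberate -- such a system is non-hyperbolic, and `is_hyperbolic()` reports
exactly which rates are at fault rather than letting a sign be chosen
silently. `find_cycles()` reports `has_cycle` from strongly connected
components (always exact) and enumerates elementary cycles with Johnson's
algorithm under a cap (default $10^5$, `cap_hit` flagged), since the cycle
count can be exponential. The GASS is identified in the catalog as the unique
*saturated* equilibrium ($r_i(I) \le 0$ for all $i \notin I$); `find_gass()`
errors loudly when zero or several candidates appear, because under VL
stability exactly one must exist and a violation means the premise, not the
answer, is wrong.

Two sufficient conditions for *maximal frondosity* (every community
admissible, which excludes heteroclinic cycles outright and, under
hyperbolicity, forces the IG to be exactly the subset order
$I \subsetneq J$) are implemented as cheap screens:
`frondosity_sufficient_dd()` evaluates
$\max_i \sum_{j \ne i} |a_{ij}/a_{jj}| < 1/(1+M)$ with
$M = \max_i b_i / \min_i b_i$, and
`frondosity_sufficient_cooperative()` covers the fully cooperative case
(all off-diagonal interactions positive, positive growth rates). Both are
sufficient only; `check_frondosity()` is the exhaustive test.

## Dynamics

`simulate_lv()` integrates the ODE with `deSolve`. Species starting at
exactly zero are removed from the integrated subsystem instead of being
carried as tiny values, so faces of the cone are invariant *exactly* and wall
dynamics are true restricted subsystems -- the property on which the
interpretation of IG edges as wall-to-wall transitions rests. The default
integrator is `vode` (relative tolerance $10^{-9}$): on VL stable systems
dying species decay exponentially toward the bottom of the floating-point
range, where `lsoda`'s dense-output interpolation was observed to fail;
`vode` and `ode45` remain robust there and either can be selected. A state
cap of $10^8$ converts blow-up (impossible under VL stability, possible under
misuse) into an informative error. The default horizon
$t_{\text{final}} = 200/|\min_i a_{ii}|$ scales the run to the slowest
self-regulation time.

`omega_limit_check()` declares convergence only when the final 10% of samples
has diameter below $10^{-6}$ (configurable), then reports the nearest
catalogued equilibrium and its distance; an unsettled window is reported as
inconclusive rather than matched.

## The experiments and what the generator does not emulate

Four reproducible studies tie the pieces together, each driven by one master
seed and a size configuration:

* `detector_benchmark()` -- recall of `detect_vl()` on `random_vl_stable()`
  output. The default study (10 matrices per dimension, dimensions up to 19,
  50 starts) reaches 100% recall with every certificate re-verified; the
  inconclusive rate in dimension 20 and beyond depends on the generator
  scales and is reported, not asserted.
* `cycle_density()` -- fraction of cyclic IGs as a function of the pinned
  ratio $|A_J|/|A_S|$ (entrywise norms of the antisymmetric and symmetric
  parts). Sampling draws a Gaussian matrix, shifts the symmetric part's
  diagonal to stability, and rescales the antisymmetric part onto the target
  ratio; with $H = I$ the sample is VL stable by construction. Growth rates
  are fixed at one, matching the package's reference systems. At ratio zero
  the matrix is symmetric, the flow is gradient, and the density is exactly
  zero; the density then rises with the ratio.
* `dd_sweep()` -- strongly row- or column-diagonally-dominant matrices with
  mixed-sign off-diagonals and growth rates, diagonals strictly negative
  (self-regulation). Cycles among single-species communities are provably
  impossible here (the product criterion
  $\prod_i |a_{i,i+1}| \ge \prod_i |a_{ii}|$ that any singleton cycle must
  satisfy contradicts dominance), and `single_species_cycle_test()` checks
  that reasoning on every cyclic sample; that *no* cycle of any kind appears
  is an open conjecture which the sweep can only support, never prove.
* `rpsls_d_sweep()` -- the five-species rock-paper-scissors-lizard-spock
  family `rpsls5(d)` across its three regimes: cycles for $d \in (-1, 0)$
  (12 admissible communities, two five-cycles), non-hyperbolicity at
  $d = -1$, and for $d < -1$ maximal frondosity with an IG identical,
  edge for edge, to that of the decoupled diagonal system.

Test and default problem sizes (dimensions mostly $\le 12$, $10^4$ samples in
the dominance sweep, 20 systems in the convergence suite) are desk-scale
choices: large enough to exercise every regime the reference systems exhibit,
small enough to run routinely; all are arguments.

What passing these studies shows -- and what it does not: the generator
produces dense Gaussian-derived interaction structure with every pair of
species interacting. Real community matrices are sparse, have broad
(non-Gaussian) interaction-strength distributions, block structure from
guilds, and are estimated with noise; none of that is emulated, so the
experiments validate the *machinery* (enumeration, graph logic, detection,
integration) and the qualitative symmetric-vs-antisymmetric story, not any
quantitative claim about empirical food webs.

## Design choices and limitations

* **Tabular surface.** Catalogs, edge lists and experiment tables are
  tibbles; fitted-object summaries follow `tidy()`/`glance()` conventions and
  each result type has an `autoplot()` method. Heavy numerics stay in plain
  matrices internally.
* **Labels.** Communities print as `"(1,2,3)"` (1-based, sorted); the empty
  community `"()"` is always a catalog entry and a graph node, with a toggle
  to hide it in exports (`write_ig(include_empty = FALSE)`).
* **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state; experiment tables are bit-reproducible from
  (seed, configuration).
* **Limitations.** No symbolic or arbitrary-precision linear algebra; no
  exact decision procedure for VL stability (certificates are floating-point
  eigenvalue statements); no computation of connecting orbits beyond the
  IG-level identification, no basin/repeller decomposition, and no
  hypergraph refinement of the attractor for cyclic cases; the $2^N$ sweep
  caps practical system size near 20 species.

## A worked example

```{r example}
A <- rpsls5(-0.5)
catalog <- enumerate_admissible(A, b = 1)
glance(catalog)

g <- build_ig(catalog)
rep <- find_cycles(g)
rep$cycles[vapply(rep$cycles, length, 1L) == 5L]

find_gass(catalog)$label

structure_verdict(catalog, g)
```

Raising self-regulation dissolves the cycles:

```{r sweep}
rpsls_d_sweep(c(-0.5, -1, -1.5))
```
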