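# lvcycles

Heteroclinic cycles and invasion graphs for generalized Lotka–Volterra
systems with Volterra–Lyapunov stable interaction matrices.

## The problem

An ecological community of N species with intrinsic growth rates `b` and
interaction matrix `A` evolves by the Lotka–Volterra equations

    du_i/dt = u_i * (b_i + sum_j a_ij * u_j)

When `A` is **Volterra–Lyapunov (VL) stable** — some positive diagonal `H`
makes `H A + Aᵀ H` negative definite — the system has a global attractor and a
unique globally stable equilibrium, yet its boundary can still contain
**heteroclinic cycles**: closed chains of community equilibria connected by
transition orbits, the dynamical signature of rock–paper–scissors–style
competitive intransitivity. `lvcycles` is a toolkit for finding, exhibiting
and excluding such cycles. It is aimed at theoretical ecologists and
dynamical-systems researchers who work with community matrices, whether
handwritten, randomly generated, or estimated.

The machinery, end to end:

* **VL stability, constructively.** Every VL stable matrix factors as
  `A = H (S + J)` with `S` symmetric stable and `J` antisymmetric
  (`vl_compose()`, `random_vl_stable()`); the identity
  `H⁻¹A + AᵀH⁻¹ = 2S` is the certificate.
* **VL stability, numerically.** `detect_vl()` minimizes the objective
  `𝒪(h) = λ_max(HA + AᵀH)` over positive diagonals `h ∈ (0,1)^N` from many
  random starts; any iterate with `𝒪 < 0` is a verifiable stability
  certificate (`verify_certificate()`), so a positive verdict is always
  correct and failure is reported as *inconclusive*, never as "unstable".
  `detect_vl_dense()` walks a fixed dense sequence instead, which halts on
  every VL stable input.
* **Communities.** `enumerate_admissible()` solves `-A(J) u = b(J)` for all
  2^N communities `J` and catalogues the admissible ones with their
  equilibria and invasion rates `r_i(J) = b_i + Σ_{j∈J} a_ij u*_j`;
  `find_gass()` identifies the unique saturated (globally stable)
  equilibrium.
* **The invasion graph.** `build_ig()` draws the edge `I → J` when every
  species of `J \ I` can invade `I` and every species of `I \ J` dies out at
  `J`; `find_cycles()` reports strongly connected components and elementary
  cycles; `structure_verdict()` combines hyperbolicity and acyclicity into a
  gradient certificate for the attractor. Frondosity screens
  (`check_frondosity()`, `frondosity_sufficient_dd()`) exclude cycles via
  diagonal dominance or full cooperativity.
* **Dynamics.** `simulate_lv()` integrates the ODE with exactly invariant
  faces; `omega_limit_check()` matches trajectories to catalogued equilibria.
* **Experiments.** `detector_benchmark()`, `cycle_density()`, `dd_sweep()`
  and `rpsls_d_sweep()` reproduce the package's computational studies from a
  single seed.

## Worked example: rock–paper–scissors–lizard–spock

The five-species matrix `rpsls5(d)` has self-regulation `d` on the diagonal
and a pentagram of ±1 antisymmetric interactions; with `d = -0.5` and unit
growth rates:

```r
library(lvcycles)

A <- rpsls5(-0.5)
catalog <- enumerate_admissible(A, b = 1)
glance(catalog)
#> # A tibble: 1 × 6
#>   n_species n_admissible n_rejected max_dim frondose hyperbolic
#>       <int>        <int>      <int>   <int> <lgl>    <lgl>
#> 1         5           12         20       5 FALSE    TRUE
```

Of the 32 possible communities, 12 are admissible: the empty community, the
five singletons, five three-species coalitions, and the full community. The
invasion graph carries three elementary cycles of length five:

```r
g <- build_ig(catalog)
rep <- find_cycles(g)
rep$cycles[vapply(rep$cycles, length, 1L) == 5L]
#> (1,2,3) -> (2,3,4) -> (3,4,5) -> (1,4,5) -> (1,2,5)
#> (1) -> (2) -> (3) -> (4) -> (5)
#> (1) -> (4) -> (2) -> (5) -> (3)
```

— a cycle through the five single-species equilibria (in both tournament
orientations) and one through the five three-species equilibria: heteroclinic
cycles on the boundary of the attractor, while the interior equilibrium is
globally stable for interior starts:

```r
find_gass(catalog)$label
#> [1] "(1,2,3,4,5)"

structure_verdict(catalog, g)
#> # A tibble: 1 × 5
#>   hyperbolic acyclic gradient_certified frondose notes
#>   <lgl>      <lgl>   <lgl>              <lgl>    <chr>
#> 1 TRUE       FALSE   FALSE              FALSE    IG has cycles; the attractor c…
```

Strengthening self-regulation dissolves the cycles: at `d = -1` the system
becomes non-hyperbolic and the cycles vanish, and for `d < -1` all 32
communities are admissible and the invasion graph equals that of the
decoupled diagonal system — an acyclic subset-order graph:

```r
rpsls_d_sweep(c(-0.5, -1, -1.5))
#> # A tibble: 3 × 7
#>       d n_admissible has_cycle n_cycles hyperbolic frondose matches_symmetric_part
#>   <dbl>        <int> <lgl>        <int> <lgl>      <lgl>    <lgl>
#> 1  -0.5           12 TRUE            13 TRUE       FALSE    NA
#> 2  -1             12 FALSE            0 FALSE      FALSE    NA
#> 3  -1.5           32 FALSE            0 TRUE       TRUE     TRUE
```

VL stability of `A` itself is certified in one optimizer start:

```r
glance(detect_vl(A, seed = 1))
#> # A tibble: 1 × 5
#>   verdict   certified_objective n_starts_used     threshold method
#>   <chr>                   <dbl>         <int>         <dbl> <chr>
#> 1 vl_stable              -0.111             1 -0.0000000001 multistart
```

`autoplot()` methods draw trajectories, invasion graphs (cycle edges in red),
and experiment tables; `write_ig()` exports DOT/GraphML; a thin command-line
wrapper lives at `inst/scripts/lvcycles-cli.R`.

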