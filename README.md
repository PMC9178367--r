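# glvmeta

Generalized Lotka-Volterra (GLV) metacommunities under high dispersal:
simulation, coherent-limit reduction, and moment theory.

## The problem

How does spatial heterogeneity in species interactions affect global
species richness in large, well-connected landscapes? `glvmeta` models a
landscape as a network of patches, each occupied by a *habitat* — an
N×N random interaction matrix with connectance *c* and nonzero entries
drawn from N(μ, σ²) — coupled by diffusive dispersal:

    dφ_ip/dt = r_i φ_ip (1 − φ_ip/K_i) + φ_ip Σ_j A^(p)_ij φ_jp
               + (D_i/h²) Σ_{q~p} (φ_iq − φ_ip)

In the random-matrix (May) framework, σ√(cN) is the complexity that
limits how many species a single community can sustain. When dispersal
is high, the species densities become *spatially coherent* (nearly equal
across patches) and the whole metacommunity reduces to a single
well-mixed GLV system governed by the patch-averaged effective matrix
Ā. Averaging across G heterogeneous habitats shrinks the entry spread —
for independent habitats

    μ̄ = cμ,   σ̄² = (c/G)(σ² + μ²(1 − c)),

with analogous closed forms for equicorrelated habitats,
σ̄² = (σ²/G)(1 + (G−1)ρ), and for nearest-neighbor-correlated chains.
Lower effective complexity σ̄√(cN) means more coexisting species, so
heterogeneity raises global richness — up to complete coexistence of the
whole pool when habitats are independent and numerous.

The package provides, for each piece: random-ensemble generators with
controlled cross-habitat correlation (`sample_ensemble`), the spatial
simulator with coherence and extinction diagnostics
(`integrate_to_equilibrium`, `find_coherent_dispersal`), the effective
reduction and its accuracy check (`effective_matrix`,
`simulate_effective`, `full_vs_effective_discrepancy`), the closed-form
moments (`moments_independent`, `variance_equicorrelated`,
`variance_nn_chain`), and reproducible experiment drivers
(`run_independent_sweep`, `run_habitat_sweep`, `run_nn_chain_sweep`,
`run_coherence_scan`).

## A worked example

```r
library(glvmeta)

params <- community_params(N = 50, c = 1, mu = 0,
                           sigma = sigma_for_complexity(1.25, 1, 50))
tbl <- run_independent_sweep(G_list = c(1, 4, 16), n_runs = 3,
                             params = params, seed = 1)
summarize_richness(tbl)[, c("G", "mean_richness", "mean_relative",
                            "mean_sigma_bar_emp", "mean_sigma_bar_theory")]
```

       G mean_richness mean_relative mean_sigma_bar_emp mean_sigma_bar_theory
    1  1      29.00000     0.5800000         0.17604484            0.17677670
    3  4      45.66667     0.9133333         0.08867639            0.08838835
    2 16      50.00000     1.0000000         0.04501478            0.04419417

A single habitat at complexity σ√(cN) = 1.25 sustains only ~58% of the
50-species pool. With 4 and then 16 independent habitats under coherent
(high) dispersal, the effective σ̄ falls as σ/√G and mean richness climbs
to complete coexistence. `sigma_bar_emp` is measured from the generated
effective matrix; `sigma_bar_theory` is the closed form.

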