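# thermoring

Analysis toolkit for hetero-oligomeric double-ring chaperonins (class II
chaperonins / thermosomes): subunit-interface energy decomposition of
double-octameric ring assemblies, assembly construction by rigid-body
superposition, steady-state ATPase kinetics with one or two classes of
ATP-binding sites, and a stochastic simulator of the neighbour-gated
allosteric ATPase cycle.

## The science

The archaeal thermosome of *Thermoplasma acidophilum* stacks two octameric
rings of alternating α and β subunits (α₈β₈). Three questions drive this
package:

**1. Which interfaces hold the assembly together?** Every subunit *s* in a
2×n ring assembly touches five topological neighbours: two side-by-side
(intraring) neighbours, its stacked (facing) partner in the other ring, and
the two *diagonal* neighbours — the intraring neighbours of the facing
partner. With a pairwise interface potential E, the package computes per
subunit

- the **global** energy `E(s | rest of assembly)`,
- the **separated** energy `E(s|left) + E(s|right) + E(s|facing)`, and
- the **diagonal** remainder `diagonal = global − separated`,

and aggregates them over snapshot trajectories into the conventional
decomposition table (intraring / interring columns, `NRG from subs`,
`NRG from seps`, `Difference`). The pairwise potential (soft-core
Lennard-Jones plus screened Coulomb with distance-dependent dielectric,
1.4 nm cutoff) is a documented stand-in for the docking-engine force field
used in published work; the decomposition's *bookkeeping identities*, not
absolute energies, are the reproducible quantities.

**2. How do the two subunit types split the ATPase work?** Steady-state
rates follow a one- or two-classes-of-sites Michaelis–Menten model,

v(S) = Σ_p sites_p · k_cat,p · S / (K_M,p + S),

fitted by bounded nonlinear least squares after blank correction. The
wild-type complex is biphasic (tight sites K_M1 ≈ 15 µM, weak sites
K_M2 ≈ 370 µM); single mutants and the all-α complex are monophasic.

**3. What does neighbour-gated allostery predict for mutants?** A ring of
typed subunits cycles apo → ATP-bound → post-hydrolysis → apo under the rule
that ATP must be bound to one subunit for its neighbour to progress (either
at product release — the rate-limiting step — or at hydrolysis). Gillespie
simulation plus an exact continuous-time Markov-chain oracle show that
binding-blocked mutants deadlock after at most n/2 hydrolyses (no steady
ATPase, as observed), while hydrolysis-blocked mutants cycle on the
unblocked subunit type only.

Synthetic-data generators (toy ring assemblies with controllable interface
gaps and thermal jitter; rate curves from the published parameter sets)
replace MD trajectories and wet-lab data for testing and exploration.

## Worked example

```r
library(thermoring)

# biphasic ATPase data from the published wild-type parameter set, 5% noise
data <- make_rate_data(kinetic_model_from_variant("WT"), noise_sd = 0.05, seed = 11)
fit  <- fit_kinetics(data, phases = 2)
tidy(fit)
#> # A tibble: 4 × 5
#>   term  phase estimate std_error unit
#>   <chr> <int>    <dbl>     <dbl> <chr>
#> 1 K_M       1    11.4      2.60  uM
#> 2 K_M       2   314.      65.4   uM
#> 3 k_cat     1     1.81     0.234 mol ATP/(mol active sites)/min
#> 4 k_cat     2     3.43     0.183 mol ATP/(mol active sites)/min
```

The two Michaelis constants straddle the generating values (15 and 370 µM):
a single noisy 20-point curve pins the weak phase less precisely, which the
standard errors report. `autoplot(fit)` draws the data with the fitted
saturation curve.

```r
# neighbour-gated cycle of the β-hydrolysis-blocked mutant (D93Kβ analogue)
exact_cycle_flux(make_cycle_config("D93Kb", n_per_ring = 8))
#> # A tibble: 2 × 2
#>   type   flux
#>   <chr> <dbl>
#> 1 alpha 0.570
#> 2 beta  0
```

Hydrolysis flux (0.57 ATP per subunit per minute at the default rates) is
carried entirely by the α subunits, because the β subunits sit permanently
ATP-bound and keep their α neighbours' release gate open — the qualitative
pattern observed for this mutant.

```r
# interface-energy decomposition of a synthetic toy assembly
toy <- make_toy_assembly(n_per_ring = 8, seed = 1)
res <- aggregate_decomposition(toy$trajectory, toy$topology,
                               energy_model(cutoff = 10), sample_interval = 0.1)
res$table[, c("intraring", "interring", "nrg_from_subs", "nrg_from_seps", "difference")]
```

For the published aggregates themselves, `interface_identity_check(ta_interface_energies())`
verifies the decomposition identities on the reference table.

A thin command-line wrapper mirrors the main operations
(`thermoring generate | decompose | build-assembly | mutate | fit-kinetics |
simulate-cycle`); see `?thermoring_cli`.

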