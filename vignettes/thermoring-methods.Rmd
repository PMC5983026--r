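---
title: "Models and methods behind thermoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoring)
```

This vignette documents the models implemented in `thermoring`, the
assumptions behind them, the parameters a user may want to change, and the
limitations to keep in mind when interpreting results. The system in mind
is the hetero-oligomeric class II chaperonin (thermosome) of
*Thermoplasma acidophilum* — two stacked octameric rings of alternating α
and β subunits — but every component is generic in the ring size and
composition.

## 1. Ring topology

A `ring_topology` describes a 2×n toroidal assembly. Each subunit has five
topological neighbours: two intraring neighbours (positions ±1 mod n in the
same ring), one facing partner in the other ring, and two diagonal
neighbours defined *topologically* as the intraring neighbours of the
facing partner — not by any distance cutoff. This matches the neighbour
enumeration used in interface-energy decompositions of double-ring
chaperonins (a subunit at position 2 contacts 1, 3, its stacked partner,
and the partner's two side neighbours).

Conventions:

* Positions are 0-based internally; printed labels and plots use 1-based
  labels. The TSV serialization is a machine format and stays 0-based.
* The facing assignment ("registration") defaults to identity — position p
  faces position p. Published interring energies for α–β assemblies split
  cleanly into α–α and β–β facing pairs, which is consistent with homotypic
  facing contacts under identity registration; the crystal-structure
  register is not otherwise documented, so identity is the default and
  geometric inference (`infer_registration()`, greedy nearest-centroid
  bipartite assignment with a deterministic lowest-index tie-break) is
  opt-in for real structures.
* Compositions are limited to two subunit types; 9-membered rings work
  (topology is generic in n ≥ 3) but three-type archaeal compositions are
  out of scope.

## 2. Structures, superposition, mutation

Snapshot trajectories are multi-model PDB files (one MODEL per snapshot),
read and written through `bio3d`. Internally all coordinates are in
nanometres; Ångström conversion happens at the PDB boundary, so round-trips
are exact to PDB precision (0.001 Å). Frame times come from a configurable
model-number→time scale (default 0.1 ns per model, the usual snapshot
spacing of the trajectories this pipeline consumes).

Superposition (`superpose_kabsch()`) pairs atoms by residue number and atom
name over backbone atoms (N, CA, C, O) only — robust to side-chain
differences between subunit types — and solves the least-squares rotation by
the SVD form of the Kabsch algorithm, with the determinant correction that
guarantees a proper rotation (never a reflection). Homo-oligomer
construction (`build_homo_assembly()`) copies a donor subunit onto every
position by backbone fit onto the original occupant; which subunit donates
is the caller's choice, as the position-wise backbone fit makes the result
insensitive to it up to the donor's internal geometry.

Point mutation (`apply_point_mutation()`) is deliberately idealized: atoms
shared by name between old and new side chain (walking outward from CB)
keep their coordinates; a larger target side chain is extended with
standard bond lengths and angles at trans (χ = 180°) torsions; a smaller
one truncates. There is **no rotamer repacking** — published workflows used
a dedicated side-chain packer here — so mutated side chains can clash with
their surroundings. This is acceptable for this package because the
interface potential is itself a stand-in (below) and the analyses that
matter are decomposition identities, not absolute energies. Cyclic side
chains (His, Phe, Tyr, Trp, Pro) are not constructible by chain extension
and raise an informative error; all mutations characterized for this system
(D→K/A/E, T→V/A) are covered.

## 3. The stand-in interface potential

Published interface energies for this system come from an empirical docking
force field whose parameterization is external to the analysis. To keep the
pipeline self-contained, `energy_model()` defines an explicit stand-in:

* soft-core Lennard-Jones: `4ε[(σ/r′)¹² − (σ/r′)⁶]` with Lorentz–Berthelot
  combining and `r′ = max(r, 0.8·σ)`, so overlapping atoms score finite;
* screened Coulomb with a distance-dependent dielectric ε(r) = 4r/nm,
  i.e. `138.935·q_a·q_b/(4r′²)` kJ/mol, with formal charges on charged
  side-chain key atoms (Asp/Glu carboxylate oxygens −0.5 e each, Lys NZ +1,
  Arg NH1/NH2 +0.5 each, His neutral) and on chain termini;
* truncation at 1.4 nm, mirroring the short-range cutoff of the simulations
  whose snapshots the pipeline consumes;
* united-atom behaviour when hydrogens are absent (their terms are simply
  missing), since crystal-structure snapshots lack them.

Default van der Waals parameters (σ in nm, ε in kJ/mol): C (0.34, 0.36),
N (0.325, 0.71), O (0.296, 0.88), S (0.356, 1.05), H (0.107, 0.06). These
are representative, configurable values; *any* self-consistent set supports
the decomposition identities, which is the point. **Absolute energies from
this model are not comparable to published force-field values** and the
package makes no such claim. The potential is strictly pairwise additive,
so a subunit's one-vs-rest energy equals the sum of its pair energies by
construction — asserted and tested, not assumed of the original engine.

## 4. The decomposition and its aggregation

For subunit *s*: `global` is the energy of *s* against the union of all
other subunits; `separated` is the sum of its two intraring and one facing
pair energies; `diagonal = global − separated` holds at machine precision
by construction and is the quantity of interest — the part of the interring
interaction the nearest interfaces miss.

`aggregate_decomposition()` reproduces the conventional summary-table
layout. Two different averaging populations coexist in that layout, and the
package follows the only convention under which the published homotypic
rows are internally consistent:

* interface columns (intraring, interring, inter-α, inter-β) average each
  *unordered interface* once, pooled over sampled frames;
* `nrg_from_subs` / `nrg_from_seps` average per *subunit* × frame.

Under this convention a uniform assembly satisfies
`nrg_from_seps = 2·intraring + interring` exactly, which the published
homotypic rows obey to printed rounding (β–β: 2·(−401) + (−123) = −925
exactly; one α-α row matches at −1050; another differs by 1 kJ/mol,
consistent with rounding of the printed means). The published tables do not
state whether their sd is across time, subunits or both; this package pools
interfaces (or subunits) and sampled frames and records the choice in the
output metadata. The default trajectory subsampling interval is 3 ns,
matching the cadence of published time profiles; it is configurable, and
tests use the raw frame spacing of their small synthetic trajectories.

## 5. Steady-state ATPase kinetics

The rate model is a sum of independent Michaelis–Menten terms, one per
class of sites: `v(S) = Σ_p sites_p·k_cat,p·S/(K_M,p + S)`, in per-complex
units with `k_cat` per active site per minute. The two-classes model is a
*non-interacting* sum — biphasic saturation is interpreted as two classes
of ATP-binding sites, and no interacting-sites model is specified for this
system. The default of 8 sites per phase reflects a hexadecamer whose two
classes each comprise one subunit type (for mutants the effective count is
an interpretation; since generator and fit share the convention, parameter
recovery is unaffected).

Blank correction subtracts the matched no-enzyme rate (spontaneous ATP
hydrolysis at assay temperature); negative corrected rates are kept but
flagged. Fitting is *unweighted* bounded nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`), as no weighting scheme is stated
for the published fits. Initialization is neutral and data-driven: K_M from
the concentration nearest half-maximal rate (split 0.1× / 10× for two
phases), k_cat from the maximal rate over the total site count; bounds keep
K_M in (0, 10·max S] and k_cat ≥ 0; phases are reordered post-fit so phase
1 is the tighter class; two-phase fits with Michaelis constants within a
factor 3 are flagged as weakly identifiable. On noiseless 20-point
log-spaced curves (1–2000 µM, bracketing both published K_M scales) the
fits recover the generating parameters to well beyond 4 significant
figures; with 5% proportional noise the tight-phase K_M is recovered with a
median error under 10% across 200 replicates, while individual noisy curves
can leave the weak phase poorly determined (the standard errors say so).

`linearity_check()` provides the maximal-rate-versus-enzyme-concentration
OLS diagnostic used to exclude mixtures of oligomeric states, and
`refolding_yield()` the percent-recovery convention for chaperonin-assisted
substrate refolding (100 × refolded/native activity).

## 6. The neighbour-gated ATPase cycle

Each subunit of a single ring is in one of three states — apo, ATP-bound,
post-hydrolysis — with transitions bind (apo→atp, propensity
`k_bind·[ATP]`), hydrolyze (atp→post, `k_hyd` per type) and release
(post→apo, `k_rel`). The allosteric rule is that ATP must be bound to a
subunit for its intraring neighbour to progress, in one of two places:

* `release_gated` (default): release requires ≥1 intraring neighbour
  ATP-bound; hydrolysis is free. Chosen as default because product release
  is the rate-limiting step of the cycle in this system.
* `hydrolysis_gated`: hydrolysis requires ≥1 intraring neighbour ATP-bound;
  release is free — the alternative placement of the same block.

The "adjacent" requirement is satisfied by either neighbour (the published
scheme does not orient it); only the two intraring neighbours gate, since
the proposed mechanism is intraring and any interring contribution is an
open question. Binding-blocked types never leave apo; hydrolysis-blocked
types never leave atp. Mutant templates map the characterized variants onto
these flags (`make_cycle_config()`).

Simulation is exact Gillespie SSA, seeded and reproducible; a deadlock
(zero total propensity) halts the run and is a legitimate outcome. The
steady-state flux is estimated from the second half of the run, in
hydrolyses per subunit (of each type) per minute.

`exact_cycle_flux()` is the verification oracle: it enumerates the states
reachable from all-apo (3ⁿ bound, n ≤ 8), finds the recurrent classes
(strongly connected components without outgoing edges, via `igraph`),
solves each stationary distribution sparsely (`Matrix`), weights multiple
classes by their absorption probabilities from the start state, and sums
exact hydrolysis fluxes per type.

**A structural property worth knowing:** under strict release gating the
all-post state (every subunit product-bound) is absorbing, and it is
reachable for any fully active ring — nothing stops every subunit
hydrolyzing before anyone releases. The exact long-run flux of a
release-gated wild-type ring is therefore zero: the ring works for a while
and then traps itself with all sites product-bound. (Transiently this even
echoes the observation that the product-bound species dominates at steady
state, but as a steady-state cycling model it is degenerate.) The package
therefore analyses *mutant* activity patterns in the default release-gated
mode — where binding-blocked rings deadlock after ≤ n/2 hydrolyses and
hydrolysis-blocked rings cycle on the unblocked type only, matching the
observed pattern — and evaluates *sustained wild-type* flux, per-type
ordering and the SSA-versus-CTMC comparison in the hydrolysis-gated mode,
where the wild-type ring is irreducible and cycles indefinitely. At the
default rates the exact n = 4 wild-type fluxes are 0.353 (α) and 0.575 (β)
hydrolyses/subunit/min, and the SSA agrees within sampling error.

Default rates are *not* fits to measured turnover (explicitly out of
scope); they are plausible round numbers that preserve the published
qualitative ordering: `k_bind = 0.06 /µM/min` at 100 µM ATP (binding fast,
non-limiting), `k_hyd = 1.7 /min` (α) and `3.2 /min` (β) — the β subunit is
the more active hydrolase — and `k_rel = 1 /min` (release rate-limiting).

## 7. Synthetic data: what it emulates and what it does not

`make_toy_assembly()` builds two stacked rings of compact pseudo-subunits
(default 12 atoms: small enough that brute-force all-pairs oracles stay
exhaustive and tests fast). The three per-interface-class nearest-atom gap
targets (intraring, facing, diagonal) are hit *exactly* by placing one
dedicated contact atom on the axis towards each neighbour: a plain
stacked-ring layout cannot satisfy three independent gap targets through
ring radius and separation alone (the diagonal centre distance is
determined by the other two), so contact-atom placement is the geometric
solver. Remaining atoms form a core blob shared across subunits in their
local frames, which makes all 2n subunits geometrically equivalent under
the assembly's dihedral symmetry — single-frame toys have 2n equal global
energies to numerical precision, a useful symmetry check. Frames beyond the
first add seeded Gaussian jitter, emulating thermal snapshot scatter and
nothing else.

What the toys do **not** emulate: real protein packing, correlated
(non-isotropic) thermal motion, side-chain chemistry at interfaces, or any
MD physics. Passing decomposition tests on toys therefore demonstrates the
*bookkeeping* — oracle agreement, exact identities, invariances, correct
interface classification — not that the stand-in potential ranks real
assemblies correctly.

`make_rate_data()` draws rate curves from a kinetic model with proportional
Gaussian noise and an optional linear spontaneous-hydrolysis blank,
reported alongside so blank correction can remove it exactly. The default
concentration grid is 20 log-spaced points, 1–2000 µM. All generators are
deterministic under a fixed seed, byte-for-byte through the file-writing
path.

## 8. Numerical choices and problem sizes

* Soft-core floor 0.8·σ: keeps jittered toys finite without affecting
  ordinary distances.
* Registration inference tie-break: ascending distance, then lowest ring-0
  position, then lowest ring-1 position — deterministic.
* Subsampling picks the nearest frame to each target time and rejects
  intervals finer than the frame spacing.
* Exact cycle analysis is capped at n = 8 (3⁸ = 6561 states); the test and
  acceptance workloads use n = 8 rings for mutant (small reachable sets)
  and n = 4 for wild-type exact-versus-SSA comparisons, 10 seeds × 400 min
  SSA runs, 2×4 toys with 8-atom subunits for energy oracles, and 200
  noisy-replicate fits — sizes chosen so the full suite runs in well under
  a minute per module.
* The tight-phase/weak-phase convention (phase 1 = smaller K_M) is enforced
  after fitting, so reported phase order never depends on optimizer
  internals.

## 9. Known limitations

* The interface potential is a stand-in; absolute energies, and therefore
  quantitative assembly-propensity rankings of real structures, are outside
  its remit.
* Idealized mutation does not repack side chains and cannot build cyclic
  side chains.
* The cycle model is single-ring and intraring-gated; interring (negative
  cooperativity) coupling and substrate folding states are not modelled,
  and simulator rates are not calibrated to measured turnover numbers.
* The two-phase kinetic model assumes independent site classes; genuinely
  interacting-site (cooperative/Hill) behaviour is out of scope.
* Release-gated rings of fully active subunits eventually self-trap in the
  all-product state (section 6); treat release-gated steady-state fluxes of
  fully active rings accordingly.
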