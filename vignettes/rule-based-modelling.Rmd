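---
title: "Rule-based modelling of signalling networks with siterules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based modelling of signalling networks with siterules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siterules)
```

## The modelling problem

Signalling proteins are multistate molecules: a protein with a handful of
phosphosites and binding surfaces can occupy combinatorially many chemical
states, and an ODE model must enumerate every one of them as a separate
variable. Rule-based modelling avoids that enumeration by describing
molecules as *agents* with named *sites* that carry internal states (e.g.
`u`/`p` phosphorylation) and binding states, and by describing chemistry as
*rules*: pattern-conditioned graph rewrites. A rule mentions only the
conditions that matter for the transformation; every concrete reaction
consistent with the pattern is implied. `siterules` implements this
formalism end to end: site-graph data structures with canonical species
identifiers, pattern embedding and rewriting, generation of the explicit
mass-action reaction network reachable from a seed mixture, the reverse
translation (condensing a reaction list into decontextualised rules),
stochastic and deterministic simulation with timed perturbations, and
mixture snapshots for dissecting which molecular species actually arise.

The package ships a worked model of the DARPP-32 (PPP1R1B) phosphorylation
network, the classic integrator of dopamine (cAMP--PKA) and glutamate
(Ca^2+^--PP2B) signals in striatal neurons, reconstructed in this rule
notation.

## Model specification

### Agents, patterns, species

An agent signature declares an agent type with its sites and allowed
internal states. Complexes and patterns are written in a restricted
Kappa-like text syntax:

```{r}
sigs <- signature_set(
  agent_signature("D", c("t34", "t75", "s137", "b"),
                  list(t34 = c("u", "p"), t75 = c("u", "p"),
                       s137 = c("u", "p"))),
  agent_signature("C", c("r", "sub")))
parse_complex("C(r,sub!1),D(t34~u,b!1)")
```

Within an agent's parentheses, `site` alone means the site is free,
`site~u` adds an internal-state condition, `site!1` a bond (labels pair the
two endpoints), `site!_` "bound to something", `site!C.sub` "bound to a
C agent through its sub site", and `site?` leaves the binding unspecified.
A site not mentioned is wholly unspecified — that omission is what makes a
pattern *decontextualised*. A *molecular species* is the opposite extreme:
a connected complex with every site's state and occupancy spelled out.

The grammar of the model file format (one declaration per line, `#`
comments) is:

```
agent_decl = "%agent:" name "(" [ site { "," site } ] ")" ;
site       = name { "~" state } ;
init_decl  = "%init:" number complex ;
obs_decl   = "%obs:" "'" name "'" [ "species" ] pattern { "|" pattern } ;
mod_decl   = "%mod:" time ( "add" number complex | "set" "'" id "'" number ) ;
rule_decl  = "'" name "'" pattern "->" pattern "@" number [ "{" id "}" ] ;
```

This is a documented subset of the Kappa language family; it is not claimed
byte-compatible with any KaSim release (dialect details differ between
released versions, so the package defines its own grammar and provides a
reader and writer for it).

### Canonical species identifiers

Counting species ("how many variants of half-active PP2B exist?") needs an
identifier that is invariant under the arbitrary order in which agents are
listed. `canonical_species()` computes one by individualization--refinement:
iterative neighbourhood refinement assigns structural classes to agents;
the search individualizes one agent of the minimal class, re-refines, and
recurses; the canonical id is the lexicographically minimal serialization
over the search leaves. One choice of this kind collapses the symmetry of,
say, a palindromic polymer, so the search stays linear for molecular
complexes of the size this package targets (≤ ~10 agents); a guard aborts
at 10,000 leaves rather than mis-canonicalise a pathological graph.
Functionally identical sites are *uniquely named* (`ca1`..`ca4` on PP2B),
so symmetric placements materialise as distinct species — the convention
that produces six variants of doubly-Ca-loaded PP2B.

### Rules and their validation

A rule has aligned left- and right-hand patterns; a `.` placeholder marks
agent creation or deletion. `validate_rule()` checks sites and state labels
against the signatures, bond-label pairing, name preservation across the
alignment, and *molecularity*: a rule that would bind two sites already
belonging to one connected component closes a ring and is flagged — the
engine's matcher assigns the components of a rule's left-hand side to
distinct complex instances, so ring-closing intramolecular binding is
outside its semantics (none of the DARPP-32 rules need it). A rule with
identical sides is accepted but flagged as a no-op.

### Rate semantics

A rule's rate constant is stochastic: events per second for a unary rule,
per second per reactant *combination* for higher arity. The propensity of a
generated reaction is `k` times the number of distinct reactant
combinations — `choose(n, 2)` = n(n−1)/2 for a homodimerisation — and no
automatic symmetry rescaling is applied to `k` (the convention of the Kappa
family; the BioNetGen family instead multiplies by the number of
indistinguishable product routes). When a rule's pattern embeds into a
reactant tuple in several ways that yield the same products, the generated
reaction's constant is the rule constant times that embedding multiplicity.

## From rules to reaction networks and back

### Network generation

`generate_network()` computes the fixed-point closure: starting from seed
species, every rule is applied to every combination of known species (one
instance per reactant copy; unordered over identical pattern components),
products are canonicalised and added, and the process repeats until no new
species appear. Closure is incremental — each round only enumerates
combinations touching species discovered in the previous round, with
per-(rule, species) embedding caches — and the result is independent of
rule and seed ordering. A configurable species cap (default 10,000) turns
runaway combinatorics (e.g. unbounded polymerisation) into an explicit
"network too large" error instead of a hang. Network-free simulation in the
style of NFsim is deliberately out of scope: the networks this package
targets are small enough to enumerate.

### Condensing reactions into rules

The reverse translation implements one criterion: reactions of the same
transformation type between the same reactants, differing only in agent
states (internal or binding) that do **not** change from reactants to
products, and carrying the same rate value, become a single rule with the
varying context removed. Concretely, each reaction is reduced to its
*transformation core* — the agents whose sites change, plus any reactant
component with no change at all (a catalyst, which fixes the reaction
arity). Unchanged agents merely riding along in a reactant complex (e.g.
the Ca^2+^ ions already sitting on a partially loaded PP2B) are context:
per site, context kept by the generalised rule is exactly what is identical
across every member of the group (free stays free, a bond to a dropped
spectator becomes a typed link, a bond whose partner varies becomes
bound-any, anything else is omitted). Rate equality is exact by default; a
relative tolerance can be supplied for floating-point imports.

Because dropping context can overgeneralise, every output is audited: the
produced rules are re-expanded over the input's species universe and must
regenerate exactly the input reaction multiset, rates included; a group
that fails the audit is demoted to fully contextual one-reaction rules. The
round trip `expand(condense(reactions)) == reactions` therefore holds by
construction, and is asserted in the test suite on hand-built and random
networks.

Species identified only by name (as in an SBML import) carry no site-graph
composition, so the criterion cannot see their states; condensation then
requires a declared composition map and otherwise fails naming the
unresolvable species.

### Combinatorial binding

When one ligand fills several uniquely named, functionally identical sites,
every placement must be its own rule. `expand_multisite_binding()` encodes
a `multisite_scheme()` — target, `n` sites, ligand, and ordered reversible
steps each binding a fixed number of ions with step-specific constants —
into one forward and one reverse rule per (occupancy at the start of the
step, site subset transacted), with occupancy explicit because the rates
are step-specific. The PP2B scheme (4 Ca^2+^ sites, two 2-ion steps) yields
6 + 6 rules per step = 24 rules and a species ladder of
`choose(4,0) + choose(4,2) + choose(4,4)` = 1 + 6 + 1 = 8 PP2B forms;
`count_intermediate_species(n, k)` is `choose(n, k)` by the unique-site
convention. Reverse rules unbind exactly the ion subsets that bind together
in a step, mirroring a two-step reversible ODE ladder
(inactive/half-active/active). If all step rates are set equal, the
condensation criterion can drop the occupancy context and the 24 rules
collapse to 12 — one bind and one unbind rule per site pair; they can never
collapse further, because rules that transact different (uniquely named)
site subsets differ in their transformation, not just their context.
Cooperative, occupancy-dependent rate modifiers beyond step constants are
out of scope.

## Simulation

Both backends run on the explicit network in copy-number units.

* **Stochastic**: the Gillespie direct method — per event two uniform
  variates choose the waiting time (exponential in the total propensity)
  and the channel. Timed perturbation events (`add_copies`, `set_rate`,
  `set_copies`) interrupt the jump clock at their trigger time, are applied
  exactly once (the interrupted waiting time is discarded, which is valid
  by memorylessness), and `set_rate` updates every reaction sharing the
  rate id before propensities are refreshed. Observables are recorded on a
  fixed `record_dt` grid, last value carried forward between jumps; values
  at an event time are the pre-event values. Snapshots of the whole mixture
  can be taken every *N*-th event (default 10,000 in the analysis helpers),
  with the final state always captured. An explicit seed is required; the
  same seed reproduces the trajectory bit for bit, and replicate *i* of
  `ssa_replicates()` uses `base_seed + i`.
* **Deterministic**: mass-action ODEs `dx/dt = N a(x)` built from the same
  combination-counting propensities and integrated with `deSolve::lsoda`
  (stiff-capable; defaults `rtol` 1e-6, `atol` 1e-9, `maxsteps` 1e5 per
  output interval — stimulus spike trains make these systems stiff).
  Events are applied as state/parameter discontinuities, restarting the
  integrator at each trigger time.

Unit conversion is the standard mass-action one: `convert_units()` maps a
deterministic constant of order 0/1/2 to `k N_A V` / `k` / `k / (N_A V)`,
and `concentration_to_copies()` rounds `c N_A V`. The reaction volume is a
required piece of context; the default `unit_context()` volume of 1e-15 L
(a femtolitre, a typical working volume for a neuronal compartment model)
is a documented assumption of this package, not a published constant.

## Observables, snapshots and censuses

A `pattern_observable()` counts, per recording point, either embeddings of
its pattern (*agent-instances*, the default — total cAMP then includes the
copies bound to the PKA holoenzyme) or copies of matching species
(*species-copies*). For imported ODE models whose species are opaque names,
`aggregate_by_name()` reconstructs observables by substring matching with
exclusions, keeping the matched-name list for audit; a pattern matching
nothing warns rather than errors.

The *sampled species census* is the union over snapshots of species present
— nondecreasing in simulation length and generally smaller than the
exhaustive reachable set from `generate_network()`, which is available for
comparison. `species_containing()` isolates the sampled species containing
a given agent together with per-species agent counts (active PP2B carries
4 Ca), the query used to dissect which species a summed observable actually
contains.

`compare_trajectories()` aligns two trajectories on a common grid and
reports the maximum mean difference scaled by the pooled replicate standard
deviation plus the area between curves. These metrics are this package's
own summary of agreement; they support plotting and inspection and are not
used as hard pass/fail criteria for full-model comparisons.

## The DARPP-32 model

`build_model()` assembles the reconstruction: DARPP-32 with phosphosites
Thr34, Thr75 and Ser137 (Ser102 and nuclear signalling are excluded);
kinases PKA (catalytic subunit C, holoenzyme R2C2), CDK5 and CK1;
phosphatases PP2B (calcineurin), PP2A (activated either by PKA
phosphorylation or by Ca^2+^) and PP2C; second messengers cAMP and Ca^2+^;
PDE as the cAMP sink. Rules are grouped into eight components mirroring the
mechanism inventory of the source reaction system (DARPP-32
phosphorylation; CK1, PDE and PP2A phosphorylation; PP2B activation; PKA
activation; cAMP & Ca^2+^ degradation; PP2A activation by Ca^2+^). Key
encodings:

* **PP2B activation** is exactly `expand_multisite_binding()` on 4 Ca sites
  in two 2-ion steps — 24 rules, 4 rate constants, asserted in the tests.
* **PKA activation** uses the same combinatorial scheme for 4 cAMP sites on
  R2C2 plus release/rebind of the two catalytic subunits. The published
  component description does not fix the cAMP step decomposition, so a
  2+2-ion structure symmetric to PP2B was chosen once; the resulting rule
  count (28) is reported by `darpp32_component_counts()`, not asserted.
  Substrate-bound C cannot rebind the holoenzyme and holoenzyme-bound C
  cannot bind substrates, which keeps complexes at most trimeric.
* **Mutations**: Ser137Ala zeroes the single CK1 catalytic rule on Ser137;
  constSer137 zeroes the single PP2C catalytic rule. Each corresponds to
  zeroing four constants in the fully expanded reaction network but one
  constant here — the asymmetry that motivates the rule notation.
* **Binding variants**: `oBS` gives DARPP-32 one partner site (competitive
  binding — one interactor at a time); `tBS` gives it three independent
  sites, one per phosphosite's enzymes (noncompetitive). Both variants have
  the same number of rules, because concurrently bound interactors do not
  influence each other.
* **Initial state**: eight species with nonzero copies (DARPP-32, R2C2 with
  both C subunits bound, PP2B, PP2A, PP2C, CK1, CDK5, PDE); cAMP and Ca^2+^
  start at zero and enter through the stimulus events.

Two ingredients of the source parameterisation are not published with the
network description and are therefore shipped as documented synthetic
defaults, clearly labelled as such:

* **Rates** (`inst/extdata/darpp32_params_synthetic.tsv`): order-of-
  magnitude stochastic constants for a 1e-15 L volume — association
  ~1e6 /M/s, weak micromolar dissociation (consistent with the network's
  characterisation as low-affinity), catalysis 1–10 /s, and initial copies
  at 0.5–10 µM with DARPP-32 in excess of its interactors. Any table with
  the same rate ids can be substituted, e.g. one derived from the published
  machine-readable model.
* **Stimulus protocol** (`darpp32_stimulus()`): 21 timed events — one cAMP
  pulse followed by a train of 20 Ca^2+^ spikes at 10 s intervals — the
  published event count with synthetic timings and amplitudes. The engine
  executes any `event_schedule()`.

Consequently the packaged model reproduces the *structure* of the published
translation (component inventory, the 24-rule PP2B block, single-rule
mutations, equal oBS/tBS rule counts, 8 initial copy numbers, 21 stimuli)
while its trajectories are those of the synthetic parameterisation, not of
the fitted original. Replicating the published trajectory comparison and
the full-model censuses (91 competitive / 137 noncompetitive sampled
species; 24 Ca-containing species against 13 name-matched ODE variables)
requires importing the published SBML model, for which `import_sbml()` and
the condensation pipeline are provided.

## What the fixtures emulate — and what they do not

The toy generators are the test substrate; golden files are reserved for
format round-trips, because stochastic outputs are only stable under a
fixed seed.

* `decay` (first-order closed form), `birth_death` (M/M/∞; stationary law
  Poisson(b/d), so mean = variance), `dimerisation` (mass-action quadratic
  fixed point) pin both backends to analytic results.
* `multisite` reproduces the PP2B encoding at its defaults.
* `phospho_spectator` is the minimal condensation case: two reactions
  differing only in a spectator phosphosite.
* `make_random_rule_system()` draws finite-closure systems (binding rules
  along a random forest over agent types plus reversible state flips) for
  property tests against brute-force oracles — an all-injections matcher
  and a breadth-first closure that share no code with the engine's
  backtracking matcher or incremental closure.

These fixtures exercise the engine's semantics exhaustively at small size;
they do not emulate the copy-number regimes, rate heterogeneity or
event-driven stiffness of real signalling data. Passing them shows the
machinery is correct, not that the synthetic DARPP-32 parameterisation is
biologically calibrated.

## Numerical choices and problem sizes

* SSA grid recording uses last-value-carried-forward; event times interrupt
  the clock exactly once regardless of the grid.
* ODE tolerances default to `rtol` 1e-6 / `atol` 1e-9. Full-model runs in
  the test suite use `atol` 1e-6: with copy numbers in the thousands, a
  1e-9 absolute floor forces the integrator to resolve sub-molecule detail
  and roughly quadruples runtime for no usable precision.
* Test problem sizes are chosen to keep the default suite desk-scale:
  closure oracles run on 50 seeded systems of 2–4 agent types; Monte-Carlo
  checks use 120–200 replicates and 3-standard-error bands; the full
  DARPP-32 checks run the competitive network (124 species, 402 reactions),
  a 150 s deterministic pre-stimulus phase, a 60 s Ca^2+^-driven phase, and
  a 1.5 s stochastic census at one-tenth copy numbers.
* Condensation compares rates exactly by default (shared constants are the
  same parameter); imports with floating-point noise should set
  `rate_tol`.

## Known limitations

* Network-based only: systems whose reachable species set explodes (long
  polymers, unrestricted multivalent scaffolds) hit the species cap by
  design.
* No intramolecular binding (ring closure); such rules are flagged at
  validation.
* No tau-leaping, hybrid or spatial simulation; no BNG-style automatic
  symmetry rate scaling (a deliberate semantic choice, documented above).
* SBML support covers the mass-action subset (irreversible reactions whose
  kinetic law is a rate symbol times the reactant species, optionally times
  the compartment) plus time-triggered events; anything richer is rejected
  by name rather than silently approximated.
* The DARPP-32 rates and stimulus amplitudes are synthetic placeholders;
  structural counts are faithful, trajectories are illustrative.
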