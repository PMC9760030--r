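# siterules

Rule-based (Kappa-style) modelling of molecular signalling networks in R.

Signalling proteins are multistate molecules: a protein with a few
phosphosites and binding surfaces occupies combinatorially many chemical
states, and an equation-based model must enumerate every one of them as a
separate variable. `siterules` represents molecules instead as **agents**
with named **sites** carrying internal states (`u`/`p`) and binding states,
and chemistry as **rules** — pattern-conditioned graph rewrites
`lhs -> rhs @ k` whose left-hand side mentions only the conditions that
matter. The package is a complete engine for this formalism:

* site-graph complexes with canonical species identifiers
  (individualization–refinement), pattern embedding and rewriting;
* generation of the explicit mass-action reaction network reachable from a
  seed mixture (`generate_network()`), with a species cap guarding against
  combinatorial explosion;
* the reverse translation (`condense_reactions()`): reactions of the same
  type between the same reactants, differing only in agent states that do
  not change and sharing one rate value, collapse into a single
  decontextualised rule — audited by re-expansion so that
  `expand(condense(reactions))` always equals the input;
* combinatorial multisite binding (`expand_multisite_binding()`): one
  ligand filling *n* uniquely named sites in reversible steps, the encoding
  needed for PP2B (4 Ca²⁺) and the PKA holoenzyme (4 cAMP);
* stochastic simulation (Gillespie direct method) and deterministic
  mass-action ODEs (`deSolve`), both with timed perturbation events
  (`add_copies`, `set_rate`), pattern observables, and event-indexed
  mixture snapshots for species censuses;
* a restricted Kappa-like model text format, a mass-action-subset SBML
  reader/writer, and a reconstructed model of the DARPP-32 (PPP1R1B)
  phosphorylation network — the striatal integrator of dopamine (cAMP–PKA)
  and glutamate (Ca²⁺–PP2B) signals — with in-silico Ser137 mutations and
  competitive/noncompetitive binding variants.

The propensity of a reaction is `k · (number of distinct reactant
combinations)` (`n(n−1)/2` for a homodimerisation), with no automatic
symmetry rescaling of `k` — the Kappa convention. The methods vignette
(`vignettes/rule-based-modelling.Rmd`) documents the semantics, the
condensation criterion, all defaults, and the package's known limitations.

## Worked example: the PP2B activation ladder

Calcineurin (PP2B) activates by binding four Ca²⁺ ions on four uniquely
named, functionally identical sites, two ions per reversible step. Because
sites are uniquely named, every placement is its own rule and every
occupancy its own species:

```r
library(siterules)

sch <- multisite_scheme("PP2B", 4, "Ca",
  list(list(ions = 2, k_on = 2.8e-3, k_off = 1),
       list(ions = 2, k_on = 2.8e-3, k_off = 0.5)),
  site_prefix = "ca",
  activity = c("0" = "inactive", "2" = "halfactive", "4" = "active"))

rules <- expand_multisite_binding(sch)
length(rules)
#> [1] 24
format_rule(rules[[1]])
#> 'PP2B_bind1_ca1_ca2' PP2B(ca1,ca2,ca3,ca4),Ca(t),Ca(t) ->
#>   PP2B(ca1!1,ca2!2,ca3,ca4),Ca(t!1),Ca(t!2) @ 0.0028

net <- generate_network(rules, list("PP2B(ca1,ca2,ca3,ca4)", "Ca(t)"),
                        scheme_signatures(sch))
net
#> Reaction network: 9 species, 24 reactions
count_intermediate_species(4, 2)   # half-active variants
#> [1] 6
```

The 24 rules reach 8 PP2B-containing species (1 inactive + 6 half-active +
1 active, plus free Ca²⁺ = 9 network species). Condensing the generated
reactions back shows which context is load-bearing: the two steps share an
on-rate here, so the 12 forward reactions regroup into 6 occupancy-free
binding rules, while the step-specific off-rates keep all 12 reverse rules
apart:

```r
condense_reactions(net)$report
#>         component reactions rules unique_rates
#> 1 PP2B activation        24    18            3
```

A stochastic run tracks the activity classes directly as pattern
observables:

```r
tr <- ssa_run(net, c("PP2B(ca1,ca2,ca3,ca4)" = 602, "Ca(t)" = 2408),
              t_end = 20, record_dt = 5, seed = 1,
              observables = scheme_observables(sch))
round(cbind(time = tr$time, tr$values))
#>      time PP2B_inactive PP2B_halfactive PP2B_active
#> [1,]    0           602               0           0
#> [2,]    5             0              72         530
#> [3,]   10             0              65         537
#> [4,]   15             0              67         535
#> [5,]   20             0              64         538
```

At 1 µM PP2B and 4 µM Ca²⁺ (femtolitre volume) the ladder saturates within
seconds; the six half-active placements together carry ~65 copies at
steady state.

## The DARPP-32 model

```r
m   <- build_model(model_variant("wild", "oBS"))     # competitive binding
net <- model_network(m)                              # 124 species, 402 reactions
tr  <- ode_run(net, m$init, t_end = 600, events = m$events,
               observables = m$observables, atol = 1e-6)
```

`build_model()` assembles eight rule components (DARPP-32 phosphorylation;
CK1, PDE and PP2A phosphorylation; PP2B and PKA activation; cAMP & Ca²⁺
degradation; PP2A activation by Ca²⁺), eight nonzero initial copy numbers,
and a 21-event stimulus protocol (one cAMP pulse, twenty Ca²⁺ spikes).
Mutations are one zeroed rule each: `ser137ala` silences the CK1 catalytic
rule on Ser137, `constser137` the PP2C one. Rate values are a clearly
labelled synthetic table (`inst/extdata/darpp32_params_synthetic.tsv`) —
the published network's fitted constants are not printed with it — so the
packaged model reproduces the structure of the translation exactly and its
dynamics illustratively; `import_sbml()` can substitute the published
parameterisation where available.

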