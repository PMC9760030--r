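Package: siterules
Title: Rule-Based Site-Graph Modelling and Simulation of Signalling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based (Kappa-style) modelling engine for molecular
    signalling networks. Molecules are agents with named sites carrying
    internal and binding states; reactions are expressed as
    pattern-conditioned graph-rewriting rules. The package generates
    explicit mass-action reaction networks from rule sets, condenses
    reaction lists back into decontextualised rules, expands
    combinatorial multisite-binding schemes (one ligand on several
    uniquely named sites), and simulates networks stochastically
    (Gillespie direct method) or deterministically (mass-action ODEs)
    with timed perturbation events, pattern observables and mixture
    snapshots. Ships a reconstructed rule-based model of the DARPP-32
    phosphorylation network, a restricted Kappa-like text format, and a
    mass-action-subset SBML reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
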