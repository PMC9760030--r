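test_that("a written network round-trips through SBML import", {
  m <- make_toy("dimerisation")
  net <- model_network(m)
  tmp <- tempfile(fileext = ".xml")
  ev <- event_schedule(list(event_add_copies(5, "A(x)", 10),
                            event_set_rate(2, "kon", 0)))
  map <- write_sbml(net, m$init, tmp, events = ev)
  imp <- import_sbml(tmp, convert = FALSE)
  expect_length(imp$network$reactions, 2L)
  expect_equal(nrow(imp$species), 3L)
  # rate constants and initial amounts survive exactly
  want_k <- sort(vapply(net$reactions, `[[`, numeric(1), "rate"))
  got_k <- sort(vapply(imp$network$reactions, `[[`, numeric(1), "rate"))
  expect_identical(got_k, want_k)
  sid_A <- map$sbml_id[map$species == "A(x)"]
  expect_equal(imp$species$initial_amount[imp$species$id == sid_A],
               unname(m$init[["A(x)"]]))
  # events: the copy assignment and the parameter assignment both arrive
  acts <- vapply(imp$events$events, `[[`, character(1), "action")
  expect_setequal(acts, c("set_copies", "set_rate"))
  expect_equal(imp$events$events[[1]]$time, 2)
})

test_that("reactant stoichiometry is encoded in the kinetic law", {
  sch <- pp2b_scheme_fixture()
  net <- pp2b_network_fixture()
  tmp <- tempfile(fileext = ".xml")
  init <- c("PP2B(ca1,ca2,ca3,ca4)" = 100, "Ca(t)" = 500)
  write_sbml(net, init, tmp)
  imp <- import_sbml(tmp, convert = FALSE)
  expect_length(imp$network$reactions, 24L)
  # the two-ion binding reactions consume Ca with stoichiometry 2
  st <- vapply(imp$network$reactions, function(rx) max(rx$reactants), numeric(1))
  expect_equal(sum(st == 2), 12)
})

test_that("non-mass-action kinetic laws are rejected by reaction id", {
  tmp <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mm"><listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S" compartment="cell" initialAmount="100"/>',
    '<species id="P" compartment="cell" initialAmount="0"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="Vmax" value="1"/><parameter id="Km" value="5"/></listOfParameters>',
    '<listOfReactions><reaction id="mm_reaction" reversible="false">',
    '<listOfReactants><speciesReference species="S"/></listOfReactants>',
    '<listOfProducts><speciesReference species="P"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><divide/><apply><times/><ci>Vmax</ci><ci>S</ci></apply>',
    '<apply><plus/><ci>Km</ci><ci>S</ci></apply></apply>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>'), tmp)
  expect_error(import_sbml(tmp), "mm_reaction")
  expect_error(import_sbml(tempfile()), "unparsable")
})

test_that("deterministic units convert on import when requested", {
  # hand-written file in concentration units with a 1e-15 L compartment
  tmp <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="conv"><listOfCompartments><compartment id="cell" size="1e-15"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="cell" initialConcentration="1e-6"/>',
    '<species id="B" compartment="cell" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfParameters><parameter id="kon" value="1e6"/></listOfParameters>',
    '<listOfReactions><reaction id="bind" reversible="false">',
    '<listOfReactants><speciesReference species="A"/><speciesReference species="B"/></listOfReactants>',
    '<listOfProducts/>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>kon</ci><ci>A</ci><ci>B</ci></apply>',
    '</math></kineticLaw></reaction></listOfReactions></model></sbml>'), tmp)
  imp <- import_sbml(tmp, convert = TRUE)
  nav <- 6.02214076e23 * 1e-15
  expect_equal(imp$network$reactions[[1]]$rate, 1e6 / nav)
  expect_equal(imp$species$initial_amount[imp$species$id == "A"], 602)
})

test_that("imported networks simulate and condense with a composition map", {
  m <- make_toy("dimerisation")
  net <- model_network(m)
  tmp <- tempfile(fileext = ".xml")
  map <- write_sbml(net, m$init, tmp)
  imp <- import_sbml(tmp, convert = FALSE)
  # ODE on the imported (name-only) network matches the source network
  init <- stats::setNames(imp$species$initial_amount, imp$species$id)
  tr_imp <- ode_run(imp$network, init, t_end = 50, record_dt = 10)
  tr_src <- ode_run(net, m$init, t_end = 50, record_dt = 10)
  ab_src <- grep("!1", colnames(tr_src$values), value = TRUE)
  ab_imp <- map$sbml_id[map$species == ab_src]
  expect_equal(unname(tr_imp$values[, ab_imp]),
               unname(tr_src$values[, ab_src]), tolerance = 1e-8)
  # condensation needs compositions: supplying them recovers the 2 rules
  registry <- stats::setNames(
    lapply(map$species, function(s) parse_complex(s, species = TRUE)),
    map$sbml_id)
  cc <- condense_reactions(imp$network$reactions, registry)
  expect_length(cc$rules, 2L)
  # without the composition map the failure names the species
  expect_error(condense_reactions(imp$network$reactions,
                                  imp$network$species), "s1")
})
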