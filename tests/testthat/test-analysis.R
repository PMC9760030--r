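test_that("snapshots respect the period, capture the final state and conserve totals", {
  m <- make_toy("dimerisation", A0 = 50, B0 = 30)
  net <- model_network(m)
  tr <- ssa_run(net, m$init, t_end = 5, record_dt = 1, seed = 8,
                snapshot_period = 1L)
  snaps <- tr$snapshots
  # one snapshot per event plus the final capture
  expect_length(snaps, tr$n_ssa_events + 1L)
  expect_true(isTRUE(snaps[[length(snaps)]]$final))
  ab <- grep("!1", names(net$species), value = TRUE)
  for (s in snaps) {
    gety <- function(id) if (id %in% names(s$counts)) s$counts[[id]] else 0
    expect_equal(gety("B(y)") + gety(ab), 30)
    expect_equal(gety("A(x)") + gety(ab), 50)
  }
  # period > 1: close to n_events / period snapshots
  tr2 <- ssa_run(net, m$init, t_end = 5, record_dt = 1, seed = 8,
                 snapshot_period = 10L)
  expect_length(tr2$snapshots, tr2$n_ssa_events %/% 10L + 1L)
})

test_that("species_containing isolates sampled species with agent counts", {
  sigs <- ab_signatures()
  net <- generate_network(ab_rules(), list("A(x)", "B(y)"), sigs)
  ab <- grep("!1", names(net$species), value = TRUE)
  snaps <- list(list(event_index = 1, time = 0.1,
                     counts = stats::setNames(c(3, 1), c("A(x)", ab))))
  cs <- species_containing(snaps, "B", net)
  expect_identical(cs$canonical_id, ab)
  expect_equal(cs$n_agent, 1)
  expect_error(species_containing(snaps, "Z", net), "unknown agent")
})

test_that("a stochastic PP2B run samples the bound-Ca species ladder", {
  net <- pp2b_network_fixture()
  init <- c("PP2B(ca1,ca2,ca3,ca4)" = 200, "Ca(t)" = 2000)
  tr <- ssa_run(net, init, t_end = 40, record_dt = 5, seed = 42,
                snapshot_period = 50L)
  cs <- species_containing(tr$snapshots, "Ca", net)
  bound <- cs[cs$canonical_id != "Ca(t)", ]
  # 6 half-active + 1 active bound forms, plus free Ca
  expect_length(bound$canonical_id, 7L)
  expect_identical(sort(unique(bound$n_agent)), c(2, 4))
  expect_true("Ca(t)" %in% cs$canonical_id)
  # total Ca (free + bound, weighted) is conserved in every snapshot
  for (s in tr$snapshots) {
    tot <- 0
    for (id in names(s$counts))
      tot <- tot + s$counts[[id]] *
        siterules:::count_agents(net$species[[id]], "Ca")
    expect_equal(tot, 2000)
  }
})

test_that("sampled species census is nondecreasing in simulation length", {
  net <- pp2b_network_fixture()
  init <- c("PP2B(ca1,ca2,ca3,ca4)" = 50, "Ca(t)" = 400)
  short <- ssa_run(net, init, t_end = 2, record_dt = 1, seed = 3,
                   snapshot_period = 20L)
  long <- ssa_run(net, init, t_end = 30, record_dt = 1, seed = 3,
                  snapshot_period = 20L)
  expect_true(all(census_species(short$snapshots) %in%
                  census_species(long$snapshots)))
})

test_that("replicate summaries compute pointwise mean and sd", {
  mk <- function(vals) structure(list(
    time = seq_along(vals) - 1,
    values = matrix(vals, ncol = 1, dimnames = list(NULL, "X"))),
    class = "sr_trajectory")
  sm <- summarize_replicates(list(mk(c(0, 0)), mk(c(2, 0))))
  expect_equal(unname(sm$values[1, "X"]), 1)
  expect_equal(unname(sm$sd[1, "X"]), sqrt(2))
  expect_equal(unname(sm$sd[2, "X"]), 0)
  expect_identical(sm$n_replicates, 2L)
  # identical replicates: zero sd everywhere
  sm2 <- summarize_replicates(list(mk(c(1, 5)), mk(c(1, 5))))
  expect_true(all(sm2$sd == 0))
  expect_error(summarize_replicates(list(mk(c(0, 0)),
    structure(list(time = c(0, 2), values = matrix(0, 2, 1,
      dimnames = list(NULL, "X"))), class = "sr_trajectory"))),
    "mismatched")
})

test_that("stationary birth-death snapshots satisfy the Poisson variance law", {
  m <- make_toy("birth_death", b = 10, d = 0.1, X0 = 100)
  net <- model_network(m)
  reps <- ssa_replicates(net, m$init, t_end = 60, record_dt = 10,
                         n_replicates = 120, base_seed = 404)
  finals <- vapply(reps, function(tr) tr$values[nrow(tr$values), 1], numeric(1))
  # variance/mean ratio near 1 for a Poisson stationary law
  expect_lt(abs(var(finals) / mean(finals) - 1), 0.5)
})

test_that("trajectory comparison reports zero self-divergence and exact areas", {
  mk <- function(time, vals, name = "X") structure(list(
    time = time, values = matrix(vals, ncol = 1,
                                 dimnames = list(NULL, name))),
    class = "sr_trajectory")
  a <- mk(0:10, rep(1, 11))
  self <- compare_trajectories(a, a)
  expect_equal(self$report$max_abs_diff, 0)
  expect_equal(self$report$area_between, 0)
  # constant 0 vs constant 1 over unit time: area 1
  z <- mk(seq(0, 1, 0.1), rep(0, 11))
  o <- mk(seq(0, 1, 0.1), rep(1, 11))
  cmpr <- compare_trajectories(z, o, pairing = c(X = "X"))
  expect_equal(cmpr$report$area_between, 1)
  # unpairable observables are listed
  b <- mk(0:10, rep(1, 11), name = "Y")
  cc <- compare_trajectories(a, b)
  expect_true(all(c("X", "Y") %in% cc$unpaired))
})

test_that("name aggregation selects by substring with exclusions", {
  nms <- c("CaA", "B", "Ca_pool", "PP2BinactiveCa2")
  ob <- aggregate_by_name("allCa", nms, patterns = "Ca",
                          exclusions = "inactive")
  expect_identical(ob$matched, c("CaA", "Ca_pool"))
  expect_warning(aggregate_by_name("none", nms, patterns = "zzz"),
                 "no species matched")
  ob2 <- aggregate_by_name("empty", nms, patterns = character(0))
  expect_length(ob2$matched, 0L)
})

test_that("observable counting modes order as instances >= species copies", {
  net <- pp2b_network_fixture()
  inst <- pattern_observable("ca_inst", "Ca()", mode = "agent-instances")
  spc <- pattern_observable("ca_sp", "Ca()", mode = "species-copies")
  wi <- siterules:::observable_weights(inst, net)
  ws <- siterules:::observable_weights(spc, net)
  expect_true(all(wi >= ws))
  expect_true(any(wi > ws))  # multi-Ca complexes count once per agent
})
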