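test_that("the model assembles its eight components with valid rules", {
  m <- darpp32_obs_fixture()
  counts <- darpp32_component_counts(m)
  expect_setequal(counts$component,
                  c("DARPP-32 phosphorylation", "CK1 phosphorylation",
                    "PDE phosphorylation", "PP2A phosphorylation",
                    "PP2B activation", "PKA activation",
                    "cAMP & Ca degradation", "PP2A activation by Ca"))
  # paper-derivable counts: the combinatorial PP2B component and the three
  # single-enzyme phosphorylation components, and the degradation block
  expect_equal(counts$rules[counts$component == "PP2B activation"], 24L)
  expect_equal(counts$unique_rates[counts$component == "PP2B activation"], 4L)
  for (cc in c("CK1 phosphorylation", "PDE phosphorylation",
               "PP2A phosphorylation"))
    expect_equal(counts$rules[counts$component == cc], 4L, info = cc)
  expect_equal(counts$rules[counts$component == "cAMP & Ca degradation"], 8L)
  viol <- unlist(lapply(m$rules, validate_rule, signatures = m$signatures))
  expect_length(viol, 0L)
})

test_that("initial state has eight nonzero copy numbers and 21 stimuli", {
  m <- darpp32_obs_fixture()
  expect_equal(sum(m$init > 0), 8)
  expect_length(m$events$events, 21L)
  # one cAMP pulse, then a train of 20 Ca spikes
  sp <- vapply(m$events$events, `[[`, character(1), "species")
  expect_equal(sum(sp == "cAMP(b)"), 1)
  expect_equal(sum(sp == "Ca(t)"), 20)
  times <- vapply(m$events$events, `[[`, numeric(1), "time")
  expect_true(all(diff(times) >= 0))
})

test_that("mutations zero the rate of exactly one rule", {
  wild <- darpp32_obs_fixture()
  for (mut in c("ser137ala", "constser137")) {
    mv <- build_model(model_variant(mut, "oBS"))
    expect_identical(vapply(mv$rules, function(r)
      siterules:::format_rule_side(r$lhs), character(1)),
      vapply(wild$rules, function(r)
        siterules:::format_rule_side(r$lhs), character(1)))
    dr <- which(vapply(seq_along(mv$rules), function(i)
      mv$rules[[i]]$rate != wild$rules[[i]]$rate, logical(1)))
    expect_length(dr, 1L)
    expect_equal(mv$rules[[dr]]$rate, 0)
    expect_identical(mv$rules[[dr]]$rate_id, mv$zeroed_rate_id)
  }
  # the two mutations hit the phosphorylation and dephosphorylation routes
  expect_identical(build_model(model_variant("ser137ala"))$zeroed_rate_id,
                   "ck1_d_cat")
  expect_identical(build_model(model_variant("constser137"))$zeroed_rate_id,
                   "pp2c_d_cat")
})

test_that("competitive and noncompetitive binding have equal rule counts", {
  obs <- darpp32_obs_fixture()
  tbs <- build_model(model_variant("wild", "tBS"))
  expect_identical(length(tbs$rules), length(obs$rules))
  expect_identical(darpp32_component_counts(tbs)$rules,
                   darpp32_component_counts(obs)$rules)
  # signatures differ only in the DARPP-32 binding sites
  expect_identical(obs$signatures$D$sites,
                   c("t34", "t75", "s137", "b"))
  expect_identical(tbs$signatures$D$sites,
                   c("t34", "t75", "s137", "b34", "b75", "b137"))
  viol <- unlist(lapply(tbs$rules, validate_rule, signatures = tbs$signatures))
  expect_length(viol, 0L)
})

test_that("the PP2B component is exactly the combinatorial-binding expansion", {
  m <- darpp32_obs_fixture()
  comp_rules <- m$rules[m$components == "PP2B activation"]
  expanded <- expand_multisite_binding(m$pp2b_scheme)
  expect_identical(sort(vapply(comp_rules, format_rule, character(1))),
                   sort(vapply(expanded, format_rule, character(1))))
})

test_that("missing rates are reported by id", {
  p <- darpp32_params()
  p <- p[setdiff(names(p), c("pka_d_cat", "ca_efflux"))]
  expect_error(build_model(params = p), "pka_d_cat")
  expect_error(build_model(params = p), "ca_efflux")
})

test_that("unaffected observables keep their pre-stimulus steady state under mutation", {
  net <- darpp32_net_fixture()
  m <- darpp32_obs_fixture()
  obs <- m$observables
  wild <- ode_run(net, m$init, t_end = 150, record_dt = 25,
                  observables = obs, atol = 1e-6)
  mut_ev <- event_schedule(list(event_set_rate(0, "ck1_d_cat", 0)))
  mut <- ode_run(net, m$init, t_end = 150, record_dt = 25,
                 observables = obs, events = mut_ev, atol = 1e-6)
  last <- nrow(wild$values)
  for (ob in c("D75", "all_cAMP", "PKA", "PDEP", "_CDK5")) {
    w <- wild$values[last, ob]; v <- mut$values[last, ob]
    expect_lt(abs(w - v) / max(abs(w), 1), 0.02)
  }
  # driven by a Ca2+ load, the Ser137 axis separates the two variants:
  # active PP2B reactivates CK1, which phosphorylates Ser137 only in wild
  init2 <- m$init
  init2["Ca(t)"] <- 3000
  wild2 <- ode_run(net, init2, t_end = 60, record_dt = 15,
                   observables = obs, atol = 1e-6)
  mut2 <- ode_run(net, init2, t_end = 60, record_dt = 15,
                  observables = obs, events = mut_ev, atol = 1e-6)
  l2 <- nrow(wild2$values)
  expect_gt(wild2$values[l2, "D137"],
            2 * max(mut2$values[l2, "D137"], 1))
})

test_that("a stochastic run of the full model samples a Ca species census", {
  net <- darpp32_net_fixture()
  m <- darpp32_obs_fixture()
  # scaled-down copy numbers keep the event count desk-sized
  init <- m$init
  init[] <- round(init / 10)
  init["Ca(t)"] <- 300
  init["cAMP(b)"] <- 100
  tr <- ssa_run(net, init, t_end = 1.5, record_dt = 0.5, seed = 2024,
                snapshot_period = 200L)
  cs <- species_containing(tr$snapshots, "Ca", net)
  expect_gt(nrow(cs), 1)
  expect_true("Ca(t)" %in% cs$canonical_id)
  # bound forms carry 1 (PP2A), 2 or 4 (PP2B) calcium ions
  expect_true(all(cs$n_agent %in% c(1, 2, 4)))
  # total Ca is conserved across snapshots (no Ca creation below t=1.5 s
  # would break this only through influx/efflux; count both flows)
  ev_counts <- vapply(tr$snapshots, function(s) {
    tot <- 0
    for (id in names(s$counts))
      tot <- tot + s$counts[[id]] *
        siterules:::count_agents(net$species[[id]], "Ca")
    tot
  }, numeric(1))
  expect_true(all(abs(ev_counts - 300) <= 300))  # flux-bounded drift
})

test_that("the model network reaches every stimulus species", {
  net <- darpp32_net_fixture()
  expect_true("Ca(t)" %in% names(net$species))
  expect_true("cAMP(b)" %in% names(net$species))
  m <- darpp32_obs_fixture()
  expect_gt(length(net$species), sum(m$init >= 0))
})

test_that("competitive and noncompetitive binding are indistinguishable at low occupancy", {
  # the mechanism behind the full-model equivalence: when interactors are
  # weakly bound and do not influence each other, giving the substrate one
  # shared site or one site per partner leaves trajectories unchanged
  build_variant <- function(three_sites) {
    bsites <- if (three_sites) c("b1", "b2") else c("b")
    s1 <- if (three_sites) "b1" else "b"
    s2 <- if (three_sites) "b2" else "b"
    sigs <- signature_set(
      agent_signature("S", c("a", bsites), list(a = c("u", "p"))),
      agent_signature("K", "sub"), agent_signature("Q", "sub"))
    rules <- list(
      rule("k_bind", sprintf("K(sub),S(a~u,%s)", s1),
           sprintf("K(sub!1),S(a~u,%s!1)", s1), 1e-3, "kon"),
      rule("k_unbind", sprintf("K(sub!1),S(a~u,%s!1)", s1),
           sprintf("K(sub),S(a~u,%s)", s1), 10, "koff"),
      rule("k_cat", sprintf("K(sub!1),S(a~u,%s!1)", s1),
           sprintf("K(sub),S(a~p,%s)", s1), 1, "kcat"),
      rule("q_bind", sprintf("Q(sub),S(%s)", s2),
           sprintf("Q(sub!1),S(%s!1)", s2), 1e-3, "qon"),
      rule("q_unbind", sprintf("Q(sub!1),S(%s!1)", s2),
           sprintf("Q(sub),S(%s)", s2), 10, "qoff"),
      rule("relax", "S(a~p)", "S(a~u)", 0.05, "krel"))
    init_s <- if (three_sites) "S(a~u,b1,b2)" else "S(a~u,b)"
    sr_model(sigs, rules,
             init = stats::setNames(c(1000, 50, 50),
                                    c(init_s, "K(sub)", "Q(sub)")),
             observables = list(pattern_observable("Sp", "S(a~p)"),
                                pattern_observable("Qbound", "Q(sub!_)")))
  }
  m1 <- build_variant(FALSE); m3 <- build_variant(TRUE)
  expect_identical(length(m1$rules), length(m3$rules))
  tr1 <- ode_run(model_network(m1), m1$init, t_end = 60, record_dt = 10,
                 observables = m1$observables)
  tr3 <- ode_run(model_network(m3), m3$init, t_end = 60, record_dt = 10,
                 observables = m3$observables)
  cmpr <- compare_trajectories(tr1, tr3)
  scale <- apply(abs(tr1$values), 2, max)
  for (i in seq_len(nrow(cmpr$report))) {
    ob <- cmpr$report$observable[i]
    expect_lt(cmpr$report$max_abs_diff[i] / max(scale[[ob]], 1), 0.02,
              label = paste("relative divergence of", ob))
  }
})
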