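test_that("rate-constant and concentration conversions follow mass action", {
  ctx <- unit_context(volume = 1e-15)
  expect_equal(convert_units(0.5, 1, ctx), 0.5)
  nav <- ctx$avogadro * ctx$volume
  expect_equal(convert_units(1e6, 2, ctx), 1e6 / nav)
  expect_equal(convert_units(2e-6, 0, ctx), 2e-6 * nav)
  # 1 uM in a femtolitre is ~602 molecules
  expect_equal(concentration_to_copies(1e-6, ctx), 602)
  expect_error(convert_units(1, 3, ctx), "unsupported")
  expect_error(unit_context(volume = 0), "positive")
  expect_error(concentration_to_copies(-1, ctx), "nonnegative")
})

test_that("deterministic decay matches its closed form", {
  m <- make_toy("decay", k = 0.1, A0 = 1000)
  net <- model_network(m)
  tr <- ode_run(net, m$init, t_end = 10, record_dt = 1)
  expect_equal(unname(tr$values[nrow(tr$values), "A(x)"]),
               m$expectations$mean(10), tolerance = 1e-5)
  # trajectory matches the closed form on the whole grid
  expect_equal(unname(tr$values[, "A(x)"]), m$expectations$mean(tr$time),
               tolerance = 1e-5)
})

test_that("deterministic dimerisation reaches the mass-action fixed point", {
  m <- make_toy("dimerisation")
  net <- model_network(m)
  tr <- ode_run(net, m$init, t_end = 200, record_dt = 20)
  ab_id <- grep("!1", colnames(tr$values), value = TRUE)
  expect_equal(unname(tr$values[nrow(tr$values), ab_id]),
               m$expectations$eq_complex, tolerance = 1e-4)
  # conservation of each agent along the whole trajectory
  totB <- tr$values[, "B(y)"] + tr$values[, ab_id]
  expect_equal(unname(totB), rep(m$expectations$B0, length(tr$time)),
               tolerance = 1e-6)
})

test_that("same seed reproduces the stochastic trajectory bit for bit", {
  m <- make_toy("birth_death")
  net <- model_network(m)
  t1 <- ssa_run(net, m$init, t_end = 20, record_dt = 1, seed = 99)
  t2 <- ssa_run(net, m$init, t_end = 20, record_dt = 1, seed = 99)
  expect_identical(t1$values, t2$values)
  expect_identical(t1$n_ssa_events, t2$n_ssa_events)
  t3 <- ssa_run(net, m$init, t_end = 20, record_dt = 1, seed = 100)
  expect_false(identical(t3$values, t1$values))
  expect_error(ssa_run(net, m$init, t_end = 20, record_dt = 1), "seed")
})

test_that("stochastic decay mean follows the exponential closed form", {
  m <- make_toy("decay", k = 0.1, A0 = 1000)
  net <- model_network(m)
  reps <- ssa_replicates(net, m$init, t_end = 10, record_dt = 1,
                         n_replicates = 200, base_seed = 500)
  sm <- summarize_replicates(reps)
  want <- m$expectations$mean(10)
  got <- sm$values[nrow(sm$values), "A(x)"]
  se <- sm$sd[nrow(sm$values), "A(x)"] / sqrt(sm$n_replicates)
  expect_lt(abs(got - want), 3 * se)
})

test_that("birth-death process is Poisson at stationarity", {
  # M/M/inf: stationary law Poisson(b/d), mean = variance = 100;
  # relaxation time 1/d = 10 s, sampled at t = 80 s from X0 = 100
  m <- make_toy("birth_death", b = 10, d = 0.1, X0 = 100)
  net <- model_network(m)
  reps <- ssa_replicates(net, m$init, t_end = 80, record_dt = 20,
                         n_replicates = 200, base_seed = 900)
  finals <- vapply(reps, function(tr) tr$values[nrow(tr$values), "X(x)"],
                   numeric(1))
  n <- length(finals)
  se_mean <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals) - 100), 3 * se_mean)
  se_var <- var(finals) * sqrt(2 / (n - 1))
  expect_lt(abs(var(finals) - 100), 3 * se_var)
})

test_that("homodimerisation propensity counts distinct pairs", {
  # exhaustive micro-state count: n molecules pair in n(n-1)/2 ways
  sigs <- signature_set(agent_signature("A", "x"))
  r <- rule("dim", "A(x),A(x)", "A(x!1),A(x!1)", 2, "k")
  net <- generate_network(list(r), list("A(x)"), sigs, species_cap = 10L)
  cmp <- siterules:::compile_network(net)
  for (n in 0:5) {
    x <- stats::setNames(numeric(length(cmp$ids)), cmp$ids)
    x["A(x)"] <- n
    a <- siterules:::propensities(x, cmp, cmp$k)
    micro <- if (n >= 2) ncol(utils::combn(n, 2)) else 0
    expect_equal(sum(a), 2 * micro, info = paste("n =", n))
  }
})

test_that("stochastic replicate means converge to the deterministic solution", {
  # linear network: first-order isomerisation chain keeps means exact
  sigs <- signature_set(agent_signature("A", "s", list(s = c("u", "p"))))
  rules <- list(rule("f", "A(s~u)", "A(s~p)", 0.3, "kf"),
                rule("b", "A(s~p)", "A(s~u)", 0.1, "kb"))
  net <- generate_network(rules, list("A(s~u)"), sigs)
  init <- c("A(s~u)" = 300)
  ode <- ode_run(net, init, t_end = 10, record_dt = 2)
  reps <- ssa_replicates(net, init, t_end = 10, record_dt = 2,
                         n_replicates = 200, base_seed = 77)
  sm <- summarize_replicates(reps)
  for (ob in colnames(ode$values)) {
    se <- sm$sd[, ob] / sqrt(sm$n_replicates)
    dev <- abs(sm$values[, ob] - ode$values[, ob])
    expect_true(all(dev <= 3 * se + 1e-9), info = ob)
  }
})
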