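test_that("embeddings honour wildcards and exact conditions", {
  sigs <- signature_set(agent_signature(
    "D", c("t34", "t75"), list(t34 = c("u", "p"), t75 = c("u", "p"))))
  mx <- mixture(list("D(t34~p,t75~u)", "D(t34~p,t75~p)", "D(t34~u,t75~u)"),
                c(1, 1, 1), sigs)
  # t75 unmentioned: wildcard
  expect_length(find_embeddings(parse_complex("D(t34~p)"), mx), 2L)
  # any pattern vs empty mixture
  empty <- mixture(list(), numeric(0), sigs)
  expect_length(find_embeddings(parse_complex("D(t34~p)"), empty), 0L)
  # copy numbers weight the mixture-level count
  mx2 <- mixture(list("D(t34~p,t75~u)", "D(t34~u,t75~u)"), c(5, 3), sigs)
  expect_equal(count_embeddings("D(t34~p)", mx2), 5)
  expect_equal(count_embeddings("D()", mx2), 8)
})

test_that("embedding counts match the brute-force all-injections oracle", {
  set.seed(202)
  targets <- c(
    "P(s1!1,s2!2,s3,s4),Ca(t!1),Ca(t!2)",
    "P(s1!1,s2!2,s3!3,s4!4),Ca(t!1),Ca(t!2),Ca(t!3),Ca(t!4)",
    "A(x~u!1),B(y!1)",
    "A(x~p)")
  patterns <- c("Ca(t!_)", "Ca()", "P(s1!_)", "P(s1!1),Ca(t!1)",
                "A(x~u)", "A(x?)", "A(x!B.y)", "Ca(t!P.s2)")
  sigs <- NULL
  for (tg in targets) {
    tcx <- parse_complex(tg, species = TRUE)
    for (pt in patterns) {
      pcx <- parse_complex(pt)
      got <- length(find_embeddings(pcx, tcx))
      want <- length(oracle_embeddings(pcx, tcx))
      expect_identical(got, want, info = paste(pt, "into", tg))
    }
  }
})

test_that("applying a rule rewrites exactly the mentioned fields", {
  sigs <- signature_set(agent_signature(
    "D", c("t34", "t75"), list(t34 = c("u", "p"), t75 = c("u", "p"))))
  r <- rule("phos", "D(t34~u)", "D(t34~p)", 1, "k")
  mx <- mixture(list("D(t34~u,t75~p)"), 3, sigs)
  m1 <- apply_rule(r, rule_matches(r, mx)$matches[[1]], mx, sigs)
  expect_equal(unname(m1$counts["D(t34~p,t75~p)"]), 1)
  expect_equal(unname(m1$counts["D(t34~u,t75~p)"]), 2)
})

test_that("bind followed by its exact unbind restores the mixture", {
  sigs <- ab_signatures()
  rs <- ab_rules()
  m0 <- mixture(list("A(x)", "B(y)"), c(4, 2), sigs)
  m1 <- apply_rule(rs[[1]], rule_matches(rs[[1]], m0)$matches[[1]], m0, sigs)
  m2 <- apply_rule(rs[[2]], rule_matches(rs[[2]], m1)$matches[[1]], m1, sigs)
  expect_identical(nonzero_counts(m2), nonzero_counts(m0))
})

test_that("degradation decreases the agent total by one", {
  sigs <- signature_set(agent_signature("cAMP", "b"))
  r <- rule("deg", "cAMP(b)", "", 0.1, "kdeg")
  mx <- mixture(list("cAMP(b)"), 5, sigs)
  expect_equal(agent_total(mx, "cAMP"), 5)
  m1 <- apply_rule(r, rule_matches(r, mx)$matches[[1]], mx, sigs)
  expect_equal(agent_total(m1, "cAMP"), 4)
})

test_that("stale embeddings are rejected", {
  sigs <- ab_signatures()
  rs <- ab_rules()
  m0 <- mixture(list("A(x)", "B(y)"), c(1, 1), sigs)
  emb <- rule_matches(rs[[1]], m0)$matches[[1]]
  m1 <- apply_rule(rs[[1]], emb, m0, sigs)
  expect_error(apply_rule(rs[[1]], emb, m1, sigs), "stale")
})

test_that("network generation closes simple systems exactly", {
  sigs <- ab_signatures()
  net <- generate_network(ab_rules(), list("A(x)", "B(y)"), sigs)
  expect_length(net$species, 3L)
  expect_length(net$reactions, 2L)
  # PP2B two-step scheme: 8 target-containing species, 24 reactions
  net4 <- pp2b_network_fixture()
  pp2b_sp <- Filter(function(cx) siterules:::count_agents(cx, "PP2B") > 0,
                    net4$species)
  expect_length(pp2b_sp, 8L)
  half <- Filter(function(cx) siterules:::count_agents(cx, "Ca") == 2, pp2b_sp)
  expect_length(half, 6L)
  expect_length(net4$reactions, 24L)
})

test_that("generated network is independent of rule and seed order", {
  sigs <- ab_signatures()
  rs <- ab_rules()
  n1 <- generate_network(rs, list("A(x)", "B(y)"), sigs)
  n2 <- generate_network(rev(rs), list("B(y)", "A(x)"), sigs)
  expect_identical(names(n1$species), names(n2$species))
  key <- function(net) sort(vapply(net$reactions, siterules:::reaction_key,
                                   character(1)))
  expect_identical(key(n1), key(n2))
})

test_that("closure equals the breadth-first oracle on seeded random systems", {
  n_ok <- 0L
  for (seed in 1:50) {
    m <- make_random_rule_system(seed, n_agents = 2 + seed %% 3,
                                 n_flips = 1 + seed %% 2)
    net <- generate_network(m$rules, as.list(names(m$init)), m$signatures,
                            species_cap = 500L)
    orc <- oracle_closure(m$rules, as.list(names(m$init)), m$signatures)
    expect_identical(sort(names(net$species)), orc$species,
                     info = paste("seed", seed))
    # one generated reaction per oracle (rule, reactants, products) class
    got <- unique(vapply(net$reactions, function(rx)
      paste(rx$provenance,
            paste(sort(rep(names(rx$reactants), rx$reactants)), collapse = "+"),
            paste(sort(rep(names(rx$products), rx$products)), collapse = "+")),
      character(1)))
    expect_equal(length(got), length(orc$reactions), info = paste("seed", seed))
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 50L)
})

test_that("species cap aborts runaway networks with a clear error", {
  # unbounded polymerisation: A.x binds A.y, chains grow without limit
  sigs <- signature_set(agent_signature("A", c("x", "y")))
  r <- rule("chain", "A(x),A(y)", "A(x!1),A(y!1)", 1, "k")
  msg <- tryCatch({
    generate_network(list(r), list("A(x,y)"), sigs, species_cap = 6L)
    ""
  }, error = conditionMessage)
  expect_match(msg, "network too large")
})
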