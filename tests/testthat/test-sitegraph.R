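test_that("complex parsing and serialization round-trip", {
  for (txt in c("A(x)", "A(x~u)", "A(x~u!1),B(y!1)",
                "PP2B(ca1!1,ca2,ca3!2,ca4),Ca(t!1),Ca(t!2)")) {
    cx <- parse_complex(txt, species = TRUE)
    expect_identical(format_complex(cx), txt)
  }
  # pattern markers survive a round trip
  p <- parse_complex("A(x~u?,y!_),B(z!B2.w)")
  expect_identical(format_complex(p), "A(x~u?,y!_),B(z!B2.w)")
})

test_that("parser rejects malformed input", {
  expect_error(parse_complex("A(x!1)"), "exactly twice")
  expect_error(parse_complex("A(x,x)"), "mentioned twice")
  expect_error(parse_complex("A(x!_)", species = TRUE), "explicit bond")
  sigs <- signature_set(agent_signature("A", "x", list(x = c("u", "p"))))
  expect_error(parse_complex("A(q)", signatures = sigs), "no site")
  expect_error(parse_complex("A(x~z)", signatures = sigs), "not declared")
})

test_that("canonical id is invariant under agent relabeling", {
  sigs <- signature_set(
    agent_signature("P", paste0("s", 1:4)),
    agent_signature("L", "t"),
    agent_signature("Q", c("a", "b"), list(a = c("u", "p"))))
  # a 6-agent complex: P bound to 4 L plus a Q hanging off... build a chain
  base <- "P(s1!1,s2!2,s3!3,s4!4),L(t!1),L(t!2),L(t!3),L(t!4)"
  id0 <- canonical_species(parse_complex(base, species = TRUE), sigs)
  cx <- parse_complex(base, species = TRUE)
  set.seed(11)
  for (i in 1:1000) {
    perm <- sample(length(cx$agents))
    shuffled <- siterules:::new_complex(cx$agents[perm])
    expect_identical(canonical_species(shuffled, sigs), id0)
  }
  # idempotence: canonicalising the canonical form is a fixed point
  expect_identical(canonical_species(parse_complex(id0, species = TRUE), sigs),
                   id0)
})

test_that("distinct site occupancy gives distinct ids", {
  sigs <- signature_set(agent_signature("PP2B", paste0("ca", 1:4)),
                        agent_signature("Ca", "t"))
  id12 <- canonical_species("PP2B(ca1!1,ca2!2,ca3,ca4),Ca(t!1),Ca(t!2)", sigs)
  id34 <- canonical_species("PP2B(ca1,ca2,ca3!1,ca4!2),Ca(t!1),Ca(t!2)", sigs)
  expect_false(id12 == id34)
  # all 2-of-4 placements are distinct: 6 ids
  ids <- vapply(combn(4, 2, simplify = FALSE), function(B) {
    s <- paste0("ca", 1:4)
    expr <- ifelse(1:4 %in% B, paste0(s, "!", cumsum(1:4 %in% B)[1:4]), s)
    lig <- paste0("Ca(t!", 1:2, ")", collapse = ",")
    canonical_species(paste0("PP2B(", paste(expr, collapse = ","), "),", lig),
                      sigs)
  }, character(1))
  expect_length(unique(ids), 6L)
})

test_that("canonicalisation rejects degenerate input", {
  expect_error(canonical_species(parse_complex("A(x),B(y)", species = TRUE)),
               "not connected")
  expect_error(canonical_species(parse_complex("A(x!_)")), "explicit bond|not fully")
  sigs <- signature_set(agent_signature("A", c("x", "y"), list(x = c("u", "p"))))
  # a stateful site mentioned without a definite state cannot make a species
  expect_error(canonical_species(parse_complex("A(x)"), sigs), "definite state")
})

test_that("free single agents serialize as their signature form", {
  sigs <- signature_set(agent_signature("Ca", "t"))
  expect_identical(canonical_species("Ca(t)", sigs), "Ca(t)")
})

test_that("species with k of n uniquely named sites bound number choose(n,k)", {
  # exhaustive enumeration oracle over explicit site subsets
  for (n in 2:5) {
    sigs <- signature_set(agent_signature("T", paste0("s", 1:n)),
                          agent_signature("L", "t"))
    for (k in 0:n) {
      subsets <- combn(n, k, simplify = FALSE)
      if (k == 0) subsets <- list(integer(0))
      ids <- vapply(subsets, function(B) {
        s <- paste0("s", 1:n)
        bond <- cumsum(1:n %in% B)
        expr <- ifelse(1:n %in% B, paste0(s, "!", bond), s)
        txt <- paste0("T(", paste(expr, collapse = ","), ")")
        if (k > 0) txt <- paste0(txt, ",", paste0("L(t!", 1:k, ")", collapse = ","))
        canonical_species(txt, sigs)
      }, character(1))
      expect_equal(length(unique(ids)), choose(n, k),
                       info = sprintf("n=%d k=%d", n, k))
      expect_equal(count_intermediate_species(n, k), choose(n, k))
    }
  }
})

test_that("validate_rule flags schema problems, ring formation and no-ops", {
  sigs <- signature_set(agent_signature("A", c("x", "w")),
                        agent_signature("B", "y"),
                        agent_signature("D", "t", list(t = c("u", "p"))))
  expect_length(validate_rule(rule("ok", "A(x),B(y)", "A(x!1),B(y!1)", 1), sigs), 0L)
  # binding two sites of one agent to each other closes a ring
  v2 <- validate_rule(rule("ring2", "A(x,w)", "A(x!1,w!1)", 1), sigs)
  expect_true(any(grepl("ring", v2)))
  # so does binding two agents that the LHS already connects
  sigs2 <- signature_set(agent_signature("A", c("x", "w")),
                         agent_signature("B", c("y", "z")))
  v2b <- validate_rule(rule("ring3", "A(x!1,w),B(y!1,z)",
                            "A(x!1,w!2),B(y!1,z!2)", 1), sigs2)
  expect_true(any(grepl("ring", v2b)))
  # undeclared state label named in the violation
  v3 <- validate_rule(rule("bad", "D(t~q)", "D(t~u)", 1), sigs)
  expect_true(any(grepl("q", v3)))
  # unknown agent
  v4 <- validate_rule(rule("bad2", "Z(q)", "Z(q)", 1), sigs)
  expect_true(any(grepl("unknown agent", v4)))
  # lhs == rhs is accepted but flagged as a no-op
  v5 <- validate_rule(rule("noop", "A(x)", "A(x)", 1), sigs)
  expect_true(any(grepl("no-op", v5)))
})

test_that("rule serialization round-trips", {
  txts <- c("'bind' A(x),B(y) -> A(x!1),B(y!1) @ 0.001",
            "'deg' A(x) ->  @ 0.10000000000000001",
            "'phos' D(t34~u) -> D(t34~p) @ 2")
  for (t in txts) {
    r <- parse_rule(t)
    r2 <- parse_rule(format_rule(r))
    expect_identical(format_rule(r2), format_rule(r))
    expect_identical(r2$rate, r$rate)
  }
})
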