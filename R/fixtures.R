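# -- Toy fixture models ----------------------------------------------------------
#
# Self-contained models with analytic expectations (documented with their
# derivations in the `expectations` field) so every engine feature is
# testable without external inputs.

#' Built-in toy models
#'
#' * `decay`: A -> 0 at rate `k`; mean A(t) = A0 exp(-k t) (first-order
#'   closed form).
#' * `birth_death`: 0 -> X at `b`, X -> 0 at `d`; the stationary law is
#'   Poisson(b/d) (M/M/inf queue), so stationary mean = variance = b/d.
#' * `dimerisation`: A + B <-> AB; the deterministic fixed point solves the
#'   mass-action quadratic (A0-c)(B0-c) kon = c koff.
#' * `multisite`: the combinatorial-binding scheme (defaults reproduce the
#'   PP2B encoding: 4 sites, two 2-ion steps, 24 rules).
#' * `phospho_spectator`: two phosphorylation reactions differing only in a
#'   spectator phosphosite; the minimal condensation fixture (1 rule when
#'   rates are equal, 2 otherwise).
#'
#' @param name one of `"decay"`, `"birth_death"`, `"dimerisation"`,
#'   `"multisite"`, `"phospho_spectator"`
#' @param ... overrides: rates (`k`, `b`, `d`, `kon`, `koff`), initial
#'   copies (`A0`, `B0`), or for `multisite` `n_sites` and `steps`
#' @return an `sr_model` with an `expectations` field
#' @export
make_toy <- function(name, ...) {
  args <- list(...)
  g <- function(nm, def) args[[nm]] %||% def
  model <- switch(
    name,
    decay = {
      k <- g("k", 0.1); A0 <- g("A0", 1000)
      m <- sr_model(signature_set(agent_signature("A", "x")),
                    list(rule("deg", "A(x)", "", k, "k")),
                    init = c("A(x)" = A0))
      m$expectations <- list(
        mean = function(t) A0 * exp(-k * t),   # dA/dt = -kA
        k = k, A0 = A0)
      m
    },
    birth_death = {
      b <- g("b", 10); d <- g("d", 0.1)
      m <- sr_model(signature_set(agent_signature("X", "x")),
                    list(rule("birth", "", "X(x)", b, "b"),
                         rule("death", "X(x)", "", d, "d")),
                    init = c("X(x)" = g("X0", 0)))
      m$expectations <- list(
        stationary_mean = b / d, stationary_var = b / d,  # Poisson(b/d)
        relaxation_time = 1 / d, b = b, d = d)
      m
    },
    dimerisation = {
      kon <- g("kon", 1e-3); koff <- g("koff", 0.5)
      A0 <- g("A0", 800); B0 <- g("B0", 500)
      m <- sr_model(signature_set(agent_signature("A", "x"),
                                  agent_signature("B", "y")),
                    list(rule("bind", "A(x),B(y)", "A(x!1),B(y!1)", kon, "kon"),
                         rule("unbind", "A(x!1),B(y!1)", "A(x),B(y)", koff, "koff")),
                    init = c("A(x)" = A0, "B(y)" = B0))
      m$expectations <- list(
        eq_complex = stats::uniroot(
          function(c) (A0 - c) * (B0 - c) * kon - c * koff,
          c(1e-12, min(A0, B0) - 1e-9))$root,
        kon = kon, koff = koff, A0 = A0, B0 = B0)
      m
    },
    multisite = {
      n <- g("n_sites", 4)
      steps <- g("steps", list(list(ions = 2, k_on = 1.7e-3, k_off = 1),
                               list(ions = 2, k_on = 1.7e-3, k_off = 1)))
      sch <- multisite_scheme(g("target", "PP2B"), n, g("ligand", "Ca"),
                              steps, site_prefix = g("site_prefix", "ca"))
      sigs <- scheme_signatures(sch)
      seed_target <- paste0(sch$target, "(",
                            paste(scheme_sites(sch), collapse = ","), ")")
      seed_ligand <- paste0(sch$ligand, "(", sch$ligand_site, ")")
      init <- stats::setNames(c(g("T0", 600), g("L0", 2400)),
                              c(seed_target, seed_ligand))
      m <- sr_model(sigs, expand_multisite_binding(sch), init = init)
      m$expectations <- list(
        n_rules = 2 * sum(vapply(seq_along(steps), function(k) {
          pre <- sum(vapply(steps[seq_len(k - 1)], `[[`, numeric(1), "ions"))
          choose(n, pre) * choose(n - pre, steps[[k]]$ions)
        }, numeric(1))),
        n_species_target = sum(choose(n, cumsum(c(0, vapply(steps, `[[`,
          numeric(1), "ions"))))),
        scheme = sch)
      m
    },
    phospho_spectator = {
      k1 <- g("k1", 1); k2 <- g("k2", k1)
      sigs <- signature_set(agent_signature(
        "D", c("t34", "t75"), list(t34 = c("u", "p"), t75 = c("u", "p"))))
      # expressed directly as two fully contextual reactions
      rules <- list(
        rule("phos_uu", "D(t34~u,t75~u)", "D(t34~p,t75~u)", k1, "k1"),
        rule("phos_up", "D(t34~u,t75~p)", "D(t34~p,t75~p)", k2, "k2"))
      m <- sr_model(sigs, rules,
                    init = c("D(t34~u,t75~u)" = 500, "D(t34~u,t75~p)" = 500))
      m$expectations <- list(n_condensed = if (k1 == k2) 1L else 2L,
                             k1 = k1, k2 = k2)
      m
    },
    stop("unknown toy model '", name, "'", call. = FALSE))
  model
}

#' Reproducible random rule systems
#'
#' Generates a pseudo-random, validator-clean rule system whose network
#' closure is finite by construction: binding rules follow a random forest
#' over agent types (each bond uses a dedicated site pair, no cycles), plus
#' reversible state-flip rules on random phosphosites. Used as the substrate
#' for property tests against brute-force oracles.
#'
#' @param seed RNG seed (same seed, same system)
#' @param n_agents number of agent types (2..6)
#' @param n_flips number of state-flip rule pairs to add
#' @param species_cap guard passed along in the result
#' @return an `sr_model` (uniform rate 1 on all rules)
#' @export
make_random_rule_system <- function(seed, n_agents = 4, n_flips = 2,
                                    species_cap = 500L) {
  stopifnot(n_agents >= 2, n_agents <= 6)
  set.seed(seed)
  nm <- paste0("Ag", seq_len(n_agents))
  sites <- stats::setNames(vector("list", n_agents), nm)
  states <- stats::setNames(vector("list", n_agents), nm)
  # random forest over agent indices: parent[i] < i for i >= 2, some absent
  rules <- list()
  for (i in 2:n_agents) {
    if (stats::runif(1) < 0.25) next      # leave some agents unbound
    parent <- sample.int(i - 1L, 1L)
    sa <- paste0("l", i)                  # site on parent
    sb <- paste0("u", i)                  # site on child
    sites[[parent]] <- c(sites[[parent]], sa)
    sites[[i]] <- c(sites[[i]], sb)
    lhs <- sprintf("%s(%s),%s(%s)", nm[parent], sa, nm[i], sb)
    rhs <- sprintf("%s(%s!1),%s(%s!1)", nm[parent], sa, nm[i], sb)
    rules[[length(rules) + 1L]] <- rule(sprintf("bind_%d", i), lhs, rhs, 1,
                                        sprintf("kb%d", i))
    rules[[length(rules) + 1L]] <- rule(sprintf("unbind_%d", i), rhs, lhs, 1,
                                        sprintf("ku%d", i))
  }
  for (f in seq_len(n_flips)) {
    a <- sample.int(n_agents, 1L)
    s <- paste0("m", f)
    sites[[a]] <- c(sites[[a]], s)
    states[[a]][[s]] <- c("u", "p")
    rules[[length(rules) + 1L]] <- rule(
      sprintf("flip_on_%d", f), sprintf("%s(%s~u)", nm[a], s),
      sprintf("%s(%s~p)", nm[a], s), 1, sprintf("kf%d", f))
    rules[[length(rules) + 1L]] <- rule(
      sprintf("flip_off_%d", f), sprintf("%s(%s~p)", nm[a], s),
      sprintf("%s(%s~u)", nm[a], s), 1, sprintf("kr%d", f))
  }
  sigs <- signature_set(lapply(seq_len(n_agents), function(i)
    agent_signature(nm[i], sites[[i]] %||% character(0), states[[i]] %||% list())))
  seeds <- vapply(seq_len(n_agents), function(i) {
    sig <- sigs[[i]]
    parse_and_complete <- parse_complex(paste0(nm[i], "()"), species = TRUE,
                                        signatures = sigs)
    canonical_species(parse_and_complete, sigs)
  }, character(1))
  m <- sr_model(sigs, rules, init = stats::setNames(rep(10, n_agents), seeds))
  m$species_cap <- species_cap
  m
}
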