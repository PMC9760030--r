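# Shared fixtures: built lazily once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  v <- get0(key, envir = .cache)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .cache)
  }
  v
}

ab_signatures <- function() {
  signature_set(agent_signature("A", "x"), agent_signature("B", "y"))
}

ab_rules <- function(kon = 0.001, koff = 0.5) {
  list(rule("bind", "A(x),B(y)", "A(x!1),B(y!1)", kon, "kon"),
       rule("unbind", "A(x!1),B(y!1)", "A(x),B(y)", koff, "koff"))
}

pp2b_scheme_fixture <- function(equal_rates = FALSE) {
  multisite_scheme(
    "PP2B", 4, "Ca",
    if (equal_rates)
      list(list(ions = 2, k_on = 1e-3, k_off = 1),
           list(ions = 2, k_on = 1e-3, k_off = 1))
    else
      list(list(ions = 2, k_on = 1e-3, k_off = 1),
           list(ions = 2, k_on = 2e-3, k_off = 0.5)),
    site_prefix = "ca",
    activity = c("0" = "inactive", "2" = "halfactive", "4" = "active"))
}

pp2b_network_fixture <- function() {
  cached("pp2b_net", function() {
    sch <- pp2b_scheme_fixture()
    generate_network(expand_multisite_binding(sch),
                     list("PP2B(ca1,ca2,ca3,ca4)", "Ca(t)"),
                     scheme_signatures(sch))
  })
}

darpp32_obs_fixture <- function() {
  cached("darpp32_obs", function() build_model(model_variant("wild", "oBS")))
}

darpp32_net_fixture <- function() {
  cached("darpp32_net", function() model_network(darpp32_obs_fixture()))
}
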