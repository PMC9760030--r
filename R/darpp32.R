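# -- DARPP-32 model library --------------------------------------------------------
#
# A rule-based reconstruction of the DARPP-32 (PPP1R1B) signalling network:
# DARPP-32 with phosphosites Thr34, Thr75 and Ser137 integrates a
# cAMP--PKA--Thr34 pathway and a Ca2+--PP2B--Thr75 pathway. PKA holoenzyme
# (R2C2) is activated by four cAMP molecules, PP2B (calcineurin) by four
# Ca2+ ions -- both encoded with the combinatorial-binding scheme on four
# uniquely named sites. Rules are organised in eight components mirroring
# the mechanism inventory of the source reaction system; rate values are
# not published with the network, so a synthetic, order-of-magnitude
# parameter table ships with the package (see
# inst/extdata/darpp32_params_synthetic.tsv) and any table with the same
# rate ids can be substituted.

#' Model variant descriptor
#'
#' @param mutation `"wild"`, `"ser137ala"` (Ser137 cannot be phosphorylated:
#'   the single CK1 catalytic rule on Ser137 is zeroed) or `"constser137"`
#'   (Ser137 permanently phosphorylated: the single PP2C catalytic rule is
#'   zeroed). In the reaction network each mutation corresponds to zeroing
#'   four reaction constants; in the rule set it is one rule.
#' @param binding `"oBS"` (competitive: one DARPP-32 binding site shared by
#'   all partners) or `"tBS"` (noncompetitive: three independent sites, one
#'   per phosphosite's enzymes). Both variants have the same number of
#'   rules.
#' @return list of class `model_variant`
#' @export
model_variant <- function(mutation = c("wild", "ser137ala", "constser137"),
                          binding = c("oBS", "tBS")) {
  structure(list(mutation = match.arg(mutation),
                 binding = match.arg(binding)),
            class = "model_variant")
}

#' Synthetic default parameters of the DARPP-32 model
#'
#' Loads the packaged synthetic rate table (stochastic constants for a
#' 1e-15 L volume: bimolecular on-rates ~1e6 /M/s, weak micromolar
#' dissociation, catalysis 1-10 /s). These are NOT the source model's
#' fitted values, which are not published with the network; they are
#' documented placeholders giving the reconstruction plausible kinetics.
#'
#' @param path optional TSV with columns `rate_id`, `value` overriding the
#'   packaged table
#' @return named numeric vector of stochastic rate constants
#' @export
darpp32_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "darpp32_params_synthetic.tsv",
                        package = "siterules", mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(tb$value, tb$rate_id)
}

darpp32_signatures <- function(binding = "oBS") {
  up <- c("u", "p")
  d_bind <- if (binding == "oBS") "b" else c("b34", "b75", "b137")
  signature_set(
    agent_signature("D", c("t34", "t75", "s137", d_bind),
                    list(t34 = up, t75 = up, s137 = up)),
    agent_signature("C", c("r", "sub")),                   # PKA catalytic
    agent_signature("R2C2", c(paste0("a", 1:4), "c1", "c2")),
    agent_signature("cAMP", "b"),
    agent_signature("Ca", "t"),
    agent_signature("PP2B", c(paste0("ca", 1:4), "sub")),
    agent_signature("CK1", c("st", "sub"), list(st = up)), # active when u
    agent_signature("PP2A", c("st", "ca", "sub"), list(st = up)),
    agent_signature("PP2C", "sub"),
    agent_signature("CDK5", "sub"),
    agent_signature("PDE", c("st", "sub"), list(st = up))  # active when p
  )
}

# site of D that an enzyme class binds, by variant
d_site <- function(binding, class) {
  if (binding == "oBS") return("b")
  switch(class, t34 = "b34", t75 = "b75", s137 = "b137")
}

# enzymatic bind/unbind/cat triple on a DARPP-32 phosphosite
d_enzyme_rules <- function(prefix, enzyme_pat_free, enzyme_pat_bound,
                           enzyme_rhs_free, site, from, to, bsite, k,
                           component, gate = "") {
  gate_txt <- if (nzchar(gate)) paste0(",", gate) else ""
  lhs_b <- sprintf("%s,D(%s~%s,%s%s)", enzyme_pat_free, site, from, bsite, gate_txt)
  rhs_b <- sprintf("%s,D(%s~%s,%s!1%s)", enzyme_pat_bound, site, from, bsite, gate_txt)
  lhs_c <- sprintf("%s,D(%s~%s,%s!1)", enzyme_pat_bound, site, from, bsite)
  rhs_c <- sprintf("%s,D(%s~%s,%s)", enzyme_rhs_free, site, to, bsite)
  out <- list(
    rule(paste0(prefix, "_bind"), lhs_b, rhs_b, k[[paste0(prefix, "_bind")]],
         rate_id = paste0(prefix, "_bind")),
    rule(paste0(prefix, "_unbind"), rhs_b, lhs_b, k[[paste0(prefix, "_unbind")]],
         rate_id = paste0(prefix, "_unbind")),
    rule(paste0(prefix, "_cat"), lhs_c, rhs_c, k[[paste0(prefix, "_cat")]],
         rate_id = paste0(prefix, "_cat")))
  for (i in seq_along(out)) attr(out[[i]], "component") <- component
  out
}

#' Build a DARPP-32 model variant
#'
#' Assembles the signatures, the eight-component rule set, the initial
#' mixture (8 nonzero initial copy numbers; cAMP and Ca2+ start at zero and
#' enter via the stimulus events), the observable set and the stimulus
#' protocol. Mutations zero the rate of one rule; the binding variant only
#' changes the DARPP-32 signature and the site each enzyme binds, not the
#' number of rules.
#'
#' @param variant a [model_variant()]
#' @param params named rate vector (see [darpp32_params()]); every rate id
#'   used by the rule set must be present
#' @param stimulus include the 21-event stimulus protocol (one cAMP pulse
#'   followed by a train of 20 Ca2+ spikes); set `FALSE` for steady-state
#'   runs
#' @return an `sr_model` with fields `variant`, `components`,
#'   `zeroed_rate_id`
#' @export
build_model <- function(variant = model_variant(), params = darpp32_params(),
                        stimulus = TRUE) {
  b <- variant$binding
  sigs <- darpp32_signatures(b)
  k <- params
  rules <- list()
  add <- function(...) for (r in list(...)) rules[[length(rules) + 1L]] <<- r
  addl <- function(rs) for (r in rs) rules[[length(rules) + 1L]] <<- r
  tag <- function(r, comp) { attr(r, "component") <- comp; r }

  missing_ids <- character(0)
  kv <- function(id) {
    if (!(id %in% names(k))) { missing_ids <<- c(missing_ids, id); return(0) }
    k[[id]]
  }

  comp1 <- "DARPP-32 phosphorylation"
  # PKA catalytic subunit phosphorylates Thr34 (requires free C: r site free)
  addl(d_enzyme_rules("pka_d", "C(r,sub)", "C(r,sub!1)", "C(r,sub)",
                      "t34", "u", "p", d_site(b, "t34"),
                      sapply(paste0("pka_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))
  # Thr75-phosphorylated DARPP-32 sequesters PKA (pseudosubstrate)
  ihs <- d_site(b, "t34")
  add(tag(rule("pka_inh_bind",
               sprintf("C(r,sub),D(t75~p,%s)", ihs),
               sprintf("C(r,sub!1),D(t75~p,%s!1)", ihs),
               kv("pka_inh_bind"), "pka_inh_bind"), comp1),
      tag(rule("pka_inh_unbind",
               sprintf("C(r,sub!1),D(t75~p,%s!1)", ihs),
               sprintf("C(r,sub),D(t75~p,%s)", ihs),
               kv("pka_inh_unbind"), "pka_inh_unbind"), comp1))
  # CDK5 phosphorylates Thr75
  addl(d_enzyme_rules("cdk5_d", "CDK5(sub)", "CDK5(sub!1)", "CDK5(sub)",
                      "t75", "u", "p", d_site(b, "t75"),
                      sapply(paste0("cdk5_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))
  # CK1 (active when unphosphorylated) phosphorylates Ser137
  addl(d_enzyme_rules("ck1_d", "CK1(st~u,sub)", "CK1(st~u,sub!1)", "CK1(st~u,sub)",
                      "s137", "u", "p", d_site(b, "s137"),
                      sapply(paste0("ck1_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))
  # active PP2B dephosphorylates Thr34, blocked by phospho-Ser137
  pp2b_free <- "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub)"
  pp2b_bound <- "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub!1)"
  addl(d_enzyme_rules("pp2b_d", pp2b_free, pp2b_bound, pp2b_free,
                      "t34", "p", "u", d_site(b, "t34"),
                      sapply(paste0("pp2b_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1, gate = "s137~u"))
  # PKA-phosphorylated PP2A dephosphorylates Thr75
  addl(d_enzyme_rules("pp2ap_d", "PP2A(st~p,sub)", "PP2A(st~p,sub!1)",
                      "PP2A(st~p,sub)", "t75", "p", "u", d_site(b, "t75"),
                      sapply(paste0("pp2ap_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))
  # Ca-activated PP2A dephosphorylates Thr75
  addl(d_enzyme_rules("pp2aca_d", "PP2A(ca!_,sub)", "PP2A(ca!_,sub!1)",
                      "PP2A(ca!_,sub)", "t75", "p", "u", d_site(b, "t75"),
                      sapply(paste0("pp2aca_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))
  # PP2C dephosphorylates Ser137
  addl(d_enzyme_rules("pp2c_d", "PP2C(sub)", "PP2C(sub!1)", "PP2C(sub)",
                      "s137", "p", "u", d_site(b, "s137"),
                      sapply(paste0("pp2c_d_", c("bind", "unbind", "cat")),
                             kv, simplify = FALSE), comp1))

  comp2 <- "CK1 phosphorylation"
  add(tag(rule("ck1_auto", "CK1(st~u,sub)", "CK1(st~p,sub)", kv("ck1_auto"),
               "ck1_auto"), comp2),
      tag(rule("pp2b_ck1_bind",
               "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub),CK1(st~p,sub)",
               "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub!1),CK1(st~p,sub!1)",
               kv("pp2b_ck1_bind"), "pp2b_ck1_bind"), comp2),
      tag(rule("pp2b_ck1_unbind",
               "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub!1),CK1(st~p,sub!1)",
               "PP2B(ca1!_,ca2!_,ca3!_,ca4!_,sub),CK1(st~p,sub)",
               kv("pp2b_ck1_unbind"), "pp2b_ck1_unbind"), comp2),
      tag(rule("pp2b_ck1_cat",
               "PP2B(sub!1),CK1(st~p,sub!1)",
               "PP2B(sub),CK1(st~u,sub)",
               kv("pp2b_ck1_cat"), "pp2b_ck1_cat"), comp2))

  comp3 <- "PDE phosphorylation"
  add(tag(rule("pka_pde_bind", "C(r,sub),PDE(st~u,sub)",
               "C(r,sub!1),PDE(st~u,sub!1)", kv("pka_pde_bind"),
               "pka_pde_bind"), comp3),
      tag(rule("pka_pde_unbind", "C(r,sub!1),PDE(st~u,sub!1)",
               "C(r,sub),PDE(st~u,sub)", kv("pka_pde_unbind"),
               "pka_pde_unbind"), comp3),
      tag(rule("pka_pde_cat", "C(sub!1),PDE(st~u,sub!1)",
               "C(sub),PDE(st~p,sub)", kv("pka_pde_cat"), "pka_pde_cat"), comp3),
      tag(rule("pde_auto_dephos", "PDE(st~p)", "PDE(st~u)",
               kv("pde_auto_dephos"), "pde_auto_dephos"), comp3))

  comp4 <- "PP2A phosphorylation"
  add(tag(rule("pka_pp2a_bind", "C(r,sub),PP2A(st~u,sub)",
               "C(r,sub!1),PP2A(st~u,sub!1)", kv("pka_pp2a_bind"),
               "pka_pp2a_bind"), comp4),
      tag(rule("pka_pp2a_unbind", "C(r,sub!1),PP2A(st~u,sub!1)",
               "C(r,sub),PP2A(st~u,sub)", kv("pka_pp2a_unbind"),
               "pka_pp2a_unbind"), comp4),
      tag(rule("pka_pp2a_cat", "C(sub!1),PP2A(st~u,sub!1)",
               "C(sub),PP2A(st~p,sub)", kv("pka_pp2a_cat"), "pka_pp2a_cat"), comp4),
      tag(rule("pp2a_auto_dephos", "PP2A(st~p)", "PP2A(st~u)",
               kv("pp2a_auto_dephos"), "pp2a_auto_dephos"), comp4))

  comp5 <- "PP2B activation"
  pp2b_scheme <- multisite_scheme(
    "PP2B", 4, "Ca",
    list(list(ions = 2, k_on = kv("PP2B_k1f"), k_off = kv("PP2B_k1r")),
         list(ions = 2, k_on = kv("PP2B_k2f"), k_off = kv("PP2B_k2r"))),
    site_prefix = "ca", ligand_site = "t",
    activity = c("0" = "inactive", "2" = "halfactive", "4" = "active"))
  addl(expand_multisite_binding(pp2b_scheme))

  comp6 <- "PKA activation"
  pka_scheme <- multisite_scheme(
    "R2C2", 4, "cAMP",
    list(list(ions = 2, k_on = kv("R2C2_k1f"), k_off = kv("R2C2_k1r")),
         list(ions = 2, k_on = kv("R2C2_k2f"), k_off = kv("R2C2_k2r"))),
    site_prefix = "a", ligand_site = "b")
  pka_rules <- expand_multisite_binding(pka_scheme)
  for (i in seq_along(pka_rules)) attr(pka_rules[[i]], "component") <- comp6
  addl(pka_rules)
  for (cs in c("c1", "c2")) {
    full <- "a1!_,a2!_,a3!_,a4!_"
    add(tag(rule(paste0("pka_release_", cs),
                 sprintf("R2C2(%s,%s!1),C(r!1)", full, cs),
                 sprintf("R2C2(%s,%s),C(r)", full, cs),
                 kv("pka_release"), "pka_release"), comp6),
        tag(rule(paste0("pka_rebind_", cs),
                 sprintf("R2C2(%s),C(r,sub)", cs),     # substrate-free C only
                 sprintf("R2C2(%s!1),C(r!1,sub)", cs),
                 kv("pka_rebind"), "pka_rebind"), comp6))
  }

  comp7 <- "cAMP & Ca degradation"
  add(tag(rule("camp_synth", "", "cAMP(b)", kv("camp_synth"), "camp_synth"), comp7),
      tag(rule("camp_deg_basal", "cAMP(b)", "", kv("camp_deg_basal"),
               "camp_deg_basal"), comp7),
      tag(rule("pde_camp_bind", "PDE(sub),cAMP(b)", "PDE(sub!1),cAMP(b!1)",
               kv("pde_camp_bind"), "pde_camp_bind"), comp7),
      tag(rule("pde_camp_unbind", "PDE(sub!1),cAMP(b!1)", "PDE(sub),cAMP(b)",
               kv("pde_camp_unbind"), "pde_camp_unbind"), comp7),
      tag(rule("pde_camp_deg_u", "PDE(st~u,sub!1),cAMP(b!1)", "PDE(st~u,sub)",
               kv("pde_camp_deg_u"), "pde_camp_deg_u"), comp7),
      tag(rule("pde_camp_deg_p", "PDE(st~p,sub!1),cAMP(b!1)", "PDE(st~p,sub)",
               kv("pde_camp_deg_p"), "pde_camp_deg_p"), comp7),
      tag(rule("ca_influx", "", "Ca(t)", kv("ca_influx"), "ca_influx"), comp7),
      tag(rule("ca_efflux", "Ca(t)", "", kv("ca_efflux"), "ca_efflux"), comp7))

  comp8 <- "PP2A activation by Ca"
  add(tag(rule("pp2a_ca_bind", "PP2A(ca),Ca(t)", "PP2A(ca!1),Ca(t!1)",
               kv("pp2a_ca_bind"), "pp2a_ca_bind"), comp8),
      tag(rule("pp2a_ca_unbind", "PP2A(ca!1),Ca(t!1)", "PP2A(ca),Ca(t)",
               kv("pp2a_ca_unbind"), "pp2a_ca_unbind"), comp8))

  if (length(missing_ids))
    stop("missing rate(s): ", paste(unique(missing_ids), collapse = ", "),
         call. = FALSE)

  # in-silico mutations: one rule's constant set to zero
  zeroed <- switch(variant$mutation,
                   wild = NA_character_,
                   ser137ala = "ck1_d_cat",
                   constser137 = "pp2c_d_cat")
  if (!is.na(zeroed)) {
    for (i in seq_along(rules))
      if (rules[[i]]$rate_id == zeroed) rules[[i]]$rate <- 0
  }

  d_sites_txt <- if (b == "oBS") "b" else "b34,b75,b137"
  init <- c(
    stats::setNames(k[["init_D"]],
                    sprintf("D(t34~u,t75~u,s137~%s,%s)",
                            if (variant$mutation == "constser137") "p" else "u",
                            d_sites_txt)),
    stats::setNames(k[["init_R2C2"]],
                    "R2C2(a1,a2,a3,a4,c1!1,c2!2),C(r!1,sub),C(r!2,sub)"),
    stats::setNames(k[["init_PP2B"]], "PP2B(ca1,ca2,ca3,ca4,sub)"),
    stats::setNames(k[["init_PP2A"]], "PP2A(st~u,ca,sub)"),
    stats::setNames(k[["init_PP2C"]], "PP2C(sub)"),
    stats::setNames(k[["init_CK1"]], "CK1(st~u,sub)"),
    stats::setNames(k[["init_CDK5"]], "CDK5(sub)"),
    stats::setNames(k[["init_PDE"]], "PDE(st~u,sub)"),
    # stimulus species start at zero and enter via the event schedule, but
    # they must seed the network so the events resolve
    c("cAMP(b)" = 0, "Ca(t)" = 0))

  # store initial species under their canonical ids so they line up with
  # the generated network's species table
  names(init) <- vapply(names(init), function(txt)
    canonical_species(parse_complex(txt, species = TRUE, signatures = sigs),
                      sigs), character(1))

  evs <- if (stimulus) darpp32_stimulus(params) else event_schedule()

  obs <- darpp32_observables(b)
  m <- sr_model(sigs, rules, init = init, observables = obs, events = evs)
  m$variant <- variant
  m$zeroed_rate_id <- zeroed
  m$components <- vapply(rules, function(r)
    attr(r, "component") %||% NA_character_, character(1))
  m$pp2b_scheme <- pp2b_scheme
  m
}

#' Default stimulus protocol (synthetic)
#'
#' 21 timed events: one cAMP pulse followed by a train of 20 Ca2+ spikes.
#' The source model's exact protocol lives in its machine-readable events
#' and is not printed with the network, so this is a documented synthetic
#' protocol with the published event count; any [event_schedule()] can be
#' passed to the simulators instead.
#'
#' @param params parameter vector supplying `stim_camp_copies`,
#'   `stim_ca_copies`, `stim_camp_time`, `stim_ca_start`, `stim_ca_interval`
#' @return an [event_schedule()] with 21 events
#' @export
darpp32_stimulus <- function(params = darpp32_params()) {
  g <- function(nm) unname(params[[nm]])
  evs <- list(event_add_copies(g("stim_camp_time"), "cAMP(b)",
                               g("stim_camp_copies")))
  for (i in 0:19) {
    evs[[length(evs) + 1L]] <- event_add_copies(
      g("stim_ca_start") + i * g("stim_ca_interval"), "Ca(t)",
      g("stim_ca_copies"))
  }
  event_schedule(evs)
}

# observable set following the selection principles: activated state for
# agents with internal states; least specific form for created/degraded
# agents; bound form for constant agents without states
darpp32_observables <- function(binding = "oBS") {
  list(
    pattern_observable("D",     "D(t34~u,t75~u,s137~u)"),
    pattern_observable("D34",   "D(t34~p)"),
    pattern_observable("D75",   "D(t75~p)"),
    pattern_observable("D137",  "D(s137~p)"),
    pattern_observable("all_cAMP", "cAMP()"),
    pattern_observable("all_Ca",   "Ca()"),
    pattern_observable("PP2Bactive", "PP2B(ca1!_,ca2!_,ca3!_,ca4!_)"),
    pattern_observable("PP2Binactive2",
                       vapply(combn_sets(4, 2), function(B) {
                         s <- paste0("ca", 1:4)
                         paste0("PP2B(", paste(ifelse(1:4 %in% B,
                           paste0(s, "!_"), s), collapse = ","), ")")
                       }, character(1))),
    pattern_observable("PKA",   "C(r)"),
    pattern_observable("CK1u",  "CK1(st~u)"),
    pattern_observable("PP2AP", "PP2A(st~p)"),
    pattern_observable("PP2ACa", "PP2A(ca!_)"),
    pattern_observable("_PP2C", "PP2C(sub!_)"),
    pattern_observable("_CDK5", "CDK5(sub!_)"),
    pattern_observable("PDEP",  "PDE(st~p)"))
}

#' Per-component rule counts of a built model
#'
#' @param model an `sr_model` from [build_model()]
#' @return data.frame: component, rules, unique rate constants
#' @export
darpp32_component_counts <- function(model) {
  comp <- model$components
  do.call(rbind, lapply(unique(comp), function(cc) {
    rs <- model$rules[comp == cc]
    data.frame(component = cc, rules = length(rs),
               unique_rates = length(unique(vapply(rs, `[[`, character(1),
                                                   "rate_id"))),
               stringsAsFactors = FALSE)
  }))
}
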