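# -- Reaction -> rule condensation ----------------------------------------------
#
# The translation criterion: reactions of the same type between the same
# reactants, differing only in agent states (internal or binding) that do
# not change from reactants to products, and carrying the same rate value,
# are condensed into one decontextualised rule. Context that varies across
# the group is removed; context shared by every member is kept. The output
# is audited by re-expansion: expanding the rules over the original species
# universe must regenerate exactly the input reaction multiset (rates
# included); any group that fails is demoted to fully contextual rules.

# type-level link descriptor of a site within a union complex
link_desc <- function(ucx, pm, i, s) {
  lk <- ucx$agents[[i]]$links[[s]]
  if (!is_bond(lk)) return(lk)
  p <- get(paste0(i, "\r", s), envir = pm)
  paste0(ucx$agents[[p$agent]]$name, ".", p$site)
}

# cost of aligning reactant agent i with product agent j (type-level)
align_cost <- function(lcx, lpm, i, pcx, ppm, j) {
  la <- lcx$agents[[i]]; pa <- pcx$agents[[j]]
  cost <- 0L
  for (s in union(names(la$states), names(pa$states))) {
    ls <- la$states[s]; ps <- pa$states[s]
    if (!identical(unname(ls), unname(ps))) cost <- cost + 1L
    ld <- if (s %in% names(la$states)) link_desc(lcx, lpm, i, s) else NA
    pd <- if (s %in% names(pa$states)) link_desc(pcx, ppm, j, s) else NA
    if (!identical(ld, pd)) cost <- cost + 1L
  }
  cost
}

# best alignment of reactant union agents to product union agents:
# per-name assignment minimising total cost; extra reactant agents are
# deleted, extra product agents created
align_union <- function(lcx, pcx) {
  lpm <- partner_map(lcx); ppm <- partner_map(pcx)
  ln <- agent_names(lcx); pn <- agent_names(pcx)
  map <- rep(NA_integer_, length(ln))    # lhs slot -> product agent
  for (nm in unique(c(ln, pn))) {
    li <- which(ln == nm); pi <- which(pn == nm)
    if (!length(li) || !length(pi)) next
    kc <- min(length(li), length(pi))
    best <- NULL; best_cost <- Inf
    # all injective assignments of li (or subsets) onto pi
    lsubs <- combn_sets_of(seq_along(li), kc)
    psubs <- combn_sets_of(seq_along(pi), kc)
    for (lsub in lsubs) for (psub in psubs) {
      for (perm in perms_list(kc)) {
        cost <- 0L
        for (t in seq_len(kc))
          cost <- cost + align_cost(lcx, lpm, li[lsub[t]], pcx, ppm,
                                    pi[psub[perm[t]]])
        if (cost < best_cost) {
          best_cost <- cost
          best <- cbind(li[lsub], pi[psub[perm]])
        }
      }
    }
    if (!is.null(best)) map[best[, 1]] <- best[, 2]
  }
  map
}

perms_list <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  rec <- function(v, acc) {
    if (!length(v)) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (i in seq_along(v)) rec(v[-i], c(acc, v[i]))
  }
  rec(seq_len(k), integer(0))
  out
}

# structural descriptor of a reaction.
# The transformation core holds the slots that appear in the condensed rule:
# every changed agent, plus every agent of a reactant component containing
# no change at all (a catalyst component, which fixes the reaction arity).
# Unchanged agents attached to a changing component are removable context.
reaction_descriptor <- function(rx, registry) {
  rcx_list <- lapply(rep(names(rx$reactants), rx$reactants), function(id) {
    cx <- registry[[id]]
    if (is.null(cx)) stop("unresolvable species composition: ", id, call. = FALSE)
    cx
  })
  pcx_list <- lapply(rep(names(rx$products), rx$products), function(id) {
    cx <- registry[[id]]
    if (is.null(cx)) stop("unresolvable species composition: ", id, call. = FALSE)
    cx
  })
  lcx <- union_complexes(rcx_list)
  pcx <- union_complexes(pcx_list)
  map <- align_union(lcx, pcx)
  lpm <- partner_map(lcx); ppm <- partner_map(pcx)
  n_l <- n_agents(lcx)
  inv <- rep(NA_integer_, n_agents(pcx)); inv[map[!is.na(map)]] <- which(!is.na(map))

  # per-slot changed sites: states and link descriptors
  changed <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    ch <- character(0)
    if (!is.na(map[i])) {
      j <- map[i]
      la <- lcx$agents[[i]]; pa <- pcx$agents[[j]]
      for (s in names(la$states)) {
        ls <- la$states[[s]]; ps <- pa$states[[s]]
        if (!identical(ls, ps)) ch <- c(ch, paste0("~", s, ":", ls, ">", ps))
        ld <- link_desc(lcx, lpm, i, s); pd <- link_desc(pcx, ppm, j, s)
        if (!identical(ld, pd)) ch <- c(ch, paste0("!", s, ":", ld, ">", pd))
      }
    } else ch <- "DEL"
    changed[[i]] <- sort(ch)
  }
  created <- which(is.na(inv))

  # core slots: changed agents + agents of catalyst-only reactant components
  comp_of <- lhs_component_of(lcx)
  has_change <- vapply(changed, length, integer(1)) > 0L
  active_comps <- unique(comp_of[has_change])
  catalyst <- !is.na(comp_of) & !(comp_of %in% active_comps)
  core <- which(has_change | catalyst)

  # canonical core order: by (role, name, changes) then context serialization
  slot_key <- vapply(core, function(i)
    paste0(if (catalyst[i]) "CAT|" else "CHG|", agent_names(lcx)[i], "|",
           paste(changed[[i]], collapse = ";")), character(1))
  ctx_key <- vapply(core, function(i) format_agents(lcx$agents[i]), character(1))
  core <- core[order(slot_key, ctx_key)]
  slot_key <- slot_key[order(slot_key, ctx_key)]
  pos <- stats::setNames(seq_along(core), core)   # union slot -> core position

  core_pos <- function(union_slot) {
    p <- pos[as.character(union_slot)]
    if (is.na(p)) NA_integer_ else unname(p)
  }
  # bond signatures restricted to bonds with both endpoints in the core (a
  # changed bond always has both endpoints changed or created)
  lhs_bond_sig <- character(0)
  for (p in bond_pairs(lcx)) {
    a <- core_pos(p$agent[1]); b <- core_pos(p$agent[2])
    if (is.na(a) || is.na(b)) next
    lhs_bond_sig <- c(lhs_bond_sig,
                      paste(sort(paste0(c(a, b), ".", p$site)), collapse = "--"))
  }
  rhs_bond_sig <- character(0)
  for (p in bond_pairs(pcx)) {
    ends <- character(2); ok <- TRUE
    for (t in 1:2) {
      sl <- inv[p$agent[t]]
      if (!is.na(sl)) {
        cp <- core_pos(sl)
        if (is.na(cp)) { ok <- FALSE; break }
        ends[t] <- paste0(cp, ".", p$site[t])
      } else ends[t] <- paste0("new", match(p$agent[t], created), ".", p$site[t])
    }
    if (ok) rhs_bond_sig <- c(rhs_bond_sig, paste(sort(ends), collapse = "--"))
  }
  created_sig <- vapply(created, function(j) {
    ag <- pcx$agents[[j]]
    paste0(ag$name, "(", paste(names(ag$states), ag$states, collapse = ","), ")")
  }, character(1))
  changed_bonds_l <- setdiff(lhs_bond_sig, rhs_bond_sig)
  changed_bonds_r <- setdiff(rhs_bond_sig, lhs_bond_sig)
  key <- paste(paste(slot_key, collapse = "&"),
               paste(sort(changed_bonds_l), collapse = "&"),
               paste(sort(changed_bonds_r), collapse = "&"),
               paste(sort(created_sig), collapse = "&"), sep = "||")
  list(key = key, lcx = lcx, pcx = pcx, map = map, inv = inv,
       changed = changed, created = created, core = core,
       catalyst = catalyst, lpm = lpm, ppm = ppm)
}

# Build the generalised rule for a group of descriptors (all with the same
# key, hence the same ordered core). Changed sites always keep their LHS
# value; context on core agents is kept only where identical across every
# member: free stays free, a bond to a dropped spectator becomes a typed
# link (!Partner.site), a bond varying in partner type becomes bound-any,
# anything varying further is omitted.
generalize_group <- function(descs, rate, name, rate_id) {
  d0 <- descs[[1]]
  core0 <- d0$core
  nc <- length(core0)
  pos_of <- stats::setNames(seq_len(nc), core0)   # d0 union slot -> core pos
  bond_counter <- 0L
  bond_ids <- new.env(parent = emptyenv())
  get_bond <- function(a, s, b, s2) {
    key <- paste(sort(c(paste0(a, ".", s), paste0(b, ".", s2))), collapse = "--")
    lab <- get0(key, envir = bond_ids)
    if (is.null(lab)) {
      bond_counter <<- bond_counter + 1L
      lab <- bond_counter
      assign(key, lab, envir = bond_ids)
    }
    lab
  }
  changed_sites <- lapply(d0$changed, function(ch)
    unique(sub("^[~!]([^:]+):.*$", "\\1", ch[ch != "DEL"])))
  lhs_agents <- vector("list", nc)
  rhs_agents <- vector("list", nc)
  for (q in seq_len(nc)) {
    i0 <- core0[q]
    ag0 <- d0$lcx$agents[[i0]]
    deleted <- identical(d0$changed[[i0]], "DEL")
    j0 <- d0$map[i0]
    l_states <- character(0); l_links <- character(0)
    r_states <- character(0); r_links <- character(0)
    for (s in names(ag0$states)) {
      is_changed <- s %in% changed_sites[[i0]] || deleted
      # context agreement across members (member t's core slot q)
      st0 <- ag0$states[[s]]
      same_state <- all(vapply(descs, function(d)
        identical(d$lcx$agents[[d$core[q]]]$states[[s]], st0), logical(1)))
      ld0 <- link_desc(d0$lcx, d0$lpm, i0, s)
      lds <- vapply(descs, function(d)
        link_desc(d$lcx, d$lpm, d$core[q], s), character(1))
      same_link <- all(lds == ld0)
      all_bound <- all(lds != ".")
      # a kept explicit bond must join the same core positions in every member
      bond_partner <- NULL
      if (is_bond(ag0$links[[s]])) {
        p0 <- get(paste0(i0, "\r", s), envir = d0$lpm)
        pq <- pos_of[as.character(p0$agent)]
        if (!is.na(pq)) {
          consistent <- all(vapply(descs, function(d) {
            pt <- get0(paste0(d$core[q], "\r", s), envir = d$lpm)
            !is.null(pt) && identical(unname(pt$agent), unname(d$core[pq])) &&
              pt$site == p0$site
          }, logical(1)))
          if (consistent) bond_partner <- list(pos = unname(pq), site = p0$site)
        }
      }
      keep_state <- !is.na(st0) && (is_changed || same_state)
      # decide lhs link expression
      lk <- NULL
      if (ag0$links[[s]] == ".") {
        if (is_changed || same_link) lk <- "."
      } else if (!is.null(bond_partner)) {
        lk <- paste0("!", get_bond(q, s, bond_partner$pos, bond_partner$site))
      } else if (is_changed || same_link) {
        lk <- paste0("!", ld0)     # typed link to a dropped spectator
      } else if (all_bound) {
        lk <- "_"
      }
      if (!keep_state && is.null(lk)) next
      l_states[s] <- if (keep_state) st0 else NA_character_
      l_links[s] <- lk %||% "?"
      if (!deleted) {
        pa <- d0$pcx$agents[[j0]]
        pst <- pa$states[[s]]
        r_states[s] <- if (is_changed && !identical(pst, st0) && !is.na(pst)) pst
                       else if (keep_state) st0 else NA_character_
        plk <- pa$links[[s]]
        if (!is_changed) {
          # untouched context: mirror the lhs expression
          r_links[s] <- l_links[[s]]
        } else if (plk == ".") {
          r_links[s] <- "."
        } else {
          pp <- get(paste0(j0, "\r", s), envir = d0$ppm)
          sl <- d0$inv[pp$agent]
          end2 <- if (!is.na(sl)) c(pos_of[as.character(sl)], pp$site)
                  else c(paste0("new", match(pp$agent, d0$created)), pp$site)
          r_links[s] <- paste0("!", get_bond(q, s, end2[1], end2[2]))
        }
      }
    }
    lhs_agents[[q]] <- new_agent(ag0$name, l_states, l_links)
    rhs_agents[[q]] <- if (deleted) NULL_AGENT
                       else new_agent(ag0$name, r_states, r_links)
  }
  # created agents appended after the core slots
  for (t in seq_along(d0$created)) {
    j <- d0$created[t]
    ag <- d0$pcx$agents[[j]]
    links <- ag$links
    for (s in names(links)) {
      if (is_bond(links[[s]])) {
        pp <- get(paste0(j, "\r", s), envir = d0$ppm)
        sl <- d0$inv[pp$agent]
        end2 <- if (!is.na(sl)) c(pos_of[as.character(sl)], pp$site)
                else c(paste0("new", match(pp$agent, d0$created)), pp$site)
        links[[s]] <- paste0("!", get_bond(paste0("new", t), s, end2[1], end2[2]))
      }
    }
    lhs_agents[[nc + t]] <- NULL_AGENT
    rhs_agents[[nc + t]] <- new_agent(ag$name, ag$states, links)
  }
  rule(name, new_complex(lhs_agents), new_complex(rhs_agents), rate,
       rate_id = rate_id)
}

#' Condense a reaction list into decontextualised rules
#'
#' Applies the condensation criterion (see the package vignette): reactions
#' of the same transformation type between the same reactants, differing
#' only in unchanging agent states and sharing one rate value, become one
#' rule with the varying context removed. Every produced rule is audited by
#' re-expanding it over the input's species universe; a group whose rule
#' does not regenerate exactly its reactions falls back to fully contextual
#' one-reaction rules, so the round trip
#' `expand(condense(reactions)) == reactions` always holds.
#'
#' @param reactions list of reactions (named multiset `reactants`,
#'   `products`, `rate`, optional `rate_id`, `component`)
#' @param registry named list mapping species id to its `sr_complex` (for
#'   networks from [generate_network()], `net$species`); an entry of `NULL`
#'   makes the species unresolvable and is an error
#' @param rate_tol relative tolerance for rate equality (default 0: exact)
#' @return list with `rules` (list of `sr_rule`, each tagged with the
#'   provenance reactions), and `report` (a [condensation_report()]
#'   data.frame)
#' @export
condense_reactions <- function(reactions, registry, rate_tol = 0) {
  if (inherits(reactions, "reaction_network")) {
    registry <- reactions$species
    reactions <- reactions$reactions
  }
  # work in canonical-id space: imported species may carry arbitrary names
  canon <- vapply(names(registry), function(nm) {
    cx <- registry[[nm]]
    if (is.null(cx)) NA_character_ else canonical_species(cx)
  }, character(1))
  remap <- function(ms) {
    if (!length(ms)) return(ms)
    nm <- names(ms)
    hit <- !is.na(canon[nm])
    nm[hit] <- canon[nm][hit]
    out <- tapply(as.numeric(ms), nm, sum)
    stats::setNames(as.numeric(out), names(out))
  }
  if (any(!is.na(canon)) && !identical(unname(canon), names(registry))) {
    reactions <- lapply(reactions, function(rx) {
      rx$reactants <- remap(rx$reactants)
      rx$products <- remap(rx$products)
      rx
    })
    reg2 <- list()
    for (nm in names(registry)) {
      key <- if (is.na(canon[[nm]])) nm else canon[[nm]]
      if (is.null(reg2[[key]]))
        reg2[[key]] <- if (is.na(canon[[nm]])) NULL else
          parse_complex(canon[[nm]], species = TRUE)
      if (is.na(canon[[nm]])) reg2[nm] <- list(NULL)
    }
    registry <- reg2
  }
  descs <- lapply(reactions, reaction_descriptor, registry = registry)
  comp <- vapply(reactions, function(rx) rx$component %||% NA_character_,
                 character(1))
  rates <- vapply(reactions, `[[`, numeric(1), "rate")
  rate_key <- if (rate_tol > 0) {
    # bucket rates by relative tolerance via sorted union-find sweep
    ordr <- order(rates)
    bucket <- integer(length(rates)); b <- 0L; last <- -Inf
    for (i in ordr) {
      if (last < 0 || (rates[i] - last) > rate_tol * max(last, .Machine$double.eps)) b <- b + 1L
      bucket[i] <- b; last <- rates[i]
    }
    as.character(bucket)
  } else format(rates, digits = 17)
  gkey <- paste(vapply(descs, `[[`, character(1), "key"), rate_key,
                ifelse(is.na(comp), "", comp), sep = "##")
  groups <- split(seq_along(reactions), gkey)

  rules <- list()
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    rid <- unique(vapply(reactions[g], function(rx) rx$rate_id %||% NA_character_,
                         character(1)))
    rid <- if (length(rid) == 1L && !is.na(rid)) rid else sprintf("rc%d", gi)
    cand <- generalize_group(descs[g], rate = rates[g[1]],
                             name = sprintf("rule_%d", gi), rate_id = rid)
    attr(cand, "component") <- if (!is.na(comp[g[1]])) comp[g[1]] else NA_character_
    attr(cand, "reactions") <- g
    ok <- audit_rule(cand, reactions[g], registry, rate_tol = rate_tol)
    if (!is.null(ok)) {
      rules[[length(rules) + 1L]] <- ok
    } else {
      # fall back: one fully contextual rule per reaction
      for (t in seq_along(g)) {
        r1 <- generalize_group(descs[g[t]], rate = rates[g[t]],
                               name = sprintf("rule_%d_%d", gi, t),
                               rate_id = paste0(rid, if (length(g) > 1) paste0("_", t) else ""))
        attr(r1, "component") <- attr(cand, "component")
        attr(r1, "reactions") <- g[t]
        r1 <- audit_rule(r1, reactions[g[t]], registry)
        if (is.null(r1))
          stop("internal: contextual rule failed its own audit for reaction ",
               g[t], call. = FALSE)
        rules[[length(rules) + 1L]] <- r1
      }
    }
  }
  # global audit: expansion over the full universe must not overgenerate
  rules <- global_audit(rules, reactions, descs, registry,
                        rate_tol = rate_tol)
  list(rules = rules, report = condensation_report(reactions, rules))
}

# expand a candidate rule over the species of its own group; returns the
# rule with its rate calibrated by embedding multiplicity, or NULL on
# mismatch with the group's reactions
audit_rule <- function(cand, group_rxns, registry, rate_tol = 0) {
  pool_ids <- unique(unlist(lapply(group_rxns, function(rx)
    c(names(rx$reactants), names(rx$products)))))
  pool <- registry[pool_ids]
  gen <- rule_reactions(cand, pool)
  want <- sort(vapply(group_rxns, function(rx) reaction_key(rx, FALSE), character(1)))
  got <- sort(vapply(gen, function(rx) reaction_key(rx, FALSE), character(1)))
  if (!identical(want, got)) return(NULL)
  if (cand$rate == 0) {
    # zero-rate reactions: multiplicity is irrelevant, keys already matched
    if (all(vapply(group_rxns, `[[`, numeric(1), "rate") == 0)) return(cand)
    return(NULL)
  }
  # multiplicity calibration: generated rate = cand$rate * m, want rx$rate
  m <- gen[[1]]$rate / cand$rate
  target <- group_rxns[[1]]$rate
  cand$rate <- target / m
  # rates of all generated must now equal their targets
  gen2 <- rule_reactions(cand, pool)
  wk <- vapply(group_rxns, function(rx) reaction_key(rx, FALSE), character(1))
  for (rx in gen2) {
    t <- group_rxns[[match(reaction_key(rx, FALSE), wk)]]
    if (abs(rx$rate - t$rate) > max(rate_tol, 1e-12) * max(1, abs(t$rate)))
      return(NULL)
  }
  cand
}

# expand all rules over the full universe and demote any rule that
# generates a reaction outside the input multiset (rates compared within
# rate_tol)
global_audit <- function(rules, reactions, descs, registry, rate_tol = 0) {
  universe_ids <- unique(unlist(lapply(reactions, function(rx)
    c(names(rx$reactants), names(rx$products)))))
  universe <- registry[universe_ids]
  want_nr <- vapply(reactions, function(rx) reaction_key(rx, FALSE), character(1))
  tol <- max(rate_tol, 1e-12)
  matches_input <- function(gen) {
    # only called when the no-rate key multisets already match
    got_nr <- vapply(gen, function(rx) reaction_key(rx, FALSE), character(1))
    ok <- rep(TRUE, length(gen))
    for (key in unique(got_nr)) {
      wr <- sort(vapply(reactions[want_nr == key], `[[`, numeric(1), "rate"))
      gi <- which(got_nr == key)
      gr <- sort(vapply(gen[gi], `[[`, numeric(1), "rate"))
      bad <- abs(gr - wr) > tol * pmax(1, abs(wr))
      ok[gi[bad]] <- FALSE
    }
    ok
  }
  repeat {
    gen <- list()
    for (r in rules) for (rx in rule_reactions(r, universe)) {
      rx$provenance_rule <- r$name
      gen[[length(gen) + 1L]] <- rx
    }
    got_nr <- vapply(gen, function(rx) reaction_key(rx, FALSE), character(1))
    if (identical(sort(want_nr), sort(got_nr))) {
      ok <- matches_input(gen)
      if (all(ok)) return(rules)
      offender <- unique(vapply(gen[!ok], `[[`, character(1),
                                "provenance_rule"))
    } else {
      extra <- setdiff(got_nr, want_nr)
      offender <- unique(vapply(Filter(function(rx)
        reaction_key(rx, FALSE) %in% extra, gen), `[[`, character(1),
        "provenance_rule"))
    }
    demote <- which(vapply(rules, function(r)
      r$name %in% offender && length(attr(r, "reactions")) > 1L, logical(1)))
    if (!length(demote))
      stop("condensation audit failed: expansion does not round-trip and no ",
           "rule can be demoted", call. = FALSE)
    new_rules <- list()
    for (idx in seq_along(rules)) {
      r <- rules[[idx]]
      if (!(idx %in% demote)) { new_rules[[length(new_rules) + 1L]] <- r; next }
      for (t in attr(r, "reactions")) {
        r1 <- generalize_group(descs[t], rate = reactions[[t]]$rate,
                               name = paste0(r$name, "_x", t),
                               rate_id = paste0(r$rate_id, "_x", t))
        attr(r1, "component") <- attr(r, "component")
        attr(r1, "reactions") <- t
        r1 <- audit_rule(r1, reactions[t], registry)
        new_rules[[length(new_rules) + 1L]] <- r1
      }
    }
    rules <- new_rules
  }
}

#' Per-component condensation report
#'
#' Counts, per model component, the input reactions, the produced rules and
#' the unique rate-constant values -- the comparison the translated model's
#' component table makes.
#'
#' @param reactions input reaction list
#' @param rules produced rules (tagged with their source reactions)
#' @return data.frame: `component`, `reactions`, `rules`, `unique_rates`
#' @export
condensation_report <- function(reactions, rules) {
  comp_of_rule <- vapply(rules, function(r)
    attr(r, "component") %||% NA_character_, character(1))
  comp_of_rxn <- vapply(reactions, function(rx)
    rx$component %||% NA_character_, character(1))
  comps <- unique(c(comp_of_rxn, comp_of_rule))
  comps[is.na(comps)] <- "all"
  comp_of_rule[is.na(comp_of_rule)] <- "all"
  comp_of_rxn[is.na(comp_of_rxn)] <- "all"
  comps <- unique(comps)
  do.call(rbind, lapply(comps, function(cc) {
    data.frame(component = cc,
               reactions = sum(comp_of_rxn == cc),
               rules = sum(comp_of_rule == cc),
               unique_rates = length(unique(vapply(
                 rules[comp_of_rule == cc], `[[`, numeric(1), "rate"))),
               stringsAsFactors = FALSE)
  }))
}

#' Write a condensation report as TSV
#'
#' Columns mirror the component table: component, reactions, rules, unique
#' rate constants.
#'
#' @param report data.frame from [condensation_report()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_condensation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
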