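# -- Mixtures -----------------------------------------------------------------

#' Construct a mixture
#'
#' A mixture maps canonical species ids to nonnegative copy numbers and
#' keeps the species graphs alongside.
#'
#' @param species list of `sr_complex` species (or texts), or a named list
#'   keyed by canonical id
#' @param counts numeric copy numbers, same length
#' @param signatures optional signature set used for canonicalisation
#' @return object of class `mixture`
#' @export
mixture <- function(species = list(), counts = numeric(0), signatures = NULL) {
  if (length(species) != length(counts))
    stop("species and counts differ in length", call. = FALSE)
  if (any(counts < 0)) stop("copy numbers must be nonnegative", call. = FALSE)
  sp <- list(); ct <- numeric(0)
  for (i in seq_along(species)) {
    cx <- species[[i]]
    if (is.character(cx)) cx <- parse_complex(cx, species = TRUE, signatures = signatures)
    id <- canonical_species(cx, signatures)
    if (id %in% names(sp)) ct[[id]] <- ct[[id]] + counts[[i]]
    else { sp[[id]] <- parse_complex(id, species = TRUE); ct[[id]] <- counts[[i]] }
  }
  structure(list(species = sp, counts = ct), class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  if (!length(x$counts)) { cat("<empty mixture>\n"); return(invisible(x)) }
  for (id in names(x$counts)) cat(sprintf("%8g  %s\n", x$counts[[id]], id))
  invisible(x)
}

mixture_add <- function(mx, id, cx, n) {
  if (!(id %in% names(mx$species))) {
    mx$species[[id]] <- cx
    mx$counts[[id]] <- 0
  }
  mx$counts[[id]] <- mx$counts[[id]] + n
  if (mx$counts[[id]] < 0) stop("negative copy number for ", id, call. = FALSE)
  mx
}

#' Total agents of a type in a mixture
#' @param mx a `mixture`
#' @param name agent type name
#' @return numeric total over all species, weighted by copy number
#' @export
agent_total <- function(mx, name) {
  tot <- 0
  for (id in names(mx$species))
    tot <- tot + mx$counts[[id]] * count_agents(mx$species[[id]], name)
  tot
}

# -- Rule application ---------------------------------------------------------

# Rewrite a disjoint-union reactant complex according to a rule.
#   ucx     : union of one instance of each reactant complex
#   mapping : integer vector, lhs live-agent index -> union agent index
# Returns list of product complexes (connected components).
rewrite_union <- function(r, ucx, mapping) {
  lhs <- r$lhs; rhs <- r$rhs
  n_lhs <- n_agents(lhs)
  agents <- ucx$agents
  next_bond <- max(c(0L, complex_bonds(ucx)$label)) + 1L
  # mapping as full vector over lhs positions (NA for placeholders)
  full_map <- rep(NA_integer_, n_lhs)
  full_map[live_agents(lhs)] <- mapping

  free_partner <- function(agents, ai, site) {
    lk <- agents[[ai]]$links[[site]]
    if (!is_bond(lk)) return(agents)
    lab <- lk
    for (j in seq_along(agents)) {
      hit <- which(agents[[j]]$links == lab)
      if (length(hit)) agents[[j]]$links[hit] <- "."
    }
    agents
  }

  created_at <- integer(0)       # rhs position -> union index of created agent
  # pass 1: create agents for rhs positions whose lhs slot is a placeholder
  for (i in seq_len(n_agents(rhs))) {
    ra <- rhs$agents[[i]]
    la <- if (i <= n_lhs) lhs$agents[[i]] else NULL_AGENT
    if (!is_null_agent(ra) && is_null_agent(la)) {
      ag <- new_agent(ra$name, ra$states, rep(".", length(ra$states)))
      names(ag$links) <- names(ra$states)
      agents[[length(agents) + 1L]] <- ag
      created_at[[as.character(i)]] <- length(agents)
    }
  }
  deleted <- integer(0)
  # pass 2: per-position edits
  for (i in seq_len(max(n_lhs, n_agents(rhs)))) {
    la <- if (i <= n_lhs) lhs$agents[[i]] else NULL_AGENT
    ra <- if (i <= n_agents(rhs)) rhs$agents[[i]] else NULL_AGENT
    if (is_null_agent(la) && is_null_agent(ra)) next
    if (!is_null_agent(la) && is_null_agent(ra)) {     # deletion
      ui <- full_map[i]
      for (s in names(agents[[ui]]$links)) agents <- free_partner(agents, ui, s)
      deleted <- c(deleted, ui)
      next
    }
    if (is_null_agent(la)) next                         # creation handled above
    ui <- full_map[i]
    for (s in names(ra$states)) {
      st <- ra$states[[s]]
      if (!is.na(st)) agents[[ui]]$states[[s]] <- st
      lk <- ra$links[[s]]
      if (lk == ".") {
        agents <- free_partner(agents, ui, s)
        agents[[ui]]$links[[s]] <- "."
      }
      # "?" and "_" leave the binding untouched; "!n" handled in pass 3
    }
  }
  # pass 3: bonds demanded by the rhs
  rhs_bonds <- bond_pairs(rhs)
  lhs_keys <- bond_key_set(lhs)
  uix <- function(pos) {
    ci <- created_at[as.character(pos)]
    if (length(ci) == 1L && !is.na(ci)) return(unname(ci))
    full_map[pos]
  }
  for (p in rhs_bonds) {
    key <- bond_key(p)
    if (key %in% lhs_keys) next        # preserved bond
    a <- uix(p$agent[1]); b <- uix(p$agent[2])
    agents <- free_partner(agents, a, p$site[1])
    agents <- free_partner(agents, b, p$site[2])
    lab <- paste0("!", next_bond); next_bond <- next_bond + 1L
    agents[[a]]$links[[p$site[1]]] <- lab
    agents[[b]]$links[[p$site[2]]] <- lab
  }
  if (length(deleted)) agents <- agents[-deleted]
  split_components(new_complex(agents))
}

#' Apply a rule at an embedding in a mixture
#'
#' Consumes one copy of each reactant species matched by the embedding and
#' adds the rewritten product species. The embedding must come from
#' [rule_matches()] on the same mixture; a stale embedding (reactant copies
#' no longer available) is rejected.
#'
#' @param r an `sr_rule`
#' @param embedding one element of `rule_matches(r, mx)$matches`
#' @param mx a `mixture`
#' @param signatures optional signature set
#' @return the updated `mixture`
#' @export
apply_rule <- function(r, embedding, mx, signatures = NULL) {
  ids <- embedding$species
  need <- table(ids)
  for (id in names(need)) {
    have <- mx$counts[id]
    if (is.na(have) || have < need[[id]])
      stop("stale embedding: mixture lacks ", need[[id]], " copy/copies of ",
           id, call. = FALSE)
  }
  ucx <- union_complexes(lapply(ids, function(id) mx$species[[id]]))
  prods <- rewrite_union(r, ucx, embedding$mapping)
  for (id in ids) mx$counts[[id]] <- mx$counts[[id]] - 1
  for (pc in prods) {
    pid <- canonical_species(pc, signatures)
    mx <- mixture_add(mx, pid, parse_complex(pid, species = TRUE), 1)
  }
  mx
}

#' Enumerate rule matches in a mixture
#'
#' One match per (unordered assignment of LHS components to species,
#' joint embedding). Each match records the reactant species ids (one copy
#' each; a species used twice appears twice) and the joint mapping from LHS
#' live agents to agent indices of the disjoint union of those copies.
#'
#' @param r an `sr_rule`
#' @param mx a `mixture`
#' @return list with `matches` (list of `list(species, mapping)`)
#' @export
rule_matches <- function(r, mx) {
  pool_ids <- names(mx$species)[mx$counts > 0]
  pool <- mx$species[pool_ids]
  list(matches = joint_embeddings(r, pool))
}

# Joint embeddings of rule LHS components into a pool of species (one
# instance per chosen copy). Returns list(species = chr vector of ids,
# mapping = int vector over lhs live agents -> union agent index).
# Unordered over permutations of identical components: ordered assignments
# are enumerated and then quotiented by the identical-component group sizes
# via a canonical-representative filter.
joint_embeddings <- function(r, pool, require_ids = NULL, caches = NULL) {
  comps <- lhs_components(r$lhs)
  live <- live_agents(r$lhs)
  if (length(comps) == 0L) {
    if (!is.null(require_ids)) return(list())   # zero-order: no new reactants
    return(list(list(species = character(0), mapping = integer(0))))
  }
  # per component: embeddings into each pool species (cached per rule/species)
  comp_str <- vapply(comps, function(ci)
    format_agents(r$lhs$agents[ci]), character(1))
  per_comp <- lapply(seq_along(comps), function(k) {
    ci <- comps[[k]]
    res <- list()
    for (id in names(pool)) {
      ems <- NULL
      ck <- NULL
      if (!is.null(caches)) {
        ck <- paste0(r$name, "\r", k, "\r", id)
        ems <- get0(ck, envir = caches$emb)
      }
      if (is.null(ems)) {
        ems <- embed_component(r$lhs, ci, pool[[id]])
        if (!is.null(ck)) assign(ck, ems, envir = caches$emb)
      }
      for (e in ems) res[[length(res) + 1L]] <- list(id = id, emb = e)
    }
    res
  })
  if (any(vapply(per_comp, length, integer(1)) == 0L)) return(list())
  # cartesian product over components; with require_ids, enumerate only the
  # combinations whose first "new" species occurs at component k (old before
  # k, new at k, anything after) so old-only combinations are never built
  combo_sets <- list()
  if (is.null(require_ids)) {
    combo_sets[[1]] <- lapply(per_comp, seq_along)
  } else {
    is_new <- lapply(per_comp, function(lst)
      vapply(lst, function(x) x$id %in% require_ids, logical(1)))
    for (k in seq_along(comps)) {
      sel <- lapply(seq_along(comps), function(j) {
        if (j < k) which(!is_new[[j]])
        else if (j == k) which(is_new[[j]])
        else seq_along(per_comp[[j]])
      })
      if (all(lengths(sel) > 0L)) combo_sets[[length(combo_sets) + 1L]] <- sel
    }
  }
  out <- list()
  for (sel in combo_sets) {
  grid <- expand.grid(sel, KEEP.OUT.ATTRS = FALSE)
  for (rix in seq_len(nrow(grid))) {
    choice <- lapply(seq_along(comps), function(k) per_comp[[k]][[grid[rix, k]]])
    ids <- vapply(choice, `[[`, character(1), "id")
    # canonical-representative filter over identical components: require the
    # chosen (id, embedding-serial) keys to be nondecreasing within each
    # group of identical component patterns
    keys <- vapply(seq_along(comps), function(k)
      paste0(choice[[k]]$id, "\r", paste(choice[[k]]$emb, collapse = ",")), character(1))
    skip <- FALSE
    for (grp in split(seq_along(comps), comp_str)) {
      if (length(grp) > 1L && is.unsorted(keys[grp])) { skip <- TRUE; break }
    }
    if (skip) next
    # identical components must not use the same (species copy, agents):
    # different copies of one species are distinct instances, so equal keys
    # are allowed only if the species has >= multiplicity copies; instances
    # are materialised per occurrence, and equal embeddings into distinct
    # copies are a single unordered representative (keys equal, kept once).
    # build union mapping with per-occurrence agent offsets
    offs <- integer(length(comps))
    off <- 0L
    for (k in seq_along(comps)) {
      offs[k] <- off
      off <- off + n_agents(pool[[ids[k]]])
    }
    mapping <- integer(length(live))
    for (k in seq_along(comps)) {
      ci <- comps[[k]]
      pos <- match(ci, live)
      mapping[pos] <- choice[[k]]$emb + offs[k]
    }
    out[[length(out) + 1L]] <- list(species = ids, mapping = mapping)
  }
  }
  out
}
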