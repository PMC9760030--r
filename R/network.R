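# -- Reaction networks --------------------------------------------------------

#' Construct a reaction network
#'
#' @param species named list of `sr_complex` (or `NULL` for name-only species
#'   imported from SBML), keyed by canonical id / species name
#' @param reactions list of reactions; each a list with `reactants` and
#'   `products` (named numeric multisets over species ids), `rate`,
#'   `rate_id`, `provenance`, optional `component`
#' @param signatures optional `signature_set`
#' @return object of class `reaction_network`
#' @export
reaction_network <- function(species, reactions, signatures = NULL) {
  for (rx in reactions) {
    bad <- setdiff(c(names(rx$reactants), names(rx$products)), names(species))
    if (length(bad))
      stop("reaction references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (rx$rate < 0) stop("negative rate constant in reaction", call. = FALSE)
  }
  structure(list(species = species, reactions = reactions,
                 signatures = signatures),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  invisible(x)
}

format_reaction <- function(rx) {
  side <- function(ms) {
    if (!length(ms)) return("0")
    paste(ifelse(ms > 1, paste0(ms, " "), ""), names(ms),
          sep = "", collapse = " + ")
  }
  sprintf("%s -> %s @ %.17g [%s]", side(rx$reactants), side(rx$products),
          rx$rate, rx$rate_id)
}

as_multiset <- function(ids) {
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  tb <- table(ids)
  stats::setNames(as.numeric(tb), names(tb))
}

# reaction identity key used for deduplication and multiset comparisons
reaction_key <- function(rx, with_rate = TRUE) {
  ms <- function(m) paste(sort(paste0(names(m), "*", m)), collapse = "+")
  k <- paste0(ms(rx$reactants), ">>", ms(rx$products))
  if (with_rate) k <- paste0(k, "@", format(rx$rate, digits = 15))
  k
}

#' Reactions generated by one rule over a species pool
#'
#' Enumerates joint embeddings of the rule LHS into the pool (one instance
#' per reactant copy), rewrites, and groups outcomes by (reactant multiset,
#' product multiset). The reaction rate constant is the rule constant times
#' the number of joint embeddings per reactant combination in the group (no
#' symmetry rescaling).
#'
#' @param r an `sr_rule`
#' @param pool named list of species complexes keyed by canonical id
#' @param signatures optional signature set
#' @param require_ids if given, only reactant combinations touching at least
#'   one of these species ids are enumerated (incremental closure)
#' @param caches optional environment with persistent embedding and
#'   canonicalisation caches
#' @return list of reactions (see [reaction_network()]); products may
#'   include species absent from `pool`
#' @keywords internal
rule_reactions <- function(r, pool, signatures = NULL, require_ids = NULL,
                           caches = NULL) {
  jes <- joint_embeddings(r, pool, require_ids = require_ids, caches = caches)
  if (!length(jes)) return(list())
  groups <- new.env(parent = emptyenv())
  prod_cache <- if (!is.null(caches)) caches$prod else new.env(parent = emptyenv())
  for (je in jes) {
    ucx <- union_complexes(lapply(je$species, function(id) pool[[id]]))
    prods <- rewrite_union(r, ucx, je$mapping)
    pids <- vapply(prods, function(pc) {
      s <- format_complex(pc)
      hit <- get0(s, envir = prod_cache)
      if (is.null(hit)) {
        hit <- canonical_species(pc, signatures)
        assign(s, hit, envir = prod_cache)
      }
      hit
    }, character(1))
    key <- paste(paste(sort(je$species), collapse = "|"), "=>",
                 paste(sort(pids), collapse = "|"))
    cur <- get0(key, envir = groups)
    if (is.null(cur)) {
      assign(key, list(reactants = je$species, products = pids, n = 1L),
             envir = groups)
    } else {
      cur$n <- cur$n + 1L
      assign(key, cur, envir = groups)
    }
  }
  out <- list()
  for (key in ls(groups)) {
    g <- get(key, envir = groups)
    out[[length(out) + 1L]] <- list(
      reactants = as_multiset(g$reactants),
      products = as_multiset(g$products),
      rate = r$rate * g$n,
      rate_id = r$rate_id,
      provenance = r$name,
      component = attr(r, "component") %||% NA_character_)
  }
  out
}

#' Generate the reaction network reachable from seed species
#'
#' Fixed-point closure: starting from the seed species, every rule is
#' applied to every combination of known species; product species are added
#' and the process repeats until no new species appear (or the species cap
#' is exceeded, which is reported as an error -- the combinatorial-explosion
#' guard).
#'
#' @param rules list of `sr_rule`
#' @param seeds list of species (`sr_complex` or text)
#' @param signatures optional `signature_set`
#' @param species_cap abort threshold on the species count
#' @return a `reaction_network`; the generated network is independent of
#'   rule and seed ordering
#' @export
generate_network <- function(rules, seeds, signatures = NULL,
                             species_cap = 10000L) {
  if (!is.null(signatures)) {
    for (r in rules) {
      v <- validate_rule(r, signatures)
      v <- v[!grepl("^no-op", v)]
      if (length(v))
        stop("invalid rule '", r$name, "': ", paste(v, collapse = "; "),
             call. = FALSE)
    }
  }
  pool <- list()
  for (s in seeds) {
    cx <- if (is.character(s)) parse_complex(s, species = TRUE, signatures = signatures) else s
    if (!is.null(signatures)) cx <- complete_against_signatures(cx, signatures, TRUE)
    id <- canonical_species(cx, signatures)
    pool[[id]] <- parse_complex(id, species = TRUE)
  }
  reactions <- list()
  caches <- list(emb = new.env(parent = emptyenv()),
                 prod = new.env(parent = emptyenv()))
  new_ids <- names(pool)    # frontier: species added in the previous round
  first <- TRUE
  while (length(new_ids)) {
    if (length(pool) > species_cap)
      stop("network too large: species cap (", species_cap, ") exceeded",
           call. = FALSE)
    pending <- list()   # products found this round; pool is frozen per round
    for (r in rules) {
      rxs <- rule_reactions(r, pool, signatures,
                            require_ids = if (first) NULL else new_ids,
                            caches = caches)
      for (rx in rxs) {
        reactions[[length(reactions) + 1L]] <- rx
        for (pid in names(rx$products)) {
          if (!(pid %in% names(pool)) && !(pid %in% names(pending)))
            pending[[pid]] <- parse_complex(pid, species = TRUE)
        }
        if (length(pool) + length(pending) > species_cap)
          stop("network too large: species cap (", species_cap,
               ") exceeded", call. = FALSE)
      }
    }
    pool <- c(pool, pending)
    new_ids <- names(pending)
    first <- FALSE
  }
  pool <- pool[order(names(pool))]
  ord <- order(vapply(reactions, reaction_key, character(1)))
  reaction_network(pool, reactions[ord], signatures)
}

# fall-back signature inference (used only when none are supplied): collect
# agent/site/state mentions from rules and seeds
infer_signatures <- function(rules, seeds) {
  env <- new.env(parent = emptyenv())
  note <- function(cx) {
    for (ag in cx$agents) {
      if (is_null_agent(ag)) next
      cur <- get0(ag$name, envir = env) %||% list(sites = character(0),
                                                  states = list())
      for (s in names(ag$states)) {
        if (!(s %in% cur$sites)) cur$sites <- c(cur$sites, s)
        st <- ag$states[[s]]
        if (!is.na(st)) cur$states[[s]] <- union(cur$states[[s]], st)
      }
      assign(ag$name, cur, envir = env)
    }
  }
  for (r in rules) { note(r$lhs); note(r$rhs) }
  for (s in seeds) note(if (is.character(s)) parse_complex(s) else s)
  sigs <- lapply(ls(env), function(nm) {
    cur <- get(nm, envir = env)
    agent_signature(nm, cur$sites, cur$states)
  })
  signature_set(sigs)
}
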