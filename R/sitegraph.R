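# -- Site-graph representation ------------------------------------------------
#
# A complex (site graph) is a list of agents. Each agent is
#   list(name = <chr>, states = <named chr, NA = unspecified>,
#        links = <named chr>)
# where names(states) == names(links) are the mentioned sites.
# Link codes: "?" unspecified, "." free, "_" bound to anything,
# "!<int>" explicit bond label, "!Agent.site" bound to a typed partner.
# A fully specified species mentions every signature site, has no NA state
# on sites that carry states, and every link is "." or "!<int>".

new_agent <- function(name, states = character(0), links = character(0)) {
  list(name = name, states = states, links = links)
}

new_complex <- function(agents) {
  structure(list(agents = agents), class = "sr_complex")
}

#' @export
print.sr_complex <- function(x, ...) {
  cat(format_complex(x), "\n")
  invisible(x)
}

n_agents <- function(cx) length(cx$agents)

agent_names <- function(cx) vapply(cx$agents, `[[`, character(1), "name")

is_bond <- function(link) grepl("^!\\d+$", link)

bond_label <- function(link) as.integer(sub("^!", "", link))

#' Bond table of a complex
#'
#' @param cx an `sr_complex`
#' @return data.frame with one row per bond endpoint:
#'   columns `label`, `agent` (index), `site`.
#' @keywords internal
complex_bonds <- function(cx) {
  lab <- integer(0); ag <- integer(0); st <- character(0)
  for (i in seq_along(cx$agents)) {
    lk <- cx$agents[[i]]$links
    b <- is_bond(lk)
    if (any(b)) {
      lab <- c(lab, vapply(lk[b], bond_label, integer(1), USE.NAMES = FALSE))
      ag <- c(ag, rep.int(i, sum(b)))
      st <- c(st, names(lk)[b])
    }
  }
  data.frame(label = lab, agent = ag, site = st, stringsAsFactors = FALSE)
}

# For each bond label return the two endpoints; errors if a label does not
# occur exactly twice.
bond_pairs <- function(cx) {
  tab <- complex_bonds(cx)
  if (nrow(tab) == 0L) return(list())
  sp <- split(seq_len(nrow(tab)), tab$label)
  bad <- names(sp)[vapply(sp, length, integer(1)) != 2L]
  if (length(bad)) {
    stop("bond label(s) ", paste(bad, collapse = ", "),
         " must occur exactly twice", call. = FALSE)
  }
  lapply(sp, function(idx) tab[idx, , drop = FALSE])
}

# partner lookup: matrix keyed by "agent\rsite" -> c(partner agent, partner site)
partner_map <- function(cx) {
  prs <- bond_pairs(cx)
  env <- new.env(parent = emptyenv(), size = max(1L, 2L * length(prs)))
  for (p in prs) {
    k1 <- paste0(p$agent[1], "\r", p$site[1])
    k2 <- paste0(p$agent[2], "\r", p$site[2])
    assign(k1, list(agent = p$agent[2], site = p$site[2]), envir = env)
    assign(k2, list(agent = p$agent[1], site = p$site[1]), envir = env)
  }
  env
}

# adjacency over agents through bonds
complex_adjacency <- function(cx) {
  n <- n_agents(cx)
  adj <- vector("list", n)
  for (p in bond_pairs(cx)) {
    a <- p$agent[1]; b <- p$agent[2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Split a complex into connected components
#'
#' Connectivity is through explicit bonds only. Bond labels are preserved
#' within each component.
#'
#' @param cx an `sr_complex`
#' @return list of `sr_complex`
#' @keywords internal
split_components <- function(cx) {
  n <- n_agents(cx)
  if (n == 0L) return(list())
  adj <- complex_adjacency(cx)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  lapply(seq_len(cur), function(k) new_complex(cx$agents[comp == k]))
}

is_connected <- function(cx) length(split_components(cx)) <= 1L

# -- Parsing ------------------------------------------------------------------

# split by commas at parenthesis depth 0
split_top <- function(txt) {
  out <- character(0); depth <- 0L; buf <- character(0)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { out <- c(out, paste(buf, collapse = "")); buf <- character(0) }
    else buf <- c(buf, ch)
  }
  c(out, paste(buf, collapse = ""))
}

parse_site <- function(txt, agent, species = FALSE) {
  m <- regmatches(txt, regexec(
    "^([A-Za-z0-9_]+)(~[A-Za-z0-9_]+)?(!(?:[0-9]+|_|[A-Za-z0-9_]+\\.[A-Za-z0-9_]+)|\\?)?$",
    txt))[[1]]
  if (length(m) == 0L)
    stop("cannot parse site '", txt, "' of agent '", agent, "'", call. = FALSE)
  site <- m[2]
  state <- if (nzchar(m[3])) sub("^~", "", m[3]) else NA_character_
  link <- if (!nzchar(m[4])) "." else if (m[4] == "?") "?" else if (m[4] == "!_") "_" else m[4]
  if (species && link %in% c("?", "_"))
    stop("species site '", txt, "' must be free or carry an explicit bond",
         call. = FALSE)
  list(site = site, state = state, link = link)
}

parse_agent <- function(txt, species = FALSE) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([A-Za-z0-9_]+)\\((.*)\\)$", txt))[[1]]
  if (length(m) == 0L) {
    if (grepl("^[A-Za-z0-9_]+$", txt)) { m <- c(txt, txt, "") }
    else stop("cannot parse agent '", txt, "'", call. = FALSE)
  }
  name <- m[2]
  states <- character(0); links <- character(0)
  if (nzchar(trimws(m[3]))) {
    for (s in split_top(m[3])) {
      p <- parse_site(trimws(s), name, species = species)
      if (p$site %in% names(states))
        stop("site '", p$site, "' mentioned twice in agent '", name, "'",
             call. = FALSE)
      states[p$site] <- p$state
      links[p$site] <- p$link
    }
  }
  new_agent(name, states, links)
}

#' Parse a complex or pattern from Kappa-like text
#'
#' Syntax: comma-separated agents `Name(site[~state][binding], ...)`.
#' Binding marks: nothing = free, `!n` = bond with label `n`, `!_` = bound
#' to an unspecified partner, `!Agent.site` = bound to a typed partner,
#' `?` = binding unspecified. A site not mentioned is fully unspecified.
#' With `species = TRUE` every mentioned site must be free or carry an
#' explicit bond, and (if `signatures` is given) every signature site must
#' be mentioned with a definite state.
#'
#' @param txt character scalar, e.g. `"A(x~u!1),B(y!1)"`
#' @param species logical; require a fully specified species
#' @param signatures optional signature set used to complete/validate
#' @return an `sr_complex`
#' @export
parse_complex <- function(txt, species = FALSE, signatures = NULL) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(new_complex(list()))
  agents <- lapply(split_top(txt), parse_agent, species = species)
  cx <- new_complex(agents)
  bond_pairs(cx) # validates pairing
  if (!is.null(signatures)) cx <- complete_against_signatures(cx, signatures, species)
  cx
}

# order sites by signature, add unmentioned sites (species: as free with the
# first declared state; pattern: leave absent), check site/state existence
complete_against_signatures <- function(cx, signatures, species = FALSE) {
  cx$agents <- lapply(cx$agents, function(ag) {
    sig <- signatures[[ag$name]]
    if (is.null(sig)) stop("unknown agent '", ag$name, "'", call. = FALSE)
    unknown <- setdiff(names(ag$states), sig$sites)
    if (length(unknown))
      stop("agent '", ag$name, "' has no site(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (s in names(ag$states)) {
      st <- ag$states[[s]]
      if (!is.na(st) && !(st %in% sig$internal_states[[s]]))
        stop("state '", st, "' not declared for site '", s, "' of '",
             ag$name, "'", call. = FALSE)
    }
    if (species) {
      for (s in sig$sites) {
        if (!(s %in% names(ag$states))) {
          ag$states[s] <- if (length(sig$internal_states[[s]]))
            sig$internal_states[[s]][1] else NA_character_
          ag$links[s] <- "."
        } else if (is.na(ag$states[[s]]) && length(sig$internal_states[[s]])) {
          stop("species agent '", ag$name, "' site '", s,
               "' needs a definite state", call. = FALSE)
        }
      }
    }
    ord <- intersect(sig$sites, names(ag$states))
    ag$states <- ag$states[ord]
    ag$links <- ag$links[ord]
    ag
  })
  cx
}

# -- Serialization ------------------------------------------------------------

format_site <- function(site, state, link) {
  out <- site
  if (!is.na(state)) out <- paste0(out, "~", state)
  if (link == "?") out <- paste0(out, "?")
  else if (link == "_") out <- paste0(out, "!_")
  else if (link != ".") out <- paste0(out, link)
  out
}

# serialize with bond labels renumbered in order of first appearance
format_agents <- function(agents) {
  seen <- character(0)
  pieces <- vapply(agents, function(ag) {
    ss <- character(length(ag$states))
    for (j in seq_along(ag$states)) {
      link <- ag$links[[j]]
      if (is_bond(link)) {
        lab <- sub("^!", "", link)
        pos <- match(lab, seen)
        if (is.na(pos)) { seen <<- c(seen, lab); pos <- length(seen) }
        link <- paste0("!", pos)
      }
      ss[j] <- format_site(names(ag$states)[j], ag$states[[j]], link)
    }
    paste0(ag$name, "(", paste(ss, collapse = ","), ")")
  }, character(1))
  paste(pieces, collapse = ",")
}

#' Serialize a complex to Kappa-like text
#'
#' Bond labels are renumbered in order of first appearance; the agent and
#' site order of the object is kept.
#'
#' @param cx an `sr_complex`
#' @return character scalar
#' @export
format_complex <- function(cx) format_agents(cx$agents)

# -- Canonicalisation ---------------------------------------------------------

is_fully_specified <- function(cx, signatures = NULL) {
  for (ag in cx$agents) {
    if (any(ag$links %in% c("?", "_"))) return(FALSE)
    if (!is.null(signatures)) {
      sig <- signatures[[ag$name]]
      if (is.null(sig)) return(FALSE)
      if (!setequal(names(ag$states), sig$sites)) return(FALSE)
      for (s in names(ag$states))
        if (is.na(ag$states[[s]]) && length(sig$internal_states[[s]])) return(FALSE)
    }
  }
  TRUE
}

# iterative neighbourhood refinement: returns integer class codes per agent;
# `init` (optional integer vector) seeds the partition, e.g. with
# individualized vertices during canonical search
refine_classes <- function(cx, pm = partner_map(cx), init = NULL) {
  n <- n_agents(cx)
  base <- vapply(seq_len(n), function(i) {
    ag <- cx$agents[[i]]
    lk <- ifelse(is_bond(ag$links), "b", ag$links)
    paste0(ag$name, "|", paste(names(ag$states), ag$states, lk,
                               sep = ":", collapse = ";"))
  }, character(1))
  if (!is.null(init)) base <- paste0(sprintf("%09d", init), "|", base)
  lab <- match(base, sort(unique(base)))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      ag <- cx$agents[[i]]
      nb <- character(0)
      for (s in names(ag$links)) {
        if (is_bond(ag$links[[s]])) {
          p <- get(paste0(i, "\r", s), envir = pm)
          nb <- c(nb, paste0(s, ">", p$site, ">", lab[p$agent]))
        }
      }
      paste0(lab[i], "#", paste(sort(nb), collapse = "&"))
    }, character(1))
    new_lab <- match(sig, sort(unique(sig)))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# serialize agents in a given order (species form)
serialize_order <- function(cx, ord) format_agents(cx$agents[ord])

#' Canonical identifier of a molecular species
#'
#' Computes a string identifier invariant under agent relabeling: iterative
#' neighbourhood refinement assigns structural classes, agents are sorted by
#' class, and the lexicographically minimal serialization over the orderings
#' of class-tied agents is returned. Distinct site occupancies (sites are
#' uniquely named) give distinct identifiers.
#'
#' @param cx an `sr_complex`, connected and fully specified
#' @param signatures optional signature set; if given, sites are ordered and
#'   completeness is checked against it
#' @return character scalar canonical id
#' @export
canonical_species <- function(cx, signatures = NULL) {
  if (is.character(cx)) cx <- parse_complex(cx, species = TRUE, signatures = signatures)
  if (!is.null(signatures)) cx <- complete_against_signatures(cx, signatures, species = TRUE)
  if (n_agents(cx) == 0L) stop("empty complex has no canonical id", call. = FALSE)
  if (!is_connected(cx)) stop("complex is not connected", call. = FALSE)
  if (!is_fully_specified(cx, signatures))
    stop("complex is not fully specified", call. = FALSE)
  n <- n_agents(cx)
  if (n == 1L) return(format_agents(cx$agents))
  # individualization-refinement search: refinement class codes are
  # relabeling-invariant, so at each step the candidates are the remaining
  # agents in the minimal class; individualizing a candidate and re-refining
  # collapses symmetric ties (e.g. palindromic chains) after one choice.
  # The canonical id is the minimal serialization over all search leaves.
  pm <- partner_map(cx)
  best <- NULL
  leaves <- 0L
  search <- function(indiv) {
    lab <- refine_classes(cx, pm, init = indiv)
    remaining <- which(indiv >= n + 1L)   # not yet individualized
    if (!length(remaining)) {
      leaves <<- leaves + 1L
      if (leaves > 10000L)
        stop("complex too symmetric to canonicalise", call. = FALSE)
      ord <- order(indiv)
      s <- serialize_order(cx, ord)
      if (is.null(best) || s < best) best <<- s
      return(invisible())
    }
    cls_min <- min(lab[remaining])
    cands <- remaining[lab[remaining] == cls_min]
    pos <- sum(indiv < n + 1L) + 1L       # next position in the ordering
    for (c in cands) {
      indiv2 <- indiv
      indiv2[c] <- pos
      search(indiv2)
    }
  }
  search(rep(n + 1L, n))
  best
}

# canonical complex: reparse the canonical id so the stored object matches it
canonical_complex <- function(cx, signatures = NULL) {
  id <- canonical_species(cx, signatures)
  structure(parse_complex(id, species = TRUE), canonical_id = id)
}

# disjoint union of complexes with bond labels kept distinct
union_complexes <- function(cxs) {
  agents <- list()
  offset <- 0L
  for (cx in cxs) {
    for (ag in cx$agents) {
      b <- is_bond(ag$links)
      if (any(b)) {
        ag$links[b] <- paste0("!", vapply(ag$links[b], bond_label, integer(1)) +
                                offset)
      }
      agents[[length(agents) + 1L]] <- ag
    }
    labs <- complex_bonds(cx)$label
    if (length(labs)) offset <- offset + max(labs)
  }
  new_complex(agents)
}

# count agents of a given name
count_agents <- function(cx, name) sum(agent_names(cx) == name)
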