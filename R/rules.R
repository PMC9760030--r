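# -- Rules --------------------------------------------------------------------
#
# A rule is a pattern-conditioned rewrite lhs -> rhs with a stochastic rate
# constant. LHS and RHS agents are aligned positionally: agent i of the LHS
# corresponds to agent i of the RHS. A "." placeholder stands for an absent
# agent (created when on the LHS side, deleted when on the RHS side); if one
# side is shorter, it is padded with placeholders.

#' Construct a rule
#'
#' @param name rule name
#' @param lhs,rhs `sr_complex` patterns (or Kappa-like text); agents aligned
#'   by position, `"."` marking creation/deletion slots
#' @param rate nonnegative stochastic rate constant (per second for unary
#'   rules, per second per reactant combination for higher arity)
#' @param rate_id identifier of the rate parameter; rules sharing a constant
#'   share a `rate_id` (defaults to the rule name)
#' @return object of class `sr_rule`
#' @examples
#' rule("bind", "A(x),B(y)", "A(x!1),B(y!1)", 1e-3)
#' @export
rule <- function(name, lhs, rhs, rate, rate_id = name) {
  if (is.character(lhs)) lhs <- parse_rule_side(lhs)
  if (is.character(rhs)) rhs <- parse_rule_side(rhs)
  stopifnot(inherits(lhs, "sr_complex"), inherits(rhs, "sr_complex"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("rate constant must be a single nonnegative number", call. = FALSE)
  nl <- n_agents(lhs); nr <- n_agents(rhs)
  n <- max(nl, nr)
  pad <- function(cx, n) {
    while (n_agents(cx) < n) cx$agents[[n_agents(cx) + 1L]] <- NULL_AGENT
    cx
  }
  lhs <- pad(lhs, n); rhs <- pad(rhs, n)
  structure(list(name = name, lhs = lhs, rhs = rhs,
                 rate = as.numeric(rate), rate_id = rate_id),
            class = "sr_rule")
}

NULL_AGENT <- list(name = NA_character_, states = character(0), links = character(0))

is_null_agent <- function(ag) is.na(ag$name)

# parse one side of a rule, "." entries become placeholders
parse_rule_side <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(new_complex(list()))
  parts <- trimws(split_top(txt))
  agents <- lapply(parts, function(p) {
    if (p == ".") NULL_AGENT else parse_agent(p)
  })
  cx <- new_complex(agents)
  bond_pairs(cx)
  cx
}

#' @export
print.sr_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

format_rule_side <- function(cx) {
  if (n_agents(cx) == 0L) return("")
  seen <- character(0)
  pieces <- vapply(cx$agents, function(ag) {
    if (is_null_agent(ag)) return(".")
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
  # drop trailing placeholders for readability (they are re-padded on parse)
  paste(pieces, collapse = ",")
}

#' Serialize a rule to Kappa-like text
#' @param r an `sr_rule`
#' @return character scalar `'name' lhs -> rhs @ rate`
#' @export
format_rule <- function(r) {
  sprintf("'%s' %s -> %s @ %.17g", r$name, format_rule_side(r$lhs),
          format_rule_side(r$rhs), r$rate)
}

#' Parse a rule from Kappa-like text
#'
#' Accepts `'name' lhs -> rhs @ k`. The name quotes are optional when the
#' name contains no spaces.
#'
#' @param txt character scalar
#' @param rate_id optional rate identifier (defaults to the rule name)
#' @return an `sr_rule`
#' @export
parse_rule <- function(txt, rate_id = NULL) {
  m <- regmatches(txt, regexec(
    "^\\s*(?:'([^']*)'\\s+)?(.*?)\\s*->\\s*(.*?)\\s*@\\s*([-+0-9.eE]+)\\s*$", txt))[[1]]
  if (length(m) == 0L) stop("cannot parse rule: ", txt, call. = FALSE)
  name <- if (nzchar(m[2])) m[2] else paste0("r_", substr(digest_chr(txt), 1, 8))
  rule(name, m[3], m[4], as.numeric(m[5]), rate_id = rate_id %||% name)
}

# small stable string hash (sum of char codes in two bases); only used for
# auto-naming, collisions are harmless
digest_chr <- function(x) {
  v <- utf8ToInt(x)
  a <- sum(v * seq_along(v)) %% 1e9
  b <- sum(v * rev(seq_along(v))) %% 1e9
  sprintf("%09d%09d", a, b)
}

# live (non-placeholder) agent indices
live_agents <- function(cx) which(!vapply(cx$agents, is_null_agent, logical(1)))

#' Validate a rule against agent signatures
#'
#' Checks that every agent, site and state label mentioned by the rule is
#' declared; that bond labels pair up on each side; that the LHS/RHS
#' transformation is limited to bond creation/deletion, internal-state
#' change and agent creation/deletion; and that the rule cannot close a
#' ring, i.e. bind two sites that already lie in the same connected
#' component of the LHS. A rule with `lhs == rhs` is flagged as a no-op.
#'
#' @param r an `sr_rule`
#' @param signatures a `signature_set`
#' @return character vector of violations; empty when the rule is valid
#' @export
validate_rule <- function(r, signatures) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  check_side <- function(cx, side) {
    for (i in live_agents(cx)) {
      ag <- cx$agents[[i]]
      sig <- signatures[[ag$name]]
      if (is.null(sig)) { say("%s: unknown agent '%s'", side, ag$name); next }
      for (s in names(ag$states)) {
        if (!(s %in% sig$sites)) {
          say("%s: agent '%s' has no site '%s'", side, ag$name, s)
          next
        }
        st <- ag$states[[s]]
        if (!is.na(st) && !(st %in% sig$internal_states[[s]]))
          say("%s: state '%s' not declared for %s.%s", side, st, ag$name, s)
        lk <- ag$links[[s]]
        if (grepl("^![A-Za-z]", lk)) {
          pa <- sub("^!", "", lk)
          pn <- strsplit(pa, ".", fixed = TRUE)[[1]]
          psig <- signatures[[pn[1]]]
          if (is.null(psig) || !(pn[2] %in% psig$sites))
            say("%s: typed link %s.%s refers to an undeclared site", side,
                pn[1], pn[2])
        }
      }
    }
    tryCatch(bond_pairs(cx), error = function(e) say("%s: %s", side, conditionMessage(e)))
  }
  check_side(r$lhs, "lhs")
  check_side(r$rhs, "rhs")
  if (length(v)) return(v)

  # ring formation: a bond created by the RHS between two agents already in
  # the same LHS connected component closes a ring
  lhs_comp <- lhs_component_of(r$lhs)
  lhs_bonds <- bond_key_set(r$lhs)
  for (p in bond_pairs(r$rhs)) {
    key <- bond_key(p)
    if (key %in% lhs_bonds) next      # bond preserved, not created
    a <- p$agent[1]; b <- p$agent[2]
    both_old <- a <= length(lhs_comp) && b <= length(lhs_comp) &&
      !is.na(lhs_comp[a]) && !is.na(lhs_comp[b])
    if (both_old && lhs_comp[a] == lhs_comp[b])
      say("rule creates a bond inside one connected component (ring formation): %s",
          key)
  }

  # transformation sanity: aligned agents must keep their names
  for (i in seq_len(n_agents(r$lhs))) {
    la <- r$lhs$agents[[i]]; ra <- r$rhs$agents[[i]]
    if (!is_null_agent(la) && !is_null_agent(ra) && la$name != ra$name)
      say("agent %d changes name %s -> %s; align created/deleted agents with '.'",
          i, la$name, ra$name)
  }
  if (identical(format_rule_side(r$lhs), format_rule_side(r$rhs)))
    say("no-op rule: lhs and rhs are identical")
  v
}

# component index per lhs agent (placeholders NA)
lhs_component_of <- function(lhs) {
  n <- n_agents(lhs)
  comp <- rep(NA_integer_, n)
  live <- live_agents(lhs)
  if (!length(live)) return(comp)
  adj <- complex_adjacency(lhs)
  cur <- 0L
  for (s in live) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      vtx <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[vtx]]) if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

bond_key <- function(p) {
  e <- sort(paste0(p$agent, ".", p$site))
  paste(e, collapse = "--")
}

bond_key_set <- function(cx) vapply(bond_pairs(cx), bond_key, character(1),
                                    USE.NAMES = FALSE)

# split the LHS into connected components of live agents; returns a list of
# list(agents = <lhs agent indices>) in a stable order
lhs_components <- function(lhs) {
  comp <- lhs_component_of(lhs)
  ks <- sort(unique(comp[!is.na(comp)]))
  lapply(ks, function(k) which(!is.na(comp) & comp == k))
}
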