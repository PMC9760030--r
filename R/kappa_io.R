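# -- Restricted Kappa-like model text format ------------------------------------
#
# EBNF (one declaration per line; '#' starts a comment):
#   model        = { line } ;
#   line         = agent_decl | init_decl | obs_decl | mod_decl | rule_decl ;
#   agent_decl   = "%agent:" name "(" [ site { "," site } ] ")" ;
#   site         = name { "~" state } ;
#   init_decl    = "%init:" number complex ;
#   obs_decl     = "%obs:" "'" name "'" [ "species" ] pattern { "|" pattern } ;
#   mod_decl     = "%mod:" time ( "add" number complex
#                               | "set" "'" rate_id "'" number ) ;
#   rule_decl    = "'" name "'" pattern "->" pattern "@" number [ "{" rate_id "}" ] ;
#   complex/pattern = agent { "," agent } ;  agent = name "(" [ sitexpr ] ")" ;
#   sitexpr      = name [ "~" state ] [ "!" (int | "_" | name "." name) | "?" ] ;
# This is a documented subset of the Kappa family of languages, not claimed
# compatible with any KaSim release.

#' Assemble a model
#'
#' @param signatures a `signature_set`
#' @param rules list of `sr_rule`
#' @param init named numeric vector: species text -> initial copies
#' @param observables list of [pattern_observable()]
#' @param events an [event_schedule()]
#' @return object of class `sr_model`
#' @export
sr_model <- function(signatures, rules, init = numeric(0),
                     observables = list(), events = event_schedule()) {
  structure(list(signatures = signatures, rules = rules, init = init,
                 observables = observables, events = events),
            class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("Model: %d agent type(s), %d rule(s), %d initial species, %d observable(s), %d event(s)\n",
              length(x$signatures), length(x$rules), length(x$init),
              length(x$observables), length(x$events$events)))
  invisible(x)
}

#' Write a model in the Kappa-like text format
#'
#' @param model an `sr_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  lines <- character(0)
  for (sig in model$signatures) {
    ss <- vapply(sig$sites, function(s) {
      st <- sig$internal_states[[s]]
      if (length(st)) paste0(s, paste0("~", st, collapse = "")) else s
    }, character(1))
    lines <- c(lines, sprintf("%%agent: %s(%s)", sig$name,
                              paste(ss, collapse = ",")))
  }
  for (i in seq_along(model$init)) {
    lines <- c(lines, sprintf("%%init: %.17g %s", model$init[[i]],
                              names(model$init)[i]))
  }
  for (ob in model$observables) {
    pats <- vapply(ob$patterns, format_complex, character(1))
    lines <- c(lines, sprintf("%%obs: '%s' %s%s", ob$name,
                              if (ob$mode == "species-copies") "species " else "",
                              paste(pats, collapse = " | ")))
  }
  for (r in model$rules) {
    lines <- c(lines, sprintf("'%s' %s -> %s @ %.17g {%s}", r$name,
                              format_rule_side(r$lhs), format_rule_side(r$rhs),
                              r$rate, r$rate_id))
  }
  for (e in model$events$events) {
    lines <- c(lines, if (e$action == "set_rate")
      sprintf("%%mod: %.17g set '%s' %.17g", e$time, e$rate_id, e$value)
      else sprintf("%%mod: %.17g %s %.17g %s", e$time,
                   if (e$action == "add_copies") "add" else "put",
                   e$n, e$species))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from the Kappa-like text format
#'
#' @param path input file
#' @return an `sr_model`
#' @export
read_model <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  sigs <- list(); rules <- list(); init <- numeric(0)
  obs <- list(); evs <- list()
  for (ln in raw) {
    if (startsWith(ln, "%agent:")) {
      body <- trimws(sub("^%agent:", "", ln))
      m <- regmatches(body, regexec("^([A-Za-z0-9_]+)\\((.*)\\)$", body))[[1]]
      if (length(m) == 0L) stop("bad %agent line: ", ln, call. = FALSE)
      sites <- character(0); states <- list()
      if (nzchar(trimws(m[3]))) {
        for (tok in trimws(split_top(m[3]))) {
          parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
          sites <- c(sites, parts[1])
          if (length(parts) > 1) states[[parts[1]]] <- parts[-1]
        }
      }
      sigs[[length(sigs) + 1L]] <- agent_signature(m[2], sites, states)
    } else if (startsWith(ln, "%init:")) {
      body <- trimws(sub("^%init:", "", ln))
      m <- regmatches(body, regexec("^([-+0-9.eE]+)\\s+(.*)$", body))[[1]]
      if (length(m) == 0L) stop("bad %init line: ", ln, call. = FALSE)
      init[[m[3]]] <- as.numeric(m[2])
    } else if (startsWith(ln, "%obs:")) {
      body <- trimws(sub("^%obs:", "", ln))
      m <- regmatches(body, regexec("^'([^']+)'\\s+(species\\s+)?(.*)$", body))[[1]]
      if (length(m) == 0L) stop("bad %obs line: ", ln, call. = FALSE)
      pats <- trimws(strsplit(m[4], "|", fixed = TRUE)[[1]])
      obs[[length(obs) + 1L]] <- pattern_observable(
        m[2], pats, mode = if (nzchar(m[3])) "species-copies" else "agent-instances")
    } else if (startsWith(ln, "%mod:")) {
      body <- trimws(sub("^%mod:", "", ln))
      m <- regmatches(body, regexec(
        "^([-+0-9.eE]+)\\s+set\\s+'([^']+)'\\s+([-+0-9.eE]+)$", body))[[1]]
      if (length(m)) {
        evs[[length(evs) + 1L]] <- event_set_rate(as.numeric(m[2]), m[3],
                                                  as.numeric(m[4]))
        next
      }
      m <- regmatches(body, regexec(
        "^([-+0-9.eE]+)\\s+(add|put)\\s+([-+0-9.eE]+)\\s+(.*)$", body))[[1]]
      if (!length(m)) stop("bad %mod line: ", ln, call. = FALSE)
      evs[[length(evs) + 1L]] <- if (m[3] == "add")
        event_add_copies(as.numeric(m[2]), m[5], as.numeric(m[4]))
      else event_set_copies(as.numeric(m[2]), m[5], as.numeric(m[4]))
    } else if (grepl("->", ln, fixed = TRUE)) {
      m <- regmatches(ln, regexec("\\{([^}]*)\\}\\s*$", ln))[[1]]
      rid <- if (length(m)) m[2] else NULL
      body <- sub("\\s*\\{[^}]*\\}\\s*$", "", ln)
      rules[[length(rules) + 1L]] <- parse_rule(body, rate_id = rid)
    } else stop("cannot parse model line: ", ln, call. = FALSE)
  }
  sigset <- signature_set(sigs)
  # normalise init species against the signatures
  if (length(init)) {
    ids <- vapply(names(init), function(s)
      canonical_species(parse_complex(s, species = TRUE, signatures = sigset),
                        sigset), character(1))
    init <- stats::setNames(as.numeric(init), ids)
  }
  sr_model(sigset, rules, init, obs, event_schedule(evs))
}

#' Initial mixture of a model
#' @param model an `sr_model`
#' @return a `mixture`
#' @export
model_init_mixture <- function(model) {
  mixture(as.list(names(model$init)), as.numeric(model$init),
          model$signatures)
}

#' Generate the reaction network of a model
#'
#' @param model an `sr_model`
#' @param species_cap passed to [generate_network()]
#' @return a `reaction_network`
#' @export
model_network <- function(model, species_cap = 10000L) {
  generate_network(model$rules, as.list(names(model$init)),
                   signatures = model$signatures, species_cap = species_cap)
}
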