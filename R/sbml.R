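# -- SBML import/export (mass-action subset) ------------------------------------
#
# No libsbml binding is available to R here, so a restricted reader/writer
# is implemented over xml2. Supported: SBML Level 2/3 core; compartments;
# species with initialAmount or initialConcentration; global and reaction-
# local parameters; irreversible reactions whose kineticLaw is a product of
# one rate symbol (or number) and the reactant species (to their
# stoichiometric powers), optionally times the compartment; events with a
# time-triggered condition and assignments to species amounts or parameter
# values. Anything else is rejected by name.

sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  # pick the sbml core namespace prefix
  hit <- names(ns)[grepl("sbml", ns)][1]
  if (is.na(hit)) stop("not an SBML document", call. = FALSE)
  hit
}

x1 <- function(node, xp, p) xml2::xml_find_first(node, gsub("s:", paste0(p, ":"), xp))
xa <- function(node, xp, p) xml2::xml_find_all(node, gsub("s:", paste0(p, ":"), xp))
attr_or <- function(node, a, default = NA_character_) {
  v <- xml2::xml_attr(node, a)
  if (is.na(v)) default else v
}

# flatten a MathML <apply><times/> ... </apply> into factor tokens
flatten_times <- function(node, p) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) return(NULL)
    return(flatten_times(kids[[1]], p))
  }
  if (nm == "ci") return(list(list(kind = "ci", id = trimws(xml2::xml_text(node)))))
  if (nm == "cn") return(list(list(kind = "cn", value = as.numeric(xml2::xml_text(node)))))
  if (nm != "apply") return(NULL)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  if (op == "times") {
    out <- list()
    for (k in kids[-1]) {
      f <- flatten_times(k, p)
      if (is.null(f)) return(NULL)
      out <- c(out, f)
    }
    return(out)
  }
  if (op == "power") {
    base <- flatten_times(kids[[2]], p)
    expo <- flatten_times(kids[[3]], p)
    if (is.null(base) || length(base) != 1L || base[[1]]$kind != "ci" ||
        is.null(expo) || length(expo) != 1L || expo[[1]]$kind != "cn")
      return(NULL)
    n <- expo[[1]]$value
    if (n != round(n) || n < 1) return(NULL)
    return(rep(base, n))
  }
  NULL
}

# parse a time-triggered event condition geq/gt(time, cn) -> trigger time
parse_trigger_time <- function(math_node, p) {
  if (is.na(math_node) || is.null(math_node)) return(NULL)
  node <- math_node
  if (xml2::xml_name(node) == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) return(NULL)
    node <- kids[[1]]
  }
  if (xml2::xml_name(node) != "apply") return(NULL)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  if (!(op %in% c("geq", "gt"))) return(NULL)
  lhs <- kids[[2]]; rhs <- kids[[3]]
  is_time <- function(n) xml2::xml_name(n) == "csymbol" &&
    grepl("time", xml2::xml_attr(n, "definitionURL"))
  tval <- function(n) if (xml2::xml_name(n) == "cn")
    as.numeric(xml2::xml_text(n)) else NULL
  if (is_time(lhs)) return(tval(rhs))
  if (is_time(rhs)) return(tval(lhs))
  NULL
}

#' Import a mass-action SBML model
#'
#' Reads species, reactions with mass-action kinetic laws, initial amounts
#' and time-triggered events into a name-only [reaction_network()] plus an
#' [event_schedule()]. Reactions whose kinetic law is not a recognisable
#' mass-action product (e.g. Michaelis-Menten) are rejected with their ids.
#'
#' Deterministic constants are converted to stochastic ones by reaction
#' order, and concentrations to copy numbers, using `ctx` (set
#' `convert = FALSE` to keep the file's units).
#'
#' @param path SBML file
#' @param ctx a [unit_context()]; when the file defines a compartment size,
#'   that size (in litres) replaces `ctx$volume`
#' @param convert convert deterministic constants/concentrations to
#'   stochastic constants/copy numbers
#' @return list with `network` (name-only `reaction_network`), `species`
#'   (data.frame: id, name, initial amount in copies), `events`
#'   (`event_schedule`), `parameters` (named vector), `notes`
#' @export
import_sbml <- function(path, ctx = unit_context(), convert = TRUE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML file: ",
                                           conditionMessage(e), call. = FALSE))
  p <- sbml_ns(doc)
  notes <- character(0)
  comp_nodes <- xa(doc, ".//s:listOfCompartments/s:compartment", p)
  comp_size <- stats::setNames(
    as.numeric(vapply(comp_nodes, attr_or, character(1), a = "size",
                      default = "1")),
    vapply(comp_nodes, attr_or, character(1), a = "id"))
  if (length(comp_size) && is.finite(comp_size[1]) && comp_size[1] > 0)
    ctx <- unit_context(volume = unname(comp_size[1]), avogadro = ctx$avogadro)

  sp_nodes <- xa(doc, ".//s:listOfSpecies/s:species", p)
  sp_id <- vapply(sp_nodes, attr_or, character(1), a = "id")
  sp_name <- vapply(sp_nodes, attr_or, character(1), a = "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  init_amt <- vapply(seq_along(sp_nodes), function(i) {
    amt <- attr_or(sp_nodes[[i]], "initialAmount")
    if (!is.na(amt)) return(as.numeric(amt))
    conc <- attr_or(sp_nodes[[i]], "initialConcentration")
    if (!is.na(conc)) {
      if (convert) return(concentration_to_copies(as.numeric(conc), ctx))
      return(as.numeric(conc))
    }
    0
  }, numeric(1))

  par_nodes <- xa(doc, ".//s:listOfParameters/s:parameter", p)
  params <- stats::setNames(
    as.numeric(vapply(par_nodes, attr_or, character(1), a = "value",
                      default = "NA")),
    vapply(par_nodes, attr_or, character(1), a = "id"))

  rx_nodes <- xa(doc, ".//s:listOfReactions/s:reaction", p)
  reactions <- list()
  rejected <- character(0)
  for (rn in rx_nodes) {
    rid <- attr_or(rn, "id", "unnamed")
    if (identical(attr_or(rn, "reversible"), "true")) {
      rejected <- c(rejected, paste0(rid, " (reversible)"))
      next
    }
    get_side <- function(tag) {
      refs <- xa(rn, paste0("./s:", tag, "/s:speciesReference"), p)
      ids <- vapply(refs, attr_or, character(1), a = "species")
      st <- as.numeric(vapply(refs, attr_or, character(1),
                              a = "stoichiometry", default = "1"))
      stats::setNames(st, ids)
    }
    reactants <- get_side("listOfReactants")
    products <- get_side("listOfProducts")
    kl <- x1(rn, "./s:kineticLaw", p)
    if (is.na(kl)) { rejected <- c(rejected, paste0(rid, " (no kineticLaw)")); next }
    local_nodes <- c(xa(kl, "./s:listOfParameters/s:parameter", p),
                     xa(kl, "./s:listOfLocalParameters/s:localParameter", p))
    local_par <- stats::setNames(
      as.numeric(vapply(local_nodes, attr_or, character(1), a = "value",
                        default = "NA")),
      vapply(local_nodes, attr_or, character(1), a = "id"))
    math <- xml2::xml_find_first(kl, ".//*[local-name()='math']")
    toks <- if (!is.na(math)) flatten_times(math, p) else NULL
    if (is.null(toks)) { rejected <- c(rejected, paste0(rid, " (non-mass-action law)")); next }
    k <- 1; k_seen <- FALSE
    sp_count <- stats::setNames(numeric(0), character(0))
    ok <- TRUE
    for (tok in toks) {
      if (tok$kind == "cn") { k <- k * tok$value; k_seen <- TRUE; next }
      id <- tok$id
      if (id %in% sp_id) {
        sp_count[id] <- (if (id %in% names(sp_count)) sp_count[[id]] else 0) + 1
      } else if (id %in% names(local_par)) {
        k <- k * local_par[[id]]; k_seen <- TRUE
      } else if (id %in% names(params)) {
        k <- k * params[[id]]; k_seen <- TRUE
      } else if (id %in% names(comp_size)) {
        notes <- c(notes, paste0(rid, ": compartment factor in rate law"))
      } else { ok <- FALSE; break }
    }
    if (!ok || !k_seen) { rejected <- c(rejected, paste0(rid, " (non-mass-action law)")); next }
    # the species factors must match the reactant stoichiometry
    want <- reactants[order(names(reactants))]
    got <- sp_count[order(names(sp_count))]
    if (!identical(names(want), names(got)) ||
        !isTRUE(all.equal(as.numeric(want), as.numeric(got)))) {
      rejected <- c(rejected, paste0(rid, " (rate law does not match reactants)"))
      next
    }
    order_n <- sum(reactants)
    if (convert) {
      if (order_n > 2) { rejected <- c(rejected, paste0(rid, " (order > 2)")); next }
      k <- convert_units(k, order_n, ctx)
    }
    reactions[[length(reactions) + 1L]] <- list(
      reactants = reactants, products = products, rate = k,
      rate_id = rid, provenance = rid, component = NA_character_)
  }
  if (length(rejected))
    stop("unsupported kinetic law(s) in: ", paste(rejected, collapse = ", "),
         call. = FALSE)

  # events
  evs <- list()
  for (en in xa(doc, ".//s:listOfEvents/s:event", p)) {
    trig <- xml2::xml_find_first(en, ".//*[local-name()='trigger']//*[local-name()='math']")
    t0 <- parse_trigger_time(trig, p)
    if (is.null(t0)) {
      notes <- c(notes, paste0("event ", attr_or(en, "id", "?"),
                               ": non-time trigger skipped"))
      next
    }
    for (asn in xa(en, ".//s:listOfEventAssignments/s:eventAssignment", p)) {
      var <- attr_or(asn, "variable")
      math <- xml2::xml_find_first(asn, ".//*[local-name()='math']")
      toks <- flatten_times(math, p)
      if (is.null(toks) || length(toks) != 1L) {
        notes <- c(notes, paste0("event assignment to ", var, " skipped"))
        next
      }
      tok <- toks[[1]]
      if (var %in% sp_id && tok$kind == "cn") {
        # event assignments to species are taken in particle numbers
        evs[[length(evs) + 1L]] <- event_set_copies(t0, var, tok$value)
      } else if (var %in% names(params) && tok$kind == "cn") {
        evs[[length(evs) + 1L]] <- event_set_rate(t0, var, tok$value)
      } else {
        notes <- c(notes, paste0("event assignment to ", var, " skipped"))
      }
    }
  }

  species_list <- stats::setNames(vector("list", length(sp_id)), sp_id)
  net <- reaction_network(species_list, reactions, signatures = NULL)
  list(network = net,
       species = data.frame(id = sp_id, name = sp_name,
                            initial_amount = init_amt,
                            stringsAsFactors = FALSE),
       events = event_schedule(evs),
       parameters = params, notes = notes, unit_context = ctx)
}

#' Write a reaction network as SBML (Level 2 Version 4)
#'
#' Minimal mass-action export used for fixtures and round-trip tests:
#' one compartment, species with initialAmount, one global parameter per
#' rate id, kinetic laws `k * reactants`, and time-triggered events.
#'
#' @param net a `reaction_network` (species ids become SBML species ids via
#'   sanitisation; the mapping is returned)
#' @param init named numeric vector of initial amounts (copy numbers)
#' @param path output file
#' @param events optional [event_schedule()]
#' @param volume compartment size
#' @return invisibly, the data.frame mapping species ids to SBML ids
#' @export
write_sbml <- function(net, init, path, events = NULL, volume = 1) {
  ids <- names(net$species)
  sid <- paste0("s", seq_along(ids))
  names(sid) <- ids
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
             '<model id="siterules_export">',
             '<listOfCompartments>',
             sprintf('<compartment id="cell" size="%.17g"/>', volume),
             '</listOfCompartments>', '<listOfSpecies>')
  for (i in seq_along(ids)) {
    amt <- if (ids[i] %in% names(init)) init[[ids[i]]] else 0
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" compartment="cell" initialAmount="%.17g"/>',
      sid[i], esc(ids[i]), amt))
  }
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  rate_ids <- unique(vapply(net$reactions, function(rx)
    rx$rate_id %||% "k", character(1)))
  for (rid in rate_ids) {
    val <- net$reactions[[which(vapply(net$reactions, function(rx)
      identical(rx$rate_id, rid), logical(1)))[1]]]$rate
    lines <- c(lines, sprintf('<parameter id="%s" value="%.17g"/>',
                              sanitize_id(rid), val))
  }
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    side <- function(ms, tag) {
      if (!length(ms)) return(character(0))
      c(sprintf('<%s>', tag),
        sprintf('<speciesReference species="%s" stoichiometry="%g"/>',
                sid[names(ms)], as.numeric(ms)),
        sprintf('</%s>', tag))
    }
    # per-reaction local parameter so reactions sharing a rate_id round-trip
    # with their own effective constants (rule multiplicities differ)
    factors <- c(sprintf('<ci>k</ci>'),
                 unlist(lapply(seq_along(rx$reactants), function(t)
                   rep(sprintf('<ci>%s</ci>', sid[names(rx$reactants)[t]]),
                       rx$reactants[[t]]))))
    math <- if (length(factors) == 1L) factors else
      c('<apply><times/>', factors, '</apply>')
    lines <- c(lines,
               sprintf('<reaction id="r%d" reversible="false">', j),
               side(rx$reactants, "listOfReactants"),
               side(rx$products, "listOfProducts"),
               '<kineticLaw>',
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               math, '</math>',
               '<listOfParameters>',
               sprintf('<parameter id="k" value="%.17g"/>', rx$rate),
               '</listOfParameters>',
               '</kineticLaw>', '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>')
  if (!is.null(events) && length(events$events)) {
    lines <- c(lines, '<listOfEvents>')
    for (e in events$events) {
      var <- if (e$action == "set_rate") sanitize_id(e$rate_id) else sid[[e$species]]
      val <- if (e$action == "set_rate") e$value else e$n
      lines <- c(lines,
                 '<event>', '<trigger>',
                 '<math xmlns="http://www.w3.org/1998/Math/MathML">',
                 '<apply><geq/>',
                 '<csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>',
                 sprintf('<cn>%.17g</cn>', e$time),
                 '</apply>', '</math>', '</trigger>',
                 '<listOfEventAssignments>',
                 sprintf('<eventAssignment variable="%s">', var),
                 '<math xmlns="http://www.w3.org/1998/Math/MathML">',
                 sprintf('<cn>%.17g</cn>', val),
                 '</math>', '</eventAssignment>',
                 '</listOfEventAssignments>', '</event>')
    }
    lines <- c(lines, '</listOfEvents>')
  }
  lines <- c(lines, '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(data.frame(species = ids, sbml_id = unname(sid),
                       stringsAsFactors = FALSE))
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
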