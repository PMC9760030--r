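# -- Observables ---------------------------------------------------------------

#' Pattern observable
#'
#' A named quantity summed over the mixture. In `agent-instances` mode the
#' observable counts embeddings of the pattern(s) (a species containing the
#' pattern twice contributes twice per copy, e.g. total cAMP includes the
#' copies bound to R2C2); in `species-copies` mode it counts copies of
#' species matched at least once.
#'
#' @param name observable name
#' @param patterns character vector of pattern texts (or list of
#'   `sr_complex`); the observable is the sum over patterns
#' @param mode `"agent-instances"` (default) or `"species-copies"`
#' @return object of class `pattern_observable`
#' @export
pattern_observable <- function(name, patterns, mode = c("agent-instances",
                                                        "species-copies")) {
  mode <- match.arg(mode)
  if (is.character(patterns)) patterns <- lapply(patterns, parse_complex)
  structure(list(name = name, patterns = patterns, mode = mode),
            class = "pattern_observable")
}

# per-species weight of an observable over a network's species
observable_weights <- function(ob, net) {
  ids <- names(net$species)
  w <- numeric(length(ids))
  if (inherits(ob, "name_observable")) {
    for (i in seq_along(ids)) {
      nm <- ids[i]
      hit <- any(vapply(ob$patterns, function(p) grepl(p, nm, fixed = TRUE),
                        logical(1)))
      excl <- length(ob$exclusions) &&
        any(vapply(ob$exclusions, function(p) grepl(p, nm, fixed = TRUE),
                   logical(1)))
      w[i] <- as.numeric(hit && !excl)
    }
    return(w)
  }
  for (i in seq_along(ids)) {
    cx <- net$species[[i]]
    if (is.null(cx)) next       # name-only species: pattern observables n/a
    nmatch <- 0
    matched <- FALSE
    for (p in ob$patterns) {
      em <- find_embeddings(p, cx)
      nmatch <- nmatch + length(em)
      matched <- matched || length(em) > 0
    }
    w[i] <- if (ob$mode == "agent-instances") nmatch else as.numeric(matched)
  }
  w
}

#' Name-matching observable over ODE species
#'
#' Aggregates species whose name contains any of the given substrings and
#' none of the exclusions -- the aggregation used to reconstruct observables
#' from an imported ODE model's variable names. A pattern matching zero
#' species raises a warning (not an error).
#'
#' @param name observable name
#' @param species_names character vector of species names to match against
#' @param patterns substrings selecting species
#' @param exclusions substrings removing species
#' @return object of classes `name_observable`/`pattern_observable`, with
#'   the audit field `matched` listing the selected names
#' @export
aggregate_by_name <- function(name, species_names, patterns,
                              exclusions = character(0)) {
  sel <- rep(FALSE, length(species_names))
  for (p in patterns) sel <- sel | grepl(p, species_names, fixed = TRUE)
  for (p in exclusions) sel <- sel & !grepl(p, species_names, fixed = TRUE)
  if (length(patterns) && !any(sel))
    warning("observable '", name, "': no species matched pattern(s) ",
            paste(patterns, collapse = ", "), call. = FALSE)
  structure(list(name = name, patterns = patterns, exclusions = exclusions,
                 matched = species_names[sel], mode = "species-copies"),
            class = c("name_observable", "pattern_observable"))
}
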