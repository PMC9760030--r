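# -- Timed perturbation events -------------------------------------------------

#' Schedule of timed perturbation events
#'
#' Events fire once, at their trigger time, during stochastic or
#' deterministic simulation. Supported actions: `add_copies` (inject `n`
#' copies of a species), `set_rate` (set the constant shared by every
#' reaction carrying a `rate_id`), and `set_copies` (clamp a species count,
#' used by SBML event assignments).
#'
#' @param events list of events, each created by [event_add_copies()],
#'   [event_set_rate()] or [event_set_copies()]
#' @return object of class `event_schedule`, events sorted by time
#' @export
event_schedule <- function(events = list()) {
  if (length(events)) {
    times <- vapply(events, `[[`, numeric(1), "time")
    events <- events[order(times)]
  }
  structure(list(events = events), class = "event_schedule")
}

#' @rdname event_schedule
#' @param time trigger time in seconds (nonnegative)
#' @param species species canonical id or name
#' @param n copies to add (nonnegative)
#' @export
event_add_copies <- function(time, species, n) {
  stopifnot(time >= 0, n >= 0)
  list(time = time, action = "add_copies", species = species, n = n)
}

#' @rdname event_schedule
#' @param rate_id rate identifier shared by the affected reactions
#' @param value new rate constant (nonnegative)
#' @export
event_set_rate <- function(time, rate_id, value) {
  stopifnot(time >= 0, value >= 0)
  list(time = time, action = "set_rate", rate_id = rate_id, value = value)
}

#' @rdname event_schedule
#' @export
event_set_copies <- function(time, species, n) {
  stopifnot(time >= 0, n >= 0)
  list(time = time, action = "set_copies", species = species, n = n)
}

#' @export
print.event_schedule <- function(x, ...) {
  if (!length(x$events)) { cat("<no events>\n"); return(invisible(x)) }
  for (e in x$events) {
    cat(sprintf("t=%-10g %s %s\n", e$time, e$action,
                if (e$action == "set_rate")
                  paste0(e$rate_id, " <- ", e$value)
                else paste0(e$species, if (e$action == "add_copies") " += " else " <- ", e$n)))
  }
  invisible(x)
}

#' Apply one event to a live simulation state
#'
#' `set_rate` updates every reaction sharing the `rate_id` (propensities are
#' refreshed by the caller); `add_copies` increments the species count;
#' `set_copies` overwrites it. Nothing else changes.
#'
#' @param event one event of an [event_schedule()]
#' @param state list with `x` (named copy-number vector over species ids)
#'   and `k` (rate constants per reaction) and `rate_ids` (per reaction)
#' @return the updated state
#' @export
apply_event <- function(event, state) {
  if (event$action == "set_rate") {
    hit <- state$rate_ids == event$rate_id
    if (!any(hit)) stop("unknown rate_id '", event$rate_id, "'", call. = FALSE)
    state$k[hit] <- event$value
  } else {
    if (!(event$species %in% names(state$x)))
      stop("unknown species '", event$species, "'", call. = FALSE)
    if (event$action == "add_copies")
      state$x[[event$species]] <- state$x[[event$species]] + event$n
    else
      state$x[[event$species]] <- event$n
  }
  state
}
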