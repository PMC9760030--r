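# -- Simulation backends -------------------------------------------------------
#
# Both backends operate on an explicit reaction_network in copy-number
# units. The propensity of reaction j is k_j times the number of distinct
# reactant combinations: prod over reactant species of choose(n_i, m_ij)
# (n(n-1)/2 for a homodimerisation). No symmetry rescaling is applied.

# precompute stoichiometry for fast propensity evaluation; reactant factors
# are stored column-wise (padded with the neutral choose(., 0) = 1) so the
# propensity vector is computed with vectorised choose() calls
compile_network <- function(net, observables = NULL) {
  ids <- names(net$species)
  nr <- length(net$reactions)
  react_idx <- vector("list", nr)   # reactant species indices
  react_m <- vector("list", nr)     # their multiplicities
  net_mat <- matrix(0, nrow = length(ids), ncol = nr,
                    dimnames = list(ids, NULL))
  k <- numeric(nr); rate_ids <- character(nr)
  for (j in seq_len(nr)) {
    rx <- net$reactions[[j]]
    ri <- match(names(rx$reactants), ids)
    react_idx[[j]] <- ri
    react_m[[j]] <- as.numeric(rx$reactants)
    net_mat[ri, j] <- net_mat[ri, j] - as.numeric(rx$reactants)
    pi <- match(names(rx$products), ids)
    net_mat[pi, j] <- net_mat[pi, j] + as.numeric(rx$products)
    k[j] <- rx$rate
    rate_ids[j] <- rx$rate_id %||% NA_character_
  }
  depth <- max(c(1L, vapply(react_idx, length, integer(1))))
  prop_idx <- matrix(1L, nrow = depth, ncol = max(nr, 1L))
  prop_m <- matrix(0, nrow = depth, ncol = max(nr, 1L))
  for (j in seq_len(nr)) {
    d <- length(react_idx[[j]])
    if (d) {
      prop_idx[seq_len(d), j] <- react_idx[[j]]
      prop_m[seq_len(d), j] <- react_m[[j]]
    }
  }
  obs <- compile_observables(net, observables)
  list(ids = ids, nr = nr, react_idx = react_idx, react_m = react_m,
       net_mat = net_mat, k = k, rate_ids = rate_ids,
       prop_idx = prop_idx, prop_m = prop_m, depth = depth,
       obs_w = obs$w, obs_names = obs$names)
}

# observable weight matrix: rows = observables, cols = species
compile_observables <- function(net, observables) {
  ids <- names(net$species)
  if (is.null(observables)) {
    w <- diag(length(ids))
    rownames(w) <- ids
    return(list(w = w, names = ids))
  }
  w <- matrix(0, nrow = length(observables), ncol = length(ids))
  nms <- character(length(observables))
  for (i in seq_along(observables)) {
    ob <- observables[[i]]
    nms[i] <- ob$name
    w[i, ] <- observable_weights(ob, net)
  }
  list(w = w, names = nms)
}

propensities <- function(x, cmp, k) {
  if (cmp$nr == 0L) return(numeric(0))
  a <- k
  for (d in seq_len(cmp$depth)) {
    m <- cmp$prop_m[d, ]
    if (all(m == 0)) break
    a <- a * choose(x[cmp$prop_idx[d, ]], m)
  }
  a
}

init_state_vector <- function(cmp, init) {
  x <- stats::setNames(numeric(length(cmp$ids)), cmp$ids)
  if (inherits(init, "mixture")) {
    for (id in names(init$counts)) {
      if (!(id %in% cmp$ids) && init$counts[[id]] > 0)
        stop("initial species ", id, " is not in the network", call. = FALSE)
      if (id %in% cmp$ids) x[[id]] <- init$counts[[id]]
    }
  } else {
    bad <- setdiff(names(init), cmp$ids)
    if (length(bad)) stop("initial species not in network: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x[names(init)] <- init
  }
  if (any(x < 0)) stop("negative initial copy numbers", call. = FALSE)
  x
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Exact direct-method SSA: each step draws the waiting time from an
#' exponential with the total propensity and the reaction channel from the
#' propensity distribution (two uniform variates per event). Timed events
#' interrupt the jump clock at their trigger times and are applied exactly
#' once. Observables are recorded on a fixed grid (last value carried
#' forward between jumps).
#'
#' @param net a `reaction_network`
#' @param init initial state: a `mixture` or named copy-number vector
#' @param t_end end time in seconds (> 0)
#' @param record_dt recording grid spacing
#' @param seed RNG seed (required; same seed, same trajectory)
#' @param events an [event_schedule()] or NULL
#' @param observables list of [pattern_observable()] or NULL (record every
#'   species)
#' @param snapshot_period record a mixture snapshot every this many SSA
#'   events (NULL = none); the final state is always captured
#' @return object of class `sr_trajectory`: `time`, `values` (matrix grid x
#'   observable), `events_log`, `snapshots`, `seed`, `final_state`
#' @export
ssa_run <- function(net, init, t_end, record_dt = t_end / 200, seed,
                    events = NULL, observables = NULL,
                    snapshot_period = NULL) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  cmp <- compile_network(net, observables)
  set.seed(seed)
  x <- init_state_vector(cmp, init)
  k <- cmp$k
  ev <- if (is.null(events)) list() else events$events
  ev_times <- vapply(ev, `[[`, numeric(1), "time")
  ev_ptr <- 1L
  grid <- seq(0, t_end, by = record_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  vals <- matrix(NA_real_, nrow = length(grid), ncol = length(cmp$obs_names),
                 dimnames = list(NULL, cmp$obs_names))
  gi <- 1L
  t <- 0
  n_events <- 0L
  snaps <- list()
  ev_log <- list()
  record_upto <- function(upto) {
    while (gi <= length(grid) && grid[gi] <= upto + 1e-12) {
      vals[gi, ] <<- as.numeric(cmp$obs_w %*% x)
      gi <<- gi + 1L
    }
  }
  next_event_time <- function() if (ev_ptr <= length(ev)) ev_times[ev_ptr] else Inf
  repeat {
    a <- propensities(x, cmp, k)
    if (any(a < 0)) stop("negative propensity", call. = FALSE)
    a0 <- sum(a)
    t_ev <- next_event_time()
    dt <- if (a0 > 0) stats::rexp(1, a0) else Inf
    t_next <- t + dt
    if (t_ev <= min(t_next, t_end)) {
      # perturbation fires first: discard the jump (memorylessness), apply
      record_upto(t_ev)
      t <- t_ev
      st <- apply_event(ev[[ev_ptr]], list(x = x, k = k, rate_ids = cmp$rate_ids))
      x <- st$x; k <- st$k
      ev_log[[length(ev_log) + 1L]] <- c(ev[[ev_ptr]],
                                         list(applied_at = t, event_index = n_events))
      ev_ptr <- ev_ptr + 1L
      next
    }
    if (t_next > t_end) { record_upto(t_end); t <- t_end; break }
    record_upto(t_next)
    t <- t_next
    j <- sample.int(cmp$nr, 1L, prob = a)
    x <- x + cmp$net_mat[, j]
    n_events <- n_events + 1L
    if (!is.null(snapshot_period) && n_events %% snapshot_period == 0L) {
      snaps[[length(snaps) + 1L]] <- list(event_index = n_events, time = t,
                                          counts = x[x > 0])
    }
  }
  if (!is.null(snapshot_period)) {
    snaps[[length(snaps) + 1L]] <- list(event_index = n_events, time = t,
                                        counts = x[x > 0], final = TRUE)
  }
  structure(list(time = grid, values = vals, seed = seed,
                 n_ssa_events = n_events, events_log = ev_log,
                 snapshots = snaps, final_state = x, kind = "ssa"),
            class = "sr_trajectory")
}

#' @export
print.sr_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d grid points, %d observable(s)%s\n",
              toupper(x$kind %||% "?"), length(x$time), ncol(x$values),
              if (!is.null(x$n_replicates)) sprintf(", mean of %d replicates",
                                                    x$n_replicates) else ""))
  invisible(x)
}

#' Run stochastic replicates
#'
#' Replicate `i` uses seed `base_seed + i`; the base seed is recorded on the
#' result.
#'
#' @inheritParams ssa_run
#' @param n_replicates number of replicates
#' @param base_seed base RNG seed
#' @return list of `sr_trajectory` with attribute `base_seed`
#' @export
ssa_replicates <- function(net, init, t_end, record_dt = t_end / 200,
                           n_replicates, base_seed, events = NULL,
                           observables = NULL) {
  out <- lapply(seq_len(n_replicates), function(i)
    ssa_run(net, init, t_end, record_dt, seed = base_seed + i,
            events = events, observables = observables))
  attr(out, "base_seed") <- base_seed
  out
}

#' Deterministic simulation (mass-action ODEs)
#'
#' Builds the mass-action rate equations dx/dt = N a(x) in copy-number units
#' (the same combination-counting propensities as the stochastic backend)
#' and integrates them with a stiff-capable adaptive method
#' (`deSolve::lsoda`). Events are applied as state/parameter discontinuities
#' at their trigger times; integration restarts after each.
#'
#' @inheritParams ssa_run
#' @param rtol,atol relative/absolute integration tolerances
#' @param maxsteps integrator step budget per output interval
#' @return an `sr_trajectory`
#' @export
ode_run <- function(net, init, t_end, record_dt = t_end / 200, events = NULL,
                    observables = NULL, rtol = 1e-6, atol = 1e-9,
                    maxsteps = 1e5) {
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  cmp <- compile_network(net, observables)
  x <- init_state_vector(cmp, init)
  k <- cmp$k
  ev <- if (is.null(events)) list() else events$events
  ev_times <- vapply(ev, `[[`, numeric(1), "time")
  keep <- ev_times <= t_end
  ev <- ev[keep]; ev_times <- ev_times[keep]
  grid <- seq(0, t_end, by = record_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  vals <- matrix(NA_real_, nrow = length(grid), ncol = length(cmp$obs_names),
                 dimnames = list(NULL, cmp$obs_names))
  rhs <- function(t, y, parms) {
    a <- propensities(pmax(y, 0), cmp, parms$k)
    list(as.numeric(cmp$net_mat %*% a))
  }
  seg_bounds <- unique(c(0, ev_times, t_end))
  seg_bounds <- sort(seg_bounds[seg_bounds <= t_end])
  ev_log <- list()
  vals[1, ] <- as.numeric(cmp$obs_w %*% x)
  for (si in seq_len(length(seg_bounds) - 1L + (seg_bounds[length(seg_bounds)] < t_end))) {
    t0 <- seg_bounds[si]
    t1 <- if (si + 1L <= length(seg_bounds)) seg_bounds[si + 1L] else t_end
    # events firing at t0
    for (ei in which(ev_times == t0)) {
      st <- apply_event(ev[[ei]], list(x = x, k = k, rate_ids = cmp$rate_ids))
      x <- st$x; k <- st$k
      ev_log[[length(ev_log) + 1L]] <- c(ev[[ei]], list(applied_at = t0))
    }
    gsel <- grid > t0 + 1e-12 & grid <= t1 + 1e-12
    times <- sort(unique(c(t0, grid[gsel], t1)))
    if (length(times) < 2L) times <- c(t0, t1)
    sol <- tryCatch(
      deSolve::lsoda(y = x, times = times, func = rhs, parms = list(k = k),
                     rtol = rtol, atol = atol, maxsteps = maxsteps),
      error = function(e) stop("integrator failure in segment [", t0, ", ",
                               t1, "]: ", conditionMessage(e), call. = FALSE))
    m <- as.matrix(sol)
    for (g in which(gsel)) {
      row <- m[which.min(abs(m[, "time"] - grid[g])), -1, drop = FALSE]
      vals[g, ] <- as.numeric(cmp$obs_w %*% as.numeric(row))
    }
    x <- stats::setNames(as.numeric(m[nrow(m), -1]), cmp$ids)
  }
  # events exactly at t_end (fire after integration)
  for (ei in which(ev_times == t_end & ev_times > 0)) {
    st <- apply_event(ev[[ei]], list(x = x, k = k, rate_ids = cmp$rate_ids))
    x <- st$x; k <- st$k
    ev_log[[length(ev_log) + 1L]] <- c(ev[[ei]], list(applied_at = t_end))
  }
  structure(list(time = grid, values = vals, events_log = ev_log,
                 final_state = x, kind = "ode"),
            class = "sr_trajectory")
}
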