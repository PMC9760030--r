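# -- Snapshots, censuses and trajectory comparison -----------------------------

#' Snapshots from a stochastic run
#'
#' Convenience wrapper: runs [ssa_run()] with a snapshot period (default
#' every 10,000th event) and returns the snapshots. Each snapshot records
#' the event index, the simulated time and the copy-number map of species
#' present; the final state is always captured.
#'
#' @inheritParams ssa_run
#' @param period_events snapshot period in SSA events (>= 1)
#' @return list of snapshots
#' @export
record_snapshots <- function(net, init, t_end, seed, period_events = 10000L,
                             events = NULL, record_dt = t_end / 200) {
  stopifnot(period_events >= 1)
  tr <- ssa_run(net, init, t_end, record_dt = record_dt, seed = seed,
                events = events, snapshot_period = period_events)
  tr$snapshots
}

#' Species census from snapshots
#'
#' The sampled species census is the union, over snapshots, of species
#' present with at least one copy. It is nondecreasing in simulation length.
#'
#' @param snapshots list of snapshots (from [record_snapshots()] or
#'   `ssa_run(..., snapshot_period = )`)
#' @return character vector of canonical species ids
#' @export
census_species <- function(snapshots) {
  ids <- character(0)
  for (s in snapshots) ids <- union(ids, names(s$counts)[s$counts > 0])
  sort(ids)
}

#' Sampled species containing an agent
#'
#' Isolates, from snapshot data, every sampled species whose complex
#' contains at least one agent of the given type, with the per-species agent
#' count (e.g. active PP2B contains 4 Ca).
#'
#' @param snapshots list of snapshots
#' @param agent agent type name
#' @param net the `reaction_network` that produced the snapshots (supplies
#'   the species graphs)
#' @return data.frame with columns `canonical_id`, `n_agent`
#' @export
species_containing <- function(snapshots, agent, net) {
  known <- vapply(net$species, function(cx)
    !is.null(cx) && any(agent_names(cx) == agent), logical(1))
  if (!is.null(net$signatures) && !(agent %in% names(net$signatures)))
    stop("unknown agent '", agent, "'", call. = FALSE)
  ids <- census_species(snapshots)
  ids <- ids[ids %in% names(net$species)[known]]
  n <- vapply(ids, function(id) count_agents(net$species[[id]], agent),
              numeric(1))
  data.frame(canonical_id = ids, n_agent = as.numeric(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize stochastic replicates
#'
#' Pointwise mean and sample standard deviation over replicate trajectories
#' sharing a common time grid.
#'
#' @param trajectories list of `sr_trajectory` (e.g. from
#'   [ssa_replicates()])
#' @return an `sr_trajectory` with `values` = mean, `sd` = pointwise sample
#'   sd, and `n_replicates`
#' @export
summarize_replicates <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  t0 <- trajectories[[1]]$time
  for (tr in trajectories)
    if (!isTRUE(all.equal(tr$time, t0)))
      stop("replicates have mismatched time grids", call. = FALSE)
  arr <- simplify2array(lapply(trajectories, `[[`, "values"))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  dimnames(mu) <- dimnames(trajectories[[1]]$values)
  dimnames(sdv) <- dimnames(trajectories[[1]]$values)
  structure(list(time = t0, values = mu, sd = sdv,
                 n_replicates = length(trajectories), kind = "ssa-mean"),
            class = "sr_trajectory")
}

#' Compare two trajectories observable by observable
#'
#' Resamples `b` onto `a`'s grid (linear interpolation) and reports, per
#' paired observable, the maximum absolute difference of means scaled by the
#' pooled standard deviation (when either trajectory carries replicate sds)
#' and the area between the curves (trapezoid rule). Unpairable observables
#' are listed, not silently dropped.
#'
#' @param a,b `sr_trajectory`
#' @param pairing named character vector: `names(pairing)` are observables
#'   of `a`, values the corresponding observables of `b`; by default
#'   observables are paired by identical name
#' @return list with `report` (data.frame: observable, max_abs_diff,
#'   max_scaled_diff, area_between), `unpaired`, and `aligned` (list of
#'   per-pair data.frames for plotting)
#' @export
compare_trajectories <- function(a, b, pairing = NULL) {
  if (is.null(pairing)) {
    shared <- intersect(colnames(a$values), colnames(b$values))
    pairing <- stats::setNames(shared, shared)
  }
  unpaired <- c(setdiff(colnames(a$values), names(pairing)),
                setdiff(colnames(b$values), pairing))
  rows <- list(); aligned <- list()
  for (oa in names(pairing)) {
    ob <- pairing[[oa]]
    if (!(oa %in% colnames(a$values)) || !(ob %in% colnames(b$values))) {
      unpaired <- c(unpaired, oa)
      next
    }
    ya <- a$values[, oa]
    yb <- stats::approx(b$time, b$values[, ob], xout = a$time, rule = 2)$y
    d <- ya - yb
    pooled <- NULL
    if (!is.null(a$sd) || !is.null(b$sd)) {
      sa <- if (!is.null(a$sd)) a$sd[, oa] else 0
      sb <- if (!is.null(b$sd))
        stats::approx(b$time, b$sd[, ob], xout = a$time, rule = 2)$y else 0
      pooled <- sqrt(sa^2 + sb^2)
    }
    scaled <- if (!is.null(pooled)) {
      ok <- pooled > 0
      if (any(ok)) max(abs(d[ok]) / pooled[ok]) else NA_real_
    } else NA_real_
    area <- trapz(a$time, abs(d))
    rows[[length(rows) + 1L]] <- data.frame(
      observable = oa, paired_with = ob, max_abs_diff = max(abs(d)),
      max_scaled_diff = scaled, area_between = area,
      stringsAsFactors = FALSE)
    aligned[[oa]] <- data.frame(time = a$time, a = ya, b = yb)
  }
  list(report = do.call(rbind, rows), unpaired = unique(unpaired),
       aligned = aligned)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Write a trajectory as tidy CSV
#'
#' Columns: `time`, `observable`, `value` and (for replicate summaries)
#' `sd`, `n_replicates`.
#'
#' @param tr an `sr_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(tr, path) {
  long <- do.call(rbind, lapply(colnames(tr$values), function(ob) {
    d <- data.frame(time = tr$time, observable = ob, value = tr$values[, ob],
                    stringsAsFactors = FALSE)
    if (!is.null(tr$sd)) { d$sd <- tr$sd[, ob]; d$n_replicates <- tr$n_replicates }
    d
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write snapshots as JSON
#' @param snapshots list of snapshots
#' @param path output file
#' @return `path`, invisibly
#' @export
write_snapshots_json <- function(snapshots, path) {
  payload <- lapply(snapshots, function(s)
    list(event_index = s$event_index, time = s$time,
         species = as.list(s$counts)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
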