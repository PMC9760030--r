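# -- Combinatorial multisite binding ------------------------------------------
#
# One ligand type binds several uniquely named, functionally identical sites
# of a target agent in a fixed number of reversible steps. Because sites are
# uniquely named (Kappa convention), every placement of ligands must be a
# separate rule, and intermediate occupancies materialise as distinct
# molecular species: the "combinatorial binding" encoding used for PP2B
# (4 Ca2+ sites, two 2-ion steps) and R2C2 (4 cAMP sites).

#' Define a multisite binding scheme
#'
#' @param target target agent name (e.g. `"PP2B"`)
#' @param n_sites number of uniquely named ligand sites on the target
#' @param ligand ligand agent name (e.g. `"Ca"`)
#' @param steps list of steps, each `list(ions = <int>, k_on = , k_off = )`;
#'   ion counts must sum to `n_sites`
#' @param site_prefix prefix for the generated site names (`site1..siteN`)
#' @param ligand_site name of the ligand's binding site
#' @param activity optional named character vector mapping bound-count (as
#'   character) to an activity label, e.g. `c("0"="inactive", "2"="half",
#'   "4"="active")`
#' @return object of class `multisite_scheme`
#' @export
multisite_scheme <- function(target, n_sites, ligand, steps,
                             site_prefix = "s", ligand_site = "t",
                             activity = NULL) {
  ions <- vapply(steps, function(s) as.integer(s$ions), integer(1))
  if (sum(ions) != n_sites)
    stop("ions per step must sum to n_sites", call. = FALSE)
  for (s in steps) {
    if (s$k_on < 0 || s$k_off < 0)
      stop("step rates must be nonnegative", call. = FALSE)
  }
  structure(list(target = target, n_sites = as.integer(n_sites),
                 ligand = ligand, steps = steps, site_prefix = site_prefix,
                 ligand_site = ligand_site, activity = activity),
            class = "multisite_scheme")
}

#' Read a multisite scheme from a YAML file
#'
#' Keys mirror the [multisite_scheme()] arguments.
#'
#' @param path YAML file
#' @return a `multisite_scheme`
#' @export
read_multisite_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  multisite_scheme(y$target, y$n_sites, y$ligand, y$steps,
                   site_prefix = y$site_prefix %||% "s",
                   ligand_site = y$ligand_site %||% "t",
                   activity = if (!is.null(y$activity)) unlist(y$activity))
}

scheme_sites <- function(sch) paste0(sch$site_prefix, seq_len(sch$n_sites))

#' Signatures implied by a multisite scheme
#' @param sch a `multisite_scheme`
#' @return a `signature_set` with the target and ligand agents
#' @export
scheme_signatures <- function(sch) {
  signature_set(agent_signature(sch$target, scheme_sites(sch)),
                agent_signature(sch$ligand, sch$ligand_site))
}

# occupancy counts at the start of each step
step_occupancy <- function(sch) {
  ions <- vapply(sch$steps, function(s) as.integer(s$ions), integer(1))
  cumsum(c(0L, ions))[seq_along(ions)]
}

#' Expand a multisite scheme into site-explicit rules
#'
#' Emits one forward rule per (occupancy set reachable at the start of a
#' step, choice of free sites to bind in that step) and the matching reverse
#' rule that unbinds exactly that ion subset. Occupancy is explicit in every
#' rule because rates are step-specific. Rules within a step share a
#' `rate_id` (`<target>_k<step>f` / `..r`).
#'
#' For the PP2B scheme (4 sites, two 2-ion steps) this yields 24 rules:
#' 6 forward + 6 reverse per step.
#'
#' @param sch a `multisite_scheme`
#' @return list of `sr_rule`, each tagged with a `"component"` attribute
#'   `<target> activation`
#' @export
expand_multisite_binding <- function(sch) {
  sites <- scheme_sites(sch)
  occ0 <- step_occupancy(sch)
  rules <- list()
  comp <- paste(sch$target, "activation")
  # reachable occupancy sets at the start of step k: unions of full previous
  # steps, i.e. any subset of size occ0[k] that decomposes into step-sized
  # blocks; with unordered site choices every subset of that size is
  # reachable (blocks are interchangeable), so enumerate all of them
  for (k in seq_along(sch$steps)) {
    st <- sch$steps[[k]]
    ions <- as.integer(st$ions)
    pre <- occ0[k]
    bound_sets <- combn_sets(sch$n_sites, pre)
    for (B in bound_sets) {
      free <- setdiff(seq_len(sch$n_sites), B)
      if (ions > length(free))
        stop("step ", k, " binds more ions than free sites", call. = FALSE)
      for (S in combn_sets_of(free, ions)) {
        rules[[length(rules) + 1L]] <- scheme_rule(sch, sites, B, S, k,
                                                   forward = TRUE, comp)
        rules[[length(rules) + 1L]] <- scheme_rule(sch, sites, B, S, k,
                                                   forward = FALSE, comp)
      }
    }
  }
  rules
}

combn_sets <- function(n, k) combn_sets_of(seq_len(n), k)

combn_sets_of <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > length(v)) return(list())
  if (length(v) == 1L) return(list(v))   # combn() would expand a scalar
  m <- utils::combn(v, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

scheme_rule <- function(sch, sites, B, S, step, forward, comp) {
  n <- sch$n_sites
  lsite <- sch$ligand_site
  # target site expressions: B bound (to anything), S the transacted subset,
  # all other sites free -- occupancy level is explicit
  tgt <- function(binding_S) {
    expr <- character(n)
    bond <- 0L
    for (i in seq_len(n)) {
      if (i %in% B) expr[i] <- paste0(sites[i], "!_")
      else if (i %in% S) {
        bond <- bond + 1L
        expr[i] <- if (binding_S) paste0(sites[i], "!", bond) else sites[i]
      } else expr[i] <- sites[i]
    }
    paste0(sch$target, "(", paste(expr, collapse = ","), ")")
  }
  ligs <- function(bound) {
    vapply(seq_along(S), function(j)
      paste0(sch$ligand, "(", lsite, if (bound) paste0("!", j) else "", ")"),
      character(1))
  }
  unbound_side <- paste(c(tgt(FALSE), ligs(FALSE)), collapse = ",")
  bound_side <- paste(c(tgt(TRUE), ligs(TRUE)), collapse = ",")
  set_lab <- paste(sites[S], collapse = "_")
  pre_lab <- if (length(B)) paste0("@", paste(sites[B], collapse = "_")) else ""
  st <- sch$steps[[step]]
  r <- if (forward) {
    rule(sprintf("%s_bind%d_%s%s", sch$target, step, set_lab, pre_lab),
         unbound_side, bound_side, st$k_on,
         rate_id = sprintf("%s_k%df", sch$target, step))
  } else {
    rule(sprintf("%s_unbind%d_%s%s", sch$target, step, set_lab, pre_lab),
         bound_side, unbound_side, st$k_off,
         rate_id = sprintf("%s_k%dr", sch$target, step))
  }
  attr(r, "component") <- comp
  r
}

#' Number of distinct intermediate species with k of n sites bound
#'
#' Sites are uniquely named, so the distinct canonical species with
#' `k_bound` ligands equal the site subsets: `choose(n_sites, k_bound)`.
#'
#' @param n_sites number of ligand sites
#' @param k_bound number of occupied sites
#' @return integer count
#' @export
count_intermediate_species <- function(n_sites, k_bound) {
  if (k_bound < 0 || k_bound > n_sites)
    stop("k_bound must lie in [0, n_sites]", call. = FALSE)
  choose(n_sites, k_bound)
}

#' Activity observables of a multisite scheme
#'
#' One pattern observable per activity label, counting target agents with
#' the corresponding number of bound sites (summed over site placements).
#'
#' @param sch a `multisite_scheme` with an `activity` map
#' @return list of `pattern_observable`
#' @export
scheme_observables <- function(sch) {
  if (is.null(sch$activity)) return(list())
  sites <- scheme_sites(sch)
  out <- list()
  for (kchr in names(sch$activity)) {
    k <- as.integer(kchr)
    pats <- vapply(combn_sets(sch$n_sites, k), function(B) {
      expr <- ifelse(seq_len(sch$n_sites) %in% B,
                     paste0(sites, "!_"), sites)
      paste0(sch$target, "(", paste(expr, collapse = ","), ")")
    }, character(1))
    out[[length(out) + 1L]] <- pattern_observable(
      name = paste0(sch$target, "_", sch$activity[[kchr]]),
      patterns = pats, mode = "agent-instances")
  }
  out
}
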