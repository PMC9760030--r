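# -- Pattern embeddings -------------------------------------------------------
#
# An embedding maps pattern agents injectively onto target agents so that
# agent names match and every specified site condition holds. Unspecified
# fields ("?" links, NA states, unmentioned sites) match anything.

# does target agent `ta` of complex `tcx` satisfy the non-bond conditions of
# pattern agent `pa`? Bond-label conditions are handled by the backtracker.
agent_site_match <- function(pa, ta, tcx, ti) {
  if (pa$name != ta$name) return(FALSE)
  for (s in names(pa$states)) {
    if (!(s %in% names(ta$states))) return(FALSE)
    st <- pa$states[[s]]
    if (!is.na(st) && !identical(ta$states[[s]], st)) return(FALSE)
    lk <- pa$links[[s]]
    tl <- ta$links[[s]]
    if (lk == "?") next
    if (lk == ".") { if (tl != ".") return(FALSE); next }
    if (lk == "_") { if (!is_bond(tl)) return(FALSE); next }
    if (grepl("^![A-Za-z]", lk)) {       # typed link !Agent.site
      if (!is_bond(tl)) return(FALSE)
      pm <- attr(tcx, "sr_pm") %||% partner_map(tcx)
      p <- get(paste0(ti, "\r", s), envir = pm)
      want <- strsplit(sub("^!", "", lk), ".", fixed = TRUE)[[1]]
      if (tcx$agents[[p$agent]]$name != want[1] || p$site != want[2]) return(FALSE)
      next
    }
    if (!is_bond(tl)) return(FALSE)      # "!n": must be bound; partner checked later
  }
  TRUE
}

#' Find all embeddings of a pattern into a species or mixture
#'
#' Returns every injective, structure-preserving match of the pattern's
#' agents onto the target's agents. For a species target each embedding is
#' an integer vector mapping pattern-agent index to target-agent index. For
#' a mixture target the pattern must be connected; the result is the list of
#' embeddings into each distinct species, each annotated with the species id
#' and weighted by its copy number in the `mixture_count` attribute of the
#' result.
#'
#' @param pattern `sr_complex` pattern (or text)
#' @param target an `sr_complex` species, or a `mixture`
#' @return list of embeddings (integer vectors); possibly empty
#' @export
find_embeddings <- function(pattern, target) {
  if (is.character(pattern)) pattern <- parse_complex(pattern)
  if (inherits(target, "mixture")) {
    if (n_agents(pattern) > 1L && !is_connected(pattern))
      stop("mixture-level matching requires a connected pattern", call. = FALSE)
    out <- list()
    total <- 0
    for (id in names(target$species)) {
      if (target$counts[[id]] <= 0) next
      em <- find_embeddings(pattern, target$species[[id]])
      for (e in em) {
        attr(e, "species") <- id
        out[[length(out) + 1L]] <- e
      }
      total <- total + length(em) * target$counts[[id]]
    }
    attr(out, "mixture_count") <- total
    return(out)
  }
  embed_component(pattern, seq_len(n_agents(pattern)), target)
}

# embeddings of the pattern agents listed in `pidx` (one connected component,
# or any agent set) into species complex `tcx`
embed_component <- function(pcx, pidx, tcx) {
  np <- length(pidx)
  if (np == 0L) return(list(integer(0)))
  nt <- n_agents(tcx)
  if (nt == 0L) return(list())
  ppm <- partner_map(pcx)
  tpm <- partner_map(tcx)
  attr(tcx, "sr_pm") <- tpm
  # order pattern agents so each (after the first of its component) touches a
  # previously placed agent when possible
  order_idx <- order_for_matching(pcx, pidx, ppm)
  res <- list()
  assign_vec <- stats::setNames(rep(NA_integer_, np), pidx)
  used <- rep(FALSE, nt)

  consistent <- function(p, t) {
    pa <- pcx$agents[[p]]
    if (!agent_site_match(pa, tcx$agents[[t]], tcx, t)) return(FALSE)
    # explicit bonds: partners already placed must correspond
    for (s in names(pa$links)) {
      if (!is_bond(pa$links[[s]])) next
      pp <- get0(paste0(p, "\r", s), envir = ppm)
      if (is.null(pp)) next
      tt <- get0(paste0(t, "\r", s), envir = tpm)
      if (is.null(tt)) return(FALSE)   # pattern bound, target free here
      placed <- assign_vec[[as.character(pp$agent)]]
      if (!is.na(placed)) {
        if (placed != tt$agent || pp$site != tt$site) return(FALSE)
      } else {
        # partner not yet placed: target partner must at least satisfy name
        if (pcx$agents[[pp$agent]]$name != tcx$agents[[tt$agent]]$name)
          return(FALSE)
        if (pp$site != tt$site) return(FALSE)
      }
    }
    TRUE
  }

  recurse <- function(k) {
    if (k > np) {
      res[[length(res) + 1L]] <<- stats::setNames(assign_vec[as.character(pidx)],
                                                  NULL)
      return(invisible())
    }
    p <- order_idx[k]
    for (t in seq_len(nt)) {
      if (used[t]) next
      if (!consistent(p, t)) next
      assign_vec[[as.character(p)]] <<- t
      used[t] <<- TRUE
      recurse(k + 1L)
      assign_vec[[as.character(p)]] <<- NA_integer_
      used[t] <<- FALSE
    }
  }
  recurse(1L)
  # each result maps pidx (in original order) -> target index
  lapply(res, function(r) stats::setNames(as.integer(r), NULL))
}

# BFS-ish ordering of pattern agents along bonds for early pruning
order_for_matching <- function(pcx, pidx, ppm) {
  remaining <- pidx
  out <- integer(0)
  adj <- complex_adjacency(pcx)
  while (length(remaining)) {
    seedpos <- 1L
    queue <- remaining[seedpos]
    remaining <- remaining[-seedpos]
    out <- c(out, queue)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- intersect(adj[[v]], remaining)
      if (length(nb)) {
        remaining <- setdiff(remaining, nb)
        out <- c(out, nb)
        queue <- c(queue, nb)
      }
    }
  }
  out
}

#' Count pattern matches in a mixture
#'
#' Agent-instances counting: the number of embeddings of the pattern into
#' the mixture, weighting each species by its copy number.
#'
#' @param pattern pattern complex or text
#' @param mixture a `mixture`
#' @return numeric count
#' @export
count_embeddings <- function(pattern, mixture) {
  em <- find_embeddings(pattern, mixture)
  attr(em, "mixture_count") %||% length(em)
}
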