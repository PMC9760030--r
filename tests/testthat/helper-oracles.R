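# Brute-force oracles, independent of the engine's matcher: all injective
# maps are enumerated and every site condition is checked directly.

all_injections <- function(np, nt) {
  if (np == 0L) return(list(integer(0)))
  if (np > nt) return(list())
  out <- list()
  rec <- function(acc, remaining) {
    if (length(acc) == np) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (t in remaining) rec(c(acc, t), setdiff(remaining, t))
  }
  rec(integer(0), seq_len(nt))
  out
}

# partner lookup table computed from scratch
oracle_partners <- function(cx) {
  tab <- list()
  lab_ends <- list()
  for (i in seq_along(cx$agents)) {
    lk <- cx$agents[[i]]$links
    for (s in names(lk)) {
      if (grepl("^!\\d+$", lk[[s]])) {
        lab <- lk[[s]]
        lab_ends[[lab]] <- c(lab_ends[[lab]], list(list(agent = i, site = s)))
      }
    }
  }
  for (lab in names(lab_ends)) {
    e <- lab_ends[[lab]]
    stopifnot(length(e) == 2L)
    tab[[paste0(e[[1]]$agent, ".", e[[1]]$site)]] <- e[[2]]
    tab[[paste0(e[[2]]$agent, ".", e[[2]]$site)]] <- e[[1]]
  }
  tab
}

# check one candidate injection pattern-agent -> target-agent
oracle_check_map <- function(pcx, tcx, map) {
  pp <- oracle_partners(pcx)
  tp <- oracle_partners(tcx)
  for (i in seq_along(pcx$agents)) {
    pa <- pcx$agents[[i]]; ta <- tcx$agents[[map[i]]]
    if (pa$name != ta$name) return(FALSE)
    for (s in names(pa$states)) {
      if (!(s %in% names(ta$states))) return(FALSE)
      st <- pa$states[[s]]
      if (!is.na(st) && !identical(ta$states[[s]], st)) return(FALSE)
      plk <- pa$links[[s]]; tlk <- ta$links[[s]]
      if (plk == "?") next
      if (plk == ".") { if (tlk != ".") return(FALSE); next }
      tgt_partner <- tp[[paste0(map[i], ".", s)]]
      if (plk == "_") { if (is.null(tgt_partner)) return(FALSE); next }
      if (grepl("^![A-Za-z]", plk)) {
        if (is.null(tgt_partner)) return(FALSE)
        want <- strsplit(sub("^!", "", plk), ".", fixed = TRUE)[[1]]
        if (tcx$agents[[tgt_partner$agent]]$name != want[1] ||
            tgt_partner$site != want[2]) return(FALSE)
        next
      }
      # explicit bond: target must be bound and partners must correspond
      if (is.null(tgt_partner)) return(FALSE)
      pat_partner <- pp[[paste0(i, ".", s)]]
      if (is.null(pat_partner)) return(FALSE)
      if (map[pat_partner$agent] != tgt_partner$agent ||
          pat_partner$site != tgt_partner$site) return(FALSE)
    }
  }
  TRUE
}

# brute-force embedding enumeration of a (connected or not) pattern into a
# single species complex
oracle_embeddings <- function(pattern, target) {
  if (is.character(pattern)) pattern <- parse_complex(pattern)
  if (is.character(target)) target <- parse_complex(target, species = TRUE)
  maps <- all_injections(length(pattern$agents), length(target$agents))
  Filter(function(m) oracle_check_map(pattern, target, m), maps)
}

# breadth-first closure oracle: species set reachable from seeds, matching
# with the brute-force matcher (one instance per reactant copy, components
# on distinct instances, unordered assignments)
oracle_closure <- function(rules, seeds, sigs, cap = 1000L) {
  pool <- character(0)
  graphs <- list()
  add_sp <- function(id) {
    if (!(id %in% pool)) {
      pool <<- c(pool, id)
      graphs[[id]] <<- parse_complex(id, species = TRUE)
    }
  }
  for (s in seeds) add_sp(canonical_species(s, sigs))
  rxn_keys <- character(0)
  emb_memo <- new.env(parent = emptyenv())     # (rule, comp, species) -> embs
  canon_memo <- new.env(parent = emptyenv())   # serialized graph -> id
  done_tuples <- new.env(parent = emptyenv())  # processed (rule, tuple)
  memo_embs <- function(r, k, ci, id) {
    key <- paste(r$name, k, id, sep = "\r")
    v <- get0(key, envir = emb_memo)
    if (is.null(v)) {
      v <- oracle_embeddings(siterules:::new_complex(r$lhs$agents[ci]),
                             graphs[[id]])
      assign(key, v, envir = emb_memo)
    }
    v
  }
  memo_canon <- function(pc) {
    s <- format_complex(pc)
    v <- get0(s, envir = canon_memo)
    if (is.null(v)) {
      v <- canonical_species(pc, sigs)
      assign(s, v, envir = canon_memo)
    }
    v
  }
  repeat {
    grew <- FALSE
    for (r in rules) {
      comps <- siterules:::lhs_components(r$lhs)
      live <- siterules:::live_agents(r$lhs)
      nc <- length(comps)
      # ordered tuples of species ids with repetition
      tuples <- if (nc == 0L) list(character(0)) else {
        grid <- do.call(expand.grid, c(rep(list(pool), nc),
                                       list(stringsAsFactors = FALSE)))
        lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
      }
      for (tp in tuples) {
        tkey <- paste(r$name, paste(tp, collapse = "\r"), sep = "\r\r")
        if (!is.null(get0(tkey, envir = done_tuples))) next
        assign(tkey, TRUE, envir = done_tuples)
        offs <- cumsum(c(0, vapply(tp, function(id)
          length(graphs[[id]]$agents), numeric(1))))
        # per-component embeddings into its assigned instance
        emb_per <- lapply(seq_len(nc), function(k)
          lapply(memo_embs(r, k, comps[[k]], tp[k]), function(e) e + offs[k]))
        if (nc && any(vapply(emb_per, length, integer(1)) == 0L)) next
        ucx <- siterules:::union_complexes(lapply(tp, function(id) graphs[[id]]))
        combos <- if (nc == 0L) list(integer(0)) else {
          g <- do.call(expand.grid, c(lapply(emb_per, seq_along),
                                      list(KEEP.OUT.ATTRS = FALSE)))
          lapply(seq_len(nrow(g)), function(i)
            unlist(lapply(seq_len(nc), function(k) emb_per[[k]][[g[i, k]]])))
        }
        for (cb in combos) {
          mapping <- integer(length(live))
          pos <- 1L
          for (k in seq_len(nc)) {
            ci <- comps[[k]]
            mapping[match(ci, live)] <- cb[pos:(pos + length(ci) - 1L)]
            pos <- pos + length(ci)
          }
          prods <- siterules:::rewrite_union(r, ucx, mapping)
          pids <- vapply(prods, memo_canon, character(1))
          key <- paste(r$name, paste(sort(tp), collapse = "+"),
                       paste(sort(pids), collapse = "+"))
          if (!(key %in% rxn_keys)) rxn_keys <- c(rxn_keys, key)
          for (pid in pids) {
            if (!(pid %in% pool)) { add_sp(pid); grew <- TRUE }
          }
          if (length(pool) > cap) stop("oracle closure cap exceeded")
        }
      }
    }
    if (!grew) break
  }
  list(species = sort(pool), reactions = sort(unique(rxn_keys)))
}

nonzero_counts <- function(mx) {
  ct <- mx$counts[mx$counts > 0]
  ct[order(names(ct))]
}
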