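# -- Agent signatures ---------------------------------------------------------

#' Declare an agent type
#'
#' An agent signature names an agent type, its sites (unique within the
#' agent) and, per site, the finite set of internal-state labels the site
#' may take (empty for pure binding sites). The first declared state is the
#' default used when a species is completed from a partial description.
#'
#' @param name agent type name
#' @param sites character vector of site names
#' @param internal_states named list mapping site name to a character vector
#'   of state labels; sites not listed carry no internal state
#' @return an object of class `agent_signature`
#' @examples
#' agent_signature("D", c("t34", "t75", "s137", "b"),
#'                 list(t34 = c("u", "p"), t75 = c("u", "p"),
#'                      s137 = c("u", "p")))
#' @export
agent_signature <- function(name, sites = character(0), internal_states = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (anyDuplicated(sites))
    stop("site names must be unique within agent '", name, "'", call. = FALSE)
  unknown <- setdiff(names(internal_states), sites)
  if (length(unknown))
    stop("internal states declared for unknown site(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  st <- stats::setNames(vector("list", length(sites)), sites)
  for (s in sites) st[[s]] <- as.character(internal_states[[s]] %||% character(0))
  structure(list(name = name, sites = sites, internal_states = st),
            class = "agent_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agent_signature <- function(x, ...) {
  ss <- vapply(x$sites, function(s) {
    st <- x$internal_states[[s]]
    if (length(st)) paste0(s, "~", paste(st, collapse = "~")) else s
  }, character(1))
  cat(sprintf("%%agent: %s(%s)\n", x$name, paste(ss, collapse = ",")))
  invisible(x)
}

#' Bundle agent signatures into a signature set
#'
#' @param ... `agent_signature` objects (or a single list of them)
#' @return named list of signatures, class `signature_set`
#' @export
signature_set <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1L && !inherits(sigs[[1]], "agent_signature"))
    sigs <- sigs[[1]]
  nm <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate agent signature(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  structure(stats::setNames(sigs, nm), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  for (s in x) print(s)
  invisible(x)
}
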