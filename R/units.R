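# -- Unit context and rate conversion -----------------------------------------

AVOGADRO <- 6.02214076e23

#' Reaction volume context
#'
#' Holds the reaction volume and Avogadro's constant used to convert
#' deterministic (concentration-based) rate constants and molar
#' concentrations into stochastic constants and copy numbers.
#'
#' @param volume reaction volume in litres (default 1e-15 L, a typical
#'   eukaryotic-compartment working volume; documented model assumption)
#' @param avogadro Avogadro constant, per mole
#' @return object of class `unit_context`
#' @export
unit_context <- function(volume = 1e-15, avogadro = AVOGADRO) {
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  structure(list(volume = volume, avogadro = avogadro), class = "unit_context")
}

#' Convert a deterministic rate constant to a stochastic one
#'
#' Standard mass-action conversion: zeroth order `k * N_A * V`
#' (M/s to copies/s), first order unchanged, second order `k / (N_A * V)`
#' (per-molar-per-second to per-pair-per-second).
#'
#' @param k_det deterministic rate constant (molar-based units)
#' @param order reaction order (0, 1 or 2; the generated networks contain at
#'   most bimolecular steps)
#' @param ctx a [unit_context()]
#' @return stochastic rate constant, per second (per reactant combination)
#' @export
convert_units <- function(k_det, order, ctx = unit_context()) {
  if (!(order %in% 0:2))
    stop("reaction order ", order, " unsupported (0, 1 or 2)", call. = FALSE)
  nav <- ctx$avogadro * ctx$volume
  switch(as.character(order),
         "0" = k_det * nav,
         "1" = k_det,
         "2" = k_det / nav)
}

#' Convert a molar concentration to a copy number
#'
#' @param conc concentration in mol/L
#' @param ctx a [unit_context()]
#' @return integer copy number `round(conc * N_A * V)`
#' @export
concentration_to_copies <- function(conc, ctx = unit_context()) {
  if (any(conc < 0)) stop("concentration must be nonnegative", call. = FALSE)
  round(conc * ctx$avogadro * ctx$volume)
}
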