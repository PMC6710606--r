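#' Convert a dissociation constant to a binding free energy
#'
#' Uses the standard signed convention \eqn{\Delta G = RT \ln K_d}, which is
#' negative for binders (\eqn{K_d < 1} M).
#'
#' @param kd Dissociation constant(s) in molar. Must be positive.
#' @param params A [ThermoParams-class] object.
#' @return Binding free energy in kcal/mol (signed), vectorized over `kd`.
#' @examples
#' deltaGFromKd(1e-9)   # a nanomolar binder, about -12.3 kcal/mol
#' deltaGFromKd(1)      # 0 by definition
#' @seealso [kdFromDeltaG()] for the inverse.
#' @export
deltaGFromKd <- function(kd, params = thermoParams()) {
  stopifnot(is(params, "ThermoParams"))
  if (!length(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be positive and finite (molar units)", call. = FALSE)
  params@gasConstant * params@temperature * log(kd)
}

#' Convert a binding free energy back to a dissociation constant
#'
#' @param deltaG Signed binding free energy in kcal/mol.
#' @param params A [ThermoParams-class] object.
#' @return Dissociation constant in molar.
#' @examples
#' kdFromDeltaG(deltaGFromKd(1e-6))  # round-trips to 1e-6
#' @export
kdFromDeltaG <- function(deltaG, params = thermoParams()) {
  stopifnot(is(params, "ThermoParams"))
  if (!length(deltaG) || any(!is.finite(deltaG)))
    stop("'deltaG' must be finite", call. = FALSE)
  exp(deltaG / (params@gasConstant * params@temperature))
}

.applyConvention <- function(value, convention) {
  value <- if (convention == "magnitude") abs(value) else value
  attr(value, "convention") <- convention
  value
}

#' Ligand efficiency
#'
#' The binding free energy normalised by heavy-atom count,
#' \eqn{LE = \Delta G / N}: the average affinity contribution per
#' non-hydrogen atom. Values around 0.3 kcal mol^-1 HA^-1 (magnitude) are
#' the conventional hit threshold in fragment-based screening.
#'
#' @param deltaG Signed binding free energy/energies in kcal/mol.
#' @param nHeavy Heavy-atom count(s); positive integers.
#' @param convention `"magnitude"` (default; `|deltaG|/N`, the familiar
#'   positive scale) or `"signed"` (`deltaG/N`). The convention used is
#'   recorded as an attribute on the result.
#' @return Ligand efficiency in kcal mol^-1 per heavy atom, vectorized.
#' @examples
#' ligandEfficiency(-12.28, 25)            # ~0.49, efficient
#' ligandEfficiency(-4, 10, "signed")      # -0.4
#' @export
ligandEfficiency <- function(deltaG, nHeavy,
                             convention = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  if (!length(deltaG) || any(!is.finite(deltaG)))
    stop("'deltaG' must be finite", call. = FALSE)
  if (any(is.na(nHeavy)) || any(nHeavy < 1) || any(nHeavy != round(nHeavy)))
    stop("'nHeavy' must contain integers >= 1", call. = FALSE)
  .applyConvention(deltaG / nHeavy, convention)
}

#' Group efficiency
#'
#' Efficiency of the atoms added between two structurally related
#' molecules A and B: \eqn{GE = \Delta\Delta G / \Delta N} with
#' \eqn{\Delta\Delta G = \Delta G_B - \Delta G_A} and
#' \eqn{\Delta N = N_B - N_A}. Undefined when both molecules have the same
#' heavy-atom count.
#'
#' @param deltaGA,nHeavyA Free energy (kcal/mol, signed) and heavy-atom
#'   count of the reference molecule A.
#' @param deltaGB,nHeavyB Same for the elaborated molecule B.
#' @param convention `"magnitude"` or `"signed"` (see
#'   [ligandEfficiency()]).
#' @return Group efficiency in kcal mol^-1 per heavy atom.
#' @examples
#' groupEfficiency(-5, 10, -7, 14)  # the 4 added atoms bring 0.5 each
#' @export
groupEfficiency <- function(deltaGA, nHeavyA, deltaGB, nHeavyB,
                            convention = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  if (any(!is.finite(c(deltaGA, deltaGB))))
    stop("free energies must be finite", call. = FALSE)
  if (any(nHeavyB == nHeavyA))
    stop("group efficiency is undefined when both molecules have the same heavy-atom count (delta N = 0)",
         call. = FALSE)
  .applyConvention((deltaGB - deltaGA) / (nHeavyB - nHeavyA), convention)
}

#' Heavy-atom count of a SMILES string
#'
#' Counts the non-hydrogen atoms of each molecule, including carbons
#' written implicitly in aromatic rings. Parsing is delegated to Open
#' Babel via ChemmineR.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer vector of heavy-atom counts, named by the input.
#' @examples
#' \dontrun{
#' heavyAtomCount(c("c1ccccc1", "CCO"))  # 6, 3
#' }
#' @export
heavyAtomCount <- function(smiles) {
  if (!length(smiles) || any(is.na(smiles)) || !is.character(smiles))
    stop("'smiles' must be a character vector without NA", call. = FALSE)
  out <- vapply(smiles, function(s) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(s)),
      error = function(e)
        stop(sprintf("cannot parse SMILES '%s': %s", s, conditionMessage(e)),
             call. = FALSE)
    )
    counts <- ChemmineR::atomcount(sdf)[[1]]
    n <- sum(counts[names(counts) != "H"])
    if (n < 1)
      stop(sprintf("cannot parse SMILES '%s': no heavy atoms found", s),
           call. = FALSE)
    as.integer(n)
  }, integer(1))
  names(out) <- smiles
  out
}

#' Per-fragment efficiency table of a library
#'
#' @param library A [PocketLibrary-class].
#' @param convention `"magnitude"` or `"signed"`.
#' @return A data.frame with one row per fragment: ids, `delta_g`,
#'   `n_heavy`, `le`, `is_binder` (signed delta G < 0) and the convention
#'   used.
#' @examples
#' lib <- PocketLibrary(data.frame(
#'   fragment_id = c("f1", "f2"), pocket_id = c("P1", "P2"),
#'   delta_g = c(-3.3, -4.2), n_heavy = c(11L, 12L)))
#' efficiencyTable(lib)
#' @export
efficiencyTable <- function(library, convention = c("magnitude", "signed")) {
  stopifnot(is(library, "PocketLibrary"))
  convention <- match.arg(convention)
  df <- fragments(library)
  le <- ligandEfficiency(df$delta_g, df$n_heavy, convention)
  data.frame(
    fragment_id = df$fragment_id, pocket_id = df$pocket_id,
    delta_g = df$delta_g, n_heavy = df$n_heavy,
    le = as.numeric(le), is_binder = df$delta_g < 0,
    convention = convention, stringsAsFactors = FALSE
  )
}
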