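#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Thermodynamic parameters
#'
#' Holds the temperature and gas constant used to interconvert dissociation
#' constants and binding free energies via \eqn{\Delta G = RT \ln K_d}.
#'
#' @slot temperature Absolute temperature in kelvin.
#' @slot gasConstant Gas constant in kcal mol^-1 K^-1.
#'
#' @seealso [thermoParams()], [deltaGFromKd()]
#' @exportClass ThermoParams
setClass("ThermoParams",
  representation(temperature = "numeric", gasConstant = "numeric"),
  prototype(temperature = 298.15, gasConstant = 1.987e-3)
)

setValidity("ThermoParams", function(object) {
  msg <- character(0)
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "'temperature' must be a single positive finite number")
  if (length(object@gasConstant) != 1 || !is.finite(object@gasConstant) ||
      object@gasConstant <= 0)
    msg <- c(msg, "'gasConstant' must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Construct thermodynamic parameters
#'
#' @param temperature Absolute temperature in kelvin. Defaults to 298.15 K
#'   (25 degrees C), the usual assay reference.
#' @param gasConstant Gas constant in kcal mol^-1 K^-1.
#' @return A [ThermoParams-class] object.
#' @examples
#' thermoParams()
#' thermoParams(temperature = 310)
#' @export
thermoParams <- function(temperature = 298.15, gasConstant = 1.987e-3) {
  new("ThermoParams", temperature = temperature, gasConstant = gasConstant)
}

.FRAGMENT_COLUMNS <- c("fragment_id", "pocket_id", "delta_g", "n_heavy", "smiles")

#' Fragment library grouped by target pocket
#'
#' The screening universe: candidate fragments, each assigned to one binding
#' position (pocket) of a target, with a signed binding free energy in
#' kcal/mol (negative for binders) and a heavy-atom count. Pocket order is
#' the order of first appearance in the fragment table and is preserved
#' throughout screening and reporting.
#'
#' @slot fragments A data.frame with columns `fragment_id`, `pocket_id`,
#'   `delta_g` (kcal/mol, signed), `n_heavy` (integer, >= 1) and `smiles`
#'   (character, may be `NA`).
#' @slot targetId Identifier of the target molecule.
#'
#' @seealso [PocketLibrary()], [readLibrary()], [screenFragments()]
#' @exportClass PocketLibrary
setClass("PocketLibrary",
  representation(fragments = "data.frame", targetId = "character")
)

setValidity("PocketLibrary", function(object) {
  df <- object@fragments
  msg <- character(0)
  missing <- setdiff(.FRAGMENT_COLUMNS, names(df))
  if (length(missing))
    return(sprintf("fragment table lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  if (length(object@targetId) != 1 || is.na(object@targetId))
    msg <- c(msg, "'targetId' must be a single string")
  if (nrow(df)) {
    if (any(is.na(df$fragment_id)) || any(is.na(df$pocket_id)))
      msg <- c(msg, "fragment_id and pocket_id must not be NA")
    if (any(!is.finite(df$delta_g)))
      msg <- c(msg, "delta_g must be finite")
    if (any(is.na(df$n_heavy)) || any(df$n_heavy < 1) ||
        any(df$n_heavy != round(df$n_heavy)))
      msg <- c(msg, "n_heavy must be integers >= 1")
    key <- paste(df$pocket_id, df$fragment_id, sep = ":")
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicate (pocket_id, fragment_id) pair(s): %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a pocket library
#'
#' @param fragments A data.frame with at least `fragment_id`, `pocket_id`,
#'   `delta_g` and `n_heavy` columns; a `smiles` column is optional.
#' @param targetId Identifier of the target molecule.
#' @return A [PocketLibrary-class] object.
#' @examples
#' lib <- PocketLibrary(data.frame(
#'   fragment_id = c("f1", "f2", "f3"),
#'   pocket_id   = c("P1", "P1", "P2"),
#'   delta_g     = c(-4.5, -2.0, -6.1),
#'   n_heavy     = c(11L, 9L, 14L)
#' ))
#' pocketIds(lib)
#' @export
PocketLibrary <- function(fragments, targetId = "target") {
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(fragments))
    fragments$smiles <- NA_character_
  fragments$fragment_id <- as.character(fragments$fragment_id)
  fragments$pocket_id <- as.character(fragments$pocket_id)
  if ("n_heavy" %in% names(fragments))
    fragments$n_heavy <- as.integer(fragments$n_heavy)
  fragments <- fragments[, .FRAGMENT_COLUMNS, drop = FALSE]
  rownames(fragments) <- NULL
  new("PocketLibrary", fragments = fragments, targetId = targetId)
}

#' Screen configuration
#'
#' Parameters of an RGC combinatorial screen.
#'
#' @slot cutoff Target apparent total ligand efficiency (LETapp) in
#'   kcal mol^-1 per heavy atom, magnitude convention; a combination is
#'   accepted when its LETapp reaches this value.
#' @slot mode Averaging mode, `"arithmetic"` or `"wrms"`.
#' @slot maxCombinationsReported Upper bound on the number of accepted
#'   combinations kept in the report (classification always uses the full
#'   accepted set).
#' @slot allowNonbinders If `FALSE` (default), fragments with a
#'   non-negative signed binding free energy are excluded before screening.
#' @slot tolerance Slack subtracted from the cutoff when testing
#'   acceptance; defaults to 0 (exact inequality).
#' @slot seed Integer seed echoed into reports; screening itself is
#'   deterministic.
#'
#' @seealso [screenConfig()], [screenFragments()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(cutoff = "numeric", mode = "character",
                 maxCombinationsReported = "numeric",
                 allowNonbinders = "logical", tolerance = "numeric",
                 seed = "integer")
)

setValidity("ScreenConfig", function(object) {
  msg <- character(0)
  if (length(object@cutoff) != 1 || !is.finite(object@cutoff) ||
      object@cutoff < 0)
    msg <- c(msg, "'cutoff' must be a single non-negative number (magnitude convention)")
  if (length(object@mode) != 1 || !object@mode %in% c("arithmetic", "wrms"))
    msg <- c(msg, "'mode' must be \"arithmetic\" or \"wrms\"")
  if (length(object@maxCombinationsReported) != 1 ||
      is.na(object@maxCombinationsReported) ||
      object@maxCombinationsReported < 1)
    msg <- c(msg, "'maxCombinationsReported' must be >= 1")
  if (length(object@tolerance) != 1 || !is.finite(object@tolerance) ||
      object@tolerance < 0)
    msg <- c(msg, "'tolerance' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a screen configuration
#'
#' @param cutoff Target LETapp (kcal mol^-1 HA^-1, magnitude convention).
#' @param mode Averaging mode: `"arithmetic"` or `"wrms"`.
#' @param maxCombinationsReported Cap on reported combinations
#'   (default `Inf`, i.e. report all accepted).
#' @param allowNonbinders Keep fragments with signed delta G >= 0?
#' @param tolerance Acceptance slack; a combination passes when
#'   `LETapp >= cutoff - tolerance`. Default 0.
#' @param seed Integer seed echoed into reports.
#' @return A [ScreenConfig-class] object.
#' @examples
#' screenConfig(cutoff = 0.3, mode = "wrms")
#' @export
screenConfig <- function(cutoff, mode = c("arithmetic", "wrms"),
                         maxCombinationsReported = Inf,
                         allowNonbinders = FALSE, tolerance = 0,
                         seed = 1L) {
  mode <- match.arg(mode)
  new("ScreenConfig", cutoff = cutoff, mode = mode,
      maxCombinationsReported = as.numeric(maxCombinationsReported),
      allowNonbinders = allowNonbinders, tolerance = tolerance,
      seed = as.integer(seed))
}

#' Result of an RGC combinatorial screen
#'
#' @slot accepted A data.frame with one row per accepted combination: one
#'   column per pocket (holding the chosen fragment id), `le_t_app` and
#'   `rescued_fragment_ids` (semicolon-joined `pocket:fragment` keys of
#'   below-cutoff members, empty string when none). Sorted by `le_t_app`
#'   descending, ties broken lexicographically by fragment ids.
#' @slot classification Named character vector mapping `pocket:fragment`
#'   keys to `"selected"`, `"rescued"` or `"rejected"`.
#' @slot counts Named integer vector with the per-class totals.
#' @slot config The [ScreenConfig-class] used.
#' @slot targetId Target identifier echoed from the library.
#' @slot stats List of search statistics (`combinations_total`,
#'   `combinations_evaluated`, `branches_pruned`, `accepted_total`).
#'
#' @seealso [screenFragments()], [writeReport()]
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(accepted = "data.frame", classification = "character",
                 counts = "integer", config = "ScreenConfig",
                 targetId = "character", stats = "list")
)

#' Synthetic-study configuration
#'
#' Describes a simulated multi-pocket fragment campaign: per-pocket ligand
#' efficiency distributions for the candidate fragments, heavy-atom counts,
#' and the linking model used to assemble drug-sized molecules (linker
#' atoms that add size but no affinity, rigid-body / linker-binding /
#' strain free-energy corrections, and whole-molecule Gaussian noise on
#' the total binding free energy).
#'
#' @slot nPockets Number of binding pockets.
#' @slot fragmentsPerPocket Candidate fragments per pocket.
#' @slot leMean Per-pocket mean fragment LE (kcal mol^-1 HA^-1, magnitude),
#'   recycled across pockets.
#' @slot leSd Per-pocket LE spread (standard deviation before truncation
#'   at zero), recycled across pockets.
#' @slot nHeavyRange Inclusive integer range of fragment heavy-atom counts.
#' @slot linkerAtoms Heavy atoms added on linking; they contribute to the
#'   molecule's size but not to its affinity.
#' @slot dgRigid Rigid-body free-energy penalty on linking (kcal/mol).
#' @slot dgLinkerBinding Linker binding free-energy term (kcal/mol).
#' @slot dgStrain Strain free-energy penalty (kcal/mol).
#' @slot noiseSd Standard deviation of Gaussian noise added to the total
#'   binding free energy of each linked molecule (kcal/mol).
#' @slot seed Integer seed; generation is bitwise reproducible under it.
#'
#' @seealso [simConfig()], [generateLibrary()], [linkFragments()],
#'   [compareLeT()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nPockets = "integer", fragmentsPerPocket = "integer",
                 leMean = "numeric", leSd = "numeric",
                 nHeavyRange = "integer", linkerAtoms = "integer",
                 dgRigid = "numeric", dgLinkerBinding = "numeric",
                 dgStrain = "numeric", noiseSd = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nPockets < 1) msg <- c(msg, "'nPockets' must be >= 1")
  if (object@fragmentsPerPocket < 1)
    msg <- c(msg, "'fragmentsPerPocket' must be >= 1")
  if (any(object@leMean <= 0)) msg <- c(msg, "'leMean' must be positive")
  if (any(object@leSd < 0)) msg <- c(msg, "'leSd' must be non-negative")
  if (length(object@nHeavyRange) != 2 ||
      object@nHeavyRange[1] < 1 ||
      object@nHeavyRange[2] < object@nHeavyRange[1])
    msg <- c(msg, "'nHeavyRange' must be an increasing integer pair with min >= 1")
  if (object@linkerAtoms < 0) msg <- c(msg, "'linkerAtoms' must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' Defaults describe a typical two-pocket fragment-linking campaign:
#' fragment LE centred on 0.3 kcal mol^-1 HA^-1 (the common hit
#' threshold) with spread 0.1, rule-of-three-sized fragments of 8-16
#' heavy atoms, and ideal additive linking (no linker atoms, no energetic
#' corrections, no noise).
#'
#' @param nPockets Number of binding pockets (default 2, the linking case).
#' @param fragmentsPerPocket Candidate fragments per pocket (default 8).
#' @param leMean Per-pocket mean fragment LE, recycled (default 0.3).
#' @param leSd Per-pocket LE standard deviation, recycled (default 0.1).
#' @param nHeavyRange Heavy-atom count range (default `c(8, 16)`).
#' @param linkerAtoms Heavy atoms added by the linker (default 0).
#' @param dgRigid,dgLinkerBinding,dgStrain Linking free-energy corrections
#'   in kcal/mol (defaults 0).
#' @param noiseSd Whole-molecule Gaussian noise on the total binding free
#'   energy, kcal/mol (default 0).
#' @param seed Integer seed (default 1).
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(nPockets = 3, noiseSd = 0.5)
#' @export
simConfig <- function(nPockets = 2L, fragmentsPerPocket = 8L,
                      leMean = 0.3, leSd = 0.1, nHeavyRange = c(8L, 16L),
                      linkerAtoms = 0L, dgRigid = 0, dgLinkerBinding = 0,
                      dgStrain = 0, noiseSd = 0, seed = 1L) {
  new("SimConfig", nPockets = as.integer(nPockets),
      fragmentsPerPocket = as.integer(fragmentsPerPocket),
      leMean = leMean, leSd = leSd,
      nHeavyRange = as.integer(nHeavyRange),
      linkerAtoms = as.integer(linkerAtoms), dgRigid = dgRigid,
      dgLinkerBinding = dgLinkerBinding, dgStrain = dgStrain,
      noiseSd = noiseSd, seed = as.integer(seed))
}
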