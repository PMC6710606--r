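#' Apparent total ligand efficiency, arithmetic mean
#'
#' Estimates the whole-molecule ligand efficiency (LETapp) as the plain
#' mean of the component fragments' LE values. Exact for fragments of
#' equal heavy-atom count; for a single fragment it returns that
#' fragment's LE.
#'
#' @param les Numeric vector of fragment LE values, all under one sign
#'   convention.
#' @return The apparent total LE (kcal mol^-1 HA^-1).
#' @examples
#' leApparentArithmetic(c(0.3, 0.5))  # 0.4
#' @seealso [leApparentWrms()] for the weighted root-mean-square form,
#'   [leDeltaArithmetic()] for the inverse problem.
#' @export
leApparentArithmetic <- function(les) {
  if (!length(les)) stop("'les' must be non-empty", call. = FALSE)
  if (any(!is.finite(les))) stop("'les' must be finite", call. = FALSE)
  mean(les)
}

#' Apparent total ligand efficiency, weighted root mean square
#'
#' Estimates the whole-molecule ligand efficiency as
#' \deqn{LETapp = \sqrt{\sum_i LE_i^2 w_i / \sum_i w_i}}
#' where the weights reflect each fragment's size (heavy-atom count by
#' default, see [defaultWeights()]). Reduces to `|LE|` for a single
#' fragment and to the common value when all LE values are equal.
#'
#' Mixed-sign signed-convention input is refused: squaring would silently
#' discard the distinction between binders and non-binders.
#'
#' @param les Numeric vector of fragment LE values (one sign convention).
#' @param weights Positive weights, same length as `les`.
#' @return The apparent total LE (kcal mol^-1 HA^-1, non-negative).
#' @examples
#' leApparentWrms(c(0.3, 0.5), c(10, 10))  # sqrt(0.17) ~ 0.412
#' @export
leApparentWrms <- function(les, weights) {
  if (!length(les)) stop("'les' must be non-empty", call. = FALSE)
  if (length(weights) != length(les))
    stop("'weights' must match 'les' in length", call. = FALSE)
  if (any(!is.finite(les)) || any(!is.finite(weights)))
    stop("inputs must be finite", call. = FALSE)
  if (any(weights <= 0)) stop("'weights' must be positive", call. = FALSE)
  if (any(les > 0) && any(les < 0))
    stop("mixed-sign LE values: use one sign convention before averaging (the root mean square would destroy sign information)",
         call. = FALSE)
  sqrt(sum(les^2 * weights) / sum(weights))
}

#' Required efficiency of not-yet-chosen fragments, arithmetic form
#'
#' The subtractive-average LE delta: given a target apparent total LE for
#' a molecule of `x` fragments of which `a = length(known)` already have
#' known LE values, returns the common LE that each of the remaining
#' `x - a` fragments must have for the molecule to reach the target:
#' \deqn{LE_\delta = (x\,LETapp - \sum_j LE_j) / (x - a)}
#'
#' With no known fragments (`a = 0`) this is the target itself; with one
#' unknown left (`x - a = 1`) it is exactly the LE that last fragment
#' must have. It shrinks as high-efficiency fragments become known —
#' the quantitative core of fragment "rescue".
#'
#' @param leTApp Target apparent total LE.
#' @param x Total number of fragments (>= 1).
#' @param known Numeric vector of the already-known fragment LE values
#'   (may be empty); must satisfy `length(known) < x`.
#' @return The required common LE of the unknown fragments.
#' @examples
#' leDeltaArithmetic(0.4, x = 3, known = 0.2)  # 0.5
#' leDeltaArithmetic(0.4, x = 4)               # 0.4: nothing known yet
#' @export
leDeltaArithmetic <- function(leTApp, x, known = numeric(0)) {
  .checkSlate(leTApp, x, length(known))
  if (any(!is.finite(known))) stop("'known' must be finite", call. = FALSE)
  (x * leTApp - sum(known)) / (x - length(known))
}

#' Required efficiency of not-yet-chosen fragments, WRMS form
#'
#' Weighted-root-mean-square counterpart of [leDeltaArithmetic()]. The
#' remaining `x - a` fragments are assigned a common "ideal" weight
#' `wDelta`, and the returned value is the unique non-negative LE which,
#' inserted for every unknown fragment, makes [leApparentWrms()] equal
#' the target:
#' \deqn{LE_\delta = \sqrt{\frac{LETapp^2 W_{tot} - \sum_j LE_j^2 w_j}{(x-a)\,w_\delta}},
#'   \quad W_{tot} = \sum_j w_j + (x-a)\,w_\delta}
#'
#' When the known fragments are already too efficient relative to the
#' target (the numerator goes negative) no real solution exists: the
#' requested LETapp is unreachable from below, and `NA` is returned as an
#' explicit infeasibility signal.
#'
#' @param leTApp Target apparent total LE (magnitude convention).
#' @param x Total number of fragments.
#' @param known LE values of the known fragments (may be empty).
#' @param knownWeights Positive weights of the known fragments.
#' @param wDelta Common positive weight assigned to the unknown
#'   fragments; by convention the mean heavy-atom count of the candidates
#'   under consideration.
#' @return The required common LE, or `NA_real_` when infeasible.
#' @examples
#' leDeltaWrms(sqrt(0.17), x = 2, known = 0.3, knownWeights = 10,
#'             wDelta = 10)  # 0.5
#' @export
leDeltaWrms <- function(leTApp, x, known = numeric(0),
                        knownWeights = numeric(0), wDelta) {
  a <- length(known)
  .checkSlate(leTApp, x, a)
  if (length(knownWeights) != a)
    stop("'knownWeights' must match 'known' in length", call. = FALSE)
  if (any(!is.finite(known)) || any(!is.finite(knownWeights)) ||
      any(knownWeights <= 0))
    stop("'known' must be finite and 'knownWeights' positive", call. = FALSE)
  if (length(wDelta) != 1 || !is.finite(wDelta) || wDelta <= 0)
    stop("'wDelta' must be a single positive weight", call. = FALSE)
  wTot <- sum(knownWeights) + (x - a) * wDelta
  bracket <- leTApp^2 * wTot - sum(known^2 * knownWeights)
  # forgive rounding-level negativity; a genuinely negative balance means
  # no real LE can close the gap
  if (bracket < 0) {
    if (bracket > -1e-12 * max(1, leTApp^2 * wTot)) bracket <- 0
    else return(NA_real_)
  }
  sqrt(bracket / ((x - a) * wDelta))
}

.checkSlate <- function(leTApp, x, a) {
  if (length(leTApp) != 1 || !is.finite(leTApp))
    stop("'leTApp' must be a single finite value", call. = FALSE)
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop("'x' must be a single integer >= 1", call. = FALSE)
  if (a >= x)
    stop(sprintf("invalid slate: %d known fragment(s) for x = %d total (need 0 <= a < x)", a, x),
         call. = FALSE)
  invisible(TRUE)
}

#' Default fragment weights for WRMS averaging
#'
#' The weight of each fragment in the weighted-root-mean-square forms
#' depends on its size. The default policy is linear in the heavy-atom
#' count; `"sqrt_n"` damps the size dependence and `"equal"` reduces the
#' WRMS to an unweighted root mean square.
#'
#' @param nHeavy Integer vector of heavy-atom counts.
#' @param policy `"n"` (default), `"sqrt_n"` or `"equal"`.
#' @return Numeric vector of positive weights.
#' @examples
#' defaultWeights(c(10, 17))             # 10, 17
#' defaultWeights(c(10, 17), "equal")    # 1, 1
#' @export
defaultWeights <- function(nHeavy, policy = c("n", "sqrt_n", "equal")) {
  policy <- match.arg(policy)
  if (!length(nHeavy) || any(is.na(nHeavy)) || any(nHeavy < 1))
    stop("'nHeavy' must be a non-empty vector of counts >= 1", call. = FALSE)
  switch(policy,
    n = as.numeric(nHeavy),
    sqrt_n = sqrt(nHeavy),
    equal = rep(1, length(nHeavy))
  )
}
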