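## Combinatorial RGC screen: depth-first enumeration over pockets with
## admissible pruning, so the accepted set is identical to exhaustive
## enumeration. A fragment is keyed by "pocket_id:fragment_id" throughout
## (identical fragment ids in different pockets are distinct entities).

.fragKey <- function(pocket, fragment) paste(pocket, fragment, sep = ":")

# numerical slack for pruning only: bounds are relaxed by this amount so a
# branch on the acceptance boundary is never cut by rounding. Acceptance
# itself uses the exact inequality.
.PRUNE_EPS <- 1e-9

#' Run an RGC combinatorial fragment screen
#'
#' Enumerates every combination of one fragment per pocket and accepts
#' exactly those whose apparent total ligand efficiency (arithmetic mean
#' or weighted root mean square of the member LE values, per
#' `config@mode`) reaches the cutoff. A depth-first search with an
#' admissible branch-and-bound bound prunes subtrees that provably cannot
#' reach the cutoff; the accepted set equals exhaustive enumeration.
#'
#' Below-cutoff fragments appearing in an accepted combination are
#' "rescued" by their higher-efficiency partners; every library fragment
#' is classified as `selected` (own LE at or above the cutoff, in an
#' accepted combination), `rescued` (below the cutoff, in an accepted
#' combination) or `rejected` (in no accepted combination). Non-binders
#' (signed delta G >= 0) are excluded before screening unless
#' `config@allowNonbinders` is set.
#'
#' @param library A [PocketLibrary-class]; every pocket must be
#'   non-empty (after any non-binder exclusion).
#' @param config A [ScreenConfig-class].
#' @return A [ScreenResult-class].
#' @examples
#' lib <- PocketLibrary(data.frame(
#'   fragment_id = c("a1", "a2", "b1", "b2"),
#'   pocket_id   = c("P1", "P1", "P2", "P2"),
#'   delta_g     = c(-5.0, -3.0, -5.0, -3.0),
#'   n_heavy     = c(10L, 10L, 10L, 10L)))
#' res <- screenFragments(lib, screenConfig(cutoff = 0.4))
#' accepted(res)
#' classification(res)
#' @seealso [requiredLeForRemaining()], [classifyFragments()],
#'   [classicSelection()], [writeReport()]
#' @export
screenFragments <- function(library, config) {
  stopifnot(is(library, "PocketLibrary"), is(config, "ScreenConfig"))
  df <- fragments(library)
  if (!nrow(df)) stop("library has no fragments", call. = FALSE)
  pocketOrder <- pocketIds(library)

  active <- if (config@allowNonbinders) rep(TRUE, nrow(df)) else df$delta_g < 0
  if (!any(active))
    stop("all fragments are non-binders (signed delta G >= 0); nothing to screen",
         call. = FALSE)
  work <- df[active, , drop = FALSE]
  emptied <- setdiff(pocketOrder, unique(work$pocket_id))
  if (length(emptied))
    stop(sprintf("pocket(s) with no screenable fragment: %s",
                 paste(emptied, collapse = ", ")), call. = FALSE)

  x <- length(pocketOrder)
  cutoff <- config@cutoff - config@tolerance
  byPocket <- split(seq_len(nrow(work)),
                    factor(work$pocket_id, levels = pocketOrder))
  le <- abs(work$delta_g) / work$n_heavy
  w <- as.numeric(work$n_heavy)

  # per-pocket best-case summaries for the admissible bounds
  pMaxLe  <- vapply(byPocket, function(i) max(le[i]), numeric(1))
  pMaxLe2w <- vapply(byPocket, function(i) max(le[i]^2 * w[i]), numeric(1))
  pMinW   <- vapply(byPocket, function(i) min(w[i]), numeric(1))
  # suffix sums over pockets k..x
  sufMaxLe  <- rev(cumsum(rev(pMaxLe)))
  sufMaxLe2w <- rev(cumsum(rev(pMaxLe2w)))
  sufMinW   <- rev(cumsum(rev(pMinW)))
  suffix <- function(v, k) if (k > x) 0 else v[k]

  env <- new.env(parent = emptyenv())
  env$combos <- list()
  env$leTApp <- numeric(0)
  env$evaluated <- 0L
  env$pruned <- 0L

  arithmetic <- config@mode == "arithmetic"
  choice <- integer(x)

  recurse <- function(k, sumLe, sumLe2w, sumW) {
    if (k > x) {
      env$evaluated <- env$evaluated + 1L
      v <- if (arithmetic) sumLe / x else sqrt(sumLe2w / sumW)
      if (v >= cutoff) {
        env$combos[[length(env$combos) + 1L]] <- choice
        env$leTApp <- c(env$leTApp, v)
      }
      return(invisible(NULL))
    }
    # admissible upper bound on the best LETapp any extension can reach
    bound <- if (arithmetic) {
      (sumLe + suffix(sufMaxLe, k)) / x
    } else {
      sqrt((sumLe2w + suffix(sufMaxLe2w, k)) / (sumW + suffix(sufMinW, k)))
    }
    if (bound < cutoff - .PRUNE_EPS) {
      env$pruned <- env$pruned + 1L
      return(invisible(NULL))
    }
    for (i in byPocket[[k]]) {
      choice[k] <<- i
      recurse(k + 1L, sumLe + le[i], sumLe2w + le[i]^2 * w[i], sumW + w[i])
    }
    invisible(NULL)
  }
  recurse(1L, 0, 0, 0)

  acceptedDf <- .buildAcceptedDf(env$combos, env$leTApp, work, le, cutoff,
                                 pocketOrder)
  cls <- .classify(df, acceptedDf, pocketOrder, cutoff)
  nReport <- min(nrow(acceptedDf), config@maxCombinationsReported)
  new("ScreenResult",
      accepted = acceptedDf[seq_len(nReport), , drop = FALSE],
      classification = cls,
      counts = c(selected = sum(cls == "selected"),
                 rescued = sum(cls == "rescued"),
                 rejected = sum(cls == "rejected")),
      config = config, targetId = targetId(library),
      stats = list(combinations_total = prod(lengths(byPocket)),
                   combinations_evaluated = env$evaluated,
                   branches_pruned = env$pruned,
                   accepted_total = nrow(acceptedDf)))
}

.buildAcceptedDf <- function(combos, leTApp, work, le, cutoff, pocketOrder) {
  x <- length(pocketOrder)
  if (!length(combos)) {
    cols <- c(stats::setNames(rep(list(character(0)), x), pocketOrder),
              list(le_t_app = numeric(0), rescued_fragment_ids = character(0)))
    return(as.data.frame(cols, stringsAsFactors = FALSE,
                         check.names = FALSE))
  }
  idx <- do.call(rbind, combos)
  ids <- matrix(work$fragment_id[idx], nrow = nrow(idx))
  rescued <- apply(idx, 1L, function(row) {
    low <- row[le[row] < cutoff]
    if (!length(low)) ""
    else paste(.fragKey(work$pocket_id[low], work$fragment_id[low]),
               collapse = ";")
  })
  out <- as.data.frame(ids, stringsAsFactors = FALSE)
  names(out) <- pocketOrder
  out$le_t_app <- leTApp
  out$rescued_fragment_ids <- rescued
  ord <- do.call(order, c(list(-out$le_t_app),
                          lapply(pocketOrder, function(p) out[[p]])))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.classify <- function(allFragments, acceptedDf, pocketOrder, cutoff) {
  keys <- .fragKey(allFragments$pocket_id, allFragments$fragment_id)
  inAccepted <- character(0)
  if (nrow(acceptedDf))
    inAccepted <- unique(unlist(lapply(pocketOrder, function(p)
      .fragKey(p, acceptedDf[[p]]))))
  le <- abs(allFragments$delta_g) / allFragments$n_heavy
  binder <- allFragments$delta_g < 0
  cls <- ifelse(keys %in% inAccepted,
                ifelse(le >= cutoff & binder, "selected", "rescued"),
                "rejected")
  stats::setNames(cls, keys)
}

#' Classify library fragments against a set of accepted combinations
#'
#' Partition of all fragments implied by a screen outcome: `selected`
#' (own LE at or above the cutoff and member of at least one accepted
#' combination), `rescued` (below the cutoff yet member of an accepted
#' combination) or `rejected` (member of none).
#'
#' @param acceptedCombos A data.frame shaped like the `accepted` slot of a
#'   [ScreenResult-class] (one column per pocket holding fragment ids).
#' @param library The [PocketLibrary-class] that was screened.
#' @param config The [ScreenConfig-class] used.
#' @return Named character vector over `pocket:fragment` keys.
#' @export
classifyFragments <- function(acceptedCombos, library, config) {
  stopifnot(is(library, "PocketLibrary"), is(config, "ScreenConfig"))
  .classify(fragments(library), acceptedCombos, pocketIds(library),
            config@cutoff - config@tolerance)
}

#' Efficiency requirement on the still-unfilled pockets
#'
#' Given a partial choice of fragments, returns the LE-delta that
#' fragments in the remaining pockets must attain (on average, in the
#' configured mode) for the full combination to reach the cutoff, and
#' whether the library can actually supply it. As high-efficiency
#' fragments are chosen, the requirement drops — each new known value
#' "pushes" the bar for the rest.
#'
#' @param partial Named character vector: names are pocket ids, values the
#'   chosen fragment ids. May be empty (the requirement is then the cutoff
#'   itself).
#' @param library A [PocketLibrary-class].
#' @param config A [ScreenConfig-class].
#' @param wDelta Ideal common weight of the unknown fragments (WRMS mode);
#'   defaults to the mean heavy-atom count of the candidate fragments in
#'   the unfilled pockets.
#' @return A list with elements `leDelta` (the requirement; `NA` when no
#'   real value can reach the cutoff), `feasible` (can the remaining
#'   pockets' best fragments meet it?) and `mode`.
#' @examples
#' lib <- PocketLibrary(data.frame(
#'   fragment_id = c("a1", "b1", "b2"), pocket_id = c("P1", "P2", "P2"),
#'   delta_g = c(-3.0, -6.0, -2.0), n_heavy = c(10L, 12L, 10L)))
#' requiredLeForRemaining(c(P1 = "a1"), lib, screenConfig(0.4))
#' @export
requiredLeForRemaining <- function(partial, library, config, wDelta = NULL) {
  stopifnot(is(library, "PocketLibrary"), is(config, "ScreenConfig"))
  df <- fragments(library)
  pocketOrder <- pocketIds(library)
  x <- length(pocketOrder)
  a <- length(partial)
  if (a >= x)
    stop("'partial' must leave at least one pocket unfilled", call. = FALSE)
  if (a > 0 && (is.null(names(partial)) || any(!names(partial) %in% pocketOrder)))
    stop("'partial' must be named by pocket ids present in the library",
         call. = FALSE)
  rows <- integer(0)
  if (a > 0) {
    rows <- vapply(seq_along(partial), function(i) {
      j <- which(df$pocket_id == names(partial)[i] &
                 df$fragment_id == partial[[i]])
      if (length(j) != 1)
        stop(sprintf("fragment '%s' not found in pocket '%s'",
                     partial[[i]], names(partial)[i]), call. = FALSE)
      j
    }, integer(1))
  }
  knownLe <- abs(df$delta_g[rows]) / df$n_heavy[rows]
  knownW <- as.numeric(df$n_heavy[rows])
  open <- setdiff(pocketOrder, names(partial))
  openRows <- df[df$pocket_id %in% open, , drop = FALSE]
  openLe <- abs(openRows$delta_g) / openRows$n_heavy

  if (config@mode == "arithmetic") {
    req <- leDeltaArithmetic(config@cutoff, x, knownLe)
    bestRemain <- sum(vapply(open, function(p)
      max(openLe[openRows$pocket_id == p]), numeric(1)))
    feasible <- bestRemain >= (x - a) * req - .PRUNE_EPS
  } else {
    if (is.null(wDelta)) wDelta <- mean(openRows$n_heavy)
    req <- leDeltaWrms(config@cutoff, x, knownLe, knownW, wDelta)
    if (is.na(req)) {
      # target already guaranteed: the known fragments alone push the WRMS
      # past the cutoff whatever the rest contribute
      feasible <- TRUE
    } else {
      num <- sum(knownLe^2 * knownW) + sum(vapply(open, function(p) {
        i <- openRows$pocket_id == p
        max(openLe[i]^2 * openRows$n_heavy[i])
      }, numeric(1)))
      den <- sum(knownW) + sum(vapply(open, function(p)
        min(openRows$n_heavy[openRows$pocket_id == p]), numeric(1)))
      feasible <- sqrt(num / den) >= config@cutoff - .PRUNE_EPS
    }
  }
  list(leDelta = req, feasible = feasible, mode = config@mode)
}

#' Best ligand efficiency available in a pocket
#'
#' The admissible bound used by the branch-and-bound search: no
#' combination can draw more efficiency from a pocket than its best
#' fragment offers.
#'
#' @param library A [PocketLibrary-class].
#' @param pocketId A pocket identifier present in the library.
#' @return The maximum individual LE (magnitude) over the pocket's
#'   fragments.
#' @export
pruneBound <- function(library, pocketId) {
  stopifnot(is(library, "PocketLibrary"))
  df <- fragments(library)
  rows <- df$pocket_id == pocketId
  if (!any(rows))
    stop(sprintf("unknown or empty pocket '%s'", pocketId), call. = FALSE)
  max(abs(df$delta_g[rows]) / df$n_heavy[rows])
}

#' Classical per-fragment screening
#'
#' The conventional triage that the RGC screen is contrasted with: each
#' fragment is judged on its own LE against the cutoff, ignoring
#' potential partners. Useful as a baseline to see which fragments only
#' survive through rescue.
#'
#' @param library A [PocketLibrary-class].
#' @param config A [ScreenConfig-class] (only `cutoff`, `tolerance` and
#'   `allowNonbinders` are used).
#' @return Named character vector over `pocket:fragment` keys with values
#'   `"selected"` or `"rejected"`.
#' @examples
#' lib <- PocketLibrary(data.frame(
#'   fragment_id = c("a1", "a2"), pocket_id = c("P1", "P1"),
#'   delta_g = c(-5, -2), n_heavy = c(10L, 10L)))
#' classicSelection(lib, screenConfig(0.3))
#' @export
classicSelection <- function(library, config) {
  stopifnot(is(library, "PocketLibrary"), is(config, "ScreenConfig"))
  df <- fragments(library)
  le <- abs(df$delta_g) / df$n_heavy
  binder <- df$delta_g < 0 | config@allowNonbinders
  cls <- ifelse(binder & le >= config@cutoff - config@tolerance,
                "selected", "rejected")
  stats::setNames(cls, .fragKey(df$pocket_id, df$fragment_id))
}
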