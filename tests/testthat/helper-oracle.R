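# Independent oracles: exhaustive enumeration of a screen and direct
# classification by definition. Deliberately written against the raw
# fragment table, not the package's search code.

oracleKey <- function(pocket, fragment) paste(pocket, fragment, sep = ":")

# exhaustive screen: every combination of one binder per pocket, accepted
# iff its apparent total LE reaches the cutoff
bruteForceScreen <- function(lib, cutoff, mode, allowNonbinders = FALSE) {
  df <- fragments(lib)
  pockets <- unique(df$pocket_id)
  keep <- if (allowNonbinders) rep(TRUE, nrow(df)) else df$delta_g < 0
  dfk <- df[keep, , drop = FALSE]
  idx <- lapply(pockets, function(p) which(dfk$pocket_id == p))
  stopifnot(all(lengths(idx) > 0))
  grid <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  le <- abs(dfk$delta_g) / dfk$n_heavy
  w <- dfk$n_heavy
  leTApp <- apply(grid, 1L, function(row) {
    if (mode == "arithmetic") mean(le[row])
    else sqrt(sum(le[row]^2 * w[row]) / sum(w[row]))
  })
  acc <- leTApp >= cutoff
  combos <- unname(apply(grid[acc, , drop = FALSE], 1L, function(row)
    paste(oracleKey(dfk$pocket_id[row], dfk$fragment_id[row]), collapse = "|")))
  if (!length(combos)) combos <- character(0)
  memberKeys <- unique(unlist(apply(grid[acc, , drop = FALSE], 1L, function(row)
    oracleKey(dfk$pocket_id[row], dfk$fragment_id[row]), simplify = FALSE)))
  allKeys <- oracleKey(df$pocket_id, df$fragment_id)
  allLe <- abs(df$delta_g) / df$n_heavy
  cls <- ifelse(allKeys %in% memberKeys,
                ifelse(allLe >= cutoff & df$delta_g < 0, "selected", "rescued"),
                "rejected")
  list(combos = sort(combos), leTApp = sort(leTApp[acc]),
       classification = setNames(cls, allKeys))
}

comboKeys <- function(result) {
  acc <- accepted(result)
  pockets <- setdiff(names(acc), c("le_t_app", "rescued_fragment_ids"))
  if (!nrow(acc)) return(character(0))
  sort(unname(apply(acc[, pockets, drop = FALSE], 1L, function(row)
    paste(oracleKey(pockets, row), collapse = "|"))))
}

# random toy library of binders, small enough for exhaustive enumeration
randomLibrary <- function(nPocketsMax = 4, nFragMax = 6) {
  nP <- sample.int(nPocketsMax, 1)
  rows <- do.call(rbind, lapply(seq_len(nP), function(p) {
    nf <- sample.int(nFragMax, 1)
    n <- sample(8:16, nf, replace = TRUE)
    le <- runif(nf, 0.05, 0.7)
    data.frame(fragment_id = sprintf("f%d_%d", p, seq_len(nf)),
               pocket_id = sprintf("P%d", p),
               delta_g = -le * n, n_heavy = as.integer(n),
               stringsAsFactors = FALSE)
  }))
  PocketLibrary(rows)
}

# toy library from explicit per-pocket LE vectors, all fragments N = 10
libraryFromLes <- function(leByPocket, nHeavy = 10L) {
  rows <- do.call(rbind, lapply(seq_along(leByPocket), function(p) {
    les <- leByPocket[[p]]
    data.frame(fragment_id = sprintf("f%d_%d", p, seq_along(les)),
               pocket_id = sprintf("P%d", p),
               delta_g = -les * nHeavy, n_heavy = nHeavy,
               stringsAsFactors = FALSE)
  }))
  PocketLibrary(rows)
}

# numeric root-finder for the WRMS LE-delta: solves the insertion
# equation directly, independent of the closed form
wrmsDeltaByRootFinder <- function(target, x, known, knownWeights, wDelta) {
  a <- length(known)
  f <- function(v)
    leApparentWrms(c(known, rep(v, x - a)), c(knownWeights, rep(wDelta, x - a))) - target
  if (f(0) > 0) return(NA_real_)
  upper <- max(c(known, target)) + target + 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-13)$root
}
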