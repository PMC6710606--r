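#' @rdname PocketLibrary-class
setMethod("fragments", "PocketLibrary", function(object) object@fragments)

#' @rdname PocketLibrary-class
setMethod("pocketIds", "PocketLibrary",
          function(object) unique(object@fragments$pocket_id))

#' @rdname PocketLibrary-class
setMethod("nPockets", "PocketLibrary",
          function(object) length(pocketIds(object)))

#' @rdname PocketLibrary-class
setMethod("nFragments", "PocketLibrary",
          function(object) nrow(object@fragments))

#' @rdname PocketLibrary-class
setMethod("targetId", "PocketLibrary", function(object) object@targetId)

setMethod("show", "PocketLibrary", function(object) {
  cat(sprintf("PocketLibrary for target '%s'\n", object@targetId))
  cat(sprintf("  %d fragment(s) across %d pocket(s)\n",
              nFragments(object), nPockets(object)))
  tab <- table(factor(object@fragments$pocket_id, levels = pocketIds(object)))
  for (p in names(tab))
    cat(sprintf("    %s: %d fragment(s)\n", p, tab[[p]]))
  invisible(NULL)
})

setMethod("show", "ThermoParams", function(object) {
  cat(sprintf("ThermoParams: T = %.2f K, R = %g kcal/(mol K), RT = %.4f kcal/mol\n",
              object@temperature, object@gasConstant,
              object@temperature * object@gasConstant))
  invisible(NULL)
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf("ScreenConfig: cutoff = %g kcal/(mol HA), mode = %s\n",
              object@cutoff, object@mode))
  cat(sprintf("  allowNonbinders = %s, tolerance = %g, seed = %d\n",
              object@allowNonbinders, object@tolerance, object@seed))
  invisible(NULL)
})

#' @rdname ScreenResult-class
setMethod("accepted", "ScreenResult", function(object) object@accepted)

#' @rdname ScreenResult-class
setMethod("classification", "ScreenResult", function(object) object@classification)

#' @rdname ScreenResult-class
setMethod("classCounts", "ScreenResult", function(object) object@counts)

#' @rdname ScreenResult-class
setMethod("screenStats", "ScreenResult", function(object) object@stats)

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult for target '%s' (%s mode, cutoff %g)\n",
              object@targetId, object@config@mode, object@config@cutoff))
  cat(sprintf("  accepted combinations: %d (reported: %d)\n",
              object@stats$accepted_total, nrow(object@accepted)))
  cat(sprintf("  fragments: %d selected, %d rescued, %d rejected\n",
              object@counts[["selected"]], object@counts[["rescued"]],
              object@counts[["rejected"]]))
  cat(sprintf("  search: %d/%d combinations evaluated, %d branch(es) pruned\n",
              object@stats$combinations_evaluated,
              object@stats$combinations_total, object@stats$branches_pruned))
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d pocket(s) x %d fragment(s), LE ~ N(%s, %s) truncated at 0\n",
              object@nPockets, object@fragmentsPerPocket,
              paste(signif(object@leMean, 3), collapse = "/"),
              paste(signif(object@leSd, 3), collapse = "/")))
  cat(sprintf("  N in [%d, %d], linker atoms %d, corrections (%g, %g, %g) kcal/mol, noise sd %g, seed %d\n",
              object@nHeavyRange[1], object@nHeavyRange[2],
              object@linkerAtoms, object@dgRigid, object@dgLinkerBinding,
              object@dgStrain, object@noiseSd, object@seed))
  invisible(NULL)
})
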