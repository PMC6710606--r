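#' @rdname PocketLibrary-class
#' @param object A package object.
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))

#' @rdname PocketLibrary-class
#' @export
setGeneric("pocketIds", function(object) standardGeneric("pocketIds"))

#' @rdname PocketLibrary-class
#' @export
setGeneric("nPockets", function(object) standardGeneric("nPockets"))

#' @rdname PocketLibrary-class
#' @export
setGeneric("nFragments", function(object) standardGeneric("nFragments"))

#' @rdname PocketLibrary-class
#' @export
setGeneric("targetId", function(object) standardGeneric("targetId"))

#' @rdname ScreenResult-class
#' @param object A package object.
#' @export
setGeneric("accepted", function(object) standardGeneric("accepted"))

#' @rdname ScreenResult-class
#' @export
setGeneric("classification", function(object) standardGeneric("classification"))

#' @rdname ScreenResult-class
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname ScreenResult-class
#' @export
setGeneric("screenStats", function(object) standardGeneric("screenStats"))
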