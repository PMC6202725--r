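#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))

#' @rdname accessors
#' @export
setGeneric("unmethCounts", function(x) standardGeneric("unmethCounts"))

#' @rdname accessors
#' @export
setGeneric("totalCoverage", function(x) standardGeneric("totalCoverage"))

#' @rdname accessors
#' @export
setGeneric("methLevel", function(x, ...) standardGeneric("methLevel"))

#' @rdname accessors
#' @export
setGeneric("siteContext", function(x) standardGeneric("siteContext"))

#' @rdname conversionRate
#' @export
setGeneric("conversionRate", function(x, ...) standardGeneric("conversionRate"))

#' @rdname filterSites
#' @export
setGeneric("filterSites", function(x, config = filterConfig(), ...)
  standardGeneric("filterSites"))

#' @rdname pcaProfiles
#' @export
setGeneric("pcaProfiles", function(x, ...) standardGeneric("pcaProfiles"))
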