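#' @include AllClasses.R
NULL

#' Accessors for DdgTable objects
#'
#' \code{ddgData} returns the underlying substitution data.frame;
#' \code{proteinLength} the protein length L; \code{referenceId} the
#' reference-sequence label. \code{accessibleSubs} returns the rows
#' flagged as reachable within one DNA change; \code{observedSubs} the
#' rows flagged as observed in wild phage and/or laboratory experiments
#' (the union by default, or one source via \code{source}).
#'
#' @param x a [DdgTable-class].
#' @param source for \code{observedSubs}: \code{"both"} (union),
#'   \code{"wild"}, or \code{"lab"}.
#' @return data.frames (for the subsetters) with the DdgTable columns.
#' @name DdgTable-accessors
#' @aliases ddgData proteinLength referenceId accessibleSubs observedSubs
#' @export
setGeneric("ddgData", function(x) standardGeneric("ddgData"))

#' @rdname DdgTable-accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname DdgTable-accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname DdgTable-accessors
#' @export
setGeneric("accessibleSubs", function(x) standardGeneric("accessibleSubs"))

#' @rdname DdgTable-accessors
#' @export
setGeneric("observedSubs", function(x, source = c("both", "wild", "lab"))
  standardGeneric("observedSubs"))

#' Count substitutions inside a stability zone
#'
#' Counts how many substitutions have ddG_fold inside the zone, ddG_bind
#' inside the zone, and both jointly. Zone membership is closed-interval.
#'
#' @param subs a [DdgTable-class] or a data.frame with \code{ddg_fold} and
#'   \code{ddg_bind} columns.
#' @param zone a [StabilityZone-class].
#' @return a [ZoneCounts-class].
#' @examples
#' z <- StabilityZone(-2, 2)
#' d <- data.frame(ddg_fold = c(0, 3, 0), ddg_bind = c(0, 0, 3))
#' zoneCounts(d, z)
#' @export
setGeneric("zoneCounts", function(subs, zone) standardGeneric("zoneCounts"))
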