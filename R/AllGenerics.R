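#' @name srsclust-generics
#' @title Accessor generics for srsclust containers
#' @description Accessors for [MonitoringSession] and [EEGTrace] slots; use
#'   these rather than reaching into slots with `@`.
#' @param x a `MonitoringSession` or `EEGTrace`.
#' @param value replacement value.
#' @return The corresponding slot value (or the modified object for setters).
NULL

#' @rdname srsclust-generics
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname srsclust-generics
#' @export
setGeneric("events<-", function(x, value) standardGeneric("events<-"))

#' @rdname srsclust-generics
#' @export
setGeneric("mouseId", function(x) standardGeneric("mouseId"))

#' @rdname srsclust-generics
#' @export
setGeneric("sessionIndex", function(x) standardGeneric("sessionIndex"))

#' @rdname srsclust-generics
#' @export
setGeneric("startClock", function(x) standardGeneric("startClock"))

#' @rdname srsclust-generics
#' @export
setGeneric("durationDays", function(x) standardGeneric("durationDays"))

#' @rdname srsclust-generics
#' @export
setGeneric("recordingGaps", function(x) standardGeneric("recordingGaps"))

#' @rdname srsclust-generics
#' @export
setGeneric("lightCycle", function(x) standardGeneric("lightCycle"))

#' @rdname srsclust-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname srsclust-generics
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname srsclust-generics
#' @export
setGeneric("epochStart", function(x) standardGeneric("epochStart"))

#' @rdname srsclust-generics
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
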