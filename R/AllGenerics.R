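#' @rdname lrrMatrix
#' @export
setGeneric("lrrMatrix", function(x) standardGeneric("lrrMatrix"))

#' @rdname markerRanges
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' @rdname sampleIDs
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname segmentLabels
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname segmentTable
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname cslvMatrix
#' @export
setGeneric("cslvMatrix", function(x, samplesAsRows = TRUE) standardGeneric("cslvMatrix"))

#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname cohort-accessors
#' @export
setGeneric("truthMatrix", function(x) standardGeneric("truthMatrix"))

#' @rdname cohort-accessors
#' @export
setGeneric("geneticHeight", function(x) standardGeneric("geneticHeight"))

#' @rdname cohort-accessors
#' @export
setGeneric("segmentScheme", function(x) standardGeneric("segmentScheme"))

#' @rdname RocResult-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname RocResult-accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname RepeatedAuc-accessors
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))

#' @rdname RepeatedAuc-accessors
#' @export
setGeneric("aucMean", function(x) standardGeneric("aucMean"))

#' @rdname RepeatedAuc-accessors
#' @export
setGeneric("aucSD", function(x) standardGeneric("aucSD"))

#' @rdname leaderboard
#' @export
setGeneric("leaderboard", function(x) standardGeneric("leaderboard"))

#' @rdname leaderboard
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname curveTable
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname importanceTable
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))
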