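#' Extract the log R ratio matrix
#'
#' Returns the markers x samples matrix of log R ratios of an [LRRSet]
#' (missing measurements are `NA`).
#'
#' @param x an [LRRSet].
#' @return numeric matrix, markers in rows, samples in columns.
#' @rdname lrrMatrix
#' @export
setMethod("lrrMatrix", "LRRSet", function(x) assay(x, "LRR"))

#' Marker coordinates of an LRRSet
#'
#' @param x an [LRRSet].
#' @return a [GenomicRanges::GRanges], names are marker ids, sorted by
#'   (chromosome, position, marker id).
#' @rdname markerRanges
#' @export
setMethod("markerRanges", "LRRSet", function(x) rowRanges(x))

#' Sample identifiers
#'
#' @param x an [LRRSet], [CSLVTable] or [SimulatedCohort].
#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "LRRSet", function(x) colnames(x))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "CSLVTable", function(x) colnames(x))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "SimulatedCohort", function(x) colnames(x@lrr))

#' Segment labels of a scheme or feature table
#'
#' Labels follow the `"chr{c}_{q}"` convention and are ordered by
#' (chromosome, segment index).
#'
#' @param x a [SegmentScheme] or [CSLVTable].
#' @rdname segmentLabels
#' @export
setMethod("segmentLabels", "SegmentScheme", function(x) names(x@segments))

#' @rdname segmentLabels
#' @export
setMethod("segmentLabels", "CSLVTable", function(x) rownames(x))

#' Per-segment summary of a segmentation scheme
#'
#' @param x a [SegmentScheme].
#' @return data.frame with one row per segment: `label`, `chromosome`, `q`,
#'   `n_markers`, and the informational half-open bp interval
#'   `bp_start`/`bp_end`.
#' @rdname segmentTable
#' @export
setMethod("segmentTable", "SegmentScheme", function(x) {
    mc <- S4Vectors::mcols(x@segments)
    data.frame(
        label = names(x@segments),
        chromosome = mc$chromosome,
        q = mc$q,
        n_markers = mc$nMarkers,
        bp_start = mc$bpStart,
        bp_end = mc$bpEnd,
        row.names = NULL
    )
})

#' Extract the CSLV feature matrix
#'
#' @param x a [CSLVTable].
#' @param samplesAsRows if `TRUE` (default) return samples x segments, the
#'   orientation the modelling functions consume; otherwise segments x
#'   samples as stored.
#' @rdname cslvMatrix
#' @export
setMethod("cslvMatrix", "CSLVTable", function(x, samplesAsRows = TRUE) {
    m <- assay(x, "cslv")
    if (samplesAsRows) t(m) else m
})

#' Accessors for simulated cohorts
#'
#' `phenotypes()` returns the per-sample phenotype table; `truthMatrix()`
#' the segments x samples matrix of true mean dosage shifts (group +
#' sex-crosstalk + CNV); `geneticHeight()` the heritable height contribution
#' in cm; `segmentScheme()` the scheme of the generative model; `lrrData()`
#' the marker-level [LRRSet].
#'
#' @param x a [SimulatedCohort].
#' @rdname cohort-accessors
#' @export
setMethod("phenotypes", "SimulatedCohort", function(x) x@phenotypes)

#' @rdname cohort-accessors
#' @export
setMethod("truthMatrix", "SimulatedCohort", function(x) x@truth)

#' @rdname cohort-accessors
#' @export
setMethod("geneticHeight", "SimulatedCohort", function(x) x@geneticHeight)

#' @rdname cohort-accessors
#' @export
setMethod("segmentScheme", "SimulatedCohort", function(x) x@scheme)

#' @rdname cohort-accessors
#' @export
lrrData <- function(x) {
    stopifnot(is(x, "SimulatedCohort"))
    x@lrr
}

#' ROC curve accessors
#'
#' @param x a [RocResult].
#' @rdname RocResult-accessors
#' @export
setMethod("aucValue", "RocResult", function(x) x@auc)

#' @rdname RocResult-accessors
#' @export
setMethod("rocPoints", "RocResult", function(x)
    data.frame(fpr = x@fpr, tpr = x@tpr))

#' Repeated-holdout AUC accessors
#'
#' @param x a [RepeatedAuc].
#' @rdname RepeatedAuc-accessors
#' @export
setMethod("aucValues", "RepeatedAuc", function(x) x@aucs)

#' @rdname RepeatedAuc-accessors
#' @export
setMethod("aucMean", "RepeatedAuc", function(x) mean(x@aucs))

#' @rdname RepeatedAuc-accessors
#' @export
setMethod("aucSD", "RepeatedAuc", function(x) stats::sd(x@aucs))

#' Leaderboard and best model of a search
#'
#' @param x a [SearchResult] or [Leaderboard].
#' @rdname leaderboard
#' @export
setMethod("leaderboard", "SearchResult", function(x) x@leaderboard@table)

#' @rdname leaderboard
#' @export
setMethod("leaderboard", "Leaderboard", function(x) x@table)

#' @rdname leaderboard
#' @export
setMethod("bestModel", "SearchResult", function(x) x@best)

#' Grouped-mean curve table
#'
#' @param x a [GroupedCurve].
#' @rdname curveTable
#' @export
setMethod("curveTable", "GroupedCurve", function(x) x@table)

#' Permutation-importance table
#'
#' @param x an [ImportanceReport].
#' @rdname importanceTable
#' @export
setMethod("importanceTable", "ImportanceReport", function(x) x@table)

setMethod("show", "SegmentScheme", function(object) {
    cat(sprintf("SegmentScheme: %d segments (%d chromosome(s) x k=%d, mode=%s)\n",
        length(object@segments),
        length(unique(S4Vectors::mcols(object@segments)$chromosome)),
        object@k, object@mode))
    cat(sprintf("  %d markers assigned\n", length(object@assignment)))
})

setMethod("show", "SimulatedCohort", function(object) {
    cat(sprintf("SimulatedCohort: %d samples, %d markers on %d chromosome(s)\n",
        ncol(object@lrr), nrow(object@lrr),
        length(unique(as.character(seqnames(rowRanges(object@lrr)))))))
    cat(sprintf("  segment scheme: %d segments (k=%d)\n",
        length(object@scheme@segments), object@scheme@k))
})

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC = %.4f (%d curve points)\n",
        object@auc, length(object@fpr)))
})

setMethod("show", "RepeatedAuc", function(object) {
    cat(sprintf("RepeatedAuc over %d splits: mean AUC = %.4f, sd = %.4f\n",
        length(object@aucs), mean(object@aucs), stats::sd(object@aucs)))
})

setMethod("show", "Leaderboard", function(object) {
    cat(sprintf("Leaderboard (%d models, metric = %s)\n",
        nrow(object@table), object@metric))
    print(utils::head(object@table, 10), row.names = FALSE)
    if (nrow(object@table) > 10) cat(sprintf("  ... %d more\n", nrow(object@table) - 10L))
})

setMethod("show", "SearchResult", function(object) {
    cat(sprintf("SearchResult: best model %s (%s = %.4f)\n",
        object@leaderboard@table$model_id[1], object@metric,
        object@leaderboard@table$metric[1]))
    show(object@leaderboard)
})

setMethod("show", "GroupedCurve", function(object) {
    cat(sprintf("GroupedCurve: %d groups over %d samples\n",
        nrow(object@table), sum(object@table$size)))
})

setMethod("show", "ImportanceReport", function(object) {
    cat(sprintf("ImportanceReport (%s, base = %.4f, %d permutation repeats)\n",
        object@metric, object@baseMetric, object@nRepeats))
    ord <- order(object@table$mean_drop, decreasing = TRUE)
    print(utils::head(object@table[ord, ], 10), row.names = FALSE)
})
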