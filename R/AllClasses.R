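#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges rowData colData
NULL

#' Container for a log R ratio matrix aligned to a marker manifest
#'
#' `LRRSet` extends [SummarizedExperiment::RangedSummarizedExperiment] with a
#' single `"LRR"` assay holding markers (rows) by samples (columns) log R
#' ratios, and marker coordinates as its `rowRanges`. Log R ratio is the
#' log-scale ratio of observed to expected total probe intensity at a marker
#' and serves as a dosage proxy: 0 at nominal two copies, positive for net
#' gains, negative for net losses. Missing measurements are `NA` and are
#' always distinct from 0.
#'
#' Markers are stored sorted by (chromosome, position, marker id); only
#' autosomes 1-22 are admitted. Construct with [LRRSet()] or one of the
#' readers ([readLRRLong()], [readLRRWide()]).
#'
#' @aliases LRRSet-class
#' @export
setClass("LRRSet", contains = "RangedSummarizedExperiment")

setValidity("LRRSet", function(object) {
    msg <- character()
    if (!"LRR" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'LRR' is required")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "marker ids (rownames) must be present and unique")
    sq <- as.character(GenomicRanges::seqnames(rowRanges(object)))
    if (length(sq) && !all(sq %in% as.character(1:22)))
        msg <- c(msg, "all markers must lie on autosomes 1-22")
    cn <- colnames(object)
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Fixed partition of each autosome into segments
#'
#' A `SegmentScheme` records how the position-sorted markers of every
#' chromosome in a manifest are partitioned into `k` contiguous segments.
#' Segments are labelled `"chr{c}_{q}"`; `q` is the 1-based segment index
#' within chromosome `c`, so the label `chr6_2` denotes the second segment of
#' chromosome 6. Each marker belongs to exactly one segment; within a
#' chromosome segments are disjoint, contiguous and cover every marker.
#'
#' @slot segments a [GenomicRanges::GRanges] of segments (names are the
#'   labels) with metadata columns `chromosome`, `q`, `nMarkers`, `bpStart`,
#'   `bpEnd` (the half-open bp interval, informational).
#' @slot assignment integer vector mapping each manifest marker (in manifest
#'   order) to its segment row.
#' @slot markerIDs marker ids in manifest order; used to verify that a
#'   scheme and an `LRRSet` describe the same markers.
#' @slot k segments per chromosome.
#' @slot mode `"equal_marker_count"` or `"equal_bp_span"`.
#' @aliases SegmentScheme-class
#' @export
setClass("SegmentScheme", representation(
    segments = "GRanges",
    assignment = "integer",
    markerIDs = "character",
    k = "integer",
    mode = "character"
))

setValidity("SegmentScheme", function(object) {
    msg <- character()
    if (length(object@assignment) != length(object@markerIDs))
        msg <- c(msg, "assignment and markerIDs lengths differ")
    ns <- length(object@segments)
    a <- object@assignment
    if (length(a) && (min(a) < 1L || max(a) > ns))
        msg <- c(msg, "assignment indexes outside the segment list")
    if (is.null(names(object@segments)))
        msg <- c(msg, "segments must be labelled")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    nm <- S4Vectors::mcols(object@segments)$nMarkers
    if (!is.null(nm) && length(a) &&
        !identical(as.integer(tabulate(a, ns)), as.integer(nm)))
        msg <- c(msg, "nMarkers inconsistent with assignment")
    if (length(msg)) msg else TRUE
})

#' Chromosome-scale length variation feature table
#'
#' `CSLVTable` extends [SummarizedExperiment::SummarizedExperiment] with one
#' `"cslv"` assay of segments (rows, labelled `"chr{c}_{q}"`) by samples
#' (columns). Each entry is the arithmetic mean log R ratio of one sample
#' over one chromosome segment: approximately 0 at nominal two copies,
#' positive under net duplication and negative under net deletion across the
#' segment. Entries may be `NA` when too few markers were observed; no value
#' is ever imputed. With the default scheme (4 segments per chromosome over
#' autosomes 1-22) a table has exactly 88 feature rows.
#'
#' @aliases CSLVTable-class
#' @export
setClass("CSLVTable", contains = "SummarizedExperiment")

setValidity("CSLVTable", function(object) {
    msg <- character()
    if (!"cslv" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'cslv' is required")
    rn <- rownames(object)
    if (is.null(rn) || !all(grepl("^chr([1-9]|1[0-9]|2[0-2])_[0-9]+$", rn)))
        msg <- c(msg, "row names must be segment labels of the form chr{c}_{q}")
    if (anyDuplicated(rn)) msg <- c(msg, "duplicate segment labels")
    if (length(msg)) msg else TRUE
})

#' A simulated SNP-array cohort with ground truth
#'
#' Bundles the outputs of [simulateCohort()]: the marker-level log R ratio
#' data (an [LRRSet]), per-sample phenotypes (sex, group label, age, height),
#' the segment scheme the generative model was expressed in, the true
#' per-sample per-segment mean dosage shift (sum of group, sex-crosstalk and
#' CNV contributions), and each sample's true genetic height contribution.
#'
#' @slot lrr an [LRRSet].
#' @slot phenotypes a [S4Vectors::DataFrame] with columns `sample_id`,
#'   `sex`, `group_label`, `age`, `height`.
#' @slot truth numeric matrix, segments x samples, of true segment-mean
#'   shifts.
#' @slot geneticHeight named numeric, the heritable height contribution in cm.
#' @slot scheme the [SegmentScheme] used by the generative model.
#' @slot config the fully-resolved simulation configuration.
#' @aliases SimulatedCohort-class
#' @export
setClass("SimulatedCohort", representation(
    lrr = "LRRSet",
    phenotypes = "DataFrame",
    truth = "matrix",
    geneticHeight = "numeric",
    scheme = "SegmentScheme",
    config = "list"
))

setValidity("SimulatedCohort", function(object) {
    msg <- character()
    ids <- colnames(object@lrr)
    if (!identical(as.character(object@phenotypes$sample_id), ids))
        msg <- c(msg, "phenotype sample ids do not match LRR columns")
    if (!identical(colnames(object@truth), ids))
        msg <- c(msg, "truth matrix columns do not match LRR columns")
    if (!identical(names(object@geneticHeight), ids))
        msg <- c(msg, "geneticHeight names do not match LRR columns")
    if (length(msg)) msg else TRUE
})

#' Receiver operating characteristic curve with its area
#'
#' Produced by [aucROC()]. The curve has one point per distinct score
#' threshold plus the (0,0) and (1,1) anchors; `auc` equals both the
#' trapezoidal area under the points and the Mann-Whitney probability that a
#' random positive outscores a random negative, ties counted half.
#'
#' @aliases RocResult-class
#' @export
setClass("RocResult", representation(
    fpr = "numeric", tpr = "numeric", auc = "numeric"
))

setValidity("RocResult", function(object) {
    msg <- character()
    if (length(object@fpr) != length(object@tpr))
        msg <- c(msg, "fpr and tpr lengths differ")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
        msg <- c(msg, "ROC points must be non-decreasing")
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0,1]")
    if (length(msg)) msg else TRUE
})

#' Test-set AUCs over repeated random train/test splits
#'
#' Produced by [repeatedHoldout()]: one held-out AUC per random split, with
#' the mean and standard deviation across splits recoverable from the
#' per-repeat values via [aucMean()] and [aucSD()].
#'
#' @aliases RepeatedAuc-class
#' @export
setClass("RepeatedAuc", representation(aucs = "numeric"))

#' Ranked table of cross-validated candidate models
#'
#' Produced by [modelSearch()]: one row per candidate (including the two
#' stacked ensembles), ranked by the cross-validated metric - descending AUC
#' for classification, ascending RMSE for regression.
#'
#' @aliases Leaderboard-class
#' @export
setClass("Leaderboard", representation(table = "data.frame", metric = "character"))

setValidity("Leaderboard", function(object) {
    tab <- object@table
    msg <- character()
    if (!all(c("rank", "model_id", "family", "metric") %in% names(tab)))
        msg <- c(msg, "table must have rank, model_id, family, metric")
    else {
        if (!identical(as.integer(tab$rank), seq_len(nrow(tab))))
            msg <- c(msg, "ranks must be contiguous from 1")
        m <- tab$metric
        if (length(m) > 1) {
            ok <- if (identical(object@metric, "auc")) all(diff(m) <= 0)
                  else all(diff(m) >= 0)
            if (!ok) msg <- c(msg, "table not sorted by metric")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Result of a cross-validated model search
#'
#' Holds the [Leaderboard] and the top-ranked model refitted on the full
#' training table (retrieve with [bestModel()]; predict with
#' [predictModel()]).
#'
#' @aliases SearchResult-class
#' @export
setClass("SearchResult", representation(
    leaderboard = "Leaderboard", best = "ANY", metric = "character"
))

#' Mean observed outcome in equal groups ranked by prediction
#'
#' Produced by [groupedMeanCurve()]: samples are sorted by predicted value,
#' cut into `nGroups` contiguous groups whose sizes differ by at most one
#' (larger groups first), and the mean predicted and mean actual value is
#' reported per group.
#'
#' @aliases GroupedCurve-class
#' @export
setClass("GroupedCurve", representation(table = "data.frame"))

setValidity("GroupedCurve", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("group", "size", "mean_predicted", "mean_actual")
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("table must have", paste(need, collapse = ", ")))
    else if (nrow(tab) && diff(range(tab$size)) > 1)
        msg <- c(msg, "group sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' Permutation feature importance report
#'
#' Produced by [permutationImportance()]: for every feature, the mean (and
#' sd over repeats) drop in the model's metric when that feature column is
#' permuted, the model-agnostic analogue of a variable-importance plot.
#'
#' @aliases ImportanceReport-class
#' @export
setClass("ImportanceReport", representation(
    table = "data.frame", baseMetric = "numeric",
    metric = "character", nRepeats = "integer"
))
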