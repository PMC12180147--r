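#' Build a marker manifest
#'
#' A manifest maps array markers to genomic coordinates and fixes the
#' coordinate frame for segmentation. Chromosome labels `"1"`, `"chr1"`,
#' `"Chr1"` are normalized to integers; markers not on autosomes 1-22 are
#' dropped with a message (sex chromosomes and mitochondria carry no signal
#' for this representation). Positions are 1-based; markers are sorted by
#' (chromosome, position) with ties broken by marker id, which makes marker
#' order deterministic.
#'
#' @param marker_id character, unique marker identifiers.
#' @param chromosome chromosome labels (coerced via the normalization above).
#' @param position_bp integer positions, 1-based, `>= 1`.
#' @return a [GenomicRanges::GRanges] with names `marker_id`, one-width
#'   ranges at the marker positions and seqlevels `"1"`..`"22"`.
#' @examples
#' mf <- markerManifest(c("m1", "m2"), c("chr2", "1"), c(100, 50))
#' names(mf)   # "m2" then "m1": chromosome 1 sorts first
#' @export
markerManifest <- function(marker_id, chromosome, position_bp) {
    marker_id <- as.character(marker_id)
    chr <- normalizeChromosome(chromosome)
    pos <- as.integer(position_bp)
    stopifnot(length(marker_id) == length(chr), length(chr) == length(pos))
    keep <- !is.na(chr)
    if (!all(keep)) {
        message(sum(!keep), " marker(s) not on autosomes 1-22 dropped")
        marker_id <- marker_id[keep]; chr <- chr[keep]; pos <- pos[keep]
    }
    if (anyDuplicated(marker_id))
        stop("duplicate marker ids: ",
             paste(utils::head(unique(marker_id[duplicated(marker_id)]), 5),
                   collapse = ", "))
    if (any(is.na(pos)) || any(pos < 1L))
        stop("positions must be integers >= 1")
    o <- order(chr, pos, marker_id)
    gr <- GRanges(
        seqnames = factor(as.character(chr[o]), levels = as.character(1:22)),
        ranges = IRanges(start = pos[o], width = 1L)
    )
    names(gr) <- marker_id[o]
    gr
}

#' Construct an LRRSet from a matrix and a manifest
#'
#' @param lrr numeric matrix of log R ratios, markers x samples, with
#'   rownames naming markers of `manifest` and unique sample colnames.
#'   Missing measurements are `NA` (never 0).
#' @param manifest a manifest [GenomicRanges::GRanges] as returned by
#'   [markerManifest()]; must cover exactly the rownames of `lrr`.
#' @return an [LRRSet] with markers in manifest (sorted) order.
#' @export
LRRSet <- function(lrr, manifest) {
    stopifnot(is.matrix(lrr), !is.null(rownames(lrr)), !is.null(colnames(lrr)))
    if (!setequal(rownames(lrr), names(manifest)))
        stop("matrix rownames and manifest marker ids differ")
    lrr <- lrr[names(manifest), , drop = FALSE]
    storage.mode(lrr) <- "double"
    new("LRRSet", SummarizedExperiment(
        assays = list(LRR = lrr), rowRanges = manifest))
}

#' Construct a CSLVTable
#'
#' @param values numeric matrix, segments x samples; rownames are segment
#'   labels `"chr{c}_{q}"`, colnames are sample ids.
#' @param segmentInfo optional data.frame of per-segment metadata (one row
#'   per segment, e.g. from [segmentTable()]); stored as `rowData`.
#' @return a [CSLVTable] with rows ordered by (chromosome, q).
#' @export
CSLVTable <- function(values, segmentInfo = NULL) {
    stopifnot(is.matrix(values), !is.null(rownames(values)))
    storage.mode(values) <- "double"
    info <- parseSegLabel(rownames(values))
    if (any(is.na(info$chromosome)))
        stop("malformed segment label(s): ",
             paste(info$label[is.na(info$chromosome)], collapse = ", "))
    o <- order(info$chromosome, info$q)
    values <- values[o, , drop = FALSE]
    rd <- info[o, c("chromosome", "q")]
    if (!is.null(segmentInfo)) {
        stopifnot(nrow(segmentInfo) == nrow(values))
        rd <- cbind(rd, segmentInfo[o, setdiff(names(segmentInfo),
                                               c("label", "chromosome", "q")),
                                    drop = FALSE])
    }
    rownames(rd) <- rownames(values)
    new("CSLVTable", SummarizedExperiment(
        assays = list(cslv = values), rowData = rd))
}
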