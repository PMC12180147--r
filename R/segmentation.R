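#' Partition each autosome of a manifest into k segments
#'
#' The chromosome-scale length variation representation averages log R
#' ratios over fixed chromosome segments; this function builds the
#' partition. Two modes are offered:
#'
#' * `equal_marker_count` (default): the position-sorted markers of a
#'   chromosome with `m` markers are cut into `k` contiguous runs, the
#'   first `m %% k` runs holding `ceiling(m/k)` markers and the rest
#'   `floor(m/k)` (maximal-balanced, larger runs first). Every segment is
#'   non-empty and segment means have near-equal sampling variance.
#' * `equal_bp_span`: the chromosome's occupied interval
#'   `[min(pos), max(pos)+1)` is cut into `k` equal bp sub-intervals and
#'   markers are assigned by position; sparse regions can leave a segment
#'   empty, which raises a warning.
#'
#' Position ties are broken by marker id (already fixed in the manifest
#' order), so the scheme is a deterministic function of (manifest, k, mode).
#'
#' @param manifest a manifest [GenomicRanges::GRanges] from
#'   [markerManifest()] (or an [LRRSet], whose manifest is used).
#' @param k segments per chromosome, `>= 1`; `k = 4` ("quarters") with all
#'   22 autosomes yields the canonical 88 features.
#' @param mode `"equal_marker_count"` or `"equal_bp_span"`.
#' @return a [SegmentScheme].
#' @examples
#' mf <- markerManifest(sprintf("m%02d", 1:10), rep(1, 10), 1:10 * 100)
#' segmentTable(makeSegments(mf, k = 4))  # sizes 3,3,2,2
#' @export
makeSegments <- function(manifest, k = 4L,
                         mode = c("equal_marker_count", "equal_bp_span")) {
    if (is(manifest, "LRRSet")) manifest <- markerRanges(manifest)
    mode <- match.arg(mode)
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
    chr <- as.integer(as.character(seqnames(manifest)))
    pos <- start(manifest)
    chroms <- sort(unique(chr))
    if (!length(chroms)) stop("empty manifest")

    assignment <- integer(length(manifest))
    segChrom <- integer(0); segQ <- integer(0); segN <- integer(0)
    segStart <- integer(0); segEnd <- integer(0)
    offset <- 0L
    for (c in chroms) {
        idx <- which(chr == c)          # manifest order = position order
        m <- length(idx)
        p <- pos[idx]
        if (mode == "equal_marker_count") {
            if (m < k)
                stop(sprintf("chromosome %d has %d markers, fewer than k = %d",
                             c, m, k), call. = FALSE)
            sizes <- rep(m %/% k, k)
            r <- m %% k
            if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
            grp <- rep(seq_len(k), times = sizes)
            bounds <- cumsum(c(0L, sizes))
            bpS <- p[bounds[seq_len(k)] + 1L]
            bpE <- p[bounds[-1]] + 1L
        } else {
            lo <- min(p); hi <- max(p) + 1L
            brk <- lo + (hi - lo) * (0:k) / k
            grp <- pmin(pmax(findInterval(p, brk), 1L), k)
            sizes <- tabulate(grp, k)
            if (any(sizes == 0L))
                warning(sprintf(
                    "chromosome %d: %d empty segment(s) under equal_bp_span",
                    c, sum(sizes == 0L)), call. = FALSE)
            bpS <- floor(brk[seq_len(k)])
            bpE <- floor(brk[-1])
        }
        assignment[idx] <- offset + grp
        segChrom <- c(segChrom, rep(c, k))
        segQ <- c(segQ, seq_len(k))
        segN <- c(segN, as.integer(sizes))
        segStart <- c(segStart, as.integer(bpS))
        segEnd <- c(segEnd, as.integer(bpE))
        offset <- offset + k
    }
    segs <- GRanges(
        seqnames = factor(as.character(segChrom), levels = as.character(1:22)),
        ranges = IRanges(start = segStart, end = pmax(segEnd - 1L, segStart)))
    names(segs) <- segLabel(segChrom, segQ)
    S4Vectors::mcols(segs) <- S4Vectors::DataFrame(
        chromosome = segChrom, q = segQ, nMarkers = segN,
        bpStart = segStart, bpEnd = segEnd)
    new("SegmentScheme", segments = segs, assignment = assignment,
        markerIDs = names(manifest), k = k, mode = mode)
}

#' Compute the CSLV feature table
#'
#' For every sample and segment, the entry is the arithmetic mean of the
#' sample's observed (non-missing) log R ratios over the segment's markers,
#' provided at least `minObservedFraction` of the segment's markers were
#' observed; otherwise the entry is missing. No value is ever imputed:
#' incomplete segments stay `NA`, and sample-level completeness is enforced
#' separately by [filterComplete()].
#'
#' @param x an [LRRSet] whose markers match the scheme's manifest.
#' @param scheme a [SegmentScheme] built from the same manifest.
#' @param minObservedFraction minimum fraction of a segment's markers that
#'   must be non-missing for the segment mean to be reported, in (0, 1].
#' @return a [CSLVTable] (segments x samples).
#' @export
computeCSLV <- function(x, scheme, minObservedFraction = 0.9) {
    stopifnot(is(x, "LRRSet"), is(scheme, "SegmentScheme"))
    if (!identical(rownames(x), scheme@markerIDs))
        stop("scheme was built from a different manifest than this LRRSet")
    if (!is.numeric(minObservedFraction) || minObservedFraction <= 0 ||
        minObservedFraction > 1)
        stop("minObservedFraction must be in (0, 1]")
    a <- assay(x, "LRR")
    obs <- !is.na(a)
    az <- a; az[!obs] <- 0
    nseg <- length(scheme@segments)
    grp <- factor(scheme@assignment, levels = seq_len(nseg))
    sums <- rowsum(az, grp, reorder = TRUE)
    cnts <- rowsum(obs + 0, grp, reorder = TRUE)
    vals <- sums / cnts                     # 0/0 -> NaN for empty counts
    nm <- S4Vectors::mcols(scheme@segments)$nMarkers
    frac <- cnts / pmax(nm, 1L)
    vals[cnts == 0 | frac < minObservedFraction] <- NA_real_
    dimnames(vals) <- list(names(scheme@segments), colnames(a))
    CSLVTable(vals, segmentInfo = segmentTable(scheme))
}

#' Keep only samples with a complete feature vector
#'
#' Complete-case filtering at the sample level: samples carrying any
#' missing segment value are removed (with a message giving the count); the
#' column (segment) set is unchanged and an empty result is allowed.
#'
#' @param x a [CSLVTable].
#' @return a [CSLVTable] restricted to complete samples.
#' @export
filterComplete <- function(x) {
    stopifnot(is(x, "CSLVTable"))
    ok <- colSums(is.na(assay(x, "cslv"))) == 0L
    if (any(!ok))
        message(sum(!ok), " sample(s) with incomplete features dropped")
    x[, ok]
}

#' Histogram of one segment's CSLV values across samples
#'
#' Summarizes the population distribution of a single feature (the display
#' used to inspect dispersion of segment means around 0). Bin edges are
#' equally spaced over `range`; non-missing values falling outside `range`
#' are clamped into the first/last bin so that counts always sum to the
#' number of non-missing entries.
#'
#' @param x a [CSLVTable].
#' @param segmentLabel a label present in `segmentLabels(x)`.
#' @param nBins number of bins, `>= 1`.
#' @param range length-2 numeric; defaults to the value range (expanded to
#'   a unit interval when degenerate).
#' @return list with `edges` (length `nBins + 1`), `counts` (length
#'   `nBins`) and `n` (number of non-missing values).
#' @export
segmentHistogram <- function(x, segmentLabel, nBins = 50L, range = NULL) {
    stopifnot(is(x, "CSLVTable"))
    if (!segmentLabel %in% rownames(x))
        stop("unknown segment label: ", segmentLabel)
    nBins <- as.integer(nBins)
    if (is.na(nBins) || nBins < 1L) stop("nBins must be >= 1")
    v <- assay(x, "cslv")[segmentLabel, ]
    v <- v[!is.na(v)]
    if (is.null(range)) {
        range <- if (length(v)) base::range(v) else c(0, 1)
        if (diff(range) == 0) range <- range + c(-0.5, 0.5)
    }
    stopifnot(length(range) == 2L, range[1] < range[2])
    edges <- seq(range[1], range[2], length.out = nBins + 1L)
    bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                nBins)
    list(edges = edges, counts = tabulate(bin, nBins), n = length(v))
}
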