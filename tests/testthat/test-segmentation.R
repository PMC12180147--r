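test_that("equal-marker-count segmentation is maximal-balanced with larger runs first", {
    st <- segmentTable(makeSegments(gridManifest(1, 8), k = 4))
    expect_identical(st$n_markers, c(2L, 2L, 2L, 2L))

    st <- segmentTable(makeSegments(gridManifest(1, 10), k = 4))
    expect_identical(st$n_markers, c(3L, 3L, 2L, 2L))

    # k = 1 is the identity partition
    st <- segmentTable(makeSegments(gridManifest(c(3, 7), 10), k = 1))
    expect_identical(st$label, c("chr3_1", "chr7_1"))
    expect_identical(st$n_markers, c(10L, 10L))

    # exhaustive: sizes sum to m, differ by at most 1, never increase
    for (m in 4:30) for (k in 1:4) {
        if (m < k) next
        sz <- segmentTable(makeSegments(gridManifest(1, m), k = k))$n_markers
        expect_identical(sum(sz), m)
        expect_lte(diff(range(sz)), 1L)
        expect_true(all(diff(sz) <= 0L))
    }

    expect_error(makeSegments(gridManifest(5, 3), k = 4), "chromosome 5")
})

test_that("equal-bp-span mode assigns by position and warns on empty segments", {
    # markers clustered at the start of the chromosome: tail segments empty
    mf <- markerManifest(sprintf("m%d", 1:6), rep(1, 6),
                         c(1, 2, 3, 4, 5, 1000))
    expect_warning(sc <- makeSegments(mf, k = 4, mode = "equal_bp_span"),
                   "empty segment")
    st <- segmentTable(sc)
    expect_identical(sum(st$n_markers), 6L)
    expect_identical(st$n_markers[1], 5L)   # the cluster
    expect_identical(st$n_markers[4], 1L)   # the far marker
})

test_that("CSLV entries are segment means over observed markers, never imputed", {
    vals <- matrix(0, 8, 3)
    x <- gridLRRSet(vals, 1, 8)
    sc <- makeSegments(markerRanges(x), k = 4)
    expect_true(all(assay(computeCSLV(x, sc), "cslv") == 0))

    # hand-computed mean over one 4-marker segment
    vals <- matrix(c(0.1, 0.1, 0.3, 0.3, rep(0, 4)), ncol = 1)
    x <- gridLRRSet(vals, 1, 8)
    sc <- makeSegments(markerRanges(x), k = 2)
    expect_equal(assay(computeCSLV(x, sc), "cslv")["chr1_1", 1], 0.2)

    # 3 of 4 markers missing: observed fraction 0.25 < 0.5 -> missing
    vals <- matrix(c(0.2, NA, NA, NA, rep(0, 4)), ncol = 1)
    x <- gridLRRSet(vals, 1, 8)
    cs <- computeCSLV(x, sc, minObservedFraction = 0.5)
    expect_true(is.na(assay(cs, "cslv")["chr1_1", 1]))
    # 2 of 4 observed at the same threshold: mean over the observed two
    vals[2, 1] <- 0.4
    cs <- computeCSLV(gridLRRSet(vals, 1, 8), sc, minObservedFraction = 0.5)
    expect_equal(assay(cs, "cslv")["chr1_1", 1], 0.3)
})

test_that("a scheme from a different manifest is rejected", {
    x <- gridLRRSet(matrix(0, 8, 2), 1, 8)
    sc <- makeSegments(gridManifest(2, 8), k = 4)
    expect_error(computeCSLV(x, sc), "different manifest")
})

test_that("complete-case filtering drops exactly the samples with gaps", {
    tab <- randomCSLVTable(5)
    expect_identical(filterComplete(tab), tab)

    v <- assay(tab, "cslv")
    v[1, 2] <- NA; v[40, 4] <- NA
    tab2 <- CSLVTable(v)
    expect_message(out <- filterComplete(tab2), "2 sample")
    expect_identical(colnames(out), colnames(tab)[-c(2, 4)])
    expect_identical(rownames(out), rownames(tab))

    v[1, ] <- NA
    expect_message(out <- filterComplete(CSLVTable(v)), "5 sample")
    expect_identical(ncol(out), 0L)
    expect_identical(rownames(out), rownames(tab))
})

test_that("segment histograms conserve counts and match the normal model", {
    tab <- randomCSLVTable(20, chroms = 1, k = 2, seed = 3)
    v <- assay(tab, "cslv"); v[1, 1:4] <- NA
    tab <- CSLVTable(v)
    h <- segmentHistogram(tab, "chr1_1", nBins = 7)
    expect_identical(sum(h$counts), 16L)
    expect_identical(h$n, 16L)
    expect_length(h$edges, 8L)
    expect_equal(diff(h$edges), rep(diff(h$edges)[1], 7))

    # constant column: all mass in a single bin
    vc <- matrix(0, 2, 50, dimnames = list(c("chr1_1", "chr1_2"), NULL))
    colnames(vc) <- sprintf("s%d", 1:50)
    hc <- segmentHistogram(CSLVTable(vc), "chr1_1", nBins = 5, range = c(-1, 1))
    expect_identical(sum(hc$counts > 0), 1L)
    expect_identical(sum(hc$counts), 50L)

    expect_error(segmentHistogram(tab, "chr9_1"), "chr9_1")

    # Normal(0, 0.01): about 68.3% of mass within one sd of the centre
    set.seed(11)
    vals <- matrix(rnorm(10000, 0, 0.01), 1,
                   dimnames = list("chr1_1", NULL))
    colnames(vals) <- sprintf("s%05d", 1:10000)
    h <- segmentHistogram(CSLVTable(vals), "chr1_1", nBins = 10,
                          range = c(-0.05, 0.05))
    inner <- sum(h$counts[5:6]) / h$n    # bins covering [-0.01, 0.01]
    expect_lt(abs(inner - 0.683), 0.02)
})

test_that("the CSLV pipeline is deterministic, shift-equivariant and order-insensitive", {
    set.seed(5)
    vals <- matrix(rnorm(32 * 6), 32, 6)
    x <- gridLRRSet(vals, chroms = c(1, 4), m = 16)
    sc <- makeSegments(markerRanges(x), k = 4)
    a <- assay(computeCSLV(x, sc), "cslv")
    b <- assay(computeCSLV(x, sc), "cslv")
    expect_identical(a, b)

    # adding delta to one sample's markers adds exactly delta to its features
    v2 <- vals; v2[, 3] <- v2[, 3] + 0.25
    a2 <- assay(computeCSLV(gridLRRSet(v2, c(1, 4), 16), sc), "cslv")
    expect_equal(a2[, 3], a[, 3] + 0.25)
    expect_identical(a2[, -3], a[, -3])

    # permuting marker values within a segment leaves its mean unchanged
    v3 <- vals
    seg1 <- 1:4   # first segment of chr1 under k=4, m=16
    v3[seg1, ] <- v3[rev(seg1), ]
    a3 <- assay(computeCSLV(gridLRRSet(v3, c(1, 4), 16), sc), "cslv")
    expect_equal(a3, a)
})

test_that("the default scheme over all autosomes yields exactly 88 features", {
    mf <- gridManifest(1:22, 8)
    sc <- makeSegments(mf, k = 4)
    expect_identical(length(segmentLabels(sc)), 88L)
    x <- LRRSet(matrix(0, length(mf), 2,
                       dimnames = list(names(mf), c("a", "b"))), mf)
    expect_identical(nrow(computeCSLV(x, sc)), 88L)
    expect_identical(dim(cslvMatrix(computeCSLV(x, sc))), c(2L, 88L))
})
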