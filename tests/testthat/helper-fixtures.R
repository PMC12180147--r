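# Fixture builders shared across test files; everything is generated in
# code, nothing is read from disk.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

# write a long-format LRR file from a data.frame-like list of rows
writeLongFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
    header <- "Sample ID\tSNP Name\tChr\tPosition\tLog R Ratio\tB Allele Freq"
    lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
    writeLines(c(header, lines), path)
    path
}

# 2 samples x 3 autosomal markers, constant LRR
tinyLongRows <- function(lrr = "0.0") {
    rows <- list()
    for (s in c("sampA", "sampB"))
        for (m in 1:3)
            rows[[length(rows) + 1L]] <-
                c(s, sprintf("m%d", m), "1", m * 100L, lrr, "0.5")
    rows
}

# random CSLVTable over a full default scheme (or custom labels)
randomCSLVTable <- function(nSamples = 3, chroms = 1:22, k = 4, seed = 1) {
    labels <- as.vector(t(outer(chroms, seq_len(k),
                                function(c, q) sprintf("chr%d_%d", c, q))))
    set.seed(seed)
    vals <- matrix(rnorm(length(labels) * nSamples, 0, 0.03),
                   length(labels), nSamples,
                   dimnames = list(labels, sprintf("S%03d", seq_len(nSamples))))
    CSLVTable(vals)
}

# manifest with m markers on each requested chromosome
gridManifest <- function(chroms = 1, m = 8) {
    markerManifest(
        as.vector(vapply(chroms, function(c) sprintf("c%02dm%04d", c, seq_len(m)),
                         character(m))),
        rep(chroms, each = m),
        rep(seq_len(m) * 100L, length(chroms)))
}

# LRRSet with given matrix over a grid manifest
gridLRRSet <- function(values, chroms = 1, m = 8) {
    mf <- gridManifest(chroms, m)
    stopifnot(nrow(values) == length(mf))
    rownames(values) <- names(mf)
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
    LRRSet(values, mf)
}

# exhaustive pair-counting AUC oracle (ties half-credited), O(n1*n0)
pairCountingAUC <- function(scores, positive) {
    sp <- scores[positive]; sn <- scores[!positive]
    tot <- 0
    for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
    tot / (length(sp) * length(sn))
}

# two-group classification config used by calibration tests
pairConfig <- function(n, chroms, k, m, deltaDiff, sigma = 0.2, seed = 1) {
    labels <- as.vector(t(outer(chroms, seq_len(k),
                                function(c, q) sprintf("chr%d_%d", c, q))))
    simConfig(
        nSamples = n, markersPerChromosome = m, chromosomes = chroms, k = k,
        lrrNoiseSD = sigma, cnvRate = 0, sexCrosstalk = FALSE,
        groups = list(
            list(label = "A", proportion = 0.5,
                 delta = stats::setNames(rep(deltaDiff, length(labels)), labels)),
            list(label = "B", proportion = 0.5)),
        seed = seed)
}
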