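#' @importFrom data.table fread
NULL

#' Column-name dialect for long-format log R ratio files
#'
#' Long ("Final-Report"-like) exports name their columns differently across
#' vendors and pipelines; a dialect maps the reader's logical fields onto
#' the file's header. The defaults match an Illumina Final Report. `baf` and
#' `genotype` are parsed-and-ignored when present: only the log R ratio
#' carries dosage signal here.
#'
#' @param sample,marker,chromosome,position,lrr required column names.
#' @param baf,genotype optional column names, accepted but discarded.
#' @return named list usable as the `dialect` argument of [readLRRLong()].
#' @export
lrrDialect <- function(sample = "Sample ID", marker = "SNP Name",
                       chromosome = "Chr", position = "Position",
                       lrr = "Log R Ratio", baf = "B Allele Freq",
                       genotype = "GT") {
    list(sample = sample, marker = marker, chromosome = chromosome,
         position = position, lrr = lrr, baf = baf, genotype = genotype)
}

.requireColumns <- function(have, dialect, required) {
    for (key in required) {
        if (!dialect[[key]] %in% have)
            stop(sprintf(
                "required column '%s' (field '%s') not found; available: %s",
                dialect[[key]], key, paste(have, collapse = ", ")),
                call. = FALSE)
    }
}

#' Read long-format (one row per sample-marker) log R ratios
#'
#' Parses a delimited text export with one row per (sample, marker)
#' observation, builds the marker manifest from the coordinate columns, and
#' pivots the log R ratios into a markers x samples matrix. Rows whose
#' chromosome is not an autosome 1-22 (`"X"`, `"Y"`, `"MT"`, ...) are
#' dropped with a message giving the count. Empty, `NA` and `NaN` log R
#' ratio tokens become missing entries (`NA`), which are always distinct
#' from 0.
#'
#' @param file path to a delimited text file with a header.
#' @param dialect column-name map from [lrrDialect()].
#' @param sep field separator, `"auto"` to sniff.
#' @return an [LRRSet]. Sample order follows first appearance in the file;
#'   marker order is manifest (chromosome, position, id) order.
#' @seealso [readLRRWide()] for the matrix layout, [writeCohort()] which
#'   emits this format.
#' @export
readLRRLong <- function(file, dialect = lrrDialect(), sep = "auto") {
    dt <- fread(file, sep = sep, header = TRUE, colClasses = "character",
                na.strings = NULL, data.table = FALSE, showProgress = FALSE)
    .requireColumns(names(dt), dialect,
                    c("sample", "marker", "chromosome", "position", "lrr"))
    sample <- dt[[dialect$sample]]
    marker <- dt[[dialect$marker]]
    chr <- normalizeChromosome(dt[[dialect$chromosome]])
    drop <- is.na(chr)
    if (any(drop)) {
        message(sum(drop), " row(s) on non-autosomal chromosomes dropped")
        dt <- dt[!drop, , drop = FALSE]
        sample <- sample[!drop]; marker <- marker[!drop]; chr <- chr[!drop]
    }
    if (!nrow(dt)) stop("no autosomal rows in ", file)
    dup <- duplicated(paste(sample, marker, sep = "\r"))
    if (any(dup)) {
        i <- which(dup)[1]
        stop(sprintf("duplicate (sample, marker) pair: (%s, %s)",
                     sample[i], marker[i]), call. = FALSE)
    }
    pos <- as.integer(dt[[dialect$position]])
    lrr <- parseNumericTokens(dt[[dialect$lrr]], "log R ratio")

    first <- !duplicated(marker)
    # coordinates must agree across a marker's rows
    key <- paste(chr, pos, sep = ":")
    nkey <- vapply(split(key, marker), function(k) length(unique(k)), 1L)
    if (any(nkey > 1L))
        stop("inconsistent coordinates for marker(s): ",
             paste(utils::head(names(nkey)[nkey > 1L], 5), collapse = ", "))
    manifest <- markerManifest(marker[first], chr[first], pos[first])
    samples <- unique(sample)
    m <- matrix(NA_real_, length(manifest), length(samples),
                dimnames = list(names(manifest), samples))
    m[cbind(match(marker, names(manifest)), match(sample, samples))] <- lrr
    LRRSet(m, manifest)
}

.readManifestFile <- function(file) {
    mf <- fread(file, header = TRUE, colClasses = "character",
                na.strings = NULL, data.table = FALSE, showProgress = FALSE)
    nm <- tolower(names(mf))
    pick <- function(cands, what) {
        i <- which(nm %in% cands)[1]
        if (is.na(i))
            stop(sprintf("manifest lacks a %s column; available: %s", what,
                         paste(names(mf), collapse = ", ")), call. = FALSE)
        mf[[i]]
    }
    markerManifest(pick(c("marker_id", "snp name", "marker"), "marker id"),
                   pick(c("chr", "chromosome"), "chromosome"),
                   as.integer(pick(c("position", "position_bp", "pos"), "position")))
}

#' Read wide-format log R ratios plus a manifest file
#'
#' The wide layout has one row per sample (first column = sample id) and one
#' column per marker; coordinates come from a separate manifest file with
#' columns `marker_id`, `chr`, `position`. Contracts match [readLRRLong()]:
#' non-autosomal manifest entries are dropped, missing tokens become `NA`,
#' and the two readers produce identical objects on equivalent content.
#'
#' @param file path to the wide TSV.
#' @param manifestFile path to the manifest TSV.
#' @return an [LRRSet].
#' @export
readLRRWide <- function(file, manifestFile) {
    dt <- fread(file, header = TRUE, colClasses = "character",
                na.strings = NULL, data.table = FALSE, showProgress = FALSE)
    if (ncol(dt) < 2L) stop("wide file needs a sample column plus markers")
    manifest <- .readManifestFile(manifestFile)
    markers <- names(dt)[-1]
    absent <- setdiff(markers, names(manifest))
    if (length(absent))
        stop("marker column(s) absent from the manifest: ",
             paste(absent, collapse = ", "), call. = FALSE)
    if (length(markers) != length(manifest))
        stop(sprintf(
            "dimension mismatch: %d marker columns but %d manifest markers",
            length(markers), length(manifest)), call. = FALSE)
    samples <- dt[[1]]
    if (anyDuplicated(samples)) stop("duplicate sample ids in wide file")
    vals <- vapply(markers, function(cn)
        parseNumericTokens(dt[[cn]], "log R ratio"), numeric(nrow(dt)))
    m <- matrix(vals, nrow = nrow(dt),
                dimnames = list(samples, markers))
    LRRSet(t(m), manifest)
}

#' Write an LRRSet as a wide matrix plus a manifest file
#'
#' Output is deterministic (byte-identical for equal input) and numeric
#' values are written with 17 significant digits so that
#' `readLRRWide(write(x))` reproduces the matrix exactly.
#'
#' @param x an [LRRSet].
#' @param file destination for the wide TSV.
#' @param manifestFile destination for the manifest TSV.
#' @export
writeLRRWide <- function(x, file, manifestFile) {
    stopifnot(is(x, "LRRSet"))
    m <- lrrMatrix(x)
    cols <- c(list(sample_id = colnames(m)),
              stats::setNames(lapply(rownames(m), function(r) m[r, ]),
                              rownames(m)))
    writeDelimExact(cols, file)
    writeManifest(markerRanges(x), manifestFile)
    invisible(NULL)
}

#' @rdname writeLRRWide
#' @param manifest a manifest [GenomicRanges::GRanges].
#' @export
writeManifest <- function(manifest, manifestFile) {
    writeDelimExact(list(
        marker_id = names(manifest),
        chr = as.character(seqnames(manifest)),
        position = start(manifest)), manifestFile)
    invisible(NULL)
}

#' Write and read CSLV feature tables
#'
#' The on-disk form is a CSV whose first column is `sample_id` followed by
#' the segment columns in (chromosome, segment-index) order, i.e. `chr1_1,
#' chr1_2, ..., chr22_4`. Values are written with 15 significant digits, so
#' a round trip preserves them to well below any biological signal; missing
#' entries are written as `NA`. Writing is deterministic.
#'
#' @param x a [CSLVTable].
#' @param file CSV path.
#' @return `readFeatureTable()` returns a [CSLVTable]; a malformed segment
#'   column name is an error naming the column.
#' @export
writeFeatureTable <- function(x, file) {
    stopifnot(is(x, "CSLVTable"))
    m <- assay(x, "cslv")
    cols <- c(list(sample_id = colnames(m)),
              stats::setNames(lapply(rownames(m), function(r) m[r, ]),
                              rownames(m)))
    cols <- lapply(cols, function(v)
        if (is.double(v)) formatExact(v, 15L) else v)
    writeDelimExact(cols, file, sep = ",")
    invisible(NULL)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(file) {
    dt <- fread(file, sep = ",", header = TRUE, colClasses = "character",
                na.strings = NULL, data.table = FALSE, showProgress = FALSE)
    if (names(dt)[1] != "sample_id") stop("first column must be sample_id")
    labs <- names(dt)[-1]
    info <- parseSegLabel(labs)
    bad <- is.na(info$chromosome) | info$chromosome > 22L
    if (any(bad))
        stop("malformed segment label(s): ", paste(labs[bad], collapse = ", "),
             call. = FALSE)
    n <- nrow(dt)
    vals <- matrix(NA_real_, length(labs), n,
                   dimnames = list(labs, dt$sample_id))
    for (j in seq_along(labs))
        vals[j, ] <- parseNumericTokens(dt[[labs[j]]], labs[j])
    CSLVTable(vals)
}

#' Read and write phenotype tables
#'
#' Phenotype CSVs carry `sample_id`, `sex` (`male`/`female` or missing),
#' `group_label` (free categorical or missing), `age` (years) and `height`
#' (cm, missing allowed; must be finite and positive when present).
#'
#' @param file CSV path.
#' @return `readPhenotypeTable()` returns a data.frame with those five
#'   columns and unique sample ids.
#' @export
readPhenotypeTable <- function(file) {
    dt <- fread(file, sep = ",", header = TRUE, colClasses = "character",
                na.strings = NULL, data.table = FALSE, showProgress = FALSE)
    need <- c("sample_id", "sex", "group_label", "age", "height")
    miss <- setdiff(need, names(dt))
    if (length(miss))
        stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(
        sample_id = dt$sample_id,
        sex = ifelse(tolower(dt$sex) %in% .missingTokens, NA, tolower(dt$sex)),
        group_label = ifelse(tolower(dt$group_label) %in% .missingTokens,
                             NA, dt$group_label),
        age = parseNumericTokens(dt$age, "age"),
        height = parseNumericTokens(dt$height, "height"),
        stringsAsFactors = FALSE
    )
    if (anyDuplicated(out$sample_id)) stop("duplicate sample ids")
    if (!all(is.na(out$sex) | out$sex %in% c("male", "female")))
        stop("sex must be 'male', 'female' or missing")
    h <- out$height
    if (any(!is.na(h) & (!is.finite(h) | h <= 0)))
        stop("height must be finite and positive when present")
    out
}

#' @rdname readPhenotypeTable
#' @param x a phenotype data.frame (or DataFrame) with the five columns.
#' @export
writePhenotypeTable <- function(x, file) {
    x <- as.data.frame(x)
    writeDelimExact(list(
        sample_id = x$sample_id, sex = x$sex, group_label = x$group_label,
        age = as.double(x$age), height = as.double(x$height)),
        file, sep = ",")
    invisible(NULL)
}
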