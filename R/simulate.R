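#' Configuration for the synthetic SNP-array cohort generator
#'
#' The generator emulates the statistical structure the CSLV representation
#' assumes: per-marker log R ratios centred near zero, with segment-level
#' mean shifts from population group membership, a small male-specific
#' "sex-crosstalk" shift on a subset of autosomal segments (autosomal probe
#' intensities being influenced by Y-chromosome presence), and sporadic CNV
#' events; plus a height model with sex, age-cohort and heritable dosage
#' effects.
#'
#' Marker model for sample i, marker j in segment `seg(j)`:
#' `LRR(i,j) = delta_group(i)[seg] + s[seg]*I(male_i) + delta_cnv(i,seg) +
#' eps_ij`, with `eps ~ Normal(0, lrrNoiseSD^2)` i.i.d. CNV events hit each
#' (sample, segment) independently with probability `cnvRate`, copy number
#' 1 or 3 equiprobable. Height for adults:
#' `height_i = beta0 + betaSex*I(male_i) + betaAge*(age_i - midAge) +
#' sum_seg gamma[seg] * truth_i[seg] + Normal(0, residSD^2)` where
#' `truth_i` is the sample's total segment-mean shift and `midAge` the
#' midpoint of `ageRange`.
#'
#' Segment-indexed parameters (`delta`, `sexCrosstalk`, `gamma`) are named
#' numeric vectors over the labels implied by `(chromosomes, k)`
#' (see [configSegmentLabels()]); unnamed segments default to 0.
#'
#' @param nSamples cohort size.
#' @param markersPerChromosome markers simulated per chromosome.
#' @param chromosomes autosomes to simulate, subset of 1:22.
#' @param k segments per chromosome.
#' @param lrrNoiseSD per-marker noise sd (LRR units). The default 0.3 with
#'   100 markers per segment gives segment means with sd 0.03, the order of
#'   dispersion seen in real array cohorts.
#' @param groups list of groups, each `list(label=, proportion=, delta=)`;
#'   proportions must sum to 1. `delta` is the group's per-segment mean
#'   shift in LRR units (positive = net duplication).
#' @param pMale probability a sample is male.
#' @param sexCrosstalk per-segment additive shift applied to males; default
#'   +0.02 on the first segment of up to eight chromosomes. `FALSE` (or an
#'   all-zero vector) disables it.
#' @param cnvRate per-(sample, segment) CNV probability in `[0, 1]`.
#' @param cnvShift named numeric `c("1" = loss, "3" = gain)` LRR shifts;
#'   defaults are the conventional attenuated one-copy values -0.45/+0.30.
#' @param height list with `beta0` (cm, female intercept), `betaSex` (cm),
#'   `betaAge` (cm/year; negative encodes the age-cohort effect, older
#'   people being shorter on average), `gamma` (cm per LRR-unit per
#'   segment), `residSD` (cm).
#' @param ageRange uniform age range in years.
#' @param seed integer seed; one seed determines the whole cohort.
#' @return a validated config (list of class `cslvSimConfig`).
#' @export
simConfig <- function(nSamples = 1000L,
                      markersPerChromosome = 400L,
                      chromosomes = 1:22,
                      k = 4L,
                      lrrNoiseSD = 0.3,
                      groups = list(list(label = "pop", proportion = 1)),
                      pMale = 0.5,
                      sexCrosstalk = NULL,
                      cnvRate = 0.01,
                      cnvShift = c("1" = -0.45, "3" = 0.30),
                      height = list(),
                      ageRange = c(21, 80),
                      seed = 1L) {
    chromosomes <- sort(unique(as.integer(chromosomes)))
    stopifnot(all(chromosomes %in% 1:22), length(chromosomes) >= 1L)
    k <- as.integer(k)
    stopifnot(k >= 1L, markersPerChromosome >= k, nSamples >= 1L,
              lrrNoiseSD >= 0, pMale >= 0, pMale <= 1,
              cnvRate >= 0, cnvRate <= 1,
              length(ageRange) == 2L, ageRange[1] <= ageRange[2])
    labels <- as.vector(t(outer(chromosomes, seq_len(k), segLabel)))

    expand <- function(v, what) {
        out <- stats::setNames(rep(0, length(labels)), labels)
        if (is.null(v) || isFALSE(v)) return(out)
        if (is.null(names(v))) {
            if (length(v) == 1L) return(out + v)
            if (length(v) != length(labels))
                stop(sprintf("%s: expected %d segment values, got %d",
                             what, length(labels), length(v)), call. = FALSE)
            return(stats::setNames(as.numeric(v), labels))
        }
        unknown <- setdiff(names(v), labels)
        if (length(unknown))
            stop(sprintf("%s: unknown segment label(s): %s", what,
                         paste(unknown, collapse = ", ")), call. = FALSE)
        out[names(v)] <- v
        out
    }

    props <- vapply(groups, function(g) g$proportion, 1.0)
    if (abs(sum(props) - 1) > 1e-8)
        stop("group proportions must sum to 1")
    groups <- lapply(groups, function(g) {
        stopifnot(is.character(g$label))
        g$delta <- expand(g$delta, sprintf("group '%s' delta", g$label))
        g
    })
    if (anyDuplicated(vapply(groups, `[[`, "", "label")))
        stop("duplicate group labels")

    if (is.null(sexCrosstalk)) {
        xt <- stats::setNames(rep(0, length(labels)), labels)
        xt[segLabel(utils::head(chromosomes, 8L), 1L)] <- 0.02
    } else xt <- expand(sexCrosstalk, "sexCrosstalk")

    if (!all(names(cnvShift) %in% c("1", "3")) || is.null(names(cnvShift)))
        stop("cnvShift must be named with copy numbers '1' and '3'")
    shift <- c("1" = -0.45, "3" = 0.30)
    shift[names(cnvShift)] <- cnvShift

    hdef <- list(beta0 = 162, betaSex = 13, betaAge = -0.06,
                 gamma = NULL, residSD = 6)
    stopifnot(all(names(height) %in% names(hdef)))
    hdef[names(height)] <- height
    hdef$gamma <- expand(hdef$gamma, "height gamma")
    stopifnot(hdef$residSD >= 0)

    structure(list(
        nSamples = as.integer(nSamples),
        markersPerChromosome = as.integer(markersPerChromosome),
        chromosomes = chromosomes, k = k,
        lrrNoiseSD = lrrNoiseSD, groups = groups, pMale = pMale,
        sexCrosstalk = xt, cnvRate = cnvRate, cnvShift = shift,
        height = hdef, ageRange = as.numeric(ageRange),
        seed = as.integer(seed), segmentLabels = labels
    ), class = "cslvSimConfig")
}

#' Segment labels implied by a simulation config
#'
#' @param config a config from [simConfig()].
#' @return character vector of `"chr{c}_{q}"` labels in (chromosome, q)
#'   order; the index frame for `delta`, `sexCrosstalk` and `gamma`.
#' @export
configSegmentLabels <- function(config) {
    stopifnot(inherits(config, "cslvSimConfig"))
    config$segmentLabels
}

.simManifest <- function(config) {
    m <- config$markersPerChromosome
    chroms <- config$chromosomes
    ids <- as.vector(vapply(chroms, function(c)
        sprintf("c%02dm%05d", c, seq_len(m)), character(m)))
    markerManifest(ids, rep(chroms, each = m),
                   rep(seq_len(m) * 1000L, times = length(chroms)))
}

#' Simulate a SNP-array cohort with known ground truth
#'
#' Draws a cohort under the generative model documented in [simConfig()].
#' The run is fully reproducible from the config's seed; random draws use
#' one sub-stream per (model component, sample), so enlarging `nSamples`
#' leaves earlier samples' data untouched.
#'
#' @param config a [simConfig()].
#' @param seed optional override of `config$seed`.
#' @return a [SimulatedCohort].
#' @examples
#' cfg <- simConfig(nSamples = 20, markersPerChromosome = 8,
#'                  chromosomes = 1:2, lrrNoiseSD = 0, cnvRate = 0,
#'                  sexCrosstalk = FALSE)
#' cohort <- simulateCohort(cfg)
#' all(lrrMatrix(lrrData(cohort)) == 0)  # noise-free null
#' @export
simulateCohort <- function(config, seed = NULL) {
    stopifnot(inherits(config, "cslvSimConfig"))
    if (!is.null(seed)) config$seed <- as.integer(seed)
    sd0 <- config$seed
    n <- config$nSamples
    manifest <- .simManifest(config)
    scheme <- makeSegments(manifest, k = config$k, mode = "equal_marker_count")
    labels <- names(scheme@segments)
    stopifnot(identical(labels, config$segmentLabels))
    nseg <- length(labels)
    nmark <- length(manifest)
    props <- vapply(config$groups, function(g) g$proportion, 1.0)
    deltas <- matrix(vapply(config$groups, function(g) g$delta, numeric(nseg)),
                     nrow = nseg)
    glabs <- vapply(config$groups, `[[`, "", "label")
    sampleIds <- sprintf("S%06d", seq_len(n))

    group <- integer(n); male <- logical(n); age <- numeric(n)
    truth <- matrix(0, nseg, n, dimnames = list(labels, sampleIds))
    lrr <- matrix(0, nmark, n, dimnames = list(names(manifest), sampleIds))
    heightNoise <- numeric(n)
    csum <- cumsum(props)
    for (i in seq_len(n)) {
        withSubstream(sd0, 1L, i, {
            group[i] <- findInterval(stats::runif(1), csum,
                                     rightmost.closed = TRUE) + 1L
            male[i] <- stats::runif(1) < config$pMale
            age[i] <- stats::runif(1, config$ageRange[1], config$ageRange[2])
        })
        tvec <- deltas[, group[i]]
        if (male[i]) tvec <- tvec + config$sexCrosstalk
        if (config$cnvRate > 0) {
            withSubstream(sd0, 2L, i, {
                hit <- stats::runif(nseg) < config$cnvRate
                if (any(hit)) {
                    gain <- stats::runif(nseg) < 0.5
                    tvec[hit] <- tvec[hit] + ifelse(gain[hit],
                        config$cnvShift[["3"]], config$cnvShift[["1"]])
                }
            })
        }
        truth[, i] <- tvec
        eps <- if (config$lrrNoiseSD > 0)
            withSubstream(sd0, 3L, i,
                          stats::rnorm(nmark, 0, config$lrrNoiseSD))
        else 0
        lrr[, i] <- tvec[scheme@assignment] + eps
        heightNoise[i] <- if (config$height$residSD > 0)
            withSubstream(sd0, 4L, i, stats::rnorm(1, 0, config$height$residSD))
        else 0
    }

    h <- config$height
    genetic <- as.numeric(crossprod(truth, h$gamma))
    names(genetic) <- sampleIds
    midAge <- mean(config$ageRange)
    height <- h$beta0 + h$betaSex * male + h$betaAge * (age - midAge) +
        genetic + heightNoise

    pheno <- S4Vectors::DataFrame(
        sample_id = sampleIds,
        sex = ifelse(male, "male", "female"),
        group_label = glabs[group],
        age = age, height = height)
    new("SimulatedCohort",
        lrr = LRRSet(lrr, manifest), phenotypes = pheno, truth = truth,
        geneticHeight = genetic, scheme = scheme, config = unclass(config))
}

#' Analytic AUC for a two-group dosage-shift contrast
#'
#' For two groups that differ only in their segment-mean shifts (no CNV, no
#' sex crosstalk), the CSLV features are equal-covariance Gaussians with
#' per-segment sd `lrrNoiseSD / sqrt(markersPerSegment)`, and the
#' Bayes-optimal linear discriminant attains
#' `AUC = pnorm(D / sqrt(2))` with
#' `D^2 = sum_seg ((delta1[seg] - delta2[seg]) / sdSeg)^2`.
#' This closed form is the oracle against which empirical classifiers on
#' simulated data are calibrated.
#'
#' @param config a [simConfig()] with `cnvRate = 0` and no active sex
#'   crosstalk (the closed form is invalid otherwise and an error is
#'   raised).
#' @param labelPair character(2), labels of the two groups to contrast.
#' @return the expected AUC, in `[0.5, 1]`.
#' @export
expectedPairAUC <- function(config, labelPair) {
    stopifnot(inherits(config, "cslvSimConfig"), length(labelPair) == 2L)
    if (config$cnvRate > 0)
        stop("closed form invalid with CNV events active (cnvRate > 0)")
    if (any(config$sexCrosstalk != 0))
        stop("closed form invalid with sex crosstalk active")
    glabs <- vapply(config$groups, `[[`, "", "label")
    i <- match(labelPair, glabs)
    if (any(is.na(i)))
        stop("unknown group label(s): ",
             paste(labelPair[is.na(i)], collapse = ", "))
    d1 <- config$groups[[i[1]]]$delta
    d2 <- config$groups[[i[2]]]$delta
    diff <- d1 - d2
    if (all(diff == 0)) return(0.5)
    if (config$lrrNoiseSD == 0) return(1.0)
    mseg <- S4Vectors::mcols(makeSegments(.simManifest(config),
                                          config$k)@segments)$nMarkers
    sdSeg <- config$lrrNoiseSD / sqrt(mseg)
    D <- sqrt(sum((diff / sdSeg)^2))
    stats::pnorm(D / sqrt(2))
}

#' Write a simulated cohort to a directory
#'
#' Emits four plain-text files: `lrr_long.tsv` (Final-Report-like long
#' format with a constant placeholder BAF of 0.5), `manifest.tsv`,
#' `phenotypes.csv` and `truth.csv` (true per-segment mean shifts, one row
#' per sample). Numeric values are written with 17 significant digits so
#' [readLRRLong()] on the output reproduces the in-memory matrix exactly,
#' and writing is deterministic: the same cohort always yields
#' byte-identical files.
#'
#' @param cohort a [SimulatedCohort].
#' @param dir destination directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SimulatedCohort"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    x <- cohort@lrr
    m <- lrrMatrix(x)
    manifest <- markerRanges(x)
    nmark <- nrow(m); nsamp <- ncol(m)
    paths <- file.path(dir, c("lrr_long.tsv", "manifest.tsv",
                              "phenotypes.csv", "truth.csv"))
    writeDelimExact(list(
        "Sample ID" = rep(colnames(m), each = nmark),
        "SNP Name" = rep(rownames(m), times = nsamp),
        "Chr" = rep(as.character(seqnames(manifest)), times = nsamp),
        "Position" = rep(start(manifest), times = nsamp),
        "Log R Ratio" = as.vector(m),
        "B Allele Freq" = rep(0.5, nmark * nsamp)), paths[1])
    writeManifest(manifest, paths[2])
    writePhenotypeTable(as.data.frame(cohort@phenotypes), paths[3])
    tr <- cohort@truth
    writeDelimExact(c(list(sample_id = colnames(tr)),
                      stats::setNames(lapply(rownames(tr), function(r) tr[r, ]),
                                      rownames(tr))),
                    paths[4], sep = ",")
    invisible(paths)
}
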