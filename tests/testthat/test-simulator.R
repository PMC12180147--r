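test_that("a noise-free null cohort is exactly zero everywhere", {
    cfg <- simConfig(nSamples = 12, markersPerChromosome = 8, chromosomes = 1:2,
                     k = 4, lrrNoiseSD = 0, cnvRate = 0, sexCrosstalk = FALSE,
                     height = list(residSD = 0), seed = 4)
    co <- simulateCohort(cfg)
    expect_true(all(lrrMatrix(lrrData(co)) == 0))
    cs <- computeCSLV(lrrData(co), segmentScheme(co))
    expect_true(all(assay(cs, "cslv") == 0))
    expect_true(all(truthMatrix(co) == 0))
})

test_that("group shifts propagate exactly to CSLV under zero noise", {
    labels <- sprintf("chr1_%d", 1:4)
    cfg <- simConfig(nSamples = 10, markersPerChromosome = 12,
                     chromosomes = 1:3, k = 4, lrrNoiseSD = 0, cnvRate = 0,
                     sexCrosstalk = FALSE,
                     groups = list(list(label = "pop", proportion = 1,
                                        delta = setNames(rep(0.3, 4), labels))),
                     seed = 4)
    co <- simulateCohort(cfg)
    cs <- assay(computeCSLV(lrrData(co), segmentScheme(co)), "cslv")
    expect_true(all(cs[labels, ] == 0.3))
    expect_true(all(cs[setdiff(rownames(cs), labels), ] == 0))
})

test_that("group means of CSLV recover the injected shifts at CLT accuracy", {
    cfg <- pairConfig(n = 400, chroms = 1, k = 4, m = 400, deltaDiff = 0.05,
                      sigma = 0.2, seed = 8)
    co <- simulateCohort(cfg)
    cs <- cslvMatrix(computeCSLV(lrrData(co), segmentScheme(co)))
    grp <- phenotypes(co)$group_label
    # segment sd is sigma/sqrt(100) = 0.02; group-mean error ~ 0.02/sqrt(200)
    diffs <- colMeans(cs[grp == "A", ]) - colMeans(cs[grp == "B", ])
    expect_true(all(abs(diffs - 0.05) < 5 * 0.02 / sqrt(100)))
})

test_that("the analytic pair AUC matches its closed form and guards its domain", {
    cfg0 <- pairConfig(n = 10, chroms = 1, k = 1, m = 400, deltaDiff = 0)
    expect_equal(expectedPairAUC(cfg0, c("A", "B")), 0.5)

    # one segment, delta 0.01, feature sd 0.2/sqrt(400) = 0.01 -> d = 1
    cfg1 <- pairConfig(n = 10, chroms = 1, k = 1, m = 400, deltaDiff = 0.01)
    expect_equal(expectedPairAUC(cfg1, c("A", "B")), pnorm(1 / sqrt(2)),
                 tolerance = 1e-12)
    expect_equal(expectedPairAUC(cfg1, c("A", "B")), 0.760, tolerance = 5e-4)

    # 20 segments of 100 markers (feature sd 0.02), delta 0.01 -> d = 0.5
    # per segment, D = sqrt(20 * 0.25) = sqrt(5)
    cfg2 <- pairConfig(n = 10, chroms = 1:5, k = 4, m = 400, deltaDiff = 0.01)
    expect_equal(expectedPairAUC(cfg2, c("A", "B")), pnorm(sqrt(5) / sqrt(2)),
                 tolerance = 1e-12)
    expect_equal(expectedPairAUC(cfg2, c("A", "B")), 0.943, tolerance = 5e-4)

    cfgCNV <- pairConfig(n = 10, chroms = 1, k = 1, m = 400, deltaDiff = 0.01)
    cfgCNV$cnvRate <- 0.05
    expect_error(expectedPairAUC(cfgCNV, c("A", "B")), "CNV")
    cfgXT <- pairConfig(n = 10, chroms = 1, k = 1, m = 400, deltaDiff = 0.01)
    cfgXT$sexCrosstalk[] <- 0.02
    expect_error(expectedPairAUC(cfgXT, c("A", "B")), "crosstalk")
})

test_that("cohort files round-trip exactly and are byte-deterministic", {
    cfg <- simConfig(nSamples = 3, markersPerChromosome = 8, chromosomes = 1:2,
                     k = 2, lrrNoiseSD = 0.3, cnvRate = 0.1, seed = 21)
    co <- simulateCohort(cfg)
    d1 <- tempfile(); d2 <- tempfile()
    writeCohort(co, d1)
    expect_setequal(list.files(d1), c("lrr_long.tsv", "manifest.tsv",
                                      "phenotypes.csv", "truth.csv"))
    back <- readLRRLong(file.path(d1, "lrr_long.tsv"))
    expect_identical(lrrMatrix(back), lrrMatrix(lrrData(co)))

    writeCohort(simulateCohort(cfg), d2)
    for (f in list.files(d1))
        expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                         readBin(file.path(d2, f), "raw", 1e7))

    co2 <- simulateCohort(cfg, seed = 22)
    expect_false(identical(lrrMatrix(lrrData(co2)), lrrMatrix(lrrData(co))))
    expect_identical(as.data.frame(markerRanges(lrrData(co2))),
                     as.data.frame(markerRanges(lrrData(co))))
})

test_that("enlarging a cohort leaves earlier samples untouched", {
    cfg20 <- simConfig(nSamples = 20, markersPerChromosome = 10,
                       chromosomes = 1, k = 2, lrrNoiseSD = 0.2,
                       cnvRate = 0.1, seed = 13)
    cfg30 <- cfg20; cfg30$nSamples <- 30L
    a <- simulateCohort(cfg20); b <- simulateCohort(cfg30)
    expect_identical(lrrMatrix(lrrData(a)),
                     lrrMatrix(lrrData(b))[, 1:20])
    expect_identical(as.data.frame(phenotypes(a)),
                     as.data.frame(phenotypes(b))[1:20, ])
})

test_that("regressing simulated height on the truth recovers the height model", {
    gamma <- setNames(rep(0, 8), sprintf("chr1_%d", 1:8))
    gamma[c("chr1_2", "chr1_5")] <- c(12, -8)
    cfg <- simConfig(nSamples = 600, markersPerChromosome = 80,
                     chromosomes = 1, k = 8, lrrNoiseSD = 0.2,
                     cnvRate = 0.15, sexCrosstalk = FALSE,
                     height = list(beta0 = 162, betaSex = 13, betaAge = -0.06,
                                   gamma = gamma, residSD = 4),
                     seed = 31)
    co <- simulateCohort(cfg)
    ph <- as.data.frame(phenotypes(co))
    tr <- t(truthMatrix(co))[, c("chr1_2", "chr1_5")]
    df <- data.frame(h = ph$height, male = ph$sex == "male",
                     age = ph$age - mean(cfg$ageRange), tr)
    fit <- summary(lm(h ~ male + age + chr1_2 + chr1_5, data = df))$coefficients
    truthCoef <- c("(Intercept)" = 162, maleTRUE = 13, age = -0.06,
                   chr1_2 = 12, chr1_5 = -8)
    for (nm in names(truthCoef))
        expect_lt(abs(fit[nm, "Estimate"] - truthCoef[[nm]]),
                  3 * fit[nm, "Std. Error"] + 1e-8)
    expect_equal(unname(geneticHeight(co)),
                 as.numeric(t(truthMatrix(co)) %*% cfg$height$gamma))
})

test_that("config validation catches malformed shift vectors", {
    expect_error(simConfig(groups = list(list(label = "a", proportion = 1,
                                              delta = c(chr9_9 = 1)))),
                 "unknown segment label")
    expect_error(simConfig(chromosomes = 1, k = 2,
                           groups = list(list(label = "a", proportion = 1,
                                              delta = c(0.1, 0.2, 0.3)))),
                 "expected 2 segment values")
    expect_error(simConfig(groups = list(list(label = "a", proportion = 0.7))),
                 "sum to 1")
})
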