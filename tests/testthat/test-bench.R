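test_that("aucROC reproduces hand-counted examples and tie conventions", {
    expect_equal(aucValue(aucROC(c(0.9, 0.8), c(TRUE, FALSE))), 1.0)
    expect_equal(aucValue(aucROC(rep(0.5, 6), rep(c(TRUE, FALSE), 3))), 0.5)
    # 4 pos-neg pairs, 3 concordant: 0.75
    r <- aucROC(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(aucValue(r), 0.75)
    expect_equal(r@fpr[1], 0); expect_equal(r@tpr[1], 0)
    expect_equal(r@fpr[length(r@fpr)], 1)
    expect_equal(r@tpr[length(r@tpr)], 1)
    expect_error(aucROC(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("aucROC equals exhaustive pair counting and its own trapezoid on random instances", {
    set.seed(100)
    for (i in 1:200) {
        n <- sample(4:50, 1)
        # coarse grid scores force plenty of ties
        scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
        pos <- as.logical(rbinom(n, 1, 0.5))
        if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
        r <- aucROC(scores, pos)
        expect_lt(abs(aucValue(r) - pairCountingAUC(scores, pos)), 1e-12)
        trap <- sum(diff(r@fpr) * (utils::head(r@tpr, -1) + utils::tail(r@tpr, -1)) / 2)
        expect_lt(abs(aucValue(r) - trap), 1e-12)
    }
})

test_that("aucROC agrees with an independent ROC implementation", {
    set.seed(7)
    for (i in 1:5) {
        scores <- round(rnorm(40), 1)
        pos <- as.logical(rbinom(40, 1, 0.4))
        if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
        ref <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                              predictor = scores,
                                              quiet = TRUE,
                                              direction = "<")))
        expect_equal(aucValue(aucROC(scores, pos)), ref, tolerance = 1e-12)
    }
})

test_that("splitCounts keeps exact products exact and floors the rest", {
    expect_identical(splitCounts(161820, 0.8),
                     c(n_train = 129456L, n_test = 32364L))
    expect_identical(splitCounts(10, 0.8), c(n_train = 8L, n_test = 2L))
    expect_identical(splitCounts(11, 0.8), c(n_train = 8L, n_test = 3L))
    expect_error(splitCounts(1, 0.8), ">= 2")
    expect_error(splitCounts(10, 1), "\\(0, 1\\)")
})

test_that("buildTask applies the task's row and column filters", {
    tab <- randomCSLVTable(9, chroms = 1:2, k = 2, seed = 2)
    ph <- data.frame(
        sample_id = colnames(tab),
        sex = rep(c("male", "female", "male"), 3),
        group_label = rep(c("A", "B", "C"), each = 3),
        age = c(20, rep(40, 8)),
        height = c(rep(170, 8), NA))

    spec <- taskSpec("binary_classification", positive = "A", negative = "B",
                     labelColumn = "group_label")
    t1 <- buildTask(tab, ph, spec)
    expect_identical(nrow(t1), 6L)
    expect_false(any(ph$sample_id[ph$group_label == "C"] %in% rownames(t1)))
    expect_identical(levels(t1$.y), c("B", "A"))

    rspec <- taskSpec("regression")
    t2 <- buildTask(tab, ph, rspec)
    # the 20-year-old and the missing-height sample are gone
    expect_identical(nrow(t2), 7L)
    expect_false(ph$sample_id[1] %in% rownames(t2))
    # predictors are age plus the segment columns, nothing else
    expect_identical(sort(setdiff(names(t2), ".y")),
                     sort(c("age", rownames(tab))))

    ph2 <- ph; ph2$group_label[1:3] <- "B"
    expect_error(buildTask(tab, ph2, spec), "fewer than 2")
})

test_that("grouped mean curves rank, balance and partition correctly", {
    g <- curveTable(groupedMeanCurve(1:100, 1:100, 50))
    expect_equal(g$mean_actual, seq(1.5, 99.5, by = 2))
    expect_true(all(diff(g$mean_actual) > 0))
    expect_identical(g$size, rep(2L, 50))

    g2 <- curveTable(groupedMeanCurve(10:1, c(101:110), 5))
    # first group holds the two smallest predicted values (inputs 10 and 9)
    expect_equal(g2$mean_predicted[1], 1.5)
    expect_equal(g2$mean_actual[1], 109.5)

    # maximal-balanced with larger groups first, summing to n
    g3 <- curveTable(groupedMeanCurve(rnorm(103), rnorm(103), 5))
    expect_identical(g3$size, c(21L, 21L, 21L, 20L, 20L))

    expect_error(groupedMeanCurve(1:3, 1:3, 5), "at least")
})

test_that("under independence the grouped curve stays near the grand mean", {
    set.seed(17)
    n <- 5000
    pred <- rnorm(n); act <- rnorm(n, 10, 2)
    g <- curveTable(groupedMeanCurve(pred, act, 50))
    bound <- 4 * sd(act) / sqrt(100)
    expect_lt(max(abs(g$mean_actual - mean(act))), bound)
})

test_that("repeated holdout is deterministic and perfect on separable data", {
    set.seed(3)
    n <- 80
    y <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 3, ifelse(y == "A", 3, -3), 0.1), n, 3,
                dimnames = list(NULL, c("chr1_1", "chr1_2", "chr1_3")))
    tb <- data.frame(.y = factor(y, levels = c("B", "A")), X,
                     check.names = FALSE)
    spec <- taskSpec("binary_classification", positive = "A", negative = "B",
                     nRepeats = 4, seed = 5)
    ra <- repeatedHoldout(tb, modelRecipe("glm"), spec)
    expect_equal(aucMean(ra), 1.0)
    expect_equal(aucSD(ra), 0.0)
    ra2 <- repeatedHoldout(tb, modelRecipe("glm"), spec)
    expect_identical(aucValues(ra), aucValues(ra2))
    expect_length(aucValues(ra), 4L)
})

test_that("model search ranks candidates, finds separable structure and respects the budget", {
    set.seed(9)
    n <- 160
    y <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 4, ifelse(y == "A", 0.5, -0.5), 0.1), n, 4,
                dimnames = list(NULL, sprintf("chr%d_1", 1:4)))
    tb <- data.frame(.y = factor(y, levels = c("B", "A")), X,
                     check.names = FALSE)
    spec <- taskSpec("binary_classification", positive = "A", negative = "B",
                     cvFolds = 3, trialBudget = 8, seed = 11)
    res <- modelSearch(tb, spec)
    lb <- leaderboard(res)
    expect_identical(lb$rank, seq_len(nrow(lb)))
    expect_true(all(diff(lb$metric) <= 0))
    expect_identical(nrow(lb), 10L)          # 8 candidates + 2 ensembles
    expect_gte(lb$metric[1], 0.99)
    expect_setequal(unique(lb$family),
                    c("glm", "gbm", "drf", "dl", "ensemble"))
    pred <- predictModel(bestModel(res), tb)
    expect_gte(aucValue(aucROC(pred, tb$.y == "A")), 0.99)

    badSpec <- spec; badSpec$trialBudget <- 3L
    expect_error(modelSearch(tb, badSpec), "families")
})

test_that("stacked ensembles never fall below the worst base model", {
    for (s in 1:5) {
        set.seed(200 + s)
        n <- 120
        y <- factor(rbinom(n, 1, 0.5), labels = c("B", "A"))
        X <- matrix(rnorm(n * 5) + 0.6 * as.numeric(y == "A"), n, 5,
                    dimnames = list(NULL, sprintf("chr1_%d", 1:5)))
        tb <- data.frame(.y = y, X, check.names = FALSE)
        spec <- taskSpec("binary_classification", positive = "A",
                         negative = "B", cvFolds = 3, trialBudget = 4,
                         seed = 300 + s)
        lb <- leaderboard(modelSearch(tb, spec))
        worstBase <- min(lb$metric[lb$family != "ensemble"])
        for (e in lb$metric[lb$family == "ensemble"])
            expect_gte(e, worstBase - 0.02)
    }
})

test_that("permutation importance separates signal from ignored and noise features", {
    set.seed(23)
    n <- 600
    y <- factor(rbinom(n, 1, 0.5), labels = c("B", "A"))
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, sprintf("chr2_%d", 1:6)))
    X[, "chr2_3"] <- X[, "chr2_3"] + 1.5 * as.numeric(y == "A")
    tb <- data.frame(.y = y, X, check.names = FALSE)
    spec <- taskSpec("binary_classification", positive = "A", negative = "B",
                     cvFolds = 3, trialBudget = 4, seed = 7)

    # a maximally-regularized linear model predicts a constant: all zero
    m0 <- cslv:::.fitModel("glm", list(alpha = 1, lambda = 1e6),
                           as.matrix(X), y, "binary_classification", 1L)
    imp0 <- importanceTable(permutationImportance(m0, tb, nRepeats = 3))
    expect_true(all(imp0$mean_drop == 0))

    m1 <- cslv:::.fitModel("glm", list(alpha = 0, lambda = 1e-3),
                           as.matrix(X), y, "binary_classification", 1L)
    imp1 <- importanceTable(permutationImportance(m1, tb, nRepeats = 5,
                                                  seed = 2))
    expect_identical(imp1$feature[which.max(imp1$mean_drop)], "chr2_3")
    # a pure-noise feature's importance sits near zero
    noise <- imp1[imp1$feature == "chr2_1", ]
    expect_lt(abs(noise$mean_drop), 0.02)

    expect_error(permutationImportance(m1, tb[, 1:3], nRepeats = 2), "absent")
})
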