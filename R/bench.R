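#' ROC curve and AUC by the Mann-Whitney convention
#'
#' Computes the receiver operating characteristic curve with one point per
#' distinct score threshold and its area. The AUC is computed from the
#' rank-sum form of the Mann-Whitney statistic, i.e. the probability that a
#' random positive outscores a random negative with tied pairs counted
#' half; the trapezoidal area of the returned curve equals this value.
#'
#' @param scores finite numeric scores, larger = more positive.
#' @param labels class labels: logical (`TRUE` = positive), or a two-level
#'   factor/character/numeric vector with `positive` naming the positive
#'   class.
#' @param positive the positive class label; defaults to `TRUE` for
#'   logical labels and to the last sorted level otherwise.
#' @return a [RocResult].
#' @examples
#' aucValue(aucROC(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)))
#' @export
aucROC <- function(scores, labels, positive = NULL) {
    pos <- .asBinary(labels, positive)
    if (length(scores) != length(pos))
        stop("scores and labels lengths differ")
    if (!all(is.finite(scores))) stop("scores must be finite")
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute an ROC curve")
    r <- rank(scores)                       # midranks: ties get half credit
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; p <- pos[o]
    keep <- c(s[-length(s)] != s[-1], TRUE) # last index of each tie block
    tpr <- c(0, cumsum(p)[keep] / n1)
    fpr <- c(0, cumsum(!p)[keep] / n0)
    new("RocResult", fpr = fpr, tpr = tpr, auc = auc)
}

.asBinary <- function(labels, positive = NULL) {
    if (is.logical(labels)) {
        if (is.null(positive)) positive <- TRUE
        return(labels == positive)
    }
    u <- sort(unique(as.character(labels)))
    if (length(u) != 2L)
        stop("labels must take exactly two values, got: ",
             paste(utils::head(u, 5), collapse = ", "))
    if (is.null(positive)) positive <- u[2]
    if (!as.character(positive) %in% u)
        stop("positive class '", positive, "' not among labels")
    as.character(labels) == as.character(positive)
}

#' Train/test partition sizes for a fractional split
#'
#' The training count is the floor of `n * trainFraction`, with exact
#' products kept exact under floating point (so 161,820 samples at 0.8
#' give exactly 129,456 / 32,364).
#'
#' @param n number of samples, `>= 2`.
#' @param trainFraction in (0, 1).
#' @return named integer vector `c(n_train, n_test)`.
#' @export
splitCounts <- function(n, trainFraction = 0.8) {
    n <- as.integer(n)
    if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
    if (!is.numeric(trainFraction) || trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must be in (0, 1)")
    nt <- n * trainFraction
    r <- round(nt)
    nTrain <- if (abs(nt - r) < 1e-9) r else floor(nt)
    nTrain <- max(1L, min(n - 1L, as.integer(nTrain)))
    c(n_train = nTrain, n_test = n - nTrain)
}

#' Specify a prediction task
#'
#' Collects the knobs of the evaluation harness: what to predict, how to
#' split, how many cross-validation folds and candidate models to use.
#'
#' @param mode `"binary_classification"` or `"regression"`.
#' @param positive,negative class labels for classification (`positive` is
#'   scored as the positive class).
#' @param labelColumn phenotype column holding the class labels
#'   (`"group_label"` or `"sex"`).
#' @param target regression target column (default `"height"`).
#' @param minAge regression-only filter: samples younger than this are
#'   excluded so only fully grown people enter the height model.
#' @param trainFraction holdout training fraction.
#' @param nRepeats random train/test splits for [repeatedHoldout()].
#' @param cvFolds cross-validation folds for [modelSearch()].
#' @param trialBudget maximum number of single-model candidates evaluated
#'   by [modelSearch()] (the two stacked ensembles come on top).
#' @param nGroups groups for [groupedMeanCurve()].
#' @param seed integer; drives folds, splits and model fits.
#' @return a list of class `cslvTaskSpec`.
#' @export
taskSpec <- function(mode = c("binary_classification", "regression"),
                     positive = NULL, negative = NULL,
                     labelColumn = "group_label", target = "height",
                     minAge = 21, trainFraction = 0.8, nRepeats = 5L,
                     cvFolds = 10L, trialBudget = 24L, nGroups = 50L,
                     seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(trainFraction > 0, trainFraction < 1, nRepeats >= 1L,
              cvFolds >= 2L, nGroups >= 1L)
    if (mode == "binary_classification" &&
        (is.null(positive) || is.null(negative)))
        stop("classification needs both 'positive' and 'negative' labels")
    structure(list(mode = mode, positive = positive, negative = negative,
                   labelColumn = labelColumn, target = target,
                   minAge = minAge, trainFraction = trainFraction,
                   nRepeats = as.integer(nRepeats),
                   cvFolds = as.integer(cvFolds),
                   trialBudget = as.integer(trialBudget),
                   nGroups = as.integer(nGroups), seed = as.integer(seed)),
              class = "cslvTaskSpec")
}

#' Assemble the modelling table for a task
#'
#' Joins a CSLV feature table with phenotypes and applies the task's row
#' and column filters. For classification the rows are restricted to the
#' two requested labels and the outcome is a two-level factor (positive
#' class last). For regression the outcome is the target (height), the
#' predictors are age plus every CSLV column - sex and group label are
#' deliberately excluded - and rows younger than `minAge` or missing the
#' target are removed. Samples with any missing feature are dropped with a
#' message (the modelling functions never impute).
#'
#' @param features a [CSLVTable].
#' @param phenotypes a phenotype data.frame (see [readPhenotypeTable()]) or
#'   the [phenotypes()] of a simulated cohort.
#' @param spec a [taskSpec()].
#' @return data.frame with the outcome in column `.y`, the predictors in
#'   the remaining columns and sample ids as row names.
#' @export
buildTask <- function(features, phenotypes, spec) {
    stopifnot(is(features, "CSLVTable"), inherits(spec, "cslvTaskSpec"))
    ph <- as.data.frame(phenotypes)
    stopifnot("sample_id" %in% names(ph))
    ids <- intersect(colnames(features), ph$sample_id)
    if (!length(ids)) stop("no shared sample ids")
    X <- cslvMatrix(features)[ids, , drop = FALSE]
    ph <- ph[match(ids, ph$sample_id), , drop = FALSE]

    if (spec$mode == "binary_classification") {
        lab <- as.character(ph[[spec$labelColumn]])
        keep <- !is.na(lab) & lab %in% c(spec$positive, spec$negative)
        X <- X[keep, , drop = FALSE]; lab <- lab[keep]; ids <- ids[keep]
        cc <- stats::complete.cases(X)
        if (any(!cc)) message(sum(!cc), " sample(s) with missing features dropped")
        X <- X[cc, , drop = FALSE]; lab <- lab[cc]; ids <- ids[cc]
        y <- factor(lab, levels = c(spec$negative, spec$positive))
        if (any(table(y) < 2L))
            stop("fewer than 2 samples in some class")
        out <- data.frame(.y = y, X, check.names = FALSE)
    } else {
        tgt <- ph[[spec$target]]
        keep <- !is.na(tgt) & !is.na(ph$age) & ph$age >= spec$minAge
        X <- cbind(age = ph$age, X)[keep, , drop = FALSE]
        tgt <- tgt[keep]; ids <- ids[keep]
        cc <- stats::complete.cases(X)
        if (any(!cc)) message(sum(!cc), " sample(s) with missing features dropped")
        X <- X[cc, , drop = FALSE]; tgt <- tgt[cc]; ids <- ids[cc]
        if (nrow(X) < 2L) stop("fewer than 2 usable samples")
        out <- data.frame(.y = tgt, X, check.names = FALSE)
    }
    rownames(out) <- ids
    out
}

# ---- model zoo -------------------------------------------------------------

.familyGrid <- function(mode, p) {
    grid <- list()
    for (a in c(0, 1)) for (l in c(1e-4, 1e-3, 1e-2))
        grid[[length(grid) + 1L]] <- list(family = "glm",
                                          params = list(alpha = a, lambda = l))
    for (d in c(2L, 4L, 6L)) for (e in c(0.1, 0.3))
        grid[[length(grid) + 1L]] <- list(family = "gbm",
            params = list(max_depth = d, eta = e, nrounds = 60L))
    mtrys <- unique(c(max(1L, ceiling(sqrt(p))), max(1L, p %/% 3L)))
    for (mt in mtrys) for (ns in c(5L, 20L))
        grid[[length(grid) + 1L]] <- list(family = "drf",
            params = list(mtry = min(mt, p), min.node.size = ns,
                          num.trees = 200L))
    for (sz in c(4L, 8L, 16L)) for (dc in c(0.01, 0.1))
        grid[[length(grid) + 1L]] <- list(family = "dl",
            params = list(size = sz, decay = dc, maxit = 150L))
    grid
}

# round-robin across families so a small budget still samples every family
.interleave <- function(grid) {
    fams <- vapply(grid, `[[`, "", "family")
    split_ <- split(seq_along(grid), factor(fams, levels = unique(fams)))
    maxlen <- max(lengths(split_))
    idx <- unlist(lapply(seq_len(maxlen), function(i)
        vapply(split_, function(v) if (i <= length(v)) v[i] else NA_integer_, 1L)))
    grid[idx[!is.na(idx)]]
}

#' A single-model recipe for the harness
#'
#' A recipe names a model family and hyperparameters; it is what
#' [repeatedHoldout()] refits on every split. Families map to glmnet
#' (`"glm"`), xgboost gradient boosting (`"gbm"`), ranger random forest
#' (`"drf"`) and a small nnet feed-forward network (`"dl"`).
#'
#' @param family one of `"glm"`, `"gbm"`, `"drf"`, `"dl"`.
#' @param params named list of hyperparameters; omitted entries take the
#'   family's first grid point.
#' @export
modelRecipe <- function(family = c("glm", "gbm", "drf", "dl"), params = list()) {
    family <- match.arg(family)
    defaults <- list(
        glm = list(alpha = 0, lambda = 1e-3),
        gbm = list(max_depth = 4L, eta = 0.1, nrounds = 60L),
        drf = list(mtry = NULL, min.node.size = 5L, num.trees = 200L),
        dl = list(size = 8L, decay = 0.01, maxit = 150L))[[family]]
    defaults[names(params)] <- params
    list(family = family, params = defaults)
}

.fitModel <- function(family, params, X, y, mode, seed) {
    cls <- mode == "binary_classification"
    model <- list(kind = "single", family = family, params = params,
                  mode = mode, features = colnames(X))
    set.seed(seed)
    if (family == "glm") {
        pad <- ncol(X) < 2L
        Xg <- if (pad) cbind(X, `.pad0` = 0) else X
        lam <- sort(unique(params$lambda * c(100, 10, 1)), decreasing = TRUE)
        fit <- glmnet::glmnet(Xg, y, family = if (cls) "binomial" else "gaussian",
                              alpha = params$alpha, lambda = lam)
        model$fit <- fit; model$pad <- pad; model$s <- params$lambda
    } else if (family == "gbm") {
        lab <- if (cls) as.numeric(y == levels(y)[2]) else y
        dtrain <- xgboost::xgb.DMatrix(X, label = lab)
        fit <- xgboost::xgb.train(
            params = list(objective = if (cls) "binary:logistic"
                          else "reg:squarederror",
                          max_depth = params$max_depth, eta = params$eta,
                          nthread = 1L, seed = seed),
            data = dtrain, nrounds = params$nrounds, verbose = 0)
        model$fit <- fit
    } else if (family == "drf") {
        mtry <- params$mtry
        if (is.null(mtry))
            mtry <- max(1L, if (cls) ceiling(sqrt(ncol(X))) else ncol(X) %/% 3L)
        fit <- ranger::ranger(
            x = as.data.frame(X), y = y, num.trees = params$num.trees,
            mtry = min(mtry, ncol(X)), min.node.size = params$min.node.size,
            probability = cls, seed = seed, num.threads = 1L)
        model$fit <- fit
    } else if (family == "dl") {
        ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
        Xs <- scale(X, ctr, scl)
        if (cls) {
            fit <- nnet::nnet(Xs, as.numeric(y == levels(y)[2]),
                              size = params$size, decay = params$decay,
                              maxit = params$maxit, entropy = TRUE,
                              trace = FALSE, MaxNWts = 100000L)
            model$yCenter <- 0; model$yScale <- 1
        } else {
            my <- mean(y); sy <- stats::sd(y); if (sy == 0) sy <- 1
            fit <- nnet::nnet(Xs, (y - my) / sy, size = params$size,
                              decay = params$decay, maxit = params$maxit,
                              linout = TRUE, trace = FALSE, MaxNWts = 100000L)
            model$yCenter <- my; model$yScale <- sy
        }
        model$fit <- fit; model$center <- ctr; model$scale <- scl
    } else stop("unknown family: ", family)
    if (cls) model$levels <- levels(y)
    class(model) <- "cslvModel"
    model
}

.predictFit <- function(model, X) {
    X <- X[, model$features, drop = FALSE]
    cls <- model$mode == "binary_classification"
    switch(model$family,
        glm = {
            Xg <- if (isTRUE(model$pad)) cbind(X, `.pad0` = 0) else X
            as.numeric(stats::predict(model$fit, Xg, s = model$s,
                                      type = "response"))
        },
        gbm = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))),
        drf = {
            pr <- stats::predict(model$fit, data = as.data.frame(X),
                                 num.threads = 1L)$predictions
            if (cls) as.numeric(pr[, model$levels[2]]) else as.numeric(pr)
        },
        dl = {
            Xs <- scale(X, model$center, model$scale)
            as.numeric(stats::predict(model$fit, Xs)) * model$yScale +
                model$yCenter
        },
        ensemble = {
            Z <- vapply(model$base, .predictFit, numeric(nrow(X)), X)
            Z <- matrix(Z, nrow = nrow(X))
            as.numeric(stats::predict(model$meta, Z, s = model$metaLambda,
                                      type = "response"))
        },
        stop("unknown family: ", model$family))
}

#' Predict from a fitted harness model
#'
#' @param model a model returned by [modelSearch()] (via [bestModel()]) or
#'   refit by [repeatedHoldout()] internals.
#' @param newdata data.frame or matrix containing the model's feature
#'   columns (extra columns, including `.y`, are ignored).
#' @return numeric vector: probability of the positive class for
#'   classification, predicted value for regression.
#' @export
predictModel <- function(model, newdata) {
    stopifnot(inherits(model, "cslvModel"))
    if (is.data.frame(newdata)) {
        miss <- setdiff(model$features, names(newdata))
        if (length(miss))
            stop("feature(s) absent from newdata: ", paste(miss, collapse = ", "))
        newdata <- as.matrix(newdata[, model$features, drop = FALSE])
    } else {
        miss <- setdiff(model$features, colnames(newdata))
        if (length(miss))
            stop("feature(s) absent from newdata: ", paste(miss, collapse = ", "))
    }
    .predictFit(model, newdata)
}

.metricValue <- function(pred, y, mode) {
    if (mode == "binary_classification")
        aucValue(aucROC(pred, y == levels(y)[2]))
    else sqrt(mean((pred - y)^2))
}

.makeFolds <- function(y, k, seed, mode) {
    n <- length(y)
    k <- min(k, n)
    set.seed(substreamSeed(seed, 10L, 0L))
    fold <- integer(n)
    if (mode == "binary_classification") {
        for (lv in levels(y)) {
            i <- which(y == lv)
            fold[i] <- sample(rep_len(seq_len(k), length(i)))
        }
    } else fold <- sample(rep_len(seq_len(k), n))
    fold
}

.fitMeta <- function(Z, y, mode, lambda = 1e-3) {
    glmnet::glmnet(Z, y,
                   family = if (mode == "binary_classification") "binomial"
                            else "gaussian",
                   alpha = 0, lambda = sort(lambda * c(100, 10, 1),
                                            decreasing = TRUE),
                   lower.limits = 0)
}

#' Cross-validated model search with stacked ensembles
#'
#' Emulates an AutoML-style search under a deterministic trial budget: a
#' fixed hyperparameter grid over four model families - regularized
#' linear/logistic models (glmnet), gradient-boosted trees (xgboost),
#' random forests (ranger) and a small feed-forward network (nnet) - is
#' consumed round-robin up to `trialBudget` candidates, each scored by
#' `cvFolds`-fold cross-validation (pooled out-of-fold AUC for
#' classification, RMSE for regression). Two stacked ensembles are then
#' built - one over all candidates, one over the best of each family -
#' whose meta-learner is a non-negatively-weighted ridge model trained on
#' out-of-fold predictions, and scored by the same folds. All candidates
#' and ensembles are ranked on a leaderboard and the top model is refitted
#' on the full table.
#'
#' @param table modelling table from [buildTask()].
#' @param spec a [taskSpec()]; `trialBudget` must be at least the number
#'   of families (4).
#' @return a [SearchResult].
#' @export
modelSearch <- function(table, spec) {
    stopifnot(inherits(spec, "cslvTaskSpec"), ".y" %in% names(table))
    mode <- spec$mode
    y <- table$.y
    if (mode == "binary_classification") stopifnot(is.factor(y), nlevels(y) == 2L)
    X <- as.matrix(table[, setdiff(names(table), ".y"), drop = FALSE])
    grid <- .interleave(.familyGrid(mode, ncol(X)))
    nfam <- length(unique(vapply(grid, `[[`, "", "family")))
    if (spec$trialBudget < nfam)
        stop(sprintf("trialBudget (%d) is smaller than the number of model families (%d)",
                     spec$trialBudget, nfam))
    cands <- grid[seq_len(min(spec$trialBudget, length(grid)))]
    fold <- .makeFolds(y, spec$cvFolds, spec$seed, mode)
    nf <- max(fold)
    n <- nrow(X)

    famCount <- integer(0)
    ids <- vapply(cands, function(cd) {
        f <- toupper(cd$family)
        famCount[f] <<- if (f %in% names(famCount)) famCount[[f]] + 1L else 1L
        sprintf("%s_%d", f, famCount[[f]])
    }, "")

    Z <- matrix(NA_real_, n, length(cands),
                dimnames = list(rownames(table), ids))
    for (ci in seq_along(cands)) {
        cd <- cands[[ci]]
        for (f in seq_len(nf)) {
            tr <- fold != f
            m <- .fitModel(cd$family, cd$params, X[tr, , drop = FALSE], y[tr],
                           mode, substreamSeed(spec$seed, 20L, ci * 100L + f))
            Z[!tr, ci] <- .predictFit(m, X[!tr, , drop = FALSE])
        }
    }
    metrics <- apply(Z, 2, .metricValue, y = y, mode = mode)

    better <- function(a, b) if (mode == "binary_classification") a > b else a < b
    fams <- vapply(cands, `[[`, "", "family")
    bofIdx <- vapply(unique(fams), function(f) {
        i <- which(fams == f)
        i[order(metrics[i], decreasing = mode == "binary_classification")[1]]
    }, 1L)

    ensembleOOF <- function(cols) {
        oof <- numeric(n)
        for (f in seq_len(nf)) {
            tr <- fold != f
            mf <- .fitMeta(Z[tr, cols, drop = FALSE], y[tr], mode)
            oof[!tr] <- as.numeric(stats::predict(
                mf, Z[!tr, cols, drop = FALSE], s = 1e-3, type = "response"))
        }
        oof
    }
    ensCols <- list(StackedEnsemble_AllModels = seq_along(cands),
                    StackedEnsemble_BestOfFamily = unname(bofIdx))
    ensMetrics <- vapply(ensCols, function(cols)
        .metricValue(ensembleOOF(cols), y, mode), 1.0)

    tab <- data.frame(
        model_id = c(ids, names(ensCols)),
        family = c(fams, "ensemble", "ensemble"),
        metric = c(unname(metrics), unname(ensMetrics)),
        stringsAsFactors = FALSE)
    o <- order(tab$metric, decreasing = mode == "binary_classification")
    tab <- tab[o, , drop = FALSE]
    tab <- data.frame(rank = seq_len(nrow(tab)), tab, row.names = NULL)
    lb <- new("Leaderboard", table = tab,
              metric = if (mode == "binary_classification") "auc" else "rmse")

    bestId <- tab$model_id[1]
    refitSeed <- substreamSeed(spec$seed, 21L, 0L)
    best <- if (bestId %in% names(ensCols)) {
        cols <- ensCols[[bestId]]
        base <- lapply(cols, function(ci)
            .fitModel(cands[[ci]]$family, cands[[ci]]$params, X, y, mode,
                      substreamSeed(spec$seed, 22L, ci)))
        meta <- .fitMeta(Z[, cols, drop = FALSE], y, mode)
        structure(list(kind = "ensemble", family = "ensemble",
                       model_id = bestId, base = base, meta = meta,
                       metaLambda = 1e-3, mode = mode,
                       features = colnames(X),
                       levels = if (is.factor(y)) levels(y) else NULL),
                  class = "cslvModel")
    } else {
        ci <- match(bestId, ids)
        m <- .fitModel(cands[[ci]]$family, cands[[ci]]$params, X, y, mode,
                       refitSeed)
        m$model_id <- bestId
        m
    }
    new("SearchResult", leaderboard = lb, best = best, metric = lb@metric)
}

#' Classification AUC over repeated random train/test splits
#'
#' For each of `nRepeats` splits the table is partitioned by
#' [splitCounts()] into training and test sets, the recipe is refitted on
#' the training rows, and the held-out AUC is recorded. A split whose test
#' set contains a single class is redrawn (with a message), at most 10
#' times before erroring. Two invocations with the same spec produce
#' identical per-repeat AUCs.
#'
#' @param table classification modelling table from [buildTask()].
#' @param recipe a [modelRecipe()].
#' @param spec a [taskSpec()] with `nRepeats >= 2`.
#' @return a [RepeatedAuc].
#' @export
repeatedHoldout <- function(table, recipe, spec) {
    stopifnot(inherits(spec, "cslvTaskSpec"),
              spec$mode == "binary_classification", ".y" %in% names(table))
    if (spec$nRepeats < 2L) stop("nRepeats must be >= 2 to report a sd")
    y <- table$.y
    stopifnot(is.factor(y), nlevels(y) == 2L)
    X <- as.matrix(table[, setdiff(names(table), ".y"), drop = FALSE])
    n <- nrow(X)
    counts <- splitCounts(n, spec$trainFraction)
    aucs <- numeric(spec$nRepeats)
    for (r in seq_len(spec$nRepeats)) {
        tr <- NULL
        for (att in 0:10) {
            if (att == 10L) stop("10 redraws failed to produce a two-class test set")
            set.seed(substreamSeed(spec$seed, 30L, r * 16L + att))
            tr <- sample.int(n, counts[["n_train"]])
            if (nlevels(droplevels(y[-tr])) == 2L &&
                nlevels(droplevels(y[tr])) == 2L) break
            message("repeat ", r, ": degenerate split redrawn")
        }
        m <- .fitModel(recipe$family, recipe$params, X[tr, , drop = FALSE],
                       y[tr], spec$mode, substreamSeed(spec$seed, 31L, r))
        pred <- .predictFit(m, X[-tr, , drop = FALSE])
        aucs[r] <- aucValue(aucROC(pred, y[-tr] == levels(y)[2]))
    }
    new("RepeatedAuc", aucs = aucs)
}

#' Mean outcome in equal-size groups ranked by prediction
#'
#' Sorts samples by predicted value (ties broken by stable input order),
#' cuts them into `nGroups` contiguous groups whose sizes differ by at
#' most one (larger groups first, so e.g. 32,364 samples in 50 groups give
#' 14 groups of 648 and 36 of 647), and reports each group's mean
#' predicted and mean actual value. Plotting mean actual against group
#' index is the standard display for a ranked regression evaluation.
#'
#' @param predicted,actual numeric vectors of equal length `n >= nGroups`.
#' @param nGroups number of groups, `>= 1`.
#' @return a [GroupedCurve].
#' @export
groupedMeanCurve <- function(predicted, actual, nGroups = 50L) {
    stopifnot(length(predicted) == length(actual))
    nGroups <- as.integer(nGroups)
    if (is.na(nGroups) || nGroups < 1L) stop("nGroups must be >= 1")
    n <- length(predicted)
    if (n < nGroups) stop("need at least nGroups samples")
    o <- order(predicted, seq_len(n))        # stable in ties
    sizes <- rep(n %/% nGroups, nGroups)
    r <- n %% nGroups
    if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    grp <- rep(seq_len(nGroups), times = sizes)
    tab <- data.frame(
        group = seq_len(nGroups),
        size = sizes,
        mean_predicted = as.numeric(tapply(predicted[o], grp, mean)),
        mean_actual = as.numeric(tapply(actual[o], grp, mean)))
    new("GroupedCurve", table = tab)
}

#' Permutation feature importance
#'
#' Model-agnostic variable importance: the base metric is computed once on
#' the table, then each feature column in turn is permuted `nRepeats`
#' times and the mean metric degradation (AUC drop for classification,
#' RMSE increase for regression) is reported with its sd over repeats. A
#' feature the model ignores scores ~0; signal spread over many segments
#' shows as many small, similar importances.
#'
#' @param model a fitted model from [modelSearch()] / [bestModel()].
#' @param table modelling table from [buildTask()] (must contain `.y` and
#'   every model feature).
#' @param nRepeats permutations per feature.
#' @param seed integer seed for the permutations.
#' @return an [ImportanceReport].
#' @export
permutationImportance <- function(model, table, nRepeats = 5L, seed = 1L) {
    stopifnot(inherits(model, "cslvModel"), ".y" %in% names(table))
    y <- table$.y
    mode <- model$mode
    miss <- setdiff(model$features, names(table))
    if (length(miss))
        stop("feature(s) absent from table: ", paste(miss, collapse = ", "))
    X <- as.matrix(table[, model$features, drop = FALSE])
    base <- .metricValue(.predictFit(model, X), y, mode)
    nRepeats <- as.integer(nRepeats)
    sgn <- if (mode == "binary_classification") 1 else -1
    drops <- matrix(NA_real_, length(model$features), nRepeats,
                    dimnames = list(model$features, NULL))
    n <- nrow(X)
    for (j in seq_along(model$features)) {
        for (r in seq_len(nRepeats)) {
            set.seed(substreamSeed(seed, 40L, j * 1000L + r))
            Xp <- X
            Xp[, j] <- X[sample.int(n), j]
            m <- .metricValue(.predictFit(model, Xp), y, mode)
            drops[j, r] <- sgn * (base - m)
        }
    }
    tab <- data.frame(feature = model$features,
                      mean_drop = rowMeans(drops),
                      sd_drop = apply(drops, 1, stats::sd),
                      row.names = NULL)
    new("ImportanceReport", table = tab, baseMetric = base,
        metric = if (mode == "binary_classification") "auc" else "rmse",
        nRepeats = nRepeats)
}
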