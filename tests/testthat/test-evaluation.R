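test_that("stratified folds on the study composition are 17/153 splits", {
    qc <- simulateCohort(defaultCohortSpec(0.5, seed = 3))
    fp <- stratifiedKFold(qc, k = 10, seed = 1)
    sizes <- tabulate(foldAssignments(fp), 10)
    expect_identical(sizes, rep(17L, 10))         # validation parts
    expect_identical(170L - sizes, rep(153L, 10)) # training partitions
})

test_that("two equal classes of five deal one record per class per fold", {
    qc <- randomCohort(5, classes = c("CF", "AS"), seed = 2)
    fp <- stratifiedKFold(qc, k = 5, seed = 4)
    a <- foldAssignments(fp)
    d <- diagnosis(qc)
    for (f in 1:5) {
        expect_identical(sum(a == f), 2L)
        expect_identical(sum(a == f & d == "CF"), 1L)
    }
})

test_that("fold plans partition records with per-class imbalance <= 1", {
    for (seed in 1:5) {
        set.seed(seed)
        qc <- randomCohort(sample(3:12, 7, replace = TRUE), seed = seed)
        k <- sample(2:6, 1)
        # small random class counts may legitimately fall below k
        fp <- suppressWarnings(stratifiedKFold(qc, k = k, seed = seed))
        a <- foldAssignments(fp)
        expect_identical(sort(names(a)), sort(recordIds(qc)))
        expect_true(all(a >= 1 & a <= k))
        for (cl in diagnosisLevels()) {
            percl <- tabulate(a[diagnosis(qc) == cl], k)
            expect_lte(max(percl) - min(percl), 1L)
        }
        sizes <- tabulate(a, k)
        expect_lte(max(sizes) - min(sizes), 1L)
        expect_true(all(diff(sizes) <= 0))  # larger folds first
    }
})

test_that("k above the smallest class count warns but still plans", {
    qc <- randomCohort(c(5, 2), classes = c("CF", "AS"), seed = 1)
    expect_warning(fp <- stratifiedKFold(qc, k = 4, seed = 1),
                   "smallest class")
    expect_identical(length(foldAssignments(fp)), 7L)
})

test_that("ROC handles perfect separation, ties and the worked example", {
    expect_equal(rocOneVsRest(c(0.9, 0.8, 0.2, 0.1),
                              c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
    expect_equal(rocOneVsRest(rep(0.5, 6),
                              c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc,
                 0.5)
    r <- rocOneVsRest(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_error(rocOneVsRest(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("trapezoidal AUC equals the concordant-pair fraction", {
    for (seed in 1:25) {
        set.seed(seed)
        n <- sample(3:12, 1)
        truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
        scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
        expect_equal(rocOneVsRest(scores, truth)$auc,
                     bruteAUC(scores, truth), tolerance = 1e-12)
    }
})

test_that("cross-validation on a separable cohort is perfect and conserves counts", {
    qc <- simulateCohort(defaultCohortSpec(1, seed = 19))
    rep <- crossValidate(qc, kinds = c("NAIVE_BAYES", "FUZZY", "LDA"),
                         k = 10, seed = 2)
    expect_equal(overallAccuracy(rep), 1)
    expect_equal(unname(sensitivities(rep)), rep(1, 7))
    cm <- confusionMatrix(rep)
    expect_equal(unname(rowSums(cm)), as.vector(classCounts(qc)))
    expect_identical(sum(cm), 170L)
    aucs <- vapply(rocCurves(rep), `[[`, numeric(1), "auc")
    expect_true(all(aucs == 1))
})

test_that("cross-validation is deterministic in (cohort, k, seed, config)", {
    qc <- randomCohort(4, seed = 23)
    r1 <- crossValidate(qc, kinds = c("NAIVE_BAYES", "NEAREST_NEIGHBOUR"),
                        k = 3, seed = 5)
    r2 <- crossValidate(qc, kinds = c("NAIVE_BAYES", "NEAREST_NEIGHBOUR"),
                        k = 3, seed = 5)
    expect_identical(r1@scores, r2@scores)
    expect_identical(r1@proposed, r2@proposed)
    expect_identical(confusionMatrix(r1), confusionMatrix(r2))
})

test_that("no-calls land in the no_call column and count as errors", {
    qc <- randomCohort(4, seed = 29)
    # an impossibly high limit forces every record to a no-call
    rep <- crossValidate(qc, kinds = "NAIVE_BAYES", k = 2, seed = 1,
                         limit = 0.999)
    cm <- confusionMatrix(rep)
    expect_identical(unname(cm[, "no_call"]), as.vector(classCounts(qc)))
    expect_equal(overallAccuracy(rep), 0)
    expect_equal(unname(sensitivities(rep)), rep(0, 7))
})

test_that("sensitivity table has the members+fusion by classes+overall shape", {
    qc <- simulateCohort(defaultCohortSpec(1, seed = 37))
    rep <- crossValidate(qc, k = 5, seed = 3)
    st <- sensitivityTable(rep)
    expect_identical(dim(st), c(9L, 8L))
    expect_identical(rownames(st), c(classifierKinds(), "FUSION"))
    expect_identical(colnames(st), c(diagnosisLevels(), "OVERALL"))
    expect_true(all(st == 1))  # perfectly separable limit
})

test_that("pooled fused ROC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    qc <- simulateCohort(defaultCohortSpec(0.6, seed = 41))
    rep <- crossValidate(qc, kinds = c("NAIVE_BAYES", "LDA"), k = 5,
                         seed = 7)
    for (cl in c("CF", "PCD", "CTRL")) {
        ours <- rocCurves(rep)[[cl]]$auc
        ref <- suppressMessages(pROC::auc(
            pROC::roc(response = rep@truth == cl,
                      predictor = rep@scores[, cl],
                      direction = "<", quiet = TRUE)))
        expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
    }
})
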