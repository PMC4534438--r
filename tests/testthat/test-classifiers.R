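test_that("every kind emits valid probability vectors on arbitrary queries", {
    qc <- randomCohort(3, seed = 11)
    set.seed(99)
    queries <- replicate(4, sample(1:6, 45, replace = TRUE))
    for (kd in classifierKinds()) {
        m <- trainClassifier(kd, qc, seed = 5)
        for (j in seq_len(ncol(queries))) {
            p <- predictProba(m, queries[, j])
            expect_length(p, 7L)
            expect_identical(names(p), diagnosisLevels())
            expect_true(all(p >= 0 & p <= 1))
            expect_lt(abs(sum(p) - 1), 1e-9)
        }
    }
})

test_that("classes absent at training receive probability exactly 0", {
    qc <- randomCohort(4, classes = c("CF", "PBB"), seed = 3)
    for (kd in classifierKinds()) {
        m <- trainClassifier(kd, qc, seed = 5)
        p <- predictProba(m, rep(3L, 45))
        expect_identical(unname(p[c("AS", "PCD", "PM", "AB", "CTRL")]),
                         rep(0, 5))
    }
})

test_that("a single-class cohort yields the degenerate constant model", {
    qc <- randomCohort(3, classes = "PM", seed = 4)
    for (kd in classifierKinds()) {
        m <- trainClassifier(kd, qc, seed = 1)
        p <- predictProba(m, sample(1:6, 45, replace = TRUE))
        expect_identical(unname(p["PM"]), 1)
    }
})

test_that("training is deterministic given identical inputs and seed", {
    qc <- simulateCohort(defaultCohortSpec(0.7, seed = 21))
    probe <- answers(randomCohort(1, seed = 77))
    for (kd in classifierKinds()) {
        p1 <- predictProba(trainClassifier(kd, qc, seed = 9), t(probe))
        p2 <- predictProba(trainClassifier(kd, qc, seed = 9), t(probe))
        expect_identical(p1, p2)
    }
})

test_that("deterministic kinds are invariant to training record order", {
    qc <- randomCohort(4, seed = 15)
    set.seed(16)
    perm <- sample(ncol(qc))
    qcPerm <- QuestionnaireCohort(answers(qc)[, perm],
                                  diagnosis = as.character(diagnosis(qc))[perm],
                                  recordIds = recordIds(qc)[perm])
    probe <- sample(1:6, 45, replace = TRUE)
    for (kd in c("FUZZY", "NAIVE_BAYES", "LDA", "NEAREST_NEIGHBOUR")) {
        p1 <- predictProba(trainClassifier(kd, qc, seed = 1), probe)
        p2 <- predictProba(trainClassifier(kd, qcPerm, seed = 1), probe)
        expect_equal(p1, p2, tolerance = 1e-12)
    }
})

test_that("missing answers are imputed from the stored training median", {
    qc <- simulateCohort(defaultCohortSpec(0.9, seed = 31))
    m <- trainClassifier("NAIVE_BAYES", qc)
    v <- answers(qc)[, 1]
    vMiss <- v; vMiss[c(3, 20)] <- NA
    vByHand <- imputeMissing(vMiss, m@imputeRef)
    expect_identical(predictProba(m, vMiss), predictProba(m, vByHand))
})

test_that("1-nearest-neighbour returns probability 1 for a training copy", {
    qc <- randomCohort(3, seed = 8)
    m <- trainClassifier("NEAREST_NEIGHBOUR", qc, hyper = list(k = 1))
    for (i in c(1, 10, 21)) {
        p <- predictProba(m, answers(qc)[, i])
        expect_equal(unname(p[as.character(diagnosis(qc)[i])]), 1)
    }
})

test_that("naive Bayes matches the hand-computed smoothed-frequency product", {
    # 4-record, 2-class toy with one informative question
    a <- matrix(3L, nrow = 45, ncol = 4)
    a[1, ] <- c(1L, 1L, 6L, 6L)
    qc <- cohortFromMatrix(a, c("CF", "CF", "AS", "AS"))
    m <- trainClassifier("NAIVE_BAYES", qc)
    query <- rep(3L, 45); query[1] <- 1L
    p <- predictProba(m, query)
    oracle <- bruteNB(t(a), factor(c("CF", "CF", "AS", "AS"),
                                   levels = c("CF", "AS")), query)
    expect_equal(unname(p[c("CF", "AS")]), unname(oracle[c("CF", "AS")]),
                 tolerance = 1e-9)
    expect_gt(p["CF"], 0.5)
})

test_that("naive Bayes equals the brute-force oracle on small cohorts", {
    for (seed in 1:6) {
        set.seed(seed)
        n <- sample(4:10, 1)
        classes <- sample(diagnosisLevels(), sample(2:3, 1))
        labels <- sample(classes, n, replace = TRUE)
        while (length(unique(labels)) < 2)
            labels <- sample(classes, n, replace = TRUE)
        a <- matrix(sample(1:6, 45 * n, replace = TRUE), nrow = 45)
        qc <- cohortFromMatrix(a, labels)
        m <- trainClassifier("NAIVE_BAYES", qc)
        query <- sample(1:6, 45, replace = TRUE)
        p <- predictProba(m, query)
        lv <- intersect(diagnosisLevels(), unique(labels))
        oracle <- bruteNB(t(a), factor(labels, levels = lv), query)
        expect_equal(unname(p[lv]), unname(oracle[lv]), tolerance = 1e-9)
    }
})

test_that("random forest separates a high-separation training set", {
    qc <- simulateCohort(defaultCohortSpec(0.95, seed = 7))
    m <- trainClassifier("RANDOM_FOREST", qc, seed = 2)
    pred <- apply(predictProba(m, t(answers(qc))), 1, function(p)
        diagnosisLevels()[which.max(p)])
    expect_gte(mean(pred == as.character(diagnosis(qc))), 0.9)
})

test_that("fuzzy membership rescales the modal answer to 1", {
    a <- matrix(2L, nrow = 45, ncol = 6)
    a[1, ] <- 4L  # every record of the single class answers 4 on q1
    qc <- cohortFromMatrix(a, rep("CF", 6))
    fz <- fuzzyTrain(qc)
    expect_equal(unname(fz$membership["CF", "q01", "4"]), 1)
    expect_lt(fz$membership["CF", "q01", "2"], 1)
})

test_that("fuzzy classifier favours the class whose modes the query matches", {
    # disjoint modal answers on every question
    a <- cbind(matrix(1L, 45, 5), matrix(6L, 45, 5))
    qc <- cohortFromMatrix(a, rep(c("CF", "AS"), each = 5))
    fz <- fuzzyTrain(qc)
    p <- fuzzyPredict(fz, rep(1L, 45))
    expect_gt(p["CF"], 0.5)
    p2 <- fuzzyPredict(fz, rep(6L, 45))
    expect_gt(p2["AS"], 0.5)
})

test_that("fuzzy output is symmetric for identically-answering classes", {
    a <- matrix(rep(rep(1:6, length.out = 45), 6), nrow = 45)
    qc <- cohortFromMatrix(a, rep(c("CF", "AS"), 3))
    fz <- fuzzyTrain(qc)
    p <- fuzzyPredict(fz, sample(1:6, 45, replace = TRUE))
    expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("ensemble persistence round-trips and is version-guarded", {
    qc <- randomCohort(2, classes = c("CF", "AS"), seed = 6)
    ens <- trainEnsemble(qc, kinds = c("NAIVE_BAYES", "FUZZY"), seed = 3)
    f <- withr::local_tempfile(fileext = ".rds")
    saveEnsemble(ens, f)
    back <- loadEnsemble(f)
    probe <- rep(4L, 45)
    expect_identical(predictCase(back, probe)@relative,
                     predictCase(ens, probe)@relative)
    # tampered version must fail loudly
    obj <- readRDS(f); obj$version <- "0.0.1"; saveRDS(obj, f)
    expect_error(loadEnsemble(f), "version")
    saveRDS(list(format = "other"), f)
    expect_error(loadEnsemble(f), "archive")
})

test_that("unknown kinds and empty cohorts are rejected", {
    qc <- randomCohort(1, classes = "CF", seed = 1)
    expect_error(trainClassifier("BOOSTING", qc), "unknown classifier kind")
    empty <- QuestionnaireCohort(matrix(integer(), 45, 0),
                                 diagnosis = character(),
                                 recordIds = character())
    expect_error(trainClassifier("SVM", empty), "empty cohort")
})
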