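# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the package internals.

# n x 45 uniform-random answer cohort over the given classes
randomCohort <- function(nPerClass, classes = diagnosisLevels(), seed = 1,
                         missingRate = 0) {
    set.seed(seed)
    n <- sum(rep(nPerClass, length.out = length(classes)))
    nv <- rep(nPerClass, length.out = length(classes))
    labels <- rep(classes, nv)
    a <- matrix(sample(1:6, 45 * n, replace = TRUE), nrow = 45)
    if (missingRate > 0)
        a[matrix(runif(length(a)) < missingRate, nrow = 45)] <- NA
    QuestionnaireCohort(a, diagnosis = labels,
                        recordIds = sprintf("r%03d", seq_len(n)))
}

# cohort built from an explicit answers matrix (questions x records)
cohortFromMatrix <- function(a, labels) {
    QuestionnaireCohort(a, diagnosis = labels,
                        recordIds = sprintf("r%03d", seq_len(ncol(a))))
}

# brute-force AUC: fraction of (positive, negative) pairs ranked
# concordantly, ties counted 1/2
bruteAUC <- function(scores, truth) {
    pos <- scores[as.logical(truth)]
    neg <- scores[!as.logical(truth)]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# brute-force categorical naive Bayes posterior with Laplace smoothing:
# prior x product over questions of (count(level, class) + a)/(n_c + 6a)
bruteNB <- function(X, y, query, alpha = 1) {
    lv <- levels(y)
    post <- sapply(lv, function(cl) {
        Xi <- X[y == cl, , drop = FALSE]
        p <- sum(y == cl) / length(y)
        for (j in seq_len(ncol(X))) {
            cnt <- sum(Xi[, j] == query[j])
            p <- p * (cnt + alpha) / (nrow(Xi) + 6 * alpha)
        }
        p
    })
    post / sum(post)
}

# brute-force information gain from the full contingency table
bruteInfoGain <- function(classes, values) {
    keep <- !is.na(classes) & !is.na(values)
    classes <- classes[keep]; values <- values[keep]
    tab <- table(values, classes)
    n <- sum(tab)
    ent <- function(counts) {
        p <- counts[counts > 0] / sum(counts)
        -sum(p * log2(p))
    }
    hClass <- ent(colSums(tab))
    hCond <- sum(apply(tab, 1, function(row) sum(row) / n * ent(row)))
    hClass - hCond
}

# smallest labelled cohort the classifier bank accepts: every class once,
# deterministic answers
tinyFullCohort <- function(seed = 1) {
    randomCohort(2, seed = seed)
}
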