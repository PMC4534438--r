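## The eight-member classifier bank.
##
## Every member consumes the 45 ordinal answers as numeric values 1..6
## (the ordinal scale interpreted numerically) and emits a posterior over
## the seven diagnosis classes. Classes absent from the training partition
## receive probability exactly 0 so the fusion stage never credits a
## diagnosis no classifier could have learned.

#' Default hyperparameters of the classifier bank
#'
#' One config block holding every member's defaults; any entry can be
#' overridden through the `hyper` argument of [trainClassifier()].
#'
#' @return Named list (one element per [classifierKinds()] code).
#' @export
defaultHyperparameters <- function() {
    list(
        SVM = list(kernel = "radial", cost = 1),
        ANN = list(size = 16L, decay = 0.1, maxit = 300L),
        FUZZY = list(alpha = 1),
        RANDOM_FOREST = list(ntree = 500L),
        LOGISTIC = list(decay = 0.01, maxit = 300L),
        LDA = list(shrinkage = 0.25),
        NAIVE_BAYES = list(laplace = 1),
        NEAREST_NEIGHBOUR = list(k = 5L)
    )
}

.imputedFeatureMatrix <- function(cohort, ref) {
    a <- answers(cohort)
    X <- t(apply(a, 2L, imputeMissing, reference = ref))
    if (ncol(a) == 1L) X <- matrix(X, nrow = 1L)
    dimnames(X) <- list(colnames(a), rownames(a))
    storage.mode(X) <- "double"
    X
}

#' Train one classifier of the bank
#'
#' Deterministic given `(kind, cohort, hyper, seed)`. The per-question
#' rounded training median is stored in the model as the imputation
#' reference applied to any missing answers at prediction time.
#'
#' @param kind one of [classifierKinds()].
#' @param cohort a fully labelled [QuestionnaireCohort-class] with at least
#'   one record.
#' @param hyper named list overriding entries of
#'   `defaultHyperparameters()[[kind]]`.
#' @param seed integer seed for the stochastic kinds; deterministic kinds
#'   ignore it but store it.
#' @return A [TrainedClassifier-class].
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.9, seed = 1))
#' m <- trainClassifier("NAIVE_BAYES", qc)
#' p <- predictProba(m, answers(qc)[, 1])
#' sum(p)  # 1
#' @export
trainClassifier <- function(kind, cohort, hyper = list(), seed = 1L) {
    if (!(kind %in% classifierKinds()))
        stop("unknown classifier kind '", kind, "'", call. = FALSE)
    if (ncol(cohort) == 0L)
        stop("cannot train on an empty cohort", call. = FALSE)
    d <- diagnosis(cohort)
    if (anyNA(d))
        stop("training cohort must be fully labelled", call. = FALSE)
    hp <- utils::modifyList(defaultHyperparameters()[[kind]], hyper)
    ref <- imputationReference(cohort)
    X <- .imputedFeatureMatrix(cohort, ref)
    y <- droplevels(d)
    classLevels <- intersect(diagnosisLevels(), levels(y))
    y <- factor(as.character(y), levels = classLevels)
    fit <- if (length(classLevels) == 1L) {
        list(trivial = TRUE)
    } else {
        .withSeed(seed, switch(kind,
            SVM = .fitSVM(X, y, hp),
            ANN = .fitANN(X, y, hp),
            FUZZY = .fitFUZZY(X, y, hp),
            RANDOM_FOREST = .fitRF(X, y, hp),
            LOGISTIC = .fitLOGISTIC(X, y, hp),
            LDA = .fitLDA(X, y, hp),
            NAIVE_BAYES = .fitNB(X, y, hp),
            NEAREST_NEIGHBOUR = .fitNN(X, y, hp)))
    }
    new("TrainedClassifier", kind = kind, fit = fit,
        classLevels = classLevels, imputeRef = ref, hyper = hp,
        seed = as.integer(seed))
}

#' Posterior class probabilities for answered questionnaires
#'
#' Returns, for each query record, a probability vector over the seven
#' canonical diagnosis classes summing to 1; classes absent at training
#' have probability exactly 0. Missing answers are imputed internally from
#' the model's stored reference.
#'
#' @param object a [TrainedClassifier-class].
#' @param newAnswers answer vector of length 45, or a matrix of queries
#'   (records in rows or the 45 x n question-major layout).
#' @param ... unused.
#' @return Named numeric vector of length 7 (single query) or an n x 7
#'   matrix.
#' @rdname predictProba
#' @export
setMethod("predictProba", "TrainedClassifier",
    function(object, newAnswers, ...) {
    single <- is.null(dim(newAnswers))
    if (single)
        newAnswers <- matrix(newAnswers, nrow = 1L)
    if (ncol(newAnswers) != nQuestions()) {
        if (nrow(newAnswers) == nQuestions()) newAnswers <- t(newAnswers)
        else stop("query must have ", nQuestions(), " answers, found ",
                  ncol(newAnswers), call. = FALSE)
    }
    for (i in seq_len(nrow(newAnswers))) {
        v <- validateRecord(newAnswers[i, ])
        if (!v$ok)
            stop("invalid query record ", i, ": ",
                 paste(v$violations, collapse = "; "), call. = FALSE)
    }
    X <- t(apply(newAnswers, 1L, imputeMissing, reference = object@imputeRef))
    if (nrow(newAnswers) == 1L) X <- matrix(X, nrow = 1L)
    storage.mode(X) <- "double"
    colnames(X) <- .qnames()
    psub <- .predictCore(object, X)
    out <- matrix(0, nrow = nrow(X), ncol = length(diagnosisLevels()),
                  dimnames = list(rownames(newAnswers), diagnosisLevels()))
    out[, object@classLevels] <- psub
    out <- pmax(out, 0)
    out <- out / rowSums(out)
    if (single) out[1L, ] else out
})

.predictCore <- function(object, X) {
    cl <- object@classLevels
    if (length(cl) == 1L)
        return(matrix(1, nrow = nrow(X), ncol = 1L,
                      dimnames = list(NULL, cl)))
    p <- switch(object@kind,
        SVM = .predSVM(object@fit, X),
        ANN = .predANN(object@fit, X),
        FUZZY = .fuzzyPredictMatrix(object@fit, X),
        RANDOM_FOREST = .predRF(object@fit, X),
        LOGISTIC = .predLOGISTIC(object@fit, X),
        LDA = .predLDA(object@fit, X),
        NAIVE_BAYES = .predNB(object@fit, X),
        NEAREST_NEIGHBOUR = .predNN(object@fit, X))
    p[, cl, drop = FALSE]
}

setMethod("show", "TrainedClassifier", function(object) {
    cat("TrainedClassifier<", object@kind, ">: classes ",
        paste(object@classLevels, collapse = ","), "\n", sep = "")
})

## ---- support vector machine (RBF kernel, Platt-style probabilities) ----

.fitSVM <- function(X, y, hp) {
    e1071::svm(x = X, y = y, kernel = hp$kernel, cost = hp$cost,
               probability = TRUE, scale = FALSE)
}

.predSVM <- function(fit, X) {
    pr <- stats::predict(fit, X, probability = TRUE)
    attr(pr, "probabilities")
}

## ---- single-hidden-layer neural network, softmax output ----

.fitANN <- function(X, y, hp) {
    Xs <- (X - 1) / 5
    net <- nnet::nnet(x = Xs, y = nnet::class.ind(y), size = hp$size,
                      softmax = TRUE, decay = hp$decay, maxit = hp$maxit,
                      trace = FALSE, MaxNWts = 100000L)
    list(net = net, levels = levels(y))
}

.predANN <- function(fit, X) {
    p <- stats::predict(fit$net, (X - 1) / 5, type = "raw")
    colnames(p) <- fit$levels
    p
}

## ---- random forest ----

.fitRF <- function(X, y, hp) {
    randomForest::randomForest(x = X, y = y, ntree = hp$ntree)
}

.predRF <- function(fit, X) {
    stats::predict(fit, X, type = "prob")
}

## ---- multinomial logistic regression with L2 weight decay ----

.fitLOGISTIC <- function(X, y, hp) {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- y
    fit <- nnet::multinom(.y ~ ., data = df, decay = hp$decay,
                          maxit = hp$maxit, trace = FALSE,
                          MaxNWts = 100000L)
    list(fit = fit, levels = levels(y))
}

.predLOGISTIC <- function(fit, X) {
    p <- stats::predict(fit$fit, data.frame(X, check.names = FALSE),
                        type = "probs")
    if (is.null(dim(p))) {
        # binary: a length-n vector of P(second level); multi-class with a
        # single query: a length-k vector
        p <- if (length(fit$levels) == 2L && length(p) == nrow(X))
            cbind(1 - p, p)
        else matrix(p, nrow = nrow(X), byrow = TRUE)
    }
    colnames(p) <- fit$levels
    p
}

## ---- shrinkage-regularised linear discriminant analysis ----
## Pooled within-class covariance shrunk towards a scaled identity:
## S* = (1 - g) S + g (tr(S)/p) I. With 45 features and ~20 records per
## class the unshrunk pooled estimator is singular, so g > 0 is required.

.fitLDA <- function(X, y, hp) {
    p <- ncol(X); lv <- levels(y)
    mu <- t(vapply(lv, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                   numeric(p)))
    Sw <- matrix(0, p, p)
    for (cl in lv) {
        Xi <- X[y == cl, , drop = FALSE]
        Xc <- sweep(Xi, 2L, mu[cl, ])
        Sw <- Sw + crossprod(Xc)
    }
    dfree <- max(nrow(X) - length(lv), 1L)
    S <- Sw / dfree
    g <- hp$shrinkage
    tr <- sum(diag(S))
    if (tr <= 0) tr <- p * 1e-6  # degenerate: identical records per class
    Sreg <- (1 - g) * S + g * (tr / p) * diag(p)
    R <- chol(Sreg)
    list(mu = mu, cholS = R, logPrior = log(table(y) / length(y)),
         levels = lv)
}

.predLDA <- function(fit, X) {
    lv <- fit$levels
    ll <- vapply(lv, function(cl) {
        Z <- backsolve(fit$cholS, t(sweep(X, 2L, fit$mu[cl, ])),
                       transpose = TRUE)
        fit$logPrior[[cl]] - 0.5 * colSums(Z^2)
    }, numeric(nrow(X)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L,
                                       dimnames = list(NULL, lv))
    .softmaxRows(ll)
}

.softmaxRows <- function(ll) {
    m <- apply(ll, 1L, max)
    e <- exp(ll - m)
    e / rowSums(e)
}

## ---- categorical naive Bayes with Laplace smoothing ----
## Answers are handled as 6-level factors so conditional tables cover the
## full scale even for levels unseen in training.

.asAnswerFactors <- function(X) {
    df <- as.data.frame(lapply(seq_len(ncol(X)), function(j)
        factor(X[, j], levels = answerLevels())))
    colnames(df) <- .qnames()
    df
}

.fitNB <- function(X, y, hp) {
    e1071::naiveBayes(x = .asAnswerFactors(X), y = y, laplace = hp$laplace)
}

.predNB <- function(fit, X) {
    stats::predict(fit, .asAnswerFactors(X), type = "raw")
}

## ---- distance-weighted k nearest neighbours ----
## All training points tied with the k-th smallest distance are included,
## making the prediction invariant under permutation of the training set.
## Exact matches (distance 0) take the whole vote.

.fitNN <- function(X, y, hp) {
    list(X = X, y = y, k = hp$k, levels = levels(y))
}

.predNN <- function(fit, X) {
    lv <- fit$levels
    out <- matrix(0, nrow = nrow(X), ncol = length(lv),
                  dimnames = list(NULL, lv))
    for (i in seq_len(nrow(X))) {
        d <- sqrt(colSums((t(fit$X) - X[i, ])^2))
        if (any(d == 0)) {
            sel <- d == 0
            w <- rep(1, sum(sel))
        } else {
            kth <- sort(d)[min(fit$k, length(d))]
            sel <- d <= kth
            w <- 1 / d[sel]
        }
        votes <- tapply(w, fit$y[sel], sum, default = 0)
        out[i, names(votes)] <- votes / sum(w)
    }
    out
}

## ---- fuzzy rule-based classifier ----

#' Fuzzy rule-based classifier internals
#'
#' The ensemble's fuzzy member uses one rule per diagnosis class. For class
#' c and question q the membership function over answer levels 1..6 is the
#' Laplace-smoothed (default alpha = 1) class-conditional answer frequency,
#' rescaled so its maximum equals 1. A query's rule strength for class c is
#' the geometric mean of the 45 memberships of its answers, and the output
#' probabilities are the rule strengths normalised to sum 1.
#'
#' `fuzzyTrain` returns the membership model; `fuzzyPredict` evaluates it
#' on one complete answer vector, returning the probability vector over the
#' classes present at training. [trainClassifier()] with kind `"FUZZY"`
#' wraps the same internals behind the common interface.
#'
#' @param cohort a fully labelled [QuestionnaireCohort-class].
#' @param alpha Laplace smoothing pseudo-count (> 0 keeps every membership
#'   positive).
#' @return `fuzzyTrain`: a list with `membership` (class x question x level
#'   array) and `levels`; `fuzzyPredict`: named probability vector.
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.9, seed = 2))
#' fz <- fuzzyTrain(qc)
#' fuzzyPredict(fz, imputeMissing(answers(qc)[, 1], rep(3L, 45)))
#' @export
fuzzyTrain <- function(cohort, alpha = 1) {
    d <- diagnosis(cohort)
    if (anyNA(d)) stop("training cohort must be fully labelled",
                       call. = FALSE)
    ref <- imputationReference(cohort)
    X <- .imputedFeatureMatrix(cohort, ref)
    y <- droplevels(d)
    lv <- intersect(diagnosisLevels(), levels(y))
    .fitFUZZY(X, factor(as.character(y), levels = lv), list(alpha = alpha))
}

.fitFUZZY <- function(X, y, hp) {
    lv <- levels(y)
    memb <- array(NA_real_,
                  dim = c(length(lv), ncol(X), 6L),
                  dimnames = list(lv, colnames(X),
                                  as.character(answerLevels())))
    for (cl in lv) {
        Xi <- X[y == cl, , drop = FALSE]
        for (q in seq_len(ncol(X))) {
            cnt <- tabulate(Xi[, q], nbins = 6L)
            f <- (cnt + hp$alpha) / (nrow(Xi) + 6 * hp$alpha)
            memb[cl, q, ] <- f / max(f)
        }
    }
    list(membership = memb, levels = lv)
}

#' @rdname fuzzyTrain
#' @param model a fuzzy model from `fuzzyTrain`.
#' @param values complete answer vector of length 45 (integers 1..6).
#' @export
fuzzyPredict <- function(model, values) {
    X <- matrix(as.numeric(values), nrow = 1L,
                dimnames = list(NULL, .qnames()))
    .fuzzyPredictMatrix(model, X)[1L, ]
}

.fuzzyPredictMatrix <- function(model, X) {
    lv <- model$levels
    ls <- vapply(lv, function(cl) {
        vapply(seq_len(nrow(X)), function(i) {
            mean(log(model$membership[cbind(cl, .qnames(),
                                            as.character(X[i, ]))]))
        }, numeric(1))
    }, numeric(nrow(X)))
    if (is.null(dim(ls))) ls <- matrix(ls, nrow = 1L,
                                       dimnames = list(NULL, lv))
    .softmaxRows(ls)  # normalised geometric-mean rule strengths
}

#' Train the full classifier ensemble
#'
#' Fits every requested kind on the same cohort; member seeds are derived
#' from `seed` deterministically.
#'
#' @param cohort a fully labelled [QuestionnaireCohort-class].
#' @param kinds classifier kinds to include (default: all eight).
#' @param hyper named list of per-kind hyperparameter overrides, e.g.
#'   `list(RANDOM_FOREST = list(ntree = 100))`.
#' @param seed integer base seed.
#' @return A [ClassifierEnsemble-class].
#' @export
trainEnsemble <- function(cohort, kinds = classifierKinds(), hyper = list(),
                          seed = 1L) {
    bad <- setdiff(kinds, classifierKinds())
    if (length(bad))
        stop("unknown classifier kind(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    members <- lapply(seq_along(kinds), function(i)
        trainClassifier(kinds[i], cohort,
                        hyper = if (kinds[i] %in% names(hyper))
                            hyper[[kinds[i]]] else list(),
                        seed = as.integer(seed) + 101L * i))
    names(members) <- kinds
    new("ClassifierEnsemble", members = members)
}

#' @describeIn trainEnsemble member accessor.
#' @param ensemble a `ClassifierEnsemble`.
#' @export
ensembleMembers <- function(ensemble) ensemble@members

setMethod("show", "ClassifierEnsemble", function(object) {
    cat("ClassifierEnsemble with", length(object@members), "member(s):",
        paste(names(object@members), collapse = ", "), "\n")
})

#' Save / load a trained ensemble
#'
#' One-file versioned archive (RDS). Loading an archive written by a
#' different package version fails loudly rather than risking silent
#' incompatibilities of the fitted state.
#'
#' @param ensemble a [ClassifierEnsemble-class].
#' @param file path.
#' @return `saveEnsemble`: `file`, invisibly; `loadEnsemble`: the ensemble.
#' @export
saveEnsemble <- function(ensemble, file) {
    saveRDS(list(format = "PulmoScreen-ensemble",
                 version = as.character(utils::packageVersion("PulmoScreen")),
                 ensemble = ensemble),
            file)
    invisible(file)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(file) {
    obj <- readRDS(file)
    if (!is.list(obj) || !identical(obj$format, "PulmoScreen-ensemble"))
        stop("not a PulmoScreen ensemble archive", call. = FALSE)
    cur <- as.character(utils::packageVersion("PulmoScreen"))
    if (!identical(obj$version, cur))
        stop("ensemble archive written by package version ", obj$version,
             ", current version is ", cur, call. = FALSE)
    obj$ensemble
}
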