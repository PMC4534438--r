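## Stratified k-fold cross-validation of the fused ensemble, per-class
## sensitivity, overall accuracy and pooled one-vs-rest ROC/AUC.

#' Stratified k-fold plan
#'
#' Within each class (canonical order), records are shuffled by `seed` and
#' dealt round-robin to folds; the deal continues across classes (the fold
#' offset carries over), so overall fold sizes differ by at most one with
#' the larger folds first, and per-class fold counts differ by at most one.
#' On a 170-record cohort with the study composition and k = 10 every fold
#' has exactly 17 records (training partitions of 153).
#'
#' @param cohort labelled [QuestionnaireCohort-class].
#' @param k number of folds (>= 2).
#' @param seed shuffling seed.
#' @return A [FoldPlan-class].
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.5, seed = 3))
#' fp <- stratifiedKFold(qc, k = 10, seed = 1)
#' table(foldAssignments(fp))  # ten folds of 17
#' @export
stratifiedKFold <- function(cohort, k, seed = 1L) {
    k <- as.integer(k)
    if (k < 2L) stop("k must be >= 2", call. = FALSE)
    d <- diagnosis(cohort)
    if (anyNA(d)) stop("cohort must be fully labelled", call. = FALSE)
    counts <- table(d)
    if (any(counts[counts > 0] < k))
        warning("k exceeds the smallest class count; some folds lack ",
                "that class in validation", call. = FALSE)
    ids <- recordIds(cohort)
    assign <- integer(length(ids)); names(assign) <- ids
    offset <- 0L
    .withSeed(seed, {
        for (cl in diagnosisLevels()) {
            idx <- which(d == cl)
            if (!length(idx)) next
            idx <- idx[sample.int(length(idx))]
            assign[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
            offset <- (offset + length(idx)) %% k
        }
    })
    new("FoldPlan", assignments = assign, k = as.integer(k),
        seed = as.integer(seed))
}

#' @describeIn foldAssignments fold index (1..k) per record id.
#' @param x a `FoldPlan`.
#' @export
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

setMethod("show", "FoldPlan", function(object) {
    cat("FoldPlan: k =", object@k, "| fold sizes:",
        paste(tabulate(object@assignments, object@k), collapse = ","), "\n")
})

#' One-vs-rest ROC curve and AUC
#'
#' Computes the ROC points (false positive rate, true positive rate) at
#' every distinct score threshold with endpoints (0,0) and (1,1), and the
#' area under the curve by the trapezoidal rule. With tied scores this
#' equals the concordant-pair statistic with ties counted 1/2.
#'
#' @param scores numeric score per record (higher = more positive).
#' @param truth logical (or 0/1) indicator of the positive class.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @examples
#' rocOneVsRest(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
rocOneVsRest <- function(scores, truth) {
    truth <- as.logical(truth)
    if (anyNA(scores) || anyNA(truth))
        stop("scores and truth must be complete", call. = FALSE)
    nPos <- sum(truth); nNeg <- sum(!truth)
    if (nPos == 0L || nNeg == 0L)
        stop("ROC needs at least one positive and one negative record",
             call. = FALSE)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; t <- truth[ord]
    # cumulative counts at each distinct threshold
    last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie
    tp <- cumsum(t)[last]; fp <- cumsum(!t)[last]
    pts <- data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos))
    auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
    list(points = pts, auc = auc)
}

#' Cross-validate the fused ensemble
#'
#' For each fold of a [stratifiedKFold()] plan, trains every requested
#' classifier kind on the out-of-fold records (imputation reference
#' included, so validation records never leak into it), fuses the members'
#' posteriors per validation record, and accumulates the confusion matrix,
#' fused relative scores and each member's own argmax predictions. A
#' below-limit no-call counts as a misclassification.
#'
#' @param cohort labelled [QuestionnaireCohort-class].
#' @param kinds classifier kinds (default all eight).
#' @param k folds (default 10).
#' @param limit fusion confidence limit.
#' @param seed seed driving the fold plan and member training.
#' @param hyper per-kind hyperparameter overrides (see [trainEnsemble()]).
#' @return An [EvaluationReport-class].
#' @export
crossValidate <- function(cohort, kinds = classifierKinds(), k = 10L,
                          limit = 0.25, seed = 1L, hyper = list()) {
    plan <- stratifiedKFold(cohort, k = k, seed = seed)
    d <- diagnosis(cohort)
    lv <- diagnosisLevels()
    n <- ncol(cohort)
    scores <- matrix(NA_real_, nrow = n, ncol = length(lv),
                     dimnames = list(recordIds(cohort), lv))
    proposed <- rep(NA_character_, n)
    perKind <- lapply(kinds, function(kd) rep(NA_character_, n))
    names(perKind) <- kinds
    a <- answers(cohort)
    for (f in seq_len(plan@k)) {
        inFold <- foldAssignments(plan) == f
        if (!any(inFold)) next
        train <- cohort[, !inFold]
        ens <- tryCatch(
            trainEnsemble(train, kinds = kinds, hyper = hyper,
                          seed = as.integer(seed) + 977L * f),
            error = function(e) stop("training failed in fold ", f, ": ",
                                     conditionMessage(e), call. = FALSE))
        Xv <- t(a[, inFold, drop = FALSE])
        probs <- lapply(ensembleMembers(ens), predictProba, newAnswers = Xv)
        for (i in seq_len(nrow(Xv))) {
            ridx <- which(inFold)[i]
            outs <- lapply(probs, function(p) p[i, ])
            fr <- fuseProbabilities(outs, limit = limit)
            scores[ridx, ] <- relativeScores(fr)
            proposed[ridx] <- proposedDiagnosis(fr)
            for (kd in kinds)
                perKind[[kd]][ridx] <- .argmaxCanonical(probs[[kd]][i, ])
        }
    }
    truth <- factor(as.character(d), levels = lv)
    confusion <- .confusionWithNoCall(truth, proposed)
    correct <- !is.na(proposed) & proposed == as.character(truth)
    sens <- vapply(lv, function(cl) {
        tot <- sum(truth == cl)
        if (tot == 0L) NA_real_ else sum(correct & truth == cl) / tot
    }, numeric(1))
    roc <- lapply(lv, function(cl) {
        pos <- truth == cl
        if (sum(pos) == 0L || sum(!pos) == 0L) return(NULL)
        rocOneVsRest(scores[, cl], pos)
    })
    names(roc) <- lv
    new("EvaluationReport", confusion = confusion,
        perClassSensitivity = sens,
        overallAccuracy = sum(correct) / n,
        roc = roc, foldPlan = plan, scores = scores, truth = truth,
        proposed = proposed, perKind = perKind,
        config = list(kinds = kinds, k = as.integer(k), limit = limit,
                      seed = as.integer(seed),
                      n = n,
                      package = as.character(
                          utils::packageVersion("PulmoScreen"))))
}

.confusionWithNoCall <- function(truth, proposed) {
    lv <- diagnosisLevels()
    prop <- factor(ifelse(is.na(proposed), "no_call", proposed),
                   levels = c(lv, "no_call"))
    tab <- table(truth, prop)
    matrix(as.integer(tab), nrow = nrow(tab),
           dimnames = list(rownames(tab), colnames(tab)))
}

#' @describeIn report-accessors 7 x 8 confusion counts (incl. `no_call`).
#' @param x an `EvaluationReport`.
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

#' @describeIn report-accessors per-class sensitivities.
#' @export
setMethod("sensitivities", "EvaluationReport",
          function(x) x@perClassSensitivity)

#' @describeIn report-accessors overall fraction correct.
#' @export
setMethod("overallAccuracy", "EvaluationReport", function(x) x@overallAccuracy)

#' @describeIn report-accessors per-class pooled one-vs-rest ROC/AUC.
#' @export
setMethod("rocCurves", "EvaluationReport", function(x) x@roc)

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %d records, k = %d, accuracy %.3f\n",
                nrow(object@scores), object@foldPlan@k,
                object@overallAccuracy))
    sens <- object@perClassSensitivity
    cat(" sensitivity:",
        paste(sprintf("%s %.2f", names(sens), sens), collapse = " "), "\n")
    aucs <- vapply(object@roc, function(r)
        if (is.null(r)) NA_real_ else r$auc, numeric(1))
    cat(" AUC:",
        paste(sprintf("%s %.3f", names(aucs), aucs), collapse = " "), "\n")
})

#' Sensitivity table: ensemble versus stand-alone members
#'
#' A (members + fusion) x (classes + overall) sensitivity matrix. The
#' fusion row comes from the fused proposals (no-calls count as errors);
#' each stand-alone row from that classifier's own argmax over its
#' cross-validated posteriors.
#'
#' @param report an [EvaluationReport-class] from [crossValidate()].
#' @return Numeric matrix with one row per classifier kind plus `FUSION`,
#'   and one column per class plus `OVERALL`.
#' @export
sensitivityTable <- function(report) {
    lv <- diagnosisLevels()
    truth <- report@truth
    rows <- c(names(report@perKind), "FUSION")
    out <- matrix(NA_real_, nrow = length(rows), ncol = length(lv) + 1L,
                  dimnames = list(rows, c(lv, "OVERALL")))
    sensOf <- function(pred) {
        correct <- !is.na(pred) & pred == as.character(truth)
        c(vapply(lv, function(cl) {
            tot <- sum(truth == cl)
            if (tot == 0L) NA_real_ else sum(correct & truth == cl) / tot
        }, numeric(1)), OVERALL = mean(correct))
    }
    for (kd in names(report@perKind))
        out[kd, ] <- sensOf(report@perKind[[kd]])
    out["FUSION", ] <- sensOf(report@proposed)
    out
}
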