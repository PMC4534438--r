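#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

#' Canonical diagnosis classes
#'
#' The seven diagnosis groups, in canonical order. This order is used for
#' all probability-vector indexing and for deterministic tie-breaking.
#'
#' @return Character vector of the 7 class codes: cystic fibrosis (CF),
#'   asthma (AS), primary ciliary dyskinesia (PCD), pneumonia (PM), acute
#'   bronchitis (AB), protracted bacterial bronchitis (PBB) and the healthy
#'   control group (CTRL).
#' @examples
#' diagnosisLevels()
#' @export
diagnosisLevels <- function() {
    c("CF", "AS", "PCD", "PM", "AB", "PBB", "CTRL")
}

#' The eight classifier kinds of the ensemble
#'
#' @return Character vector of the 8 classifier codes.
#' @examples
#' classifierKinds()
#' @export
classifierKinds <- function() {
    c("SVM", "ANN", "FUZZY", "RANDOM_FOREST", "LOGISTIC", "LDA",
      "NAIVE_BAYES", "NEAREST_NEIGHBOUR")
}

#' Number of questionnaire items
#' @return The integer 45.
#' @export
nQuestions <- function() 45L

#' Answer levels of the ordinal agreement scale
#' @return Integer vector 1:6 (1 = does not apply at all, 6 = applies
#'   completely).
#' @export
answerLevels <- function() 1:6

.qnames <- function() sprintf("q%02d", seq_len(nQuestions()))

#' QuestionnaireCohort: a cohort of answered questionnaires
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment].
#' The single assay `"answers"` is a 45 x n integer matrix (questions in
#' rows `q01..q45`, one column per record) with values in 1..6 and `NA`
#' marking missing answers. `colData(x)$diagnosis` carries the optional
#' diagnosis label as a factor over [diagnosisLevels()]; `NA` marks an
#' unlabelled (query) record. `rowData(x)` holds the question registry
#' (short label and text; metadata only, never used in computation).
#'
#' @seealso [QuestionnaireCohort()] for the constructor, [readCohort()] and
#'   [writeCohort()] for CSV I/O, [simulateCohort()] for synthetic cohorts.
#' @aliases QuestionnaireCohort-class
#' @exportClass QuestionnaireCohort
setClass("QuestionnaireCohort", contains = "SummarizedExperiment")

setValidity("QuestionnaireCohort", function(object) {
    msg <- character()
    if (!"answers" %in% assayNames(object))
        msg <- c(msg, "assay 'answers' is required")
    else {
        a <- assay(object, "answers")
        if (nrow(a) != nQuestions())
            msg <- c(msg, sprintf("answers must have %d rows, found %d",
                                  nQuestions(), nrow(a)))
        bad <- !is.na(a) & !(a %in% answerLevels())
        if (any(bad))
            msg <- c(msg, sprintf("%d answer(s) outside the 1..6 scale",
                                  sum(bad)))
    }
    if (!"diagnosis" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'diagnosis' is required")
    else {
        d <- colData(object)$diagnosis
        if (!is.factor(d) || !identical(levels(d), diagnosisLevels()))
            msg <- c(msg, "diagnosis must be a factor over the canonical levels")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "record ids (colnames) must be unique")
    if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Class-conditional answer distributions for each of the 45 questions,
#' per-class record counts, a missingness rate and a seed. Instances are
#' usually built with [defaultCohortSpec()].
#'
#' @slot perClassN named integer vector of record counts, one per class.
#' @slot dists named list (one element per class) of 45 x 6 row-stochastic
#'   matrices: row q gives the class's answer distribution on question q.
#' @slot missingRate fraction in `[0, 1)`: each answer is independently
#'   replaced by the missing marker with this probability.
#' @slot seed integer seed making generation fully deterministic.
#' @aliases CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(perClassN = "integer", dists = "list",
                   missingRate = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    lv <- diagnosisLevels()
    if (!identical(names(object@perClassN), lv))
        msg <- c(msg, "perClassN must be named by the canonical classes")
    if (any(object@perClassN < 0L))
        msg <- c(msg, "per-class counts must be >= 0")
    if (!identical(names(object@dists), lv))
        msg <- c(msg, "dists must be named by the canonical classes")
    for (cl in names(object@dists)) {
        m <- object@dists[[cl]]
        if (!is.matrix(m) || !identical(dim(m), c(nQuestions(), 6L))) {
            msg <- c(msg, sprintf("dists[['%s']] must be a 45 x 6 matrix", cl))
            next
        }
        if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
            msg <- c(msg, sprintf(
                "dists[['%s']] rows must be probability vectors", cl))
    }
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' TrainedClassifier: one fitted member of the ensemble
#'
#' @slot kind one of [classifierKinds()].
#' @slot fit opaque fitted state (kind-specific).
#' @slot classLevels classes present at training, in canonical order;
#'   classes absent at training receive probability exactly 0 at prediction.
#' @slot imputeRef per-question imputation values (rounded training
#'   medians), used to fill missing answers at prediction time.
#' @slot hyper hyperparameters the model was trained with.
#' @slot seed the training seed.
#' @aliases TrainedClassifier-class
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
    representation(kind = "character", fit = "ANY", classLevels = "character",
                   imputeRef = "integer", hyper = "list", seed = "integer"))

#' ClassifierEnsemble: the fused eight-member classifier group
#'
#' @slot members named list of [TrainedClassifier-class] objects.
#' @aliases ClassifierEnsemble-class
#' @exportClass ClassifierEnsemble
setClass("ClassifierEnsemble", representation(members = "list"))

#' FusionResult: a fused diagnostic suggestion
#'
#' @slot rawScores per-class sums of the member classifiers' probabilities;
#'   the total equals the number of contributing classifiers.
#' @slot relative `rawScores` normalised to sum 1 (reportable as
#'   percentages).
#' @slot proposed the proposed diagnosis, or `NA_character_` for a no-call
#'   (top relative score did not strictly exceed the limit).
#' @slot limit the confidence limit that was applied.
#' @slot ranking class codes sorted by relative score, descending (ties by
#'   canonical order).
#' @slot audit per-classifier probability matrix (classifiers x classes),
#'   or a 0-row matrix when fusion was called on bare vectors.
#' @aliases FusionResult-class
#' @exportClass FusionResult
setClass("FusionResult",
    representation(rawScores = "numeric", relative = "numeric",
                   proposed = "character", limit = "numeric",
                   ranking = "character", audit = "matrix"))

#' FoldPlan: a stratified cross-validation partition
#'
#' @slot assignments integer fold index (1..k) named by record id.
#' @slot k number of folds.
#' @slot seed the shuffling seed.
#' @aliases FoldPlan-class
#' @exportClass FoldPlan
setClass("FoldPlan",
    representation(assignments = "integer", k = "integer", seed = "integer"))

#' PairHeatMap: answer-frequency differences for one diagnosis pair
#'
#' For the ordered pair (d1, d2), `delta[q, a]` is the relative frequency of
#' answer level `a` on question `q` among d1 records minus the same relative
#' frequency among d2 records. Entries lie in `[-1, 1]`; +1 means every d1
#' record and no d2 record chose that answer, -1 the opposite, 0 equal
#' relative frequencies. Each question's six entries sum to 0.
#'
#' @slot pair character vector of length 2, the ordered (d1, d2) classes.
#' @slot delta 45 x 6 numeric matrix (questions x answer levels).
#' @aliases PairHeatMap-class
#' @exportClass PairHeatMap
setClass("PairHeatMap",
    representation(pair = "character", delta = "matrix"))

#' EvaluationReport: cross-validated performance of the ensemble
#'
#' @slot confusion 7 x 8 count matrix: true class (rows) by proposed class
#'   plus a `no_call` column.
#' @slot perClassSensitivity named fractions, correct(c)/count(c).
#' @slot overallAccuracy fraction of records proposed correctly (no-calls
#'   count as errors).
#' @slot roc per-class list with elements `points` (data.frame of fpr, tpr)
#'   and `auc`, from pooled one-vs-rest fused relative scores.
#' @slot foldPlan the [FoldPlan-class] used.
#' @slot scores n x 7 matrix of fused relative scores per validation record.
#' @slot truth factor of true classes, aligned with `scores` rows.
#' @slot proposed character vector of fused proposals (`NA` = no-call).
#' @slot perKind named list: each classifier kind's own argmax predictions.
#' @slot config list fingerprint of the run configuration.
#' @aliases EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(confusion = "matrix", perClassSensitivity = "numeric",
                   overallAccuracy = "numeric", roc = "list",
                   foldPlan = "FoldPlan", scores = "matrix",
                   truth = "factor", proposed = "character",
                   perKind = "list", config = "list"))
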