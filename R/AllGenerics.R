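#' Answer matrix of a cohort
#'
#' @param x a [QuestionnaireCohort-class].
#' @param ... unused.
#' @return 45 x n integer matrix (NA = missing).
#' @rdname answers
#' @export
setGeneric("answers", function(x, ...) standardGeneric("answers"))

#' Diagnosis labels of a cohort
#'
#' @param x a [QuestionnaireCohort-class].
#' @param ... unused.
#' @return Factor over [diagnosisLevels()]; `NA` = unlabelled record.
#' @rdname diagnosis
#' @export
setGeneric("diagnosis", function(x, ...) standardGeneric("diagnosis"))

#' Per-class record counts of a cohort
#'
#' @param x a [QuestionnaireCohort-class].
#' @param ... unused.
#' @return Table of labelled-record counts per canonical class.
#' @rdname classCounts
#' @export
setGeneric("classCounts", function(x, ...) standardGeneric("classCounts"))

#' Record identifiers of a cohort
#'
#' @param x a [QuestionnaireCohort-class].
#' @return Character vector of unique record ids.
#' @rdname recordIds
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' Posterior class probabilities of a trained classifier
#'
#' @param object a [TrainedClassifier-class].
#' @param newAnswers query answers.
#' @param ... unused.
#' @rdname predictProba
#' @export
setGeneric("predictProba", function(object, newAnswers, ...)
    standardGeneric("predictProba"))

#' FusionResult accessors
#'
#' Read-only access to the components of a fused diagnostic suggestion:
#' raw per-class score sums, normalised relative scores, the proposed
#' diagnosis (`NA` for a no-call), the descending class ranking, and the
#' per-classifier audit trail.
#'
#' @param x a [FusionResult-class].
#' @name fusion-accessors
#' @rdname fusion-accessors
NULL

#' @rdname fusion-accessors
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname fusion-accessors
#' @export
setGeneric("relativeScores", function(x) standardGeneric("relativeScores"))

#' @rdname fusion-accessors
#' @export
setGeneric("proposedDiagnosis", function(x) standardGeneric("proposedDiagnosis"))

#' @rdname fusion-accessors
#' @export
setGeneric("classRanking", function(x) standardGeneric("classRanking"))

#' @rdname fusion-accessors
#' @export
setGeneric("auditTrail", function(x) standardGeneric("auditTrail"))

#' Fold assignments of a cross-validation plan
#'
#' @param x a [FoldPlan-class].
#' @return Integer fold index (1..k) named by record id.
#' @rdname foldAssignments
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' EvaluationReport accessors
#'
#' Read-only access to cross-validation results: the confusion matrix
#' (including the `no_call` column), per-class sensitivities, overall
#' accuracy, and the pooled one-vs-rest ROC curves with their AUCs.
#'
#' @param x an [EvaluationReport-class].
#' @name report-accessors
#' @rdname report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname report-accessors
#' @export
setGeneric("sensitivities", function(x) standardGeneric("sensitivities"))

#' @rdname report-accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname report-accessors
#' @export
setGeneric("rocCurves", function(x) standardGeneric("rocCurves"))

#' Difference matrix of a pair heat map
#'
#' @param x a [PairHeatMap-class].
#' @return The 45 x 6 answer-frequency-difference matrix.
#' @rdname heatmapDelta
#' @export
setGeneric("heatmapDelta", function(x) standardGeneric("heatmapDelta"))
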