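## Score-summation fusion of the classifier bank.
##
## Each member contributes its full posterior; the per-class sums form the
## diagnostic score. The top class is proposed only if its normalised
## (relative) score strictly exceeds the confidence limit, otherwise the
## result is a no-call carrying the ranked shortlist.

.argmaxCanonical <- function(p) {
    # ties resolved towards the earlier canonical class (which.max is first)
    diagnosisLevels()[which.max(p)]
}

#' Fuse per-classifier probability vectors into a diagnostic score
#'
#' Sums the classifiers' per-class probabilities into raw scores,
#' normalises them to relative scores, and proposes the top class when its
#' relative score strictly exceeds `limit` (argmax ties broken by canonical
#' class order). The default limit 0.25 sits at about 1.75 times the 1/7
#' chance level.
#'
#' @param outputs list of probability vectors over [diagnosisLevels()] (or
#'   a classifiers x 7 matrix).
#' @param limit confidence limit in `[0, 1)` applied to the top relative
#'   score.
#' @return A [FusionResult-class].
#' @examples
#' a <- c(0.6, 0.4, 0, 0, 0, 0, 0)
#' b <- c(0.3, 0.7, 0, 0, 0, 0, 0)
#' fr <- fuseProbabilities(list(a, b), limit = 0.25)
#' relativeScores(fr)   # 0.45, 0.55, ...
#' proposedDiagnosis(fr)  # "AS"
#' @export
fuseProbabilities <- function(outputs, limit = 0.25) {
    if (is.matrix(outputs))
        outputs <- lapply(seq_len(nrow(outputs)), function(i) outputs[i, ])
    if (!length(outputs))
        stop("at least one classifier output is required", call. = FALSE)
    if (limit < 0 || limit >= 1)
        stop("limit must be in [0, 1)", call. = FALSE)
    k <- length(diagnosisLevels())
    audit <- do.call(rbind, lapply(outputs, function(p) {
        if (length(p) != k)
            stop("each output must cover the ", k, " canonical classes",
                 call. = FALSE)
        as.numeric(p)
    }))
    colnames(audit) <- diagnosisLevels()
    raw <- colSums(audit)
    rel <- raw / sum(raw)
    ranking <- diagnosisLevels()[order(-rel, seq_len(k))]
    top <- ranking[1L]
    proposed <- if (rel[[top]] > limit) top else NA_character_
    new("FusionResult", rawScores = raw, relative = rel,
        proposed = proposed, limit = as.numeric(limit), ranking = ranking,
        audit = audit)
}

#' Classify one questionnaire with the full ensemble
#'
#' Runs every member's [predictProba()] on the answers and fuses the
#' resulting vectors with [fuseProbabilities()]. The returned result keeps
#' the per-classifier audit trail so a report can show each member's own
#' posterior alongside the fused score.
#'
#' @param ensemble a [ClassifierEnsemble-class].
#' @param values answer vector of length 45 (missing entries allowed).
#' @param limit confidence limit, as in [fuseProbabilities()].
#' @return A [FusionResult-class] whose `auditTrail()` has one row per
#'   member.
#' @export
predictCase <- function(ensemble, values, limit = 0.25) {
    members <- ensembleMembers(ensemble)
    if (!length(members))
        stop("ensemble has no members", call. = FALSE)
    cls <- lapply(members, function(m) m@classLevels)
    if (length(unique(vapply(cls, paste, character(1), collapse = ","))) > 1L)
        stop("ensemble members were trained on different class sets",
             call. = FALSE)
    outs <- lapply(members, predictProba, newAnswers = values)
    res <- fuseProbabilities(outs, limit = limit)
    rownames(res@audit) <- names(members)
    res
}

#' @describeIn fusion-accessors raw per-class score sums.
#' @param x a `FusionResult`.
#' @export
setMethod("rawScores", "FusionResult", function(x) x@rawScores)

#' @describeIn fusion-accessors normalised per-class scores (sum 1).
#' @export
setMethod("relativeScores", "FusionResult", function(x) x@relative)

#' @describeIn fusion-accessors proposed class code or `NA` (no-call).
#' @export
setMethod("proposedDiagnosis", "FusionResult", function(x) x@proposed)

#' @describeIn fusion-accessors classes by descending relative score.
#' @export
setMethod("classRanking", "FusionResult", function(x) x@ranking)

#' @describeIn fusion-accessors per-classifier probability matrix.
#' @export
setMethod("auditTrail", "FusionResult", function(x) x@audit)

setMethod("show", "FusionResult", function(object) {
    rel <- object@relative
    top3 <- object@ranking[1:3]
    if (is.na(object@proposed))
        cat(sprintf("FusionResult: no-call (limit %.2f); shortlist %s\n",
                    object@limit,
                    paste(sprintf("%s: %.0f%%", top3, 100 * rel[top3]),
                          collapse = "; ")))
    else
        cat(sprintf("FusionResult: %s (%s)\n", object@proposed,
                    paste(sprintf("%s: %.0f%%", top3, 100 * rel[top3]),
                          collapse = "; ")))
})
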