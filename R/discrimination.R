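## Pairwise answer-frequency heat maps and information-gain question
## ranking.

.relFreqMatrix <- function(cohort, cl) {
    a <- answers(cohort)[, diagnosis(cohort) %in% cl, drop = FALSE]
    out <- matrix(NA_real_, nrow = nQuestions(), ncol = 6L,
                  dimnames = list(.qnames(), as.character(answerLevels())))
    for (q in seq_len(nQuestions())) {
        v <- a[q, ]
        v <- v[!is.na(v)]
        if (length(v))
            out[q, ] <- tabulate(v, nbins = 6L) / length(v)
    }
    out
}

#' Answer-frequency-difference heat map for one diagnosis pair
#'
#' For the ordered pair `(d1, d2)`, entry `[q, a]` is the relative
#' frequency of answer `a` on question `q` among `d1` records minus the
#' corresponding `d2` frequency. +1 means every `d1` record and no `d2`
#' record chose that answer; -1 the opposite; 0 equal relative frequencies.
#' Relative frequencies use each class's non-missing count for that
#' question as denominator, so each question's six differences sum to 0.
#'
#' @param cohort labelled [QuestionnaireCohort-class].
#' @param d1,d2 diagnosis codes from [diagnosisLevels()].
#' @return A [PairHeatMap-class].
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.9, seed = 4))
#' hm <- heatmapPair(qc, "PCD", "PBB")
#' range(heatmapDelta(hm))
#' @export
heatmapPair <- function(cohort, d1, d2) {
    for (cl in c(d1, d2)) {
        if (!(cl %in% diagnosisLevels()))
            stop("unknown diagnosis '", cl, "'", call. = FALSE)
        if (!any(diagnosis(cohort) %in% cl))
            stop("cohort contains no records of class ", cl, call. = FALSE)
    }
    delta <- .relFreqMatrix(cohort, d1) - .relFreqMatrix(cohort, d2)
    new("PairHeatMap", pair = c(d1, d2), delta = delta)
}

#' @describeIn heatmapDelta the 45 x 6 difference matrix.
#' @param x a `PairHeatMap`.
#' @export
setMethod("heatmapDelta", "PairHeatMap", function(x) x@delta)

setMethod("show", "PairHeatMap", function(object) {
    top <- discriminativeQuestions(object)[1:3]
    cat(sprintf("PairHeatMap %s vs %s | max |delta| = %.3f | top questions: %s\n",
                object@pair[1], object@pair[2],
                max(abs(object@delta), na.rm = TRUE),
                paste(top, collapse = ", ")))
})

#' Questions ranked by discriminative strength for one pair
#'
#' Questions ordered by `max over answers of |delta[q, a]|`, descending
#' (ties towards the lower question index).
#'
#' @param heatmap a [PairHeatMap-class].
#' @return Integer vector of question indices (length 45).
#' @export
discriminativeQuestions <- function(heatmap) {
    score <- apply(abs(heatmap@delta), 1L, max)
    score[is.na(score)] <- -Inf
    order(-score, seq_len(nQuestions()))
}

#' Heat maps for all diagnosis pairs
#'
#' Emits each of the 21 unordered class pairs once, in canonical order
#' (the earlier canonical class first), together with the per-pair question
#' ranking. Classes absent from the cohort are skipped.
#'
#' @param cohort labelled [QuestionnaireCohort-class] with >= 2 classes.
#' @return Named list (one `"D1_vs_D2"` element per pair) of lists with
#'   `heatmap` ([PairHeatMap-class]) and `questions` (ranked indices).
#' @export
heatmapAllPairs <- function(cohort) {
    present <- diagnosisLevels()[diagnosisLevels() %in%
                                 diagnosis(cohort)[!is.na(diagnosis(cohort))]]
    if (length(present) < 2L)
        stop("at least two classes are required", call. = FALSE)
    out <- list()
    for (i in seq_len(length(present) - 1L)) {
        for (j in (i + 1L):length(present)) {
            hm <- heatmapPair(cohort, present[i], present[j])
            out[[paste0(present[i], "_vs_", present[j])]] <-
                list(heatmap = hm,
                     questions = discriminativeQuestions(hm))
        }
    }
    out
}

#' Information gain of one question for the diagnosis
#'
#' The reduction in class-label Shannon entropy (base 2, bits) achieved by
#' conditioning on the question's answer:
#' `gain = H(class) - sum_a p(a) H(class | answer = a)`, with `0 log 0 = 0`.
#' Records with a missing answer on the question (or no label) are
#' excluded, and `H(class)` is computed over the same retained records.
#'
#' @param cohort labelled [QuestionnaireCohort-class] with >= 2 classes.
#' @param q question index in 1..45.
#' @return Gain in bits, in `[0, log2(nclasses)]`.
#' @export
informationGain <- function(cohort, q) {
    if (length(q) != 1L || is.na(q) || q < 1L || q > nQuestions())
        stop("question index must be in 1..", nQuestions(), call. = FALSE)
    d <- as.character(diagnosis(cohort))
    v <- answers(cohort)[q, ]
    keep <- !is.na(d) & !is.na(v)
    d <- d[keep]; v <- v[keep]
    if (length(unique(d)) < 2L)
        stop("at least two classes are required", call. = FALSE)
    H <- function(x) {
        p <- table(x) / length(x)
        p <- p[p > 0]
        -sum(p * log2(p))
    }
    cond <- 0
    for (a in unique(v)) {
        sel <- v == a
        cond <- cond + mean(sel) * H(d[sel])
    }
    max(H(d) - cond, 0)  # clamp float round-off on uninformative questions
}

#' Rank all questions by information gain
#'
#' @param cohort labelled [QuestionnaireCohort-class] with >= 2 classes.
#' @return data.frame with columns `question`, `short_label`, `gain`
#'   (bits), sorted by descending gain with ties broken by ascending
#'   question index.
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.9, seed = 5))
#' head(rankQuestions(qc))
#' @export
rankQuestions <- function(cohort) {
    gains <- vapply(seq_len(nQuestions()),
                    function(q) informationGain(cohort, q), numeric(1))
    ord <- order(-gains, seq_len(nQuestions()))
    data.frame(question = ord,
               short_label = sprintf("Q%d", ord),
               gain = gains[ord],
               row.names = NULL)
}
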