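## Synthetic questionnaire cohorts.
##
## Each class's answer behaviour on each question is a categorical
## distribution over the six ordinal levels. The default spec mixes a
## uniform background with class-specific triangular peaks, controlled by a
## single `separation` knob, and reproduces the study's cohort composition
## (CF 33, AS 27, PCD 24, PM 21, AB 23, PBB 18, CTRL 24; total 170).

.studyComposition <- function() {
    stats::setNames(c(33L, 27L, 24L, 21L, 23L, 18L, 24L), diagnosisLevels())
}

## triangular kernel over levels 1..6, peak at `mode`, half-width 2 levels
.triangularDist <- function(mode) {
    w <- pmax(0, 1 - abs(answerLevels() - mode) / 2)
    w / sum(w)
}

#' Construct a CohortSpec manually
#'
#' @param perClassN named integer counts per class (canonical names).
#' @param dists named list of 45 x 6 row-stochastic matrices per class.
#' @param missingRate per-answer missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(perClassN, dists, missingRate = 0, seed = 1L) {
    new("CohortSpec",
        perClassN = stats::setNames(as.integer(perClassN), names(perClassN)),
        dists = dists, missingRate = as.numeric(missingRate),
        seed = as.integer(seed))
}

#' Default synthetic cohort specification at the study's composition
#'
#' Builds a [CohortSpec-class] with the study cohort composition (CF 33,
#' AS 27, PCD 24, PM 21, AB 23, PBB 18, CTRL 24; total 170). Questions
#' 1..42 are split into seven blocks of six; on its own block a class peaks
#' at answer level 6 and on every other class's block at level 1, so any
#' two classes differ on twelve designated questions. Questions 43..45 are
#' uninformative. Each question's distribution is the mixture
#' `(1 - separation) * uniform + separation * triangular(mode)`:
#' `separation = 0` gives the uniform distribution everywhere (chance-level
#' problem) and `separation = 1` near-degenerate class-specific modes.
#'
#' @param separation mixture weight in `[0, 1]` controlling class
#'   discriminability.
#' @param seed integer seed stored in the spec.
#' @param missingRate per-answer missingness probability, default 0.
#' @return A [CohortSpec-class] with `sum(perClassN) == 170`.
#' @examples
#' spec <- defaultCohortSpec(0.9, seed = 7)
#' sum(spec@perClassN)  # 170
#' @export
defaultCohortSpec <- function(separation, seed = 1L, missingRate = 0) {
    if (!is.numeric(separation) || length(separation) != 1L ||
        is.na(separation) || separation < 0 || separation > 1)
        stop("separation must be a single value in [0, 1]", call. = FALSE)
    lv <- diagnosisLevels()
    unif <- rep(1 / 6, 6)
    dists <- lapply(seq_along(lv), function(ci) {
        m <- matrix(unif, nrow = nQuestions(), ncol = 6, byrow = TRUE,
                    dimnames = list(.qnames(), as.character(answerLevels())))
        for (bj in seq_along(lv)) {
            block <- ((bj - 1L) * 6L + 1L):(bj * 6L)
            mode <- if (bj == ci) 6L else 1L
            peak <- .triangularDist(mode)
            for (q in block)
                m[q, ] <- (1 - separation) * unif + separation * peak
        }
        m  # questions 43..45 stay uniform at every separation
    })
    names(dists) <- lv
    cohortSpec(.studyComposition(), dists, missingRate = missingRate,
               seed = seed)
}

#' Generate a labelled cohort from a CohortSpec
#'
#' A pure function of the spec (seed included): identical specs give
#' byte-identical cohorts. Answers are drawn independently per record and
#' question from the class's distribution (class-conditional independence),
#' then each answer is independently replaced by the missing marker with
#' probability `missingRate`. Each class consumes its own seeded stream in
#' record-major, question-minor order, so adding classes never perturbs
#' another class's draws.
#'
#' @param spec a [CohortSpec-class].
#' @return A [QuestionnaireCohort-class] with exactly `perClassN` records
#'   per class.
#' @examples
#' qc <- simulateCohort(defaultCohortSpec(0.9, seed = 7))
#' classCounts(qc)
#' @export
simulateCohort <- function(spec) {
    validObject(spec)
    lv <- diagnosisLevels()
    mats <- list(); labels <- character(); ids <- character()
    for (ci in seq_along(lv)) {
        cl <- lv[ci]
        n <- spec@perClassN[[cl]]
        if (n == 0L) next
        dist <- spec@dists[[cl]]
        old <- .saveSeed()
        set.seed(spec@seed + 1009L * ci)
        m <- matrix(NA_integer_, nrow = nQuestions(), ncol = n)
        for (r in seq_len(n)) {
            for (q in seq_len(nQuestions()))
                m[q, r] <- sample.int(6L, 1L, prob = dist[q, ])
            if (spec@missingRate > 0) {
                drop <- stats::runif(nQuestions()) < spec@missingRate
                m[drop, r] <- NA_integer_
            }
        }
        .restoreSeed(old)
        mats[[cl]] <- m
        labels <- c(labels, rep(cl, n))
        ids <- c(ids, sprintf("%s_%03d", cl, seq_len(n)))
    }
    if (!length(mats)) {
        amat <- matrix(NA_integer_, nrow = nQuestions(), ncol = 0)
        return(QuestionnaireCohort(amat, diagnosis = character(),
                                   recordIds = character()))
    }
    QuestionnaireCohort(do.call(cbind, mats), diagnosis = labels,
                        recordIds = ids)
}

## run `expr` under a fixed seed without disturbing the caller's RNG stream
.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
}

.withSeed <- function(seed, expr) {
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(seed)
    expr
}
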