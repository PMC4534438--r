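#' Construct a QuestionnaireCohort
#'
#' @param answers 45 x n integer matrix (questions x records) with values in
#'   1..6 and `NA` for missing answers, or an n x 45 matrix which is
#'   transposed if its column count is 45 and row count is not.
#' @param diagnosis character or factor of length n with class codes from
#'   [diagnosisLevels()] (case-insensitive); `NA` for unlabelled records.
#' @param recordIds character vector of unique record identifiers; defaults
#'   to `rec0001..`.
#' @param questions optional question registry data.frame with columns
#'   `index`, `short_label`, `text`; defaults to [questionRegistry()].
#' @return A [QuestionnaireCohort-class] object.
#' @examples
#' a <- matrix(3L, nrow = 45, ncol = 2)
#' qc <- QuestionnaireCohort(a, diagnosis = c("CF", NA))
#' classCounts(qc)
#' @export
QuestionnaireCohort <- function(answers, diagnosis = NULL, recordIds = NULL,
                                questions = questionRegistry()) {
    if (nrow(answers) != nQuestions() && ncol(answers) == nQuestions())
        answers <- t(answers)
    storage.mode(answers) <- "integer"
    n <- ncol(answers)
    if (is.null(recordIds))
        recordIds <- sprintf("rec%04d", seq_len(n))
    if (is.null(diagnosis))
        diagnosis <- rep(NA_character_, n)
    diagnosis <- .parseDiagnosis(as.character(diagnosis))
    dimnames(answers) <- list(.qnames(), as.character(recordIds))
    rd <- S4Vectors::DataFrame(questions, row.names = .qnames())
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(answers = answers),
        rowData = rd,
        colData = S4Vectors::DataFrame(diagnosis = diagnosis,
                                       row.names = as.character(recordIds)))
    new("QuestionnaireCohort", se)
}

.parseDiagnosis <- function(x) {
    lv <- diagnosisLevels()
    out <- lv[match(toupper(trimws(x)), lv)]
    unknown <- !is.na(x) & nzchar(trimws(x)) & is.na(out)
    if (any(unknown))
        stop("unknown diagnosis token(s): ",
             paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    factor(out, levels = lv)
}

#' The packaged question registry
#'
#' A 45-row table (index, short_label, text) describing the questionnaire
#' items. The shipped texts are synthetic placeholders; they are metadata
#' only and never enter any computation.
#'
#' @return data.frame with columns `index`, `short_label`, `text`.
#' @export
questionRegistry <- function() {
    path <- system.file("extdata", "questions-synthetic.tsv",
                        package = "PulmoScreen")
    if (!nzchar(path)) {  # during development before installation
        return(data.frame(index = seq_len(nQuestions()),
                          short_label = sprintf("Q%d", seq_len(nQuestions())),
                          text = sprintf("Question %d", seq_len(nQuestions()))))
    }
    reg <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(identical(reg$index, seq_len(nQuestions())))
    reg
}

#' @describeIn answers the 45 x n answer matrix of a cohort.
#' @param x a `QuestionnaireCohort`.
#' @param ... unused.
#' @export
setMethod("answers", "QuestionnaireCohort", function(x, ...)
    assay(x, "answers"))

#' @describeIn diagnosis diagnosis labels of a cohort (factor; `NA` =
#'   unlabelled).
#' @param x a `QuestionnaireCohort`.
#' @param ... unused.
#' @export
setMethod("diagnosis", "QuestionnaireCohort", function(x, ...)
    colData(x)$diagnosis)

#' @describeIn recordIds record identifiers of a cohort.
#' @param x a `QuestionnaireCohort`.
#' @export
setMethod("recordIds", "QuestionnaireCohort", function(x) colnames(x))

#' @describeIn classCounts labelled-record count per diagnosis class.
#' @param x a `QuestionnaireCohort`.
#' @param ... unused.
#' @export
setMethod("classCounts", "QuestionnaireCohort", function(x, ...)
    table(diagnosis(x)))

setMethod("show", "QuestionnaireCohort", function(object) {
    cat("QuestionnaireCohort:", ncol(object), "record(s),",
        nrow(object), "questions\n")
    d <- diagnosis(object)
    cat(" labelled:", sum(!is.na(d)), " unlabelled:", sum(is.na(d)), "\n")
    if (any(!is.na(d))) {
        tab <- table(d)
        cat(" ", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
            "\n")
    }
    miss <- sum(is.na(answers(object)))
    if (miss > 0) cat(" missing answers:", miss, "\n")
})

#' Validate one questionnaire record
#'
#' Checks a single answer vector (and optional label) against the
#' questionnaire contract: exactly 45 entries, every present value in 1..6,
#' label (if any) among the canonical codes. Returns a verdict object, never
#' throws.
#'
#' @param values vector of answers; `NA` marks missing.
#' @param label optional diagnosis code.
#' @return list with `ok` (logical) and `violations` (character vector,
#'   empty when ok). Every out-of-range value is named with its question
#'   index.
#' @examples
#' validateRecord(rep(1, 45), "CF")$ok          # TRUE
#' validateRecord(rep(1, 44))$violations        # length contract
#' @export
validateRecord <- function(values, label = NA) {
    violations <- character()
    if (length(values) != nQuestions())
        violations <- c(violations,
            sprintf("length %d != %d", length(values), nQuestions()))
    vv <- suppressWarnings(as.numeric(values))
    present <- !is.na(vv)
    bad <- present & (!(vv %in% answerLevels()) | vv != round(vv))
    nonnum <- !is.na(values) & is.na(vv)
    bad <- bad | nonnum
    if (any(bad)) {
        idx <- which(bad)
        violations <- c(violations, sprintf(
            "question %d: value '%s' not in 1..6", idx,
            as.character(values)[idx]))
    }
    if (length(label) != 1L)
        violations <- c(violations, "label must have length 1")
    else if (!is.na(label) &&
             !(toupper(trimws(as.character(label))) %in% diagnosisLevels()))
        violations <- c(violations,
            sprintf("unknown diagnosis label '%s'", as.character(label)))
    list(ok = length(violations) == 0L, violations = violations)
}

#' Read a questionnaire cohort from CSV
#'
#' Canonical dialect: comma-separated, UTF-8, header
#' `record_id,diagnosis,q01,...,q45`; empty cells are missing answers;
#' diagnosis tokens are matched case-insensitively against
#' [diagnosisLevels()] and may be empty for unlabelled records.
#'
#' @param file path or connection.
#' @return A [QuestionnaireCohort-class].
#' @seealso [writeCohort()]; `readCohort(writeCohort(x, f))` is the identity.
#' @export
readCohort <- function(file) {
    df <- utils::read.csv(file, colClasses = "character", check.names = FALSE)
    expected <- c("record_id", "diagnosis", .qnames())
    if (!identical(colnames(df), expected))
        stop("malformed header: expected columns ",
             paste(expected[1:3], collapse = ","), ",...,q45; found ",
             paste(utils::head(colnames(df), 4), collapse = ","),
             call. = FALSE)
    n <- nrow(df)
    amat <- matrix(NA_integer_, nrow = nQuestions(), ncol = n,
                   dimnames = list(.qnames(), df$record_id))
    for (j in seq_len(nQuestions())) {
        col <- df[[.qnames()[j]]]
        col[!nzchar(trimws(col))] <- NA
        amat[j, ] <- suppressWarnings(as.integer(col))
    }
    labels <- df$diagnosis
    labels[!nzchar(trimws(labels))] <- NA
    for (i in seq_len(n)) {
        v <- validateRecord(amat[, i], labels[i])
        if (!v$ok)
            stop(sprintf("row %d (record '%s'): %s", i, df$record_id[i],
                         paste(v$violations, collapse = "; ")),
                 call. = FALSE)
    }
    if (anyDuplicated(df$record_id))
        stop("duplicate record_id values in input", call. = FALSE)
    QuestionnaireCohort(amat, diagnosis = labels, recordIds = df$record_id)
}

#' Write a questionnaire cohort to CSV
#'
#' Inverse of [readCohort()]: the canonical comma-separated dialect with
#' missing answers as empty cells. Reading the written file reproduces the
#' cohort exactly.
#'
#' @param cohort a [QuestionnaireCohort-class].
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
writeCohort <- function(cohort, file) {
    a <- answers(cohort)
    df <- data.frame(record_id = recordIds(cohort),
                     diagnosis = as.character(diagnosis(cohort)),
                     t(a), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("record_id", "diagnosis", .qnames())
    utils::write.csv(df, file, row.names = FALSE, na = "", quote = FALSE)
    invisible(file)
}

#' Impute missing answers from a per-question reference
#'
#' Present values are left untouched; each missing value is replaced by the
#' reference value for that question. The evaluation pipeline derives the
#' reference from the training partition (rounded per-question medians, see
#' [imputationReference()]) so validation records never leak into it.
#'
#' @param values answer vector of length 45 (`NA` = missing).
#' @param reference integer vector of length 45 with values in 1..6.
#' @return Complete integer answer vector.
#' @export
imputeMissing <- function(values, reference) {
    if (length(reference) != nQuestions() ||
        any(is.na(reference)) || !all(reference %in% answerLevels()))
        stop("imputation reference must supply one value in 1..6 per question",
             call. = FALSE)
    if (length(values) != nQuestions())
        stop("answer vector must have length ", nQuestions(), call. = FALSE)
    out <- as.integer(values)
    miss <- is.na(out)
    out[miss] <- as.integer(reference)[miss]
    out
}

#' Per-question imputation reference of a cohort
#'
#' The rounded median answer per question over non-missing values (halves
#' round up, result clamped to 1..6). Questions with no observed answers
#' fall back to the scale midpoint 3.
#'
#' @param cohort a [QuestionnaireCohort-class] (typically a training
#'   partition).
#' @return Integer vector of length 45.
#' @export
imputationReference <- function(cohort) {
    a <- answers(cohort)
    ref <- apply(a, 1L, function(r) {
        r <- r[!is.na(r)]
        if (!length(r)) return(3L)
        as.integer(floor(stats::median(r) + 0.5))
    })
    pmin(pmax(ref, 1L), 6L)
}
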