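#' Embed a question as an IDF-weighted sum of word vectors
#'
#' The question text is tokenized with the same normalizer used for the
#' corpus; each in-vocabulary token contributes its embedding vector scaled
#' by its IDF weight, with repeated tokens counted at every occurrence.
#' Tokens missing from either the embedding vocabulary or the IDF table are
#' skipped (they contribute the zero vector). IDF weights are used raw, not
#' renormalized within the question.
#'
#' @param text question text (or a one-row slice of a
#'   [Questionnaire-class]'s questions).
#' @param emb an [EmbeddingTable-class].
#' @param idf an [IdfTable-class].
#' @param stem passed to [preprocessText()]; must match how `emb`/`idf` were
#'   built.
#' @return Numeric vector of length `embeddingDim(emb)`. A question whose
#'   tokens are all out of vocabulary yields the zero vector with a warning.
#' @export
embedQuestion <- function(text, emb, idf, stem = FALSE) {
    toks <- preprocessText(text, stem = stem)
    d <- embeddingDim(emb)
    keep <- toks[toks %in% tokens(emb) & toks %in% tokens(idf)]
    if (!length(keep)) {
        warning("all tokens out of vocabulary for question: ",
                substr(text, 1, 40))
        return(numeric(d))
    }
    w <- idfWeight(idf, keep)
    v <- embeddingVector(emb, keep)
    as.numeric(crossprod(v, w))
}

#' Question-vector matrix for a questionnaire
#'
#' @param qn a [Questionnaire-class].
#' @inheritParams embedQuestion
#' @return Matrix (questions x d) with question ids as rownames.
#' @export
questionVectors <- function(qn, emb, idf, stem = FALSE) {
    q <- qn@questions
    m <- t(vapply(q$text, embedQuestion, numeric(embeddingDim(emb)),
                  emb = emb, idf = idf, stem = stem, USE.NAMES = FALSE))
    rownames(m) <- q$question_id
    m
}

imputeAnswers <- function(a, policy) {
    allMissing <- rowSums(!is.na(a)) == 0L
    if (any(allMissing) && policy != "drop")
        stop("patient(s) with no answers: ",
             paste(rownames(a)[allMissing], collapse = ", "))
    switch(policy,
        zero = { a[is.na(a)] <- 0; a },
        median = {
            for (j in seq_len(ncol(a))) {
                miss <- is.na(a[, j])
                if (any(miss))
                    a[miss, j] <- round(stats::median(a[!miss, j]))
            }
            if (anyNA(a)) stop("question(s) with no observed answers cannot be imputed")
            a
        },
        drop = a[stats::complete.cases(a), , drop = FALSE]
    )
}

#' Survey-level patient embedding matrix
#'
#' Row i of the result is the sum over questions j of `a_ij * q_j`, where
#' `a_ij` is patient i's ordinal answer and `q_j` the IDF-weighted question
#' vector — so raising an answer from 1 to 2 adds exactly one extra copy of
#' that question's vector to the patient's row, and an answer of 0
#' contributes nothing.
#'
#' @param qn a [Questionnaire-class].
#' @param responses a [ResponseMatrix-class] whose columns are exactly the
#'   questionnaire's question ids.
#' @inheritParams embedQuestion
#' @param missing policy for missing answers: `"median"` (impute the
#'   per-question median of observed answers, rounded; default), `"zero"`, or
#'   `"drop"` (drop incomplete patients).
#' @return A [SurveyMatrix-class], patients x d.
#' @export
embedSurvey <- function(qn, responses, emb, idf,
                        missing = c("median", "zero", "drop"), stem = FALSE) {
    missing <- match.arg(missing)
    a <- as.matrix(responses)
    qid <- questionIds(qn)
    unknown <- setdiff(colnames(a), qid)
    if (length(unknown))
        stop("responses contain unknown question id(s): ",
             paste(unknown, collapse = ", "))
    absent <- setdiff(qid, colnames(a))
    if (length(absent))
        stop("responses missing question id(s): ", paste(absent, collapse = ", "))
    a <- a[, qid, drop = FALSE]
    q <- qn@questions
    for (j in seq_along(qid)) {
        v <- a[, j]; v <- v[!is.na(v)]
        if (length(v) && (any(v < q$scale_min[j]) || any(v > q$scale_max[j])))
            stop("answers out of scale [", q$scale_min[j], ",", q$scale_max[j],
                 "] for question ", qid[j])
    }
    a <- imputeAnswers(a, missing)
    qv <- questionVectors(qn, emb, idf, stem = stem)
    SurveyMatrix(surveyId(qn), a %*% qv)
}

#' Survey matrices for a battery of questionnaires
#'
#' Builds one [SurveyMatrix-class] per instrument, enforcing a single shared
#' patient roster across all surveys. Patients are ordered lexicographically
#' by id unless `roster` fixes the order.
#'
#' @param questionnaires list of [Questionnaire-class] objects.
#' @param responses list of [ResponseMatrix-class] objects, parallel to
#'   `questionnaires` (or named by survey id).
#' @inheritParams embedSurvey
#' @param roster optional character vector fixing patient order.
#' @return Named list of [SurveyMatrix-class], identical patient ordering.
#' @export
buildAllSurveys <- function(questionnaires, responses, emb, idf,
                            missing = "median", roster = NULL, stem = FALSE) {
    ids <- vapply(questionnaires, surveyId, character(1))
    if (!is.null(names(responses))) responses <- responses[ids]
    rosters <- lapply(responses, patientIds)
    ref <- sort(rosters[[1L]])
    for (k in seq_along(rosters)) {
        dif <- c(setdiff(rosters[[k]], ref), setdiff(ref, rosters[[k]]))
        if (length(dif))
            stop("patient roster mismatch for survey '", ids[k], "': ",
                 paste(sort(unique(dif)), collapse = ", "))
    }
    ord <- if (is.null(roster)) ref else {
        if (!setequal(roster, ref)) stop("roster does not match response patients")
        roster
    }
    out <- lapply(seq_along(questionnaires), function(k) {
        sm <- embedSurvey(questionnaires[[k]],
                          ResponseMatrix(as.matrix(responses[[k]])[ord, , drop = FALSE]),
                          emb, idf, missing = missing, stem = stem)
        sm
    })
    names(out) <- ids
    out
}
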