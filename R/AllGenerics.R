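#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `embeddingDim` and
#' `tokens` for [EmbeddingTable-class] / [IdfTable-class], `patientIds` and
#' `questionIds` for the patient-level containers, `surveyId` for survey-bound
#' objects, and `as.matrix` methods to drop down to base matrices.
#'
#' @param object an object of one of the package's S4 classes.
#' @return `embeddingDim`: integer; `tokens`, `patientIds`, `questionIds`:
#'   character vectors; `surveyId`: a string; `nDocuments`: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(object) standardGeneric("embeddingDim"))

#' @rdname accessors
#' @export
setGeneric("tokens", function(object) standardGeneric("tokens"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("questionIds", function(object) standardGeneric("questionIds"))

#' @rdname accessors
#' @export
setGeneric("surveyId", function(object) standardGeneric("surveyId"))

#' @rdname accessors
#' @export
setGeneric("nDocuments", function(object) standardGeneric("nDocuments"))

#' @rdname accessors
setMethod("embeddingDim", "EmbeddingTable", function(object) ncol(object@vectors))

#' @rdname accessors
setMethod("tokens", "EmbeddingTable", function(object) rownames(object@vectors))

#' @rdname accessors
setMethod("tokens", "IdfTable", function(object) names(object@weights))

#' @rdname accessors
setMethod("nDocuments", "IdfTable", function(object) object@nDocuments)

#' @rdname accessors
setMethod("patientIds", "ResponseMatrix", function(object) rownames(object@answers))

#' @rdname accessors
setMethod("questionIds", "ResponseMatrix", function(object) colnames(object@answers))

#' @rdname accessors
setMethod("patientIds", "SurveyMatrix", function(object) rownames(object@embedding))

#' @rdname accessors
setMethod("surveyId", "SurveyMatrix", function(object) object@surveyId)

#' @rdname accessors
setMethod("surveyId", "Questionnaire", function(object) object@surveyId)

#' @rdname accessors
setMethod("questionIds", "Questionnaire", function(object) object@questions$question_id)

#' @rdname accessors
#' @param x object to coerce.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "EmbeddingTable", function(x, ...) x@vectors)

#' @rdname accessors
#' @export
setMethod("as.matrix", "SurveyMatrix", function(x, ...) x@embedding)

#' @rdname accessors
#' @export
setMethod("as.matrix", "ResponseMatrix", function(x, ...) x@answers)

#' Look up IDF weights
#'
#' @param object an [IdfTable-class].
#' @param token character vector of tokens.
#' @return Numeric vector of weights, NA for tokens absent from the corpus
#'   vocabulary.
#' @export
setGeneric("idfWeight", function(object, token) standardGeneric("idfWeight"))

#' @rdname idfWeight
setMethod("idfWeight", "IdfTable", function(object, token) {
    w <- object@weights[token]
    names(w) <- token
    w
})

#' Look up embedding vectors
#'
#' @param object an [EmbeddingTable-class].
#' @param token character vector of tokens; all must be in vocabulary.
#' @return Matrix of vectors, one row per requested token.
#' @export
setGeneric("embeddingVector", function(object, token) standardGeneric("embeddingVector"))

#' @rdname embeddingVector
setMethod("embeddingVector", "EmbeddingTable", function(object, token) {
    missing <- setdiff(token, rownames(object@vectors))
    if (length(missing))
        stop("tokens not in vocabulary: ", paste(missing, collapse = ", "))
    object@vectors[token, , drop = FALSE]
})

setMethod("show", "EmbeddingTable", function(object) {
    cat("EmbeddingTable:", nrow(object@vectors), "tokens x",
        ncol(object@vectors), "dimensions\n")
})

setMethod("show", "IdfTable", function(object) {
    cat("IdfTable:", length(object@weights), "tokens over",
        object@nDocuments, "documents\n")
})

setMethod("show", "Questionnaire", function(object) {
    cat("Questionnaire '", object@surveyId, "': ", nrow(object@questions),
        " ordinal questions\n", sep = "")
})

setMethod("show", "ResponseMatrix", function(object) {
    a <- object@answers
    cat("ResponseMatrix:", nrow(a), "patients x", ncol(a), "questions (",
        sum(is.na(a)), "missing )\n")
})

setMethod("show", "SurveyMatrix", function(object) {
    cat("SurveyMatrix '", object@surveyId, "': ", nrow(object@embedding),
        " patients x ", ncol(object@embedding), " dimensions\n", sep = "")
})
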