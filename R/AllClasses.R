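#' @import methods
NULL

#' Word-embedding table
#'
#' Maps vocabulary tokens to dense real vectors of a common dimension. Rows of
#' the underlying matrix are tokens, columns embedding dimensions.
#'
#' @slot vectors numeric matrix; rownames are the tokens.
#' @seealso [EmbeddingTable()], [readEmbeddings()], [trainEmbeddings()]
#' @exportClass EmbeddingTable
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
    v <- object@vectors
    if (!is.numeric(v)) return("'vectors' must be a numeric matrix")
    if (ncol(v) < 1L) return("embedding dimension must be >= 1")
    if (is.null(rownames(v)) || any(rownames(v) == ""))
        return("every row must be named by its token")
    if (anyDuplicated(rownames(v))) return("tokens must be unique")
    if (!all(is.finite(v))) return("embedding vectors must be finite")
    TRUE
})

#' Construct an EmbeddingTable
#'
#' @param vectors numeric matrix with one row per token (rownames = tokens)
#'   and one column per embedding dimension.
#' @return An [EmbeddingTable-class] object.
#' @examples
#' emb <- EmbeddingTable(matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL)))
#' embeddingDim(emb)
#' @export
EmbeddingTable <- function(vectors) {
    storage.mode(vectors) <- "double"
    colnames(vectors) <- NULL
    new("EmbeddingTable", vectors = vectors)
}

#' Inverse-document-frequency table
#'
#' Log-scaled rarity weights for tokens across a document corpus, together
#' with the number of documents the corpus contained.
#'
#' @slot nDocuments integer; number of documents the weights were computed on.
#' @slot weights named numeric; token -> nonnegative IDF weight.
#' @seealso [computeIdf()]
#' @exportClass IdfTable
setClass("IdfTable", representation(nDocuments = "integer", weights = "numeric"))

setValidity("IdfTable", function(object) {
    if (length(object@nDocuments) != 1L || object@nDocuments < 1L)
        return("'nDocuments' must be a single positive integer")
    w <- object@weights
    if (length(w) && (is.null(names(w)) || any(names(w) == "")))
        return("weights must be named by token")
    if (anyDuplicated(names(w))) return("tokens must be unique")
    if (!all(is.finite(w)) || any(w < 0))
        return("IDF weights must be finite and nonnegative")
    TRUE
})

#' Construct an IdfTable
#'
#' @param weights named numeric vector of nonnegative IDF weights.
#' @param nDocuments number of documents in the corpus.
#' @return An [IdfTable-class] object.
#' @export
IdfTable <- function(weights, nDocuments) {
    new("IdfTable", nDocuments = as.integer(nDocuments), weights = weights)
}

#' Questionnaire: an ordered set of ordinal-response questions
#'
#' Only ordinal-response items are represented: each question carries its
#' printed ordinal scale `[scaleMin, scaleMax]`.
#'
#' @slot surveyId single string naming the instrument.
#' @slot questions data.frame with columns `question_id`, `text`,
#'   `scale_min`, `scale_max`.
#' @exportClass Questionnaire
setClass("Questionnaire", representation(surveyId = "character", questions = "data.frame"))

setValidity("Questionnaire", function(object) {
    if (length(object@surveyId) != 1L || !nzchar(object@surveyId))
        return("'surveyId' must be a single non-empty string")
    q <- object@questions
    need <- c("question_id", "text", "scale_min", "scale_max")
    if (!all(need %in% names(q)))
        return(paste("questions must have columns:", paste(need, collapse = ", ")))
    if (nrow(q) < 1L) return("a questionnaire needs at least one question")
    if (anyDuplicated(q$question_id)) return("question ids must be unique within a survey")
    if (any(!nzchar(trimws(q$text)))) return("question text must be non-empty")
    if (any(q$scale_min >= q$scale_max)) return("scale_min must be < scale_max")
    TRUE
})

#' Construct a Questionnaire
#'
#' @param surveyId instrument name.
#' @param questions data.frame with columns `question_id`, `text`,
#'   `scale_min`, `scale_max`.
#' @return A [Questionnaire-class] object.
#' @export
Questionnaire <- function(surveyId, questions) {
    questions$question_id <- as.character(questions$question_id)
    questions$text <- as.character(questions$text)
    new("Questionnaire", surveyId = surveyId, questions = questions)
}

#' Patient-by-question ordinal response matrix
#'
#' Integer answers (NA = missing) with patients as rows and question ids as
#' columns. Range checks against a questionnaire's scales happen at embedding
#' time, when the two are brought together.
#'
#' @slot answers integer matrix; rownames patient ids, colnames question ids.
#' @exportClass ResponseMatrix
setClass("ResponseMatrix", representation(answers = "matrix"))

setValidity("ResponseMatrix", function(object) {
    a <- object@answers
    if (!is.numeric(a)) return("'answers' must be numeric")
    if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
        return("rows must carry unique patient ids")
    if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
        return("columns must carry unique question ids")
    if (any(a[!is.na(a)] != round(a[!is.na(a)])))
        return("answers must be integers (or NA)")
    TRUE
})

#' Construct a ResponseMatrix
#'
#' @param answers integer matrix with patient ids as rownames and question
#'   ids as colnames; NA marks a missing answer.
#' @return A [ResponseMatrix-class] object.
#' @export
ResponseMatrix <- function(answers) {
    storage.mode(answers) <- "double"
    new("ResponseMatrix", answers = answers)
}

#' Survey-level embedding matrix
#'
#' One d-dimensional embedding vector per patient for a single survey: row i
#' is the response-weighted sum of the survey's IDF-weighted question vectors.
#'
#' @slot surveyId single string.
#' @slot embedding numeric matrix, patients x d; rownames patient ids.
#' @exportClass SurveyMatrix
setClass("SurveyMatrix", representation(surveyId = "character", embedding = "matrix"))

setValidity("SurveyMatrix", function(object) {
    if (length(object@surveyId) != 1L) return("'surveyId' must be a single string")
    m <- object@embedding
    if (!is.numeric(m)) return("'embedding' must be numeric")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("rows must carry unique patient ids")
    if (!all(is.finite(m))) return("embedding entries must be finite")
    TRUE
})

#' Construct a SurveyMatrix
#'
#' @param surveyId survey name.
#' @param embedding patients x d numeric matrix (rownames = patient ids).
#' @return A [SurveyMatrix-class] object.
#' @export
SurveyMatrix <- function(surveyId, embedding) {
    storage.mode(embedding) <- "double"
    colnames(embedding) <- NULL
    new("SurveyMatrix", surveyId = surveyId, embedding = embedding)
}
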