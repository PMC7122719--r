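#' Read a questionnaire schema file
#'
#' Delimited file with columns `survey_id`, `question_id`, `text`,
#' `scale_min`, `scale_max`; one row per ordinal question, possibly several
#' surveys per file.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return Named list of [Questionnaire-class] objects, one per survey id.
#' @export
readQuestionnaires <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"")
    need <- c("survey_id", "question_id", "text", "scale_min", "scale_max")
    if (!all(need %in% names(df)))
        stop("schema file must have columns: ", paste(need, collapse = ", "))
    out <- lapply(split(df, df$survey_id), function(q)
        Questionnaire(q$survey_id[1L], q[setdiff(need, "survey_id")]))
    out[unique(df$survey_id)]
}

#' Read / write a patient response matrix as CSV
#'
#' CSV with a `patient_id` column plus one integer column per question id;
#' empty cells are missing answers.
#'
#' @param path file path.
#' @return `readResponses`: a [ResponseMatrix-class].
#' @export
readResponses <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"patient_id" %in% names(df)) stop("responses need a patient_id column")
    m <- as.matrix(df[setdiff(names(df), "patient_id")])
    rownames(m) <- df$patient_id
    ResponseMatrix(m)
}

#' @rdname readResponses
#' @param responses a [ResponseMatrix-class].
#' @export
writeResponses <- function(responses, path) {
    m <- as.matrix(responses)
    utils::write.csv(data.frame(patient_id = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE)
    invisible(path)
}

#' Write / read a survey-level embedding matrix as CSV
#'
#' Columns: `patient_id`, then `e1 .. ed`.
#'
#' @param sm a [SurveyMatrix-class].
#' @param path file path.
#' @export
writeSurveyMatrix <- function(sm, path) {
    m <- as.matrix(sm)
    colnames(m) <- paste0("e", seq_len(ncol(m)))
    utils::write.csv(data.frame(patient_id = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSurveyMatrix
#' @param surveyId survey name for the reconstructed object.
#' @export
readSurveyMatrix <- function(path, surveyId = "survey") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[setdiff(names(df), "patient_id")])
    rownames(m) <- df$patient_id
    SurveyMatrix(surveyId, m)
}

#' Read RDoC seed words
#'
#' Plain-text file, one domain per line: `domain<TAB>seed1 seed2 ...`.
#'
#' @param path file path.
#' @return Named list: domain -> character vector of seed tokens.
#' @export
readDomainSeeds <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(lines, "\t")
    bad <- vapply(parts, length, integer(1)) < 2L
    if (any(bad)) stop("malformed seed line(s): ", paste(lines[bad], collapse = "; "))
    seeds <- lapply(parts, function(p)
        strsplit(trimws(p[2L]), "[[:space:]]+")[[1L]])
    names(seeds) <- vapply(parts, `[`, character(1), 1L)
    if (anyDuplicated(names(seeds))) stop("duplicate domain names in seed file")
    if (any(vapply(seeds, length, integer(1)) < 1L))
        stop("every domain needs at least one seed token")
    seeds
}
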