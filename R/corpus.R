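#' Tokenize free text into lowercase unigrams
#'
#' Deterministic lexical normalizer: strips all punctuation (every character
#' that is neither alphanumeric nor whitespace), lowercases, and splits on
#' whitespace. An optional light suffix stripper (plural/gerund/past endings)
#' stands in for heavier lexical normalization; it is off by default so that
#' tokens match pretrained vocabularies verbatim.
#'
#' Idempotent: preprocessing the space-joined output returns the same tokens.
#'
#' @param raw character string (possibly empty).
#' @param stem logical; strip common inflectional suffixes ("...ies" -> "...y",
#'   trailing "s" (not "ss"), "ing"/"ed" on stems of length >= 3).
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' preprocessText("I felt scared, without any good reason.")
#' @export
preprocessText <- function(raw, stem = FALSE) {
    if (length(raw) != 1L) stop("'raw' must be a single string")
    if (is.na(raw)) return(character(0))
    x <- tolower(raw)
    x <- gsub("[^[:alnum:][:space:]]+", " ", x)
    toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (stem && length(toks)) toks <- vapply(toks, stemToken, character(1), USE.NAMES = FALSE)
    toks
}

stemToken <- function(tok) {
    if (grepl("ies$", tok) && nchar(tok) > 4L) return(sub("ies$", "y", tok))
    if (grepl("ing$", tok) && nchar(tok) > 5L) return(sub("ing$", "", tok))
    if (grepl("ed$", tok) && nchar(tok) > 4L) return(sub("ed$", "", tok))
    if (grepl("[^s]s$", tok) && nchar(tok) > 3L) return(sub("s$", "", tok))
    tok
}

#' Tokenize a corpus of documents
#'
#' @param docs character vector, one document per element; empty documents
#'   (no tokens after preprocessing) are dropped with a message reporting the
#'   count.
#' @param stem passed to [preprocessText()].
#' @return List of token vectors, one per retained document.
#' @export
tokenizeCorpus <- function(docs, stem = FALSE) {
    toks <- lapply(docs, preprocessText, stem = stem)
    empty <- vapply(toks, length, integer(1)) == 0L
    if (any(empty))
        message(sum(empty), " empty document(s) dropped after preprocessing")
    toks[!empty]
}

#' Inverse document frequency over a corpus
#'
#' For each token with document frequency df out of N documents, the classic
#' variant assigns `ln(N / df)` (so a token present in every document gets
#' weight 0); the smoothed variant assigns `ln((1 + N) / (1 + df)) + 1`.
#'
#' @param docs character vector of raw documents, or a list of pre-tokenized
#'   documents (character vectors).
#' @param variant `"classic"` (default) or `"smooth"`.
#' @param stem passed to the tokenizer when `docs` is raw text.
#' @return An [IdfTable-class]; tokens absent from the corpus are simply not
#'   in the table.
#' @examples
#' idf <- computeIdf(c("a b", "a c"))
#' idfWeight(idf, c("a", "b", "zzz"))
#' @export
computeIdf <- function(docs, variant = c("classic", "smooth"), stem = FALSE) {
    variant <- match.arg(variant)
    toks <- if (is.list(docs)) docs else tokenizeCorpus(docs, stem = stem)
    if (!length(toks)) stop("corpus contains no documents")
    df <- table(unlist(lapply(toks, unique), use.names = FALSE))
    n <- length(toks)
    w <- if (variant == "classic") log(n / as.numeric(df))
         else log((1 + n) / (1 + as.numeric(df))) + 1
    names(w) <- names(df)
    IdfTable(w, n)
}

#' Train word embeddings by skip-gram with negative sampling
#'
#' Trains dense word vectors on a tokenized corpus with the standard
#' skip-gram objective: each centre token predicts its context tokens within
#' a dynamically shrunk window, contrasted against noise tokens drawn from
#' the unigram distribution raised to the 3/4 power. Training is
#' single-threaded with an internal seeded RNG, so a given seed reproduces
#' the table bit for bit.
#'
#' Defaults mirror common large-corpus settings for this kind of model:
#' 500 dimensions, window 10, 10 negative samples, minimum total token
#' frequency 100, 5 epochs.
#'
#' @param docs character vector of raw documents or list of token vectors.
#' @param dimension embedding dimension d.
#' @param window maximum context window (actual window per position is
#'   uniform on 1..window).
#' @param negative number of noise tokens per observed pair.
#' @param minCount minimum total corpus frequency for a token to enter the
#'   vocabulary.
#' @param epochs passes over the corpus.
#' @param alpha initial learning rate, decayed linearly to `alpha/10000`.
#' @param seed integer seed for the internal RNG.
#' @param stem passed to the tokenizer when `docs` is raw text.
#' @return An [EmbeddingTable-class] with one row per vocabulary token.
#' @export
trainEmbeddings <- function(docs, dimension = 500L, window = 10L, negative = 10L,
                            minCount = 100L, epochs = 5L, alpha = 0.025,
                            seed = 1L, stem = FALSE) {
    stopifnot(dimension >= 1L, window >= 1L, negative >= 1L,
              minCount >= 1L, epochs >= 1L, alpha > 0)
    toks <- if (is.list(docs)) docs else tokenizeCorpus(docs, stem = stem)
    freq <- table(unlist(toks, use.names = FALSE))
    vocab <- names(freq)[freq >= minCount]
    if (!length(vocab))
        stop("no token reaches the minimum frequency of ", minCount)
    vocab <- sort(vocab)
    counts <- as.numeric(freq[vocab])
    idx <- seq_along(vocab); names(idx) <- vocab
    sent <- lapply(toks, function(tt) {
        m <- idx[tt[tt %in% vocab]]
        as.integer(unname(m) - 1L)
    })
    sent <- sent[vapply(sent, length, integer(1)) >= 2L]
    if (!length(sent))
        stop("no document retains >= 2 in-vocabulary tokens")
    vecs <- sgns_train(sent, length(vocab), as.integer(dimension),
                       as.integer(window), as.integer(negative),
                       as.integer(epochs), alpha, counts, as.integer(seed))
    rownames(vecs) <- vocab
    EmbeddingTable(vecs)
}

#' Read / write embeddings in word2vec plain-text format
#'
#' The format is a header line `"<vocab> <dim>"` followed by one line per
#' token: the token then `dim` space-separated floats. `writeEmbeddings`
#' prints components with enough digits that a write/read round trip
#' reproduces the table to within 1e-6 per component.
#'
#' @param path file path.
#' @return `readEmbeddings`: an [EmbeddingTable-class].
#' @export
readEmbeddings <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty embedding file")
    hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
        stop("malformed header: expected '<vocab> <dim>'")
    nv <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (length(body) != nv)
        stop("header announces ", nv, " tokens but file has ", length(body), " rows")
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) != d + 1L)
    if (length(bad))
        stop("row ", bad[1L], " has wrong length: expected token + ", d, " floats")
    toks <- vapply(parts, `[`, character(1), 1L)
    if (anyDuplicated(toks))
        stop("duplicate tokens in embedding file: ",
             paste(unique(toks[duplicated(toks)]), collapse = ", "))
    vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(d))
    m <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
    rownames(m) <- toks
    EmbeddingTable(m)
}

#' @rdname readEmbeddings
#' @param table an [EmbeddingTable-class].
#' @export
writeEmbeddings <- function(table, path) {
    m <- as.matrix(table)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(m), ncol(m)), con)
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste(rownames(m)[i], paste(formatC(m[i, ], format = "g", digits = 9),
                                    collapse = " ")), character(1))
    writeLines(rows, con)
    invisible(path)
}
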