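# Fixtures built in code; every stochastic fixture takes an explicit seed.

tinyEmbedding <- function(vectors = rbind(a = c(1, 0), b = c(0, 1))) {
    EmbeddingTable(vectors)
}

tinyIdf <- function(weights = c(a = 1, b = 2), n = 10L) {
    IdfTable(weights, n)
}

# random embedding + idf + questionnaire + responses for property tests
randomSurveyFixture <- function(seed, nPatients = 25L, nQuestions = 6L,
                                d = 8L, vocabPerQ = 4L, levels = 5L) {
    set.seed(seed)
    vocab <- paste0("w", seq_len(nQuestions * vocabPerQ))
    vecs <- matrix(rnorm(length(vocab) * d), length(vocab), d,
                   dimnames = list(vocab, NULL))
    emb <- EmbeddingTable(vecs)
    idf <- IdfTable(setNames(runif(length(vocab), 0.2, 3), vocab), 100L)
    qid <- sprintf("Q%02d", seq_len(nQuestions))
    txt <- vapply(seq_len(nQuestions), function(j)
        paste(sample(vocab, vocabPerQ, replace = TRUE), collapse = " "),
        character(1))
    qn <- Questionnaire("S1", data.frame(
        question_id = qid, text = txt, scale_min = 0L,
        scale_max = levels - 1L))
    a <- matrix(sample(0:(levels - 1L), nPatients * nQuestions, replace = TRUE),
                nPatients, nQuestions,
                dimnames = list(sprintf("P%03d", seq_len(nPatients)), qid))
    list(emb = emb, idf = idf, qn = qn, responses = ResponseMatrix(a))
}

# independent oracle: survey embedding by explicit loops over
# (patient, question, token) -- never uses the matrix implementation
tripleLoopSurvey <- function(qn, responses, emb, idf) {
    a <- as.matrix(responses)
    q <- qn@questions
    d <- embeddingDim(emb)
    V <- as.matrix(emb)
    w <- setNames(idf@weights, names(idf@weights))
    out <- matrix(0, nrow(a), d, dimnames = list(rownames(a), NULL))
    for (i in seq_len(nrow(a))) {
        for (j in seq_len(nrow(q))) {
            toks <- preprocessText(q$text[j])
            qv <- numeric(d)
            for (tk in toks) {
                if (tk %in% rownames(V) && tk %in% names(w))
                    qv <- qv + w[[tk]] * V[tk, ]
            }
            out[i, ] <- out[i, ] + a[i, q$question_id[j]] * qv
        }
    }
    out
}

# independent oracle: AUC by enumerating every (positive, negative) pair
bruteAuc <- function(prob, labels) {
    pos <- prob[labels == 1]; neg <- prob[labels == 0]
    s <- 0
    for (p in pos) for (q in neg)
        s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    s / (length(pos) * length(neg))
}

smallStudy <- function(seed = 42L, n = 120L, effectSize = 2, d = 30L,
                       vocab = 200L) {
    simulateStudy(simConfig(nPatients = n, embedDim = d, vocabSize = vocab,
                            effectSize = effectSize, seed = seed))
}
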