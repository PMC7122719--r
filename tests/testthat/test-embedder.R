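test_that("embedQuestion is the IDF-weighted token sum, repeats counted", {
    emb <- tinyEmbedding(); idf <- tinyIdf()
    expect_equal(embedQuestion("a b", emb, idf), c(1, 2))
    expect_equal(embedQuestion("a a b", emb, idf), c(2, 2))
    expect_warning(v <- embedQuestion("zzz yyy", emb, idf), "out of vocabulary")
    expect_equal(v, c(0, 0))
})

test_that("embedSurvey weights question vectors by the ordinal answers", {
    emb <- tinyEmbedding(); idf <- tinyIdf(c(a = 1, b = 1))
    qn <- Questionnaire("S", data.frame(
        question_id = c("q1", "q2"), text = c("a", "b"),
        scale_min = 0L, scale_max = 4L))
    resp <- ResponseMatrix(matrix(c(3, 0, 4, 0), 2, 2,
                                  dimnames = list(c("p1", "p2"), c("q1", "q2"))))
    sm <- embedSurvey(qn, resp, emb, idf)
    expect_s4_class(sm, "SurveyMatrix")
    expect_equal(as.matrix(sm)["p1", ], c(3, 4))   # linear combination
    expect_equal(as.matrix(sm)["p2", ], c(0, 0))   # all-zero answers
})

test_that("raising one answer from 1 to 2 adds exactly one question vector", {
    fx <- randomSurveyFixture(101)
    a1 <- as.matrix(fx$responses)
    a1[] <- 1
    a2 <- a1
    lastQ <- ncol(a2)
    a2["P001", lastQ] <- 2
    s1 <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a1), fx$emb, fx$idf))
    s2 <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a2), fx$emb, fx$idf))
    qv <- questionVectors(fx$qn, fx$emb, fx$idf)
    expect_equal(s2["P001", ] - s1["P001", ], unname(qv[lastQ, ]),
                 tolerance = 1e-12)
    expect_identical(s2[-1, ], s1[-1, ])   # other patients untouched
})

test_that("embedSurvey validates question ids, ranges, and empty patients", {
    fx <- randomSurveyFixture(7)
    a <- as.matrix(fx$responses)
    colnames(a)[1] <- "rogue"
    expect_error(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf),
                 "rogue")
    a <- as.matrix(fx$responses)
    a[2, 3] <- 99
    expect_error(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf),
                 "out of scale")
    a <- as.matrix(fx$responses)
    a[4, ] <- NA
    expect_error(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf),
                 "P004")
})

test_that("missing-answer policies behave as documented", {
    fx <- randomSurveyFixture(13)
    a <- as.matrix(fx$responses)
    a[1, 2] <- NA
    med <- round(median(a[-1, 2]))
    s_med <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf))
    a_imp <- a; a_imp[1, 2] <- med
    s_ref <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a_imp), fx$emb, fx$idf))
    expect_equal(s_med, s_ref)
    a_zero <- a; a_zero[1, 2] <- 0
    s_zero <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf,
                                    missing = "zero"))
    expect_equal(s_zero,
                 as.matrix(embedSurvey(fx$qn, ResponseMatrix(a_zero), fx$emb, fx$idf)))
    s_drop <- embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf,
                          missing = "drop")
    expect_false("P001" %in% patientIds(s_drop))
})

test_that("survey embedding is linear in the answers", {
    for (seed in c(21, 22)) {
        fx <- randomSurveyFixture(seed)
        a <- as.matrix(fx$responses)
        s1 <- as.matrix(embedSurvey(fx$qn, ResponseMatrix(a), fx$emb, fx$idf))
        # homogeneity: doubling a patient's answers doubles the row
        a2 <- a; a2[3, ] <- 2 * a2[3, ]
        qn2 <- fx$qn; qn2@questions$scale_max <- 2L * qn2@questions$scale_max
        s2 <- as.matrix(embedSurvey(qn2, ResponseMatrix(a2), fx$emb, fx$idf))
        expect_equal(s2[3, ], 2 * s1[3, ])
        # additivity over answer matrices
        b <- matrix(sample(0:2, length(a), replace = TRUE), nrow(a),
                    dimnames = dimnames(a))
        sb <- as.matrix(embedSurvey(qn2, ResponseMatrix(b), fx$emb, fx$idf))
        sab <- as.matrix(embedSurvey(qn2, ResponseMatrix(a + b), fx$emb, fx$idf))
        expect_equal(sab, s1 + sb, tolerance = 1e-12)
        # permutation equivariance: question order is irrelevant
        perm <- sample(ncol(a))
        qnp <- Questionnaire("S1", fx$qn@questions[perm, ])
        sp <- as.matrix(embedSurvey(qnp, ResponseMatrix(a[, perm]), fx$emb, fx$idf))
        expect_equal(sp, s1, tolerance = 1e-12)
    }
})

test_that("buildAllSurveys enforces one patient roster and its order", {
    fx1 <- randomSurveyFixture(31)
    qn2 <- fx1$qn
    qn2@surveyId <- "S2"
    qn2@questions$question_id <- paste0("S2", qn2@questions$question_id)
    a2 <- as.matrix(fx1$responses)
    colnames(a2) <- qn2@questions$question_id
    out <- buildAllSurveys(list(fx1$qn, qn2),
                           list(S1 = fx1$responses, S2 = ResponseMatrix(a2)),
                           fx1$emb, fx1$idf)
    expect_named(out, c("S1", "S2"))
    expect_identical(patientIds(out$S1), patientIds(out$S2))
    expect_equal(dim(as.matrix(out$S1)), c(25L, 8L))
    # roster mismatch names the symmetric difference
    a3 <- a2[-7, ]
    expect_error(buildAllSurveys(list(fx1$qn, qn2),
                                 list(S1 = fx1$responses, S2 = ResponseMatrix(a3)),
                                 fx1$emb, fx1$idf),
                 "P007")
})
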