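test_that("pcaScores recovers variance structure and fixes signs", {
    set.seed(1)
    # rank-1 matrix: first component carries all the variance
    u <- rnorm(30); v <- rnorm(6)
    r1 <- pcaScores(outer(u, v), nComponents = 2)
    expect_gt(r1$evr[1], 1 - 1e-10)
    expect_true(all(diff(r1$evr) <= 1e-12))
    # sign convention: largest-|loading| entry positive
    expect_true(all(apply(r1$loadings, 2, function(l) l[which.max(abs(l))] >= 0)))
    # isotropic data: every ratio near 1/d
    x <- matrix(rnorm(2000 * 5), 2000, 5)
    ri <- pcaScores(x, nComponents = 2)
    expect_true(all(abs(ri$evr - 1 / 5) < 0.03))
    # rotation invariance of the spectrum
    q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    rr <- pcaScores(x %*% q, nComponents = 2)
    expect_equal(rr$evr, ri$evr, tolerance = 1e-8)
    expect_error(pcaScores(matrix(1, 10, 3), 1), "zero variance")
})

test_that("pcaScores agrees with an eigendecomposition oracle", {
    for (seed in 1:3) {
        set.seed(seed)
        x <- matrix(rnorm(20 * 6), 20, 6)
        p <- pcaScores(x, nComponents = 3)
        xc <- scale(x, center = TRUE, scale = FALSE)
        e <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
        oracleScores <- xc %*% e$vectors[, 1:3]
        for (k in 1:3) {
            expect_equal(e$values[k] / sum(e$values), p$evr[k], tolerance = 1e-8)
            agree <- min(max(abs(oracleScores[, k] - p$scores[, k])),
                         max(abs(oracleScores[, k] + p$scores[, k])))
            expect_lt(agree, 1e-8)   # equal up to sign
        }
    }
})

test_that("first canonical correlation is maximal and bounded", {
    set.seed(5)
    n <- 200
    x <- matrix(rnorm(n * 4), n, 4)
    y <- matrix(rnorm(n * 5), n, 5)
    y[, 3] <- x[, 2]    # shared direction
    cc <- ccaFirstVariable(x, y)
    expect_equal(cc$rho, 1, tolerance = 1e-8)
    # maximality over all single pairs, on several fixtures
    for (seed in 6:8) {
        set.seed(seed)
        x <- matrix(rnorm(150 * 3), 150, 3)
        y <- 0.5 * x[, c(1, 2, 3, 1)] + matrix(rnorm(150 * 4), 150, 4)
        cc <- ccaFirstVariable(x, y)
        expect_true(cc$rho >= max(abs(stats::cor(x, y))) - 1e-10)
        expect_true(cc$rho >= 0 && cc$rho <= 1)
        # independent oracle: stats::cancor on the standardized blocks
        oracle <- stats::cancor(scale(x), scale(y))$cor[1]
        expect_equal(cc$rho, oracle, tolerance = 1e-6)
    }
    # independent blocks: first canonical correlation stays small
    set.seed(9)
    xi <- matrix(rnorm(2000 * 2), 2000, 2)
    yi <- matrix(rnorm(2000 * 13), 2000, 13)
    expect_lt(ccaFirstVariable(xi, yi)$rho, 0.15)
    expect_error(ccaFirstVariable(matrix(rnorm(20), 10, 2),
                                  matrix(rnorm(130), 10, 13)),
                 "fewer components")
})

test_that("canonical correlation is invariant to affine maps of either block", {
    set.seed(10)
    n <- 120
    x <- matrix(rnorm(n * 3), n, 3)
    y <- 0.4 * x[, c(1, 1, 2, 3)] + matrix(rnorm(n * 4), n, 4)
    base <- ccaFirstVariable(x, y)$rho
    A <- matrix(rnorm(9), 3, 3) + diag(3)
    B <- matrix(rnorm(16), 4, 4) + diag(4)
    shifted <- sweep(x %*% A, 2, c(5, -2, 7), "+")
    expect_equal(ccaFirstVariable(shifted, y)$rho, base, tolerance = 1e-6)
    expect_equal(ccaFirstVariable(x, y %*% B)$rho, base, tolerance = 1e-6)
})

test_that("RDoC domain vectors are IDF-weighted seed averages", {
    emb <- tinyEmbedding(); idf <- tinyIdf(c(a = 1, b = 1))
    expect_equal(rdocDomainVector("a", emb, idf), c(1, 0))
    expect_equal(rdocDomainVector(c("a", "b"), emb, idf), c(0.5, 0.5))
    idf2 <- tinyIdf(c(a = 1, b = 3))
    expect_equal(rdocDomainVector(c("a", "b"), emb, idf2), c(0.25, 0.75))
    expect_error(rdocDomainVector(c("nope"), emb, idf, domain = "valence"),
                 "valence")
})

test_that("RDoC patient vectors are |weight|-normalized question averages", {
    q <- rbind(c(1, 0), c(0, 1))
    dv <- c(1, 0)
    # single question, answer 1, cosine 1 -> the question vector itself
    expect_equal(rdocPatientVector(c(1, 0), q, dv), c(1, 0))
    expect_warning(z <- rdocPatientVector(c(0, 0), q, dv), "zero")
    expect_equal(z, c(0, 0))
    # weights 1 and 3 on orthogonal unit questions
    qd <- rbind(c(1, 0), c(0, 1))
    dv2 <- c(1, 1) / sqrt(2)
    pv <- rdocPatientVector(c(1, 3), qd, dv2)
    w <- c(1, 3) * c(cos(pi / 4), cos(pi / 4))
    expect_equal(pv, (w[1] * qd[1, ] + w[2] * qd[2, ]) / sum(abs(w)))
    expect_equal(pv, c(0.25, 0.75))
})

test_that("rdocScore is a cosine with the zero-vector convention", {
    v <- c(1, 2, 3)
    expect_equal(rdocScore(v, v), 1)
    expect_equal(rdocScore(c(1, 0), c(0, 1)), 0)
    expect_equal(rdocScore(v, -v), -1)
    expect_equal(rdocScore(c(0, 0), v[1:2]), 0)
    # invariance to positive rescaling of either argument
    set.seed(2)
    for (i in 1:5) {
        a <- rnorm(6); b <- rnorm(6)
        s <- rdocScore(a, b)
        expect_equal(rdocScore(a * runif(1, 0.1, 9), b), s, tolerance = 1e-12)
        expect_equal(rdocScore(a, b * runif(1, 0.1, 9)), s, tolerance = 1e-12)
    }
})

test_that("RDoC scores track their own latent domain on synthetic cohorts", {
    st <- smallStudy(seed = 77L, n = 150L)
    sc <- rdocScores(st$cohort$questionnaires, st$cohort$responses,
                     st$space$emb, st$space$idf, st$space$seeds)
    z <- st$cohort$truth$z
    expect_identical(sc$patient_id, rownames(z))
    co <- cor(as.matrix(sc[-1]), z)
    for (k in seq_len(ncol(z)))
        expect_gt(co[k, k], max(co[k, -k]))   # diagonally dominant rows
})

test_that("scoreTable assembles named PC and CCV columns", {
    st <- smallStudy(seed = 5L, n = 60L)
    tab <- scoreTable(st$surveys, nPcs = 2, dsm = st$cohort$dsm)
    expect_true(all(c("SVY01_PC1", "SVY01_PC2", "SVY01_CCV1",
                      "SVY09_CCV1") %in% names(tab)))
    expect_equal(nrow(tab), 60L)
    expect_true(all(vapply(tab[-1], function(x) all(is.finite(x)), logical(1))))
    expect_false(anyDuplicated(names(tab)) > 0)
})
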