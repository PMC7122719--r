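test_that("contrastLabels maps the three groups onto both binary contrasts", {
    g <- c("case", "control", "supercontrol", "case")
    expect_equal(contrastLabels(g, "C_vs_CS"), c(1L, 0L, 0L, 1L))
    expect_equal(contrastLabels(g, "CC_vs_S"), c(1L, 1L, 0L, 1L))
    expect_error(contrastLabels(c("case", "patient")), "patient")
})

test_that("two-component GMM recovers well-separated generating components", {
    set.seed(8)
    n <- 100
    x <- rbind(matrix(rnorm(n * 2, mean = -5), n, 2),
               matrix(rnorm(n * 2, mean = 5), n, 2))
    truth <- rep(1:2, each = n)
    fit <- fitGmmBinary(x)
    expect_equal(rowSums(fit$posterior), rep(1, 2 * n), tolerance = 1e-12)
    hard <- fit$classification
    acc <- max(mean(hard == truth), mean(hard == 3 - truth))
    expect_gte(acc, 0.99)
})

test_that("alignClusters orients posteriors so AUC is at least 0.5", {
    y <- c(1, 1, 0, 0)
    p <- c(0.1, 0.2, 0.9, 0.8)               # perfectly anti-aligned
    expect_equal(aucRank(p, y), 0)
    a <- alignClusters(p, y)
    expect_equal(aucRank(a, y), 1)
    expect_equal(a, 1 - p)
    pneutral <- c(0.5, 0.5, 0.5, 0.5)        # tie: orientation unchanged
    expect_identical(alignClusters(pneutral, y), pneutral)
    set.seed(4)
    for (i in 1:10) {
        pr <- runif(40); yy <- sample(0:1, 40, replace = TRUE, prob = c(.4, .6))
        expect_gte(aucRank(alignClusters(pr, yy), yy), 0.5)
    }
    # null behaviour at large n: oriented AUC barely above chance
    set.seed(5)
    pr <- runif(4000); yy <- rep(0:1, 2000)
    expect_lt(aucRank(alignClusters(pr, yy), yy), 0.6)
})

test_that("classificationMetrics matches hand-computed confusion and AUC", {
    p <- c(0.9, 0.8, 0.3, 0.1); y <- c(1, 0, 1, 0)
    m <- classificationMetrics(p, y)
    expect_equal(unname(m["AUC"]), 0.75)
    expect_equal(unname(m["ACC"]), 0.5)
    expect_equal(unname(m["FPR"]), 0.5)
    expect_equal(unname(m["FNR"]), 0.5)
    perfect <- classificationMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
    expect_equal(unname(perfect), c(1, 1, 0, 0))
    expect_equal(unname(classificationMetrics(rep(0.5, 4), c(1, 0, 1, 0))["AUC"]),
                 0.5)   # all-tied scores
    expect_error(classificationMetrics(c(.2, .3), c(1, 1)), "both classes")
})

test_that("rank-statistic AUC equals brute-force pair enumeration", {
    set.seed(11)
    for (i in 1:20) {
        n <- sample(5:50, 1)
        prob <- round(runif(n), 2)            # rounding forces ties
        y <- sample(0:1, n, replace = TRUE)
        if (length(unique(y)) < 2) next
        expect_identical(aucRank(prob, y), bruteAuc(prob, y))
    }
})

test_that("ACC identity and CI ordering hold for every bootstrap cell", {
    st <- smallStudy(seed = 19L, n = 90L)
    f <- featureMatrix("1PC", st$surveys)
    y <- contrastLabels(st$cohort$groups, "CC_vs_S")
    for (method in c("gmm", "logistic")) {
        be <- bootstrapEvaluate(f, y, method, B = 8, seed = 2)
        s <- be$summary
        expect_true(all(s$lo <= s$mean + 1e-12 & s$mean <= s$hi + 1e-12))
        expect_true(all(s$mean >= 0 & s$mean <= 1))
        r <- be$replicates
        n1 <- sum(y == 1); n0 <- sum(y == 0)
        expect_equal(r[, "ACC"],
                     1 - (r[, "FPR"] * n0 + r[, "FNR"] * n1) / (n0 + n1),
                     tolerance = 1e-12)
    }
})

test_that("bootstrapEvaluate is reproducible and identical across runs", {
    st <- smallStudy(seed = 23L, n = 80L)
    f <- featureMatrix("2PC", st$surveys)
    y <- contrastLabels(st$cohort$groups, "C_vs_CS")
    a <- bootstrapEvaluate(f, y, "logistic", B = 5, seed = 77)
    b <- bootstrapEvaluate(f, y, "logistic", B = 5, seed = 77)
    expect_identical(a$replicates, b$replicates)
})

test_that("out-of-fold logistic metrics ignore patient ordering", {
    st <- smallStudy(seed = 29L, n = 80L)
    f <- featureMatrix("2PC", st$surveys)
    y <- contrastLabels(st$cohort$groups, "C_vs_CS")
    p1 <- psychembed:::logisticOofProb(f, y, foldSeed = 5)
    perm <- sample(nrow(f))
    p2 <- psychembed:::logisticOofProb(f[perm, ], y[perm], foldSeed = 5)
    expect_equal(p2, p1[perm], tolerance = 1e-9)
})

test_that("permutation test returns exact extremes and valid p-values", {
    expect_equal(permutationTestMeans(c(1, 2, 3), c(1, 2, 3), nPerm = 999), 1)
    a <- rnorm(50, mean = 10); b <- rnorm(50, mean = 0)
    expect_lte(permutationTestMeans(a, b, nPerm = 999), 0.002)
    expect_error(permutationTestMeans(1, c(1, 2)), "at least 2")
    set.seed(3)
    p <- permutationTestMeans(rnorm(30), rnorm(30), nPerm = 199, seed = 4)
    expect_true(p > 0 && p <= 1)
})

test_that("tSNE projection separates separated clusters and is seeded", {
    set.seed(6)
    x <- rbind(matrix(rnorm(40 * 5, mean = 0), 40, 5),
               matrix(rnorm(40 * 5, mean = 8), 40, 5))
    yy <- tsneProject(x, perplexity = 10, maxIter = 250, seed = 3)
    expect_equal(dim(yy), c(80L, 2L))
    d <- as.matrix(dist(yy))
    grp <- rep(1:2, each = 40)
    within <- mean(d[grp == 1, grp == 1])
    between <- mean(d[grp == 1, grp == 2])
    expect_gt(between, within)
    yy2 <- tsneProject(x, perplexity = 10, maxIter = 250, seed = 3)
    expect_identical(yy, yy2)
    expect_error(tsneProject(x[1:20, ], perplexity = 10), "perplexity")
})

test_that("featureMatrix produces the documented feature-space widths", {
    st <- smallStudy(seed = 37L, n = 60L)
    expect_equal(ncol(featureMatrix("1PC", st$surveys)), 9L)
    expect_equal(ncol(featureMatrix("2PC", st$surveys)), 18L)
    expect_equal(ncol(featureMatrix("CCV", st$surveys, dsm = st$cohort$dsm)), 9L)
    raw <- featureMatrix("raw", st$cohort$responses)
    expect_equal(ncol(raw), 90L)     # nine 10-question instruments
    expect_error(featureMatrix("CCV", st$surveys), "symptom matrix")
})
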