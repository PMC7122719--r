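#' Binary diagnostic contrasts over the three a-priori groups
#'
#' Maps the three cohort groups (case / control / supercontrol) to a binary
#' outcome: `"C_vs_CS"` contrasts cases against controls plus supercontrols;
#' `"CC_vs_S"` contrasts cases plus controls against supercontrols.
#'
#' @param groups character vector of group labels, values in
#'   `c("case", "control", "supercontrol")`.
#' @param contrast `"C_vs_CS"` or `"CC_vs_S"`.
#' @return Integer vector of 0/1 labels (1 = positive class).
#' @export
contrastLabels <- function(groups, contrast = c("C_vs_CS", "CC_vs_S")) {
    contrast <- match.arg(contrast)
    bad <- setdiff(unique(groups), c("case", "control", "supercontrol"))
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    pos <- if (contrast == "C_vs_CS") "case" else c("case", "control")
    as.integer(groups %in% pos)
}

zscoreCols <- function(x, center = NULL, scale = NULL) {
    if (is.null(center)) center <- colMeans(x)
    if (is.null(scale)) {
        scale <- apply(x, 2L, stats::sd)
        scale[scale == 0] <- 1
    }
    sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' Two-component Gaussian mixture posteriors
#'
#' Fits a two-cluster Gaussian mixture by EM (full covariance first, falling
#' back to more constrained covariance structures if the full model is
#' degenerate) on column-standardized features, and returns each patient's
#' posterior probability of belonging to cluster 1.
#'
#' @param features patients x p numeric matrix.
#' @param modelNames covariance structures to try, in order.
#' @return List with `posterior` (n x 2, rows sum to 1), `classification`,
#'   and `model` (the chosen covariance structure).
#' @export
fitGmmBinary <- function(features, modelNames = c("VVV", "VVI", "EEE", "EII")) {
    xr <- as.matrix(features)
    ctr <- colMeans(xr)
    scl <- apply(xr, 2L, stats::sd); scl[scl == 0] <- 1
    x <- zscoreCols(xr, ctr, scl)
    fit <- NULL
    for (mn in modelNames) {
        fit <- suppressWarnings(
            mclust::Mclust(x, G = 2, modelNames = mn, verbose = FALSE))
        if (!is.null(fit) && all(is.finite(fit$z))) break
    }
    if (is.null(fit))
        stop("EM failed to fit a two-component mixture under all covariance models")
    if (min(table(factor(fit$classification, levels = 1:2))) < 2L)
        warning("degenerate mixture: a cluster holds fewer than 2 patients")
    z <- fit$z / rowSums(fit$z)
    list(posterior = z, classification = fit$classification,
         model = fit$modelName, fit = fit, center = ctr, scale = scl)
}

#' Rank-statistic AUC with tie averaging
#'
#' @param prob numeric scores (higher = more case-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
aucRank <- function(prob, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(prob, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Orient mixture posteriors toward the positive class
#'
#' A mixture fit does not know which cluster is the "case" cluster; this
#' picks the orientation whose in-sample AUC against the labels is >= 0.5.
#' At exactly 0.5 the orientation is left unchanged (cluster 1 = case).
#'
#' @param posterior n x 2 posterior matrix (or a vector of cluster-1
#'   probabilities).
#' @param labels 0/1 labels.
#' @return Numeric vector: oriented case probability per patient.
#' @export
alignClusters <- function(posterior, labels) {
    p <- if (is.matrix(posterior)) posterior[, 1L] else posterior
    if (aucRank(p, labels) < 0.5) p <- 1 - p
    p
}

#' Threshold classification metrics
#'
#' Accuracy, AUC, false positive rate and false negative rate for
#' probabilistic predictions: ACC/FPR/FNR from the confusion matrix at the
#' probability threshold (a patient is called positive when its probability
#' exceeds the threshold), AUC by the rank statistic with ties averaged.
#'
#' @param prob case probabilities in [0, 1].
#' @param labels 0/1 labels, both classes present.
#' @param threshold classification threshold (default 0.5).
#' @return Named numeric vector: `ACC`, `AUC`, `FPR`, `FNR`.
#' @export
classificationMetrics <- function(prob, labels, threshold = 0.5) {
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L) stop("both classes must be present")
    if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
    pred <- as.integer(prob > threshold)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    fpr <- sum(pred == 1L & labels == 0L) / n0
    fnr <- sum(pred == 0L & labels == 1L) / n1
    acc <- mean(pred == labels)
    c(ACC = acc, AUC = aucRank(prob, labels), FPR = fpr, FNR = fnr)
}

logisticOofProb <- function(features, labels, folds = 10L, foldSeed = 1L,
                            lambda = 1e-3, groupIds = NULL) {
    # groupIds: fold assignment unit. In bootstrap replicates the copies of
    # one resampled patient share a groupId, so they never straddle a
    # train/test split (which would leak and inflate out-of-fold metrics).
    x <- as.matrix(features); y <- labels
    n <- nrow(x)
    if (is.null(groupIds))
        groupIds <- if (!is.null(rownames(x))) rownames(x) else seq_len(n)
    rng <- splitRng(foldSeed)
    ug <- sort(unique(groupIds))   # stable: invariant to patient order
    gcl <- y[match(ug, groupIds)]
    gfold <- integer(length(ug))
    for (cl in unique(gcl)) {   # stratified fold assignment over patients
        i <- which(gcl == cl)
        gfold[i] <- rep_len(1:folds, length(i))[order(rngUnif(rng, length(i)))]
    }
    fold <- gfold[match(groupIds, ug)]
    prob <- numeric(n)
    for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        if (!any(te)) next
        if (length(unique(y[tr])) < 2L) stop("fold lost a class")
        ctr <- colMeans(x[tr, , drop = FALSE])
        scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd); scl[scl == 0] <- 1
        xtr <- zscoreCols(x[tr, , drop = FALSE], ctr, scl)
        xte <- zscoreCols(x[te, , drop = FALSE], ctr, scl)
        fit <- glmnet::glmnet(xtr, y[tr], family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE)
        prob[te] <- as.numeric(stats::predict(fit, xte, type = "response"))
    }
    prob
}

# Small deterministic RNG (Lehmer/MINSTD) independent of R's global RNG
# stream: fold assignment stays reproducible regardless of surrounding code.
splitRng <- function(seed) {
    e <- new.env(parent = emptyenv())
    e$s <- (as.double(abs(seed)) %% 2147483646) + 1
    e
}
rngUnif <- function(rng, n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
        rng$s <- (rng$s * 48271) %% 2147483647
        out[i] <- rng$s / 2147483647
    }
    out
}

#' Bootstrap evaluation of a diagnostic contrast
#'
#' Repeats the chosen classifier over `B` bootstrap replicates (patients
#' resampled with replacement, stratified by class so both classes survive)
#' and reports the bootstrap mean and percentile 95% CI of ACC, AUC, FPR and
#' FNR at the 0.5 threshold.
#'
#' Methods: `"gmm"` fits a two-component Gaussian mixture per replicate and
#' scores it in-sample after label alignment (set `outOfBag = TRUE` to score
#' the out-of-bag patients instead — the honest null-calibration mode);
#' `"logistic"` runs stratified 10-fold cross-validated ridge-regularized
#' logistic regression inside each replicate and scores out-of-fold
#' predictions.
#'
#' @param features patients x p numeric matrix.
#' @param labels 0/1 labels (see [contrastLabels()]).
#' @param method `"gmm"` or `"logistic"`.
#' @param B bootstrap replicates (the reference analysis uses 500).
#' @param folds CV folds for the logistic method.
#' @param seed integer seed.
#' @param outOfBag for `"gmm"`: evaluate on out-of-bag patients.
#' @param threshold classification threshold.
#' @return List with `summary` (data.frame: metric, mean, lo, hi) and
#'   `replicates` (B x 4 matrix of per-replicate metrics).
#' @export
bootstrapEvaluate <- function(features, labels, method = c("gmm", "logistic"),
                              B = 500L, folds = 10L, seed = 1L,
                              outOfBag = FALSE, threshold = 0.5) {
    method <- match.arg(method)
    x <- as.matrix(features); y <- as.integer(labels)
    if (length(unique(y)) < 2L) stop("both classes must be present")
    set.seed(seed)
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    reps <- matrix(NA_real_, B, 4L,
                   dimnames = list(NULL, c("ACC", "AUC", "FPR", "FNR")))
    for (b in seq_len(B)) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        xb <- x[idx, , drop = FALSE]; yb <- y[idx]
        if (method == "gmm") {
            fit <- suppressWarnings(fitGmmBinary(xb))
            if (outOfBag) {
                oob <- setdiff(seq_len(nrow(x)), unique(idx))
                if (length(unique(y[oob])) < 2L) next
                # orient on the bootstrap sample, score the held-out patients
                flip <- aucRank(fit$posterior[, 1L], yb) < 0.5
                post <- predictGmm(fit, x[oob, , drop = FALSE])
                p <- if (flip) 1 - post else post
                reps[b, ] <- classificationMetrics(p, y[oob], threshold)
            } else {
                p <- alignClusters(fit$posterior, yb)
                reps[b, ] <- classificationMetrics(p, yb, threshold)
            }
        } else {
            p <- logisticOofProb(xb, yb, folds = folds,
                                 foldSeed = (seed * 131L + b) %% 2147483647L,
                                 groupIds = idx)
            reps[b, ] <- classificationMetrics(p, yb, threshold)
        }
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    s <- data.frame(metric = colnames(reps),
                    mean = colMeans(reps),
                    lo = apply(reps, 2L, stats::quantile, 0.025),
                    hi = apply(reps, 2L, stats::quantile, 0.975),
                    row.names = NULL)
    list(summary = s, replicates = reps)
}

# posterior prob of component 1 for new points under a fitted binary mixture
predictGmm <- function(fit, xnew) {
    xn <- zscoreCols(as.matrix(xnew), fit$center, fit$scale)
    pr <- mclust::predict.Mclust(fit$fit, newdata = xn)
    z <- pr$z / rowSums(pr$z)
    z[, 1L]
}

#' Permutation test for a difference in bootstrap-mean metrics
#'
#' Two-sided test of the difference between the means of two samples of
#' replicate-level metric values (for example, embedding-feature AUCs versus
#' raw-score AUCs over bootstrap replicates), by shuffling replicate values
#' between the two groups.
#'
#' @param a,b numeric vectors of replicate metrics (length >= 2 each).
#' @param nPerm number of permutations (>= 999 recommended).
#' @param seed integer seed.
#' @return Two-sided p-value `(1 + #(|d*| >= |d|)) / (nPerm + 1)`.
#' @export
permutationTestMeans <- function(a, b, nPerm = 999L, seed = 1L) {
    if (length(a) < 2L || length(b) < 2L)
        stop("need at least 2 values per group")
    set.seed(seed)
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b); na <- length(a); n <- length(pool)
    tot <- sum(pool)
    perm <- replicate(nPerm, {
        sa <- sum(pool[sample.int(n, na)])
        abs(sa / na - (tot - sa) / (n - na))
    })
    (1 + sum(perm >= obs - 1e-15)) / (nPerm + 1)
}

#' t-SNE projection to two dimensions
#'
#' Exact (dense) t-distributed stochastic neighbour embedding: input
#' affinities from a per-point perplexity calibration, Student-t low-
#' dimensional kernel, gradient descent with momentum and early
#' exaggeration. Quadratic in n, intended for cohort-scale inputs; the
#' reference workflow projects the 18 leading survey PCs for display with
#' mixture contours.
#'
#' @param features n x p matrix.
#' @param perplexity effective neighbourhood size; must be < n / 3.
#' @param maxIter gradient-descent iterations.
#' @param seed integer seed (initial layout).
#' @return n x 2 coordinate matrix.
#' @export
tsneProject <- function(features, perplexity = 30, maxIter = 400L, seed = 1L) {
    x <- as.matrix(features)
    n <- nrow(x)
    if (perplexity >= n / 3) stop("perplexity must be < n/3")
    d2 <- as.matrix(stats::dist(x))^2
    P <- matrix(0, n, n)
    logU <- log(perplexity)
    for (i in seq_len(n)) {      # binary search for each point's bandwidth
        beta <- 1; bmin <- -Inf; bmax <- Inf
        di <- d2[i, -i]
        for (it in 1:50) {
            p <- exp(-di * beta); s <- sum(p)
            if (s == 0) { H <- 0; p <- rep(1 / length(di), length(di)) }
            else { p <- p / s; H <- -sum(p * log(pmax(p, 1e-300))) }
            if (abs(H - logU) < 1e-5) break
            if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
            else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
        }
        P[i, -i] <- p
    }
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P, 1e-12)
    set.seed(seed)
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    eta <- 200
    for (it in seq_len(maxIter)) {
        ex <- if (it <= 100) 4 else 1     # early exaggeration
        qd <- 1 / (1 + as.matrix(stats::dist(Y))^2)
        diag(qd) <- 0
        Q <- pmax(qd / sum(qd), 1e-12)
        W <- (ex * P - Q) * qd
        grad <- 4 * (diag(rowSums(W)) - W) %*% Y
        dir <- sign(grad) == sign(G)
        gains <- ifelse(dir, gains * 0.8, gains + 0.2)
        gains <- pmax(gains, 0.01)
        mom <- if (it <= 100) 0.5 else 0.8
        G <- mom * G - eta * gains * grad
        Y <- Y + G
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- c("tSNE1", "tSNE2")
    Y
}

#' Assemble classifier feature matrices from survey-level data
#'
#' Builds the feature sets of the diagnostic-contrast analysis from a list
#' of per-survey patient matrices (embedding matrices, or raw ordinal
#' matrices for the benchmark): `"1PC"`/`"2PC"` take the leading 1 or 2 PCs
#' of each survey (9 or 18 features for nine instruments), `"CCV"` takes
#' each survey's first canonical variable against the symptom matrix (9
#' features), `"raw"` concatenates the columns unchanged.
#'
#' @param matrices named list of patients x * matrices (or
#'   [SurveyMatrix-class] objects), shared patient order.
#' @param type `"CCV"`, `"1PC"`, `"2PC"`, or `"raw"`.
#' @param dsm symptom matrix, required for `"CCV"`.
#' @return Patients x features numeric matrix with named columns.
#' @export
featureMatrix <- function(type = c("2PC", "1PC", "CCV", "raw"), matrices,
                          dsm = NULL) {
    type <- match.arg(type)
    ms <- lapply(matrices, function(m) if (is(m, "SurveyMatrix")) as.matrix(m) else as.matrix(m))
    if (type == "raw") {
        out <- do.call(cbind, lapply(names(ms), function(nm) {
            m <- ms[[nm]]
            colnames(m) <- paste0(nm, "_", if (is.null(colnames(ms[[nm]])))
                seq_len(ncol(m)) else colnames(ms[[nm]]))
            m
        }))
        return(out)
    }
    if (type == "CCV") {
        if (is.null(dsm)) stop("CCV features require the symptom matrix")
        cols <- lapply(names(ms), function(nm) {
            p <- pcaScores(ms[[nm]], nComponents = choosePcCount(
                pcaScores(ms[[nm]], 1L)$evr))
            ccaFirstVariable(p$scores, as.matrix(dsm))$scores
        })
        out <- do.call(cbind, cols)
        colnames(out) <- paste0(names(ms), "_CCV1")
        return(out)
    }
    k <- if (type == "1PC") 1L else 2L
    cols <- lapply(names(ms), function(nm) {
        s <- pcaScores(ms[[nm]], nComponents = k)$scores
        colnames(s) <- paste0(nm, "_PC", seq_len(k))
        s
    })
    do.call(cbind, cols)
}
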