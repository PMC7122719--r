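#' Spearman rank-correlation matrix with p-values
#'
#' Rank correlation between every predictor column (survey PCs or RDoC
#' scores) and every outcome column (neurocognitive measures), with tie
#' correction and two-sided p-values. Cells use pairwise-complete
#' observations; a cell with fewer than 3 complete pairs, or a constant
#' column, is left missing. Significance stars mark p < 0.1 (*), < 0.05
#' (**), < 0.01 (***).
#'
#' @param predictors data.frame or matrix of predictor columns.
#' @param outcomes data.frame or matrix of outcome columns, same row order.
#' @return Long-format data.frame: `predictor`, `outcome`, `rho`, `p`, `n`,
#'   `stars`.
#' @export
spearmanMatrix <- function(predictors, outcomes) {
    px <- as.data.frame(predictors); oy <- as.data.frame(outcomes)
    if (nrow(px) != nrow(oy)) stop("row counts differ")
    res <- expand.grid(predictor = names(px), outcome = names(oy),
                       stringsAsFactors = FALSE)
    res$rho <- NA_real_; res$p <- NA_real_; res$n <- NA_integer_
    for (i in seq_len(nrow(res))) {
        x <- px[[res$predictor[i]]]; y <- oy[[res$outcome[i]]]
        ok <- stats::complete.cases(x, y)
        res$n[i] <- sum(ok)
        if (sum(ok) < 3L) next
        x <- x[ok]; y <- y[ok]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        ct <- suppressWarnings(
            stats::cor.test(x, y, method = "spearman", exact = FALSE))
        res$rho[i] <- unname(ct$estimate)
        res$p[i] <- ct$p.value
    }
    res$stars <- ifelse(is.na(res$p), "",
                 ifelse(res$p < 0.01, "***",
                 ifelse(res$p < 0.05, "**",
                 ifelse(res$p < 0.1, "*", ""))))
    res
}

#' Log-transform skewed outcome columns
#'
#' Columns whose sample skewness exceeds the threshold in absolute value are
#' replaced by `ln(x - min(x) + 1)` (the shift guards nonpositive values).
#' Constant columns have skewness treated as 0 and are left unchanged.
#'
#' @param outcomes data.frame of numeric outcome columns.
#' @param skewThreshold absolute skewness above which a column is
#'   transformed (default 1).
#' @return List with `outcomes` (transformed data.frame) and `transformed`
#'   (character vector of the columns that were log-transformed).
#' @export
logTransformSkewed <- function(outcomes, skewThreshold = 1) {
    out <- as.data.frame(outcomes)
    hit <- character(0)
    for (nm in names(out)) {
        x <- out[[nm]]
        ok <- !is.na(x)
        if (sum(ok) < 3L || stats::sd(x[ok]) == 0) next
        g1 <- e1071::skewness(x[ok], type = 3)
        if (is.finite(g1) && abs(g1) > skewThreshold) {
            out[[nm]][ok] <- log(x[ok] - min(x[ok]) + 1)
            hit <- c(hit, nm)
        }
    }
    list(outcomes = out, transformed = hit)
}

#' LASSO regression with the penalty chosen by AIC
#'
#' Fits the L1 path (at least 50 log-spaced penalties, via glmnet) on
#' z-scored predictors and a centred outcome, then picks the path point
#' minimizing `AIC = n * ln(RSS / n) + 2 * df`, where df is the number of
#' nonzero coefficients (the standard LARS-style df estimate). Deterministic
#' given X and y.
#'
#' @param X patients x p predictor matrix (e.g. the 18 leading survey PCs).
#' @param y numeric outcome; rows with missing y are dropped listwise.
#' @param nlambda path length.
#' @param lambda optional fixed penalty overriding the AIC choice (0 gives
#'   the ordinary least-squares limit).
#' @return List with `coefficients` (named, on the z-scored predictor
#'   scale), `lambda` (chosen penalty), `aic` (the AIC path), `active`
#'   (names of nonzero coefficients).
#' @export
lassoAicFit <- function(X, y, nlambda = 100L, lambda = NULL) {
    X <- as.matrix(X)
    ok <- stats::complete.cases(X, y)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    n <- length(y)
    if (n <= 2L) stop("need more than 2 complete observations")
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
    Xs <- zscoreCols(X, ctr, scl)
    yc <- y - mean(y)
    fit <- glmnet::glmnet(Xs, yc, alpha = 1, nlambda = nlambda,
                          standardize = FALSE, intercept = FALSE)
    if (!is.null(lambda)) {
        # refit with the requested penalty on the path (warm-started descent)
        lam <- sort(unique(c(fit$lambda, lambda)), decreasing = TRUE)
        fit2 <- glmnet::glmnet(Xs, yc, alpha = 1, lambda = lam,
                               standardize = FALSE, intercept = FALSE,
                               thresh = 1e-12)
        beta <- as.numeric(stats::coef(fit2, s = lambda)[-1L])
        names(beta) <- colnames(X)
        return(list(coefficients = beta, lambda = lambda, aic = NA_real_,
                    active = names(beta)[beta != 0],
                    center = ctr, scale = scl, intercept = mean(y)))
    }
    pred <- stats::predict(fit, Xs)
    rss <- colSums((yc - pred)^2)
    df <- fit$df
    aic <- n * log(rss / n) + 2 * df
    best <- which.min(aic)
    beta <- as.numeric(fit$beta[, best])
    names(beta) <- colnames(X)
    list(coefficients = beta, lambda = fit$lambda[best], aic = aic,
         active = names(beta)[beta != 0],
         center = ctr, scale = scl, intercept = mean(y))
}

predictLassoAic <- function(fit, Xnew) {
    Xs <- zscoreCols(as.matrix(Xnew), fit$center, fit$scale)
    as.numeric(Xs %*% fit$coefficients) + fit$intercept
}

#' Cross-validated rank correlation of LASSO predictions
#'
#' For each bootstrap replicate: resample patients with replacement, run
#' k-fold cross-validation refitting the AIC-tuned LASSO inside every
#' training fold, pool the out-of-fold predictions, and take the Spearman
#' correlation between predicted and observed outcome. Reports the mean and
#' percentile 95% CI over replicates. A replicate whose pooled predictions
#' are constant contributes rho = 0 and is counted in `flagged`.
#'
#' @param X predictor matrix.
#' @param y numeric outcome.
#' @param folds CV folds per replicate (default 10).
#' @param B bootstrap replicates (the reference analysis uses 500).
#' @param seed integer seed.
#' @return List with `mean`, `lo`, `hi`, `replicates`, `flagged`.
#' @export
cvRankCorrelation <- function(X, y, folds = 10L, B = 500L, seed = 1L) {
    X <- as.matrix(X)
    ok <- stats::complete.cases(X, y)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    n <- length(y)
    set.seed(seed)
    rhos <- numeric(B); flagged <- 0L
    for (b in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        fold <- rep_len(seq_len(folds), n)[sample.int(n)]
        pred <- numeric(n)
        for (f in seq_len(folds)) {
            tr <- fold != f
            fitf <- lassoAicFit(xb[tr, , drop = FALSE], yb[tr])
            pred[!tr] <- predictLassoAic(fitf, xb[!tr, , drop = FALSE])
        }
        if (stats::sd(pred) == 0) { rhos[b] <- 0; flagged <- flagged + 1L }
        else rhos[b] <- stats::cor(pred, yb, method = "spearman")
    }
    list(mean = mean(rhos),
         lo = unname(stats::quantile(rhos, 0.025)),
         hi = unname(stats::quantile(rhos, 0.975)),
         replicates = rhos, flagged = flagged)
}

#' Export regression coefficients as a tidy table
#'
#' Long-format (outcome, feature, coefficient) table from a named list of
#' [lassoAicFit()] results, zero coefficients included as explicit rows —
#' ready for heatmap plotting or CSV export.
#'
#' @param fits named list of fits (names = outcome names).
#' @return data.frame with columns `outcome`, `feature`, `coefficient`.
#' @export
coefficientTable <- function(fits) {
    do.call(rbind, lapply(names(fits), function(nm) {
        b <- fits[[nm]]$coefficients
        data.frame(outcome = nm, feature = names(b), coefficient = unname(b),
                   row.names = NULL)
    }))
}
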