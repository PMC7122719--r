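cosineSim <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
}

fixSigns <- function(scores, loadings) {
    # deterministic orientation: component's largest-|loading| entry positive
    for (k in seq_len(ncol(loadings))) {
        j <- which.max(abs(loadings[, k]))
        if (loadings[j, k] < 0) {
            loadings[, k] <- -loadings[, k]
            scores[, k] <- -scores[, k]
        }
    }
    list(scores = scores, loadings = loadings)
}

#' Principal-component scores of a survey matrix
#'
#' Column-centres the matrix and projects onto the leading right singular
#' directions. Component signs are fixed deterministically (the
#' largest-magnitude loading is made positive) so repeated and bootstrap
#' runs are comparable.
#'
#' @param m a [SurveyMatrix-class] or plain numeric matrix (patients x d).
#' @param nComponents number of leading components to return.
#' @return List with `scores` (patients x nComponents), `evr`
#'   (explained-variance ratios, non-increasing), and `loadings` (d x
#'   nComponents).
#' @export
pcaScores <- function(m, nComponents = 2L) {
    x <- if (is(m, "SurveyMatrix")) as.matrix(m) else m
    if (nComponents > min(nrow(x), ncol(x)))
        stop("nComponents exceeds min(#patients, dimension)")
    if (all(apply(x, 2L, stats::sd) == 0)) stop("zero variance: matrix is constant")
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    evr <- p$sdev^2 / sum(p$sdev^2)
    k <- seq_len(nComponents)
    fixed <- fixSigns(p$x[, k, drop = FALSE], p$rotation[, k, drop = FALSE])
    scores <- fixed$scores
    rownames(scores) <- rownames(x)
    colnames(scores) <- paste0("PC", k)
    list(scores = scores, evr = evr, loadings = fixed$loadings)
}

#' First canonical correlation variable against a symptom matrix
#'
#' Finds the linear combination of the leading embedding PCs maximally
#' correlated with a linear combination of the 13-domain self-rated symptom
#' matrix. Both blocks are column-standardized and the block covariances
#' ridge-regularized (1e-8) before the whitened cross-covariance is
#' decomposed, so rank-deficient blocks do not fail.
#'
#' @param pcs patients x k matrix of leading PC scores.
#' @param dsm patients x q symptom matrix (the paper's setting has q = 13),
#'   same patient order.
#' @param ridge ridge added to each block covariance diagonal.
#' @return List with `scores` (the first canonical variable of the PC block,
#'   length n, sign-fixed), `rho` (first canonical correlation, in [0,1]),
#'   and `xcoef` (the canonical direction in PC space).
#' @export
ccaFirstVariable <- function(pcs, dsm, ridge = 1e-8) {
    x <- as.matrix(pcs); y <- as.matrix(dsm)
    if (nrow(x) != nrow(y)) stop("patient rosters differ between blocks")
    n <- nrow(x)
    if (ncol(x) > n - 1L || ncol(y) > n - 1L)
        stop("more variables than n - 1 in a block; use fewer components")
    zs <- function(m) {
        s <- apply(m, 2L, stats::sd)
        s[s == 0] <- 1
        scale(m, center = TRUE, scale = s)
    }
    x <- zs(x); y <- zs(y)
    sxx <- crossprod(x) / (n - 1) + diag(ridge, ncol(x))
    syy <- crossprod(y) / (n - 1) + diag(ridge, ncol(y))
    sxy <- crossprod(x, y) / (n - 1)
    isq <- function(s) {
        e <- eigen(s, symmetric = TRUE)
        e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), ncol(s)) %*% t(e$vectors)
    }
    k <- isq(sxx) %*% sxy %*% isq(syy)
    sv <- svd(k)
    rho <- min(max(sv$d[1L], 0), 1)
    a <- isq(sxx) %*% sv$u[, 1L]
    j <- which.max(abs(a))
    if (a[j] < 0) a <- -a
    scores <- as.numeric(x %*% a)
    names(scores) <- rownames(pcs)
    list(scores = scores, rho = rho, xcoef = as.numeric(a))
}

#' Choose how many leading PCs feed the canonical analysis
#'
#' Data-adaptive default: the smallest number of components explaining at
#' least `target` of the variance, capped at `cap`.
#'
#' @param evr explained-variance ratios from [pcaScores()].
#' @param target cumulative variance target (default 0.8).
#' @param cap upper bound on the count (default 10).
#' @return Integer component count (>= 1).
#' @export
choosePcCount <- function(evr, target = 0.8, cap = 10L) {
    k <- which(cumsum(evr) >= target)[1L]
    if (is.na(k)) k <- length(evr)
    max(1L, min(k, cap, length(evr)))
}

#' RDoC domain reference vector from seed words
#'
#' IDF-weighted average of the embedding vectors of the domain's seed words:
#' `sum(idf_w * v_w) / sum(idf_w)` over in-vocabulary seeds.
#'
#' @param seeds character vector of seed tokens for one domain.
#' @param emb an [EmbeddingTable-class].
#' @param idf an [IdfTable-class].
#' @param domain domain name, used in error messages.
#' @return Numeric vector of length `embeddingDim(emb)`.
#' @export
rdocDomainVector <- function(seeds, emb, idf, domain = "domain") {
    keep <- seeds[seeds %in% tokens(emb) & seeds %in% tokens(idf)]
    if (!length(keep))
        stop("all seed words out of vocabulary for domain '", domain, "'")
    w <- idfWeight(idf, keep)
    v <- embeddingVector(emb, keep)
    as.numeric(crossprod(v, w)) / sum(w)
}

#' Patient vector for one RDoC domain
#'
#' Weighted average of question vectors pooled across all surveys, with
#' weight `w_j = a_j * cos(q_j, domainVec)` — the patient's ordinal answer
#' times the cosine similarity between the question and the domain reference
#' vector. Because cosine weights can be negative, the normalizer is the sum
#' of absolute weights: `sum(w_j * q_j) / sum(|w_j|)`.
#'
#' @param answers numeric vector of the patient's ordinal answers, one per
#'   pooled question (NA treated as 0 contribution).
#' @param qvecs pooled question-vector matrix (questions x d), rows aligned
#'   with `answers`.
#' @param domainVec domain reference vector from [rdocDomainVector()].
#' @return Numeric vector of length d; zero vector (with a warning) when all
#'   weights vanish.
#' @export
rdocPatientVector <- function(answers, qvecs, domainVec) {
    stopifnot(length(answers) == nrow(qvecs))
    a <- ifelse(is.na(answers), 0, answers)
    cosj <- apply(qvecs, 1L, cosineSim, y = domainVec)
    w <- a * cosj
    denom <- sum(abs(w))
    if (denom == 0) {
        warning("all question weights zero; returning zero patient vector")
        return(numeric(ncol(qvecs)))
    }
    as.numeric(crossprod(qvecs, w)) / denom
}

#' RDoC score: cosine between patient and domain vectors
#'
#' @param patientVec patient domain vector.
#' @param domainVec domain reference vector.
#' @return Cosine similarity in [-1, 1]; 0 if either vector is zero.
#' @export
rdocScore <- function(patientVec, domainVec) cosineSim(patientVec, domainVec)

#' RDoC domain scores for a cohort
#'
#' Pools the ordinal answers and question vectors of all questionnaires
#' (the default pooled-across-surveys mode; set `perSurvey = TRUE` to score
#' each survey separately and average), then scores every patient against
#' every domain.
#'
#' @param questionnaires list of [Questionnaire-class] objects.
#' @param responses list of [ResponseMatrix-class], parallel to
#'   `questionnaires`; identical patient order assumed (see
#'   [buildAllSurveys()]).
#' @param emb,idf embedding and IDF tables.
#' @param seeds named list: domain -> character vector of seed words.
#' @param missing missing-answer policy, as in [embedSurvey()].
#' @param perSurvey score per survey then average, instead of pooling.
#' @param stem passed to the tokenizer.
#' @return data.frame with `patient_id` and one `RDoC_<domain>` column per
#'   domain.
#' @export
rdocScores <- function(questionnaires, responses, emb, idf, seeds,
                       missing = "median", perSurvey = FALSE, stem = FALSE) {
    ids <- vapply(questionnaires, surveyId, character(1))
    if (!is.null(names(responses))) responses <- responses[ids]
    pts <- patientIds(responses[[1L]])
    qv <- list(); ans <- list()
    for (k in seq_along(questionnaires)) {
        qn <- questionnaires[[k]]
        a <- as.matrix(responses[[k]])[pts, questionIds(qn), drop = FALSE]
        a <- imputeAnswers(a, missing)
        qv[[k]] <- questionVectors(qn, emb, idf, stem = stem)
        ans[[k]] <- a
    }
    dvecs <- lapply(names(seeds), function(dn)
        rdocDomainVector(seeds[[dn]], emb, idf, domain = dn))
    names(dvecs) <- names(seeds)
    scoreBlock <- function(qmat, amat) {
        vapply(names(dvecs), function(dn) {
            dv <- dvecs[[dn]]
            vapply(seq_len(nrow(amat)), function(i) {
                pv <- suppressWarnings(rdocPatientVector(amat[i, ], qmat, dv))
                rdocScore(pv, dv)
            }, numeric(1))
        }, numeric(nrow(amat)))
    }
    if (perSurvey) {
        blocks <- lapply(seq_along(qv), function(k) scoreBlock(qv[[k]], ans[[k]]))
        sc <- Reduce(`+`, blocks) / length(blocks)
    } else {
        sc <- scoreBlock(do.call(rbind, qv), do.call(cbind, ans))
    }
    sc <- matrix(sc, nrow = length(pts),
                 dimnames = list(NULL, paste0("RDoC_", names(dvecs))))
    data.frame(patient_id = pts, sc, check.names = FALSE)
}

#' Derived score table for a cohort
#'
#' Assembles the low-dimensional patient scores: per-survey leading PCs
#' (`<survey>_PC1`, ...), and — when a symptom matrix is supplied — the first
#' canonical correlation variable per survey (`<survey>_CCV1`), obtained by
#' correlating each survey's leading PCs (adaptive count, see
#' [choosePcCount()]) with the symptom block.
#'
#' @param surveys named list of [SurveyMatrix-class] (see
#'   [buildAllSurveys()]), shared patient order.
#' @param nPcs PCs kept per survey in the score table.
#' @param dsm optional patients x 13 symptom matrix (rownames = patient ids,
#'   or same order as the surveys).
#' @param ccaPcTarget,ccaPcCap passed to [choosePcCount()] for the CCA block.
#' @return data.frame with `patient_id` and the named score columns.
#' @export
scoreTable <- function(surveys, nPcs = 2L, dsm = NULL,
                       ccaPcTarget = 0.8, ccaPcCap = 10L) {
    pts <- patientIds(surveys[[1L]])
    out <- data.frame(patient_id = pts)
    for (nm in names(surveys)) {
        if (!identical(patientIds(surveys[[nm]]), pts))
            stop("surveys do not share a patient ordering")
        p <- pcaScores(surveys[[nm]], nComponents = nPcs)
        cols <- p$scores
        colnames(cols) <- paste0(nm, "_PC", seq_len(nPcs))
        out <- cbind(out, cols)
        if (!is.null(dsm)) {
            dd <- as.matrix(dsm)
            if (!is.null(rownames(dd))) dd <- dd[pts, , drop = FALSE]
            k <- choosePcCount(p$evr, target = ccaPcTarget, cap = ccaPcCap)
            full <- pcaScores(surveys[[nm]], nComponents = k)
            cc <- ccaFirstVariable(full$scores, dd)
            out[[paste0(nm, "_CCV1")]] <- cc$scores
        }
    }
    rownames(out) <- NULL
    out
}
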