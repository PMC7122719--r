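#' Configuration for the synthetic study generator
#'
#' Encodes the study conditions the generator emulates: a three-group cohort
#' (case / control / supercontrol) answering nine multi-question ordinal
#' instruments, driven by latent per-domain severities, with a 13-column
#' DSM-style self-rated symptom matrix and outcome measures linearly tied to
#' the latent severities. Defaults mirror the reference cohort where stated
#' (310 patients, 9 surveys, 5 domains) and scale the embedding space down
#' (d = 50, vocabulary 500) so full pipelines run in seconds; paper-scale
#' d = 500 is reachable by configuration.
#'
#' @param nPatients cohort size.
#' @param groupProportions named proportions for case, control,
#'   supercontrol; must sum to 1.
#' @param nDomains latent symptom domains (5 = the original RDoC domains).
#' @param nSurveys number of instruments.
#' @param questionsPerSurvey ordinal questions per instrument.
#' @param vocabSize tokens in the synthetic embedding space.
#' @param embedDim embedding dimension.
#' @param effectSize latent mean shift Delta: case groups are shifted by
#'   Delta, controls by Delta/2, supercontrols not at all, on affected
#'   domains.
#' @param affectedDomains indices of domains carrying the group shift
#'   (default: all).
#' @param ordinalLevels answers take values 0 .. ordinalLevels - 1.
#' @param noiseSd sd of the answer-level noise around the latent severity.
#' @param seed integer master seed; every generator draw derives from it.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nPatients = 310L,
                      groupProportions = c(case = 0.64, control = 0.12,
                                           supercontrol = 0.24),
                      nDomains = 5L, nSurveys = 9L, questionsPerSurvey = 10L,
                      vocabSize = 500L, embedDim = 50L, effectSize = 2,
                      affectedDomains = NULL, ordinalLevels = 5L,
                      noiseSd = 1, seed = 1L) {
    if (is.null(affectedDomains)) affectedDomains <- seq_len(nDomains)
    cfg <- list(nPatients = as.integer(nPatients),
                groupProportions = groupProportions,
                nDomains = as.integer(nDomains),
                nSurveys = as.integer(nSurveys),
                questionsPerSurvey = as.integer(questionsPerSurvey),
                vocabSize = as.integer(vocabSize),
                embedDim = as.integer(embedDim),
                effectSize = effectSize,
                affectedDomains = as.integer(affectedDomains),
                ordinalLevels = as.integer(ordinalLevels),
                noiseSd = noiseSd, seed = as.integer(seed))
    stopifnot(cfg$nPatients > 0, cfg$nDomains > 0, cfg$nSurveys > 0,
              cfg$questionsPerSurvey > 0, cfg$vocabSize > 0,
              cfg$embedDim > 0, cfg$ordinalLevels >= 2, cfg$noiseSd > 0,
              cfg$effectSize >= 0)
    if (!setequal(names(groupProportions), c("case", "control", "supercontrol")))
        stop("groupProportions must be named case/control/supercontrol")
    if (abs(sum(groupProportions) - 1) > 1e-8)
        stop("group proportions must sum to 1")
    if (cfg$vocabSize < cfg$nDomains * 10L)
        stop("vocabSize must be at least 10 tokens per domain")
    class(cfg) <- "SimConfig"
    cfg
}

rdocDomainNames <- function(n) {
    base <- c("negative_valence", "positive_valence", "cognitive_systems",
              "social_processes", "arousal_regulatory")
    if (n <= length(base)) base[seq_len(n)]
    else c(base, paste0("domain", seq_len(n - length(base)) + length(base)))
}

#' Synthetic semantic embedding space
#'
#' Partitions the vocabulary into domain topics around near-orthogonal unit
#' centroids; each token's vector is its topic centroid plus isotropic
#' Gaussian noise, so related tokens cluster (within-topic cosines exceed
#' between-topic cosines). IDF weights are drawn log-uniformly; the seed
#' words of each domain are the tokens closest to its centroid.
#'
#' @param cfg a [simConfig()].
#' @param seedsPerDomain seed words exported per domain.
#' @param tokenNoise sd multiplier for token scatter around the centroid
#'   (per-coordinate sd is `tokenNoise / sqrt(d)`).
#' @return List: `emb` ([EmbeddingTable-class]), `idf` ([IdfTable-class]),
#'   `seeds` (named list domain -> tokens), `centroids`, `tokenDomain`,
#'   `domains`.
#' @export
makeEmbeddingSpace <- function(cfg, seedsPerDomain = 5L, tokenNoise = 0.7) {
    set.seed(cfg$seed)
    d <- cfg$embedDim; D <- cfg$nDomains; V <- cfg$vocabSize
    domains <- rdocDomainNames(D)
    centroids <- qr.Q(qr(matrix(stats::rnorm(d * D), d, D)))  # orthonormal
    toks <- sprintf("tok%04d", seq_len(V))
    tokenDomain <- rep_len(seq_len(D), V)
    noise <- matrix(stats::rnorm(V * d, sd = tokenNoise / sqrt(d)), V, d)
    vecs <- t(centroids[, tokenDomain]) + noise
    rownames(vecs) <- toks
    idfW <- exp(stats::runif(V, log(0.5), log(5)))
    names(idfW) <- toks
    seeds <- lapply(seq_len(D), function(k) {
        i <- which(tokenDomain == k)
        cs <- vecs[i, , drop = FALSE] %*% centroids[, k] /
            sqrt(rowSums(vecs[i, , drop = FALSE]^2))
        toks[i[order(-cs)][seq_len(min(seedsPerDomain, length(i)))]]
    })
    names(seeds) <- domains
    list(emb = EmbeddingTable(vecs),
         idf = IdfTable(idfW, nDocuments = V),
         seeds = seeds, centroids = centroids,
         tokenDomain = tokenDomain, domains = domains)
}

#' Synthetic cohort: latent severities, questionnaires, answers, symptoms
#'
#' Latent severity `z[i, k] ~ N(mu_group, 1)` per domain, with
#' `mu = Delta, Delta/2, 0` for cases, controls and supercontrols on
#' affected domains. Question texts are sampled from their domain's topic
#' tokens; ordinal answers follow a graded-threshold model — the latent
#' severity of the question's domain plus Gaussian noise, discretized into
#' the ordinal levels by fixed population thresholds. The 13-column
#' DSM-style matrix is a noisy linear map of z.
#'
#' @param cfg a [simConfig()].
#' @param space output of [makeEmbeddingSpace()].
#' @param tokensPerQuestion length of each sampled question text.
#' @return List: `questionnaires` (list of [Questionnaire-class]),
#'   `responses` (named list of [ResponseMatrix-class]), `dsm` (patients x
#'   13 matrix), `groups` (named character vector), `truth` (list: `z`,
#'   `questionDomain`, `groups`).
#' @export
makeCohort <- function(cfg, space, tokensPerQuestion = 8L) {
    set.seed(cfg$seed + 1L)
    n <- cfg$nPatients; D <- cfg$nDomains; L <- cfg$ordinalLevels
    pid <- sprintf("P%04d", seq_len(n))
    prop <- cfg$groupProportions[c("case", "control", "supercontrol")]
    counts <- floor(prop * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]] + 1L
    groups <- sample(rep(names(counts), counts))
    names(groups) <- pid
    mu <- c(case = cfg$effectSize, control = cfg$effectSize / 2, supercontrol = 0)
    z <- matrix(stats::rnorm(n * D), n, D,
                dimnames = list(pid, space$domains))
    for (k in cfg$affectedDomains) z[, k] <- z[, k] + mu[groups]
    # fixed population thresholds for the graded ordinal model
    pooledMean <- if (length(cfg$affectedDomains))
        sum(mu * prop) else 0
    thr <- stats::qnorm(seq_len(L - 1) / L, mean = pooledMean,
                        sd = sqrt(1 + cfg$noiseSd^2))
    toks <- tokens(space$emb)
    questionnaires <- list(); responses <- list()
    questionDomain <- list()
    for (s in seq_len(cfg$nSurveys)) {
        sid <- sprintf("SVY%02d", s)
        qdom <- rep_len(seq_len(D), cfg$questionsPerSurvey)
        qid <- sprintf("%s_Q%02d", sid, seq_len(cfg$questionsPerSurvey))
        txt <- vapply(qdom, function(k) {
            paste(sample(toks[space$tokenDomain == k], tokensPerQuestion,
                         replace = TRUE), collapse = " ")
        }, character(1))
        qn <- Questionnaire(sid, data.frame(
            question_id = qid, text = txt,
            scale_min = 0L, scale_max = L - 1L))
        u <- z[, qdom, drop = FALSE] +
            matrix(stats::rnorm(n * length(qid), sd = cfg$noiseSd), n)
        a <- matrix(findInterval(u, thr), n,
                    dimnames = list(pid, qid))
        questionnaires[[sid]] <- qn
        responses[[sid]] <- ResponseMatrix(a)
        questionDomain[[sid]] <- stats::setNames(qdom, qid)
    }
    dsmDomain <- rep_len(seq_len(D), 13L)
    dsm <- z[, dsmDomain, drop = FALSE] * 0.9 +
        matrix(stats::rnorm(n * 13L, sd = 0.5), n)
    colnames(dsm) <- sprintf("DSM%02d", seq_len(13L))
    list(questionnaires = questionnaires, responses = responses,
         dsm = dsm, groups = groups,
         truth = list(z = z, questionDomain = questionDomain, groups = groups))
}

#' Synthetic neurocognitive outcomes
#'
#' Each outcome is `beta * z[, assigned domain] + noise`; a pure-noise
#' column (`noise_control`) is always appended as a negative control.
#'
#' @param cfg a [simConfig()].
#' @param truth the `truth` element of [makeCohort()].
#' @param nOutcomes signal-carrying outcomes (domains assigned cyclically).
#' @param beta linear effect of the latent severity.
#' @param noiseSd outcome noise sd.
#' @return data.frame with `patient_id` and outcome columns.
#' @export
makeOutcomes <- function(cfg, truth, nOutcomes = 6L, beta = 1, noiseSd = 0.5) {
    set.seed(cfg$seed + 2L)
    z <- truth$z; n <- nrow(z)
    dom <- rep_len(seq_len(ncol(z)), nOutcomes)
    out <- vapply(seq_len(nOutcomes), function(k)
        beta * z[, dom[k]] + stats::rnorm(n, sd = noiseSd), numeric(n))
    colnames(out) <- sprintf("OUT%02d_%s", seq_len(nOutcomes), colnames(z)[dom])
    data.frame(patient_id = rownames(z), out,
               noise_control = stats::rnorm(n), check.names = FALSE)
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: embedding space, cohort, survey-level embedding
#' matrices, and outcomes in one call.
#'
#' @param cfg a [simConfig()].
#' @param ... passed to [makeOutcomes()].
#' @return List: `space`, `cohort`, `surveys` (list of
#'   [SurveyMatrix-class]), `outcomes`.
#' @export
simulateStudy <- function(cfg, ...) {
    space <- makeEmbeddingSpace(cfg)
    cohort <- makeCohort(cfg, space)
    surveys <- buildAllSurveys(cohort$questionnaires, cohort$responses,
                               space$emb, space$idf)
    outcomes <- makeOutcomes(cfg, cohort$truth, ...)
    list(space = space, cohort = cohort, surveys = surveys,
         outcomes = outcomes)
}
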