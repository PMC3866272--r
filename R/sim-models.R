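## Synthetic data generator: independent rare SNPs under HWE, logistic /
## linear trait models with marginal, gene-gene and gene-environment terms,
## retrospective case-control sampling.

# Built-in scenario registry. Coefficient defaults are the package's own
# documented choices (see the methods vignette); the *shapes* are fixed:
#   null1 - complete null (baseline penetrance only)
#   null2 - environmental marginal effect only
#   s1    - 5 risk SNPs, constant effect
#   s2    - 5 risk SNPs, effect size ~ |log10 MAF|
#   s3    - 5 risk + 5 protective SNPs, effect size ~ |log10 MAF|
#   s4    - pure G-by-G: 50% of SNPs (5 disjoint pairs), MAF fixed 0.01
#   s5    - pure G-by-G: 75% of SNPs involved, MAF fixed 0.01
#   s6    - weak main effects + the s4 interactions
#   s7    - binary env, env main effect + positive G-by-E terms
#   s8    - binary env, env main effect + mixed-sign G-by-E terms
.scenarioRegistry <- function(scenario, nSnps, traitType) {
    K <- nSnps
    u <- c(1e-4, 0.01)
    def <- list(mafLaw = "uniform", mafParams = u,
                causalSnps = integer(0), effectType = "constant",
                effectSize = 0, effectSigns = numeric(0),
                interactionPairs = matrix(integer(0), 0, 2),
                interactionCoefs = numeric(0),
                envLevels = 0L, envProbs = numeric(0),
                envMainEffect = numeric(0),
                gxeTerms = matrix(integer(0), 0, 2), gxeCoefs = numeric(0))
    pairUp <- function(n) cbind(seq(1, 2 * n, by = 2), seq(2, 2 * n, by = 2))
    env2 <- function(effect) list(envLevels = 2L, envProbs = c(0.5, 0.5),
                                  envMainEffect = c(0, effect))
    mod <- switch(scenario,
        null1 = list(),
        null2 = env2(log(3)),
        s1 = list(causalSnps = 1:5, effectType = "constant",
                  effectSize = log(3), effectSigns = rep(1, 5)),
        s2 = list(causalSnps = 1:5, effectType = "maf_inverse",
                  effectSize = 0.4, effectSigns = rep(1, 5)),
        s3 = list(causalSnps = 1:10, effectType = "maf_inverse",
                  effectSize = 0.4,
                  effectSigns = rep(c(1, -1), each = 5)),
        s4 = list(mafLaw = "fixed", mafParams = 0.01,
                  interactionPairs = pairUp(5),
                  interactionCoefs = rep(3, 5)),
        s5 = list(mafLaw = "fixed", mafParams = 0.01,
                  interactionPairs = rbind(pairUp(7), c(14L, 15L)),
                  interactionCoefs = rep(3, 8)),
        s6 = list(mafLaw = "fixed", mafParams = 0.01,
                  causalSnps = 1:5, effectType = "constant",
                  effectSize = log(1.5), effectSigns = rep(1, 5),
                  interactionPairs = pairUp(5),
                  interactionCoefs = rep(3, 5)),
        s7 = c(env2(log(2)),
               list(gxeTerms = cbind(1:5, rep(2L, 5)),
                    gxeCoefs = rep(1.5, 5))),
        s8 = c(env2(log(2)),
               list(gxeTerms = cbind(1:5, rep(2L, 5)),
                    gxeCoefs = c(1.5, 1.5, 1.5, -1.5, -1.5))),
        custom = list(),
        stop(.spaError("invalid_spec",
                       paste("unknown scenario", scenario))))
    out <- utils::modifyList(def, mod)
    out$baseline <- if (traitType == "binary") qlogis(0.01) else 0
    out$noiseSd <- 1
    out
}

#' Declare a simulation scenario
#'
#' Builds a \linkS4class{ScenarioSpec} from a named scenario shape
#' (\code{"null1"}, \code{"null2"}, \code{"s1"}..\code{"s8"}) or from
#' scratch (\code{"custom"}). Any registry default can be overridden through
#' the named arguments. The study conditions follow the simulation design
#' the statistics were validated under: 20 independent rare SNPs under HWE,
#' MAF either fixed at 0.01 or uniform on (0.0001, 0.01), equal numbers of
#' cases and controls sampled retrospectively from a logistic disease model
#' with baseline prevalence 0.01 (binary), or a linear model with unit
#' residual SD (continuous).
#'
#' @param scenario scenario identifier.
#' @param nSnps number of SNPs in the region (default 20).
#' @param traitType \code{"binary"} (default) or \code{"continuous"}.
#' @param nCases,nControls retrospective sample composition for binary
#'   traits.
#' @param nSubjects sample size for continuous traits.
#' @param mafLaw,mafParams,causalSnps,effectType,effectSize,effectSigns
#'   marginal-effect structure overrides.
#' @param interactionPairs,interactionCoefs G-by-G structure overrides.
#' @param envLevels,envProbs,envMainEffect,gxeTerms,gxeCoefs environmental
#'   structure overrides.
#' @param baseline,noiseSd model intercept and residual SD overrides.
#' @return A validated \linkS4class{ScenarioSpec}.
#' @examples
#' spaScenario("null1", nCases = 500, nControls = 500)
#' @export
spaScenario <- function(scenario = c("null1", "null2", "s1", "s2", "s3",
                                     "s4", "s5", "s6", "s7", "s8", "custom"),
                        nSnps = 20L,
                        traitType = c("binary", "continuous"),
                        nCases = 500L, nControls = 500L, nSubjects = 1000L,
                        mafLaw = NULL, mafParams = NULL, causalSnps = NULL,
                        effectType = NULL, effectSize = NULL,
                        effectSigns = NULL, interactionPairs = NULL,
                        interactionCoefs = NULL, envLevels = NULL,
                        envProbs = NULL, envMainEffect = NULL,
                        gxeTerms = NULL, gxeCoefs = NULL,
                        baseline = NULL, noiseSd = NULL) {
    scenario <- match.arg(scenario)
    traitType <- match.arg(traitType)
    p <- .scenarioRegistry(scenario, as.integer(nSnps), traitType)
    override <- list(mafLaw = mafLaw, mafParams = mafParams,
                     causalSnps = causalSnps, effectType = effectType,
                     effectSize = effectSize, effectSigns = effectSigns,
                     interactionPairs = interactionPairs,
                     interactionCoefs = interactionCoefs,
                     envLevels = envLevels, envProbs = envProbs,
                     envMainEffect = envMainEffect, gxeTerms = gxeTerms,
                     gxeCoefs = gxeCoefs, baseline = baseline,
                     noiseSd = noiseSd)
    p <- utils::modifyList(p, override[!vapply(override, is.null, TRUE)])
    ip <- p$interactionPairs
    if (!is.matrix(ip)) ip <- matrix(as.integer(ip), ncol = 2)
    storage.mode(ip) <- "integer"
    gt <- p$gxeTerms
    if (!is.matrix(gt)) gt <- matrix(as.integer(gt), ncol = 2)
    storage.mode(gt) <- "integer"
    methods::new("ScenarioSpec", scenarioId = scenario,
                 nSnps = as.integer(nSnps), mafLaw = p$mafLaw,
                 mafParams = as.numeric(p$mafParams), traitType = traitType,
                 causalSnps = as.integer(p$causalSnps),
                 effectType = p$effectType,
                 effectSize = as.numeric(p$effectSize),
                 effectSigns = as.numeric(p$effectSigns),
                 interactionPairs = ip,
                 interactionCoefs = as.numeric(p$interactionCoefs),
                 envLevels = as.integer(p$envLevels),
                 envProbs = as.numeric(p$envProbs),
                 envMainEffect = as.numeric(p$envMainEffect),
                 gxeTerms = gt, gxeCoefs = as.numeric(p$gxeCoefs),
                 baseline = as.numeric(p$baseline),
                 noiseSd = as.numeric(p$noiseSd),
                 nCases = as.integer(nCases),
                 nControls = as.integer(nControls),
                 nSubjects = as.integer(nSubjects))
}

setMethod("show", "ScenarioSpec", function(object) {
    cat(sprintf("ScenarioSpec '%s': %d SNPs, %s MAF, %s trait\n",
                object@scenarioId, object@nSnps,
                if (object@mafLaw == "fixed")
                    sprintf("fixed %g", object@mafParams)
                else sprintf("U(%g, %g)", object@mafParams[1],
                             object@mafParams[2]),
                object@traitType))
    if (length(object@causalSnps))
        cat(sprintf("  %d causal SNPs (%s, size %g)\n",
                    length(object@causalSnps), object@effectType,
                    object@effectSize))
    if (nrow(object@interactionPairs))
        cat(sprintf("  %d GxG interaction pair(s)\n",
                    nrow(object@interactionPairs)))
    if (object@envLevels > 0L)
        cat(sprintf("  env factor with %d levels, %d GxE term(s)\n",
                    object@envLevels, nrow(object@gxeTerms)))
    if (object@traitType == "binary")
        cat(sprintf("  sampling %d cases / %d controls\n",
                    object@nCases, object@nControls))
    else
        cat(sprintf("  %d subjects, residual SD %g\n", object@nSubjects,
                    object@noiseSd))
    invisible(NULL)
})

.drawMaf <- function(spec) {
    if (spec@mafLaw == "fixed") rep(spec@mafParams, spec@nSnps)
    else stats::runif(spec@nSnps, spec@mafParams[1], spec@mafParams[2])
}

# Per-SNP log-odds (or trait-unit) marginal coefficients, possibly
# MAF-dependent.
.mainCoefs <- function(spec, maf) {
    beta <- numeric(spec@nSnps)
    if (length(spec@causalSnps)) {
        size <- if (spec@effectType == "constant") spec@effectSize
                else spec@effectSize * abs(log10(maf[spec@causalSnps]))
        beta[spec@causalSnps] <- spec@effectSigns * size
    }
    beta
}

# Linear predictor for a block of subjects: marginal dosage terms,
# both-carrier indicator interactions, env main effect, and dosage-by-level
# GxE terms.
.linearPredictor <- function(spec, g, env, maf) {
    eta <- rep(spec@baseline, nrow(g))
    beta <- .mainCoefs(spec, maf)
    if (any(beta != 0)) eta <- eta + drop(g %*% beta)
    if (nrow(spec@interactionPairs)) {
        ip <- spec@interactionPairs
        for (p in seq_len(nrow(ip))) {
            both <- (g[, ip[p, 1]] >= 1) & (g[, ip[p, 2]] >= 1)
            eta <- eta + spec@interactionCoefs[p] * both
        }
    }
    if (spec@envLevels > 0L) {
        eta <- eta + spec@envMainEffect[env]
        if (nrow(spec@gxeTerms)) {
            gt <- spec@gxeTerms
            for (t in seq_len(nrow(gt)))
                eta <- eta + spec@gxeCoefs[t] * g[, gt[t, 1]] *
                       (env == gt[t, 2])
        }
    }
    eta
}

.hasGeneticTerms <- function(spec)
    length(spec@causalSnps) > 0L || nrow(spec@interactionPairs) > 0L ||
        nrow(spec@gxeTerms) > 0L

#' Draw genotypes for independent rare SNPs under HWE
#'
#' Each SNP gets a minor-allele frequency from the scenario's MAF law (drawn
#' once per call, i.e. per replicate) and genotypes are i.i.d.
#' Binomial(2, MAF) across subjects; columns are mutually independent.
#'
#' @param nSubjects number of subjects.
#' @param spec a \linkS4class{ScenarioSpec} (its MAF law and SNP count are
#'   used).
#' @param maf optional frequencies to use instead of drawing new ones.
#' @return Integer matrix nSubjects x nSnps with attribute \code{"maf"} (the
#'   realized frequencies).
#' @export
drawGenotypes <- function(nSubjects, spec, maf = NULL) {
    if (is.null(maf)) maf <- .drawMaf(spec)
    g <- matrix(rbinom(nSubjects * spec@nSnps, 2L, rep(maf, each = nSubjects)),
                nrow = nSubjects, ncol = spec@nSnps)
    colnames(g) <- paste0("snp", seq_len(spec@nSnps))
    attr(g, "maf") <- maf
    g
}

#' Draw an environmental factor
#'
#' i.i.d. categorical draws over the scenario's J levels with the scenario's
#' level probabilities.
#'
#' @inheritParams drawGenotypes
#' @return Integer vector of levels 1..J, or \code{NULL} when the scenario
#'   has no environmental factor.
#' @export
simulateEnv <- function(nSubjects, spec) {
    if (spec@envLevels < 1L) return(NULL)
    if (abs(sum(spec@envProbs) - 1) > 1e-8)
        stop(.spaError("invalid_spec", "env probabilities must sum to 1"))
    sample.int(spec@envLevels, nSubjects, replace = TRUE,
               prob = spec@envProbs)
}

#' Simulate a case-control dataset from a disease-model scenario
#'
#' Subjects are simulated prospectively — genotype (and environmental level)
#' drawn from their population law, disease status Bernoulli with
#' probability \code{plogis(eta)} where \code{eta} is the scenario's
#' logistic linear predictor — and sampled retrospectively until exactly
#' \code{nCases} cases and \code{nControls} controls are retained.
#'
#' Two exact shortcuts avoid needless prospective draws: when the scenario
#' has no effects at all (complete null), disease status is independent of
#' everything, so genotypes/env are drawn for the retained sample directly;
#' when it has no genetic terms (e.g. an environmental main effect only),
#' (env, status) pairs are drawn prospectively first and genotypes attached
#' afterwards. Both are distributionally identical to the full prospective
#' procedure.
#'
#' @param spec a binary-trait \linkS4class{ScenarioSpec}.
#' @param maxDraws stall guard: abort if this many prospective draws do not
#'   fill the case/control quota.
#' @return A \linkS4class{SpaDataSet}; \code{metadata(x)$truth} holds the
#'   spec and the realized MAFs.
#' @export
simulateBinary <- function(spec, maxDraws = 1e7) {
    raw <- .simulateBinaryRaw(spec, maxDraws)
    .assemble(spec, raw$g, raw$y, raw$env, raw$maf)
}

.simulateBinaryRaw <- function(spec, maxDraws = 1e7) {
    if (spec@traitType != "binary")
        stop(.spaError("invalid_spec", "spec is not a binary scenario"))
    nA <- spec@nCases; nU <- spec@nControls
    N <- nA + nU
    maf <- .drawMaf(spec)
    if (!.hasGeneticTerms(spec) && spec@envLevels > 0L &&
        any(spec@envMainEffect != 0)) {
        ## env-only model: draw (env, status) prospectively, attach genotypes
        env <- .retroSampleEnv(spec, nA, nU, maxDraws)
        g <- drawGenotypes(N, spec, maf)
        y <- c(rep(1, nA), rep(0, nU))
        return(list(g = g, y = y, env = env, maf = maf))
    }
    if (!.hasGeneticTerms(spec)) {
        ## complete null: status independent of genotype and env
        g <- drawGenotypes(N, spec, maf)
        y <- c(rep(1, nA), rep(0, nU))
        env <- simulateEnv(N, spec)
        return(list(g = g, y = y, env = env, maf = maf))
    }
    ## general prospective + retrospective path
    gA <- matrix(0L, 0, spec@nSnps); gU <- matrix(0L, 0, spec@nSnps)
    eA <- integer(0); eU <- integer(0)
    drawn <- 0
    batch <- max(2000L, as.integer(ceiling(
        N / max(plogis(spec@baseline), 1e-4))))
    while (nrow(gA) < nA || nrow(gU) < nU) {
        if (drawn >= maxDraws)
            stop(.spaError("simulation_stall", sprintf(
                "case/control quota not reached after %g prospective draws",
                drawn)))
        nb <- min(batch, maxDraws - drawn)
        g <- drawGenotypes(nb, spec, maf)
        env <- simulateEnv(nb, spec)
        pr <- plogis(.linearPredictor(spec, g, env, maf))
        case <- rbinom(nb, 1L, pr) == 1L
        drawn <- drawn + nb
        if (nrow(gA) < nA && any(case)) {
            idx <- which(case)[seq_len(min(sum(case), nA - nrow(gA)))]
            gA <- rbind(gA, g[idx, , drop = FALSE])
            if (!is.null(env)) eA <- c(eA, env[idx])
        }
        if (nrow(gU) < nU && any(!case)) {
            idx <- which(!case)[seq_len(min(sum(!case), nU - nrow(gU)))]
            gU <- rbind(gU, g[idx, , drop = FALSE])
            if (!is.null(env)) eU <- c(eU, env[idx])
        }
    }
    g <- rbind(gA, gU)
    env <- if (spec@envLevels > 0L) c(eA, eU) else NULL
    list(g = g, y = c(rep(1, nA), rep(0, nU)), env = env, maf = maf)
}

# Prospective (env, status) sampler for scenarios whose predictor involves
# env only. Returns env levels ordered cases-first to match the label
# layout.
.retroSampleEnv <- function(spec, nA, nU, maxDraws) {
    eA <- integer(0); eU <- integer(0)
    drawn <- 0
    batch <- max(5000L, as.integer(ceiling(
        (nA + nU) / max(plogis(spec@baseline), 1e-4))))
    while (length(eA) < nA || length(eU) < nU) {
        if (drawn >= maxDraws)
            stop(.spaError("simulation_stall",
                "case/control quota not reached"))
        nb <- min(batch, maxDraws - drawn)
        env <- simulateEnv(nb, spec)
        pr <- plogis(spec@baseline + spec@envMainEffect[env])
        case <- rbinom(nb, 1L, pr) == 1L
        drawn <- drawn + nb
        if (length(eA) < nA)
            eA <- c(eA, env[case][seq_len(min(sum(case), nA - length(eA)))])
        if (length(eU) < nU)
            eU <- c(eU, env[!case][seq_len(min(sum(!case), nU - length(eU)))])
    }
    c(eA, eU)
}

.assemble <- function(spec, g, y, env, maf) {
    # guarantee every env level is occupied (validity requirement);
    # relabel to the occupied set if a level came up empty
    if (!is.null(env)) {
        occ <- sort(unique(env))
        if (length(occ) < spec@envLevels) env <- match(env, occ)
    }
    ds <- SpaDataSet(g, phenotype = y, traitType = spec@traitType,
                     env = env, maf = maf)
    S4Vectors::metadata(ds)$truth <- list(spec = spec, maf = maf)
    ds
}

#' Simulate a quantitative-trait dataset
#'
#' \eqn{Y = } baseline + genetic terms (marginal dosage effects,
#' both-carrier interaction terms, env and G-by-E terms) +
#' Normal(0, noiseSd^2); all \code{nSubjects} subjects are retained (no
#' sampling step).
#'
#' @param spec a continuous-trait \linkS4class{ScenarioSpec}.
#' @return A \linkS4class{SpaDataSet}.
#' @export
simulateContinuous <- function(spec) {
    raw <- .simulateContinuousRaw(spec)
    .assemble(spec, raw$g, raw$y, raw$env, raw$maf)
}

.simulateContinuousRaw <- function(spec) {
    if (spec@traitType != "continuous")
        stop(.spaError("invalid_spec", "spec is not a continuous scenario"))
    if (spec@noiseSd <= 0)
        stop(.spaError("invalid_spec", "noiseSd must be > 0"))
    N <- spec@nSubjects
    maf <- .drawMaf(spec)
    g <- drawGenotypes(N, spec, maf)
    env <- simulateEnv(N, spec)
    y <- .linearPredictor(spec, g, env, maf) + rnorm(N, 0, spec@noiseSd)
    list(g = g, y = y, env = env, maf = maf)
}

# raw (g, y, env) draw shared by the experiment harness; identical draws to
# simulateScenario under the same seed, without container construction
.simulateRaw <- function(spec) {
    if (spec@traitType == "binary") .simulateBinaryRaw(spec)
    else .simulateContinuousRaw(spec)
}

#' Simulate one dataset from a scenario
#'
#' Dispatches to \code{\link{simulateBinary}} or
#' \code{\link{simulateContinuous}} by the scenario's trait type.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param seed optional integer seed for reproducibility.
#' @return A \linkS4class{SpaDataSet}.
#' @export
simulateScenario <- function(spec, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (spec@traitType == "binary") simulateBinary(spec)
    else simulateContinuous(spec)
}
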