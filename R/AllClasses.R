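#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats rbinom rnorm plogis qlogis binom.test setNames
#' @importFrom utils read.delim write.table
NULL

#' SpaDataSet: genotypes, phenotype and environmental factor for one region
#'
#' A \linkS4class{SummarizedExperiment} holding the minor-allele dosage matrix
#' for a region of rare variants (one assay, \code{"dosage"}, variants in rows
#' and subjects in columns, entries 0/1/2), the trait in
#' \code{colData(x)$phenotype}, and an optional categorical environmental
#' factor in \code{colData(x)$env} (integer level codes \code{1..J}). The
#' trait type (\code{"binary"} or \code{"continuous"}) lives in
#' \code{metadata(x)$traitType}.
#'
#' Use the \code{\link{SpaDataSet}} constructor rather than building the
#' object by hand; it orients the matrix, auto-detects the trait type and
#' recodes missing genotypes.
#'
#' @seealso \code{\link{SpaDataSet}}, \code{\link{computeI1}},
#'   \code{\link{spaTest}}
#' @export
setClass("SpaDataSet", contains = "SummarizedExperiment")

setValidity("SpaDataSet", function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !(d %in% c(0L, 1L, 2L) | is.na(d))
        if (any(bad))
            msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
        if (ncol(d) < 2L)
            msg <- c(msg, "at least 2 subjects are required")
        if (nrow(d) < 1L)
            msg <- c(msg, "at least 1 variant is required")
        if (anyDuplicated(rownames(d)))
            msg <- c(msg, "variant (SNP) ids must be unique")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"phenotype" %in% colnames(cd))
        msg <- c(msg, "colData column 'phenotype' is required")
    tt <- S4Vectors::metadata(object)$traitType
    if (is.null(tt) || !tt %in% c("binary", "continuous"))
        msg <- c(msg, "metadata(x)$traitType must be 'binary' or 'continuous'")
    else if ("phenotype" %in% colnames(cd)) {
        y <- cd$phenotype
        if (anyNA(y))
            msg <- c(msg, "phenotype must not contain NA")
        else if (tt == "binary") {
            if (!all(y %in% c(0, 1)))
                msg <- c(msg, "binary phenotype values must be 0/1")
            else if (sum(y == 1) < 1L || sum(y == 0) < 1L)
                msg <- c(msg, "binary phenotype needs at least one case and one control")
        }
    }
    if ("env" %in% colnames(cd)) {
        e <- cd$env
        if (anyNA(e) || !all(e == as.integer(e)) || any(e < 1L))
            msg <- c(msg, "env levels must be positive integers 1..J")
        else {
            J <- max(e)
            if (!all(seq_len(J) %in% e))
                msg <- c(msg, "every env level 1..J must be occupied")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' SpaResult: one permutation test result
#'
#' Holds the observed value of one SPA statistic, its permutation p-value,
#' the permutation strategy and count, and (optionally) the null ensemble.
#' For the adaptive statistic \code{"pstar"} the observed value is the min-p
#' score in \[0,1\]; for \code{"I1"}, \code{"I2"} and \code{"I1E"} it is a
#' nonnegative influence score.
#'
#' @slot statistic character, one of \code{"I1"}, \code{"I2"}, \code{"pstar"},
#'   \code{"I1E"}.
#' @slot value observed statistic.
#' @slot pValue permutation p-value (add-one estimator), in
#'   \[1/(B+1), 1\].
#' @slot B integer number of permutations.
#' @slot strategy \code{"global"}, \code{"local"} or \code{"none"}.
#' @slot nullValues numeric null ensemble of length B (may be empty if
#'   dropped to save memory).
#' @export
setClass("SpaResult",
    representation(statistic = "character", value = "numeric",
                   pValue = "numeric", B = "integer",
                   strategy = "character", nullValues = "numeric"))

setValidity("SpaResult", function(object) {
    msg <- NULL
    if (!object@statistic %in% c("I1", "I2", "pstar", "I1E"))
        msg <- c(msg, "unknown statistic name")
    if (object@B < 1L)
        msg <- c(msg, "B must be >= 1")
    pmin_ <- 1 / (object@B + 1)
    if (object@pValue < pmin_ - 1e-12 || object@pValue > 1 + 1e-12)
        msg <- c(msg, "pValue must lie in [1/(B+1), 1]")
    if (object@statistic != "pstar" && object@value < 0)
        msg <- c(msg, "observed I1/I2/I1E must be nonnegative")
    if (object@statistic == "pstar" &&
        (object@value < 0 || object@value > 1))
        msg <- c(msg, "observed pstar must lie in [0,1]")
    if (!object@strategy %in% c("global", "local", "none"))
        msg <- c(msg, "unknown permutation strategy")
    if (length(object@nullValues) &&
        length(object@nullValues) != object@B)
        msg <- c(msg, "nullValues must have length B (or 0)")
    if (is.null(msg)) TRUE else msg
})

#' ScenarioSpec: declarative description of one simulation scenario
#'
#' Encodes everything the generator needs: the minor-allele-frequency law,
#' the causal SNP set and the shape of their effects, gene-gene interaction
#' pairs, the environmental factor and gene-environment terms, the baseline
#' (logit prevalence for a binary trait, trait mean for a continuous one),
#' the residual SD for continuous traits, and the target sample composition.
#'
#' @slot scenarioId identifier (\code{"null1"}, \code{"null2"},
#'   \code{"s1"}..\code{"s8"} or \code{"custom"}).
#' @slot nSnps number of independent rare SNPs in the region.
#' @slot mafLaw \code{"fixed"} or \code{"uniform"}.
#' @slot mafParams for \code{"fixed"} the single MAF; for \code{"uniform"}
#'   the (lower, upper) support.
#' @slot traitType \code{"binary"} or \code{"continuous"}.
#' @slot causalSnps indices of SNPs with marginal effects.
#' @slot effectType \code{"constant"} or \code{"maf_inverse"} (effect size
#'   proportional to |log10 MAF|).
#' @slot effectSize magnitude (log-odds / trait units for
#'   \code{"constant"}; the proportionality constant for
#'   \code{"maf_inverse"}).
#' @slot effectSigns one sign (+1/-1) per causal SNP.
#' @slot interactionPairs integer matrix with columns (i, j).
#' @slot interactionCoefs one coefficient per pair, applied to the
#'   both-carrier indicator.
#' @slot envLevels number of environmental levels J (0 = no env factor).
#' @slot envProbs level probabilities (length J).
#' @slot envMainEffect per-level main effect, length J, first level is the
#'   reference (0).
#' @slot gxeTerms integer matrix with columns (snp, level).
#' @slot gxeCoefs one coefficient per G-by-E term, applied to
#'   dosage * level indicator.
#' @slot baseline intercept (logit scale for binary).
#' @slot noiseSd residual SD for continuous traits.
#' @slot nCases,nControls binary sample composition (retrospective).
#' @slot nSubjects continuous-trait sample size.
#' @export
setClass("ScenarioSpec",
    representation(scenarioId = "character", nSnps = "integer",
                   mafLaw = "character", mafParams = "numeric",
                   traitType = "character",
                   causalSnps = "integer", effectType = "character",
                   effectSize = "numeric", effectSigns = "numeric",
                   interactionPairs = "matrix", interactionCoefs = "numeric",
                   envLevels = "integer", envProbs = "numeric",
                   envMainEffect = "numeric",
                   gxeTerms = "matrix", gxeCoefs = "numeric",
                   baseline = "numeric", noiseSd = "numeric",
                   nCases = "integer", nControls = "integer",
                   nSubjects = "integer"))

setValidity("ScenarioSpec", function(object) {
    msg <- NULL
    K <- object@nSnps
    if (K < 1L) msg <- c(msg, "nSnps must be >= 1")
    if (!object@mafLaw %in% c("fixed", "uniform"))
        msg <- c(msg, "mafLaw must be 'fixed' or 'uniform'")
    if (object@mafLaw == "fixed" &&
        (length(object@mafParams) != 1L ||
         object@mafParams <= 0 || object@mafParams >= 0.5))
        msg <- c(msg, "fixed mafParams must be one value in (0, 0.5)")
    if (object@mafLaw == "uniform" &&
        (length(object@mafParams) != 2L ||
         object@mafParams[1] <= 0 || object@mafParams[2] >= 0.5 ||
         object@mafParams[1] >= object@mafParams[2]))
        msg <- c(msg, "uniform mafParams must be (lo, hi) within (0, 0.5)")
    if (!object@traitType %in% c("binary", "continuous"))
        msg <- c(msg, "traitType must be 'binary' or 'continuous'")
    if (length(object@causalSnps) &&
        (any(object@causalSnps < 1L) || any(object@causalSnps > K)))
        msg <- c(msg, "causalSnps out of range")
    if (length(object@causalSnps) != length(object@effectSigns))
        msg <- c(msg, "effectSigns must match causalSnps in length")
    if (nrow(object@interactionPairs)) {
        ip <- object@interactionPairs
        if (ncol(ip) != 2L || any(ip < 1L) || any(ip > K) ||
            any(ip[, 1] == ip[, 2]))
            msg <- c(msg, "interactionPairs must be distinct in-range (i, j)")
        if (anyDuplicated(paste(pmin(ip[, 1], ip[, 2]),
                                pmax(ip[, 1], ip[, 2]))))
            msg <- c(msg, "duplicate interaction pair")
        if (nrow(ip) != length(object@interactionCoefs))
            msg <- c(msg, "one coefficient per interaction pair required")
    }
    J <- object@envLevels
    if (J > 0L) {
        if (length(object@envProbs) != J ||
            abs(sum(object@envProbs) - 1) > 1e-8)
            msg <- c(msg, "envProbs must have length J and sum to 1")
        if (length(object@envMainEffect) != J)
            msg <- c(msg, "envMainEffect must have length J")
        if (nrow(object@gxeTerms)) {
            gt <- object@gxeTerms
            if (ncol(gt) != 2L || any(gt[, 1] < 1L) || any(gt[, 1] > K) ||
                any(gt[, 2] < 1L) || any(gt[, 2] > J))
                msg <- c(msg, "gxeTerms must be in-range (snp, level)")
            if (nrow(gt) != length(object@gxeCoefs))
                msg <- c(msg, "one coefficient per G-by-E term required")
        }
    } else if (nrow(object@gxeTerms)) {
        msg <- c(msg, "gxeTerms require an environmental factor")
    }
    if (object@traitType == "continuous" && object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0 for continuous traits")
    if (object@traitType == "binary" &&
        (object@nCases < 1L || object@nControls < 1L))
        msg <- c(msg, "binary scenarios need nCases >= 1 and nControls >= 1")
    if (object@scenarioId == "null1" &&
        (length(object@causalSnps) || nrow(object@interactionPairs) ||
         nrow(object@gxeTerms) || any(object@envMainEffect != 0)))
        msg <- c(msg, "null1 must have no genetic, env or GxE coefficients")
    if (object@scenarioId == "null2" &&
        (length(object@causalSnps) || nrow(object@interactionPairs) ||
         nrow(object@gxeTerms)))
        msg <- c(msg, "null2 must have an env main effect only")
    if (is.null(msg)) TRUE else msg
})

#' ExperimentSummary: rejection rates from a replicated simulation study
#'
#' One object per \code{\link{runExperiment}} call: empirical rejection rates
#' at each nominal level for each statistic, with exact binomial 95%
#' confidence intervals, the replicate p-values, and the settings that
#' produced them.
#'
#' @slot scenarioId scenario identifier.
#' @slot statistics statistic labels (e.g. \code{"I1"},
#'   \code{"I1E-local"}).
#' @slot sampleSize total number of subjects per replicate.
#' @slot alphas nominal significance levels.
#' @slot R number of replicates.
#' @slot B permutations per test.
#' @slot seed master seed.
#' @slot pValues R x length(statistics) matrix of replicate p-values.
#' @slot rejectionRate statistics x alphas matrix.
#' @slot ciLow,ciHigh exact binomial 95% CI bounds, same shape.
#' @export
setClass("ExperimentSummary",
    representation(scenarioId = "character", statistics = "character",
                   sampleSize = "integer", alphas = "numeric",
                   R = "integer", B = "integer", seed = "integer",
                   pValues = "matrix", rejectionRate = "matrix",
                   ciLow = "matrix", ciHigh = "matrix"))

setValidity("ExperimentSummary", function(object) {
    msg <- NULL
    if (any(object@rejectionRate < 0 | object@rejectionRate > 1))
        msg <- c(msg, "rejection rates must lie in [0,1]")
    if (any(object@ciLow > object@rejectionRate + 1e-12) ||
        any(object@ciHigh < object@rejectionRate - 1e-12))
        msg <- c(msg, "CI must contain the rejection rate")
    if (is.null(msg)) TRUE else msg
})
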