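## Replicated simulation studies: type-I error and power estimation.

#' Deterministic per-replicate seed ladder
#'
#' Derives replicate r's seed from the master seed by one step of a
#' Lehmer-style congruential mix modulo 2^31 - 1, so partial runs are
#' reproducible and replicates can be farmed out independently with
#' identical results.
#'
#' @param master master seed (integer).
#' @param r replicate index (>= 1).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
replicateSeed <- function(master, r) {
    m <- 2147483647
    s <- ((as.numeric(master) %% m) * 48271 + as.numeric(r) * 16807) %% m
    s[s == 0] <- 1
    as.integer(s)
}

# statistic labels accepted by runExperiment; "I1E" alone means global
.parseStatistic <- function(label) {
    parts <- strsplit(label, "-", fixed = TRUE)[[1]]
    stat <- parts[1]
    strategy <- if (length(parts) > 1) parts[2] else "global"
    if (!stat %in% c("I1", "I2", "pstar", "I1E") ||
        !strategy %in% c("global", "local"))
        stop(.spaError("config", paste("unknown statistic label", label)))
    list(stat = stat, strategy = strategy)
}

#' Run a replicated simulation experiment
#'
#' For each replicate: simulate a dataset from the scenario, run every
#' requested test, and record its p-value; then report the rejection
#' proportion at each nominal level with exact binomial 95% confidence
#' intervals. Replicate r runs under \code{\link{replicateSeed}(seed, r)},
#' so any subset of replicates reproduces identically.
#'
#' Statistics sharing a permutation strategy share one permutation ensemble
#' per replicate (and \code{"pstar"} shares its ensemble with I1/I2 by
#' construction), which is what makes desk-scale calibration runs feasible.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param statistics character vector from \code{"I1"}, \code{"I2"},
#'   \code{"pstar"}, \code{"I1E-global"}, \code{"I1E-local"} (plain
#'   \code{"I1E"} means global).
#' @param B permutations per test.
#' @param R number of replicates.
#' @param alphas nominal significance levels.
#' @param seed master seed.
#' @param normalize passed to the I2 evaluation.
#' @return An \linkS4class{ExperimentSummary}.
#' @examples
#' spec <- spaScenario("null1", nCases = 50, nControls = 50)
#' runExperiment(spec, "I1", B = 99, R = 20, seed = 1)
#' @export
runExperiment <- function(spec, statistics = "I1", B = 1000L, R = 1000L,
                          alphas = c(0.05, 0.01), seed = 1L,
                          normalize = TRUE) {
    R <- as.integer(R); B <- as.integer(B)
    if (R < 1L) stop(.spaError("config", "R must be >= 1"))
    parsed <- lapply(statistics, .parseStatistic)
    needGlobal <- any(vapply(parsed, function(p)
        p$strategy == "global", TRUE))
    needLocal <- any(vapply(parsed, function(p)
        p$strategy == "local", TRUE))
    needPairs <- any(vapply(parsed, function(p)
        p$stat %in% c("I2", "pstar"), TRUE))
    pv <- matrix(NA_real_, R, length(statistics),
                 dimnames = list(NULL, statistics))
    for (r in seq_len(R)) {
        set.seed(replicateSeed(seed, r))
        raw <- tryCatch(.simulateRaw(spec), error = function(e)
            stop(.spaError("replicate", sprintf(
                "replicate %d: %s", r, conditionMessage(e)))))
        g <- raw$g; storage.mode(g) <- "double"
        y <- raw$y
        env <- raw$env
        tt <- spec@traitType
        st <- if (needPairs) .pairStructure(g) else NULL
        obsY <- matrix(y, ncol = 1)
        Yg <- if (needGlobal) .permutationMatrix(y, B, "global") else NULL
        Yl <- if (needLocal) .permutationMatrix(y, B, "local", env) else NULL
        loo1g <- loo2g <- NULL  # shared min-p pieces, computed lazily
        for (k in seq_along(parsed)) {
            p <- parsed[[k]]
            Y <- if (p$strategy == "global") Yg else Yl
            if (p$stat == "pstar") {
                obs1 <- .i1Null(g, obsY, tt)[1]
                null1 <- .i1Null(g, Y, tt)
                obs2 <- .i2Null(st, obsY, normalize)[1]
                null2 <- .i2Null(st, Y, normalize)
                pObs <- min(permutationPValue(obs1, null1),
                            permutationPValue(obs2, null2))
                pNull <- pmin(.looPValues(null1), .looPValues(null2))
                pv[r, k] <- (1 + sum(pNull <= pObs)) / (1 + B)
            } else {
                obs <- .nullEnsemble(p$stat, g, obsY, tt, env, st = st,
                                     normalize = normalize)[1]
                nul <- .nullEnsemble(p$stat, g, Y, tt, env, st = st,
                                     normalize = normalize)
                pv[r, k] <- permutationPValue(obs, nul)
            }
        }
    }
    nStat <- length(statistics); nA <- length(alphas)
    rate <- ciL <- ciH <- matrix(NA_real_, nStat, nA,
        dimnames = list(statistics, paste0("alpha", alphas)))
    for (k in seq_len(nStat)) for (a in seq_len(nA)) {
        hits <- sum(pv[, k] <= alphas[a])
        bt <- binom.test(hits, R)
        rate[k, a] <- hits / R
        ciL[k, a] <- bt$conf.int[1]
        ciH[k, a] <- bt$conf.int[2]
    }
    n <- if (spec@traitType == "binary") spec@nCases + spec@nControls
         else spec@nSubjects
    methods::new("ExperimentSummary", scenarioId = spec@scenarioId,
                 statistics = statistics, sampleSize = as.integer(n),
                 alphas = alphas, R = R, B = B, seed = as.integer(seed),
                 pValues = pv, rejectionRate = rate, ciLow = ciL,
                 ciHigh = ciH)
}

#' @rdname ExperimentSummary-accessors
#' @export
setGeneric("rejectionRate", function(object, ...)
    standardGeneric("rejectionRate"))

#' Accessors for ExperimentSummary
#'
#' \code{rejectionRate} returns the statistics-by-alphas matrix of
#' empirical rejection proportions (optionally one entry);
#' \code{replicatePValues} the R-by-statistics matrix of per-replicate
#' p-values.
#'
#' @param object an \linkS4class{ExperimentSummary}.
#' @param statistic,alpha optional selectors.
#' @param ... unused.
#' @name ExperimentSummary-accessors
NULL

#' @rdname ExperimentSummary-accessors
#' @export
setMethod("rejectionRate", "ExperimentSummary",
    function(object, statistic = NULL, alpha = NULL) {
        m <- object@rejectionRate
        if (is.null(statistic) && is.null(alpha)) return(m)
        i <- if (is.null(statistic)) seq_len(nrow(m))
             else match(statistic, object@statistics)
        j <- if (is.null(alpha)) seq_len(ncol(m))
             else match(alpha, object@alphas)
        m[i, j]
    })

#' @rdname ExperimentSummary-accessors
#' @export
setGeneric("replicatePValues", function(object)
    standardGeneric("replicatePValues"))

#' @rdname ExperimentSummary-accessors
#' @export
setMethod("replicatePValues", "ExperimentSummary",
          function(object) object@pValues)

setMethod("show", "ExperimentSummary", function(object) {
    cat(sprintf("ExperimentSummary: scenario '%s', n = %d, R = %d, B = %d, seed = %d\n",
                object@scenarioId, object@sampleSize, object@R, object@B,
                object@seed))
    df <- summarizeExperiments(list(object))
    print(df[, c("statistic", "strategy", "alpha", "rate", "ci_low",
                 "ci_high")], row.names = FALSE, digits = 3)
    invisible(NULL)
})

#' Long-format table of experiment summaries
#'
#' Binds one row per (statistic, alpha) combination across the supplied
#' summaries, in a stable column order, and optionally writes it as TSV.
#' No aggregation is performed across seeds or summaries; a round-trip read
#' of the TSV reproduces every numeric field exactly.
#'
#' @param summaries a list of \linkS4class{ExperimentSummary} objects (a
#'   single object is accepted).
#' @param file optional TSV path.
#' @return A data.frame with columns scenario, statistic, strategy, n,
#'   alpha, rate, ci_low, ci_high, R, B, seed.
#' @export
summarizeExperiments <- function(summaries, file = NULL) {
    if (methods::is(summaries, "ExperimentSummary"))
        summaries <- list(summaries)
    if (!length(summaries))
        stop(.spaError("config", "no summaries supplied"))
    rows <- lapply(summaries, function(s) {
        grid <- expand.grid(k = seq_along(s@statistics),
                            a = seq_along(s@alphas))
        parsed <- lapply(s@statistics, .parseStatistic)
        data.frame(
            scenario = s@scenarioId,
            statistic = vapply(parsed[grid$k], `[[`, "", "stat"),
            strategy = vapply(parsed[grid$k], `[[`, "", "strategy"),
            n = s@sampleSize,
            alpha = s@alphas[grid$a],
            rate = s@rejectionRate[cbind(grid$k, grid$a)],
            ci_low = s@ciLow[cbind(grid$k, grid$a)],
            ci_high = s@ciHigh[cbind(grid$k, grid$a)],
            R = s@R, B = s@B, seed = s@seed,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(file)) {
        fmt <- out
        # full-precision formatting so the TSV round-trips exactly
        num <- vapply(fmt, is.double, TRUE)
        fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
        write.table(fmt, file, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    out
}
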