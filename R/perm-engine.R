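## Permutation engine: null ensembles, p-values, and the adaptive min-p test.

# N x B matrix whose columns are permuted phenotypes. Global strategy
# permutes across all subjects; local permutes independently within each
# stratum of the environmental factor, so no label ever crosses a stratum.
.permutationMatrix <- function(y, B, strategy = c("global", "local"),
                               env = NULL) {
    strategy <- match.arg(strategy)
    N <- length(y)
    if (strategy == "global") {
        idx <- vapply(seq_len(B), function(b) sample.int(N), integer(N))
        return(matrix(y[idx], N, B))
    }
    if (is.null(env))
        stop(.spaError("config", "local permutation requires an env factor"))
    out <- matrix(0, N, B)
    for (j in seq_len(max(env))) {
        rows <- which(env == j)
        nj <- length(rows)
        idx <- vapply(seq_len(B), function(b) sample.int(nj), integer(nj))
        out[rows, ] <- matrix(y[rows][idx], nj, B)
    }
    out
}

#' Permute a phenotype globally or within environmental strata
#'
#' Global permutation shuffles the trait among all subjects (preserving the
#' overall case/control counts); local permutation shuffles independently
#' within each stratum of the environmental factor (preserving each
#' stratum's counts), which removes the environmental marginal effect from
#' the null.
#'
#' @param phenotype numeric trait vector.
#' @param strategy \code{"global"} or \code{"local"}.
#' @param env integer env levels 1..J; required for \code{"local"}.
#' @return A permuted phenotype vector.
#' @export
permutePhenotype <- function(phenotype, strategy = c("global", "local"),
                             env = NULL) {
    strategy <- match.arg(strategy)
    drop(.permutationMatrix(as.numeric(phenotype), 1L, strategy, env))
}

#' Add-one permutation p-value
#'
#' \deqn{p = \frac{1 + \#\{b : T_b \ge T_{obs}\}}{1 + B}.}
#' Ties count against rejection; the smallest attainable value is
#' \eqn{1/(B+1)} and the estimator is valid (never anti-conservative) for
#' any B.
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of the statistic on permuted data.
#' @return p-value in \eqn{[1/(B+1), 1]}.
#' @examples
#' permutationPValue(5, rep(1, 99))  # 0.01
#' @export
permutationPValue <- function(observed, nullValues) {
    B <- length(nullValues)
    if (B < 1) stop(.spaError("config", "at least one permutation required"))
    (1 + sum(nullValues >= observed)) / (1 + B)
}

# Leave-one-out add-one p-values for every member of a null ensemble:
# p_b = (1 + #{b' != b : T_b' >= T_b}) / (1 + B). Used by the shared-ensemble
# min-p construction so each permuted statistic is ranked the same way the
# observed one is.
.looPValues <- function(nullValues) {
    B <- length(nullValues)
    r <- rank(nullValues, ties.method = "min")
    (B - r + 1) / (B + 1)
}

# Dispatch a statistic label to its null-ensemble worker. st: precomputed
# pair structure (I2 only).
.nullEnsemble <- function(statistic, g, Y, traitType, env = NULL,
                          weights = NULL, st = NULL, normalize = FALSE) {
    switch(statistic,
        I1 = .i1Null(g, Y, traitType, weights),
        I2 = .i2Null(st, Y, normalize),
        I1E = .i1eNull(g, Y, env),
        stop(.spaError("config", paste("unknown statistic", statistic))))
}

#' Permutation test for one SPA statistic
#'
#' Computes the observed statistic and a permutation p-value from B
#' phenotype permutations under the chosen strategy. The evaluation is
#' vectorized (one matrix product per ensemble) and exactly equals
#' per-permutation evaluation. With \code{statistic = "pstar"} this runs the
#' adaptive min-p test (see \code{\link{adaptivePStar}}).
#'
#' @param x a \linkS4class{SpaDataSet}, or a subjects-by-SNPs dosage matrix
#'   (then supply \code{phenotype} and, if needed, \code{env}).
#' @param statistic one of \code{"I1"}, \code{"I2"}, \code{"I1E"},
#'   \code{"pstar"}.
#' @param B number of permutations (>= 1).
#' @param strategy \code{"global"} (default) or \code{"local"}
#'   (within-stratum; requires an env factor).
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the result is reproducible.
#' @param phenotype,traitType,env used when \code{x} is a matrix.
#' @param weights optional I1 weights (summing to 1).
#' @param pairs,normalize passed to the I2 evaluation.
#' @param keepNull keep the null ensemble in the result (default TRUE).
#' @return A \linkS4class{SpaResult}.
#' @examples
#' set.seed(1)
#' g <- matrix(rbinom(400, 2, 0.05), 100, 4)
#' res <- spaTest(g, phenotype = rep(c(1, 0), 50), statistic = "I1",
#'                B = 99, seed = 7)
#' pValue(res)
#' @export
spaTest <- function(x, statistic = c("I1", "I2", "I1E", "pstar"),
                    B = 1000L, strategy = c("global", "local"),
                    seed = NULL, phenotype = NULL, traitType = "auto",
                    env = NULL, weights = NULL, pairs = NULL,
                    normalize = TRUE, keepNull = TRUE) {
    statistic <- match.arg(statistic)
    strategy <- match.arg(strategy)
    B <- as.integer(B)
    if (B < 1L) stop(.spaError("config", "B must be >= 1"))
    if (!is.null(seed)) set.seed(seed)
    if (statistic == "pstar")
        return(adaptivePStar(x, B = B, strategy = strategy,
                             phenotype = phenotype, traitType = traitType,
                             env = env, weights = weights, pairs = pairs,
                             normalize = normalize, keepNull = keepNull))
    d <- .unpack(x, phenotype, traitType, env)
    .checkShapes(d$g, d$y)
    if (d$traitType == "binary") .checkBinary(d$y)
    if (statistic == "I1E") {
        if (d$traitType != "binary")
            stop(.spaError("unsupported_trait",
                "I1E is defined for case-control traits only"))
        if (is.null(d$env))
            stop(.spaError("config", "I1E requires an env factor"))
    }
    if (strategy == "local" && is.null(d$env))
        stop(.spaError("config", "local permutation requires an env factor"))
    st <- if (statistic == "I2") {
        if (ncol(d$g) < 2) warning("I2 requires at least 2 SNPs; statistic is 0")
        .pairStructure(d$g, pairs)
    } else NULL
    obsY <- matrix(d$y, ncol = 1)
    observed <- .nullEnsemble(statistic, d$g, obsY, d$traitType, d$env,
                              weights, st, normalize)[1]
    Y <- .permutationMatrix(d$y, B, strategy, d$env)
    nullValues <- .nullEnsemble(statistic, d$g, Y, d$traitType, d$env,
                                weights, st, normalize)
    methods::new("SpaResult", statistic = statistic, value = observed,
                 pValue = permutationPValue(observed, nullValues),
                 B = B, strategy = strategy,
                 nullValues = if (keepNull) nullValues else numeric(0))
}

#' Adaptive min-p test p*
#'
#' The adaptive score is \eqn{p^* = \min\{p(I_1), p(I_2)\}}: it inherits
#' power from whichever of the marginal and interaction statistics is better
#' suited to the (unknown) genetic architecture. Its significance is
#' assessed on a single shared permutation ensemble (the min-p /
#' Westfall-Young construction): both statistics are evaluated on every
#' permutation, each permuted value is converted to a p-value by its
#' leave-one-out add-one rank within its own null ensemble, per-permutation
#' minima form the null of \eqn{p^*}, and
#' \deqn{p(p^*) = \frac{1 + \#\{b : p^*_b \le p^*_{obs}\}}{1 + B}.}
#' This avoids nested permutation (cost B instead of \eqn{B^2}) at
#' equivalent validity.
#'
#' With a single-SNP region \eqn{I_2} is uninformative and the test
#' degenerates to \eqn{p(I_1)} (with a warning).
#'
#' @inheritParams spaTest
#' @return A \linkS4class{SpaResult} with \code{statistic = "pstar"}; the
#'   observed \code{value} is the min-p score in \[0,1\].
#' @export
adaptivePStar <- function(x, B = 1000L, strategy = c("global", "local"),
                          seed = NULL, phenotype = NULL, traitType = "auto",
                          env = NULL, weights = NULL, pairs = NULL,
                          normalize = TRUE, keepNull = TRUE) {
    strategy <- match.arg(strategy)
    B <- as.integer(B)
    if (B < 1L) stop(.spaError("config", "B must be >= 1"))
    if (!is.null(seed)) set.seed(seed)
    d <- .unpack(x, phenotype, traitType, env)
    .checkShapes(d$g, d$y)
    if (d$traitType == "binary") .checkBinary(d$y)
    if (strategy == "local" && is.null(d$env))
        stop(.spaError("config", "local permutation requires an env factor"))
    if (ncol(d$g) < 2)
        warning("region has a single SNP: p* degenerates to p(I1)")
    st <- .pairStructure(d$g, pairs)
    obsY <- matrix(d$y, ncol = 1)
    Y <- .permutationMatrix(d$y, B, strategy, d$env)
    obs1 <- .i1Null(d$g, obsY, d$traitType, weights)[1]
    null1 <- .i1Null(d$g, Y, d$traitType, weights)
    obs2 <- .i2Null(st, obsY, normalize)[1]
    null2 <- .i2Null(st, Y, normalize)
    pObs <- min(permutationPValue(obs1, null1),
                permutationPValue(obs2, null2))
    pNull <- pmin(.looPValues(null1), .looPValues(null2))
    methods::new("SpaResult", statistic = "pstar", value = pObs,
                 pValue = (1 + sum(pNull <= pObs)) / (1 + B),
                 B = B, strategy = strategy,
                 nullValues = if (keepNull) pNull else numeric(0))
}

## ---- SpaResult accessors ---------------------------------------------------

#' @rdname SpaResult-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' Accessors for SpaResult
#'
#' @param object a \linkS4class{SpaResult}.
#' @return \code{pValue}: the permutation p-value; \code{observedStat}: the
#'   observed statistic (min-p score for \code{"pstar"});
#'   \code{nullDistribution}: the null ensemble (possibly empty);
#'   \code{nPermutations}: B; \code{permStrategy}: the permutation strategy.
#' @name SpaResult-accessors
NULL

#' @rdname SpaResult-accessors
#' @export
setMethod("pValue", "SpaResult", function(object) object@pValue)

#' @rdname SpaResult-accessors
#' @export
setGeneric("observedStat", function(object) standardGeneric("observedStat"))

#' @rdname SpaResult-accessors
#' @export
setMethod("observedStat", "SpaResult", function(object) object@value)

#' @rdname SpaResult-accessors
#' @export
setGeneric("nullDistribution",
           function(object) standardGeneric("nullDistribution"))

#' @rdname SpaResult-accessors
#' @export
setMethod("nullDistribution", "SpaResult",
          function(object) object@nullValues)

#' @rdname SpaResult-accessors
#' @export
setGeneric("nPermutations", function(object) standardGeneric("nPermutations"))

#' @rdname SpaResult-accessors
#' @export
setMethod("nPermutations", "SpaResult", function(object) object@B)

#' @rdname SpaResult-accessors
#' @export
setGeneric("permStrategy", function(object) standardGeneric("permStrategy"))

#' @rdname SpaResult-accessors
#' @export
setMethod("permStrategy", "SpaResult", function(object) object@strategy)

setMethod("show", "SpaResult", function(object) {
    cat(sprintf("SPA %s test (%s permutation, B = %d)\n", object@statistic,
                object@strategy, object@B))
    lab <- if (object@statistic == "pstar") "observed min-p" else "observed"
    cat(sprintf("  %s = %g, p-value = %g\n", lab, object@value,
                object@pValue))
    invisible(NULL)
})
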