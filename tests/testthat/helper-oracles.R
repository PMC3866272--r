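# Naive loop-based reference implementations, kept deliberately independent
# of the package's vectorized code paths.

oracleI1 <- function(g, y, trait, weights = NULL) {
    tot <- 0
    ybar <- mean(y)
    for (i in seq_len(ncol(g))) {
        n_i <- 0; a_i <- 0; carriers <- integer(0)
        for (s in seq_len(nrow(g))) {
            n_i <- n_i + g[s, i]
            if (trait == "binary") a_i <- a_i + g[s, i] * y[s]
            if (g[s, i] >= 1) carriers <- c(carriers, s)
        }
        if (n_i == 0) next
        dev <- if (trait == "binary") a_i / n_i - ybar
               else mean(y[carriers]) - ybar
        w <- if (is.null(weights)) n_i^2 else weights[i]
        tot <- tot + w * dev^2
    }
    tot
}

oracleI2 <- function(g, y, normalize = FALSE, pairs = NULL) {
    ybar <- mean(y)
    K <- ncol(g)
    if (is.null(pairs)) {
        pairs <- NULL
        for (i in seq_len(K - 1)) for (j in (i + 1):K)
            pairs <- rbind(pairs, c(i, j))
    }
    tot <- 0
    for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        ci <- g[, i] >= 1; cj <- g[, j] >= 1
        cells <- list(which(ci & !cj), which(!ci & cj), which(ci & cj))
        contrib <- 0
        for (cell in cells) {
            n <- length(cell)
            if (n == 0) next
            contrib <- contrib + n^2 * (mean(y[cell]) - ybar)^2
        }
        if (normalize) {
            nu <- sum(ci | cj)
            contrib <- if (nu > 0) contrib / nu else 0
        }
        tot <- tot + contrib
    }
    tot
}

oracleI1E <- function(g, y, env) {
    pibar <- mean(y)
    tot <- 0
    for (j in sort(unique(env))) for (i in seq_len(ncol(g))) {
        n_ij <- 0; a_ij <- 0
        for (s in which(env == j)) {
            n_ij <- n_ij + g[s, i]
            a_ij <- a_ij + g[s, i] * y[s]
        }
        if (n_ij == 0) next
        tot <- tot + n_ij^2 * (a_ij / n_ij - pibar)^2
    }
    tot
}

# Exhaustive-permutation p-value for a binary phenotype with fixed case
# count: evaluates `statFun(y)` over every distinct case placement.
oracleExhaustiveP <- function(y, statFun) {
    N <- length(y); nA <- sum(y == 1)
    obs <- statFun(y)
    combos <- utils::combn(N, nA)
    vals <- apply(combos, 2, function(cases) {
        yy <- numeric(N); yy[cases] <- 1
        statFun(yy)
    })
    mean(vals >= obs - 1e-12)
}

# Random small test instance (binary or continuous) for oracle comparisons.
randomInstance <- function(trait = "binary", N = NULL, K = NULL,
                           maxN = 50, maxK = 6) {
    if (is.null(N)) N <- sample(4:maxN, 1)
    if (is.null(K)) K <- sample(2:maxK, 1)
    g <- matrix(rbinom(N * K, 2, runif(1, 0.02, 0.2)), N, K)
    y <- if (trait == "binary") {
        nA <- sample(seq_len(N - 1), 1)
        sample(c(rep(1, nA), rep(0, N - nA)))
    } else rnorm(N)
    env <- sample(1:2, N, replace = TRUE)
    if (length(unique(env)) < 2) env[1:2] <- c(1L, 2L)
    list(g = g, y = y, env = env)
}
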