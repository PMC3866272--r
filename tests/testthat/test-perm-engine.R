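test_that("add-one permutation p-values follow the rank arithmetic", {
    expect_equal(permutationPValue(5, rep(1, 99)), 0.01)
    expect_equal(permutationPValue(2, rep(2, 9)), 1.0)
    # observed at the median of 999 distinct null values
    nullv <- seq_len(999)
    expect_equal(permutationPValue(500, nullv), (1 + 500) / 1000)
    # monotonicity at fixed null ensemble
    set.seed(3)
    nullv <- rnorm(200)
    obs <- sort(rnorm(50))
    p <- vapply(obs, permutationPValue, 0, nullValues = nullv)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p >= 1 / 201 & p <= 1))
})

test_that("global and local permutation preserve the right multisets", {
    set.seed(5)
    y <- c(rep(1, 7), rep(0, 13))
    env <- rep(c(1L, 2L), 10)
    for (i in 1:20) {
        yg <- permutePhenotype(y, "global")
        expect_equal(sum(yg), sum(y))
        yl <- permutePhenotype(y, "local", env = env)
        for (j in 1:2)
            expect_equal(sum(yl[env == j]), sum(y[env == j]))
    }
    expect_error(permutePhenotype(y, "local"), class = "spa_config_error")
})

test_that("N = 2 global permutation is uniform over {identity, swap}", {
    set.seed(11)
    draws <- replicate(600, permutePhenotype(c(1, 2), "global")[1])
    phat <- mean(draws == 1)
    expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("spaTest is deterministic given a seed", {
    set.seed(2)
    g <- matrix(rbinom(200 * 5, 2, 0.05), 200, 5)
    y <- sample(rep(c(1, 0), 100))
    for (stat in c("I1", "I2", "pstar")) {
        r1 <- spaTest(g, phenotype = y, statistic = stat, B = 200, seed = 42)
        r2 <- spaTest(g, phenotype = y, statistic = stat, B = 200, seed = 42)
        expect_identical(observedStat(r1), observedStat(r2))
        expect_identical(pValue(r1), pValue(r2))
        expect_identical(nullDistribution(r1), nullDistribution(r2))
    }
})

test_that("vectorized null ensembles equal per-permutation evaluation", {
    set.seed(8)
    g <- matrix(rbinom(60 * 4, 2, 0.15), 60, 4)
    y <- sample(rep(c(1, 0), 30))
    env <- rep(1:2, 30)
    B <- 40
    for (stat in c("I1", "I2", "I1E")) {
        res <- spaTest(g, phenotype = y, statistic = stat, env = env,
                       B = B, seed = 17)
        set.seed(17)
        Y <- spaRV:::.permutationMatrix(y, B, "global")
        naive <- vapply(seq_len(B), function(b) {
            switch(stat,
                I1 = computeI1(g, phenotype = Y[, b]),
                I2 = computeI2(g, phenotype = Y[, b]),
                I1E = computeI1E(g, phenotype = Y[, b], env = env))
        }, 0)
        expect_equal(nullDistribution(res), naive, tolerance = 1e-12)
    }
})

test_that("Monte-Carlo p-values converge to the exhaustive-permutation oracle", {
    set.seed(23)
    for (rep in 1:4) {
        N <- sample(5:7, 1)
        nA <- sample(2:(N - 2), 1)
        g <- matrix(rbinom(N * 3, 2, 0.4), N, 3)
        y <- sample(c(rep(1, nA), rep(0, N - nA)))
        pExact <- oracleExhaustiveP(y, function(yy)
            computeI1(g, phenotype = yy, traitType = "binary"))
        B <- 2000
        res <- spaTest(g, phenotype = y, statistic = "I1", B = B,
                       seed = 100 + rep)
        se <- sqrt(pExact * (1 - pExact) / B)
        expect_lt(abs(pValue(res) - (1 + B * pExact) / (1 + B)),
                  3 * se + 2 / B)
    }
})

test_that("a SNP carried only by cases is detected", {
    set.seed(29)
    g <- matrix(rbinom(100 * 3, 2, 0.02), 100, 3)
    y <- rep(c(1, 0), each = 50)
    g[, 1] <- 0
    g[1:12, 1] <- 1   # carried by 12 cases, no controls
    res <- spaTest(g, phenotype = y, statistic = "I1", B = 999, seed = 1)
    expect_lte(pValue(res), 0.05)
})

test_that("p* tracks p(I1) when the I2 arm is uninformative", {
    set.seed(37)
    g <- matrix(rbinom(80 * 4, 2, 0.1), 80, 4)
    g[, 3:4] <- 0   # the tested pair is monomorphic: I2 constant at 0
    y <- sample(rep(c(1, 0), 40))
    B <- 500
    ps <- spaTest(g, phenotype = y, statistic = "pstar", B = B, seed = 9,
                  pairs = rbind(c(3L, 4L)))
    i1 <- spaTest(g, phenotype = y, statistic = "I1", B = B, seed = 9)
    expect_lt(abs(pValue(ps) - pValue(i1)), 3 / (B + 1))
})

test_that("local permutation respects strata inside spaTest", {
    set.seed(43)
    g <- matrix(rbinom(60 * 3, 2, 0.1), 60, 3)
    env <- rep(1:3, each = 20)
    y <- c(rep(1, 15), rep(0, 5), rep(1, 5), rep(0, 15), rep(1, 10),
           rep(0, 10))
    res <- spaTest(g, phenotype = y, statistic = "I1E", env = env,
                   strategy = "local", B = 100, seed = 3)
    expect_s4_class(res, "SpaResult")
    expect_equal(permStrategy(res), "local")
    expect_error(spaTest(g, phenotype = y, statistic = "I1E", env = env,
                         strategy = "local", B = 0),
                 class = "spa_config_error")
    expect_error(spaTest(g, phenotype = y, statistic = "I1E",
                         strategy = "local", B = 10),
                 class = "spa_config_error")
})
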