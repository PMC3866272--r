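test_that("genotype draws honor the MAF law under HWE", {
    spec <- spaScenario("null1", mafLaw = "fixed", mafParams = 0.01)
    set.seed(1)
    g <- drawGenotypes(1e5, spec)
    freq <- colSums(g) / (2 * 1e5)
    se <- sqrt(0.01 * 0.99 / (2 * 1e5))
    expect_true(all(abs(freq - 0.01) < 3 * se + 1e-6))
    specU <- spaScenario("null1")
    set.seed(2)
    gu <- drawGenotypes(100, specU)
    maf <- attr(gu, "maf")
    expect_true(all(maf > 1e-4 & maf < 0.01))
    expect_length(maf, 20)
})

test_that("binary scenarios deliver the exact case/control composition", {
    for (sc in c("null1", "null2", "s1", "s4", "s7")) {
        spec <- spaScenario(sc, nCases = 40, nControls = 60)
        set.seed(10)
        ds <- simulateBinary(spec)
        y <- phenotype(ds)
        expect_equal(sum(y == 1), 40)
        expect_equal(sum(y == 0), 60)
        expect_equal(nrow(ds), 20)
        if (spec@envLevels > 0) expect_false(is.null(envFactor(ds)))
    }
})

test_that("null1 genotype and phenotype are independent", {
    spec <- spaScenario("null1", nCases = 50, nControls = 50,
                        mafLaw = "fixed", mafParams = 0.05)
    set.seed(3)
    cors <- replicate(200, {
        ds <- simulateBinary(spec)
        cor(genotypeMatrix(ds)[, 1], phenotype(ds))
    })
    cors <- cors[!is.na(cors)]
    expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})

test_that("logistic model limits behave as expected", {
    # all coefficients zero, baseline logit 0: P(case) = 0.5 everywhere
    spec <- spaScenario("null1", baseline = 0)
    g <- matrix(rbinom(100, 2, 0.01), 5, 20)
    eta <- spaRV:::.linearPredictor(spec, g, NULL, rep(0.01, 20))
    expect_equal(plogis(eta), rep(0.5, 5))
    # one huge-effect SNP: its carriers end up almost entirely as cases
    spec2 <- spaScenario("custom", causalSnps = 1L, effectSize = 10,
                         effectSigns = 1, mafLaw = "fixed",
                         mafParams = 0.2, nCases = 200, nControls = 200)
    set.seed(4)
    ds <- simulateBinary(spec2)
    carrier <- genotypeMatrix(ds)[, 1] >= 1
    y <- phenotype(ds)
    expect_gt(mean(carrier[y == 1]), 0.9)
    expect_lt(mean(carrier[y == 0]), 0.1)
})

test_that("continuous simulation recovers its generating parameters", {
    spec <- spaScenario("custom", traitType = "continuous",
                        nSubjects = 4000, baseline = 2, noiseSd = 1)
    set.seed(5)
    ds <- simulateContinuous(spec)
    y <- phenotype(ds)
    expect_lt(abs(mean(y) - 2), 3 / sqrt(4000))
    # single causal SNP: regression recovers beta within 3 SE
    spec2 <- spaScenario("custom", traitType = "continuous",
                         nSubjects = 5000, causalSnps = 1L,
                         effectSize = 1.5, effectSigns = 1,
                         mafLaw = "fixed", mafParams = 0.05)
    set.seed(6)
    ds2 <- simulateContinuous(spec2)
    fit <- summary(lm(phenotype(ds2) ~ genotypeMatrix(ds2)[, 1]))
    expect_lt(abs(fit$coefficients[2, 1] - 1.5),
              3 * fit$coefficients[2, 2])
    expect_error(spaScenario("custom", traitType = "continuous",
                             noiseSd = -1))
})

test_that("environmental draws follow the level probabilities", {
    spec <- spaScenario("null2", nCases = 10, nControls = 10)
    set.seed(7)
    e <- simulateEnv(1e4, spec)
    expect_lt(abs(mean(e == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
    spec1 <- spaScenario("custom", envLevels = 1L, envProbs = 1,
                         envMainEffect = 0)
    expect_true(all(simulateEnv(50, spec1) == 1L))
})

test_that("simulation is deterministic under a fixed seed", {
    spec <- spaScenario("s7", nCases = 30, nControls = 30)
    d1 <- simulateScenario(spec, seed = 123)
    d2 <- simulateScenario(spec, seed = 123)
    expect_identical(genotypeMatrix(d1), genotypeMatrix(d2))
    expect_identical(phenotype(d1), phenotype(d2))
    expect_identical(envFactor(d1), envFactor(d2))
})

test_that("scenario configs round-trip losslessly", {
    spec <- spaScenario("custom", nSnps = 12L, traitType = "binary",
                        nCases = 111, nControls = 222,
                        mafLaw = "uniform", mafParams = c(0.0002, 0.013),
                        causalSnps = c(2L, 5L), effectType = "maf_inverse",
                        effectSize = 0.37, effectSigns = c(1, -1),
                        interactionPairs = rbind(c(1L, 3L), c(4L, 6L)),
                        interactionCoefs = c(2.25, -0.5),
                        envLevels = 3L, envProbs = c(0.2, 0.3, 0.5),
                        envMainEffect = c(0, log(2), -0.1),
                        gxeTerms = rbind(c(2L, 2L)), gxeCoefs = 1.75,
                        baseline = qlogis(0.013))
    path <- tempfile(fileext = ".cfg")
    writeScenarioConfig(spec, path)
    back <- readScenarioConfig(path)
    for (sl in methods::slotNames("ScenarioSpec"))
        expect_identical(methods::slot(back, sl), methods::slot(spec, sl),
                         label = sl)
    # registry scenarios round-trip too
    for (sc in c("null1", "null2", "s3", "s5", "s8")) {
        sp <- spaScenario(sc)
        writeScenarioConfig(sp, path)
        expect_identical(readScenarioConfig(path)@interactionCoefs,
                         sp@interactionCoefs)
        expect_identical(readScenarioConfig(path)@envMainEffect,
                         sp@envMainEffect)
    }
})

test_that("scenario validity catches structural mistakes", {
    expect_error(spaScenario("s1", causalSnps = c(1L, 25L),
                             effectSigns = c(1, 1)))
    expect_error(spaScenario("custom", interactionPairs = rbind(c(1L, 1L)),
                             interactionCoefs = 1))
    expect_error(spaScenario("custom", envLevels = 2L,
                             envProbs = c(0.7, 0.7),
                             envMainEffect = c(0, 1)))
    expect_error(spaScenario("null1", causalSnps = 1L, effectSize = 1,
                             effectSigns = 1))
})
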