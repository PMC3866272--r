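test_that("influencePR matches hand-computed partitions", {
    # one cell: cell mean equals grand mean, score is zero
    expect_equal(influencePR(c(3, 1, 4, 1), rep(1, 4)), 0)
    # binary Y, two balanced cells
    expect_equal(influencePR(c(1, 1, 0, 0), c("a", "a", "b", "b")), 2)
    # continuous Y, singleton cells
    expect_equal(influencePR(c(2, 4, 6), 1:3), 8)
    expect_error(influencePR(c(1, 0), c(1, 1, 2)), class = "spa_shape_error")
})

test_that("I1 matches hand-computed values and degenerate cases", {
    # monomorphic region: empty sum
    expect_equal(computeI1(matrix(0, 4, 3), phenotype = c(1, 1, 0, 0)), 0)
    # two SNPs: het case carrier (n=1, pi=1), hom control carrier (n=2, pi=0)
    g <- matrix(0, 4, 2); g[1, 1] <- 1; g[3, 2] <- 2
    expect_equal(computeI1(g, phenotype = c(1, 1, 0, 0)), 1.25)
    # alleles split between cases and controls in proportion pibar
    g1 <- matrix(c(1, 0, 1, 0), 4, 1)
    expect_equal(computeI1(g1, phenotype = c(1, 1, 0, 0)), 0)
    expect_error(computeI1(g, phenotype = rep(1, 4)),
                 class = "spa_degenerate_phenotype_error")
})

test_that("I1 weights must sum to one and replace the n^2 weight", {
    g <- matrix(0, 4, 2); g[1, 1] <- 1; g[3, 2] <- 2
    y <- c(1, 1, 0, 0)
    expect_error(computeI1(g, phenotype = y, weights = c(0.9, 0.2)),
                 class = "spa_invalid_weights_error")
    expect_error(computeI1(g, phenotype = y, weights = 1),
                 class = "spa_invalid_weights_error")
    # w1*(1-0.5)^2 + w2*(0-0.5)^2
    expect_equal(computeI1(g, phenotype = y, weights = c(0.25, 0.75)), 0.25)
    set.seed(41)
    for (rep in 1:10) {
        inst <- randomInstance("binary")
        w <- runif(ncol(inst$g)); w <- w / sum(w)
        expect_equal(computeI1(inst$g, phenotype = inst$y, weights = w),
                     oracleI1(inst$g, inst$y, "binary", w),
                     tolerance = 1e-12)
    }
})

test_that("pair cells partition carriers correctly", {
    g <- rbind(c(1, 2), c(1, 0), c(0, 1))
    pc <- buildPairCells(g, 1, 2)
    expect_equal(pc@mm, 1L); expect_equal(pc@mM, 2L)
    expect_equal(pc@Mm, 3L); expect_equal(pc@nUnion, 3L)
    # no carriers at either SNP
    pc0 <- buildPairCells(matrix(0, 3, 2), 1, 2)
    expect_equal(pc0@nUnion, 0L)
    expect_length(pc0@mM, 0)
    # single hom carrier at SNP i
    pc1 <- buildPairCells(rbind(c(2, 0), c(0, 0)), 1, 2)
    expect_equal(pc1@mM, 1L)
    expect_length(pc1@Mm, 0); expect_length(pc1@mm, 0)
    expect_error(buildPairCells(g, 2, 2), class = "spa_invalid_pair_error")
    expect_error(buildPairCells(g, 1, 5), class = "spa_invalid_pair_error")
})

test_that("I2 matches hand-computed values and is column-order invariant", {
    # N=6, cases s1,s2: s1 in mm, s2 in mM, s3 in Mm; the raw three-cell
    # sum is 1.0 and the pair's carrier union has 3 subjects
    g <- matrix(0, 6, 2); g[1, ] <- 1; g[2, 1] <- 1; g[3, 2] <- 1
    y <- c(1, 1, 0, 0, 0, 0)
    expect_equal(computeI2(g, phenotype = y, normalize = FALSE), 1.0)
    expect_equal(computeI2(g, phenotype = y), 1 / 3)
    # no co-carriers, each SNP's carriers at case fraction pibar -> 0
    g2 <- matrix(0, 4, 2); g2[1, 1] <- 1; g2[2, 1] <- 1
    g2[3, 2] <- 1; g2[4, 2] <- 1
    expect_equal(computeI2(g2, phenotype = c(1, 0, 1, 0)), 0)
    # single-SNP region: statistic defined as 0 with a warning
    expect_warning(v <- computeI2(matrix(c(1, 0, 0, 1), 4, 1),
                                  phenotype = c(1, 1, 0, 0)))
    expect_equal(v, 0)
    set.seed(7)
    for (rep in 1:10) {
        inst <- randomInstance("binary")
        perm <- sample(ncol(inst$g))
        expect_equal(computeI2(inst$g, phenotype = inst$y),
                     computeI2(inst$g[, perm], phenotype = inst$y),
                     tolerance = 1e-12)
    }
    expect_error(computeI2(g, phenotype = y, pairs = rbind(c(1, 1))),
                 class = "spa_invalid_pair_error")
    expect_error(computeI2(g, phenotype = y,
                           pairs = rbind(c(1, 2), c(2, 1))),
                 class = "spa_invalid_pair_error")
})

test_that("I1E matches hand computation and reduces to I1 when J = 1", {
    g <- matrix(c(1, 0, 0, 1), 4, 1)
    y <- c(1, 1, 0, 0)
    expect_equal(computeI1E(g, phenotype = y, env = c(1, 2, 1, 2)), 0.5)
    set.seed(13)
    for (rep in 1:10) {
        inst <- randomInstance("binary")
        expect_equal(
            computeI1E(inst$g, phenotype = inst$y,
                       env = rep(1L, length(inst$y))),
            computeI1(inst$g, phenotype = inst$y),
            tolerance = 1e-12)
    }
    expect_error(computeI1E(g, phenotype = c(0.2, 1.4, 0, 3),
                            env = c(1, 2, 1, 2)),
                 class = "spa_unsupported_trait_error")
    expect_error(computeI1E(g, phenotype = y, env = c(1, 3, 1, 3)),
                 class = "spa_config_error")
})

test_that("vectorized statistics equal the naive loop oracles", {
    set.seed(20)
    for (trait in c("binary", "continuous")) {
        for (rep in 1:30) {
            inst <- randomInstance(trait)
            expect_equal(computeI1(inst$g, phenotype = inst$y,
                                   traitType = trait),
                         oracleI1(inst$g, inst$y, trait),
                         tolerance = 1e-10)
            expect_equal(computeI2(inst$g, phenotype = inst$y,
                                   traitType = trait, normalize = FALSE),
                         oracleI2(inst$g, inst$y),
                         tolerance = 1e-10)
            expect_equal(computeI2(inst$g, phenotype = inst$y,
                                   traitType = trait),
                         oracleI2(inst$g, inst$y, normalize = TRUE),
                         tolerance = 1e-10)
            if (trait == "binary")
                expect_equal(computeI1E(inst$g, phenotype = inst$y,
                                        env = inst$env),
                             oracleI1E(inst$g, inst$y, inst$env),
                             tolerance = 1e-10)
        }
    }
})

test_that("case/control relabeling is a symmetry of binary I1", {
    # swapping labels maps pi-hat -> 1 - pi-hat and pibar -> 1 - pibar,
    # so every squared deviation is preserved, whatever N_A/N_U
    set.seed(99)
    inst <- randomInstance("binary", N = 20)
    yBal <- sample(rep(c(1, 0), 10))
    expect_equal(computeI1(inst$g, phenotype = yBal),
                 computeI1(inst$g, phenotype = 1 - yBal),
                 tolerance = 1e-12)
    yUnb <- c(rep(1, 5), rep(0, 15))
    g <- matrix(rbinom(20 * 4, 2, 0.3), 20, 4)
    expect_equal(computeI1(g, phenotype = yUnb),
                 computeI1(g, phenotype = 1 - yUnb), tolerance = 1e-12)
})

test_that("a zero-genotype subject affects binary I1 only through pibar", {
    set.seed(31)
    inst <- randomInstance("binary", N = 30, K = 4)
    gAug <- rbind(inst$g, 0)
    yAug <- c(inst$y, 0)
    # recompute from the original allele counts with the new grand mean
    n <- colSums(inst$g)
    a <- colSums(inst$g * inst$y)
    expect_equal(computeI1(gAug, phenotype = yAug),
                 sum((a - n * mean(yAug))^2), tolerance = 1e-12)
})

test_that("carrier-count I1 equals the carrier-cell influencePR term", {
    set.seed(55)
    inst <- randomInstance("binary", N = 40, K = 1)
    carrier <- inst$g[, 1] >= 1
    if (!any(carrier)) inst$g[1:3, 1] <- 1
    carrier <- inst$g[, 1] >= 1
    # recode hom carriers to 1 so allele counts become carrier counts
    gCarrier <- matrix(pmin(inst$g[, 1], 1), ncol = 1)
    full <- influencePR(inst$y, ifelse(carrier, "carrier", "none"))
    nonCarrierTerm <- sum(!carrier)^2 *
        (mean(inst$y[!carrier]) - mean(inst$y))^2
    expect_equal(computeI1(gCarrier, phenotype = inst$y),
                 full - nonCarrierTerm, tolerance = 1e-10)
})

test_that("rare-variant filter keeps polymorphic columns under the cutoff", {
    set.seed(61)
    g <- matrix(rbinom(100 * 3, 2, 0.2), 100, 3)
    colnames(g) <- c("a", "b", "c")
    expect_equal(rareVariantFilter(g, 0.5), g, ignore_attr = TRUE)
    # monomorphic column dropped at any threshold
    g0 <- cbind(g, d = 0)
    expect_equal(colnames(rareVariantFilter(g0, 0.5)), c("a", "b", "c"))
    # 12 minor alleles in N=100 -> MAF 0.06
    g6 <- matrix(0, 100, 2)
    g6[1:12, 1] <- 1
    g6[1:2, 2] <- 1
    colnames(g6) <- c("maf06", "maf01")
    expect_equal(colnames(rareVariantFilter(g6, 0.05)), "maf01")
    expect_equal(colnames(rareVariantFilter(g6, 0.07)), c("maf06", "maf01"))
    expect_error(rareVariantFilter(matrix(0, 10, 2), 0.05),
                 class = "spa_empty_region_error")
    # SpaDataSet route records dropped ids
    ds <- SpaDataSet(g6, phenotype = rep(c(1, 0), 50))
    out <- rareVariantFilter(ds, 0.05)
    expect_equal(S4Vectors::metadata(out)$droppedSnps, "maf06")
    expect_equal(nrow(out), 1L)
})

test_that("statistics are nonnegative on random inputs", {
    set.seed(77)
    for (rep in 1:20) {
        inst <- randomInstance(sample(c("binary", "continuous"), 1))
        trait <- if (all(inst$y %in% c(0, 1))) "binary" else "continuous"
        expect_gte(computeI1(inst$g, phenotype = inst$y, traitType = trait), 0)
        expect_gte(computeI2(inst$g, phenotype = inst$y, traitType = trait), 0)
        if (trait == "binary")
            expect_gte(computeI1E(inst$g, phenotype = inst$y,
                                  env = inst$env), 0)
    }
})

test_that("SpaDataSet validates its contents and recodes missing calls", {
    g <- matrix(c(1, 0, NA, 0, 2, 0, 0, 1), 4, 2)
    expect_message(ds <- SpaDataSet(g, phenotype = c(1, 0, 1, 0)),
                   "missing")
    expect_equal(genotypeMatrix(ds)[3, 1], 0L, ignore_attr = TRUE)
    expect_equal(traitType(ds), "binary")
    expect_error(SpaDataSet(matrix(3, 2, 1), phenotype = c(1, 0)))
    expect_error(SpaDataSet(matrix(0:1, 2, 1), phenotype = c(1, 1)))
    ds2 <- SpaDataSet(matrix(0:1, 4, 2), phenotype = c(0.1, 2, 3, 1),
                      env = c("A", "B", "A", "B"))
    expect_equal(traitType(ds2), "continuous")
    expect_equal(envFactor(ds2), c(1L, 2L, 1L, 2L))
})
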