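## Core SPA statistics.
##
## Every score below is a partition-retention (PR) influence measure: a sum,
## over partition cells, of n_c^2 (Ybar_c - Ybar)^2, where n_c is a cell
## weight and Ybar_c the cell mean of the trait. For a case-control trait the
## cell mean is a case fraction and Ybar = pibar = N_A/N. All vectorized
## evaluation uses the exact identity
##     n_c^2 (S_c/n_c - ref)^2 = (S_c - n_c * ref)^2
## with S_c the cell sum of the (possibly permuted) trait, which makes empty
## cells (S_c = n_c = 0) contribute exactly 0 without special-casing.

#' Partition-retention influence measure
#'
#' The reference influence score all SPA statistics specialize: given a
#' partition of the subjects into non-overlapping cells,
#' \deqn{I = \sum_i n_i^2 (\bar Y_i - \bar Y)^2,}
#' where \eqn{n_i} is the size of cell \eqn{i}, \eqn{\bar Y_i} its mean
#' response and \eqn{\bar Y} the grand mean. For a 0/1 case-control trait
#' \eqn{\bar Y_i} is the case fraction in the cell and \eqn{\bar Y = N_A/N}.
#' Empty cells contribute 0.
#'
#' @param phenotype numeric response vector.
#' @param partition vector of the same length assigning each subject to
#'   exactly one cell (any label type).
#' @return The nonnegative influence score.
#' @examples
#' influencePR(c(1, 1, 0, 0), c("a", "a", "b", "b"))  # 2
#' @export
influencePR <- function(phenotype, partition) {
    y <- as.numeric(phenotype)
    if (length(partition) != length(y))
        stop(.spaError("shape",
            "partition length does not match the number of subjects"))
    if (length(y) < 2)
        stop(.spaError("shape", "at least 2 subjects are required"))
    f <- factor(partition)
    n <- tabulate(f, nbins = nlevels(f))
    s <- vapply(split(y, f), sum, numeric(1))
    ybar <- mean(y)
    sum((s - n * ybar)^2)
}

## ---- vectorized null-ensemble workers -------------------------------------
## g: N x K dosage matrix; Y: N x B matrix whose columns are (permuted)
## phenotypes. All columns of Y share the same mean, so the reference mean is
## a scalar. Each worker returns the length-B vector of statistic values.

.i1Null <- function(g, Y, traitType, weights = NULL) {
    ref <- mean(Y[, 1])
    if (traitType == "binary") {
        n <- colSums(g)                       # allele counts per SNP
        A <- crossprod(g, Y)                  # case alleles per SNP (K x B)
        if (is.null(weights))
            return(colSums((A - n * ref)^2))
        dev <- A / n - ref                    # pi-hat minus pibar
        dev[n == 0, ] <- 0
        return(colSums(weights * dev^2))
    }
    C <- (g >= 1) + 0                         # carrier indicators
    cc <- colSums(C)                          # carrier counts
    n <- colSums(g)                           # allele-count weights
    S <- crossprod(C, Y)                      # carrier trait sums (K x B)
    dev <- S / cc - ref                       # carrier mean minus grand mean
    dev[cc == 0, ] <- 0
    if (is.null(weights)) colSums((n * dev)^2) else colSums(weights * dev^2)
}

# Precompute the pair-cell structure once per dataset; reused for every
# permutation. Co-carrier columns are kept only for pairs that actually have
# co-carriers (rare variants make these very sparse).
.pairStructure <- function(g, pairs = NULL) {
    K <- ncol(g)
    if (is.null(pairs)) {
        if (K < 2) return(NULL)
        pairs <- t(utils::combn(K, 2L))
    } else {
        pairs <- matrix(as.integer(pairs), ncol = 2L)
        if (any(pairs < 1L) || any(pairs > K) || any(pairs[, 1] == pairs[, 2]))
            stop(.spaError("invalid_pair", "pair indices out of range or i = j"))
        key <- paste(pmin(pairs[, 1], pairs[, 2]),
                     pmax(pairs[, 1], pairs[, 2]))
        if (anyDuplicated(key))
            stop(.spaError("invalid_pair", "duplicate SNP pair"))
    }
    C <- (g >= 1) + 0
    nC <- colSums(C)
    P <- nrow(pairs)
    i <- pairs[, 1]; j <- pairs[, 2]
    # which pairs can have co-carriers at all
    active <- which(nC[i] > 0 & nC[j] > 0)
    nCo <- numeric(P)
    coIdx <- integer(0)
    D <- NULL
    if (length(active)) {
        Dall <- C[, i[active], drop = FALSE] * C[, j[active], drop = FALSE]
        cs <- colSums(Dall)
        keep <- cs > 0
        nCo[active] <- cs
        if (any(keep)) {
            D <- Dall[, keep, drop = FALSE]
            coIdx <- active[keep]
        }
    }
    list(i = i, j = j, P = P, C = C, nC = nC, D = D, coIdx = coIdx,
         nCo = nCo, nUnion = nC[i] + nC[j] - nCo)
}

.i2Null <- function(st, Y, normalize = FALSE) {
    B <- ncol(Y)
    if (is.null(st)) return(numeric(B))
    ref <- mean(Y[, 1])
    AC <- crossprod(st$C, Y)                  # trait sums over carriers (K x B)
    ACo <- matrix(0, st$P, B)
    if (!is.null(st$D))
        ACo[st$coIdx, ] <- crossprod(st$D, Y) # trait sums over co-carriers
    SmM <- AC[st$i, , drop = FALSE] - ACo
    SMm <- AC[st$j, , drop = FALSE] - ACo
    nmM <- st$nC[st$i] - st$nCo
    nMm <- st$nC[st$j] - st$nCo
    contrib <- (SmM - nmM * ref)^2 + (SMm - nMm * ref)^2 +
               (ACo - st$nCo * ref)^2
    if (normalize) {
        w <- ifelse(st$nUnion > 0, 1 / st$nUnion, 0)
        contrib <- contrib * w
    }
    colSums(contrib)
}

.i1eNull <- function(g, Y, env) {
    ref <- mean(Y[, 1])
    out <- numeric(ncol(Y))
    for (j in seq_len(max(env))) {
        idx <- which(env == j)
        gj <- g[idx, , drop = FALSE]
        nj <- colSums(gj)
        Aj <- crossprod(gj, Y[idx, , drop = FALSE])
        out <- out + colSums((Aj - nj * ref)^2)
    }
    out
}

## ---- user-facing statistics ------------------------------------------------

#' Marginal rare-variant association score I1
#'
#' Sums, over the K SNPs of the region, the squared count-weighted deviation
#' of each SNP's conditional trait mean from the grand mean. For a
#' case-control trait, with \eqn{n_i} the total minor-allele count at SNP i
#' and \eqn{\hat\pi_i} the fraction of those alleles carried by cases,
#' \deqn{I_1 = \sum_i n_i^2 (\hat\pi_i - \bar\pi)^2, \qquad
#'       \bar\pi = N_A/N.}
#' For a continuous trait the case fraction is replaced by the mean trait
#' among carriers (subjects with at least one minor allele) and the grand
#' mean of the trait; the weight \eqn{n_i} remains the allele count. SNPs
#' with no observed minor allele contribute 0.
#'
#' When \code{weights} (summing to 1) are supplied, the implicit
#' \eqn{n_i^2} weight is replaced by the user weight on the squared
#' deviation — the weighted generalization of the score.
#'
#' @param x a \linkS4class{SpaDataSet}, or a subjects-by-SNPs dosage matrix.
#' @param phenotype,traitType,env only used when \code{x} is a matrix.
#' @param weights optional K-vector of nonnegative weights summing to 1.
#' @return The nonnegative observed score.
#' @seealso \code{\link{spaTest}} for permutation p-values.
#' @examples
#' g <- matrix(c(1, 0, 0, 0, 0, 0, 2, 0), nrow = 4)
#' computeI1(g, phenotype = c(1, 1, 0, 0))  # 1.25
#' @export
computeI1 <- function(x, phenotype = NULL, traitType = "auto",
                      weights = NULL, env = NULL) {
    d <- .unpack(x, phenotype, traitType, env)
    .checkShapes(d$g, d$y)
    if (d$traitType == "binary") .checkBinary(d$y)
    if (!is.null(weights)) {
        if (length(weights) != ncol(d$g))
            stop(.spaError("invalid_weights", "one weight per SNP required"))
        if (abs(sum(weights) - 1) > 1e-8)
            stop(.spaError("invalid_weights", "weights must sum to 1"))
    }
    .i1Null(d$g, matrix(d$y, ncol = 1), d$traitType, weights)[1]
}

#' PairCells: carrier partition for one SNP pair
#'
#' @slot snpI,snpJ the SNP indices.
#' @slot mM subjects carrying a minor allele at SNP i only.
#' @slot Mm subjects carrying a minor allele at SNP j only.
#' @slot mm subjects carrying minor alleles at both SNPs.
#' @slot nUnion number of subjects carrying at least one minor allele at
#'   either SNP (the MM cell, no minor allele at either, is excluded).
#' @export
setClass("PairCells",
    representation(snpI = "integer", snpJ = "integer", mM = "integer",
                   Mm = "integer", mm = "integer", nUnion = "integer"))

setValidity("PairCells", function(object) {
    sets <- list(object@mM, object@Mm, object@mm)
    all_ <- unlist(sets)
    msg <- NULL
    if (anyDuplicated(all_))
        msg <- c(msg, "mM, Mm and mm must be pairwise disjoint")
    if (length(all_) != object@nUnion)
        msg <- c(msg, "|mM| + |Mm| + |mm| must equal nUnion")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PairCells", function(object) {
    cat(sprintf("PairCells (SNP %d, SNP %d): |mM|=%d |Mm|=%d |mm|=%d (union %d)\n",
                object@snpI, object@snpJ, length(object@mM),
                length(object@Mm), length(object@mm), object@nUnion))
    invisible(NULL)
})

#' Carrier cells for a pair of SNPs
#'
#' Partitions the carriers of a SNP pair into the three interaction cells:
#' \code{mM} (minor allele at i only), \code{Mm} (at j only) and \code{mm}
#' (at both). Carrier status means dosage >= 1. Subjects with no minor allele
#' at either SNP (the MM cell) are excluded.
#'
#' @param x a \linkS4class{SpaDataSet} or dosage matrix.
#' @param i,j distinct SNP column indices.
#' @return A \linkS4class{PairCells} object.
#' @export
buildPairCells <- function(x, i, j) {
    g <- if (methods::is(x, "SpaDataSet")) genotypeMatrix(x)
         else .sanitizeDosage(x)
    i <- as.integer(i); j <- as.integer(j)
    if (i == j) stop(.spaError("invalid_pair", "i and j must differ"))
    if (min(i, j) < 1L || max(i, j) > ncol(g))
        stop(.spaError("invalid_pair", "SNP index out of range"))
    ci <- g[, i] >= 1; cj <- g[, j] >= 1
    mM <- which(ci & !cj); Mm <- which(!ci & cj); mm <- which(ci & cj)
    methods::new("PairCells", snpI = i, snpJ = j, mM = mM, Mm = Mm, mm = mm,
                 nUnion = length(mM) + length(Mm) + length(mm))
}

#' Pairwise gene-gene interaction score I2
#'
#' For every requested SNP pair, partitions the pair's carriers into the
#' \code{mM}/\code{Mm}/\code{mm} cells (see \code{\link{buildPairCells}})
#' and accumulates the PR contributions
#' \deqn{I_2 = \sum_{i<j} \frac{1}{n_{union}}
#'       \sum_{c \in \{mM, Mm, mm\}} n_c^2 (\bar Y_c - \bar Y)^2,}
#' with \eqn{\bar Y_c} the case fraction (binary) or mean trait (continuous)
#' in the cell, \eqn{n_c} the cell's subject count, and \eqn{n_{union}} the
#' number of subjects carrying a minor allele at either SNP of the pair.
#' Empty cells and pairs without carriers contribute 0.
#'
#' The per-pair division by \eqn{n_{union}} keeps the large single-SNP
#' carrier cells (which duplicate marginal information across the
#' \eqn{K-1} pairs every SNP belongs to) from dominating the sum, so the
#' score stays focused on joint-carrier structure; \code{normalize = FALSE}
#' gives the plain unnormalized sum (permutation inference is valid either
#' way, the choice only reweights pairs).
#'
#' @inheritParams computeI1
#' @param pairs optional two-column matrix of SNP index pairs; default all
#'   \eqn{K(K-1)/2} pairs.
#' @param normalize divide each pair's contribution by its carrier union
#'   size (default TRUE).
#' @return The nonnegative observed score; 0 (with a warning) when the
#'   region has a single SNP.
#' @export
computeI2 <- function(x, phenotype = NULL, traitType = "auto",
                      pairs = NULL, normalize = TRUE, env = NULL) {
    d <- .unpack(x, phenotype, traitType, env)
    .checkShapes(d$g, d$y)
    if (d$traitType == "binary") .checkBinary(d$y)
    if (ncol(d$g) < 2) {
        warning("I2 requires at least 2 SNPs; returning 0")
        return(0)
    }
    st <- .pairStructure(d$g, pairs)
    .i2Null(st, matrix(d$y, ncol = 1), normalize)[1]
}

#' Gene-environment interaction score I1E
#'
#' Extends \code{\link{computeI1}} by crossing the per-SNP allele partitions
#' with the J non-overlapping strata of a categorical environmental factor:
#' \deqn{I_1^E = \sum_{j=1}^{J} \sum_{i=1}^{K}
#'       n_{ij}^2 (\hat\pi_{ij} - \bar\pi)^2,}
#' where \eqn{n_{ij}} is the minor-allele count of SNP i among subjects at
#' env level j and \eqn{\hat\pi_{ij}} the fraction of those alleles carried
#' by cases. Deviations are measured from the global case fraction
#' \eqn{\bar\pi = N_A/N}, so the score retains the environmental marginal
#' signal (its global-permutation null tests "no association at all"; the
#' stratum-local permutation null removes the environmental marginal
#' effect). Only case-control traits are supported. With J = 1 the score
#' equals \eqn{I_1}.
#'
#' @inheritParams computeI1
#' @param env integer env levels 1..J when \code{x} is a matrix (taken from
#'   the object otherwise).
#' @return The nonnegative observed score.
#' @export
computeI1E <- function(x, phenotype = NULL, env = NULL) {
    d <- .unpack(x, phenotype, "auto", env)
    .checkShapes(d$g, d$y)
    if (d$traitType != "binary")
        stop(.spaError("unsupported_trait",
            "I1E is defined for case-control traits only"))
    .checkBinary(d$y)
    if (is.null(d$env))
        stop(.spaError("config", "an environmental factor is required"))
    env <- as.integer(d$env)
    if (length(env) != nrow(d$g))
        stop(.spaError("shape", "env length does not match subjects"))
    if (!all(seq_len(max(env)) %in% env))
        stop(.spaError("config", "every env level 1..J must be occupied"))
    .i1eNull(d$g, matrix(d$y, ncol = 1), env)[1]
}

#' Restrict a region to its rare polymorphic variants
#'
#' Keeps SNP columns whose sample minor-allele frequency (allele count over
#' 2N non-missing calls) is strictly positive and at most
#' \code{mafThreshold}. Subject order is preserved; kept and dropped SNP ids
#' are recorded in the result's metadata (attribute \code{"dropped"} for a
#' matrix input).
#'
#' @param x a \linkS4class{SpaDataSet} or dosage matrix.
#' @param mafThreshold MAF cutoff in (0, 0.5]; the conventional rare-variant
#'   cutoff for real-data analysis is 0.05.
#' @return Object of the same kind as \code{x}, with only the rare
#'   polymorphic columns.
#' @export
rareVariantFilter <- function(x, mafThreshold = 0.05) {
    if (mafThreshold <= 0 || mafThreshold > 0.5)
        stop(.spaError("config", "mafThreshold must lie in (0, 0.5]"))
    isDs <- methods::is(x, "SpaDataSet")
    g <- if (isDs) genotypeMatrix(x) else as.matrix(x)
    nonmiss <- colSums(!is.na(g))
    maf <- colSums(g, na.rm = TRUE) / (2 * nonmiss)
    keep <- !is.na(maf) & maf > 0 & maf <= mafThreshold
    ids <- colnames(g)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(g)))
    if (!any(keep))
        stop(.spaError("empty_region", paste0(
            "no polymorphic variant with MAF <= ", mafThreshold,
            " in region of ", ncol(g), " SNPs")))
    if (isDs) {
        out <- x[keep, ]
        S4Vectors::metadata(out)$droppedSnps <- ids[!keep]
        S4Vectors::metadata(out)$keptSnps <- ids[keep]
        out
    } else {
        out <- g[, keep, drop = FALSE]
        attr(out, "dropped") <- ids[!keep]
        out
    }
}
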