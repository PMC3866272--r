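#' Build a SpaDataSet from a genotype matrix and a phenotype
#'
#' @param genotypes integer matrix of minor-allele dosages with subjects in
#'   rows and SNPs in columns (entries 0/1/2; \code{NA} is recoded to 0 and
#'   counted in a message, the conservative convention for rare variants).
#' @param phenotype numeric vector of length \code{nrow(genotypes)}; 0/1 for
#'   a case-control trait.
#' @param traitType \code{"auto"} (default; exactly \{0,1\} means binary),
#'   \code{"binary"} or \code{"continuous"}.
#' @param env optional environmental factor: integer level codes, a factor,
#'   or a character vector (encoded to 1..J in first-appearance order).
#' @param snpIds,sampleIds optional identifiers; defaults are taken from
#'   \code{dimnames(genotypes)} or generated.
#' @param maf optional known per-SNP minor-allele frequencies, stored in
#'   \code{rowData}.
#'
#' @return A \linkS4class{SpaDataSet}.
#' @examples
#' g <- matrix(c(1, 0, 0, 0, 0, 0, 2, 0), nrow = 4)
#' ds <- SpaDataSet(g, phenotype = c(1, 1, 0, 0))
#' genotypeMatrix(ds)
#' @export
SpaDataSet <- function(genotypes, phenotype,
                       traitType = c("auto", "binary", "continuous"),
                       env = NULL, snpIds = NULL, sampleIds = NULL,
                       maf = NULL) {
    traitType <- match.arg(traitType)
    genotypes <- as.matrix(genotypes)
    N <- nrow(genotypes); K <- ncol(genotypes)
    if (length(phenotype) != N)
        stop(.spaError("shape",
            "phenotype length does not match the number of subjects"))
    if (traitType == "auto")
        traitType <- if (all(phenotype %in% c(0, 1))) "binary" else "continuous"
    nMissing <- sum(is.na(genotypes))
    if (nMissing > 0) {
        message("recoding ", nMissing, " missing genotype call(s) to 0")
        genotypes[is.na(genotypes)] <- 0L
    }
    if (is.null(snpIds)) snpIds <- colnames(genotypes)
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(K))
    if (is.null(sampleIds)) sampleIds <- rownames(genotypes)
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(N))
    cd <- S4Vectors::DataFrame(phenotype = as.numeric(phenotype),
                               row.names = sampleIds)
    if (!is.null(env)) {
        if (is.factor(env) || is.character(env)) {
            lev <- unique(as.character(env))
            env <- match(as.character(env), lev)
        }
        cd$env <- as.integer(env)
    }
    rd <- S4Vectors::DataFrame(row.names = snpIds)
    if (!is.null(maf)) rd$maf <- as.numeric(maf)
    dosage <- t(genotypes)
    dimnames(dosage) <- list(snpIds, sampleIds)
    storage.mode(dosage) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), colData = cd, rowData = rd,
        metadata = list(traitType = traitType))
    methods::new("SpaDataSet", se)
}

#' @rdname SpaDataSet-accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' Accessors for SpaDataSet
#'
#' \code{genotypeMatrix} returns the subjects-by-SNPs minor-allele dosage
#' matrix; \code{phenotype} the trait vector; \code{traitType}
#' \code{"binary"} or \code{"continuous"}; \code{envFactor} the integer env
#' level codes (or \code{NULL}); \code{snpIds} the SNP identifiers.
#'
#' @param x a \linkS4class{SpaDataSet}.
#' @return See the description of each accessor.
#' @name SpaDataSet-accessors
#' @aliases genotypeMatrix phenotype traitType envFactor snpIds
NULL

#' @rdname SpaDataSet-accessors
#' @export
setMethod("genotypeMatrix", "SpaDataSet", function(x)
    t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname SpaDataSet-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname SpaDataSet-accessors
#' @export
setMethod("phenotype", "SpaDataSet", function(x)
    SummarizedExperiment::colData(x)$phenotype)

#' @rdname SpaDataSet-accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname SpaDataSet-accessors
#' @export
setMethod("traitType", "SpaDataSet", function(x)
    S4Vectors::metadata(x)$traitType)

#' @rdname SpaDataSet-accessors
#' @export
setGeneric("envFactor", function(x) standardGeneric("envFactor"))

#' @rdname SpaDataSet-accessors
#' @export
setMethod("envFactor", "SpaDataSet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("env" %in% colnames(cd)) cd$env else NULL
})

#' @rdname SpaDataSet-accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname SpaDataSet-accessors
#' @export
setMethod("snpIds", "SpaDataSet", function(x) rownames(x))

setMethod("show", "SpaDataSet", function(object) {
    tt <- traitType(object)
    cat("SpaDataSet:", ncol(object), "subjects x", nrow(object),
        "rare variants;", tt, "trait")
    if (tt == "binary") {
        y <- phenotype(object)
        cat(" (", sum(y == 1), " cases / ", sum(y == 0), " controls)",
            sep = "")
    }
    e <- envFactor(object)
    if (!is.null(e)) cat("; env factor with", max(e), "levels")
    cat("\n")
    invisible(NULL)
})
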