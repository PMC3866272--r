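# Classed conditions so callers (and the CLI) can react to specific failures.
.spaError <- function(class, msg, call = sys.call(-1)) {
    structure(class = c(paste0("spa_", class, "_error"), "error", "condition"),
              list(message = msg, call = call))
}

# Dosage sanitation shared by the matrix-level statistic entry points:
# coerces to numeric matrix, recodes NA to 0 alleles (counted), checks range.
.sanitizeDosage <- function(genotypes) {
    g <- as.matrix(genotypes)
    storage.mode(g) <- "double"
    if (anyNA(g)) {
        message("recoding ", sum(is.na(g)), " missing genotype call(s) to 0")
        g[is.na(g)] <- 0
    }
    if (any(!g %in% c(0, 1, 2)))
        stop(.spaError("shape", "genotype entries must be 0, 1 or 2"))
    g
}

.checkShapes <- function(g, y) {
    if (length(y) != nrow(g))
        stop(.spaError("shape",
            "phenotype length does not match the number of subjects"))
    if (anyNA(y))
        stop(.spaError("shape", "phenotype must not contain NA"))
}

.checkBinary <- function(y) {
    if (!all(y %in% c(0, 1)))
        stop(.spaError("degenerate_phenotype",
            "binary phenotype values must be 0/1"))
    if (sum(y == 1) < 1 || sum(y == 0) < 1)
        stop(.spaError("degenerate_phenotype",
            "binary phenotype needs at least one case and one control"))
}

# Extract (genotype matrix, phenotype, trait type, env) from either a
# SpaDataSet or raw pieces, so every statistic has one code path.
.unpack <- function(x, phenotype = NULL, traitType = NULL, env = NULL) {
    if (methods::is(x, "SpaDataSet")) {
        list(g = genotypeMatrix(x), y = phenotype(x),
             traitType = traitType(x), env = envFactor(x))
    } else {
        g <- .sanitizeDosage(x)
        if (is.null(phenotype))
            stop(.spaError("shape", "phenotype is required"))
        if (is.null(traitType) || identical(traitType, "auto"))
            traitType <- if (all(phenotype %in% c(0, 1))) "binary"
                         else "continuous"
        list(g = g, y = as.numeric(phenotype), traitType = traitType,
             env = if (is.null(env)) NULL else as.integer(env))
    }
}
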