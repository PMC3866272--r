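## File-format ingestion and emission: VCF genotypes, phenotype/env TSV,
## scenario config files, and the region-test orchestration behind the CLI.

#' Read a region's genotypes from a VCF file
#'
#' Parses GT fields into a subjects-by-SNPs matrix of minor-allele dosages.
#' The minor allele is the less frequent of REF/ALT *in the sample* (ties
#' go to ALT), so a column whose ALT frequency exceeds 0.5 is flipped to
#' \code{2 - dosage} — "rare variant" always refers to the minor allele.
#' Multiallelic records are skipped with a warning; missing calls become 0
#' minor alleles (counted in a message). Sample order is taken from the VCF
#' header.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region optional \code{"chrom:start-end"} string or
#'   \code{GRanges} restricting the variants (1-based inclusive).
#' @param snpIds optional explicit variant id list (alternative to
#'   \code{region}).
#' @return Numeric matrix (samples x variants) with dimnames and attribute
#'   \code{"maf"} (sample minor-allele frequencies).
#' @export
readGenotypesVcf <- function(path, region = NULL, snpIds = NULL) {
    if (!file.exists(path))
        stop(.spaError("io", paste("no such file:", path)))
    if (!is.null(region) && !is.null(snpIds))
        stop(.spaError("config",
            "give either a region or a SNP id list, not both"))
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
    nMulti <- sum(S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) != 1L)
    if (nMulti > 0) {
        warning("skipping ", nMulti, " multiallelic record(s)")
        vcf <- vcf[S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) == 1L]
    }
    if (!is.null(region)) {
        if (is.character(region)) {
            m <- regmatches(region,
                regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
            if (length(m) != 4)
                stop(.spaError("config",
                    "region must look like 'chrom:start-end'"))
            region <- GenomicRanges::GRanges(m[2],
                IRanges::IRanges(as.integer(m[3]), as.integer(m[4])))
        }
        hit <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(vcf),
                                    region)
        vcf <- vcf[hit]
    }
    if (!is.null(snpIds))
        vcf <- vcf[rownames(vcf) %in% snpIds]
    if (nrow(vcf) == 0)
        stop(.spaError("empty_region", "no variants in the requested region"))
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop(.spaError("io", "VCF has no GT field"))
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
    miss <- a1 == "." | a2 == "." | a2 == ""
    dose <- (a1 == "1") + (a2 == "1")
    dose[miss] <- NA_real_
    nonmiss <- rowSums(!miss)
    altFreq <- rowSums(dose, na.rm = TRUE) / (2 * pmax(nonmiss, 1))
    flip <- !is.na(altFreq) & altFreq > 0.5
    if (any(flip))
        dose[flip, ] <- 2 - dose[flip, , drop = FALSE]
    nMiss <- sum(is.na(dose))
    if (nMiss > 0) {
        message("recoding ", nMiss, " missing genotype call(s) to 0")
        dose[is.na(dose)] <- 0
    }
    out <- t(dose)  # samples x variants
    attr(out, "maf") <- unname(pmin(altFreq, 1 - altFreq))
    out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with one biallelic record per SNP (REF A, ALT T —
#' the ALT allele is the minor allele) and GT-only genotype fields, on a
#' single pseudo-chromosome with 1-based positions. A matrix written here
#' and read back with \code{\link{readGenotypesVcf}} is identical
#' entry-for-entry (no column reaches ALT frequency above 0.5 for rare
#' variants, so the flip rule never triggers).
#'
#' @param genotypes subjects-by-SNPs dosage matrix (0/1/2).
#' @param path output file.
#' @param chrom pseudo-chromosome name.
#' @param positions 1-based positions (default 1..K).
#' @return \code{path}, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path, chrom = "1",
                              positions = NULL) {
    g <- as.matrix(genotypes)
    N <- nrow(g); K <- ncol(g)
    ids <- colnames(g); if (is.null(ids)) ids <- paste0("snp", seq_len(K))
    samples <- rownames(g)
    if (is.null(samples)) samples <- paste0("s", seq_len(N))
    if (is.null(positions)) positions <- seq_len(K)
    gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1], N, K)
    header <- c("##fileformat=VCFv4.2",
                "##source=spaRV",
                sprintf("##contig=<ID=%s>", chrom),
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
    body <- vapply(seq_len(K), function(k)
        paste(c(chrom, positions[k], ids[k], "A", "T", ".", ".", ".",
                "GT", gtStr[, k]), collapse = "\t"), "")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a phenotype (and optional env) table
#'
#' Expects a TSV with header columns \code{sample_id}, \code{phenotype}
#' and optionally \code{env}. The trait type is auto-detected (values
#' exactly \{0,1\} mean binary) unless overridden; an env column is
#' label-encoded to 1..J in first-appearance order (the mapping is
#' reported in a message).
#'
#' @param path TSV file.
#' @param traitType \code{"auto"} (default), \code{"binary"} or
#'   \code{"continuous"}.
#' @return A list with elements \code{sampleIds}, \code{phenotype},
#'   \code{traitType}, \code{env} (integer codes or \code{NULL}) and
#'   \code{envLevels} (the original labels in code order, or \code{NULL}).
#' @export
readPhenotypeTable <- function(path, traitType = c("auto", "binary",
                                                   "continuous")) {
    traitType <- match.arg(traitType)
    if (!file.exists(path))
        stop(.spaError("io", paste("no such file:", path)))
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "phenotype")
    if (!all(need %in% colnames(tab)))
        stop(.spaError("io",
            "phenotype table needs columns sample_id and phenotype"))
    if (anyDuplicated(tab$sample_id))
        stop(.spaError("io", paste("duplicate sample ids:",
            paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                  collapse = ", "))))
    y <- as.numeric(tab$phenotype)
    if (anyNA(y))
        stop(.spaError("io", "phenotype column must be numeric, no NA"))
    isBinaryValued <- all(y %in% c(0, 1))
    if (traitType == "binary" && !isBinaryValued)
        stop(.spaError("typed_override",
            "trait declared binary but phenotype values are not all 0/1"))
    if (traitType == "auto")
        traitType <- if (isBinaryValued) "binary" else "continuous"
    if (traitType == "binary" && length(unique(y)) < 2)
        stop(.spaError("degenerate_phenotype",
            "binary phenotype is constant"))
    env <- NULL; envLevels <- NULL
    if ("env" %in% colnames(tab)) {
        envLevels <- unique(as.character(tab$env))
        env <- match(as.character(tab$env), envLevels)
        message("env levels encoded: ",
                paste(sprintf("%s=%d", envLevels, seq_along(envLevels)),
                      collapse = ", "))
    }
    list(sampleIds = as.character(tab$sample_id), phenotype = y,
         traitType = traitType, env = env, envLevels = envLevels)
}

#' Write a dataset's phenotype/env table (TSV)
#'
#' Companion to \code{\link{writeGenotypesVcf}} for simulated datasets:
#' columns \code{sample_id}, \code{phenotype} and, when present,
#' \code{env}.
#'
#' @param ds a \linkS4class{SpaDataSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePhenotypeTable <- function(ds, path) {
    df <- data.frame(sample_id = colnames(ds),
                     phenotype = phenotype(ds))
    e <- envFactor(ds)
    if (!is.null(e)) df$env <- e
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Region-based association test from files
#'
#' The real-data entry point behind the command line: reads genotypes from
#' a VCF and the phenotype (plus optional env factor) from a TSV, joins the
#' two by sample id (never positionally), applies the rare-variant MAF
#' filter, runs the requested statistics, and returns (and optionally
#' writes) one result row per statistic.
#'
#' @param vcf path to the genotype VCF.
#' @param phenotypeFile path to the phenotype TSV (see
#'   \code{\link{readPhenotypeTable}}).
#' @param stats character vector of statistics
#'   (\code{"I1"}, \code{"I2"}, \code{"pstar"}, \code{"I1E"}).
#' @param B permutations.
#' @param strategy \code{"global"} or \code{"local"}.
#' @param seed integer seed (reproducibility contract: identical invocation,
#'   identical output).
#' @param mafCutoff rare-variant MAF cutoff (default 0.05, the conventional
#'   real-data choice).
#' @param region,snpIds optional variant restriction (see
#'   \code{\link{readGenotypesVcf}}).
#' @param traitType trait type override for the phenotype table.
#' @param normalize passed to the I2 evaluation.
#' @param out optional TSV path for the result table.
#' @return A data.frame with columns region, K, statistic, value, p_value,
#'   B, strategy, seed.
#' @export
runRegionTest <- function(vcf, phenotypeFile, stats = "I1", B = 1000L,
                          strategy = c("global", "local"), seed = 1L,
                          mafCutoff = 0.05, region = NULL, snpIds = NULL,
                          traitType = "auto", normalize = TRUE,
                          out = NULL) {
    strategy <- match.arg(strategy)
    g <- readGenotypesVcf(vcf, region = region, snpIds = snpIds)
    ph <- readPhenotypeTable(phenotypeFile, traitType = traitType)
    vcfSamples <- rownames(g)
    missing_ <- setdiff(vcfSamples, ph$sampleIds)
    extra <- setdiff(ph$sampleIds, vcfSamples)
    if (length(missing_) || length(extra))
        stop(.spaError("aligned_join", paste0(
            "sample sets differ between VCF and phenotype table",
            if (length(missing_)) paste0("; missing phenotype for: ",
                paste(missing_, collapse = ", ")),
            if (length(extra)) paste0("; not in VCF: ",
                paste(extra, collapse = ", ")))))
    ord <- match(vcfSamples, ph$sampleIds)
    ds <- SpaDataSet(g, phenotype = ph$phenotype[ord],
                     traitType = ph$traitType,
                     env = if (is.null(ph$env)) NULL else ph$env[ord])
    ds <- rareVariantFilter(ds, mafCutoff)
    K <- nrow(ds)
    regionLabel <- if (is.null(region)) basename(vcf)
                   else if (is.character(region)) region else "region"
    set.seed(as.integer(seed))
    rows <- lapply(stats, function(s) {
        res <- spaTest(ds, statistic = s, B = B, strategy = strategy,
                       normalize = normalize, keepNull = FALSE)
        data.frame(region = regionLabel, K = K, statistic = s,
                   value = observedStat(res), p_value = pValue(res),
                   B = nPermutations(res), strategy = permStrategy(res),
                   seed = as.integer(seed), stringsAsFactors = FALSE)
    })
    resTab <- do.call(rbind, rows)
    if (!is.null(out)) {
        fmt <- resTab
        fmt$value <- sprintf("%.17g", fmt$value)
        fmt$p_value <- sprintf("%.17g", fmt$p_value)
        write.table(fmt, out, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    resTab
}

## ---- scenario config files -------------------------------------------------

.fmtNum <- function(x) paste(sprintf("%.17g", x), collapse = ",")
.fmtPairs <- function(m, coefs)
    paste(sprintf("%d:%d:%.17g", m[, 1], m[, 2], coefs), collapse = ";")

#' Write a scenario to a plain-text config file
#'
#' Flat \code{key = value} format (one key per line, comma-separated
#' vectors, \code{i:j:coef} triplets for pair terms); numbers are written
#' at full precision so \code{\link{readScenarioConfig}} round-trips the
#' spec losslessly.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScenarioConfig <- function(spec, path) {
    lines <- c(
        "# spaRV scenario configuration",
        paste("scenario_id =", spec@scenarioId),
        paste("n_snps =", spec@nSnps),
        paste("maf_law =", spec@mafLaw),
        paste("maf_params =", .fmtNum(spec@mafParams)),
        paste("trait_type =", spec@traitType),
        paste("causal_snps =", paste(spec@causalSnps, collapse = ",")),
        paste("effect_type =", spec@effectType),
        paste("effect_size =", .fmtNum(spec@effectSize)),
        paste("effect_signs =", .fmtNum(spec@effectSigns)),
        paste("interaction_terms =",
              .fmtPairs(spec@interactionPairs, spec@interactionCoefs)),
        paste("env_levels =", spec@envLevels),
        paste("env_probs =", .fmtNum(spec@envProbs)),
        paste("env_main_effect =", .fmtNum(spec@envMainEffect)),
        paste("gxe_terms =", .fmtPairs(spec@gxeTerms, spec@gxeCoefs)),
        paste("baseline =", .fmtNum(spec@baseline)),
        paste("noise_sd =", .fmtNum(spec@noiseSd)),
        paste("n_cases =", spec@nCases),
        paste("n_controls =", spec@nControls),
        paste("n_subjects =", spec@nSubjects))
    writeLines(lines, path)
    invisible(path)
}

.parseNum <- function(s) {
    s <- trimws(s)
    if (s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1]])
}
.parseTriplets <- function(s) {
    s <- trimws(s)
    if (s == "")
        return(list(pairs = matrix(integer(0), 0, 2), coefs = numeric(0)))
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    m <- t(vapply(parts, function(p)
        c(as.integer(p[1]), as.integer(p[2])), integer(2)))
    list(pairs = m, coefs = vapply(parts, function(p)
        as.numeric(p[3]), 0))
}

#' Read a scenario config file
#'
#' Inverse of \code{\link{writeScenarioConfig}}.
#'
#' @param path config file.
#' @return A validated \linkS4class{ScenarioSpec}.
#' @export
readScenarioConfig <- function(path) {
    if (!file.exists(path))
        stop(.spaError("io", paste("no such file:", path)))
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*)$", lines))
    bad <- vapply(kv, length, 0L) != 3L
    if (any(bad))
        stop(.spaError("io", paste("unparseable config line:",
                                   lines[bad][1])))
    vals <- setNames(vapply(kv, function(m) trimws(m[3]), ""),
                     vapply(kv, function(m) m[2], ""))
    it <- .parseTriplets(vals[["interaction_terms"]])
    gx <- .parseTriplets(vals[["gxe_terms"]])
    methods::new("ScenarioSpec",
        scenarioId = vals[["scenario_id"]],
        nSnps = as.integer(vals[["n_snps"]]),
        mafLaw = vals[["maf_law"]],
        mafParams = .parseNum(vals[["maf_params"]]),
        traitType = vals[["trait_type"]],
        causalSnps = as.integer(.parseNum(vals[["causal_snps"]])),
        effectType = vals[["effect_type"]],
        effectSize = .parseNum(vals[["effect_size"]]),
        effectSigns = .parseNum(vals[["effect_signs"]]),
        interactionPairs = it$pairs, interactionCoefs = it$coefs,
        envLevels = as.integer(vals[["env_levels"]]),
        envProbs = .parseNum(vals[["env_probs"]]),
        envMainEffect = .parseNum(vals[["env_main_effect"]]),
        gxeTerms = gx$pairs, gxeCoefs = gx$coefs,
        baseline = .parseNum(vals[["baseline"]]),
        noiseSd = .parseNum(vals[["noise_sd"]]),
        nCases = as.integer(vals[["n_cases"]]),
        nControls = as.integer(vals[["n_controls"]]),
        nSubjects = as.integer(vals[["n_subjects"]]))
}
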