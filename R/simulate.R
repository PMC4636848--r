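#' Configure the synthetic cohort generator
#'
#' Builds a [SimulationConfig-class] describing a tumor methylation cohort
#' with three planted subtypes.  The generated cohort carries the structure
#' the subtyping pipeline assumes: a melanocyte-like tumor-intrinsic profile,
#' promoter-island hypermethylation strongest in subtype MS1, genome-wide
#' heterochromatin demethylation strongest in MS1, leukocyte admixture
#' strongest in MS3, plus the Infinium type-II beta compression, sporadic
#' missing values, matched expression modules and survival times.
#'
#' @param nPerSubtype integer(3), samples per subtype MS1/MS2/MS3.
#' @param nCpgs total number of CpG probes.
#' @param classFractions named fractions over the probe classes
#'   `poised_promoter_island`, `heterochromatin_opensea`,
#'   `celltype_discriminating`, `neutral`, `sex_chromosome`; must sum to 1.
#' @param promoterMeans tumor-intrinsic beta at poised promoter islands per
#'   subtype; strictly decreasing MS1 > MS2 > MS3.
#' @param heterochromatinMeans tumor-intrinsic beta at heterochromatic
#'   open-sea probes per subtype (MS1 most demethylated).
#' @param purityMeans mean tumor-cell fraction per subtype; strictly
#'   increasing from MS3 to MS1.
#' @param betaPrecision concentration of the Beta measurement-noise
#'   distribution (larger = less noise).
#' @param type2Compression `(a, b)`: type-II probes report `a + (b - a) * beta`.
#' @param missingRate marginal probability that an observed tumor beta is
#'   missing.
#' @param fractionType2 fraction of probes assayed with type-II chemistry.
#' @param nMelanocyteRefs number of melanocyte reference arrays.
#' @param probePrecision concentration of the per-probe baseline-mean draws
#'   around their class mean.
#' @param neutralModes `(low, high)` centres of the unmethylated/methylated
#'   components of the neutral probe class.
#' @param neutralWeights weights of the low/high/mid-uniform components of
#'   the neutral class.
#' @param probeShiftSd sd of the per-probe aberration-depth shift shared
#'   across subtypes (poised and heterochromatin classes).
#' @param purityPrecision concentration of per-sample purity draws.
#' @param nGenes,nModuleGenes expression matrix size and genes per module.
#' @param hazardRatioMS1 hazard ratio of MS1 versus the other subtypes.
#' @param baselineHazard exponential event rate of non-MS1 samples
#'   (per time unit).
#' @param censoringMax upper bound of the uniform censoring time.
#' @param platformSeed seed of the probe-level draws (probe classes, baseline
#'   means, aberration depths, assay chemistry, annotation).  Cohorts sharing
#'   a `platformSeed` share their probe universe — the synthetic analogue of
#'   two cohorts profiled on the same array — so centroids transfer between
#'   them.
#' @param seed seed of the sample-level draws (purity, measurement noise,
#'   missingness, expression, survival); the whole cohort is reproducible
#'   from `(platformSeed, seed)`.
#'
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nPerSubtype = c(6, 5, 5), nCpgs = 1000)
#' @export
simulationConfig <- function(nPerSubtype = c(20L, 15L, 15L),
                             nCpgs = 20000L,
                             classFractions = c(
                                 poised_promoter_island  = 0.10,
                                 heterochromatin_opensea = 0.10,
                                 celltype_discriminating = 0.05,
                                 neutral                 = 0.72,
                                 sex_chromosome          = 0.03),
                             promoterMeans = c(0.70, 0.45, 0.25),
                             heterochromatinMeans = c(0.30, 0.45, 0.60),
                             purityMeans = c(0.90, 0.70, 0.50),
                             betaPrecision = 50,
                             type2Compression = c(0.08, 0.92),
                             missingRate = 5e-4,
                             fractionType2 = 0.7,
                             nMelanocyteRefs = 6L,
                             probePrecision = 300,
                             neutralModes = c(0.015, 0.985),
                             neutralWeights = c(low = 0.4, high = 0.4, mid = 0.2),
                             probeShiftSd = 0.05,
                             purityPrecision = 100,
                             nGenes = 600L,
                             nModuleGenes = 50L,
                             hazardRatioMS1 = 2.5,
                             baselineHazard = log(2) / 36,
                             censoringMax = 120,
                             platformSeed = 20150L,
                             seed = 1L) {
    new("SimulationConfig",
        nPerSubtype = as.integer(nPerSubtype), nCpgs = as.integer(nCpgs),
        classFractions = classFractions[.CPG_CLASSES],
        promoterMeans = promoterMeans,
        heterochromatinMeans = heterochromatinMeans,
        purityMeans = purityMeans, betaPrecision = betaPrecision,
        type2Compression = type2Compression, missingRate = missingRate,
        fractionType2 = fractionType2,
        nMelanocyteRefs = as.integer(nMelanocyteRefs),
        probePrecision = probePrecision, neutralModes = neutralModes,
        neutralWeights = neutralWeights / sum(neutralWeights),
        probeShiftSd = probeShiftSd, purityPrecision = purityPrecision,
        nGenes = as.integer(nGenes), nModuleGenes = as.integer(nModuleGenes),
        hazardRatioMS1 = hazardRatioMS1, baselineHazard = baselineHazard,
        censoringMax = censoringMax, platformSeed = as.integer(platformSeed),
        seed = as.integer(seed))
}

.clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

## Beta draws parameterized by (mean, concentration); means clamped away from
## the boundary so the shape parameters stay positive.
.rbetaMean <- function(n, mean, precision) {
    m <- .clamp01(mean, 1e-3)
    stats::rbeta(n, m * precision, (1 - m) * precision)
}

#' Simulate survival times for labelled samples
#'
#' Exponential event times with a proportional-hazards effect for subtype
#' MS1 and independent uniform censoring.
#'
#' @param labels factor of subtype labels (level `MS1` carries the hazard
#'   ratio).
#' @param hazardRatio hazard ratio of MS1 versus the remaining samples.
#' @param baselineHazard event rate of non-MS1 samples.
#' @param censoringMax censoring times are Uniform(0, `censoringMax`).
#' @return data.frame with `sample_id`, `time`, `event` (0/1), `label`.
#' @export
simulateSurvival <- function(labels, hazardRatio = 2.5,
                             baselineHazard = log(2) / 36,
                             censoringMax = 120) {
    n <- length(labels)
    rate <- baselineHazard * ifelse(labels == "MS1", hazardRatio, 1)
    tevent <- stats::rexp(n, rate)
    tcens <- stats::runif(n, 0, censoringMax)
    ids <- names(labels)
    if (is.null(ids)) ids <- sprintf("T%03d", seq_len(n))
    data.frame(sample_id = ids,
               time = pmin(tevent, tcens),
               event = as.integer(tevent <= tcens),
               label = as.character(labels),
               stringsAsFactors = FALSE)
}

#' Generate a synthetic methylation cohort with planted subtypes
#'
#' Draws a cohort under the generative model described in
#' [simulationConfig()]: per-probe baseline means for melanocyte and
#' leukocyte reference cells, tumor-intrinsic subtype shifts at the poised
#' promoter-island and heterochromatin open-sea classes, per-sample
#' purity-weighted mixing of tumor and leukocyte signal, Beta-distributed
#' measurement noise, affine type-II compression and sporadic missingness.
#' Matched expression (immune module tracking admixture, cell-cycle module
#' elevated in MS1/MS2) and survival data are generated from the same seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SyntheticCohort-class] holding the observed matrices and the
#'   planted ground truth (labels, aberrant CpG sets, purity,
#'   pre-compression betas).
#' @examples
#' cohort <- generateCohort(simulationConfig(nPerSubtype = c(6, 5, 5),
#'                                           nCpgs = 1000, seed = 7))
#' table(subtypeLabels(cohort))
#' @export
generateCohort <- function(config) {
    validObject(config)
    platform <- withr::with_seed(config@platformSeed,
                                 .generatePlatform(config))
    withr::with_seed(config@seed, .generateSamples(config, platform))
}

## Probe-level structure: classes, reference-cell baseline means, tumor
## subtype means, assay chemistry, annotation. Depends only on the config
## values and platformSeed, so cohorts with different sample seeds share it.
.generatePlatform <- function(cf) {
    p <- cf@nCpgs
    probeIds <- sprintf("cg%08d", seq_len(p))

    ## probe classes, exact counts from the fractions
    counts <- diff(round(cumsum(c(0, cf@classFractions)) * p))
    cls <- sample(rep(.CPG_CLASSES, counts))

    ## per-probe baseline means for the two reference cell types
    mMel <- mLeu <- numeric(p)
    neutralComp <- character(p)
    for (cl in .CPG_CLASSES) {
        idx <- which(cls == cl)
        ni <- length(idx)
        if (!ni) next
        if (cl == "poised_promoter_island") {
            mMel[idx] <- .rbetaMean(ni, 0.05, cf@probePrecision)
            mLeu[idx] <- .rbetaMean(ni, 0.05, cf@probePrecision)
        } else if (cl == "heterochromatin_opensea") {
            mMel[idx] <- .rbetaMean(ni, 0.95, cf@probePrecision)
            mLeu[idx] <- .rbetaMean(ni, 0.95, cf@probePrecision)
        } else if (cl == "celltype_discriminating") {
            melLow <- seq_along(idx) <= ni / 2
            mMel[idx] <- .rbetaMean(ni, ifelse(melLow, 0.05, 0.95),
                                    cf@probePrecision)
            mLeu[idx] <- .rbetaMean(ni, ifelse(melLow, 0.95, 0.05),
                                    cf@probePrecision)
        } else {  # neutral and sex_chromosome: bimodal background
            comp <- sample(c("low", "high", "mid"), ni, replace = TRUE,
                           prob = cf@neutralWeights)
            m <- numeric(ni)
            m[comp == "low"] <- .rbetaMean(sum(comp == "low"),
                                           cf@neutralModes[1],
                                           cf@probePrecision)
            m[comp == "high"] <- .rbetaMean(sum(comp == "high"),
                                            cf@neutralModes[2],
                                            cf@probePrecision)
            m[comp == "mid"] <- stats::runif(sum(comp == "mid"), 0.15, 0.85)
            mMel[idx] <- m
            mLeu[idx] <- m
            neutralComp[idx] <- comp
        }
    }

    ## tumor-intrinsic means per probe and subtype; aberration depth varies
    ## by probe but is shared across subtypes (a probe-level random effect)
    tumorMeans <- matrix(rep(mMel, 3L), ncol = 3L)
    shift <- stats::rnorm(p, 0, cf@probeShiftSd)
    poised <- cls == "poised_promoter_island"
    hetero <- cls == "heterochromatin_opensea"
    for (s in 1:3) {
        tumorMeans[poised, s] <- .clamp01(cf@promoterMeans[s] + shift[poised])
        tumorMeans[hetero, s] <- .clamp01(cf@heterochromatinMeans[s] + shift[hetero])
    }

    assayType <- ifelse(stats::runif(p) < cf@fractionType2, "II", "I")
    annotation <- .annotationWithAssay(
        .annotateProbes(probeIds, cls, neutralComp), assayType)

    list(probeIds = probeIds, cls = cls, mMel = mMel, mLeu = mLeu,
         tumorMeans = tumorMeans, assayType = assayType,
         annotation = annotation, poised = poised, hetero = hetero)
}

## Sample-level draws: purity, measurement noise, compression, missingness,
## reference arrays, expression and survival.
.generateSamples <- function(cf, pf) {
    nPer <- cf@nPerSubtype
    n <- sum(nPer)
    p <- cf@nCpgs
    subtype <- rep(1:3, nPer)
    sampleIds <- sprintf("T%03d", seq_len(n))
    probeIds <- pf$probeIds
    mLeu <- pf$mLeu
    assayType <- pf$assayType

    ## per-sample purity and the purity-weighted mixture means
    purity <- .rbetaMean(n, cf@purityMeans[subtype], cf@purityPrecision)
    names(purity) <- sampleIds
    mu <- sweep(pf$tumorMeans[, subtype, drop = FALSE], 2L, purity, "*") +
        outer(mLeu, 1 - purity)

    ## measurement noise, then the planted type-II affine compression
    truthBeta <- matrix(.rbetaMean(length(mu), mu, cf@betaPrecision),
                        nrow = p, dimnames = list(probeIds, sampleIds))
    a <- cf@type2Compression[1]; b <- cf@type2Compression[2]
    observed <- truthBeta
    observed[assayType == "II", ] <- a + (b - a) * observed[assayType == "II", ]

    ## sporadic missingness; every probe keeps at least one observation
    if (cf@missingRate > 0) {
        miss <- stats::runif(length(observed)) < cf@missingRate
        miss <- matrix(miss, nrow = p)
        allGone <- rowSums(!miss) == 0L
        miss[allGone, 1L] <- FALSE
        observed[miss] <- NA_real_
    }

    ## reference arrays observed with the same noise and chemistry
    drawRef <- function(meanVec, k, prefix) {
        m <- matrix(.rbetaMean(p * k, rep(meanVec, k), cf@betaPrecision),
                    nrow = p,
                    dimnames = list(probeIds, sprintf("%s%d", prefix, seq_len(k))))
        m[assayType == "II", ] <- a + (b - a) * m[assayType == "II", ]
        m
    }
    melRef <- drawRef(pf$mMel, cf@nMelanocyteRefs, "MEL")
    leuRef <- drawRef(mLeu, 1L, "LEU")

    ## matched expression: immune module tracks admixture, cell-cycle module
    ## is elevated in the proliferative subtypes MS1/MS2
    nm <- cf@nModuleGenes
    geneIds <- c(sprintf("IMM%03d", seq_len(nm)), sprintf("CCY%03d", seq_len(nm)),
                 sprintf("GEN%03d", seq_len(max(0L, cf@nGenes - 2L * nm))))
    expr <- matrix(0, nrow = length(geneIds), ncol = n,
                   dimnames = list(geneIds, sampleIds))
    imm <- grepl("^IMM", geneIds)
    ccy <- grepl("^CCY", geneIds)
    oth <- !(imm | ccy)
    expr[imm, ] <- 6 + 4 * rep(1 - purity, each = sum(imm)) +
        stats::rnorm(sum(imm) * n, 0, 0.5)
    expr[ccy, ] <- 6 + 1.5 * rep(as.numeric(subtype <= 2L), each = sum(ccy)) +
        stats::rnorm(sum(ccy) * n, 0, 0.5)
    expr[oth, ] <- stats::rnorm(sum(oth), 8, 1.5) +
        stats::rnorm(sum(oth) * n, 0, 0.5)

    labels <- factor(.MS_LEVELS[subtype], levels = .MS_LEVELS)
    names(labels) <- sampleIds
    surv <- simulateSurvival(labels, cf@hazardRatioMS1, cf@baselineHazard,
                             cf@censoringMax)

    new("SyntheticCohort",
        tumor = BetaSet(observed, pf$annotation),
        melanocyteRef = melRef, leukocyteRef = leuRef, truthBeta = truthBeta,
        truthLabels = labels,
        truthMethylated = probeIds[pf$poised],
        truthDemethylated = probeIds[pf$hetero],
        truthPurity = purity,
        expression = expr,
        modules = list(immune_response = geneIds[imm], cell_cycle = geneIds[ccy]),
        survival = surv, config = cf)
}

.annotateProbes <- function(probeIds, cls, neutralComp) {
    p <- length(probeIds)
    chrom <- sample(paste0("chr", 1:22), p, replace = TRUE)
    sexIdx <- cls == "sex_chromosome"
    chrom[sexIdx] <- sample(c("X", "Y"), sum(sexIdx), replace = TRUE,
                            prob = c(0.7, 0.3))
    region <- character(p); island <- character(p); state <- character(p)
    tss <- function(k) sample(c("TSS200", "TSS1500"), k, replace = TRUE)
    for (cl in unique(cls)) {
        idx <- which(cls == cl)
        k <- length(idx)
        if (cl == "poised_promoter_island") {
            region[idx] <- tss(k); island[idx] <- "island"
            state[idx] <- "poised_promoter"
        } else if (cl == "heterochromatin_opensea") {
            region[idx] <- "none"; island[idx] <- "open_sea"
            state[idx] <- "heterochromatin"
        } else if (cl == "celltype_discriminating") {
            region[idx] <- sample(c("body", "none"), k, replace = TRUE)
            island[idx] <- "shore_shelf"; state[idx] <- "quiescent"
        } else {
            comp <- neutralComp[idx]
            low <- comp == "low"; high <- comp == "high"; mid <- comp == "mid"
            region[idx][low] <- tss(sum(low))
            island[idx][low] <- "island"; state[idx][low] <- "active_promoter"
            region[idx][high] <- sample(c("none", "body"), sum(high),
                                        replace = TRUE)
            island[idx][high] <- "open_sea"; state[idx][high] <- "quiescent"
            region[idx][mid] <- "body"
            island[idx][mid] <- "shore_shelf"; state[idx][mid] <- "quiescent"
        }
    }
    data.frame(probe_id = probeIds, chromosome = chrom, gene_region = region,
               island_relation = island, chromatin_state = state,
               cpg_class = cls, stringsAsFactors = FALSE)
}

.annotationWithAssay <- function(annotation, assayType) {
    annotation$assay_type <- assayType
    annotation
}
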