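# Shared fixtures built in code. Small cohorts for unit tests; the full-size
# default cohorts used by the end-to-end checks are built lazily and cached
# so several test files can share one pipeline run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtures))
        assign(key, force(expr), envir = .fixtures)
    get(key, envir = .fixtures)
}

small_config <- function(seed = 7L, ...) {
    simulationConfig(nPerSubtype = c(8L, 7L, 7L), nCpgs = 3000L,
                     seed = seed, ...)
}

small_cohort <- function(seed = 7L) {
    memo(paste0("small_", seed), generateCohort(small_config(seed)))
}

# generate -> preprocess -> select -> cluster for a small cohort
small_pipeline <- function(seed = 7L, nBoot = 100L) {
    memo(paste0("smallpipe_", seed, "_", nBoot), {
        co <- small_cohort(seed)
        tum <- preprocessPipeline(co@tumor)
        mel <- preprocessPipeline(BetaSet(co@melanocyteRef,
                                          probeAnnotation(co)))
        sets <- selectAberrantCpGs(tum, mel)
        res <- discoverSubtypes(tum, combineSets(sets), nBoot = nBoot,
                                seed = seed + 100L)
        list(cohort = co, tum = tum, mel = mel, sets = sets, res = res)
    })
}

# full-size study conditions: 50 tumors (20/15/15), 20,000 CpGs, 200
# bootstraps — shared by the acceptance checks
full_pipeline <- function(cohortSeed, bootSeed) {
    memo(paste0("full_", cohortSeed), {
        co <- generateCohort(simulationConfig(seed = cohortSeed))
        tum <- preprocessPipeline(co@tumor)
        mel <- preprocessPipeline(BetaSet(co@melanocyteRef,
                                          probeAnnotation(co)))
        sets <- selectAberrantCpGs(tum, mel)
        res <- discoverSubtypes(tum, combineSets(sets), nBoot = 200L,
                                seed = bootSeed)
        list(cohort = co, tum = tum, mel = mel, sets = sets, res = res)
    })
}

sens_spec <- function(selected, truth, universe) {
    neg <- setdiff(universe, truth)
    c(sensitivity = mean(truth %in% selected),
      specificity = 1 - sum(neg %in% selected) / length(neg))
}

label_match <- function(assigned, truth) {
    mean(as.character(assigned) == as.character(truth[names(assigned)]))
}
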