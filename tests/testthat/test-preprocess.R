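probes <- function(n) sprintf("cg%03d", seq_len(n))

test_that("beta computation follows M/(M+U) with undefined ratios missing", {
    dn <- list(probes(3), "S1")
    M <- matrix(c(100, 0, 0), 3, dimnames = dn)
    U <- matrix(c(0, 100, 0), 3, dimnames = dn)
    b <- betas(computeBeta(M, U))
    expect_equal(unname(b[, 1]), c(1, 0, NA))

    expect_error(computeBeta(-M, U), "negative")
    expect_error(computeBeta(M, U[1:2, , drop = FALSE]), "dimensions")
})

test_that("KNN imputation handles the degenerate contracts", {
    m <- matrix(runif(20), 5, 4, dimnames = list(probes(5), paste0("S", 1:4)))
    expect_identical(imputeKNN(m), m)     # nothing to impute

    # all close neighbours hold 0.4 in the missing column
    m2 <- matrix(0.5, 12, 4, dimnames = list(probes(12), paste0("S", 1:4)))
    m2[2:12, 4] <- 0.4
    m2[1, 4] <- NA
    expect_equal(imputeKNN(m2, k = 10)[1, 4], 0.4)

    m3 <- m
    m3[2, ] <- NA
    expect_error(imputeKNN(m3), "no observed values")

    m4 <- matrix(runif(8), 4, 2, dimnames = list(probes(4), c("S1", "S2")))
    m4[1, 1] <- NA
    expect_warning(imputeKNN(m4, k = 10), "fewer than k")
})

test_that("KNN imputation matches the brute-force oracle", {
    for (seed in 1:10) {
        nr <- sample(10:50, 1)
        nc <- sample(4:10, 1)
        m <- masked_matrix(nr, nc, nmask = sample(2:6, 1), seed = seed * 37L)
        got <- suppressWarnings(imputeKNN(m, k = 10))
        want <- knn_oracle(m, k = 10)
        expect_lt(max(abs(got - want)), 1e-9)
        expect_false(anyNA(got))
    }
})

test_that("density peaks are located and guarded", {
    v <- withr::with_seed(1L, pmin(1, pmax(0, c(rnorm(10000, 0.2, 0.01),
                                                rnorm(10000, 0.8, 0.01)))))
    pk <- estimatePeaks(v)
    expect_true(pk$ok)
    expect_lt(abs(pk$pUnmeth - 0.2), 0.01)
    expect_lt(abs(pk$pMeth - 0.8), 0.01)

    # reflection x -> 1 - x swaps the peaks
    rk <- estimatePeaks(1 - v)
    expect_lt(abs(rk$pUnmeth - (1 - pk$pMeth)), 0.002)
    expect_lt(abs(rk$pMeth - (1 - pk$pUnmeth)), 0.002)

    # unimodal data near 0.5: separation below the guard
    u <- withr::with_seed(2L, pmin(1, pmax(0, rnorm(5000, 0.5, 0.02))))
    expect_false(estimatePeaks(u)$ok)

    # too few values
    expect_false(estimatePeaks(runif(10))$ok)
})

test_that("peak correction applies the stated linear stretch and cap", {
    n <- 4000
    v <- withr::with_seed(3L, pmin(1, pmax(0, c(rnorm(n, 0.2, 0.005),
                                                rnorm(n, 0.8, 0.005)))))
    v <- c(v, 0.5, 0.1)
    m <- matrix(v, ncol = 1, dimnames = list(probes(length(v)), "S1"))
    ann <- data.frame(probe_id = rownames(m), assay_type = "II")
    out <- peakCorrect(m, ann)
    expect_true(all(out$peaks$corrected))
    pu <- out$peaks$p_unmeth; pm <- out$peaks$p_meth
    # the stated map on the two probes appended after the modes
    expect_equal(out$betas[n * 2 + 1, 1],
                 (0.5 - pu) / (pm - pu), tolerance = 1e-12)
    expect_equal(unname(out$betas[n * 2 + 2, 1]), 0)   # capped at 0
    expect_true(all(out$betas >= 0 & out$betas <= 1))

    # an unusable slice is left untouched and flagged
    uni <- matrix(withr::with_seed(4L, pmin(1, pmax(0, rnorm(500, 0.5, 0.02)))),
                  ncol = 1, dimnames = list(probes(500), "S1"))
    annU <- data.frame(probe_id = rownames(uni), assay_type = "I")
    outU <- peakCorrect(uni, annU)
    expect_false(any(outU$peaks$corrected))
    expect_identical(outU$betas, uni)

    # missing entries stay missing
    m2 <- m; m2[5, 1] <- NA
    out2 <- peakCorrect(m2, ann)
    expect_true(is.na(out2$betas[5, 1]))
})

test_that("sex-chromosome probes are removed, preserving order", {
    m <- matrix(runif(300), 100, 3,
                dimnames = list(probes(100), paste0("S", 1:3)))
    chrom <- rep("chr1", 100)
    chrom[2:8] <- "X"; chrom[11:13] <- "Y"
    ann <- data.frame(probe_id = rownames(m), chromosome = chrom)
    out <- removeSexChromosomes(m, ann)
    expect_equal(nrow(out), 90)
    expect_identical(rownames(out),
                     rownames(m)[!(chrom %in% c("X", "Y"))])

    annA <- data.frame(probe_id = rownames(m), chromosome = "chr2")
    expect_identical(removeSexChromosomes(m, annA), m)
})

test_that("the pipeline undoes the planted type-II compression", {
    pp <- small_pipeline()
    co <- pp$cohort
    tum <- pp$tum
    ann <- probeAnnotation(tum)
    t2 <- ann$assay_type == "II"
    truth <- co@truthBeta[rownames(tum), colnames(tum)]
    mae_corr <- mean(abs(betas(tum)[t2, ] - truth[t2, ]))
    expect_lte(mae_corr, 0.02)

    # correction must beat leaving the compression in place
    raw <- removeSexChromosomes(imputeKNN(co@tumor))
    mae_raw <- mean(abs(betas(raw)[t2, ] - truth[t2, ]))
    expect_lt(mae_corr, mae_raw)

    # deterministic: the pipeline has no random stage
    again <- preprocessPipeline(co@tumor)
    expect_identical(betas(tum), betas(again))
})

test_that("correction is near-idempotent: corrected peaks sit at the ends", {
    tum <- small_pipeline()$tum
    pk2 <- peakCorrect(tum)$peaks
    expect_true(all(pk2$p_unmeth <= 0.05))
    expect_true(all(pk2$p_meth >= 0.95))
})

test_that("corrected-vs-truth error beats uncorrected over many cohorts", {
    wins <- vapply(1:8, function(s) {
        co <- generateCohort(simulationConfig(
            nPerSubtype = c(4L, 3L, 3L), nCpgs = 2000L, seed = 400L + s))
        tum <- preprocessPipeline(co@tumor)
        t2 <- probeAnnotation(tum)$assay_type == "II"
        truth <- co@truthBeta[rownames(tum), colnames(tum)]
        raw <- removeSexChromosomes(imputeKNN(co@tumor))
        mean(abs(betas(tum)[t2, ] - truth[t2, ])) <
            mean(abs(betas(raw)[t2, ] - truth[t2, ]))
    }, logical(1))
    expect_true(all(wins))
})

test_that("a cohort without distortion passes through almost unchanged", {
    co <- generateCohort(small_config(seed = 15L, missingRate = 0,
                                      type2Compression = c(0, 1)))
    out <- preprocessPipeline(co@tumor)
    shared <- rownames(out)
    expect_lte(mean(abs(betas(out) - betas(co)[shared, ])), 0.02)
})
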