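test_that("region-set means aggregate the annotated probes", {
    n <- 40
    ann <- data.frame(probe_id = sprintf("cg%03d", 1:n),
                      gene_region = rep(c("TSS200", "none"), each = n / 2),
                      island_relation = rep(c("island", "open_sea"),
                                            each = n / 2),
                      chromatin_state = "quiescent")
    m <- matrix(0.3, n, 4, dimnames = list(ann$probe_id, paste0("S", 1:4)))
    sets <- regionSetDefaults()
    expect_equal(unname(regionSetMeans(m, sets$promoter_island, ann)),
                 rep(0.3, 4))
    expect_error(regionSetMeans(m, sets$poised_promoter, ann), "no probes")
})

test_that("region-set orderings on the synthetic cohort follow the subtypes", {
    pp <- small_pipeline()
    sets <- regionSetDefaults()
    lab <- subtypeLabels(pp$cohort)
    gm <- function(def) {
        v <- regionSetMeans(pp$tum, def)
        tapply(v[names(lab)], lab, mean)
    }
    promo <- gm(sets$promoter_island)
    poised <- gm(sets$poised_promoter)
    opensea <- gm(sets$away_from_genes)
    expect_true(promo[["MS1"]] > promo[["MS2"]] &&
                promo[["MS2"]] > promo[["MS3"]])
    expect_true(poised[["MS1"]] > poised[["MS2"]] &&
                poised[["MS2"]] > poised[["MS3"]])
    expect_true(opensea[["MS1"]] < opensea[["MS2"]] &&
                opensea[["MS2"]] < opensea[["MS3"]])
})

test_that("groupwise tests behave at the degenerate and strong-signal ends", {
    g <- rep(c("A", "B", "C"), each = 20)
    same <- rep(1, 60)
    expect_equal(groupwiseTest(same, g, "kruskal")$statistic, 0)

    strong <- withr::with_seed(3L, rep(c(0, 1, 2), each = 20) +
                                   rnorm(60, 0, 0.1))
    expect_lt(groupwiseTest(strong, g, "kruskal")$p_value, 1e-6)
    expect_lt(groupwiseTest(strong, g, "anova")$p_value, 1e-6)

    # jointly permuting values and labels leaves the statistic unchanged
    perm <- withr::with_seed(4L, sample(60))
    expect_equal(groupwiseTest(strong, g, "kruskal")$statistic,
                 groupwiseTest(strong[perm], g[perm], "kruskal")$statistic)

    expect_error(groupwiseTest(strong[1:21], g[1:21]), "at least 2 members")
})

test_that("the gene panel ANOVA applies the step-up adjustment", {
    withr::with_seed(8L, {
        expr <- matrix(rnorm(20 * 30), 20, 30,
                       dimnames = list(sprintf("G%02d", 1:20),
                                       sprintf("S%02d", 1:30)))
        labels <- setNames(rep(c("MS1", "MS2", "MS3"), each = 10),
                           colnames(expr))
        expr["G01", ] <- rep(c(0, 2, 4), each = 10) + rnorm(30, 0, 0.3)
        expr["G02", ] <- 1   # constant gene
    })
    expect_warning(
        res <- genePanelAnova(expr, labels, c(rownames(expr), "NOPE")),
        "unknown")
    expect_equal(res$p_value[res$gene == "G02"], 1)
    expect_lt(res$fdr[res$gene == "G01"], 1e-6)
    expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-12)
    # step-up adjustment never exceeds Bonferroni
    expect_true(all(res$fdr <= pmin(1, res$p_value * nrow(res)) + 1e-12))
})

test_that("fdr adjustment matches the brute-force step-up oracle", {
    expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    for (s in 1:20) {
        p <- withr::with_seed(600L + s, runif(sample(3:40, 1)))
        expect_lt(max(abs(stats::p.adjust(p, "BH") - bh_oracle(p))), 1e-9)
    }
})

test_that("subtype association tests react to structure and keep the null", {
    aligned <- setNames(rep(c("MS1", "MS2", "MS3"), each = 20),
                        sprintf("S%02d", 1:60))
    res <- subtypeAssociation(aligned, aligned, seed = 5L)
    expect_lt(res$p_value, 1e-3)
    expect_equal(sum(res$contingency), 60)

    # 2x2 diagonal table: closed-form two-sided Fisher p = 2 / choose(20, 10)
    a <- setNames(rep(c("X", "Y"), each = 10), sprintf("S%02d", 1:20))
    res2 <- subtypeAssociation(a, a)
    expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-9)

    # independent labels: the test keeps its size (binomial tolerance)
    rej <- withr::with_seed(41L, vapply(1:200, function(i) {
        x <- setNames(sample(c("MS1", "MS2", "MS3"), 60, replace = TRUE),
                      names(aligned))
        subtypeAssociation(aligned, x, seed = i, B = 1e3)$p_value < 0.05
    }, logical(1)))
    expect_lte(mean(rej), 0.09)
})

test_that("survival comparisons respect rank invariance and detect hazards", {
    t0 <- c(5, 10, 15, 20, 25, 30)
    ev <- c(1, 1, 0, 1, 0, 1)
    time <- c(t0, t0); event <- c(ev, ev)
    lab <- rep(c("MS1", "MS2"), each = 6)
    res <- survivalCompare(time, event, lab)
    expect_equal(res$logrank_chisq, 0, tolerance = 1e-12)

    # doubling all times cannot move the rank-based statistic
    withr::with_seed(10L, {
        surv <- simulateSurvival(factor(rep(c("MS1", "MS2", "MS3"),
                                            each = 60)))
    })
    r1 <- survivalCompare(surv$time, surv$event, surv$label)
    r2 <- survivalCompare(surv$time * 2, surv$event, surv$label)
    expect_equal(r1$logrank_chisq, r2$logrank_chisq, tolerance = 1e-9)

    # a planted MS1 hazard is detected at n = 180
    expect_gt(r1$hr_ms1, 1)
    expect_lt(r1$cox_p_ms1, 0.05)

    expect_error(survivalCompare(t0, rep(0, 6), rep(c("A", "B"), 3)),
                 "no events")
})

test_that("the RNA-seq normalization chain follows its printed order", {
    withr::with_seed(12L, {
        counts <- matrix(sample(1:100000, 24), 4, 6,   # tie-free columns
                         dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
    })
    counts[1, 1] <- 0
    counts[2, 2] <- 2e6    # must be capped
    out <- normalizeRnaseq(counts)

    # oracle: quantile-normalize by sorted-column means, then the chain
    sorted <- apply(counts, 2, sort)
    target <- rowMeans(sorted)
    q <- counts
    for (j in seq_len(ncol(counts))) {
        o <- order(counts[, j])
        q[o, j] <- target
    }
    manual <- log2(pmin(q + 32, 65000))
    manual <- sweep(manual, 1, apply(manual, 1, stats::median), "-")
    expect_equal(out, manual, tolerance = 1e-9)

    # every gene is median-centred
    expect_equal(unname(apply(out, 1, stats::median)), rep(0, 4))

    expect_error(normalizeRnaseq(-counts), "negative")
})

test_that("signature scores mirror the planted expression modules", {
    co <- small_cohort()
    lab <- subtypeLabels(co)
    imm <- signatureScore(co@expression, co@modules$immune_response)
    ccy <- signatureScore(co@expression, co@modules$cell_cycle)
    gm <- function(v) tapply(v[names(lab)], lab, mean)
    gi <- gm(imm); gc_ <- gm(ccy)
    expect_gt(gi[["MS3"]], gi[["MS1"]])          # immune tracks admixture
    expect_gt(min(gc_[["MS1"]], gc_[["MS2"]]), gc_[["MS3"]])

    single <- signatureScore(co@expression, co@modules$cell_cycle[1])
    expect_equal(single, co@expression[co@modules$cell_cycle[1], ])
    expect_error(signatureScore(co@expression, c("NO1", "NO2")),
                 "no module genes")
})

test_that("duplicate gene symbols are median-merged", {
    m <- matrix(c(1, 3, 10, 2, 4, 20), 3, 2,
                dimnames = list(NULL, c("S1", "S2")))
    out <- medianMergeBySymbol(m, c("A", "A", "B"))
    expect_equal(out["A", ], c(S1 = 2, S2 = 3))
    expect_equal(out["B", ], c(S1 = 10, S2 = 20))
})
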