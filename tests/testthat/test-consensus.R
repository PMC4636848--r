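two_blob_matrix <- function(nProbes = 40, perBlob = 6, seed = 2L) {
    withr::with_seed(seed, {
        n <- perBlob * 2
        m <- matrix(0, nProbes, n,
                    dimnames = list(sprintf("cg%03d", seq_len(nProbes)),
                                    sprintf("S%02d", seq_len(n))))
        m[, seq_len(perBlob)] <- 0.1 + rnorm(nProbes * perBlob, 0, 0.01)
        m[, perBlob + seq_len(perBlob)] <- 0.9 + rnorm(nProbes * perBlob, 0, 0.01)
        m[] <- pmin(1, pmax(0, m))
        m
    })
}

test_that("well-separated blobs never co-cluster across the gap", {
    m <- two_blob_matrix()
    blob <- rep(1:2, each = 6)
    same <- outer(blob, blob, "==")

    # every 2-cut must split between the blobs: within 1, between 0
    cc2 <- bootstrapCoclustering(m, rownames(m), nBoot = 100L, seed = 4L,
                                 ks = c(2L, 2L))
    v2 <- coclustering(cc2)
    expect_true(all(v2[same] == 1))
    expect_true(all(v2[!same] == 0))

    # with alternating 2/3-cuts a blob is sometimes subdivided, but no pair
    # ever crosses the gap and the consensus cut recovers the blobs exactly
    cc <- bootstrapCoclustering(m, rownames(m), nBoot = 100L, seed = 4L)
    v <- coclustering(cc)
    expect_true(all(v[!same] == 0))
    expect_true(all(v[same] > 0.5))
    got <- consensusGroups(cc, k = 2)$groups
    expect_equal(length(unique(got[blob == 1])), 1)
    expect_equal(length(unique(got[blob == 2])), 1)
    expect_false(got[1] == got[12])
})

test_that("co-clustering matrices are symmetric, unit-diagonal and reproducible", {
    pp <- small_pipeline()
    m <- betas(pp$tum)[combineSets(pp$sets), ]
    cc1 <- bootstrapCoclustering(m, rownames(m), nBoot = 50L, seed = 7L)
    cc2 <- bootstrapCoclustering(m, rownames(m), nBoot = 50L, seed = 7L)
    v <- coclustering(cc1)
    expect_identical(v, coclustering(cc2))
    expect_equal(v, t(v))
    expect_equal(unname(diag(v)), rep(1, ncol(m)))
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(sort(unique(cc1@ksUsed)), c(2L, 3L))
})

test_that("degenerate clustering inputs are rejected", {
    m <- two_blob_matrix()
    expect_error(bootstrapCoclustering(m[, 1:2], rownames(m), nBoot = 10L),
                 "3 samples")
    expect_error(bootstrapCoclustering(m, character(0), nBoot = 10L), "empty")
    expect_error(bootstrapCoclustering(m, c(rownames(m), "cgXXX"),
                                       nBoot = 10L), "absent")
    mNA <- m; mNA[1, 1] <- NA
    expect_error(bootstrapCoclustering(mNA, rownames(m), nBoot = 10L),
                 "missing")
})

test_that("a block-diagonal frequency matrix yields its blocks", {
    n <- 12
    blocks <- rep(1:3, each = 4)
    v <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
    dimnames(v) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
    cc <- new("CoClusteringMatrix", values = v, nBoot = 100L,
              ksUsed = rep(c(2L, 3L), 50))
    got <- consensusGroups(cc, k = 3)$groups
    expect_equal(length(unique(got)), 3)
    expect_true(all(tapply(got, blocks, function(x) length(unique(x))) == 1))

    singletons <- consensusGroups(cc, k = n)$groups
    expect_equal(length(unique(singletons)), n)
})

test_that("groups are renamed by decreasing promoter-island methylation", {
    nProbe <- 30
    ann <- data.frame(probe_id = sprintf("cg%03d", 1:nProbe),
                      gene_region = "TSS200", island_relation = "island")
    m <- matrix(rep(c(0.2, 0.6, 0.4), each = nProbe * 3), nProbe, 9,
                dimnames = list(ann$probe_id, sprintf("S%02d", 1:9)))
    groups <- rep(1:3, each = 3)
    names(groups) <- colnames(m)
    lab <- relabelByPromoterMethylation(groups, m, ann)
    expect_identical(as.character(lab[1:3]), rep("MS3", 3))   # mean 0.2
    expect_identical(as.character(lab[4:6]), rep("MS1", 3))   # mean 0.6
    expect_identical(as.character(lab[7:9]), rep("MS2", 3))   # mean 0.4

    # renaming the incoming group ids does not move the final labels
    lab2 <- relabelByPromoterMethylation(
        setNames(c(7L, 1L, 5L)[groups], names(groups)), m, ann)
    expect_identical(lab, lab2)

    expect_error(relabelByPromoterMethylation(groups[1:6], m[, 1:6], ann),
                 "3 groups")
})

test_that("consensus subtypes recover the planted groups", {
    pp <- small_pipeline()
    ari <- mclust::adjustedRandIndex(subtypeLabels(pp$res),
                                     subtypeLabels(pp$cohort))
    expect_gte(ari, 0.9)
    # the relabelling rule maps the top-promoter group to MS1
    expect_gte(label_match(subtypeLabels(pp$res),
                           subtypeLabels(pp$cohort)), 0.9)
})

test_that("permuting the samples permutes the labels identically", {
    pp <- small_pipeline()
    m <- betas(pp$tum)
    probes <- combineSets(pp$sets)
    perm <- withr::with_seed(9L, sample(ncol(m)))
    resP <- discoverSubtypes(m[, perm], probes, nBoot = 50L, seed = 31L,
                             annotation = probeAnnotation(pp$tum))
    resO <- discoverSubtypes(m, probes, nBoot = 50L, seed = 31L,
                             annotation = probeAnnotation(pp$tum))
    expect_identical(subtypeLabels(resO)[names(subtypeLabels(resP))],
                     subtypeLabels(resP))
})

test_that("labels are robust to halving the probe set", {
    pp <- small_pipeline()
    probes <- combineSets(pp$sets)
    half <- withr::with_seed(17L, sample(probes, length(probes) %/% 2))
    resH <- discoverSubtypes(pp$tum, half, nBoot = 100L, seed = 19L)
    changed <- mean(as.character(subtypeLabels(resH)) !=
                    as.character(subtypeLabels(pp$res)))
    expect_lte(changed, 0.1)
})

test_that("different bootstrap seeds give the same subtypes", {
    pp <- small_pipeline()
    res2 <- discoverSubtypes(pp$tum, combineSets(pp$sets), nBoot = 100L,
                             seed = 999L)
    ari <- mclust::adjustedRandIndex(subtypeLabels(pp$res),
                                     subtypeLabels(res2))
    expect_gte(ari, 0.9)
})
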