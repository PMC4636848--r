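#' Bootstrap co-clustering of samples over an aberrant CpG set
#'
#' For each of `nBoot` iterations the probe rows of the selected subset are
#' resampled with replacement to their original number, samples are
#' clustered by hierarchical clustering (Euclidean distance, Ward linkage)
#' and the dendrogram is cut into 2 clusters on odd iterations and 3 on even
#' ones.  The result is the frequency, over all iterations, with which each
#' sample pair fell into the same cluster.  Resampling probes keeps every
#' sample pair present in every iteration, so the frequency denominator is
#' exactly `nBoot`.
#'
#' @param x [BetaSet-class] or beta matrix without missing values.
#' @param probes probe IDs to cluster over (the combined aberrant set).
#' @param nBoot number of bootstrap iterations (default 1000).
#' @param seed RNG seed; the matrix is deterministic given it.
#' @param ks cluster counts alternated across iterations (default `c(2, 3)`).
#' @return a [CoClusteringMatrix-class].
#' @export
bootstrapCoclustering <- function(x, probes, nBoot = 1000L, seed = 1L,
                                  ks = c(2L, 3L)) {
    m <- betas(x)
    if (ncol(m) < 3L) stop("at least 3 samples are required")
    if (!length(probes)) stop("empty probe subset")
    missingProbes <- setdiff(probes, rownames(m))
    if (length(missingProbes))
        stop("probes absent from the matrix: ",
             paste(utils::head(missingProbes, 5), collapse = ", "))
    sub <- m[probes, , drop = FALSE]
    if (anyNA(sub)) stop("missing values present; impute first")
    n <- ncol(sub)
    nBoot <- as.integer(nBoot)
    if (nBoot < 2L) stop("nBoot must be >= 2")
    kSeq <- rep_len(as.integer(ks), nBoot)
    counts <- matrix(0, n, n)
    withr::with_seed(as.integer(seed), {
        for (b in seq_len(nBoot)) {
            idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
            hc <- stats::hclust(stats::dist(t(sub[idx, , drop = FALSE])),
                                method = "ward.D2")
            cl <- stats::cutree(hc, k = kSeq[b])
            counts <- counts + outer(cl, cl, "==")
        }
    })
    freq <- counts / nBoot
    dimnames(freq) <- list(colnames(sub), colnames(sub))
    new("CoClusteringMatrix", values = freq, nBoot = nBoot, ksUsed = kSeq)
}

#' Cut consensus groups from a co-clustering matrix
#'
#' The co-clustering frequency matrix is reordered by hierarchical
#' clustering with Pearson correlation distance (`1 - cor` of its rows) and
#' Ward linkage, and the dendrogram is cut into `k` consensus groups.
#' Samples whose co-clustering row is constant (zero variance) are assigned
#' distance 1 to every other sample, with a message.
#'
#' @param x a [CoClusteringMatrix-class].
#' @param k number of consensus groups (default 3).
#' @return list with `groups` (named integer vector of group indices, in
#'   dendrogram merge order) and `ordering` (leaf order for heatmap display).
#' @export
consensusGroups <- function(x, k = 3L) {
    stopifnot(is(x, "CoClusteringMatrix"))
    v <- x@values
    n <- nrow(v)
    if (k < 2L || k > n) stop("k must lie in [2, n_samples]")
    sds <- apply(v, 1L, stats::sd)
    if (any(sds == 0))
        message("constant co-clustering row(s): ",
                paste(rownames(v)[sds == 0], collapse = ", "),
                "; assigned unit distance to all samples")
    cmat <- suppressWarnings(stats::cor(t(v)))
    d <- 1 - cmat
    d[!is.finite(d)] <- 1
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    groups <- stats::cutree(hc, k = k)
    list(groups = groups, ordering = hc$order)
}

#' Rename consensus groups by promoter-island methylation
#'
#' Methylation subtypes are named by their promoter-island methylation
#' level: the group with the highest mean beta over promoter-island probes
#' (`gene_region` in TSS200/TSS1500 and `island_relation == "island"`)
#' becomes MS1 and the lowest MS3.  Exact ties are broken by the original
#' group index.
#'
#' @param groups integer or factor group membership (3 groups), named by
#'   sample.
#' @param x [BetaSet-class] or beta matrix of the same samples.
#' @param annotation probe annotation (taken from `x` when possible).
#' @return named factor with levels `MS1`, `MS2`, `MS3`.
#' @export
relabelByPromoterMethylation <- function(groups, x, annotation = NULL) {
    m <- betas(x)
    ann <- .resolveAnnotation(x, annotation,
                              require = c("gene_region", "island_relation"))
    g <- as.integer(factor(groups))
    names(g) <- if (is.null(names(groups))) colnames(m) else names(groups)
    if (length(unique(g)) != 3L) stop("exactly 3 groups are required")
    promo <- ann[rownames(m), "gene_region"] %in% c("TSS200", "TSS1500") &
        ann[rownames(m), "island_relation"] == "island"
    if (!any(promo)) stop("no promoter-island probes in the annotation")
    sampleMeans <- colMeans(m[promo, , drop = FALSE], na.rm = TRUE)
    groupMeans <- tapply(sampleMeans[names(g)], g, mean)
    ord <- order(-groupMeans, as.integer(names(groupMeans)))
    newLabel <- character(3L)
    newLabel[as.integer(names(groupMeans))[ord]] <- .MS_LEVELS
    out <- factor(newLabel[g], levels = .MS_LEVELS)
    names(out) <- names(g)
    out
}

#' Discover consensus methylation subtypes
#'
#' Convenience wrapper chaining [bootstrapCoclustering()],
#' [consensusGroups()] and [relabelByPromoterMethylation()].
#'
#' @param x annotated [BetaSet-class] without missing values.
#' @param probes the combined aberrant probe set to cluster over.
#' @param nBoot bootstrap iterations.
#' @param k number of consensus groups.
#' @param seed RNG seed for the bootstrap.
#' @param annotation probe annotation (defaults to the rowData of `x`).
#' @return a [ConsensusResult-class].
#' @export
discoverSubtypes <- function(x, probes, nBoot = 1000L, k = 3L, seed = 1L,
                             annotation = NULL) {
    cocl <- bootstrapCoclustering(x, probes, nBoot = nBoot, seed = seed)
    cut <- consensusGroups(cocl, k = k)
    labels <- if (k == 3L) {
        relabelByPromoterMethylation(cut$groups, x, annotation)
    } else {
        f <- factor(cut$groups)
        names(f) <- names(cut$groups)
        f
    }
    new("ConsensusResult", labels = labels, coclustering = cocl,
        ordering = as.integer(cut$ordering), k = as.integer(k),
        seed = as.integer(seed),
        dialect = "hclust ward.D2 (minimum-variance on unsquared distances)")
}
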