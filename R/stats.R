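#' Genome-wide CpG region sets
#'
#' A region set is a named list of predicates over the probe annotation
#' columns: each element names an annotation column and gives the admissible
#' values.  `regionSetDefaults()` returns the three standard sets used to
#' characterize methylation subtypes: promoter-island CpGs, CpGs away from
#' genes and islands, and poised-promoter CpGs (embryonic stem cell
#' chromatin state).
#'
#' @param name region set name.
#' @param ... `column = values` predicates (character vectors).
#' @return a `RegionSetDefinition` (a named list with a `name` attribute).
#' @export
regionSet <- function(name, ...) {
    pred <- list(...)
    if (!length(pred) || is.null(names(pred)) || any(names(pred) == ""))
        stop("predicates must be given as column = values")
    structure(pred, name = name, class = "RegionSetDefinition")
}

#' @rdname regionSet
#' @export
regionSetDefaults <- function() {
    list(
        promoter_island = regionSet("promoter_island",
            gene_region = c("TSS200", "TSS1500"),
            island_relation = "island"),
        away_from_genes = regionSet("away_from_genes",
            gene_region = "none",
            island_relation = "open_sea"),
        poised_promoter = regionSet("poised_promoter",
            chromatin_state = "poised_promoter"))
}

#' Per-sample mean beta over a CpG region set
#'
#' @param x [BetaSet-class] or beta matrix.
#' @param setDef a `RegionSetDefinition` from [regionSet()].
#' @param annotation probe annotation (taken from `x` when possible).
#' @return named numeric vector, one mean beta per sample.
#' @export
regionSetMeans <- function(x, setDef, annotation = NULL) {
    m <- betas(x)
    ann <- .resolveAnnotation(x, annotation, require = names(setDef))
    ann <- ann[rownames(m), , drop = FALSE]
    keep <- rep(TRUE, nrow(m))
    for (col in names(setDef))
        keep <- keep & as.character(ann[[col]]) %in% setDef[[col]]
    if (!any(keep))
        stop("region set '", attr(setDef, "name"),
             "' selects no probes")
    colMeans(m[keep, , drop = FALSE], na.rm = TRUE)
}

#' Test a per-sample quantity across subtype groups
#'
#' Kruskal-Wallis rank test (default) or one-way ANOVA of a numeric
#' per-sample value against the subtype labels.
#'
#' @param values named numeric vector.
#' @param labels group labels, named by sample or aligned with `values`.
#' @param method `"kruskal"` or `"anova"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
groupwiseTest <- function(values, labels, method = c("kruskal", "anova")) {
    method <- match.arg(method)
    labels <- .matchToValues(values, labels)
    g <- factor(as.character(labels))
    if (nlevels(g) < 2L) stop("at least 2 groups are required")
    if (any(table(g) < 2L)) stop("every group needs at least 2 members")
    if (method == "kruskal") {
        if (stats::sd(values) == 0)   # all ranks tied: the statistic is 0
            return(list(statistic = 0, p_value = 1, method = "kruskal"))
        kt <- stats::kruskal.test(values, g)
        list(statistic = unname(kt$statistic), p_value = kt$p.value,
             method = "kruskal")
    } else {
        fit <- stats::aov(values ~ g)
        sm <- summary(fit)[[1]]
        list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
             method = "anova")
    }
}

.matchToValues <- function(values, labels) {
    if (!is.null(names(values)) && !is.null(names(labels))) {
        missing <- setdiff(names(values), names(labels))
        if (length(missing))
            stop("labels missing for: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        labels[names(values)]
    } else {
        if (length(labels) != length(values))
            stop("labels and values must align")
        labels
    }
}

#' Per-gene ANOVA across subtypes with Benjamini-Hochberg adjustment
#'
#' One-way ANOVA of each panel gene's expression against the subtype
#' labels; p-values are adjusted over the panel with the Benjamini-Hochberg
#' step-up procedure.  Genes with zero variance get `p = 1` by contract;
#' genes absent from the matrix are skipped with a warning.
#'
#' @param expression gene-by-sample matrix (log scale).
#' @param labels subtype labels, named by sample or aligned with columns.
#' @param genes gene IDs of the panel.
#' @return data.frame with `gene`, `p_value`, `fdr`, ordered as `genes`.
#' @export
genePanelAnova <- function(expression, labels, genes) {
    known <- genes %in% rownames(expression)
    if (any(!known))
        warning("unknown gene(s) skipped: ",
                paste(utils::head(genes[!known], 5), collapse = ", "))
    genes <- genes[known]
    if (!length(genes)) stop("no panel genes present")
    g <- factor(as.character(.matchToValues(expression[1, ], labels)))
    p <- vapply(genes, function(gene) {
        y <- expression[gene, ]
        if (stats::sd(y, na.rm = TRUE) == 0) return(1)
        sm <- summary(stats::aov(y ~ g))[[1]]
        sm[["Pr(>F)"]][1]
    }, numeric(1))
    data.frame(gene = genes, p_value = unname(p),
               fdr = stats::p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Association between two categorical subtype labelings
#'
#' Contingency table over the common samples and Fisher's exact test
#' (Monte-Carlo with a fixed seed when the table exceeds 2x2).
#'
#' @param labelsA,labelsB named label vectors.
#' @param seed RNG seed for the Monte-Carlo test.
#' @param B Monte-Carlo replicates.
#' @return list with `contingency` and `p_value`.
#' @export
subtypeAssociation <- function(labelsA, labelsB, seed = 1L, B = 1e5) {
    a <- .asNamed(labelsA); b <- .asNamed(labelsB)
    common <- intersect(names(a), names(b))
    if (length(common) < 2L) stop("fewer than 2 common samples")
    tab <- table(factor(as.character(a[common])),
                 factor(as.character(b[common])))
    mc <- nrow(tab) > 2L || ncol(tab) > 2L
    p <- withr::with_seed(as.integer(seed),
        stats::fisher.test(tab, simulate.p.value = mc, B = B)$p.value)
    list(contingency = tab, p_value = p)
}

#' Survival comparison across methylation subtypes
#'
#' Log-rank test over all groups plus proportional-hazards fits: a Cox
#' model with the full subtype factor and the MS1-versus-rest contrast
#' (hazard ratio of MS1).
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param labels subtype labels aligned with `time`.
#' @return list with `logrank_chisq`, `logrank_p`, `hr_ms1` (MS1 vs rest
#'   hazard ratio), `hr_ms1_ci` (95% CI), `cox_p_ms1`, and `cox_fit` (the
#'   full-factor model).
#' @export
survivalCompare <- function(time, event, labels) {
    if (any(time < 0)) stop("negative times are not allowed")
    if (sum(event) == 0) stop("no events observed")
    g <- factor(as.character(labels))
    for (lv in levels(g))
        if (sum(event[g == lv]) == 0)
            warning("no events in group ", lv)
    s <- survival::Surv(time, event)
    sd_ <- survival::survdiff(s ~ g)
    ms1 <- factor(ifelse(g == "MS1", "MS1", "rest"), levels = c("rest", "MS1"))
    cox1 <- survival::coxph(s ~ ms1)
    coxAll <- survival::coxph(s ~ g)
    sm <- summary(cox1)
    list(logrank_chisq = unname(sd_$chisq),
         logrank_p = stats::pchisq(sd_$chisq, length(sd_$n) - 1,
                                   lower.tail = FALSE),
         hr_ms1 = unname(sm$conf.int[1, "exp(coef)"]),
         hr_ms1_ci = unname(sm$conf.int[1, c("lower .95", "upper .95")]),
         cox_p_ms1 = unname(sm$coefficients[1, "Pr(>|z|)"]),
         cox_fit = coxAll)
}

#' Normalize an RNA-seq count matrix for signature scoring
#'
#' The normalization chain applied, in order: quantile normalization across
#' samples, offset of +32, cap at 65,000, log2 transform, and per-gene
#' median centring.
#'
#' @param counts non-negative gene-by-sample matrix.
#' @return gene-by-sample matrix on the centred log2 scale.
#' @export
normalizeRnaseq <- function(counts) {
    m <- as.matrix(counts)
    if (any(m < 0, na.rm = TRUE)) stop("negative counts are not allowed")
    q <- limma::normalizeQuantiles(m)
    q <- q + 32
    q <- pmin(q, 65000)
    q <- log2(q)
    sweep(q, 1L, apply(q, 1L, stats::median, na.rm = TRUE), "-")
}

#' Per-sample mean expression of a gene module
#'
#' @param expression gene-by-sample matrix (log scale).
#' @param module gene IDs of the module; at least one must be present.
#' @return named numeric vector of per-sample module scores.
#' @export
signatureScore <- function(expression, module) {
    present <- intersect(module, rownames(expression))
    if (!length(present)) stop("no module genes present in the matrix")
    colMeans(expression[present, , drop = FALSE], na.rm = TRUE)
}

#' Median-merge duplicate gene symbols
#'
#' Expression rows sharing a gene symbol are collapsed to their per-sample
#' median, the conventional reduction for multi-probe arrays.
#'
#' @param expression probe-by-sample matrix.
#' @param symbols gene symbol per row.
#' @return gene-by-sample matrix with unique symbols.
#' @export
medianMergeBySymbol <- function(expression, symbols) {
    stopifnot(length(symbols) == nrow(expression))
    groups <- split(seq_along(symbols), symbols)
    out <- t(vapply(groups, function(idx) {
        apply(expression[idx, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    }, numeric(ncol(expression))))
    colnames(out) <- colnames(expression)
    out
}
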