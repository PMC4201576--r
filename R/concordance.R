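#' Spearman correlation with AS 89 significance
#'
#' Rank correlation (average ranks for ties) with the p-value of the
#' AS 89 algorithm as implemented by [stats::cor.test()]: exact
#' enumeration of the rank-statistic distribution for n <= 9 without
#' ties, an Edgeworth-series approximation for larger n, and the
#' t-distribution approximation when ties are present (exactness is
#' impossible under ties).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (undefined) for a
#'   constant input.
#' @examples
#' spearmanAS89(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearmanAS89 <- function(x, y) {
    if (length(x) != length(y))
        stop("validation error: length mismatch")
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L) stop("validation error: need >= 4 paired observations")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n))
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = !ties))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Protein-mRNA abundance concordance per gene
#'
#' For each gene measured on both platforms, the Spearman correlation
#' between log2 protein intensity and qPCR mean Cq across paired animals.
#' Cq is inverse to abundance (more mRNA = lower Cq), so agreement
#' between the platforms appears as a *negative* rho on this scale; pass
#' `abundance_scale = TRUE` to correlate against -Cq instead (exactly
#' flips the sign).
#'
#' @param x An [AbundanceExperiment-class].
#' @param cq Cq table (`animal_id`, `gene`, `mean_cq`), see
#'   [readCqTable()].
#' @param genes genes to evaluate; default those present in both
#'   datasets.
#' @param abundance_scale correlate against `-Cq` instead of Cq.
#' @return `data.frame` with columns `gene`, `rho`, `p`, `n` (paired
#'   animals); genes with fewer than 4 pairs or a constant vector get
#'   `NA` rho.
#' @examples
#' sim <- simulateDataset(syntheticConfig(mrna_coupling = 0.9, seed = 1L))
#' proteinMrnaConcordance(sim$abundance, sim$cq)
#' @export
proteinMrnaConcordance <- function(x, cq, genes = NULL,
                                   abundance_scale = FALSE) {
    cq <- validateCqTable(cq)
    if (is.null(genes))
        genes <- intersect(rownames(x), unique(cq$gene))
    ints <- maskedIntensities(x)
    dropped <- sum(!cq$animal_id %in% colnames(ints))
    if (dropped)
        message(dropped, " Cq record(s) without a matching animal dropped")
    rows <- lapply(genes, function(g) {
        sub <- cq[cq$gene == g & cq$animal_id %in% colnames(ints), ]
        prot <- ints[g, sub$animal_id]
        ok <- !is.na(prot)
        if (sum(ok) < 4L)
            return(data.frame(gene = g, rho = NA_real_, p = NA_real_,
                              n = sum(ok)))
        yy <- if (abundance_scale) -sub$mean_cq[ok] else sub$mean_cq[ok]
        sp <- spearmanAS89(log2(prot[ok]), yy)
        data.frame(gene = g, rho = sp$rho, p = sp$p, n = sp$n)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Concordance of combination-stability scores across platforms
#'
#' Spearman correlation between two combination-stability score vectors
#' (e.g. protein-based and mRNA-based) matched by combination label; the
#' ordering of scores is more meaningful than their magnitude, hence the
#' rank metric.
#'
#' @param protein_scores,mrna_scores `data.frame`s with columns
#'   `combination` and `stability` (as from
#'   [enumerateCombinationStability()]).
#' @return list with `rho`, `p`, `n` (overlapping combinations).
#' @export
stabilityScoreConcordance <- function(protein_scores, mrna_scores) {
    a <- as.data.frame(protein_scores)
    b <- as.data.frame(mrna_scores)
    shared <- intersect(a$combination, b$combination)
    if (length(shared) < 4L)
        stop("validation error: < 4 overlapping combination keys")
    spearmanAS89(a$stability[match(shared, a$combination)],
                 b$stability[match(shared, b$combination)])
}

#' Combination stability of mRNA (Cq) data
#'
#' Scores every gene combination on the qPCR side through the same
#' variance-decomposition code path as the protein data, using -Cq as a
#' log2-scale abundance proxy (Cq is log-scale and inverse to abundance).
#' Animal grouping and cohort membership come from the matching
#' [AbundanceExperiment-class].
#'
#' @inheritParams proteinMrnaConcordance
#' @inheritParams stabilityScores
#' @return `data.frame` as from [enumerateCombinationStability()].
#' @export
cqCombinationStability <- function(x, cq, cohort = "overall",
                                   cohortMap = assignCohort,
                                   genes = NULL) {
    cq <- validateCqTable(cq)
    if (is.null(genes))
        genes <- intersect(candidateNames(x), unique(cq$gene))
    sub <- .cohortSubset(x, cohort, cohortMap)
    anim <- animalInfo(sub)
    M <- matrix(NA_real_, length(genes), nrow(anim),
                dimnames = list(genes, anim$animal_id))
    hit <- cq$gene %in% genes & cq$animal_id %in% anim$animal_id
    M[cbind(match(cq$gene[hit], genes),
            match(cq$animal_id[hit], anim$animal_id))] <- -cq$mean_cq[hit]
    M <- .completeCases(M)
    groups <- anim$treated[match(colnames(M), anim$animal_id)]
    combinationStabilityMatrix(M, groups,
        cohort = match.arg(cohort, c("overall", "training", "validation")))
}
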