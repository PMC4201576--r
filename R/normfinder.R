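#' Variance-decomposition components of the stability model
#'
#' Per (protein i, group g): `MS`, the mean square of double-centered
#' residuals; `sigma2`, the corrected intra-group variance estimate; `d`,
#' the inter-group expression difference; `d_tilde`, its empirical-Bayes
#' shrunk version (all log2 units or log2 units squared).  `gamma2` is the
#' shared estimate of the variance of true inter-group differences and
#' `rho` the per-protein stability value (log2 units; lower = more
#' stable).
#'
#' @name NormFinderComponents-class
#' @exportClass NormFinderComponents
setClass("NormFinderComponents",
    representation(MS = "matrix", sigma2 = "matrix", d = "matrix",
                   d_tilde = "matrix", gamma2 = "numeric", rho = "numeric",
                   n_per_group = "integer"))

setMethod("show", "NormFinderComponents", function(object) {
    cat("NormFinderComponents:", nrow(object@MS), "proteins,",
        ncol(object@MS), "groups (n =",
        paste(object@n_per_group, collapse = ", "), ")\n")
    cat("  gamma2:", format(object@gamma2, digits = 4), "\n")
    print(sort(object@rho))
    invisible(NULL)
})

#' @describeIn NormFinderComponents-class extract the named stability
#'   values.
#' @param x A `NormFinderComponents`.
#' @export
stabilityValues <- function(x) x@rho

#' Log2 intensity matrix for the stability model
#'
#' The variance model operates on log2 intensities, where multiplicative
#' densitometry error is additive.  Excluded wells become `NA`.
#'
#' @param x An [AbundanceExperiment-class].
#' @param proteins rows to keep; default the loading-control candidates
#'   (positive control dropped).
#' @return numeric matrix (proteins x animals) of log2 intensities with
#'   `NA` for excluded/unmeasured wells.
#' @export
log2Matrix <- function(x, proteins = candidateNames(x)) {
    ints <- maskedIntensities(x)[proteins, , drop = FALSE]
    if (any(ints <= 0, na.rm = TRUE))
        stop("validation error: non-positive intensity")
    log2(ints)
}

## Complete-case filter: the model needs every protein observed on every
## animal it uses; animals with any missing value are dropped listwise.
.completeCases <- function(Y, quiet = FALSE) {
    keep <- colSums(is.na(Y)) == 0L
    if (!all(keep) && !quiet)
        message(sum(!keep),
                " animal(s) dropped (missing values) for stability analysis")
    Y[, keep, drop = FALSE]
}

.nfCheck <- function(Y, groups) {
    if (nrow(Y) < 3L)
        stop("insufficient-candidates error: need >= 3 proteins")
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stop("insufficient-replication error: need >= 2 groups")
    ng <- table(groups)
    if (any(ng < 2L))
        stop("insufficient-replication error: every group needs >= 2 animals")
    groups
}

## Core estimator.  Within each group, residuals are double-centered
## (protein effect and per-animal sample effect removed); their mean square
## is corrected by n/(n-2) and the shared leakage term sum(MS)/(n(n-1)) to
## give an estimate of each protein's intra-group variance.  Inter-group
## differences d are shrunk toward zero by gamma2/(gamma2 + sigma2/ng); the
## stability value is the group-average of |shrunk d| plus its posterior SD.
.nfCore <- function(Y, groups) {
    groups <- .nfCheck(Y, groups)
    n <- nrow(Y)
    lev <- levels(groups)
    G <- length(lev)
    ng <- as.integer(table(groups)[lev])
    yi_all <- rowMeans(Y)
    y_all <- mean(Y)
    MS <- d <- matrix(NA_real_, n, G, dimnames = list(rownames(Y), lev))
    for (k in seq_along(lev)) {
        Yg <- Y[, groups == lev[k], drop = FALSE]
        ygj <- colMeans(Yg)
        yig <- rowMeans(Yg)
        yg <- mean(Yg)
        R <- Yg - yig - rep(ygj - yg, each = n)
        MS[, k] <- rowSums(R^2) / (ng[k] - 1L)
        d[, k] <- (yig - yg) - (yi_all - y_all)
    }
    sigma2 <- vapply(seq_len(G), function(k)
        pmax(0, n / (n - 2) * (MS[, k] - sum(MS[, k]) / (n * (n - 1)))),
        numeric(n))
    dimnames(sigma2) <- dimnames(MS)
    s2n <- sweep(sigma2, 2L, ng, "/")
    gamma2 <- max(0, sum(d^2) / (n * (G - 1)) - mean(s2n))
    denom <- gamma2 + s2n
    shrink <- ifelse(denom > 0, gamma2 / denom, 0)
    d_tilde <- d * shrink
    rho <- rowMeans(abs(d_tilde) + sqrt(s2n * shrink))
    new("NormFinderComponents", MS = MS, sigma2 = sigma2, d = d,
        d_tilde = d_tilde, gamma2 = gamma2, rho = rho,
        n_per_group = ng)
}

#' Decompose log2 abundance variance into stability components
#'
#' The model-based stability estimator: for log2 value `y_igj` of protein
#' i, group g, animal j, residuals are double-centered within each group,
#' `MS_ig = sum_j (y_igj - ybar_ig. - ybar_.gj + ybar_.g.)^2 / (n_g - 1)`;
#' the corrected intra-group variance is
#' `sigma2_ig = max(0, n/(n-2) * (MS_ig - sum_i' MS_i'g / (n (n-1))))`;
#' inter-group differences
#' `d_ig = (ybar_ig. - ybar_.g.) - (ybar_i.. - ybar_...)` sum to zero over
#' proteins; their dispersion `gamma2 = max(0, sum d^2 / (n (G-1)) -
#' mean(sigma2_ig / n_g))` drives the shrinkage
#' `d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g)`; and the stability
#' value is `rho_i = mean_g(|d~_ig| + sqrt((sigma2_ig / n_g) * gamma2 /
#' (gamma2 + sigma2_ig / n_g)))`.  Lower `rho` = more stable.  Negative
#' variance estimates are truncated at zero.
#'
#' @param log_matrix numeric matrix of log2 intensities (proteins x
#'   animals), at least 3 proteins; animals with any `NA` are dropped
#'   listwise (count reported).
#' @param groups group label per animal (e.g. treated/control); at least
#'   two groups with two animals each.
#' @return A [NormFinderComponents-class] object.
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' Y <- log2Matrix(sim$abundance)
#' nf <- decomposeVariance(Y, animalInfo(sim$abundance)$treated)
#' sort(stabilityValues(nf))
#' @export
decomposeVariance <- function(log_matrix, groups) {
    stopifnot(ncol(log_matrix) == length(groups))
    keep <- colSums(is.na(log_matrix)) == 0L
    if (!all(keep))
        message(sum(!keep),
                " animal(s) dropped (missing values) for stability analysis")
    .nfCore(log_matrix[, keep, drop = FALSE], groups[keep])
}

.cohortSubset <- function(x, cohort, cohortMap) {
    cohort <- match.arg(cohort, c("overall", "training", "validation"))
    if (cohort == "overall") return(x)
    x[, cohortMap(animalInfo(x)$experiment) == cohort]
}

#' Per-candidate stability values in a cohort
#'
#' Restricts the dataset to a cohort, groups animals as TCDD-treated
#' versus control, and runs [decomposeVariance()] on the candidates'
#' log2 intensities.
#'
#' @param x An [AbundanceExperiment-class].
#' @param cohort `"overall"`, `"training"` or `"validation"`.
#' @param cohortMap function mapping experiment numbers to cohort labels;
#'   default the study split ([assignCohort()]).
#' @param proteins candidate set; default [candidateNames()].
#' @return named numeric vector of stability values (lower = more stable).
#' @export
stabilityScores <- function(x, cohort = "overall",
                            cohortMap = assignCohort,
                            proteins = candidateNames(x)) {
    sub <- .cohortSubset(x, cohort, cohortMap)
    Y <- log2Matrix(sub, proteins)
    stabilityValues(decomposeVariance(Y, animalInfo(sub)$treated))
}

#' Geometric-mean pseudo-candidate of a protein subset
#'
#' Per animal, the arithmetic mean of the members' log2 values, i.e. the
#' log2 of the geometric mean of their intensities.  Animals missing any
#' member get `NA` (dropped when the pseudo-candidate is scored).
#'
#' @param log_matrix log2 intensity matrix (proteins x animals).
#' @param subset non-empty character vector of member row names.
#' @return named numeric vector, one value per animal.
#' @export
combinationPseudocandidate <- function(log_matrix, subset) {
    if (!length(subset)) stop("subset must be non-empty")
    if (!all(subset %in% rownames(log_matrix)))
        stop("unknown protein(s): ",
             paste(setdiff(subset, rownames(log_matrix)), collapse = ", "))
    colMeans(log_matrix[subset, , drop = FALSE])
}

## Score pseudo-candidates against the centering terms (per-animal sample
## effects, per-group means, MS-sum leakage correction, shared gamma2)
## estimated once from the full candidate matrix: the sample effect is a
## property of the animal/blot, not of the chosen subset.  A singleton
## subset reproduces the full-matrix single-candidate score exactly.
.nfComboScores <- function(Y, groups, subsets) {
    groups <- .nfCheck(Y, groups)
    full <- .nfCore(Y, groups)
    n <- nrow(Y)
    lev <- levels(groups)
    G <- length(lev)
    ng <- full@n_per_group
    y_all <- mean(Y)
    ctr <- lapply(seq_along(lev), function(k) {
        Yg <- Y[, groups == lev[k], drop = FALSE]
        list(ygj = colMeans(Yg), yg = mean(Yg),
             ms_sum = sum(full@MS[, k]))
    })
    gamma2 <- full@gamma2
    vapply(subsets, function(S) {
        u <- colMeans(Y[S, , drop = FALSE])
        u_all <- mean(u)
        acc <- 0
        for (k in seq_along(lev)) {
            uk <- u[groups == lev[k]]
            ug <- mean(uk)
            r <- uk - ug - (ctr[[k]]$ygj - ctr[[k]]$yg)
            MSg <- sum(r^2) / (ng[k] - 1L)
            s2 <- max(0, n / (n - 2) *
                          (MSg - ctr[[k]]$ms_sum / (n * (n - 1))))
            dg <- (ug - ctr[[k]]$yg) - (u_all - y_all)
            denom <- gamma2 + s2 / ng[k]
            shr <- if (denom > 0) gamma2 / denom else 0
            acc <- acc + abs(dg * shr) + sqrt(s2 / ng[k] * shr)
        }
        acc / G
    }, numeric(1))
}

.subsetLabels <- function(subsets)
    vapply(subsets, function(S) paste(sort(S), collapse = "+"), character(1))

#' Stability of every geometric-mean combination of candidates
#'
#' Enumerates all non-empty subsets of the candidate set (127 for 7
#' candidates), forms each subset's geometric-mean pseudo-candidate, and
#' scores it with the variance-decomposition model, re-using the sample
#' centering and correction terms of the full candidate matrix (so
#' singleton scores equal [stabilityScores()] exactly).
#'
#' @inheritParams stabilityScores
#' @return `data.frame` with columns `combination` ("+"-joined sorted
#'   ids), `size`, `cohort`, `stability`, ordered by size then label.
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' combos <- enumerateCombinationStability(sim$abundance, "training")
#' head(combos[order(combos$stability), ])
#' @export
enumerateCombinationStability <- function(x, cohort = "overall",
                                          cohortMap = assignCohort,
                                          proteins = candidateNames(x)) {
    sub <- .cohortSubset(x, cohort, cohortMap)
    Y <- .completeCases(log2Matrix(sub, proteins))
    groups <- animalInfo(sub)$treated[match(colnames(Y),
                                            animalInfo(sub)$animal_id)]
    combinationStabilityMatrix(Y, groups,
        cohort = match.arg(cohort, c("overall", "training", "validation")))
}

#' @describeIn enumerateCombinationStability matrix-level worker, also
#'   used to score mRNA (-Cq) data through the same code path.
#' @param Y complete-case log2 abundance matrix (proteins x animals).
#' @param groups group label per column of `Y`.
#' @export
combinationStabilityMatrix <- function(Y, groups, cohort = "overall") {
    prots <- sort(rownames(Y))
    subsets <- unlist(lapply(seq_along(prots), function(k)
        utils::combn(prots, k, simplify = FALSE)), recursive = FALSE)
    scores <- .nfComboScores(Y, groups, subsets)
    data.frame(combination = .subsetLabels(subsets),
               size = lengths(subsets),
               cohort = cohort,
               stability = unname(scores))
}
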