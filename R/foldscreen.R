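#' Fold-difference between treated and control groups
#'
#' The fold-difference M is the ratio of the treated-group mean intensity
#' to the control-group mean, on the linear scale; it is reported together
#' with its log2 and the SD of the per-animal log2 ratios
#' `log2(treated_j / mean(control))` (the error bar of the screen).
#'
#' @param treated,control positive intensity values of the two groups.
#' @return list with elements `M`, `log2M`, `sd_log2M` (`NA` when the
#'   treated group has a single animal).
#' @examples
#' foldDifference(c(8, 8), c(2, 2))               # M = 4, log2M = 2
#' foldDifference(c(10, 20, 30), c(5, 10, 15))    # M = 2
#' @export
foldDifference <- function(treated, control) {
    if (!length(treated) || !length(control))
        stop("undefined-comparison error: empty group")
    if (any(treated <= 0) || any(control <= 0))
        stop("validation error: intensities must be > 0")
    M <- mean(treated) / mean(control)
    lr <- log2(treated / mean(control))
    list(M = M, log2M = log2(M),
         sd_log2M = if (length(treated) >= 2L) stats::sd(lr) else NA_real_)
}

#' Welch two-sample t-test on intensities
#'
#' Unpaired, two-tailed t-test with the Welch-Satterthwaite adjustment for
#' unequal variances (via [stats::t.test()]).  Groups of fewer than two
#' animals are untestable and return `NA` results rather than an error.
#' Two exactly constant groups are handled at the limit: equal constants
#' give `t = 0, p = 1`; different constants give `p = 0`.
#'
#' @param a,b numeric intensity vectors.
#' @return list with `t`, `df`, `p`, `testable`.
#' @examples
#' welchTest(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
#' @export
welchTest <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                    testable = FALSE))
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b))
            return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                        testable = TRUE))
        return(list(t = sign(mean(a) - mean(b)) * Inf,
                    df = length(a) + length(b) - 2, p = 0, testable = TRUE))
    }
    fit <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value, testable = TRUE)
}

#' Per-condition fold-differences and Welch tests for every candidate
#'
#' For every treated-versus-control condition ([buildConditions()]) and
#' every protein, computes the fold-difference and the Welch t-test on the
#' linear-scale intensities of non-excluded animals.  Group sizes are
#' protein-specific (exclusions differ between candidates); a comparison
#' is `testable` only with two or more measured animals on both sides.
#'
#' @param x An [AbundanceExperiment-class].
#' @param alpha significance level for the `significant` flag
#'   (uncorrected, per the screen's convention).
#' @param proteins rows to screen; default all rows (candidates and
#'   positive control).
#' @param test_scale `"linear"` (default) or `"log2"`: scale on which the
#'   t-test is run (fold-differences are always reported in log2).
#' @return `data.frame`, one row per condition x protein, with the
#'   condition key columns plus `protein`, `M`, `log2M`, `sd_log2M`, `t`,
#'   `df`, `p`, `n_treated`, `n_control`, `testable`, `significant`.
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' cc <- conditionComparisons(sim$abundance)
#' head(cc[cc$protein == "CYP1A1", c("experiment", "dose", "log2M", "p")])
#' @export
conditionComparisons <- function(x, alpha = 0.05, proteins = rownames(x),
                                 test_scale = c("linear", "log2")) {
    stopifnot(alpha > 0, alpha < 1)
    test_scale <- match.arg(test_scale)
    cond <- buildConditions(x)
    ints <- maskedIntensities(x)[proteins, , drop = FALSE]
    anim <- animalInfo(x)
    akey <- .groupKey(anim)
    rows <- lapply(seq_len(nrow(cond)), function(r) {
        ck <- cond[r, ]
        tkey <- .groupKey(ck)
        ckey <- .groupKey(transform(ck, dose = 0))
        tcols <- which(akey == tkey)
        ccols <- which(akey == ckey)
        per <- lapply(proteins, function(p) {
            tv <- ints[p, tcols]; tv <- tv[!is.na(tv)]
            cv <- ints[p, ccols]; cv <- cv[!is.na(cv)]
            fd <- if (length(tv) && length(cv)) foldDifference(tv, cv)
                  else list(M = NA_real_, log2M = NA_real_,
                            sd_log2M = NA_real_)
            wt <- if (test_scale == "linear") welchTest(tv, cv)
                  else welchTest(log2(tv), log2(cv))
            data.frame(protein = p, M = fd$M, log2M = fd$log2M,
                       sd_log2M = fd$sd_log2M, t = wt$t, df = wt$df,
                       p = wt$p, n_treated = length(tv),
                       n_control = length(cv), testable = wt$testable)
        })
        cbind(ck[rep(1L, length(proteins)), .groupKeyCols],
              do.call(rbind, per))
    })
    out <- do.call(rbind, rows)
    out$significant <- out$testable & !is.na(out$p) & out$p < alpha
    rownames(out) <- NULL
    out
}

#' Significance profile of one candidate across the screen
#'
#' Counts the testable conditions in which a candidate's abundance differs
#' significantly (Welch p < `alpha`, uncorrected) between treated and
#' control animals.  A good loading control scores low.
#'
#' @inheritParams conditionComparisons
#' @param protein a single protein id present in `x`.
#' @return list with `n_sig` and `n_comparisons`.
#' @export
significanceProfile <- function(x, protein, alpha = 0.05) {
    if (!protein %in% rownames(x))
        stop("unknown-candidate error: ", protein)
    cc <- conditionComparisons(x, alpha = alpha, proteins = protein)
    cc <- cc[cc$testable, , drop = FALSE]
    list(n_sig = sum(cc$significant), n_comparisons = nrow(cc))
}

#' Correlation of two candidates' fold-difference profiles
#'
#' Pearson correlation of the log2 fold-difference vectors of two
#' candidates over the conditions in which both are evaluable; candidates
#' that respond alike across the design correlate highly.
#'
#' @inheritParams significanceProfile
#' @param protein_a,protein_b protein ids.
#' @return Pearson correlation coefficient.
#' @export
foldProfileCorrelation <- function(x, protein_a, protein_b) {
    cc <- conditionComparisons(x, proteins = c(protein_a, protein_b))
    key <- .groupKey(cc)
    a <- cc[cc$protein == protein_a, ]
    b <- cc[cc$protein == protein_b, ]
    b <- b[match(.groupKey(a), .groupKey(b)), ]
    ok <- is.finite(a$log2M) & is.finite(b$log2M)
    if (sum(ok) < 3L)
        stop("insufficient-data error: < 3 shared evaluable conditions")
    stats::cor(a$log2M[ok], b$log2M[ok])
}
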