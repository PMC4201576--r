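#' Normalize one candidate's abundances by another
#'
#' The pairwise comparative statistic (an intensity-scale adaptation of
#' the comparative delta-Cq idea) asks how flat a target protein becomes
#' after division by a reference.  Per animal,
#' `v_j = (y_target,j / y_ref,j) * median_j(y_ref,j)`: the ratio is
#' rescaled by the reference's median so the result keeps intensity units
#' (which is why a reference with very large absolute intensities, like
#' ACTB, carries large absolute scores).
#'
#' @param x An [AbundanceExperiment-class].
#' @param target,reference distinct protein ids.
#' @return named numeric vector over animals with both proteins measured
#'   (others dropped).
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' head(referenceNormalize(sim$abundance, "GAPDH", "HPRT"))
#' @export
referenceNormalize <- function(x, target, reference) {
    if (identical(target, reference))
        stop("target and reference must differ")
    ints <- maskedIntensities(x)
    if (!all(c(target, reference) %in% rownames(ints)))
        stop("unknown protein id")
    yt <- ints[target, ]
    yr <- ints[reference, ]
    med <- stats::median(yr, na.rm = TRUE)
    ok <- !is.na(yt) & !is.na(yr) & yr > 0
    (yt[ok] / yr[ok]) * med
}

#' Pairwise comparative-normalization stability scores
#'
#' For each candidate used as the reference, the other candidates are
#' normalized by it ([referenceNormalize()]); the SD of the normalized
#' values is taken within each experimental group (animals of one
#' (experiment, strain, sex, genotype, dose, time) cell, i.e.
#' biologically-equivalent replicates, so genuine treatment responses of
#' the targets do not dominate), averaged over groups, and finally
#' averaged over the target proteins.  A low mean SD means the reference
#' removes variation well.  Scores scale with overall intensity: doubling
#' all intensities doubles every score.
#'
#' @param x An [AbundanceExperiment-class].
#' @param proteins candidate set; default [candidateNames()].
#' @return list with `scores` (`data.frame`: `reference`, `mean_sd`,
#'   lower = better) and `pairs` (`data.frame`: `reference`, `target`,
#'   `sd`, the per-target group-averaged SDs).
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' comparativeStability(sim$abundance)$scores
#' @export
comparativeStability <- function(x, proteins = candidateNames(x)) {
    if (length(proteins) < 2L)
        stop("need at least two candidates")
    anim <- animalInfo(x)
    gkey <- .groupKey(anim)
    names(gkey) <- anim$animal_id
    pairs <- expand.grid(reference = proteins, target = proteins,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$reference != pairs$target, ]
    pairs$sd <- mapply(function(ref, tgt) {
        v <- referenceNormalize(x, tgt, ref)
        g <- gkey[names(v)]
        sds <- tapply(v, g, function(z)
            if (length(z) >= 2L) stats::sd(z) else NA_real_)
        mean(sds, na.rm = TRUE)
    }, pairs$reference, pairs$target)
    scores <- stats::aggregate(sd ~ reference, data = pairs, FUN = mean)
    names(scores)[2L] <- "mean_sd"
    scores <- scores[order(match(scores$reference, proteins)), ]
    rownames(scores) <- NULL
    pairs <- pairs[order(match(pairs$reference, proteins),
                         match(pairs$target, proteins)), ]
    rownames(pairs) <- NULL
    list(scores = scores, pairs = pairs)
}
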