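#' Linear-model attribution of combination stability
#'
#' Fits, by ordinary least squares with no intercept, the model
#' `Y = a_1 x_1 + ... + a_k x_k + e` where `Y` is the stability value of a
#' candidate combination and `x_p` is a Boolean indicator for candidate
#' p's membership.  The design covers all `2^k - 1` non-empty subsets of
#' one cohort's score table.  A negative coefficient means including the
#' candidate lowers the stability value, i.e. stabilizes combinations.
#' Two-sided p-values come from the t distribution; q-values are
#' Benjamini-Hochberg FDR across the k coefficients.
#'
#' @param scores `data.frame` with columns `combination` ("+"-joined ids)
#'   and `stability`, covering every non-empty subset of one candidate set
#'   for a single cohort (as produced by
#'   [enumerateCombinationStability()]).
#' @return `data.frame` with columns `candidate`, `coef`, `se`, `p`,
#'   `q_bh`, ordered by candidate id.
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' combos <- enumerateCombinationStability(sim$abundance, "overall")
#' fitLinearAttribution(combos)
#' @export
fitLinearAttribution <- function(scores) {
    scores <- as.data.frame(scores)
    stopifnot(all(c("combination", "stability") %in% colnames(scores)))
    if ("cohort" %in% colnames(scores) &&
        length(unique(scores$cohort)) > 1L)
        stop("scores must come from a single cohort")
    members <- strsplit(scores$combination, "+", fixed = TRUE)
    candidates <- sort(unique(unlist(members)))
    k <- length(candidates)
    expected <- 2^k - 1L
    if (nrow(scores) != expected ||
        anyDuplicated(vapply(members, function(m)
            paste(sort(m), collapse = "+"), character(1))))
        stop("incomplete-design error: need all ", expected,
             " non-empty subsets exactly once")
    X <- vapply(candidates, function(p)
        as.numeric(vapply(members, function(m) p %in% m, logical(1))),
        numeric(nrow(scores)))
    colnames(X) <- candidates
    stopifnot(all(rowSums(X) >= 1), qr(X)$rank == k)
    fit <- stats::lm(scores$stability ~ 0 + X)
    cf <- summary(fit)$coefficients
    out <- data.frame(candidate = candidates,
                      coef = unname(cf[, 1L]),
                      se = unname(cf[, 2L]),
                      p = unname(cf[, 4L]))
    out$q_bh <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
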