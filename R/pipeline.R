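#' Run the full reference-protein stability pipeline
#'
#' Executes, in order: the per-condition fold-difference/Welch screen;
#' single-candidate stability values in the training, validation and
#' overall cohorts; stability of all geometric-mean combinations per
#' cohort; the pairwise comparative-normalization statistic; linear-model
#' attribution of combination stability (overall cohort); and, when a Cq
#' table is supplied, per-gene protein-mRNA concordance and the
#' cross-platform concordance of combination-stability vectors.  The
#' analysis is deterministic: identical inputs give bit-identical output.
#'
#' @param x An [AbundanceExperiment-class].
#' @param cq optional Cq table (`animal_id`, `gene`, `mean_cq`); when
#'   `NULL` the concordance stage is skipped with a log notice.
#' @param alpha significance level of the Welch screen.
#' @param cohortMap function mapping experiment to cohort; default
#'   [assignCohort()].
#' @param test_scale scale for the Welch screen, see
#'   [conditionComparisons()].
#' @return list of result tables: `conditions` (per condition x protein
#'   screen rows), `table2_like` (per candidate: `n_sig`,
#'   `n_comparisons`, `nf_training`, `nf_validation`, `compnorm_score`),
#'   `combinations` (127 rows per cohort), `pairwise_sd`, `attribution`,
#'   and with Cq data `table3_like` (per gene rho/p/n) and
#'   `stability_concordance`; plus `log`, a list of run metadata
#'   (settings, dropped-record counts, group sizes).
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' res <- runPipeline(sim$abundance, sim$cq)
#' res$table2_like
#' @export
runPipeline <- function(x, cq = NULL, alpha = 0.05,
                        cohortMap = assignCohort,
                        test_scale = c("linear", "log2")) {
    test_scale <- match.arg(test_scale)
    log <- list(alpha = alpha, log_base = 2, test_scale = test_scale,
                n_animals = ncol(x), n_proteins = nrow(x),
                n_excluded_wells = sum(exclusionMask(x)))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    }
    cands <- candidateNames(x)

    conditions <- stage("fold_screen",
        conditionComparisons(x, alpha = alpha, test_scale = test_scale))
    tc <- conditions[conditions$protein %in% cands & conditions$testable, ]
    n_sig <- tapply(tc$significant, tc$protein, sum)[cands]
    n_cmp <- tapply(tc$testable, tc$protein, sum)[cands]

    nf_tr <- stage("normfinder",
        stabilityScores(x, "training", cohortMap, cands))
    nf_va <- stage("normfinder",
        stabilityScores(x, "validation", cohortMap, cands))
    combos <- stage("normfinder", do.call(rbind, lapply(
        c("training", "validation", "overall"), function(ch)
            enumerateCombinationStability(x, ch, cohortMap, cands))))

    comp <- stage("comparative_norm", comparativeStability(x, cands))

    table2 <- data.frame(candidate = cands,
                         n_sig = as.integer(n_sig),
                         n_comparisons = as.integer(n_cmp),
                         nf_training = unname(nf_tr[cands]),
                         nf_validation = unname(nf_va[cands]),
                         compnorm_score =
                             comp$scores$mean_sd[match(cands,
                                                       comp$scores$reference)])

    attribution <- stage("attribution",
        fitLinearAttribution(combos[combos$cohort == "overall", ]))

    out <- list(conditions = conditions, table2_like = table2,
                combinations = combos, pairwise_sd = comp$pairs,
                attribution = attribution)

    if (is.null(cq)) {
        log$concordance <- "skipped: no Cq data supplied"
        message("concordance stage skipped: no Cq data supplied")
    } else {
        out$table3_like <- stage("concordance",
            proteinMrnaConcordance(x, cq, genes = cands))
        cq_combos <- stage("concordance",
            cqCombinationStability(x, cq, "overall", cohortMap))
        sc <- stage("concordance", stabilityScoreConcordance(
            combos[combos$cohort == "overall", ], cq_combos))
        out$stability_concordance <-
            data.frame(entity = "stability-vector", rho = sc$rho,
                       p = sc$p, n = sc$n)
        log$concordance <- sprintf("%d combinations compared", sc$n)
    }
    cond_sizes <- unique(conditions[, c(.groupKeyCols, "n_treated",
                                        "n_control", "testable")])
    log$n_conditions <- nrow(unique(conditions[.groupKeyCols]))
    log$n_testable_max <- max(tapply(tc$testable, tc$protein, sum))
    out$log <- log
    out$condition_sizes <- cond_sizes
    out
}

#' Write a pipeline result bundle to disk
#'
#' Writes every result table via [writeResults()] plus a `run_log.json`
#' with the run metadata.
#'
#' @param res result list from [runPipeline()].
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
writePipelineResults <- function(res, out_dir) {
    tables <- res[vapply(res, is.data.frame, logical(1))]
    paths <- writeResults(tables, out_dir)
    log_path <- file.path(out_dir, "run_log.json")
    writeLines(jsonlite::toJSON(res$log, auto_unbox = TRUE, pretty = TRUE),
               log_path)
    invisible(c(paths, log_path))
}

#' Diagnostic plot of combination stability by subset size
#'
#' Base-graphics stripchart of stability values against the number of
#' candidates included, one panel point cloud per cohort present.
#'
#' @param combos combination table from
#'   [enumerateCombinationStability()] (one or more cohorts).
#' @return invisibly, `NULL`.
#' @export
plotCombinationStability <- function(combos) {
    combos <- as.data.frame(combos)
    cohorts <- unique(combos$cohort)
    pch <- stats::setNames(seq_along(cohorts), cohorts)
    plot(jitter(combos$size, 0.2), combos$stability,
         pch = pch[combos$cohort],
         xlab = "candidates in combination",
         ylab = "stability value (log2 units)",
         main = "Combination stability")
    graphics::legend("topright", legend = cohorts, pch = pch, bty = "n")
    invisible(NULL)
}
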