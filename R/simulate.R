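#' Configuration of the synthetic-data generator
#'
#' Holds the generative parameters of the simulator: per-candidate baseline
#' log2 intensity, per-candidate intra-group SD of log2 intensity, a
#' per-candidate treatment-effect function `delta(dose, time_h)` in log2
#' units (0 for an ideal reference; large positive for the CYP1A1-like
#' positive control), the SD of a shared per-blot log2 shift, the target
#' Spearman correlation between log2 protein intensity and -Cq per gene,
#' the qPCR baseline and SD in cycles, and the RNG seed.  With all SDs zero
#' and all effects zero, generated intensities are exactly `2^baseline`.
#'
#' @name SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(baseline = "numeric", sigma_intra = "numeric",
                   treatment_effect = "list", blot_effect_sd = "numeric",
                   mrna_coupling = "numeric", cq_baseline = "numeric",
                   cq_sd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    nms <- names(object@baseline)
    if (is.null(nms) || anyDuplicated(nms))
        msg <- c(msg, "baseline must be uniquely named by candidate")
    for (s in c("sigma_intra", "treatment_effect", "cq_baseline", "cq_sd"))
        if (!identical(names(methods::slot(object, s)), nms))
            msg <- c(msg, paste0("'", s, "' names must match baseline"))
    if (any(object@sigma_intra < 0) || object@blot_effect_sd < 0 ||
        any(object@cq_sd < 0))
        msg <- c(msg, "config error: SDs must be >= 0")
    if (abs(object@mrna_coupling) > 1)
        msg <- c(msg, "config error: mrna_coupling must lie in [-1, 1]")
    if (!all(vapply(object@treatment_effect, is.function, logical(1))))
        msg <- c(msg, "treatment_effect must be a list of functions")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", length(object@baseline), "proteins; seed",
        object@seed, "\n")
    cat("  blot_effect_sd:", object@blot_effect_sd,
        "| mrna_coupling:", object@mrna_coupling, "\n")
    print(data.frame(baseline = object@baseline,
                     sigma_intra = object@sigma_intra))
    invisible(NULL)
})

.zeroEffect <- function(dose, time_h) rep(0, length(dose))

## Constant log2 shift for any positive dose: the simplest treatment
## response a candidate can have.
.stepEffect <- function(size) {
    force(size)
    function(dose, time_h) ifelse(dose > 0, size, 0)
}

#' Build a synthetic-data configuration
#'
#' Defaults emulate the study panel: seven loading-control candidates with
#' modest, candidate-specific intra-group noise and small (|log2| <= 0.22)
#' candidate-specific treatment shifts -- no real housekeeping protein is
#' perfectly inert to a transcriptional toxicant -- plus a CYP1A1-like
#' positive control strongly induced (+6 log2 units) by any TCDD dose.
#' ACTB is given a markedly higher baseline than the other candidates, as
#' observed on infrared scanners.  A per-blot (= per experiment) log2
#' shift models systematic run-to-run variation.
#'
#' @param baseline named numeric, log2 intensity per protein.
#' @param sigma_intra named numeric, within-group SD of log2 intensity.
#' @param treatment_effect named list of functions `f(dose, time_h)`
#'   returning a log2 shift; names must match `baseline`.
#' @param blot_effect_sd SD of the shared per-blot log2 shift.
#' @param mrna_coupling target Spearman correlation between log2 intensity
#'   and -Cq, per gene, in [-1, 1].
#' @param cq_baseline,cq_sd named numeric, qPCR mean-Cq location and SD
#'   (cycles).
#' @param seed integer RNG seed.
#' @return A [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(seed = 7L)
#' cfg
#' @export
syntheticConfig <- function(
        baseline = c(ACTB = 13.5, EEF1A1 = 9.6, GAPDH = 10.2, HPRT = 8.6,
                     PGK1 = 9.1, PPIA = 9.9, SDHA = 8.9, CYP1A1 = 7.2),
        sigma_intra = c(ACTB = 0.14, EEF1A1 = 0.17, GAPDH = 0.13,
                        HPRT = 0.10, PGK1 = 0.22, PPIA = 0.21, SDHA = 0.11,
                        CYP1A1 = 0.30),
        treatment_effect = NULL,
        blot_effect_sd = 0.25,
        mrna_coupling = 0.2,
        cq_baseline = NULL,
        cq_sd = NULL,
        seed = 1L) {
    nms <- names(baseline)
    if (is.null(treatment_effect)) {
        default_shift <- c(ACTB = 0.10, EEF1A1 = 0.22, GAPDH = 0.10,
                           HPRT = 0.04, PGK1 = 0.16, PPIA = 0.16,
                           SDHA = 0.20, CYP1A1 = 6)
        treatment_effect <- stats::setNames(lapply(nms, function(i)
            if (i %in% names(default_shift))
                .stepEffect(default_shift[[i]]) else .zeroEffect), nms)
    }
    if (is.null(cq_baseline))
        cq_baseline <- stats::setNames(
            rep(22, length(nms)) - (baseline - mean(baseline)) / 2, nms)
    if (is.null(cq_sd))
        cq_sd <- stats::setNames(rep(0.5, length(nms)), nms)
    new("SyntheticConfig", baseline = baseline,
        sigma_intra = sigma_intra[nms],
        treatment_effect = treatment_effect[nms],
        blot_effect_sd = blot_effect_sd, mrna_coupling = mrna_coupling,
        cq_baseline = cq_baseline[nms], cq_sd = cq_sd[nms],
        seed = as.integer(seed))
}

## Deterministic 31-bit stream key from (seed, string): every blot and every
## animal owns its own substream, so subsetting the design never shifts the
## draws of the remaining units.
.streamSeed <- function(seed, key) {
    h <- as.double(seed %% 2147483647L)
    for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
    as.integer(h)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulate an abundance + Cq dataset over a design
#'
#' For animal j on blot b and protein i, the generator draws
#' `log2(intensity) = baseline_i + delta_i(dose_j, time_j) + blot_b +
#' eps_ij`, with `blot_b ~ N(0, blot_effect_sd^2)` and
#' `eps_ij ~ N(0, sigma_intra_i^2)`; intensities are `2^` that value
#' (log-additive noise, i.e. multiplicative on the intensity scale).  Mean
#' Cq values carry the same treatment effect (one cycle per log2 unit,
#' sign inverted since lower Cq = more mRNA) and noise generated by a
#' Gaussian copula against the protein noise, so that for an unresponsive
#' gene the Spearman correlation between log2 intensity and -Cq
#' approximates `mrna_coupling`.  All draws come from per-blot / per-animal substreams
#' keyed on the seed, so the output is bit-reproducible and stable under
#' design subsetting.
#'
#' @param config A [SyntheticConfig-class].
#' @param design `data.frame` of animals, as from [designFixture()].
#' @return list with elements `abundance` (an
#'   [AbundanceExperiment-class]), `cq` (long `data.frame`:
#'   `animal_id`, `gene`, `mean_cq`) and `truth` (the planted stability
#'   order, see [trueStabilityOrder()]).
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 42L))
#' sim$abundance
#' @export
simulateDataset <- function(config, design = designFixture()) {
    validObject(config)
    if (!nrow(design)) stop("empty design")
    nms <- names(config@baseline)
    K <- length(nms)
    seed <- config@seed
    blots <- sort(unique(design$blot_id))
    blot_shift <- vapply(blots, function(b)
        .withSeed(.streamSeed(seed, paste0("blot:", b)),
                  stats::rnorm(1, 0, config@blot_effect_sd)),
        numeric(1))
    delta <- vapply(nms, function(i)
        config@treatment_effect[[i]](design$dose, design$time_h),
        numeric(nrow(design)))
    if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1L,
                                             dimnames = list(NULL, nms))
    draws <- vapply(design$animal_id, function(id)
        .withSeed(.streamSeed(seed, paste0("animal:", id)),
                  stats::rnorm(2L * K)),
        numeric(2L * K))
    eps <- draws[seq_len(K), , drop = FALSE]
    w <- draws[K + seq_len(K), , drop = FALSE]
    log2int <- config@baseline + config@sigma_intra * eps +
        t(delta) + rep(blot_shift[design$blot_id], each = K)
    dimnames(log2int) <- list(nms, design$animal_id)
    ## Gaussian copula: Pearson r on latent normals giving Spearman
    ## `mrna_coupling` for a bivariate normal pair.
    r <- 2 * sin(pi * config@mrna_coupling / 6)
    sd_tot <- sqrt(config@sigma_intra^2 + config@blot_effect_sd^2)
    znoise <- log2int - config@baseline - t(delta)
    z <- ifelse(sd_tot > 0, 1 / sd_tot, 0) * znoise
    ## Treatment effects transfer to the qPCR side one-to-one (one cycle
    ## per log2 unit, sign inverted); noise coupling is the copula's job.
    cq <- config@cq_baseline - t(delta) -
        config@cq_sd * (r * z + sqrt(1 - r^2) * w)
    ae <- AbundanceExperiment(2^log2int, design)
    cq_df <- data.frame(animal_id = rep(design$animal_id, each = K),
                        gene = rep(nms, nrow(design)),
                        mean_cq = as.vector(cq))
    list(abundance = ae, cq = cq_df,
         truth = trueStabilityOrder(config, design))
}

#' Planted stability order of a synthetic configuration
#'
#' Ranks proteins by their total planted variation over a design: the
#' intra-group variance `sigma_intra^2` plus the between-group variance of
#' the treatment effect `delta(dose, time_h)` across the design's distinct
#' experimental groups (unweighted).  Lower total variation = more stable;
#' ties share a rank.
#'
#' @inheritParams simulateDataset
#' @return `data.frame` (ascending total variation) with columns
#'   `protein`, `sigma2_intra`, `var_between`, `total_variation`, `rank`.
#' @export
trueStabilityOrder <- function(config, design = designFixture()) {
    validObject(config)
    grp <- unique(design[c("dose", "time_h", "experiment", "strain",
                           "sex", "genotype")])
    nms <- names(config@baseline)
    var_b <- vapply(nms, function(i) {
        d <- config@treatment_effect[[i]](grp$dose, grp$time_h)
        mean((d - mean(d))^2)
    }, numeric(1))
    total <- config@sigma_intra^2 + var_b
    out <- data.frame(protein = nms,
                      sigma2_intra = unname(config@sigma_intra^2),
                      var_between = unname(var_b),
                      total_variation = unname(total),
                      rank = unname(rank(total, ties.method = "min")))
    out <- out[order(out$total_variation, out$protein), ]
    rownames(out) <- NULL
    out
}
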