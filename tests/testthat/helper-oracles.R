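## Independent oracles and small fixture builders used across the suite.

## Textbook Welch t-test (Welch-Satterthwaite df), written from the
## formulas, independent of stats::t.test.
welchOracle <- function(a, b) {
    v1 <- stats::var(a) / length(a)
    v2 <- stats::var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
        (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## All permutations of 1..n as a matrix (n! rows).
permEnum <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- permEnum(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[as.vector(sub)], nrow(sub)))
    }))
}

## Exact two-sided permutation p-value for Spearman's rho by full
## enumeration (feasible to n = 8).
spearmanPermP <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    obs <- stats::cor(rx, ry)
    P <- permEnum(length(x))
    rhos <- apply(P, 1L, function(p) stats::cor(rx[p], ry))
    mean(abs(rhos) >= abs(obs) - 1e-12)
}

## Tiny AbundanceExperiment: one experiment, groups defined by dose.
toyAE <- function(intensity, dose, experiment = 1L, time_h = 6,
                  excluded = NULL) {
    if (is.null(colnames(intensity)))
        colnames(intensity) <- sprintf("a%02d", seq_len(ncol(intensity)))
    animals <- data.frame(
        animal_id = colnames(intensity), experiment = experiment,
        strain = "C57BL/6", sex = "M", genotype = "WT", dose = dose,
        time_h = time_h, blot_id = paste0("blot_", experiment))
    AbundanceExperiment(intensity, animals, excluded = excluded,
                        role = rep("candidate", nrow(intensity)))
}

## Synthetic configuration with a planted, recoverable stability order:
## intra-group SDs double in variance at each step and treated-shift
## deviations from the panel mean grow in magnitude with the same order
## (a zero-sum deviation pattern, so the inter-group component of the
## stability model sees the same ranking).
recoveryConfig <- function(seed, s = 0.03) {
    nm <- paste0("N", 1:7)
    sig <- stats::setNames(0.05 * 2^((0:6) / 2), nm)
    dev <- s * c(-1, -2, -3, -4, -5, -6, 21)
    eff <- stats::setNames(lapply(dev, function(d0) {
        force(d0)
        function(dose, time_h) ifelse(dose > 0, d0, 0)
    }), nm)
    syntheticConfig(baseline = stats::setNames(rep(10, 7), nm),
                    sigma_intra = sig, treatment_effect = eff,
                    blot_effect_sd = 0.25,
                    cq_baseline = stats::setNames(rep(22, 7), nm),
                    cq_sd = stats::setNames(rep(0.5, 7), nm),
                    seed = seed)
}

## Configuration with every SD and effect at zero: intensities must be
## exactly 2^baseline.
zeroNoiseConfig <- function(seed = 1L) {
    nm <- c("ACTB", "EEF1A1", "GAPDH", "HPRT", "PGK1", "PPIA", "SDHA",
            "CYP1A1")
    zero <- stats::setNames(rep(0, length(nm)), nm)
    eff <- stats::setNames(rep(list(function(dose, time_h)
        rep(0, length(dose))), length(nm)), nm)
    syntheticConfig(sigma_intra = zero, treatment_effect = eff,
                    blot_effect_sd = 0, mrna_coupling = 0,
                    cq_sd = zero, seed = seed)
}

## Path to a user-supplied export of the study's supplementary data
## (per-animal abundances / Cq); empty string when not installed.
studyPath <- function(f)
    system.file("extdata", "study", f, package = "refstab")
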