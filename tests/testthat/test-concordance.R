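test_that("rank correlation handles monotone, antitone and degenerate inputs", {
    x <- c(1.2, 3.4, 5.6, 7.8, 9.1, 11.3)
    expect_equal(spearmanAS89(x, exp(x))$rho, 1)
    expect_equal(spearmanAS89(x, -x^3)$rho, -1)
    expect_true(is.na(spearmanAS89(x, rep(2, 6))$rho))
    expect_error(spearmanAS89(1:5, 1:4), "length mismatch")
    expect_error(spearmanAS89(1:3, 3:1), ">= 4")

    ## invariance under strictly monotone transforms of either input
    set.seed(5)
    a <- rnorm(12)
    b <- rnorm(12)
    base <- spearmanAS89(a, b)
    expect_equal(spearmanAS89(exp(a), b)$rho, base$rho)
    expect_equal(spearmanAS89(a, 3 * b - 100)$p, base$p)
})

test_that("AS89 p-values match exact permutation enumeration at n = 8", {
    set.seed(88)
    for (i in 1:3) {
        x <- rnorm(8)
        y <- rnorm(8)
        got <- spearmanAS89(x, y)
        expect_equal(got$p, spearmanPermP(x, y), tolerance = 0.005)
    }
})

test_that("protein-mRNA concordance recovers the planted copula coupling", {
    nm <- paste0("G", 1:4)
    zeroeff <- stats::setNames(rep(list(function(dose, time_h)
        rep(0, length(dose))), 4), nm)
    ## no blot component: the copula construction is exact for i.i.d.
    ## pairs; a shared per-blot shift (10 distinct values) widens the
    ## seed-to-seed spread of the realized rank coupling
    cfg <- syntheticConfig(baseline = stats::setNames(rep(10, 4), nm),
                           sigma_intra = stats::setNames(rep(0.2, 4), nm),
                           treatment_effect = zeroeff,
                           blot_effect_sd = 0, mrna_coupling = 0.9,
                           cq_baseline = stats::setNames(rep(22, 4), nm),
                           cq_sd = stats::setNames(rep(0.5, 4), nm),
                           seed = 9L)
    sim <- simulateDataset(cfg)
    conc <- proteinMrnaConcordance(sim$abundance, sim$cq,
                                   genes = nm, abundance_scale = TRUE)
    expect_equal(conc$n, rep(192L, 4))
    expect_true(all(abs(conc$rho - 0.9) <= 0.05))

    ## flipping the Cq axis flips the sign exactly
    conc_cq <- proteinMrnaConcordance(sim$abundance, sim$cq, genes = nm)
    expect_equal(conc_cq$rho, -conc$rho, tolerance = 1e-12)
    expect_equal(conc_cq$p, conc$p, tolerance = 1e-12)
})

test_that("a constant Cq vector yields an undefined correlation marker", {
    sim <- simulateDataset(syntheticConfig(seed = 2L))
    cq <- sim$cq
    cq$mean_cq[cq$gene == "HPRT"] <- 20
    conc <- proteinMrnaConcordance(sim$abundance, cq, genes = "HPRT")
    expect_true(is.na(conc$rho))
})

test_that("stability-vector concordance matches keys and detects identity", {
    sim <- simulateDataset(syntheticConfig(seed = 2L))
    combos <- enumerateCombinationStability(sim$abundance, "overall")
    self <- stabilityScoreConcordance(combos, combos)
    expect_equal(self$rho, 1)
    expect_equal(self$n, 127L)
    other <- combos
    other$combination <- paste0("x_", other$combination)
    expect_error(stabilityScoreConcordance(combos, other),
                 "overlapping combination keys")

    ## independent score vectors are uncorrelated on average
    set.seed(33)
    rhos <- replicate(300, {
        a <- data.frame(combination = as.character(1:40),
                        stability = rnorm(40))
        b <- data.frame(combination = as.character(1:40),
                        stability = rnorm(40))
        stabilityScoreConcordance(a, b)$rho
    })
    expect_lt(abs(mean(rhos)), 0.02)
})

test_that("mRNA combination stability runs the shared code path on -Cq", {
    sim <- simulateDataset(syntheticConfig(seed = 2L))
    cqc <- cqCombinationStability(sim$abundance, sim$cq)
    expect_equal(nrow(cqc), 127L)
    expect_true(all(cqc$stability >= 0))
    ## protein and mRNA stability vectors are positively concordant when
    ## the treatment structure transfers across platforms
    sc <- stabilityScoreConcordance(
        enumerateCombinationStability(sim$abundance, "overall"), cqc)
    expect_gt(sc$rho, 0.2)
})
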