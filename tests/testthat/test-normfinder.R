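test_that("log2 matrix construction masks exclusions and shifts under scaling", {
    Y <- matrix(c(1024, 4, 8, 2, 16, 32), 3, 2,
                dimnames = list(c("A", "B", "C"), c("a1", "a2")))
    excl <- matrix(FALSE, 3, 2, dimnames = dimnames(Y))
    excl["B", 1L] <- TRUE
    ae <- toyAE(Y, dose = c(0, 500), excluded = excl)
    L <- log2Matrix(ae, c("A", "B", "C"))
    expect_equal(L["A", "a1"], 10)
    expect_true(is.na(L["B", "a1"]))

    sim <- simulateDataset(syntheticConfig(seed = 6L))
    ae1 <- sim$abundance
    ae2 <- AbundanceExperiment(2 * intensities(ae1), animalInfo(ae1))
    expect_equal(log2Matrix(ae2), log2Matrix(ae1) + 1, tolerance = 1e-12)
    expect_equal(stabilityScores(ae2), stabilityScores(ae1),
                 tolerance = 1e-12)
})

test_that("duplicated candidates receive identical stability values", {
    set.seed(31)
    n <- 24L
    Y <- rbind(A = rnorm(n, 10, 0.2), C = rnorm(n, 8, 0.4))
    Y <- rbind(Y, B = Y["A", ])
    groups <- rep(c("ctl", "trt"), each = n / 2)
    rho <- stabilityValues(decomposeVariance(Y, groups))
    expect_equal(rho[["A"]], rho[["B"]], tolerance = 1e-12)
})

test_that("intra-group variance estimates agree with the two-way ANOVA oracle", {
    set.seed(77)
    n <- 5L
    for (rep_i in 1:3) {
        Y1 <- matrix(rnorm(n * 10, 10, 1), n, 10)
        Y2 <- matrix(rnorm(n * 12, 10, 1), n, 12)
        Y <- cbind(Y1, Y2)
        rownames(Y) <- paste0("g", seq_len(n))
        colnames(Y) <- paste0("a", seq_len(ncol(Y)))
        groups <- rep(c("A", "B"), c(10L, 12L))
        nf <- decomposeVariance(Y, groups)
        for (k in 1:2) {
            Yg <- Y[, groups == c("A", "B")[k]]
            long <- data.frame(y = as.vector(Yg),
                               gene = factor(rep(rownames(Yg), ncol(Yg))),
                               animal = factor(rep(colnames(Yg),
                                                   each = n)))
            fit <- stats::aov(y ~ gene + animal, data = long)
            ms_resid <- summary(fit)[[1L]]["Residuals", "Mean Sq"]
            ## the candidate-average of the corrected variance estimates
            ## equals the classical residual mean square exactly
            expect_equal(mean(nf@sigma2[, k]), ms_resid,
                         tolerance = 1e-9)
        }
    }
})

test_that("stability model structural invariants hold", {
    sim <- simulateDataset(syntheticConfig(seed = 12L))
    ae <- sim$abundance
    Y <- log2Matrix(ae)
    groups <- animalInfo(ae)$treated
    nf <- decomposeVariance(Y, groups)
    ## inter-group differences sum to zero over the candidate set
    expect_equal(colSums(nf@d), c("FALSE" = 0, "TRUE" = 0),
                 tolerance = 1e-10)
    expect_true(all(nf@sigma2 >= 0))
    expect_true(all(stabilityValues(nf) >= 0))
    expect_true(all(abs(nf@d_tilde) <= abs(nf@d) + 1e-12))

    ## rescaling one blot (one experiment's animals) changes nothing
    ints <- intensities(ae)
    anim <- animalInfo(ae)
    ints[, anim$experiment == 6L] <- ints[, anim$experiment == 6L] * 3.7
    ae_blot <- AbundanceExperiment(ints, anim)
    expect_equal(stabilityScores(ae_blot, "training"),
                 stabilityScores(ae, "training"), tolerance = 1e-10)
    ## global rescaling changes nothing either
    ae_glob <- AbundanceExperiment(intensities(ae) * 0.01, anim)
    expect_equal(stabilityScores(ae_glob), stabilityScores(ae),
                 tolerance = 1e-10)

    expect_error(decomposeVariance(Y[1:2, ], groups),
                 "insufficient-candidates")
    expect_error(decomposeVariance(Y, rep("one", ncol(Y))),
                 "insufficient-replication")
})

test_that("raising a candidate's planted noise never lowers its expected score", {
    ## small balanced two-group design with a planted inter-group pattern,
    ## direct matrix simulation for speed
    gen <- function(seed, sig1) {
        set.seed(seed)
        sig <- c(sig1, 0.15, 0.2, 0.25, 0.3)
        d <- c(0.05, -0.1, 0.15, -0.05, -0.05)
        n_g <- 12L
        Y <- vapply(seq_len(2L * n_g), function(j)
            10 + (if (j > n_g) d else 0) + rnorm(5, 0, sig),
            numeric(5))
        rownames(Y) <- paste0("g", 1:5)
        stabilityValues(decomposeVariance(Y, rep(1:2, each = n_g)))[["g1"]]
    }
    lo <- mean(vapply(1:200, gen, numeric(1), sig1 = 0.10))
    hi <- mean(vapply(1:200, gen, numeric(1), sig1 = 0.30))
    expect_gt(hi, lo)
})

test_that("combination pseudo-candidates follow the geometric mean", {
    Y <- matrix(log2(c(4, 16, 2, 8, 32, 64)), 3, 2, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("a1", "a2")))
    expect_equal(combinationPseudocandidate(Y, "A"), Y["A", ])
    expect_equal(combinationPseudocandidate(Y, c("A", "B"))[["a1"]],
                 log2(sqrt(4 * 2)))
    expect_equal(combinationPseudocandidate(Y, c("A", "B", "C")),
                 colMeans(Y))
    expect_error(combinationPseudocandidate(Y, character()), "non-empty")
    expect_error(combinationPseudocandidate(Y, "Z"), "unknown")
})

test_that("combination enumeration is complete, consistent and minimized by the full set", {
    sim <- simulateDataset(syntheticConfig(seed = 2L))
    singles <- list(training = stabilityScores(sim$abundance, "training"),
                    validation = stabilityScores(sim$abundance,
                                                 "validation"))
    for (ch in c("training", "validation")) {
        combos <- enumerateCombinationStability(sim$abundance, ch)
        expect_equal(nrow(combos), 127L)
        expect_equal(anyDuplicated(combos$combination), 0L)
        ## singleton scores equal the single-candidate scores exactly
        sg <- combos[combos$size == 1L, ]
        expect_equal(sg$stability[match(names(singles[[ch]]),
                                        sg$combination)],
                     unname(singles[[ch]]), tolerance = 1e-12)
        ## the all-7 combination attains the minimum
        expect_equal(combos$combination[which.min(combos$stability)],
                     paste(sort(candidateNames(sim$abundance)),
                           collapse = "+"))
    }
})

test_that("expected combination score decreases with subset size for null candidates", {
    one <- function(seed) {
        set.seed(seed)
        n_g <- 10L
        Y <- matrix(rnorm(5 * 2 * n_g, 10, 0.2), 5, 2 * n_g)
        rownames(Y) <- paste0("g", 1:5)
        colnames(Y) <- paste0("a", seq_len(2L * n_g))
        co <- combinationStabilityMatrix(Y, rep(1:2, each = n_g))
        tapply(co$stability, co$size, mean)
    }
    avg <- Reduce(`+`, lapply(1:150, one)) / 150
    expect_true(all(diff(avg) < 0))
})
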