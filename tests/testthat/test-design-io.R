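test_that("design fixture reproduces the study's animal and group structure", {
    d <- designFixture()
    expect_equal(nrow(d), 192L)
    grp <- unique(d[, c("experiment", "strain", "sex", "genotype",
                        "dose", "time_h")])
    expect_equal(nrow(grp), 47L)
    e9 <- d[d$experiment == 9L, ]
    expect_equal(as.vector(table(e9$dose)[as.character(c(0, 125, 250,
                                                         500, 1000))]),
                 c(5L, 3L, 1L, 4L, 3L))
    expect_equal(length(unique(d$blot_id)), 10L)
    one_blot <- tapply(d$blot_id, d$experiment,
                       function(b) length(unique(b)))
    expect_true(all(one_blot == 1L))
    expect_equal(anyDuplicated(d$animal_id), 0L)
    expect_identical(d$treated, d$dose > 0)
})

test_that("cohort assignment is a partition of the ten experiments", {
    expect_equal(assignCohort(1L), "training")
    expect_equal(assignCohort(10L), "validation")
    ch <- assignCohort(1:10)
    expect_setequal(which(ch == "training"), c(1L, 4L, 6L, 8L, 9L))
    expect_setequal(which(ch == "validation"), c(2L, 3L, 5L, 7L, 10L))
    expect_true(all(ch %in% c("training", "validation")))
    expect_error(assignCohort(11L), "1..10", fixed = TRUE)
    expect_error(assignCohort(0L), "1..10", fixed = TRUE)
})

test_that("condition construction pairs treated groups with their controls", {
    cond <- buildConditions(designFixture())
    expect_equal(nrow(cond), 32L)
    expect_equal(sum(cond$testable), 31L)
    un <- cond[!cond$testable, ]
    expect_equal(un$experiment, 9L)
    expect_equal(un$dose, 250)
    expect_equal(un$n_treated, 1L)
    ## deterministic sort order
    expect_true(!is.unsorted(cond$experiment))

    d <- designFixture()
    d1 <- d[d$experiment == 1L & d$sex == "M", ]
    expect_equal(nrow(buildConditions(d1)), 1L)
    expect_warning(c2 <- buildConditions(d1[d1$dose > 0, ]),
                   "no matching control")
    expect_equal(nrow(c2), 0L)
})

test_that("abundance tables round-trip through the long text format", {
    sim <- simulateDataset(syntheticConfig(seed = 5L))
    df <- asLongTable(sim$abundance)
    expect_equal(nrow(df), 8L * 192L)
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path))
    writeResults(list(abundances = df), dirname(path))
    ab_path <- file.path(dirname(path), "abundances.tsv")
    ae2 <- readAbundanceTable(ab_path)
    expect_equal(dim(ae2), dim(sim$abundance))
    expect_equal(maskedIntensities(ae2)[rownames(sim$abundance),
                                        colnames(sim$abundance)],
                 maskedIntensities(sim$abundance), tolerance = 1e-11)
    unlink(ab_path)
})

test_that("reader rejects malformed tables with named errors", {
    sim <- simulateDataset(syntheticConfig(seed = 5L))
    df <- asLongTable(sim$abundance)
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path))

    utils::write.table(df[, setdiff(colnames(df), "candidate")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readAbundanceTable(path), "candidate")

    expect_error(longToExperiment(rbind(df, df[1L, ])), "duplication")

    bad <- df
    bad$intensity[3L] <- -5
    expect_error(longToExperiment(bad), "non-positive")
    bad$excluded[3L] <- TRUE  # flagged rows may carry any intensity
    expect_s4_class(longToExperiment(bad), "AbundanceExperiment")
})

test_that("writer produces header-only files for empty tables and exact round-trips", {
    dir <- tempfile()
    on.exit(unlink(dir, recursive = TRUE))
    empty <- data.frame(a = integer(), b = numeric())
    two <- data.frame(a = 1:2, b = c(pi, exp(1)))
    writeResults(list(empty = empty, two = two), dir)
    re <- utils::read.table(file.path(dir, "empty.tsv"), header = TRUE,
                            sep = "\t")
    expect_equal(nrow(re), 0L)
    expect_equal(colnames(re), c("a", "b"))
    rt <- utils::read.table(file.path(dir, "two.tsv"), header = TRUE,
                            sep = "\t")
    expect_identical(rt$a, two$a)
    expect_equal(rt$b, two$b, tolerance = 1e-11)
})

test_that("background subtraction enforces positivity", {
    expect_equal(backgroundSubtract(1000, 200), 800)
    expect_true(is.na(backgroundSubtract(200, 200)))
    x <- c(3.5, 120, 9e4)
    expect_equal(backgroundSubtract(x, 0), x)
    expect_error(backgroundSubtract(-1, 0), ">= 0")
    expect_error(backgroundSubtract(1, Inf), "finite")
})

test_that("excluded wells never influence downstream statistics", {
    sim <- simulateDataset(syntheticConfig(seed = 8L))
    ae <- sim$abundance
    excl <- exclusionMask(ae)
    set.seed(42)
    excl[sample(length(excl), 25L)] <- TRUE
    ae_flag <- AbundanceExperiment(intensities(ae), animalInfo(ae),
                                   excluded = excl)
    df <- asLongTable(ae_flag)
    ae_del <- longToExperiment(df[!df$excluded, ])
    expect_equal(suppressMessages(stabilityScores(ae_flag)),
                 suppressMessages(stabilityScores(ae_del)))
    cc_flag <- conditionComparisons(ae_flag, proteins = "GAPDH")
    cc_del <- conditionComparisons(ae_del, proteins = "GAPDH")
    expect_equal(cc_flag$p, cc_del$p)
    expect_equal(cc_flag$n_treated, cc_del$n_treated)
    cs_flag <- comparativeStability(ae_flag)$scores
    cs_del <- comparativeStability(ae_del)$scores
    expect_equal(cs_flag, cs_del)
})

test_that("experiment constructor validates treatment flags and intensities", {
    Y <- matrix(c(4, 8, 2, 16, 3, 5), 3, 2,
                dimnames = list(c("A", "B", "C"), c("a1", "a2")))
    ae <- toyAE(Y, dose = c(0, 500))
    expect_identical(animalInfo(ae)$treated, c(FALSE, TRUE))
    Yb <- Y
    Yb[1L, 1L] <- -2
    expect_error(toyAE(Yb, dose = c(0, 500)), "finite and > 0")
})
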