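#' The encoded study design: 192 mice in 47 experimental groups
#'
#' Returns the full factorial layout of the underlying TCDD study: ten
#' experiments varying mouse strain, sex, Ahr genotype, TCDD dose (ug/kg by
#' oral gavage) and tissue-harvest time (hours), with the published group
#' sizes.  Experiments 1-5 are the timecourse arm (0 vs 500 ug/kg at 6, 24,
#' 72 and 144 h; experiment 2 adds 5 ug/kg at 19 h in two genetic models);
#' experiments 6-10 are the dose-response arm (0, 125, 250, 500, 1000 ug/kg
#' at 96 h).  Animal ids are synthetic but stable; each experiment was run
#' on a single western blot, so `blot_id` is one per experiment.
#'
#' @return `data.frame` with one row per animal and columns `animal_id`,
#'   `experiment`, `strain`, `sex`, `genotype`, `dose`, `time_h`,
#'   `blot_id`, `treated`.
#' @examples
#' d <- designFixture()
#' nrow(d)                                   # 192 animals
#' nrow(unique(d[, c("experiment", "strain", "sex",
#'                   "genotype", "dose", "time_h")]))  # 47 groups
#' @export
designFixture <- function() {
    row <- function(experiment, strain, sex, genotype, doses, time_h, n)
        data.frame(experiment = experiment, strain = strain, sex = sex,
                   genotype = genotype, dose = doses, time_h = time_h,
                   n = n)
    layout <- rbind(
        row(1L,  "C57BL/6", "M", "WT",        c(0, 500),                 6,   c(4, 5)),
        row(1L,  "C57BL/6", "F", "WT",        c(0, 500),                 6,   c(4, 5)),
        row(2L,  "C57BL/6", "M", "rWT",       c(0, 5, 500),              19,  c(4, 4, 4)),
        row(2L,  "DBA/2J",  "M", "Ala375Val", c(0, 5, 500),              19,  c(4, 4, 4)),
        row(3L,  "C57BL/6", "M", "WT",        c(0, 500),                 24,  c(4, 5)),
        row(3L,  "C57BL/6", "F", "WT",        c(0, 500),                 24,  c(3, 5)),
        row(4L,  "C57BL/6", "M", "WT",        c(0, 500),                 72,  c(4, 5)),
        row(4L,  "C57BL/6", "F", "WT",        c(0, 500),                 72,  c(4, 5)),
        row(5L,  "C57BL/6", "M", "WT",        c(0, 500),                 144, c(3, 4)),
        row(5L,  "C57BL/6", "F", "WT",        c(0, 500),                 144, c(3, 5)),
        row(6L,  "C57BL/6", "M", "WT",        c(0, 125, 250, 500, 1000), 96,  c(4, 4, 4, 4, 4)),
        row(7L,  "C57BL/6", "M", "DEL",       c(0, 125, 250, 500, 1000), 96,  c(5, 4, 3, 3, 4)),
        row(8L,  "C57BL/6", "M", "INS",       c(0, 125, 250, 500, 1000), 96,  c(5, 4, 4, 4, 5)),
        row(9L,  "C57BL/6", "M", "rWT",       c(0, 125, 250, 500, 1000), 96,  c(5, 3, 1, 4, 3)),
        row(10L, "C57BL/6", "F", "WT",        c(0, 125, 250, 500, 1000), 96,  c(5, 5, 4, 4, 5)))
    design <- layout[rep(seq_len(nrow(layout)), layout$n), ]
    design$n <- NULL
    idx <- stats::ave(seq_len(nrow(design)),
                      design$experiment, design$strain, design$sex,
                      design$genotype, design$dose, design$time_h,
                      FUN = seq_along)
    design$animal_id <- sprintf("E%02d_%s_%s_%s_d%04d_a%d",
                                design$experiment,
                                sub("/", "", design$strain), design$sex,
                                design$genotype, design$dose, idx)
    design$blot_id <- sprintf("blot_%02d", design$experiment)
    design$treated <- design$dose > 0
    rownames(design) <- NULL
    design[, .ANIMAL_COLS]
}

#' Assign experiments to training/validation cohorts
#'
#' The study's ten experiments are split into two cohorts with similar
#' composition: experiments 1, 4, 6, 8 and 9 form the training cohort and
#' 2, 3, 5, 7 and 10 the validation cohort.  The split is a partition:
#' every experiment belongs to exactly one cohort.
#'
#' @param experiment integer vector of experiment numbers in 1..10.
#' @return character vector, `"training"` or `"validation"`.
#' @examples
#' assignCohort(c(1L, 10L))
#' @export
assignCohort <- function(experiment) {
    experiment <- as.integer(experiment)
    if (any(is.na(experiment)) || any(experiment < 1L | experiment > 10L))
        stop("experiment must be an integer in 1..10")
    ifelse(experiment %in% c(1L, 4L, 6L, 8L, 9L), "training", "validation")
}

.groupKeyCols <- c("experiment", "strain", "sex", "genotype", "dose", "time_h")

.groupKey <- function(df)
    do.call(paste, c(df[.groupKeyCols], list(sep = "|")))

#' Enumerate treated-versus-control comparison conditions
#'
#' Each distinct treated group (dose > 0) is paired with the control
#' (dose = 0) group of the same experiment, strain, sex, genotype and
#' harvest time.  Treated groups with no matching control are dropped with a
#' warning.  A comparison is flagged `testable` when both groups contain at
#' least two animals; groups of one (the study design contains one such
#' group) admit a fold-difference but no t-test.
#'
#' @param x An [AbundanceExperiment-class] or a design `data.frame` as
#'   returned by [designFixture()].
#' @return `data.frame` sorted by (experiment, dose, time_h, strain, sex,
#'   genotype) with the condition key columns plus `n_treated`,
#'   `n_control`, `testable`.
#' @examples
#' cond <- buildConditions(designFixture())
#' nrow(cond)           # 32 treated groups
#' sum(cond$testable)   # 31 with >= 2 animals on both sides
#' @export
buildConditions <- function(x) {
    anim <- if (is(x, "AbundanceExperiment")) animalInfo(x)
            else as.data.frame(x)
    if (!nrow(anim)) stop("empty dataset")
    grp <- unique(anim[.groupKeyCols])
    counts <- table(.groupKey(anim))
    grp$n <- as.integer(counts[.groupKey(grp)])
    treated <- grp[grp$dose > 0, , drop = FALSE]
    control <- grp[grp$dose == 0, , drop = FALSE]
    ctrl_key <- do.call(paste, c(control[c("experiment", "strain", "sex",
                                           "genotype", "time_h")],
                                 list(sep = "|")))
    trt_key <- do.call(paste, c(treated[c("experiment", "strain", "sex",
                                          "genotype", "time_h")],
                                list(sep = "|")))
    m <- match(trt_key, ctrl_key)
    if (anyNA(m)) {
        orphan <- treated[is.na(m), , drop = FALSE]
        warning(sprintf(
            "%d treated group(s) have no matching control and were dropped",
            nrow(orphan)))
        treated <- treated[!is.na(m), , drop = FALSE]
        m <- m[!is.na(m)]
    }
    out <- treated
    names(out)[names(out) == "n"] <- "n_treated"
    out$n_control <- control$n[m]
    out$testable <- out$n_treated >= 2L & out$n_control >= 2L
    ord <- order(out$experiment, out$dose, out$time_h, out$strain,
                 out$sex, out$genotype)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}
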