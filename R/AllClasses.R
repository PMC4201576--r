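#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Candidate panel of the study configuration: 7 loading-control candidates
## plus one TCDD-inducible positive control.
.CANDIDATES <- c("ACTB", "EEF1A1", "GAPDH", "HPRT", "PGK1", "PPIA", "SDHA")
.POSITIVE_CONTROL <- "CYP1A1"

.ANIMAL_COLS <- c("animal_id", "experiment", "strain", "sex", "genotype",
                  "dose", "time_h", "blot_id", "treated")

#' Container for background-normalized western-blot intensities
#'
#' `AbundanceExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `intensity`, the background-normalized band intensity (arbitrary
#' fluorescence units, candidates in rows, animals in columns; `NA` where a
#' band was not measured), and `excluded`, a logical mask marking wells with
#' unsatisfactory loading patterns.  Excluded records are retained for
#' provenance but never enter any downstream statistic.  `colData` carries
#' the animal metadata (experiment, strain, sex, genotype, TCDD dose in
#' ug/kg, harvest time in hours, blot id, treatment flag); `rowData` carries
#' the candidate role (`candidate` or `positive_control`).
#'
#' @name AbundanceExperiment-class
#' @aliases AbundanceExperiment-class
#' @exportClass AbundanceExperiment
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
    msg <- character()
    if (!all(c("intensity", "excluded") %in% assayNames(object)))
        msg <- c(msg, "assays 'intensity' and 'excluded' are required")
    else {
        ints <- assay(object, "intensity")
        excl <- assay(object, "excluded")
        if (!is.logical(excl))
            msg <- c(msg, "'excluded' assay must be logical")
        else {
            keep <- !excl & !is.na(ints)
            if (any(!is.finite(ints[keep]) | ints[keep] <= 0))
                msg <- c(msg,
                    "non-excluded intensities must be finite and > 0")
        }
    }
    cd <- colData(object)
    missing_cols <- setdiff(.ANIMAL_COLS, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing_cols, collapse = ", ")))
    else {
        if (any(cd$dose < 0)) msg <- c(msg, "dose must be >= 0")
        if (!identical(as.logical(cd$treated), cd$dose > 0))
            msg <- c(msg, "'treated' must equal dose > 0")
        if (anyDuplicated(cd$animal_id))
            msg <- c(msg, "duplicated animal_id in colData")
    }
    if (!"role" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData lacks column 'role'")
    else if (!all(rowData(object)$role %in% c("candidate", "positive_control")))
        msg <- c(msg, "role must be 'candidate' or 'positive_control'")
    if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param intensity numeric matrix, candidates x animals; `NA` = unmeasured.
#' @param animals `data.frame` or `DataFrame` of animal metadata with columns
#'   `animal_id`, `experiment`, `strain`, `sex`, `genotype`, `dose`,
#'   `time_h`, `blot_id` (and optionally `treated`, recomputed as
#'   `dose > 0`).  One row per column of `intensity`, matched by
#'   `animal_id` against `colnames(intensity)`.
#' @param excluded logical matrix, same dimensions as `intensity`; wells to
#'   drop from all statistics.  Default: none.
#' @param role character vector per row of `intensity`, `"candidate"` or
#'   `"positive_control"`.  Default: `"CYP1A1"` is the positive control,
#'   everything else a candidate.
#' @return An [AbundanceExperiment-class] object.
#' @examples
#' sim <- simulateDataset(syntheticConfig(seed = 1L))
#' ae <- sim$abundance
#' ae
#' @export
AbundanceExperiment <- function(intensity, animals, excluded = NULL,
                                role = NULL) {
    if (is.null(colnames(intensity)))
        stop("'intensity' must have animal ids as colnames")
    if (is.null(rownames(intensity)))
        stop("'intensity' must have candidate ids as rownames")
    animals <- as.data.frame(animals)
    if (!all(colnames(intensity) %in% animals$animal_id))
        stop("every intensity column needs a matching animals row")
    animals <- animals[match(colnames(intensity), animals$animal_id), ,
                       drop = FALSE]
    animals$experiment <- as.integer(animals$experiment)
    animals$dose <- as.numeric(animals$dose)
    animals$time_h <- as.numeric(animals$time_h)
    animals$treated <- animals$dose > 0
    rownames(animals) <- animals$animal_id
    if (is.null(excluded))
        excluded <- matrix(FALSE, nrow(intensity), ncol(intensity),
                           dimnames = dimnames(intensity))
    if (is.null(role))
        role <- ifelse(rownames(intensity) == .POSITIVE_CONTROL,
                       "positive_control", "candidate")
    se <- SummarizedExperiment(
        assays = list(intensity = intensity, excluded = excluded),
        colData = DataFrame(animals),
        rowData = DataFrame(role = role, row.names = rownames(intensity)))
    new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment-class intensity matrix (candidates x
#'   animals), with excluded wells left as recorded.
#' @param x An `AbundanceExperiment`.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn AbundanceExperiment-class logical exclusion mask.
#' @export
exclusionMask <- function(x) assay(x, "excluded")

#' @describeIn AbundanceExperiment-class intensity matrix with excluded
#'   wells masked to `NA`; the only view any statistic ever sees.
#' @export
maskedIntensities <- function(x) {
    ints <- assay(x, "intensity")
    ints[assay(x, "excluded")] <- NA_real_
    ints
}

#' @describeIn AbundanceExperiment-class animal metadata as a `data.frame`.
#' @export
animalInfo <- function(x) as.data.frame(colData(x))

#' @describeIn AbundanceExperiment-class ids of rows with role
#'   `"candidate"` (loading-control candidates, positive control excluded).
#' @export
candidateNames <- function(x)
    rownames(x)[rowData(x)$role == "candidate"]

setMethod("show", "AbundanceExperiment", function(object) {
    cd <- colData(object)
    cat("AbundanceExperiment:", nrow(object), "proteins x",
        ncol(object), "animals\n")
    cat("  candidates:", paste(candidateNames(object), collapse = ", "), "\n")
    pc <- rownames(object)[rowData(object)$role == "positive_control"]
    if (length(pc)) cat("  positive control:", paste(pc, collapse = ", "), "\n")
    cat("  experiments:", paste(sort(unique(cd$experiment)), collapse = ", "),
        "\n")
    cat("  treated:", sum(cd$treated), "| control:", sum(!cd$treated), "\n")
    n_excl <- sum(assay(object, "excluded"))
    cat("  excluded wells:", n_excl, "\n")
    invisible(NULL)
})
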