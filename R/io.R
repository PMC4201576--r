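.LONG_COLS <- c("animal_id", "experiment", "strain", "sex", "genotype",
                "dose_ug_per_kg", "time_h", "blot_id", "candidate",
                "intensity", "excluded")

#' Background subtraction for band intensities
#'
#' Average band intensity minus the local background estimate.  A
#' non-positive difference means the band is indistinguishable from
#' background; the value is returned as `NA` and the well must be flagged
#' excluded downstream.
#'
#' @param band_mean,background_mean finite, non-negative intensities
#'   (vectors recycle as usual).
#' @return numeric; `NA` where the difference is <= 0.
#' @examples
#' backgroundSubtract(1000, 200)   # 800
#' backgroundSubtract(200, 200)    # NA -> exclude
#' @export
backgroundSubtract <- function(band_mean, background_mean) {
    if (any(!is.finite(band_mean)) || any(!is.finite(background_mean)))
        stop("inputs must be finite")
    if (any(band_mean < 0) || any(background_mean < 0))
        stop("inputs must be >= 0")
    out <- band_mean - background_mean
    out[out <= 0] <- NA_real_
    out
}

#' Read a long-format abundance table
#'
#' One row per animal x candidate with columns `animal_id`, `experiment`,
#' `strain`, `sex`, `genotype`, `dose_ug_per_kg`, `time_h`, `blot_id`,
#' `candidate`, `intensity`, `excluded`.  Rows with `excluded = TRUE` are
#' retained but masked from every statistic.
#'
#' @param path tab- (or `sep`-) delimited text file.
#' @param sep field separator, default tab.
#' @return An [AbundanceExperiment-class].
#' @export
readAbundanceTable <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    missing_cols <- setdiff(.LONG_COLS, colnames(df))
    if (length(missing_cols))
        stop("schema error: missing column(s): ",
             paste(missing_cols, collapse = ", "))
    if (!is.numeric(df$intensity))
        stop("validation error: non-numeric 'intensity'")
    df$excluded <- as.logical(df$excluded)
    if (anyNA(df$excluded))
        stop("validation error: 'excluded' must be TRUE/FALSE")
    longToExperiment(df)
}

#' Assemble an AbundanceExperiment from a long-format data.frame
#'
#' @param df `data.frame` with the columns of [readAbundanceTable()]
#'   (`dose` accepted as an alias of `dose_ug_per_kg`).
#' @return An [AbundanceExperiment-class].
#' @export
longToExperiment <- function(df) {
    if ("dose_ug_per_kg" %in% colnames(df) && !"dose" %in% colnames(df))
        names(df)[names(df) == "dose_ug_per_kg"] <- "dose"
    key <- paste(df$animal_id, df$candidate, sep = "\r")
    if (anyDuplicated(key))
        stop("duplication error: more than one record per (animal, candidate): ",
             paste(utils::head(sub("\r", " / ", key[duplicated(key)]), 3),
                   collapse = "; "))
    bad <- !df$excluded & (!is.finite(df$intensity) | df$intensity <= 0)
    bad[!df$excluded & is.na(df$intensity)] <- FALSE  # unmeasured well
    if (any(bad, na.rm = TRUE))
        stop("validation error: non-positive intensity in non-excluded record")
    candidates <- sort(unique(df$candidate))
    candidates <- c(intersect(c(.CANDIDATES, .POSITIVE_CONTROL), candidates),
                    setdiff(candidates, c(.CANDIDATES, .POSITIVE_CONTROL)))
    animals <- unique(df[.ANIMAL_COLS[.ANIMAL_COLS != "treated"]])
    if (anyDuplicated(animals$animal_id))
        stop("validation error: inconsistent metadata for an animal_id")
    ints <- matrix(NA_real_, length(candidates), nrow(animals),
                   dimnames = list(candidates, animals$animal_id))
    excl <- matrix(FALSE, length(candidates), nrow(animals),
                   dimnames = dimnames(ints))
    ii <- cbind(match(df$candidate, candidates),
                match(df$animal_id, animals$animal_id))
    ints[ii] <- df$intensity
    excl[ii] <- df$excluded
    AbundanceExperiment(ints, animals, excluded = excl)
}

#' Flatten an AbundanceExperiment to the long format
#'
#' Inverse of [readAbundanceTable()]; unmeasured wells are omitted.
#'
#' @param x An [AbundanceExperiment-class].
#' @return long-format `data.frame`.
#' @export
asLongTable <- function(x) {
    ints <- intensities(x)
    excl <- exclusionMask(x)
    anim <- animalInfo(x)
    idx <- which(!is.na(ints) | excl, arr.ind = TRUE)
    df <- anim[idx[, 2L], .ANIMAL_COLS[.ANIMAL_COLS != "treated"]]
    names(df)[names(df) == "dose"] <- "dose_ug_per_kg"
    df$candidate <- rownames(ints)[idx[, 1L]]
    df$intensity <- ints[idx]
    df$excluded <- excl[idx]
    ord <- order(df$animal_id, df$candidate)
    df <- df[ord, .LONG_COLS]
    rownames(df) <- NULL
    df
}

#' Read a qPCR mean-Cq table
#'
#' Columns `animal_id`, `gene`, `mean_cq` (quantification cycle; lower Cq =
#' more abundant mRNA).
#'
#' @param path delimited text file.
#' @param sep field separator, default tab.
#' @return validated `data.frame`.
#' @export
readCqTable <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    validateCqTable(df)
}

#' @rdname readCqTable
#' @param df a candidate Cq `data.frame` to validate.
#' @export
validateCqTable <- function(df) {
    need <- c("animal_id", "gene", "mean_cq")
    missing_cols <- setdiff(need, colnames(df))
    if (length(missing_cols))
        stop("schema error: missing column(s): ",
             paste(missing_cols, collapse = ", "))
    if (!is.numeric(df$mean_cq) || any(!is.finite(df$mean_cq)))
        stop("validation error: 'mean_cq' must be finite numeric")
    if (anyDuplicated(paste(df$animal_id, df$gene, sep = "\r")))
        stop("duplication error: more than one Cq record per (animal, gene)")
    df[, need]
}

.fmtNum <- function(x) {
    if (is.double(x)) sprintf("%.12g", x) else x
}

.writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out)) out[[j]] <- .fmtNum(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Write result tables as TSV files
#'
#' Writes every element of `tables` (named list of data.frames) to
#' `<out_dir>/<name>.tsv` with fixed column order and floats serialized to
#' 12 significant digits, so re-reading reproduces values to that precision
#' (integers bit-identically).
#'
#' @param tables named list of `data.frame`s.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the written paths.
#' @export
writeResults <- function(tables, out_dir) {
    stopifnot(is.list(tables), !is.null(names(tables)))
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("I/O error: cannot create ", out_dir)
    paths <- vapply(names(tables), function(nm) {
        .writeTsv(as.data.frame(tables[[nm]]),
                  file.path(out_dir, paste0(nm, ".tsv")))
    }, character(1))
    invisible(paths)
}
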