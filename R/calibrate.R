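#' Calibrate a score cutoff from positive and negative score curves
#'
#' Sorts the positive scores in descending order and the negative scores in
#' ascending order, truncates both curves to the shorter length so ranks
#' align, and scans for the first rank at which the negative curve strictly
#' exceeds the positive curve. The cutoff is the midpoint of the two curve
#' values at that rank. When the curves never cross and every negative score
#' lies below every positive score, the curves are separable and the cutoff
#' is the midpoint of `max(negative)` and `min(positive)`. When the negative
#' curve already dominates at the first rank, or the curves are neither
#' crossing nor separable (e.g. identical distributions), no meaningful
#' cutoff exists and a calibration-failure error is raised carrying both
#' curves.
#'
#' @param posScores Numeric scores of genomes known present in the positive
#'   calibration sample.
#' @param negScores Numeric scores of model genomes under the negative
#'   (site-absent) calibration sample.
#' @return A [CutoffResult-class]. `crossingRank` is the 1-based rank of the
#'   crossing, or `NULL` for separable curves.
#' @examples
#' estimateCutoff(c(10, 9, 8), c(1, 2, 3))   # separable: cutoff 5.5
#' estimateCutoff(c(10, 5, 1), c(2, 4, 9))   # crossing:  cutoff 5
#' @export
estimateCutoff <- function(posScores, negScores) {
    if (!length(posScores) || !length(negScores))
        stop("invalid-parameter: both score lists must be non-empty",
             call. = FALSE)
    if (anyNA(posScores) || anyNA(negScores))
        stop("invalid-parameter: scores must not contain NA", call. = FALSE)
    pos <- sort(as.numeric(posScores), decreasing = TRUE)
    neg <- sort(as.numeric(negScores), decreasing = FALSE)
    L <- min(length(pos), length(neg))
    pos <- pos[seq_len(L)]
    neg <- neg[seq_len(L)]
    cross <- which(neg > pos)
    if (length(cross)) {
        i <- cross[1L]
        if (i == 1L) {
            cond <- structure(
                class = c("calibrationFailure", "error", "condition"),
                list(message = paste0(
                         "calibration-failure: negative scores dominate the ",
                         "positive curve from the first rank"),
                     call = sys.call(-1L),
                     positiveCurve = pos, negativeCurve = neg))
            stop(cond)
        }
        return(methods::new("CutoffResult",
                            cutoff = (neg[i] + pos[i]) / 2,
                            crossingRank = i,
                            positiveCurve = pos, negativeCurve = neg,
                            separable = FALSE))
    }
    if (max(neg) < min(pos)) {
        return(methods::new("CutoffResult",
                            cutoff = (max(neg) + min(pos)) / 2,
                            crossingRank = NULL,
                            positiveCurve = pos, negativeCurve = neg,
                            separable = TRUE))
    }
    cond <- structure(
        class = c("calibrationFailure", "error", "condition"),
        list(message = paste0(
                 "calibration-failure: curves neither cross nor separate ",
                 "(overlapping score distributions)"),
             call = sys.call(-1L),
             positiveCurve = pos, negativeCurve = neg))
    stop(cond)
}

#' Calibrate a cutoff by scoring calibration read sets
#'
#' Scores the model against a positive read sample (reads drawn from
#' genomes known to be in the model's body site) and a negative read sample
#' (reads from genomes foreign to the site). The positive curve is the
#' final score of each truth genome under the positive sample; the negative
#' curve is the final score of every model genome under the negative sample
#' (those are exactly the false-positive scores the cutoff must bound).
#' [estimateCutoff()] then locates the crossing.
#'
#' @param model A [Dsem-class].
#' @param positiveReads,negativeReads Read inputs accepted by
#'   [collectSampleNgrams()].
#' @param positiveTruth Character vector of genome ids known present in the
#'   positive sample; must all be model genomes.
#' @param positiveMate2,negativeMate2 Optional mate-2 inputs.
#' @return A [CutoffResult-class].
#' @export
calibrateFromReads <- function(model, positiveReads, positiveTruth,
                               negativeReads, positiveMate2 = NULL,
                               negativeMate2 = NULL) {
    stopifnot(methods::is(model, "Dsem"))
    missing <- setdiff(positiveTruth, model@genomeIds)
    if (length(missing))
        stop("configuration error: truth genomes absent from the model: ",
             paste(missing, collapse = ", "), call. = FALSE)
    posScores <- scoreGenomes(
        collectSampleNgrams(positiveReads, mate2 = positiveMate2,
                            n = model@n, orientation = model@orientation),
        model)
    negScores <- scoreGenomes(
        collectSampleNgrams(negativeReads, mate2 = negativeMate2,
                            n = model@n, orientation = model@orientation),
        model)
    pos <- posScores$fS[posScores$genome_id %in% positiveTruth]
    neg <- negScores$fS
    estimateCutoff(pos, neg)
}

#' Write a calibration result as JSON (plus optional curve TSV)
#'
#' @param result A [CutoffResult-class].
#' @param path Output JSON path.
#' @param curvesPath Optional TSV path for the rank-aligned curves.
#' @return `path`, invisibly.
#' @export
writeCutoff <- function(result, path, curvesPath = NULL) {
    stopifnot(methods::is(result, "CutoffResult"))
    .write_json(list(cutoff = result@cutoff,
                     crossing_rank = result@crossingRank,
                     separable = result@separable,
                     n_pos = length(result@positiveCurve),
                     n_neg = length(result@negativeCurve)),
                path)
    if (!is.null(curvesPath)) {
        .write_tsv(data.frame(rank = seq_along(result@positiveCurve),
                              positive = result@positiveCurve,
                              negative = result@negativeCurve),
                   curvesPath)
    }
    invisible(path)
}
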