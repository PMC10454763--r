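#' Confusion counts over a closed genome universe
#'
#' Classifies every genome of the universe (the model's genome set — the
#' only negatives the method can name) into TP / FP / TN / FN given the
#' predicted and truth id sets, so `TP + FP + TN + FN == |universe|`.
#'
#' @param predicted Character vector of ids called present (subset of
#'   `universe`).
#' @param truth Character vector of ids actually present (subset of
#'   `universe`).
#' @param universe Character vector: the closed set of candidate ids.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(predicted, truth, universe) {
    predicted <- unique(as.character(predicted))
    truth <- unique(as.character(truth))
    universe <- unique(as.character(universe))
    if (!all(truth %in% universe))
        stop("configuration error: truth genomes absent from the universe: ",
             paste(setdiff(truth, universe), collapse = ", "),
             call. = FALSE)
    if (!all(predicted %in% universe))
        stop("configuration error: predicted genomes absent from the universe: ",
             paste(setdiff(predicted, universe), collapse = ", "),
             call. = FALSE)
    TP <- length(intersect(predicted, truth))
    FP <- length(setdiff(predicted, truth))
    FN <- length(setdiff(truth, predicted))
    TN <- length(universe) - TP - FP - FN
    c(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Sensitivity, specificity and F1 from confusion counts
#'
#' Sensitivity (recall) is `TP / (TP + FN)`, specificity `TN / (TN + FP)`
#' and F1 `TP / (TP + (FP + FN) / 2)` — algebraically the harmonic mean of
#' precision and recall. A zero denominator yields `NA` with the
#' corresponding `undefined` flag set, never an error.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN` (as from
#'   [confusionCounts()]).
#' @return A list with `sensitivity`, `specificity`, `f1`, `undefined`
#'   (named logical) and the `counts`.
#' @export
computeMetrics <- function(counts) {
    stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
    TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
    TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
    if (any(c(TP, FP, TN, FN) < 0))
        stop("invalid-parameter: confusion counts must be non-negative",
             call. = FALSE)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- safe(TP, TP + FN)
    spec <- safe(TN, TN + FP)
    f1 <- safe(TP, TP + (FP + FN) / 2)
    list(sensitivity = sens, specificity = spec, f1 = f1,
         undefined = c(sensitivity = is.na(sens), specificity = is.na(spec),
                       f1 = is.na(f1)),
         counts = counts)
}

#' Roll strain-level sets up to species / genus level
#'
#' Maps strain ids through a user-supplied taxonomy and deduplicates per
#' level, returning the predicted/truth/universe sets at strain, species
#' and genus level; metrics at a higher level are then computed on the
#' mapped sets with the mapped universe.
#'
#' @param predicted,truth,universe Character vectors of strain ids.
#' @param taxonomy A `data.frame` with columns `strain_id`, `species`,
#'   `genus` (e.g. read from a TSV); every strain id in use must be mapped.
#' @return A list with elements `strain`, `species`, `genus`, each a list
#'   of `predicted`, `truth`, `universe` character sets.
#' @export
rollupTaxa <- function(predicted, truth, universe, taxonomy) {
    if (!is.data.frame(taxonomy) ||
        !all(c("strain_id", "species", "genus") %in% names(taxonomy)) ||
        !nrow(taxonomy))
        stop("configuration error: taxonomy needs non-empty columns ",
             "strain_id, species, genus", call. = FALSE)
    need <- unique(c(predicted, truth, universe))
    unmapped <- setdiff(need, taxonomy$strain_id)
    if (length(unmapped))
        stop("configuration error: strains missing from the taxonomy: ",
             paste(unmapped, collapse = ", "), call. = FALSE)
    lvl <- function(col) {
        map <- stats::setNames(as.character(taxonomy[[col]]),
                               taxonomy$strain_id)
        list(predicted = unique(unname(map[unique(predicted)])),
             truth = unique(unname(map[unique(truth)])),
             universe = unique(unname(map[unique(universe)])))
    }
    list(strain = list(predicted = unique(predicted),
                       truth = unique(truth),
                       universe = unique(universe)),
         species = lvl("species"),
         genus = lvl("genus"))
}

#' Evaluate a prediction against truth, per taxonomic level
#'
#' Convenience wrapper: [confusionCounts()] + [computeMetrics()] at strain
#' level, and additionally at species and genus level when a taxonomy is
#' supplied.
#'
#' @inheritParams rollupTaxa
#' @param taxonomy Optional taxonomy `data.frame`; `NULL` for strain level
#'   only.
#' @return A named list of [computeMetrics()] results, one per level.
#' @export
evaluatePrediction <- function(predicted, truth, universe, taxonomy = NULL) {
    if (is.null(taxonomy)) {
        sets <- list(strain = list(predicted = predicted, truth = truth,
                                   universe = universe))
    } else {
        sets <- rollupTaxa(predicted, truth, universe, taxonomy)
    }
    lapply(sets, function(s)
        computeMetrics(confusionCounts(s$predicted, s$truth, s$universe)))
}
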