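#' Accessors for strainsig classes
#'
#' Small accessor generics: `ngramLength()` returns the n-gram size of a
#' model or sample set; `modelSize()` the number of genomes in a model (the
#' scoring function's |c|); `orientationMode()` the strand handling mode;
#' `genomeTable()` the per-genome summary table; `scoreTable()` the
#' per-genome score table of a prediction; `predictedGenomes()` the ids
#' called present; `abundanceTable()` the per-genome abundance rows;
#' `cutoffValue()` the threshold carried by a prediction or calibration
#' result.
#'
#' @param x An object of the documented class.
#' @return See the individual description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ngramLength", function(x) standardGeneric("ngramLength"))

#' @rdname accessors
#' @export
setGeneric("modelSize", function(x) standardGeneric("modelSize"))

#' @rdname accessors
#' @export
setGeneric("orientationMode", function(x) standardGeneric("orientationMode"))

#' @rdname accessors
#' @export
setGeneric("genomeTable", function(x) standardGeneric("genomeTable"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("predictedGenomes", function(x) standardGeneric("predictedGenomes"))

#' @rdname accessors
#' @export
setGeneric("abundanceTable", function(x) standardGeneric("abundanceTable"))

#' @rdname accessors
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname accessors
#' @export
setMethod("ngramLength", "Dsem", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("ngramLength", "SampleNgramSet", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("modelSize", "Dsem", function(x) length(x@genomeIds))

#' @rdname accessors
#' @export
setMethod("orientationMode", "Dsem", function(x) x@orientation)

#' @rdname accessors
#' @export
setMethod("orientationMode", "SampleNgramSet", function(x) x@orientation)

#' @rdname accessors
#' @export
setMethod("genomeTable", "Dsem", function(x) {
    S4Vectors::DataFrame(
        genome_id = x@genomeIds,
        display_name = x@displayNames,
        total_length = x@totalLength,
        n_t = x@nT,
        unique_count = x@uniqueCount
    )
})

#' @rdname accessors
#' @export
setMethod("scoreTable", "PredictionSet", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("predictedGenomes", "PredictionSet", function(x) x@predicted)

#' @rdname accessors
#' @export
setMethod("abundanceTable", "AbundanceTable", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("cutoffValue", "PredictionSet", function(x) x@cutoff)

#' @rdname accessors
#' @export
setMethod("cutoffValue", "CutoffResult", function(x) x@cutoff)

setMethod("show", "Dsem", function(object) {
    rep <- object@metadata$buildReport
    cat("Dsem model: ", length(object@genomeIds), " genomes, n = ",
        object@n, ", orientation = ", object@orientation, "\n", sep = "")
    cat("  distinct n-grams: ", length(object@kmers),
        " (unique ", sum(object@m == 1L), ", common ",
        sum(object@m > 1L), ")\n", sep = "")
    if (!is.null(rep$warnings) && length(rep$warnings))
        cat("  build warnings: ", paste(rep$warnings, collapse = "; "),
            "\n", sep = "")
})

setMethod("show", "SampleNgramSet", function(object) {
    cat("SampleNgramSet: ", length(object@ngrams),
        " distinct n-grams (n = ", object@n, ", ", object@orientation,
        ") from ", object@readsSeen, " reads\n", sep = "")
})

setMethod("show", "PredictionSet", function(object) {
    cat("PredictionSet: ", length(object@predicted), " of ",
        nrow(object@scores), " genomes called present at cutoff ",
        format(object@cutoff), "\n", sep = "")
})

setMethod("show", "CutoffResult", function(object) {
    cat("CutoffResult: cutoff = ", format(object@cutoff), sep = "")
    if (object@separable) {
        cat(" (curves separable)\n")
    } else {
        cat(" (crossing at rank ", object@crossingRank, ")\n", sep = "")
    }
})

setMethod("show", "AbundanceTable", function(object) {
    cat("AbundanceTable: ", nrow(object@table), " genomes, ",
        sum(object@table$assigned_reads), " assigned / ",
        object@unassignedReads, " unassigned of ", object@totalReads,
        " reads\n", sep = "")
})
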