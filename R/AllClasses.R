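#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("integer_OR_NULL", c("integer", "NULL"))

#' DSEM: a DNA signature element model
#'
#' A `Dsem` indexes every distinct n-gram (k-mer) of a set of reference
#' genomes together with the genomes that contain it. The index is stored in
#' compressed sparse form: `kmers` holds the sorted distinct encoded n-grams,
#' `m` the number of genomes each occurs in (its document frequency), and
#' `postings` the concatenated 0-based genome ordinals, grouped per n-gram in
#' ascending order. Genomes are kept sorted by `genome_id`, so ordinals
#' coincide with identifier order. Discriminatory n-gram weights are not
#' stored; they are recomputed from `m` and the model size via
#' [scoreNgram()].
#'
#' @slot n Integer, n-gram length in bases.
#' @slot orientation `"canonical"` (strand-neutral; each n-gram replaced by
#'   the smaller of itself and its reverse complement) or `"forward"`
#'   (reference forward strand only).
#' @slot genomeIds Character, sorted genome identifiers.
#' @slot displayNames Character, free-text genome names.
#' @slot totalLength Numeric, genome lengths in bases.
#' @slot nT Numeric, distinct n-gram count per genome (the n-gram total used
#'   by the score normalizer).
#' @slot uniqueCount Numeric, count of n-grams private to each genome.
#' @slot kmers Numeric, sorted distinct encoded n-grams (exact integers).
#' @slot m Integer, genomes-containing count per n-gram.
#' @slot postings Integer, concatenated genome ordinals (0-based).
#' @slot metadata List; carries the build report.
#'
#' @seealso [buildDsem()], [scoreGenomes()], [saveDsem()]
#' @export
setClass("Dsem", representation(
    n = "integer",
    orientation = "character",
    genomeIds = "character",
    displayNames = "character",
    totalLength = "numeric",
    nT = "numeric",
    uniqueCount = "numeric",
    kmers = "numeric",
    m = "integer",
    postings = "integer",
    metadata = "list"
))

setValidity("Dsem", function(object) {
    msg <- character()
    G <- length(object@genomeIds)
    if (G < 2L)
        msg <- c(msg, "a model needs at least 2 genomes")
    if (anyDuplicated(object@genomeIds))
        msg <- c(msg, "genome identifiers must be unique")
    if (is.unsorted(object@genomeIds, strictly = TRUE))
        msg <- c(msg, "genomes must be sorted by genome_id")
    if (length(object@displayNames) != G || length(object@totalLength) != G ||
        length(object@nT) != G || length(object@uniqueCount) != G)
        msg <- c(msg, "genome table columns must have one entry per genome")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
        msg <- c(msg, "n must be a single positive integer")
    if (!object@orientation %in% c("canonical", "forward"))
        msg <- c(msg, "orientation must be 'canonical' or 'forward'")
    if (length(object@postings) != sum(object@m))
        msg <- c(msg, "postings length must equal sum(m)")
    if (any(object@m < 1L))
        msg <- c(msg, "every posting list must be non-empty")
    if (length(object@kmers) != length(object@m))
        msg <- c(msg, "kmers and m must be parallel")
    if (length(object@kmers) > 1L && is.unsorted(object@kmers, strictly = TRUE))
        msg <- c(msg, "kmers must be strictly increasing")
    if (length(object@postings) &&
        (min(object@postings) < 0L || max(object@postings) >= G))
        msg <- c(msg, "posting ordinals must reference genomes of the model")
    if (length(object@postings)) {
        tallied <- tabulate(object@postings + 1L, nbins = G)
        if (!isTRUE(all.equal(as.numeric(tallied), object@nT)))
            msg <- c(msg, "per-genome n_t must equal its posting membership count")
    }
    if (length(msg)) msg else TRUE
})

#' Distinct n-gram set of a metagenomic sample
#'
#' The deduplicated n-gram content of a whole read collection, produced by
#' [collectSampleNgrams()]. Identification operates on this set; read
#' multiplicity enters only at quantification.
#'
#' @slot ngrams Numeric, sorted distinct encoded n-grams.
#' @slot n Integer n-gram length.
#' @slot orientation Extraction orientation, must match the model scored
#'   against.
#' @slot readsSeen Integer number of reads consumed.
#' @slot sourceFiles Character, provenance (possibly empty).
#' @export
setClass("SampleNgramSet", representation(
    ngrams = "numeric",
    n = "integer",
    orientation = "character",
    readsSeen = "integer",
    sourceFiles = "character"
))

setValidity("SampleNgramSet", function(object) {
    if (length(object@ngrams) > 1L &&
        is.unsorted(object@ngrams, strictly = TRUE))
        return("ngrams must be sorted and duplicate-free")
    TRUE
})

#' Per-genome scores with a presence call
#'
#' Result of thresholding genome scores at a cutoff: the full score table
#' (one row per model genome) plus the subset called present.
#'
#' @slot scores A [S4Vectors::DataFrame] with columns `genome_id`, `S_g`,
#'   `n_c`, `n_t`, `nFactor`, `fS`, `predicted`, ordered by descending `fS`
#'   (ties by `genome_id`).
#' @slot cutoff Numeric threshold applied (inclusive: `fS >= cutoff`).
#' @slot predicted Character vector of genome ids called present.
#' @export
setClass("PredictionSet", representation(
    scores = "DataFrame",
    cutoff = "numeric",
    predicted = "character"
))

setValidity("PredictionSet", function(object) {
    if (!all(object@predicted %in% object@scores$genome_id))
        return("predicted genomes must be a subset of the scored genomes")
    TRUE
})

#' Calibrated score cutoff
#'
#' Result of the curve-intersection calibration: positive genome scores
#' sorted descending, negative scores sorted ascending, and the rank at which
#' the negative curve first exceeds the positive curve (or the separable
#' fallback when it never does).
#'
#' @slot cutoff Numeric calibrated threshold.
#' @slot crossingRank Integer 1-based rank of the crossing, or `NULL` when
#'   the curves never cross.
#' @slot positiveCurve,negativeCurve Numeric score curves (already sorted and
#'   truncated to a common length).
#' @slot separable Logical; `TRUE` when every negative score is below every
#'   positive score.
#' @export
setClass("CutoffResult", representation(
    cutoff = "numeric",
    crossingRank = "integer_OR_NULL",
    positiveCurve = "numeric",
    negativeCurve = "numeric",
    separable = "logical"
))

#' Relative abundance table
#'
#' Per-genome assigned-read counts and normalized relative abundances over
#' the predicted genomes, plus the count of reads no rule could place.
#'
#' @slot table A [S4Vectors::DataFrame] with columns `genome_id`,
#'   `assigned_reads`, `relative_abundance` (one row per predicted genome,
#'   zeros included).
#' @slot unassignedReads Integer.
#' @slot totalReads Integer reads processed (each mate counted separately).
#' @export
setClass("AbundanceTable", representation(
    table = "DataFrame",
    unassignedReads = "integer",
    totalReads = "integer"
))

setValidity("AbundanceTable", function(object) {
    tab <- object@table
    if (sum(tab$assigned_reads) + object@unassignedReads != object@totalReads)
        return("assigned + unassigned reads must equal total reads")
    if (sum(tab$assigned_reads) > 0 &&
        abs(sum(tab$relative_abundance) - 1) > 1e-9)
        return("relative abundances must sum to 1 when any read is assigned")
    TRUE
})
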