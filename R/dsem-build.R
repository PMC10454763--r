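#' Discriminatory weight of an n-gram
#'
#' The weight of an n-gram contained in `m` of the `C` genomes of a model is
#' \deqn{S = \left(\frac{\ln(C/m)}{\ln C}\right)^2,}
#' an inverse-document-frequency-style score normalized to \[0, 1\]: an
#' n-gram private to a single genome scores exactly 1, one present in every
#' genome scores exactly 0, and the squared logarithmic ratio decays rapidly
#' as the n-gram becomes more widely shared, so discriminatory sequence
#' dominates while common n-grams still contribute.
#'
#' @param m Integer vector: number of model genomes containing the n-gram
#'   (its document frequency), in `[1, C]`.
#' @param C Single integer: total genomes in the model, at least 2.
#' @return Numeric vector of weights in `[0, 1]`, strictly decreasing in
#'   `m`.
#' @examples
#' scoreNgram(1, 488)            # unique n-gram: 1
#' scoreNgram(488, 488)          # ubiquitous n-gram: 0
#' scoreNgram(2, 488)
#' @export
scoreNgram <- function(m, C) {
    if (length(C) != 1L || is.na(C) || C != as.integer(C) || C < 2)
        stop("model-too-small: a model needs at least 2 genomes (C >= 2)",
             call. = FALSE)
    if (!length(m)) return(numeric())
    if (anyNA(m) || any(m != as.integer(m)) || any(m < 1) || any(m > C))
        stop("invalid-count: m must be integer in [1, C]", call. = FALSE)
    (log(C / m) / log(C))^2
}

#' Build a DNA signature element model from reference genomes
#'
#' Extracts the distinct n-gram set of every genome, merges the sets into a
#' posting index (n-gram to the ordinals of the genomes containing it) and
#' records per-genome totals. Genomes are sorted by `genome_id`, so all
#' downstream tie-breaking is reproducible. Weights are not stored in the
#' model; they derive from the posting counts via [scoreNgram()].
#'
#' @param genomes One of: a named list of [Biostrings::DNAStringSet] (one
#'   element per genome, multi-record allowed), a named character vector of
#'   FASTA (optionally gzipped) paths, a manifest `data.frame` with columns
#'   `genome_id` and `path`, or the path of a manifest TSV
#'   (`genome_id <TAB> path`).
#' @param n Integer n-gram length, 1 to 26 (default 21; shorter n-grams lose
#'   strain-level discriminatory power, longer ones grow the index with
#'   little gain; see [ngramSizeSurvey()]).
#' @param orientation `"canonical"` (default) indexes the strand-neutral
#'   canonical form of every n-gram; `"forward"` indexes the forward strand
#'   as written.
#' @param plasmidFilter Logical; drop records whose header mentions
#'   "plasmid" before indexing.
#' @return A [Dsem-class] object. Its `metadata$buildReport` lists the
#'   total/unique/common distinct n-gram counts and any warnings.
#' @details Models built from fewer than 50 genomes trigger a warning:
#'   small genome sets confer little discriminatory power on the shared
#'   n-gram weights (the model still builds, which the toy examples rely
#'   on).
#' @examples
#' g <- generateGenomes(3, 2000, seed = 1)
#' model <- suppressWarnings(buildDsem(g, n = 21))
#' genomeTable(model)
#' @export
buildDsem <- function(genomes, n = 21L,
                      orientation = c("canonical", "forward"),
                      plasmidFilter = FALSE) {
    orientation <- match.arg(orientation)
    n <- .check_n(n)
    glist <- .as_genome_list(genomes)
    if (length(glist) < 2L)
        stop("model-too-small: at least 2 genomes are required",
             call. = FALSE)
    if (plasmidFilter) glist <- lapply(glist, filterPlasmids)
    empty <- vapply(glist, function(x)
        length(x) == 0L || sum(Biostrings::width(x)) == 0L, logical(1))
    if (any(empty))
        stop("empty genome sequence for: ",
             paste(names(glist)[empty], collapse = ", "), call. = FALSE)
    glist <- glist[order(names(glist))]

    canonical <- orientation == "canonical"
    sets <- lapply(glist, function(x)
        cpp_collect_distinct(as.character(x), n, canonical))
    merged <- cpp_merge_postings(sets)

    G <- length(glist)
    uniq_ord <- merged$postings[rep.int(merged$m == 1L, merged$m)]
    uniqueCount <- as.numeric(tabulate(uniq_ord + 1L, nbins = G))
    displayNames <- vapply(glist, function(x) {
        nm <- names(x)
        if (is.null(nm) || !length(nm) || nm[1] == "") "" else nm[1]
    }, character(1))

    warnings <- character()
    if (G < 50L) {
        warnings <- paste0("model built from only ", G, " genomes; at least ",
                           "50 are recommended for discriminatory power")
        warning(warnings, call. = FALSE)
    }

    obj <- methods::new(
        "Dsem",
        n = n, orientation = orientation,
        genomeIds = names(glist),
        displayNames = unname(displayNames),
        totalLength = vapply(glist, function(x)
            as.numeric(sum(Biostrings::width(x))), numeric(1),
            USE.NAMES = FALSE),
        nT = vapply(sets, function(s) as.numeric(length(s)), numeric(1),
                    USE.NAMES = FALSE),
        uniqueCount = uniqueCount,
        kmers = merged$kmers,
        m = merged$m,
        postings = merged$postings,
        metadata = list(buildReport = list(
            total_distinct = length(merged$kmers),
            unique = sum(merged$m == 1L),
            common = sum(merged$m > 1L),
            warnings = warnings
        ))
    )
    methods::validObject(obj)
    obj
}

#' Survey unique/common n-gram counts over candidate n-gram sizes
#'
#' For each candidate `n`, counts the distinct n-grams of the genome set and
#' how many are unique to one genome versus shared, using the same
#' extraction rules as [buildDsem()]. The survey guides the choice of n: the
#' unique count saturates beyond some n while index size keeps growing.
#' Counts only are computed, so n up to 31 is supported here.
#'
#' @inheritParams buildDsem
#' @param nValues Integer vector of candidate n-gram sizes (default the
#'   codon-stride ladder 12, 15, 18, 21, 24, 27).
#' @return A `data.frame` with columns `n`, `total_distinct`, `unique`,
#'   `common`.
#' @export
ngramSizeSurvey <- function(genomes, nValues = c(12L, 15L, 18L, 21L, 24L, 27L),
                            orientation = c("canonical", "forward")) {
    orientation <- match.arg(orientation)
    if (!length(nValues))
        stop("invalid-parameter: nValues must be non-empty", call. = FALSE)
    nValues <- vapply(nValues, .check_n, integer(1), max = .MAX_N_COUNT)
    glist <- .as_genome_list(genomes)
    if (length(glist) < 2L)
        stop("model-too-small: at least 2 genomes are required",
             call. = FALSE)
    glist <- glist[order(names(glist))]
    counts <- cpp_survey(lapply(glist, as.character), nValues,
                         orientation == "canonical")
    data.frame(n = nValues,
               total_distinct = counts[, 1],
               unique = counts[, 2],
               common = counts[, 3])
}
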