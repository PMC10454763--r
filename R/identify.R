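#' Collect the distinct n-gram set of a metagenomic read collection
#'
#' Deconstructs every read into overlapping n-grams and pools them into one
#' deduplicated sample set; multiplicity is deliberately discarded here
#' (identification scores the distinct n-gram content of the sample, read
#' depth enters at quantification). In `"canonical"` mode every n-gram is
#' replaced by its strand-neutral canonical form; in `"forward"` mode reads
#' are taken as written and mate-2 reads are reverse-complemented into
#' forward direction before extraction.
#'
#' @param reads Mate-1 reads: a [Biostrings::DNAStringSet], FASTQ file
#'   path(s) (optionally gzipped), or a character vector of sequences.
#' @param mate2 Optional mate-2 reads, same forms.
#' @param n Integer n-gram length; must match the model scored against.
#' @param orientation `"canonical"` (default) or `"forward"`.
#' @return A [SampleNgramSet-class].
#' @export
collectSampleNgrams <- function(reads, mate2 = NULL, n = 21L,
                                orientation = c("canonical", "forward")) {
    orientation <- match.arg(orientation)
    n <- .check_n(n)
    src <- character()
    if (.is_file_path(reads)) src <- c(src, reads)
    if (!is.null(mate2) && .is_file_path(mate2)) src <- c(src, mate2)
    r1 <- .as_reads(reads)
    r2 <- .as_reads(mate2, "mate2")
    if (!is.null(r2) && orientation == "forward")
        r2 <- reverseComplement(r2)
    all <- if (is.null(r2)) r1 else c(r1, r2)
    ngrams <- cpp_collect_distinct(as.character(all), n,
                                   orientation == "canonical")
    methods::new("SampleNgramSet",
                 ngrams = ngrams, n = n, orientation = orientation,
                 readsSeen = length(all), sourceFiles = src)
}

#' Score every model genome against a sample n-gram set
#'
#' Conceptually fills the matrix W (sample n-grams as rows, genomes as
#' columns, cell = the n-gram's weight when the genome contains it) and
#' takes column sums; the implementation accumulates the sums directly from
#' the posting index. For genome g:
#' \deqn{S_g = \sum_{i} w_{n_i g}, \quad
#'       \mathrm{nFactor}_g = n_c / n_t, \quad fS_g = S_g \cdot
#'       \mathrm{nFactor}_g,}
#' where the sum runs over sample n-grams contained in g, `n_c` counts those
#' n-grams and `n_t` is the genome's distinct n-gram total in the model. The
#' matched-fraction normalizer penalizes large genomes matched only on a
#' sliver of their content.
#'
#' @param sample A [SampleNgramSet-class] from [collectSampleNgrams()].
#' @param model A [Dsem-class]; `n` and orientation must match the sample.
#' @return A [S4Vectors::DataFrame] with columns `genome_id`, `S_g`, `n_c`,
#'   `n_t`, `nFactor`, `fS`, ordered by descending `fS` (ties broken by
#'   `genome_id` ascending).
#' @export
scoreGenomes <- function(sample, model) {
    stopifnot(methods::is(sample, "SampleNgramSet"),
              methods::is(model, "Dsem"))
    if (sample@n != model@n)
        stop("configuration error: sample n-gram size (", sample@n,
             ") does not match the model (", model@n, ")", call. = FALSE)
    if (sample@orientation != model@orientation)
        stop("configuration error: sample orientation (",
             sample@orientation, ") does not match the model (",
             model@orientation, ")", call. = FALSE)
    G <- modelSize(model)
    acc <- cpp_score_sample(sample@ngrams, model@kmers, model@m,
                            model@postings, G)
    nFactor <- ifelse(model@nT > 0, acc$nc / model@nT, 0)
    fS <- acc$S * nFactor
    df <- S4Vectors::DataFrame(
        genome_id = model@genomeIds,
        S_g = acc$S,
        n_c = acc$nc,
        n_t = model@nT,
        nFactor = nFactor,
        fS = fS
    )
    df[order(-df$fS, df$genome_id), , drop = FALSE]
}

#' Call present genomes at a score cutoff
#'
#' Thresholds the final scores: a genome is predicted present when
#' `fS >= cutoff` (inclusive, so a genome sitting exactly at the cutoff is
#' called). A cutoff of 0 therefore predicts every genome, which is why a
#' calibrated positive cutoff (see [estimateCutoff()]) is used in practice.
#'
#' @param scores The score table from [scoreGenomes()] (or a `data.frame`
#'   with columns `genome_id` and `fS`).
#' @param cutoff Single non-negative number.
#' @return A [PredictionSet-class].
#' @export
applyCutoff <- function(scores, cutoff) {
    if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0)
        stop("invalid-parameter: cutoff must be a single non-negative number",
             call. = FALSE)
    if (is.data.frame(scores)) scores <- S4Vectors::DataFrame(scores)
    stopifnot(all(c("genome_id", "fS") %in% colnames(scores)))
    hit <- scores$fS >= cutoff
    scores$predicted <- hit
    methods::new("PredictionSet",
                 scores = scores,
                 cutoff = as.numeric(cutoff),
                 predicted = sort(scores$genome_id[hit]))
}

#' One-call identification of strains in a read set
#'
#' Convenience wrapper: [collectSampleNgrams()] with the model's n-gram size
#' and orientation, [scoreGenomes()], then [applyCutoff()].
#'
#' @inheritParams collectSampleNgrams
#' @param model A [Dsem-class].
#' @param cutoff Presence threshold, typically from [calibrateFromReads()].
#' @return A [PredictionSet-class].
#' @export
identifyStrains <- function(reads, model, cutoff, mate2 = NULL) {
    sample <- collectSampleNgrams(reads, mate2 = mate2, n = model@n,
                                  orientation = model@orientation)
    applyCutoff(scoreGenomes(sample, model), cutoff)
}

#' Write an identification score table and run summary
#'
#' Writes the scores of a [PredictionSet-class] as TSV (floats with 6
#' significant digits, the `predicted` flag as 0/1) and, optionally, a JSON
#' run summary beside it.
#'
#' @param prediction A [PredictionSet-class].
#' @param path Output TSV path.
#' @param summary Optional list of extra fields for the JSON summary; set to
#'   `NULL` to skip the summary file.
#' @return `path`, invisibly.
#' @export
writeScores <- function(prediction, path, summary = list()) {
    stopifnot(methods::is(prediction, "PredictionSet"))
    df <- as.data.frame(prediction@scores)
    for (col in c("S_g", "nFactor", "fS"))
        if (col %in% names(df)) df[[col]] <- signif(df[[col]], 6L)
    df$predicted <- as.integer(df$predicted)
    .write_tsv(df, path)
    if (!is.null(summary)) {
        info <- c(list(cutoff = prediction@cutoff,
                       genomes = nrow(df),
                       predicted = length(prediction@predicted)),
                  summary)
        .write_json(info, paste0(path, ".json"))
    }
    invisible(path)
}
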