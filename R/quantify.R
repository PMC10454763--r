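.RULE_LABELS <- c(`0` = "unassigned", `1` = "unique", `2` = "common-argmax")

# Ordinals (0-based) of the predicted genomes of a prediction set.
.predicted_ordinals <- function(model, predicted) {
    if (!length(predicted))
        stop("invalid-parameter: the predicted genome set is empty",
             call. = FALSE)
    missing <- setdiff(predicted, model@genomeIds)
    if (length(missing))
        stop("configuration error: predicted genomes absent from the model: ",
             paste(missing, collapse = ", "), call. = FALSE)
    sort(match(predicted, model@genomeIds) - 1L)
}

#' Assign one read to a predicted genome
#'
#' Applies the two-tier assignment rule to the distinct n-gram set of a
#' single read. Rule 1: if the read carries n-grams unique (document
#' frequency 1) to predicted genomes, assign to the predicted genome with
#' the most such unique n-grams; a tie falls through to rule 2 restricted to
#' the tied genomes. Rule 2: compute the read-genome score
#' \eqn{R_{jg} = \sum_i S_{n_i g}} (the summed weights of the n-grams shared
#' between read and genome) and assign to the argmax; remaining ties are
#' broken by `genome_id` ascending and flagged. Rule 3: a read sharing no
#' n-gram with any predicted genome stays unassigned.
#'
#' @param readNgrams Numeric vector of encoded n-grams of one read
#'   (deduplicated internally), or a single read sequence string.
#' @param model A [Dsem-class].
#' @param predicted Character vector of predicted genome ids, or a
#'   [PredictionSet-class].
#' @return A list with `assigned_genome` (id or `NA` for unassigned),
#'   `rule_used` (`"unique"`, `"common-argmax"` or `"unassigned"`) and
#'   `tie_broken` (logical).
#' @export
assignRead <- function(readNgrams, model, predicted) {
    stopifnot(methods::is(model, "Dsem"))
    if (methods::is(predicted, "PredictionSet"))
        predicted <- predictedGenomes(predicted)
    ord <- .predicted_ordinals(model, predicted)
    if (is.character(readNgrams) && length(readNgrams) == 1L) {
        res <- cpp_assign_reads(readNgrams, model@n,
                                model@orientation == "canonical",
                                model@kmers, model@m, model@postings,
                                ord, modelSize(model))
    } else {
        res <- cpp_assign_kmer_sets(list(as.numeric(readNgrams)),
                                    model@kmers, model@m, model@postings,
                                    ord, modelSize(model))
    }
    list(assigned_genome = if (res$assigned[1L] < 0L) NA_character_
                           else model@genomeIds[res$assigned[1L] + 1L],
         rule_used = unname(.RULE_LABELS[as.character(res$rule[1L])]),
         tie_broken = res$tie[1L])
}

#' Quantify relative abundances by read assignment
#'
#' Passes every read (each mate independently) through the [assignRead()]
#' rules against the predicted genomes and tallies assigned reads per
#' genome. Relative abundance is the assigned-read fraction,
#' `assigned_reads / sum(assigned_reads)`; genomes predicted but receiving
#' no reads keep a zero row. When no read at all is assigned the abundances
#' are reported as 0 with a warning. With `lengthNormalize = TRUE`, counts
#' are divided by genome length before renormalizing (relevant when genome
#' sizes differ markedly and a cell-fraction-like estimate is wanted).
#'
#' @param reads Read input accepted by [collectSampleNgrams()].
#' @param model A [Dsem-class].
#' @param prediction A [PredictionSet-class] from the same model (or a
#'   character vector of predicted genome ids).
#' @param mate2 Optional mate-2 reads; in `"forward"` orientation they are
#'   reverse-complemented before n-gram extraction.
#' @param lengthNormalize Logical, default `FALSE` (abundance = read
#'   fraction).
#' @param perRead Logical; also keep the per-read assignment stream.
#' @return An [AbundanceTable-class]. With `perRead = TRUE` the per-read
#'   stream (a [S4Vectors::DataFrame] with columns `read_id`, `genome_id`,
#'   `rule`, `tie_broken`) is attached as `attr(result, "perRead")`.
#' @export
quantifyReads <- function(reads, model, prediction, mate2 = NULL,
                          lengthNormalize = FALSE, perRead = FALSE) {
    stopifnot(methods::is(model, "Dsem"))
    predicted <- if (methods::is(prediction, "PredictionSet"))
        predictedGenomes(prediction) else as.character(prediction)
    ord <- .predicted_ordinals(model, predicted)
    r1 <- .as_reads(reads)
    r2 <- .as_reads(mate2, "mate2")
    if (!is.null(r2) && model@orientation == "forward")
        r2 <- reverseComplement(r2)
    all <- if (is.null(r2)) r1 else c(r1, r2)
    res <- cpp_assign_reads(as.character(all), model@n,
                            model@orientation == "canonical",
                            model@kmers, model@m, model@postings,
                            ord, modelSize(model))
    predictedIds <- model@genomeIds[ord + 1L]
    counts <- tabulate(match(res$assigned, ord), nbins = length(ord))
    unassigned <- sum(res$assigned < 0L)
    weights <- as.numeric(counts)
    if (lengthNormalize) {
        len <- model@totalLength[ord + 1L]
        weights <- ifelse(len > 0, weights / len, 0)
    }
    total_w <- sum(weights)
    if (sum(counts) == 0L) {
        warning("no read could be assigned to any predicted genome",
                call. = FALSE)
        rel <- rep(0, length(ord))
    } else {
        rel <- weights / total_w
    }
    tab <- S4Vectors::DataFrame(genome_id = predictedIds,
                                assigned_reads = counts,
                                relative_abundance = rel)
    out <- methods::new("AbundanceTable", table = tab,
                        unassignedReads = as.integer(unassigned),
                        totalReads = length(all))
    if (perRead) {
        ids <- names(all) %||% character(0)
        if (!length(ids) || any(ids == ""))
            ids <- sprintf("read%06d", seq_along(all))
        attr(out, "perRead") <- S4Vectors::DataFrame(
            read_id = ids,
            genome_id = ifelse(res$assigned < 0L, "UNASSIGNED",
                               model@genomeIds[res$assigned + 1L]),
            rule = unname(.RULE_LABELS[as.character(res$rule)]),
            tie_broken = res$tie)
    }
    out
}

#' Write an abundance table as TSV
#'
#' @param abundance An [AbundanceTable-class].
#' @param path Output TSV path (`genome_id`, `assigned_reads`,
#'   `relative_abundance`).
#' @param perReadPath Optional TSV path for the per-read assignment stream
#'   (requires `quantifyReads(..., perRead = TRUE)`).
#' @return `path`, invisibly.
#' @export
writeAbundance <- function(abundance, path, perReadPath = NULL) {
    stopifnot(methods::is(abundance, "AbundanceTable"))
    .write_tsv(as.data.frame(abundance@table), path)
    if (!is.null(perReadPath)) {
        pr <- attr(abundance, "perRead")
        if (is.null(pr))
            stop("invalid-parameter: abundance has no per-read stream ",
                 "(use perRead = TRUE)", call. = FALSE)
        .write_tsv(as.data.frame(pr), perReadPath)
    }
    invisible(path)
}
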