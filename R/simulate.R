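#' Generate random synthetic genomes
#'
#' Generates `k` genomes of i.i.d. uniform bases. Distinct random genomes
#' of realistic length are n-gram-disjoint in practice for n around 21 (the
#' chance of a shared 21-gram between two 100-kb genomes is ~1e-3; between
#' 5-kb toys, ~1e-6), which makes them convenient fixtures for recovery
#' experiments. With `sharedBlockFraction > 0`, one common block of that
#' fraction of the genome length is implanted at the same position in every
#' genome, manufacturing common n-grams with document frequency `k`.
#'
#' @param k Number of genomes.
#' @param length Genome length in bases.
#' @param sharedBlockFraction Fraction of the length occupied by the
#'   implanted common block (0 = none).
#' @param seed Optional integer seed; the output is bit-reproducible under
#'   a fixed seed.
#' @param prefix Identifier prefix; genomes are named `prefix01`,
#'   `prefix02`, ...
#' @return A named [Biostrings::DNAStringSet], one record per genome.
#' @export
generateGenomes <- function(k, length, sharedBlockFraction = 0,
                            seed = NULL, prefix = "g") {
    stopifnot(k >= 1, length >= 1)
    if (sharedBlockFraction < 0 || sharedBlockFraction > 1)
        stop("invalid-parameter: sharedBlockFraction must be in [0, 1]",
             call. = FALSE)
    .with_seed(seed, {
        seqs <- vapply(seq_len(k), function(i)
            paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = ""), character(1))
        blen <- round(sharedBlockFraction * length)
        if (blen > 0) {
            block <- paste(sample(c("A", "C", "G", "T"), blen,
                                  replace = TRUE), collapse = "")
            at <- max(1L, (length - blen) %/% 2L)
            for (i in seq_len(k))
                substr(seqs[i], at, at + blen - 1L) <- block
        }
        out <- DNAStringSet(seqs)
        names(out) <- sprintf("%s%02d", prefix, seq_len(k))
        out
    })
}

.community <- function(ids, proportions, label) {
    out <- data.frame(genome_id = as.character(ids),
                      proportion = proportions,
                      stringsAsFactors = FALSE)
    stopifnot(abs(sum(out$proportion) - 1) < 1e-9, all(out$proportion > 0))
    attr(out, "label") <- label
    out
}

#' Mock community compositions
#'
#' `mockEven()` builds the even 12-member community (each genome at
#' proportion 1/12, i.e. 0.083); `mockStaggered()` builds the staggered
#' 20-member community whose proportions span 0.0002 to 0.18 — a
#' deterministic geometric ladder between those endpoints, renormalized to
#' sum to one, so the raw max/min ratio is 900.
#'
#' @param genomeIds Exactly 12 (`mockEven`) or 20 (`mockStaggered`) genome
#'   ids; ladder proportions are assigned in the order given, smallest
#'   first.
#' @return A `data.frame` with columns `genome_id`, `proportion` (summing
#'   to 1) and a `label` attribute (`"even"` / `"staggered"`).
#' @export
mockEven <- function(genomeIds) {
    if (length(genomeIds) != 12L)
        stop("invalid-parameter: the even mock community has exactly 12 ",
             "genomes (got ", length(genomeIds), ")", call. = FALSE)
    .community(genomeIds, rep(1 / 12, 12L), "even")
}

#' @rdname mockEven
#' @export
mockStaggered <- function(genomeIds) {
    if (length(genomeIds) != 20L)
        stop("invalid-parameter: the staggered mock community has exactly ",
             "20 genomes (got ", length(genomeIds), ")", call. = FALSE)
    lo <- 2e-4
    hi <- 0.18
    raw <- lo * (hi / lo)^((0:19) / 19)
    .community(genomeIds, raw / sum(raw), "staggered")
}

#' Simulate metagenomic reads from a community
#'
#' Draws each fragment's source genome from the community proportions, its
#' start uniformly along the genome and its strand uniformly, then reports
#' either a single read per fragment or a 150+150 bp pair (mate 2 is the
#' reverse complement of the opposite fragment end; fragments are
#' back-to-back, `2 * readLength` long). Substitution errors are applied
#' i.i.d. per base. Base qualities, indels and fragment-size variation are
#' deliberately not modelled: error-model fidelity is orthogonal to the
#' signature-matching algorithm being exercised.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (single record per
#'   genome) or named character vector of sequences.
#' @param composition A community `data.frame` (`genome_id`, `proportion`),
#'   e.g. from [mockEven()]; ids must exist in `genomes`.
#' @param readLength Read length in bases (default 150).
#' @param nReads Number of fragments (a paired run yields `2 * nReads`
#'   FASTQ records). Exactly one of `nReads` / `coverage` must be given.
#' @param coverage Target fold-coverage over the summed community genome
#'   lengths; converted as `round(coverage * totalLength / readLength /
#'   (2 if paired))` fragments.
#' @param substitutionRate Per-base substitution probability in `[0, 0.2]`.
#' @param paired Logical (default `TRUE`).
#' @param seed Optional integer seed (bit-reproducible output).
#' @return A list: `reads` (mate-1 `DNAStringSet`, names
#'   `r<i>/<genome_id>`), `mate2` (`DNAStringSet` or `NULL`), and `truth`
#'   (`data.frame` of `genome_id`, `true_proportion`).
#' @export
simulateReads <- function(genomes, composition, readLength = 150L,
                          nReads = NULL, coverage = NULL,
                          substitutionRate = 0, paired = TRUE,
                          seed = NULL) {
    if (is.character(genomes)) genomes <- DNAStringSet(genomes)
    stopifnot(methods::is(genomes, "DNAStringSet"),
              !is.null(names(genomes)))
    if (is.null(nReads) == is.null(coverage))
        stop("invalid-parameter: give exactly one of nReads or coverage",
             call. = FALSE)
    if (substitutionRate < 0 || substitutionRate > 0.2)
        stop("invalid-parameter: substitutionRate must be in [0, 0.2]",
             call. = FALSE)
    missing <- setdiff(composition$genome_id, names(genomes))
    if (length(missing))
        stop("configuration error: composition genomes not supplied: ",
             paste(missing, collapse = ", "), call. = FALSE)
    gseq <- as.character(genomes[composition$genome_id])
    glen <- nchar(gseq)
    span <- if (paired) 2L * readLength else readLength
    short <- glen < span
    if (any(short))
        stop("fragment span (", span, ") exceeds genome length for: ",
             paste(composition$genome_id[short], collapse = ", "),
             call. = FALSE)
    if (is.null(nReads))
        nReads <- round(coverage * sum(glen) / readLength / (if (paired) 2 else 1))
    nReads <- as.integer(nReads)

    .with_seed(seed, {
        src <- sample.int(nrow(composition), nReads, replace = TRUE,
                          prob = composition$proportion)
        start <- floor(stats::runif(nReads) * (glen[src] - span + 1)) + 1
        fwd <- stats::runif(nReads) < 0.5
        frag <- substring(gseq[src], start, start + span - 1L)
        ids <- sprintf("r%07d/%s", seq_len(nReads),
                       composition$genome_id[src])
        if (paired) {
            left <- substr(frag, 1L, readLength)
            right <- as.character(reverseComplement(DNAStringSet(
                substr(frag, span - readLength + 1L, span))))
            r1 <- ifelse(fwd, left, right)
            r2 <- ifelse(fwd, right, left)
        } else {
            r1 <- ifelse(fwd, frag,
                         as.character(reverseComplement(DNAStringSet(frag))))
            r2 <- NULL
        }
        if (substitutionRate > 0) {
            r1 <- cpp_mutate_reads(r1, substitutionRate)
            if (!is.null(r2)) r2 <- cpp_mutate_reads(r2, substitutionRate)
        }
        reads <- DNAStringSet(r1)
        names(reads) <- ids
        mate2 <- NULL
        if (!is.null(r2)) {
            mate2 <- DNAStringSet(r2)
            names(mate2) <- ids
        }
        list(reads = reads, mate2 = mate2,
             truth = data.frame(genome_id = composition$genome_id,
                                true_proportion = composition$proportion,
                                stringsAsFactors = FALSE))
    })
}

#' Subsample a read set to a fraction or target coverage
#'
#' Samples `round(fraction * N)` fragments without replacement, keeping
#' mate pairs together and preserving the original record order. In
#' coverage mode the fraction is `coverage * sum(genomeLengths) /
#' totalBases`, where `totalBases` counts both mates.
#'
#' @param reads Mate-1 [Biostrings::DNAStringSet] (or FASTQ path).
#' @param mate2 Optional mate-2 reads.
#' @param fraction Fraction of fragments to keep, in (0, 1].
#' @param coverage Target coverage (requires `genomeLengths`); exactly one
#'   of `fraction` / `coverage` must be given.
#' @param genomeLengths Numeric vector of community genome lengths.
#' @param seed Optional integer seed.
#' @return A list with `reads` and `mate2` (subset, original order).
#' @export
subsampleReads <- function(reads, mate2 = NULL, fraction = NULL,
                           coverage = NULL, genomeLengths = NULL,
                           seed = NULL) {
    r1 <- .as_reads(reads)
    r2 <- .as_reads(mate2, "mate2")
    if (is.null(fraction) == is.null(coverage))
        stop("invalid-parameter: give exactly one of fraction or coverage",
             call. = FALSE)
    if (!is.null(coverage)) {
        if (is.null(genomeLengths))
            stop("invalid-parameter: coverage mode needs genomeLengths",
                 call. = FALSE)
        totalBases <- sum(Biostrings::width(r1)) +
            if (is.null(r2)) 0 else sum(Biostrings::width(r2))
        fraction <- coverage * sum(genomeLengths) / totalBases
    }
    if (fraction <= 0 || fraction > 1)
        stop("invalid-parameter: fraction must be in (0, 1]", call. = FALSE)
    N <- length(r1)
    keep <- .with_seed(seed, sort(sample.int(N, round(fraction * N))))
    list(reads = r1[keep], mate2 = if (is.null(r2)) NULL else r2[keep])
}

#' Truncate reference genomes to emulate incomplete drafts
#'
#' Keeps a contiguous window of each genome: by default the prefix of
#' `keepFraction` of its length (draft assemblies lose contiguous
#' sequence), or a random window per genome when `randomWindow = TRUE`.
#'
#' @param genomes Named [Biostrings::DNAStringSet].
#' @param keepFraction Fraction of each genome to keep, in (0, 1].
#' @param randomWindow Logical; pick the window start at random (under
#'   `seed`) instead of the prefix.
#' @param seed Optional integer seed (used with `randomWindow`).
#' @return A `DNAStringSet` of truncated genomes, same names.
#' @export
degradeReferences <- function(genomes, keepFraction, randomWindow = FALSE,
                              seed = NULL) {
    stopifnot(methods::is(genomes, "DNAStringSet"))
    if (keepFraction <= 0 || keepFraction > 1)
        stop("invalid-parameter: keepFraction must be in (0, 1]",
             call. = FALSE)
    w <- Biostrings::width(genomes)
    keep <- pmax(1L, as.integer(round(keepFraction * w)))
    starts <- .with_seed(seed, {
        if (randomWindow)
            floor(stats::runif(length(w)) * (w - keep + 1)) + 1
        else rep(1L, length(w))
    })
    out <- Biostrings::subseq(genomes, start = starts,
                              end = starts + keep - 1L)
    names(out) <- names(genomes)
    out
}
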