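#' @useDynLib strainsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# n-grams are packed 2 bits/base into an integer carried as an R double,
# which represents integers exactly up to 2^53, i.e. for n <= 26. All
# operations that move encoded values across the R boundary enforce that
# ceiling; count-only operations (the size survey) go up to 31.
.MAX_N_EXPORT <- 26L
.MAX_N_COUNT <- 31L

.check_n <- function(n, max = .MAX_N_EXPORT) {
    if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1L || n > max)
        stop("invalid-parameter: n must be a single integer in [1, ",
             max, "]", call. = FALSE)
    as.integer(n)
}

#' Encode and decode fixed-length n-grams
#'
#' DNA windows are packed two bits per base, most-significant bits first,
#' under the fixed code A=00, C=01, G=10, T=11 (a uniform-depth prefix code
#' over the 4-symbol alphabet). `encodeNgram("ACGT")` is `27`;
#' `decodeNgram(27, 4)` recovers `"ACGT"`. Values are exact R doubles, so n
#' is limited to 26 (4^26 < 2^53).
#'
#' @param x Character vector of base strings, all of the same length n;
#'   lowercase accepted. Any character outside A/C/G/T is an error.
#' @param value Numeric vector of encoded n-grams in `[0, 4^n)`.
#' @param n Integer n-gram length in bases.
#' @return `encodeNgram()` a numeric vector of encoded values;
#'   `decodeNgram()` a character vector of upper-case base strings.
#' @examples
#' encodeNgram(c("ACGT", "TTTT"))
#' decodeNgram(27, 4)
#' @export
encodeNgram <- function(x) {
    if (!length(x)) return(numeric())
    n <- unique(nchar(x))
    if (length(n) != 1L)
        stop("invalid-parameter: all windows must have the same length",
             call. = FALSE)
    .check_n(n)
    cpp_encode(x)
}

#' @rdname encodeNgram
#' @export
decodeNgram <- function(value, n) {
    n <- .check_n(n)
    cpp_decode(as.numeric(value), n)
}

#' Reverse complement and canonical form of encoded n-grams
#'
#' `revcompNgram()` reverse-complements an encoded n-gram without decoding
#' it; `canonicalNgram()` returns the smaller (under unsigned-integer
#' ordering of the 2-bit code) of an n-gram and its reverse complement, the
#' strand-neutral representative used in canonical orientation mode.
#'
#' @inheritParams decodeNgram
#' @return Numeric vector of encoded n-grams.
#' @examples
#' revcompNgram(encodeNgram("AAAA"), 4) == encodeNgram("TTTT")
#' canonicalNgram(encodeNgram("TTTT"), 4) == encodeNgram("AAAA")
#' @export
revcompNgram <- function(value, n) {
    n <- .check_n(n)
    cpp_revcomp(as.numeric(value), n)
}

#' @rdname revcompNgram
#' @export
canonicalNgram <- function(value, n) {
    n <- .check_n(n)
    value <- as.numeric(value)
    pmin(value, cpp_revcomp(value, n))
}

#' Extract all n-gram windows of a sequence
#'
#' Slides a window of length `n` over the sequence: a sequence of length x
#' has `max(0, x - n + 1)` windows, each emitted in order. Windows containing
#' any character outside A/C/G/T (N, IUPAC ambiguity codes, ...) are skipped
#' and counted, so `length(ngrams) + windows_skipped == windows_total` when
#' `distinct = FALSE`.
#'
#' @param sequence A single base string (lowercase accepted).
#' @param n Integer n-gram length.
#' @param distinct Logical; deduplicate the emitted multiset (first
#'   occurrence kept).
#' @param orientation `"as-is"` to emit windows as written, `"canonical"` to
#'   canonicalize each window before collection.
#' @return A list with elements `ngrams` (numeric encoded values),
#'   `windows_total` and `windows_skipped`.
#' @examples
#' extractNgrams("ACGTNACGT", 4)$windows_skipped
#' @export
extractNgrams <- function(sequence, n, distinct = FALSE,
                          orientation = c("as-is", "canonical")) {
    orientation <- match.arg(orientation)
    n <- .check_n(n)
    stopifnot(is.character(sequence), length(sequence) == 1L)
    res <- cpp_extract(sequence, n, distinct, orientation == "canonical")
    res$windows_total <- as.numeric(res$windows_total)
    res$windows_skipped <- as.numeric(res$windows_skipped)
    res
}
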