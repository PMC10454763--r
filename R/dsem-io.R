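# Model serialization. Fixed little-endian binary layout:
#   magic "DSEM" | version u16 | n u8 | orientation u8 (0 forward,
#   1 canonical) | genome count u32 | per genome: id (u16 length-prefixed
#   UTF-8), display name (u16 length-prefixed UTF-8), total_length u64,
#   n_t u64, unique_count u64 | postings sorted ascending by encoded
#   n-gram: n-gram u64, m u32, delta-encoded genome ordinals (u32 each).
# u64 values are written as two u32 words (low word first).

.DSEM_MAGIC <- charToRaw("DSEM")
.DSEM_VERSION <- 1L

.u32_to_signed <- function(x) {
    x <- as.numeric(x)
    as.integer(ifelse(x >= 2^31, x - 2^32, x))
}

.signed_to_u32 <- function(x) {
    x <- as.numeric(x)
    ifelse(x < 0, x + 2^32, x)
}

.w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                    endian = "little")
.w_u32 <- function(con, x) writeBin(.u32_to_signed(x), con, size = 4L,
                                    endian = "little")
.w_u64 <- function(con, x) {
    x <- as.numeric(x)
    lo <- x %% 2^32
    hi <- x %/% 2^32
    .w_u32(con, as.vector(rbind(lo, hi)))
}
.w_str <- function(con, s) {
    r <- charToRaw(enc2utf8(s))
    .w_u16(con, length(r))
    if (length(r)) writeBin(r, con)
}

#' Save and load a signature model
#'
#' `saveDsem()` writes a [Dsem-class] model in a compact custom binary
#' layout (magic bytes `DSEM`, versioned, little-endian, delta-encoded
#' posting lists); `loadDsem()` reads it back bit-exactly: the genome
#' table, posting index, n and orientation round-trip unchanged, so scores
#' computed before and after serialization are identical.
#'
#' @param model A [Dsem-class] object.
#' @param path File path; written atomically (temp file + rename).
#' @return `saveDsem()` the path, invisibly; `loadDsem()` a [Dsem-class].
#' @export
saveDsem <- function(model, path) {
    stopifnot(methods::is(model, "Dsem"))
    methods::validObject(model)
    .atomic_write(path, function(tmp) {
        con <- file(tmp, "wb")
        on.exit(close(con))
        writeBin(.DSEM_MAGIC, con)
        .w_u16(con, .DSEM_VERSION)
        writeBin(as.integer(model@n), con, size = 1L)
        writeBin(as.integer(model@orientation == "canonical"), con, size = 1L)
        G <- length(model@genomeIds)
        .w_u32(con, G)
        for (g in seq_len(G)) {
            .w_str(con, model@genomeIds[g])
            .w_str(con, model@displayNames[g])
            .w_u64(con, c(model@totalLength[g], model@nT[g],
                          model@uniqueCount[g]))
        }
        # postings: interleave [kmer_lo, kmer_hi, m, deltas...] per n-gram
        K <- length(model@kmers)
        P <- length(model@postings)
        lo <- model@kmers %% 2^32
        hi <- model@kmers %/% 2^32
        delta <- model@postings
        if (P > 1L) {
            starts <- cumsum(c(1L, model@m))[seq_len(K)]
            d <- c(delta[1L], diff(delta))
            d[starts] <- delta[starts]
            delta <- d
        }
        key_i <- c(rep(seq_len(K), times = 3L), rep.int(seq_len(K), model@m))
        key_j <- c(rep(1:3, each = K), 3L + sequence(model@m))
        vals <- c(lo, hi, as.numeric(model@m), as.numeric(delta))
        .w_u32(con, vals[order(key_i, key_j)])
    })
}

#' @rdname saveDsem
#' @export
loadDsem <- function(path) {
    if (!file.exists(path))
        stop("corrupt-model: file not found: ", path, call. = FALSE)
    raw <- readBin(path, what = "raw", n = file.info(path)$size)
    pos <- 0L
    take <- function(k, what = "header") {
        if (pos + k > length(raw))
            stop("corrupt-model: truncated ", what, call. = FALSE)
        out <- raw[(pos + 1L):(pos + k)]
        pos <<- pos + k
        out
    }
    if (length(raw) < 4L || !identical(take(4L), .DSEM_MAGIC))
        stop("unsupported-format: not a DSEM model file", call. = FALSE)
    version <- readBin(take(2L), integer(), size = 2L, endian = "little",
                       signed = FALSE)
    if (version != .DSEM_VERSION)
        stop("unsupported-format: model format version ", version,
             call. = FALSE)
    n <- readBin(take(1L), integer(), size = 1L, signed = FALSE)
    ori <- readBin(take(1L), integer(), size = 1L, signed = FALSE)
    G <- .signed_to_u32(readBin(take(4L), integer(), size = 4L,
                                endian = "little"))
    r_str <- function() {
        len <- readBin(take(2L, "genome table"), integer(), size = 2L,
                       endian = "little", signed = FALSE)
        if (len == 0L) return("")
        rawToChar(take(len, "genome table"))
    }
    r_u64 <- function(k) {
        words <- .signed_to_u32(readBin(take(8L * k, "genome table"),
                                        integer(), n = 2L * k, size = 4L,
                                        endian = "little"))
        words[seq(1L, 2L * k, by = 2L)] + words[seq(2L, 2L * k, by = 2L)] * 2^32
    }
    ids <- character(G); disp <- character(G)
    totalLength <- numeric(G); nT <- numeric(G); uniqueCount <- numeric(G)
    for (g in seq_len(G)) {
        ids[g] <- r_str()
        disp[g] <- r_str()
        v <- r_u64(3L)
        totalLength[g] <- v[1L]; nT[g] <- v[2L]; uniqueCount[g] <- v[3L]
    }
    nWords <- (length(raw) - pos) / 4L
    if (nWords != floor(nWords))
        stop("corrupt-model: truncated posting section", call. = FALSE)
    words <- readBin(raw[(pos + 1L):length(raw)], integer(), n = nWords,
                     size = 4L, endian = "little")
    merged <- cpp_parse_postings(words)
    obj <- methods::new(
        "Dsem",
        n = n, orientation = if (ori == 1L) "canonical" else "forward",
        genomeIds = ids, displayNames = disp,
        totalLength = totalLength, nT = nT, uniqueCount = uniqueCount,
        kmers = merged$kmers, m = merged$m, postings = merged$postings,
        metadata = list(buildReport = list(
            total_distinct = length(merged$kmers),
            unique = sum(merged$m == 1L),
            common = sum(merged$m > 1L),
            warnings = character()
        ))
    )
    methods::validObject(obj)
    obj
}
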