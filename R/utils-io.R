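#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom utils read.delim write.table
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
    if (is.null(seed)) return(code)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

.is_file_path <- function(x) {
    is.character(x) && length(x) >= 1L && !anyNA(x) &&
        all(nchar(x) < 1000) && all(file.exists(x))
}

# Normalize read input to a DNAStringSet: accepts a DNAStringSet, FASTQ
# file path(s) (optionally gzipped), or a plain character vector of
# sequences.
.as_reads <- function(x, what = "reads") {
    if (is.null(x)) return(NULL)
    if (methods::is(x, "DNAStringSet")) return(x)
    if (methods::is(x, "XStringSet")) return(DNAStringSet(x))
    if (.is_file_path(x)) {
        sets <- lapply(x, function(f) {
            tryCatch(readDNAStringSet(f, format = "fastq"),
                     error = function(e) stop(
                         "parse error reading FASTQ '", f, "': ",
                         conditionMessage(e), call. = FALSE))
        })
        return(do.call(c, sets))
    }
    if (is.character(x)) return(DNAStringSet(x))
    stop("invalid-parameter: ", what,
         " must be a DNAStringSet, FASTQ path(s), or sequences",
         call. = FALSE)
}

# Normalize genome input to a named list of DNAStringSet (one element per
# genome, possibly multi-record). Accepts:
#  - a named list of DNAStringSet / character sequences,
#  - a named character vector of FASTA paths (one file per genome),
#  - a manifest data.frame with columns genome_id, path,
#  - a path to a manifest TSV (genome_id <TAB> path).
.as_genome_list <- function(genomes) {
    if (is.data.frame(genomes)) {
        if (!all(c("genome_id", "path") %in% names(genomes)))
            stop("configuration error: manifest needs columns genome_id, path",
                 call. = FALSE)
        g <- as.character(genomes$path)
        names(g) <- as.character(genomes$genome_id)
        genomes <- g
    }
    if (is.character(genomes) && length(genomes) == 1L &&
        is.null(names(genomes)) && file.exists(genomes)) {
        man <- read.delim(genomes, header = FALSE, stringsAsFactors = FALSE)
        if (ncol(man) < 2L)
            stop("configuration error: manifest TSV needs genome_id <TAB> path",
                 call. = FALSE)
        dir <- dirname(genomes)
        paths <- ifelse(file.exists(man[[2L]]), man[[2L]],
                        file.path(dir, man[[2L]]))
        genomes <- structure(paths, names = man[[1L]])
    }
    if (is.character(genomes)) {
        if (is.null(names(genomes)) || any(names(genomes) == ""))
            stop("configuration error: genome FASTA paths must be named by genome_id",
                 call. = FALSE)
        genomes <- lapply(genomes, function(f) {
            if (!file.exists(f))
                stop("genome FASTA not found: ", f, call. = FALSE)
            readDNAStringSet(f, format = "fasta")
        })
    }
    if (methods::is(genomes, "DNAStringSet")) {
        # a named DNAStringSet is taken as one single-record genome per entry
        if (is.null(names(genomes)) || any(names(genomes) == ""))
            stop("configuration error: genomes must be named by genome_id",
                 call. = FALSE)
        nms <- names(genomes)
        genomes <- lapply(seq_along(genomes), function(i) genomes[i])
        names(genomes) <- nms
    }
    if (!is.list(genomes) || is.null(names(genomes)) ||
        any(names(genomes) == ""))
        stop("configuration error: genomes must be named by genome_id",
             call. = FALSE)
    if (anyDuplicated(names(genomes)))
        stop("configuration error: duplicate genome_id: ",
             paste(unique(names(genomes)[duplicated(names(genomes))]),
                   collapse = ", "), call. = FALSE)
    lapply(genomes, function(x) {
        if (methods::is(x, "DNAStringSet")) x else DNAStringSet(as.character(x))
    })
}

#' Drop plasmid records from a genome assembly
#'
#' Removes FASTA records whose header contains the token "plasmid"
#' (case-insensitive); all other records pass through unchanged, in order.
#'
#' @param records A [Biostrings::DNAStringSet] with record names.
#' @return A `DNAStringSet` without the plasmid records.
#' @export
filterPlasmids <- function(records) {
    stopifnot(methods::is(records, "DNAStringSet"))
    keep <- !grepl("plasmid", names(records) %||% character(length(records)),
                   ignore.case = TRUE)
    records[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reads as 4-line FASTQ
#'
#' Writes a `DNAStringSet` as FASTQ with a constant placeholder quality
#' ("I", Phred 40), optionally gzip-compressed when the path ends in `.gz`.
#'
#' @param reads A [Biostrings::DNAStringSet]; unnamed reads get sequential
#'   ids.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeFastq <- function(reads, path) {
    stopifnot(methods::is(reads, "DNAStringSet"))
    if (is.null(names(reads)) || any(names(reads) == ""))
        names(reads) <- sprintf("read%06d", seq_along(reads))
    quals <- Biostrings::BStringSet(
        vapply(Biostrings::width(reads),
               function(w) strrep("I", w), character(1)))
    writeXStringSet(reads, path, format = "fastq", qualities = quals,
                    compress = endsWith(path, ".gz"))
    invisible(path)
}

# Atomic write: run writer() against a temp path in the same directory, then
# rename over the target.
.atomic_write <- function(path, writer) {
    tmp <- tempfile(tmpdir = dirname(path),
                    fileext = paste0(".", basename(path)))
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path)) {
        file.copy(tmp, path, overwrite = TRUE)
        unlink(tmp)
    }
    invisible(path)
}

.write_tsv <- function(df, path) {
    .atomic_write(path, function(tmp)
        write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

.write_json <- function(x, path) {
    .atomic_write(path, function(tmp)
        jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null"))
}
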