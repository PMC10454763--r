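# String-level oracles, independent of the packed-integer implementation,
# plus small fixture builders shared across test files.

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

str_revcomp <- function(s) {
    vapply(s, function(x)
        chartr("ACGT", "TGCA",
               paste(rev(strsplit(x, "")[[1]]), collapse = "")),
        character(1), USE.NAMES = FALSE)
}

str_canonical <- function(s) pmin(s, str_revcomp(s))

# All length-n windows of a sequence, dropping those with non-ACGT bases.
str_windows <- function(s, n) {
    L <- nchar(s)
    if (L < n) return(character())
    w <- substring(toupper(s), 1:(L - n + 1), n:L)
    w[grepl("^[ACGT]+$", w)]
}

str_kmer_set <- function(s, n, canonical = FALSE) {
    w <- unlist(lapply(s, str_windows, n = n))
    if (canonical) w <- str_canonical(w)
    sort(unique(w))
}

# Explicit matrix-W oracle for genome scoring: materializes the full
# (sample n-gram x genome) weight matrix and takes column sums.
oracle_score_genomes <- function(sample_kmers, genome_sets, n_t) {
    C <- length(genome_sets)
    member <- vapply(genome_sets, function(g) sample_kmers %in% g,
                     logical(length(sample_kmers)))
    member <- matrix(member, nrow = length(sample_kmers))
    m <- rowSums(member)
    W <- matrix(0, nrow = length(sample_kmers), ncol = C)
    for (i in which(m > 0)) W[i, ] <- member[i, ] * scoreNgram(m[i], C)
    S <- colSums(W)
    n_c <- colSums(member)
    data.frame(genome_id = names(genome_sets), S_g = S, n_c = n_c,
               nFactor = ifelse(n_t > 0, n_c / n_t, 0),
               fS = S * ifelse(n_t > 0, n_c / n_t, 0),
               stringsAsFactors = FALSE)
}

# Brute-force read assignment oracle over string k-mer sets.
oracle_assign <- function(read_kmers, genome_sets, C, predicted, m_of) {
    shared <- lapply(genome_sets[predicted], function(g)
        intersect(read_kmers, g))
    ucnt <- vapply(shared, function(s) sum(m_of[s] == 1), numeric(1))
    wsum <- vapply(shared, function(s)
        if (length(s)) sum(scoreNgram(m_of[s], C)) else 0, numeric(1))
    if (all(vapply(shared, length, integer(1)) == 0))
        return(list(genome = NA_character_, rule = "unassigned",
                    tie = FALSE))
    cand <- predicted
    if (max(ucnt) > 0) {
        cand <- predicted[ucnt == max(ucnt)]
        if (length(cand) == 1L)
            return(list(genome = cand, rule = "unique", tie = FALSE))
    }
    best <- cand[wsum[cand] == max(wsum[cand])]
    list(genome = sort(best)[1], rule = "common-argmax",
         tie = length(best) > 1)
}

# Fixture: toy genome set with an engineered shared block, as a named
# character vector (ids sorted), suitable for buildDsem().
toy_genomes <- function(k = 3, L = 600, shared = 120, seed = 42) {
    set.seed(seed)
    g <- vapply(seq_len(k), function(i) random_dna(L), character(1))
    if (shared > 0) {
        block <- random_dna(shared)
        for (i in seq_len(k))
            substr(g[i], 200, 200 + shared - 1) <- block
    }
    names(g) <- sprintf("t%02d", seq_len(k))
    g
}

build_quiet <- function(...) suppressWarnings(buildDsem(...))

as_sample <- function(kmer_values, n, orientation = "canonical") {
    new("SampleNgramSet", ngrams = sort(unique(as.numeric(kmer_values))),
        n = as.integer(n), orientation = orientation,
        readsSeen = 0L, sourceFiles = character())
}
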