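# A small model with engineered sharing for assignment tests: genomes with
# private sequence plus blocks shared pairwise, built once per file.
quant_fixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        set.seed(71)
        g <- vapply(1:5, function(i) random_dna(800), character(1))
        names(g) <- sprintf("q%02d", 1:5)
        ab <- random_dna(150)          # shared by q01 + q02
        cde <- random_dna(150)         # shared by q03 + q04 + q05
        substr(g[1], 300, 449) <- ab
        substr(g[2], 500, 649) <- ab
        for (i in 3:5) substr(g[i], 100, 249) <- cde
        model <- build_quiet(as.list(g), n = 21, orientation = "forward")
        cache <<- list(g = g, model = model,
                       sets = lapply(g, str_kmer_set, n = 21),
                       m_of = NULL)
        m_of <- table(unlist(cache$sets))
        cache$m_of <<- setNames(as.integer(m_of), names(m_of))
        cache
    }
})

test_that("reads with unique n-grams are assigned by rule 1", {
    fx <- quant_fixture()
    # a read from q02's private region: unique n-grams of q02 only
    read <- substring(fx$g[2], 1, 100)
    res <- assignRead(read, fx$model, names(fx$g))
    expect_equal(res$assigned_genome, "q02")
    expect_equal(res$rule_used, "unique")
    expect_false(res$tie_broken)
})

test_that("reads without any model match stay unassigned", {
    fx <- quant_fixture()
    set.seed(72)
    res <- assignRead(random_dna(100), fx$model, names(fx$g))
    expect_true(is.na(res$assigned_genome))
    expect_equal(res$rule_used, "unassigned")
    # matching only non-predicted genomes is also unassigned
    read <- substring(fx$g[1], 1, 100)
    res <- assignRead(read, fx$model, c("q03", "q04"))
    expect_equal(res$rule_used, "unassigned")
})

test_that("common-only reads go to the maximum read-genome score", {
    fx <- quant_fixture()
    # a read inside the q01/q02 shared block: no unique n-grams, equal
    # R_jg for both sharers -> tie broken by genome_id, flagged
    read <- substring(fx$g[1], 310, 430)
    res <- assignRead(read, fx$model, names(fx$g))
    expect_equal(res$assigned_genome, "q01")
    expect_equal(res$rule_used, "common-argmax")
    expect_true(res$tie_broken)
    # restricting the predicted set picks the only sharer present
    res <- assignRead(read, fx$model, c("q02", "q03"))
    expect_equal(res$assigned_genome, "q02")
    expect_false(res$tie_broken)
})

test_that("assignment agrees with the all-pairs R_jg oracle on random reads", {
    fx <- quant_fixture()
    set.seed(73)
    C <- 5L
    for (i in 1:100) {
        src <- sample(5, 1)
        start <- sample(650, 1)
        read <- substring(fx$g[src], start, start + 120)
        if (runif(1) < 0.3)   # perturb some reads
            read <- strainsig:::cpp_mutate_reads(read, 0.05)
        predicted <- sort(sample(names(fx$g), sample(2:5, 1)))
        got <- assignRead(read, fx$model, predicted)
        want <- oracle_assign(str_kmer_set(read, 21), fx$sets, C,
                              predicted, fx$m_of)
        expect_equal(got$assigned_genome, want$genome)
        expect_equal(got$rule_used, want$rule)
        expect_equal(got$tie_broken, want$tie)
    }
})

test_that("assignment needs a non-empty predicted set from the model", {
    fx <- quant_fixture()
    expect_error(assignRead("ACGT", fx$model, character()),
                 "invalid-parameter")
    expect_error(assignRead("ACGT", fx$model, "nope"),
                 "configuration error")
})

test_that("abundances are assigned-read fractions over predicted genomes", {
    fx <- quant_fixture()
    set.seed(74)
    reads <- c(
        vapply(1:75, function(i) {
            s <- sample(650, 1); substring(fx$g[1], s, s + 100)
        }, character(1)),
        # q02 reads kept clear of its q01-shared block so each carries
        # unique q02 n-grams and cannot tie over to q01
        vapply(1:25, function(i) {
            s <- sample(380, 1); substring(fx$g[2], s, s + 100)
        }, character(1)))
    ab <- quantifyReads(reads, fx$model, c("q01", "q02", "q03"),
                        perRead = TRUE)
    tab <- as.data.frame(abundanceTable(ab))
    expect_equal(tab$genome_id, c("q01", "q02", "q03"))
    expect_equal(sum(tab$assigned_reads) + ab@unassignedReads, 100L)
    expect_equal(sum(tab$relative_abundance), 1)
    expect_equal(tab$assigned_reads[1:2], c(75L, 25L))
    expect_equal(tab$relative_abundance, c(0.75, 0.25, 0))
    pr <- attr(ab, "perRead")
    expect_equal(nrow(pr), 100L)
    expect_true(all(pr$genome_id %in% c("q01", "q02", "q03", "UNASSIGNED")))
})

test_that("quantification is independent of read order and counts mates", {
    fx <- quant_fixture()
    set.seed(75)
    r1 <- vapply(1:30, function(i) {
        s <- sample(650, 1); substring(fx$g[sample(3, 1)], s, s + 100)
    }, character(1))
    r2 <- str_revcomp(r1)
    a <- quantifyReads(r1, fx$model, names(fx$g))
    expect_equal(a@totalReads, 30L)
    perm <- sample(30)
    b <- quantifyReads(r1[perm], fx$model, names(fx$g))
    expect_equal(as.data.frame(abundanceTable(a)),
                 as.data.frame(abundanceTable(b)))
    # forward-orientation models reverse-complement mate 2 internally;
    # this model is forward-built, so mates land on the same genome
    ab <- quantifyReads(r1, fx$model, names(fx$g), mate2 = r2)
    expect_equal(ab@totalReads, 60L)
    expect_equal(as.data.frame(abundanceTable(ab))$assigned_reads,
                 2L * as.data.frame(abundanceTable(a))$assigned_reads)
})

test_that("a fully unassignable read set warns and reports zero abundance", {
    fx <- quant_fixture()
    set.seed(76)
    alien <- vapply(1:5, function(i) random_dna(100), character(1))
    expect_warning(ab <- quantifyReads(alien, fx$model, c("q01", "q02")),
                   "no read could be assigned")
    tab <- as.data.frame(abundanceTable(ab))
    expect_equal(tab$assigned_reads, c(0L, 0L))
    expect_equal(tab$relative_abundance, c(0, 0))
    expect_equal(ab@unassignedReads, 5L)
})

test_that("length normalization divides counts by genome length", {
    set.seed(77)
    g <- list(a = random_dna(400), b = random_dna(800))
    model <- build_quiet(g, n = 21, orientation = "forward")
    reads <- c(substring(g$a, 1, 100), substring(g$a, 101, 200),
               substring(g$b, 1, 100), substring(g$b, 101, 200))
    plain <- quantifyReads(reads, model, c("a", "b"))
    expect_equal(as.data.frame(abundanceTable(plain))$relative_abundance,
                 c(0.5, 0.5))
    norm <- quantifyReads(reads, model, c("a", "b"), lengthNormalize = TRUE)
    # equal counts over lengths 400 and 800 renormalize to 2/3 vs 1/3
    expect_equal(as.data.frame(abundanceTable(norm))$relative_abundance,
                 c(2 / 3, 1 / 3))
})
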