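test_that("scoring function hits its anchors and decays monotonically", {
    for (C in c(2L, 10L, 488L)) {
        expect_identical(scoreNgram(1, C), 1)   # unique n-gram
        expect_identical(scoreNgram(C, C), 0)   # ubiquitous n-gram
    }
    # frozen high-precision oracle values for the closed form
    expect_equal(scoreNgram(2, 488), 0.788592241467884, tolerance = 1e-14)
    expect_equal(scoreNgram(3, 10), 0.273402182265940, tolerance = 1e-14)
    expect_equal(scoreNgram(5, 50), 0.346440436597236, tolerance = 1e-14)
    # strict monotone decrease in m, exhaustive for C <= 50
    for (C in 2:50) {
        s <- scoreNgram(1:C, C)
        expect_true(all(diff(s) < 0))
        expect_true(all(s >= 0 & s <= 1))
    }
    expect_error(scoreNgram(1, 1), "model-too-small")
    expect_error(scoreNgram(0, 10), "invalid-count")
    expect_error(scoreNgram(11, 10), "invalid-count")
})

test_that("builder matches the naive string-set oracle", {
    set.seed(21)
    genomes <- vapply(1:5, function(i) random_dna(5000), character(1))
    names(genomes) <- sprintf("g%02d", 1:5)
    # implant a block shared by genomes 2 and 4 to create common n-grams
    block <- random_dna(200)
    substr(genomes[2], 1000, 1199) <- block
    substr(genomes[4], 3000, 3199) <- block
    for (n in c(4L, 11L, 21L)) {
        for (ori in c("canonical", "forward")) {
            model <- build_quiet(as.list(genomes), n = n, orientation = ori)
            canon <- ori == "canonical"
            sets <- lapply(genomes, str_kmer_set, n = n, canonical = canon)
            union_all <- sort(unique(unlist(sets)))
            m_oracle <- rowSums(vapply(sets, function(s) union_all %in% s,
                                       logical(length(union_all))))
            expect_equal(length(model@kmers), length(union_all))
            expect_equal(sort(decodeNgram(model@kmers, n)), union_all)
            # per-genome totals and unique/common partition
            expect_equal(model@nT, unname(lengths(sets)))
            uniq_oracle <- vapply(seq_along(sets), function(i) {
                others <- unique(unlist(sets[-i]))
                sum(!sets[[i]] %in% others)
            }, numeric(1))
            expect_equal(model@uniqueCount, uniq_oracle)
            expect_equal(model@metadata$buildReport$unique,
                         sum(m_oracle == 1))
            expect_equal(model@metadata$buildReport$common,
                         sum(m_oracle > 1))
        }
    }
})

test_that("posting-count conservation laws hold", {
    g <- toy_genomes(4, L = 800, shared = 150, seed = 22)
    model <- build_quiet(as.list(g), n = 21)
    expect_equal(length(model@postings), sum(model@m))
    expect_equal(sum(model@m == 1L), sum(model@uniqueCount))
    expect_equal(length(model@kmers),
                 model@metadata$buildReport$total_distinct)
    expect_equal(as.numeric(tabulate(model@postings + 1L, 4)), model@nT)
})

test_that("duplicated genomes share every n-gram and score zero", {
    set.seed(23)
    s <- random_dna(1000)
    model <- build_quiet(list(a = s, b = s), n = 21)
    expect_equal(model@uniqueCount, c(0, 0))
    expect_true(all(model@m == 2L))
    expect_true(all(scoreNgram(model@m, 2) == 0))
})

test_that("an engineered shared 21-mer yields exactly one common posting", {
    shared <- "ACGTACGTACGTACGTACGTA"  # 21 bases
    tails <- c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG")
    g <- as.list(setNames(paste0(shared, tails), c("a", "b", "c")))
    model <- build_quiet(g, n = 21, orientation = "forward")
    expect_equal(sum(model@m >= 2L), 1L)
    common <- model@kmers[model@m >= 2L]
    expect_equal(decodeNgram(common, 21), shared)
    expect_equal(model@m[model@kmers == common], 3L)
})

test_that("canonical models are invariant to strand flips of the input", {
    g <- toy_genomes(3, L = 700, shared = 100, seed = 24)
    flipped <- str_revcomp(g)
    names(flipped) <- names(g)
    m1 <- build_quiet(as.list(g), n = 21, orientation = "canonical")
    m2 <- build_quiet(as.list(flipped), n = 21, orientation = "canonical")
    expect_identical(m1@kmers, m2@kmers)
    expect_identical(m1@m, m2@m)
    expect_identical(m1@postings, m2@postings)
    expect_identical(m1@nT, m2@nT)
})

test_that("builder validates its inputs", {
    g <- toy_genomes(3, seed = 25)
    expect_error(buildDsem(as.list(g)[1]), "model-too-small")
    dup <- as.list(g)[c(1, 1, 2)]
    expect_error(buildDsem(dup), "duplicate genome_id")
    empty <- c(as.list(g), list(zz = ""))
    expect_error(build_quiet(empty), "empty genome sequence.*zz")
    expect_warning(buildDsem(as.list(g), n = 21), "only 3 genomes")
})

test_that("n-gram size survey equals brute-force enumeration", {
    set.seed(26)
    g <- list(a = random_dna(300), b = random_dna(300))
    rows <- ngramSizeSurvey(g, nValues = c(4L, 8L))
    for (i in seq_len(nrow(rows))) {
        n <- rows$n[i]
        sets <- lapply(g, str_kmer_set, n = n, canonical = TRUE)
        union_all <- unique(unlist(sets))
        shared <- intersect(sets[[1]], sets[[2]])
        expect_equal(rows$total_distinct[i], length(union_all))
        expect_equal(rows$common[i], length(shared))
        expect_equal(rows$unique[i], length(union_all) - length(shared))
        expect_equal(rows$unique[i] + rows$common[i], rows$total_distinct[i])
    }
    # duplicated genomes: nothing is unique at any n
    dup <- ngramSizeSurvey(list(a = g$a, b = g$a), nValues = c(6L, 12L))
    expect_true(all(dup$unique == 0))
    # n exceeding every genome length: nothing to count (counts support n>26)
    tiny <- list(a = random_dna(20), b = random_dna(24))
    big <- ngramSizeSurvey(tiny, nValues = 27L)
    expect_equal(big$total_distinct, 0)
})

test_that("plasmid records are filtered by header token, case-insensitive", {
    recs <- Biostrings::DNAStringSet(c("ACGTACGT", "GGGGCCCC", "TTTTAAAA"))
    names(recs) <- c("chr1 complete genome", "pXY Plasmid sequence",
                     "chr2")
    kept <- filterPlasmids(recs)
    expect_equal(names(kept), c("chr1 complete genome", "chr2"))
    expect_equal(filterPlasmids(recs[c(1, 3)]), recs[c(1, 3)])
})
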