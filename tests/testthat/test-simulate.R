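test_that("genome generation is seed-reproducible and block sharing works", {
    a <- generateGenomes(3, 2000, seed = 81)
    b <- generateGenomes(3, 2000, seed = 81)
    expect_identical(as.character(a), as.character(b))
    expect_equal(names(a), c("g01", "g02", "g03"))
    expect_false(identical(as.character(generateGenomes(3, 2000, seed = 82)),
                           as.character(a)))
    # without a shared block, random genomes share no 21-mers
    model <- build_quiet(a, n = 21)
    expect_equal(model@metadata$buildReport$common, 0L)
    # a 50% shared block makes its interior n-grams common to all k genomes
    shared <- generateGenomes(4, 2000, sharedBlockFraction = 0.5, seed = 83)
    m2 <- build_quiet(shared, n = 21)
    expect_gte(sum(m2@m == 4L), 1000 - 21)
})

test_that("mock community compositions match their stated designs", {
    even <- mockEven(sprintf("e%02d", 1:12))
    expect_equal(even$proportion, rep(1 / 12, 12))
    expect_equal(sum(even$proportion), 1)
    expect_equal(attr(even, "label"), "even")
    expect_error(mockEven(sprintf("e%02d", 1:11)), "exactly 12")

    stag <- mockStaggered(sprintf("s%02d", 1:20))
    expect_equal(sum(stag$proportion), 1)
    expect_true(all(diff(stag$proportion) > 0))
    raw_ratio <- stag$proportion[20] / stag$proportion[1]
    expect_equal(raw_ratio, 0.18 / 2e-4)   # 900, the stated span
    expect_equal(attr(stag, "label"), "staggered")
    expect_error(mockStaggered("one"), "exactly 20")
})

test_that("error-free reads are exact substrings of a genome strand", {
    g <- generateGenomes(2, 3000, seed = 84)
    sim <- simulateReads(g, data.frame(genome_id = "g01", proportion = 1),
                         nReads = 50, paired = FALSE, seed = 85)
    expect_length(sim$reads, 50L)
    fwd <- as.character(g[["g01"]])
    rev <- str_revcomp(fwd)
    hits <- vapply(as.character(sim$reads), function(r)
        grepl(r, fwd, fixed = TRUE) || grepl(r, rev, fixed = TRUE),
        logical(1))
    expect_true(all(hits))
    # paired mode: nReads fragments give 2x records, mates from opposite ends
    simp <- simulateReads(g, data.frame(genome_id = "g01", proportion = 1),
                          nReads = 1000, paired = TRUE, seed = 86)
    expect_length(simp$reads, 1000L)
    expect_length(simp$mate2, 1000L)
    expect_true(all(Biostrings::width(simp$reads) == 150L))
})

test_that("read counts follow composition proportions (binomial oracle)", {
    g <- generateGenomes(2, 5000, seed = 87)
    comp <- data.frame(genome_id = c("g01", "g02"),
                       proportion = c(0.75, 0.25))
    sim <- simulateReads(g, comp, nReads = 100000, paired = FALSE,
                         seed = 88)
    src <- sub("^.*/", "", names(sim$reads))
    n1 <- sum(src == "g01")
    # within 4 binomial standard deviations of expectation
    expect_lt(abs(n1 - 75000), 4 * sqrt(100000 * 0.75 * 0.25))
})

test_that("coverage-mode read counts follow the coverage formula", {
    g <- generateGenomes(2, 3000, seed = 89)
    comp <- data.frame(genome_id = c("g01", "g02"),
                       proportion = c(0.5, 0.5))
    sim <- simulateReads(g, comp, coverage = 10, paired = TRUE, seed = 90)
    expect_length(sim$reads, round(10 * 6000 / 150 / 2))
    simu <- simulateReads(g, comp, coverage = 10, paired = FALSE, seed = 90)
    expect_length(simu$reads, round(10 * 6000 / 150))
})

test_that("substitution errors hit at about the requested rate", {
    g <- generateGenomes(1, 3000, seed = 91)
    comp <- data.frame(genome_id = "g01", proportion = 1)
    clean <- simulateReads(g, comp, nReads = 400, paired = FALSE, seed = 92)
    noisy <- simulateReads(g, comp, nReads = 400, paired = FALSE, seed = 92,
                           substitutionRate = 0.05)
    diffs <- sum(vapply(seq_len(400), function(i) {
        a <- strsplit(as.character(clean$reads[[i]]), "")[[1]]
        b <- strsplit(as.character(noisy$reads[[i]]), "")[[1]]
        sum(a != b)
    }, numeric(1)))
    total <- 400 * 150
    expect_lt(abs(diffs - 0.05 * total), 4 * sqrt(total * 0.05 * 0.95))
})

test_that("simulation validates its parameters", {
    g <- generateGenomes(2, 1000, seed = 93)
    comp <- data.frame(genome_id = c("g01", "g02"),
                       proportion = c(0.5, 0.5))
    expect_error(simulateReads(g, comp), "exactly one of nReads or coverage")
    expect_error(simulateReads(g, comp, nReads = 10, coverage = 5),
                 "exactly one of nReads or coverage")
    expect_error(simulateReads(g, comp, nReads = 10,
                               substitutionRate = 0.5), "substitutionRate")
    expect_error(simulateReads(g, data.frame(genome_id = "zz",
                                             proportion = 1), nReads = 1),
                 "configuration error")
    expect_error(simulateReads(g, comp, nReads = 10, readLength = 600,
                               paired = TRUE), "exceeds genome length")
})

test_that("subsampling keeps pairs together, in order, without replacement", {
    g <- generateGenomes(2, 3000, seed = 94)
    comp <- data.frame(genome_id = c("g01", "g02"),
                       proportion = c(0.5, 0.5))
    sim <- simulateReads(g, comp, nReads = 100, seed = 95)
    # fraction 1: identity, original order
    all_kept <- subsampleReads(sim$reads, sim$mate2, fraction = 1)
    expect_identical(names(all_kept$reads), names(sim$reads))
    half <- subsampleReads(sim$reads, sim$mate2, fraction = 0.5, seed = 96)
    expect_length(half$reads, 50L)
    expect_true(all(names(half$reads) %in% names(sim$reads)))
    expect_identical(names(half$reads), names(half$mate2))  # pairs together
    expect_equal(anyDuplicated(names(half$reads)), 0L)
    idx <- match(names(half$reads), names(sim$reads))
    expect_true(all(diff(idx) > 0))                          # original order
    # coverage mode: 1x requested from a 120x set keeps 1/120 of fragments
    cov <- subsampleReads(sim$reads, sim$mate2, coverage = 1,
                          genomeLengths = c(3000, 3000),
                          seed = 97)
    have_cov <- 100 * 300 / 6000
    expect_length(cov$reads, round(100 / have_cov))
    expect_error(subsampleReads(sim$reads, fraction = 0), "fraction")
    expect_error(subsampleReads(sim$reads, fraction = 0.5, coverage = 1),
                 "exactly one")
})

test_that("reference degradation truncates contiguously and shrinks models", {
    g <- generateGenomes(3, 4000, seed = 98)
    expect_identical(as.character(degradeReferences(g, 1)),
                     as.character(g))
    half <- degradeReferences(g, 0.5)
    expect_true(all(Biostrings::width(half) == 2000L))
    expect_identical(as.character(half),
                     substr(as.character(g), 1, 2000))   # prefix truncation
    rnd1 <- degradeReferences(g, 0.25, randomWindow = TRUE, seed = 99)
    rnd2 <- degradeReferences(g, 0.25, randomWindow = TRUE, seed = 99)
    expect_identical(as.character(rnd1), as.character(rnd2))
    full_model <- build_quiet(g, n = 21)
    half_model <- build_quiet(half, n = 21)
    expect_true(all(half_model@nT < full_model@nT))
})
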