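# strainsig

Strain-level identification and quantification of microbes in whole-genome
metagenomic sequencing data, using body-site-specific **n-gram signature
models**.

## The problem and the method

Generic metagenomic profilers match reads against databases spanning all
known microbes, which inflates the search space and the false-positive rate.
When the body site (or environment) of a sample is known, a model built from
only the genomes resident at that site is both smaller and more
discriminative — and it can be built from draft-quality assemblies, because
the method never aligns: it indexes every distinct n-gram (k-mer, default
n = 21) of the reference set.

For a model of `C` genomes, an n-gram contained in `m` of them carries the
weight

    S(m) = ( ln(C/m) / ln(C) )^2

so n-grams private to one genome score exactly 1, n-grams present everywhere
score exactly 0, and the squared logarithmic ratio decays fast in between:
discriminatory sequence dominates while common sequence still contributes.
This index — genome table plus n-gram-to-genome posting lists — is the **DNA
signature element model (DSEM)**.

A sample is profiled in three steps:

1. **Identification.** The reads are pooled into one deduplicated n-gram
   set. Each genome `g` accumulates `S_g`, the summed weights of the sample
   n-grams it contains, normalized by the matched fraction of its own
   content: `fS_g = S_g * n_c / n_t` (with `n_c` matched and `n_t` total
   distinct n-grams of the genome). Genomes with `fS` at or above a cutoff
   are called present.
2. **Cutoff calibration.** Scores of genomes under a positive (site) read
   set, sorted descending, are plotted rank-by-rank against scores under a
   negative (non-site) read set, sorted ascending; the cutoff sits at the
   first rank where the negative curve strictly exceeds the positive one
   (midpoint of the two values), or halfway between the curves when they
   separate completely.
3. **Quantification.** Each read is assigned to one predicted genome —
   preferring the genome with the most n-grams unique to it, falling back
   to the highest summed-weight read–genome score `R_jg` — and relative
   abundance is the assigned-read fraction.

A bundled simulator (synthetic genomes, even/staggered mock communities,
coverage subsampling, reference degradation) makes every stage testable
without downloading any reference data, and `confusionCounts()` /
`computeMetrics()` provide the standard sensitivity/specificity/F1
evaluation over the closed model universe.

## Worked example

Five synthetic 20-kb genomes, a model at n = 21, a 20x paired-end sample
containing three of them at 50/30/20%, and a cutoff calibrated against an
unrelated negative genome set:

```r
library(strainsig)

g     <- generateGenomes(5, 20000, seed = 42)
model <- buildDsem(g, n = 21)          # warns: fewer than 50 genomes
model
#> Dsem model: 5 genomes, n = 21, orientation = canonical
#>   distinct n-grams: 99900 (unique 99900, common 0)

comp <- data.frame(genome_id = c("g01", "g02", "g03"),
                   proportion = c(0.5, 0.3, 0.2))
sim  <- simulateReads(g, comp, coverage = 20, seed = 43)

alien <- generateGenomes(5, 20000, seed = 44, prefix = "x")
pos <- simulateReads(g,     data.frame(genome_id = names(g),     proportion = rep(0.2, 5)),
                     coverage = 0.5, seed = 45)
neg <- simulateReads(alien, data.frame(genome_id = names(alien), proportion = rep(0.2, 5)),
                     coverage = 0.5, seed = 46)
cal <- calibrateFromReads(model, pos$reads, names(g), neg$reads,
                          positiveMate2 = pos$mate2, negativeMate2 = neg$mate2)
cal
#> CutoffResult: cutoff = 880.8931 (curves separable)

pred <- identifyStrains(sim$reads, model, cutoffValue(cal), mate2 = sim$mate2)
as.data.frame(scoreTable(pred))
#>   genome_id   S_g   n_c   n_t   nFactor       fS predicted
#> 1       g02 19970 19970 19980 0.9994995 19960.01      TRUE
#> 2       g01 19962 19962 19980 0.9990991 19944.02      TRUE
#> 3       g03 19947 19947 19980 0.9983483 19914.05      TRUE
#> 4       g04     0     0 19980 0.0000000     0.00     FALSE
#> 5       g05     0     0 19980 0.0000000     0.00     FALSE

ab <- quantifyReads(sim$reads, model, pred, mate2 = sim$mate2)
as.data.frame(abundanceTable(ab))
#>   genome_id assigned_reads relative_abundance
#> 1       g01           4012            0.50150
#> 2       g02           2366            0.29575
#> 3       g03           1622            0.20275
```

The three community members are recovered with `fS` around 2 x 10^4 — five
orders of magnitude above the absent genomes — and the estimated abundances
sit within half a percentage point of the simulated proportions.
`evaluatePrediction()` on this run reports sensitivity, specificity and F1
of 1.

The same pipeline is available from a shell via `exec/strainsig`
(subcommands `build`, `survey`, `calibrate`, `identify`, `quantify`,
`simulate`, `subsample`, `evaluate`; see `exec/strainsig --help`).

## Vignette

`vignettes/signature-models.Rmd` documents the model, the calibration
procedure, the simulator's scope, and the numerical and design choices in
detail.
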