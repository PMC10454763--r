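---
title: "Site-specific n-gram signature models for strain-level metagenomics"
author: "strainsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific n-gram signature models for strain-level metagenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsig)
```

## The model

A **DNA signature element model (DSEM)** is an inverted index over the
distinct fixed-length n-grams (k-mers) of a set of reference genomes: for
every n-gram, the posting list of genomes containing it. The *document
frequency* `m` of an n-gram — how many of the `C` model genomes contain it
— determines its discriminatory weight

$$S(m) = \left(\frac{\ln(C/m)}{\ln C}\right)^2,$$

which is 1 for an n-gram private to a single genome, 0 for one present in
every genome, and decays faster than linearly in between. The squared form
is the unique member of this family satisfying all the constraints the
scheme is built around: range $[0,1]$, the two exact anchors, strict
monotonicity in `m`, and rapid damping of widely shared sequence. Weights
are recomputed from `m` and `C` at query time rather than stored, which
keeps the model file minimal and isolates the algebra in one function
(`scoreNgram()`) should a variant ever be wanted.

The per-genome total `n_t` counts **distinct** n-grams (the index is a
set), not windows with multiplicity. This matches the identification step,
which also operates on distinct n-grams; window multiplicity would make
`n_t` depend on repeat content in a way the matched count `n_c` never can,
biasing the normalizer below.

### Identification

The sample's reads are deconstructed into one deduplicated n-gram set —
read depth deliberately does not enter here; it returns at quantification.
Conceptually a matrix $W$ is formed (sample n-grams as rows, genomes as
columns, cell = the n-gram's weight where the genome contains it) and
column sums are taken; the implementation accumulates the sums directly:

$$S_g = \sum_{i \,:\, g \ni n_i} S(m_i), \qquad
  fS_g = S_g \cdot \frac{n_c}{n_t}.$$

The factor $n_c/n_t$ (matched fraction of the genome's own content)
penalizes genomes matched only on a sliver of their sequence. Genomes with
$fS$ at or above the cutoff are called present. The comparison is
**inclusive** (`>=`) — some convention is needed for exact ties and the
inclusive one keeps "cutoff equal to a genome's score" a positive call.
Ranked output breaks ties by `genome_id` ascending so reports are
reproducible. Genome ordinals follow sorted `genome_id` order throughout,
which makes every downstream tie-break well defined without a second key.

### Cutoff calibration

Absolute $fS$ magnitudes depend on the model and on sample depth, so the
presence threshold is calibrated empirically per site: score the model's
genomes under a *positive* read set (drawn from genomes known to belong to
the site) and under a *negative* read set (genomes foreign to the site);
sort the positive scores descending and the negative scores ascending;
scan for the first rank where the negative curve **strictly** exceeds the
positive one. Choices fixed here, where the procedure itself leaves room:

* Curves of unequal length are truncated to the shorter length after
  sorting — the scan compares ranks, so ranks must align.
* The cutoff value at a crossing is the midpoint of the two curve values
  at that rank: symmetric, reproducible, and independent of any
  interpolation scheme.
* If the curves never cross and every negative score is below every
  positive score, the distributions are separable and the cutoff is the
  midpoint of the two extremes.
* If the negative curve dominates from the first rank, or the curves
  neither cross nor separate (e.g. flat identical distributions), no
  threshold is meaningful: a `calibrationFailure` error carries both
  curves for inspection.

The negative curve uses **all** model genomes' scores — these are exactly
the false-positive scores the cutoff exists to bound.

One practical point the procedure implies: the calibration sets fix the
scale of the cutoff relative to sample depth, so positives should be
simulated near the *bottom* of the intended operating range. The bundled
end-to-end experiments calibrate at 0.5x coverage and then operate from 1x
upwards; a cutoff calibrated at high coverage would sit above the scores
that genuinely present genomes reach in a shallow sample.

### Quantification

Each read (each mate independently — pair-level assignment is deliberately
not attempted) is assigned by a two-tier rule over the *predicted* genomes
only:

1. If the read contains n-grams unique to predicted genomes, assign to the
   genome with the most such unique n-grams. A tie falls through to rule 2
   restricted to the tied genomes (ties here arise mainly from sequencing
   errors creating spurious unique matches).
2. Otherwise maximize the read–genome score $R_{jg} = \sum_i S(m_i)$ over
   n-grams shared between read and genome; residual ties go to the
   smallest `genome_id` and are flagged per read.
3. A read sharing no n-gram with any predicted genome stays unassigned.

Relative abundance is the assigned-read fraction. No genome-length
normalization is applied by default: the mock-community designs the method
is validated against mix roughly equal-sized genomes by DNA quantity, and
read fraction is the quantity those truths are stated in.
`lengthNormalize = TRUE` divides counts by genome length before
renormalizing for settings where a cell-fraction-like estimate is wanted.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `n` | 21 bases | Signature length. Shorter n-grams collide across strains and lose discriminatory power; longer ones inflate the index with little gain in unique content. The survey tool (`ngramSizeSurvey()`, codon-stride ladder 12–27) lets a user re-derive the choice for their own genome set. |
| `orientation` | `"canonical"` | Strand handling. Canonical mode maps every n-gram (reference and reads) to the smaller of itself and its reverse complement, making matching strand-neutral — sequencing fragments come from both strands. `"forward"` mode indexes the reference as written and reverse-complements only mate-2 reads, reproducing a forward-strand-only construction; it is kept because whether a reference index should include both strands is a genuine design fork and the two modes differ in shared-n-gram statistics. |
| `cutoff` | calibrated | Presence threshold on $fS$; see above. Never hard-coded: it is a property of the model and the operating depth. |
| `readLength` | 150 bp | Matches common short-read instruments. |
| `substitutionRate` | 0 | Simulator error knob, capped at 0.2. |
| model size | warn < 50 | Models with few genomes build fine (tests rely on it) but a warning marks them: with few genomes almost everything is "unique" and the weighting carries little information. |

## What the simulator does and does not emulate

`generateGenomes()` draws i.i.d. uniform bases, so distinct genomes are
n-gram-disjoint in practice at n = 21 (a shared 21-gram between two 100-kb
random genomes has probability about $10^{-3}$); an implanted shared block
manufactures common n-grams when sharing is wanted. `simulateReads()`
draws each fragment's genome from the community proportions, position and
strand uniformly, and applies i.i.d. substitutions; `subsampleReads()`
thins to a coverage; `degradeReferences()` truncates genomes contiguously
to emulate incomplete drafts. `mockEven()` (12 genomes at 1/12) and
`mockStaggered()` (20 genomes, geometric ladder from 0.0002 to 0.18,
renormalized — only the endpoints of the real staggered product are
published, so the interior of the ladder is a package choice) reproduce
the standard mock-community designs.

Deliberately absent: position-dependent quality/error models, indels,
fragment-size distributions, GC bias, and real inter-genome homology.
Consequently, passing the bundled recovery tests shows the *algorithm*
(indexing, weighting, calibration, assignment) behaves as specified under
controlled conditions; it does not certify performance on real communities,
where shared biology (not implanted blocks) generates the common n-gram
structure and where error profiles are structured. The simulator's
substitution model is sufficient to exercise every code path that real
errors exercise: lost true n-grams and spurious novel ones.

## Numerical and engineering choices

* **Encoding.** n-grams are packed 2 bits per base (A=00, C=01, G=10,
  T=11, MSB first) — a uniform-depth prefix code over a 4-symbol alphabet;
  any uniform code is storage-equivalent, so the table is fixed for
  portability. Values cross the R boundary as doubles, which represent
  integers exactly up to $2^{53}$, giving a hard ceiling of n = 26
  wherever encoded values are exported ($4^{26} < 2^{53} < 4^{27}$).
  Count-only operations (the size survey) run entirely in 64-bit integer
  space and accept n up to 31.
* **Windows.** A sequence of length $x$ yields $\max(0, x-n+1)$ windows;
  any window containing a character outside A/C/G/T (N, IUPAC codes) is
  voided and counted, after uppercasing. Emitted + skipped always equals
  the window total.
* **Degenerate inputs.** Sequences shorter than n extract nothing;
  a genome whose `n_t` is 0 gets `nFactor` 0 rather than 0/0; an empty
  sample scores every genome 0; a fully unassignable read set reports
  zero abundances with a warning rather than dividing by zero; cutoff 0
  predicts *every* genome (inclusive comparison), which is the documented
  reason calibrated cutoffs are strictly positive.
* **Serialization.** The model file is a fixed little-endian binary layout
  (magic `DSEM`, version, genome table, delta-encoded posting lists)
  written atomically; round-trips are bit-exact, which the tests verify by
  comparing scores before and after. A custom layout was chosen over a
  generic container because bit-exactness and posting compactness are the
  only requirements.
* **Determinism.** All simulator functions take explicit seeds and restore
  the caller's RNG state; scoring and assignment are order-independent;
  CLI runs with identical flags and seed produce byte-identical outputs.

## Scale of the bundled experiments

The recovery experiments shipped with the package run at desk scale,
chosen as the smallest sizes at which the phenomena of interest are
cleanly measurable: 30 genomes of 100 kb (about 3 million distinct
21-grams), 120x paired coverage of a 12-member even community (480,000
fragments), subsamples down to 1x, 120,000 reads for abundance recovery,
and a 300,000-read staggered community. Real site models are three to four
orders of magnitude larger; construction is memory-proportional to the
distinct n-gram count, and external-memory construction is out of scope.

## Known limitations

* Abundance assignment is hard (one genome per read); no EM-style
  redistribution of ambiguous reads, no fractional assignment.
* The closed universe for specificity is the model's genome set — the
  method cannot name a negative it has never indexed.
* Identification consumes distinct n-grams only; extremely uneven
  communities are therefore identified by content, not depth, and a
  genome's presence call saturates once its content is covered.
* Models with n > 26 would require a different cross-boundary encoding;
  nothing in the method itself needs n that large.
* Quality scores are ignored on input and written as constants on output.
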