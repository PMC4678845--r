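---
title: "Simulating and analysing amplicon bisulfite sequencing with lesion-bypass polymerases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing amplicon bisulfite sequencing with lesion-bypass polymerases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamplicon)
```

## The problem

Bisulfite sequencing maps 5-methylcytosine (5mC) by chemistry: sodium
bisulfite deaminates unmethylated cytosine through a sulfonated
intermediate, 5,6-dihydrouridine-6-sulfonate (dhU6S), which alkaline
desulphonation decomposes to uracil; 5mC is protected and survives as C.
After PCR, a converted position reads as T, a protected one as C, so the
surviving Cs report methylation.

The catch is the polymerase. The dhU6S adduct is bulky, charged and
non-planar, and most polymerases stall at it; uracil-rich templates
(especially homopolymeric dU runs) also slow conventional Taq. Complete
desulphonation removes the adducts but requires heat and high pH that
degrade the sample. The practical trade-off — milder chemistry versus
amplifiable DNA — is what this package models: how a Taq-like enzyme, an
engineered lesion-bypass enzyme (called `P5D4` here), and blends of the two
behave on bisulfite-treated templates, and what the downstream sequencing
statistics look like.

`bsamplicon` contains two halves that meet at a FASTQ file:

* a **simulator**: bisulfite chemistry at single-molecule resolution,
  primer extension and PCR under parameterized polymerase profiles, and a
  read generator;
* an **analysis pipeline**: in-silico converted references,
  bisulfite-aware banded alignment, pileup, per-CpG methylation fractions,
  the non-CpG conversion statistic, and error rates with the C-to-T
  exclusion rules standard in this assay.

Because the simulator is generative and fully seeded, every analysis
statistic can be checked against the parameters that produced the data —
the package's test suite is built around exactly that loop.

## The chemistry model

A template molecule is a string over `ACGT` with a methylation probability
for every cytosine (`methylated_template`). Treatment
(`apply_bisulfite()`) maps it to a seven-letter state string
(`treated_strand`):

* each cytosine is assigned a methylation state by a Bernoulli draw on its
  per-position probability; methylated Cs stay `C`;
* each unmethylated C becomes `S` (dhU6S) with probability `p_conv`;
* each `S` resolves to `U` with probability `p_desulf`;
* any position becomes a blocking lesion `X` with probability `p_lesion`,
  and each backbone bond breaks with probability `p_frag`, splitting the
  molecule into fragments. A broken molecule can no longer template a
  full-length product.

All events are independent Bernoulli draws; no neighbour cooperativity is
modelled because none is established for this chemistry. Only the top
strand is modelled: bisulfite conversion makes the two strands
non-complementary and amplicon assays are strand-specific by design. The
two C6 diastereoisomers of dhU6S are collapsed into the single state `S`;
whether they template differently is unknown, so the model does not guess.

The condition presets encode the usual regimes by *relative harshness*,
not by measured efficiencies (none are published for these protocols):

| preset | p_conv | p_desulf | p_lesion | p_frag | reading |
|--------|-------:|---------:|---------:|-------:|---------|
| BS1    | 0.99 | 0.99  | 0.001 | 0.0002 | standard alkaline desulphonation |
| BS1T   | 0.99 | 0.999 | 0.002 | 0.0004 | + hot step: most complete, most damaging |
| BS2    | 0.99 | 0.50  | 0     | 0      | mild, unheated: half the adducts remain |
| BS3    | 0.99 | 0.95  | 0.001 | 0.0002 | high-pH variant, near complete |
| WATER  | 0.99 | 0     | 0     | 0      | no desulphonation at all |

Damage defaults are non-zero only for heated conditions. Every number is
overridable; the presets exist to give the qualitative ordering a stable,
documented anchor.

## The polymerase model

A `polymerase_profile` gives, for each non-canonical template state, the
probability that the enzyme reads through it on one encounter
(`bypass[U]`, `bypass[S]`, `bypass[X]`), a `homopolymer_penalty`
multiplying the bypass once per additional consecutive `U`/`S` beyond the
first, a per-cycle substitution rate, and a `time_boost` controlling how
extension time helps. The effective per-encounter bypass at extension time
$t$ minutes is

$$ b_\mathrm{eff}(t) = 1 - (1 - b\,\rho^{k-1})^{f(t)}, \qquad
   f(t) = 1 + \beta\,(\log(1+t) - \log(1.5)) $$

where $b$ is the nominal bypass, $\rho$ the homopolymer penalty, $k$ the
position within the run, and $f$ is normalized to 1 at the standard 30 s
extension step. Raising the time acts like giving the enzyme repeated
attempts (the failure probability shrinks as a power), which keeps the
quantity a probability without clamping and makes read-through strictly
monotone in time.

The presets are calibration conventions — the experiments this model is
built to mirror report gel bands and qPCR curves, not per-encounter rates:

* `TAQ`: bypass U 0.80, S 0.05, X 0; penalty 0.85; error 5e-5/cycle.
  Isolated uracil is tolerable, uracil runs stall, sulfonate adducts and
  lesions block.
* `P5D4`: bypass U 0.9995, S 0.92, X 0.30; penalty 0.9995; error
  3e-4/cycle. Uracil runs are copied at full speed even at short
  extension times, most adducts are bypassed, at the cost of a roughly
  five-fold higher error rate.

The values were fixed once so that the package's directional behaviours
hold simultaneously: a dU8 run is copied to ≥95% full length by `P5D4` in
30 s while Taq stalls visibly even at 15 min; a ~350 nt amplicon with
~100 sulfonate adducts is unamplifiable by Taq at any first-cycle
extension up to 10 min but amplifiable by blends; and an extended (5–10
min) first cycle rescues Taq on desulphonated but not on sulphonated
templates.

A `polymerase_blend` mixes profiles with weights; the acting enzyme is
drawn per molecule per copying event, the simplest model consistent with a
distributive polymerase re-binding between extension events.

## PCR, molecule counts and errors

`run_pcr()` treats the reaction as a branching process over molecule
*classes* rather than individual molecules. Original treated strands
persist and each cycle seed new clean copies with probability equal to
their full-length extension probability (the closed form
`full_length_prob()`, the product of effective bypasses over all
obstacles). Copies are clean DNA — `U` and bypassed `S` template as T — so
they double deterministically, and the bookkeeping tracks counts by
*generation*: the number of synthesis events in a molecule's ancestry.
Counts are drawn stochastically while they fit machine integers and
continued as expectations beyond that; the reported trajectory is capped
at a plateau (default 10^12) while totals continue analytically. The
threshold cycle Ct is computed qPCR-style against a fixed molecule count
(default 10^9) with log-linear interpolation, so exact doubling gives
`ct = log2(threshold / n0)` and ten-fold input dilutions are spaced by
log2(10) ≈ 3.32 cycles.

Nested and indexing PCRs (`continue_pcr()`) double every molecule per
cycle under the new enzyme's error rate; the treated originals are
considered diluted out of the later rounds.

Per-cycle substitution errors attach to generations, not to cycles of wall
time: a read sampled from a generation-$g$ molecule mutates each base with
probability $1 - (1-e_1)(1-\bar e)^{g-1} \prod_s (1-e_s)^{j_s}$, where
$e_1$ is the error rate of the enzyme that made the first copy off the
treated template, $\bar e$ the blend-average rate afterwards, and $j_s$
the synthesis events drawn per later round (Binomial($k_s$, 1/2) under
doubling — in a doubling reaction half of the final molecules are new each
cycle). Mutated bases are uniform over the three alternatives.

## Reads

`generate_reads()` emits fixed-length, 5'-anchored reads — the layout of
amplicon deep sequencing, where 117–120 bp from the amplicon 5' end is
typical — with a flat additional sequencing error and constant placeholder
qualities. For a `treated_pool` input (a large pool of independently
treated molecules of one template), each read draws a *fresh* conversion
and methylation pattern over its window. That is the exact behaviour of a
large input pool: with 10^6 input molecules and 10^4–10^5 reads, two reads
descending from the same treated molecule are rare, so per-read
independence is the correct limit, and it keeps methylation fractions
exactly binomial at any depth, which the recovery tests rely on.

Three simplifications are deliberate and worth knowing about:

* PCR errors are drawn independently per read; shared ancestry ("jackpot"
  mutations from an early-cycle error) is ignored. Expectations are
  unaffected; the variance of error rates across amplicons is
  underestimated.
* Molecules carrying residual `S` are slightly less likely to be
  amplified, which in reality biases sequenced molecules toward fewer
  adducts; the read generator ignores this selection. At the desulphonation
  levels of the presets the effect is far below the statistical resolution
  of the tests.
* No indels, no quality-score structure, no strand asymmetry: reads are
  top-strand and forward-oriented, as amplicon designs make them.

## The analysis side

`insilico_convert()` builds the alignment reference by replacing every C
with T while retaining the original sequence and CpG positions.
`align_bisulfite()` performs banded dynamic programming on three-letter
collapsed strings (C→T on both sides), so a converted read aligns without
penalty and a retained (methylated) C is equally a match — the asymmetric
C/T uncertainty never counts against a read. Scoring is +1/−2/−3
(match/mismatch/linear gap), global in the read and free at the reference
ends, ties broken toward the leftmost reference offset. Bands of
half-width 16 diagonals are placed over the best seed diagonals (seeds
scored by their best ungapped segment, Kadane-style, with up to four
non-overlapping bands examined); the suite verifies equality with an
exhaustive full-matrix DP on hundreds of random instances. Reads below 90%
collapsed identity are dropped and counted — the "high-quality read"
filter, whose exact published counterpart is unspecified, is made explicit
here.

`build_pileup()` accumulates original read bases per reference position;
calling then follows the assay's standard rules:

* **methylation** (`cpg_methylation()`): at each CpG cytosine, fraction =
  C/(C+T); A/G observations are noise, reported as `other` and excluded
  from the denominator (an explicit choice — folding sequencing errors
  into the fraction would conflate two error processes). Sites with fewer
  than 10 informative observations are flagged, not dropped.
* **conversion** (`conversion_rate()`): % of observations reading T among
  T+C at *non-CpG* original-C positions only. Non-CpG cytosines are
  assumed unmethylated, which is what makes the statistic a chemistry
  control rather than a biology measurement; CpG positions contribute
  nothing. Zero eligible observations give `NA`, never a silent 0.
* **error rates** (`error_rates()`): any T observed at an original-C
  position is indistinguishable from conversion, so C-to-T events are
  excluded from the calculation — removed from numerator *and*
  denominator. The per-nucleotide breakdown is computed only where the
  original base is G, A or T. The cumulative error divided by the total
  cycle count (default 20+30+20 = 70, a typical nested library) gives the
  per-cycle rate; the identity `per_cycle_rate × total_cycles =
  cumulative fraction` holds exactly before display rounding (percentages
  print to 1 decimal, rates to 2 significant figures).

```{r example}
ref <- insilico_convert("TACGTACCTACGTT")
m <- matrix(0, 14, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
m[3, "C"] <- 70; m[3, "T"] <- 30      # CpG 1: 70% methylated
m[11, "C"] <- 10; m[11, "T"] <- 90    # CpG 2: 10% methylated
m[8, "T"] <- 99; m[8, "C"] <- 1       # non-CpG C: 99% converted
p <- pileup_from_counts(ref, m)
cpg_methylation(p)$sites$fraction
conversion_rate(p)
```

## Reproducibility machinery

A single master seed expands into named substreams (`template`,
`treatment`, `pcr`, `reads`, `analysis`) via `substream_seed()`, so
changing, say, the read-sampling seed leaves the treatment output
byte-identical — a property the suite asserts on the written files.
`run_end_to_end()` executes treatment → PCR → reads → analysis, writes
every artifact (FASTA/TSV/FASTQ/JSON) plus a provenance record, and
produces byte-identical reports for identical configurations.

## Problem sizes and test design

The package's own verification uses, as its standard working point: one
amplicon of 120–350 nt, 10^6 input molecules summarized by 200
representative treated strands, 70 total cycles, 10^4 reads of 120 nt, and
sequencing error 10^-3. At that depth the binomial standard error of a
methylation fraction is ≈0.004 and of the conversion statistic ≈0.03
percentage points, comfortably resolving the recovery tolerances the
tests assert (3 standard errors). Monte Carlo checks of extension
probabilities use 10^3–10^4 molecules per condition. These sizes were
chosen so the complete suite exercises every statistical claim in well
under a minute of simulation per test file.

What a green suite shows — and what it does not: the pipeline recovers the
parameters of its own generative model at the stated depths, its exclusion
rules are exactly right on crafted inputs, and its aligner is exact
against brute force on realistic instances. It does not certify behaviour
on real libraries, whose primer artefacts, coverage decay along the
amplicon, context-dependent chemistry failures and quality-dependent
miscalls the generator deliberately does not emulate.

## Known limitations

* Bypass probabilities, the homopolymer penalty and the time-boost form
  are conventions fitted to qualitative orderings; absolute Ct values and
  band intensities are not comparable to any specific instrument.
* The single `S` state hides possible diastereoisomer differences.
* No mispriming or primer thermodynamics on the reduced three-letter
  alphabet; primer sites are assumed to work.
* Reverse-complement alignment exists behind a flag but the simulator
  never produces bottom-strand reads.
* CHH/CHG context taxonomy is out of scope; contexts are only "CpG" and
  "non-CpG C".
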