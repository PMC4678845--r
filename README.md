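# bsamplicon

Simulation and analysis of targeted (amplicon) bisulfite sequencing, with
the polymerase as a first-class citizen.

## Why

Bisulfite sequencing reads 5-methylcytosine by chemistry: unmethylated
cytosine is deaminated via the sulfonated intermediate
5,6-dihydrouridine-6-sulfonate (dhU6S) and resolved to uracil by alkaline
desulphonation, while 5mC survives as C. The weak link is amplification:
dhU6S blocks conventional polymerases, uracil runs stall Taq, and the
harsh desulphonation needed to remove the adducts degrades the sample.
Engineered lesion-bypass polymerases change that trade-off — they copy
past uracil runs and most sulfonate adducts, making milder chemistry
amplifiable at the cost of a higher per-cycle error rate.

`bsamplicon` is for people who work on (or teach) this assay and want a
fully seeded, parameterized sandbox for it:

* **chemistry**: per-molecule bisulfite treatment over the states
  `{C, U, S (dhU6S), X (lesion)}` with condition presets (standard, hot,
  mild, high-pH, water-only) ordered by harshness;
* **polymerases**: per-encounter bypass probabilities, homopolymer
  stalling, extension-time effects and per-cycle misincorporation, with a
  Taq-like preset, an engineered lesion-bypass preset (`P5D4`), and blends
  (10/1, 5/1, 1/1);
* **PCR/qPCR**: generation-tracked branching process with fractional Ct,
  plateau cap, extended-first-cycle rescue, nested re-amplification;
* **reads**: fixed-length 5'-anchored FASTQ with flat sequencing error;
* **analysis**: in-silico converted references, bisulfite-aware banded
  alignment (C→T collapsed scoring, original bases kept for calling),
  pileup, per-CpG methylation fractions, the non-CpG conversion
  statistic, and error rates with C-to-T events excluded, reported
  cumulatively and per PCR cycle.

The statistic definitions follow the conventions of amplicon bisulfite
analyses: conversion efficiency is computed over non-CpG cytosines only,
C-to-T observations never count as sequencing errors, and per-nucleotide
error breakdowns are restricted to original G/A/T positions.

## The core quantities

For a pileup over an amplicon whose untreated sequence is known:

* per-CpG methylation: `fraction = C / (C + T)` at each CpG cytosine
  (A/G observations are "other" and excluded);
* conversion: `100 × T / (T + C)` summed over **non-CpG** original-C
  positions;
* error: `100 × mismatches / observations` with every T-at-original-C
  observation removed from both numerator and denominator;
  `per_cycle_rate = (error/100) / total_cycles` (default 20+30+20 = 70
  cycles for a nested library).

On the simulation side, a polymerase passes each template obstacle with
effective probability `1 − (1 − b·ρ^(k−1))^f(t)` — nominal bypass `b`,
homopolymer penalty `ρ` within a run, time factor `f(t)` normalized to the
standard 30 s extension — and a molecule's full-length probability is the
product over its obstacles. See the methods vignette
(`vignettes/bsamplicon-methods.Rmd`) for the model in full.

## Worked example

Simulate a 350 bp amplicon carrying 10 CpG sites methylated at 0.8,
treat it at conversion probability 0.995 with complete desulphonation,
amplify 10^6 molecules through a nested 70-cycle library (first round with
a 5/1 Taq/5D4 blend), sequence 10^4 reads of 120 nt, and analyse:

```r
library(bsamplicon)
tpl  <- make_benchmark_template("custom", length = 350, n_c = 90,
                                n_cpg = 10, cpg_meth = 0.8, seed = 1,
                                name = "amplicon1")
cond <- treatment_condition("CUSTOM", p_conv = 0.995, p_desulf = 1)
pool <- treated_pool(tpl, cond, n0 = 1e6, seed = 1)
run  <- run_pcr(pool, taq_5d4_blend("5/1"), cycles = 20, seed = 1)
run  <- continue_pcr(run, polymerase_profile("TAQ"), 30)
run  <- continue_pcr(run, polymerase_profile("TAQ"), 20)
reads <- generate_reads(run, 10000, read_len = 120, seq_error = 0.001,
                        seed = 1)
an <- analyze_reads(reads, insilico_convert(tpl), total_cycles = 70)
an$errors
#> error_report for 'amplicon1' (70 cycles):
#>   conversion: 99.4%
#>   overall error (C-to-T excluded): 0.4%  (5.9e-05 /cycle)
#>   per-base error: A 0.3%  G 0.3%  T 0.3%
head(an$methylation$sites[, c("cpg_index", "pos0", "fraction")], 3)
#>   cpg_index pos0  fraction
#> 1         1   12 0.7969518
#> 2         2  100 0.8040493
#> 3         3  103 0.7949309
```

Reading it: the chemistry was simulated at 99.5% conversion and the
pipeline recovers 99.4% (the residual gap is PCR error restoring a few
T→C); the cumulative substitution error over 70 cycles is 0.4%, i.e.
5.9×10⁻⁵ per cycle; and each CpG fraction lands within binomial noise of
the simulated 0.8. Reads in this example cover the first 120 nt, so CpGs
beyond the read window are flagged `low_depth` rather than reported.

A thin command-line wrapper over the same functions ships at
`inst/cli/bsamplicon.R` with subcommands `simulate-treatment`,
`simulate-pcr`, `simulate-reads`, `analyze`, `run-all` and `dump-config`.

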